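test_that("assembly curves agree with the regularized incomplete gamma oracle", {
  # the four polynomial-exponential forms are analytically the Erlang CDF
  # times c_max; pgamma is the independent route
  t <- 0:300
  for (n in 1:4) {
    for (k in c(0.01, 0.1, 1)) {
      expect_lt(
        max(abs(assembly_curve(t, n, k, 0.9) - 0.9 * pgamma(k * t, n, 1))),
        1e-9
      )
    }
  }
})

test_that("assembly curve closed-form values and limits", {
  for (n in 1:4) expect_equal(assembly_curve(0, n, 0.3, 0.8), 0)
  expect_equal(assembly_curve(log(2), 1, 1, 1), 0.5, tolerance = 1e-12)
  # P(2, 2) = 1 - 3 exp(-2)
  expect_equal(assembly_curve(2, 2, 1, 1), 1 - 3 * exp(-2), tolerance = 1e-12)
  expect_equal(assembly_curve(1000, 4, 0.1, 0.5), 0.5, tolerance = 1e-9)
  # numerically stable at extreme kt
  expect_equal(assembly_curve(1e3, 1, 1e3, 1), 1)
  expect_error(assembly_curve(1, 5, 1, 1))
})

test_that("curves are monotone in t and lag-ordered in step count", {
  tg <- seq(0, 300, by = 1)
  for (n in 1:4) {
    f <- assembly_curve(tg, n, 0.05, 0.9)
    expect_true(all(diff(f) >= 0))
    expect_equal(f[1], 0)
  }
  # more steps at fixed k => longer lag: f_{n+1}(t) < f_n(t) for t > 0
  for (n in 1:3) {
    f_lo <- assembly_curve(tg[-1], n, 0.05, 0.9)
    f_hi <- assembly_curve(tg[-1], n + 1, 0.05, 0.9)
    expect_true(all(f_hi < f_lo))
  }
})

test_that("threshold crossing matches closed forms and is monotone in k and n", {
  tt <- time_to_threshold(list(n_steps = 1, k = 0.1, c_max = 0.6))
  expect_false(tt$censored)
  expect_equal(tt$time_min, -log(1 - 0.5) / 0.1, tolerance = 1e-6)

  # independent bisection oracle on 1 - (1 + x) e^-x = 0.5
  x50 <- uniroot(function(x) 1 - (1 + x) * exp(-x) - 0.5, c(0, 10),
                 tol = 1e-12)$root
  tt2 <- time_to_threshold(list(n_steps = 2, k = 1, c_max = 1),
                           threshold = 0.5)
  expect_equal(tt2$time_min, x50, tolerance = 1e-6)

  # crossing value equals the threshold
  expect_equal(assembly_curve(tt$time_min, 1, 0.1, 0.6), 0.30,
               tolerance = 1e-6)

  # strictly decreasing in k, strictly increasing in n
  t_by_k <- vapply(c(0.05, 0.1, 0.2, 0.4), function(k) {
    time_to_threshold(list(n_steps = 2, k = k, c_max = 0.8))$time_min
  }, numeric(1))
  expect_true(all(diff(t_by_k) < 0))
  t_by_n <- vapply(1:4, function(n) {
    time_to_threshold(list(n_steps = n, k = 0.1, c_max = 0.8))$time_min
  }, numeric(1))
  expect_true(all(diff(t_by_n) > 0))
})

test_that("censoring convention: unreachable thresholds report > t_max", {
  tt <- time_to_threshold(list(n_steps = 1, k = 0.1, c_max = 0.25))
  expect_true(tt$censored)
  expect_equal(tt$time_min, 180)
  expect_equal(format(tt), "> 180 min")
  expect_error(time_to_threshold(list(n_steps = 1, k = 0.1, c_max = 0.5),
                                 threshold = 1.2))
})

test_that("fitting exact curve samples recovers the generating parameters", {
  ser <- exact_series(2, 0.05, 0.6)
  fit <- fit_fixed_steps(ser, 2)
  expect_lt(abs(fit$k - 0.05) / 0.05, 1e-6)
  expect_lt(abs(fit$c_max - 0.6) / 0.6, 1e-6)
  expect_lt(fit$chi2, 1e-12)
  expect_true(fit$converged)
})

test_that("model selection picks the generating step count on exact data", {
  for (n_true in c(1, 3)) {
    ser <- exact_series(n_true, calibrate_k(n_true, 0.7, 40), 0.7)
    sel <- select_model(ser)
    expect_equal(sel$n_steps, n_true)
    expect_lt(sel$chi2, 1e-12)
    # rejected models fit strictly worse
    other <- sel$candidates$chi2[sel$candidates$n_steps != n_true]
    expect_true(all(other > 1e-6))
    # selected chi2 is the minimum of all four
    expect_true(all(sel$chi2 <= sel$candidates$chi2))
  }
})

test_that("all-zero series yields a non-informative censored fit", {
  ser <- as_assembly_series(data.frame(
    time_min = rep(c(0, 5, 10, 30, 60), 3),
    replicate = rep(1:3, each = 5),
    n_dna = 3000, n_colocalized = 0
  ))
  fit <- fit_fixed_steps(ser, 1)
  expect_false(fit$informative)
  expect_lte(fit$c_max, 1e-6)
  expect_true(fit$t30$censored)
})

test_that("binomial-noise series recover c_max within tolerance", {
  # Ndc10-like truth over several simulation seeds
  errs <- vapply(1:20, function(s) {
    cfg <- sim_config(n_dna_per_field = 200, n_fields_per_timepoint = 15,
                      kinetic_truth = list(n_steps = 1, k = 0.1057,
                                           c_max = 0.87),
                      seed = s)
    fit <- fit_fixed_steps(simulate_series(cfg)$series, 1)
    abs(fit$c_max - 0.87)
  }, numeric(1))
  expect_lte(median(errs), 0.02)
})

test_that("bootstrap uncertainties are deterministic and tight on clean data", {
  cfg <- sim_config(n_dna_per_field = 200, n_fields_per_timepoint = 15,
                    kinetic_truth = list(n_steps = 2, k = 0.031, c_max = 0.47),
                    seed = 5)
  ser <- simulate_series(cfg)$series
  fit <- fit_fixed_steps(ser, 2)
  f1 <- estimate_uncertainties(ser, fit, n_boot = 60, seed = 11)
  f2 <- estimate_uncertainties(ser, fit, n_boot = 60, seed = 11)
  expect_identical(f1$se_cmax, f2$se_cmax)
  expect_identical(f1$se_t30, f2$se_t30)
  # Mif2-like design (N = 3000 x 3 reps): SEs on the order of the printed
  # +/- 1% (c_max) and +/- 4 min (T30) uncertainties
  expect_lt(f1$se_cmax, 0.05)
  expect_gt(f1$se_cmax, 0.001)
  expect_lt(f1$se_t30, 15)
  expect_gt(f1$se_t30, 0.3)
})

test_that("mostly-censored bootstrap withholds se_t30 with a warning", {
  # plateau barely above the threshold and a crossing just inside the
  # observation window, with a small DNA count: the point fit is
  # uncensored but binomial bootstrap replicates censor more often than not
  ser <- exact_series(1, 0.022, 0.306, n_dna = 60)
  fit <- fit_fixed_steps(ser, 1)
  expect_false(fit$t30$censored)
  expect_warning(
    out <- estimate_uncertainties(ser, fit, n_boot = 40, seed = 3),
    "censored"
  )
  expect_true(is.na(out$se_t30))
  expect_gt(out$n_boot_censored, 20)
})

test_that("compare_curves orders by T30 with censored fits last", {
  early <- fit_fixed_steps(exact_series(1, calibrate_k(1, 0.87, 4), 0.87), 1)
  late <- fit_fixed_steps(exact_series(2, calibrate_k(2, 0.47, 70), 0.47), 2)
  censored <- fit_fixed_steps(exact_series(1, 0.05, 0.22), 1)
  cmp <- compare_curves(list(Ndc10 = early, Mif2 = late, Wip1 = censored))
  expect_equal(cmp$table$label, c("Ndc10", "Mif2", "Wip1"))
  expect_true(cmp$table$t30_censored[3])
  expect_match(cmp$table$t30_label[3], "^> ")
  # pairwise difference between the uncensored pair
  expect_equal(nrow(cmp$deltas), 1)
  expect_equal(cmp$deltas$delta_t30, late$t30$time_min - early$t30$time_min)
  # identical fits order stably by label
  cmp2 <- compare_curves(list(b = early, a = early))
  expect_equal(cmp2$table$label, c("a", "b"))
})

test_that("tidy and glance expose fit results in broom layout", {
  fit <- fit_fixed_steps(exact_series(1, 0.1057, 0.87), 1)
  td <- tidy(fit)
  expect_equal(td$term, c("k", "c_max", "t30"))
  expect_equal(td$estimate[2], 0.87, tolerance = 1e-6)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_false(gl$t30_censored)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})
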