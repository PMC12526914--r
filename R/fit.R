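# Chi-squared fitting of multi-step irreversible assembly curves.
#
# The objective is chi2 = sum_t ((y_t - f(t; n, k, c_max)) / sigma_t)^2
# over per-timepoint mean fractions, with sigma_t the replicate SD floored
# at the pooled binomial SE (see summarise_series). Exactly two parameters
# are free: k and c_max. Because f is linear in c_max, c_max is profiled
# in closed form (weighted least squares, clamped to (0, 1]) and the search
# reduces to one dimension in log k, started from a deterministic grid.

.profile_cmax <- function(y, g, w, lower = 1e-6) {
  denom <- sum(w * g * g)
  if (denom <= 0) return(lower)
  min(max(sum(w * y * g) / denom, lower), 1)
}

.chi2_at <- function(log_k, n_steps, y, t, w) {
  # keep k finite when the line search overshoots
  k <- exp(min(max(log_k, log(1e-10)), log(1e8)))
  g <- assembly_curve(t, n_steps, k, 1)
  c_max <- .profile_cmax(y, g, w)
  sum(w * (y - c_max * g)^2)
}

#' Fit an assembly series with a fixed number of irreversible steps
#'
#' Minimizes the chi-squared deviation between the per-timepoint mean
#' colocalization fractions and the `n_steps`-step assembly curve, with
#' the rate constant `k` optimized on a log scale from a deterministic
#' multi-start grid (16 starts log-spaced over 1e-4 to 1 per minute) and
#' the plateau `c_max` constrained to (0, 1]. The model passes through
#' f(0) = 0 by its functional form, so t = 0 observations are included
#' in the fit without any extra constraint.
#'
#' @param series an assembly series (see [as_assembly_series()])
#' @param n_steps number of irreversible transitions to fit (1..4)
#' @param threshold threshold fraction used for the crossing-time
#'   statistic (default 0.30, i.e. T30)
#' @param t_max last observed timepoint for censoring; defaults to the
#'   largest timepoint in `series`
#' @param sigma_floor lower bound on per-timepoint sigma
#' @param n_starts number of log-spaced k starts (default 16)
#' @param k_range range of the start grid in per-minute units
#' @return an object of class `kinetic_fit`: a list carrying `n_steps`,
#'   `k`, `c_max`, `chi2`, `t30` (a [time_to_threshold()] result),
#'   `threshold`, `t_max`, `converged`, `informative`, the per-timepoint
#'   `data` used, and the original `series`
#' @export
fit_fixed_steps <- function(series, n_steps, threshold = 0.30, t_max = NULL,
                            sigma_floor = 1e-3, n_starts = 16,
                            k_range = c(1e-4, 1)) {
  stopifnot(length(n_steps) == 1, n_steps %in% 1:4)
  series <- as_assembly_series(series)
  summ <- summarise_series(series, sigma_floor = sigma_floor)
  if (nrow(summ) < 3) stop("need at least 3 timepoints with data to fit")
  if (is.null(t_max)) t_max <- max(summ$time_min)

  t <- summ$time_min
  y <- summ$mean_fraction
  w <- 1 / summ$sigma^2
  informative <- any(y > 0)

  starts <- log(exp(seq(log(k_range[1]), log(k_range[2]), length.out = n_starts)))
  local_opts <- lapply(starts, function(s) {
    stats::optim(s, .chi2_at, method = "BFGS",
                 n_steps = n_steps, y = y, t = t, w = w,
                 control = list(reltol = 1e-12, maxit = 500))
  })
  vals <- vapply(local_opts, `[[`, numeric(1), "value")
  best <- local_opts[[which.min(vals)]]

  # joint polish over (log k, c_max)
  k0 <- exp(best$par)
  g0 <- assembly_curve(t, n_steps, k0, 1)
  c0 <- .profile_cmax(y, g0, w)
  polish <- stats::optim(
    c(best$par, c0),
    function(p) {
      f <- assembly_curve(t, n_steps, exp(p[1]), 1)
      sum(w * (y - p[2] * f)^2)
    },
    method = "L-BFGS-B",
    lower = c(log(1e-8), 1e-6), upper = c(log(1e4), 1),
    control = list(factr = 10, pgtol = 1e-14, maxit = 1000)
  )
  converged <- polish$convergence == 0 || best$convergence == 0
  if (polish$value <= best$value) {
    k_hat <- exp(polish$par[1]); c_hat <- polish$par[2]; chi2 <- polish$value
  } else {
    k_hat <- k0; c_hat <- c0; chi2 <- best$value
  }
  if (!informative) {
    c_hat <- 1e-6
    chi2 <- sum(w * (y - assembly_curve(t, n_steps, k_hat, c_hat))^2)
  }

  fit <- structure(
    list(
      n_steps = as.integer(n_steps), k = k_hat, c_max = c_hat, chi2 = chi2,
      threshold = threshold, t_max = t_max,
      converged = converged, informative = informative,
      se_cmax = NA_real_, se_t30 = NA_real_,
      data = summ, series = series,
      protein = if ("protein" %in% names(series)) series$protein[1] else NA_character_,
      condition = if ("condition" %in% names(series)) series$condition[1] else NA_character_
    ),
    class = "kinetic_fit"
  )
  fit$t30 <- time_to_threshold(fit, threshold = threshold, t_max = t_max)
  fit
}

#' Select the best-fitting step count by minimum chi-squared
#'
#' Fits the series with all four assembly curves (one, two, three, and
#' four irreversible transitions) and returns the fit with the minimum
#' chi-squared deviation from the data. Chi-squared ties (difference
#' below 1e-9) are broken toward fewer steps (parsimony). All four
#' candidate fits are retained in the `candidates` element of the
#' returned fit.
#'
#' @inheritParams fit_fixed_steps
#' @param ... passed on to [fit_fixed_steps()]
#' @return a `kinetic_fit` (the selected model) whose `candidates`
#'   element is a tibble summarising all four fits and whose
#'   `candidate_fits` element holds the fit objects themselves
#' @export
select_model <- function(series, threshold = 0.30, t_max = NULL, ...) {
  fits <- lapply(1:4, function(n) {
    fit_fixed_steps(series, n, threshold = threshold, t_max = t_max, ...)
  })
  chi2 <- vapply(fits, `[[`, numeric(1), "chi2")
  # minimum chi2 with ties (< 1e-9) broken toward fewer steps
  best_idx <- which(chi2 <= min(chi2) + 1e-9)[1]
  if (!fits[[best_idx]]$converged) {
    warning("selected fit did not converge cleanly; inspect candidates")
  }
  out <- fits[[best_idx]]
  out$candidates <- tibble::tibble(
    n_steps = vapply(fits, `[[`, integer(1), "n_steps"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    c_max = vapply(fits, `[[`, numeric(1), "c_max"),
    chi2 = chi2,
    t30 = vapply(fits, function(f) f$t30$time_min, numeric(1)),
    t30_censored = vapply(fits, function(f) f$t30$censored, logical(1)),
    selected = seq_along(fits) == best_idx
  )
  out$candidate_fits <- fits
  out
}

#' Bootstrap uncertainties for c_max and T30
#'
#' Parametric bootstrap around the fitted curve: for every replicate and
#' timepoint, colocalization counts are resampled as
#' Binomial(n_dna, f_hat(t)) and the model refit with the selected step
#' count. The reported standard errors are the SDs of c_max and T30 over
#' bootstrap replicates; bootstrap replicates whose T30 is censored are
#' excluded from the T30 SD (their count is reported), and if more than
#' half are censored `se_t30` is returned absent with a warning. The
#' uncertainty procedure is a convention of this package, not a
#' reproduction of any published method.
#'
#' @param series the observed assembly series
#' @param fit the selected `kinetic_fit`
#' @param n_boot number of bootstrap replicates (default 200)
#' @param seed integer seed; results are deterministic given the seed
#' @return the fit with `se_cmax`, `se_t30`, and a `bootstrap` element
#'   (tibble of per-replicate c_max and t30) filled in
#' @export
estimate_uncertainties <- function(series, fit, n_boot = 200, seed = 1) {
  series <- as_assembly_series(series)
  if (!fit$converged) stop("cannot bootstrap a non-converged fit")
  f_hat <- assembly_curve(series$time_min, fit$n_steps, fit$k, fit$c_max)
  draws <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      stats::rbinom(nrow(series), size = series$n_dna, prob = f_hat)
    })
  })
  boot <- purrr::map_dfr(draws, function(counts) {
    sim <- series
    sim$n_colocalized <- counts
    sim$fraction <- NULL
    bf <- fit_fixed_steps(sim, fit$n_steps, threshold = fit$threshold,
                          t_max = fit$t_max)
    tibble::tibble(c_max = bf$c_max, t30 = bf$t30$time_min,
                   censored = bf$t30$censored)
  })
  fit$se_cmax <- stats::sd(boot$c_max)
  n_cens <- sum(boot$censored)
  if (n_cens > n_boot / 2) {
    warning(n_cens, "/", n_boot,
            " bootstrap replicates censored; se_t30 not reported")
    fit$se_t30 <- NA_real_
  } else {
    fit$se_t30 <- stats::sd(boot$t30[!boot$censored])
  }
  fit$bootstrap <- boot
  fit$n_boot_censored <- n_cens
  fit
}

#' Order fitted proteins by assembly timing
#'
#' Sorts fits by T30 (censored values last, ordered among themselves by
#' descending c_max; remaining ties by label) and tabulates the fitted
#' parameters. Pairwise T30 differences between uncensored fits carry a
#' propagated SE, sqrt(se1^2 + se2^2), when bootstrap SEs are available.
#'
#' @param fits a named list of `kinetic_fit` objects, or a list with
#'   `label` fields; names take precedence
#' @return a list with `table` (one row per fit, in assembly order) and
#'   `deltas` (pairwise T30 differences between uncensored fits)
#' @export
compare_curves <- function(fits) {
  if (length(fits) < 2) stop("need at least two fits to compare")
  labels <- names(fits)
  if (is.null(labels)) {
    labels <- vapply(seq_along(fits), function(i) {
      p <- fits[[i]]$protein
      if (is.na(p)) paste0("fit", i) else p
    }, character(1))
  }
  tab <- purrr::map2_dfr(fits, labels, function(f, lab) {
    tibble::tibble(
      label = lab, n_steps = f$n_steps, k = f$k,
      c_max = f$c_max, se_cmax = f$se_cmax,
      t30 = f$t30$time_min, t30_censored = f$t30$censored,
      se_t30 = f$se_t30, chi2 = f$chi2,
      t30_label = format(f$t30)
    )
  })
  tab <- dplyr::arrange(
    tab, .data$t30_censored,
    ifelse(tab$t30_censored, -tab$c_max, tab$t30),
    .data$label
  )
  unc <- dplyr::filter(tab, !.data$t30_censored)
  deltas <- if (nrow(unc) >= 2) {
    pairs <- utils::combn(nrow(unc), 2)
    tibble::tibble(
      label_1 = unc$label[pairs[1, ]],
      label_2 = unc$label[pairs[2, ]],
      delta_t30 = unc$t30[pairs[2, ]] - unc$t30[pairs[1, ]],
      se_delta = sqrt(unc$se_t30[pairs[1, ]]^2 + unc$se_t30[pairs[2, ]]^2)
    )
  } else {
    tibble::tibble(label_1 = character(), label_2 = character(),
                   delta_t30 = numeric(), se_delta = numeric())
  }
  list(table = tab, deltas = deltas)
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Kinetic fit:", x$n_steps, "irreversible step(s)\n")
  cat(sprintf("  k     = %.4g /min\n", x$k))
  cat(sprintf("  c_max = %.4g%s\n", x$c_max,
              if (!is.na(x$se_cmax)) sprintf(" (se %.2g)", x$se_cmax) else ""))
  cat(sprintf("  chi2  = %.4g\n", x$chi2))
  cat("  T", round(100 * x$threshold), "   = ", format(x$t30),
      if (!is.na(x$se_t30)) sprintf(" (se %.2g)", x$se_t30) else "",
      "\n", sep = "")
  invisible(x)
}
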