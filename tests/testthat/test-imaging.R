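test_that("detection returns no spots on pure background", {
  expect_equal(nrow(detect_spots(matrix(100, 128, 128), 1.3, 5)), 0)
  set.seed(1)
  noise <- matrix(rnorm(128 * 128, 100, 10), 128, 128)
  expect_lte(nrow(detect_spots(noise, 1.3, 5)), 1)
  expect_error(detect_spots(matrix(c(NA, rep(1, 128 * 128 - 1)), 128, 128),
                            1.3, 5), "non-finite")
})

test_that("a single spot is found with subpixel accuracy", {
  pos <- tibble::tibble(x_px = 100.3, y_px = 200.7)
  set.seed(7)
  img <- kinasm:::render_field(pos, 100, 512, 1.3, 100, 10)  # SNR 10
  spots <- detect_spots(img, 1.3, 5)
  expect_equal(nrow(spots), 1)
  expect_lt(abs(spots$x_px - 100.3), 0.2)
  expect_lt(abs(spots$y_px - 200.7), 0.2)
  expect_gt(spots$peak_intensity, spots$background)
})

test_that("well-separated spots are resolved individually", {
  pos <- tibble::tibble(x_px = c(60, 60 + 8 * 1.3), y_px = c(60, 60))
  set.seed(8)
  img <- kinasm:::render_field(pos, 100, 128, 1.3, 100, 10)
  spots <- detect_spots(img, 1.3, 5)
  expect_equal(nrow(spots), 2)
})

test_that("detection meets precision and recall targets on dense fields", {
  # SNR 5, 300 spots per 512 px field
  scores <- lapply(1:3, function(s) {
    cfg <- sim_config(n_dna_per_field = 300, dna_snr = 5, seed = s,
                      kinetic_truth = list(n_steps = 1, k = 0.1, c_max = 0.5))
    fp <- simulate_field_pair(cfg, t = 30)
    detection_scores(fp$truth, detect_spots(fp$dna, 1.3, 5), 512, 1.3)
  })
  expect_gte(mean(vapply(scores, `[[`, numeric(1), "precision")), 0.95)
  expect_gte(mean(vapply(scores, `[[`, numeric(1), "recall")), 0.95)

  # centroid accuracy at SNR 10
  cent <- vapply(4:6, function(s) {
    cfg <- sim_config(n_dna_per_field = 300, dna_snr = 10, seed = s,
                      kinetic_truth = list(n_steps = 1, k = 0.1, c_max = 0.5))
    fp <- simulate_field_pair(cfg, t = 30)
    detection_scores(fp$truth, detect_spots(fp$dna, 1.3, 5), 512, 1.3)$rms
  }, numeric(1))
  expect_lte(sqrt(mean(cent^2)), 0.2)
})

test_that("greedy matching follows the stated geometry and tie rules", {
  ref <- tibble::tibble(x_px = 10, y_px = 10)
  qry <- tibble::tibble(x_px = 10.5, y_px = 10)
  m <- match_spots(ref, qry, 1.5)
  expect_equal(nrow(m), 1)
  expect_equal(m$distance_px, 0.5)

  expect_equal(nrow(match_spots(ref, tibble::tibble(x_px = 12, y_px = 10),
                                1.5)), 0)

  # two refs equidistant from one query: lower ref index wins
  ref2 <- tibble::tibble(x_px = c(9, 11), y_px = c(10, 10))
  m2 <- match_spots(ref2, tibble::tibble(x_px = 10, y_px = 10), 1.5)
  expect_equal(nrow(m2), 1)
  expect_equal(m2$ref_idx, 1L)

  # one-to-one: each spot matched at most once
  ref3 <- tibble::tibble(x_px = c(10, 10.6), y_px = c(10, 10))
  qry3 <- tibble::tibble(x_px = c(10.2, 10.9), y_px = c(10, 10))
  m3 <- match_spots(ref3, qry3, 1.5)
  expect_equal(nrow(m3), 2)
  expect_equal(anyDuplicated(m3$ref_idx), 0)
  expect_equal(anyDuplicated(m3$query_idx), 0)
  # sorted by distance
  expect_true(!is.unsorted(m3$distance_px))
})

test_that("matching is invariant to input order away from exact ties", {
  set.seed(20)
  ref <- tibble::tibble(x_px = runif(40, 0, 100), y_px = runif(40, 0, 100))
  qry <- tibble::tibble(x_px = runif(35, 0, 100), y_px = runif(35, 0, 100))
  m1 <- match_spots(ref, qry, 3)
  perm <- sample(nrow(ref))
  m2 <- match_spots(ref[perm, ], qry, 3)
  m2$ref_idx <- perm[m2$ref_idx]
  expect_equal(
    dplyr::arrange(m1, ref_idx)[c("ref_idx", "query_idx")],
    dplyr::arrange(m2, ref_idx)[c("ref_idx", "query_idx")]
  )
})

test_that("colocalization fraction handles edge cases and monotonicity", {
  set.seed(21)
  dna <- tibble::tibble(x_px = runif(100, 5, 95), y_px = runif(100, 5, 95))
  res <- colocalization_fraction(dna, dna, 1.5)
  expect_equal(res$fraction, 1.0)

  empty <- dna[0, ]
  expect_equal(colocalization_fraction(dna, empty, 1.5)$fraction, 0)
  expect_true(is.na(colocalization_fraction(empty, dna, 1.5)$fraction))

  # n_colocalized never decreases as the radius grows
  gfp <- tibble::tibble(x_px = runif(80, 5, 95), y_px = runif(80, 5, 95))
  n_by_r <- vapply(c(0.5, 1, 2, 4, 8), function(r) {
    colocalization_fraction(dna, gfp, r)$n_colocalized
  }, numeric(1))
  expect_true(all(diff(n_by_r) >= 0))

  # invariant under a global translation of both channels
  sh <- function(d, dx, dy) {
    d$x_px <- d$x_px + dx
    d$y_px <- d$y_px + dy
    d
  }
  a <- colocalization_fraction(dna, gfp, 2)
  b <- colocalization_fraction(sh(dna, 3.7, -2.1), sh(gfp, 3.7, -2.1), 2)
  expect_equal(a$n_colocalized, b$n_colocalized)
})

test_that("transposition estimates the chance-colocalization floor", {
  set.seed(22)
  # independent placement: chance estimate ~ raw fraction
  dna <- tibble::tibble(x_px = runif(200, 0, 511), y_px = runif(200, 0, 511))
  gfp <- tibble::tibble(x_px = runif(200, 0, 511), y_px = runif(200, 0, 511))
  raw <- colocalization_fraction(dna, gfp, 1.5)$fraction
  chance <- estimate_chance_colocalization(dna, gfp, 1.5, c(512, 512))
  expect_lt(abs(chance - raw), 0.02)

  # true colocalization: chance estimate collapses while raw stays 1
  gfp2 <- dna[dna$x_px + dna$y_px > 150, ]  # avoid the symmetric diagonal
  dna2 <- gfp2
  raw2 <- colocalization_fraction(dna2, gfp2, 1.5)$fraction
  chance2 <- estimate_chance_colocalization(dna2, gfp2, 1.5, c(512, 512))
  expect_equal(raw2, 1.0)
  expect_lt(chance2, 0.05)

  expect_equal(estimate_chance_colocalization(dna, dna[0, ], 1.5,
                                              c(512, 512)), 0)
})

test_that("scored field series track the ground-truth fractions", {
  # compact end-to-end check; the full-series version runs in acceptance
  cfg <- sim_config(n_dna_per_field = 250, n_fields_per_timepoint = 2,
                    n_replicates = 1, timepoints_min = c(0, 10, 60),
                    kinetic_truth = list(n_steps = 1, k = 0.1057,
                                         c_max = 0.87),
                    seed = 17)
  grid <- tidyr::expand_grid(replicate = 1L, time_min = cfg$timepoints_min,
                             field = 1:2)
  fields <- purrr::pmap_dfr(grid, function(replicate, time_min, field) {
    fp <- simulate_field_pair(cfg, time_min, replicate, field)
    tibble::tibble(time_min = time_min, replicate = replicate,
                   dna = list(fp$dna), gfp = list(fp$gfp),
                   truth = attr(fp$truth, "true_fraction"))
  })
  ser <- suppressWarnings(
    score_field_series(fields, psf_sigma_px = 1.3, radius_px = 1.5)
  )
  truth <- fields |>
    dplyr::group_by(time_min) |>
    dplyr::summarise(truth = mean(truth))
  merged <- dplyr::left_join(ser, truth, by = "time_min")
  expect_true(all(abs(merged$fraction - merged$truth) <= 0.03))
  # all-bound sanity: duplicated channels give fraction 1
  fp <- simulate_field_pair(cfg, 60)
  both <- tibble::tibble(time_min = 60, replicate = 1L,
                         dna = list(fp$dna), gfp = list(fp$dna))
  ser1 <- suppressWarnings(score_field_series(both))
  expect_equal(ser1$fraction, 1.0)
})

test_that("pooling warns below the minimum DNA count", {
  cfg <- sim_config(n_dna_per_field = 50, field_size_px = 256, seed = 33,
                    timepoints_min = c(0, 30))
  fp <- simulate_field_pair(cfg, 30)
  fields <- tibble::tibble(time_min = 30, replicate = 1L,
                           dna = list(fp$dna), gfp = list(fp$gfp))
  expect_warning(score_field_series(fields), "below 3000")
})
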