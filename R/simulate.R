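#' Configuration for the synthetic TIRFM assay
#'
#' Describes one simulated time-course colocalization experiment:
#' sparse surface-tethered DNA molecules imaged as diffraction-limited
#' spots in a 647 nm channel, with GFP occupancy in a 488 nm channel
#' drawn per DNA and per timepoint from a chosen multi-step kinetic
#' curve. Defaults follow the assay geometry and sampling design of the
#' time-series experiment the package analyses: 512 x 512 px fields at
#' 0.11 um/px, incubation times 0-180 min, three biological replicates,
#' and enough fields per timepoint that >= 3000 DNAs are pooled.
#'
#' @param n_dna_per_field DNA molecules per field (default 200, a sparse
#'   surface density at which spot overlap is rare)
#' @param n_fields_per_timepoint fields imaged per timepoint (default 16,
#'   so 3200 DNAs pool per timepoint)
#' @param field_size_px field edge length in pixels (default 512)
#' @param pixel_size_um pixel size in micrometres (default 0.11)
#' @param timepoints_min incubation times in minutes, strictly increasing
#' @param n_replicates biological replicates (default 3)
#' @param psf_sigma_px Gaussian PSF sigma in pixels (default 1.3)
#' @param dna_snr,gfp_snr peak spot amplitude over background noise SD
#' @param kinetic_truth list with `n_steps` (1..4), `k` (/min), `c_max`
#'   giving the generating occupancy curve
#' @param mutant_mode logical; `TRUE` emulates the assembly-blocking
#'   mutant CEN DNA (binding probability 0 at all times)
#' @param n_gfp_independent number of GFP spots per field placed
#'   independently of the DNA positions (default 0); used to probe the
#'   chance-colocalization floor of the assay
#' @param registration_offset_px constant (x, y) offset of the GFP
#'   channel relative to the DNA channel, in pixels
#' @param false_coloc_rate additive false-colocalization probability used
#'   by [simulate_series()] (default 0)
#' @param min_sep_px minimum pairwise spot separation within a channel;
#'   default 4 * psf_sigma_px
#' @param background,noise_sd camera background level and Gaussian read
#'   noise SD, in arbitrary counts
#' @param seed mandatory integer seed
#' @return a validated list of class `sim_config`
#' @export
sim_config <- function(n_dna_per_field = 200,
                       n_fields_per_timepoint = 16,
                       field_size_px = 512,
                       pixel_size_um = 0.11,
                       timepoints_min = c(0, 5, 10, 30, 60, 90, 120, 150, 180),
                       n_replicates = 3,
                       psf_sigma_px = 1.3,
                       dna_snr = 10,
                       gfp_snr = 8,
                       kinetic_truth = list(n_steps = 1, k = 0.1057, c_max = 0.87),
                       mutant_mode = FALSE,
                       n_gfp_independent = 0,
                       registration_offset_px = c(0, 0),
                       false_coloc_rate = 0,
                       min_sep_px = NULL,
                       background = 100,
                       noise_sd = 10,
                       seed = 1) {
  if (is.null(min_sep_px)) min_sep_px <- 4 * psf_sigma_px
  cfg <- list(
    n_dna_per_field = n_dna_per_field,
    n_fields_per_timepoint = n_fields_per_timepoint,
    field_size_px = field_size_px,
    pixel_size_um = pixel_size_um,
    timepoints_min = timepoints_min,
    n_replicates = n_replicates,
    psf_sigma_px = psf_sigma_px,
    dna_snr = dna_snr,
    gfp_snr = gfp_snr,
    kinetic_truth = kinetic_truth,
    mutant_mode = isTRUE(mutant_mode),
    n_gfp_independent = n_gfp_independent,
    registration_offset_px = registration_offset_px,
    false_coloc_rate = false_coloc_rate,
    min_sep_px = min_sep_px,
    background = background,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$field_size_px >= 64,
    cfg$pixel_size_um > 0,
    cfg$n_dna_per_field >= 1,
    cfg$n_fields_per_timepoint >= 1,
    cfg$n_replicates >= 1,
    cfg$psf_sigma_px > 0,
    cfg$dna_snr > 0, cfg$gfp_snr > 0,
    cfg$noise_sd > 0,
    cfg$n_gfp_independent >= 0,
    cfg$false_coloc_rate >= 0, cfg$false_coloc_rate <= 1,
    length(cfg$registration_offset_px) == 2,
    length(cfg$seed) == 1
  )
  tp <- cfg$timepoints_min
  if (any(tp < 0) || any(diff(tp) <= 0)) {
    stop("timepoints_min must be non-negative and strictly increasing")
  }
  kt <- cfg$kinetic_truth
  if (!all(c("n_steps", "k", "c_max") %in% names(kt)) ||
      !kt$n_steps %in% 1:4 || kt$k <= 0 || kt$c_max < 0 || kt$c_max > 1) {
    stop("kinetic_truth must give n_steps in 1..4, k > 0, c_max in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

# True binding probability at time t under a config.
truth_fraction <- function(config, t) {
  if (config$mutant_mode) return(rep(0, length(t)))
  kt <- config$kinetic_truth
  assembly_curve(t, kt$n_steps, kt$k, kt$c_max)
}

# Uniform positions over the field with a minimum pairwise separation
# (rejection sampling). Coordinates are subpixel, x = column and
# y = row, origin at the centre of the top-left pixel.
sample_positions <- function(n, field_size_px, min_sep, max_tries = 200 * n,
                             existing = NULL) {
  xs <- numeric(n); ys <- numeric(n)
  ex_x <- if (is.null(existing)) numeric(0) else existing$x_px
  ex_y <- if (is.null(existing)) numeric(0) else existing$y_px
  placed <- 0L; tries <- 0L
  lim <- field_size_px - 1
  min_sep2 <- min_sep^2
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not place ", n, " spots with min separation ", min_sep,
           " px in a ", field_size_px, " px field (density limit reached)")
    }
    x <- stats::runif(1, 0, lim); y <- stats::runif(1, 0, lim)
    others_x <- c(ex_x, xs[seq_len(placed)])
    others_y <- c(ex_y, ys[seq_len(placed)])
    if (length(others_x)) {
      d2 <- (others_x - x)^2 + (others_y - y)^2
      if (min(d2) < min_sep2) next
    }
    placed <- placed + 1L
    xs[placed] <- x; ys[placed] <- y
  }
  tibble::tibble(x_px = xs, y_px = ys)
}

# Render a field as a sum of symmetric 2D Gaussian spots on a constant
# background plus Gaussian read noise. Spots near the edge are clipped
# by the field boundary, as in a real camera frame.
render_field <- function(positions, amplitude, field_size_px, psf_sigma_px,
                         background, noise_sd) {
  img <- matrix(background, nrow = field_size_px, ncol = field_size_px)
  if (nrow(positions) > 0) {
    half <- ceiling(5 * psf_sigma_px)
    s2 <- 2 * psf_sigma_px^2
    for (i in seq_len(nrow(positions))) {
      x <- positions$x_px[i]; y <- positions$y_px[i]
      cols <- max(0, floor(x) - half):min(field_size_px - 1, ceiling(x) + half)
      rows <- max(0, floor(y) - half):min(field_size_px - 1, ceiling(y) + half)
      dx2 <- (cols - x)^2
      dy2 <- (rows - y)^2
      patch <- amplitude * exp(-outer(dy2, dx2, `+`) / s2)
      img[rows + 1, cols + 1] <- img[rows + 1, cols + 1] + patch
    }
  }
  img + matrix(stats::rnorm(field_size_px^2, 0, noise_sd),
               field_size_px, field_size_px)
}

#' Simulate one two-channel TIRFM field
#'
#' Draws DNA positions uniformly over the field with a minimum pairwise
#' separation, marks each DNA bound with the probability given by the
#' configured kinetic curve at time `t` (or 0 in mutant mode), and
#' renders both channels as Gaussian-PSF spots on a constant background
#' with Gaussian read noise. GFP spots appear only at bound DNAs, offset
#' by the configured channel registration error.
#'
#' @param config a [sim_config()]
#' @param t incubation time in minutes (must be one of
#'   `config$timepoints_min`)
#' @param replicate replicate index (used only to derive the seed)
#' @param field field index (used only to derive the seed)
#' @param seed integer seed; defaults to a seed derived deterministically
#'   from `config$seed`, `t`, `replicate`, and `field`
#' @return a list with `dna` and `gfp` (numeric matrices), and `truth`, a
#'   tibble of DNA positions with their bound state (`x_px`, `y_px`,
#'   `bound`) plus attributes `true_fraction` and `t`
#' @export
simulate_field_pair <- function(config, t, replicate = 1, field = 1,
                                seed = NULL) {
  config <- validate_sim_config(config)
  if (!t %in% config$timepoints_min) {
    stop("t = ", t, " is not one of the configured timepoints")
  }
  if (is.null(seed)) {
    seed <- derive_seed(config$seed, match(t, config$timepoints_min),
                        replicate, field)
  }
  p_bound <- truth_fraction(config, t)
  with_seed(seed, {
    pos <- sample_positions(config$n_dna_per_field, config$field_size_px,
                            config$min_sep_px)
    bound <- stats::runif(nrow(pos)) < p_bound
    dna_amp <- config$dna_snr * config$noise_sd
    gfp_amp <- config$gfp_snr * config$noise_sd
    dna_img <- render_field(pos, dna_amp, config$field_size_px,
                            config$psf_sigma_px, config$background,
                            config$noise_sd)
    gfp_pos <- pos[bound, , drop = FALSE]
    gfp_pos$x_px <- gfp_pos$x_px + config$registration_offset_px[1]
    gfp_pos$y_px <- gfp_pos$y_px + config$registration_offset_px[2]
    if (config$n_gfp_independent > 0) {
      indep <- sample_positions(config$n_gfp_independent,
                                config$field_size_px, config$min_sep_px,
                                existing = gfp_pos)
      gfp_pos <- dplyr::bind_rows(gfp_pos, indep)
    }
    gfp_img <- render_field(gfp_pos, gfp_amp, config$field_size_px,
                            config$psf_sigma_px, config$background,
                            config$noise_sd)
    truth <- pos
    truth$bound <- bound
    attr(truth, "true_fraction") <- mean(bound)
    attr(truth, "t") <- t
    list(dna = dna_img, gfp = gfp_img, truth = truth)
  })
}

#' Simulate a colocalization time series at the count level
#'
#' Spot-level shortcut that skips image rendering: for each replicate
#' and timepoint, the number of colocalized DNAs is drawn as
#' Binomial(N, f(t)) with N the pooled DNA count per timepoint
#' (`n_dna_per_field * n_fields_per_timepoint`) and f(t) the configured
#' kinetic curve (plus the optional additive false-colocalization rate).
#'
#' @param config a [sim_config()]
#' @param protein,condition optional labels carried into the series
#' @return a list with `series` (an `assembly_series` tibble) and
#'   `truth` (tibble of `time_min`, `replicate`, `true_fraction` — the
#'   generating probability at each timepoint)
#' @export
simulate_series <- function(config, protein = "sim", condition = "wild-type") {
  config <- validate_sim_config(config)
  n_total <- config$n_dna_per_field * config$n_fields_per_timepoint
  grid <- tidyr::expand_grid(
    replicate = seq_len(config$n_replicates),
    time_min = config$timepoints_min
  )
  f_true <- truth_fraction(config, grid$time_min)
  p <- pmin(1, f_true + config$false_coloc_rate)
  counts <- with_seed(config$seed, stats::rbinom(nrow(grid), n_total, p))
  series <- as_assembly_series(
    tibble::tibble(
      time_min = grid$time_min,
      replicate = grid$replicate,
      n_dna = n_total,
      n_colocalized = counts
    ),
    protein = protein,
    condition = if (config$mutant_mode) "mutant CEN" else condition
  )
  truth <- tibble::tibble(
    time_min = grid$time_min, replicate = grid$replicate,
    true_fraction = f_true
  )
  list(series = series, truth = truth)
}

#' Simulate photobleaching intensity traces
#'
#' Each trace is piecewise constant with `steps_per_trace` downward
#' steps of equal height at frames drawn uniformly from the interior of
#' the trace (the first and last 5% of frames are excluded), plus
#' Gaussian noise with SD `step_height / snr`. A single-fluorophore
#' spot bleaches in one step; multi-fluorophore spots show several.
#'
#' @param n_traces number of traces
#' @param steps_per_trace true number of bleaching steps per trace (>= 0)
#' @param snr step height over noise SD
#' @param n_frames frames per trace (>= 10)
#' @param seed integer seed
#' @param step_height intensity drop per step (arbitrary units)
#' @param frame_interval_s frame interval in seconds (metadata)
#' @return a list with `traces`, a long tibble
#'   (`spot_id`, `frame`, `intensity`), and `truth`, a tibble with
#'   `spot_id`, `n_steps`, and a `step_frames` list-column giving the
#'   first frame of each new (lower) level
#' @export
simulate_traces <- function(n_traces, steps_per_trace, snr, n_frames = 100,
                            seed = 1, step_height = 100,
                            frame_interval_s = 1) {
  stopifnot(n_frames >= 10, steps_per_trace >= 0, snr > 0, n_traces >= 1)
  lo <- ceiling(0.05 * n_frames) + 1
  hi <- floor(0.95 * n_frames)
  interior <- seq(lo, hi)
  if (steps_per_trace > length(interior)) {
    stop("steps_per_trace = ", steps_per_trace,
         " does not fit in the interior of a ", n_frames, "-frame trace")
  }
  noise_sd <- step_height / snr
  with_seed(seed, {
    out <- lapply(seq_len(n_traces), function(id) {
      frames <- sort(sample(interior, steps_per_trace))
      level <- steps_per_trace - findInterval(seq_len(n_frames), frames)
      mu <- level * step_height
      tibble::tibble(
        spot_id = id,
        frame = seq_len(n_frames),
        intensity = mu + stats::rnorm(n_frames, 0, noise_sd),
        .frames = list(frames)
      )
    })
    traces <- dplyr::bind_rows(out)
    truth <- traces |>
      dplyr::distinct(.data$spot_id, .keep_all = TRUE) |>
      dplyr::transmute(
        spot_id = .data$spot_id,
        n_steps = steps_per_trace,
        step_frames = .data$.frames
      )
    traces$.frames <- NULL
    attr(traces, "frame_interval_s") <- frame_interval_s
    list(traces = traces, truth = truth)
  })
}
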