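# Photobleaching step counting by penalized binary segmentation.
#
# A spot containing a single fluorophore bleaches in one abrupt step;
# counting steps in per-frame intensity traces therefore verifies the
# single-molecule character of surface-tethered DNA foci.

segment_rss <- function(csum, csum2, a, b) {
  # residual sum of squares of frames a..b (1-based, inclusive)
  s <- csum[b + 1] - csum[a]
  s2 <- csum2[b + 1] - csum2[a]
  s2 - s^2 / (b - a + 1)
}

best_split <- function(csum, csum2, a, b) {
  # best single changepoint within [a, b]; the changepoint c means the
  # new level starts at frame c (so c in a+1 .. b)
  if (b - a < 1) return(list(gain = -Inf, at = NA_integer_))
  whole <- segment_rss(csum, csum2, a, b)
  cps <- (a + 1):b
  rss <- vapply(cps, function(cp) {
    segment_rss(csum, csum2, a, cp - 1) + segment_rss(csum, csum2, cp, b)
  }, numeric(1))
  i <- which.min(rss)
  list(gain = whole - rss[i], at = cps[i])
}

#' Count photobleaching steps in an intensity trace
#'
#' Fits piecewise-constant models by binary segmentation: changepoints
#' are added greedily (each new split is the one giving the largest
#' residual sum-of-squares reduction among all current segments), and
#' the number of steps is chosen to minimize
#' RSS + m x penalty x sigma2 x log(n), where sigma2 is the trace noise
#' variance estimated robustly from first differences (MAD / sqrt(2),
#' squared) so that the steps themselves do not inflate it. Ties are
#' broken toward fewer steps, and a zero-variance constant trace yields
#' zero steps. Steps are counted regardless of sign; a downward-only
#' count is carried alongside for pure-bleaching use.
#'
#' @param trace numeric vector of per-frame intensities (>= 10 frames),
#'   or a data frame with columns `frame` and `intensity`
#' @param penalty penalty multiplier (> 0, default 3; BIC-style)
#' @param max_steps maximum segmentation depth (default 10)
#' @return a list of class `bleach_steps`: `n_steps`, `n_steps_down`,
#'   `step_frames` (first frame of each new level), `level_means`,
#'   `penalty_used`, `sigma2`
#' @export
count_bleach_steps <- function(trace, penalty = 3, max_steps = 10) {
  if (is.data.frame(trace)) {
    trace <- trace$intensity[order(trace$frame)]
  }
  x <- as.numeric(trace)
  n <- length(x)
  if (n < 10) stop("trace must have at least 10 frames")
  if (!all(is.finite(x))) stop("trace contains non-finite intensities")
  stopifnot(penalty > 0)

  sigma2 <- (stats::mad(diff(x)) / sqrt(2))^2
  pen <- penalty * sigma2 * log(n)

  csum <- c(0, cumsum(x))
  csum2 <- c(0, cumsum(x^2))

  # greedy global binary segmentation to max depth: nested models
  # RSS_0 >= RSS_1 >= ... with recorded gains
  bounds <- list(c(1L, n))
  splits <- integer(0)
  gains <- numeric(0)
  cand <- list(best_split(csum, csum2, 1L, n))
  for (m in seq_len(min(max_steps, n - 1))) {
    g <- vapply(cand, `[[`, numeric(1), "gain")
    i <- which.max(g)
    if (!is.finite(g[i]) || g[i] <= 0) break
    cp <- cand[[i]]$at
    splits <- c(splits, cp)
    gains <- c(gains, g[i])
    a <- bounds[[i]][1]; b <- bounds[[i]][2]
    bounds[[i]] <- c(a, cp - 1L)
    bounds[[length(bounds) + 1]] <- c(cp, b)
    cand[[i]] <- best_split(csum, csum2, a, cp - 1L)
    cand[[length(cand) + 1]] <- best_split(csum, csum2, cp, b)
  }

  # refine each candidate model by coordinate descent: re-optimize every
  # changepoint holding the others fixed (recovers closely spaced steps
  # that the greedy split order compromises between)
  rss_of <- function(cps) {
    edges <- c(1L, sort(cps), n + 1L)
    sum(vapply(seq_len(length(edges) - 1), function(i) {
      segment_rss(csum, csum2, edges[i], edges[i + 1] - 1L)
    }, numeric(1)))
  }
  refine <- function(cps) {
    if (length(cps) == 0) return(cps)
    for (sweep in 1:3) {
      changed <- FALSE
      for (j in seq_along(cps)) {
        others <- sort(cps[-j])
        lo <- if (any(others < cps[j])) max(others[others < cps[j]]) else 1L
        hi <- if (any(others > cps[j])) min(others[others > cps[j]]) - 1L else n
        bs <- best_split(csum, csum2, as.integer(lo), as.integer(hi))
        if (!is.na(bs$at) && bs$at != cps[j]) {
          cand <- sort(c(others, bs$at))
          if (rss_of(cand) < rss_of(sort(cps)) - 1e-9) {
            cps[j] <- bs$at
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    sort(cps)
  }
  models <- lapply(0:length(splits), function(m) refine(splits[seq_len(m)]))
  rss_path <- vapply(models, rss_of, numeric(1))

  # model size minimizing RSS_m + m * pen; ties toward fewer steps
  cost <- rss_path + pen * (0:length(splits))
  m_best <- which.min(cost) - 1L

  step_frames <- models[[m_best + 1L]]
  edges <- c(1L, step_frames, n + 1L)
  level_means <- vapply(seq_len(length(edges) - 1), function(i) {
    mean(x[edges[i]:(edges[i + 1] - 1)])
  }, numeric(1))
  n_down <- sum(diff(level_means) < 0)

  structure(
    list(
      n_steps = m_best, n_steps_down = n_down,
      step_frames = step_frames, level_means = level_means,
      penalty_used = pen, sigma2 = sigma2
    ),
    class = "bleach_steps"
  )
}

#' @export
print.bleach_steps <- function(x, ...) {
  cat("Bleach steps:", x$n_steps,
      sprintf("(%d downward) at frame(s) %s\n", x$n_steps_down,
              if (length(x$step_frames)) paste(x$step_frames, collapse = ", ")
              else "-"))
  invisible(x)
}

#' Fraction of traces that bleach in a single step
#'
#' Applies [count_bleach_steps()] to every trace and reports the
#' fraction with exactly one downward step — the single-molecule
#' verification statistic — together with the histogram of step counts.
#'
#' @param traces a long tibble (`spot_id`, `frame`, `intensity`) such as
#'   [simulate_traces()] produces, or a list of numeric vectors
#' @param penalty penalty multiplier passed to [count_bleach_steps()]
#' @return a list: `fraction_one_step`, `histogram` (tibble of `n_steps`
#'   and `n_traces`), and `per_trace` (tibble of `spot_id`, `n_steps`,
#'   `n_steps_down`)
#' @export
single_molecule_fraction <- function(traces, penalty = 3) {
  if (is.data.frame(traces)) {
    d <- traces[order(traces$spot_id, traces$frame), ]
    traces <- split(d$intensity, d$spot_id)
  }
  if (length(traces) < 1) stop("need at least one trace")
  ids <- names(traces)
  if (is.null(ids)) ids <- as.character(seq_along(traces))
  per_trace <- purrr::map2_dfr(traces, ids, function(x, id) {
    res <- count_bleach_steps(x, penalty = penalty)
    tibble::tibble(spot_id = id, n_steps = res$n_steps,
                   n_steps_down = res$n_steps_down)
  })
  hist <- per_trace |>
    dplyr::count(.data$n_steps, name = "n_traces") |>
    tidyr::complete(n_steps = 0:max(per_trace$n_steps),
                    fill = list(n_traces = 0L))
  list(
    fraction_one_step = mean(per_trace$n_steps_down == 1),
    histogram = hist,
    per_trace = per_trace
  )
}
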