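#' Build or validate an assembly time series
#'
#' An assembly time series is the tabular readout of the time-course
#' colocalization assay: for each incubation time and biological
#' replicate, the number of surface-tethered DNA molecules scored
#' (`n_dna`) and the number carrying a colocalized GFP spot
#' (`n_colocalized`). A `fraction` column is derived. Protein and
#' condition labels travel as ordinary columns so series for different
#' strains can be row-bound and compared.
#'
#' @param data a data frame with columns `time_min`, `replicate`,
#'   `n_dna`, `n_colocalized`
#' @param protein,condition optional labels added as columns when absent
#' @return a tibble with class `assembly_series`
#' @export
as_assembly_series <- function(data, protein = NULL, condition = NULL) {
  need <- c("time_min", "replicate", "n_dna", "n_colocalized")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("series is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- tibble::as_tibble(data)
  if (!is.null(protein) && !"protein" %in% names(out)) out$protein <- protein
  if (!is.null(condition) && !"condition" %in% names(out)) out$condition <- condition
  if (any(out$time_min < 0)) stop("timepoints must be non-negative")
  bad <- !is.na(out$n_colocalized) & out$n_colocalized > out$n_dna
  if (any(bad)) stop("n_colocalized exceeds n_dna in ", sum(bad), " row(s)")
  if (any(out$n_dna < 0)) stop("n_dna must be non-negative")
  out$fraction <- ifelse(out$n_dna > 0, out$n_colocalized / out$n_dna, NA_real_)
  class(out) <- unique(c("assembly_series", class(out)))
  out
}

#' Per-timepoint summary of an assembly series
#'
#' Pools replicates at each timepoint: the mean of the replicate
#' fractions, their standard deviation (the error bar of the assay,
#' taken over biological replicates), the pooled DNA count, and the
#' fitting weight sigma. The per-timepoint sigma used for chi-squared
#' fitting is the replicate SD floored at the pooled binomial standard
#' error sqrt(p(1-p)/N) and at `sigma_floor`; the SD of three
#' replicates can be spuriously zero, so the binomial floor keeps
#' weights finite and honest.
#'
#' @param series an assembly series (see [as_assembly_series()])
#' @param sigma_floor absolute lower bound on sigma (default 1e-3)
#' @return a tibble with one row per timepoint: `time_min`, `n_reps`,
#'   `n_dna_total`, `mean_fraction`, `sd_fraction`, `se_binomial`, `sigma`
#' @export
summarise_series <- function(series, sigma_floor = 1e-3) {
  series <- as_assembly_series(series)
  series |>
    dplyr::filter(!is.na(.data$fraction)) |>
    dplyr::group_by(.data$time_min) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      n_dna_total = sum(.data$n_dna),
      mean_fraction = mean(.data$fraction),
      sd_fraction = ifelse(dplyr::n() > 1, stats::sd(.data$fraction), 0),
      p_pooled = sum(.data$n_colocalized) / sum(.data$n_dna),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      se_binomial = sqrt(.data$p_pooled * (1 - .data$p_pooled) / .data$n_dna_total),
      sigma = pmax(.data$sd_fraction, .data$se_binomial, sigma_floor)
    ) |>
    dplyr::select(-"p_pooled") |>
    dplyr::arrange(.data$time_min)
}

#' Read / write assembly series CSV
#'
#' The on-disk schema is `time_min,replicate,n_dna,n_colocalized`
#' (extra label columns are preserved), shared between the simulator
#' output and the imaging stage so pipeline stages compose.
#'
#' @param path CSV file path
#' @param series an assembly series
#' @return `read_series_csv()` returns an `assembly_series` tibble;
#'   `write_series_csv()` returns `path` invisibly.
#' @export
read_series_csv <- function(path) {
  as_assembly_series(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_series_csv
#' @export
write_series_csv <- function(series, path) {
  df <- as.data.frame(series)
  df$fraction <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
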