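# File I/O for field images, spot tables, and traces.

#' Read and write single-plane grayscale field TIFFs
#'
#' Images are stored as 16-bit grayscale TIFF, one file per channel per
#' field. Intensities (camera counts) are clipped to \[0, 65535\] and
#' rounded on write, so write/read round-trips are exact at integer
#' counts.
#'
#' @param image numeric matrix of intensities
#' @param path TIFF file path
#' @return `write_field_tiff()` returns `path` invisibly;
#'   `read_field_tiff()` returns a numeric matrix of counts.
#' @export
write_field_tiff <- function(image, path) {
  scaled <- pmin(pmax(round(image), 0), 65535) / 65535
  tiff::writeTIFF(scaled, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  round(img * 65535)
}

#' Standard field image filename
#'
#' `{condition}_{t}min_rep{r}_field{i}_{647|488}.tif`
#'
#' @param condition condition label
#' @param t timepoint in minutes
#' @param replicate,field indices
#' @param channel `"647"` (DNA) or `"488"` (GFP)
#' @return filename string
#' @export
field_filename <- function(condition, t, replicate, field, channel) {
  channel <- match.arg(as.character(channel), c("647", "488"))
  sprintf("%s_%smin_rep%d_field%d_%s.tif", condition, t, replicate,
          field, channel)
}

#' Read / write spot tables
#'
#' Spot tables are CSV with header `field,channel,x_px,y_px,bound`
#' (detection output omits `bound`; extra columns are preserved).
#'
#' @param spots a tibble of spots
#' @param path CSV path
#' @return `read_spots_csv()` returns a tibble; the writer returns
#'   `path` invisibly.
#' @export
write_spots_csv <- function(spots, path) {
  utils::write.csv(as.data.frame(spots), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spots_csv
#' @export
read_spots_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read / write intensity traces
#'
#' Long-format CSV with header `spot_id,frame,intensity`.
#'
#' @param traces long tibble of traces
#' @param path CSV path
#' @return `read_traces_csv()` returns a tibble; the writer returns
#'   `path` invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  utils::write.csv(as.data.frame(traces), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Serialize a kinetic fit (with candidates) to JSON
#'
#' Writes the selected fit, its T30/censoring status, and all four
#' candidate fits to a JSON report readable by [read_fit_json()].
#'
#' @param fit a `kinetic_fit` (ideally from [select_model()])
#' @param path JSON path
#' @return `path`, invisibly
#' @export
write_fit_json <- function(fit, path) {
  payload <- list(
    protein = fit$protein, condition = fit$condition,
    n_steps = fit$n_steps, k = fit$k, c_max = fit$c_max,
    chi2 = fit$chi2, threshold = fit$threshold, t_max = fit$t_max,
    t30 = fit$t30$time_min, t30_censored = fit$t30$censored,
    t30_label = format(fit$t30),
    se_cmax = fit$se_cmax, se_t30 = fit$se_t30,
    converged = fit$converged, informative = fit$informative,
    candidates = if (!is.null(fit$candidates)) fit$candidates else NULL
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$t30 <- structure(
    list(time_min = x$t30, censored = x$t30_censored,
         threshold = x$threshold, t_max = x$t_max),
    class = "t_threshold"
  )
  class(x) <- "kinetic_fit"
  x
}
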