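#' Read and write REDOR curve tables
#'
#' CSV files with a `time_ms` column plus either a `ratio` column or the
#' raw `S`, `S0` intensity columns (ratio is then computed as S/S0, with
#' `sigma` from the quotient rule when a per-point noise column `eps` is
#' present). Extra grouping columns (`fraction`, `scheme`, `replicate`,
#' `label`) pass through untouched, so calibration families and replicate
#' sets live naturally in one file.
#'
#' @param path CSV file.
#' @return A tibble with at least `time_ms` and `ratio`.
#' @export
read_redor_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("REDOR file '%s' not found.", path))
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  if (!"time_ms" %in% names(tbl)) {
    abort(sprintf("'%s' has no `time_ms` column.", path))
  }
  if (!"ratio" %in% names(tbl)) {
    if (!all(c("S", "S0") %in% names(tbl))) {
      abort(sprintf("'%s' needs either a `ratio` column or `S` and `S0`.", path))
    }
    tbl$ratio <- tbl$S / tbl$S0
    if ("eps" %in% names(tbl) && !"sigma" %in% names(tbl)) {
      tbl$sigma <- abs(tbl$ratio) *
        sqrt((tbl$eps / tbl$S)^2 + (tbl$eps / tbl$S0)^2)
    }
  }
  tbl
}

#' @rdname read_redor_csv
#' @param curve Curve tibble to write.
#' @export
write_redor_csv <- function(curve, path) {
  readr::write_csv(curve, path)
  invisible(path)
}

#' JSON round-trip for curve tables
#'
#' @param curve A curve tibble.
#' @param path JSON file.
#' @return `read_redor_json()` returns the tibble.
#' @export
write_redor_json <- function(curve, path) {
  jsonlite::write_json(curve, path, dataframe = "columns", digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_redor_json
#' @export
read_redor_json <- function(path) {
  as_tibble(jsonlite::fromJSON(path))
}

#' Serialize a mixing fit to JSON
#'
#' Writes `p43`, `p34`, `chi4`, `Q` with uncertainties, plus provenance
#' (window, brackets, effective number of points, natural-abundance
#' handling).
#'
#' @param fit A `mixing_fit` from [estimate_full_dataset()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_estimate_json <- function(fit, path) {
  stopifnot(inherits(fit, "mixing_fit"))
  p <- fit$probabilities
  d <- fit$descriptors
  out <- list(
    p43 = p$p43, p43_err = p$p43_err,
    p34 = p$p34, p34_err = p$p34_err,
    chi4 = d$chi4, chi4_err = d$chi4_err,
    Q = d$Q, Q_err = d$Q_err,
    window_ms = fit$window,
    brackets = fit$brackets,
    n_points = setNames(as.list(fit$estimates$n_points), fit$estimates$scheme),
    na_correct = fit$na_correct,
    scheme_p43 = fit$scheme_p43)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
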