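#' Read / write PSM tables
#'
#' The PSM table dialect is a UTF-8 tab-separated file with a header row and
#' columns `psm_id`, `spectrum_id`, `sample_id`, `replicate_id`, `sequence`,
#' `mods` (semicolon list of `pos:name`, see [format_mods()]), `charge`,
#' `is_decoy` (0/1), `protein_ids` (comma list), `base_score`,
#' `observed_rt`, `predicted_rt`, followed by any number of feature columns
#' prefixed `feat_`.
#'
#' @param path Path to a PSM TSV file.
#' @return A tibble; `is_decoy` is converted to logical and `protein_ids`
#'   to a list column.
#' @export
read_psms <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("psm_id", "spectrum_id", "sequence", "is_decoy", "base_score")
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    abort(sprintf("PSM table missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  x$is_decoy <- as.logical(as.integer(x$is_decoy))
  if ("protein_ids" %in% names(x)) {
    x$protein_ids <- strsplit(as.character(x$protein_ids), ",", fixed = TRUE)
  }
  x
}

#' @rdname read_psms
#' @param psms A PSM tibble (e.g. from [read_psms()] or the simulator).
#' @return For `write_psms`, `path` invisibly.
#' @export
write_psms <- function(psms, path) {
  out <- psms
  out$is_decoy <- as.integer(as.logical(out$is_decoy))
  if (is.list(out$protein_ids)) {
    out$protein_ids <- vapply(out$protein_ids, paste, character(1),
                              collapse = ",")
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a predicted-intensity table
#'
#' Tab-separated with columns `spectrum_id`, `sequence`, `mods` and
#' `predicted` (semicolon-joined intensities in charge-1 `b` then `y`
#' fragment order).
#'
#' @param path Path to the TSV file.
#' @return A tibble with `predicted` as a list column of numeric vectors.
#' @export
read_predicted_intensities <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  x$predicted <- lapply(strsplit(as.character(x$predicted), ";", fixed = TRUE),
                        as.numeric)
  x
}

#' @rdname read_predicted_intensities
#' @param predictions Tibble with a `predicted` list column.
#' @export
write_predicted_intensities <- function(predictions, path) {
  out <- predictions
  out$predicted <- vapply(out$predicted,
                          function(v) paste(sprintf("%.6g", v), collapse = ";"),
                          character(1))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
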