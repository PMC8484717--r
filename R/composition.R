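#' Database composition report
#'
#' Summarises a three-source search space (reference proteome R, OpenProt-style
#' predictions O, ribosome-profiling predictions S) as the seven disjoint
#' Venn cells over distinct sequences, with derived percentages: the share of
#' the database coming only from proteogenomics sources, only from the
#' reference, and from reference/prediction overlap. Percentages are rounded
#' half-up to one decimal. With `total == 0` the percentages are undefined
#' and reported as `NA`.
#'
#' @param cells Named numeric vector (or list) of the seven disjoint cell
#'   counts: `R_only`, `O_only`, `S_only`, `RO`, `RS`, `OS`, `ROS`.
#' @param pct_small Optional percentage of database entries shorter than
#'   100 amino acids (computed by [compute_composition()] when sequences are
#'   available).
#' @return An object of class `sorfpep_composition`: a list with `cells`
#'   (tibble), `total`, `pct_proteogenomics_only`, `pct_reference_only`,
#'   `pct_reference_overlap`, `pct_small`.
#' @export
composition_report <- function(cells, pct_small = NA_real_) {
  wanted <- c("R_only", "O_only", "S_only", "RO", "RS", "OS", "ROS")
  cells <- unlist(cells)
  if (!all(wanted %in% names(cells))) {
    abort(sprintf("cells must contain: %s", paste(wanted, collapse = ", ")))
  }
  cells <- cells[wanted]
  if (any(cells < 0)) abort("cell counts must be non-negative")
  total <- sum(cells)
  pg_only <- unname(cells["O_only"] + cells["OS"] + cells["S_only"])
  ref_overlap <- unname(cells["RO"] + cells["RS"] + cells["ROS"])
  pct <- function(x) {
    if (total == 0) NA_real_ else round_half_up(100 * x / total, 1)
  }
  structure(list(
    cells = tibble(cell = wanted, n = unname(cells)),
    total = total,
    pct_proteogenomics_only = pct(pg_only),
    pct_reference_only = pct(unname(cells["R_only"])),
    pct_reference_overlap = pct(ref_overlap),
    pct_small = pct_small
  ), class = "sorfpep_composition")
}

#' Classify distinct sequences into Venn cells
#'
#' Each set is deduplicated first; every distinct sequence in the union is
#' assigned to exactly one of the seven disjoint membership cells.
#'
#' @param ref_seqs,openprot_seqs,sorfs_seqs Character vectors of sequences
#'   (or `seq_records` tibbles, in which case the `sequence` column is used).
#' @return A `sorfpep_composition` report (see [composition_report()]).
#' @export
compute_composition <- function(ref_seqs, openprot_seqs, sorfs_seqs) {
  as_seqs <- function(x) {
    if (is.data.frame(x)) x <- x$sequence
    unique(as.character(x))
  }
  r <- as_seqs(ref_seqs); o <- as_seqs(openprot_seqs); s <- as_seqs(sorfs_seqs)
  all_seqs <- unique(c(r, o, s))
  in_r <- all_seqs %in% r; in_o <- all_seqs %in% o; in_s <- all_seqs %in% s
  cell <- dplyr::case_when(
    in_r & !in_o & !in_s ~ "R_only",
    !in_r & in_o & !in_s ~ "O_only",
    !in_r & !in_o & in_s ~ "S_only",
    in_r & in_o & !in_s ~ "RO",
    in_r & !in_o & in_s ~ "RS",
    !in_r & in_o & in_s ~ "OS",
    TRUE ~ "ROS"
  )
  counts <- table(factor(cell, levels = c("R_only", "O_only", "S_only",
                                          "RO", "RS", "OS", "ROS")))
  pct_small <- if (length(all_seqs)) {
    round_half_up(100 * mean(nchar(all_seqs) < 100), 1)
  } else NA_real_
  composition_report(setNames(as.numeric(counts), names(counts)),
                     pct_small = pct_small)
}

#' @export
print.sorfpep_composition <- function(x, ...) {
  cat("Proteogenomic database composition\n")
  cat(sprintf("  total distinct sequences: %s\n",
              format(x$total, big.mark = ",")))
  for (i in seq_len(nrow(x$cells))) {
    cat(sprintf("  %-7s %s\n", x$cells$cell[i],
                format(x$cells$n[i], big.mark = ",")))
  }
  cat(sprintf("  proteogenomics-only: %.1f%%  reference-only: %.1f%%  overlap: %.1f%%\n",
              x$pct_proteogenomics_only, x$pct_reference_only,
              x$pct_reference_overlap))
  if (!is.na(x$pct_small)) {
    cat(sprintf("  entries < 100 aa: %.1f%%\n", x$pct_small))
  }
  invisible(x)
}

#' Convert a composition report to JSON
#'
#' @param x A `sorfpep_composition` object.
#' @param path Optional path; when given the JSON is written there.
#' @return The JSON string, invisibly when written to a file.
#' @export
composition_json <- function(x, path = NULL) {
  obj <- c(as.list(setNames(x$cells$n, x$cells$cell)),
           list(total = x$total,
                pct_proteogenomics_only = x$pct_proteogenomics_only,
                pct_reference_only = x$pct_reference_only,
                pct_reference_overlap = x$pct_reference_overlap,
                pct_small = x$pct_small))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname composition_report
#' @param object,x A `sorfpep_composition` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.sorfpep_composition <- function(object, ...) {
  df <- object$cells
  df$cell <- factor(df$cell, levels = df$cell)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Venn cell (R = reference, O = OpenProt, S = sORFs)",
                  y = "distinct sequences",
                  title = "Search-database composition") +
    ggplot2::theme_minimal()
}
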