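#' Group validated PSMs into peptidoforms
#'
#' Decoys are excluded, PSMs with q-value strictly below the threshold are
#' kept, and the survivors are grouped by their peptidoform key (sequence
#' plus modifications by default; sequence only with `by_mods = FALSE`).
#'
#' @param psms Rescored PSM tibble with `q_value` (or a `sorfpep_rescore`
#'   object, whose `psms` are used).
#' @param q_threshold Strict upper bound on the q-value (a PSM at exactly
#'   the threshold is excluded).
#' @param by_mods Include modifications in the grouping key.
#' @return A tibble of peptide groups: `key`, `sequence`, `mods`,
#'   `psm_ids` (list), `psm_count`, `samples` (list), `replicates` (list),
#'   `best_q`, `protein_ids` (list).
#' @export
group_peptides <- function(psms, q_threshold = 0.01, by_mods = TRUE) {
  if (inherits(psms, "sorfpep_rescore")) psms <- psms$psms
  psms <- as_tibble(psms)
  if (!"mods" %in% names(psms)) psms$mods <- ""
  if (!"sample_id" %in% names(psms)) psms$sample_id <- NA_character_
  if (!"replicate_id" %in% names(psms)) psms$replicate_id <- NA_character_
  if (!"protein_ids" %in% names(psms)) psms$protein_ids <- list(character())
  if (!is.list(psms$protein_ids)) {
    psms$protein_ids <- strsplit(as.character(psms$protein_ids), ",",
                                 fixed = TRUE)
  }
  keep <- !as.logical(psms$is_decoy) & psms$q_value < q_threshold
  x <- psms[keep, ]
  mods <- ifelse(is.na(x$mods), "", x$mods)
  x$key <- if (by_mods) paste0(x$sequence, "/", mods) else x$sequence
  x |>
    group_by(.data$key) |>
    summarise(
      sequence = first(.data$sequence),
      mods = if (by_mods) first(.data$mods) else NA_character_,
      psm_ids = list(.data$psm_id),
      psm_count = n(),
      samples = list(sort(unique(stats::na.omit(.data$sample_id)))),
      replicates = list(sort(unique(stats::na.omit(.data$replicate_id)))),
      best_q = min(.data$q_value),
      protein_ids = list(sort(unique(unlist(.data$protein_ids)))),
      .groups = "drop"
    )
}

#' Read a neuropeptide reference table
#'
#' Tab-separated with columns `precursor_name`, `accession`,
#' `neuropeptide_name`, `family`, `sequence` (the mature peptide).
#'
#' @param path Path to the TSV file.
#' @return A tibble of reference entries.
#' @export
read_neuropep <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("precursor_name", "accession", "neuropeptide_name",
                "family", "sequence")
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    abort(sprintf("neuropeptide table missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (any(is.na(x$sequence) | !nzchar(x$sequence))) {
    abort("neuropeptide reference contains empty mature sequences")
  }
  x
}

#' Annotate peptide groups against a neuropeptide reference
#'
#' A group matches a reference entry when either sequence contains the other
#' (bidirectional substring containment), which captures the truncation
#' ladders produced by endogenous proteolytic processing. Groups that match
#' no mature peptide but are contained in a supplied precursor sequence are
#' flagged `precursor_only`.
#'
#' @param groups Peptide groups from [group_peptides()].
#' @param reference Neuropeptide reference tibble (see [read_neuropep()]).
#' @param precursor_seqs Optional named character vector of precursor
#'   protein sequences.
#' @return A list with `groups` (annotated: list column `neuropeptides`,
#'   `families`, logical `matched`, `precursor_only`, `precursor_hits`) and
#'   `summary` (one-row tibble: `n_groups`, `n_matched_groups`,
#'   `n_neuropeptides`, `n_families`, `n_precursor_only`).
#' @export
annotate_neuropeptides <- function(groups, reference, precursor_seqs = NULL) {
  hit_lists <- lapply(groups$sequence, function(s) {
    hits <- stringr::str_detect(reference$sequence, stringr::fixed(s)) |
      stringr::str_detect(s, stringr::fixed(reference$sequence))
    which(hits)
  })
  groups$neuropeptides <- lapply(hit_lists, function(i)
    unique(reference$neuropeptide_name[i]))
  groups$families <- lapply(hit_lists, function(i)
    unique(reference$family[i]))
  groups$matched <- lengths(hit_lists) > 0L
  groups$precursor_hits <- rep(list(character()), nrow(groups))
  if (!is.null(precursor_seqs) && length(precursor_seqs)) {
    groups$precursor_hits <- lapply(groups$sequence, function(s) {
      names(precursor_seqs)[stringr::str_detect(precursor_seqs,
                                                stringr::fixed(s))]
    })
  }
  groups$precursor_only <- !groups$matched &
    lengths(groups$precursor_hits) > 0L
  summary <- tibble(
    n_groups = nrow(groups),
    n_matched_groups = sum(groups$matched),
    n_neuropeptides = length(unique(unlist(
      groups$neuropeptides[groups$matched]))),
    n_families = length(unique(unlist(groups$families[groups$matched]))),
    n_precursor_only = sum(groups$precursor_only)
  )
  list(groups = groups, summary = summary)
}

#' Compare identification sets between two methods
#'
#' Exact set arithmetic over comparable keys (e.g. peptidoform keys); the
#' union always satisfies inclusion-exclusion.
#'
#' @param set_a,set_b Character vectors (duplicates ignored).
#' @return A list with the key vectors `both`, `only_a`, `only_b` and a
#'   `counts` one-row tibble (`both`, `only_a`, `only_b`, `union`).
#' @export
compare_methods <- function(set_a, set_b) {
  a <- unique(as.character(set_a)); b <- unique(as.character(set_b))
  both <- intersect(a, b)
  only_a <- setdiff(a, b)
  only_b <- setdiff(b, a)
  n_both <- length(both); n_a <- length(only_a); n_b <- length(only_b)
  list(both = both, only_a = only_a, only_b = only_b,
       counts = tibble(both = n_both, only_a = n_a, only_b = n_b,
                       union = n_both + n_a + n_b))
}

#' Total peptides attributed to known precursors
#'
#' Adds peptides matched through the neuropeptide reference and additional
#' per-precursor counts (e.g. precursors absent from the reference), keeping
#' the per-source breakdown.
#'
#' @param neuropep_matched_count Count of reference-linked peptides.
#' @param additional_precursor_counts Named numeric vector of extra counts.
#' @return A list with `total` and `breakdown` (tibble of `source`, `n`).
#' @export
precursor_totals <- function(neuropep_matched_count,
                             additional_precursor_counts = numeric()) {
  counts <- c(neuropep_linked = neuropep_matched_count,
              additional_precursor_counts)
  if (any(counts < 0)) abort("counts must be non-negative")
  list(total = sum(counts),
       breakdown = tibble(source = names(counts), n = unname(counts)))
}

#' Write a peptide-group summary
#'
#' One row per group with per-sample presence columns, plus a JSON summary.
#'
#' @param annotated Result of [annotate_neuropeptides()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_peptide_summary <- function(annotated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- annotated$groups
  all_samples <- sort(unique(unlist(g$samples)))
  flat <- tibble(
    key = g$key, sequence = g$sequence, mods = g$mods,
    psm_count = g$psm_count, best_q = g$best_q,
    protein_ids = vapply(g$protein_ids, paste, character(1), collapse = ","),
    neuropeptides = vapply(g$neuropeptides, paste, character(1),
                           collapse = ","),
    families = vapply(g$families, paste, character(1), collapse = ","),
    matched = g$matched, precursor_only = g$precursor_only
  )
  for (s in all_samples) {
    flat[[paste0("in_", s)]] <-
      vapply(g$samples, function(x) s %in% x, logical(1))
  }
  readr::write_tsv(flat, file.path(dir, "peptide_summary.tsv"),
                   progress = FALSE)
  s <- annotated$summary
  writeLines(jsonlite::toJSON(list(
    n_peptides = s$n_groups, n_neuropeptides = s$n_neuropeptides,
    n_families = s$n_families, n_precursor_only = s$n_precursor_only
  ), auto_unbox = TRUE, digits = NA), file.path(dir, "summary.json"))
  invisible(dir)
}
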