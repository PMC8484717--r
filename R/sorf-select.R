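#' Keep small proteins
#'
#' sORF-encoded proteins are defined by a length at or below the threshold
#' (inclusive boundary: a 100-aa protein with the default is kept).
#'
#' @param proteins Tibble with a `length` column (or a `sequence` column
#'   from which lengths are taken).
#' @param max_len Maximum length in amino acids.
#' @return The filtered tibble.
#' @export
filter_small <- function(proteins, max_len = 100) {
  proteins <- as_tibble(proteins)
  len <- if ("length" %in% names(proteins)) proteins$length
         else nchar(proteins$sequence)
  proteins[len <= max_len, ]
}

#' Assign the identification category of a database entry
#'
#' Maps source and header evidence to one of `SWISS`, `TrEMBL`,
#' `OpenProt_predicted`, `sORFs_org_predicted`: reference entries are split
#' by their UniProt header prefix (`sp|` reviewed, `tr|` unreviewed);
#' predicted entries keep their prediction source unless the header carries
#' a UniProt cross-reference.
#'
#' @param records A `seq_records` tibble (columns `id`, `source`,
#'   `description`).
#' @return Character vector of categories, one per record.
#' @export
assign_category <- function(records) {
  src <- records$source
  id <- records$id
  desc <- ifelse(is.na(records$description), "", records$description)
  out <- character(nrow(records))
  is_sp <- startsWith(id, "sp|") | grepl("\\bsp\\|", desc)
  is_tr <- startsWith(id, "tr|") | grepl("\\btr\\|", desc)
  out[src == "reference" & is_sp] <- "SWISS"
  out[src == "reference" & !is_sp & is_tr] <- "TrEMBL"
  out[src == "openprot" & is_sp] <- "SWISS"
  out[src == "openprot" & !is_sp & is_tr] <- "TrEMBL"
  out[src == "openprot" & !is_sp & !is_tr] <- "OpenProt_predicted"
  out[src == "sorfs_org"] <- "sORFs_org_predicted"
  bad <- !nzchar(out)
  if (any(bad)) {
    abort(sprintf("cannot categorise record(s): %s",
                  paste(head(id[bad], 5), collapse = ", ")))
  }
  out
}

#' Select candidates on non-coding genes
#'
#' Excludes candidates whose gene biotype is `protein_coding`; biotypes such
#' as lncRNA, TEC and pseudogene are retained. Filtering is at gene level.
#' Candidates whose gene lacks a biotype are retained with a
#' `biotype_missing` flag (they correspond to poorly characterised predicted
#' genes); genes on the allowlist are always retained.
#'
#' @param candidates Tibble with `gene_id` (and optionally `gene_biotype`).
#' @param biotype_table Tibble `gene_id`, `biotype` (Ensembl vocabulary);
#'   optional when `candidates` already carries `gene_biotype`.
#' @param allowlist Character vector of gene ids retained regardless of
#'   biotype.
#' @return The retained candidates with columns `gene_biotype` and
#'   `biotype_missing` filled in.
#' @export
noncoding_filter <- function(candidates, biotype_table = NULL,
                             allowlist = character()) {
  candidates <- as_tibble(candidates)
  if (!is.null(biotype_table)) {
    bt <- biotype_table$biotype[match(candidates$gene_id,
                                      biotype_table$gene_id)]
    if ("gene_biotype" %in% names(candidates)) {
      candidates$gene_biotype <- dplyr::coalesce(bt,
                                                 candidates$gene_biotype)
    } else {
      candidates$gene_biotype <- bt
    }
  }
  candidates$biotype_missing <- is.na(candidates$gene_biotype)
  if (any(candidates$biotype_missing)) {
    warn(sprintf("%d candidate(s) without gene biotype retained and flagged",
                 sum(candidates$biotype_missing)))
  }
  allowed <- !is.na(candidates$gene_id) & candidates$gene_id %in% allowlist
  keep <- allowed | candidates$biotype_missing |
    candidates$gene_biotype != "protein_coding"
  candidates[keep, ]
}

#' Read a gene-biotype table / allowlist
#'
#' @param path TSV with columns `gene_id`, `gene_name`, `biotype`
#'   (for `read_biotypes`) or one gene id per line (`read_allowlist`).
#' @return A tibble / character vector.
#' @export
read_biotypes <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("gene_id", "biotype"), names(x))
  if (length(miss)) {
    abort(sprintf("biotype table missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  x
}

#' @rdname read_biotypes
#' @export
read_allowlist <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Scan a peptide tag for near-identical proteome matches
#'
#' A gap-free uniqueness surrogate for short MS sequence tags: reports every
#' exact-substring hit plus every length-`nchar(tag)` window with at most
#' `max_mismatches` mismatches (Hamming distance). A tag is unique when it
#' has no hits outside its own source protein. This windowed scan stands in
#' for an alignment-based homology search at short tag lengths; the mismatch
#' bound plays the role of an e-value cutoff and is documented, not claimed
#' equivalent.
#'
#' @param tag Peptide sequence (length >= 8; shorter tags are refused as
#'   unreliable).
#' @param proteome A `seq_records` tibble or named character vector of
#'   protein sequences.
#' @param max_mismatches Maximum Hamming mismatches per window.
#' @param own_ids Protein ids considered the tag's own source (excluded when
#'   judging uniqueness).
#' @return A tibble of hits (`protein_id`, `start`, `end`, `mismatches`)
#'   with attribute `unique` (logical).
#' @export
uniqueness_scan <- function(tag, proteome, max_mismatches = 1,
                            own_ids = character()) {
  if (nchar(tag) < 8) abort("tags shorter than 8 residues are not scanned")
  if (is.data.frame(proteome)) {
    seqs <- setNames(proteome$sequence, proteome$id)
  } else {
    seqs <- proteome
  }
  subject <- Biostrings::AAStringSet(seqs)
  m <- Biostrings::vmatchPattern(tag, subject,
                                 max.mismatch = max_mismatches,
                                 with.indels = FALSE, fixed = TRUE)
  hits <- purrr::map_dfr(seq_along(m), function(i) {
    r <- m[[i]]
    if (length(r) == 0L) return(NULL)
    starts <- IRanges::start(r)
    mm <- vapply(starts, function(st) {
      win <- substring(seqs[[i]], st, st + nchar(tag) - 1L)
      sum(strsplit(win, "")[[1]] != strsplit(tag, "")[[1]])
    }, numeric(1))
    tibble(protein_id = names(seqs)[i], start = starts,
           end = starts + nchar(tag) - 1L, mismatches = mm)
  })
  if (nrow(hits) == 0L) {
    hits <- tibble(protein_id = character(), start = integer(),
                   end = integer(), mismatches = numeric())
  }
  attr(hits, "unique") <- !any(!hits$protein_id %in% own_ids)
  hits
}

#' Sequence coverage of a protein by identified peptides
#'
#' Every occurrence of every peptide is located in the protein (exact
#' substring matches; a peptide absent from the protein is an error naming
#' the pair) and the percentage of residues covered by the union of matches
#' is returned.
#'
#' @param protein_seq Protein sequence.
#' @param peptides Character vector of peptide sequences.
#' @return Coverage percentage in `[0, 100]`.
#' @export
coverage <- function(protein_seq, peptides) {
  n <- nchar(protein_seq)
  covered <- logical(n)
  for (pep in peptides) {
    pos <- gregexpr(pep, protein_seq, fixed = TRUE)[[1]]
    if (pos[1] == -1L) {
      abort(sprintf("peptide '%s' not found in protein '%s'", pep,
                    substr(protein_seq, 1, 20)))
    }
    for (st in pos) covered[st:(st + nchar(pep) - 1L)] <- TRUE
  }
  100 * sum(covered) / n
}

#' Coverage bin labels
#'
#' @param pct Coverage percentages.
#' @return Factor with levels `">30%"`, `"10-30%"`, `"<10%"`.
#' @export
coverage_bin <- function(pct) {
  factor(ifelse(pct > 30, ">30%", ifelse(pct < 10, "<10%", "10-30%")),
         levels = c(">30%", "10-30%", "<10%"))
}

#' Cross-reference PSM ids against a reference-proteome search
#'
#' Validation step for non-coding candidates: the PSMs supporting them must
#' not have been assigned in the parallel searches against the reference
#' proteome. The check passes when the intersection is empty.
#'
#' @param candidate_psm_ids,reference_search_psm_ids Character vectors.
#' @return The intersection (empty on a passing check).
#' @export
cross_reference_psm_ids <- function(candidate_psm_ids,
                                    reference_search_psm_ids) {
  intersect(unique(candidate_psm_ids), unique(reference_search_psm_ids))
}

#' Append a totals row to a per-category table
#'
#' The totals row equals the column sums of all numeric columns; this is
#' asserted so that emitted tables can never disagree with their margins.
#'
#' @param tbl Per-category tibble; first column is the category label.
#' @param label Label of the totals row.
#' @return The tibble with a totals row appended.
#' @export
add_totals <- function(tbl, label = "Total") {
  num <- vapply(tbl, is.numeric, logical(1))
  totals <- tbl[1, ]
  totals[[1]] <- label
  for (nm in names(tbl)[num]) totals[[nm]] <- sum(tbl[[nm]])
  for (nm in names(tbl)[!num][-1]) totals[[nm]] <- NA
  out <- bind_rows(tbl, totals)
  stopifnot(all(vapply(names(tbl)[num], function(nm)
    isTRUE(all.equal(out[[nm]][nrow(out)], sum(tbl[[nm]]))), logical(1))))
  out
}

#' Aggregate sORF candidates into overview tables
#'
#' Produces the two standard report shapes: an overview table of per-category
#' sORF/PSM/peptide counts with the non-coding subset alongside, and a
#' validation-feature table over the non-coding candidates (homology,
#' MS/translation-efficiency/orthology evidence, transmembrane helices).
#' Flag columns that are absent are treated as all-`FALSE`.
#'
#' @param candidates Tibble with `protein_id`, `category`, `psm_count`,
#'   `peptide_count`, logical `non_coding`, and optional logical flag
#'   columns `conservation_hit`, `ms_evidence`, `te_evidence`, `orthology`,
#'   `tmh`.
#' @return A list with `table1` and `table2` tibbles, each ending in a
#'   totals row equal to its column sums.
#' @export
summary_tables <- function(candidates) {
  candidates <- as_tibble(candidates)
  for (nm in c("conservation_hit", "ms_evidence", "te_evidence",
               "orthology", "tmh")) {
    if (!nm %in% names(candidates)) candidates[[nm]] <- FALSE
  }
  cat_levels <- c("SWISS", "TrEMBL", "OpenProt_predicted",
                  "sORFs_org_predicted")
  candidates$category <- factor(candidates$category, levels = cat_levels)
  t1 <- candidates |>
    group_by(.data$category, .drop = FALSE) |>
    summarise(
      sorfs = n(),
      total_psms = sum(.data$psm_count),
      total_peptides = sum(.data$peptide_count),
      non_coding = sum(.data$non_coding),
      non_coding_psms = sum(.data$psm_count[.data$non_coding]),
      non_coding_peptides = sum(.data$peptide_count[.data$non_coding]),
      .groups = "drop"
    ) |>
    mutate(category = as.character(.data$category)) |>
    add_totals("Total sORFs")
  nc <- candidates[candidates$non_coding, ]
  t2 <- nc |>
    group_by(.data$category, .drop = FALSE) |>
    summarise(
      total = n(),
      blastp = sum(.data$conservation_hit),
      ms_evidence = sum(.data$ms_evidence),
      te_evidence = sum(.data$te_evidence),
      orthology = sum(.data$orthology),
      tmh = sum(.data$tmh),
      .groups = "drop"
    ) |>
    mutate(category = as.character(.data$category)) |>
    add_totals("Total")
  list(table1 = t1, table2 = t2)
}
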