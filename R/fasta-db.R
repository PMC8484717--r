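#' Sequence record tables
#'
#' Database entries are held in a tibble with one row per sequence: `id`,
#' `description`, `sequence` (uppercase amino acids), `source` (one of
#' `reference`, `openprot`, `sorfs_org`, `contaminant`, `decoy`), and optional
#' genomic metadata: `chrom`, `strand`, `block_starts`/`block_ends` (list
#' columns of 0-based half-open exon-block coordinates), `stop_coord`
#' (strand-aware 3'-most coding coordinate), `gene_id`, `gene_biotype`.
#'
#' @param id Character vector of record ids (unique within a database).
#' @param sequence Character vector of amino-acid sequences.
#' @param source Source tag, recycled; one of the values above.
#' @param description Optional descriptions.
#' @param chrom,strand,gene_id,gene_biotype Optional metadata vectors.
#' @param block_starts,block_ends Optional list columns of integer vectors
#'   (0-based half-open block coordinates, sorted, non-overlapping).
#' @return A `seq_records` tibble.
#' @export
seq_records <- function(id, sequence, source,
                        description = "",
                        chrom = NA_character_, strand = NA_character_,
                        block_starts = NULL, block_ends = NULL,
                        gene_id = NA_character_,
                        gene_biotype = NA_character_) {
  x <- tibble(
    id = as.character(id),
    description = as.character(description),
    sequence = toupper(as.character(sequence)),
    source = as.character(source),
    chrom = as.character(chrom),
    strand = as.character(strand),
    block_starts = block_starts %||% rep(list(NULL), length(id)),
    block_ends = block_ends %||% rep(list(NULL), length(id)),
    gene_id = as.character(gene_id),
    gene_biotype = as.character(gene_biotype)
  )
  x <- mutate(x, stop_coord = locus_stop_coord(.data$strand,
                                               .data$block_starts,
                                               .data$block_ends))
  validate_seq_records(x)
}

DB_SOURCES <- c("reference", "openprot", "sorfs_org", "contaminant", "decoy")

validate_seq_records <- function(x) {
  stopifnot(is.data.frame(x))
  bad_src <- setdiff(unique(x$source), DB_SOURCES)
  if (length(bad_src)) {
    abort(sprintf("unknown source tag(s): %s", paste(bad_src, collapse = ", ")))
  }
  if (any(nchar(x$sequence) < 1L)) abort("sequences must have length >= 1")
  if (any(grepl("[[:space:]-]", x$sequence))) {
    abort("sequences must not contain whitespace or gap characters")
  }
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "XU]"),
               x$sequence)
  if (any(bad)) {
    abort(sprintf("non amino-acid characters in sequence(s): %s",
                  paste(head(x$id[bad], 5), collapse = ", ")))
  }
  as_tibble(x)
}

# Strand-aware 3'-most coding coordinate of a locus: last block end - 1 on the
# plus strand, first block start on the minus strand (0-based half-open).
locus_stop_coord <- function(strand, block_starts, block_ends) {
  out <- mapply(function(s, bs, be) {
    if (is.null(bs) || length(bs) == 0L || is.na(s)) return(NA_real_)
    stopifnot(length(bs) == length(be), all(bs < be),
              !is.unsorted(bs, strictly = TRUE),
              all(utils::head(be, -1) <= utils::tail(bs, -1)))
    if (s == "+") be[length(be)] - 1 else bs[1]
  }, strand, block_starts, block_ends, USE.NAMES = FALSE)
  as.numeric(unlist(out) %||% numeric(0))
}

#' Read a protein FASTA file into a record table
#'
#' Headers are split at the first whitespace into `id` and `description`;
#' sequences are uppercased with line breaks removed. Malformed files (a
#' sequence line before any header, or a header with an empty sequence) raise
#' an error naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @param source Source tag recorded on every record.
#' @return A `seq_records` tibble.
#' @export
read_fasta <- function(path, source = "reference") {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) {
    return(seq_records(character(), character(), character()))
  }
  is_hdr <- startsWith(trimws(lines), ">")
  if (!is_hdr[nonempty[1]]) {
    abort(sprintf("malformed FASTA: sequence before any header at line %d",
                  nonempty[1]))
  }
  hdr_idx <- which(is_hdr)
  nseq <- vapply(seq_along(hdr_idx), function(i) {
    from <- hdr_idx[i] + 1L
    to <- if (i < length(hdr_idx)) hdr_idx[i + 1L] - 1L else length(lines)
    if (from > to) 0L else sum(nzchar(trimws(lines[from:to])))
  }, integer(1))
  if (any(nseq == 0L)) {
    abort(sprintf("malformed FASTA: entry with empty sequence at line %d",
                  hdr_idx[which(nseq == 0L)[1]]))
  }
  aas <- Biostrings::readAAStringSet(path)
  headers <- names(aas)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seq_records(id = id, sequence = as.character(aas), source = source,
              description = desc)
}

#' Write a record table as FASTA
#'
#' Headers follow the database dialect `>{source}|{id}|{gene_id}|{biotype}`
#' with the original description appended after a space; sequence lines are
#' wrapped at 60 characters.
#'
#' @param records A `seq_records` tibble.
#' @param path Output path.
#' @param dialect_headers Write the four-field header dialect (default);
#'   `FALSE` writes `>{id} {description}`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, dialect_headers = TRUE) {
  aas <- Biostrings::AAStringSet(records$sequence)
  if (dialect_headers) {
    hdr <- sprintf("%s|%s|%s|%s", records$source, records$id,
                   ifelse(is.na(records$gene_id), "", records$gene_id),
                   ifelse(is.na(records$gene_biotype), "",
                          records$gene_biotype))
  } else {
    hdr <- records$id
  }
  has_desc <- !is.na(records$description) & nzchar(records$description)
  names(aas) <- ifelse(has_desc, paste(hdr, records$description), hdr)
  Biostrings::writeXStringSet(aas, path, width = 60L)
  invisible(path)
}

#' Read a 6-column stranded BED file
#'
#' @param path Path to a BED file.
#' @return A tibble with `chrom`, `start`, `end` (0-based half-open),
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else NA_character_,
    score = if (!is.null(gr$score)) as.numeric(gr$score) else 0,
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Write stranded intervals as 6-column BED
#'
#' @param x A tibble with `chrom`, `start`, `end`, `strand` and optionally
#'   `name`, `score` columns (0-based half-open coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  out <- data.frame(
    chrom = x$chrom, start = x$start, end = x$end,
    name = if ("name" %in% names(x)) x$name else ".",
    score = if ("score" %in% names(x)) x$score else 0,
    strand = x$strand
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Keep only the longest predicted sORF per stop position
#'
#' Predicted sORFs sharing a stop codon are redundant nested proposals; only
#' the longest is kept. Records are grouped by `(chrom, strand, stop_coord)`;
#' within a group ties on length are broken by lexicographically smallest
#' sequence, then smallest id, so the result is deterministic.
#'
#' @param records A `seq_records` tibble in which every record has a locus.
#' @return The surviving records, original order of first appearance.
#' @export
select_longest_per_stop <- function(records) {
  no_locus <- is.na(records$stop_coord) | is.na(records$chrom) |
    is.na(records$strand)
  if (any(no_locus)) {
    abort(sprintf("records without locus: %s",
                  paste(head(records$id[no_locus], 10), collapse = ", ")))
  }
  records |>
    mutate(.len = nchar(.data$sequence), .ord = row_number()) |>
    group_by(.data$chrom, .data$strand, .data$stop_coord) |>
    arrange(dplyr::desc(.data$.len), .data$sequence, .data$id,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$.ord) |>
    select(-".len", -".ord")
}

#' Drop single-exon sORFs overlapping annotated coding exons
#'
#' A predicted sORF is removed iff it has exactly one exon block and that
#' block overlaps (>= 1 nt, same chromosome and strand) any annotated
#' protein-coding exon. Multi-block sORFs are always retained.
#'
#' @param sorfs A `seq_records` tibble with loci.
#' @param coding_exons A tibble of stranded intervals (`chrom`, `start`,
#'   `end`, `strand`; 0-based half-open), e.g. from [read_bed()].
#' @return The retained records.
#' @export
drop_single_exon_coding_overlaps <- function(sorfs, coding_exons) {
  if (nrow(sorfs) == 0L || is.null(coding_exons) || nrow(coding_exons) == 0L) {
    return(sorfs)
  }
  nblocks <- lengths(sorfs$block_starts)
  single <- which(nblocks == 1L)
  if (length(single) == 0L) return(sorfs)
  sorf_gr <- GenomicRanges::GRanges(
    seqnames = sorfs$chrom[single],
    ranges = IRanges::IRanges(
      start = vapply(sorfs$block_starts[single], `[[`, numeric(1), 1L) + 1,
      end = vapply(sorfs$block_ends[single], `[[`, numeric(1), 1L)
    ),
    strand = sorfs$strand[single]
  )
  exon_gr <- GenomicRanges::GRanges(
    seqnames = coding_exons$chrom,
    ranges = IRanges::IRanges(start = coding_exons$start + 1,
                              end = coding_exons$end),
    strand = coding_exons$strand
  )
  hits <- GenomicRanges::findOverlaps(sorf_gr, exon_gr, ignore.strand = FALSE)
  drop <- single[unique(S4Vectors::queryHits(hits))]
  if (length(drop)) sorfs[-drop, ] else sorfs
}

#' Collapse records with identical sequences
#'
#' One record survives per distinct sequence. The survivor is chosen by
#' source precedence `reference > openprot > sorfs_org > contaminant`, then
#' smallest id; absorbed ids are appended to the survivor's description and
#' returned in a merge map. Idempotent.
#'
#' @param records A `seq_records` tibble.
#' @return A list with `records` (deduplicated tibble) and `merge_map`
#'   (tibble of `survivor_id`, `absorbed_id`).
#' @export
dedupe_identical <- function(records) {
  prec <- match(records$source, c("reference", "openprot", "sorfs_org",
                                  "contaminant", "decoy"))
  ord <- order(records$sequence, prec, records$id)
  x <- records[ord, ]
  grp <- cumsum(!duplicated(x$sequence))
  keep_idx <- which(!duplicated(grp))
  absorbed <- x[duplicated(grp), c("id", "sequence")]
  survivors <- x[keep_idx, ]
  merge_map <- tibble(
    survivor_id = survivors$id[match(absorbed$sequence, survivors$sequence)],
    absorbed_id = absorbed$id
  )
  if (nrow(merge_map)) {
    add <- merge_map |>
      group_by(.data$survivor_id) |>
      summarise(.merged = paste(.data$absorbed_id, collapse = ","))
    i <- match(add$survivor_id, survivors$id)
    survivors$description[i] <- trimws(paste0(
      survivors$description[i], " merged:", add$.merged))
  }
  survivors <- survivors[order(match(survivors$id, records$id)), ]
  list(records = survivors, merge_map = merge_map)
}

#' Remove predicted sequences identical to a reference sequence
#'
#' Predicted records whose full sequence exactly matches any reference
#' sequence are dropped. With `containment = TRUE`, predicted sequences that
#' occur as substrings of a reference sequence are dropped as well (a more
#' aggressive reading that risks removing genuinely distinct proteoforms,
#' hence off by default).
#'
#' @param predicted,reference `seq_records` tibbles.
#' @param containment Also remove proper-substring matches.
#' @return The surviving predicted records; the number removed is attached as
#'   attribute `n_removed` and reported via a message.
#' @export
exclude_reference_identical <- function(predicted, reference,
                                        containment = FALSE) {
  drop <- predicted$sequence %in% unique(reference$sequence)
  if (containment && nrow(predicted)) {
    haystack <- paste(unique(reference$sequence), collapse = "#")
    drop <- drop | stringr::str_detect(
      haystack, stringr::fixed(predicted$sequence))
  }
  out <- predicted[!drop, ]
  inform(sprintf("excluded %d predicted sequence(s) identical to reference",
                 sum(drop)))
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Append reversed-sequence decoys
#'
#' One decoy per target record, with the fully reversed sequence and the id
#' prefixed. Reversal is an involution; palindromic decoys (identical to
#' their target) are allowed but flagged with a message.
#'
#' @param records Target `seq_records` (must not already contain decoys).
#' @param prefix Decoy id prefix.
#' @return The decoy records (same number of rows as `records`).
#' @export
generate_decoys <- function(records, prefix = "DECOY_") {
  if (any(startsWith(records$id, prefix)) | any(records$source == "decoy")) {
    abort("input already contains decoy records or prefix-matching ids")
  }
  rev_seq <- as.character(
    Biostrings::reverse(Biostrings::AAStringSet(records$sequence)))
  pal <- rev_seq == records$sequence
  if (any(pal)) {
    inform(sprintf("%d palindromic decoy(s): %s", sum(pal),
                   paste(head(records$id[pal], 5), collapse = ", ")))
  }
  dec <- records
  dec$id <- paste0(prefix, records$id)
  dec$sequence <- rev_seq
  dec$source <- "decoy"
  dec
}

#' Build the concatenated proteogenomic search database
#'
#' Runs the full pipeline: per-source deduplication; longest-per-stop
#' selection and single-exon coding-overlap removal for ribosome-profiling
#' predictions (when loci are present); cross-source deduplication of the two
#' predicted sets; removal of predictions identical to reference entries;
#' concatenation of reference + predicted + contaminants; reversed-decoy
#' generation. The composition report is computed on the three pre-decoy,
#' pre-contaminant sequence sets.
#'
#' @param reference,openprot,sorfs_org,contaminants `seq_records` tibbles
#'   (predicted and contaminant sets may be empty, `NULL` treated as empty).
#' @param coding_exons Optional coding-exon intervals for the single-exon
#'   filter (see [drop_single_exon_coding_overlaps()]).
#' @param decoy_prefix Decoy id prefix.
#' @param containment Passed to [exclude_reference_identical()].
#' @param out_fasta Optional path: write the final database as FASTA.
#' @return A list with `records` (targets + decoys), `composition`
#'   (a [composition_report()]), and `stage_counts` (a tibble of record
#'   counts after each stage).
#' @export
build_database <- function(reference, openprot = NULL, sorfs_org = NULL,
                           contaminants = NULL, coding_exons = NULL,
                           decoy_prefix = "DECOY_", containment = FALSE,
                           out_fasta = NULL) {
  empty <- seq_records(character(), character(), character())
  openprot <- openprot %||% empty
  sorfs_org <- sorfs_org %||% empty
  contaminants <- contaminants %||% empty

  reference <- dedupe_identical(reference)$records
  openprot <- dedupe_identical(openprot)$records
  sorfs_org <- dedupe_identical(sorfs_org)$records
  contaminants <- dedupe_identical(contaminants)$records
  counts <- list(per_source_dedup = nrow(reference) + nrow(openprot) +
                   nrow(sorfs_org) + nrow(contaminants))

  if (nrow(sorfs_org) && all(!is.na(sorfs_org$stop_coord))) {
    sorfs_org <- select_longest_per_stop(sorfs_org)
    sorfs_org <- drop_single_exon_coding_overlaps(sorfs_org, coding_exons)
  }
  counts$sorf_filtered <- nrow(sorfs_org)

  composition <- compute_composition(reference$sequence, openprot$sequence,
                                     sorfs_org$sequence)

  predicted <- dedupe_identical(bind_rows(openprot, sorfs_org))$records
  counts$predicted_dedup <- nrow(predicted)
  predicted <- exclude_reference_identical(predicted, reference,
                                           containment = containment)
  counts$predicted_vs_reference <- nrow(predicted)

  targets <- bind_rows(reference, predicted, contaminants)
  if (anyDuplicated(targets$id)) {
    abort("duplicate ids across sources; ids must be unique in the database")
  }
  decoys <- generate_decoys(targets, prefix = decoy_prefix)
  records <- bind_rows(targets, decoys)
  counts$targets <- nrow(targets)
  counts$final_with_decoys <- nrow(records)

  if (!is.null(out_fasta)) write_fasta(records, out_fasta)
  list(records = records, composition = composition,
       stage_counts = tibble(stage = names(counts),
                             n = unlist(counts, use.names = FALSE)))
}
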