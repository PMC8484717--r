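test_that("FASTA parsing normalises case, splits headers, handles edge files", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">sp|P1|X some desc", "mkv", ">B", "ACDE", "FGHI"), f)
  recs <- read_fasta(f, source = "reference")
  expect_equal(recs$id, c("sp|P1|X", "B"))
  expect_equal(recs$description, c("some desc", ""))
  expect_equal(recs$sequence, c("MKV", "ACDEFGHI"))

  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(), empty)
  expect_equal(nrow(read_fasta(empty)), 0L)

  bad1 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c("MKV", ">A", "ACD"), bad1)
  expect_error(read_fasta(bad1), "line 1")
  bad2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">A", "MKV", ">EMPTY", ">B", "ACD"), bad2)
  expect_error(read_fasta(bad2), "line 3")
})

test_that("FASTA write/read round trip is lossless and 60-char wrapped", {
  recs <- seq_records(
    id = c("A1", "B2"),
    sequence = c(paste(rep("ACDEFGHIKL", 13), collapse = ""), "MKV"),
    source = c("openprot", "reference"),
    description = c("first entry", ""))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, f, dialect_headers = FALSE)
  lines <- readLines(f)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
  back <- read_fasta(f, source = "openprot")
  expect_equal(back$sequence, recs$sequence)
  expect_equal(back$id, recs$id)
  # dialect headers carry source/gene metadata
  write_fasta(recs, f)
  expect_true(startsWith(readLines(f)[1], ">openprot|A1||"))
})

test_that("longest-per-stop keeps one survivor per stop with deterministic ties", {
  mk <- function(id, seq, stop, strand = "+") {
    seq_records(id = id, sequence = seq, source = "sorfs_org",
                chrom = "chr1", strand = strand,
                block_starts = list(if (strand == "+") stop + 1 - 3 * nchar(seq)
                                    else stop),
                block_ends = list(if (strand == "+") stop + 1
                                  else stop + 3 * nchar(seq)))
  }
  two <- dplyr::bind_rows(mk("a", strrep("A", 30), 999),
                          mk("b", strrep("G", 45), 999))
  expect_equal(select_longest_per_stop(two)$id, "b")

  distinct <- dplyr::bind_rows(mk("a", "MKVA", 999), mk("b", "MKVA", 500))
  expect_equal(nrow(select_longest_per_stop(distinct)), 2L)

  # equal length ties: lexicographically smallest sequence, then smallest id
  ties <- dplyr::bind_rows(mk("z", "MKVC", 999), mk("a", "MKVA", 999),
                           mk("b", "MKVA", 999))
  expect_equal(select_longest_per_stop(ties)$id, "a")

  no_locus <- seq_records("x", "MKV", "sorfs_org")
  expect_error(select_longest_per_stop(no_locus), "x")
})

test_that("longest-per-stop equals the brute-force group maximum on random input", {
  withr::local_seed(421)
  n <- 50
  stops <- sample(c(rep(1000 * (1:10), each = 2), sample(50000, 30)))
  recs <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    L <- sample(10:40, 1)
    s <- random_peptide(c(L, L))
    strand <- "+"
    seq_records(id = sprintf("r%02d", i), sequence = s, source = "sorfs_org",
                chrom = "chr1", strand = strand,
                block_starts = list(stops[i] + 1 - 3 * L),
                block_ends = list(stops[i] + 1))
  }))
  got <- select_longest_per_stop(recs)
  # oracle: split by key, pick max length / min sequence / min id
  keys <- paste(recs$chrom, recs$strand, recs$stop_coord)
  expected <- unlist(lapply(split(seq_len(n), keys), function(idx) {
    g <- recs[idx, ]
    g$id[order(-nchar(g$sequence), g$sequence, g$id)[1]]
  }))
  expect_setequal(got$id, expected)
  expect_false(any(duplicated(paste(got$chrom, got$strand, got$stop_coord))))
  # every survivor is at least as long as everyone in its group
  for (k in unique(keys)) {
    g <- recs[keys == k, ]
    expect_gte(nchar(got$sequence[got$id %in% g$id]), max(nchar(g$sequence)))
  }
})

test_that("single-exon coding overlaps are dropped, multi-exon retained", {
  single <- seq_records("s1", strrep("A", 10), "sorfs_org", chrom = "chr1",
                        strand = "+", block_starts = list(100),
                        block_ends = list(130))
  multi <- seq_records("m1", strrep("G", 10), "sorfs_org", chrom = "chr1",
                       strand = "+", block_starts = list(c(100, 200)),
                       block_ends = list(c(115, 215)))
  exons <- tibble::tibble(chrom = "chr1", start = 120, end = 300,
                          strand = "+")
  both <- dplyr::bind_rows(single, multi)
  expect_equal(drop_single_exon_coding_overlaps(both, exons)$id, "m1")
  # strand-specific: opposite-strand exon does not remove
  exons_minus <- dplyr::mutate(exons, strand = "-")
  expect_equal(nrow(drop_single_exon_coding_overlaps(both, exons_minus)), 2L)
  # empty exon set: identity
  expect_equal(nrow(drop_single_exon_coding_overlaps(both, NULL)), 2L)
})

test_that("single-exon filter equals the O(n*m) overlap oracle on random input", {
  withr::local_seed(99)
  sorfs <- dplyr::bind_rows(lapply(1:100, function(i) {
    nb <- sample(1:2, 1)
    st <- sort(sample(10000, nb))
    seq_records(id = sprintf("s%03d", i), sequence = random_peptide(),
                source = "sorfs_org", chrom = sample(c("chr1", "chr2"), 1),
                strand = sample(c("+", "-"), 1),
                block_starts = list(st), block_ends = list(st + 20))
  }))
  exons <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 20, replace = TRUE),
    start = sample(10000, 20), strand = sample(c("+", "-"), 20, TRUE))
  exons$end <- exons$start + sample(30:200, 20, TRUE)
  got <- drop_single_exon_coding_overlaps(sorfs, exons)
  expect_equal(got$id, oracle_single_exon_drop(sorfs, exons))
})

test_that("deduplication keeps one record per sequence by source precedence", {
  recs <- seq_records(
    id = c("op1", "srf1", "ref1", "solo"),
    sequence = c("MKVLE", "MKVLE", "MKVLE", "ACDEF"),
    source = c("openprot", "sorfs_org", "reference", "contaminant"))
  out <- dedupe_identical(recs)
  expect_equal(sort(out$records$id), c("ref1", "solo"))
  expect_equal(sort(out$merge_map$absorbed_id), c("op1", "srf1"))
  expect_match(out$records$description[out$records$id == "ref1"], "merged:")
  # openprot beats sorfs_org when no reference present
  two <- recs[1:2, ]
  expect_equal(dedupe_identical(two)$records$id, "op1")
  # identity on all-distinct input, and idempotence
  distinct_in <- seq_records(c("a", "b"), c("MKV", "ACD"), "reference")
  expect_equal(dedupe_identical(distinct_in)$records$sequence,
               distinct_in$sequence)
  again <- dedupe_identical(out$records)
  expect_equal(again$records$id, out$records$id)
  expect_equal(nrow(again$merge_map), 0L)
})

test_that("dedup recovers set cardinality on input with planted duplicates", {
  withr::local_seed(7)
  base <- replicate(30, random_peptide())
  seqs <- c(base, sample(base, 15, replace = TRUE))
  recs <- seq_records(id = sprintf("r%02d", seq_along(seqs)), sequence = seqs,
                      source = sample(c("openprot", "sorfs_org"),
                                      length(seqs), TRUE))
  out <- dedupe_identical(recs)
  expect_equal(nrow(out$records), length(unique(seqs)))
  expect_equal(nrow(out$merge_map), length(seqs) - length(unique(seqs)))
})

test_that("reference-identical predictions are excluded, substrings retained", {
  ref <- seq_records("R1", "MKVLEACDEF", "reference")
  pred <- seq_records(c("p1", "p2", "p3"),
                      c("MKVLEACDEF", "KVLEA", "WWWWW"), "openprot")
  out <- suppressMessages(exclude_reference_identical(pred, ref))
  expect_setequal(out$id, c("p2", "p3"))
  expect_equal(attr(out, "n_removed"), 1L)
  # containment mode also removes the substring
  out2 <- suppressMessages(
    exclude_reference_identical(pred, ref, containment = TRUE))
  expect_equal(out2$id, "p3")
  # random sets: survivors equal the set difference
  withr::local_seed(13)
  rs <- unique(replicate(40, random_peptide()))
  ref2 <- seq_records(paste0("R", 1:15), rs[1:15], "reference")
  pr2 <- seq_records(paste0("P", 1:30), rs[6:35], "openprot")
  got <- suppressMessages(exclude_reference_identical(pr2, ref2))
  expect_setequal(got$sequence, setdiff(rs[6:35], rs[1:15]))
})

test_that("decoy generation reverses sequences, preserves counts, is an involution", {
  recs <- seq_records(c("a", "b", "c"), c("MKVLE", "M", "QM"), "reference")
  dec <- suppressMessages(generate_decoys(recs))
  expect_equal(dec$sequence, c("ELVKM", "M", "MQ"))
  expect_equal(dec$id, paste0("DECOY_", recs$id))
  expect_true(all(dec$source == "decoy"))
  expect_equal(nrow(dec), nrow(recs))
  # involution: reversing the decoys recovers the targets
  rerev <- suppressMessages(generate_decoys(
    dplyr::mutate(dec, id = sub("^DECOY_", "", id), source = "reference"),
    prefix = "X_"))
  expect_equal(rerev$sequence, recs$sequence)
  # refuses input that already contains decoys
  expect_error(suppressMessages(generate_decoys(dec)), "decoy")
})

test_that("build_database runs the staged pipeline with decoy parity", {
  ref <- seq_records(paste0("R", 1:3), c("MKVLEACDEF", "WWPPWWPP", "GGHHGGHH"),
                     "reference")
  sim <- simulate_sorf_predictions(n_sorfs = 20, dup_stop_groups = 3,
                                   single_exon_planted = 2, seed = 5)
  openprot <- seq_records(c("IP1", "IP2", "IP3"),
                          c("MKVLEACDEF", "AAACCCDDD", "EEEFFFGGG"),
                          "openprot")
  crap <- seq_records("CON1", "PPPQQQRRR", "contaminant")
  db <- suppressMessages(build_database(
    ref, openprot, sim$sorfs, crap, coding_exons = sim$coding_exons))
  n_sorf_final <- length(sim$expected_final)
  # stage bookkeeping matches the simulator's planted ground truth
  sc <- tibble::deframe(db$stage_counts)
  expect_equal(unname(sc["sorf_filtered"]), n_sorf_final)
  # IP1 identical to R1 is excluded
  expect_equal(unname(sc["predicted_vs_reference"]), n_sorf_final + 2)
  expect_equal(unname(sc["targets"]), 3 + n_sorf_final + 2 + 1)
  # decoy parity
  expect_equal(nrow(db$records), 2 * sc[["targets"]])
  expect_equal(sum(db$records$source == "decoy"), sc[["targets"]])
  # composition excludes contaminants and decoys
  expect_equal(db$composition$total,
               length(unique(c(ref$sequence, openprot$sequence,
                               sim$sorfs$sequence[sim$sorfs$id %in%
                                                    sim$expected_final]))))
})

test_that("build_database without predictions is reference + contaminants + decoys", {
  ref <- seq_records(c("R1", "R2"), c("MKVLE", "ACDEF"), "reference")
  crap <- seq_records("CON1", "PPPQQQ", "contaminant")
  db <- suppressMessages(build_database(ref, NULL, NULL, crap))
  expect_equal(nrow(db$records), 2 * 3)
  expect_setequal(db$records$source[db$records$source != "decoy"],
                  c("reference", "contaminant"))
})

test_that("rebuilding from a built database's targets is a fixed point", {
  ref <- seq_records(paste0("R", 1:4),
                     c("MKVLEACDEF", "WWPPWWPP", "GGHHGGHH", "LLLMMMNNN"),
                     "reference")
  openprot <- seq_records(c("IP1", "IP2"), c("AAACCCDDD", "EEEFFFGGG"),
                          "openprot")
  db1 <- suppressMessages(build_database(ref, openprot))
  targets <- db1$records[db1$records$source != "decoy", ]
  db2 <- suppressMessages(build_database(
    targets[targets$source == "reference", ],
    targets[targets$source == "openprot", ]))
  t2 <- db2$records[db2$records$source != "decoy", ]
  expect_equal(sort(t2$sequence), sort(targets$sequence))
  expect_equal(sort(t2$id), sort(targets$id))
})

test_that("BED round trip preserves stranded half-open intervals", {
  x <- tibble::tibble(chrom = c("chr1", "chr2"), start = c(100, 0),
                      end = c(150, 30), name = c("a", "b"), score = c(0, 0),
                      strand = c("+", "-"))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, f)
  back <- read_bed(f)
  expect_equal(back$start, x$start)
  expect_equal(back$end, x$end)
  expect_equal(back$strand, x$strand)
})
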