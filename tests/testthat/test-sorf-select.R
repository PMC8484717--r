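test_that("small-protein filter has an inclusive boundary", {
  prot <- tibble::tibble(protein_id = c("a", "b", "c"),
                         length = c(100, 101, 50))
  kept <- filter_small(prot)
  expect_setequal(kept$protein_id, c("a", "c"))
  # lengths derived from sequences, random input vs comprehension oracle
  withr::local_seed(4)
  p2 <- tibble::tibble(protein_id = sprintf("p%02d", 1:40),
                       sequence = replicate(40, random_peptide(c(80, 120))))
  expect_equal(filter_small(p2)$protein_id,
               p2$protein_id[nchar(p2$sequence) <= 100])
})

test_that("category assignment maps source and header evidence", {
  recs <- seq_records(
    id = c("sp|P1|X", "tr|Q1|Y", "IP_001", "SORF007", "IP_002"),
    sequence = rep("MKVLEACD", 5),
    source = c("reference", "reference", "openprot", "sorfs_org",
               "openprot"),
    description = c("", "", "", "", "cross-ref sp|P9|Z"))
  expect_equal(assign_category(recs),
               c("SWISS", "TrEMBL", "OpenProt_predicted",
                 "sORFs_org_predicted", "SWISS"))
  bad <- seq_records("x", "MKV", "contaminant")
  expect_error(assign_category(bad), "categorise")
})

test_that("non-coding selection excludes protein-coding genes at gene level", {
  cand <- tibble::tibble(
    protein_id = paste0("p", 1:5),
    gene_id = c("g1", "g2", "g3", "g4", "g5"))
  bt <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    biotype = c("lncRNA", "protein_coding", "TEC", "pseudogene"))
  out <- suppressWarnings(noncoding_filter(cand, bt))
  expect_setequal(out$protein_id, c("p1", "p3", "p4", "p5"))
  # g5 has no biotype: retained but flagged
  expect_true(out$biotype_missing[out$protein_id == "p5"])
  expect_warning(noncoding_filter(cand, bt), "without gene biotype")
  # allowlisted protein-coding genes are retained
  out2 <- suppressWarnings(noncoding_filter(cand, bt, allowlist = "g2"))
  expect_true("p2" %in% out2$protein_id)
})

test_that("non-coding filter recovers planted per-biotype counts", {
  cand <- tibble::tibble(
    protein_id = sprintf("c%02d", 1:60),
    gene_id = sprintf("g%02d", 1:60),
    gene_biotype = c(rep("lncRNA", 17), rep("TEC", 9),
                     rep("pseudogene", 14), rep("protein_coding", 20)))
  allow <- sprintf("g%02d", 47:50) # four predicted genes kept by curation
  out <- noncoding_filter(cand, allowlist = allow)
  expect_equal(nrow(out), 17 + 9 + 14 + 4)
  # order-independence with the small-protein filter
  cand$length <- rep(c(50, 150), 30)
  a <- noncoding_filter(filter_small(cand), allowlist = allow)
  b <- filter_small(noncoding_filter(cand, allowlist = allow))
  expect_equal(a, b)
})

test_that("uniqueness scan finds exact and near-identical tag hits", {
  prots <- c(A = "MMMMKVLEACDFMMMM", B = "WWWWKVLEACDFWWWW",
             C = "GGGGGGGGGGGG")
  hits <- uniqueness_scan("KVLEACDF", prots, max_mismatches = 0)
  expect_setequal(hits$protein_id, c("A", "B"))
  expect_false(attr(hits, "unique"))
  # with the tag's own protein excluded it is still non-unique
  hits_own <- uniqueness_scan("KVLEACDF", prots, own_ids = "A")
  expect_false(attr(hits_own, "unique"))
  # 1-mismatch copy visible only at max_mismatches >= 1
  prots2 <- c(A = "MMMMKVLEACDFMMMM", D = "HHHHKVLEACEFHHHH")
  h0 <- uniqueness_scan("KVLEACDF", prots2, max_mismatches = 0)
  expect_equal(h0$protein_id, "A")
  h1 <- uniqueness_scan("KVLEACDF", prots2, max_mismatches = 1)
  expect_setequal(h1$protein_id, c("A", "D"))
  expect_equal(h1$mismatches[h1$protein_id == "D"], 1)
  expect_error(uniqueness_scan("SHORT", prots), "shorter than 8")
})

test_that("uniqueness scan equals the exhaustive window oracle", {
  withr::local_seed(272)
  for (rep in 1:3) {
    prots <- setNames(replicate(15, random_peptide(c(30, 60))),
                      paste0("prot", 1:15))
    # plant the tag and a 1-mismatch variant
    tag <- random_peptide(c(10, 10))
    variant <- tag
    substr(variant, 5, 5) <- if (substr(tag, 5, 5) == "A") "G" else "A"
    prots[1] <- paste0(prots[1], tag)
    prots[2] <- paste0(variant, prots[2])
    for (mm in 0:1) {
      got <- uniqueness_scan(tag, prots, max_mismatches = mm)
      exp <- oracle_tag_scan(tag, prots, mm)
      expect_equal(nrow(got), nrow(exp))
      expect_setequal(paste(got$protein_id, got$start, got$mismatches),
                      paste(exp$protein_id, exp$start, exp$mismatches))
    }
  }
})

test_that("coverage unions peptide positions, errors on absent peptides", {
  prot <- strrep("A", 25)
  expect_equal(coverage(paste0(prot, strrep("G", 25)), prot), 50.0)
  # overlapping peptides 1-20 and 11-30 of a 100-aa protein cover 30%
  prot2 <- paste(c(strrep("K", 10), strrep("V", 10), strrep("W", 10),
                   strrep("H", 70)), collapse = "")
  expect_equal(coverage(prot2, c(substr(prot2, 1, 20),
                                 substr(prot2, 11, 30))), 30.0)
  # full-length peptide covers 100%
  expect_equal(coverage("MKVLEACD", "MKVLEACD"), 100.0)
  expect_error(coverage("MKVLEACD", "YYY"), "not found")
  # random placements vs a position-set oracle
  withr::local_seed(31)
  for (rep in 1:5) {
    prot3 <- random_peptide(c(60, 80))
    starts <- sample(nchar(prot3) - 12, 4)
    peps <- vapply(starts, function(s) substr(prot3, s, s + 11),
                   character(1))
    mask <- logical(nchar(prot3))
    for (pep in peps) {
      hits <- gregexpr(pep, prot3, fixed = TRUE)[[1]]
      for (h in hits) mask[h:(h + nchar(pep) - 1)] <- TRUE
    }
    expect_equal(coverage(prot3, peps), 100 * mean(mask))
  }
  expect_equal(as.character(coverage_bin(c(35, 20, 5, 10, 30))),
               c(">30%", "10-30%", "<10%", "10-30%", "10-30%"))
})

test_that("candidate PSM ids are cross-referenced against reference searches", {
  expect_equal(cross_reference_psm_ids(c("a", "b"), c("c", "d")),
               character(0))
  expect_equal(cross_reference_psm_ids(c("a", "b"), c("b", "z")), "b")
  withr::local_seed(5)
  a <- sample(letters, 10); b <- sample(letters, 10)
  expect_setequal(cross_reference_psm_ids(a, b), intersect(a, b))
})

test_that("summary tables aggregate planted per-category counts with exact totals", {
  # per-category identification structure of a small-protein discovery run
  counts <- tibble::tibble(
    category = c(rep("SWISS", 24), rep("TrEMBL", 16),
                 rep("OpenProt_predicted", 105),
                 rep("sORFs_org_predicted", 22)))
  psm_per <- c(SWISS = 1235, TrEMBL = 1989, OpenProt_predicted = 128,
               sORFs_org_predicted = 45)
  pep_per <- c(SWISS = 516, TrEMBL = 562, OpenProt_predicted = 123,
               sORFs_org_predicted = 41)
  nc_per <- c(SWISS = 2, TrEMBL = 2, OpenProt_predicted = 44,
              sORFs_org_predicted = 0)
  cand <- counts |>
    dplyr::group_by(category) |>
    dplyr::mutate(
      protein_id = paste0(category, dplyr::row_number()),
      non_coding = dplyr::row_number() <= nc_per[category[1]],
      # spread the per-category PSM/peptide totals over members
      psm_count = {
        n <- dplyr::n(); tot <- psm_per[category[1]]
        base <- tot %/% n; extra <- tot %% n
        base + (dplyr::row_number() <= extra)
      },
      peptide_count = {
        n <- dplyr::n(); tot <- pep_per[category[1]]
        base <- tot %/% n; extra <- tot %% n
        base + (dplyr::row_number() <= extra)
      }) |>
    dplyr::ungroup()
  tabs <- summary_tables(cand)
  t1 <- tabs$table1
  last <- nrow(t1)
  expect_equal(t1$sorfs[last], 167)
  expect_equal(t1$total_psms[last], 3397)
  expect_equal(t1$total_peptides[last], 1242)
  expect_equal(t1$non_coding[last], 48)
  expect_equal(t1$sorfs[1:4], c(24, 16, 105, 22))
  # totals row equals column sums on every numeric column
  for (nm in names(t1)[-1]) {
    expect_equal(t1[[nm]][last], sum(t1[[nm]][-last]))
  }
})

test_that("validation-feature table recovers planted flag counts", {
  cand <- tibble::tibble(
    category = c(rep("SWISS", 2), rep("TrEMBL", 4),
                 rep("OpenProt_predicted", 78)),
    protein_id = paste0("c", 1:84),
    psm_count = 1, peptide_count = 1, non_coding = TRUE,
    conservation_hit = c(rep(TRUE, 2), rep(TRUE, 4),
                         rep(c(TRUE, FALSE), c(31, 47))),
    tmh = c(rep(FALSE, 6), rep(c(TRUE, FALSE), c(9, 69))))
  t2 <- summary_tables(cand)$table2
  last <- nrow(t2)
  expect_equal(t2$total[last], 84)
  expect_equal(t2$blastp[last], 37)
  expect_equal(t2$tmh[last], 9)
  # empty candidate list: all-zero tables
  t0 <- summary_tables(cand[0, ])
  expect_true(all(t0$table1$sorfs == 0))
  expect_true(all(t0$table2$total == 0))
})

test_that("biotype tables and allowlists are read and validated", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(gene_id = "g1", gene_name = "G1",
                                  biotype = "lncRNA"), f)
  expect_equal(read_biotypes(f)$biotype, "lncRNA")
  readr::write_tsv(tibble::tibble(gene_id = "g1"), f)
  expect_error(read_biotypes(f), "missing column")
  a <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "g1", "", "g2"), a)
  expect_equal(read_allowlist(a), c("g1", "g2"))
})
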