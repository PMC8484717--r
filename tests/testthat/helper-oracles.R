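# Independent brute-force oracles used by the derived-value tests. These are
# deliberately naive (loops, exhaustive scans) and share no code with the
# implementation paths they check.

# q-values by exhaustive threshold enumeration (assumes no tied scores).
oracle_qvalues <- function(scores, is_decoy, plus_one = FALSE) {
  fdr_at <- function(s) {
    d <- sum(is_decoy & scores >= s)
    t <- sum(!is_decoy & scores >= s)
    (d + as.numeric(plus_one)) / max(t, 1)
  }
  vapply(scores, function(s) {
    min(1, min(vapply(scores[scores <= s], fdr_at, numeric(1))))
  }, numeric(1))
}

# nearest-peak matching by exhaustive scan
oracle_match_peaks <- function(peaks, theo, tol) {
  vapply(theo, function(t) {
    d <- abs(peaks$mz - t)
    if (!length(d) || min(d) > tol) return(0)
    cand <- which(d == min(d))
    max(peaks$intensity[cand])
  }, numeric(1))
}

# interval overlap by O(n*m) scan over single-block sORFs
oracle_single_exon_drop <- function(sorfs, exons) {
  drop <- vapply(seq_len(nrow(sorfs)), function(i) {
    bs <- sorfs$block_starts[[i]]; be <- sorfs$block_ends[[i]]
    if (length(bs) != 1L) return(FALSE)
    any(vapply(seq_len(nrow(exons)), function(j) {
      exons$chrom[j] == sorfs$chrom[i] &&
        exons$strand[j] == sorfs$strand[i] &&
        bs[1] < exons$end[j] && exons$start[j] < be[1]
    }, logical(1)))
  }, logical(1))
  sorfs$id[!drop]
}

# windowed Hamming scan over a named character vector of proteins
oracle_tag_scan <- function(tag, seqs, max_mm) {
  k <- nchar(tag)
  tagv <- strsplit(tag, "")[[1]]
  out <- list()
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    if (nchar(s) < k) next
    for (st in seq_len(nchar(s) - k + 1L)) {
      win <- strsplit(substring(s, st, st + k - 1L), "")[[1]]
      mm <- sum(win != tagv)
      if (mm <= max_mm) {
        out[[length(out) + 1L]] <- data.frame(protein_id = nm, start = st,
                                              mismatches = mm)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(protein_id = character(), start = integer(),
               mismatches = numeric())
}

# textbook Pearson correlation from the definition
oracle_pcc <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  num / den
}

random_peptide <- function(len_range = c(8, 30)) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  len <- len_range[1] + sample.int(len_range[2] - len_range[1] + 1L, 1) - 1L
  paste(sample(aas, len, replace = TRUE), collapse = "")
}

# random peptidoform with admissible modifications
random_peptidoform <- function(len_range = c(8, 30)) {
  s <- random_peptide(len_range)
  mpos <- which(strsplit(s, "")[[1]] == "M")
  peptidoform(
    s,
    amidated = runif(1) < 0.3,
    oxidized = mpos[runif(length(mpos)) < 0.5],
    pyro_glu = substring(s, 1, 1) %in% c("Q", "E") && runif(1) < 0.5
  )
}
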