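# Seed-deterministic generators of synthetic inputs with known ground truth.
# Each generator restores the caller's RNG state and is a pure function of
# its arguments, so reruns with the same seed are byte-stable.

random_aa_seqs <- function(n, len_range, distinct = TRUE, max_tries = 50L) {
  draw <- function(k) {
    lens <- len_range[1] +
      sample.int(len_range[2] - len_range[1] + 1L, k, replace = TRUE) - 1L
    vapply(lens, function(L)
      paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = ""),
      character(1))
  }
  out <- draw(n)
  tries <- 0L
  while (distinct && anyDuplicated(out) && tries < max_tries) {
    dup <- which(duplicated(out))
    out[dup] <- draw(length(dup))
    tries <- tries + 1L
  }
  if (distinct && anyDuplicated(out)) {
    abort("cannot generate enough distinct sequences; widen the length range")
  }
  out
}

#' Simulate a three-source proteome with planted Venn-cell structure
#'
#' Generates distinct random amino-acid sequences and assigns them to the
#' seven disjoint membership cells over the reference (R), OpenProt-style
#' (O) and ribosome-profiling (S) sets, so that [compute_composition()]
#' recovers the planted counts exactly.
#'
#' @param venn_cells Named counts for `R_only`, `O_only`, `S_only`, `RO`,
#'   `RS`, `OS`, `ROS`.
#' @param seq_len_range Length range (aa) of generated sequences.
#' @param seed Integer seed.
#' @param dir Optional directory: writes `reference.fa`, `openprot.fa`,
#'   `sorfs.fa` there.
#' @return A list with `reference`, `openprot`, `sorfs_org` (`seq_records`
#'   tibbles), and `truth` (tibble `sequence`, `cell`).
#' @export
simulate_proteome <- function(venn_cells, seq_len_range = c(20, 80),
                              seed = 1L, dir = NULL) {
  wanted <- c("R_only", "O_only", "S_only", "RO", "RS", "OS", "ROS")
  venn_cells <- unlist(venn_cells)[wanted]
  if (anyNA(venn_cells) || any(venn_cells < 0)) {
    abort("venn_cells must provide non-negative counts for all 7 cells")
  }
  total <- sum(venn_cells)
  space <- sum(20^seq(seq_len_range[1], min(seq_len_range[2],
                                            seq_len_range[1] + 3)))
  if (total > space / 2) abort("infeasible cell counts for the length range")
  with_seed(seed, {
    seqs <- random_aa_seqs(total, seq_len_range)
    cell <- rep(wanted, times = venn_cells)
    in_r <- cell %in% c("R_only", "RO", "RS", "ROS")
    in_o <- cell %in% c("O_only", "RO", "OS", "ROS")
    in_s <- cell %in% c("S_only", "RS", "OS", "ROS")
    mk <- function(mask, prefix, source) {
      s <- seqs[mask]
      seq_records(id = sprintf("%s%05d", prefix, seq_along(s)),
                  sequence = s, source = source)
    }
    out <- list(
      reference = mk(in_r, "REF", "reference"),
      openprot = mk(in_o, "IP_", "openprot"),
      sorfs_org = mk(in_s, "SORF", "sorfs_org"),
      truth = tibble(sequence = seqs, cell = cell)
    )
  })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(out$reference, file.path(dir, "reference.fa"),
                dialect_headers = FALSE)
    write_fasta(out$openprot, file.path(dir, "openprot.fa"),
                dialect_headers = FALSE)
    write_fasta(out$sorfs_org, file.path(dir, "sorfs.fa"),
                dialect_headers = FALSE)
  }
  out
}

#' Simulate sORF predictions with planted redundancy
#'
#' Generates predicted sORFs with genomic loci, planting (i) groups of
#' predictions sharing a stop coordinate (the longest member is the known
#' survivor) and (ii) single-exon-block sORFs overlapping annotated coding
#' exons (known removals). The expected outputs of
#' [select_longest_per_stop()] and [drop_single_exon_coding_overlaps()] are
#' emitted alongside.
#'
#' @param n_sorfs Total number of predicted sORFs (including planted group
#'   members).
#' @param dup_stop_groups Number of stop-sharing groups.
#' @param group_size Members per stop-sharing group (>= 2).
#' @param single_exon_planted Number of planted single-exon coding overlaps
#'   (among the surviving sORFs).
#' @param seq_len_range Length range (aa).
#' @param seed Integer seed.
#' @param dir Optional directory: writes `sorfs.fa` and `coding_exons.bed`.
#' @return A list with `sorfs` (records), `coding_exons` (interval tibble),
#'   `expected_after_longest` and `expected_final` (id vectors).
#' @export
simulate_sorf_predictions <- function(n_sorfs = 50, dup_stop_groups = 5,
                                      group_size = 3,
                                      single_exon_planted = 5,
                                      seq_len_range = c(20, 80), seed = 1L,
                                      dir = NULL) {
  n_grouped <- dup_stop_groups * group_size
  n_single <- n_sorfs - n_grouped
  if (n_single < single_exon_planted) {
    abort("n_sorfs too small for the requested planted structure")
  }
  # A locus of `n_blocks` blocks with total width 3*L whose strand-aware
  # 3'-most coordinate is exactly `s3` (0-based half-open blocks, 50-nt gap).
  make_locus <- function(L, s3, strand, n_blocks) {
    w <- 3 * L
    gap <- 50L
    if (n_blocks == 1L) {
      if (strand == "+") return(list(starts = s3 + 1 - w, ends = s3 + 1))
      return(list(starts = s3, ends = s3 + w))
    }
    a <- w %/% 2L; b <- w - a
    if (strand == "+") {
      list(starts = c(s3 + 1 - b - gap - a, s3 + 1 - b),
           ends = c(s3 + 1 - b - gap, s3 + 1))
    } else {
      list(starts = c(s3, s3 + a + gap),
           ends = c(s3 + a, s3 + a + gap + b))
    }
  }
  out <- with_seed(seed, {
    seqs <- random_aa_seqs(n_sorfs, seq_len_range)
    stops <- sample(seq(1000, 10000 * (dup_stop_groups + n_single)),
                    dup_stop_groups + n_single)
    strands <- sample(c("+", "-"), dup_stop_groups + n_single, replace = TRUE)
    rec <- list(); truth_survivor <- character()
    for (g in seq_len(dup_stop_groups)) {
      members <- seqs[((g - 1) * group_size + 1):(g * group_size)]
      stop3 <- stops[g]; strand <- strands[g]
      ids <- sprintf("SORF_G%02d_%d", g, seq_len(group_size))
      blocks <- lapply(nchar(members), make_locus, s3 = stop3,
                       strand = strand, n_blocks = 2L)
      rec[[length(rec) + 1L]] <- seq_records(
        id = ids, sequence = members, source = "sorfs_org",
        chrom = "chr1", strand = strand,
        block_starts = lapply(blocks, `[[`, "starts"),
        block_ends = lapply(blocks, `[[`, "ends"))
      keep <- order(-nchar(members), members, ids)[1]
      truth_survivor <- c(truth_survivor, ids[keep])
    }
    singles <- seqs[(n_grouped + 1):n_sorfs]
    sing_stops <- stops[(dup_stop_groups + 1):length(stops)]
    sing_strand <- strands[(dup_stop_groups + 1):length(strands)]
    is_single_block <- seq_len(n_single) <= single_exon_planted
    sing_ids <- sprintf("SORF_S%03d", seq_len(n_single))
    sing_blocks <- lapply(seq_len(n_single), function(i) {
      make_locus(nchar(singles[i]), sing_stops[i], sing_strand[i],
                 n_blocks = if (is_single_block[i]) 1L else 2L)
    })
    rec[[length(rec) + 1L]] <- seq_records(
      id = sing_ids, sequence = singles, source = "sorfs_org",
      chrom = "chr1", strand = sing_strand,
      block_starts = lapply(sing_blocks, `[[`, "starts"),
      block_ends = lapply(sing_blocks, `[[`, "ends"))
    sorfs <- bind_rows(rec)
    # coding exons covering exactly the planted single-block sORFs
    planted <- sing_ids[is_single_block]
    exons <- tibble(
      chrom = "chr1",
      start = vapply(sing_blocks[is_single_block],
                     function(b) b$starts[1], numeric(1)),
      end = vapply(sing_blocks[is_single_block],
                   function(b) b$ends[1], numeric(1)),
      name = paste0("exon_", seq_len(sum(is_single_block))),
      score = 0,
      strand = sing_strand[is_single_block]
    )
    expected_after_longest <- c(truth_survivor, sing_ids)
    expected_final <- setdiff(expected_after_longest, planted)
    list(sorfs = sorfs, coding_exons = exons,
         expected_after_longest = expected_after_longest,
         expected_final = expected_final)
  })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(out$sorfs, file.path(dir, "sorfs.fa"))
    write_bed(out$coding_exons, file.path(dir, "coding_exons.bed"))
  }
  out
}

#' Simulate spectra with tunable predicted-versus-observed correlation
#'
#' For each generated peptidoform, predicted charge-1 b/y intensities are
#' drawn from the chosen intensity model; the observed spectrum places peaks
#' at the theoretical m/z values with intensities constructed as a convex
#' mixture in transformed-intensity space so that the expected
#' post-transform Pearson correlation is close to `rho`, plus uniform noise
#' peaks. With `rho = 1` the observed intensities equal the prediction
#' exactly. Peptide lengths span the searchable 8-50 aa range, precursor
#' charges 1-6, and a planted fraction of non-tryptic C-termini emulates
#' enzyme-free peptidomics.
#'
#' @param n_peptides Number of peptidoforms/spectra.
#' @param rho Target correlation in `[-1, 1]`.
#' @param noise_peaks Number of extra random peaks per spectrum.
#' @param intensity_model `"geometric"` (exponentially decaying ladder) or
#'   `"gamma"` (i.i.d. gamma intensities).
#' @param frac_nontryptic Planted fraction of peptides not ending on K/R.
#' @param len_range Peptide length range.
#' @param seed Integer seed.
#' @return A list with `spectra` (tibble as from [read_mgf()]),
#'   `predictions` (tibble `spectrum_id`, `sequence`, `mods`, `predicted`
#'   list column) and `peptidoforms` (list of `peptidoform`).
#' @export
simulate_spectra <- function(n_peptides = 50, rho = 0.9, noise_peaks = 10,
                             intensity_model = c("geometric", "gamma"),
                             frac_nontryptic = 0.8, len_range = c(8, 50),
                             seed = 1L) {
  intensity_model <- match.arg(intensity_model)
  stopifnot(rho >= -1, rho <= 1)
  with_seed(seed, {
    n_nt <- round(n_peptides * frac_nontryptic)
    ct_pool_nt <- setdiff(AA_ALPHABET, c("K", "R"))
    rows <- vector("list", n_peptides)
    preds <- vector("list", n_peptides)
    pforms <- vector("list", n_peptides)
    for (i in seq_len(n_peptides)) {
      L <- len_range[1] + sample.int(len_range[2] - len_range[1] + 1L, 1) - 1L
      body <- paste(sample(AA_ALPHABET, L - 1, replace = TRUE),
                    collapse = "")
      ct <- if (i <= n_nt) sample(ct_pool_nt, 1) else sample(c("K", "R"), 1)
      p <- peptidoform(paste0(body, ct))
      charge <- sample(1:6, 1)
      frags <- fragment_mz(p, max_frag_charge = 1L)
      npos <- nrow(frags)
      pred <- switch(intensity_model,
        geometric = 0.75^(sample(npos) - 1),
        gamma = stats::rgamma(npos, shape = 1.2, rate = 1))
      pred <- pred / sum(pred)
      if (rho == 1) {
        obs <- pred
      } else {
        tp <- transform_intensities(pred)
        eps <- rnorm(npos, 0, sd(tp))
        tobs <- mean(tp) + rho * (tp - mean(tp)) +
          sqrt(1 - rho^2) * (eps - mean(eps))
        obs <- pmax((2^tobs - 1) / 1e4, 0)
        if (sum(obs) > 0) obs <- obs / sum(obs)
      }
      pk <- tibble(mz = frags$mz, intensity = obs)
      if (noise_peaks > 0) {
        pk <- bind_rows(pk, tibble(
          mz = runif(noise_peaks, 100, 1500),
          intensity = runif(noise_peaks, 0, max(obs) / 5)))
      }
      pk <- pk[pk$intensity > 0, ]
      pk <- arrange(pk, .data$mz)
      sid <- sprintf("scan=%04d", i)
      rows[[i]] <- tibble(
        spectrum_id = sid,
        precursor_mz = (monoisotopic_mass(p) + charge * PROTON_MASS) / charge,
        precursor_charge = charge,
        rt = runif(1, 10, 3000),
        peaks = list(pk),
        extra = list(character()))
      preds[[i]] <- tibble(spectrum_id = sid, sequence = p$sequence,
                           mods = format_mods(p), predicted = list(pred))
      pforms[[i]] <- p
    }
    list(spectra = bind_rows(rows), predictions = bind_rows(preds),
         peptidoforms = pforms)
  })
}

#' Simulate a target-decoy PSM score mixture with ground truth
#'
#' Correct target PSMs draw their base score from
#' `Normal(mu_correct, sigma)`; incorrect targets and decoys from
#' `Normal(mu_incorrect, sigma)` (the core target-decoy modelling
#' assumption). Informative auxiliary features are shifted by
#' `feature_effect` for correct PSMs only; uninformative features are
#' standard normal for everyone. The true `is_correct` labels are returned
#' so that downstream false-discovery proportions can be scored exactly.
#'
#' @param n_targets,n_decoys PSM counts.
#' @param pi_correct Fraction of targets that are correct.
#' @param mu_correct,mu_incorrect,sigma Score-mixture parameters.
#' @param n_informative Number of informative auxiliary features.
#' @param n_uninformative Number of pure-noise features.
#' @param feature_effect Mean shift of informative features for correct
#'   PSMs.
#' @param seed Integer seed.
#' @return A PSM tibble (dialect of [read_psms()]) with extra logical
#'   column `is_correct` (always `FALSE` for decoys).
#' @export
simulate_psm_scores <- function(n_targets = 1500, n_decoys = 1500,
                                pi_correct = 0.35, mu_correct = 3,
                                mu_incorrect = 0, sigma = 1,
                                n_informative = 3, n_uninformative = 10,
                                feature_effect = 1.2, seed = 1L) {
  stopifnot(pi_correct > 0, pi_correct < 1)
  with_seed(seed, {
    n <- n_targets + n_decoys
    is_decoy <- c(rep(FALSE, n_targets), rep(TRUE, n_decoys))
    is_correct <- c(runif(n_targets) < pi_correct, rep(FALSE, n_decoys))
    base_score <- rnorm(n, ifelse(is_correct, mu_correct, mu_incorrect),
                        sigma)
    feats <- list()
    for (j in seq_len(n_informative)) {
      feats[[paste0("feat_info", j)]] <-
        rnorm(n) + feature_effect * is_correct
    }
    for (j in seq_len(n_uninformative)) {
      feats[[paste0("feat_noise", j)]] <- rnorm(n)
    }
    seqs <- random_aa_seqs(n, c(8, 30), distinct = FALSE)
    tibble(
      psm_id = sprintf("psm%05d", seq_len(n)),
      spectrum_id = sprintf("scan=%05d", seq_len(n)),
      sample_id = "sim", replicate_id = "r1",
      sequence = seqs,
      mods = "",
      charge = sample(1:6, n, replace = TRUE),
      is_decoy = is_decoy,
      protein_ids = ifelse(is_decoy, "DECOY_simprot", "simprot"),
      base_score = base_score,
      observed_rt = NA_real_, predicted_rt = NA_real_,
      !!!feats,
      is_correct = is_correct
    )
  })
}
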