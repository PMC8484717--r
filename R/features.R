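#' Predicted-versus-observed spectral features
#'
#' Builds the observed fragment-intensity vector by matching the charge-1
#' b/y ladder of the peptidoform against the spectrum at `tol`, normalises
#' both vectors to their total ion current and applies the
#' `log2(x * 1e4 + 1)` transform, then computes correlation features between
#' predicted and observed intensities. The Pearson correlation of a
#' zero-variance vector is defined as 0.
#'
#' @param observed A spectrum row (list with `peaks`) or a peaks tibble.
#' @param predicted Numeric vector of predicted intensities aligned to the
#'   charge-1 fragment order `b_1..b_{n-1}, y_1..y_{n-1}`.
#' @param p The `peptidoform` being scored.
#' @param tol Fragment matching tolerance in Da.
#' @return A one-row tibble: `pcc_all`, `pcc_b`, `pcc_y`, `spectral_angle`,
#'   `fraction_matched`, `n_matched`.
#' @export
spectral_features <- function(observed, predicted, p, tol = 0.02) {
  if (is.character(p)) p <- peptidoform(p)
  frags <- fragment_mz(p, max_frag_charge = 1L)
  if (length(predicted) != nrow(frags)) {
    abort(sprintf("predicted vector length %d does not match %d fragment positions",
                  length(predicted), nrow(frags)))
  }
  peaks <- if (is.data.frame(observed)) observed else observed$peaks
  if (is.list(peaks) && !is.data.frame(peaks)) peaks <- peaks[[1]]
  obs_raw <- match_peaks(peaks, frags$mz, tol = tol)
  obs <- transform_intensities(obs_raw)
  prd <- transform_intensities(predicted)
  is_b <- frags$ion == "b"
  tibble(
    pcc_all = safe_pcc(prd, obs),
    pcc_b = safe_pcc(prd[is_b], obs[is_b]),
    pcc_y = safe_pcc(prd[!is_b], obs[!is_b]),
    spectral_angle = spectral_angle(prd, obs),
    fraction_matched = mean(obs_raw > 0),
    n_matched = sum(obs_raw > 0)
  )
}

# TIC normalisation followed by a log transform stable at zero.
transform_intensities <- function(x) {
  s <- sum(x)
  if (s > 0) x <- x / s
  log2(x * 1e4 + 1)
}

safe_pcc <- function(x, y) {
  if (length(x) < 2L || sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)
}

# Normalised spectral contrast angle in [-1, 1].
spectral_angle <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  cosim <- max(-1, min(1, sum(x * y) / (nx * ny)))
  1 - 2 * acos(cosim) / pi
}

#' Retention-time error features
#'
#' @param observed_rt,predicted_rt Retention times in seconds (observed may
#'   be `NA`; the features are then `NA` and imputed downstream).
#' @param run_rt_span Retention-time span of the run in seconds (> 0).
#' @return A one-row tibble: `abs_rt_error`, `signed_rt_error`,
#'   `relative_rt_error`.
#' @export
rt_features <- function(observed_rt, predicted_rt, run_rt_span) {
  if (run_rt_span <= 0) abort("run_rt_span must be > 0")
  signed <- observed_rt - predicted_rt
  tibble(abs_rt_error = abs(signed), signed_rt_error = signed,
         relative_rt_error = abs(signed) / run_rt_span)
}

#' Is a peptide tryptic-like?
#'
#' Endogenous (enzyme-free) peptidomics yields mostly peptides that do not
#' end on Lys or Arg; "tryptic-like" means the C-terminal residue is K or R.
#'
#' @param p A `peptidoform` or character vector of sequences.
#' @return Logical vector.
#' @export
tryptic_like <- function(p) {
  seqs <- if (inherits(p, "peptidoform")) p$sequence else as.character(p)
  substring(seqs, nchar(seqs), nchar(seqs)) %in% c("K", "R")
}
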