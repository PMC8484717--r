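#' Target-decoy q-values
#'
#' PSMs are ranked by decreasing score (score ties are broken decoy-first,
#' the conservative choice); at each threshold the FDR estimate is
#' `(decoys + plus_one) / max(targets, 1)`, monotonised into q-values by a
#' running minimum from the bottom of the ranking and clipped to `[0, 1]`.
#'
#' @param scores Numeric vector (higher is better).
#' @param is_decoy Logical vector, same length.
#' @param plus_one Add 1 to the decoy count in the numerator (the correction
#'   used by some rescoring tools); default `FALSE`.
#' @return Numeric vector of q-values in the input order (decoy PSMs receive
#'   the q-value at their rank as well).
#' @export
compute_qvalues <- function(scores, is_decoy, plus_one = FALSE) {
  stopifnot(length(scores) == length(is_decoy))
  if (!any(is_decoy)) abort("cannot estimate q-values without decoys")
  if (all(is_decoy)) abort("cannot estimate q-values without targets")
  ord <- order(-scores, !is_decoy)
  d <- cumsum(is_decoy[ord])
  t <- cumsum(!is_decoy[ord])
  fdr <- (d + as.numeric(plus_one)) / pmax(t, 1)
  q <- rev(cummin(rev(fdr)))
  q <- pmin(pmax(q, 0), 1)
  q[order(ord)]
}

#' Posterior error probabilities from the target-decoy ranking
#'
#' Estimates the local probability that a PSM at a given score is incorrect:
#' the decoy fraction in a sliding window over the score ranking, made
#' monotone non-increasing in score by isotonic regression. In the
#' uninformative limit (all scores equal) every PSM gets `D / (D + T)`.
#'
#' @inheritParams compute_qvalues
#' @param window Odd window width for the local decoy fraction; default
#'   adapts to the collection size.
#' @return Numeric vector of PEP estimates in the input order.
#' @export
pep_estimate <- function(scores, is_decoy, window = NULL) {
  stopifnot(length(scores) == length(is_decoy))
  if (!any(is_decoy)) abort("cannot estimate PEP without decoys")
  if (all(is_decoy)) abort("cannot estimate PEP without targets")
  n <- length(scores)
  if (length(unique(scores)) == 1L) {
    return(rep(mean(is_decoy), n))
  }
  if (is.null(window)) window <- max(11L, 2L * (n %/% 40L) + 1L)
  window <- min(window, if (n %% 2L == 1L) n else n - 1L)
  ord <- order(-scores, !is_decoy)
  y <- as.numeric(is_decoy[ord])
  half <- window %/% 2L
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  local <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  # non-decreasing in rank == non-increasing in score
  pep <- isoreg(seq_len(n), local)$yf
  pep <- pmin(pmax(pep, 0), 1)
  pep[order(ord)]
}
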