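#' Median-impute a feature matrix
#'
#' Non-finite feature values are replaced by the column median (0 when a
#' whole column is missing) and a 0/1 indicator column `<name>_missing` is
#' appended for every column that had missing values.
#'
#' @param features A data frame / tibble of numeric feature columns.
#' @return A tibble with no non-finite values.
#' @export
impute_features <- function(features) {
  features <- as_tibble(features)
  masks <- list()
  for (nm in names(features)) {
    v <- features[[nm]]
    bad <- !is.finite(v)
    if (any(bad)) {
      med <- median(v[!bad])
      if (!is.finite(med)) med <- 0
      v[bad] <- med
      features[[nm]] <- v
      masks[[paste0(nm, "_missing")]] <- as.numeric(bad)
    }
  }
  if (length(masks)) features <- bind_cols(features, as_tibble(masks))
  features
}

# Deterministic, leakage-free fold assignment: all PSMs of one spectrum land
# in the same fold.
assign_folds <- function(spectrum_ids, folds, seed) {
  1L + as.integer(string_hash(spectrum_ids, seed = seed) %% folds)
}

# Ridge-logistic fit of positives (1) vs decoys (0); lambda picked by an
# inner 2-fold split maximising training targets accepted at q_select.
fit_linear_scorer <- function(x, y, x_all, is_decoy_all, is_target_all,
                              q_select, inner_fold, lambda_grid) {
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = lambda_grid, standardize = TRUE)
  n_ok <- vapply(seq_along(fit$lambda), function(j) {
    s <- as.numeric(x_all %*% fit$beta[, j])
    sum(vapply(1:2, function(h) {
      held <- inner_fold == h
      if (!any(is_decoy_all[held]) || !any(is_target_all[held])) return(0L)
      q <- compute_qvalues(s[held], is_decoy_all[held])
      sum(q <= q_select & is_target_all[held])
    }, integer(1)))
  }, integer(1))
  j <- which.max(n_ok)
  list(beta = fit$beta[, j], a0 = fit$a0[j], lambda = fit$lambda[j])
}

#' Semi-supervised cross-validated PSM rescoring
#'
#' Re-ranks PSMs with an iteratively retrained L2-regularised logistic
#' scorer, in the style of semi-supervised target-decoy rescoring: PSMs are
#' split spectrum-wise into folds; within each training set, positives are
#' initialised as targets passing `q_select` on the base score, a ridge
#' classifier of positives versus decoys is fitted, training PSMs are
#' rescored and the positive set reselected, iterating to stability; the
#' held-out fold is then scored with the trained weights. Per-fold scores
#' are standardised on the held-out decoys before merging, and final
#' q-values come from [compute_qvalues()] on the merged scores. Labels and
#' the PSM set are never altered, only scores and q-values.
#'
#' @param psms A tibble with at least `psm_id`, `spectrum_id`, `is_decoy`
#'   (logical or 0/1), `base_score`. Feature columns prefixed `feat_` are
#'   used unless `features` is given.
#' @param features Optional data frame of additional numeric features (one
#'   row per PSM).
#' @param folds Number of spectrum-wise cross-validation folds.
#' @param q_select q-value threshold defining positives during training.
#' @param max_iter Maximum positive-reselection iterations per fold.
#' @param seed Integer seed controlling fold assignment.
#' @param plus_one Passed to [compute_qvalues()].
#' @return A `sorfpep_rescore` object: list with `psms` (input plus `score`,
#'   `q_value`, `fold`, `base_q`), `weights` (per-fold coefficient tibble),
#'   `iterations`, and the configuration. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
semi_supervised_rescore <- function(psms, features = NULL, folds = 3L,
                                    q_select = 0.01, max_iter = 10L,
                                    seed = 1L, plus_one = FALSE) {
  psms <- as_tibble(psms)
  stopifnot(all(c("psm_id", "spectrum_id", "is_decoy", "base_score")
                %in% names(psms)))
  is_decoy <- as.logical(psms$is_decoy)
  if (is.null(features)) {
    features <- psms[grepl("^feat_", names(psms))]
  }
  features <- impute_features(as_tibble(features))
  xmat <- cbind(base_score = psms$base_score,
                as.matrix(features))
  drop_const <- apply(xmat, 2, function(col) sd(col) == 0)
  xmat <- xmat[, !drop_const, drop = FALSE]
  if (ncol(xmat) < 2L) {
    # ridge fits need >= 2 predictors; a zero column is inert
    xmat <- cbind(xmat, .null_feature = 0)
  }

  fold <- assign_folds(psms$spectrum_id, folds, seed)
  base_q <- compute_qvalues(psms$base_score, is_decoy, plus_one = plus_one)
  n <- nrow(psms)
  score <- numeric(n)
  weights <- list()
  iters <- integer(folds)

  for (k in seq_len(folds)) {
    train <- fold != k
    held <- !train
    tr_decoy <- is_decoy & train
    tr_target <- !is_decoy & train
    if (!any(held)) next
    q_tr <- tryCatch(
      compute_qvalues(psms$base_score[train], is_decoy[train],
                      plus_one = plus_one),
      error = function(e) NULL)
    if (!is.null(q_tr)) {
      pos_tr <- !is_decoy[train] & q_tr <= q_select
    } else {
      pos_tr <- logical(sum(train))
    }
    if (!any(tr_decoy) || !any(pos_tr)) {
      warn(sprintf("fold %d: no decoys or no positives; using base score", k))
      s_held <- psms$base_score[held]
      score[held] <- standardize_on_decoys(s_held, is_decoy[held])
      next
    }
    inner <- 1L + as.integer(
      string_hash(psms$spectrum_id[train], seed = seed + 1000L * k) %% 2L)
    lambda_grid <- c(10, 1, 0.1, 0.01)
    model <- NULL
    for (it in seq_len(max_iter)) {
      idx_pos <- which(pos_tr)
      idx_neg <- which(is_decoy[train])
      x_fit <- xmat[train, , drop = FALSE][c(idx_pos, idx_neg), , drop = FALSE]
      y_fit <- c(rep(1, length(idx_pos)), rep(0, length(idx_neg)))
      model <- fit_linear_scorer(
        x_fit, y_fit,
        x_all = xmat[train, , drop = FALSE],
        is_decoy_all = is_decoy[train],
        is_target_all = !is_decoy[train],
        q_select = q_select, inner_fold = inner,
        lambda_grid = lambda_grid)
      s_tr <- as.numeric(xmat[train, , drop = FALSE] %*% model$beta)
      q_new <- compute_qvalues(s_tr, is_decoy[train], plus_one = plus_one)
      pos_new <- !is_decoy[train] & q_new <= q_select
      iters[k] <- it
      if (!any(pos_new)) break
      if (identical(pos_new, pos_tr)) { pos_tr <- pos_new; break }
      pos_tr <- pos_new
    }
    s_held <- as.numeric(xmat[held, , drop = FALSE] %*% model$beta)
    # normalise on the training decoys: larger sample, and independent of
    # the held-out fold being scored
    s_tr_final <- as.numeric(xmat[train, , drop = FALSE] %*% model$beta)
    mu_d <- mean(s_tr_final[is_decoy[train]])
    sd_d <- sd(s_tr_final[is_decoy[train]])
    score[held] <- if (is.finite(sd_d) && sd_d > 0) (s_held - mu_d) / sd_d
                   else standardize_on_decoys(s_held, is_decoy[held])
    weights[[k]] <- tibble(fold = k, term = names(model$beta),
                           estimate = as.numeric(model$beta),
                           lambda = model$lambda)
  }

  q_value <- compute_qvalues(score, is_decoy, plus_one = plus_one)
  out <- psms
  out$fold <- fold
  out$base_q <- base_q
  out$score <- score
  out$q_value <- q_value
  structure(list(
    psms = out,
    weights = if (length(weights)) bind_rows(weights) else tibble(),
    iterations = iters,
    config = list(folds = folds, q_select = q_select, max_iter = max_iter,
                  seed = seed, plus_one = plus_one)
  ), class = "sorfpep_rescore")
}

# z-scale scores on the decoy sub-population (falls back to the overall sd
# when there are no/constant decoys).
standardize_on_decoys <- function(s, is_decoy) {
  ref <- s[is_decoy]
  if (length(ref) < 2L || sd(ref) == 0) ref <- s
  if (sd(ref) == 0) return(s - mean(ref))
  (s - mean(ref)) / sd(ref)
}

#' @export
print.sorfpep_rescore <- function(x, ...) {
  g <- glance(x)
  cat("<sorfpep_rescore>\n")
  cat(sprintf("  %d PSMs (%d targets / %d decoys), %d folds\n",
              g$n_psms, g$n_targets, g$n_decoys, x$config$folds))
  cat(sprintf("  accepted at q<=%.3g: %d (base score: %d)\n",
              x$config$q_select, g$n_accepted, g$n_accepted_base))
  invisible(x)
}

#' @rdname semi_supervised_rescore
#' @param x,object A `sorfpep_rescore` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.sorfpep_rescore <- function(x, ...) {
  x$weights
}

#' @rdname semi_supervised_rescore
#' @exportS3Method generics::glance
glance.sorfpep_rescore <- function(x, ...) {
  p <- x$psms
  dec <- as.logical(p$is_decoy)
  qs <- x$config$q_select
  tibble(
    n_psms = nrow(p),
    n_targets = sum(!dec),
    n_decoys = sum(dec),
    n_accepted = sum(!dec & p$q_value <= qs),
    n_accepted_base = sum(!dec & p$base_q <= qs),
    folds = x$config$folds,
    max_iterations = max(x$iterations)
  )
}

#' @rdname semi_supervised_rescore
#' @exportS3Method ggplot2::autoplot
autoplot.sorfpep_rescore <- function(object, ...) {
  p <- object$psms
  dec <- as.logical(p$is_decoy)
  grid <- sort(unique(c(seq(0.001, 0.1, by = 0.001))))
  curve <- purrr::map_dfr(grid, function(t) {
    tibble(q = t,
           rescored = sum(!dec & p$q_value <= t),
           `base score` = sum(!dec & p$base_q <= t))
  }) |>
    tidyr::pivot_longer(c("rescored", "base score"),
                        names_to = "ranking", values_to = "n_accepted")
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$q, y = .data$n_accepted,
                                      colour = .data$ranking)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$config$q_select,
                        linetype = "dashed") +
    ggplot2::labs(x = "q-value threshold", y = "accepted target PSMs",
                  title = "Rescoring gain over the base score") +
    ggplot2::theme_minimal()
}
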