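# Permuted discriminant function analysis (pDFA).
#
# Calls from the same recording day are not independent, so the significance
# of a DFA classifying calls to males must come from a restricted permutation
# scheme that moves whole recording-day blocks of calls between males. The
# observed statistic is the cross-validated correct-classification rate
# averaged over balanced random selections of training calls.

# --- linear discriminant machinery -----------------------------------------
#
# Classification with equal priors and a pooled within-class covariance is
# Mahalanobis nearest-centroid: sphere the space by the Cholesky factor of
# the pooled covariance, then assign to the nearest class mean. Implemented
# directly (rather than via a formula interface) because it sits inside a
# 100-selection x 1000-permutation loop; rank-deficient covariances are
# ridge-regularized.

lda_fit <- function(x, class, ridge = 1e-8) {
  x <- as.matrix(x)
  class <- as.character(class)
  levels <- sort(unique(class))
  if (length(levels) < 2) stop_input("need >= 2 classes to discriminate")
  p <- ncol(x)
  means <- matrix(0, length(levels), p, dimnames = list(levels, colnames(x)))
  W <- matrix(0, p, p)
  for (k in seq_along(levels)) {
    xk <- x[class == levels[k], , drop = FALSE]
    means[k, ] <- colMeans(xk)
    W <- W + crossprod(sweep(xk, 2, means[k, ]))
  }
  W <- W / (nrow(x) - length(levels))
  eps <- 0
  ch <- tryCatch(chol(W), error = function(e) NULL)
  while (is.null(ch)) {
    eps <- if (eps == 0) ridge * mean(diag(W)) else eps * 10
    ch <- tryCatch(chol(W + diag(eps, p)), error = function(e) NULL)
    if (eps > 1e6 * mean(diag(W))) stop_input("within-class covariance irreparably singular")
  }
  list(levels = levels, means = means, chol = ch, ridge_eps = eps, pooled = W)
}

lda_predict <- function(fit, newx) {
  # distances in the sphered space; t(backsolve) maps rows through W^{-1/2}
  z <- t(backsolve(fit$chol, t(as.matrix(newx)), transpose = TRUE))
  m <- t(backsolve(fit$chol, t(fit$means), transpose = TRUE))
  d2 <- outer(rowSums(z^2), rowSums(m^2), "+") - 2 * z %*% t(m)
  fit$levels[max.col(-d2, ties.method = "first")]
}

#' Balanced random selection of training calls
#'
#' Selects exactly `n_select` calls per male uniformly without replacement;
#' the remainder is held out for cross-classification. Males with too few
#' calls (fewer than `n_select + 1`) are excluded with a message.
#'
#' @param dataset data.frame with `male_id` and feature columns.
#' @param n_select training calls per male (23 in the reference design: one
#'   more than the 22 parameters).
#' @param seed integer seed.
#' @return list: `train` and `heldout` row indices into `dataset`,
#'   `excluded` male ids.
#' @export
balanced_selection <- function(dataset, n_select = 23, seed = 1) {
  counts <- table(dataset$male_id)
  excluded <- names(counts)[counts < n_select + 1]
  if (length(excluded)) {
    message("excluding males with <= ", n_select, " calls: ",
            paste(excluded, collapse = ", "))
  }
  keep <- setdiff(names(counts), excluded)
  with_seed(seed, {
    train <- unlist(lapply(keep, function(m) {
      idx <- which(dataset$male_id == m)
      idx[sample.int(length(idx), n_select)]
    }), use.names = FALSE)
    heldout <- setdiff(which(dataset$male_id %in% keep), train)
    list(train = sort(train), heldout = sort(heldout), excluded = excluded)
  })
}

#' Cross-classify held-out calls
#'
#' Derives linear discriminant functions on the training calls (equal priors,
#' matching the balanced design) and assigns each held-out call to the
#' nearest class centroid in the sphered (Mahalanobis) space.
#'
#' @param train data.frame with `male_id` and feature columns.
#' @param heldout same structure.
#' @param feature_cols names of the feature columns; default: all numeric
#'   columns shared by both tables except identifiers.
#' @return percent of held-out calls assigned to their true male.
#' @export
classify_heldout <- function(train, heldout, feature_cols = NULL) {
  if (is.null(feature_cols)) feature_cols <- pdfa_feature_cols(train)
  fit <- lda_fit(train[, feature_cols, drop = FALSE], train$male_id)
  pred <- lda_predict(fit, heldout[, feature_cols, drop = FALSE])
  100 * mean(pred == heldout$male_id)
}

pdfa_feature_cols <- function(dataset) {
  setdiff(names(dataset)[vapply(dataset, is.numeric, logical(1))],
          c("recording_day", "call_id"))
}

#' Permute recording-day blocks of calls between males
#'
#' Reassigns whole recording-day blocks to male labels such that every male
#' keeps its original number of recording days; calls recorded on the same
#' day by the same male move together. This is the restricted permutation
#' scheme under which calls are exchangeable at the day level.
#'
#' @param dataset data.frame with `male_id` and `recording_day` (day blocks
#'   are the unique `recording_day` values; a day shared by two males forms
#'   two blocks when `recording_day` encodes the male-day pair).
#' @param seed integer seed.
#' @return `dataset` with `male_id` replaced by the permuted labels.
#' @export
permute_day_blocks <- function(dataset, seed) {
  blocks <- unique(dataset[, c("male_id", "recording_day")])
  if (any(table(blocks$male_id) < 2) && length(unique(blocks$male_id)) == 2) {
    warning("a male has a single recording day; the day-permutation space is degenerate")
  }
  with_seed(seed, {
    perm <- sample.int(nrow(blocks))
    new_label <- blocks$male_id            # multiset of labels preserved
    blocks$new_male <- new_label[perm]
    key <- paste(dataset$male_id, dataset$recording_day, sep = "\r")
    bkey <- paste(blocks$male_id, blocks$recording_day, sep = "\r")
    dataset$male_id <- blocks$new_male[match(key, bkey)]
    dataset
  })
}

#' Run the permuted discriminant function analysis
#'
#' The observed statistic is the mean cross-validated percent-correct over
#' `n_selections` balanced selections. The same statistic (with
#' `perm_selections` selections, defaulting to the full `n_selections`) is
#' computed for each of `n_permutations - 1` day-wise permuted datasets; the
#' original arrangement counts as one permutation, so the p-value is
#' (number of permuted statistics >= observed, + 1) / `n_permutations`, with
#' lower bound 1/`n_permutations`. Ties count as exceedances (conservative).
#'
#' @param dataset data.frame with `male_id`, `recording_day` and feature
#'   columns (transformed call parameters).
#' @param n_select training calls per male.
#' @param n_selections balanced selections averaged for the observed rate.
#' @param n_permutations total permutations including the observed.
#' @param perm_selections selections per permuted dataset (reduce for speed).
#' @param seed master seed; selection and permutation streams are derived
#'   from it.
#' @return object of class `pdfa_result`: `observed_rate`, `chance_level`,
#'   `p_value`, `n_selections`, `n_permutations`, `per_selection_rates`,
#'   `perm_rates`, `n_males`, `excluded`.
#' @export
run_pdfa <- function(dataset, n_select = 23, n_selections = 100,
                     n_permutations = 1000, perm_selections = n_selections,
                     seed = 1) {
  counts <- table(dataset$male_id)
  excluded <- names(counts)[counts < n_select + 1]
  dataset <- dataset[!(dataset$male_id %in% excluded), , drop = FALSE]
  if (length(excluded)) {
    message("pDFA excludes males with <= ", n_select, " calls: ",
            paste(excluded, collapse = ", "))
  }
  k <- length(unique(dataset$male_id))
  if (k < 2) stop_input("fewer than 2 males with enough calls")
  feature_cols <- pdfa_feature_cols(dataset)
  feats <- as.matrix(dataset[, feature_cols, drop = FALSE])

  statistic <- function(labels, n_sel, seed0) {
    d <- data.frame(male_id = labels, feats, check.names = FALSE)
    rates <- vapply(seq_len(n_sel), function(s) {
      sel <- suppressMessages(balanced_selection(d, n_select, derive_seed(seed0, s)))
      classify_heldout(d[sel$train, , drop = FALSE], d[sel$heldout, , drop = FALSE],
                       feature_cols)
    }, numeric(1))
    rates
  }

  obs_rates <- statistic(dataset$male_id, n_selections, derive_seed(seed, 101L))
  observed <- mean(obs_rates)

  perm_rates <- vapply(seq_len(n_permutations - 1), function(b) {
    pd <- permute_day_blocks(dataset[, c("male_id", "recording_day")],
                             derive_seed(seed, 20000L + b))
    mean(statistic(pd$male_id, perm_selections, derive_seed(seed, 40000L + b)))
  }, numeric(1))

  p <- (sum(perm_rates >= observed) + 1) / n_permutations
  structure(list(
    observed_rate = observed, chance_level = 100 / k, p_value = p,
    n_selections = n_selections, n_permutations = n_permutations,
    perm_selections = perm_selections,
    per_selection_rates = obs_rates, perm_rates = perm_rates,
    n_males = k, n_calls = nrow(dataset), excluded = excluded, seed = seed
  ), class = "pdfa_result")
}

#' @export
print.pdfa_result <- function(x, ...) {
  cat(sprintf("pDFA: %d males, %d calls\n", x$n_males, x$n_calls))
  cat(sprintf("  cross-classified correct: %.1f%% (chance %.1f%%)\n",
              x$observed_rate, x$chance_level))
  cat(sprintf("  p = %.4g (%d day-wise permutations, %d selections)\n",
              x$p_value, x$n_permutations, x$n_selections))
  invisible(x)
}

#' Discriminant structure of an all-calls DFA
#'
#' Fits a single DFA on all calls and reports the discriminant-function
#' eigenvalues together with structure loadings: the correlation of every
#' feature with every discriminant score. Loadings with |r| >= `flag_at` are
#' flagged as the features carrying the discrimination.
#'
#' @param dataset data.frame with `male_id` and feature columns.
#' @param flag_at absolute-loading threshold to flag (default 0.5).
#' @return list: `eigenvalues` (between/within mean-square ratios per
#'   discriminant function), `loadings` (features x functions correlation
#'   matrix), `flagged` (data.frame of feature/function pairs above the
#'   threshold), `n_functions`, `scores` (per-call discriminant scores).
#' @export
dfa_structure <- function(dataset, flag_at = 0.5) {
  feature_cols <- pdfa_feature_cols(dataset)
  x <- as.matrix(dataset[, feature_cols, drop = FALSE])
  class <- as.character(dataset$male_id)
  fit <- lda_fit(x, class)
  k <- length(fit$levels)
  # between-class scatter of class means about the grand mean (weighted)
  nk <- as.numeric(table(factor(class, fit$levels)))
  gm <- colSums(fit$means * nk) / sum(nk)
  B <- crossprod(sweep(fit$means, 2, gm) * sqrt(nk)) / (k - 1)
  Winv_half <- backsolve(fit$chol, diag(ncol(x)), transpose = TRUE)
  M <- t(Winv_half) %*% B %*% Winv_half
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  n_fun <- min(k - 1, ncol(x))
  vecs <- Winv_half %*% e$vectors[, seq_len(n_fun), drop = FALSE]
  scores <- x %*% vecs
  colnames(scores) <- paste0("df", seq_len(n_fun))
  loadings <- stats::cor(x, scores)
  flagged <- which(abs(loadings) >= flag_at, arr.ind = TRUE)
  flagged <- data.frame(
    feature = rownames(loadings)[flagged[, 1]],
    fun = colnames(scores)[flagged[, 2]],
    loading = loadings[flagged], stringsAsFactors = FALSE
  )
  list(eigenvalues = e$values[seq_len(n_fun)], loadings = loadings,
       flagged = flagged, n_functions = n_fun, scores = scores)
}
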