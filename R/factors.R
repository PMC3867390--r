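# Factor analysis of the 22 call parameters: per-parameter symmetrizing
# transformations, sampling-adequacy diagnostics (Bartlett sphericity, KMO),
# principal-component extraction with the eigenvalue > 1 retention rule,
# varimax rotation, and regression-method factor scores.

#' Default transformation map for the 22 call parameters
#'
#' The per-parameter transformations used before factor analysis, chosen to
#' make each distribution approximately symmetric: `log` for durations and
#' interval maxima, `sqrt` for the variation block and the max-F0 location,
#' `sqrt_shift` (sqrt of the value minus the training-data minimum) for the
#' left-bounded interval and F0 maxima, identity otherwise.
#'
#' @return named character vector over [call_parameter_names()], values in
#'   `identity`, `log`, `sqrt`, `sqrt_shift`.
#' @export
default_transforms <- function() {
  tr <- stats::setNames(rep("identity", 22), call_parameter_names())
  tr["call_duration"] <- "log"
  tr["mean_interval_duration"] <- "sqrt_shift"
  tr["mean_loc_max_f0"] <- "sqrt"
  tr["maximum_interval_duration"] <- "log"
  tr["maximum_end_f0"] <- "sqrt_shift"
  tr["maximum_mean_f0"] <- "sqrt_shift"
  tr["maximum_loc_max_f0"] <- "sqrt"
  tr["variation_element_duration"] <- "sqrt"
  tr["variation_interval_duration"] <- "log"
  tr["variation_start_f0"] <- "sqrt"
  tr["variation_end_f0"] <- "sqrt"
  tr["variation_mean_f0"] <- "sqrt"
  tr["variation_max_f0"] <- "sqrt"
  tr["variation_loc_max_f0"] <- "sqrt"
  tr
}

#' Build a transform specification from data
#'
#' Records, for every `sqrt_shift` parameter, the minimum observed in the
#' fitting data, so the same shift is reapplied to new data.
#'
#' @param feature_table data.frame containing the parameter columns.
#' @param transforms named character vector (see [default_transforms()]).
#' @return object of class `transform_spec`.
#' @export
transform_spec <- function(feature_table, transforms = default_transforms()) {
  missing_cols <- setdiff(names(transforms), names(feature_table))
  if (length(missing_cols)) {
    stop_input("feature table lacks columns: %s", paste(missing_cols, collapse = ", "))
  }
  minima <- vapply(names(transforms), function(nm) {
    if (transforms[[nm]] == "sqrt_shift") min(feature_table[[nm]], na.rm = TRUE) else NA_real_
  }, numeric(1))
  structure(list(transforms = transforms, minima = minima),
            class = "transform_spec")
}

#' Apply per-parameter transformations
#'
#' Natural logarithms are used for `log` (the base only rescales columns and
#' leaves any analysis of the correlation matrix unchanged). Missing values
#' propagate; a nonpositive input to `log` or a negative input to `sqrt`
#' after shifting is a data error naming the offending rows.
#'
#' @param feature_table data.frame containing the parameter columns.
#' @param spec a [transform_spec()].
#' @return data.frame with transformed parameter columns (other columns
#'   untouched).
#' @export
apply_transforms <- function(feature_table, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  out <- feature_table
  for (nm in names(spec$transforms)) {
    x <- out[[nm]]
    tx <- switch(spec$transforms[[nm]],
      identity = x,
      log = {
        bad <- which(!is.na(x) & x <= 0)
        if (length(bad)) stop_input("log transform of nonpositive %s at rows %s",
                                    nm, paste(utils::head(bad, 5), collapse = ", "))
        log(x)
      },
      sqrt = {
        bad <- which(!is.na(x) & x < 0)
        if (length(bad)) stop_input("sqrt transform of negative %s at rows %s",
                                    nm, paste(utils::head(bad, 5), collapse = ", "))
        sqrt(x)
      },
      sqrt_shift = {
        y <- x - spec$minima[[nm]]
        bad <- which(!is.na(y) & y < 0)
        if (length(bad)) {
          y[bad] <- 0                 # new data slightly below the training minimum
        }
        sqrt(y)
      })
    out[[nm]] <- tx
  }
  out
}

#' Sampling-adequacy diagnostics: Bartlett's sphericity test and KMO
#'
#' Bartlett's test statistic is
#' \eqn{-((n-1) - (2p+5)/6)\,\log|R|} on \eqn{p(p-1)/2} df; the
#' Kaiser-Meyer-Olkin measure compares squared correlations to squared
#' partial correlations (anti-image) over all variable pairs.
#'
#' @param x numeric matrix or data.frame of transformed parameters (complete
#'   rows are used).
#' @return list: `bartlett_chi2`, `bartlett_df`, `bartlett_p`, `kmo`.
#' @export
sampling_adequacy <- function(x) {
  x <- as.matrix(x[stats::complete.cases(x), , drop = FALSE])
  n <- nrow(x); p <- ncol(x)
  if (n < 2) stop_input("need at least 2 complete rows")
  R <- stats::cor(x)
  chi2 <- -((n - 1) - (2 * p + 5) / 6) * determinant(R, logarithm = TRUE)$modulus[1]
  df <- p * (p - 1) / 2
  pval <- stats::pchisq(chi2, df, lower.tail = FALSE)
  Ri <- tryCatch(solve(R), error = function(e) {
    warning("singular correlation matrix; KMO uses a pseudo-inverse")
    e_dec <- eigen(R, symmetric = TRUE)
    pos <- e_dec$values > 1e-10
    e_dec$vectors[, pos] %*% diag(1 / e_dec$values[pos], sum(pos)) %*% t(e_dec$vectors[, pos])
  })
  d <- 1 / sqrt(diag(Ri))
  Q <- -Ri * tcrossprod(d)                   # partial correlations
  off <- upper.tri(R)
  kmo <- sum(R[off]^2) / (sum(R[off]^2) + sum(Q[off]^2))
  list(bartlett_chi2 = as.numeric(chi2), bartlett_df = df,
       bartlett_p = as.numeric(pval), kmo = kmo)
}

#' Fit the factor model
#'
#' Extraction is by principal components of the correlation matrix; factors
#' are retained while their eigenvalue exceeds 1, and the retained loadings
#' are varimax-rotated with Kaiser normalization. Regression-method score
#' weights \eqn{W = R^{-1}\Lambda} are stored with the model. Rows with any
#' missing parameter (single-element calls) are dropped listwise and counted.
#'
#' @param feature_table transformed feature table (data.frame with the 22
#'   parameter columns, or any numeric set of columns named in `spec`).
#' @param spec optional [transform_spec()]; when supplied its parameter names
#'   select the columns, otherwise all numeric columns are used.
#' @param rotate apply varimax rotation (default `TRUE`).
#' @return object of class `factor_model`: `loadings` (rotated), `eigenvalues`
#'   (all p), `variance_explained` (% per retained factor, rotated),
#'   `n_factors`, `score_weights`, `center`, `scale`, `diagnostics`,
#'   `n_dropped`.
#' @export
fit_factor_model <- function(feature_table, spec = NULL, rotate = TRUE) {
  cols <- if (!is.null(spec)) names(spec$transforms) else {
    names(feature_table)[vapply(feature_table, is.numeric, logical(1))]
  }
  x <- as.matrix(feature_table[, cols, drop = FALSE])
  cc <- stats::complete.cases(x)
  n_dropped <- sum(!cc)
  x <- x[cc, , drop = FALSE]
  if (nrow(x) < ncol(x) + 1) stop_input("need more rows (%d) than variables (%d)",
                                        nrow(x), ncol(x))
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0)) stop_input("constant parameter column(s): %s",
                                paste(cols[scl == 0], collapse = ", "))
  R <- stats::cor(x)
  e <- eigen(R, symmetric = TRUE)
  n_factors <- sum(e$values > 1 + 1e-8)    # tolerance guards exact-identity input
  if (n_factors == 0) stop_input("no eigenvalue exceeds 1; nothing to retain")
  L <- e$vectors[, seq_len(n_factors), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(n_factors)]), n_factors)
  rownames(L) <- cols
  if (rotate && n_factors > 1) {
    rot <- stats::varimax(L, normalize = TRUE)
    L <- L %*% rot$rotmat
  }
  # order rotated factors by explained variance, sign so each column's
  # largest-magnitude loading is positive
  ssl <- colSums(L^2)
  ord <- order(ssl, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  ssl <- ssl[ord]
  for (k in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, k])), k] < 0) L[, k] <- -L[, k]
  }
  colnames(L) <- paste0("factor", seq_len(n_factors))
  W <- solve(R, L)
  structure(list(
    loadings = L, eigenvalues = e$values,
    variance_explained = 100 * ssl / ncol(x),
    n_factors = n_factors, score_weights = W,
    center = ctr, scale = scl,
    diagnostics = sampling_adequacy(x),
    n_dropped = n_dropped, parameters = cols
  ), class = "factor_model")
}

#' Regression-method factor scores
#'
#' Scores are the standardized data (using the fitting-data means and SDs)
#' multiplied by the stored regression weights, so they have mean zero over
#' the fitting data by construction.
#'
#' @param feature_table transformed feature table containing the model's
#'   parameter columns; rows with missing parameters get `NA` scores.
#' @param model a [fit_factor_model()].
#' @return data.frame of `factor1..factorK` scores, one row per input row.
#' @export
factor_scores <- function(feature_table, model) {
  stopifnot(inherits(model, "factor_model"))
  missing_cols <- setdiff(model$parameters, names(feature_table))
  if (length(missing_cols)) stop_input("unseen parameter names: %s",
                                       paste(missing_cols, collapse = ", "))
  x <- as.matrix(feature_table[, model$parameters, drop = FALSE])
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  s <- z %*% model$score_weights
  out <- as.data.frame(s)
  names(out) <- colnames(model$loadings)
  out
}

#' Serialize a factor model (with its transform spec) to JSON
#'
#' @param model a [fit_factor_model()].
#' @param spec the [transform_spec()] used upstream (optional).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_factor_model <- function(model, path, spec = NULL) {
  obj <- list(
    loadings = as.data.frame(model$loadings),
    parameters = model$parameters,
    eigenvalues = model$eigenvalues,
    variance_explained = model$variance_explained,
    n_factors = model$n_factors,
    diagnostics = model$diagnostics,
    center = as.list(model$center), scale = as.list(model$scale),
    n_dropped = model$n_dropped
  )
  if (!is.null(spec)) {
    obj$transforms <- as.list(spec$transforms)
    obj$minima <- as.list(spec$minima[!is.na(spec$minima)])
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
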