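# Gaussian linear mixed models for the factor scores, with a Gaussian-kernel
# residual temporal-autocorrelation covariate.
#
# Each factor score is modeled with male status, age, and the between/within
# androgen terms as fixed effects; random intercepts for group, male, date
# within male, and song (nested in male-date by the data geometry); and a
# random slope of within-centered androgen by male. Temporal dependence is
# absorbed by the "autocorrelation term": for every call, a Gaussian-kernel
# weighted average of the residuals of the same male's other calls, with the
# kernel bandwidth chosen to maximize the likelihood of the refitted model.

#' Gaussian-kernel autocorrelation term
#'
#' For observation i of male m, the term is the weighted average of the
#' residuals of all the male's other observations, with weights
#' \eqn{w_{ij} = \exp(-(t_i - t_j)^2 / (2\sigma^2))}. Males with a single
#' observation get 0 (flagged via the `n_other` attribute).
#'
#' @param residuals numeric residual per observation.
#' @param times observation times, continuous days.
#' @param male_ids subject label per observation.
#' @param sigma kernel SD in days (> 0).
#' @return numeric vector of autocorrelation-term values (not yet
#'   z-transformed), with attribute `n_other` (other-observation counts).
#' @export
build_ac_term <- function(residuals, times, male_ids, sigma) {
  if (!is.numeric(sigma) || sigma <= 0) stop_input("sigma must be > 0")
  n <- length(residuals)
  stopifnot(length(times) == n, length(male_ids) == n)
  out <- numeric(n)
  n_other <- integer(n)
  for (m in unique(male_ids)) {
    idx <- which(male_ids == m)
    if (length(idx) == 1) { out[idx] <- 0; n_other[idx] <- 0L; next }
    t_m <- times[idx]
    W <- exp(-outer(t_m, t_m, "-")^2 / (2 * sigma^2))
    diag(W) <- 0                              # each observation excludes itself
    out[idx] <- as.numeric(W %*% residuals[idx]) / rowSums(W)
    n_other[idx] <- length(idx) - 1L
  }
  attr(out, "n_other") <- n_other
  out
}

#' Model specification for one factor-score response
#'
#' @param response name of the response column.
#' @param slope_corr allow correlation between the random intercept and the
#'   within-androgen random slope by male (default `FALSE`: with around a
#'   dozen subjects there is little information to estimate it).
#' @return object of class `glmm_spec` carrying the lme4 formula pieces.
#' @export
glmm_spec <- function(response = "response", slope_corr = FALSE) {
  slope <- if (slope_corr) "(1 + androgen_within | male_id)" else
    "(1 | male_id) + (0 + androgen_within | male_id)"
  fixed <- c("status", "age", "androgen_between", "androgen_within")
  random <- paste("(1 | group_id)", slope, "(1 | male_id:date)", "(1 | song_id)",
                  sep = " + ")
  structure(list(response = response, fixed = fixed, random = random,
                 slope_corr = slope_corr), class = "glmm_spec")
}

glmm_formula <- function(spec, extra_fixed = NULL) {
  fixed <- paste(c(spec$fixed, extra_fixed), collapse = " + ")
  stats::as.formula(paste(spec$response, "~", fixed, "+", spec$random))
}

prepare_glmm_data <- function(data, spec) {
  need <- c(spec$response, "status", "age", "androgen_between",
            "androgen_within", "group_id", "male_id", "date", "song_id",
            "time_days")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop_input("data lacks columns: %s", paste(miss, collapse = ", "))
  data <- data[stats::complete.cases(data[, need]), , drop = FALSE]
  # subadults never enter the models; treatment coding with the pair-living
  # male and adult age class as reference levels
  data <- data[data$age %in% c("adult", "senior"), , drop = FALSE]
  data$status <- factor(data$status,
                        levels = intersect(c("pair_primary", "multi_primary", "secondary"),
                                           unique(data$status)))
  data$age <- factor(data$age, levels = intersect(c("adult", "senior"), unique(data$age)))
  data$male_id <- factor(data$male_id)
  data$group_id <- factor(data$group_id)
  data$date <- factor(data$date)
  data$song_id <- factor(data$song_id)
  data
}

lmer_quiet <- function(formula, data, reml = FALSE, optimizer = "nloptwrap") {
  ctrl <- lme4::lmerControl(optimizer = optimizer,
                            check.conv.singular = "ignore",
                            check.conv.grad = "ignore",
                            check.conv.hess = "ignore",
                            check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.rankZ = "ignore",
                            check.nobs.vs.nRE = "ignore")
  suppressMessages(suppressWarnings(
    lme4::lmer(formula, data = data, REML = reml, control = ctrl)))
}

# Likelihood-ratio tests need both models at their global optimum; the
# default optimizer occasionally stalls in a local one, so inference fits
# are run with two optimizers and the better likelihood kept.
lmer_best <- function(formula, data, reml = FALSE) {
  fits <- list(
    tryCatch(lmer_quiet(formula, data, reml, "nloptwrap"), error = function(e) NULL),
    tryCatch(lmer_quiet(formula, data, reml, "bobyqa"), error = function(e) NULL)
  )
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop_input("model failed to fit under all optimizers")
  ll <- vapply(fits, function(f) as.numeric(stats::logLik(f)), numeric(1))
  fits[[which.max(ll)]]
}

#' Fit a factor-score model with the autocorrelation term
#'
#' Procedure: (1) fit the full model without the autocorrelation term by
#' maximum likelihood and extract its residuals; (2) for candidate kernel
#' bandwidths on a log-spaced grid (smallest positive within-male lag to the
#' study span), build the z-transformed autocorrelation term from those
#' residuals, refit, and record the log-likelihood; (3) refine the best
#' bandwidth by golden-section search and return the likelihood-maximizing
#' fit. ML is used throughout the search for comparability across bandwidths;
#' the returned model is also refit by REML for variance components. The term
#' is built once from the no-AC residuals (optionally iterated with
#' `iterate_ac`).
#'
#' @param data modeling table (see [simulate_model_table()] for the columns).
#' @param spec a [glmm_spec()].
#' @param sigma_grid number of log-spaced grid points (default 25).
#' @param tol golden-section tolerance in days (default 1e-3).
#' @param iterate_ac if `TRUE`, rebuild the term from the AC-model residuals
#'   until the bandwidth changes by less than `tol` (max 10 rounds).
#' @return object of class `glmm_fit`: `model` (ML lme4 fit with the AC
#'   term), `model_reml`, `model_noac`, `residuals_used` (the no-AC-model
#'   conditional residuals the term was built from), `sigma_hat`, `logLik_profile`
#'   (data.frame sigma/logLik), `ac_term` (z-transformed values used),
#'   `data` (with `ac_term` column), `spec`.
#' @export
fit_with_ac <- function(data, spec = glmm_spec(), sigma_grid = 25, tol = 1e-3,
                        iterate_ac = FALSE) {
  data <- prepare_glmm_data(data, spec)
  for (fac in intersect(c("status", "age"), spec$fixed)) {
    if (nlevels(data[[fac]]) < 2) {
      warning(fac, " has a single level; dropped from the model")
      spec$fixed <- setdiff(spec$fixed, fac)
    }
  }
  base_form <- glmm_formula(spec)
  fit0 <- lmer_quiet(base_form, data)
  # Conditional residuals feed the autocorrelation term. Marginal residuals
  # would retain the male-level effect and the term would soak up the
  # between-male information the androgen test needs; conditional residuals
  # leak across observations only through BLUP shrinkage of very small
  # (1-2 observation) date/song groups, a caveat documented in the methods
  # vignette.
  ac_resid <- function(fit) stats::resid(fit)
  res <- ac_resid(fit0)

  lags <- unlist(lapply(split(data$time_days, data$male_id), function(t) {
    if (length(t) < 2) return(numeric(0))
    d <- abs(diff(sort(t)))
    d[d > 0]
  }), use.names = FALSE)
  lo <- max(min(lags, na.rm = TRUE), 1e-3)
  spans <- vapply(split(data$time_days, data$male_id),
                  function(t) diff(range(t)), numeric(1))
  # cap the bandwidth at a quarter of the median within-male span: beyond it
  # the kernel is nearly flat within males and the leave-one-out average
  # degenerates toward a linear function of the observation's own residual,
  # producing a spurious likelihood rise
  hi <- max(stats::median(spans[spans > 0]) / 4, lo * 2)
  grid <- exp(seq(log(lo), log(hi), length.out = sigma_grid))

  ac_form <- glmm_formula(spec, "ac_term")
  profile_rows <- list()
  eval_sigma <- function(sigma, residuals) {
    ac <- build_ac_term(residuals, data$time_days, data$male_id, sigma)
    if (stats::sd(ac) == 0) return(list(ll = -Inf))
    d2 <- data
    d2$ac_term <- as.numeric(scale(ac))
    fit <- tryCatch(lmer_quiet(ac_form, d2), error = function(e) NULL)
    if (is.null(fit)) return(list(ll = -Inf))
    list(ll = as.numeric(stats::logLik(fit)), fit = fit, data = d2)
  }

  search_sigma <- function(residuals) {
    lls <- vapply(grid, function(s) {
      r <- eval_sigma(s, residuals)
      profile_rows[[length(profile_rows) + 1L]] <<- c(sigma = s, logLik = r$ll)
      r$ll
    }, numeric(1))
    if (all(!is.finite(lls))) stop_input("no bandwidth yielded a convergent fit")
    i <- which.max(lls)
    # golden-section refinement inside the bracketing grid cells
    a <- log(grid[max(1, i - 1)]); b <- log(grid[min(length(grid), i + 1)])
    phi <- (sqrt(5) - 1) / 2
    x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
    f1 <- eval_sigma(exp(x1), residuals)$ll
    f2 <- eval_sigma(exp(x2), residuals)$ll
    while ((b - a) > tol / max(exp(a), 1)) {
      if (f1 < f2) {
        a <- x1; x1 <- x2; f1 <- f2
        x2 <- a + phi * (b - a); f2 <- eval_sigma(exp(x2), residuals)$ll
      } else {
        b <- x2; x2 <- x1; f2 <- f1
        x1 <- b - phi * (b - a); f1 <- eval_sigma(exp(x1), residuals)$ll
      }
      if ((b - a) < 1e-12) break
    }
    cand <- c(grid[i], exp((a + b) / 2))
    lls_c <- c(lls[i], eval_sigma(exp((a + b) / 2), residuals)$ll)
    cand[which.max(lls_c)]
  }

  sigma_hat <- search_sigma(res)
  if (iterate_ac) {
    for (it in 1:10) {
      r <- eval_sigma(sigma_hat, res)
      res_new <- ac_resid(r$fit)
      sigma_new <- search_sigma(res_new)
      if (abs(sigma_new - sigma_hat) < tol) { sigma_hat <- sigma_new; break }
      sigma_hat <- sigma_new
      res <- res_new
    }
  }
  best <- eval_sigma(sigma_hat, res)
  final <- tryCatch(lmer_best(ac_form, best$data), error = function(e) NULL)
  if (!is.null(final)) {
    best$fit <- final
    best$ll <- as.numeric(stats::logLik(final))
  }
  reml <- tryCatch(lmer_best(ac_form, best$data, reml = TRUE),
                   error = function(e) {
                     warning("REML refit failed; variance components from the ML fit")
                     NULL
                   })
  profile <- as.data.frame(do.call(rbind, profile_rows))
  structure(list(
    model = best$fit, model_reml = reml, model_noac = fit0,
    residuals_used = res,
    sigma_hat = sigma_hat,
    logLik = best$ll,
    logLik_profile = profile[order(profile$sigma), ],
    ac_term = best$data$ac_term, data = best$data, spec = spec
  ), class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("mixed model for %s with autocorrelation term\n", x$spec$response))
  cat(sprintf("  kernel bandwidth sigma_hat = %.3f days, logLik = %.2f\n",
              x$sigma_hat, x$logLik))
  print(summary(x$model)$coefficients)
  invisible(x)
}

#' Simes step-up adjusted p-values
#'
#' Step-up adjustment over the ordered raw p-values:
#' \eqn{\tilde p_{(i)} = \min_{j \ge i} (m/j) p_{(j)}}, capped at 1 and
#' monotone by construction.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the input order.
#' @export
simes_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")   # identical to the step-up Simes formula
}

# Likelihood-ratio p-value for dropping `term` from the full model, by the
# asymptotic chi-square or a parametric bootstrap of the LR statistic
# (simulate from the reduced fit, refit both models).
lrt_pvalue <- function(full, reduced, method = c("lrt", "bootstrap"),
                       n_boot = 1000, seed = 1) {
  method <- match.arg(method)
  stat <- 2 * (as.numeric(stats::logLik(full)) - as.numeric(stats::logLik(reduced)))
  stat <- max(stat, 0)
  df <- attr(stats::logLik(full), "df") - attr(stats::logLik(reduced), "df")
  if (method == "lrt") {
    return(list(p = stats::pchisq(stat, df, lower.tail = FALSE), stat = stat,
                df = df, n_fail = 0L))
  }
  boot_stats <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    y <- stats::simulate(reduced)[[1]]
    tryCatch({
      d2 <- full@frame
      d2[[1]] <- y
      r1 <- lmer_best(stats::formula(reduced), d2)
      r2 <- lmer_best(stats::formula(full), d2)
      2 * (as.numeric(stats::logLik(r2)) - as.numeric(stats::logLik(r1)))
    }, error = function(e) NA_real_)
  }, numeric(1)))
  n_fail <- sum(is.na(boot_stats))
  boot_stats <- boot_stats[!is.na(boot_stats)]
  p <- (sum(boot_stats >= stat) + 1) / (length(boot_stats) + 1)
  list(p = p, stat = stat, df = df, n_fail = n_fail)
}

#' Test the fixed effects across the six factor-score models
#'
#' For every fitted model and every predictor (status, age, androgen between,
#' androgen within), computes a raw p-value by a likelihood-ratio test of the
#' full model against the model without that predictor (asymptotic by
#' default, or by parametric bootstrap of the LR statistic), then applies the
#' Simes step-up adjustment across the response models per predictor.
#' Direction indicators come from the estimate signs (or the adult-vs-senior
#' contrast for age).
#'
#' @param fits named list of [fit_with_ac()] results (one per factor score).
#' @param method "lrt" (asymptotic; default) or "bootstrap" (parametric
#'   bootstrap with `n_boot` simulations).
#' @param n_boot bootstrap simulations per test.
#' @param seed integer seed for the bootstrap.
#' @return data.frame with one row per (response, predictor): `estimate`
#'   (first contrast for factors), `se`, `p_raw`, `p_adj`, `direction`.
#'   Attribute `n_fail` totals bootstrap refit failures.
#' @export
test_fixed_effects <- function(fits, method = c("lrt", "bootstrap"),
                               n_boot = 1000, seed = 1) {
  method <- match.arg(method)
  predictors <- c("androgen_between", "androgen_within", "age", "status")
  rows <- list()
  n_fail <- 0L
  for (resp in names(fits)) {
    fx <- fits[[resp]]
    dat <- fx$data
    full_form <- glmm_formula(fx$spec, "ac_term")
    full <- lmer_best(full_form, dat)
    coefs <- summary(full)$coefficients
    for (pr in predictors) {
      if (!pr %in% fx$spec$fixed) {
        warning("predictor ", pr, " has a single level in ", resp, "; dropped")
        next
      }
      drop_form <- stats::update(full_form, stats::as.formula(paste(". ~ . -", pr)))
      reduced <- lmer_best(drop_form, dat)
      lr <- lrt_pvalue(full, reduced, method, n_boot,
                       derive_seed(seed, nchar(resp) * 131L + nchar(pr)))
      n_fail <- n_fail + lr$n_fail
      est_row <- switch(pr,
        androgen_between = "androgen_between",
        androgen_within = "androgen_within",
        age = grep("^age", rownames(coefs), value = TRUE)[1],
        status = grep("^status", rownames(coefs), value = TRUE)[1])
      est <- if (!is.na(est_row) && est_row %in% rownames(coefs)) coefs[est_row, "Estimate"] else NA
      se <- if (!is.na(est_row) && est_row %in% rownames(coefs)) coefs[est_row, "Std. Error"] else NA
      direction <- if (is.na(est)) "" else if (pr == "age") {
        if (est < 0) "A>S" else "S>A"         # senior contrast vs adult reference
      } else if (est > 0) "up" else "down"
      rows[[length(rows) + 1L]] <- data.frame(
        response = resp, predictor = pr, estimate = est, se = se,
        p_raw = lr$p, df = lr$df, direction = direction,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  for (pr in unique(out$predictor)) {
    i <- out$predictor == pr
    out$p_adj[i] <- simes_adjust(out$p_raw[i])
  }
  if (method == "bootstrap" && n_fail > 0.1 * n_boot * nrow(out)) {
    warning("parametric-bootstrap non-convergence rate exceeds 10%")
  }
  attr(out, "n_fail") <- n_fail
  rownames(out) <- NULL
  out
}

#' Leave-one-subject-out stability of the fixed effects
#'
#' Refits the autocorrelation-term model once per excluded male (the
#' bandwidth is re-searched each time) and summarizes the range of every
#' fixed-effect estimate.
#'
#' @param data modeling table.
#' @param spec a [glmm_spec()].
#' @param sigma_grid grid size passed to [fit_with_ac()].
#' @return list: `estimates` (males x coefficients matrix, `NA` on refit
#'   failure), `spread` (per-coefficient min/max/range), `failed` (male ids).
#' @export
loso_stability <- function(data, spec = glmm_spec(), sigma_grid = 10) {
  males <- unique(data$male_id)
  if (length(males) < 3) stop_input("need >= 3 males for leave-one-out stability")
  est <- list()
  failed <- character(0)
  for (m in males) {
    fit <- tryCatch(
      fit_with_ac(data[data$male_id != m, , drop = FALSE], spec, sigma_grid),
      error = function(e) NULL)
    if (is.null(fit)) { failed <- c(failed, m); next }
    est[[m]] <- lme4::fixef(fit$model)
  }
  all_names <- unique(unlist(lapply(est, names)))
  mat <- matrix(NA_real_, length(est), length(all_names),
                dimnames = list(names(est), all_names))
  for (m in names(est)) mat[m, names(est[[m]])] <- est[[m]]
  spread <- data.frame(
    coefficient = all_names,
    min = apply(mat, 2, min, na.rm = TRUE),
    max = apply(mat, 2, max, na.rm = TRUE)
  )
  spread$range <- spread$max - spread$min
  rownames(spread) <- NULL
  list(estimates = mat, spread = spread, failed = failed)
}
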