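test_that("the autocorrelation term matches hand limits and excludes self", {
  # two observations per male: each term is exactly the other's residual
  r <- c(1.5, -0.7)
  ac <- build_ac_term(r, c(0, 3), c("a", "a"), sigma = 0.8)
  expect_equal(as.numeric(ac), c(-0.7, 1.5))

  # sigma -> infinity: equal weights, term = mean of the male's others
  r5 <- c(2, -1, 0.5, 3, -2)
  t5 <- c(0, 1, 4, 9, 20)
  ac_inf <- build_ac_term(r5, t5, rep("m", 5), sigma = 1e9)
  oracle_inf <- vapply(1:5, function(i) mean(r5[-i]), numeric(1))
  expect_equal(as.numeric(ac_inf), oracle_inf, tolerance = 1e-9)

  # singleton male flagged with zero term
  ac1 <- build_ac_term(c(1, 2, 3), c(0, 1, 5), c("a", "a", "b"), sigma = 2)
  expect_equal(as.numeric(ac1)[3], 0)
  expect_equal(attr(ac1, "n_other"), c(1L, 1L, 0L))

  expect_error(build_ac_term(r5, t5, rep("m", 5), sigma = 0), "sigma")
})

test_that("autocorrelation values equal a brute-force double loop", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 40
    male <- sample(c("a", "b", "c"), n, replace = TRUE)
    times <- cumsum(runif(n, 0.1, 3))
    res <- rnorm(n)
    sigma <- runif(1, 0.3, 6)
    ac <- build_ac_term(res, times, male, sigma)
    oracle <- vapply(seq_len(n), function(i) {
      num <- 0; den <- 0
      for (j in seq_len(n)) {
        if (j == i || male[j] != male[i]) next
        w <- exp(-(times[i] - times[j])^2 / (2 * sigma^2))
        num <- num + w * res[j]; den <- den + w
      }
      if (den == 0) 0 else num / den
    }, numeric(1))
    expect_equal(as.numeric(ac), oracle, tolerance = 1e-12)
  }
})

test_that("the bandwidth search returns a reproducible likelihood optimum", {
  d <- simulate_model_table(n_males = 8, days_per_male = 8, songs_per_day = 1,
                            calls_per_song = 2, sigma_ac = 0.6, seed = 44)
  fit <- fit_with_ac(d, glmm_spec(), sigma_grid = 6, tol = 0.05)
  expect_gt(fit$sigma_hat, 0)
  expect_true(all(diff(fit$logLik_profile$sigma) >= 0))

  # refitting at sigma_hat reproduces the stored log-likelihood
  dd <- fit$data
  ac <- build_ac_term(fit$residuals_used, dd$time_days, dd$male_id,
                      fit$sigma_hat)
  dd$ac_term <- as.numeric(scale(ac))
  refit <- gibbonsong:::lmer_best(formula(fit$model), dd)
  expect_equal(as.numeric(logLik(refit)), fit$logLik, tolerance = 1e-6)

  # the included AC term shrinks residual lag-1 autocorrelation on
  # autocorrelated data, relative to the fit without it
  d2 <- simulate_model_table(n_males = 10, days_per_male = 12, songs_per_day = 1,
                             calls_per_song = 1, sd_date = 0.1, sd_song = 0.1,
                             sigma_ac = 0.8, sigma_e = 0.6, seed = 45)
  f2 <- fit_with_ac(d2, glmm_spec(), sigma_grid = 6, tol = 0.05)
  lag1 <- function(res, data) {
    mean(unlist(lapply(split(seq_len(nrow(data)), data$male_id), function(i) {
      o <- i[order(data$time_days[i])]
      r <- res[o]
      if (length(r) < 3) return(NULL)
      cor(r[-1], r[-length(r)])
    })))
  }
  expect_lt(abs(lag1(resid(f2$model), f2$data)),
            abs(lag1(resid(f2$model_noac), f2$data)) + 0.05)
})

test_that("the autocorrelation term is discriminative, not spuriously loaded", {
  # Under independent residuals the likelihood gain from the selected-bandwidth
  # term stays small (flat profile); under genuine day-scale autocorrelation it
  # is several times larger. The Wald t of the term itself is not a valid null
  # statistic here: bandwidth selection and the z-transform inflate it (see the
  # methods vignette), so the test compares likelihood gains.
  gain <- function(sig_ac, seed) {
    d <- simulate_model_table(n_males = 8, days_per_male = 10, songs_per_day = 1,
                              calls_per_song = 1, sd_date = 0.1, sd_song = 0.1,
                              sigma_ac = sig_ac, ac_sigma_true = 2,
                              sigma_e = 0.6, seed = seed)
    fit <- fit_with_ac(d, glmm_spec(), sigma_grid = 5, tol = 0.2)
    fit$logLik - as.numeric(logLik(fit$model_noac))
  }
  g_null <- vapply(1:10, function(r) gain(0, 800 + r), numeric(1))
  g_ac <- vapply(1:10, function(r) gain(0.8, 800 + r), numeric(1))
  expect_lt(median(g_null), 4)                  # flat profile under the null
  expect_gt(median(g_ac), 2 * median(g_null))   # real signal separates clearly
})

test_that("Simes adjustment follows the step-up definition", {
  expect_equal(simes_adjust(c(0.01, 0.02, 0.5)), c(0.03, 0.03, 0.5))
  expect_equal(simes_adjust(rep(1, 4)), rep(1, 4))

  # direct-formula oracle: p~(i) = min_{j>=i} (m/j) p_(j)
  set.seed(3)
  for (rep in 1:20) {
    p <- runif(6)^2
    o <- order(p)
    m <- length(p)
    adj_sorted <- rev(cummin(rev(pmin(1, (m / seq_len(m)) * p[o]))))
    oracle <- numeric(m); oracle[o] <- adj_sorted
    mine <- simes_adjust(p)
    expect_equal(mine, oracle, tolerance = 1e-12)
    expect_true(all(mine >= p & mine <= 1))
    expect_equal(order(mine[o]), seq_len(m))  # order-preserving
  }
})

test_that("fixed-effect tests report estimates, raw and adjusted p-values", {
  d <- simulate_model_table(n_males = 10, days_per_male = 3, calls_per_song = 6,
                            beta = c(intercept = 0, androgen_between = 1,
                                     androgen_within = 0, age_senior = 0,
                                     status_multi_primary = 0, status_secondary = 0),
                            seed = 52)
  fit <- fit_with_ac(d, glmm_spec(), sigma_grid = 5, tol = 0.2)
  eff <- test_fixed_effects(list(factor1 = fit), method = "lrt")
  expect_setequal(eff$predictor,
                  c("androgen_between", "androgen_within", "age", "status"))
  expect_true(all(eff$p_adj >= eff$p_raw - 1e-12))
  expect_true(all(eff$p_adj <= 1))
  b <- eff[eff$predictor == "androgen_between", ]
  expect_lt(b$p_raw, 0.05)
  expect_equal(b$direction, "up")

  # single-level age: predictor dropped with a warning
  d_ad <- d[d$age == "adult", ]
  fit_ad <- fit_with_ac(d_ad, glmm_spec(), sigma_grid = 4, tol = 0.2)
  expect_warning(eff_ad <- test_fixed_effects(list(factor1 = fit_ad), method = "lrt"),
                 "single level")
  expect_false("age" %in% eff_ad$predictor)

  # parametric bootstrap path returns valid probabilities on a small case
  pb <- gibbonsong:::lrt_pvalue(
    fit$model,
    gibbonsong:::lmer_best(update(formula(fit$model), . ~ . - androgen_between),
                           fit$data),
    method = "bootstrap", n_boot = 19, seed = 2)
  expect_true(pb$p >= 1 / 20 && pb$p <= 1)
})

test_that("leave-one-subject-out refits are stable for homogeneous males", {
  d <- simulate_model_table(n_males = 7, days_per_male = 3, calls_per_song = 6,
                            seed = 61)
  st <- loso_stability(d, glmm_spec(), sigma_grid = 4)
  expect_equal(nrow(st$estimates), 7)
  expect_length(st$failed, 0)
  full <- fit_with_ac(d, glmm_spec(), sigma_grid = 4, tol = 0.2)
  se_b <- summary(full$model)$coefficients["androgen_between", "Std. Error"]
  expect_lt(st$spread$range[st$spread$coefficient == "androgen_between"], 4 * se_b)

  # a planted outlier male produces the extreme estimate when excluded
  d_out <- d
  out_male <- "M03"
  d_out$response[d_out$male_id == out_male] <-
    d_out$response[d_out$male_id == out_male] + 20
  st_out <- loso_stability(d_out, glmm_spec(), sigma_grid = 4)
  # removing the outlier yields the one uncontaminated (extreme low) intercept
  ints <- st_out$estimates[, "(Intercept)"]
  expect_equal(names(which.min(ints)), out_male)

  expect_error(loso_stability(d[d$male_id %in% c("M01", "M02"), ]), ">= 3 males")
})
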