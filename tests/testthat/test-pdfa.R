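test_that("balanced selection is exact, deterministic, and uniform", {
  d <- simulate_call_features(n_males = 10, calls_per_male = 30, seed = 1)
  sel <- balanced_selection(d, n_select = 23, seed = 5)
  expect_length(sel$train, 230)
  expect_length(sel$heldout, 70)
  expect_true(all(table(d$male_id[sel$train]) == 23))
  expect_identical(sel, balanced_selection(d, n_select = 23, seed = 5))

  expect_message(balanced_selection(d[1:40, ], n_select = 25, seed = 1),
                 "excluding")

  # per-call selection frequencies are uniform (chi-square goodness of fit)
  d1 <- d[d$male_id == "M01", ]
  hits <- numeric(30)
  for (r in 1:2000) {
    s <- balanced_selection(d1, n_select = 10, seed = r)
    hits[s$train] <- hits[s$train] + 1
  }
  chi <- sum((hits - mean(hits))^2 / mean(hits))
  expect_gt(pchisq(chi, df = 29, lower.tail = FALSE), 0.01)
})

test_that("cross-classification matches separable truth and the MASS oracle", {
  # two males, centroids 10 within-SDs apart: perfect classification
  d <- simulate_call_features(n_males = 2, calls_per_male = 20, separation = 10,
                              seed = 3)
  sel <- balanced_selection(d, n_select = 12, seed = 1)
  expect_equal(classify_heldout(d[sel$train, ], d[sel$heldout, ]), 100)

  # agreement with MASS::lda (the field-standard engine) on overlapping classes
  d3 <- simulate_call_features(n_males = 3, calls_per_male = 25, separation = 1.5,
                               n_features = 6, seed = 8)
  cols <- sprintf("f%02d", 1:6)
  fit <- gibbonsong:::lda_fit(d3[, cols], d3$male_id)
  mine <- gibbonsong:::lda_predict(fit, d3[, cols])
  mass <- MASS::lda(d3[, cols], grouping = d3$male_id,
                    prior = rep(1 / 3, 3))
  expect_equal(mine, as.character(predict(mass, d3[, cols])$class))

  # shuffled labels classify at chance
  set.seed(42)
  rates <- replicate(100, {
    ds <- d3
    ds$male_id <- sample(ds$male_id)
    sel <- suppressMessages(balanced_selection(ds, n_select = 15,
                                               seed = sample.int(1e6, 1)))
    classify_heldout(ds[sel$train, ], ds[sel$heldout, ], cols)
  })
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 100 / 3), 3 * se + 1e-9)
})

test_that("ridge regularization handles rank-deficient features", {
  d <- simulate_call_features(n_males = 3, calls_per_male = 10, n_features = 4,
                              seed = 2)
  d$f05 <- d$f01 + d$f02                      # exactly collinear
  fit <- gibbonsong:::lda_fit(d[, sprintf("f%02d", 1:5)], d$male_id)
  expect_gt(fit$ridge_eps, 0)
  pred <- gibbonsong:::lda_predict(fit, d[, sprintf("f%02d", 1:5)])
  expect_length(pred, nrow(d))
})

test_that("day-block permutation conserves blocks and is uniform", {
  d <- simulate_call_features(n_males = 3, calls_per_male = 12, days_per_male = 3,
                              seed = 4)
  orig_days <- table(unique(d[, c("male_id", "recording_day")])$male_id)
  perm <- permute_day_blocks(d, seed = 9)
  perm_days <- table(unique(perm[, c("male_id", "recording_day")])$male_id)
  expect_equal(as.vector(perm_days), as.vector(orig_days))
  # calls of one day stay together under one label
  expect_true(all(tapply(perm$male_id, perm$recording_day,
                         function(x) length(unique(x))) == 1))

  # each block visits each male uniformly over repeated permutations
  visits <- matrix(0, 9, 3, dimnames = list(unique(d$recording_day),
                                            unique(d$male_id)))
  for (r in 1:1800) {
    p <- permute_day_blocks(d, seed = r)
    b <- unique(p[, c("recording_day", "male_id")])
    visits[cbind(b$recording_day, b$male_id)] <-
      visits[cbind(b$recording_day, b$male_id)] + 1
  }
  expected <- 1800 / 3
  chi <- sum((visits - expected)^2 / expected)
  expect_gt(pchisq(chi, df = 9 * 2, lower.tail = FALSE), 0.01)

  d2 <- simulate_call_features(n_males = 2, calls_per_male = 4, days_per_male = 1,
                               seed = 1)
  expect_warning(permute_day_blocks(d2, seed = 1), "degenerate")
})

test_that("pDFA p-values respect their floor and the observed-as-permutation rule", {
  d <- simulate_call_features(n_males = 5, calls_per_male = 15, separation = 6,
                              n_features = 8, seed = 6)
  r <- run_pdfa(d, n_select = 10, n_selections = 5, n_permutations = 50,
                perm_selections = 2, seed = 3)
  expect_equal(r$chance_level, 20)
  expect_equal(r$p_value, 1 / 50)            # floor: observed counted once
  expect_length(r$perm_rates, 49)
  expect_length(r$per_selection_rates, 5)
  expect_gt(r$observed_rate, 95)

  # increasing separation never decreases the mean observed rate
  rates <- vapply(c(0.5, 2, 6), function(sep) {
    dd <- simulate_call_features(n_males = 4, calls_per_male = 12,
                                 separation = sep, n_features = 6, seed = 7)
    mean(vapply(1:10, function(s) {
      sel <- balanced_selection(dd, n_select = 8, seed = s)
      classify_heldout(dd[sel$train, ], dd[sel$heldout, ])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("all-calls DFA structure matches a direct correlation oracle", {
  d <- simulate_call_features(n_males = 2, calls_per_male = 15, separation = 3,
                              n_features = 5, seed = 10)
  s <- dfa_structure(d)
  expect_equal(s$n_functions, 1)              # k - 1 bound

  d3 <- simulate_call_features(n_males = 4, calls_per_male = 15, separation = 2,
                               n_features = 6, seed = 11)
  s3 <- dfa_structure(d3)
  cols <- sprintf("f%02d", 1:6)
  oracle <- cor(as.matrix(d3[, cols]), s3$scores)
  expect_equal(unname(s3$loadings), unname(oracle), tolerance = 1e-10)

  # a single planted discriminative variable dominates the first function
  set.seed(13)
  n <- 120
  planted <- data.frame(
    male_id = rep(c("A", "B", "C"), each = n / 3),
    recording_day = rep(1:6, each = n / 6),
    f01 = rnorm(n) + rep(c(-4, 0, 4), each = n / 3),
    f02 = rnorm(n), f03 = rnorm(n), f04 = rnorm(n)
  )
  sp <- dfa_structure(planted)
  expect_equal(which.max(abs(sp$loadings[, 1])), c(f01 = 1))
  expect_true("f01" %in% sp$flagged$feature)
})
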