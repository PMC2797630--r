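test_that("design matrices standardize on training statistics", {
  set.seed(41)
  tr <- matrix(rnorm(58 * 4), 58, 4,
               dimnames = list(NULL, c("a", "b", "c", "d")))
  te <- matrix(rnorm(2 * 4), 2, 4, dimnames = list(NULL, colnames(tr)))
  des <- build_design(tr, te)
  expect_equal(dim(des$train), c(58L, 5L))
  expect_equal(dim(des$test), c(2L, 5L))
  expect_equal(colMeans(des$train[, -1]), rep(0, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(apply(des$train[, -1], 2, sd), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  # affine images of the training predictors standardize identically
  tr2 <- sweep(sweep(tr, 2, c(2, 3, 0.5, 10), `*`), 2, c(1, -2, 0, 5), `+`)
  des2 <- build_design(tr2, sweep(sweep(te, 2, c(2, 3, 0.5, 10), `*`),
                                  2, c(1, -2, 0, 5), `+`))
  expect_equal(des2$train, des$train, tolerance = 1e-12)
  expect_equal(des2$test, des$test, tolerance = 1e-12)
  expect_error(build_design(cbind(tr, tr[, 1])), "rank deficient")
  trna <- tr; trna[1, 1] <- NA
  expect_error(build_design(trna), "missing predictor")
})

test_that("the per-voxel regression recovers exact coefficients", {
  set.seed(43)
  X <- cbind(1, matrix(rnorm(58 * 4), 58, 4))
  B <- matrix(rnorm(5 * 30), 5, 30)
  Y <- X %*% B
  fit <- fit_generative(X, Y)
  expect_equal(unname(fit$coefficients), B, tolerance = 1e-9)
  # per-voxel independence: permuting voxels permutes coefficients
  perm <- sample(30)
  fit2 <- fit_generative(X, Y[, perm])
  expect_equal(fit2$coefficients, fit$coefficients[, perm],
               tolerance = 1e-12)
  expect_error(fit_generative(cbind(X, X[, 2]), Y), "rank deficient")
})

test_that("cosine pair matching picks the right pairing", {
  p <- rbind(c(1, 0, 0.2), c(0, 1, 0.1))
  expect_true(predict_and_match(p, p)$correct)
  expect_false(predict_and_match(p, p[c(2, 1), ])$correct)
  # orthogonal cross-pairs, positive straight cosines
  p2 <- rbind(c(1, 0), c(0, 1))
  o2 <- rbind(c(2, 0), c(0, 3))
  res <- predict_and_match(p2, o2)
  expect_true(res$correct)
  expect_equal(res$straight, 2)
  expect_equal(res$swapped, 0)
  # invariance to positive rescaling of any image
  res2 <- predict_and_match(p2 * 10, o2)
  expect_equal(res2$straight, res$straight)
  # exact ties count as incorrect
  tie <- predict_and_match(rbind(c(1, 0), c(1, 0)), rbind(c(1, 0), c(1, 0)))
  expect_false(tie$correct)
  expect_error(predict_and_match(rbind(c(0, 0), c(1, 0)), o2), "zero-norm")
})

test_that("fold enumeration counts match the design", {
  expect_length(cv_folds(6, 2), 15L)
  expect_length(cv_folds(60, 2), 1770L)
})

test_that("the binomial chance threshold reproduces known values", {
  # 1,770 matching trials at alpha = .001
  expect_equal(round(chance_match_threshold(1770, 0.001), 3), 0.537)
  # 10 trials: only a perfect run beats the bound (2^-10 < .001)
  expect_equal(chance_match_threshold(10, 0.001), 1.0)
  # exact-binomial oracle at a small n
  n <- 25
  k_oracle <- min(which(sapply(0:n, function(k) {
    sum(choose(n, k:n)) / 2^n
  }) <= 0.01)) - 1
  expect_equal(chance_match_threshold(n, 0.01), k_oracle / n)
  # large n: threshold approaches 0.5
  expect_lt(chance_match_threshold(1e6, 0.001), 0.502)
  expect_error(chance_match_threshold(100, 1.5), "alpha")
})

test_that("rating-aligned factor scores match their target dimensions", {
  sim <- fix_discovery()
  fm <- fix_discovery_model()
  rat <- generate_ratings(sim$truth, rating_noise_sd = 0, seed = 3)
  targets <- as.matrix(rat[, c("shelter", "manipulation", "eating",
                               "length")])
  al <- align_scores_to_targets(
    fm$model$second_level$profiles[fm$top, , drop = FALSE], targets)
  expect_equal(rownames(al$scores),
               c("shelter", "manipulation", "eating", "length"))
  for (i in 1:4) {
    expect_gt(cor(al$scores[i, ], targets[, i]), 0.9)
  }
})

test_that("zero-shot matching is near-perfect on effectively noiseless data", {
  sim <- fix_clean()
  rat <- generate_ratings(sim$truth, rating_noise_sd = 0, seed = 5)
  m <- leave_two_words_out(sim$dataset, 1, rat, pairs = 10, seed = 6,
                           predictors = "ratings")
  expect_equal(m$accuracy, 1.0)
  expect_equal(m$n_folds, 10L)
})

test_that("zero-shot selection never sees the held-out words", {
  sim <- fix_discovery()
  ds <- sim$dataset
  pair <- c(7L, 33L)
  train_idx <- setdiff(1:60, pair)
  ds2 <- ds
  ds2$values[, , pair, ] <- rnorm(length(ds2$values[, , pair, ]))
  s1 <- voxel_stability(subset_words(ds, train_idx), 1)
  s2 <- voxel_stability(subset_words(ds2, train_idx), 1)
  expect_identical(s1, s2)
})

test_that("cross-participant generative prediction works for a shared code", {
  sim <- fix_discovery()
  rat <- generate_ratings(sim$truth, rating_noise_sd = 0, seed = 5)
  cg <- cross_participant_generative(sim$dataset, rat, participants = 1,
                                     pairs = 5, seed = 9)
  expect_equal(cg$mean_accuracy, 1.0)
  expect_length(cg$results[["1"]], 5L)
})
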