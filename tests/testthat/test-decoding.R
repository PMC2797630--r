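test_that("semantic-stability scores multiply correlation and stability", {
  set.seed(2)
  f <- rnorm(20)
  v <- f * 0.9 + rnorm(20) * sqrt(1 - 0.81) # correlation ~0.9
  r <- cor(v, f)
  expect_equal(semantic_stability_score(v, f, 0.5), abs(r) * 0.5)
  expect_equal(semantic_stability_score(f, f, 1), 1)
  expect_equal(semantic_stability_score(-f, f, 0.5), 0.5)  # abs convention
  expect_equal(semantic_stability_score(-f, f, 0.5, use_abs = FALSE), -0.5)
  expect_error(semantic_stability_score(rep(1, 20), f, 1), "constant")
})

test_that("GNB pooled variance follows the sample-variance convention", {
  # class A {-1, 1}, class B {1, 3}: means 0 and 2, pooled var 4/3
  x <- matrix(c(-1, 1, 1, 3), ncol = 1)
  m <- gnb_fit(x, c("A", "A", "B", "B"))
  expect_equal(as.numeric(m$means), c(0, 2))
  expect_equal(unname(m$pooled_var), 4 / 3)
  expect_equal(m$priors, c(0.5, 0.5))
  # order invariance
  m2 <- gnb_fit(x[c(3, 1, 4, 2), , drop = FALSE], c("B", "A", "B", "A"))
  expect_equal(m2$pooled_var, m$pooled_var)
  expect_equal(m2$means[c("A", "B"), 1], m$means[c("A", "B"), 1])
  # degenerate: zero within-class variance
  xz <- matrix(c(0, 0, 2, 2), ncol = 1)
  expect_error(gnb_fit(xz, c("A", "A", "B", "B")), "zero pooled variance")
})

test_that("GNB ranking matches hand-computed Gaussian log-likelihoods", {
  x <- matrix(c(-1, 1, 1, 3), ncol = 1)
  m <- gnb_fit(x, c("A", "A", "B", "B"))
  m$pooled_var <- 1  # hand case uses unit variance
  ranked <- gnb_rank(m, 0.5)
  # log-liks: -0.125 (mean 0) vs -1.125 (mean 2), plus equal priors
  expect_equal(ranked$label, c("A", "B"))
  expect_equal(diff(rev(ranked$log_posterior)), -0.125 - (-1.125))
  # equidistant test point: tie broken by class order in the model
  tie <- gnb_rank(m, 1)
  expect_equal(tie$label[1], "A")
})

test_that("GNB ranking equals a brute-force density oracle", {
  set.seed(31)
  for (rep in 1:10) {
    n_class <- sample(2:4, 1)
    n_feat <- sample(1:3, 1)
    x <- matrix(rnorm(n_class * 3 * n_feat), n_class * 3, n_feat)
    y <- rep(letters[1:n_class], each = 3)
    m <- gnb_fit(x, y)
    xt <- rnorm(n_feat)
    ranked <- gnb_rank(m, xt)
    dens <- vapply(seq_len(n_class), function(ci) {
      prod(dnorm(xt, m$means[ci, ], sqrt(m$pooled_var))) * m$priors[ci]
    }, numeric(1))
    oracle <- m$classes[order(-dens)]
    expect_equal(ranked$label, oracle)
  }
})

test_that("normalized rank accuracy maps ranks to [0, 1] with chance 0.5", {
  expect_equal(rank_accuracy(1, 60), 1)
  expect_equal(rank_accuracy(60, 60), 0)
  expect_equal(mean(rank_accuracy(1:60, 60)), 0.5)  # uniform-rank mean
  expect_error(rank_accuracy(0, 60), "out of range")
  expect_error(rank_accuracy(61, 60), "out of range")
})

test_that("GNB accuracy is invariant to feature order", {
  set.seed(5)
  x <- matrix(rnorm(40), 10, 4)
  y <- rep(c("a", "b"), 5)
  m <- gnb_fit(x, y)
  xt <- rnorm(4)
  r1 <- gnb_rank(m, xt)
  perm <- c(3, 1, 4, 2)
  m2 <- gnb_fit(x[, perm], y)
  r2 <- gnb_rank(m2, xt[perm])
  expect_equal(r1$label, r2$label)
})

test_that("within-participant CV enumerates 15 folds and separates clean data", {
  sim <- fix_clean()
  res <- within_participant_cv(sim$dataset, 1,
                               list(mode = "stability_only",
                                    n_features = 80))
  expect_length(res$folds, choose(6, 2))
  expect_equal(res$mean_accuracy, 1.0)
  expect_true(all(res$fold_accuracy >= 0 & res$fold_accuracy <= 1))
})

test_that("feature selection never touches held-out presentations", {
  sim <- fix_discovery()
  ds <- sim$dataset
  train_pres <- c(1, 2, 3, 4)
  stab1 <- voxel_stability(ds, 1, train_pres)
  ds2 <- ds
  ds2$values[1, 5:6, , ] <- rnorm(length(ds2$values[1, 5:6, , ]))
  stab2 <- voxel_stability(ds2, 1, train_pres)
  expect_identical(stab1, stab2)
  f1 <- select_stable_voxels(stab1, 80)
  f2 <- select_stable_voxels(stab2, 80)
  expect_identical(f1, f2)
})

test_that("factor-based selection yields per-volume features of the planted code", {
  sim <- fix_discovery()
  fm <- fix_discovery_model()
  volumes <- make_search_volumes(fm$localization, sim$dataset)
  expect_length(volumes, 16L)
  stab <- voxel_stability(sim$dataset, 1, 1:4)
  prof <- normalize_across_words(
    mean_word_profiles(sim$dataset, 1, 1:4)$profiles)
  fs <- select_features(prof, stab, "factor_based", volumes = volumes,
                        factor_profiles = fm$model$second_level$profiles,
                        grid = sim$dataset$voxels)
  expect_equal(nrow(fs), 80L)
  expect_s3_class(fs, "feature_set")
  # single-factor mode restricts to that factor's volumes
  f1 <- volumes[[1]]$factor
  n1 <- sum(vapply(volumes, function(v) v$factor == f1, logical(1)))
  fs1 <- select_features(prof, stab, "single_factor", volumes = volumes,
                         factor_profiles = fm$model$second_level$profiles,
                         grid = sim$dataset$voxels, factor_ids = f1)
  expect_equal(nrow(fs1), 5L * n1)
  # selected features overwhelmingly lie in planted clusters
  planted <- unique(unlist(sim$truth$clusters$members))
  expect_gt(mean(fs$voxel %in% planted), 0.9)
})

test_that("within-category identification is harder than random candidates", {
  sim <- fix_discovery()
  res <- within_participant_cv(sim$dataset, 1,
                               list(mode = "stability_only",
                                    n_features = 80),
                               keep_posteriors = TRUE)
  wc <- within_category_accuracy(res, sim$dataset$words,
                                 random_control = TRUE, seed = 7)
  expect_true(wc$within_category >= 0 && wc$within_category <= 1)
  expect_true(wc$random_candidates >= 0 && wc$random_candidates <= 1)
  # category structure in the planted semantic profiles makes same-category
  # words more confusable than random ones
  expect_lt(wc$within_category, wc$random_candidates + 1e-9)
})

test_that("cross-participant CV decodes a shared code but not the held-out data", {
  sim <- fix_discovery()
  res <- cross_participant_cv(sim$dataset,
                              list(mode = "stability_only",
                                   n_features = 80))
  expect_length(res$per_participant, 4L)
  expect_gt(res$mean_accuracy, 0.9)
  # guard: perturbing the held-out participant's data does not change
  # cross-participant stability for the training set
  ds2 <- sim$dataset
  ds2$values[1, , , ] <- 0
  s_a <- voxel_stability(sim$dataset, participants = 2:4)
  s_b <- voxel_stability(ds2, participants = 2:4)
  expect_identical(s_a, s_b)
})

test_that("permutation thresholds are reproducible and near chance", {
  sim <- fix_discovery()
  cvf <- function(ps) {
    within_participant_cv(sim$dataset, 1,
                          list(mode = "stability_only", n_features = 40),
                          permute_seed = ps)
  }
  thr1 <- permutation_threshold(cvf, n_permutations = 5, alpha = 0.2,
                                seed = 77)
  thr2 <- permutation_threshold(cvf, n_permutations = 5, alpha = 0.2,
                                seed = 77)
  expect_equal(as.numeric(thr1), as.numeric(thr2))
  accs <- attr(thr1, "accuracies")
  expect_true(all(abs(accs - 0.5) < 0.15))
  expect_gt(as.numeric(thr1), 0.5 - 0.15)
})
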