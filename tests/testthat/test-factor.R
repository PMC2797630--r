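# analytic one-factor correlation structure: R_ij = l_i l_j, unit diagonal
one_factor_R <- function(l) {
  R <- outer(l, l)
  diag(R) <- 1
  R
}

test_that("principal axis factoring recovers an analytic one-factor model", {
  l <- c(0.9, 0.8, 0.7)
  fit <- principal_axis_factoring(one_factor_R(l), k = 1)
  expect_equal(abs(as.numeric(fit$loadings)), l, tolerance = 1e-3)
})

test_that("an identity correlation matrix yields near-zero loadings", {
  fit <- principal_axis_factoring(diag(6), k = 1)
  expect_lt(max(abs(fit$loadings)), 1e-3)
})

test_that("PAF recovers a planted rank-2 loading subspace", {
  set.seed(7)
  L <- cbind(c(0.8, 0.7, 0.6, 0.1, 0.1, 0.1),
             c(0.1, 0.1, 0.1, 0.8, 0.7, 0.6))
  R <- L %*% t(L)
  diag(R) <- 1
  fit <- principal_axis_factoring(R, k = 2)
  # oracle: eigendecomposition of the noiseless reduced matrix
  Rh <- R
  diag(Rh) <- rowSums(L^2)
  eo <- eigen(Rh, symmetric = TRUE)
  oracle <- eo$vectors[, 1:2]
  # principal angles between the two 2-D subspaces ~ 0
  qa <- qr.Q(qr(fit$loadings))
  qb <- qr.Q(qr(oracle))
  angles <- acos(pmin(svd(t(qa) %*% qb)$d, 1))
  expect_lt(max(angles), 1e-3)
})

test_that("PAF validates its input matrix", {
  R <- one_factor_R(c(0.9, 0.8, 0.7))
  expect_error(principal_axis_factoring(R, k = 3), "smaller")
  R2 <- R; R2[1, 2] <- 0.5
  expect_error(principal_axis_factoring(R2, k = 1), "symmetric")
  R3 <- R; diag(R3) <- 2
  expect_error(principal_axis_factoring(R3, k = 1), "unit diagonal")
})

# varimax criterion with Kaiser row normalization, for the oracle
varimax_criterion <- function(L) {
  h <- sqrt(rowSums(L^2))
  W <- L / h
  sum(apply(W^2, 2, function(col) mean(col^2) - mean(col)^2))
}

test_that("varimax rotation matches a rotation-angle grid search on 2-factor toys", {
  # simple structure mixed by a 35-degree rotation
  S <- rbind(c(0.9, 0), c(0, 0.8), c(0.85, 0.1), c(0.05, 0.7))
  th0 <- 35 * pi / 180
  mix <- matrix(c(cos(th0), -sin(th0), sin(th0), cos(th0)), 2, 2)
  L <- S %*% mix
  out <- varimax_rotate(L, eps = 1e-12)
  # oracle: exhaustive grid over the 2-D rotation angle (both reflections)
  thetas <- seq(0, pi, length.out = 40001)
  crits <- vapply(thetas, function(th) {
    Rm <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    varimax_criterion(L %*% Rm)
  }, numeric(1))
  expect_gte(varimax_criterion(out$loadings), max(crits) - 1e-6)
  # the mixture rotates back to near-axis simple structure
  expect_equal(sort(abs(as.numeric(out$loadings))),
               sort(abs(as.numeric(S))), tolerance = 0.05)
})

test_that("varimax preserves communalities and returns an orthonormal rotation", {
  set.seed(3)
  L <- matrix(rnorm(30), 10, 3)
  out <- varimax_rotate(L)
  expect_equal(t(out$rotmat) %*% out$rotmat, diag(3), tolerance = 1e-10)
  expect_equal(rowSums(out$loadings^2), rowSums(L^2), tolerance = 1e-10)
  expect_equal(L %*% out$rotmat, out$loadings, tolerance = 1e-12,
               ignore_attr = TRUE)
  # simple structure is a fixed point up to column sign/order
  S <- rbind(c(1, 0), c(0, 1), c(0.9, 0), c(0, 0.8))
  fs <- varimax_rotate(S)
  expect_equal(sort(abs(as.numeric(fs$loadings))),
               sort(abs(as.numeric(S))), tolerance = 1e-6)
})

test_that("factor profiles solve the least-squares system", {
  V <- matrix(rnorm(4 * 6), 4, 6)
  expect_equal(solve_factor_profiles(diag(4), V), V, ignore_attr = TRUE)
  # hand case: C = [[2], [0]], V = [2f; 0] -> f
  f <- rnorm(6)
  C <- matrix(c(2, 0), 2, 1)
  V2 <- rbind(2 * f, rep(0, 6))
  expect_equal(as.numeric(solve_factor_profiles(C, V2)), f,
               tolerance = 1e-12)
  # exact recovery of planted profiles
  C3 <- matrix(rnorm(12), 4, 3)
  F3 <- matrix(rnorm(18), 3, 6)
  expect_equal(unname(solve_factor_profiles(C3, C3 %*% F3)), F3,
               tolerance = 1e-9)
  expect_error(solve_factor_profiles(cbind(C, C), V2), "rank deficient")
})

test_that("threshold assignment follows the maximum absolute loading rule", {
  expect_equal(assign_by_max_loading(c(0.5, 0.3)), 1L)
  expect_true(is.na(assign_by_max_loading(c(0.35, 0.30))))
  expect_equal(assign_by_max_loading(c(-0.45, 0.2)), 1L)
  expect_equal(assign_by_max_loading(c(0.1, 0.41, 0.2)), 2L)
  expect_equal(assign_by_max_loading(c(0.2, 0.3), threshold = 0.25), 2L)
})

test_that("first-level analysis recovers a planted single factor per lobe", {
  cfg <- synthetic_config(n_participants = 1, clusters_per_factor = 1,
                          noise_sd = 0.15, seed = 51)
  sim <- generate_dataset(cfg)
  # factor f is planted in region f (round-robin assignment)
  for (f in 1:2) {
    reg <- sim$truth$clusters$table$region[
      sim$truth$clusters$table$factor == rownames(sim$truth$profiles)[f]]
    fm <- first_level_analysis(sim$dataset, 1, reg, n_voxels = 30,
                               n_factors = 3)
    r <- abs(cor(fm$profiles[1, ], sim$truth$profiles[f, ]))
    expect_gte(r, 0.9)
  }
})

test_that("varimax rotation does not change the least-squares fit", {
  set.seed(11)
  C <- matrix(rnorm(40), 10, 4)
  V <- C %*% matrix(rnorm(24), 4, 6) + matrix(rnorm(60), 10, 6) * 0.1
  F1 <- solve_factor_profiles(C, V)
  rot <- varimax_rotate(C)
  F2 <- solve_factor_profiles(rot$loadings, V)
  expect_equal(sum((V - C %*% F1)^2),
               sum((V - rot$loadings %*% F2)^2), tolerance = 1e-9)
})

test_that("duplicated second-level inputs receive identical loadings", {
  set.seed(13)
  base <- matrix(rnorm(12 * 60), 12, 60)
  P <- rbind(base, base[1:2, ])
  fm <- second_level_analysis(P, n_factors = 3)
  expect_equal(fm$loadings[1, ], fm$loadings[13, ], tolerance = 1e-6)
  expect_equal(fm$loadings[2, ], fm$loadings[14, ], tolerance = 1e-6)
})

test_that("factor alignment finds the permutation and signs", {
  set.seed(17)
  truth <- matrix(rnorm(3 * 30), 3, 30)
  rec <- truth[c(3, 1, 2), ] * c(-1, 1, -1) +
    matrix(rnorm(90), 3, 30) * 0.05
  al <- align_factors(rec, truth)
  expect_equal(al$perm, c(2L, 3L, 1L))
  expect_equal(sign(al$cors), c(1, -1, -1))
  expect_true(all(abs(al$cors) > 0.95))
})
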