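toy_grid <- function(dims = c(12, 12, 12)) {
  idx <- expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                     k = 0:(dims[3] - 1))
  data.frame(voxel = seq_len(nrow(idx)), i = idx$i, j = idx$j, k = idx$k,
             region = "frontal", x = idx$i, y = idx$j, z = idx$k,
             stringsAsFactors = FALSE)
}

vox_at <- function(grid, coords) {
  vapply(seq_len(nrow(coords)), function(r) {
    grid$voxel[grid$i == coords[r, 1] & grid$j == coords[r, 2] &
                 grid$k == coords[r, 3]]
  }, integer(1))
}

test_that("cluster finding keeps components of at least five neighbors", {
  g <- toy_grid()
  line5 <- vox_at(g, cbind(0:4, 0, 0))
  cl <- find_clusters(line5, g)
  expect_length(cl, 1L)
  expect_setequal(cl[[1]], line5)
  # 4 adjacent voxels: below minimum size
  expect_length(find_clusters(vox_at(g, cbind(0:3, 0, 0)), g), 0L)
  # two groups of 5 separated by more than one voxel
  far <- vox_at(g, cbind(0:4, 8, 8))
  cl2 <- find_clusters(c(line5, far), g)
  expect_length(cl2, 2L)
})

test_that("connectivity choice changes diagonal adjacency", {
  g <- toy_grid()
  diag5 <- vox_at(g, cbind(0:4, 0:4, 0:4))   # corner-connected chain
  expect_length(find_clusters(diag5, g, connectivity = 26), 1L)
  expect_length(find_clusters(diag5, g, connectivity = 6), 0L)
  edge5 <- vox_at(g, cbind(0:4, 0:4, 0))     # edge-connected chain
  expect_length(find_clusters(edge5, g, connectivity = 18), 1L)
  expect_error(find_clusters(diag5, g, connectivity = 7), "connectivity")
})

test_that("cluster spheres use the centroid and mean radial dispersion", {
  g <- toy_grid()
  # cross of 5 voxels at (5,5,5)+/-1 in x/y: centroid center, radius 0.8
  coords <- rbind(c(6, 5, 5), c(4, 5, 5), c(5, 6, 5), c(5, 4, 5), c(5, 5, 5))
  loc <- cluster_sphere(vox_at(g, coords), g)
  expect_equal(loc$centroid, c(5, 5, 5))
  expect_equal(loc$radius, 0.8)
  expect_equal(loc$n_voxels, 5L)
  # single voxel: radius 0
  single <- cluster_sphere(vox_at(g, cbind(3, 3, 3)), g)
  expect_equal(single$radius, 0)
  # translation equivariance
  loc2 <- cluster_sphere(vox_at(g, coords + 2), g)
  expect_equal(loc2$centroid, loc$centroid + 2)
  expect_equal(loc2$radius, loc$radius)
})

test_that("search volumes are one-voxel-expanded cuboids clipped at edges", {
  g <- toy_grid()
  single <- cluster_sphere(vox_at(g, cbind(5, 5, 5)), g)
  vol <- make_search_volume(single, g, c(12, 12, 12), c(1, 1, 1))
  expect_equal(vol$lo, c(4, 4, 4))
  expect_equal(vol$hi, c(6, 6, 6))           # 3x3x3 around a point
  corner <- cluster_sphere(vox_at(g, cbind(0, 0, 0)), g)
  volc <- make_search_volume(corner, g, c(12, 12, 12), c(1, 1, 1))
  expect_equal(volc$lo, c(0, 0, 0))          # clipped at the grid edge
})

test_that("search volumes always contain their cluster's member voxels", {
  g <- toy_grid()
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    seedpt <- sample(2:9, 3, replace = TRUE)
    offs <- matrix(sample(-2:2, n * 3, replace = TRUE), n, 3)
    coords <- unique(pmin(pmax(sweep(offs, 2, seedpt, `+`), 0), 11))
    ids <- vox_at(g, coords)
    loc <- cluster_sphere(ids, g)
    vol <- make_search_volume(loc, g, c(12, 12, 12), c(1, 1, 1))
    inside <- volume_voxels(vol, g)
    expect_true(all(ids %in% inside))
  }
})

test_that("factor localization recovers the planted cluster geometry", {
  sim <- fix_discovery()
  fm <- fix_discovery_model()
  rep <- fm$localization$report
  truth_tab <- sim$truth$clusters$table
  al <- align_factors(fm$model$second_level$profiles[fm$top, , drop = FALSE],
                      sim$truth$profiles)
  vox_mm <- sim$dataset$voxel_size_mm
  for (tf in seq_len(nrow(sim$truth$profiles))) {
    fname <- rownames(sim$truth$profiles)[tf]
    rec_f <- fm$top[al$perm[tf]]
    rows <- rep[rep$factor == rec_f, ]
    planted <- truth_tab[truth_tab$factor == fname, ]
    expect_equal(nrow(rows), nrow(planted))   # cluster count recovered
    for (q in seq_len(nrow(planted))) {
      ctr <- c(planted$ci[q] * vox_mm[1], planted$cj[q] * vox_mm[2],
               planted$ck[q] * vox_mm[3])
      d <- sqrt((rows$x - ctr[1])^2 + (rows$y - ctr[2])^2 +
                  (rows$z - ctr[3])^2)
      expect_lt(min(d), max(vox_mm))          # within one voxel size
    }
  }
  # unassigned voxels never appear in any cluster
  assigned <- unique(fm$model$assignments$voxel)
  for (locs in fm$localization$clusters) {
    for (loc in locs) expect_true(all(loc$voxels %in% assigned))
  }
})

test_that("clusters partition each factor's assigned voxels", {
  fm <- fix_discovery_model()
  for (f in names(fm$localization$clusters)) {
    locs <- fm$localization$clusters[[f]]
    if (!length(locs)) next
    member_lists <- lapply(locs, `[[`, "voxels")
    all_members <- unlist(member_lists)
    expect_equal(anyDuplicated(all_members), 0L)
    assigned <- fm$model$assignments$voxel[
      fm$model$assignments$second_factor == as.integer(f)]
    expect_true(all(all_members %in% assigned))
  }
})
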