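#' Connected voxel clusters
#'
#' Partitions a set of voxels into connected components on the grid and
#' discards components smaller than `min_size`. Connectivity can be 6
#' (faces), 18 (faces + edges) or 26 (faces + edges + corners; default).
#'
#' @param voxel_ids Integer voxel ids.
#' @param grid Voxel table (data frame with `voxel`, `i`, `j`, `k`), e.g.
#'   `dataset$voxels`.
#' @param min_size Minimum component size to retain (default 5).
#' @param connectivity 6, 18 or 26.
#' @return List of integer vectors, each a retained cluster's voxel ids,
#'   ordered by decreasing size.
#' @export
find_clusters <- function(voxel_ids, grid, min_size = 5L,
                          connectivity = 26L) {
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("connectivity must be 6, 18 or 26")
  }
  if (!length(voxel_ids)) return(list())
  sub <- grid[match(voxel_ids, grid$voxel), ]
  if (anyNA(sub$voxel)) stop("voxel ids not on the dataset grid")
  off <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  off <- off[!(off$di == 0 & off$dj == 0 & off$dk == 0), ]
  ord <- abs(off$di) + abs(off$dj) + abs(off$dk)
  off <- off[(connectivity == 26L & ord <= 3) |
               (connectivity == 18L & ord <= 2) |
               (connectivity == 6L & ord <= 1), ]
  key <- function(i, j, k) paste(i, j, k, sep = ",")
  lookup <- stats::setNames(seq_along(voxel_ids), key(sub$i, sub$j, sub$k))
  comp <- integer(length(voxel_ids))
  cur <- 0L
  for (s in seq_along(voxel_ids)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb_keys <- key(sub$i[v] + off$di, sub$j[v] + off$dj, sub$k[v] + off$dk)
      nb <- lookup[nb_keys]
      nb <- nb[!is.na(nb)]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  clusters <- split(voxel_ids, comp)
  clusters <- clusters[lengths(clusters) >= min_size]
  clusters[order(-lengths(clusters))]
}

#' Centroid/radius sphere of a voxel cluster
#'
#' The cluster's location is summarized by the centroid of its member voxel
#' centers (in mm) and a radius equal to the mean Euclidean distance of the
#' members from the centroid (mean radial dispersion).
#'
#' @param voxel_ids Member voxel ids (>= 1).
#' @param grid Voxel table with mm coordinates `x`, `y`, `z`.
#' @param factor_id Optional factor label carried through to the result.
#' @return A list of class `cluster_location`: `factor`, `voxels`,
#'   `centroid` (mm triple), `radius` (mm), `n_voxels`.
#' @export
cluster_sphere <- function(voxel_ids, grid, factor_id = NA) {
  stopifnot(length(voxel_ids) >= 1)
  sub <- grid[match(voxel_ids, grid$voxel), ]
  if (anyNA(sub$voxel)) stop("voxel ids not on the dataset grid")
  centroid <- c(mean(sub$x), mean(sub$y), mean(sub$z))
  d <- sqrt((sub$x - centroid[1])^2 + (sub$y - centroid[2])^2 +
              (sub$z - centroid[3])^2)
  structure(list(
    factor = factor_id, voxels = voxel_ids,
    centroid = centroid, radius = mean(d), n_voxels = length(voxel_ids)
  ), class = "cluster_location")
}

#' Cuboid search volume around a cluster sphere
#'
#' Builds the cuboid (in voxel indices, inclusive bounds) used for feature
#' selection: the bounding box of the cluster's sphere, enlarged to cover
#' all member voxels, expanded by one voxel in every direction and clipped
#' at the grid edges.
#'
#' @param location A `cluster_location`.
#' @param grid Voxel table.
#' @param grid_dims Integer triple of grid dimensions.
#' @param voxel_size_mm Voxel size triple (mm).
#' @param grid_origin_mm Origin triple (mm).
#' @return A list of class `search_volume`: `factor`, `lo`, `hi` (0-based
#'   inclusive index bounds).
#' @export
make_search_volume <- function(location, grid, grid_dims, voxel_size_mm,
                               grid_origin_mm = c(0, 0, 0)) {
  stopifnot(inherits(location, "cluster_location"))
  c_idx <- (location$centroid - grid_origin_mm) / voxel_size_mm
  r_idx <- location$radius / voxel_size_mm
  lo <- ceiling(c_idx - r_idx)
  hi <- floor(c_idx + r_idx)
  sub <- grid[match(location$voxels, grid$voxel), ]
  lo <- pmin(lo, c(min(sub$i), min(sub$j), min(sub$k)))
  hi <- pmax(hi, c(max(sub$i), max(sub$j), max(sub$k)))
  lo <- pmax(lo - 1, 0)
  hi <- pmin(hi + 1, grid_dims - 1)
  structure(list(factor = location$factor, lo = lo, hi = hi),
            class = "search_volume")
}

# Voxel ids inside a search volume.
volume_voxels <- function(volume, grid) {
  grid$voxel[grid$i >= volume$lo[1] & grid$i <= volume$hi[1] &
               grid$j >= volume$lo[2] & grid$j <= volume$hi[2] &
               grid$k >= volume$lo[3] & grid$k <= volume$hi[3]]
}

#' Localize factors as voxel clusters
#'
#' For each selected second-level factor, finds the connected clusters of
#' its assigned voxels, summarizes each as a centroid/radius sphere, and
#' emits a tabular report (factor, region of the centroid, centroid mm
#' coordinates, voxel count, radius).
#'
#' @param model A `two_level_model` from [run_two_level()].
#' @param dataset The `activation_dataset` the model was fit on.
#' @param factors Indices of second-level factors to localize (default: all).
#' @param min_size Minimum cluster size (default 5).
#' @param connectivity Cluster connectivity (default 26).
#' @return A list of class `factor_localization`: `clusters` (per factor, a
#'   list of `cluster_location`s) and `report` (one row per cluster).
#' @export
localize_factors <- function(model, dataset, factors = NULL, min_size = 5L,
                             connectivity = 26L) {
  stopifnot(inherits(model, "two_level_model"))
  factors <- factors %||% seq_len(ncol(model$second_level$loadings))
  grid <- dataset$voxels
  clusters <- list()
  rows <- list()
  for (f in factors) {
    vox <- unique(model$assignments$voxel[model$assignments$second_factor == f])
    cl <- find_clusters(vox, grid, min_size = min_size,
                        connectivity = connectivity)
    locs <- lapply(cl, cluster_sphere, grid = grid, factor_id = f)
    clusters[[as.character(f)]] <- locs
    for (loc in locs) {
      sub <- grid[match(loc$voxels, grid$voxel), ]
      near <- which.min((sub$x - loc$centroid[1])^2 +
                          (sub$y - loc$centroid[2])^2 +
                          (sub$z - loc$centroid[3])^2)
      rows[[length(rows) + 1L]] <- data.frame(
        factor = f, region = sub$region[near],
        x = loc$centroid[1], y = loc$centroid[2], z = loc$centroid[3],
        n_voxels = loc$n_voxels, radius = loc$radius)
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(factor = integer(), region = character(), x = numeric(),
               y = numeric(), z = numeric(), n_voxels = integer(),
               radius = numeric())
  structure(list(clusters = clusters, report = report),
            class = "factor_localization")
}

#' Search volumes for a set of localized factors
#'
#' @param localization A `factor_localization`.
#' @param dataset The `activation_dataset`.
#' @return List of `search_volume` objects, one per cluster, carrying their
#'   factor ids.
#' @export
make_search_volumes <- function(localization, dataset) {
  stopifnot(inherits(localization, "factor_localization"))
  out <- list()
  for (locs in localization$clusters) {
    for (loc in locs) {
      out[[length(out) + 1L]] <- make_search_volume(
        loc, dataset$voxels, dataset$grid_dims, dataset$voxel_size_mm,
        dataset$grid_origin_mm)
    }
  }
  out
}
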