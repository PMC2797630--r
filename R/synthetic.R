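#' Region ("lobe") labels used on the synthetic voxel grid
#' @keywords internal
REGION_LABELS <- c("frontal", "parietal", "temporal", "occipital", "fusiform")

#' Factor names available to the generator, in canonical order
#' @keywords internal
FACTOR_NAMES <- c("shelter", "manipulation", "eating", "word_length")

#' Configuration for the synthetic activation generator
#'
#' Bundles and validates the parameters of the synthetic data generator. The
#' defaults emulate the study conditions the package targets: 11 participants,
#' 6 presentations of 60 words, voxels of 3.125 x 3.125 x 6 mm on a grid
#' partitioned into five "lobes" (slabs along x), and four planted latent
#' factors (three semantic: shelter, manipulation, eating; plus word length)
#' whose voxel clusters number 5, 4, 3 and 4 respectively (16 in total).
#'
#' @param n_participants Number of participants to simulate.
#' @param n_presentations Presentations of the word set per participant
#'   (must be >= 2 so stability is defined).
#' @param grid_dims Integer triple, voxel grid dimensions. The first dimension
#'   is split into five equal-width slabs, one per region label.
#' @param voxel_size_mm Real triple, physical voxel size in mm.
#' @param grid_origin_mm Real triple, mm coordinate of voxel index (0, 0, 0).
#' @param n_factors Number of planted factors (1 to 4, taken in the order
#'   shelter, manipulation, eating, word length).
#' @param clusters_per_factor Integer scalar or vector (recycled to
#'   `n_factors`): number of spatial clusters planted per factor.
#' @param cluster_radius Radius of each planted cluster in voxel-index units;
#'   1.5 yields 19-voxel clusters.
#' @param noise_sd SD of the additive Gaussian measurement noise, on the scale
#'   of the signal (planted factor profiles have SD 1 over words and loadings
#'   have magnitude near 1).
#' @param participant_gain_sd SD of the per-participant multiplicative gain
#'   (gains are drawn from Normal(1, participant_gain_sd^2)).
#' @param shared_code If `TRUE` (default) all participants share one set of
#'   loadings and cluster locations (a common neural code). If `FALSE`, each
#'   participant gets idiosyncratic cluster placements and loadings (factor
#'   profiles stay shared), which should defeat cross-participant decoding.
#' @param seed Integer seed; identical configurations produce bitwise
#'   identical datasets.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_participants = 11L,
                             n_presentations = 6L,
                             grid_dims = c(15L, 12L, 10L),
                             voxel_size_mm = c(3.125, 3.125, 6),
                             grid_origin_mm = c(0, 0, 0),
                             n_factors = 4L,
                             clusters_per_factor = c(5L, 4L, 3L, 4L),
                             cluster_radius = 1.5,
                             noise_sd = 0.3,
                             participant_gain_sd = 0.1,
                             shared_code = TRUE,
                             seed = 1L) {
  stopifnot(
    n_participants >= 1, n_presentations >= 2,
    length(grid_dims) == 3, all(grid_dims >= 1),
    length(voxel_size_mm) == 3, all(voxel_size_mm > 0),
    n_factors >= 1, n_factors <= length(FACTOR_NAMES),
    all(clusters_per_factor >= 1), cluster_radius > 0,
    is.finite(noise_sd), noise_sd >= 0, participant_gain_sd >= 0
  )
  if (grid_dims[1] < length(REGION_LABELS)) {
    stop("grid_dims[1] must allow at least one voxel per region")
  }
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_presentations = as.integer(n_presentations),
    grid_dims = as.integer(grid_dims),
    voxel_size_mm = as.numeric(voxel_size_mm),
    grid_origin_mm = as.numeric(grid_origin_mm),
    n_factors = as.integer(n_factors),
    clusters_per_factor = as.integer(rep_len(clusters_per_factor, n_factors)),
    cluster_radius = cluster_radius,
    noise_sd = noise_sd,
    participant_gain_sd = participant_gain_sd,
    shared_code = isTRUE(shared_code),
    seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  cfg
}

# Build the voxel table for a grid: 0-based indices, region slab along x,
# mm coordinate = origin + index * voxel size.
build_voxel_grid <- function(cfg) {
  d <- cfg$grid_dims
  idx <- expand.grid(i = 0:(d[1] - 1L), j = 0:(d[2] - 1L), k = 0:(d[3] - 1L))
  slab <- pmin(floor(idx$i / (d[1] / length(REGION_LABELS))), length(REGION_LABELS) - 1L)
  data.frame(
    voxel = seq_len(nrow(idx)),
    i = idx$i, j = idx$j, k = idx$k,
    region = REGION_LABELS[slab + 1L],
    x = cfg$grid_origin_mm[1] + idx$i * cfg$voxel_size_mm[1],
    y = cfg$grid_origin_mm[2] + idx$j * cfg$voxel_size_mm[2],
    z = cfg$grid_origin_mm[3] + idx$k * cfg$voxel_size_mm[3],
    stringsAsFactors = FALSE
  )
}

# Candidate cluster-center slots within one region slab: centers far enough
# apart that clusters cannot touch even under 26-connectivity, and confined
# to the slab. Returns a data frame of (i, j, k) centers.
region_slots <- function(cfg, region_index) {
  d <- cfg$grid_dims
  slab_w <- d[1] / length(REGION_LABELS)
  i0 <- floor((region_index - 1L) * slab_w)
  i1 <- floor(region_index * slab_w) - 1L
  m <- floor(cfg$cluster_radius)  # max axis offset of a member voxel
  ci <- i0 + floor((i1 - i0) / 2)
  if (ci - m < i0 || ci + m > i1) {
    stop("region slab too narrow to host a cluster of radius ", cfg$cluster_radius)
  }
  # centers spaced so two clusters are never 26-adjacent (gap >= 2 voxels)
  js <- seq(m, d[2] - 1L - m, by = 2L * m + 2L)
  ks <- seq(m, d[3] - 1L - m, by = 2L * m + 2L)
  if (!length(js) || !length(ks)) {
    stop("grid too small to host clusters of radius ", cfg$cluster_radius)
  }
  expand.grid(i = ci, j = js, k = ks)
}

# Rank of each word in alphabetical order. Word-indexed random draws are made
# in this canonical order, so permuting the word set permutes the generator's
# output identically.
canonical_rank <- function(words) match(words$word, sort(words$word))

# Draw n x m standard-normal variates indexed by word (rows), invariant to
# word order: row for word w gets the draw of w's alphabetical rank.
canonical_norm <- function(words, m, sd) {
  draws <- matrix(stats::rnorm(nrow(words) * m, 0, sd), nrow(words), m)
  draws[canonical_rank(words), , drop = FALSE]
}

# Semantic category weights defining the three semantic factor profiles.
semantic_weights <- function() {
  list(
    shelter = c("buildings" = 1, "building parts" = 0.8, "vehicles" = 0.7,
                "furniture" = 0.3),
    manipulation = c("tools" = 1, "kitchen utensils" = 0.8,
                     "man-made objects" = 0.5, "body parts" = 0.3),
    eating = c("vegetables" = 1, "kitchen utensils" = 0.7, "animals" = 0.3)
  )
}

# Build the planted factor profiles: three category-indicator mixtures with a
# small seeded within-category jitter, plus the z-scored letter count. Each
# profile is z-scored over words (mean 0, SD 1). Assumes RNG state is set.
build_factor_profiles <- function(words, n_factors) {
  w <- semantic_weights()
  nm <- FACTOR_NAMES[seq_len(n_factors)]
  profiles <- matrix(0, n_factors, nrow(words),
                     dimnames = list(nm, words$word))
  for (f in nm) {
    if (f == "word_length") {
      profiles[f, ] <- zscore(words$length)
    } else {
      base <- unname(w[[f]][words$category])
      base[is.na(base)] <- 0
      profiles[f, ] <- zscore(base + canonical_norm(words, 1L, 0.1)[, 1])
    }
  }
  profiles
}

# Plant cluster locations for each factor: clusters are assigned to regions
# round-robin (so a factor spans several lobes) and occupy distinct slots.
# Returns data frame (factor, region, ci, cj, ck) plus member voxel ids.
plant_clusters <- function(cfg, grid) {
  n_reg <- length(REGION_LABELS)
  slots <- lapply(seq_len(n_reg), function(r) region_slots(cfg, r))
  used <- integer(n_reg)
  rows <- list()
  for (f in seq_len(cfg$n_factors)) {
    for (c in seq_len(cfg$clusters_per_factor[f])) {
      reg <- ((f - 1L + c - 1L) %% n_reg) + 1L
      used[reg] <- used[reg] + 1L
      if (used[reg] > nrow(slots[[reg]])) {
        stop("grid too small to host ", sum(cfg$clusters_per_factor),
             " non-overlapping clusters; enlarge grid_dims")
      }
      # rotate slot order by region so one factor's clusters in adjacent
      # slabs never share (j, k) and thus never touch across the boundary
      slot_idx <- ((used[reg] - 1L + (reg - 1L)) %% nrow(slots[[reg]])) + 1L
      s <- slots[[reg]][slot_idx, ]
      rows[[length(rows) + 1L]] <- data.frame(
        factor = FACTOR_NAMES[f], region = REGION_LABELS[reg],
        ci = s$i, cj = s$j, ck = s$k
      )
    }
  }
  cl <- do.call(rbind, rows)
  cl$cluster <- seq_len(nrow(cl))
  members <- lapply(seq_len(nrow(cl)), function(q) {
    d2 <- (grid$i - cl$ci[q])^2 + (grid$j - cl$cj[q])^2 + (grid$k - cl$ck[q])^2
    grid$voxel[d2 <= cfg$cluster_radius^2]
  })
  if (any(lengths(members) < 5L)) {
    stop("cluster_radius too small: planted clusters must contain >= 5 voxels")
  }
  list(table = cl, members = members)
}

# Draw a loading matrix (voxels x factors) for one planted geometry.
# In-cluster voxels load on their factor with magnitude near 1; all other
# entries are exactly 0. Assumes RNG state is set.
draw_loadings <- function(cfg, grid, plan) {
  L <- matrix(0, nrow(grid), cfg$n_factors,
              dimnames = list(NULL, FACTOR_NAMES[seq_len(cfg$n_factors)]))
  for (q in seq_len(nrow(plan$table))) {
    f <- plan$table$factor[q]
    vox <- plan$members[[q]]
    L[vox, f] <- stats::runif(length(vox), 0.8, 1.2)
  }
  L
}

#' Generate a synthetic multi-participant activation dataset
#'
#' Simulates per-presentation activation with known latent structure. The
#' activation of voxel i for word w, presentation r, participant p is
#' `gain_p * sum_k loadings[i, k] * profiles[k, w] + noise`, with loadings
#' nonzero only inside planted spherical clusters confined to single regions.
#' With `shared_code = TRUE` the loadings and cluster geometry are identical
#' across participants (a common neural code in a shared coordinate frame);
#' participants differ only by a scalar gain and independent noise.
#'
#' @param config A [synthetic_config()].
#' @param words A `wordset`; defaults to [builtin_wordset()].
#' @return A list with components `dataset` (class `activation_dataset`) and
#'   `truth` (class `ground_truth` holding `profiles` — factors x words,
#'   each row mean 0 / SD 1 —, `loadings`, the planted `clusters` table with
#'   member voxels, and the participant gains).
#' @examples
#' cfg <- synthetic_config(n_participants = 2, grid_dims = c(15, 12, 10),
#'                         noise_sd = 0.1, seed = 7)
#' sim <- generate_dataset(cfg)
#' dim(sim$dataset$values)   # participant x presentation x word x voxel
#' @export
generate_dataset <- function(config, words = builtin_wordset()) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_wordset(words)
  grid <- build_voxel_grid(config)
  local_seed(config$seed, {
    profiles <- build_factor_profiles(words, config$n_factors)
    plan <- plant_clusters(config, grid)
    prof_list <- NULL
    if (config$shared_code) {
      loadings <- draw_loadings(config, grid, plan)
      load_list <- NULL
      plan_list <- NULL
    } else {
      # idiosyncratic code: each participant gets its own cluster placement
      # (shuffled across all available slots), own loadings, and own factor
      # profiles, so nothing about the word-to-voxel mapping is shared
      load_list <- vector("list", config$n_participants)
      plan_list <- vector("list", config$n_participants)
      prof_list <- vector("list", config$n_participants)
      all_slots <- do.call(rbind, lapply(seq_along(REGION_LABELS), function(r) {
        s <- region_slots(config, r)
        s$region <- REGION_LABELS[r]
        s
      }))
      n_cl <- sum(config$clusters_per_factor)
      for (p in seq_len(config$n_participants)) {
        pick <- sample(nrow(all_slots), n_cl)
        tab <- all_slots[pick, ]
        tab$factor <- rep(FACTOR_NAMES[seq_len(config$n_factors)],
                          config$clusters_per_factor)
        tab$cluster <- seq_len(n_cl)
        names(tab)[names(tab) %in% c("i", "j", "k")] <- c("ci", "cj", "ck")
        members <- lapply(seq_len(nrow(tab)), function(q) {
          d2 <- (grid$i - tab$ci[q])^2 + (grid$j - tab$cj[q])^2 +
            (grid$k - tab$ck[q])^2
          grid$voxel[d2 <= config$cluster_radius^2]
        })
        plan_list[[p]] <- list(table = tab, members = members)
        load_list[[p]] <- draw_loadings(config, grid, plan_list[[p]])
        pp <- canonical_norm(words, config$n_factors, 1)
        prof_list[[p]] <- t(apply(pp, 2, zscore))
        dimnames(prof_list[[p]]) <- dimnames(profiles)
      }
      loadings <- NULL
    }
    gains <- stats::rnorm(config$n_participants, 1, config$participant_gain_sd)
    nw <- nrow(words)
    nv <- nrow(grid)
    values <- array(
      0, dim = c(config$n_participants, config$n_presentations, nw, nv),
      dimnames = list(paste0("P", seq_len(config$n_participants)),
                      paste0("pres", seq_len(config$n_presentations)),
                      words$word, NULL)
    )
    for (p in seq_len(config$n_participants)) {
      L <- if (config$shared_code) loadings else load_list[[p]]
      P <- if (config$shared_code) profiles else prof_list[[p]]
      signal <- gains[p] * t(L %*% P)  # words x voxels
      for (r in seq_len(config$n_presentations)) {
        eps <- if (config$noise_sd > 0) {
          canonical_norm(words, nv, config$noise_sd)
        } else 0
        values[p, r, , ] <- signal + eps
      }
    }
    dataset <- structure(list(
      values = values,
      words = words,
      voxels = grid,
      voxel_size_mm = config$voxel_size_mm,
      grid_origin_mm = config$grid_origin_mm,
      grid_dims = config$grid_dims,
      participants = seq_len(config$n_participants),
      config = config
    ), class = "activation_dataset")
    truth <- structure(list(
      profiles = profiles,
      profiles_by_participant = prof_list,
      loadings = loadings,
      loadings_by_participant = load_list,
      clusters = if (config$shared_code) plan else NULL,
      clusters_by_participant = plan_list,
      gains = gains,
      shared_code = config$shared_code
    ), class = "ground_truth")
    list(dataset = dataset, truth = truth)
  })
}

#' Generate behavioral-style semantic ratings from ground truth
#'
#' Produces per-word 1-7 ratings for each planted semantic factor (word
#' length is excluded: it is a stimulus property, not a rated dimension).
#' Each rating column is an affine rescaling of the true factor profile into
#' \[1, 7\] plus truncated Gaussian noise; with `rating_noise_sd = 0` each
#' column correlates exactly 1 with its profile.
#'
#' @param truth A `ground_truth` object from [generate_dataset()].
#' @param rating_noise_sd SD of the additive rating noise (rating-scale units).
#' @param seed Integer seed.
#' @param words The `wordset` the truth was generated for.
#' @return A data frame of class `ratings_table` with columns `word`, one
#'   column per semantic factor, and `length`.
#' @export
generate_ratings <- function(truth, rating_noise_sd = 0.5, seed = 1L,
                             words = builtin_wordset()) {
  stopifnot(inherits(truth, "ground_truth"), rating_noise_sd >= 0)
  sem <- setdiff(rownames(truth$profiles), "word_length")
  if (!length(sem)) stop("ground truth has no semantic factors to rate")
  local_seed(seed, {
    out <- data.frame(word = words$word, stringsAsFactors = FALSE)
    for (f in sem) {
      p <- truth$profiles[f, words$word]
      r <- 1 + 6 * (p - min(p)) / (max(p) - min(p))
      r <- r + canonical_norm(words, 1L, rating_noise_sd)[, 1]
      out[[f]] <- pmin(pmax(r, 1), 7)
    }
    out$length <- words$length
    class(out) <- c("ratings_table", "data.frame")
    out
  })
}

#' @export
print.activation_dataset <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<activation_dataset> %d participants x %d presentations x %d words x %d voxels\n",
    d[1], d[2], d[3], d[4]))
  cat(sprintf("  grid %s, voxel %s mm, regions: %s\n",
              paste(x$grid_dims, collapse = "x"),
              paste(x$voxel_size_mm, collapse = "x"),
              paste(unique(x$voxels$region), collapse = ", ")))
  invisible(x)
}

#' Restrict a dataset to a subset of words
#'
#' @param dataset An `activation_dataset`.
#' @param word_idx Integer indices (into the word set) to keep.
#' @return The dataset restricted to those words, in the given order.
#' @keywords internal
#' @export
subset_words <- function(dataset, word_idx) {
  stopifnot(inherits(dataset, "activation_dataset"))
  dataset$values <- dataset$values[, , word_idx, , drop = FALSE]
  dataset$words <- dataset$words[word_idx, , drop = FALSE]
  dataset
}
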