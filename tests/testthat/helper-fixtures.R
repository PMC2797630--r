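# Shared synthetic fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), .fixture_cache)
  }
  get(name, .fixture_cache, inherits = FALSE)
}

# The four-participant discovery-style dataset: 4 planted factors, 16
# clusters, moderate noise (0.3 x signal scale).
fix_discovery <- function() {
  memo("discovery", {
    cfg <- synthetic_config(n_participants = 4, noise_sd = 0.3, seed = 101)
    generate_dataset(cfg)
  })
}

# Its fitted two-level model and localization, reused across tests.
fix_discovery_model <- function() {
  memo("discovery_model", {
    sim <- fix_discovery()
    tl <- run_two_level(sim$dataset, 1:4)
    top <- order(-tl$explained)[1:4]
    loc <- localize_factors(tl, sim$dataset, factors = top)
    list(model = tl, localization = loc, top = top)
  })
}

# Nearly noise-free dataset (tiny noise keeps stability defined while the
# signal is effectively exact) used for decoding/generative limit checks.
fix_clean <- function() {
  memo("clean", {
    cfg <- synthetic_config(n_participants = 4, noise_sd = 0.02,
                            participant_gain_sd = 0, seed = 202)
    generate_dataset(cfg)
  })
}

# Signal-free dataset: same geometry, activation replaced by pure noise.
fix_null <- function() {
  memo("null", {
    sim <- fix_discovery()
    ds <- sim$dataset
    n <- length(ds$values)
    ds$values[] <- local_seed_for_tests(303, stats::rnorm(n))
    ds
  })
}

local_seed_for_tests <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Wrap a plain 4-d array (participant x presentation x word x voxel) as an
# activation_dataset on a simple grid, for hand-built examples.
manual_dataset <- function(values, voxel_size = c(1, 1, 1),
                           regions = NULL) {
  d <- dim(values)
  nv <- d[4]
  side <- ceiling(nv^(1 / 3))
  idx <- expand.grid(i = 0:(side - 1), j = 0:(side - 1), k = 0:(side - 1))
  idx <- idx[seq_len(nv), ]
  words <- builtin_wordset()[seq_len(d[3]), ]
  grid <- data.frame(
    voxel = seq_len(nv), i = idx$i, j = idx$j, k = idx$k,
    region = regions %||% rep("frontal", nv),
    x = idx$i * voxel_size[1], y = idx$j * voxel_size[2],
    z = idx$k * voxel_size[3], stringsAsFactors = FALSE)
  dimnames(values) <- list(paste0("P", seq_len(d[1])),
                           paste0("pres", seq_len(d[2])),
                           words$word, NULL)
  structure(list(values = values, words = words, voxels = grid,
                 voxel_size_mm = voxel_size, grid_origin_mm = c(0, 0, 0),
                 grid_dims = c(side, side, side),
                 participants = seq_len(d[1]), config = NULL),
            class = "activation_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
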