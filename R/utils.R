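# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed and a stream index, kept < 2^31.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 1103L + as.numeric(stream) * 12289) %% 2147483629
}

# z-score with the sample SD (n - 1) convention used throughout the package.
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot z-score a constant vector")
  }
  (x - mean(x)) / s
}

# Generate all permutations of 1..n (n small; used for factor alignment).
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_permutations(n - 1L)
    for (p in rest) {
      idx <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, idx[p])
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
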