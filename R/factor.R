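#' Principal axis factoring
#'
#' Extracts `k` common factors from a correlation matrix by iterated
#' principal axis factoring: the unit diagonal is replaced by communality
#' estimates, the top-k eigenpairs of the reduced matrix give loadings
#' (eigenvector times square root of eigenvalue), communalities are updated
#' to row sums of squared loadings, and the cycle repeats until the largest
#' absolute communality change falls below `tol`.
#'
#' Initial communalities are squared multiple correlations where the matrix
#' is invertible; for singular correlation matrices (e.g. more items than
#' observations) the maximum absolute off-diagonal correlation of each row is
#' used instead. Negative eigenvalues of the reduced matrix are clamped to
#' zero.
#'
#' @param R Symmetric correlation matrix with unit diagonal.
#' @param k Number of factors (< dimension of `R`).
#' @param tol Convergence tolerance on communalities.
#' @param max_iter Maximum number of iterations; non-convergence is an error
#'   carrying the iteration trace.
#' @param on_stall `"error"` (default): hitting `max_iter` is always an
#'   error. `"accept"`: if the iteration has stalled in a small limit cycle
#'   (final communality change below 0.01 — immaterial for the factor
#'   solution, and typical of rank-deficient matrices whose boundary
#'   eigenvalues are tied), return the current solution with
#'   `converged = FALSE` instead of failing.
#' @return A list of class `paf_fit`: `loadings` (items x k, unrotated),
#'   `eigenvalues` (the k retained eigenvalues at convergence),
#'   `communalities`, `iterations` and `converged`.
#' @export
principal_axis_factoring <- function(R, k, tol = 1e-4, max_iter = 100L,
                                     on_stall = c("error", "accept")) {
  on_stall <- match.arg(on_stall)
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  if (max(abs(R - t(R))) > 1e-8) stop("R must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8) stop("R must have unit diagonal")
  p <- nrow(R)
  if (k >= p) stop("k must be smaller than the dimension of R")
  h <- tryCatch({
    smc <- 1 - 1 / diag(solve(R))
    if (any(!is.finite(smc))) stop("non-finite SMC")
    pmin(pmax(smc, 0), 1 - 1e-6)
  }, error = function(e) {
    offdiag <- abs(R)
    diag(offdiag) <- 0
    pmin(apply(offdiag, 1, max), 1 - 1e-6)
  })
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    Rh <- R
    diag(Rh) <- h
    e <- eigen(Rh, symmetric = TRUE)
    ev <- pmax(e$values[seq_len(k)], 0)
    L <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev), k)
    h_new <- pmin(rowSums(L^2), 1)
    delta <- max(abs(h_new - h))
    trace <- c(trace, delta)
    if (it > 10L && delta >= trace[it - 2L] * 0.999) {
      # no progress over two iterations: a limit cycle (common on
      # rank-deficient matrices); damp the update to break it
      h <- (h + h_new) / 2
    } else {
      h <- h_new
    }
    if (delta < tol || (it == max_iter && on_stall == "accept" &&
                          delta < 0.01)) {
      dimnames(L) <- list(rownames(R), paste0("F", seq_len(k)))
      return(structure(list(loadings = L, eigenvalues = ev,
                            communalities = h, iterations = it,
                            converged = delta < tol),
                       class = "paf_fit"))
    }
  }
  stop("principal axis factoring did not converge in ", max_iter,
       " iterations; communality-change trace: ",
       paste(signif(utils::tail(trace, 5), 3), collapse = ", "))
}

#' Varimax rotation of a loading matrix
#'
#' Orthogonally rotates loadings to simple structure by maximizing the
#' varimax criterion (sum over factors of the variance of squared loadings),
#' with Kaiser row normalization. After rotation, each factor is flipped so
#' its largest-magnitude loading is positive and factors are reordered by
#' decreasing sum of squared loadings, so the output is deterministic.
#' Per-item communalities (row sums of squared loadings) are preserved.
#'
#' @param loadings Items x factors matrix. With a single factor the identity
#'   rotation is returned.
#' @param eps Convergence tolerance of the rotation.
#' @return List with `loadings` (rotated) and `rotmat` (orthonormal matrix
#'   such that `loadings %*% rotmat` equals the rotated loadings).
#' @export
varimax_rotate <- function(loadings, eps = 1e-6) {
  stopifnot(is.matrix(loadings))
  k <- ncol(loadings)
  if (k == 1L) {
    rot <- diag(1)
    L <- loadings
  } else {
    v <- stats::varimax(loadings, normalize = TRUE, eps = eps)
    L <- loadings %*% v$rotmat
    rot <- v$rotmat
  }
  # canonical sign: largest |loading| positive in every column
  signs <- vapply(seq_len(ncol(L)), function(j) {
    s <- sign(L[which.max(abs(L[, j])), j])
    if (s == 0) 1 else s
  }, numeric(1))
  L <- sweep(L, 2, signs, `*`)
  rot <- sweep(rot, 2, signs, `*`)
  # canonical order: decreasing explained sum of squares
  ord <- order(-colSums(L^2))
  L <- L[, ord, drop = FALSE]
  rot <- rot[, ord, drop = FALSE]
  colnames(L) <- paste0("F", seq_len(ncol(L)))
  list(loadings = L, rotmat = rot)
}

#' Solve for factor profiles by least squares
#'
#' Given loadings `C` (items x k) and item profiles `V` (items x words), the
#' factor model `V = C F` is solved for the factor profiles `F` (k x words)
#' by ordinary least squares, columnwise over words. The resulting rows are
#' the factor scores of each word.
#'
#' @param C Loading matrix, full column rank (rank deficiency is an error).
#' @param V Item-profile matrix with `nrow(V) == nrow(C)`.
#' @return k x words matrix of factor profiles.
#' @export
solve_factor_profiles <- function(C, V) {
  stopifnot(is.matrix(C), is.matrix(V), nrow(C) == nrow(V))
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    stop("loading matrix is rank deficient (rank ", qrC$rank, " < ",
         ncol(C), "); factor profiles are not identifiable")
  }
  F <- qr.coef(qrC, V)
  rownames(F) <- colnames(C)
  colnames(F) <- colnames(V)
  F
}

#' Assign an item to a factor by its maximum absolute loading
#'
#' An item is uniquely assigned to the factor on which it has the largest
#' absolute loading, provided that loading exceeds the threshold; otherwise
#' it is unassigned. The same rule is applied to voxels (first level) and to
#' first-level factors (second level).
#'
#' @param loading_row Numeric vector of loadings of one item.
#' @param threshold Minimum absolute loading (default 0.4).
#' @return Integer factor index, or `NA_integer_` if unassigned.
#' @export
assign_by_max_loading <- function(loading_row, threshold = 0.4) {
  j <- which.max(abs(loading_row))
  if (length(j) == 0L || abs(loading_row[j]) < threshold) {
    return(NA_integer_)
  }
  as.integer(j)
}

# Drop extracted factors that carry essentially no common variance (sum of
# squared loadings below tol). On rank-deficient correlation matrices —
# e.g. (nearly) noiseless data whose rank is below the requested number of
# factors — the surplus factors come out with null loadings; they are not
# factors and would make the least-squares profile solve unidentifiable.
drop_null_factors <- function(loadings, tol = 1e-6) {
  keep <- colSums(loadings^2) > tol
  if (!any(keep)) stop("no factor carries common variance")
  loadings[, keep, drop = FALSE]
}

#' First-level factor analysis of one lobe of one participant
#'
#' Runs the within-lobe pipeline: average activation over the presentations,
#' select the `n_voxels` most stable voxels in the region, normalize their
#' profiles across words, factor the voxel intercorrelation matrix by
#' principal axis factoring with varimax rotation, and recover factor
#' profiles by least squares.
#'
#' @param dataset An `activation_dataset`.
#' @param participant Participant index.
#' @param region Region label.
#' @param n_voxels Number of stable voxels used as items (default 50).
#' @param n_factors Number of factors retained (default 5).
#' @param presentations Presentation subset (default all).
#' @param paf_max_iter Iteration cap passed to [principal_axis_factoring()].
#' @return A list of class `factor_model` with `level = 1`, `loadings`
#'   (voxels x factors), `profiles` (factors x words), `eigenvalues`,
#'   `voxels` (selected ids), `participant` and `region`.
#' @export
first_level_analysis <- function(dataset, participant, region,
                                 n_voxels = 50L, n_factors = 5L,
                                 presentations = NULL, paf_max_iter = 1000L) {
  region_vox <- dataset$voxels$voxel[dataset$voxels$region == region]
  if (length(region_vox) < n_voxels) {
    stop("region ", region, " has fewer than ", n_voxels, " voxels")
  }
  stab <- voxel_stability(dataset, participant, presentations,
                          voxels = region_vox)
  sel <- select_stable_voxels(stab, n_voxels)
  prof <- mean_word_profiles(dataset, participant, presentations)
  V <- normalize_across_words(prof$profiles[sel, , drop = FALSE])
  R <- stats::cor(t(V))
  fit <- principal_axis_factoring(R, n_factors, max_iter = paf_max_iter,
                                 on_stall = "accept")
  rot <- varimax_rotate(fit$loadings)
  L <- drop_null_factors(rot$loadings)
  F <- solve_factor_profiles(L, V)
  structure(list(
    level = 1L, loadings = L, profiles = F,
    eigenvalues = fit$eigenvalues, voxels = sel,
    participant = participant, region = region,
    stability = stab[as.character(sel)]
  ), class = "factor_model")
}

#' Second-level factor analysis over pooled first-level profiles
#'
#' Factors the correlation matrix of the pooled first-level factor profiles
#' (items = first-level factors) to identify factors common across lobes and
#' participants, then recovers second-level factor profiles by least squares
#' from the row-standardized input profiles.
#'
#' @param profiles Items x words matrix of first-level factor profiles.
#' @param n_factors Number of second-level factors retained (default 10).
#' @param item_origin Optional data frame describing the provenance of each
#'   row (participant, region, within-analysis factor index).
#' @param paf_max_iter Iteration cap passed to [principal_axis_factoring()].
#' @return A `factor_model` with `level = 2`, `loadings` (items x factors),
#'   `profiles` (factors x words), `eigenvalues`, `explained` (per-factor
#'   share of variation: sum of squared loadings / number of items) and
#'   `item_origin`.
#' @export
second_level_analysis <- function(profiles, n_factors = 10L,
                                  item_origin = NULL, paf_max_iter = 1000L) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= n_factors)
  P <- normalize_across_words(profiles)
  R <- stats::cor(t(P))
  fit <- principal_axis_factoring(R, n_factors, max_iter = paf_max_iter,
                                 on_stall = "accept")
  rot <- varimax_rotate(fit$loadings)
  L <- drop_null_factors(rot$loadings)
  G <- solve_factor_profiles(L, P)
  structure(list(
    level = 2L, loadings = L, profiles = G,
    eigenvalues = fit$eigenvalues,
    explained = colSums(L^2) / nrow(L),
    item_origin = item_origin
  ), class = "factor_model")
}

#' Two-level factor analysis with voxel-to-factor mapping
#'
#' Chains [first_level_analysis()] over every (participant, region) pair,
#' pools the first-level factor profiles, runs [second_level_analysis()],
#' and composes the two loading-threshold assignments into a voxel-to-
#' second-level-factor mapping. A second-level factor's commonality is the
#' number of distinct participants contributing assigned voxels.
#'
#' @param dataset An `activation_dataset`.
#' @param participants Participant subset to analyze.
#' @param n_stable_per_region Stable voxels per lobe at the first level
#'   (default 50).
#' @param n_first_factors First-level factors per analysis (default 5).
#' @param n_second_factors Second-level factors (default 10).
#' @param threshold Loading threshold for unique assignment (default 0.4).
#' @param presentations Presentation subset (default all).
#' @return A list of class `two_level_model`: `first_level` (list of
#'   `factor_model`s), `second_level`, `assignments` (one row per assigned
#'   voxel: participant, region, voxel, first- and second-level factor),
#'   `commonality` (per second-level factor), `explained`, and the
#'   parameters used.
#' @export
run_two_level <- function(dataset, participants,
                          n_stable_per_region = 50L, n_first_factors = 5L,
                          n_second_factors = 10L, threshold = 0.4,
                          presentations = NULL) {
  regions <- unique(dataset$voxels$region)
  firsts <- list()
  for (p in participants) {
    for (rg in regions) {
      firsts[[paste0("P", p, ".", rg)]] <-
        first_level_analysis(dataset, p, rg,
                             n_voxels = n_stable_per_region,
                             n_factors = n_first_factors,
                             presentations = presentations)
    }
  }
  pooled <- do.call(rbind, lapply(firsts, function(fm) fm$profiles))
  origin <- do.call(rbind, lapply(firsts, function(fm) {
    data.frame(participant = fm$participant, region = fm$region,
               factor_in_analysis = seq_len(nrow(fm$profiles)))
  }))
  rownames(pooled) <- paste0(
    "P", origin$participant, ".", origin$region, ".F",
    origin$factor_in_analysis)
  second <- second_level_analysis(pooled, n_second_factors,
                                  item_origin = origin)
  # second-level assignment of each first-level factor
  first_to_second <- apply(second$loadings, 1, assign_by_max_loading,
                           threshold = threshold)
  # first-level assignment of each voxel, composed with the above
  rows <- list()
  item <- 0L
  for (fm in firsts) {
    for (v in seq_along(fm$voxels)) {
      jf <- assign_by_max_loading(fm$loadings[v, ], threshold = threshold)
      if (!is.na(jf)) {
        global_item <- item + jf
        js <- first_to_second[global_item]
        if (!is.na(js)) {
          rows[[length(rows) + 1L]] <- data.frame(
            participant = fm$participant, region = fm$region,
            voxel = fm$voxels[v], first_factor = global_item,
            second_factor = js)
        }
      }
    }
    item <- item + nrow(fm$profiles)
  }
  assignments <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(participant = integer(), region = character(),
               voxel = integer(), first_factor = integer(),
               second_factor = integer())
  }
  commonality <- vapply(seq_len(ncol(second$loadings)), function(k) {
    length(unique(assignments$participant[assignments$second_factor == k]))
  }, integer(1))
  names(commonality) <- rownames(second$profiles)
  structure(list(
    first_level = firsts, second_level = second,
    assignments = assignments, commonality = commonality,
    explained = second$explained, threshold = threshold,
    params = list(n_stable_per_region = n_stable_per_region,
                  n_first_factors = n_first_factors,
                  n_second_factors = n_second_factors),
    participants = participants
  ), class = "two_level_model")
}

#' Single-level factor analysis variant
#'
#' Pools the per-(participant, region) stable-voxel profiles of all
#' participants into one item set and runs a single factor analysis, for
#' comparison with the two-level procedure.
#'
#' @inheritParams run_two_level
#' @param n_factors Number of factors retained.
#' @return A `factor_model` whose items are pooled voxels.
#' @export
run_single_level <- function(dataset, participants,
                             n_stable_per_region = 50L, n_factors = 10L,
                             presentations = NULL) {
  regions <- unique(dataset$voxels$region)
  blocks <- list()
  origin <- list()
  for (p in participants) {
    prof <- mean_word_profiles(dataset, p, presentations)
    for (rg in regions) {
      region_vox <- dataset$voxels$voxel[dataset$voxels$region == rg]
      stab <- voxel_stability(dataset, p, presentations, voxels = region_vox)
      sel <- select_stable_voxels(stab, n_stable_per_region)
      blocks[[paste0("P", p, ".", rg)]] <-
        normalize_across_words(prof$profiles[sel, , drop = FALSE])
      origin[[paste0("P", p, ".", rg)]] <-
        data.frame(participant = p, region = rg, voxel = sel)
    }
  }
  V <- do.call(rbind, blocks)
  R <- stats::cor(t(V))
  fit <- principal_axis_factoring(R, n_factors, max_iter = 1000L,
                                 on_stall = "accept")
  rot <- varimax_rotate(fit$loadings)
  L <- drop_null_factors(rot$loadings)
  F <- solve_factor_profiles(L, V)
  structure(list(
    level = 1L, loadings = L, profiles = F,
    eigenvalues = fit$eigenvalues,
    explained = colSums(L^2) / nrow(L),
    item_origin = do.call(rbind, origin)
  ), class = "factor_model")
}

#' Align recovered factors to reference profiles
#'
#' Factor profiles are identified only up to column order and sign. This
#' helper finds, by exhaustive search over permutations, the assignment of
#' recovered factors to reference profiles maximizing the total absolute
#' Pearson correlation, and the accompanying signs.
#'
#' @param recovered k x words matrix of recovered factor profiles.
#' @param reference m x words matrix of reference profiles (m <= k).
#' @return List with `perm` (for each reference row, the index of the
#'   matched recovered row), `signs`, and `cors` (the signed correlations of
#'   the matched pairs).
#' @export
align_factors <- function(recovered, reference) {
  stopifnot(ncol(recovered) == ncol(reference),
            nrow(reference) <= nrow(recovered))
  cors <- stats::cor(t(reference), t(recovered))  # m x k
  m <- nrow(reference)
  best <- NULL
  best_val <- -Inf
  # choose m of the k recovered factors, in order: search permutations of the
  # top candidates -- for small k an exhaustive search over injections
  combos <- utils::combn(nrow(recovered), m, simplify = FALSE)
  perms <- all_permutations(m)
  for (cmb in combos) {
    for (pp in perms) {
      idx <- cmb[pp]
      val <- sum(abs(cors[cbind(seq_len(m), idx)]))
      if (val > best_val) {
        best_val <- val
        best <- idx
      }
    }
  }
  matched <- cors[cbind(seq_len(m), best)]
  list(perm = best, signs = ifelse(matched >= 0, 1, -1), cors = matched)
}
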