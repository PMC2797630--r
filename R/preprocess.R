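#' Normalize a single image across voxels
#'
#' Standardizes a vector of per-voxel activation to mean 0 and SD 1 (sample
#' SD, denominator n - 1), the within-image normalization applied to each
#' per-word mean image.
#'
#' @param image Numeric vector of per-voxel activation (length >= 2).
#' @return The standardized vector.
#' @export
normalize_within_image <- function(image) {
  if (length(image) < 2L) stop("image must contain at least 2 voxels")
  s <- stats::sd(image)
  if (!is.finite(s) || s == 0) {
    stop("degenerate image: constant across voxels, cannot normalize")
  }
  (image - mean(image)) / s
}

#' Mean word-activation profiles of one participant's voxels
#'
#' Averages activation over a subset of presentations, yielding each voxel's
#' activation profile over the words. No normalization is applied here; see
#' [normalize_across_words()].
#'
#' @param dataset An `activation_dataset`.
#' @param participant Participant index.
#' @param presentations Integer subset of presentations to average (default:
#'   all).
#' @return A list of class `voxel_profiles` with `profiles` (voxels x words
#'   matrix) and `presentations`.
#' @export
mean_word_profiles <- function(dataset, participant, presentations = NULL) {
  stopifnot(inherits(dataset, "activation_dataset"))
  if (!participant %in% dataset$participants) {
    stop("unknown participant: ", participant)
  }
  n_pres <- dim(dataset$values)[2]
  presentations <- presentations %||% seq_len(n_pres)
  if (!length(presentations) || !all(presentations %in% seq_len(n_pres))) {
    stop("unknown presentation id in subset")
  }
  sub <- dataset$values[participant, presentations, , , drop = FALSE]
  d <- dim(sub)
  m <- matrix(colMeans(matrix(sub, nrow = d[2])), d[3], d[4])  # words x voxels
  structure(list(
    profiles = t(m),                  # voxels x words
    presentations = sort(presentations),
    participant = participant,
    words = dimnames(dataset$values)[[3]]
  ), class = "voxel_profiles")
}

#' Normalize voxel profiles across words
#'
#' Standardizes each voxel's activation profile over the words to mean 0 and
#' SD 1 (sample SD). Correlations between voxels are unchanged.
#'
#' @param profiles A `voxel_profiles` object or a voxels x words matrix.
#' @return Object of the same shape with every row standardized.
#' @export
normalize_across_words <- function(profiles) {
  m <- if (inherits(profiles, "voxel_profiles")) profiles$profiles else profiles
  mu <- rowMeans(m)
  s <- apply(m, 1, stats::sd)
  bad <- which(!is.finite(s) | s == 0)
  if (length(bad)) {
    stop("constant activation profile for voxel(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         "; cannot normalize across words")
  }
  z <- (m - mu) / s
  if (inherits(profiles, "voxel_profiles")) {
    profiles$profiles <- z
    profiles
  } else {
    z
  }
}

#' Per-voxel stability scores
#'
#' A voxel's stability is the mean Pearson correlation between its word
#' activation profiles over all unordered pairs of presentations. With
#' several participants given, each participant's mean profile (averaged over
#' their presentations) is treated as one pseudo-presentation and stability
#' is the mean pairwise correlation across participants — the cross-
#' participant screening rule.
#'
#' @param dataset An `activation_dataset`.
#' @param participants One participant index (within-participant stability)
#'   or several (cross-participant stability).
#' @param presentations Presentation subset (within-participant scope only;
#'   default all). At least 2 profiles are required.
#' @param voxels Optional voxel indices to restrict to (default: all).
#' @return Numeric vector of stability scores in \[-1, 1\], one per voxel,
#'   with attribute `presentations`.
#' @export
voxel_stability <- function(dataset, participants, presentations = NULL,
                            voxels = NULL) {
  stopifnot(inherits(dataset, "activation_dataset"))
  voxels <- voxels %||% seq_len(dim(dataset$values)[4])
  if (length(participants) == 1L) {
    n_pres <- dim(dataset$values)[2]
    presentations <- presentations %||% seq_len(n_pres)
    if (length(presentations) < 2L) {
      stop("stability requires at least 2 presentations")
    }
    nw <- dim(dataset$values)[3]
    mats <- lapply(presentations, function(r) {
      matrix(dataset$values[participants, r, , voxels], nrow = nw)
    })
  } else {
    mats <- lapply(participants, function(p) {
      t(mean_word_profiles(dataset, p, presentations)$profiles[voxels, ,
                                                               drop = FALSE])
    })
  }
  n_prof <- length(mats)
  nobs <- nrow(mats[[1]])
  zmats <- vector("list", n_prof)
  for (a in seq_len(n_prof)) {
    z <- scale(mats[[a]])
    bad <- which(!is.finite(attr(z, "scaled:scale")) |
                   attr(z, "scaled:scale") == 0)
    if (length(bad)) {
      stop("constant activation profile for voxel(s) ",
           paste(utils::head(voxels[bad], 5), collapse = ", "),
           " in profile ", a, "; stability undefined")
    }
    zmats[[a]] <- z
  }
  acc <- numeric(length(voxels))
  n_pairs <- 0L
  for (a in seq_len(n_prof - 1L)) {
    for (b in (a + 1L):n_prof) {
      acc <- acc + colSums(zmats[[a]] * zmats[[b]]) / (nobs - 1)
      n_pairs <- n_pairs + 1L
    }
  }
  out <- acc / n_pairs
  names(out) <- voxels
  attr(out, "presentations") <- presentations
  out
}

#' Select the most stable voxels
#'
#' Returns the `n` voxels with highest stability, either over the whole
#' cortex or separately within each region ("lobe"). Ties are broken by
#' ascending voxel id, so the selection is a deterministic function of the
#' scores.
#'
#' @param scores Named numeric vector of stability scores (names = voxel
#'   ids), as returned by [voxel_stability()].
#' @param n Number of voxels to select (per region, for per-region scope).
#' @param scope `"all"` (default) or `"per-region"`.
#' @param regions Per-voxel region labels aligned with `scores` (required for
#'   per-region scope).
#' @return Integer vector of selected voxel ids, ordered by decreasing
#'   stability (within region for per-region scope).
#' @export
select_stable_voxels <- function(scores, n, scope = c("all", "per-region"),
                                 regions = NULL) {
  scope <- match.arg(scope)
  ids <- as.integer(names(scores))
  if (scope == "all") {
    if (n > length(scores)) stop("n exceeds number of voxels in scope")
    ord <- order(-scores, ids)
    ids[ord[seq_len(n)]]
  } else {
    if (is.null(regions)) stop("per-region scope requires region labels")
    stopifnot(length(regions) == length(scores))
    unlist(lapply(unique(regions), function(rg) {
      sel <- regions == rg
      if (n > sum(sel)) {
        stop("n exceeds number of voxels in region ", rg)
      }
      sub <- scores[sel]
      sub_ids <- ids[sel]
      ord <- order(-sub, sub_ids)
      sub_ids[ord[seq_len(n)]]
    }), use.names = FALSE)
  }
}
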