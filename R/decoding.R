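#' Semantic-times-stability score of a voxel
#'
#' The feature-selection score combining a voxel's match to a factor with its
#' reliability: the absolute Pearson correlation between the voxel's mean
#' activation profile and the factor's profile, multiplied by the voxel's
#' stability. The absolute value is taken because factor profiles carry an
#' arbitrary sign after rotation; set `use_abs = FALSE` for the signed
#' variant.
#'
#' @param voxel_profile Numeric vector over words.
#' @param factor_profile Numeric vector over the same words.
#' @param stability The voxel's stability score.
#' @param use_abs Take the absolute correlation (default `TRUE`).
#' @return The scalar score.
#' @export
semantic_stability_score <- function(voxel_profile, factor_profile,
                                     stability, use_abs = TRUE) {
  stopifnot(length(voxel_profile) == length(factor_profile))
  if (stats::sd(voxel_profile) == 0 || stats::sd(factor_profile) == 0) {
    stop("constant profile: correlation undefined")
  }
  r <- stats::cor(voxel_profile, factor_profile)
  (if (use_abs) abs(r) else r) * stability
}

#' Select classifier features
#'
#' Builds the voxel feature set from training data only. Modes:
#' `factor_based` takes, from each search volume, the `per_volume` voxels
#' with the highest product of semantic and stability scores against that
#' volume's factor profile; `stability_only` takes the `n_features` most
#' stable voxels anywhere in cortex; `single_factor` and `semantic_only`
#' are `factor_based` restricted to the volumes of the given factor(s).
#'
#' @param train_profiles Voxels x words matrix of normalized mean profiles
#'   computed from training presentations only (needed for factor modes).
#' @param stability Named stability vector over all voxels (training data
#'   only).
#' @param mode One of `"factor_based"`, `"stability_only"`,
#'   `"single_factor"`, `"semantic_only"`.
#' @param volumes List of `search_volume`s (factor modes).
#' @param factor_profiles Factors x words matrix of factor profiles aligned
#'   with the volumes' factor ids (factor modes).
#' @param grid Voxel table.
#' @param n_features Feature count for `stability_only` (default 80).
#' @param per_volume Voxels per search volume (default 5).
#' @param factor_ids For `single_factor` / `semantic_only`: the factor id(s)
#'   whose volumes are used.
#' @param use_abs Passed to [semantic_stability_score()].
#' @return A data frame of class `feature_set` with columns `voxel`,
#'   `factor` (NA for stability mode) and `score`.
#' @export
select_features <- function(train_profiles = NULL, stability, mode,
                            volumes = NULL, factor_profiles = NULL,
                            grid = NULL, n_features = 80L, per_volume = 5L,
                            factor_ids = NULL, use_abs = TRUE) {
  mode <- match.arg(mode, c("factor_based", "stability_only",
                            "single_factor", "semantic_only"))
  if (mode == "stability_only") {
    sel <- select_stable_voxels(stability, n_features)
    fs <- data.frame(voxel = sel, factor = NA_integer_,
                     score = unname(stability[as.character(sel)]))
  } else {
    if (is.null(volumes) || is.null(factor_profiles) || is.null(grid) ||
          is.null(train_profiles)) {
      stop("factor modes require volumes, factor_profiles, grid and ",
           "train_profiles")
    }
    if (mode %in% c("single_factor", "semantic_only")) {
      if (is.null(factor_ids)) stop("factor_ids required for this mode")
      volumes <- Filter(function(v) v$factor %in% factor_ids, volumes)
      if (!length(volumes)) stop("no search volumes for the given factor(s)")
    }
    rows <- lapply(volumes, function(vol) {
      vox <- volume_voxels(vol, grid)
      if (length(vox) < per_volume) {
        stop("search volume for factor ", vol$factor, " contains ",
             length(vox), " voxels (< ", per_volume, "); grid too small")
      }
      fp <- factor_profiles[vol$factor, ]
      sc <- vapply(vox, function(v) {
        semantic_stability_score(train_profiles[v, ], fp,
                                 stability[[as.character(v)]],
                                 use_abs = use_abs)
      }, numeric(1))
      ord <- order(-sc, vox)
      data.frame(voxel = vox[ord[seq_len(per_volume)]],
                 factor = vol$factor,
                 score = sc[ord[seq_len(per_volume)]])
    })
    fs <- do.call(rbind, rows)
  }
  class(fs) <- c("feature_set", "data.frame")
  fs
}

#' Fit a Gaussian Naive Bayes classifier with pooled variance
#'
#' Class-conditional feature distributions are Gaussian with per-class means
#' and a single per-feature variance pooled over all classes: the sample
#' variance (denominator N - 1) of the pooled training values after
#' subtracting each value's class mean.
#'
#' @param x Examples x features numeric matrix.
#' @param y Class labels (one per example; every class must appear).
#' @return A list of class `gnb_model`: `means` (classes x features),
#'   `pooled_var` (per feature), `priors`, `classes`.
#' @export
gnb_fit <- function(x, y) {
  stopifnot(is.matrix(x), nrow(x) == length(y), nrow(x) >= 2)
  y <- as.character(y)
  classes <- unique(y)
  means <- matrix(0, length(classes), ncol(x),
                  dimnames = list(classes, colnames(x)))
  for (ci in seq_along(classes)) {
    means[ci, ] <- colMeans(x[y == classes[ci], , drop = FALSE])
  }
  centered <- x - means[match(y, classes), , drop = FALSE]
  pooled_var <- apply(centered, 2, stats::var)
  bad <- which(pooled_var <= 0 | !is.finite(pooled_var))
  if (length(bad)) {
    stop("zero pooled variance for feature(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         "; classifier is degenerate")
  }
  priors <- as.numeric(table(y)[classes]) / length(y)
  structure(list(means = means, pooled_var = pooled_var,
                 priors = priors, classes = classes),
            class = "gnb_model")
}

#' Rank class labels for a test vector
#'
#' Computes, in log space, the posterior of each class (prior times the
#' product of Gaussian feature likelihoods under the pooled variance) and
#' returns the labels ordered by decreasing posterior. Ties are broken by
#' the class order stored in the model, so the ranking is deterministic.
#'
#' @param model A `gnb_model`.
#' @param x Numeric test vector, one value per feature.
#' @return Data frame with `label`, `log_posterior` and `rank` (1 = best),
#'   ordered by rank.
#' @export
gnb_rank <- function(model, x) {
  stopifnot(inherits(model, "gnb_model"),
            length(x) == length(model$pooled_var))
  diff2 <- sweep(model$means, 2, x)^2
  ll <- log(model$priors) -
    rowSums(sweep(diff2, 2, 2 * model$pooled_var, `/`))
  ord <- order(-ll)  # stable: ties keep class order
  data.frame(label = model$classes[ord],
             log_posterior = ll[ord],
             rank = seq_along(ord),
             stringsAsFactors = FALSE)
}

#' Normalized rank accuracy
#'
#' Maps the rank of the correct label in an N-way ranked list to
#' `(N - r) / (N - 1)`: 1 when ranked first, 0 when last, and 0.5 on average
#' under a uniformly random rank.
#'
#' @param r Rank of the correct label (1-based).
#' @param n_classes Number of classes N.
#' @return The normalized rank accuracy.
#' @export
rank_accuracy <- function(r, n_classes) {
  if (any(r < 1 | r > n_classes)) stop("rank out of range")
  (n_classes - r) / (n_classes - 1)
}

# Build z-scored training examples for one presentation / pseudo-presentation:
# words x features matrix, each feature standardized across words.
normalize_feature_block <- function(block) {
  mu <- colMeans(block)
  s <- apply(block, 2, stats::sd)
  if (any(s == 0)) stop("constant feature across words; cannot normalize")
  sweep(sweep(block, 2, mu), 2, s, `/`)
}

# Resolve a feature policy for one fold. `policy` is a list with $mode and
# mode-specific entries (see select_features); `stability` and
# `train_profiles` come from training data only.
resolve_features <- function(policy, stability, train_profiles, grid) {
  select_features(
    train_profiles = train_profiles, stability = stability,
    mode = policy$mode, volumes = policy$volumes,
    factor_profiles = policy$factor_profiles, grid = grid,
    n_features = policy$n_features %||% 80L,
    per_volume = policy$per_volume %||% 5L,
    factor_ids = policy$factor_ids,
    use_abs = policy$use_abs %||% TRUE)
}

#' Within-participant cross-validated word decoding
#'
#' Leave-two-presentations-out word identification: for each of the
#' C(6, 2) = 15 folds, stability and feature selection use only the four
#' training presentations, a GNB-pooled classifier is trained on the
#' per-presentation examples (each feature z-scored across words separately
#' per presentation), and the mean of the two left-out presentations is
#' classified. Per-word normalized rank accuracies are averaged over folds,
#' then over words.
#'
#' @param dataset An `activation_dataset` (needs >= 3 presentations).
#' @param participant Participant index.
#' @param features Feature policy: a list with `mode` and the entries
#'   required by [select_features()] (e.g. `list(mode = "stability_only",
#'   n_features = 80)` or `list(mode = "factor_based", volumes = ...,
#'   factor_profiles = ...)`).
#' @param n_test_presentations Held-out presentations per fold (default 2).
#' @param permute_seed If non-`NULL`, word labels of the training examples
#'   are permuted by a single random permutation (drawn from this seed) in
#'   every fold — the null model used by [permutation_threshold()].
#' @param keep_posteriors Keep per-fold log-posterior matrices (needed by
#'   [within_category_accuracy()]).
#' @return A list of class `decoding_result`: `fold_accuracy` (folds x
#'   words), `word_accuracy`, `mean_accuracy`, `folds`, and optionally
#'   `posteriors`.
#' @export
within_participant_cv <- function(dataset, participant, features,
                                  n_test_presentations = 2L,
                                  permute_seed = NULL,
                                  keep_posteriors = FALSE) {
  stopifnot(inherits(dataset, "activation_dataset"))
  n_pres <- dim(dataset$values)[2]
  words <- dataset$words$word
  nw <- length(words)
  folds <- cv_folds(n_pres, n_test_presentations)
  perm <- NULL
  if (!is.null(permute_seed)) {
    perm <- local_seed(permute_seed, sample(nw))
  }
  fold_acc <- matrix(NA_real_, length(folds), nw,
                     dimnames = list(NULL, words))
  posteriors <- if (keep_posteriors) vector("list", length(folds)) else NULL
  for (fi in seq_along(folds)) {
    test_pres <- folds[[fi]]
    train_pres <- setdiff(seq_len(n_pres), test_pres)
    stab <- voxel_stability(dataset, participant, train_pres)
    train_prof <- NULL
    if (features$mode != "stability_only") {
      train_prof <- normalize_across_words(
        mean_word_profiles(dataset, participant, train_pres)$profiles)
    }
    fs <- resolve_features(features, stab, train_prof, dataset$voxels)
    # training examples: one per (presentation, word)
    xs <- list()
    ys <- list()
    for (r in train_pres) {
      block <- dataset$values[participant, r, , fs$voxel, drop = FALSE]
      block <- matrix(block, nrow = nw)
      xs[[length(xs) + 1L]] <- normalize_feature_block(block)
      lab <- words
      if (!is.null(perm)) lab <- words[perm]
      ys[[length(ys) + 1L]] <- lab
    }
    model <- gnb_fit(do.call(rbind, xs), unlist(ys))
    # test: mean of the left-out presentations, z-scored across words
    sub <- dataset$values[participant, test_pres, , fs$voxel, drop = FALSE]
    test_block <- matrix(colMeans(matrix(sub, nrow = dim(sub)[2])), nw)
    test_block <- normalize_feature_block(test_block)
    if (keep_posteriors) {
      post <- matrix(NA_real_, nw, nw, dimnames = list(words, words))
    }
    for (w in seq_len(nw)) {
      ranked <- gnb_rank(model, test_block[w, ])
      r <- ranked$rank[ranked$label == words[w]]
      fold_acc[fi, w] <- rank_accuracy(r, nw)
      if (keep_posteriors) {
        post[w, ranked$label] <- ranked$log_posterior
      }
    }
    if (keep_posteriors) posteriors[[fi]] <- post
  }
  word_acc <- colMeans(fold_acc)
  structure(list(
    fold_accuracy = fold_acc, word_accuracy = word_acc,
    mean_accuracy = mean(word_acc), folds = folds,
    posteriors = posteriors, participant = participant
  ), class = "decoding_result")
}

#' Word identification restricted to taxonomic categories
#'
#' Re-ranks each test word's posteriors among only the five candidates of
#' its own taxonomic category (the classifier itself was trained on all 60
#' words) and returns the mean normalized 5-way rank accuracy. Optionally
#' also computes the matched control in which each word competes against
#' four randomly chosen other words.
#'
#' @param result A `decoding_result` with `keep_posteriors = TRUE`.
#' @param words A `wordset`.
#' @param random_control If `TRUE`, also compute the random-candidate
#'   control.
#' @param seed Seed for the random control draws.
#' @return List with `within_category` (mean accuracy) and, if requested,
#'   `random_candidates`.
#' @export
within_category_accuracy <- function(result, words, random_control = FALSE,
                                     seed = 1L) {
  stopifnot(inherits(result, "decoding_result"))
  if (is.null(result$posteriors)) {
    stop("result lacks posteriors; rerun with keep_posteriors = TRUE")
  }
  nw <- nrow(words)
  cat_acc <- numeric(0)
  rnd_acc <- numeric(0)
  rnd_sets <- NULL
  if (random_control) {
    rnd_sets <- local_seed(seed, {
      lapply(seq_len(nw), function(w) {
        c(w, sample(setdiff(seq_len(nw), w), 4L))
      })
    })
  }
  for (post in result$posteriors) {
    for (w in seq_len(nw)) {
      cand <- which(words$category == words$category[w])
      ll <- post[w, words$word[cand]]
      r <- which(order(-ll, cand) == match(w, cand))
      cat_acc <- c(cat_acc, rank_accuracy(r, length(cand)))
      if (random_control) {
        cand2 <- rnd_sets[[w]]
        ll2 <- post[w, words$word[cand2]]
        r2 <- which(order(-ll2, seq_along(cand2)) == 1L)
        rnd_acc <- c(rnd_acc, rank_accuracy(r2, length(cand2)))
      }
    }
  }
  out <- list(within_category = mean(cat_acc))
  if (random_control) out$random_candidates <- mean(rnd_acc)
  out
}

#' Cross-participant word decoding
#'
#' Leave-one-participant-out identification: for each held-out participant,
#' every training participant's presentations are averaged into one mean
#' image per word and treated as one pseudo-presentation; stability is the
#' mean pairwise correlation across training participants' mean profiles;
#' features are selected from training data only; the GNB classifier is
#' trained on the pseudo-presentation examples and tested on the held-out
#' participant's mean images. The held-out participant's data are never
#' touched during selection or training.
#'
#' @param dataset An `activation_dataset` with >= 2 participants.
#' @param features Feature policy as in [within_participant_cv()], or a
#'   function of the training participant indices returning such a policy
#'   (used to derive factor volumes/profiles excluding the test
#'   participant).
#' @param participants Participants to test (default: all).
#' @param permute_seed As in [within_participant_cv()].
#' @return List of class `cross_decoding_result`: `per_participant` (named
#'   mean accuracies), `mean_accuracy`, `results` (per-participant word
#'   accuracies).
#' @export
cross_participant_cv <- function(dataset, features, participants = NULL,
                                 permute_seed = NULL) {
  stopifnot(inherits(dataset, "activation_dataset"))
  all_p <- dataset$participants
  if (length(all_p) < 2) stop("cross-participant CV needs >= 2 participants")
  participants <- participants %||% all_p
  words <- dataset$words$word
  nw <- length(words)
  perm <- NULL
  if (!is.null(permute_seed)) {
    perm <- local_seed(permute_seed, sample(nw))
  }
  per_part <- numeric(0)
  word_accs <- list()
  for (test_p in participants) {
    train_ps <- setdiff(all_p, test_p)
    policy <- if (is.function(features)) features(train_ps) else features
    stab <- voxel_stability(dataset, train_ps)
    train_mats <- lapply(train_ps, function(p) {
      t(mean_word_profiles(dataset, p)$profiles)   # words x voxels
    })
    train_prof <- NULL
    if (policy$mode != "stability_only") {
      pooled <- Reduce(`+`, train_mats) / length(train_mats)
      train_prof <- normalize_across_words(t(pooled))
    }
    fs <- resolve_features(policy, stab, train_prof, dataset$voxels)
    xs <- lapply(train_mats, function(m) {
      normalize_feature_block(m[, fs$voxel, drop = FALSE])
    })
    lab <- if (is.null(perm)) words else words[perm]
    model <- gnb_fit(do.call(rbind, xs),
                     rep(lab, times = length(train_mats)))
    test_block <- t(mean_word_profiles(dataset, test_p)$profiles)
    test_block <- normalize_feature_block(test_block[, fs$voxel,
                                                     drop = FALSE])
    acc <- vapply(seq_len(nw), function(w) {
      ranked <- gnb_rank(model, test_block[w, ])
      rank_accuracy(ranked$rank[ranked$label == words[w]], nw)
    }, numeric(1))
    per_part[as.character(test_p)] <- mean(acc)
    word_accs[[as.character(test_p)]] <- stats::setNames(acc, words)
  }
  structure(list(per_participant = per_part,
                 mean_accuracy = mean(per_part),
                 results = word_accs),
            class = "cross_decoding_result")
}

#' Permutation threshold for decoding accuracy
#'
#' Re-runs a cross-validation procedure with randomly permuted training
#' labels and returns the empirical (1 - alpha) quantile of the permuted
#' mean accuracies — the significance threshold used to judge observed
#' accuracies.
#'
#' @param cv_fun Function taking a single `permute_seed` argument and
#'   returning an object with a `mean_accuracy` component (wrap
#'   [within_participant_cv()] or [cross_participant_cv()]).
#' @param n_permutations Number of permutation runs.
#' @param alpha Significance level (default 0.001).
#' @param seed Base seed; permutation run i uses a seed derived from it.
#' @return The threshold (numeric scalar) with attribute `accuracies`
#'   holding the permuted means.
#' @export
permutation_threshold <- function(cv_fun, n_permutations, alpha = 0.001,
                                  seed = 1L) {
  stopifnot(n_permutations >= 1, alpha > 0, alpha < 1)
  accs <- vapply(seq_len(n_permutations), function(i) {
    cv_fun(child_seed(seed, i))$mean_accuracy
  }, numeric(1))
  thr <- unname(stats::quantile(accs, 1 - alpha, type = 1))
  attr(thr, "accuracies") <- accs
  thr
}
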