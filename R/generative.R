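#' Align recovered factor scores to rating dimensions
#'
#' Matches recovered factor profiles (arbitrary order and sign) to the rated
#' semantic dimensions plus word length, by exhaustive search over
#' assignments maximizing total absolute correlation over the training
#' words, and flips signs so each matched factor correlates positively with
#' its dimension.
#'
#' @param scores k x words matrix of recovered factor scores (k >= number of
#'   target dimensions).
#' @param targets words x m matrix of target predictor values (rating
#'   columns and word length), column names = dimension names.
#' @return List with `scores` (m x words, matched and sign-flipped, rows
#'   named after the targets), `perm` and `cors`.
#' @export
align_scores_to_targets <- function(scores, targets) {
  al <- align_factors(scores, t(targets))
  out <- scores[al$perm, , drop = FALSE] * al$signs
  rownames(out) <- colnames(targets)
  list(scores = out, perm = al$perm, cors = al$cors)
}

#' Build a regression design matrix
#'
#' Standardizes predictor columns over the training words (mean 0, SD 1,
#' sample SD) and appends an intercept. Test rows are standardized with the
#' *training* means and SDs, so training predictors (factor scores) and test
#' predictors (behavioral ratings) live on a common scale.
#'
#' @param train_predictors Training words x predictors matrix.
#' @param test_predictors Optional test words x predictors matrix (same
#'   columns), standardized using the training statistics.
#' @return List with `train` (n x (p+1) matrix, intercept first), `test`
#'   (or `NULL`), `center`, `scale`.
#' @export
build_design <- function(train_predictors, test_predictors = NULL) {
  stopifnot(is.matrix(train_predictors))
  if (anyNA(train_predictors)) stop("missing predictor value")
  ctr <- colMeans(train_predictors)
  scl <- apply(train_predictors, 2, stats::sd)
  if (any(scl == 0)) stop("constant predictor column")
  ztr <- sweep(sweep(train_predictors, 2, ctr), 2, scl, `/`)
  train <- cbind(intercept = 1, ztr)
  test <- NULL
  if (!is.null(test_predictors)) {
    if (anyNA(test_predictors)) stop("missing predictor value")
    zte <- sweep(sweep(test_predictors, 2, ctr), 2, scl, `/`)
    test <- cbind(intercept = 1, zte)
  }
  qrX <- qr(train)
  if (qrX$rank < ncol(train)) stop("design matrix is rank deficient")
  list(train = train, test = test, center = ctr, scale = scl)
}

#' Fit the per-voxel generative regression
#'
#' Independent ordinary least squares of each selected voxel's activation on
#' the design matrix over the training words.
#'
#' @param design Training design matrix (words x predictors, intercept
#'   included), full rank.
#' @param activations Training words x voxels activation matrix.
#' @return A list of class `generative_model` with `coefficients`
#'   (predictors x voxels) and `design_colnames`.
#' @export
fit_generative <- function(design, activations) {
  stopifnot(is.matrix(design), is.matrix(activations),
            nrow(design) == nrow(activations))
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) stop("design matrix is rank deficient")
  B <- qr.coef(qrX, activations)
  structure(list(coefficients = B, design_colnames = colnames(design)),
            class = "generative_model")
}

# Cosine similarity of two vectors; zero-norm input is an error.
cosine <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-norm vector in cosine similarity")
  sum(a * b) / (na * nb)
}

#' Match two predicted images to two observed images
#'
#' Chooses between the straight pairing (prediction 1 with observation A,
#' prediction 2 with observation B) and the swapped pairing by the larger
#' total cosine similarity. The match is correct iff the straight pairing
#' wins; an exact tie counts as incorrect (conservative).
#'
#' @param predicted 2 x voxels matrix of predicted images.
#' @param observed 2 x voxels matrix of observed images, row i the true
#'   image of predicted row i.
#' @return List with `correct` (logical), `straight` and `swapped` cosine
#'   sums.
#' @export
predict_and_match <- function(predicted, observed) {
  stopifnot(nrow(predicted) == 2, nrow(observed) == 2,
            ncol(predicted) == ncol(observed))
  straight <- cosine(predicted[1, ], observed[1, ]) +
    cosine(predicted[2, ], observed[2, ])
  swapped <- cosine(predicted[1, ], observed[2, ]) +
    cosine(predicted[2, ], observed[1, ])
  list(correct = straight > swapped, straight = straight, swapped = swapped)
}

#' Enumerate leave-out folds
#'
#' All unordered subsets of size `k` from `n` items — the cross-validation
#' fold sets: `cv_folds(6, 2)` are the 15 held-out presentation pairs,
#' `cv_folds(60, 2)` the 1,770 held-out word pairs.
#'
#' @param n Number of items.
#' @param k Held-out subset size.
#' @return List of integer vectors.
#' @export
cv_folds <- function(n, k) {
  utils::combn(n, k, simplify = FALSE)
}

#' Binomial chance threshold for pair matching
#'
#' The smallest proportion of correct binary matches that is significant at
#' level `alpha` under the null of coin-flip matching: the least k with
#' P(X >= k) <= alpha for X ~ Binomial(n_trials, 0.5), returned as
#' k / n_trials.
#'
#' @param n_trials Number of matching attempts.
#' @param alpha Significance level in (0, 1) (default 0.001).
#' @return The threshold proportion.
#' @export
chance_match_threshold <- function(n_trials, alpha = 0.001) {
  stopifnot(n_trials >= 1)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  k <- seq(0, n_trials)
  tail_p <- stats::pbinom(k - 1, n_trials, 0.5, lower.tail = FALSE)
  ok <- which(tail_p <= alpha)
  if (!length(ok)) return(Inf)
  k[min(ok)] / n_trials
}

# Shared per-fold machinery of the generative protocols. Re-runs the factor
# pipeline on the 58 training words using the reference participants,
# localizes the top factors, selects per-volume features from the supplied
# stability/profiles, and returns the fold's feature set, aligned factor
# scores and volumes. `targets` is the words x m predictor target matrix
# (over training words).
generative_fold_features <- function(train_ds, reference_participants,
                                     targets, stability, train_profiles,
                                     params) {
  tl <- run_two_level(
    train_ds, reference_participants,
    n_stable_per_region = params$n_stable_per_region %||% 50L,
    n_first_factors = params$n_first_factors %||% 5L,
    n_second_factors = params$n_second_factors %||% 10L,
    threshold = params$threshold %||% 0.4)
  n_use <- params$n_factors_use %||% ncol(targets)
  top <- order(-tl$explained)[seq_len(n_use)]
  loc <- localize_factors(tl, train_ds, factors = top,
                          min_size = params$min_cluster %||% 5L,
                          connectivity = params$connectivity %||% 26L)
  volumes <- make_search_volumes(loc, train_ds)
  if (!length(volumes)) stop("no factor clusters found in this fold")
  scores <- tl$second_level$profiles[top, , drop = FALSE]
  al <- align_scores_to_targets(scores, targets)
  fs <- select_features(
    train_profiles = train_profiles, stability = stability,
    mode = "factor_based", volumes = volumes,
    factor_profiles = tl$second_level$profiles, grid = train_ds$voxels,
    per_volume = params$per_volume %||% 5L)
  list(features = fs, scores = al$scores, volumes = volumes, model = tl)
}

# Normalize a voxels x words profile matrix by per-voxel mean/SD computed on
# the training words, and apply the same statistics to held-out columns.
train_normalized_profiles <- function(profiles, train_idx, test_idx) {
  tr <- profiles[, train_idx, drop = FALSE]
  mu <- rowMeans(tr)
  s <- apply(tr, 1, stats::sd)
  if (any(s == 0)) stop("constant voxel profile over training words")
  list(train = (tr - mu) / s,
       test = (profiles[, test_idx, drop = FALSE] - mu) / s)
}

#' Leave-two-words-out generative prediction
#'
#' Zero-shot prediction protocol: for each held-out word pair, the factor
#' pipeline is re-run on the remaining 58 words using the reference
#' participants, the per-fold factor locations drive voxel selection, a
#' per-voxel regression of the analyzed participant's activation on the
#' factor-score predictors is fit over the 58 words, the two held-out words'
#' activations are predicted from their standardized behavioral ratings
#' (plus word length), and the two predictions are matched to the two
#' observed images by cosine similarity.
#'
#' @param dataset An `activation_dataset`.
#' @param participant Participant whose activation is modeled and tested.
#' @param ratings A `ratings_table` covering all words.
#' @param reference_participants Participants whose data drive the per-fold
#'   factor analysis and locations (default: all others).
#' @param pairs `"all"` for all C(60, 2) = 1770 word pairs, or an integer n
#'   for a seeded random subsample of n pairs.
#' @param seed Seed for pair subsampling.
#' @param predictors `"scores"` (default): train on per-fold factor scores,
#'   test on z-scored ratings; `"ratings"`: use z-scored ratings for both
#'   training and test rows.
#' @param feature_mode `"factor_based"` (default): per-fold factor locations
#'   drive voxel selection; `"stability_only"`: the most stable voxels are
#'   used regardless of location (the baseline variant; requires
#'   `predictors = "ratings"` since no factor scores are computed).
#' @param params Optional list of pipeline parameters
#'   (`n_stable_per_region`, `n_first_factors`, `n_second_factors`,
#'   `threshold`, `per_volume`, `min_cluster`, `connectivity`,
#'   `n_factors_use`, `n_features`).
#' @return A list of class `match_result`: `accuracy`, `n_folds`, `fold_log`
#'   (pair, correct, cosine sums).
#' @export
leave_two_words_out <- function(dataset, participant, ratings,
                                reference_participants = NULL,
                                pairs = "all", seed = 1L,
                                predictors = c("scores", "ratings"),
                                feature_mode = c("factor_based",
                                                 "stability_only"),
                                params = list()) {
  stopifnot(inherits(dataset, "activation_dataset"))
  predictors <- match.arg(predictors)
  feature_mode <- match.arg(feature_mode)
  if (feature_mode == "stability_only" && predictors != "ratings") {
    stop("stability_only feature selection computes no factor scores; ",
         "use predictors = \"ratings\"")
  }
  reference_participants <- reference_participants %||%
    setdiff(dataset$participants, participant)
  if (!length(reference_participants)) {
    stop("no reference participants for the per-fold factor analysis")
  }
  nw <- nrow(dataset$words)
  stopifnot(all(dataset$words$word %in% ratings$word))
  rat <- ratings[match(dataset$words$word, ratings$word), ]
  target_cols <- setdiff(names(rat), c("word"))
  targets_all <- as.matrix(rat[, target_cols, drop = FALSE])
  all_pairs <- cv_folds(nw, 2)
  if (!identical(pairs, "all")) {
    stopifnot(is.numeric(pairs), pairs >= 1)
    all_pairs <- local_seed(seed, sample(all_pairs, min(pairs,
                                                        length(all_pairs))))
  }
  prof_all <- mean_word_profiles(dataset, participant)$profiles
  log_rows <- vector("list", length(all_pairs))
  for (fi in seq_along(all_pairs)) {
    pair <- all_pairs[[fi]]
    train_idx <- setdiff(seq_len(nw), pair)
    train_ds <- subset_words(dataset, train_idx)
    stab <- voxel_stability(train_ds, participant)
    if (feature_mode == "stability_only") {
      fs <- select_features(stability = stab, mode = "stability_only",
                            n_features = params$n_features %||% 80L)
      ff <- list(features = fs)
    } else {
      train_prof_norm <- normalize_across_words(
        mean_word_profiles(train_ds, participant)$profiles)
      ff <- generative_fold_features(train_ds, reference_participants,
                                     targets_all[train_idx, , drop = FALSE],
                                     stab, train_prof_norm, params)
    }
    train_pred <- if (predictors == "scores") {
      t(ff$scores)                               # words x predictors
    } else {
      targets_all[train_idx, , drop = FALSE]
    }
    des <- build_design(train_pred, targets_all[pair, , drop = FALSE])
    if (predictors == "scores") {
      # test rows must be standardized on the ratings scale, not the
      # factor-score scale: restandardize using training-word ratings
      des2 <- build_design(targets_all[train_idx, , drop = FALSE],
                           targets_all[pair, , drop = FALSE])
      des$test <- des2$test
    }
    np <- train_normalized_profiles(prof_all[ff$features$voxel, ,
                                             drop = FALSE],
                                    train_idx, pair)
    fit <- fit_generative(des$train, t(np$train))
    predicted <- des$test %*% fit$coefficients
    res <- predict_and_match(predicted, t(np$test))
    log_rows[[fi]] <- data.frame(
      word1 = dataset$words$word[pair[1]], word2 = dataset$words$word[pair[2]],
      correct = res$correct, straight = res$straight, swapped = res$swapped)
  }
  fold_log <- do.call(rbind, log_rows)
  structure(list(accuracy = mean(fold_log$correct),
                 n_folds = nrow(fold_log), fold_log = fold_log,
                 participant = participant),
            class = "match_result")
}

#' Cross-participant generative prediction
#'
#' Predicts two unseen words for an unseen participant: the per-fold factor
#' pipeline and the regression are driven entirely by the other
#' participants' data (their mean images for the 58 training words,
#' averaged), and the predictions are matched to the held-out participant's
#' observed images for the two held-out words.
#'
#' @param dataset An `activation_dataset` with >= 2 participants.
#' @param ratings A `ratings_table`.
#' @param participants Held-out participants to evaluate (default: all).
#' @param pairs,seed,predictors,params As in [leave_two_words_out()].
#' @return A list of class `cross_match_result`: `per_participant`
#'   accuracies, `mean_accuracy`, `results`.
#' @export
cross_participant_generative <- function(dataset, ratings,
                                         participants = NULL,
                                         pairs = 50, seed = 1L,
                                         predictors = c("scores", "ratings"),
                                         params = list()) {
  stopifnot(inherits(dataset, "activation_dataset"))
  predictors <- match.arg(predictors)
  all_p <- dataset$participants
  if (length(all_p) < 2) stop("needs >= 2 participants")
  participants <- participants %||% all_p
  nw <- nrow(dataset$words)
  rat <- ratings[match(dataset$words$word, ratings$word), ]
  targets_all <- as.matrix(rat[, setdiff(names(rat), "word"), drop = FALSE])
  all_pairs <- cv_folds(nw, 2)
  if (!identical(pairs, "all")) {
    all_pairs <- local_seed(seed, sample(all_pairs, min(pairs,
                                                        length(all_pairs))))
  }
  per_part <- numeric(0)
  results <- list()
  for (test_p in participants) {
    train_ps <- setdiff(all_p, test_p)
    test_prof <- mean_word_profiles(dataset, test_p)$profiles
    train_prof_list <- lapply(train_ps, function(p) {
      mean_word_profiles(dataset, p)$profiles
    })
    correct <- logical(length(all_pairs))
    for (fi in seq_along(all_pairs)) {
      pair <- all_pairs[[fi]]
      train_idx <- setdiff(seq_len(nw), pair)
      train_ds <- subset_words(dataset, train_idx)
      stab <- voxel_stability(train_ds, train_ps)
      pooled <- Reduce(`+`, train_prof_list) / length(train_prof_list)
      pooled_norm <- normalize_across_words(pooled[, train_idx,
                                                   drop = FALSE])
      ff <- generative_fold_features(train_ds, train_ps,
                                     targets_all[train_idx, , drop = FALSE],
                                     stab, pooled_norm, params)
      train_pred <- if (predictors == "scores") t(ff$scores) else
        targets_all[train_idx, , drop = FALSE]
      des <- build_design(train_pred, targets_all[pair, , drop = FALSE])
      if (predictors == "scores") {
        des2 <- build_design(targets_all[train_idx, , drop = FALSE],
                             targets_all[pair, , drop = FALSE])
        des$test <- des2$test
      }
      # regression target: training participants' pooled images
      np_train <- train_normalized_profiles(
        pooled[ff$features$voxel, , drop = FALSE], train_idx, pair)
      fit <- fit_generative(des$train, t(np_train$train))
      predicted <- des$test %*% fit$coefficients
      np_test <- train_normalized_profiles(
        test_prof[ff$features$voxel, , drop = FALSE], train_idx, pair)
      res <- predict_and_match(predicted, t(np_test$test))
      correct[fi] <- res$correct
    }
    per_part[as.character(test_p)] <- mean(correct)
    results[[as.character(test_p)]] <- correct
  }
  structure(list(per_participant = per_part,
                 mean_accuracy = mean(per_part), results = results),
            class = "cross_match_result")
}
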