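# On-disk format: a directory of delimited text tables plus a JSON manifest.
# Values are written at full double precision so a round trip is exact.

write_tsv_exact <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) formatC(col, digits = 17,
                                                   format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Save an activation dataset to a directory
#'
#' Writes the dataset as inspectable delimited text: `words.tsv`,
#' `voxels.tsv`, one `values_p<P>_r<R>.tsv` matrix (words x voxels) per
#' participant and presentation, and `manifest.json` recording the grid
#' geometry, the generating configuration and seed, and the file list.
#'
#' @param dataset An `activation_dataset`.
#' @param path Directory to create/write into.
#' @return The manifest, invisibly.
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "activation_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_tsv_exact(dataset$words, file.path(path, "words.tsv"))
  write_tsv_exact(dataset$voxels, file.path(path, "voxels.tsv"))
  d <- dim(dataset$values)
  files <- character(0)
  for (p in seq_len(d[1])) {
    for (r in seq_len(d[2])) {
      f <- sprintf("values_p%d_r%d.tsv", p, r)
      m <- matrix(dataset$values[p, r, , ], nrow = d[3])
      write_tsv_exact(m, file.path(path, f))
      files <- c(files, f)
    }
  }
  manifest <- list(
    format = "neurosem-dataset",
    n_participants = d[1], n_presentations = d[2],
    n_words = d[3], n_voxels = d[4],
    grid_dims = dataset$grid_dims,
    voxel_size_mm = dataset$voxel_size_mm,
    grid_origin_mm = dataset$grid_origin_mm,
    seed = dataset$config$seed %||% NA,
    config = dataset$config[setdiff(names(dataset$config), NULL)],
    files = files
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Load an activation dataset from a directory
#'
#' Reads a directory written by [save_dataset()], validating presence of
#' every piece named in the manifest and the consistency of dimensions and
#' region labels.
#'
#' @param path Directory containing `manifest.json`.
#' @return An `activation_dataset`.
#' @export
load_dataset <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stop("missing manifest.json in ", path)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  for (f in c("words.tsv", "voxels.tsv", mf$files)) {
    if (!file.exists(file.path(path, f))) stop("missing dataset file: ", f)
  }
  words <- utils::read.delim(file.path(path, "words.tsv"),
                             stringsAsFactors = FALSE)
  class(words) <- c("wordset", "data.frame")
  validate_wordset(words)
  voxels <- utils::read.delim(file.path(path, "voxels.tsv"),
                              stringsAsFactors = FALSE)
  if (nrow(words) != mf$n_words) stop("word count mismatch with manifest")
  if (nrow(voxels) != mf$n_voxels) stop("voxel count mismatch with manifest")
  if (anyNA(voxels$region)) stop("voxel table has missing region labels")
  values <- array(NA_real_,
                  dim = c(mf$n_participants, mf$n_presentations,
                          mf$n_words, mf$n_voxels),
                  dimnames = list(paste0("P", seq_len(mf$n_participants)),
                                  paste0("pres", seq_len(mf$n_presentations)),
                                  words$word, NULL))
  for (p in seq_len(mf$n_participants)) {
    for (r in seq_len(mf$n_presentations)) {
      f <- sprintf("values_p%d_r%d.tsv", p, r)
      m <- as.matrix(utils::read.delim(file.path(path, f)))
      if (!all(dim(m) == c(mf$n_words, mf$n_voxels))) {
        stop("matrix ", f, " has inconsistent dimensions")
      }
      values[p, r, , ] <- m
    }
  }
  if (anyNA(values)) stop("dataset contains missing values")
  cfg <- mf$config
  structure(list(
    values = values, words = words, voxels = voxels,
    voxel_size_mm = mf$voxel_size_mm,
    grid_origin_mm = mf$grid_origin_mm,
    grid_dims = mf$grid_dims,
    participants = seq_len(mf$n_participants),
    config = cfg
  ), class = "activation_dataset")
}

#' Export stability scores as a TSV table
#'
#' @param scores Named stability vector from [voxel_stability()].
#' @param dataset The `activation_dataset`.
#' @param path Output file path.
#' @return The written data frame, invisibly.
#' @export
export_stability_tsv <- function(scores, dataset, path) {
  ids <- as.integer(names(scores))
  sub <- dataset$voxels[match(ids, dataset$voxels$voxel), ]
  df <- data.frame(voxel_id = ids, x_mm = sub$x, y_mm = sub$y, z_mm = sub$z,
                   region = sub$region, stability = as.numeric(scores))
  write_tsv_exact(df, path)
  invisible(df)
}

#' Export one word's mean image as a NIfTI volume
#'
#' Optional interoperability export (requires the RNifti package): writes
#' the participant's mean activation image for one word as a 3-D NIfTI
#' volume whose header voxel size matches the dataset geometry.
#'
#' @param dataset An `activation_dataset`.
#' @param participant Participant index.
#' @param word Word (name or index).
#' @param path Output `.nii` path.
#' @return The path, invisibly.
#' @export
export_nifti <- function(dataset, participant, word, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("RNifti is required for NIfTI export")
  }
  if (is.character(word)) word <- match(word, dataset$words$word)
  prof <- mean_word_profiles(dataset, participant)$profiles[, word]
  vol <- array(0, dim = dataset$grid_dims)
  vol[cbind(dataset$voxels$i + 1L, dataset$voxels$j + 1L,
            dataset$voxels$k + 1L)] <- prof
  img <- RNifti::asNifti(vol, reference = NULL)
  RNifti::pixdim(img) <- dataset$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
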