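#' The 60-word stimulus set
#'
#' Returns the fixed stimulus set used throughout the package: 60 concrete
#' nouns, five exemplars from each of 12 taxonomic categories (body parts,
#' furniture, vehicles, animals, kitchen utensils, tools, buildings, building
#' parts, clothing, insects, vegetables, man-made objects), in their standard
#' order together with letter counts.
#'
#' @return A data frame of class `wordset` with columns `word`, `category`
#'   and `length` (letter count), one row per word, 60 rows.
#' @examples
#' ws <- builtin_wordset()
#' nrow(ws)                      # 60
#' table(ws$category)            # 5 exemplars per category
#' @export
builtin_wordset <- function() {
  cats <- list(
    "body parts"       = c("leg", "arm", "eye", "foot", "hand"),
    "furniture"        = c("chair", "table", "bed", "desk", "dresser"),
    "vehicles"         = c("car", "airplane", "train", "truck", "bicycle"),
    "animals"          = c("horse", "dog", "bear", "cow", "cat"),
    "kitchen utensils" = c("glass", "knife", "bottle", "cup", "spoon"),
    "tools"            = c("chisel", "hammer", "screwdriver", "pliers", "saw"),
    "buildings"        = c("apartment", "barn", "house", "church", "igloo"),
    "building parts"   = c("window", "door", "chimney", "closet", "arch"),
    "clothing"         = c("coat", "dress", "shirt", "skirt", "pants"),
    "insects"          = c("fly", "ant", "bee", "butterfly", "beetle"),
    "vegetables"       = c("lettuce", "tomato", "carrot", "corn", "celery"),
    "man-made objects" = c("refrigerator", "key", "telephone", "watch", "bell")
  )
  words <- unlist(cats, use.names = FALSE)
  ws <- data.frame(
    word = words,
    category = rep(names(cats), each = 5L),
    length = nchar(words),
    stringsAsFactors = FALSE
  )
  class(ws) <- c("wordset", "data.frame")
  ws
}

#' Validate a word set
#'
#' @param ws A `wordset` data frame (see [builtin_wordset()]).
#' @return `ws`, invisibly, after checking uniqueness of words and that every
#'   category has the same number of exemplars.
#' @keywords internal
validate_wordset <- function(ws) {
  stopifnot(is.data.frame(ws), all(c("word", "category", "length") %in% names(ws)))
  if (anyDuplicated(ws$word)) stop("word set contains duplicated words")
  if (any(ws$length < 1L)) stop("word lengths must be positive")
  invisible(ws)
}
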