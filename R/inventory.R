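#' Load the character/feature inventory
#'
#' The inventory lists the 14 copying-task stimuli, their decomposition into
#' straight and curved sub-letter features (one or more allographs per
#' character), the per-feature accuracy-rule parameters, and practice flags.
#' The shipped configuration decomposes the non-practice characters into 20
#' letter features (14 straight, 6 curved) and 12 symbol features (8
#' straight, 4 curved); any user-supplied configuration must satisfy the
#' same totals.
#'
#' @param path YAML inventory file; `NULL` loads the built-in inventory.
#' @return an object of class `inventory`: a list with `characters` (named
#'   list of character specs) and `features` (a tibble with one row per
#'   primary-allograph feature).
#' @export
load_inventory <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "inventory.yaml", package = "penfluency")
  }
  if (!file.exists(path)) stop_pf("inventory file not found: ", path)
  doc <- yaml::yaml.load_file(path)
  chars <- list()
  for (ch in doc$characters) {
    allo <- lapply(ch$allographs, function(a) {
      feats <- lapply(a$features, function(f) {
        list(feature_id = f$id, shape_kind = f$shape,
             rules = f$rules %||% list())
      })
      list(allograph_id = a$id, features = feats)
    })
    chars[[ch$id]] <- list(
      character_id = ch$id, glyph = ch$glyph, is_letter = isTRUE(ch$is_letter),
      practice = isTRUE(ch$practice), allographs = allo
    )
  }
  feat_rows <- purrr::map_dfr(chars, function(ch) {
    prim <- ch$allographs[[1]]
    tibble::tibble(
      character_id = ch$character_id,
      glyph = ch$glyph,
      is_letter = ch$is_letter,
      practice = ch$practice,
      allograph_id = prim$allograph_id,
      feature_id = vapply(prim$features, `[[`, "", "feature_id"),
      shape_kind = vapply(prim$features, `[[`, "", "shape_kind")
    )
  })
  inv <- structure(list(characters = chars, features = feat_rows),
                   class = "inventory")
  validate_inventory(inv)
  inv
}

validate_inventory <- function(inv) {
  f <- inv$features[!inv$features$practice, ]
  counts <- table(ifelse(f$is_letter, "letter", "symbol"), f$shape_kind)
  expected <- c(letter_straight = 14L, letter_curved = 6L,
                symbol_straight = 8L, symbol_curved = 4L)
  got <- c(letter_straight = sum(f$is_letter & f$shape_kind == "straight"),
           letter_curved = sum(f$is_letter & f$shape_kind == "curved"),
           symbol_straight = sum(!f$is_letter & f$shape_kind == "straight"),
           symbol_curved = sum(!f$is_letter & f$shape_kind == "curved"))
  if (!identical(got, expected)) {
    stop_pf("inventory violates the feature-count invariants (",
            paste(names(got), got, sep = "=", collapse = ", "),
            "; expected ",
            paste(names(expected), expected, sep = "=", collapse = ", "), ")")
  }
  if (!all(inv$features$shape_kind %in% c("straight", "curved"))) {
    stop_pf("inventory contains an unknown shape kind")
  }
  invisible(inv)
}

#' @export
print.inventory <- function(x, ...) {
  f <- x$features
  cat(sprintf("<inventory> %d characters, %d primary features (%d practice characters)\n",
              length(x$characters), nrow(f),
              sum(vapply(x$characters, `[[`, TRUE, "practice"))))
  invisible(x)
}

#' Summarise feature counts by letter status and shape
#'
#' @param inv an [load_inventory()] object.
#' @param include_practice count practice characters too?
#' @return a tibble with `is_letter`, `shape_kind`, `n`.
#' @export
feature_counts <- function(inv, include_practice = FALSE) {
  f <- inv$features
  if (!include_practice) f <- f[!f$practice, ]
  dplyr::count(f, .data$is_letter, .data$shape_kind, name = "n")
}

#' Letters used in the dictation task
#'
#' The analysable dictation targets: letters whose production demands
#' similar motor plans in upper and lower case. Each entry lists the
#' shape-kind decomposition of both case allographs, used by
#' [validate_dictation_response()].
#'
#' @return a named list of character specs (id, allographs of shape kinds).
#' @export
dictation_inventory <- function() {
  spec <- list(
    l = list(lower = c("straight"), upper = c("straight", "straight")),
    f = list(lower = c("curved", "straight"),
             upper = c("straight", "straight", "straight")),
    i = list(lower = c("straight", "straight"), upper = c("straight")),
    b = list(lower = c("straight", "curved"),
             upper = c("straight", "curved", "curved")),
    o = list(lower = c("curved"), upper = c("curved")),
    p = list(lower = c("straight", "curved"),
             upper = c("straight", "curved")),
    u = list(lower = c("curved", "straight"), upper = c("curved")),
    s = list(lower = c("curved"), upper = c("curved")),
    k = list(lower = c("straight", "straight", "straight"),
             upper = c("straight", "straight", "straight")),
    v = list(lower = c("straight", "straight"),
             upper = c("straight", "straight"))
  )
  purrr::imap(spec, function(allo, id) {
    list(character_id = id, is_letter = TRUE,
         allographs = purrr::imap(allo, function(shapes, case) {
           list(allograph_id = case,
                features = purrr::imap(shapes, function(s, i) {
                  list(feature_id = paste0(id, "_", case, "_f", i),
                       shape_kind = s, rules = list())
                }))
         }))
  })
}
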