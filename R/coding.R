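#' Rule-based accuracy coding of one produced feature
#'
#' A feature is coded `malformed` if its geometry violates any rule in its
#' specification; otherwise `accurate`. Rules are parameter-driven: an angle
#' band at the junction with a sibling feature, a straightness tolerance
#' (fraction of chord length), a length-ratio tolerance against a sibling,
#' and a junction gap/overlap tolerance. The uppercase-A uprights carry the
#' full rule set (angle 20-90 degrees, all ratio tolerances 1/6); other
#' features apply whichever subset their inventory entry specifies.
#'
#' @param segment produced geometry of the feature (n x 2 matrix or
#'   [pen_trace()]).
#' @param spec feature spec: a list with a `rules` element as stored in the
#'   inventory (`angle_bounds`, `angle_sibling`, `straightness_tol`,
#'   `length_sibling`, `length_tol`, `junction_sibling`, `junction_tol`).
#' @param context named list of sibling segments (geometry keyed by
#'   feature id), required when any sibling rule is present.
#' @return a list with `verdict` (`"accurate"`/`"malformed"`) and
#'   `fired_rules` (character vector of rule names that fired, with the
#'   measured values as names' attributes in `measures`).
#' @export
code_accuracy <- function(segment, spec, context = list()) {
  rules <- spec$rules %||% list()
  seg <- as_poly(segment)
  fired <- character(0)
  measures <- list()

  get_sib <- function(id, rule) {
    sib <- context[[id]]
    if (is.null(sib)) {
      stop_pf("accuracy rule '", rule, "' needs sibling segment '", id,
              "' in context")
    }
    as_poly(sib)
  }

  if (!is.null(rules$straightness_tol)) {
    dev <- straightness_deviation(seg)
    measures$straightness <- dev
    if (dev > rules$straightness_tol) fired <- c(fired, "straightness")
  }
  if (!is.null(rules$angle_bounds)) {
    sib <- get_sib(rules$angle_sibling, "angle")
    ang <- junction_angle(seg, sib)
    measures$angle <- ang
    if (ang < rules$angle_bounds[[1]] || ang > rules$angle_bounds[[2]]) {
      fired <- c(fired, "angle")
    }
  }
  if (!is.null(rules$length_tol)) {
    sib <- get_sib(rules$length_sibling, "length")
    len <- polyline_arclength(seg)
    len_sib <- polyline_arclength(sib)
    ratio <- abs(len - len_sib) / len_sib
    measures$length_ratio <- ratio
    if (ratio > rules$length_tol) fired <- c(fired, "length")
  }
  if (!is.null(rules$junction_tol)) {
    sib <- get_sib(rules$junction_sibling, "junction")
    gap <- junction_gap(seg, sib)
    measures$junction_gap <- gap
    if (gap > rules$junction_tol) fired <- c(fired, "junction")
  }
  list(verdict = if (length(fired)) "malformed" else "accurate",
       fired_rules = fired, measures = measures)
}

# order-preserving injective match of mark shape kinds onto target shape
# kinds (longest common subsequence); returns integer map mark -> feature
# index (NA when unmatched)
match_shapes <- function(mark_shapes, target_shapes) {
  n <- length(mark_shapes); m <- length(target_shapes)
  L <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    L[i + 1L, j + 1L] <- if (mark_shapes[i] == target_shapes[j]) {
      L[i, j] + 1L
    } else max(L[i, j + 1L], L[i + 1L, j])
  }
  assign <- rep(NA_integer_, n)
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    if (mark_shapes[i] == target_shapes[j] && L[i + 1L, j + 1L] == L[i, j] + 1L) {
      assign[i] <- j; i <- i - 1L; j <- j - 1L
    } else if (L[i, j + 1L] >= L[i + 1L, j]) i <- i - 1L else j <- j - 1L
  }
  assign
}

#' Match produced marks to the features of a target character
#'
#' Tries every allograph of the target and keeps the one matching the most
#' marks. Matching is order-preserving and injective on shape kinds, so a
#' production can be incomplete (missing features) or contain extra marks.
#' Completeness requires every target feature of the chosen allograph to be
#' matched; shape quality is not assessed here (badly shaped features still
#' match).
#'
#' @param marks a [feature_marks()] tibble (only `shape_kind` and order are
#'   used).
#' @param character_spec one character from [load_inventory()]
#'   (`inv$characters[[id]]`) or [dictation_inventory()].
#' @return list with `allograph_id`, `assignment` (tibble mark row ->
#'   target feature id), and `complete` flag.
#' @export
match_features <- function(marks, character_spec) {
  mark_shapes <- marks$shape_kind
  best <- NULL
  for (a in character_spec$allographs) {
    target <- vapply(a$features, `[[`, "", "shape_kind")
    ids <- vapply(a$features, `[[`, "", "feature_id")
    assign <- match_shapes(mark_shapes, target)
    n_matched <- sum(!is.na(assign))
    cand <- list(
      allograph_id = a$allograph_id,
      assignment = tibble::tibble(
        mark_row = seq_along(mark_shapes),
        mark_feature_id = marks$feature_id,
        target_feature_id = ifelse(is.na(assign), NA_character_, ids[assign])
      ),
      n_matched = n_matched,
      complete = n_matched == length(target)
    )
    if (is.null(best) || cand$n_matched > best$n_matched ||
        (cand$n_matched == best$n_matched && cand$complete && !best$complete)) {
      best <- cand
    }
  }
  best
}

#' Code accuracy for all marked features of one character production
#'
#' Convenience wrapper: slices each marked feature from the trace, looks up
#' its rule spec in the inventory (matching marks to the target character's
#' features first), and runs [code_accuracy()] with the sibling context.
#'
#' @param trace a [pen_trace()].
#' @param marks a [feature_marks()] tibble.
#' @param character_spec target character spec from [load_inventory()].
#' @return tibble with one row per mark: `feature_id`, `target_feature_id`,
#'   `verdict`, `fired_rules` (list-column).
#' @export
code_character_accuracy <- function(trace, marks, character_spec) {
  mt <- match_features(marks, character_spec)
  segs <- lapply(seq_len(nrow(marks)), function(i) {
    s <- slice_feature(trace, marks[i, ])
    cbind(s$samples$x, s$samples$y)
  })
  # context keyed by *target* feature id
  ctx <- list()
  for (i in seq_len(nrow(marks))) {
    tid <- mt$assignment$target_feature_id[i]
    if (!is.na(tid)) ctx[[tid]] <- segs[[i]]
  }
  allo <- NULL
  for (a in character_spec$allographs) {
    if (a$allograph_id == mt$allograph_id) allo <- a
  }
  specs <- setNames(allo$features,
                    vapply(allo$features, `[[`, "", "feature_id"))
  purrr::map_dfr(seq_len(nrow(marks)), function(i) {
    tid <- mt$assignment$target_feature_id[i]
    if (is.na(tid)) {
      return(tibble::tibble(feature_id = marks$feature_id[i],
                            target_feature_id = NA_character_,
                            verdict = "unmatched",
                            fired_rules = list(character(0))))
    }
    res <- code_accuracy(segs[[i]], specs[[tid]], context = ctx)
    tibble::tibble(feature_id = marks$feature_id[i],
                   target_feature_id = tid,
                   verdict = res$verdict,
                   fired_rules = list(res$fired_rules))
  })
}
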