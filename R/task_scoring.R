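#' Select the scored spans of a pen-control task
#'
#' Applies the task-specific selection rules: for lines and circles the
#' first two valid units are dropped and the next five consecutive units
#' produced without any pen lift are scored; for garlands all pen movement
#' is scored as one span; for figure eights every produced repetition (at
#' most seven separate traces) is scored.
#'
#' @param traces a single [pen_trace()] with a `units` attribute (lines,
#'   circles, garlands; see [gen_pencontrol_trace()]) or a list of traces
#'   (eights). Real recordings need unit boundaries from an external
#'   segmentation supplied as the `units` attribute.
#' @param task `"lines"`, `"circles"`, `"garlands"` or `"eights"`.
#' @return a list of scored spans, each `list(trace, span = c(first, last))`.
#' @export
select_scored_units <- function(traces, task) {
  task <- match.arg(task, c("lines", "circles", "garlands", "eights"))
  if (task == "eights") {
    if (inherits(traces, "pen_trace")) traces <- list(traces)
    if (length(traces) > 7L) traces <- traces[1:7]
    return(lapply(traces, function(tr) list(trace = tr, span = c(1L, n_samples(tr)))))
  }
  tr <- traces
  if (!inherits(tr, "pen_trace")) stop_pf("expected a single pen_trace for ", task)
  if (task == "garlands") {
    return(list(list(trace = tr, span = c(1L, n_samples(tr)))))
  }
  units <- attr(tr, "units")
  if (is.null(units)) stop_pf("trace has no unit delimitation ('units' attribute)")
  valid <- units[units$valid, ]
  if (nrow(valid) < 7L) {
    stop_pf("insufficient repetitions: ", nrow(valid),
            " valid units (need 2 to drop + 5 to score)")
  }
  pool <- valid[-(1:2), ]  # drop the first two valid units
  runs <- rle(!pool$pen_lift)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in seq_along(runs$values)) {
    if (runs$values[r] && runs$lengths[r] >= 5L) {
      sel <- pool[starts[r]:(starts[r] + 4L), ]
      return(list(list(trace = tr,
                       span = c(sel$start_index[1], sel$end_index[5]))))
    }
  }
  stop_pf("insufficient repetitions: no run of 5 consecutive pen-lift-free units")
}

#' Score one pen-control task for one child
#'
#' Runs [select_scored_units()] and sums [snvpd()] over the selected spans
#' (for eights: over all produced repetitions).
#'
#' @inheritParams select_scored_units
#' @param child_id identifier stamped on the score row.
#' @param fs,cutoffs,order passed to [snvpd()].
#' @return a one-row tibble: `child_id`, `task`, `snvpd`, `n_units_scored`.
#' @export
score_task <- function(traces, task, child_id = NA_character_, fs = 133,
                       cutoffs = c(10, 5), order = 4L) {
  spans <- select_scored_units(traces, task)
  vals <- vapply(spans, function(sp) {
    as.numeric(snvpd(sp$trace, span = sp$span, fs = fs, cutoffs = cutoffs,
                     order = order))
  }, numeric(1))
  n_units <- switch(match.arg(task, c("lines", "circles", "garlands", "eights")),
                    lines = 5L, circles = 5L, garlands = 1L,
                    eights = length(spans))
  tibble::tibble(child_id = child_id, task = task, snvpd = sum(vals),
                 n_units_scored = n_units)
}

#' The canonical dictation trial schedule
#'
#' Two researcher-spoken warm-up sounds followed by nine computer-played
#' sounds; the first computer sound is a technical buffer. The ten
#' analysable targets are the letters whose upper- and lower-case forms
#' demand similar motor plans.
#'
#' @return tibble with `trial`, `source` (`"researcher"`/`"computer"`),
#'   `letter`.
#' @export
canonical_dictation_schedule <- function() {
  tibble::tibble(
    trial = 1:11,
    source = c("researcher", "researcher", rep("computer", 9)),
    letter = c("l", "f", "a", "i", "b", "o", "p", "u", "s", "k", "v")
  )
}

#' Filter a dictation trial schedule down to the analysable trials
#'
#' Researcher-spoken trials are kept; the first computer-played trial is
#' dropped (it is the one most likely to be affected by technical
#' difficulties). On the canonical schedule this yields exactly 10 trials.
#'
#' @param schedule a tibble as returned by [canonical_dictation_schedule()].
#' @return the analysable subset, same columns.
#' @export
filter_dictation_trials <- function(schedule) {
  need <- c("trial", "source", "letter")
  miss <- setdiff(need, names(schedule))
  if (length(miss)) stop_pf("schedule missing column(s): ",
                            paste(miss, collapse = ", "))
  if (!all(schedule$source %in% c("researcher", "computer"))) {
    stop_pf("schedule has unknown trial source")
  }
  comp <- which(schedule$source == "computer")
  keep <- seq_len(nrow(schedule))
  if (length(comp)) keep <- setdiff(keep, comp[1])
  schedule[keep, ]
}

#' Decide whether a dictation response is an attempt at the target
#'
#' A response counts as an attempt if all features of the target letter are
#' present — however badly shaped, sized or positioned — under either case
#' variant (children chose upper or lower case freely). Feature presence is
#' assessed with [match_features()].
#'
#' @param marks a [feature_marks()] tibble for the response.
#' @param target target letter (single character, e.g. `"b"`), looked up in
#'   [dictation_inventory()].
#' @return `"attempt"` or `"non-attempt"`.
#' @export
validate_dictation_response <- function(marks, target) {
  inv <- dictation_inventory()
  spec <- inv[[target]]
  if (is.null(spec)) stop_pf("letter ", target, " is not a dictation target")
  m <- match_features(marks, spec)
  if (m$complete) "attempt" else "non-attempt"
}

#' Score the letter-knowledge tasks
#'
#' Sums correct/incorrect flags for the four tasks. The phoneme-isolation
#' and phoneme-blending tasks terminate after two consecutive failures:
#' trials after the termination point are scored 0 regardless of the
#' recorded responses. Maxima: encoding 24, decoding 24, isolation 10,
#' blending 8.
#'
#' @param responses named list of 0/1 vectors: `encoding`, `decoding`,
#'   `isolation`, `blending`. Shorter vectors are allowed (unattempted
#'   trials score 0); longer ones are an error.
#' @return a one-row tibble of the four scores.
#' @export
score_knowledge <- function(responses) {
  maxima <- c(encoding = 24L, decoding = 24L, isolation = 10L, blending = 8L)
  terminated <- c("isolation", "blending")
  out <- list()
  for (task in names(maxima)) {
    r <- as.integer(responses[[task]] %||% integer(0))
    if (length(r) > maxima[[task]]) {
      stop_pf(task, " has ", length(r), " responses; maximum is ", maxima[[task]])
    }
    if (any(!r %in% c(0L, 1L))) stop_pf(task, " responses must be 0 or 1")
    if (task %in% terminated && length(r) >= 2L) {
      fails <- which(r[-1L] == 0L & r[-length(r)] == 0L)
      if (length(fails) && fails[1] + 2L <= length(r)) {
        r[(fails[1] + 2L):length(r)] <- 0L
      }
    }
    out[[task]] <- sum(r)
  }
  tibble::as_tibble(out)
}
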