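#' Construct a pen trace
#'
#' A `pen_trace` holds the timestamped samples of one production episode
#' recorded from a digitising tablet: time in milliseconds, pen-tip position
#' in millimetres, and whether the pen was touching the surface. The default
#' nominal sampling rate (133 Hz, i.e. samples roughly every 7.5 ms) and
#' spatial resolution (330 lines/cm) correspond to a Wacom Intuos class
#' tablet.
#'
#' @param samples data frame with columns `t_ms` (strictly increasing),
#'   `x`, `y` (millimetres; y increases upward) and `pen_down` (logical or
#'   0/1).
#' @param nominal_rate nominal sampling rate in Hz (> 0).
#' @param spatial_resolution tablet spatial resolution in lines/cm.
#' @param trace_id,child_id,item_id identifiers carried through the analysis.
#' @return An object of class `pen_trace`: the sample tibble plus recording
#'   metadata.
#' @examples
#' tr <- pen_trace(data.frame(t_ms = c(0, 7.5, 15), x = 0:2, y = 0,
#'                            pen_down = TRUE))
#' n_samples(tr)
#' @export
pen_trace <- function(samples, nominal_rate = 133, spatial_resolution = 330,
                      trace_id = NA_character_, child_id = NA_character_,
                      item_id = NA_character_) {
  need <- c("t_ms", "x", "y", "pen_down")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop_pf("pen trace samples missing column(s): ", paste(miss, collapse = ", "))
  }
  samples <- tibble::as_tibble(samples)[need]
  if (nrow(samples) < 1L) stop_pf("a pen trace needs at least one sample")
  bad <- first_nonmonotone(samples$t_ms)
  if (bad > 0L) stop_pf("non-monotone time at row ", bad)
  assert_scalar_num(nominal_rate, "nominal_rate", positive = TRUE)
  samples$pen_down <- as.logical(samples$pen_down)
  structure(
    list(samples = samples,
         nominal_rate = nominal_rate,
         spatial_resolution = spatial_resolution,
         trace_id = as.character(trace_id),
         child_id = as.character(child_id),
         item_id = as.character(item_id)),
    class = "pen_trace"
  )
}

#' @export
print.pen_trace <- function(x, ...) {
  dur <- diff(range(x$samples$t_ms))
  cat(sprintf("<pen_trace %s> %d samples, %.1f ms, nominal %g Hz\n",
              x$trace_id, nrow(x$samples), dur, x$nominal_rate))
  invisible(x)
}

#' Number of samples in a pen trace
#' @param trace a [pen_trace()].
#' @return integer count.
#' @export
n_samples <- function(trace) nrow(trace$samples)

#' Read a pen trace from a delimited text file
#'
#' The expected dialect is a UTF-8 CSV with header `t_ms,x,y,pen_down`
#' (time in milliseconds, coordinates in millimetres, pen state 0/1), one
#' file per production episode.
#'
#' @param path file to read.
#' @param dialect file dialect; only `"csv"` is implemented.
#' @param ... passed to [pen_trace()] (identifiers, nominal rate).
#' @return a [pen_trace()].
#' @export
read_trace <- function(path, dialect = "csv", ...) {
  if (!identical(dialect, "csv")) stop_pf("unknown trace dialect: ", dialect)
  if (!file.exists(path)) stop_pf("trace file not found: ", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop_pf("cannot parse ", path, ": ",
                                             conditionMessage(e)))
  if (nrow(df) == 0L) stop_pf("empty trace file: ", path)
  need <- c("t_ms", "x", "y", "pen_down")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_pf("trace file ", path, " missing column(s): ",
            paste(miss, collapse = ", "))
  }
  bad <- first_nonmonotone(df$t_ms)
  if (bad > 0L) stop_pf("non-monotone time in ", path, " at row ", bad)
  pen_trace(df, ...)
}

#' Write a pen trace to a delimited text file
#'
#' Inverse of [read_trace()]: the written file re-reads to a trace with
#' identical sample values.
#'
#' @param trace a [pen_trace()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (!inherits(trace, "pen_trace")) stop_pf("not a pen_trace")
  if (n_samples(trace) < 1L) stop_pf("refusing to write a trace with no samples")
  df <- trace$samples
  df$pen_down <- as.integer(df$pen_down)
  ok <- tryCatch({
    suppressWarnings(write.csv(df, path, row.names = FALSE, quote = FALSE))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_pf("cannot write trace to ", path)
  invisible(path)
}

#' Construct feature mark-up for one character production
#'
#' Feature marks delimit the sub-letter features of a character within a pen
#' trace. Indices are 1-based and inclusive at both ends (the file dialect
#' written by [write_markup()] is 0-based; conversion is handled on IO).
#' Marks of one character must not overlap.
#'
#' @param marks data frame with columns `feature_id`, `start_index`,
#'   `end_index` (1-based, inclusive) and `shape_kind`
#'   (`"straight"`/`"curved"`).
#' @param trace_id id of the trace the marks refer to.
#' @param character_id id of the character produced.
#' @param target_is_letter whether the target character is a letter (as
#'   opposed to a non-letter symbol).
#' @return a `feature_marks` tibble with mark-up metadata attributes.
#' @export
feature_marks <- function(marks, trace_id = NA_character_,
                          character_id = NA_character_,
                          target_is_letter = NA) {
  need <- c("feature_id", "start_index", "end_index", "shape_kind")
  miss <- setdiff(need, names(marks))
  if (length(miss)) {
    stop_pf("mark-up missing column(s): ", paste(miss, collapse = ", "))
  }
  marks <- tibble::as_tibble(marks)[need]
  if (any(marks$start_index < 1L)) stop_pf("mark start_index below 1")
  if (any(marks$end_index <= marks$start_index)) {
    stop_pf("mark end_index must be greater than start_index")
  }
  if (!all(marks$shape_kind %in% c("straight", "curved"))) {
    stop_pf("shape_kind must be 'straight' or 'curved'")
  }
  o <- order(marks$start_index)
  so <- marks$start_index[o]; eo <- marks$end_index[o]
  if (nrow(marks) > 1L && any(so[-1L] <= eo[-length(eo)])) {
    stop_pf("overlapping mark index ranges")
  }
  structure(marks,
            trace_id = as.character(trace_id),
            character_id = as.character(character_id),
            target_is_letter = target_is_letter,
            class = c("feature_marks", class(marks)))
}

#' Read feature mark-up from a JSON file
#'
#' The file schema is one JSON document per trace:
#' `{trace_id, character_id, target_is_letter, marks: [{feature_id,
#' start_index, end_index, shape_kind}]}` with 0-based inclusive indices.
#' Indices are converted to this package's 1-based convention.
#'
#' @param path JSON file.
#' @return a [feature_marks()] tibble.
#' @export
read_markup <- function(path) {
  if (!file.exists(path)) stop_pf("mark-up file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(doc$marks) || NROW(doc$marks) == 0L) {
    stop_pf("mark-up file ", path, " contains no marks")
  }
  m <- tibble::as_tibble(doc$marks)
  m$start_index <- as.integer(m$start_index) + 1L
  m$end_index <- as.integer(m$end_index) + 1L
  feature_marks(m,
                trace_id = doc$trace_id %||% NA_character_,
                character_id = doc$character_id %||% NA_character_,
                target_is_letter = doc$target_is_letter %||% NA)
}

#' Write feature mark-up to a JSON file
#'
#' @param marks a [feature_marks()] tibble.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_markup <- function(marks, path) {
  if (!inherits(marks, "feature_marks")) stop_pf("not a feature_marks object")
  out <- list(
    trace_id = attr(marks, "trace_id"),
    character_id = attr(marks, "character_id"),
    target_is_letter = attr(marks, "target_is_letter"),
    marks = data.frame(
      feature_id = marks$feature_id,
      start_index = marks$start_index - 1L,
      end_index = marks$end_index - 1L,
      shape_kind = marks$shape_kind
    )
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Extract the samples of one feature from a trace
#'
#' @param trace a [pen_trace()].
#' @param mark one mark: a single row of a [feature_marks()] tibble, or any
#'   list with `start_index`/`end_index` (1-based, inclusive).
#' @return a [pen_trace()] containing exactly the marked samples, inheriting
#'   the parent trace's metadata.
#' @export
slice_feature <- function(trace, mark) {
  if (!inherits(trace, "pen_trace")) stop_pf("not a pen_trace")
  s <- as.integer(mark$start_index[1]); e <- as.integer(mark$end_index[1])
  n <- n_samples(trace)
  if (is.na(s) || is.na(e) || s < 1L || e > n || s >= e) {
    stop_pf("mark indices [", s, ", ", e, "] out of range for trace of ",
            n, " samples")
  }
  pen_trace(trace$samples[s:e, ],
            nominal_rate = trace$nominal_rate,
            spatial_resolution = trace$spatial_resolution,
            trace_id = trace$trace_id,
            child_id = trace$child_id,
            item_id = trace$item_id)
}
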