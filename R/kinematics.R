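#' Resample a pen trace onto a uniform time grid
#'
#' Tablet timestamps arrive only approximately on the nominal grid (samples
#' at "around" 7.5 ms), so kinematic analysis starts by linear interpolation
#' of `x` and `y` onto an exactly uniform grid. The pen state is resampled
#' by nearest neighbour.
#'
#' @param trace a [pen_trace()] with strictly increasing time stamps.
#' @param fs target sampling rate in Hz (default: the trace's nominal rate).
#' @return a [pen_trace()] with `t_ms` spaced exactly `1000/fs` ms apart and
#'   the same duration (within one sample period).
#' @export
resample_uniform <- function(trace, fs = trace$nominal_rate) {
  if (!inherits(trace, "pen_trace")) stop_pf("not a pen_trace")
  assert_scalar_num(fs, "fs", positive = TRUE)
  s <- trace$samples
  if (nrow(s) < 2L) stop_pf("resampling needs at least 2 samples")
  dt <- 1000 / fs
  grid <- seq(s$t_ms[1], s$t_ms[nrow(s)], by = dt)
  x <- approx(s$t_ms, s$x, xout = grid, ties = "ordered")$y
  y <- approx(s$t_ms, s$y, xout = grid, ties = "ordered")$y
  # nearest-neighbour pen state
  idx <- findInterval(grid, s$t_ms, all.inside = TRUE)
  right <- idx + 1L
  use_right <- (s$t_ms[right] - grid) < (grid - s$t_ms[idx])
  pen <- s$pen_down[ifelse(use_right, right, idx)]
  pen_trace(tibble::tibble(t_ms = grid, x = x, y = y, pen_down = pen),
            nominal_rate = fs,
            spatial_resolution = trace$spatial_resolution,
            trace_id = trace$trace_id, child_id = trace$child_id,
            item_id = trace$item_id)
}

#' Construct a velocity profile
#'
#' Internal constructor; users normally obtain profiles from
#' [tangential_velocity()].
#'
#' @param t time in seconds, uniformly spaced.
#' @param v tangential speed in mm/s (non-negative).
#' @param fs sampling rate in Hz.
#' @param filter filter provenance: `"raw"` or a list
#'   `(kind, order, cutoff_hz)`.
#' @param pen_down logical mask, same length as `v`.
#' @return an object of class `velocity_profile`.
#' @export
velocity_profile <- function(t, v, fs, filter = "raw", pen_down = NULL) {
  if (length(t) != length(v)) stop_pf("t and v lengths differ")
  if (length(t) >= 2L && max(abs(diff(t) - 1 / fs)) > 1e-9) {
    stop_pf("velocity profile time grid is not uniform at fs")
  }
  if (is.null(pen_down)) pen_down <- rep(TRUE, length(v))
  structure(list(t = t, v = pmax(v, 0), fs = fs, filter = filter,
                 pen_down = pen_down),
            class = "velocity_profile")
}

#' @export
print.velocity_profile <- function(x, ...) {
  filt <- if (identical(x$filter, "raw")) "raw" else
    sprintf("%s order %d, %.3g Hz", x$filter$kind, x$filter$order,
            x$filter$cutoff_hz)
  cat(sprintf("<velocity_profile> %d samples @ %g Hz [%s]\n",
              length(x$v), x$fs, filt))
  invisible(x)
}

#' Tangential pen-tip velocity of a uniformly sampled trace
#'
#' Speed is computed by central differences of position (one-sided at the
#' ends). Samples where the pen is lifted are masked out of downstream peak
#' counting but remain on the time grid.
#'
#' @param trace a uniformly sampled [pen_trace()] (see [resample_uniform()]).
#' @return a [velocity_profile()] with `filter = "raw"`.
#' @export
tangential_velocity <- function(trace) {
  if (!inherits(trace, "pen_trace")) stop_pf("not a pen_trace")
  s <- trace$samples
  n <- nrow(s)
  if (n < 2L) stop_pf("velocity needs at least 2 samples")
  dts <- diff(s$t_ms)
  if (max(abs(dts - dts[1])) > 1e-6) {
    stop_pf("trace is not uniformly sampled; call resample_uniform() first")
  }
  dt <- dts[1] / 1000
  fs <- 1 / dt
  v <- numeric(n)
  if (n > 2L) {
    i <- 2:(n - 1L)
    v[i] <- sqrt((s$x[i + 1L] - s$x[i - 1L])^2 +
                 (s$y[i + 1L] - s$y[i - 1L])^2) / (2 * dt)
  }
  v[1] <- sqrt((s$x[2] - s$x[1])^2 + (s$y[2] - s$y[1])^2) / dt
  v[n] <- sqrt((s$x[n] - s$x[n - 1L])^2 + (s$y[n] - s$y[n - 1L])^2) / dt
  velocity_profile((s$t_ms - s$t_ms[1]) / 1000, v, fs,
                   filter = "raw", pen_down = s$pen_down)
}

# zero-phase Butterworth low-pass on a plain numeric vector.
# `order` is the effective (two-pass) order and must be even: a filter of
# half the order is designed and applied forward and backward, so peak
# locations are not lagged. The signal is extended by odd reflection at both
# ends before filtering to suppress edge transients.
butter_zerophase <- function(x, fs, cutoff, order = 4L) {
  if (order %% 2L != 0L) stop_pf("effective filter order must be even")
  if (cutoff >= fs / 2) {
    stop_pf("cutoff ", cutoff, " Hz is at or above the Nyquist frequency (",
            fs / 2, " Hz)")
  }
  n <- length(x)
  bf <- signal::butter(order / 2L, cutoff / (fs / 2), type = "low")
  pad <- min(n - 1L, max(12L, ceiling(3 * fs / cutoff)))
  if (pad > 0L) {
    head_ext <- 2 * x[1] - x[seq(pad + 1L, 2L)]
    tail_ext <- 2 * x[n] - x[seq(n - 1L, n - pad)]
    xe <- c(head_ext, x, tail_ext)
  } else xe <- x
  y <- signal::filter(bf, xe)
  y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
  if (pad > 0L) y <- y[(pad + 1L):(pad + n)]
  y
}

#' Low-pass filter a velocity profile
#'
#' Applies a zero-phase Butterworth low-pass of the stated effective order
#' (default 4, the handwriting-kinematics standard of a 10 Hz fourth-order
#' filter for removing measurement noise). Zero-phase filtering is obtained
#' by a forward and a backward pass of a half-order design, so the magnitude
#' response has the stated order and peaks are not shifted in time. Negative
#' post-filter speeds are clamped to zero.
#'
#' @param profile a [velocity_profile()].
#' @param cutoff cutoff frequency in Hz (must be below Nyquist).
#' @param order effective filter order (even; default 4).
#' @return a filtered [velocity_profile()] with updated filter provenance.
#' @export
lowpass <- function(profile, cutoff, order = 4L) {
  if (!inherits(profile, "velocity_profile")) stop_pf("not a velocity_profile")
  assert_scalar_num(cutoff, "cutoff", positive = TRUE)
  y <- butter_zerophase(profile$v, profile$fs, cutoff, order)
  velocity_profile(profile$t, pmax(y, 0), profile$fs,
                   filter = list(kind = "butterworth", order = as.integer(order),
                                 cutoff_hz = cutoff),
                   pen_down = profile$pen_down)
}

#' Analytic magnitude response of the zero-phase Butterworth low-pass
#'
#' The gain that [lowpass()] applies to a sinusoid of frequency `f`:
#' the squared magnitude of the digital (bilinear-transform) Butterworth
#' design of half the effective order, since the filter is applied forward
#' and backward. Useful as an independent oracle for filter-contract and
#' SNvpd tests.
#'
#' @param f frequency in Hz (vectorised).
#' @param fs sampling rate in Hz.
#' @param cutoff cutoff frequency in Hz.
#' @param order effective (two-pass) filter order.
#' @return amplitude gain in `[0, 1]`.
#' @export
butterworth_gain <- function(f, fs, cutoff, order = 4L) {
  # prewarped normalized frequency of the bilinear design
  w <- tan(pi * f / fs) / tan(pi * cutoff / fs)
  (1 / sqrt(1 + w^order))^2
}

# strict local maxima of a numeric vector, endpoints excluded; a plateau of
# equal values counts once (at its midpoint) when both neighbours are lower.
peak_indices <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  r <- rle(v)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mid <- (starts + ends) %/% 2L
  j <- 2:(k - 1L)
  is_peak <- r$values[j] > r$values[j - 1L] & r$values[j] > r$values[j + 1L]
  mid[j][is_peak]
}

#' Count velocity peaks in a span of a profile
#'
#' Counts strict local maxima of the speed signal in the open interior of
#' the requested span. Plateaus (runs of exactly equal values) count once,
#' at their midpoint; span endpoints are never peaks. Samples where the pen
#' is lifted split the span, and counts are summed over the resulting
#' pen-down sub-spans.
#'
#' @param profile a [velocity_profile()].
#' @param span integer vector `c(first, last)` of sample indices (1-based,
#'   inclusive); default the whole profile.
#' @return integer peak count.
#' @export
count_velocity_peaks <- function(profile, span = NULL) {
  if (!inherits(profile, "velocity_profile")) stop_pf("not a velocity_profile")
  n <- length(profile$v)
  if (is.null(span)) span <- c(1L, n)
  a <- as.integer(span[1]); b <- as.integer(span[2])
  if (is.na(a) || is.na(b) || a < 1L || b > n || a > b) {
    stop_pf("span [", a, ", ", b, "] out of range for profile of ", n,
            " samples")
  }
  idx <- a:b
  down <- profile$pen_down[idx]
  if (!any(down)) return(0L)
  runs <- rle(down)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  total <- 0L
  for (r in which(runs$values)) {
    seg <- profile$v[idx[starts[r]:ends[r]]]
    total <- total + length(peak_indices(seg))
  }
  total
}

#' Per-feature disfluency score
#'
#' The disfluency score of one sub-letter feature is the number of velocity
#' maxima during its production, after resampling to a uniform grid,
#' tangential-velocity computation, and 10 Hz fourth-order zero-phase
#' Butterworth low-pass filtering. A competent writer produces a feature as
#' a single ballistic stroke, giving a score of 1; each additional velocity
#' inversion adds one. The count is floored at 1 for any feature with
#' non-zero pen movement.
#'
#' @param trace a [pen_trace()] covering the whole character production.
#' @param mark one feature mark (row of a [feature_marks()] tibble).
#' @param fs resampling rate in Hz.
#' @param cutoff low-pass cutoff in Hz.
#' @param order effective filter order.
#' @return integer disfluency score (peak count).
#' @export
feature_disfluency <- function(trace, mark, fs = 133, cutoff = 10, order = 4L) {
  if (!inherits(trace, "pen_trace")) stop_pf("not a pen_trace")
  s <- as.integer(mark$start_index[1]); e <- as.integer(mark$end_index[1])
  n <- n_samples(trace)
  if (s < 1L || e > n || s >= e) stop_pf("invalid mark span [", s, ", ", e, "]")
  t0 <- trace$samples$t_ms[s]; t1 <- trace$samples$t_ms[e]
  seg <- trace$samples[s:e, ]
  moved <- polyline_arclength(cbind(seg$x, seg$y)) > 0
  u <- resample_uniform(trace, fs)
  prof <- lowpass(tangential_velocity(u), cutoff, order)
  gi <- which(u$samples$t_ms >= t0 - 1e-9 & u$samples$t_ms <= t1 + 1e-9)
  if (length(gi) < 2L) return(if (moved) 1L else 0L)
  k <- count_velocity_peaks(prof, span = c(gi[1], gi[length(gi)]))
  if (moved) max(k, 1L) else k
}

#' Signal-to-noise velocity peaks difference (SNvpd)
#'
#' SNvpd is the difference between the velocity-peak counts obtained after
#' 10 Hz and after 5 Hz low-pass filtering of the same resampled velocity
#' signal. Peaks surviving the 5 Hz filter are taken to reflect propulsive
#' ballistic movement; additional peaks appearing only at 10 Hz reflect
#' non-propulsive (noise) movement, so larger values indicate less fluent
#' pen control.
#'
#' @param trace a [pen_trace()].
#' @param span optional `c(first, last)` sample indices on the original
#'   trace delimiting the scored movement; default the whole trace.
#' @param fs resampling rate in Hz.
#' @param cutoffs the two cutoff frequencies, `c(noise, signal)` in Hz.
#' @param order effective filter order.
#' @return integer count difference `N10 - N5`.
#' @export
snvpd <- function(trace, span = NULL, fs = 133, cutoffs = c(10, 5),
                  order = 4L) {
  if (!inherits(trace, "pen_trace")) stop_pf("not a pen_trace")
  n <- n_samples(trace)
  if (is.null(span)) span <- c(1L, n)
  a <- as.integer(span[1]); b <- as.integer(span[2])
  if (a < 1L || b > n || a >= b) stop_pf("invalid span [", a, ", ", b, "]")
  t0 <- trace$samples$t_ms[a]; t1 <- trace$samples$t_ms[b]
  u <- resample_uniform(trace, fs)
  raw <- tangential_velocity(u)
  gi <- which(u$samples$t_ms >= t0 - 1e-9 & u$samples$t_ms <= t1 + 1e-9)
  if (length(gi) < 3L) return(0L)
  gspan <- c(gi[1], gi[length(gi)])
  n_hi <- count_velocity_peaks(lowpass(raw, cutoffs[1], order), gspan)
  n_lo <- count_velocity_peaks(lowpass(raw, cutoffs[2], order), gspan)
  n_hi - n_lo
}

#' Build the long-format fluency analysis table for one marked trace
#'
#' Runs [feature_disfluency()] for every mark and returns one row per
#' feature, the unit of analysis for the mixed-model sequences.
#'
#' @param trace a [pen_trace()].
#' @param marks a [feature_marks()] tibble for that trace.
#' @param malformed optional logical vector (one per mark) from the accuracy
#'   coder or ground truth.
#' @inheritParams feature_disfluency
#' @return a tibble with columns `child_id`, `item_id`, `feature_id`,
#'   `peak_count`, `malformed`, `shape_kind`, `target_is_letter`.
#' @export
trace_fluency_table <- function(trace, marks, malformed = NA, fs = 133,
                                cutoff = 10, order = 4L) {
  if (!inherits(marks, "feature_marks")) stop_pf("not a feature_marks object")
  counts <- vapply(seq_len(nrow(marks)), function(i) {
    as.integer(feature_disfluency(trace, marks[i, ], fs = fs, cutoff = cutoff,
                                  order = order))
  }, integer(1))
  tibble::tibble(
    child_id = trace$child_id,
    item_id = attr(marks, "character_id") %||% trace$item_id,
    feature_id = marks$feature_id,
    peak_count = counts,
    malformed = rep_len(malformed, nrow(marks)),
    shape_kind = marks$shape_kind,
    target_is_letter = rep_len(attr(marks, "target_is_letter"), nrow(marks))
  )
}
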