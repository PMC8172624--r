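#' Count local maxima of a densely sampled signal (oracle)
#'
#' A deliberately simple reference counter used to validate the kinematic
#' pipeline against generator ground truth: walks the signal once, counting
#' every point that is strictly higher than the nearest distinct values on
#' both sides (plateaus count once; endpoints never count). It shares no
#' code with [count_velocity_peaks()].
#'
#' @param v numeric signal, typically a dense noise-free speed profile from
#'   the generator's ground truth.
#' @param tol ignore fluctuations smaller than `tol` (default 0: strict).
#' @return integer count of interior local maxima.
#' @export
dense_peak_count <- function(v, tol = 0) {
  n <- length(v)
  if (n < 3L) return(0L)
  count <- 0L
  last_distinct <- v[1]
  rising <- FALSE
  for (i in 2:n) {
    if (v[i] > last_distinct + tol) {
      rising <- TRUE
      last_distinct <- v[i]
    } else if (v[i] < last_distinct - tol) {
      if (rising) count <- count + 1L
      rising <- FALSE
      last_distinct <- v[i]
    }
  }
  count
}
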