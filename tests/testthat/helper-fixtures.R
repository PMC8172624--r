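# shared fixtures and independent oracles for the test suite

# Independent local-maximum counter: plain index walk, shares no code with
# count_velocity_peaks() or dense_peak_count(). Plateaus count once;
# endpoints never count.
naive_peak_count <- function(v) {
  n <- length(v)
  count <- 0L
  i <- 2L
  while (i <= n - 1L) {
    j <- i
    while (j < n && v[j + 1L] == v[j]) j <- j + 1L
    if (j < n && v[i] > v[i - 1L] && v[j + 1L] < v[j]) count <- count + 1L
    i <- j + 1L
  }
  count
}

templates <- stroke_templates()

template_feature <- function(character_id, idx = 1L) {
  templates[[character_id]]$allographs[[1]]$features[[idx]]
}

all_template_features <- local({
  out <- list()
  for (ch in names(templates)) {
    for (f in templates[[ch]]$allographs[[1]]$features) {
      out[[f$feature_id]] <- f
    }
  }
  out
})

# run the full kinematic pipeline on a trace and count peaks
pipeline_peaks <- function(trace, cutoff = 10, fs = 133) {
  prof <- lowpass(tangential_velocity(resample_uniform(trace, fs)), cutoff)
  count_velocity_peaks(prof)
}

# dense analytic-gain oracle for SNvpd garland fixtures: applies the
# analytic Butterworth amplitude gain at the ripple frequency to the
# designed ripple, then enumerates maxima on the dense signal
oracle_snvpd_garland <- function(truth, fs = 133) {
  g10 <- butterworth_gain(truth$ripple_freq, fs, 10)
  g5 <- butterworth_gain(truth$ripple_freq, fs, 5)
  n10 <- dense_peak_count(truth$v_dense + truth$ripple_amp * g10 * truth$ripple_dense)
  n5 <- dense_peak_count(truth$v_dense + truth$ripple_amp * g5 * truth$ripple_dense)
  n10 - n5
}

uniform_trace <- function(x, y, fs = 133) {
  n <- length(x)
  pen_trace(tibble::tibble(t_ms = (seq_len(n) - 1) * 1000 / fs, x = x, y = y,
                           pen_down = TRUE), nominal_rate = fs)
}
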