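test_that("resampling produces an exactly uniform grid and preserves values", {
  # already-uniform trace: values unchanged at grid points (x linear in t,
  # so interpolation must reproduce it exactly)
  t_ms <- (0:133) * 1000 / 133
  tr <- uniform_trace(x = 0.01 * t_ms, y = rep(0, 134))
  u <- resample_uniform(tr, 133)
  expect_equal(u$samples$x, 0.01 * u$samples$t_ms, tolerance = 1e-12)

  # jittered timestamps: output spacing exactly 1/133 s
  set.seed(5)
  s <- tr$samples
  s$t_ms <- s$t_ms + c(0, runif(nrow(s) - 1L, -0.5, 0.5))
  tj <- pen_trace(s)
  uj <- resample_uniform(tj, 133)
  expect_lt(max(abs(diff(uj$samples$t_ms) - 1000 / 133)), 1e-9)

  expect_error(resample_uniform(pen_trace(s[1, ])), "at least 2")
})

test_that("tangential velocity matches analytic profiles", {
  fs <- 133
  t <- seq(0, 2, by = 1 / fs)
  # straight line at 10 mm/s
  tr <- uniform_trace(10 * t * cos(0.4), 10 * t * sin(0.4))
  v <- tangential_velocity(tr)$v
  expect_lt(max(abs(v - 10)), 1e-9)
  # stationary pen
  tr0 <- uniform_trace(rep(3, length(t)), rep(4, length(t)))
  expect_equal(max(tangential_velocity(tr0)$v), 0)
  # circle of radius r at angular rate w: speed r*w within O(1/fs^2)
  r <- 8; w <- 2 * pi * 1.2
  trc <- uniform_trace(r * cos(w * t), r * sin(w * t))
  vc <- tangential_velocity(trc)$v
  interior <- vc[3:(length(vc) - 2)]
  expect_lt(max(abs(interior - r * w)) / (r * w), (w / fs)^2)
  # non-uniform input refused
  s <- tr$samples; s$t_ms[5] <- s$t_ms[5] + 1
  expect_error(tangential_velocity(pen_trace(s)), "not uniformly sampled")
})

test_that("the low-pass filter matches its analytic Butterworth response", {
  fs <- 133
  t <- seq(0, 8, by = 1 / fs)
  for (f0 in c(2, 7, 20, 30)) {
    vp <- velocity_profile(t, 50 + 20 * sin(2 * pi * f0 * t), fs)
    out <- lowpass(vp, 10)$v
    mid <- out[round(length(out) * 0.25):round(length(out) * 0.75)]
    gain <- (max(mid) - min(mid)) / 2 / 20
    expect_equal(gain, butterworth_gain(f0, fs, 10), tolerance = 0.02)
  }
  vp <- velocity_profile(t, sin(t), fs)
  expect_error(lowpass(vp, 80), "Nyquist")
  expect_equal(lowpass(vp, 10)$filter$cutoff_hz, 10)
  expect_equal(lowpass(vp, 10)$filter$order, 4L)
})

test_that("peak counting agrees with the naive scan and handles plateaus", {
  fs <- 133
  # k well-separated minimum-jerk bells
  for (k in c(1, 3, 5)) {
    g <- gen_feature_trace(template_feature("T"), k, seed = 10 + k)
    prof <- lowpass(tangential_velocity(resample_uniform(g$trace, fs)), 10)
    expect_equal(count_velocity_peaks(prof), k)
    expect_equal(count_velocity_peaks(prof), naive_peak_count(prof$v))
  }
  # monotone signal has no peaks; endpoints are never peaks
  vp <- velocity_profile(seq(0, 1, by = 1 / fs),
                         seq(10, 50, length.out = 134), fs)
  expect_equal(count_velocity_peaks(vp), 0L)
  # plateau counts once
  v <- c(0, 1, 3, 3, 3, 1, 0, 2, 0)
  vpl <- velocity_profile((0:8) / fs, v, fs)
  expect_equal(count_velocity_peaks(vpl), 2L)
  expect_equal(count_velocity_peaks(vpl), naive_peak_count(v))
  # pen-up samples split the span
  vps <- velocity_profile((0:8) / fs, v, fs,
                          pen_down = c(rep(TRUE, 7), FALSE, TRUE))
  expect_equal(count_velocity_peaks(vps), 1L)
  expect_error(count_velocity_peaks(vpl, span = c(5, 20)), "out of range")
})

test_that("random peak profiles agree between implementation and naive scan", {
  set.seed(42)
  fs <- 133
  for (i in 1:25) {
    v <- pmax(0, cumsum(rnorm(60)))
    vp <- velocity_profile((seq_along(v) - 1) / fs, v, fs)
    expect_equal(count_velocity_peaks(vp), naive_peak_count(vp$v))
  }
})

test_that("feature disfluency recovers sub-movement counts and is invariant
           to similarity transforms", {
  g <- gen_character_trace("A", c(1, 4, 2), seed = 20)
  counts <- vapply(1:3, function(i) feature_disfluency(g$trace, g$marks[i, ]),
                   integer(1))
  expect_equal(counts, c(1L, 4L, 2L))

  # tremor above the cutoff does not change the score
  gt <- gen_character_trace("A", c(1, 4, 2), seed = 20,
                            tremor = list(amp = 6, freq = 20))
  countst <- vapply(1:3, function(i) feature_disfluency(gt$trace, gt$marks[i, ]),
                    integer(1))
  expect_equal(countst, c(1L, 4L, 2L))

  # uniform scaling and rigid rotation leave the score unchanged
  th <- 37 * pi / 180
  s <- g$trace$samples
  s2 <- s
  s2$x <- 2.5 * (cos(th) * s$x - sin(th) * s$y) + 40
  s2$y <- 2.5 * (sin(th) * s$x + cos(th) * s$y) - 11
  tr2 <- pen_trace(s2, nominal_rate = g$trace$nominal_rate)
  counts2 <- vapply(1:3, function(i) feature_disfluency(tr2, g$marks[i, ]),
                    integer(1))
  expect_equal(counts2, counts)
})

test_that("snvpd is zero for band-limited movement and positive with
           mid-band ripple", {
  tr <- gen_pencontrol_trace("garland_up", 8, seed = 30)
  expect_equal(snvpd(tr), 0L)
  trr <- gen_pencontrol_trace("garland_up", 8,
                              ripple = list(amp = 9, freq = 9.5), seed = 31)
  d <- snvpd(trr)
  expect_gt(d, 0)
  expect_equal(d, oracle_snvpd_garland(attr(trr, "truth")))
})

test_that("peak counts are ordered: 5 Hz <= 10 Hz <= dense oracle on raw", {
  set.seed(55)
  for (i in 1:12) {
    f <- all_template_features[[sample(names(all_template_features), 1)]]
    g <- gen_feature_trace(f, sample(1:5, 1),
                           tremor = list(amp = 5, freq = 18), seed = 500 + i)
    raw <- tangential_velocity(resample_uniform(g$trace, 133))
    n5 <- count_velocity_peaks(lowpass(raw, 5))
    n10 <- count_velocity_peaks(lowpass(raw, 10))
    expect_lte(n5, n10)
    expect_lte(n10, dense_peak_count(g$truth$v_dense_full))
  }
})

test_that("tremor well above the cutoff rarely changes the disfluency
           score", {
  # the 4th-order rolloff needs nearly an octave of margin: at 18-30 Hz the
  # residual after 10 Hz filtering is below ~8% of the tremor amplitude and
  # leaves counts unchanged; nearer the cutoff (12-16 Hz) leakage of 20-30%
  # can add maxima at near-zero-speed valleys between sub-movements
  set.seed(56)
  n_fix <- 100L
  changed <- 0L
  ids <- names(all_template_features)
  for (i in seq_len(n_fix)) {
    f <- all_template_features[[sample(ids, 1)]]
    k <- sample(1:4, 1)
    clean <- gen_feature_trace(f, k, seed = 600 + i)
    noisy <- gen_feature_trace(f, k, seed = 600 + i,
                               tremor = list(amp = 6,
                                             freq = runif(1, 18, 30)))
    changed <- changed +
      (pipeline_peaks(noisy$trace) != pipeline_peaks(clean$trace))
  }
  expect_lte(changed / n_fix, 0.01)
})

test_that("fluency tables carry identifiers and one row per feature", {
  g <- gen_character_trace("R", 2, seed = 33, child_id = "c9")
  tab <- trace_fluency_table(g$trace, g$marks, malformed = FALSE)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$child_id, rep("c9", 3))
  expect_equal(tab$item_id, rep("R", 3))
  expect_true(all(tab$peak_count == 2L))
  expect_true(all(tab$target_is_letter))
})
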