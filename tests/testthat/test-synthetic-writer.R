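test_that("minimum-jerk speed has the closed form, boundary zeros, and unit
           integral", {
  expect_equal(minimum_jerk_speed(1, 1, 0.5), 1.875)
  expect_equal(minimum_jerk_speed(2, 5, 0), 0)
  expect_equal(minimum_jerk_speed(2, 5, 2), 0)
  # quadrature oracle: the profile integrates to the amplitude
  for (TA in list(c(1, 1), c(0.35, 22), c(2, 7.5))) {
    q <- stats::integrate(function(t) minimum_jerk_speed(TA[1], TA[2], t),
                          0, TA[1], rel.tol = 1e-10)
    expect_equal(q$value, TA[2], tolerance = 1e-6)
  }
  # single interior maximum at T/2
  t <- seq(0, 0.4, by = 1e-3)
  v <- minimum_jerk_speed(0.4, 10, t)
  expect_equal(naive_peak_count(v), 1L)
  expect_equal(t[which.max(v)], 0.2)
  expect_error(minimum_jerk_speed(1, 1, 1.5), "outside")
  expect_error(minimum_jerk_speed(-1, 1, 0.5), "> 0")
})

test_that("generated features follow the template geometry and ground truth
           matches the dense oracle", {
  f <- template_feature("A")
  set.seed(7)
  for (k in 1:6) {
    g <- gen_feature_trace(f, k, seed = 100 + k)
    expect_equal(g$truth$n_submovements, k)
    expect_equal(dense_peak_count(g$truth$v_dense), k)
    expect_equal(naive_peak_count(g$truth$v_dense), k)
    # endpoints of the trace lie on the template's endpoints
    s <- g$trace$samples
    expect_lt(sqrt((s$x[1] - f$path[1, 1])^2 + (s$y[1] - f$path[1, 2])^2), 0.3)
    n <- nrow(s)
    expect_lt(sqrt((s$x[n] - f$path[2, 1])^2 + (s$y[n] - f$path[2, 2])^2), 0.3)
  }
  # tremor: dense full profile has extra maxima, 10 Hz filtering removes them
  gt <- gen_feature_trace(f, 1, tremor = list(amp = 8, freq = 20), seed = 9)
  expect_gt(dense_peak_count(gt$truth$v_dense_full), 1L)
  expect_equal(pipeline_peaks(gt$trace), 1L)
  expect_error(gen_feature_trace(f, 1, tremor = list(amp = 5, freq = 80)),
               "twice the tremor frequency")
  expect_error(gen_feature_trace(f, 0), ">= 1")
})

test_that("character generation emits consistent mark-up and known defects", {
  g <- gen_character_trace("A", 1, seed = 40)
  expect_equal(g$marks$feature_id,
               c("a_upright_l", "a_upright_r", "a_crossbar"))
  expect_true(all(g$marks$shape_kind == "straight"))
  expect_equal(attr(g$marks, "character_id"), "A")

  go <- gen_character_trace("O_slash", 1, seed = 41)
  expect_equal(nrow(go$marks), 2L)
  expect_setequal(go$marks$shape_kind, c("curved", "straight"))

  expect_error(gen_character_trace("Z", 1), "unknown character_id")
  expect_error(gen_character_trace("A", 1,
                                   defect_spec = list(zz = list(type = "angle",
                                                                value = 15))),
               "unknown feature")
})

test_that("pen-control generation respects task structure", {
  e <- gen_pencontrol_trace("eights", 7, seed = 50)
  expect_length(e, 7L)
  expect_s3_class(e[[1]], "pen_trace")

  tr <- gen_pencontrol_trace("h_lines", 10, seed = 51)
  u <- attr(tr, "units")
  expect_equal(nrow(u), 10L)
  expect_true(all(diff(u$start_index) > 0))

  expect_error(gen_pencontrol_trace("spirals", 10), "unsupported task")
  expect_error(gen_pencontrol_trace("cw_circles", 5), "at least 7")

  # determinism: same seed, identical trace
  a <- gen_pencontrol_trace("cw_circles", 8, seed = 52)
  b <- gen_pencontrol_trace("cw_circles", 8, seed = 52)
  expect_identical(a$samples, b$samples)

  # one extra sub-movement per circle doubles the per-unit peak count
  tr2 <- gen_pencontrol_trace("cw_circles", 8, submovements_per_unit = 2,
                              seed = 53)
  truth <- attr(tr2, "truth")
  expect_equal(dense_peak_count(truth$v_dense), 16L)
})

test_that("cohort generation is reproducible, honours degenerate configs, and
           matches target malformation rates", {
  # degenerate: no noise, no effects -> exactly 1 (straight) or
  # 1 + curve_offset (curved) peaks everywhere
  cfg0 <- cohort_config(n_children = 8, beta_pen_control = 0,
                        beta_letter_knowledge = 0, sigma_child = 0,
                        sigma_item = 0, sigma_resid = 0, seed = 60)
  b0 <- gen_cohort(cfg0)
  expect_true(all(b0$copy_table$peak_count[b0$copy_table$shape_kind ==
                                             "straight"] == 1L))
  expect_true(all(b0$copy_table$peak_count[b0$copy_table$shape_kind ==
                                             "curved"] == 2L))

  # bit-reproducible from the seed
  cfg <- cohort_config(n_children = 20, seed = 61)
  b1 <- gen_cohort(cfg)
  b2 <- gen_cohort(cfg)
  expect_identical(b1$copy_table, b2$copy_table)
  expect_identical(b1$covariates, b2$covariates)
  expect_identical(b1$dictation_table, b2$dictation_table)

  # malformation frequencies converge to malform_prob (binomial MC error)
  cfgm <- cohort_config(n_children = 60, seed = 62)
  bm <- gen_cohort(cfgm)
  tab <- dplyr::count(bm$copy_table,
                      key = paste0(ifelse(target_is_letter, "letter_",
                                          "symbol_"), shape_kind),
                      wt = malformed, name = "mal")
  ns <- dplyr::count(bm$copy_table,
                     key = paste0(ifelse(target_is_letter, "letter_",
                                         "symbol_"), shape_kind))
  for (k in tab$key) {
    p_hat <- tab$mal[tab$key == k] / ns$n[ns$key == k]
    p <- cfgm$malform_prob[[k]]
    se <- sqrt(p * (1 - p) / ns$n[ns$key == k])
    expect_lt(abs(p_hat - p), 4 * se + 1e-9)
  }

  # invalid configs are rejected
  expect_error(cohort_config(malform_prob = c(letter_straight = 1.2,
                                              letter_curved = 0.1,
                                              symbol_straight = 0.1,
                                              symbol_curved = 0.1)),
               "malform_prob")
  badR <- default_predictor_correlation()
  badR[1, 2] <- badR[2, 1] <- 2
  expect_error(cohort_config(predictor_correlation = badR),
               "positive semi-definite")
})

test_that("cohort trace generation reproduces the tabled peak counts", {
  cfg <- cohort_config(n_children = 2, seed = 63)
  b <- gen_cohort(cfg, generate_traces = TRUE, trace_children = 1L)
  expect_gt(length(b$traces), 0)
  g <- b$traces[[1]]
  tab <- trace_fluency_table(g$trace, g$marks)
  truth <- g$truth$n_submovements[tab$feature_id]
  expect_equal(tab$peak_count, unname(truth))
})
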