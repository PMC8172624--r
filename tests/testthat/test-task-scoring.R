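test_that("line/circle selection drops two valid units then takes five
           consecutive lift-free units", {
  tr <- gen_pencontrol_trace("h_lines", 10, seed = 80)
  u <- attr(tr, "units")
  sel <- select_scored_units(tr, "lines")
  expect_length(sel, 1L)
  expect_equal(sel[[1]]$span, c(u$start_index[3], u$end_index[7]))

  # a pen lift inside the first candidate run pushes selection later
  tr2 <- gen_pencontrol_trace("cw_circles", 12, pen_lift_units = 5, seed = 81)
  u2 <- attr(tr2, "units")
  sel2 <- select_scored_units(tr2, "circles")
  expect_equal(sel2[[1]]$span, c(u2$start_index[6], u2$end_index[10]))

  # invalid units do not count towards the drop
  tr3 <- gen_pencontrol_trace("cw_circles", 12, invalid_units = 1, seed = 82)
  u3 <- attr(tr3, "units")
  sel3 <- select_scored_units(tr3, "circles")
  expect_equal(sel3[[1]]$span, c(u3$start_index[4], u3$end_index[8]))

  # 6 units cannot satisfy 2 + 5
  tr4 <- gen_pencontrol_trace("cw_circles", 7, invalid_units = 7, seed = 83)
  expect_error(select_scored_units(tr4, "circles"),
               "insufficient repetitions")
  # lifts everywhere after the drop
  tr5 <- gen_pencontrol_trace("h_lines", 9, pen_lift_units = c(3:9),
                              seed = 84)
  expect_error(select_scored_units(tr5, "lines"),
               "insufficient repetitions")
})

test_that("task scores sum SNvpd over the scored spans", {
  # noise-free band-limited fixtures score 0 on every task
  expect_equal(score_task(gen_pencontrol_trace("h_lines", 10, seed = 85),
                          "lines", "c1")$snvpd, 0)
  expect_equal(score_task(gen_pencontrol_trace("ccw_circles", 10, seed = 86),
                          "circles", "c1")$snvpd, 0)
  expect_equal(score_task(gen_pencontrol_trace("garland_down", 9, seed = 87),
                          "garlands", "c1")$snvpd, 0)
  e <- gen_pencontrol_trace("eights", 7, seed = 88)
  s8 <- score_task(e, "eights", "c1")
  expect_equal(s8$snvpd, 0)
  expect_equal(s8$n_units_scored, 7L)

  # a garland with injected mid-band ripple scores the dense-oracle value
  trr <- gen_pencontrol_trace("garland_up", 10,
                              ripple = list(amp = 9, freq = 9.5), seed = 89)
  want <- oracle_snvpd_garland(attr(trr, "truth"))
  expect_gt(want, 0)
  expect_equal(score_task(trr, "garlands", "c1")$snvpd, want)

  # summation across repetitions: one noisy production among fluent ones
  mixed <- c(e[1:6], list(trr))
  expect_equal(score_task(mixed, "eights", "c1")$snvpd, want)
})

test_that("the dictation filter keeps researcher trials and drops the first
           computer trial", {
  sched <- canonical_dictation_schedule()
  out <- filter_dictation_trials(sched)
  expect_equal(nrow(out), 10L)
  expect_setequal(out$letter,
                  c("l", "f", "i", "b", "o", "p", "u", "s", "k", "v"))
  expect_false("a" %in% out$letter)

  res_only <- sched[sched$source == "researcher", ]
  expect_equal(filter_dictation_trials(res_only), res_only)

  bad <- sched; bad$source[3] <- "parent"
  expect_error(filter_dictation_trials(bad), "unknown trial source")

  # never more than 10 analysable trials from schedules of canonical size
  for (k in 3:9) {
    expect_lte(nrow(filter_dictation_trials(sched[1:k, ])), 10L)
  }
})

test_that("dictation responses are attempts iff all target features are
           present under some case variant", {
  mk <- function(shapes) {
    feature_marks(data.frame(
      feature_id = paste0("m", seq_along(shapes)),
      start_index = seq_along(shapes) * 10L,
      end_index = seq_along(shapes) * 10L + 5L,
      shape_kind = shapes))
  }
  # complete lower-case b (stem + bowl), however badly shaped, is an attempt
  expect_equal(validate_dictation_response(mk(c("straight", "curved")), "b"),
               "attempt")
  expect_equal(validate_dictation_response(mk("straight"), "b"),
               "non-attempt")
  # upper-case variant: a single curve is a complete U
  expect_equal(validate_dictation_response(mk("curved"), "u"), "attempt")
  expect_error(validate_dictation_response(mk("curved"), "e"),
               "not a dictation target")
})

test_that("knowledge scoring applies maxima and early termination", {
  all_right <- list(encoding = rep(1, 24), decoding = rep(1, 24),
                    isolation = rep(1, 10), blending = rep(1, 8))
  ks <- score_knowledge(all_right)
  expect_equal(unlist(ks), c(encoding = 24, decoding = 24, isolation = 10,
                             blending = 8))

  # failures at isolation trials 3 and 4 terminate the task: trials >= 5
  # score 0 even if recorded as correct
  iso <- c(1, 1, 0, 0, 1, 1, 1, 1, 1, 1)
  ks2 <- score_knowledge(list(isolation = iso))
  expect_equal(ks2$isolation, 2)
  # encoding has no termination rule
  ks3 <- score_knowledge(list(encoding = c(1, 0, 0, 1, 1)))
  expect_equal(ks3$encoding, 3)

  expect_equal(score_knowledge(list(blending = integer(0)))$blending, 0)
  expect_error(score_knowledge(list(isolation = rep(1, 11))), "maximum is 10")
  expect_error(score_knowledge(list(encoding = c(1, 2))), "0 or 1")
})
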