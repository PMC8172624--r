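make_gaussian_lmm_data <- function(n_child = 120, n_item = 24, n_rep = 3,
                                   sd_child = 1.5, sd_item = 1, sd_e = 2,
                                   mean0 = 10, seed = 1) {
  set.seed(seed)
  d <- expand.grid(child_id = sprintf("c%03d", 1:n_child),
                   item_id = sprintf("i%02d", 1:n_item),
                   rep = 1:n_rep, KEEP.OUT.ATTRS = FALSE)
  uc <- rnorm(n_child, 0, sd_child)
  ui <- rnorm(n_item, 0, sd_item)
  d$peak_count <- mean0 + uc[as.integer(factor(d$child_id))] +
    ui[as.integer(factor(d$item_id))] + rnorm(nrow(d), 0, sd_e)
  d
}

test_that("fit_lmm recovers variance structure and its report is internally
           consistent", {
  d <- make_gaussian_lmm_data()
  f <- fit_lmm(d, character(0))
  truth_icc_child <- 1.5^2 / (1.5^2 + 1^2 + 2^2)
  truth_icc_item <- 1^2 / (1.5^2 + 1^2 + 2^2)
  expect_lt(abs(f$icc_child - truth_icc_child), 0.08)
  expect_lt(abs(f$icc_item - truth_icc_item), 0.08)
  expect_lt(f$marginal_r2, 0.01)  # intercept only: no fixed-effect variance
  expect_equal(f$fixed_effects$estimate[1], 10, tolerance = 0.15)

  # ICC / marginal R2 equal their closed-form recomputation from the
  # reported components and the fitted fixed-effect predictions
  var_fixed <- var(as.numeric(stats::model.matrix(f$model) %*%
                                lme4::fixef(f$model)))
  denom <- var_fixed + f$var_child + f$var_item + f$var_resid
  expect_equal(f$icc_child, f$var_child / denom)
  expect_equal(f$icc_item, f$var_item / denom)
  expect_equal(f$marginal_r2, var_fixed / denom)

  # Satterthwaite inference populates df and the CI brackets the estimate
  fs <- fit_lmm(d, character(0), satterthwaite = TRUE)
  expect_true(all(is.finite(fs$fixed_effects$df)))
  expect_true(all(fs$fixed_effects$ci_lo < fs$fixed_effects$estimate &
                    fs$fixed_effects$estimate < fs$fixed_effects$ci_hi))
})

test_that("likelihood-ratio tests are arithmetic on the two log-likelihoods", {
  d <- make_gaussian_lmm_data(n_child = 60, seed = 2)
  set.seed(3)
  d$x1 <- rnorm(nrow(d)); d$x2 <- rnorm(nrow(d))
  d$x3 <- rnorm(nrow(d)); d$x4 <- rnorm(nrow(d))
  f0 <- fit_lmm(d, character(0))
  f4 <- fit_lmm(d, c("x1", "x2", "x3", "x4"))
  lt <- lr_test(f0, f4)
  expect_equal(lt$df, 4L)
  expect_equal(lt$chisq, max(0, 2 * (f4$loglik - f0$loglik)))
  expect_equal(lt$p, pchisq(lt$chisq, 4, lower.tail = FALSE))

  same <- lr_test(f0, f0)
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)

  f1 <- fit_lmm(d, "x1")
  f2 <- fit_lmm(d, "x2")
  expect_error(lr_test(f1, f2), "not nested")
})

test_that("the copy sequence lists the steps in order and applies the
           retention policy", {
  b <- gen_cohort(cohort_config(n_children = 60, seed = 90))
  rep <- run_copy_sequence(b$copy_table, b$covariates, inference = TRUE)
  expect_equal(rep$comparison$model, paste("Model", c(1:3, 4:8)))
  expect_equal(nrow(rep$comparison), 8L)
  # the letter dummy is retained by policy even when non-significant
  m3 <- rep$comparison[rep$comparison$model == "Model 3", ]
  expect_true(m3$retained)
  # with age present, the sequence has 9 candidate steps
  rep9 <- run_copy_sequence(b$copy_table, b$covariates, include_age = TRUE)
  expect_equal(nrow(rep9$comparison), 9L)
  expect_true("Model 3a" %in% rep9$comparison$model)
  # dropped steps do not appear among the best model's terms
  dropped <- rep$comparison[!rep$comparison$retained, ]
  for (tm in unlist(strsplit(dropped$terms_added, " \\+ "))) {
    expect_false(tm %in% rep$best_terms)
  }
  expect_s3_class(rep$best_fit, "model_fit")
  expect_error(run_copy_sequence(b$copy_table[, 1:3], b$covariates),
               "missing column")
})

test_that("injected pen-control and knowledge effects give the sequence power
           at steps 4 and 7", {
  hits4 <- 0L; hits7 <- 0L
  n_rep <- 20L
  for (i in seq_len(n_rep)) {
    b <- gen_cohort(cohort_config(n_children = 80, seed = 700 + i))
    rep <- run_copy_sequence(b$copy_table, b$covariates)
    p4 <- rep$comparison$p[rep$comparison$model == "Model 4"]
    p7 <- rep$comparison$p[rep$comparison$model == "Model 7"]
    hits4 <- hits4 + (p4 < 0.05)
    hits7 <- hits7 + (p7 < 0.05)
  }
  expect_gte(hits4 / n_rep, 0.8)
  expect_gte(hits7 / n_rep, 0.8)
})

test_that("dictation sequences split by shape and mirror the generator's
           straight-only knowledge effect", {
  b <- gen_cohort(cohort_config(n_children = 176, seed = 91))
  # a child whose every trial failed is excluded, with a message
  forced <- b$dictation_table
  forced$attempted[forced$child_id == "c001"] <- FALSE
  expect_message(run_dictation_models(forced, b$covariates),
                 "no retrieved letters")
  reps <- suppressMessages(run_dictation_models(b$dictation_table,
                                                b$covariates))
  expect_named(reps, c("straight", "curved"))
  expect_equal(reps$straight$comparison$model, paste("Model", 1:3))
  # copy-fluency aggregates carry real signal for both shapes
  expect_lt(reps$straight$comparison$p[2], 0.05)
  expect_lt(reps$curved$comparison$p[2], 0.05)
  # knowledge was injected for straight features only
  expect_lt(reps$straight$comparison$p[3], 0.05)
  expect_gt(reps$curved$comparison$p[3], 0.05)

  # an empty curved subset is flagged, not fatal
  straight_only <- b$dictation_table[b$dictation_table$shape_kind ==
                                       "straight", ]
  reps2 <- suppressMessages(run_dictation_models(straight_only,
                                                 b$covariates))
  expect_true(isTRUE(reps2$curved$insufficient_data))
})

test_that("the malformation GLMM sequence detects the curve and letter
           effects in the generator", {
  b <- gen_cohort(cohort_config(n_children = 150, seed = 92))
  rep <- run_accuracy_glmm(b$copy_table)
  expect_lt(rep$comparison$p[1], 0.05)  # curves malformed more often
  expect_lt(rep$comparison$p[2], 0.05)  # symbols malformed more often
  expect_gt(rep$comparison$p[3], 0.05)  # no interaction injected
})

test_that("parameter recovery reports are reproducible and structured", {
  cfg <- cohort_config(n_children = 60, seed = 1)
  r1 <- recover_parameters(cfg, n_replicates = 3, seed = 5)
  r2 <- recover_parameters(cfg, n_replicates = 3, seed = 5)
  expect_identical(r1, r2)
  expect_setequal(r1$parameter, c("beta_pen_control",
                                  "beta_letter_knowledge"))
  expect_true(all(is.finite(r1$bias)))
  expect_error(recover_parameters(cfg, n_replicates = 1), ">= 2")
})
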