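#' Prepare the copy-task analysis table for modelling
#'
#' Joins the per-feature fluency table to the child covariates and derives
#' the model variables: `curved` and `is_letter` dummies, `malformed` as
#' 0/1, a child-level z-scored age, and the (already z-scored) pen-control
#' and letter-knowledge predictors.
#'
#' @param analysis_table per-feature table (`child_id`, `item_id`,
#'   `peak_count`, `malformed`, `shape_kind`, `target_is_letter`).
#' @param covariates child-level table with the predictor columns.
#' @return a tibble ready for [run_copy_sequence()].
#' @export
prepare_copy_data <- function(analysis_table, covariates) {
  d <- dplyr::left_join(analysis_table, covariates, by = "child_id")
  d$curved <- as.integer(d$shape_kind == "curved")
  d$is_letter <- as.integer(d$target_is_letter)
  d$malformed <- as.integer(d$malformed)
  if ("age_months" %in% names(d)) d$age_z <- as.numeric(scale(d$age_months))
  d$child_id <- factor(d$child_id)
  d$item_id <- factor(d$item_id)
  d
}

quiet_fit <- function(expr) {
  withCallingHandlers(
    suppressMessages(expr),
    warning = function(w) {
      if (grepl("singular|converge|deprecated", conditionMessage(w),
                ignore.case = TRUE)) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

#' Fit one linear mixed model of the sequence
#'
#' Fits `outcome ~ fixed terms + (1 | child_id) + (1 | item_id)` by maximum
#' likelihood (so that likelihood-ratio tests between fixed-effect
#' structures are valid) and extracts the reporting quantities: fixed
#' effects with 95% CIs and (optionally) Satterthwaite degrees of freedom
#' and t-based p-values, variance components, intra-class correlations, and
#' the marginal R-squared (variance of the fixed-effect predictions over
#' total modelled variance).
#'
#' @param data a table from [prepare_copy_data()] (or any table with
#'   `child_id`/`item_id` and the referenced columns).
#' @param fixed character vector of fixed-effect terms (may include `:`
#'   interactions); empty for the intercept-only model.
#' @param outcome outcome column name.
#' @param satterthwaite compute Satterthwaite df/p (slower); otherwise
#'   Wald z inference is reported.
#' @return an object of class `model_fit`.
#' @export
fit_lmm <- function(data, fixed = character(0), outcome = "peak_count",
                    satterthwaite = FALSE) {
  rhs <- paste(c("1", fixed), collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs,
                                 "+ (1 | child_id) + (1 | item_id)"))
  fit <- if (satterthwaite) {
    quiet_fit(lmerTest::lmer(fml, data = data, REML = FALSE))
  } else {
    quiet_fit(lme4::lmer(fml, data = data, REML = FALSE,
                         control = lme4::lmerControl(calc.derivs = FALSE)))
  }
  sm <- summary(fit)
  ct <- as.data.frame(sm$coefficients)
  if (satterthwaite) {
    fe <- tibble::tibble(
      term = rownames(ct), estimate = ct[, "Estimate"],
      se = ct[, "Std. Error"], df = ct[, "df"], statistic = ct[, "t value"],
      p = ct[, "Pr(>|t|)"]
    )
    crit <- qt(0.975, fe$df)
  } else {
    fe <- tibble::tibble(
      term = rownames(ct), estimate = ct[, "Estimate"],
      se = ct[, "Std. Error"], df = NA_real_, statistic = ct[, "t value"],
      p = 2 * pnorm(-abs(ct[, "t value"]))
    )
    crit <- qnorm(0.975)
  }
  fe$ci_lo <- fe$estimate - crit * fe$se
  fe$ci_hi <- fe$estimate + crit * fe$se
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_child <- vc$vcov[vc$grp == "child_id"]
  var_item <- vc$vcov[vc$grp == "item_id"]
  var_resid <- vc$vcov[vc$grp == "Residual"]
  var_fixed <- var(as.numeric(stats::model.matrix(fit) %*% lme4::fixef(fit)))
  denom <- var_fixed + var_child + var_item + var_resid
  structure(list(
    formula = deparse(fml), terms = fixed, outcome = outcome,
    loglik = as.numeric(logLik(fit)), n_par = length(lme4::fixef(fit)),
    n_obs = stats::nobs(fit),
    fixed_effects = fe,
    var_child = var_child, var_item = var_item, var_resid = var_resid,
    marginal_r2 = var_fixed / denom,
    icc_child = var_child / denom, icc_item = var_item / denom,
    singular = lme4::isSingular(fit),
    model = fit
  ), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s\n  logLik %.1f | marginal R2 %.3f | ICC child %.2f, item %.2f%s\n",
              x$formula, x$loglik, x$marginal_r2, x$icc_child, x$icc_item,
              if (x$singular) " | singular" else ""))
  print(x$fixed_effects, n = Inf)
  invisible(x)
}

#' Likelihood-ratio test between two nested model fits
#'
#' @param smaller,larger [fit_lmm()] (or [fit_glmm()]) results on the same
#'   data; `smaller`'s fixed terms must be a subset of `larger`'s.
#' @return tibble with `chisq`, `df`, `p`.
#' @export
lr_test <- function(smaller, larger) {
  if (!all(smaller$terms %in% larger$terms)) {
    stop_pf("models are not nested (fixed terms of the smaller model are ",
            "not a subset of the larger model's)")
  }
  if (smaller$n_obs != larger$n_obs) {
    stop_pf("models were fitted to different numbers of observations")
  }
  chisq <- max(0, 2 * (larger$loglik - smaller$loglik))
  df <- larger$n_par - smaller$n_par
  p <- if (df > 0) pchisq(chisq, df, lower.tail = FALSE) else 1
  tibble::tibble(chisq = chisq, df = df, p = p)
}

copy_sequence_steps <- function(include_age = FALSE) {
  pc <- c("lines", "circles", "garlands", "eights")
  lk <- c("encoding", "isolation", "blending")
  steps <- list(
    list(label = "Model 1", desc = "feature malformed", terms = "malformed"),
    list(label = "Model 2", desc = "feature is a curve", terms = "curved"),
    list(label = "Model 3", desc = "character is a letter",
         terms = "is_letter", retain_always = TRUE),
    if (include_age) list(label = "Model 3a", desc = "child age",
                          terms = "age_z"),
    list(label = "Model 4", desc = "pen-control measures", terms = pc),
    list(label = "Model 5", desc = "pen-control x curve",
         terms = paste0(pc, ":curved")),
    list(label = "Model 6", desc = "pen-control x letter",
         terms = paste0(pc, ":is_letter")),
    list(label = "Model 7", desc = "letter-knowledge measures", terms = lk),
    list(label = "Model 8", desc = "letter-knowledge x letter",
         terms = paste0(lk, ":is_letter"))
  )
  steps[!vapply(steps, is.null, TRUE)]
}

run_sequence <- function(data, steps, fitter, alpha = 0.05) {
  current <- fitter(data, character(0))
  fits <- list("Model 0" = current)
  rows <- list()
  current_terms <- character(0)
  for (st in steps) {
    cand_terms <- c(current_terms, st$terms)
    cand <- fitter(data, cand_terms)
    lt <- lr_test(current, cand)
    retained <- lt$p < alpha || isTRUE(st$retain_always)
    rows[[st$label]] <- tibble::tibble(
      model = st$label, terms_added = paste(st$terms, collapse = " + "),
      description = st$desc, chisq = lt$chisq, df = lt$df, p = lt$p,
      retained = retained
    )
    fits[[st$label]] <- cand
    if (retained) {
      current <- cand
      current_terms <- cand_terms
    }
  }
  best_label <- if (length(rows)) {
    retained_labels <- names(rows)[vapply(rows, function(r) r$retained, TRUE)]
    if (length(retained_labels)) tail(retained_labels, 1) else "Model 0"
  } else "Model 0"
  structure(list(
    comparison = dplyr::bind_rows(rows),
    best_label = best_label,
    best_terms = current_terms,
    best_fit = NULL,
    fits = fits
  ), class = "model_sequence_report")
}

#' @export
print.model_sequence_report <- function(x, ...) {
  cat("<model_sequence_report> best:", x$best_label, "\n")
  print(x$comparison, n = Inf)
  invisible(x)
}

#' Run the nested model sequence for character-copying fluency
#'
#' Starting from an intercept-only model with by-child and by-item random
#' intercepts, adds fixed effects incrementally — malformed, curve, letter
#' status, optionally age, the four pen-control scores, their interactions
#' with curve and letter status, the three letter-knowledge scores, and
#' their interaction with letter status — testing each step with a
#' likelihood-ratio chi-squared test. The letter-status dummy is retained
#' regardless of significance (so later interactions are interpretable);
#' other non-significant steps are omitted from subsequent models and from
#' the final model.
#'
#' @param analysis_table per-feature copy table (see [prepare_copy_data()]).
#' @param covariates child covariate table.
#' @param alpha retention threshold for a step.
#' @param include_age include the age step (needs `age_months`).
#' @param inference also refit the best model with Satterthwaite inference
#'   (populates `best_fit`).
#' @return a `model_sequence_report`: the comparison table (label, added
#'   terms, chi-squared, df, p, retained), the best model label/terms, all
#'   fits, and optionally the best fit with full inference.
#' @export
run_copy_sequence <- function(analysis_table, covariates, alpha = 0.05,
                              include_age = FALSE, inference = FALSE) {
  need <- c("malformed", "shape_kind", "target_is_letter")
  miss <- setdiff(need, names(analysis_table))
  if (length(miss)) stop_pf("analysis table missing column(s): ",
                            paste(miss, collapse = ", "))
  d <- prepare_copy_data(analysis_table, covariates)
  rep <- run_sequence(d, copy_sequence_steps(include_age),
                      fitter = function(data, terms) fit_lmm(data, terms),
                      alpha = alpha)
  if (inference) {
    rep$best_fit <- fit_lmm(d, rep$best_terms, satterthwaite = TRUE)
  }
  rep
}

#' Run the dictation model sequences (straight and curved features)
#'
#' For each shape kind, fits the nested sequence: intercept-only, plus the
#' malformed dummy (Model 1), plus the child-aggregated letter-copy and
#' symbol-copy fluency (Model 2), plus the three letter-knowledge measures
#' (Model 3). Only features from trials coded as attempts enter the
#' analysis; children with no attempts at all are excluded (with a
#' message).
#'
#' @param dictation_table per-feature dictation table with an `attempted`
#'   column.
#' @param covariates child covariates including `letter_copy_z`,
#'   `symbol_copy_z` and the knowledge scores.
#' @param alpha retention threshold.
#' @param inference compute Satterthwaite inference on each best model.
#' @return named list of `model_sequence_report`s (`straight`, `curved`);
#'   a shape with no analysable data yields an `insufficient_data` flag.
#' @export
run_dictation_models <- function(dictation_table, covariates, alpha = 0.05,
                                 inference = FALSE) {
  att <- dictation_table[dictation_table$attempted, ]
  all_children <- unique(dictation_table$child_id)
  kept_children <- unique(att$child_id)
  dropped <- setdiff(all_children, kept_children)
  if (length(dropped)) {
    message(length(dropped),
            " child(ren) with no retrieved letters excluded from the ",
            "dictation analysis")
  }
  steps <- list(
    list(label = "Model 1", desc = "feature malformed", terms = "malformed"),
    list(label = "Model 2", desc = "copy-fluency aggregates",
         terms = c("symbol_copy_z", "letter_copy_z")),
    list(label = "Model 3", desc = "letter-knowledge measures",
         terms = c("encoding", "isolation", "blending"))
  )
  out <- list()
  for (shape in c("straight", "curved")) {
    sub <- att[att$shape_kind == shape, ]
    if (nrow(sub) < 20L || length(unique(sub$child_id)) < 5L) {
      out[[shape]] <- structure(
        list(insufficient_data = TRUE, n_rows = nrow(sub)),
        class = "model_sequence_report")
      next
    }
    d <- prepare_copy_data(sub, covariates)
    rep <- run_sequence(d, steps,
                        fitter = function(data, terms) fit_lmm(data, terms),
                        alpha = alpha)
    if (inference) rep$best_fit <- fit_lmm(d, rep$best_terms,
                                           satterthwaite = TRUE)
    out[[shape]] <- rep
  }
  out
}

#' Fit one logistic generalised linear mixed model
#'
#' @inheritParams fit_lmm
#' @return a `model_fit` (z-based inference).
#' @export
fit_glmm <- function(data, fixed = character(0), outcome = "malformed") {
  rhs <- paste(c("1", fixed), collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs,
                                 "+ (1 | child_id) + (1 | item_id)"))
  flagged <- FALSE
  fit <- withCallingHandlers(
    suppressMessages(lme4::glmer(fml, data = data, family = stats::binomial())),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  ct <- as.data.frame(summary(fit)$coefficients)
  fe <- tibble::tibble(
    term = rownames(ct), estimate = ct[, "Estimate"],
    se = ct[, "Std. Error"], df = NA_real_, statistic = ct[, "z value"],
    p = ct[, "Pr(>|z|)"]
  )
  fe$ci_lo <- fe$estimate - qnorm(0.975) * fe$se
  fe$ci_hi <- fe$estimate + qnorm(0.975) * fe$se
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_child <- vc$vcov[vc$grp == "child_id"]
  var_item <- vc$vcov[vc$grp == "item_id"]
  var_resid <- pi^2 / 3  # latent-scale residual of the logit link
  var_fixed <- var(as.numeric(stats::model.matrix(fit) %*% lme4::fixef(fit)))
  denom <- var_fixed + var_child + var_item + var_resid
  structure(list(
    formula = deparse(fml), terms = fixed, outcome = outcome,
    loglik = as.numeric(logLik(fit)), n_par = length(lme4::fixef(fit)),
    n_obs = stats::nobs(fit),
    fixed_effects = fe,
    var_child = var_child, var_item = var_item, var_resid = var_resid,
    marginal_r2 = var_fixed / denom,
    icc_child = var_child / denom, icc_item = var_item / denom,
    singular = lme4::isSingular(fit), convergence_flagged = flagged,
    model = fit
  ), class = "model_fit")
}

#' Run the accuracy (malformation) GLMM sequence
#'
#' Logistic mixed models predicting whether a feature was malformed:
#' intercept-only, plus the curve dummy (Model 1), plus the letter dummy
#' (Model 2), plus their interaction (Model 3), compared by likelihood
#' ratio. Inference on coefficients is z-based. Convergence or separation
#' problems are flagged on the fit, not fatal.
#'
#' @param analysis_table per-feature table with `malformed`.
#' @param alpha retention threshold.
#' @return a `model_sequence_report`.
#' @export
run_accuracy_glmm <- function(analysis_table, alpha = 0.05) {
  d <- analysis_table
  d$curved <- as.integer(d$shape_kind == "curved")
  d$is_letter <- as.integer(d$target_is_letter)
  d$malformed <- as.integer(d$malformed)
  d$child_id <- factor(d$child_id)
  d$item_id <- factor(d$item_id)
  steps <- list(
    list(label = "Model 1", desc = "feature is a curve", terms = "curved"),
    list(label = "Model 2", desc = "character is a letter",
         terms = "is_letter"),
    list(label = "Model 3", desc = "curve x letter",
         terms = "curved:is_letter")
  )
  run_sequence(d, steps, fitter = function(data, terms) fit_glmm(data, terms),
               alpha = alpha)
}

#' Parameter recovery study for the cohort generator + LMM pipeline
#'
#' Repeatedly generates cohorts from `config` (with replicate-specific
#' seeds derived from `seed`), fits the correctly specified fluency model
#' (`peak_count ~ curved + pen-control composite + encoding + random
#' intercepts`), and summarises bias, RMSE, and 95% CI coverage of the two
#' injected child-level effects.
#'
#' @param config a [cohort_config()].
#' @param n_replicates number of simulated cohorts (>= 2).
#' @param seed master seed; replicate seeds are derived deterministically.
#' @return tibble with one row per recovered parameter: `truth`,
#'   `mean_estimate`, `bias`, `rmse`, `coverage`.
#' @export
recover_parameters <- function(config, n_replicates = 50, seed = 1L) {
  if (n_replicates < 2) stop_pf("n_replicates must be >= 2")
  res <- purrr::map_dfr(seq_len(n_replicates), function(i) {
    cfg <- config
    cfg$seed <- as.integer(derive_seed(seed, i))
    b <- gen_cohort(cfg)
    d <- b$copy_table
    d$curved <- as.integer(d$shape_kind == "curved")
    d$pc <- b$truth$pc_composite[match(d$child_id,
                                       b$covariates$child_id)]
    d$enc <- b$truth$encoding_z[match(d$child_id, b$covariates$child_id)]
    d$child_id <- factor(d$child_id); d$item_id <- factor(d$item_id)
    f <- fit_lmm(d, c("curved", "pc", "enc"))
    fe <- f$fixed_effects
    tibble::tibble(
      replicate = i,
      parameter = c("beta_pen_control", "beta_letter_knowledge"),
      truth = c(config$beta_pen_control, config$beta_letter_knowledge),
      estimate = fe$estimate[match(c("pc", "enc"), fe$term)],
      ci_lo = fe$ci_lo[match(c("pc", "enc"), fe$term)],
      ci_hi = fe$ci_hi[match(c("pc", "enc"), fe$term)]
    )
  })
  res |>
    dplyr::group_by(.data$parameter, .data$truth) |>
    dplyr::summarise(
      mean_estimate = mean(.data$estimate),
      bias = mean(.data$estimate - .data$truth),
      rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
      coverage = mean(.data$ci_lo <= .data$truth & .data$truth <= .data$ci_hi),
      .groups = "drop"
    )
}

#' Empirical type-I error of the copy model sequence
#'
#' Simulates cohorts from a null configuration (no fixed effects: both
#' betas and the curve offset zero) and records, for each step of the copy
#' sequence, how often its likelihood-ratio test rejects at `alpha`.
#'
#' @param config a null [cohort_config()].
#' @param n_replicates number of simulated cohorts.
#' @param alpha nominal level.
#' @param seed master seed.
#' @return tibble with `model`, `rejection_rate`, `n_replicates`.
#' @export
type1_error_study <- function(config, n_replicates = 500, alpha = 0.05,
                              seed = 1L) {
  ps <- purrr::map_dfr(seq_len(n_replicates), function(i) {
    cfg <- config
    cfg$seed <- as.integer(derive_seed(seed, i))
    b <- gen_cohort(cfg)
    rep <- run_copy_sequence(b$copy_table, b$covariates, alpha = alpha)
    dplyr::mutate(rep$comparison[c("model", "p")], replicate = i)
  })
  ps |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(rejection_rate = mean(.data$p < alpha),
                     n_replicates = dplyr::n(), .groups = "drop")
}
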