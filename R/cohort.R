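#' Default correlation matrix of the child-level predictors
#'
#' Correlation structure among the seven child-level measures (phoneme
#' isolation, phoneme blending, phoneme-to-grapheme encoding, and the four
#' pen-control SNvpd scores), patterned on the bivariate correlations
#' observed in first-grade cohorts: letter-knowledge measures correlate
#' strongly with each other, pen-control measures moderately with each
#' other, and the two families only weakly.
#'
#' @return a 7 x 7 correlation matrix with dimnames
#'   `isolation, blending, encoding, lines, circles, garlands, eights`.
#' @export
default_predictor_correlation <- function() {
  nm <- c("isolation", "blending", "encoding", "lines", "circles",
          "garlands", "eights")
  R <- diag(7)
  dimnames(R) <- list(nm, nm)
  set_r <- function(a, b, r) {
    R[a, b] <<- r; R[b, a] <<- r
  }
  set_r("isolation", "blending", 0.56)
  set_r("isolation", "encoding", 0.59)
  set_r("blending", "encoding", 0.51)
  set_r("isolation", "lines", -0.07); set_r("isolation", "circles", -0.11)
  set_r("isolation", "garlands", 0.09); set_r("isolation", "eights", 0.00)
  set_r("blending", "lines", -0.08); set_r("blending", "circles", -0.26)
  set_r("blending", "garlands", 0.02); set_r("blending", "eights", 0.00)
  set_r("encoding", "lines", 0.01); set_r("encoding", "circles", -0.11)
  set_r("encoding", "garlands", 0.04); set_r("encoding", "eights", -0.12)
  set_r("lines", "circles", 0.40); set_r("lines", "garlands", 0.18)
  set_r("lines", "eights", 0.04)
  set_r("circles", "garlands", 0.24); set_r("circles", "eights", 0.04)
  set_r("garlands", "eights", 0.30)
  R
}

#' Configuration of the synthetic cohort generator
#'
#' Defines the generative structure mirrored on the study design: children
#' with correlated letter-knowledge and pen-control scores, producing every
#' non-practice inventory character feature by feature, with expected peak
#' count
#' `1 + curve_offset * is_curve + beta_pen_control * pc + beta_letter_knowledge * enc + u_child + u_item`
#' where `pc` is the child's standardised mean of the four pen-control
#' scores and `enc` the standardised encoding score. Realised counts are
#' `max(1, round(mu + resid))`. Malformation is drawn independently per
#' feature with probabilities by (letter status, shape), defaulting to the
#' rates observed in beginning writers (letters 4%/13%, symbols 9%/32% for
#' straight/curved).
#'
#' The variance defaults (`sigma_resid = 1`, `sigma_child = 0.61`,
#' `sigma_item = 0.49` peaks) reproduce intra-class correlations of about
#' 0.23 (child) and 0.15 (item), the structure reported for first-grade
#' copying data.
#'
#' @param n_children cohort size.
#' @param beta_pen_control fixed effect (peaks per SD) of the pen-control
#'   composite; positive = worse pen control, more velocity peaks.
#' @param beta_letter_knowledge fixed effect (peaks per SD) of encoding;
#'   negative = better letter knowledge, fewer peaks.
#' @param predictor_correlation 7 x 7 correlation matrix (see
#'   [default_predictor_correlation()]).
#' @param sigma_child,sigma_item random-intercept SDs (peaks).
#' @param sigma_resid residual SD (peaks).
#' @param curve_offset extra expected peaks for curved features.
#' @param malform_prob named numeric: `letter_straight`, `letter_curved`,
#'   `symbol_straight`, `symbol_curved`.
#' @param dictation list of dictation-generator settings: `beta_letter_copy`
#'   and `beta_symbol_copy` (peaks per SD of the child's copy-fluency
#'   aggregates), `beta_letter_knowledge` (applied to straight features
#'   only when `knowledge_straight_only`), `attempt_intercept`/
#'   `attempt_slope` (logistic model of per-trial letter retrieval on the
#'   encoding z-score), and its own variance components.
#' @param age_mean_months,age_sd_months child age distribution (age has no
#'   generative effect; it exists to exercise the age step of the model
#'   sequence).
#' @param seed integer seed; the bundle is fully reproducible from it.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_children = 176,
                          beta_pen_control = 0.5,
                          beta_letter_knowledge = -0.5,
                          predictor_correlation = default_predictor_correlation(),
                          sigma_child = 0.61, sigma_item = 0.49,
                          sigma_resid = 1,
                          curve_offset = 1,
                          malform_prob = c(letter_straight = 0.04,
                                           letter_curved = 0.13,
                                           symbol_straight = 0.09,
                                           symbol_curved = 0.32),
                          dictation = list(),
                          age_mean_months = 74.6, age_sd_months = 3.4,
                          seed = 1L) {
  stopifnot(sigma_child >= 0, sigma_item >= 0, sigma_resid >= 0)
  if (any(malform_prob < 0 | malform_prob > 1)) {
    stop_pf("malform_prob values must be in [0, 1]")
  }
  ev <- eigen(predictor_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop_pf("predictor_correlation is not positive semi-definite")
  }
  dict_defaults <- list(
    beta_letter_copy = 0.5, beta_symbol_copy = 0.3,
    beta_letter_knowledge = -0.5, knowledge_straight_only = TRUE,
    attempt_intercept = 0.2, attempt_slope = 0.8,
    sigma_child = 0.61, sigma_item = 0.3, sigma_resid = 1
  )
  structure(
    list(n_children = as.integer(n_children),
         beta_pen_control = beta_pen_control,
         beta_letter_knowledge = beta_letter_knowledge,
         predictor_correlation = predictor_correlation,
         sigma_child = sigma_child, sigma_item = sigma_item,
         sigma_resid = sigma_resid, curve_offset = curve_offset,
         malform_prob = malform_prob,
         dictation = modifyList(dict_defaults, dictation),
         age_mean_months = age_mean_months, age_sd_months = age_sd_months,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws the child-level predictor scores, random intercepts, per-feature
#' peak counts and malformation flags for the copying task over every
#' non-practice inventory character, and (optionally) the dictation task
#' over the ten dictation letters. All quantities that the analysis models
#' try to recover are returned as ground truth. Generation is
#' bit-reproducible from `(config, config$seed)`.
#'
#' @param config a [cohort_config()].
#' @param generate_traces also synthesise pen traces (and mark-up) for the
#'   copy productions of the first `trace_children` children; slow, off by
#'   default.
#' @param trace_children number of children to synthesise traces for.
#' @return a `cohort_bundle` list: `covariates` (one row per child,
#'   z-scored predictors), `copy_table` (one row per produced feature),
#'   `dictation_table`, `truth` (betas, variance components, latent
#'   composites, clamp log), and optionally `traces`.
#' @export
gen_cohort <- function(config, generate_traces = FALSE, trace_children = 2L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_children
  R <- config$predictor_correlation
  scores <- MASS::mvrnorm(n, mu = rep(0, ncol(R)), Sigma = R)
  colnames(scores) <- colnames(R)
  zscore <- function(x) as.numeric(scale(x))
  child_id <- sprintf("c%03d", seq_len(n))
  covariates <- tibble::tibble(
    child_id = child_id,
    age_months = rnorm(n, config$age_mean_months, config$age_sd_months)
  )
  for (nm in colnames(scores)) covariates[[nm]] <- zscore(scores[, nm])
  pc_z <- zscore(rowMeans(scores[, c("lines", "circles", "garlands", "eights")]))
  enc_z <- covariates$encoding

  inv <- load_inventory()
  feats <- inv$features[!inv$features$practice, ]
  items <- unique(feats$character_id)
  u_child <- rnorm(n, 0, config$sigma_child)
  u_item <- setNames(rnorm(length(items), 0, config$sigma_item), items)

  tbl <- tidyr::crossing(child_idx = seq_len(n),
                         feats[c("character_id", "feature_id", "shape_kind",
                                 "is_letter")])
  is_curve <- tbl$shape_kind == "curved"
  mu <- 1 + config$curve_offset * is_curve +
    config$beta_pen_control * pc_z[tbl$child_idx] +
    config$beta_letter_knowledge * enc_z[tbl$child_idx] +
    u_child[tbl$child_idx] + u_item[tbl$character_id]
  eps <- rnorm(nrow(tbl), 0, config$sigma_resid)
  realized <- pmax(1L, as.integer(round(mu + eps)))
  n_clamped <- sum(round(mu + eps) < 1)
  pkey <- paste0(ifelse(tbl$is_letter, "letter_", "symbol_"), tbl$shape_kind)
  malformed <- rbinom(nrow(tbl), 1, config$malform_prob[pkey]) == 1L

  copy_table <- tibble::tibble(
    child_id = child_id[tbl$child_idx],
    item_id = tbl$character_id,
    feature_id = tbl$feature_id,
    peak_count = realized,
    malformed = malformed,
    shape_kind = tbl$shape_kind,
    target_is_letter = tbl$is_letter,
    mu_true = mu
  )

  # child-level copy-fluency aggregates (mean peaks per feature)
  agg <- copy_table |>
    dplyr::group_by(.data$child_id, .data$target_is_letter) |>
    dplyr::summarise(m = mean(.data$peak_count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "target_is_letter", values_from = "m") |>
    dplyr::rename(letter_copy = "TRUE", symbol_copy = "FALSE")
  covariates <- dplyr::left_join(covariates, agg, by = "child_id")
  covariates$letter_copy_z <- zscore(covariates$letter_copy)
  covariates$symbol_copy_z <- zscore(covariates$symbol_copy)

  # dictation task ---------------------------------------------------------
  dc <- config$dictation
  dinv <- dictation_inventory()
  letters10 <- names(dinv)
  attempt_p <- plogis(dc$attempt_intercept + dc$attempt_slope * enc_z)
  u_child2 <- rnorm(n, 0, dc$sigma_child)
  u_item2 <- setNames(rnorm(length(letters10), 0, dc$sigma_item), letters10)
  dict_feats <- purrr::map_dfr(dinv, function(sp) {
    lower <- sp$allographs$lower
    tibble::tibble(
      item_id = sp$character_id,
      feature_id = vapply(lower$features, `[[`, "", "feature_id"),
      shape_kind = vapply(lower$features, `[[`, "", "shape_kind")
    )
  })
  dtab <- tidyr::crossing(child_idx = seq_len(n), dict_feats)
  attempted <- rbinom(nrow(dtab), 1, attempt_p[dtab$child_idx]) == 1L
  # attempt is decided per (child, letter): collapse feature rows
  key <- paste(dtab$child_idx, dtab$item_id)
  first_of_key <- !duplicated(key)
  att_by_key <- setNames(attempted[first_of_key], key[first_of_key])
  attempted <- att_by_key[key]
  d_curve <- dtab$shape_kind == "curved"
  lk_term <- if (isTRUE(dc$knowledge_straight_only)) {
    dc$beta_letter_knowledge * enc_z[dtab$child_idx] * (!d_curve)
  } else dc$beta_letter_knowledge * enc_z[dtab$child_idx]
  mu_d <- 1 + config$curve_offset * d_curve +
    dc$beta_letter_copy * covariates$letter_copy_z[dtab$child_idx] +
    dc$beta_symbol_copy * covariates$symbol_copy_z[dtab$child_idx] +
    lk_term + u_child2[dtab$child_idx] + u_item2[dtab$item_id]
  realized_d <- pmax(1L, as.integer(round(mu_d + rnorm(nrow(dtab), 0, dc$sigma_resid))))
  malform_d <- rbinom(nrow(dtab), 1,
                      config$malform_prob[paste0("letter_", dtab$shape_kind)]) == 1L
  dictation_table <- tibble::tibble(
    child_id = child_id[dtab$child_idx],
    item_id = dtab$item_id,
    feature_id = dtab$feature_id,
    attempted = attempted,
    peak_count = realized_d,
    malformed = malform_d,
    shape_kind = dtab$shape_kind,
    target_is_letter = TRUE,
    mu_true = mu_d
  )

  bundle <- list(
    config = config,
    covariates = covariates,
    copy_table = copy_table,
    dictation_table = dictation_table,
    truth = list(
      pc_composite = pc_z, encoding_z = enc_z,
      u_child = u_child, u_item = u_item,
      n_clamped = n_clamped,
      icc_child = config$sigma_child^2 /
        (config$sigma_child^2 + config$sigma_item^2 + config$sigma_resid^2),
      icc_item = config$sigma_item^2 /
        (config$sigma_child^2 + config$sigma_item^2 + config$sigma_resid^2)
    )
  )
  if (n_clamped > 0) {
    bundle$truth$clamp_note <- sprintf(
      "%d of %d copy productions clamped to the floor of 1 peak",
      n_clamped, nrow(copy_table))
  }

  if (generate_traces) {
    tmpl <- stroke_templates()
    kids <- head(child_id, trace_children)
    traces <- list()
    for (cid in kids) {
      rows <- copy_table[copy_table$child_id == cid, ]
      for (item in unique(rows$item_id)) {
        rr <- rows[rows$item_id == item, ]
        g <- gen_character_trace(item, n_submovements = rr$peak_count,
                                 seed = derive_seed(config$seed,
                                                    match(cid, child_id) * 100 +
                                                      match(item, items)),
                                 child_id = cid,
                                 trace_id = paste0(cid, "_", item))
        traces[[paste0(cid, "_", item)]] <- g
      }
    }
    bundle$traces <- traces
  }
  class(bundle) <- "cohort_bundle"
  bundle
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("<cohort_bundle> %d children, %d copy rows, %d dictation rows\n",
              x$config$n_children, nrow(x$copy_table), nrow(x$dictation_table)))
  invisible(x)
}

#' Write a cohort bundle's tables to a directory
#'
#' Emits `covariates.csv`, `copy_table.csv`, `dictation_table.csv` and, if
#' traces were generated, one trace CSV and mark-up JSON per production, in
#' the package's file dialects.
#'
#' @param bundle a [gen_cohort()] result.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(bundle$covariates, file.path(dir, "covariates.csv"),
            row.names = FALSE)
  write.csv(bundle$copy_table, file.path(dir, "copy_table.csv"),
            row.names = FALSE)
  write.csv(bundle$dictation_table, file.path(dir, "dictation_table.csv"),
            row.names = FALSE)
  if (!is.null(bundle$traces)) {
    tdir <- file.path(dir, "traces")
    dir.create(tdir, showWarnings = FALSE)
    for (nm in names(bundle$traces)) {
      write_trace(bundle$traces[[nm]]$trace, file.path(tdir, paste0(nm, ".csv")))
      write_markup(bundle$traces[[nm]]$marks, file.path(tdir, paste0(nm, ".json")))
    }
  }
  invisible(dir)
}
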