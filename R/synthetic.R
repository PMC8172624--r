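#' Minimum-jerk speed profile of a single ballistic stroke
#'
#' The speed of a point-to-point movement of amplitude `A` and duration `T`
#' that minimises integrated squared jerk: `v(t) = (30 A / T) tau^2 (1 -
#' tau)^2` with `tau = t/T`. The profile is bell shaped, zero at both ends,
#' has a single interior maximum at `t = T/2`, and integrates to `A`. It is
#' the standard motor-control model of one smooth sub-movement and the
#' building block of every synthetic trace in this package.
#'
#' @param T movement duration in seconds (> 0).
#' @param A movement amplitude in mm (> 0).
#' @param t time(s) in seconds within `[0, T]`.
#' @return speed in mm/s, vectorised over `t`.
#' @examples
#' minimum_jerk_speed(1, 1, 0.5)  # 1.875 mm/s
#' @export
minimum_jerk_speed <- function(T, A, t) {
  assert_scalar_num(T, "T", positive = TRUE)
  assert_scalar_num(A, "A", positive = TRUE)
  if (any(t < -1e-12 | t > T + 1e-12)) stop_pf("t outside [0, T]")
  tau <- pmin(pmax(t / T, 0), 1)
  (30 * A / T) * tau^2 * (1 - tau)^2
}

# Core trace synthesiser: traverse `path` with a concatenation of
# minimum-jerk bells (amplitudes bell_amps summing to the path length,
# durations bell_durs, optional pauses after each bell), add optional
# sinusoidal tremor to the speed, and sample at fs with optional timestamp
# jitter. Returns the trace plus dense noise-free ground truth.
synth_speed_trace <- function(path, bell_amps, bell_durs, pauses = 0,
                              tremor = NULL, fs = 133, seed = NULL,
                              jitter_ms = 0.5, dense_fs = 1000,
                              speed_fun = NULL, duration = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  path <- densify_polyline(as_poly(path), max_step = 0.2)
  L <- polyline_arclength(path)
  if (L <= 0) stop_pf("zero-length template path")

  if (is.null(speed_fun)) {
    k <- length(bell_amps)
    pauses <- rep_len(pauses, k)
    pauses[k] <- 0
    starts <- cumsum(c(0, head(bell_durs + pauses, -1L)))
    total_T <- sum(bell_durs) + sum(pauses[-k])
    base_speed <- function(t) {
      v <- numeric(length(t))
      for (j in seq_len(k)) {
        inb <- t >= starts[j] & t <= starts[j] + bell_durs[j]
        if (any(inb)) {
          v[inb] <- v[inb] +
            minimum_jerk_speed(bell_durs[j], bell_amps[j], t[inb] - starts[j])
        }
      }
      v
    }
    peak_times <- starts + bell_durs / 2
  } else {
    base_speed <- speed_fun
    total_T <- duration
    peak_times <- numeric(0)
  }

  if (!is.null(tremor)) {
    if (fs <= 2 * tremor$freq) {
      stop_pf("sampling rate must exceed twice the tremor frequency")
    }
    phase <- runif(1, 0, 2 * pi)
    # tremor modulates ongoing movement: its amplitude ramps in with the
    # base speed (a resting pen does not oscillate), full strength once the
    # base speed exceeds twice the tremor amplitude
    full_speed <- function(t) {
      b <- base_speed(t)
      gate <- pmin(1, b / (2 * tremor$amp))
      pmax(b + tremor$amp * gate * sin(2 * pi * tremor$freq * t + phase), 0)
    }
  } else full_speed <- base_speed

  t_dense <- seq(0, total_T, by = 1 / dense_fs)
  v_base <- base_speed(t_dense)
  v_full <- full_speed(t_dense)
  s_dense <- cumsum(c(0, (v_full[-1] + v_full[-length(v_full)]) / 2)) / dense_fs
  if (is.null(speed_fun)) s_dense <- s_dense * (L / max(s_dense[length(s_dense)], 1e-12))

  t_samp <- seq(0, total_T, by = 1 / fs)
  if (jitter_ms > 0 && length(t_samp) > 2L) {
    jit <- runif(length(t_samp), -jitter_ms, jitter_ms) / 1000
    jit[c(1L, length(t_samp))] <- 0
    t_samp <- t_samp + jit
  }
  s_samp <- approx(t_dense, s_dense, xout = t_samp, rule = 2, ties = "ordered")$y
  xy <- polyline_at(path, s_samp)
  trace <- pen_trace(
    tibble::tibble(t_ms = t_samp * 1000, x = xy[, 1], y = xy[, 2],
                   pen_down = TRUE),
    nominal_rate = fs
  )
  truth <- list(
    n_submovements = if (is.null(speed_fun)) length(bell_amps) else NA_integer_,
    peak_times = peak_times,
    t_dense = t_dense, v_dense = v_base, v_dense_full = v_full,
    s_dense = s_dense, path_length = L, duration = total_T
  )
  list(trace = trace, truth = truth)
}

#' Generate one synthetic feature production
#'
#' Produces a pen trace following the template geometry whose speed profile
#' is a concatenation of `n_submovements` minimum-jerk bells partitioning
#' the path, with near-zero speed between bells. Each bell contributes one
#' velocity peak, so `n_submovements` is the ground-truth disfluency score.
#' High-frequency tremor (a zero-mean sinusoidal speed modulation, removable
#' by 10 Hz filtering) and timestamp jitter around the sampling grid can be
#' added to emulate measurement conditions.
#'
#' @param feature a template feature (list with `path`), or an n x 2 path
#'   matrix.
#' @param n_submovements number of ballistic sub-movements (>= 1).
#' @param tremor `NULL` or `list(amp = mm/s, freq = Hz)`; requires
#'   `fs > 2 * freq`.
#' @param fs sampling rate in Hz.
#' @param seed RNG seed for the amplitude split, jitter, and tremor phase.
#' @param bell_duration per-sub-movement duration in seconds (scalar or
#'   vector); consecutive peaks are separated by at least the mean bell
#'   duration.
#' @param pause pause between bells in seconds.
#' @param jitter_ms half-width of the uniform timestamp jitter (ms); 0
#'   disables.
#' @return list with `trace` (a [pen_trace()]) and `truth` (ground truth:
#'   `n_submovements`, bell `peak_times`, and the dense noise-free speed
#'   profile `t_dense`/`v_dense` for oracle checks).
#' @export
gen_feature_trace <- function(feature, n_submovements = 1L, tremor = NULL,
                              fs = 133, seed = NULL, bell_duration = 0.35,
                              pause = 0.04, jitter_ms = 0.5) {
  if (n_submovements < 1L) stop_pf("n_submovements must be >= 1")
  path <- if (is.list(feature) && !is.null(feature$path)) feature$path else feature
  path <- as_poly(path)
  L <- polyline_arclength(densify_polyline(path, 0.2))
  if (L <= 0) stop_pf("zero-length template path")
  k <- as.integer(n_submovements)
  if (!is.null(seed)) set.seed(seed)
  w <- runif(k, 0.85, 1.15)
  amps <- L * w / sum(w)
  durs <- rep_len(bell_duration, k)
  synth_speed_trace(path, amps, durs, pauses = pause, tremor = tremor,
                    fs = fs, seed = NULL, jitter_ms = jitter_ms)
}

# find the endpoint of `path` closest to any endpoint of `sib`; returns the
# junction point and endpoint index (1 = first, 2 = last row)
junction_of <- function(path, sib) {
  ea <- rbind(path[1, ], path[nrow(path), ])
  eb <- rbind(sib[1, ], sib[nrow(sib), ])
  dd <- outer(seq_len(2), seq_len(2),
              Vectorize(function(i, j) sqrt(sum((ea[i, ] - eb[j, ])^2))))
  w <- which(dd == min(dd), arr.ind = TRUE)[1, ]
  list(point = ea[w[1], ], which_end = w[1])
}

rotate_about <- function(p, centre, theta) {
  rel <- sweep(p, 2, centre)
  rot <- cbind(rel[, 1] * cos(theta) - rel[, 2] * sin(theta),
               rel[, 1] * sin(theta) + rel[, 2] * cos(theta))
  sweep(rot, 2, centre, `+`)
}

# apply one geometric defect to a feature path (used to construct fixtures
# whose accuracy-coder verdict is known)
apply_defect <- function(path, defect, sibling_path = NULL) {
  type <- defect$type
  val <- defect$value
  path <- as_poly(path)
  if (type == "straightness") {
    p <- densify_polyline(path, 0.2)
    a <- p[1, ]; b <- p[nrow(p), ]
    chord <- sqrt(sum((b - a)^2))
    d <- (b - a) / chord
    perp <- c(-d[2], d[1])
    cs <- cumulative_arclength(p)
    frac <- cs / cs[length(cs)]
    bump <- val * chord * (1 - abs(2 * frac - 1))
    p + outer(bump, perp)
  } else if (type == "angle") {
    if (is.null(sibling_path)) stop_pf("angle defect needs the sibling path")
    sib <- as_poly(sibling_path)
    j <- junction_of(path, sib)
    cur <- junction_angle(path, sib)
    for (delta in c(cur - val, val - cur) * pi / 180) {
      cand <- rotate_about(path, j$point, delta)
      if (abs(junction_angle(cand, sib) - val) < 0.5) return(cand)
    }
    stop_pf("could not realise junction angle of ", val, " degrees")
  } else if (type == "length") {
    if (is.null(sibling_path)) stop_pf("length defect needs the sibling path")
    j <- junction_of(path, as_poly(sibling_path))
    sweep(sweep(path, 2, j$point) * val, 2, j$point, `+`)
  } else if (type == "junction") {
    if (is.null(sibling_path)) stop_pf("junction defect needs the sibling path")
    sib <- as_poly(sibling_path)
    j <- junction_of(path, sib)
    len <- polyline_arclength(path)
    far <- if (j$which_end == 1L) path[nrow(path), ] else path[1, ]
    dir <- (far - j$point) / sqrt(sum((far - j$point)^2))
    sweep(path, 2, dir * val * len, `+`)
  } else stop_pf("unknown defect type: ", type)
}

#' Generate one synthetic character production with mark-up
#'
#' Concatenates one feature trace per template feature (separated by brief
#' pen-up transitions), emits the matching feature mark-up, and optionally
#' perturbs feature geometry with defects so that the accuracy coder's
#' verdict is known in advance. Supported defect types: `straightness`
#' (value = chord-fraction deviation), `angle` (value = target junction
#' angle in degrees), `length` (value = length scale factor), `junction`
#' (value = gap as fraction of feature length).
#'
#' @param character_id a character id from the inventory (e.g. `"A"`).
#' @param n_submovements scalar or per-feature vector of sub-movement
#'   counts.
#' @param defect_spec named list `feature_id -> list(type, value)`.
#' @param fs sampling rate in Hz.
#' @param seed RNG seed.
#' @param tremor optional tremor, as in [gen_feature_trace()].
#' @param allograph which allograph of the character to produce (index).
#' @param templates template set from [stroke_templates()].
#' @param child_id,trace_id identifiers stamped on the outputs.
#' @return list with `trace`, `marks` (a [feature_marks()] tibble), and
#'   `truth` (per-feature sub-movement counts, defects applied, dense
#'   profiles).
#' @export
gen_character_trace <- function(character_id, n_submovements = 1L,
                                defect_spec = NULL, fs = 133, seed = NULL,
                                tremor = NULL, allograph = 1L,
                                templates = stroke_templates(),
                                child_id = NA_character_,
                                trace_id = NA_character_) {
  tmpl <- templates[[character_id]]
  if (is.null(tmpl)) stop_pf("unknown character_id: ", character_id)
  feats <- tmpl$allographs[[allograph]]$features
  nf <- length(feats)
  nsub <- rep_len(as.integer(n_submovements), nf)
  if (!is.null(seed)) set.seed(seed)

  ids <- vapply(feats, `[[`, "", "feature_id")
  paths <- lapply(feats, `[[`, "path")
  names(paths) <- ids
  if (!is.null(defect_spec)) {
    for (fid in names(defect_spec)) {
      if (!fid %in% ids) stop_pf("defect references unknown feature ", fid)
      d <- defect_spec[[fid]]
      sib <- if (!is.null(d$sibling)) paths[[d$sibling]] else {
        others <- setdiff(ids, fid)
        if (length(others)) paths[[others[1]]] else NULL
      }
      paths[[fid]] <- apply_defect(paths[[fid]], d, sib)
    }
  }

  samples <- NULL
  mark_rows <- list()
  truths <- list()
  t_off <- 0
  gap_ms <- 3 * 1000 / fs
  for (i in seq_len(nf)) {
    g <- gen_feature_trace(paths[[i]], n_submovements = nsub[i],
                           tremor = tremor, fs = fs, seed = NULL)
    s <- g$trace$samples
    s$t_ms <- s$t_ms + t_off
    start_idx <- if (is.null(samples)) 1L else nrow(samples) + 1L
    if (!is.null(samples)) {
      # pen-up transition between features
      prev <- samples[nrow(samples), ]
      tgap <- seq(prev$t_ms + gap_ms / 3, s$t_ms[1] - gap_ms / 3, length.out = 2)
      lift <- tibble::tibble(
        t_ms = tgap,
        x = seq(prev$x, s$x[1], length.out = 4)[2:3],
        y = seq(prev$y, s$y[1], length.out = 4)[2:3],
        pen_down = FALSE
      )
      samples <- dplyr::bind_rows(samples, lift)
      start_idx <- nrow(samples) + 1L
    }
    samples <- dplyr::bind_rows(samples, s)
    mark_rows[[i]] <- tibble::tibble(
      feature_id = ids[i],
      start_index = start_idx,
      end_index = nrow(samples),
      shape_kind = feats[[i]]$shape_kind
    )
    truths[[ids[i]]] <- g$truth
    t_off <- samples$t_ms[nrow(samples)] + gap_ms
  }
  trace <- pen_trace(samples, nominal_rate = fs, trace_id = trace_id,
                     child_id = child_id, item_id = character_id)
  marks <- feature_marks(dplyr::bind_rows(mark_rows),
                         trace_id = trace_id, character_id = character_id,
                         target_is_letter = tmpl$is_letter)
  list(trace = trace, marks = marks,
       truth = list(n_submovements = setNames(nsub, ids),
                    defects = defect_spec, features = truths))
}

# pen-control task geometry ------------------------------------------------

garland_path <- function(n_loops, width = 17, height = 12, up = TRUE) {
  u <- seq(0, n_loops, by = 0.01)
  y <- height / 2 * (1 - cos(2 * pi * u))
  if (!up) y <- -y
  cbind(u * (width * 10 / n_loops), y)  # 17 cm baseline in mm
}

eight_path <- function(w = 20, h = 22) {
  t <- seq(0, 2 * pi, length.out = 400)
  cbind(w / 2 * sin(2 * t) / 2 + w / 2, h / 2 * sin(t) + h / 2)
}

#' Generate synthetic pen-control task traces
#'
#' Emulates the repetitive pen-control tasks: overlapping horizontal or
#' vertical lines, clockwise/anticlockwise circles, garlands along a
#' baseline, and isolated figure eights. Each repetition ("unit") is drawn
#' with a controllable number of minimum-jerk sub-movements; tremor and a
#' mid-band speed ripple (for SNvpd fixtures) can be injected. Unit
#' boundaries, validity, and pen lifts are recorded as ground truth in the
#' `units` attribute so that selection rules can be tested independently of
#' unit segmentation.
#'
#' @param task one of `"h_lines"`, `"v_lines"`, `"cw_circles"`,
#'   `"ccw_circles"`, `"garland_up"`, `"garland_down"`, `"eights"`.
#' @param n_repetitions number of units (lines/circles/loops/eights).
#'   Lines and circles need >= 7 for the selection rules to apply; eights
#'   are produced as up to 7 separate traces.
#' @param submovements_per_unit ballistic sub-movements per unit (1 =
#'   fluent).
#' @param tremor optional `list(amp, freq)` high-frequency tremor.
#' @param ripple optional `list(amp, freq)` mid-band (5-10 Hz) speed ripple;
#'   only supported for garlands, where the base speed is then a slow
#'   sinusoidal modulation rather than discrete bells.
#' @param invalid_units integer indices of units to mark invalid (e.g.
#'   circles drawn in the wrong direction).
#' @param pen_lift_units integer indices of units given an internal pen
#'   lift.
#' @param fs sampling rate in Hz.
#' @param seed RNG seed.
#' @return for `"eights"`, a list of [pen_trace()]s (ground truth attached
#'   to each); otherwise a single [pen_trace()] with a `units` attribute
#'   (tibble: `unit`, `start_index`, `end_index`, `valid`, `pen_lift`) and a
#'   `truth` attribute with the dense speed profiles.
#' @export
gen_pencontrol_trace <- function(task, n_repetitions = 10,
                                 submovements_per_unit = 1L, tremor = NULL,
                                 ripple = NULL, invalid_units = integer(0),
                                 pen_lift_units = integer(0), fs = 133,
                                 seed = NULL) {
  tasks <- c("h_lines", "v_lines", "cw_circles", "ccw_circles",
             "garland_up", "garland_down", "eights")
  if (!task %in% tasks) stop_pf("unsupported task name: ", task)
  if (!is.null(seed)) set.seed(seed)
  if (task %in% c("h_lines", "v_lines", "cw_circles", "ccw_circles") &&
      n_repetitions < 7) {
    stop_pf("lines and circles need at least 7 repetitions")
  }

  if (task == "eights") {
    n <- min(n_repetitions, 7L)
    return(lapply(seq_len(n), function(i) {
      g <- synth_unit_run(eight_path(), n_units = 1L,
                          subs = max(2L, submovements_per_unit + 1L),
                          tremor = tremor, fs = fs)
      g$trace
    }))
  }

  if (task %in% c("garland_up", "garland_down") && !is.null(ripple)) {
    # Designed SNvpd fixture. Base speed: one trapezoidal speed wave per
    # loop (linear rise at +150 mm/s^2, faster fall, cosine-rounded
    # corners), giving exactly one propulsive maximum per loop that
    # survives any low-pass. Ripple: a mid-band sinusoidal burst gated onto
    # the linear rising flank of each loop, phase-locked to the gate. On
    # the flank the full-amplitude ripple dominates the base slope (one
    # extra maximum per ripple cycle at 10 Hz) while its 5 Hz leakage stays
    # well below the base slope (no extra maxima at 5 Hz), so the pipeline
    # and the dense analytic-gain oracle agree count for count.
    path <- garland_path(n_repetitions, up = task == "garland_up")
    period <- 1.0
    rise <- 0.6
    dv <- 75
    round_w <- 0.06
    dur <- n_repetitions * period
    v0 <- 60
    # base speed: integrate a continuous piecewise-linear slope profile
    # (0 -> +s_rise -> -s_fall -> 0 with short ramps) on a fine grid, then
    # remove the residual drift so the wave is exactly periodic
    s_rise <- dv / rise
    s_fall <- -dv / (period - rise)
    dt_g <- period / 8192
    tg <- seq(0, period, by = dt_g)
    slope_of <- function(t) {
      ifelse(t < round_w, s_rise * t / round_w,
      ifelse(t <= rise - round_w, s_rise,
      ifelse(t < rise + round_w,
             s_rise + (s_fall - s_rise) * (t - rise + round_w) / (2 * round_w),
      ifelse(t <= period - round_w, s_fall,
             s_fall * (period - t) / round_w))))
    }
    sg <- slope_of(tg)
    vg <- cumsum(c(0, (sg[-1] + sg[-length(sg)]) / 2)) * dt_g
    vg <- vg - tg / period * vg[length(vg)]  # enforce periodicity
    base <- function(t) {
      u <- (t %% period)
      v0 + approx(tg, vg, xout = u, rule = 2, ties = "ordered")$y
    }
    gate_lo <- 0.10
    gate_hi <- 0.46
    edge <- 0.08
    envelope <- function(t) {
      tt <- t %% period
      up <- pmin(pmax((tt - gate_lo) / edge, 0), 1)
      down <- pmin(pmax((gate_hi - tt) / edge, 0), 1)
      e <- pmin(up, down)
      e^2 * (3 - 2 * e)  # smoothstep
    }
    ripple_wave <- function(t) {
      tt <- t %% period
      envelope(t) * sin(2 * pi * ripple$freq * (tt - gate_lo))
    }
    full <- function(t) base(t) + ripple$amp * ripple_wave(t)
    # scale the path to the designed travel distance, with shallow loops so
    # that path curvature cannot modulate the reconstructed speed
    path <- garland_path(n_repetitions, height = 5,
                         up = task == "garland_up")
    tt_fine <- seq(0, dur, by = 1e-3)
    dist <- sum(full(tt_fine)) * 1e-3
    path <- path * (dist / polyline_arclength(densify_polyline(path, 0.5)))
    g <- synth_speed_trace(path, speed_fun = full, duration = dur, fs = fs,
                           jitter_ms = 0.3, seed = seed)
    g$truth$v_dense <- base(g$truth$t_dense)
    g$truth$ripple_dense <- ripple_wave(g$truth$t_dense)
    g$truth$ripple_amp <- ripple$amp
    g$truth$ripple_freq <- ripple$freq
    tr <- g$trace
    attr(tr, "units") <- tibble::tibble(
      unit = 1L, start_index = 1L, end_index = n_samples(tr),
      valid = TRUE, pen_lift = FALSE)
    attr(tr, "truth") <- g$truth
    return(tr)
  }

  path <- switch(task,
    h_lines = {
      p <- seg(0, 0, 40, 0)
      do.call(rbind, lapply(seq_len(n_repetitions), function(i) {
        if (i %% 2L == 1L) p else p[2:1, ]
      }))
    },
    v_lines = {
      p <- seg(0, 0, 0, 40)
      do.call(rbind, lapply(seq_len(n_repetitions), function(i) {
        if (i %% 2L == 1L) p else p[2:1, ]
      }))
    },
    cw_circles = {
      th <- seq(pi / 2, pi / 2 - 2 * pi * n_repetitions, length.out = 200 * n_repetitions)
      cbind(20 + 15 * cos(th), 25 + 15 * sin(th))
    },
    ccw_circles = {
      th <- seq(pi / 2, pi / 2 + 2 * pi * n_repetitions, length.out = 200 * n_repetitions)
      cbind(20 + 15 * cos(th), 25 + 15 * sin(th))
    },
    garland_up = garland_path(n_repetitions, up = TRUE),
    garland_down = garland_path(n_repetitions, up = FALSE)
  )
  g <- synth_unit_run(path, n_units = n_repetitions,
                      subs = submovements_per_unit, tremor = tremor, fs = fs)
  tr <- g$trace
  units <- g$units
  units$valid <- !(units$unit %in% invalid_units)
  units$pen_lift <- units$unit %in% pen_lift_units
  if (length(pen_lift_units)) {
    s <- tr$samples
    for (u in pen_lift_units) {
      a <- units$start_index[units$unit == u]
      b <- units$end_index[units$unit == u]
      mid <- (a + b) %/% 2L
      s$pen_down[mid:min(mid + 2L, b)] <- FALSE
    }
    tr <- pen_trace(s, nominal_rate = tr$nominal_rate, trace_id = tr$trace_id,
                    child_id = tr$child_id, item_id = tr$item_id)
  }
  attr(tr, "units") <- units
  attr(tr, "truth") <- g$truth
  tr
}

# draw a path consisting of n_units equal arc-length units, each produced
# with `subs` minimum-jerk bells; returns trace + unit index table + truth
synth_unit_run <- function(path, n_units, subs, tremor, fs) {
  path <- densify_polyline(as_poly(path), 0.25)
  L <- polyline_arclength(path)
  unit_len <- L / n_units
  k <- n_units * subs
  amps <- rep(unit_len / subs, k) * runif(k, 0.95, 1.05)
  amps <- amps * (L / sum(amps))
  durs <- rep(0.35, k)
  g <- synth_speed_trace(path, amps, durs, pauses = 0.02, fs = fs,
                         tremor = tremor, jitter_ms = 0.3)
  # unit boundaries at arc-length multiples of unit_len
  s_samp <- approx(g$truth$t_dense, g$truth$s_dense,
                   xout = g$trace$samples$t_ms / 1000, rule = 2,
                   ties = "ordered")$y
  bounds <- unit_len * (0:n_units)
  idx <- findInterval(s_samp, bounds, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L; idx[idx > n_units] <- n_units
  units <- purrr::map_dfr(seq_len(n_units), function(u) {
    w <- which(idx == u)
    tibble::tibble(unit = u, start_index = min(w), end_index = max(w),
                   valid = TRUE, pen_lift = FALSE)
  })
  list(trace = g$trace, units = units, truth = g$truth)
}
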