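# internal assertions and small helpers

stop_pf <- function(..., class = "penfluency_error") {
  rlang::abort(paste0(...), class = class)
}

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_pf(name, " must be a finite numeric scalar")
  }
  if (positive && x <= 0) stop_pf(name, " must be > 0")
  invisible(x)
}

# strictly increasing check returning index of first offender (or 0L)
first_nonmonotone <- function(t) {
  if (length(t) < 2L) return(0L)
  bad <- which(diff(t) <= 0)
  if (length(bad)) bad[1L] + 1L else 0L
}

# cumulative arc length of a 2-column polyline matrix
polyline_arclength <- function(p) {
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

cumulative_arclength <- function(p) {
  c(0, cumsum(sqrt(rowSums(diff(p)^2))))
}

# evaluate points along a polyline at arc-length positions s (clamped)
polyline_at <- function(p, s) {
  cs <- cumulative_arclength(p)
  L <- cs[length(cs)]
  s <- pmin(pmax(s, 0), L)
  x <- approx(cs, p[, 1], xout = s, ties = "ordered")$y
  y <- approx(cs, p[, 2], xout = s, ties = "ordered")$y
  cbind(x, y)
}

# densify a polyline so no segment exceeds max_step (mm)
densify_polyline <- function(p, max_step = 0.25) {
  if (nrow(p) < 2L) return(p)
  out <- list(p[1, , drop = FALSE])
  for (i in seq_len(nrow(p) - 1L)) {
    a <- p[i, ]; b <- p[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(len / max_step))
    tt <- seq_len(k) / k
    out[[i + 1L]] <- cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
  }
  m <- do.call(rbind, out)
  dimnames(m) <- NULL
  m
}

# circular arc polyline (theta in radians, counter-clockwise when th1 > th0)
arc_points <- function(cx, cy, r, th0, th1, n = 64L) {
  th <- seq(th0, th1, length.out = n)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# derive a child RNG seed (< 2^31) from a base seed and an index
derive_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(i)) %% 2147483629 + 1
}
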