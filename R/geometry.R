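# Geometry primitives operationalising the verbal feature-accuracy rules.
# All measures are ratios or angles, so verdicts are invariant under uniform
# scaling and rigid motion of the whole character.

as_poly <- function(p) {
  if (inherits(p, "pen_trace")) p <- cbind(p$samples$x, p$samples$y)
  p <- as.matrix(p)
  if (ncol(p) != 2L || nrow(p) < 2L) stop_pf("segment needs >= 2 points")
  p
}

#' Straightness deviation of a polyline
#'
#' Maximum perpendicular distance of any point from the endpoint chord,
#' divided by the chord length. A perfect line scores 0; a right-isosceles
#' bend at the midpoint scores 0.5.
#'
#' @param p an n x 2 point matrix or a [pen_trace()].
#' @return non-negative fraction of chord length.
#' @export
straightness_deviation <- function(p) {
  p <- as_poly(p)
  a <- p[1, ]; b <- p[nrow(p), ]
  chord <- sqrt(sum((b - a)^2))
  if (chord <= 0) stop_pf("degenerate zero-length segment")
  d <- b - a
  # perpendicular distance via 2D cross product
  rel <- sweep(p, 2, a)
  dist <- abs(rel[, 1] * d[2] - rel[, 2] * d[1]) / chord
  max(dist) / chord
}

#' Junction angle between two segments (degrees)
#'
#' The junction is the closest pair of endpoints of the two segments; the
#' angle is measured between the endpoint-chord direction vectors of each
#' segment, both oriented away from the junction.
#'
#' @param seg_a,seg_b point matrices or [pen_trace()]s.
#' @return angle in degrees in `[0, 180]`.
#' @export
junction_angle <- function(seg_a, seg_b) {
  a <- as_poly(seg_a); b <- as_poly(seg_b)
  ea <- rbind(a[1, ], a[nrow(a), ])
  eb <- rbind(b[1, ], b[nrow(b), ])
  dd <- outer(seq_len(2), seq_len(2),
              Vectorize(function(i, j) sqrt(sum((ea[i, ] - eb[j, ])^2))))
  w <- which(dd == min(dd), arr.ind = TRUE)[1, ]
  ja <- w[1]; jb <- w[2]
  ua <- ea[3 - ja, ] - ea[ja, ]
  ub <- eb[3 - jb, ] - eb[jb, ]
  na <- sqrt(sum(ua^2)); nb <- sqrt(sum(ub^2))
  if (na <= 0 || nb <= 0) stop_pf("degenerate zero-length segment")
  cosang <- sum(ua * ub) / (na * nb)
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Junction gap or overlap between two segments
#'
#' Minimum distance between any endpoint of `seg_a` and any endpoint of
#' `seg_b`, divided by the length of `seg_a`. Both a separation and an
#' overshoot past the intended junction displace the nearest endpoints
#' apart, so one measure covers gap and overlap.
#'
#' @param seg_a,seg_b point matrices or [pen_trace()]s.
#' @return non-negative fraction of `seg_a`'s length.
#' @export
junction_gap <- function(seg_a, seg_b) {
  a <- as_poly(seg_a); b <- as_poly(seg_b)
  len_a <- polyline_arclength(a)
  if (len_a <= 0) stop_pf("degenerate zero-length segment")
  ea <- rbind(a[1, ], a[nrow(a), ])
  eb <- rbind(b[1, ], b[nrow(b), ])
  dmin <- min(outer(seq_len(2), seq_len(2),
                    Vectorize(function(i, j) sqrt(sum((ea[i, ] - eb[j, ])^2)))))
  dmin / len_a
}
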