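# Geometry templates for the synthetic writer.
#
# Every inventory feature has a nominal path inside the 25 x 25 mm response
# box (y increases upward, units mm). Curved features are stored as densely
# sampled circular arcs, straight features as two-point segments. The shapes
# are schematic: the generator's purpose is controlled kinematics and known
# ground truth, not letter aesthetics.

seg <- function(x0, y0, x1, y1) cbind(c(x0, x1), c(y0, y1))

#' Stroke templates for the built-in inventory
#'
#' Returns the nominal feature geometry used by the synthetic writer, keyed
#' by character id. Each template lists, per allograph, the feature paths in
#' production order.
#'
#' @return named list of stroke templates; each has `character_id`,
#'   `is_letter`, and `allographs`, where every feature is a list
#'   `(feature_id, shape_kind, path)` with `path` an n x 2 matrix in mm.
#' @export
stroke_templates <- function() {
  paths <- list(
    # practice letter: circle + slash
    oslash_circle = arc_points(12.5, 12.5, 8, pi / 2, pi / 2 + 2 * pi),
    oslash_slash = seg(6, 3, 19, 22),
    # practice symbol: omega body + feet
    omega_body = arc_points(12.5, 14, 7, -pi / 3, 4 * pi / 3),
    omega_foot_l = seg(9, 7.9, 5, 7),
    omega_foot_r = seg(16, 7.9, 20, 7),
    # A, two-upright allograph (apex at 12.5, 23)
    a_upright_l = seg(4, 2, 12.5, 23),
    a_upright_r = seg(12.5, 23, 21, 2),
    a_crossbar = seg(7.5, 10, 17.5, 10),
    a_arch = arc_points(12.5, 4, 10.5, pi, 0),
    # double-barred stem
    dblbar_stem = seg(12.5, 2, 12.5, 23),
    dblbar_bar1 = seg(7, 16, 18, 16),
    dblbar_bar2 = seg(7, 9, 18, 9),
    # M
    m_left = seg(4, 2, 4, 23),
    m_diag_l = seg(4, 23, 12.5, 6),
    m_diag_r = seg(12.5, 6, 21, 23),
    m_right = seg(21, 23, 21, 2),
    # d
    d_bowl = arc_points(9, 8, 5, pi / 4, pi / 4 + 2 * pi),
    d_stem = seg(14, 23, 14, 3),
    # psi: cup + stem
    psi_cup = arc_points(12.5, 15, 6, pi, 2 * pi),
    psi_stem = seg(12.5, 22, 12.5, 2),
    # h
    h_stem = seg(6, 23, 6, 2),
    h_arch = arc_points(10.5, 8, 4.5, pi, 0),
    h_leg = seg(15, 8, 15, 2),
    # T
    t_bar = seg(4, 23, 21, 23),
    t_stem = seg(12.5, 23, 12.5, 2),
    # gamma with hooked tail
    gamma_arm_l = seg(5, 23, 12.5, 10),
    gamma_arm_r = seg(20, 23, 12.5, 10),
    gamma_tail = arc_points(12.5, 5, 5, pi / 2, -pi),
    # e as a single open curve
    e_curve = arc_points(12.5, 8, 5, 0.3, 5.8),
    # hiragana wi stand-in
    wi_top = seg(6, 20, 18, 20),
    wi_diag = seg(12, 23, 9, 12),
    wi_loop = arc_points(12.5, 8, 5.5, 2.2, -2.6),
    wi_tail = arc_points(14, 6, 3, -2.6, 0.8),
    # g
    g_bowl = arc_points(10, 16, 4.5, pi / 4, pi / 4 + 2 * pi),
    g_hook = arc_points(10.5, 10, 4, 0, -1.2 * pi),
    # R
    r_stem = seg(5, 2, 5, 23),
    r_bowl = arc_points(5, 18, 5, pi / 2, -pi / 2),
    r_leg = seg(5, 13, 16, 2)
  )
  inv <- load_inventory()
  purrr::map(inv$characters, function(ch) {
    allos <- purrr::map(ch$allographs, function(a) {
      feats <- purrr::map(a$features, function(f) {
        p <- paths[[f$feature_id]]
        if (is.null(p)) stop_pf("no geometry template for ", f$feature_id)
        list(feature_id = f$feature_id, shape_kind = f$shape_kind, path = p)
      })
      list(allograph_id = a$allograph_id, features = feats)
    })
    list(character_id = ch$character_id, is_letter = ch$is_letter,
         practice = ch$practice, allographs = allos)
  })
}
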