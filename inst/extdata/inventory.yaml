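# Character inventory for the copying task: 14 stimuli decomposed into
# straight / curved sub-letter features. Decompositions and rule parameters
# are a documented stand-in chosen to satisfy the published feature totals
# (letters: 14 straight + 6 curved; symbols: 8 straight + 4 curved, over the
# 12 non-practice characters). The uppercase-A rules are the fully specified
# exemplar: its leftmost upright must meet the second upright at an acute
# angle of 20-90 degrees, deviate from straight by no more than 1/6 of its
# length, differ in length from the second upright by no more than 1/6 of
# that upright's length, and meet it with a gap or overlap of no more than
# 1/6 of its length. Unspecified characters inherit the same 1/6 tolerance
# family where a rule applies.
characters:
  - id: O_slash
    glyph: "Ø"
    is_letter: true
    practice: true
    allographs:
      - id: primary
        features:
          - {id: oslash_circle, shape: curved}
          - {id: oslash_slash, shape: straight,
             rules: {straightness_tol: 0.1667}}
  - id: Omega
    glyph: "Ω"
    is_letter: false
    practice: true
    allographs:
      - id: primary
        features:
          - {id: omega_body, shape: curved}
          - {id: omega_foot_l, shape: straight,
             rules: {straightness_tol: 0.1667}}
          - {id: omega_foot_r, shape: straight,
             rules: {straightness_tol: 0.1667}}
  - id: A
    glyph: "A"
    is_letter: true
    practice: false
    allographs:
      - id: two_uprights
        features:
          - {id: a_upright_l, shape: straight,
             rules: {angle_sibling: a_upright_r, angle_bounds: [20, 90],
                     straightness_tol: 0.1667,
                     length_sibling: a_upright_r, length_tol: 0.1667,
                     junction_sibling: a_upright_r, junction_tol: 0.1667}}
          - {id: a_upright_r, shape: straight,
             rules: {angle_sibling: a_upright_l, angle_bounds: [20, 90],
                     straightness_tol: 0.1667,
                     length_sibling: a_upright_l, length_tol: 0.1667,
                     junction_sibling: a_upright_l, junction_tol: 0.1667}}
          - {id: a_crossbar, shape: straight,
             rules: {straightness_tol: 0.1667}}
      - id: arch
        features:
          - {id: a_arch, shape: curved}
          - {id: a_crossbar, shape: straight,
             rules: {straightness_tol: 0.1667}}
  - id: dbl_bar
    glyph: "ǂ"
    is_letter: false
    practice: false
    allographs:
      - id: primary
        features:
          - {id: dblbar_stem, shape: straight,
             rules: {straightness_tol: 0.1667}}
          - {id: dblbar_bar1, shape: straight,
             rules: {straightness_tol: 0.1667}}
          - {id: dblbar_bar2, shape: straight,
             rules: {straightness_tol: 0.1667}}
  - id: M
    glyph: "M"
    is_letter: true
    practice: false
    allographs:
      - id: primary
        features:
          - {id: m_left, shape: straight, rules: {straightness_tol: 0.1667}}
          - {id: m_diag_l, shape: straight, rules: {straightness_tol: 0.1667}}
          - {id: m_diag_r, shape: straight, rules: {straightness_tol: 0.1667}}
          - {id: m_right, shape: straight, rules: {straightness_tol: 0.1667}}
  - id: d
    glyph: "d"
    is_letter: true
    practice: false
    allographs:
      - id: primary
        features:
          - {id: d_bowl, shape: curved}
          - {id: d_stem, shape: straight, rules: {straightness_tol: 0.1667}}
  - id: Psi
    glyph: "Ψ"
    is_letter: false
    practice: false
    allographs:
      - id: primary
        features:
          - {id: psi_cup, shape: curved}
          - {id: psi_stem, shape: straight, rules: {straightness_tol: 0.1667}}
  - id: h
    glyph: "h"
    is_letter: true
    practice: false
    allographs:
      - id: primary
        features:
          - {id: h_stem, shape: straight, rules: {straightness_tol: 0.1667}}
          - {id: h_arch, shape: curved}
          - {id: h_leg, shape: straight, rules: {straightness_tol: 0.1667}}
  - id: T
    glyph: "T"
    is_letter: true
    practice: false
    allographs:
      - id: primary
        features:
          - {id: t_bar, shape: straight, rules: {straightness_tol: 0.1667}}
          - {id: t_stem, shape: straight, rules: {straightness_tol: 0.1667}}
  - id: gamma_hook
    glyph: "Ɣ"
    is_letter: false
    practice: false
    allographs:
      - id: primary
        features:
          - {id: gamma_arm_l, shape: straight,
             rules: {straightness_tol: 0.1667}}
          - {id: gamma_arm_r, shape: straight,
             rules: {straightness_tol: 0.1667}}
          - {id: gamma_tail, shape: curved}
  - id: e
    glyph: "e"
    is_letter: true
    practice: false
    allographs:
      - id: primary
        features:
          - {id: e_curve, shape: curved}
  - id: wi
    glyph: "ゐ"
    is_letter: false
    practice: false
    allographs:
      - id: primary
        features:
          - {id: wi_top, shape: straight, rules: {straightness_tol: 0.1667}}
          - {id: wi_diag, shape: straight, rules: {straightness_tol: 0.1667}}
          - {id: wi_loop, shape: curved}
          - {id: wi_tail, shape: curved}
  - id: g
    glyph: "g"
    is_letter: true
    practice: false
    allographs:
      - id: primary
        features:
          - {id: g_bowl, shape: curved}
          - {id: g_hook, shape: curved}
  - id: R
    glyph: "R"
    is_letter: true
    practice: false
    allographs:
      - id: primary
        features:
          - {id: r_stem, shape: straight, rules: {straightness_tol: 0.1667}}
          - {id: r_bowl, shape: curved}
          - {id: r_leg, shape: straight, rules: {straightness_tol: 0.1667}}
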