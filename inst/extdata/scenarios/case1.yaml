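# Patient case 1: Th1 activity above, Th2 activity below healthy levels.
# Overrides are multiplicative factors on the healthy baseline; exactly ten
# parameters are perturbed per case, chosen among the production rates of
# Th1, Th2 and their polarizing cytokines. Provenance "nominal": authored
# for this package to realize the stated qualitative pattern (steady-state
# Th1 above and Th2 below healthy; TNF-alpha elevated).
label: case1
provenance: nominal
description: >
  Th1-dominant disease: elevated Th1 differentiation and IL-12 drive,
  reduced Th2/IL-4 axis, reduced IL-10 production, elevated TNF-alpha
  production.
overrides:
  v_T1:      2.0
  b_T1:      2.0
  v_T2:      0.5
  b_T2:      0.5
  v_12M:     1.8
  v_10M:     0.7
  v_10r:     0.7
  v_alpha_M: 1.5
  v_alpha_1: 1.5
  v_42:      0.8
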