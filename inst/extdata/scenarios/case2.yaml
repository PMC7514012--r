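# Patient case 2: Th1 activity below, Th2 activity above healthy levels.
# TNF-alpha production by macrophages is raised strongly so that TNF-alpha
# remains elevated (the pattern shared by all four cases) despite the low
# Th1 level. Provenance "nominal" (see case1.yaml).
label: case2
provenance: nominal
description: >
  Th2-dominant disease: reduced Th1 differentiation, elevated Th2
  differentiation, reduced IL-10/IL-4 output, strongly elevated
  macrophage-derived TNF-alpha.
overrides:
  v_T1:      0.55
  b_T1:      0.55
  v_T2:      2.2
  b_T2:      2.2
  v_42:      0.5
  v_alpha_M: 2.5
  v_alpha_1: 1.3
  v_10M:     0.6
  v_10r:     0.6
  v_12M:     1.4
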