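# Patient case 4: both Th1 and Th2 activities below healthy levels.
# TNF-alpha production carries its highest override here, reflecting the
# reported pattern that the TNF-alpha parameter is largest in case 4 and
# smallest in case 1 (fragmentary in the source; realized here through
# v_alpha_M). Provenance "nominal" (see case1.yaml).
label: case4
provenance: nominal
description: >
  Hypoactive helper-T compartments with strongly elevated innate
  (macrophage-derived) TNF-alpha; anti-inflammatory cytokines reduced.
overrides:
  v_T1:      0.5
  b_T1:      0.5
  v_T2:      0.5
  b_T2:      0.5
  v_alpha_M: 3.0
  v_alpha_1: 1.5
  v_10M:     0.7
  v_10r:     0.7
  v_12M:     0.9
  v_42:      0.8
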