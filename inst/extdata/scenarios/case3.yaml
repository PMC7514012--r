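# Patient case 3: both Th1 and Th2 activities above healthy levels; the
# anti-inflammatory cytokines IL-4 and IL-10 are also above healthy, the
# one case in which they are. Provenance "nominal" (see case1.yaml).
# Note: the source material fragmentarily reports an IFN-gamma coefficient
# raised to 194% of normal in this case; which exact coefficient cannot be
# determined from the available text, so it is recorded here and not
# enforced.
label: case3
provenance: nominal
description: >
  Mixed hyperactivation: both helper-T axes elevated together with both
  anti-inflammatory cytokines; TNF-alpha and IL-12 elevated.
overrides:
  v_T1:      1.9
  b_T1:      1.9
  v_T2:      1.9
  b_T2:      1.9
  v_10M:     1.5
  v_10r:     1.5
  v_42:      1.6
  v_alpha_M: 1.6
  v_alpha_1: 1.6
  v_12M:     1.9
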