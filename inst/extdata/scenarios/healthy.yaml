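# Healthy reference: the baseline with no overrides (all factors 1).
label: healthy
provenance: nominal
description: Healthy baseline; no parameter overrides.
overrides: {}
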