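# Nominal healthy-baseline configuration of the IBD immune network.
#
# All rate constants are per week; concentrations are in g/cm^3 (arbitrary
# nominal scale). Provenance "nominal" marks values authored for this
# package: the published network this model follows prints parameter
# definitions only, so the baseline is an order-of-magnitude-reasonable set
# calibrated to reproduce the qualitative patient-case sign patterns.
# Replace values (provenance "user") to transcribe an external
# parameterization without code changes.
name: healthy
provenance: nominal
time_unit: week

# State-vector order. The three drug-coupled cytokines (I_alpha, I_12, I_10)
# and the drug compartments (D_alpha, D_12, D_10) have built-in rate laws;
# every other species is governed by the [terms] registry below.
species:
  - M1        # inflammatory (M1) macrophages
  - M2        # tissue-repair (M2) macrophages
  - Th1       # type-1 helper T cells
  - Th2       # type-2 helper T cells
  - Th17      # type-17 helper T cells
  - Treg      # regulatory T cells
  - I_alpha   # TNF-alpha
  - I_12      # IL-12
  - I_10      # IL-10
  - I_gamma   # IFN-gamma
  - I_2       # IL-2
  - I_4       # IL-4
  - D_alpha   # anti-TNF-alpha antibody
  - D_12      # anti-IL-12 antibody
  - D_10      # recombinant IL-10

params:
  # -- TNF-alpha (built-in) --
  v_alpha_M:      1.0    # production of TNF-alpha by M1 macrophages
  v_alpha_1:      1.0    # production of TNF-alpha by Th1 cells
  delta_alpha:    2.0    # degradation of TNF-alpha
  # -- IL-12 (built-in) --
  v_12M:          2.0    # production of IL-12 by M1 macrophages
  zeta_10:        1.0    # half-saturation of IL-10 suppression of IL-12
  delta_12:       2.0    # degradation of IL-12
  # -- IL-10 (built-in) --
  v_10M:          1.0    # production of IL-10 by M2 macrophages
  v_10r:          1.0    # production of IL-10 by Treg cells
  n_2r:           0.5    # IFN-gamma aid / IL-2 interference coefficient
  zeta_2:         1.0    # half-saturation constant for IL-2 (see docs)
  delta_10:       2.0    # degradation of IL-10
  # -- drug parameters (built-in) --
  sigma_D_alpha:  2.0    # rate at which I_alpha is neutralized by D_alpha
  delta_D_alpha:  0.35   # clearance of anti-TNF-alpha (~2-week half-life)
  sigma_D_12:     2.0    # rate at which I_12 is neutralized by D_12
  delta_D_12:     0.35   # clearance of anti-IL-12
  v_D10:          2.0    # rate at which the drug acts as IL-10
  delta_D_10:     1.0    # total elimination of recombinant IL-10
  # -- macrophages --
  v_M1:           0.4    # basal M1 turnover source
  a_M1g:          0.4    # IFN-gamma-driven M1 polarization
  z_g:            1.0    # half-saturation, IFN-gamma on M1
  a_M1a:          0.3    # TNF-alpha autocrine activation of M1
  z_a:            1.0    # half-saturation, TNF-alpha on M1
  d_M1:           1.0    # M1 turnover
  v_M2:           0.4    # basal M2 turnover source
  a_M24:          0.4    # IL-4-driven M2 polarization
  z_4m:           1.0    # half-saturation, IL-4 on M2
  d_M2:           1.0    # M2 turnover
  # -- helper T cells --
  b_T1:           0.1    # basal Th1 differentiation
  v_T1:           1.0    # IL-12-driven Th1 differentiation
  z_12t:          1.0    # half-saturation, IL-12 on Th1
  z_s10:          1.0    # half-saturation, IL-10 suppression of Th1
  d_T1:           1.0    # Th1 turnover
  b_T2:           0.1    # basal Th2 differentiation
  v_T2:           1.0    # IL-4-driven Th2 differentiation
  z_4t:           1.0    # half-saturation, IL-4 on Th2
  z_sg:           1.0    # half-saturation, IFN-gamma suppression of Th2
  d_T2:           1.0    # Th2 turnover
  b_T17:          0.15   # basal Th17 differentiation
  a_T17a:         0.3    # TNF-alpha-driven Th17 expansion
  z_17:           1.0    # half-saturation, TNF-alpha on Th17
  d_T17:          1.0    # Th17 turnover
  b_Tr:           0.2    # basal Treg differentiation
  v_Tr10:         0.6    # IL-10-driven Treg expansion
  z_r10:          1.0    # half-saturation, IL-10 on Treg
  d_Tr:           1.0    # Treg turnover
  # -- remaining cytokines --
  v_g1:           2.0    # production of IFN-gamma by Th1
  d_g:            2.0    # degradation of IFN-gamma
  v_21:           2.0    # production of IL-2 by Th1
  d_2:            2.0    # degradation of IL-2
  v_42:           2.0    # production of IL-4 by Th2
  d_4:            2.0    # degradation of IL-4

# Term registry for the base-network species. Each term adds
#   sign * rate * prod(factors)
# to the target's derivative. Factor types:
#   linear:     X                  (fields: species)
#   saturating: X / (K + X)        (fields: species, K = parameter name)
#   inhibition: 1 / (1 + X / K)    (fields: species, K)
#   aided:      1 + n * A/(K + B)  (fields: aid, interfere, n, K)
# "decay" is shorthand for sign -1, linear in the target.
terms:
  - {target: M1, rate: v_M1}
  - {target: M1, rate: a_M1g,
     factors: [{type: saturating, species: I_gamma, K: z_g}]}
  - {target: M1, rate: a_M1a,
     factors: [{type: saturating, species: I_alpha, K: z_a}]}
  - {target: M1, type: decay, rate: d_M1}
  - {target: M2, rate: v_M2}
  - {target: M2, rate: a_M24,
     factors: [{type: saturating, species: I_4, K: z_4m}]}
  - {target: M2, type: decay, rate: d_M2}
  - {target: Th1, rate: b_T1,
     factors: [{type: inhibition, species: I_10, K: z_s10}]}
  - {target: Th1, rate: v_T1,
     factors: [{type: saturating, species: I_12, K: z_12t},
               {type: inhibition, species: I_10, K: z_s10}]}
  - {target: Th1, type: decay, rate: d_T1}
  - {target: Th2, rate: b_T2,
     factors: [{type: inhibition, species: I_gamma, K: z_sg}]}
  - {target: Th2, rate: v_T2,
     factors: [{type: saturating, species: I_4, K: z_4t},
               {type: inhibition, species: I_gamma, K: z_sg}]}
  - {target: Th2, type: decay, rate: d_T2}
  - {target: Th17, rate: b_T17}
  - {target: Th17, rate: a_T17a,
     factors: [{type: saturating, species: I_alpha, K: z_17}]}
  - {target: Th17, type: decay, rate: d_T17}
  - {target: Treg, rate: b_Tr}
  - {target: Treg, rate: v_Tr10,
     factors: [{type: saturating, species: I_10, K: z_r10}]}
  - {target: Treg, type: decay, rate: d_Tr}
  - {target: I_gamma, rate: v_g1,
     factors: [{type: linear, species: Th1}]}
  - {target: I_gamma, type: decay, rate: d_g}
  - {target: I_2, rate: v_21,
     factors: [{type: linear, species: Th1}]}
  - {target: I_2, type: decay, rate: d_2}
  - {target: I_4, rate: v_42,
     factors: [{type: linear, species: Th2}]}
  - {target: I_4, type: decay, rate: d_4}

# Default dose magnitudes per therapy: a short (1-day) infusion delivering
# dose_total units of drug; rate = dose_total / infusion_duration.
# Antibody doses are large relative to cytokine levels (as for therapeutic
# antibodies); the recombinant IL-10 dose is calibrated toward the typical
# patient IL-10 deficit so the therapy aims at, not far past, the healthy
# level.
dosing:
  dose_total:
    anti_tnf: 12.0
    anti_il12: 12.0
    il10: 1.5
  infusion_duration: 0.142857142857143   # 1/7 week = 1 day
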