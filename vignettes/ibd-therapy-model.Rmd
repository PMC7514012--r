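---
title: "Modeling biologic therapies for IBD: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling biologic therapies for IBD: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdtherapy)
```

## The model

Inflammatory bowel disease (IBD) is characterized by an imbalance between
pro-inflammatory cytokines (TNF-α, IL-12, IFN-γ, IL-2) and
anti-inflammatory cytokines (IL-10, IL-4), mediated by the helper-T-cell
response. `ibdtherapy` simulates a compartmental ODE model of this network
— M1/M2 macrophages, Th1/Th2/Th17/Treg cells and their signature cytokines
— coupled to three drug interventions, and evaluates how well each therapy
returns a patient's immune state to health.

Concentrations are in g/cm³ and time is in **weeks**; all rate constants
are per week, matching the weekly granularity of clinical dosing schedules.

Three drug mechanisms are built in:

* **Antibody neutralization** (anti-TNF-α, anti-IL-12). The antibody
  compartment `D` obeys `dD/dt = vM(t) − σ·I·D − δ_D·D`, and the target
  cytokine loses the same mass-action term `σ·I·D`. The symmetry of that
  term is a structural invariant: in a reduced system containing only
  neutralization, `I − D` is exactly conserved, and the test suite checks
  this numerically over 50 weeks.
* **Recombinant IL-10**. The injected protein `D_10` obeys
  `dD_10/dt = vM(t) − δ_D10·D_10` and feeds the endogenous IL-10 pool at
  rate `v_D10·D_10` — only a fraction of the injected protein acts as
  IL-10. We keep the drug equation exactly in this published form even
  though the `v_D10·D_10` source has no matching sink in `D_10`; `δ_D10` is
  interpreted as *total* elimination, conversion included. This is a
  documented modeling convention, not an oversight, and we deliberately do
  not "fix" it.

The IL-10 production law deserves a note. The printed source equation is
typographically garbled; we adopt the reading

    dI_10/dt = v_10M·M2 + v_10r·[1 + n_2r·I_γ/(ζ_2 + I_2)]·Treg
               − δ_10·I_10 + v_D10·D_10

because the accompanying prose states that IL-10 is produced by M2
macrophages and Treg cells, with IFN-γ aiding and IL-2 interfering with the
Treg contribution — which is exactly what the bracketed modulation factor
does. The factor is expressed through the configurable term machinery, so
an alternative reading can be swapped in from configuration. The
half-saturation constant `ζ_2` has no published definition beyond its
appearance in this equation; it lives in the baseline parameter set and is
flagged as such in the configuration file.

## The term registry

Only the three drug-coupled cytokine equations are printed in full by the
source material; the rest of the network is described as interaction
directions (IL-12 drives Th1; IL-4 drives Th2 and M2 polarization; IFN-γ
suppresses Th2 and activates M1; IL-10 suppresses IL-12 and Th1 and
supports Treg; TNF-α activates M1 and Th17; Th1 produces IFN-γ and IL-2;
Th2 produces IL-4). We therefore implement the base network as a **term
registry**: each species' derivative is a sum of terms
`sign · rate · ∏ factors`, with factor types

| type        | form              | used for                          |
|-------------|-------------------|-----------------------------------|
| `linear`     | `X`               | production proportional to a producer |
| `saturating` | `X/(K+X)`         | saturating (Hill-type) activation |
| `inhibition` | `1/(1+X/K)`       | suppression by a cytokine         |
| `aided`      | `1 + n·A/(K+B)`   | the IFN-γ/IL-2 Treg modulation    |

plus `decay` shorthand for first-order loss. The registry is configuration
(`inst/extdata/model_healthy.yaml`), validated on load, so a user holding
the full published parameterization of the underlying network can
transcribe it — species, rate laws and constants — without touching code.

## Nominal parameters and the four patient cases

The source material defines the parameters (production, degradation,
neutralization, clearance rates) but does not print their values. The
shipped baseline is therefore a **nominal** set: order-of-magnitude
reasonable rates (cell and cytokine turnover of order 1–2 per week,
half-saturation constants of order the resulting steady-state
concentrations), chosen once so that the four patient cases reproduce every
qualitative pattern stated for them, and marked `provenance: nominal` in
the configuration. The same applies to the drug parameters: antibody doses
are large relative to cytokine levels (as for real therapeutic antibodies,
dose 12 units vs cytokine steady states of order 0.3–1), antibody clearance
0.35/week corresponds to the ~2-week serum half-life typical of IgG
biologics, and the recombinant IL-10 dose (1.5 units at `v_D10 = 2`/week,
elimination 1/week) is sized toward the typical patient IL-10 deficit
rather than far past it. The calibration target is the *sanity property*
that under the standard schedule the target cytokine dips below its
pre-treatment patient level — which it does, by an order of magnitude at
the post-infusion peak.

Patients are classified by the steady-state balance of the two helper-T
axes relative to healthy:

* **case 1**: Th1 above, Th2 below;
* **case 2**: Th1 below, Th2 above;
* **case 3**: both above — the one case in which the anti-inflammatory
  cytokines IL-4 and IL-10 are also above healthy;
* **case 4**: both below.

TNF-α is elevated in *all* cases (its production override is largest in
case 4 and smallest in case 1). Each case multiplies exactly ten baseline
parameters — production rates of Th1, Th2 and their polarizing cytokines —
by nominal factors documented in `inst/extdata/scenarios/`.

One caveat is worth stating plainly. The literature this model follows
describes the taxonomy in terms of helper-T *activity* while also reporting
Th1 *concentrations* above healthy in all four cases; with a single Th1
compartment those two statements cannot hold simultaneously for cases 2
and 4 (activity and concentration are distinguishable only in the richer
source network). This package defines the taxonomy operationally on
steady-state concentrations — that is what `load_case()`,
`generate_synthetic_case()` and the tests enforce — and asserts the
all-cases elevation for TNF-α, where it is consistent.

## Dosing

`infliximab_schedule()` generates the standard biologic regimen: induction
at weeks 0, 2, 4 and 8, then maintenance every 8 weeks (for a 50-week
horizon: starts at 0, 2, 4, 8, 16, 24, 32, 40, 48). An infusion is modeled
as a 1-day (1/7-week) window at constant rate `dose_total/duration`;
infusion length and dose are knobs, not constants. Window membership is
half-open, `[start, start + duration)`, so boundaries are never counted
twice, and the integral of the forcing over the horizon equals
`dose · #windows` exactly.

Because the forcing is piecewise constant, the integrator is **restarted at
every window boundary** rather than asked to step across a discontinuity:
`simulate_therapy()` splits the horizon into segments on which `vM` is
constant and chains `lsoda` solves (rtol `1e-8`, atol `1e-10` by default),
sampling onto a uniform 0.01-week output grid. A halving of the tolerances
moves the occupancy statistics by far less than 0.1 percentage points (this
is a test), so the defaults are not load-bearing.

With non-negative parameters and initial conditions, every loss term in the
model vanishes as its compartment reaches zero, so trajectories cannot go
negative; the simulator treats any excursion below `−10·atol` as an
integration failure and raises a diagnostic instead of silently clipping.

## Steady states

`steady_state()` computes drug-free steady states (patient baselines and
the healthy reference) by integrating for 500 weeks and polishing with a
damped Newton iteration on the finite-difference Jacobian, to a residual
below `1e-10` in the max-norm. Drug compartments are held at zero — an
invariant set of the drug-free dynamics. Only the steady state reachable
from the given initial condition is reported; the nominal network appears
globally attracting in practice (the burn-in alone typically lands below
the tolerance), but no search for alternative equilibria is attempted.

Treatment simulations start at the patient's drug-free steady state with
empty drug compartments. A non-steady start is supported (`init` argument)
and simply lengthens the initial transient; the 14-week burn-in of the
analysis window (below) exists precisely to discount such transients.

## Evaluation statistics

**Healthy interval.** For each compartment, health is bracketed by the band
centered on the healthy steady state `h` with half-width half the
patient–healthy gap: `[h − |p−h|/2, h + |p−h|/2]`. **Occupancy** is the
percentage of the analysis window (weeks 14–50 of a 50-week treatment by
default; the first 13 weeks are discarded as initial-value-dominated) the
trajectory spends inside the closed band, computed by counting grid points
on the uniform output grid — matching the percentage granularity of the
statistic; refining the grid below 0.01 weeks moves occupancies by less
than 0.1 points. A patient already at the healthy level has a zero-width
band; membership is tested with absolute tolerance `1e-9·h` so such a
compartment scores 100%, not 0% — the statistic measures departure from
health. Whether near-misses should count with any wider tolerance is
unknowable from the source; we use the tolerance only to rescue the exact
degenerate case.

**Ratios.** Pro/anti-inflammatory balance is summarized by ratio time
series over the window for configured pairs (defaults: TNF-α and IL-12
against IL-10 and IL-4, plus Th1/Th2 and Th1/Treg), reporting min and max
(the system oscillates over each dosing cycle) and the percent change
against the healthy steady-state ratio. Grid points where the denominator
is not strictly positive are excluded and counted as flagged gaps rather
than propagating infinities. The pro/anti group membership is
configuration; the defaults are the compartments this literature names.

**Fold changes.** Case-vs-healthy steady-state ratios, grouped as
pro-inflammatory cytokines, anti-inflammatory cytokines and immune cells.

## Synthetic patients

`generate_synthetic_case(taxonomy, seed, spread)` models patient
heterogeneity: each of the case's ten override factors is perturbed by an
independent log-normal multiplier (median 1, log-sd `spread`, default 0.2 —
roughly ±20% parameter variability, a typical inter-individual scale for
immune kinetic rates), and draws are rejected until the steady state
satisfies the case's Th1/Th2 sign pattern. Rejection sampling was chosen
over constrained optimization deliberately: it is simple, auditable, and
its acceptance rate is itself a diagnostic — at the default spread nearly
every draw is accepted (the nominal cases sit well inside their taxonomy
regions), while larger spreads lower the rate and flag how sharply the
taxonomy constrains heterogeneity. Generation is deterministic given the
seed and leaves the global RNG untouched.

## Problem sizes and limitations

The shipped analyses use a 15-compartment network, 50-week horizons at a
0.01-week output grid (5001 points), and batches of tens of synthetic
patients — desk-scale sizes chosen so a full case × therapy matrix runs in
seconds and the complete test suite in well under a minute.

What passing tests show — and what they do not: the suite verifies the
structural properties of the equations (closed forms, conservation,
drug-free equivalence, monotone suppression), the exact arithmetic of the
evaluation statistics, and that the nominal scenarios realize the
qualitative disease patterns. Because the baseline is nominal rather than
transcribed from a published parameter table, *quantitative* outputs
(occupancy percentages, ratio extrema) characterize this package's study
conditions, not any published patient cohort; they become comparable to
published figures only after a user transcribes the source network's
values into the configuration. The model also omits, by design:
pharmacokinetic distribution compartments and body-weight-based dosing
(the dose is an abstract concentration), parameter fitting to clinical
data, Th17-pathway cytokines and B-cell extensions, spatial structure, and
any claim that one drug is clinically superior to another.
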