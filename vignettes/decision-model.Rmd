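---
title: "A tunnel-state Markov model for prostate-biopsy cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A tunnel-state Markov model for prostate-biopsy cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biopsycea)
```

## The decision problem

Prostate biopsy can be performed transperineally (TP), without antibiotic
prophylaxis, or transrectally (TR) with rectal-swab-targeted prophylaxis.
The two approaches trade off differently: TP has higher disposable-equipment
costs and more immediate procedural pain; TR adds the swab and antibiotic
costs and carries higher probabilities of post-biopsy infection and urinary
retention. `biopsycea` asks which strategy a health-care payer should prefer
over the two weeks following a single office-based, MRI-guided biopsy, in
2024 US dollars and quality-adjusted life years (QALYs), at a
willingness-to-pay of $100,000/QALY.

## Model structure

The cohort model has five health states — Healthy, Infection, Urinary
Retention, Combined (both complications), Recovered — advanced in 1-day
cycles over a 14-day horizon. The complication states are *tunnel states*:
time in state is fixed by unrolling each into per-day sub-states. Infection
lasts exactly 7 cycles, retention 3, and Combined 3 cycles before the
infection continues on its own tunnel (day 4 onward) once the retention has
resolved. Everyone starts Healthy.

Complication risks are observed as 7-day cumulative probabilities $p$ and
converted to constant daily hazards $r = -\ln(1-p)/t$ with $t = 7$ days, so
the per-cycle probability is $1 - e^{-r}$. New complications can arise only
during the 7-day event window (no complications are observed later), after
which the model simply lets the tunnels run out.

### Independent first-event hazards

Each complication is modelled as a *first-event* process whose daily hazard
applies to everyone who has not yet had that complication: the infection
hazard reaches Healthy patients, patients in the retention tunnel, and
patients whose retention has already resolved (held in an explicit
`PostRetention` bookkeeping state, at full health but still at risk inside
the window); the retention hazard reaches Healthy patients and the
infection tunnel. Joint acquisition — on the same day from Healthy, or one
complication striking during the other's tunnel — routes to the Combined
tunnel. Two properties recommend this structure:

* cumulative incidence is exact in closed form: entries into the infection
  tunnel integrate back to precisely $p_\mathrm{inf}$ (and retention to
  $p_\mathrm{ret}$), so a 1.6% 7-day input yields exactly 16.0 infections
  per 1000 patients — the alternative, complications arising from Healthy
  only, suppresses incidence by 0.5–1.5% through competing-risk depletion
  and makes the printed per-1000 counts unreachable;
* the Combined state is reachable with non-negligible probability. Under a
  Healthy-only structure the only route is same-day joint acquisition
  (~2.5 per *million* daily), which would make a dedicated Combined state
  pointless; sequential acquisition is what actually populates it.

One second-order consequence is accepted: patients who pass through
Combined re-enter the infection tunnel and are again exposed to the
retention hazard, inflating retention incidence by < 1e-7 — far below
every tolerance in the test suite.

Events are counted by state *entry* (incidence), not occupancy, and
complication treatment costs are charged once per entry; this is the only
accounting under which the treatment-cost lines equal incidence times unit
cost.

## Parameters

All parameters live in two registries: [strategy()] (per-arm) and
[shared_parameters()] (common), overridable via [load_config()] YAML/JSON
files.

| parameter | TP | TR | units / note |
|---|---|---|---|
| infection, 7-day | 0 | 1.6% | trial-observed |
| retention, 7-day | 0.3% | 1.1% | trial-observed |
| MRI / procedure fee | 466 / 2066 | 466 / 2066 | US$, common "fixed bundle" ($2532) |
| disposables (gross) | 218.92 | 57.03 | US$ |
| antibiotics / swab | — | 5.51 / 91 | US$ |
| pain utility, duration | 0.83, 1 h | 1, — | see below |

Shared: treatment costs $8399 (infection), $1776 (retention), $23,435
(sepsis); utilities 1.00 healthy/recovered, 0.74 infection, 0.87 retention,
0.51 sepsis; willingness-to-pay $100,000/QALY.

The pain utility encodes a 1.2-fold higher immediate post-procedural pain
score for TP (utility $1/1.2 = 0.83$) assumed to persist one hour: cycle 1
contributes $0.83 \times 1/24 + 1 \times 23/24$ for TP patients still
Healthy. Durations beyond 24 h spill into later cycles.

### Disposable-cost accounting

Strategy totals count disposables **net of the standard transrectal kit**
($57.03, the `cost_disposables_baseline` shared parameter): TR's disposable
line enters as $0 and TP's as $218.92 − 57.03 = $161.89. This is the
accounting identity under which the per-strategy totals and all four
published totals this model reproduces are internally consistent; every
*incremental* quantity (the decision-relevant surface) is invariant to the
choice of baseline. A frequently-quoted per-arm disposable figure of
$218.89 is exactly net + rounded baseline ($161.89 + 57$), i.e. a display
artifact, so the registry keeps only the gross $218.92.

### QALY accumulation

QALYs accumulate over `horizon_days + 1 = 15` daily slots (cycle-0
occupancy through cycle 14), each contributing the occupancy-weighted mean
utility × 1/365 year. Perfect health over the horizon is therefore
$15/365 = 0.0410959$. This slot convention and `days_per_year = 365` are
the unique simple pair under which the published QALY totals are
reproduced to ~1e-6; no half-cycle correction is applied (the horizon is
14 cycles and the calibration succeeds without one). The Combined state's
utility is the product $u_\mathrm{inf} \times u_\mathrm{ret}$
(multiplicative disutility; the choice moves totals by < 1e-6 QALY).

Sepsis is an overlay on the infection tunnel, not a separate state: a
fraction $p_\mathrm{sep}/p_\mathrm{inf}$ of infection entrants carries the
sepsis utility and the incremental sepsis treatment cost. (The published
scenario QALYs are consistent with sepsis applied to costs only; this
package applies the utility as well, since a sepsis utility is part of the
parameter set — the difference touches no reported cost or count.)

## Decision metrics

[compare()] reports incremental cost and QALYs (comparator − reference),
the ICER $\Delta C/\Delta Q$ where informative, a dominance verdict
otherwise, and net monetary benefit $\mathrm{NMB} = \lambda Q - C$. All
threshold and acceptability decisions use the NMB comparison, which agrees
with the ICER rule in every quadrant without its sign ambiguity (a
property-based test exercises the equivalence).

`cost_per_event_prevented` adds the event's treatment-cost difference back
to the incremental cost before dividing by events prevented per 1000:
$(\Delta C + \Delta C_\mathrm{event})/\Delta n_\mathrm{event}$. This
isolates what is spent beyond the complication treatment itself to avoid
one event. For sepsis the add-back is the full infection cost line, of
which sepsis treatment is a part. The same construction reproduces five
independently published values across the base case and two scenarios,
which is the evidence for it; it is an inferred definition, stated here
prominently because it is a design choice, not a universal convention.

## One-way thresholds

[one_way_threshold()] brackets a verdict flip on a 65-point scan of the
parameter range, then bisects to a relative precision of 1e-6. Parameters
whose margin is affine in the parameter (all unit costs) are
cross-checked in the tests against an exact two-point linear solve. The
pain-*utility* row never flips the NMB verdict on $[0,1]$ — TP's QALY
advantage would have to reverse *and* overcome its cost advantage — so
that row is additionally reported under an incremental-QALY criterion
(where does TP stop being more effective), which flips near 0.22.

## Probabilistic sensitivity analysis

[run_psa()] draws all parameters simultaneously each replicate: beta
distributions for probabilities and utilities, gamma for costs, fitted by
method of moments. Variance choices, in order of preference:

* trial-reported SDs where they exist (utility 0.74 ± 0.02 infection,
  0.87 ± 0.03 retention);
* binomial sampling variance $\sqrt{p(1-p)/n}$ for the observed
  complication probabilities, with a configurable arm size (default
  `arm_size = 375`; the trial denominators are not part of the parameter
  table, so this is an assumption surfaced as an argument);
* otherwise SD = 20% of baseline (all costs, the sepsis utility, the pain
  utility).

A probability observed at **zero** events (TP infection) has zero
trial-reported sampling variance and stays fixed at 0 by default
(`zero_prob = "fixed"`). A Jeffreys-style `beta(0.5, n + 0.5)` alternative
is available (`zero_prob = "jeffreys"`); it shifts the median infections
prevented down by roughly 1.3/1000, and the fixed default is the variant
consistent with the published PSA medians. Pain *duration* is an
assumption, not a measured parameter, and is exercised in the one-way
analysis instead of the PSA. Costs genuinely common to both arms (MRI,
procedure fee) share one draw per replicate so they cancel in the
comparison; arm-specific costs draw per arm; shared parameters draw once
and apply to every strategy.

CEACs are computed on a $0–$2,000,000 grid ($10,000 steps) as the fraction
of draws in which each strategy has the highest NMB, ties broken toward
the reference (a measure-zero event, broken deterministically). With 5000
draws the acceptability of TP is lowest at $\lambda = 0$ — a pure cost
comparison, where the gamma-distributed infection-treatment line gives TR
its best chance — at about 0.87 under the default variance assumptions,
rising above 0.95 near $1.7M/QALY. A published floor of ≥ 0.89 across all
thresholds is *not* reproduced under binomial arm-size-375 variances; the
20%-SD-rule variant that would clear it is inconsistent with the published
PSA interquartile ranges, so the package keeps the trial-variance rule and
reports the floor honestly (the corresponding acceptance test is expected
to fail and documents why).

## The microsimulation oracle

[simulate_patients()] is the brute-force validator: per patient, daily
Bernoulli draws over the event window for each first-event process,
explicit tunnel mechanics, and the same accounting rules, so its sample
means must converge to the cohort engine's expectations at $1/\sqrt{n}$.
The test suite checks agreement within 3 Monte Carlo SEs at $n = 200{,}000$
for cost, QALY and both event rates, and separately re-derives each
simulated patient's cost and QALY from the expanded per-day state sequence
([trajectories()]) with a naive per-slot summation written independently
of the vectorized accountant — guarding against a bug shared between
engine and oracle.

What the simulation emulates is exactly the model's event structure — it
is a variance-bearing version of the same assumptions, not real-world
data. Passing oracle tests therefore shows internal consistency (the
deterministic trace is the correct expectation of the stochastic process),
and nothing about, e.g., hazard non-constancy, complication dependence, or
late complications in real patients.

## Numerical choices and degenerate inputs

* Transition-matrix rows are validated to sum to 1 within 1e-12; cohort
  mass is conserved within 1e-10 per cycle (both enforced, not just
  tested).
* Rate conversions use `log1p`/`expm1`; the round trip
  $p \to r \to p_\mathrm{daily} \to p$ is exact to 1e-12 on $[0, 0.999]$;
  $p = 1$ is a domain error (no finite hazard), negative inputs are
  validation errors.
* `p_sepsis > p_infection` is rejected at construction; a drawn sepsis
  probability exceeding its drawn infection probability in the PSA is
  clamped to it.
* A beta fit with sd$^2 \ge m(1-m)$ or mean on the boundary is an error,
  not a silent fallback; degenerate parameters must be declared fixed.
* Zero-variance PSA (`sd_scale = 0`) reproduces the base case bit-for-bit,
  which the tests assert with `identical()`.
* Monetary values are kept at full precision throughout; rounding to cents
  happens only in printing.

## Problem sizes

The shipped analyses use the model's native sizes: a deterministic cohort
(15 slots × 16 states), 5000 PSA replicates (the acceptance suite repeats
this over five seeds), and 200,000 microsimulation patients for the oracle
comparison. A full test-suite run takes a few minutes, dominated by the
repeated-seed PSA.

## Known limitations

* Two published per-patient quantities sit just outside their strictest
  reproduction bands: the TR total cost (ours $2782.43 vs $2782.84) and
  the infection-treatment-cost threshold (ours ~$2767 vs $2744.05). Both
  inherit the same root cause — the published per-1000 incidence carries a
  small positive excess (16.03 vs the closed-form 16.00; 11.08 vs 11.00)
  that is not derivable from the stated model structure under any variant
  we tried (Healthy-only, cross-acquisition, rate-as-probability,
  recovered-re-exposure). The corresponding acceptance tests are left
  failing rather than tuned.
* The published empiric-prophylaxis arm's infection-cost line ($883.27) is
  not reproducible from its stated incidence and unit costs (ours:
  $718.50); all *incremental* metrics are invariant to this line and do
  reproduce.
* No death state, no discounting (two-week horizon), no cancer-detection
  outcomes, no societal perspective or antibiotic-stewardship valuation —
  all out of scope by design.
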