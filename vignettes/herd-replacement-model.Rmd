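---
title: "A monthly Markov replacement model for dairy herds with abortion dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A monthly Markov replacement model for dairy herds with abortion dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdabort)
```

## The model

A dairy herd is treated as a population of independent, exchangeable cows
evolving on a monthly clock. Each cow is described by her parity `PAR`
(number of calvings, 1–15), gestation month `PREG` (0 = open, 1–9; calving
at 9), and month in lactation `MIL` (1–24). Because insemination starts in
the second lactation month, gestation month $p$ can first be observed at
`MIL` $= p + 2$; the 54 `(PREG, MIL)` combinations violating this are
structurally infeasible, leaving 186 of the nominal 240 combinations per
parity and $186 \times 15 = 2790$ base-model states (nominal matrix order
$3600$).

The extended model adds a fourth coordinate `AB` for abortion history:
0 = never aborted, 1 = rebreeding abortion (RA: the fetus is lost, the cow
keeps lactating in the same parity and is re-inseminated), 2 = new-lactation
abortion (NLA: the cow starts a new lactation, incrementing parity). This
triples the space to 8370 states (nominal order 10 800).

Each month, competing risks resolve in a fixed order:

1. **Exit.** Death (probability `mortality[MIL, class]`) and involuntary
   culling (`inv_cull[MIL, class]`, multiplied by 1.9 for cows with abortion
   history in the extended model) remove the cow; she is immediately
   replaced by a heifer in the initial state `(AB=0, PAR=1, PREG=0, MIL=1)`,
   which keeps the herd-level chain row-stochastic and irreducible on its
   reachable class.
2. **Voluntary culling.** A surviving open cow whose `MIL` equals the policy
   threshold for her parity class is replaced. The threshold acts at the
   moment the cow *reaches* it: a cow pushed past the threshold by an
   abortion is not retroactively culled — she is re-inseminated while
   conception rates remain positive (through `MIL` 15) and is force-replaced
   at `MIL` 24 otherwise. This reading is what lets the rebreeding-abortion
   pool accumulate; the alternative ("cull at any `MIL` at or beyond the
   threshold") empties the RA compartment within a month of each abortion
   and cannot reproduce the reported herd composition.
3. **Reproduction.** Surviving open cows conceive with the monthly
   class-specific pregnancy rate or stay open, aging one lactation month.
   Pregnant cows abort with a gestation-month hazard (3.5, 2.5, 1.5, 0.5,
   0.25, 0.1, 0.1 % for months 2–8, totalling 8.45 %; month 1 abortions are
   undetectable and month 9 is calving). An abortion at `PREG` $\le 2$ is
   not recorded (`AB` unchanged, cow continues open at `MIL`+1). A later
   abortion is RA with probability $1 - 1.9/12.5 \approx 84.8\,\%$ and NLA
   otherwise; `AB` is updated monotonically (`AB` $\gets \max$(`AB`, type))
   and persists through subsequent calvings — only replacement resets it.
   Calving moves the cow to `(PAR+1, 0, 1)`; completing parity 15 forces
   replacement.

Primiparous means `PAR = 1` for the rate tables; the milk curve's
second-parity column covers parities 1–2 and its mature column parities 3+.

The stationary distribution $\pi$ ($\pi P = \pi$) is the long-run herd
structure; every reported quantity is an expectation under $\pi$.

## Parameters

* **Biology** (`default_rates()`): monthly conception, mortality and
  involuntary-culling probabilities by lactation month and parity class
  (Cabrera's 2012 herd parameters), the De Vries gestation-month abortion
  hazards, and the Keshavarzi RA/NLA odds `1.9/12.5`. All probabilities;
  validated so that mortality + culling + conception never exceeds 1 in any
  month.
* **Abortion effects** (`default_effects()`): milk-yield reductions of
  7.3 % (RA) and 19.4 % (NLA) and the 1.9× involuntary-culling multiplier.
  The multiplier applies to involuntary culling only, not mortality, and is
  capped so the exit mass never exceeds 1. `conception_reduction` (default
  0) scales the conception rate of aborted cows for the sensitivity
  analysis.
* **Economics** (`default_scenario()`): milk 0.36 USD/kg, calf 100 USD,
  carcass 1.16 USD/kg, replacement heifer 1300 USD, veterinary cost 50 USD
  per calving, feed 0.17 (lactating) / 0.13 (dry) USD/kg DM, DMI 25 kg/day,
  30-day months, and the parity-class milk curve (kg/month, lactation
  months 1–10; months 11–12 carry the month-10 yield forward; no milk is
  sold past month 12).

### Gaps the published tables leave open

Four economic inputs are needed by the cash-flow identity but appear in no
published table; they are shipped as explicit, overridable scenario fields:

* **Carcass weight** (563 kg) and **AI cost** (35 USD/service). These two
  were fixed by a single calibration pass against the two cleanest published
  anchors. The month-2 culling policy admits no insemination, calving or
  abortion at all, so its net value (−8.76 USD/cow/month) is determined by
  milk, feed, mortality and the salvage/replacement flow alone — solving it
  for the carcass weight gives 563 kg, a realistic live weight for a cull
  Holstein at 1.16 USD/kg. With salvage fixed, the level of the sweep
  optimum pins the AI cost near 35 USD/service (semen plus technician),
  inside the usual 15–50 USD range. Both values are ordinary scenario fields
  and can be overridden.
* **Veterinary cost basis**: charged per calving event (configurable by
  editing the cash-flow inputs); **twin-calving loss**: 0 by default.
* **Milking window**: milking is governed by the lactation month alone
  (maximum 12 months milked), because the published milk table and milking
  rule are keyed on `MIL` only and no gestation-based dry-off is described;
  the dry feed price applies to lactation months beyond the milking window.
  A conventional dry-off two months before calving can be imposed with
  `dry_off_preg = 8`, which lowers mid-sweep net values by roughly 7 %.

Salvage is credited for culled cows only — a cow that dies yields no
carcass revenue. AI is charged to open cows in the insemination window
(`MIL` ≥ 2, positive conception rate) that are not scheduled for voluntary
culling that month, one service per open month.

## Cash flow

Per state $c$ and month, with event probabilities from the kernel:

$$\mathrm{net}_c = \mathrm{IOFC}_c + \mathrm{calf}_c + \mathrm{salvage}_c
  - \mathrm{replacement}_c - \mathrm{AI}_c - \mathrm{vet}_c -
  \mathrm{twins}_c,$$

where $\mathrm{IOFC}_c = \text{milk}_c \times \text{price} - \text{DMI}
\times \text{days} \times \text{feed cost}$ is income over feed cost and the
event-weighted terms use the calving and exit probabilities of state $c$.
The herd value is $\sum_c \pi_c\,\mathrm{net}_c$ (USD per cow per month); no
discounting is applied — the "present value" of the stationary herd is its
expected monthly value, and the annual figure is 12 times it. All components
are linear in $\pi$ and in their prices, which the tests exploit.

## Numerical choices

* **Stationary solve.** Default is a direct sparse LU solve of
  $(P^\top - I)\pi = 0$ on the communicating class reachable from the
  heifer state (found by breadth-first search), with the normalization
  $\sum_i \pi_i = 1$ replacing one balance equation; unreachable feasible
  states (e.g. `AB = 2` with `PAR = 1`) get exact zeros. Power iteration
  (tolerance $10^{-12}$ in the $\infty$-norm, cap $10^6$ iterations) is
  retained as an independent cross-check; the two agree to $10^{-12}$ on
  the full extended model and every solve is verified to a stationarity
  residual below $10^{-10}$.
* **Enumeration order** is lexicographic in `(AB, PAR, PREG, MIL)`, making
  matrices and reports byte-reproducible.
* **Degenerate rows.** Open cows at `MIL` 24 and (structurally present but
  unreachable) pregnant cows at `MIL` 24 are force-replaced so that every
  row of the kernel is a probability distribution for any parameter set.
* **Capping.** If the culling multiplier would push a row's exit mass past
  1 it is capped at the survival budget and counted in `n_capped` (never
  triggered by the packaged parameters).

## Validation and what it shows

Three independent routes check the implementation:

1. **Published steady state.** The base model under the validation policy
   (cull open primiparous cows at `MIL` 11, multiparous at 10) reproduces
   the published second-parity `MIL × PREG` table cell-by-cell; the
   `validate` workflow reports the maximum relative difference (0.5 % with
   the packaged inputs, inside the ±2 % acceptance band; the original
   publication itself deviates by up to ~1 % from *its* reference).
2. **Abortion-history composition.** Under the optimal policy (primiparous
   threshold 6, multiparous 10) the extended model's stationary mass with
   abortion history matches the published 2.96 % (2.37 % RA, 0.59 % NLA)
   to two decimals — a sharp joint test of the hazards, the RA/NLA split,
   the culling-timing rule and the `AB` bookkeeping.
3. **Monte-Carlo cohort.** `simulate()` advances 10⁴ cows for 600 months by
   multinomial partition of per-state counts (distributionally identical to
   per-cow sampling from the same kernel) and averages occupancy over the
   final 120 months: total-variation distance to the analytic $\pi$ is
   ~0.005, and the simulated net benefit falls within sampling error
   (batch-means standard errors) of the analytic value.

The culling-month sweep applies the threshold to both parity classes (the
published comparison table has a single threshold column, and its full
dynamic range is only attainable when the whole herd's policy moves). Its
optima match the published values to ~0.2 % (178.54 vs 178.77 extended,
178.16 vs 178.08 base). Two fine-grained features of the published table are
*not* reproduced and are left as documented discrepancies rather than being
fitted: our maximum sits at month 7 rather than 6 (the two months differ by
about 1 USD, under 1 % of the net value, a margin governed by cost terms the
publication does not itemize), and the base/extended difference column,
while positive through month 8 and of the right size at the optimum (0.64
vs 0.69), declines at long thresholds instead of growing to 2.52. The
stationary structure itself is reproduced essentially exactly, so these
residuals are economic-accounting differences, not chain errors.

## The randomized-table fixture and its limits

`random_rate_tables(seed)` draws rate tables satisfying every structural
invariant (probability ranges, the per-month risk budget, hazard support on
gestation months 2–8, a split summing to 1) with conception confined to the
eligible window (months 2–15), and is deterministic per seed. It emulates
the *shape* of real herd parameter tables, not their smoothness or
correlation over lactation months: passing the 100-seed stationarity and
stochasticity suites demonstrates that the kernel, solver and accounting are
correct over the whole legal parameter region, not that any particular herd
is well described. Field data differ in ways the generator does not model —
seasonality, heat stress, parity-specific abortion risk, disease states
other than abortion, and correlated month-to-month rates.

## Problem sizes

The test and acceptance workloads use the model at its natural size — 2790
(base) and 8370 (extended) states; a full two-model sweep over fourteen
thresholds solves 28 stationary systems in well under a minute, and the
validation cohort uses 10⁴ cows over 600 months. The equivalence and
invariant suites run the base-model space with 10–100 randomized tables.

## Known limitations

* Threshold policies only: the model optimizes a voluntary-culling month,
  not a full state-dependent replacement action space.
* The extra non-pregnancy days that field studies attribute to abortion
  types (+132 days RA, −15 days NLA) are not part of the state dynamics;
  the `conception_reduction` sensitivity bounds their direction — net
  benefit declines monotonically as aborted cows' conception is reduced.
  With abortion-history prevalence near 3 % the aggregate effect is small
  (on the order of 0.1 USD/cow/month across a 2–60 % reduction grid);
  definitions that perturb the whole herd's conception instead would give
  much larger figures, and published numbers of this kind are sensitive to
  that choice.
* Monetary outputs inherit the uncertainty of the unpublished economic
  inputs (AI cost, carcass weight, veterinary basis, twin loss); the
  structural results (herd composition, prevalence, sweep shape) do not.
* One cow at a time: no herd-level constraints (quota, housing) or price
  dynamics.
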