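---
title: "Benchmarking antimicrobial usage: ATI versus nDDDch/animal/year"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking antimicrobial usage: ATI versus nDDDch/animal/year}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amubench)
```

## The two indicators and why they disagree

Treatment-frequency indicators for antimicrobial usage (AMU) answer the
question *how often is an average animal on this farm treated per year?*
Two constructions are in common use:

* the **Animal Treatment Index (ATI)** counts applications directly:
  one treatment is one application to one animal on one day, and each
  active agent of a combination product counts separately. For a therapy
  event, `NT = n_animals * n_days * n_agents`; the ATI is the farm-year sum
  of NT divided by the yearly animal denominator.
* **nDDDch/animal/year** counts *defined daily doses*: the administered
  mass of each active substance is divided by `DDD (mg/kg/day) * SW (kg)`,
  where DDD is the nationally defined daily dose and SW the standard
  weight of the age category (4 kg suckling piglets, 12 kg weaned piglets,
  50 kg fattening pigs, 220 kg sows). The per-substance dose counts are
  summed and divided by the same denominator.

The denominator counts animals *housed* per year for the two sow
categories and animals *produced* per year for the growing categories,
reflecting how a breeding herd versus a throughput category is censused.

Algebraically, one event's contribution to nDDDch is
`amount / (DDD * SW) = (applied_dose / DDD) * (true_weight / SW) * n_animals * n_days`.
If every treatment were dosed exactly at the national DDD for an animal of
exactly standard weight, the first two factors would be 1 and nDDDch would
equal NT *identically* — the indicators can only disagree through dose and
weight deviations. That identity is the backbone of this package's test
suite (the "identity limit"), and its violation in practice — farmers
dose per label of a concrete product, animals are not at standard weight —
is what the agreement analysis quantifies. Changing the dosage changes the
number of defined daily doses but never the number of treatments.

## Inclusion filters

Four filters precede any computation, mirroring the data-quality rules of
an electronic-journal monitoring programme. Each returns the kept journal
plus a validation report whose counts always reconcile
(`n_input = n_kept + n_rejected`):

1. **Study window** (default 2018-10-01 to 2019-09-30): events applied
   outside are rejected (`out_of_window`).
2. **Entry lag**: entries made more than 7 days after application violate
   the programme's recording requirement (`entry_lag`). The boundary is
   inclusive: lag 7 is kept, lag 8 rejected. The filter removes *records*,
   not farms; per-farm rejection fractions remain auditable from the
   report, so a stricter whole-farm policy can be applied downstream.
3. **Continuous recording**: a farm/category is only analysable if its
   census entry exists and is flagged as continuously recording. Journal
   sparsity alone cannot distinguish a low-usage farm from a non-recording
   one, so the census flag is authoritative.
4. **Plausibility caps** for records "clearly identified as incorrect".
   No published quantification of that phrase exists, so the defaults are
   deliberately loose, intended to catch data-entry errors only: at most
   20,000 animals per event, at most 365 treatment days, and an implied
   per-kg-per-day dose of at most 10 x the catalog DDD (an order of
   magnitude above label dosing). All three caps are arguments of
   `plausibility_rules()`. A substance missing from the catalog rejects
   the record (`unknown_substance`) rather than crashing a batch run.

## Benchmarking and tie handling

Within one age category, farms are ranked descending by one indicator and
the top `round_half_up(fraction * n)` are flagged high-usage. Two
decisions here were genuinely open:

* **round-half-up** for the target count: symmetric, explainable, and
  exact for the cohort sizes of interest (e.g. 25 % of 360 farms = 90).
* **ties at the cut**: the whole tie group is included and the
  classification carries a `tie_flag`. Excluding tied farms by input order
  would make Kappa depend on row order; the tie rule is order-free, which
  the suite verifies by permutation. Zero-usage farms get explicit zero
  rows so they enter the ranking — omitting them would bias the percentile
  thresholds upward.

## Agreement statistics

* **Percent agreement**: share of farms rated identically by both
  indicators, `100 * (n11 + n00) / n`.
* **Cohen's Kappa**: `(p_o - p_e) / (1 - p_e)` on the 2x2 high/low table.
  When both classifications are constant the formula is 0/0; the package
  returns 1 for perfect agreement and 0 otherwise, always with a
  `degenerate` attribute, keeping batch runs total while making the
  convention auditable.
* **Spearman's Rho** on the continuous values, computed as the Pearson
  correlation of mid-ranks. Mid-ranks (average ranks for ties) matter
  because zero-usage farms tie heavily at the bottom. A constant vector
  has no defined rank correlation and yields a flagged `NA`. A
  Shapiro-Wilk-style normality gate is deliberately *not* wired into the
  pipeline: rank statistics are used unconditionally, so a normality flag
  would not change any output.
* **Bland–Altman**: per-farm differences `ATI - nDDDch/animal/year`
  against their means, limits of agreement `mean ± 1.96 * SD` with the
  sample SD (n-1; the conventional choice — no published variant states
  otherwise), outliers strictly outside the limits. A tiny absolute
  tolerance (1e-12 x data scale) guards the degenerate all-equal case
  against floating-point noise, so the identity limit reports exactly zero
  outliers.

## The synthetic-data generator

The generator is the package's stated world: it produces cohorts with the
structure the analysis assumes, so every claim the tests make is a claim
about this world, not about any real herd population.

* **Farm types and counts** default to the published cohort composition:
  399 fattening, 14 plain breeding, 190 sow-pool-affiliated and 277
  farrow-to-finish farms (880 total). Sow-pool farms house either
  lactating sows + suckling + weaned piglets, or gestating sows only,
  drawn per farm.
* **Herd sizes** are log-normal around the published per-category medians
  (2,200 suckling, 2,000 weaned, 1,050 fattening produced; 22 lactating,
  75 gestating sows housed) with log-sd 0.8, which reproduces the order of
  magnitude of the published min–max ranges (weaned piglets 100–15,000).
* **Therapy events** per farm-year and category are negative-binomial
  (default means 4–6, dispersion 1.2 — free parameters; no per-event
  distributions are published, so these are chosen once for plausible
  magnitudes and documented here). Group sizes are a Beta(1.2, 6) fraction
  of the *standing* herd (annual production divided by a per-category
  turnover: 10 suckling, 8 weaned, 3 fattening, 1 sows), durations follow
  a truncated geometric on 1–14 days.
* **The divergence mechanism**: each substance draw carries a dose
  multiplier `dose_bias * exp(dose_sigma * z)` and each event a weight
  multiplier `exp(weight_sigma * z_w)`; the administered amount is
  `DDD * multipliers * SW * n_animals * n_days`. At
  `dose_sigma = weight_sigma = 0` the identity limit holds exactly; as
  `dose_sigma` grows, nDDDch drifts while NT is untouched. Because the
  normal draws `z` are taken regardless of sigma and each farm has its own
  counter-derived seed stream, runs with different sigmas share an
  identical event structure — this pairing is what makes the monotone
  rho-versus-sigma property testable without Monte-Carlo slack.
* **Corruption**: a configured fraction of events is corrupted for filter
  testing, half by multiplying amounts by 100 (caught by the dose cap),
  half by entry lags of 8–30 days (caught by the lag rule). The truth
  tables record which events were corrupted, so recovery can be checked on
  the kept subset.
* **Truth**: exact NT/nDDD per farm, category and class are computed from
  the generative multipliers directly (not by re-dividing the amounts),
  giving an algebraically independent bookkeeping route; the pipeline must
  reproduce it to 1e-9 relative error.

What the generator does **not** emulate: substance-specific systematic
dose biases calibrated to any real cohort (the per-substance `dose_bias`
hook exists but ships neutral), seasonal treatment patterns, indication
structure, or farm-level correlation between usage and herd size. A green
identity-limit or divergence test therefore establishes the correctness of
the arithmetic and the qualitative mechanism — not that any particular
published agreement value would be reproduced, which would require the
original confidential journals.

## Numerical and interface choices

* Percentiles in summaries use linear interpolation between order
  statistics (quantile type 7, the common statistical-software default);
  nearest-rank (type 1) is available via `method = "nearest"`. No
  published percentile method is stated for the tables this layout
  follows.
* nDDD values are kept as full-precision reals; rounding happens only at
  presentation.
* Units are fixed — amounts mg, doses mg/kg/day, weights kg — with no
  unit inference. Products dosed per animal rather than per kg must be
  converted to mg of active substance before import; the package requires
  amounts already in mg and says so rather than guessing.
* Long-acting products: the catalog carries a per-substance multiplier
  that scales treatment days, but it is off by default; it matters when
  comparing substances of different pharmaceutical activity, not when
  comparing the two indicators, and the reference analysis disregarded it.
* The one-year census denominator is scaled proportionally
  (`window_days / 365`) for sub-year windows — an extension beyond the
  one-year design, flagged as such.
* Substance matching between journal and catalog is exact after trimming
  and lower-casing; no fuzzy matching, to avoid silent mis-mapping.
* All randomness lives in the generator; the analysis path is fully
  deterministic, and identical inputs produce byte-identical output files.

## Known limitations

* The DDD catalog shipped for examples is synthetic; results on real data
  are only as good as the national DDD values supplied.
* Kappa's single-class convention (1/0 with a flag) is a convention, not
  an estimate; consumers should filter on the degeneracy flag before
  averaging kappas.
* The plausibility caps are heuristics; a cap of 10 x DDD will not catch a
  5 x data-entry error, and legitimately high metaphylactic doses close to
  the cap would be censored. The caps are configurable per run.
* Percentile benchmarking with the tie rule can flag more than
  `fraction * n` farms when ties straddle the cut; downstream consumers
  must use the flag rather than assume exact counts.
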