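---
title: "Disproportionality signal detection for infant combination vaccines: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection for infant combination vaccines: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aefisignal)
```

## The problem

Spontaneous reporting systems such as VAERS collect adverse events following
immunization (AEFIs) without a denominator of doses administered, so
incidence cannot be estimated. What can be estimated is *reporting
disproportion*: whether an event is mentioned more often, relative to all
reports, for one product than for a comparator. `aefisignal` implements this
comparison for two infant combination vaccines — pentavalent DTaP-IPV-Hib and
hexavalent DTaP-IPV-Hib-HepB — in infants aged 6 weeks to 2 years, together
with a logistic model of which reports are classified as death. All outputs
are hypothesis-generating reporting signals, not causal or incidence
estimates.

## Cohort construction

Reports enter the cohort when (i) at least one vaccine row's `VAX_NAME`
matches a combination-vaccine name pattern (a name matching both patterns
resolves to hexavalent, the stricter HepB-containing pattern), (ii) the
patient's age lies in the 6-week-to-2-year window, (iii) the report id has
not been seen before (first occurrence in file order wins), and (iv) the
report's PT set is not composed entirely of vaccination-error terms, which
describe administration mistakes rather than clinical events. Attrition at
each rule is logged so a selection flow can be audited.

Age handling deserves a note. `AGE_YRS` in the extract dialect carries two
decimals, but the window boundaries — 42 days and 730 days — are not
representable at that precision (42 d = 0.11499 y). Comparisons therefore
tolerate half a rounding step (0.005 y), so an infant aged exactly 6 weeks,
stored as 0.11, is retained. Age groups use 30.44-day months and half-open
intervals: G1 = [6 wk, 4 mo), G2 = [4 mo, 8 mo), G3 = [8 mo, 2 y]; the
labels leave open/closed ends unstated, and this choice makes the groups a
partition. The group is always recomputed from the stored (rounded) age, so
the generator, the reader and the stratifier agree on every record.

The composite *serious* flag is the disjunction of death, life-threatening
event, hospitalization, prolonged hospitalization and disability — exactly
the five flags the summary table enumerates; emergency-room-only visits do
not count. Percentages are rounded half-up to one decimal with the class
size as denominator, matching the published table's formatting.

## Contingency tables

Every statistic is computed from a report-level 2×2 table: `a` target-class
reports mentioning the event, `b` not mentioning it, `c`/`d` the comparator
counts. A report mentioning an event through several PTs counts once, and a
report with PTs in two SOCs contributes once to each SOC's table. The
default comparator is the other vaccine class's cohort (the comparative
question is penta vs hexa); an external-background mode is provided because
classical practice screens a product against all other reports in the
database. Events never reported for the target class are not scored — no
threshold can flag them — so every emitted table has `a ≥ 1`.

## The four statistics and their thresholds

With `N = a+b+c+d` and expected count `E = (a+b)(a+c)/N`:

* **ROR** `= (a·d)/(b·c)`, CI `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`.
  Flag: ROR ≥ 3 and lower bound > 1.
* **PRR** `= [a/(a+b)]/[c/(c+d)]`, with the Yates-corrected chi-square
  reported alongside. Flag: PRR ≥ 2 and `a ≥ 3` (the "N ≥ 3" of the usual
  criterion read as the target event count).
* **BCPNN IC** `= log2((a+0.5)/(E+0.5))` in bits; the shrunk reporting
  ratio has posterior `Gamma(a+0.5, E+0.5)` and `IC025` is the log2 of its
  2.5% quantile. Flag: IC025 > 0.
* **MGPS**: the relative reporting rate λ has a two-component gamma mixture
  prior fitted by marginal maximum likelihood (the marginal count
  distribution is a negative-binomial mixture). `EBGM = 2^{E[log2 λ]}`
  via the digamma closed form; `EB05` is the posterior 5th percentile by
  bracketed root-finding on the mixture CDF. Flag: EB05 > 2.

Zero cells receive the Haldane–Anscombe +0.5 on all four cells, applied
only when a zero is present. Thresholds use the comparison operators
exactly as published (≥ for the ratios, strict > for the bounds). An event
is a **consensus signal** when at least two of the four methods flag it.
No further multiple-testing adjustment is applied beyond the consensus rule
and MGPS's intrinsic shrinkage; this mirrors the source analysis and is a
documented limitation.

The mixture prior is fitted on log/logit-transformed parameters by BFGS
from six fixed starting points (the classical `(0.2, 0.1, 2, 4, 1/3)`
start plus five dispersed alternatives); the best converged optimum wins.
Gamma mixtures are non-identifiable up to relabelling and near-flat
directions, so recovery is judged on the induced shrinkage curve (EBGM as
a function of E), not on raw parameters. With fewer than 20 events the
five hyperparameters are not identifiable and fitting refuses; the
pipeline then reports MGPS columns as missing and treats its flag as not
flagged, which makes SOC-level runs (typically ~13 events) conservative
for the consensus rule. `EB05` root-finding brackets the component
quantiles with a floating-point pad and falls back to zero as a lower
bound, since the mixture CDF minus the target level is negative there by
construction.

An optional stratified expected count (summing `(a+b)(a+c)/N` within
age-by-sex strata) is available for the Bayesian statistics but is off by
default; the default expected count is the unstratified independence
product.

## Subgroups and the death model

Stratified analyses rerun the identical table + statistic machinery inside
each level of age group, sex, or the serious composite; comparators are
drawn within the same stratum, which is the confounding-control intent of
stratifying. Missing levels form their own stratum rather than being
dropped. Top-K tables rank PTs by target-class count with alphabetical
tie-break (the published figures do not state their ordering).

Death classification is modelled per vaccine class (the published table
shows two separate columns) by logistic regression on age group
(reference G1), sex (reference male) and co-administration (reference
vaccine-alone). Reports with unknown sex are excluded, with the count
reported, because the model contrasts female vs male. Fitting is
IRLS maximum likelihood with a tightened tolerance (1e-10, 100 iterations);
intervals are Wald, `exp(β ± 1.96·SE)`, matching the symmetric-on-log-scale
style of the published table, with two-sided Wald p-values; p < 0.05 is an
annotation, not a gate. Covariate levels with all-death or no-death
outcomes are warned about by name, since they signal quasi-separation.

## The synthetic generator

Because the source data are an external extract, the package ships a
seeded generator whose defaults emulate the published cohort: 3,259
pentavalent and 1,720 hexavalent reports; ~45% female and 6% unknown sex;
co-administration on 68% / 88% of pentavalent / hexavalent reports; a
~50-PT toy vocabulary across 13 SOCs with baseline per-report reporting
probabilities chosen so that common infant AEFIs (pyrexia, injection-site
reactions, crying) dominate and rarer clinical events sit at 0.3–3%; and a
death process with strongly protective older-age and female effects and a
harmful co-administration effect, in the direction of the published
regression. Age-group shares default to 50/30/20 across G1–G3, reflecting
that most reports concern the primary series.

PT occurrences are conditionally independent given vaccine class — no
joint model among PTs, or between PTs and seriousness, is published, so
independence is the transparent choice. Planted signals multiply a PT's
baseline by a class-specific relative rate, clamped at probability 1 with
a warning. A report drawing no PT (or only vaccination-error PTs) receives
the benign fallback PT "Pyrexia", so report counts are exact and every
synthetic report survives cohort selection; the fallback PT's empirical
frequency therefore intentionally exceeds its nominal baseline.
Seriousness flags other than death are independent draws; the serious
composite is derived, so death always implies seriousness. Ages are drawn
uniformly within the sampled group and stored at two decimals.

What the generator does *not* emulate: reporting delays and stimulated
reporting, inter-PT correlation (syndromes), duplicate submissions,
free-text narratives, and realistic MedDRA granularity. Tests passing on
synthetic cohorts therefore validate the statistical machinery, not the
behaviour of real VAERS data.

A deterministic fixture reproduces every margin of the published
characteristics table exactly. Only margins are published, so the joint
structure is an arbitrary deterministic layout: seriousness flags are
assigned consecutively with wrap-around over the serious block, making the
composite count exact. One internal inconsistency in the source is worth
noting: the stated total of 4,980 reports does not equal the printed class
sizes 3,259 + 1,720 = 4,979; the class sizes are taken as authoritative
since every other printed count is consistent with them.

## Problem sizes and numerical choices

The validation suite uses cohorts of 2,000–5,000 reports per class for
consensus calibration and power (50 planted and null replicates each in
the acceptance script), 5,000 events for mixture-prior recovery, 500
null replicates at n = 20,000 for Wald coverage, and 40–200 replicates at
n = 50,000 for planted odds-ratio recovery — sizes at which binomial and
Wald standard errors are small relative to the 10% recovery bands being
checked. Monte-Carlo oracles for IC025 use 2×10⁵ posterior draws, giving
a worst-case quantile standard error of ~0.007 bits at the smallest scored
count (`a = 1`). Root-finding tolerances are 1e-10 (well inside the 1e-6
agreement checked against an independent bisection oracle).

## Known limitations

* Disproportionality ≠ risk: no denominators, reporting bias, and
  consensus thresholds tuned for screening specificity rather than
  estimation.
* The comparator choice (other class vs external background) changes every
  statistic's meaning; the package defaults to the comparative
  other-class design and flags this prominently.
* The SOC level usually has too few events to fit the MGPS prior; its
  consensus is then effectively 2-of-3.
* Wald intervals (not profile likelihood) can misbehave under
  quasi-separation; the fit warns rather than switching to a penalized
  estimator.

## A minimal example

```{r example, eval = FALSE}
g <- generate_reports(sim_config(
  planted_rr = data.frame(pt = "Apnoea", vaccine_class = "hexa", rr = 4),
  seed = 1))
tables <- build_all_tables(g$reports, level = "PT", target_class = "hexa")
signals <- compute_signals(tables)
head(signals[signals$consensus, c("event", "a", "ror", "ic025", "eb05")])
```
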