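---
title: "Phenotyping statin intolerance and simulating oral LLT escalation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping statin intolerance and simulating oral LLT escalation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statinsim)
```

## Scope and data model

`statinsim` answers two linked questions on longitudinal outpatient EMR
data: which patients show the prescription-level fingerprint of statin
intolerance (SI), and what fraction of them would reach their risk-based
LDL-C target if ezetimibe and bempedoic acid were added stepwise. The
data substrate is four delimited tables — patients, prescriptions, LDL-C
laboratory values, diagnosis events on a closed category enum — because
that is what claims extracts reduce to once drug and diagnosis codes have
been normalised upstream. The package deliberately contains no ICD/ATC
parsing: code-to-category mapping is site-specific preprocessing.

## Timeline construction

All interval arithmetic is in whole days on half-open intervals: a
prescription on day $d$ with $s$ supply days covers $[d, d+s)$. Supply
duration is rarely recorded in ambulatory data, so rows without one
default to 90 days (`default_supply_days`), the typical quarterly
prescribing rhythm in German general practice; it is overridable per row.

Discontinuation is measured from *end of supply*, not prescription date:
a 180-day rule on raw prescription dates would misclassify every
quarterly refill pattern as discontinuation. A statin-free gap strictly
longer than `discontinuation_gap_days` (180) marks long-term
discontinuation; when the gap runs to the index date with no statin after
it, discontinuation is permanent. Consecutive same-regimen prescriptions
whose gap does not exceed the discontinuation threshold merge into one
episode; a regimen change always starts a new episode, which is what the
switch and down-titration detectors operate on. Two statins dispensed on
the same day resolve to the higher intensity — deterministic, and
conservative for down-titration detection.

The statin intensity catalog (molecule × dose band → low/moderate/high)
is a configurable table; the default follows common intensity
classifications (e.g. 5 mg rosuvastatin and any-dose pravastatin or
fluvastatin are low intensity, 40–80 mg atorvastatin high). "Low-dose"
is treated as synonymous with low-intensity throughout.

The index date is the last LDL-C in the selection window (default July
2020 – June 2021) that is *attributable*: every regimen episode covering
the draw must have started at least `llt_stability_days` (28) before it,
since a value drawn days after a regimen change reflects the old
treatment. Outlier trimming (0.001 per tail, type-6 quantiles clamped to
the sample range so small cohorts lose nothing) is applied to the pooled
LDL-C distribution before index selection; the order of trimming and
selection is a design choice here, made cohort-wide to mirror
laboratory-level exclusion.

## Classification rules

The intolerance classifier is two-layered. `detect_signals()` reduces a
timeline plus the diagnosis stream to a named boolean vector:
down-titration (same/different molecule; any later episode of strictly
lower intensity rank), molecule switches between consecutive episodes,
the specific switch from atorvastatin/simvastatin to 5 mg rosuvastatin or
any-dose pravastatin/fluvastatin, documented intolerance notes, muscle
symptoms and other intolerance events within the 3-year look-back, and
the regimen-state flags. Intermittent dosing is not defined in most rule
sets; the default here is at least two supply gaps each in (60, 180]
days — gaps of 60 days or less are refill noise, and anything beyond 180
days is already discontinuation by the main rule. The lower bound is
configurable (`intermittent_min_gap_days`).

`classify_si()` then evaluates named boolean expressions from the config
file. The load-bearing distinction is the prose one: **absolute**
intolerance requires permanent discontinuation together with any
intolerance evidence; **partial** requires continued statin use (no
long-term gap, supply active at index) together with a
tolerability-driven regimen signal. Absolute is evaluated first and wins
on conflict — permanent discontinuation dominates clinically. The exact
assignment of criteria to latest-regimen strata in published tabulations
is ambiguous; the shipped rule set is this package's explicit reading,
and because rules are declarative config, an alternative reading is a
drop-in replacement, not a code change. Patients with no statin history
and no events are `none`: statin-naïve is not intolerant.

## Risk categories and targets

Risk assignment uses category-specific look-backs anchored at the index
date: 12 months for hypertension and smoking, 60 months for chronic
kidney disease, unrestricted for atherosclerotic disease, diabetes and
the chronic comorbidities. The default table is a standard 2019 ESC/EAS
reading restricted to the two categories the analysis needs: documented
atherosclerotic disease or CKD → very-high; diabetes with both additional
risk factors → very-high; diabetes alone, or hypertension plus smoking →
high; anything else is outside the study population and excluded (with
the exclusion recorded). Organ-damage modifiers are approximated by risk-
factor counts because the closed diagnosis enum carries no organ-damage
category. Targets are strict: < 55 mg/dL (very-high), < 70 mg/dL (high).

## The escalation simulation

Fractional LDL-C reductions are modelled as beta random variables on
[0, 1], with shapes fitted by the method of moments
($\nu = \mu(1-\mu)/\sigma^2 - 1$, $\alpha = \mu\nu$,
$\beta = (1-\mu)\nu$). The beta family is used for both drugs — for
bempedoic acid only the observed mean/SD pairs are published, and both
pairs satisfy the beta feasibility bound $\sigma^2 < \mu(1-\mu)$ — with a
degenerate zero-variance mode per model for hand-checkable oracles. A
consequence of the [0, 1] support is that no simulated patient's LDL-C
ever increases; patient-level trial data would contain increases, so
simulated attainment is, if anything, slightly optimistic.

Each run stages patients as the treatment algorithm routes them: at
target at baseline → stop; not at target and not on ezetimibe → one
ezetimibe draw; patients already on ezetimibe keep their measured LDL-C
(it already reflects the drug); still not at target → one bempedoic-acid
draw from the model matching the baseline statin stratum
(moderate/high-intensity vs low/none). Draws are independent per patient,
per drug and per run — there is no persistent responder effect across
runs. Patients on bempedoic acid or a PCSK9 inhibitor at baseline are
excluded before simulation; the PCSK9-inhibitor step itself is out of
scope here.

Aggregation follows the median-of-runs convention: per stage, the median
over runs of the within-run mean LDL-C (median-of-means), of the
within-run median, and of the count at target. Median counts can be
half-integral for even run counts; attainment proportions are computed on
the unrounded median and displayed to one decimal, round-half-up — the
rounding convention of every reported percentage in the package (the
Bonferroni helper truncates instead, matching its conventional
conservative reporting). Attainment is reported against two denominators,
both emitted: the full intolerant cohort (cumulative convention) and the
population entering each stage (prior-step convention).

Reproducibility: the master seed draws one substream seed per run
(without replacement), and patients consume draws in sorted `patient_id`
order, so results are bit-identical across repetitions and independent of
input row order.

## The synthetic cohort generator

No public EMR cohort with these semantics exists, so the generator *is*
the test substrate, built so that expected outcomes are provable rather
than statistical hopes:

* Category counts (absolute/partial/none, risk mixes, therapy mixes) use
  largest-remainder apportionment — integer counts hit their targets
  exactly and reproducibly.
* Every intolerant patient's history is the canonical template of one
  classifier rule, with ±10-day jitter per prescription and design
  margins of ≥ 20 days to every rule boundary (the 60/180-day gap
  thresholds, the 28-day stability window, the 3-year look-back). Label
  recovery by the classifier is therefore an exact oracle: tests assert
  100% agreement, not approximate agreement.
* LDL-C is log-normal per treatment stratum with shape/scale solved from
  the target arithmetic mean and SD (mean 152.1, SD 43.5 mg/dL without
  therapy; 92.1, SD 31.5 on therapy) — strictly positive and
  right-skewed like real lipid panels. Demographics: age normal
  (69.5, SD 11.9, clamped to 30–99), 45% female.
* Risk is planted jointly with intolerance (73.7/26.3 very-high/high
  within the intolerant subgroup; the non-intolerant remainder is set so
  the overall 66.1/33.9 mix holds). Very-high patients receive coronary
  artery disease, high patients diabetes; smoking is never planted on
  high-risk patients because together with the freely planted
  hypertension it would escalate them. Overall smoking/diabetes
  prevalences therefore deviate from their marginal targets — a
  deliberate trade of marginal fidelity for exact risk-label recovery.
* 1.3% of intolerant patients carry baseline bempedoic-acid
  prescriptions, exercising the simulation's exclusion path.

What the generator does **not** emulate: inter-practice clustering,
seasonality, joint LDL-C/intensity structure within the intolerant
subgroup beyond the summary strata, irregular refill noise beyond the
jitter, and coding errors. Passing tests therefore demonstrate
correctness of the algorithms under the stated population structure, not
that real-data headline percentages will be reproduced; attainment
results on synthetic cohorts are qualitative analogues (ordering and
rough magnitude), not replications.

## Numerical choices and degenerate inputs

* Quantile type 6 for outlier trimming (clamped); removal is strict
  beyond the bounds, so constant vectors and tiny samples are untouched.
* An index date before all events yields an empty timeline, not an
  error; an empty cohort is an error for the simulator (there is nothing
  to aggregate) but a legal all-zero table for prevalence reporting.
* A gap of exactly 180 days is *not* discontinuation (strict
  inequality), and supply ending exactly on the index date means
  statin-free at index (half-open intervals).
* Beta fitting rejects infeasible moment pairs
  ($\sigma^2 \ge \mu(1-\mu)$) with the bound named in the error.

## Problem sizes used in the shipped checks

The package's own test and acceptance runs use cohorts of 30–1,000
patients for exact-recovery and calibration properties, a 1,000-patient
all-intolerant cohort (calibrated to the intolerant-subgroup structure:
20.7/79.3 absolute/partial, LDL-C mean 105.6 SD 39.8 mg/dL, within-SI
risk mix, template weights approximating the intolerant therapy mix) at
10,000 Monte Carlo runs for the simulation properties, and a
10,000-patient mixed cohort for end-to-end accounting — sizes chosen so
the full suite exercises every code path at meaningful scale while
remaining quick to run routinely.

## Known limitations

* The shipped intensity catalog and risk table are standard readings,
  not site-validated code lists; both are config-replaceable.
* Free-text intolerance documentation arrives pre-extracted as a
  diagnosis category; no NLP is attempted.
* No rechallenge/dechallenge causality logic for muscle symptoms.
* Effects are sampled independently across runs and drugs; correlated
  responder behaviour would widen the attainment distribution.
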