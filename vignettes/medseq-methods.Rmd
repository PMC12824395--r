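---
title: "Medication-use state sequence analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Medication-use state sequence analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medseq)
```

## The problem

Maintenance pharmacotherapy of bipolar disorder is guideline-governed —
anticonvulsant mood-stabilizers, lithium and antipsychotics constitute
adequate treatment, antidepressant monotherapy does not — yet individual
treatment courses are irregular: late initiation, early discontinuation,
switches and augmentations. Summarizing three years of dispensing data into
a single "adherent / non-adherent" flag discards exactly the longitudinal
structure of interest. **medseq** instead treats each person's medication
use as a *categorical time series* (a state sequence) and provides the full
analysis chain: exposure modelling from pharmacy dispensings, cohort
eligibility filters, sequence construction, optimal-matching
dissimilarities, clustered treatment typologies, trajectory classification,
and multinomial association models. A synthetic registry generator with
known ground truth makes every stage testable, since real
person-level register data cannot be redistributed.

## From dispensings to states

### Exposure model

Dispensing records (person, ATC code, date, estimated days' supply) are
mapped to four medication classes by ordered longest-prefix ATC rules
(default: `N06A` antidepressants, `N03A` anticonvulsant mood-stabilizers,
`N05AN` lithium shadowing `N05A` antipsychotics). Per person and class,
each dispensing covers `[date, date + supply - 1]`, where the supply
estimate is the sliding mean of the last `window = 3` dispensed supplies of
that class — a person who stockpiles three months of tablets and returns
late is smoothed toward their habitual coverage rather than treated as
discontinuing. Coverage intervals separated by at most `grace_days = 30`
days merge into maximal use periods. This is a deliberately simple
continuous-exposure model built on the sliding-average principle of
dose-based exposure algorithms; it does not model package sizes, tapering
or hospital-dispensed medication (hospital days are handled at the
binarization stage instead). Both parameters are configurable and their
defaults are stated wherever they apply.

### Eligibility

`apply_eligibility()` implements incidence filters in a fixed order,
recording *all* triggered reasons per person: prior bipolar codes (F30/F31)
in a 3-year lookback; a medication washout excluding anyone with
antipsychotic, mood-stabilizer or lithium use overlapping the window 455 to
91 days (15 to 3 months) before diagnosis; psychosis-spectrum or dementia
codes from lookback through follow-up; continuous residency over lookback
plus follow-up (or until death); and age 16–65 at diagnosis. Calendar
periods are rendered in days (one month = 91/3 days, three years = 1095
days) to stay commensurate with the 91-day period grid; day arithmetic on
half-open intervals with the diagnosis date as day 0 is used throughout.
Antidepressant use never triggers the washout, so incident cases treated
for prior depression are retained by design.

### The period grid and the state decision tree

Follow-up is divided into twelve 91-day periods (1092 days). Per period,
each class receives a binary indicator: positive when the class's use
periods cover at least 50% of the period's non-hospital days. Inpatient
days are subtracted from both numerator and denominator; a period with 46
or more inpatient days (≥ 50% of 91) is not assessable and takes the
*following* period's resolved state, with resolution right-to-left so
chains of alternating valid/invalid periods are well defined. Two
consecutive non-assessable periods exclude the person. A non-assessable
final period takes period 11's resolved state — the substitution idea
applied to the only available neighbour.

The four indicators map to seven mutually exclusive states by a fixed
decision tree (`assign_state()`): lithium plus another adequate class is
*lithium with augmentation*; lithium alone *lithium*; mood-stabilizers plus
antipsychotics *augmentation*; then *mood-stabilizers*, *antipsychotics*,
*antidepressant monotherapy*, and *lack of treatment*. Concomitant
antidepressants are ignored whenever any adequate class is present. Death
censors every period from the period containing the death date onward
(`CENSORED`, absorbing); the partial exposure of the death period is
discarded as a conservative choice. Persons censored from period 1 are
excluded. If an unassessable period's substitute is `CENSORED`, the period
becomes `CENSORED` as well, which keeps censoring monotone.

## Sequence analysis kernel

**Transition rates.** `transition_rates()` pools weighted first-order
transition counts over periods 1–11. Rows for states never observed as an
origin are flagged (`empty_origins`) and zeroed rather than propagating
`NaN`.

**Substitution costs.** Costs follow the transition-rate (TRATE)
convention: `cost(i, j) = cval − p(i→j) − p(j→i)` for `i ≠ j`, floored at
0, diagonal 0, with `cval = 2` and `indel = cval/2 = 1` by default — states
that frequently interchange are cheap to substitute. The censoring symbol
participates in the alphabet and the cost estimation: it is a real
absorbing state of the data, and excluding it would make sequences of
different effective lengths incomparable. Both choices (and `cval`,
`indel`) are arguments, not constants.

**Optimal matching.** `om_distance()` is the standard dynamic program over
substitutions and indels, implemented in C++ for the quadratic
all-pairs computation. `dissimilarity_matrix()` first collapses identical
sequences into unique rows with multiplicity weights (observed cohorts
concentrate massively on a few patterns, so this is the difference between
thousands and hundreds of rows) and orders them lexicographically, making
the result independent of input order. The implementation is tested
against a brute-force edit-script recursion on all pairs of length ≤ 4
over a 3-letter alphabet, and for metric costs symmetry and the triangle
inequality are property-tested.

**Descriptive statistics.** Transversal entropy is the Shannon entropy of
the weighted state distribution at each period; longitudinal entropy the
within-sequence analogue; both are normalized by `log(8)` (the full
alphabet, a switch `norm_size` exposes the 7-state alternative since either
normalization is defensible). The complexity index is
`sqrt((transitions / 11) × longitudinal entropy)`. Mean time in state is
reported per group both as periods and as the proportion of each person's
*non-censored* periods, with the censored share reported separately — so
treatment-state shares sum to one over the living follow-up. Group
contrasts use Poisson log-link regression of per-person period counts with
an offset for observed periods ("log-linear regression" admits several
readings; count regression with a rate offset is the one that matches the
mean-time quantity), with HC0 sandwich variances by default.

## Typologies

Clustering operates on the weighted unique-sequence dissimilarity matrix.

* **Ward** (`ward_cluster()`): `stats::hclust` with the `ward.D2`
  criterion and `members =` weights. `hclust` interprets its input as
  *between-initial-cluster* distances, so raw distances are first rescaled
  by the Ward factor `sqrt(2 w_i w_j / (w_i + w_j))`; clustering the
  weighted unique rows is then provably identical to clustering the fully
  expanded multiset (property-tested).
* **PAM** (`pam_cluster()`): weighted partitioning around medoids —
  deterministic greedy BUILD seeding, then steepest-descent single-swap
  SWAP until no exchange lowers the weighted objective. Classical
  BUILD+SWAP carries no global-optimality guarantee and can stop in a
  local optimum even on eight points (the reference `cluster::pam` does
  too, on the same instance), so instances where `choose(m, k) ≤ 5000`
  are solved exactly by enumerating medoid subsets; the heuristic path is
  cross-checked against `cluster::pam` on unweighted data. All
  tie-breaking is lowest-index-first; no randomness anywhere.
* **Hybrid** (`pam_cluster(init = )`): per-cluster medoids extracted from a
  Ward cut, then SWAP only.

Silhouettes use the weighted form in which the `w_i − 1` zero-distance
duplicates of a unique row count as own-cluster neighbours, matching the
expanded-data silhouette exactly. Conventions: singletons and degenerate
`a = b = 0` cases score 0. `select_typologies()` fits every method for
`k = 2…15` and returns the solution maximizing the weighted average
silhouette width (ASW; ~0.3 reasonable, ~0.5 good), ties broken toward
smaller `k` and then PAM > hybrid > Ward; if no solution reaches ASW 0.25
the result is flagged structureless. Clusters are named by their medoid's
modal non-censored state (*treatment failure* for LACK-dominated medoids,
*persistent lithium* for lithium medoids, and so on), with ties labelled
`unclassified`.

## Initiation, discontinuation, trajectories

Sequences are dichotomized (lack = 0, any treatment = 1, censoring ends the
evaluable window). The calendar labels map onto the 91-day grid in the only
commensurate way: initiation in period 1 is *early (0–3 months)*, periods
2–4 *delayed (4–12 months)*, periods 5–12 *delayed (≥ 12 months)*.
Antidepressant monotherapy already ongoing at diagnosis and continuing into
period 1 counts as early initiation. Discontinuation is the first 1→0
transition after initiation; with gap `g` periods it is binned ≤ 2 within
6 months, 3–4 within 1 year, 5–8 within 2 years, ≥ 9 after 2 years — only
the first event counts, later re-initiations and re-discontinuations are
ignored. The five-trajectory cross (early/delayed × discontinued/not, plus
continuous lack) partitions every cohort. Summary tables restrict the
discontinuation denominator to persons initiating within one year, report
counts with percentages rounded half-up to one decimal, and every emitted
percentage is self-checked against its count ratio. Persons censored before
an event contribute to the "none"/"never" categories within their evaluable
window — a simplification (no survival weighting) stated here deliberately.

## Association models

`fit_multinomial()` wraps a maximum-likelihood softmax regression
(`nnet::multinom`, deterministic from zero initialization, observed-information
standard errors) with the conventions of this analysis: the reference
outcome is the largest typology, the reference population the native-born
majority, covariates dummy-coded categorical with no interactions — group
differences in covariate effects are examined by refitting per stratum
rather than by interaction terms. `odds_ratios()` returns `exp(coef)` with
Wald 95% intervals (the register-epidemiology default; a profile-likelihood
check backs the tests). `fitted_probabilities()` performs marginal
standardization (g-computation): set every person's factor to level ℓ,
average predicted typology probabilities over the (optionally stratified)
sample. Predicted-at-reference would be the alternative reading of "fitted
probabilities"; marginal standardization was chosen because it averages
over the realized covariate distribution and is the quantity usually
plotted.

## The synthetic registry generator

`generate_cohort()` emulates the *structure* of a national
incident-bipolar-disorder register: four population groups at the exact
cohort proportions 20361/1867/1462/888 over 24,578; nine binary/ordinal
covariates at plausible prevalences; a latent typology per person drawn
from a multinomial logit whose default coefficients point the way the
epidemiology points (refugees and low education toward treatment failure,
high education/partner/prior depression toward mood-stabilizers and
lithium); the latent sequence is the typology's archetype with
independent per-period noise (default 0.05); dispensings are emitted so the
exposure and sequence modules reconstruct the latent sequence exactly when
noise, hospitalization and death are absent (each use period gets one
dispensing of a class-appropriate ATC code with a 91-day supply);
hospital stays (default rate 0.05, 10–70 days) and uniformly-timed deaths
(default 0.01) exercise the substitution and censoring rules. Archetypes
default to the seven typology patterns, with *treatment failure* rendered
as two periods of mood-stabilizers followed by ten of lack — initiation
then discontinuation — and the six others as constant sequences.

What the generator does **not** emulate: within-class drug switching,
seasonal or trend structure in dispensing, correlated covariates, partial
adherence, the empirical diversity of observed sequences (real cohorts show
thousands of distinct sequences; the generator's diversity is governed by
the noise rate and is a tunable, not a target), or informative censoring.
Passing recovery tests therefore demonstrate that the pipeline's machinery
is correct and self-consistent — not that it would reproduce any particular
register study's estimates.

## Numerical choices and problem sizes

Dates are integer days; intervals half-open; all thresholds (`≥ 50%`,
`≥ 46` inpatient days, washout bounds) are exact integer comparisons.
Percentages round half away from zero to one decimal, matching the usual
table style. The test suite sizes are chosen to keep the full run within a
few minutes while leaving no tolerance doing silent work: typology recovery
uses n = 2,000 persons at noise 0.05 (selected k must equal 7, adjusted
Rand index ≥ 0.9 against the latent truth); confidence-interval coverage
uses 200 simulated cohorts of n = 5,000 (pooled Wald coverage required in
92–98%); the zero-noise round-trip uses n = 400 and must be exact. The
`scripts/acceptance.R` entry point recomputes all of these from scratch at
a caller-supplied seed.

## Known limitations

The exposure model is a stand-in for dose-level exposure algorithms and
will misestimate coverage for irregular dosing. The washout and lookback
windows use day-count conventions that can differ from calendar-month
implementations by a few days. Sequence states are defined by the 50%
binarization; sensitivity to that threshold is not explored automatically.
PAM above the exact-solve limit is a local-search heuristic. Trajectory
statistics ignore censoring-time differences (no survival weighting).
`nnet::multinom` can emit non-finite standard errors under separation in
very small strata; the package surfaces rather than masks such fits.
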