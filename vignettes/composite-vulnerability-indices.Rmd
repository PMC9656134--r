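---
title: "Composite vulnerability indices for district-level epidemic risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite vulnerability indices for district-level epidemic risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epivuln)
```

## The problem

Droplet-borne epidemics spread through interpersonal contact, and the
frequency and structure of contact differ sharply between administrative
districts: population density, housing crowding, retail and cultural
infrastructure, care institutions, commuting and tourism all shape how many
people meet, and how often. When case registries are incomplete or lagged,
a *composite vulnerability index* built from routine pre-epidemic
statistics gives crisis managers a ranking of districts by expected
exposure, available before the epidemic reaches them.

`epivuln` implements such an index pipeline for district-level
(LAU-1-style) data: indicator screening, normalization and aggregation
into synthetic indices, four-class delimitation, temporal correlation with
cumulative incidence, and stepwise refinement of the indicator set. A
latent-factor generator produces synthetic district data with known ground
truth so every stage can be exercised and its recovery behavior measured.

## Indicators and their metadata

Each indicator carries three pieces of metadata (see `default_registry()`
for the packaged set of 33):

* **orientation** — a *stimulant* is favorable at high values (e.g.
  dwelling floor area per person: more space, fewer in-home contacts); a
  *destimulant* is unfavorable at high values (e.g. population density).
  Orientation decides the direction of normalization.
* **nature** — demographic (D), social (S), economic (E) or land-use /
  spatial-development (L). The registry tags the unemployment rate as
  social rather than economic: within this framework it proxies
  labor-market-mediated contact patterns, which operate through the social
  fabric of a district.
* **relations** — whether the contacts the indicator proxies are
  *intended* (deliberate, tie-maintaining: work, family, institutions) or
  *unintended* (incidental: shops, transit, tourism). An indicator can
  carry both tags and then contributes to both relation-component indices,
  so that decomposition is deliberately not disjoint.

## Stage 1 — screening

Two filters run in fixed order (`screen_indicators()`):

1. **Quasi-constant filter.** The coefficient of variation, sample
   standard deviation over |mean|, is computed per indicator; indicators
   with CV ≤ 0.1 are removed. The sample (n−1) standard deviation is the
   standard choice for small-area panels, and dividing by |mean| keeps
   balance-type indicators (net migration can average near zero) well
   defined — a zero-mean, nonzero-spread column gets CV = ∞ and is always
   retained. The boundary is removed (CV exactly 0.1 goes out), reading
   "does not exceed" literally.
2. **Collinearity pruning.** While any kept pair has |r| > 0.6, the
   indicator involved in an offending pair with the largest mean absolute
   correlation to all other kept indicators is dropped; ties drop the
   later code in registry order. The rule is deterministic, and keeps the
   more independent member of each redundant cluster. The output always
   satisfies max pairwise |r| ≤ 0.6, asserted on every run.

Districts with missing indicator values are dropped (and counted) by
default; mean imputation is available via `na_action = "impute"` for
panels where dropping would bias the district set.

## Stage 2 — normalization and aggregation

**Zero unitarization** (`unitize()`) maps each indicator onto [0, 1]
within the analyzed district set:

* stimulant: v = (x − min x) / (max x − min x)
* destimulant: v = (max x − x) / (max x − min x)

Both formulas orient the unit interval the same way — 1 is the most
favorable (least vulnerable) observed value — and the destimulant column
is exactly one minus its stimulant counterpart. Min and max come from the
data themselves, not external norms, so the index is a *relative* ranking
of the analyzed districts; adding or removing districts changes the
scale. The transform is invariant to positive affine rescaling, so unit
changes in raw indicators never matter.

**Perkal standardized sums** (`perkal_index()`, `compute_indices()`)
aggregate a group of unitized columns by their per-district arithmetic
mean, giving the general index WO (all kept indicators) and six
components: Wd, Ws, Wg, Wzp by nature (D, S, E, L) and Wz, Wn by relation
type. Equal weights follow from the standardized-sums definition; a
weighted variant was deliberately left out of the default surface to keep
the index reproducible from the registry alone. Because every column is
oriented favorably, **a lower index means higher vulnerability**: a
district at the maximum of every destimulant and the minimum of every
stimulant scores exactly 0. WO is algebraically the group-size-weighted
mean of the four nature components, which the tests assert.

## Classification

`classify_index()` delimits four classes from the mean (Rav) and sample
standard deviation (s) of the index: I (low vulnerability, Ri > Rav + s),
II (medium, Rav < Ri ≤ Rav + s), III (quite high, Rav − s < Ri ≤ Rav),
IV (high, Ri ≤ Rav − s). Published formulations of this rule are often
strict on both sides, leaving boundary values unassigned; here boundaries
are closed downward, assigning ties to the more vulnerable class — the
conservative choice for a screening instrument, and it makes the
partition exhaustive. Degenerate zero-variance input assigns everyone to
class III with a warning. Whether to classify raw index values or their
ranks is genuinely ambiguous in practice (the mean ± SD rule is applied
both ways in the comparative-analysis literature); both modes are
implemented (`on = "values"` is the default, `on = "ranks"` available)
and give identical results whenever the index distribution is symmetric
enough that ranks preserve the mean ± SD geometry.

## Temporal association and refinement

`correlation_series()` computes the Pearson correlation (and two-sided
p-value) between each index and cumulative registered cases at every
snapshot date, aligning districts by id and excluding missing districts
pairwise — the n actually used is reported per computation rather than
forced to a common value. Counts are correlated as-is by default; a
`log1p_cases` option exists because cumulative counts are strongly
right-skewed and the log scale often shows the association more cleanly
(see the generator discussion below). Raw p-values are reported;
significance flagging is left to the caller's α.

`stepwise_select()` refines the indicator set against incidence at a
chosen snapshot (default: the final one, where cumulative counts carry
the most signal). It is the classical bidirectional p-value stepwise:
from the empty model, add the candidate with the smallest p-value while
it is below `alpha_enter` (ties broken by registry order), then remove
any term whose p-value has risen to `alpha_remove` or above, largest
first. Defaults are 0.05 / 0.10 — the conventional pairing in which every
retained term is individually significant at 5%. The candidate set
defaults to *all* registry indicators rather than the screening
survivors: screening optimizes the index for balance across domains,
while regression-based refinement should be free to recover predictive
indicators that screening discarded for redundancy. Both modes are
supported (`candidates` argument of `run_pipeline()`).

`refined_index()` then re-runs unitization and Perkal aggregation over
exactly the selected codes, and `univariate_relate()` fits the
straight-line relation between each selected raw attribute and the
refined index. The two regression directions (attribute-on-index and
index-on-attribute) answer different questions and are *not* reciprocal
slopes unless r² = 1, so both are reported explicitly along with the
shared r².

## The synthetic generator

`generate_districts()` draws one standard-normal latent vulnerability
factor V per district. Indicator j with location m, scale s and loading
λ ∈ [0, 1] is

x = m + s · (d · λ · V + √(1 − λ²) · ε),  ε ~ N(0, 1),

with direction d = +1 for destimulants and −1 for stimulants, so higher
latent vulnerability raises destimulants and lowers stimulants, and the
resulting WO correlates *negatively* with V. Cumulative cases at snapshot
t are round(exp(α_t + β_t·V + σ·η)), forced non-decreasing by a running
maximum; β_t grows linearly from 0.1 to 1.0 over the 8 snapshots, so the
coupling between vulnerability and incidence strengthens over time.

Default conditions (`default_scenario()`): 314 districts, the 33
registered indicators, 8 monthly snapshots (30 April – 30 November),
11 informative indicators at λ = 0.7, two quasi-constant injections
(hypermarket counts and town counts, both nearly invariant across rural
districts) for the CV filter to catch, and two collinear injections (bed
places copying accommodation establishments, occupancy copying tourist
numbers — pairs that are near-duplicates in real statistics) for the
pruner to break up. Locations and scales imitate the order of magnitude
of rural-district statistics (e.g. ~55 persons/km², ~3.1 persons per
apartment, unemployment ~8%); the net-migration balances have zero/near-
zero means so the |mean| convention in the CV is exercised. The log-scale
incidence dispersion σ = 0.5 reflects the large unexplained
between-district variation in registered counts (testing intensity,
reporting practice). The baseline α_t rises log-linearly from ~20 to
~1500 cases, the scale of a first epidemic wave in districts of this
size. All randomness derives from one master seed; the same seed
reproduces the dataset bit for bit.

**What the generator does and does not emulate.** It reproduces the
statistical structure the pipeline assumes — mixed-orientation indicators
loading on a common vulnerability factor, quasi-constant and collinear
nuisance columns, cumulative counts with time-strengthening coupling and
a negative index–incidence correlation. It deliberately omits spatial
autocorrelation, multi-factor structure (a per-nature latent hook is easy
to add but is not the default), count-specific noise (counts are rounded
log-normals, not Poisson-family draws) and any mechanistic transmission
dynamics. Passing tests therefore demonstrate that the pipeline recovers
the structure it is designed for; they say nothing about confounding,
spatial spillovers or reporting artifacts in real registries.

Two behaviors of the default conditions deserve explicit statement,
because they bound what recovery tests can show:

* **Stepwise selects a proxy subset, not the full informative set.** The
  11 informative indicators are exchangeable proxies of one factor
  (pairwise r = λ² ≈ 0.49), and incidence depends on that factor only.
  Once a handful of proxies are in the model, the remaining ones add
  almost no partial information — their entry t-statistics fall below any
  conventional threshold — so the procedure typically retains 5–7 of the
  11, with at most a couple of spurious entries. This is correct stepwise
  behavior under collinearity, not a defect: variable *selection* and
  factor *recovery* are different goals.
* **The raw-scale correlation magnitude saturates late.** For lognormal
  counts, corr(V, exp(βV + ση)) = β / √(exp(β² + σ²) − 1), which peaks
  before β reaches 1: the heavy right tail grows faster than the linear
  signal. The expected |corr(WO, cases)| therefore rises steeply early,
  then flattens and can dip over the final snapshots, and snapshot-level
  noise adds small inversions. On the log1p scale the coupling-to-noise
  ratio grows every snapshot and the magnitude rises essentially
  monotonically — one reason the `log1p_cases` option exists.

## Numerical and testing choices

* Sample (n−1) standard deviations everywhere (CV, classification), for
  internal consistency.
* Constant columns are an error in `unitize()` and `correlation_prune()`
  rather than silently handled: they indicate screening was skipped.
* Rank-deficient OLS designs raise an error naming the collinear columns.
* Stepwise ties (identical p-values) resolve by candidate order, making
  selection fully deterministic; a repeated-state guard stops the
  add/remove loop if thresholds are set so that it could cycle.
* The test suite checks the stepwise path against an independently coded
  brute-force application of the entry/removal rules (nested-model F
  tests) on small instances, recovery and trend behavior over 20
  generator seeds at the default 314-district size, and Monte-Carlo null
  behavior at n = 200–300 with fixed seeds. These sizes keep the whole
  suite under half a minute while leaving the Monte-Carlo margins wide
  relative to the thresholds tested.

## Limitations

The index is relative to the analyzed district set; it cannot be compared
across analyses with different district pools without re-unitization.
Equal weighting is a modeling choice, not an optimality claim. The
classification inherits the instability of mean ± SD cutoffs under heavy
skew (the rank mode is more robust there). Stepwise p-value selection
inherits all known caveats of stepwise procedures — post-selection
inference on the reported p-values is optimistic, and under collinearity
the selected subset is one of several near-equivalent subsets. None of
the pipeline stages model spatial dependence; districts are treated as
exchangeable observations.
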