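---
title: "Constructing a stemness gene score: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing a stemness gene score: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(stemscore)
```

## The problem

Tumours with a larger stem-like compartment tend to behave more
aggressively, and in breast cancer a number of curated "stemness" gene
sets capture transcriptional programmes of that compartment. The idea
behind a stemness gene score (SGS) is to turn a whole collection of such
sets into a single prognostic number per sample: score every set in every
sample, keep the sets whose scores carry survival information, and
combine them with signs matching their hazard direction. Because the
scoring is single-sample and rank-based, the same score can be computed
for a bulk RNA-seq sample, a microarray profile, or an individual cell.

The pipeline has five stages:

1. **Enrich** — single-sample gene-set enrichment (ssGSEA) of every set
   in every sample, normalised cohort-wide to NES.
2. **Screen** — univariate Cox proportional-hazards regression of each
   set's NES on overall survival; sets with a Wald p-value below 0.05 are
   retained and labelled *risk* (HR > 1) or *protective* (HR < 1).
3. **Score** — `SGS_s = sum over risk sets of NES[k, s] - sum over
   protective sets of NES[j, s]`.
4. **Stratify** — samples split at the median SGS into high and low
   groups.
5. **Compare** — Kaplan–Meier curves and the log-rank test for the two
   groups; the Wilcoxon rank-sum test for non-survival comparisons
   (e.g. infiltration scores between groups).

## The enrichment score

For one sample, genes are ranked `1..N` with the most highly expressed
gene at rank `N` (ties averaged). Conceptually the ES walks the genes in
decreasing rank order and sums, over all `N` positions, the difference
between the rank-weighted in-set empirical CDF (weights `rank^alpha`)
and the uniform out-of-set CDF. That sum collapses to a closed form,

```
ES(S) = sum_{g in S} r_g^alpha r_g / sum_{g in S} r_g^alpha
        - sum_{g not in S} r_g / (N - |S|),
```

the alpha-weighted mean rank of the set minus the mean rank of its
complement. We evaluate the closed form because it is exactly the walk
on untied data (the test suite checks agreement with a literal
position-by-position walk to 1e-12), it vectorises over all sets and
samples at once, and — crucially for sparse single-cell columns, where
most values tie at zero — with average-tie ranks it equals the walk
*averaged over all orderings of tied genes*. The literal walk depends on
the arbitrary order in which tied genes are visited; the closed form
does not, which is what makes per-cell scores deterministic and
invariant to gene order in the input file.

Consequences worth knowing: the ES depends on expression only through
ranks, so it is invariant under any strictly increasing per-sample
transform (log-scale vs linear-scale input does not matter), and at
`alpha = 0` a set and its complement score exact opposites.

### Tunable parameters

* `alpha` (dimensionless, default **0.25**): the customary ssGSEA
  weighting exponent. Larger values emphasise the very top of the
  ranking; `alpha = 0` weighs all ranks equally.
* `norm` (default **"global_range"**): NES = ES divided by
  `max(ES) - min(ES)` over the whole set x sample grid, putting cohorts
  of different size and platform on a comparable scale, as the cited
  ssGSEA implementations do. `"none"` keeps raw ES (used by the oracle
  tests). The constant is recorded in every output header.
* `min_size` (default 2): sets shrinking below this after intersection
  with the gene universe are dropped with a warning rather than scored.

## The survival screen

Each set's NES vector is the single covariate of a Cox proportional-
hazards model fitted by Newton–Raphson from beta = 0 with the Efron tie
correction (Breslow available for cross-checks), standard errors from
the observed information, and a two-sided Wald p-value — the standard
behaviour of the survival ecosystem, which this package calls rather
than reimplements. The screen keeps sets with p below the threshold
(default 0.05, raw — no multiplicity correction, by design: the screen
is a filter feeding a composite score, not a discovery list) and labels
them by the identity `HR = exp(beta)`: HR > 1 risk, HR < 1 protective.
A fit whose coefficient runs beyond |beta| = 15 has a separating
covariate and no trustworthy direction; it is flagged and dropped rather
than clamped. The test suite verifies the fitted coefficient against an
independent 1-D search of a hand-written partial likelihood and against
a closed-form three-subject fixture (`beta = log sqrt 2`).

Note the NES scale: range normalisation puts the whole NES grid inside a
span of 1, so per-NES-unit hazard ratios are numerically large (an HR of
20 per NES unit is unremarkable). Direction, not magnitude, is what the
SGS consumes.

## Stratification choices

* The cutoff is the **median of the analysis cohort** (mean of the middle
  two for even n). Scores tied at the cutoff go to **low**: determinate,
  and conservative in the sense that a tied patient is not called
  high-risk. With no ties this yields `floor(n/2)` high and
  `ceiling(n/2)` low samples.
* `stratify_median(cutoff =)` accepts a frozen cutoff so a validation
  cohort can be split at a training cohort's median instead of its own;
  by default each cohort is split at its own median.
* An "optimal cutpoint" search (maximising log-rank separation) is
  deliberately not implemented: it contradicts the median rule used for
  the primary analysis and inflates type-I error.

## Single-cell application

Per-cell scoring reuses the bulk code path unchanged: average-tie ranks,
range normalisation computed **within the cell matrix being scored**
(not frozen from a bulk run — the bulk constant reflects a different
grid; the choice is recorded in output headers), and the signed
combination with risk/protective labels imported from a prior bulk
screen, because per-cell survival does not exist. All-zero cells carry
no rank information and are excluded with a warning. Patient summaries
are arithmetic means of cell scores, and patients are then median-split
exactly as bulk samples are.

## The synthetic generator

Real cohorts with linked expression and survival are access-restricted,
so validation runs on simulated cohorts whose ground truth is known by
construction. The generator emulates exactly the statistical structure
the pipeline assumes:

* latent per-sample set activities `a[k, s] ~ N(0, 1)`;
* expression `x[g, s] = mu_g + signal_strength * sum_{k: g in S_k}
  a[k, s] + eps`, `mu_g ~ N(6, 2)` (a log2-like scale),
  `eps ~ N(0, noise_sd)`; genes in overlapping sets receive summed
  contributions;
* survival times exponential with hazard
  `lambda0 * exp(sum_k beta_k a[k, s])` — the simplest law satisfying
  the proportional-hazards assumption the screen relies on;
* independent exponential censoring, with the censoring rate solved
  numerically so the expected censored fraction equals the target
  (monotone 1-D root; reproducible);
* one integer seed drives a single stream, and the caller's RNG state is
  restored afterwards, so a dataset is bit-reproducible from
  (parameters, seed).

Defaults: `n_samples = 200`, `n_genes = 1000`, 36 sets of 20–25 genes,
`signal_strength = 1`, `noise_sd = 1`, `censor_rate = 0.3`,
`lambda0 = 0.1` — a cohort of a few hundred patients, roughly 30%
censoring, and set signals strong enough that a planted log-hazard of
0.7 is detectable at n = 400, which is the regime the method is meant
for.

The single-cell generator gives every patient one activity vector shared
by its cells, plus independent per-cell noise and Bernoulli dropout
(each value zeroed with probability `dropout_rate`). The sets named in
`shifted_sets` carry the planted patient shift **deterministically**
(`a[k, p] = shift_p`): the shift is the ground truth being recovered, so
it is not buried under a random patient-level draw — with a random draw
a +2 shift would be mis-ordered in about 8% of simulations through no
fault of the scoring. Unshifted sets keep `N(0, 1)` patient activity.

What the simulations do *not* emulate: count noise (negative binomial),
platform-specific intensity distributions, realistic gene–gene
correlation beyond shared set membership, PAM50-like subtype structure,
or biology-specific marker genes. Passing tests therefore demonstrate
that the pipeline recovers the model it assumes — planted directions,
calibrated type-I error, survival separation — not that any particular
real cohort will separate.

## Calibration checks and their design

Two null checks deserve a note:

* **Screen calibration**: on all-null cohorts the fraction of retained
  sets should sit near the nominal 0.05. The screen therefore must
  *report* zero-retention cohorts rather than error on them; the
  hard error ("no set passed, enlarge the cohort or threshold") is
  raised by the end-to-end pipeline, where an empty screen really is a
  dead end, via `require_retained = TRUE`.
* **Split calibration**: under the null there is usually no screened SGS
  to test, and screening and testing on the same data would build in
  selection bias. The null calibration of the median-split log-rank
  chain therefore fixes an a-priori 18/18 risk/protective assignment,
  testing the splitting and testing machinery itself at nominal level.

Simulation sizes used by the automated checks (200 null cohorts of
n = 200 for screen calibration, 100 planted cohorts of n = 400 for
direction recovery, 50 + 200 cohorts for the end-to-end checks, 20
single-cell cohorts of 2 x 200 cells) were chosen so binomial noise on
the estimated rates is small relative to the acceptance bands.

## Numerical choices and degenerate inputs

* Duplicate gene rows on load collapse by per-sample maximum (the
  highest-expressed probeset wins, the usual microarray policy).
* Batch merging is exact per-gene batch-mean centering (each value loses
  its batch mean and gains the unweighted mean of batch means): it
  equalises batch means exactly, preserves within-batch variance, and is
  idempotent. It assumes log-scale input and adjusts no covariates —
  cohort merging needs nothing more here. Missing values are an error by
  default (`drop_gene` and `zero` policies are opt-in).
* Time units are caller-declared and never converted.
* Degenerate inputs error loudly rather than silently: all-identical
  scores (no median split), all-identical ES (no range), constant Cox
  covariate, no events, empty gene-set intersections, all-zero cells,
  patients with zero retained cells.
* Writers emit 17-significant-digit TSV with a `#` header recording the
  package version and parameters, so a write/read round trip is exact
  and every output file can be traced to its run manifest.

## Limitations

* The screen is univariate; clinical covariates are not adjusted for.
* Raw p-values at 0.05 retain ~5% of null sets by construction; the
  composite score tolerates this, but the retained-set list should not
  be read as a discovery list.
* Range normalisation couples every NES to the cohort's extreme ES
  values; adding samples changes the constant (it is recorded in the
  output header for exactly this reason).
* The median split discards within-group score information; two cohorts
  split at their own medians are not on a common risk scale unless a
  frozen cutoff is used.
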