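---
title: "Hierarchical diffusion modelling of two-choice reading data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical diffusion modelling of two-choice reading data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftage)
```

## The model

Two-alternative forced-choice decisions are modelled as a Wiener diffusion
process: evidence accumulates from a starting point $z = z_{rel} \cdot a$
between two absorbing boundaries $0$ and $a$ with drift $v$ and unit
diffusion coefficient, and the response time is the first passage time plus
a non-decision component $t$ (stimulus encoding and motor execution).
Under *accuracy coding* the upper boundary is the correct response, so an
error is a lower-boundary passage.  Three quantities carry the psychology:

* $t$ — non-decision time, in seconds;
* $a$ — boundary separation; larger values mean more conservative,
  slower, more accurate responding;
* $v$ — drift rate, the speed of information uptake.

The package fixes the relative starting point at $z_{rel} = 0.5$ (the
two response options are equiprobable by design, so no bias is assumed)
and all trial-to-trial variability parameters at zero.  The diffusion
scaling constant is $s = 1$.  That choice is forced by the magnitudes of
the fitted group parameters this package ships as generator defaults
($a \approx 1.6$–$2.2$, $v \approx 1.1$–$3.6$, $t \approx 0.38$–$0.64$ s):
with $s = 1$ the closed-form mean RT
$t + \frac{a}{2v}\tanh\!\frac{av}{2}$ lands on the observed task means
(601 ms for young adults in letter identification against a published
599 ms), while $s = 0.1$ would be off by an order of magnitude.

The likelihood is the defective first-passage-time density.  It is
evaluated by the classic pair of series expansions — the image (small-time)
and spectral (large-time) representations — with the truncation length of
each chosen from the standard error bounds and the cheaper branch taken,
so the absolute density error stays below `tol` ($10^{-7}$ by default)
across the whole RT range.

## The hierarchy

Each task is modelled independently.  Within a task, every individual $i$
has free $(t_i, a_i, v_i)$ drawn from the age group's distribution,

$$\theta_i \sim \mathcal{N}(\mu_{g(i)}, \sigma_{g(i)}^2)
  \quad\text{truncated to the parameter domain},$$

with one location $\mu$ and spread $\sigma$ per (task, group, parameter).
With 4 tasks, 3 groups and 3 parameters the model has exactly 36
group-location parameters, the quantities all group inference is about;
the spreads are estimated but not counted among the 36.

Priors are weakly informative and centred on typical speeded-task values:
locations $t \sim \mathcal{N}(0.4, 0.3^2)$ truncated at 0 (seconds),
$a \sim \mathcal{N}(2, 1.5^2)$ truncated at 0,
$v \sim \mathcal{N}(2, 3^2)$; spreads half-normal$(0, 1)$.  At the
cohort sizes used here the likelihood dominates: the desk-scale recovery
runs (below) bound the priors' influence on the group locations.

## Estimation

`find_map()` supplies starting values.  A remark on what "maximum
posterior" can mean here: the joint posterior of a centered hierarchy is
unbounded along $\sigma \to 0$ with all individuals stacked on $\mu$, so
its literal global maximiser is degenerate and useless.  `find_map()`
therefore returns the non-degenerate local maximiser that initialisation
actually needs: subjects start at closed-form moment (EZ-style) estimates
and are polished by bounded quasi-Newton steps, the group level is
optimised against its conditionals with the spread floored at the
empirical scatter of the subject estimates, and sweeps repeat until the
joint log posterior stabilises.

`run_chains()` samples with adaptive Metropolis-within-Gibbs.  Each
iteration:

1. updates every subject's $(t, a, v)$ triple jointly with a multivariate
   random-walk proposal whose covariance is learned from the chain history
   during burn-in (subjects are conditionally independent given the group
   level, so this block is vectorised across subjects and repeated three
   times per iteration — the triples dominate the posterior's mixing
   time);
2. updates each group location by a scalar random walk and each spread by
   a log-scale random walk against their full conditionals;
3. applies two *ensemble* moves per group: a joint translation of
   $(\mu, \theta_{1..n})$ and a multiplicative rescaling of
   $(\sigma, \theta_{1..n} - \mu)$ with the appropriate Jacobian.  These
   target the two slow modes of a centered hierarchy — location drift and
   the spread/deviation funnel — which scalar updates alone traverse far
   too slowly (without them we observed $\hat R$ up to 3 on group
   locations at desk scale).

All proposal scales adapt towards 0.3 acceptance during burn-in only and
are frozen afterwards, so the retained draws come from a fixed, valid
kernel.  Chains start from the MAP state with 1% relative jitter and are
bit-reproducible given `(seed, chain)`.

Two profiles are used throughout: the **paper preset** (3 chains of
15,000 iterations, 5,000 burn-in, 500 posterior-predictive replicates,
full cohort sizes) mirrors the published analysis protocol, and the
**desk preset** (3 chains of 8,000, burn-in 3,000, 30 subjects per group,
200 replicates) is the package's reduced profile for recovery studies and
tests.  The desk chain length was set by convergence quality: the group
spread of boundary separation is the slowest coordinate, and 8,000
iterations bring its classic Gelman–Rubin statistic to $\approx 1.01$
(well under the conventional 1.02 criterion) across seeds, at roughly
four minutes per task fit on one CPU.

## Diagnostics and inference

* **Convergence** uses the classic (non-split, non-rank-normalised)
  Gelman–Rubin statistic on retained draws, matching the criterion
  semantics of the era the protocol comes from; the pass threshold is
  1.02.  Posterior tables report equal-tailed 2.5%–97.5% credibility
  intervals (the bracketed bounds of published tables are treated as
  equal-tailed; highest-density intervals are out of scope).
* **Posterior-predictive checking** simulates replicate datasets by
  drawing, per replicate and per subject, one posterior draw uniformly
  from the retained draws (full parameter uncertainty propagated, rather
  than plugging in posterior means) and simulating that subject's full
  trial set.  Observed and replicate correct-response RT quantiles
  (0.1, 0.3, 0.5, 0.7, 0.9) are compared through a pooled Pearson
  correlation and the coverage of the equal-tailed 95% replicate band.
  The correlation is pooled over all (subject, task, quantile) cells —
  whether the published statistic pooled this way is not recoverable from
  its description, so the choice is recorded in the report metadata.
* **Group comparison** reports, for every task, parameter and ordered
  group pair, the posterior exceedance probability $P(\mu_A > \mu_B)$
  from aligned draws, ties counted as one half — the directional
  probability that "proportion of overlap of the posteriors" denotes in
  the toolbox convention this protocol followed.  A kernel-density
  overlap coefficient is attached as a secondary descriptive statistic.
  Probabilities are reported to three decimals and never claimed to be
  exactly 1 unless every aligned draw agrees.

## The synthetic cohort generator

No raw data are distributed with the study design this package targets,
so `generate_cohort()` emulates it: three groups (young,
high-performing older, low-performing older; full-scale sizes
384/384/1039), four tasks (letter identification, lexical, phonological
and semantic decision), 80 trials per subject and task in a 40/40
target/non-target split, and a 3 s response deadline.  Group mean
parameters default to the published fitted values
(`group_param_defaults()`); individual parameters are drawn from
truncated normals around them.  The between-subject spread defaults to
10% of each group mean — an invented, synthetic-only assumption, since
published group-level estimates do not pin down between-subject
heterogeneity.  Optionally a fraction of trials is replaced by
uniform-RT guesses (contaminants).  Deadline hits are emitted as flagged
non-responses and dropped by preprocessing.  Stimulus type is carried as
a label only: the fitted model estimates one drift per subject per task,
so items do not get their own parameters, and no linguistic item
structure (frequency, neighborhood) is simulated.

What passing recovery tests on such cohorts shows — and does not show:
they demonstrate that the estimation machinery is self-consistent under
the model's own assumptions at realistic design sizes.  They cannot
certify the unpublished between-subject spreads of any real cohort, nor
item-level effects the generator does not contain.

## Preprocessing, and a deliberate mismatch worth knowing about

Two exclusion rules are applied, in the published order: responses
faster than 300 ms are removed (strict inequality: 299 ms is excluded,
300 ms kept), then, within each subject × task × stimulus-type cell,
trials deviating more than 2.5 sample standard deviations from the cell
mean (computed once, including the candidates; single pass; cells with
fewer than two trials untouched).  Whether the original rule used sample
or population SD is not stated anywhere; sample SD is fixed here for
testability, and at cell sizes of 40 the difference is negligible.

First-passage RT distributions are strongly right-skewed, so the SD rule
trims roughly 2–3% of *clean* model-generated data — essentially the
slow tail.  Refitting after that truncation is not neutral: drift rates
recover about 8–16% high and boundary separations about 5–15% high
(non-decision time is nearly unaffected; in a desk-scale run young-group
letter values came back $t = 0.362$, $a = 1.71$, $v = 3.97$ against
generating values $0.376 / 1.62 / 3.58$).  The same fit applied to the
*un-truncated* trials recovers every group location within about 1%, so
this is purely the exclusion-step/model mismatch, not an estimation
defect.  The likelihood deliberately does not correct for the truncation:
the analysis protocol this package re-implements fitted the plain
first-passage density to excluded data, and reproducing the protocol —
including this property — is the point.  Anyone analysing real data with
this package should know that the conventional 2.5 SD rule inflates
fitted drift rates by roughly this much whenever the generating process
resembles the model.

## Numerical choices

* Density series truncated at absolute error `tol` $= 10^{-7}$, crossover
  chosen by comparing the term counts of the two expansions.
* Trial simulation inverts the analytic defective CDFs of both boundaries
  on a fine decision-time grid (default 0.5 ms; the boundary and the
  decision time are drawn jointly), which is exact up to interpolation —
  no Euler discretisation of the SDE is involved.  Posterior-predictive
  replicates use a 2 ms grid, ample for quantile summaries averaged over
  hundreds of replicates.
* Internal unit is seconds; trial tables at the I/O boundary are in
  milliseconds.
* Truncated-normal draws in the generator redraw rather than clip.
* Degenerate diagnostics fail loudly: zero within-chain variance is an
  error, not an $\hat R$ value; empty correct-response cells are flagged
  and excluded from the PPC correlation rather than imputed.

## Problem sizes used by the test-suite and acceptance runs

Recovery runs use 30 subjects per group (the upper end of the 15–30
desk band) with 80 trials per subject, chosen so that the sampling noise
of a realized cohort's group mean ($\sigma/\sqrt{30}$, about 1.8% of the
mean for boundary separation at the 10% spread default) sits well inside
the 5% recovery band — at 15 subjects that noise alone would consume
half the band.  Forward-consistency checks simulate $10^5$ trials per
condition.  The full paper preset (3 × 15,000 iterations, cohorts of
hundreds to a thousand subjects) is exposed through
`pipeline_config(preset = "paper")` and scales linearly in subjects and
iterations from the desk numbers above.

## Known limitations

* Inter-trial variability parameters ($s_v, s_t, s_z$) are fixed at zero
  by design and cannot be freed.
* Only lower-truncation-free, unbiased ($z_{rel} = 0.5$) closed forms are
  provided for the mean decision time; biased starting points are carried
  by the data types but not by the hierarchical model.
* The exceedance probabilities are reported without multiplicity
  adjustment, matching the protocol.
* Group comparisons assume the groups were fitted in one model so draws
  align by (chain, iteration).
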