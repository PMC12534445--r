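---
title: "Quantifying object-use exploration in immature chimpanzees: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying object-use exploration in immature chimpanzees: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(explorindex)
```

## The scientific problem

Wild immature chimpanzees interact with leaves, sticks, stones and other
natural objects during play and exploration. Some of these interactions
follow the typical adult forms of their community; others are *atypical* —
either *omission* uses (attempts at an adult behavior missing key motor
elements) or *commission* uses (novel, modified or recontextualized uses).
Commission uses are of particular interest because they are the behavioral
raw material of innovation. `explorindex` implements the quantitative
pipeline for such data: from coded bout records to a composite Exploration
Index, a high/low explorer classification, and the inferential models that
ask who explores (sex, maternal parity, age) and whether maternal siblings
resemble each other.

The unit of observation is the *bout*: one discrete interaction between one
individual and one object, coded with an age at bout, one of seven closed
ethogram categories (tool, doll, aggression, game, locomotion aid, physical
stimulation, play nest), and a typicality code.

## The Exploration Index

For each individual $i$ with at least one bout, five metrics are computed:

1. $m_{1i}$ — total number of bouts;
2. $m_{2i}$ — category diversity (distinct categories used, 1–7);
3. $m_{3i}$ — atypical proportion (atypical bouts / total bouts);
4. $m_{4i}$ — object-use rate (bouts per observation hour);
5. $m_{5i}$ — age diversity (distinct integer age points
   $\lfloor \text{age} \rfloor$ at which bouts occurred).

Each metric is z-transformed across individuals,
$z_{ki} = (m_{ki} - \bar m_k)/s_k$ with the sample SD $s_k$
(denominator $n-1$), and the index is the unweighted sum
$EI_i = \sum_{k=1}^5 z_{ki}$. Consequences that the tests exercise as
invariants: each z column has mean 0 and SD 1; the indexes sum to zero; and
the index is invariant to affine rescaling of any raw metric (hours in
minutes, counts doubled, ...), which is the point of z-scoring before
summing.

Three conventions deserve note. First, descriptions of the fourth metric
vary between "observation hours" and "bouts per observation hour"; the rate
is the operational definition used here, because raw effort is a property
of the observer rather than the animal. A `metric4 = "hours"` switch is
retained for sensitivity analyses. Second, age points are
$\lfloor \text{age} \rfloor$, so a 0.5-year-old's bout counts toward age
point 0; this realizes the "0, 1, 2, ... years" enumeration with half-open
yearly bins. Third, a zero-variance metric (possible in degenerate
simulated data) contributes 0 to every individual's index rather than
erroring; all profiled individuals enter every z-transform.

## Explorer classes: exact 1-D k-means and the elbow

Indexes are clustered with k-means. Because the data are one-dimensional,
the package does not use Lloyd's heuristic: an optimal k-means partition of
scalar data is contiguous in sorted order, so `kmeans_1d()` finds the
*global* optimum by dynamic programming over the $k-1$ cut positions. The
partition is deterministic — no random initialization, no seed sensitivity —
which matters because the partition itself is a headline result. Tests
verify the DP against exhaustive search over contiguous partitions and
against 200-restart Lloyd's runs.

The number of clusters is selected by the elbow method, formalized (the
method is usually named without a formula) as the $k \in \{2, \dots,
k_{\max}-1\}$ maximizing the discrete second difference
$W(k-1) - 2W(k) + W(k+1)$ of the within-cluster sum of squares, ties broken
toward smaller $k$; constant input returns $k = 1$ with a note. The default
$k_{\max} = 6$ reflects that 36 individuals cannot support finer scans.

When $k = 2$, the higher-mean cluster is labeled *high*. Contiguity makes
every optimal 2-means split a threshold rule, so every high index exceeds
every low index and the Mann-Whitney U for the high cluster is exactly
$n_1 n_2$ (and 0 in the opposite orientation). With 9 high and 27 low
explorers both published values of the statistic — 243.0 and 0.0 — are the
two orientation conventions of one perfectly separated comparison;
`partition_explorers()` reports the high-group (maximum) orientation and
carries `u_min` for the other.

## Inferential models

All estimators are implemented in the package rather than delegated, and
each is tested against an independent oracle (grid minimization of its
objective, full enumeration, or a reference implementation).

**OLS and Huber robust regression.** The index is modeled as
$EI \sim \text{sex} + \text{parity} + \text{central age}$ with treatment
contrasts (female, primiparous as reference levels) and central age defined
as the individual's mean age across its bouts. OLS is fit first; because
index residuals are prone to heavy tails, the headline fit is Huber's
M-estimator: IRLS on $\psi_c(u) = \max(-c, \min(c, u))$ with $c = 1.345$
(95% Gaussian efficiency), residual scale re-estimated each iteration as
the normal-consistent MAD about zero ($1.4826 \cdot \mathrm{median}|r|$),
convergence when the largest coefficient change drops below $10^{-8}$ or
after 50 iterations. Standard errors use Huber's small-sample-corrected
sandwich form (the default of mainstream robust-regression stacks), and
inference is normal-based ($z$ statistics, $\pm 1.96\,SE$ intervals), the
convention implied by published z-value columns. As $c \to \infty$ the
estimator reduces to OLS (tested at $c = 10^6$). A zero MAD (majority of
residuals exactly on the fit) falls back to the OLS scale with a warning.

**Logistic regression of atypicality.** Bout-level by default: atypical
(1) vs. typical (0) on age at bout, fit by Newton-Raphson with
step-halving (the log-likelihood is non-decreasing across iterations, an
invariant under test), observed-information standard errors, and explicit
detection of perfect separation (raised as an error naming the separating
covariate, rather than silently diverging). The bout level is chosen
because the published comparison is phrased in percentages *of bouts*; no
clustering adjustment is applied, matching the simple model reported. An
individual-level aggregation (binomial counts per individual, central age
as predictor) is available as a configuration alternative.

**Mann-Whitney U.** Midranks for ties; both orientations returned. The
two-sided p-value is exact — computed from the full enumeration null
distribution of U via the standard counting recurrence — when the pooled
sample size is at most 20 and tie-free (the enumeration-cost threshold);
otherwise the normal approximation with tie correction and continuity
correction is used. The exact path is verified against enumeration over
all $\binom{n_1+n_2}{n_1}$ labelings and against the reference
implementation.

**Variance components and ICC.** The similarity of maternal siblings is
quantified by the one-way random-intercept model $y_{ij} = \mu + a_i +
e_{ij}$ with maternal ID as the grouping factor and no fixed predictors.
The REML criterion is profiled analytically down to one dimension and
maximized over the intraclass correlation $\rho \in [0, 1)$ by Brent
optimization (tolerance $10^{-12}$), handling unbalanced sibship sizes;
negative components are truncated at zero. The ANOVA (method-of-moments)
estimator is always computed alongside as a cross-check; on balanced
designs with interior solutions the two coincide (tested to $10^{-6}$),
and unbalanced fits are cross-checked against `lme4::lmer`. REML rather
than ML is the default because it is the default of the stacks such
analyses are run in; the ICC is $\hat\sigma^2_b / (\hat\sigma^2_b +
\hat\sigma^2_w)$.

## The in-study fixture

`table1_fixture()` reconstructs the published 67-bout / 36-individual
accounting exactly: category and subcategory counts, the 34/33
typical/atypical split with 2 omission and 31 commission uses, the
young/old atypical shares (30/56 = 53.6% at ages $\le 4$; 3/11 = 27.3%
above), per-category bout-age ranges, the bout-count distribution
(1 x 5, 2 x 4, 8 x 3, 5 x 2, 20 x 1: mean 1.86, SD 1.13, sixteen
individuals with more than one bout, four observed at more than one
integer age), the 18/18 sex split, seven maternal sibling pairs, and
observation hours totalling 569.58 with range 2.72–37.24. (The source
prints a mean of 14.99 h alongside that total; 569.58/36 is 15.82, so the
total and range are preserved and the implied mean follows.)

What the fixture cannot honor is anything the source does not print per
individual: exact hours, the sexes of unnamed subjects, parity, and
maternal pairings beyond the one published juvenile–infant sibling pair
are deterministic *synthetic* placeholders. Aggregate statistics computed
from the fixture (frequency tables, typicality percentages, mean bouts)
reproduce the published values; *regressions* computed from it
characterize the fixture, not the study sample, because their inputs are
exactly the unpublished per-individual attributes. Reproducing the
published coefficient table therefore requires the study's deposited
per-individual data files, which are not redistributable inside this
package — the package applies the full documented estimator conventions,
and the acceptance suite records the deviation that remains without those
files rather than masking it. One further printed aggregate ("47/67 bouts
at ages 1–3") is jointly incompatible with the printed per-category age
ranges and the constraints above; the fixture yields 52/67 there.

## The synthetic-data generator

`simulate_dataset()` draws datasets with the statistical structure the
analysis assumes, so every stage can be tested with known truth and
without any download. Structure: individuals receive sex
(`p_female = 0.5`), maternal parity, observation hours uniform over the
observed 2.72–37.24 h range, and a central age uniform over 0.5–13 years;
seven sibling pairs share mothers (pair mothers are multiparous by
construction, since they have two offspring in the data); each individual
carries a latent log-scale exploration propensity split into maternal and
individual Gaussian components, with the maternal share set by
`maternal_icc_target = 0.10` through the closed-form mapping
$\sigma_m = \sigma_g \sqrt{t}$, $\sigma_e = \sigma_g \sqrt{1-t}$. Bout
counts are zero-truncated Poisson (profiled individuals used objects at
least once) with intensity
`bout_rate_base * hours * effect_sex^{female} * effect_parity^{multiparous} * exp(propensity)`;
bout ages fall within ±0.75 years of the central age; categories are
multinomial with probabilities proportional to the published 67-bout
frequency table; typicality is Bernoulli with logit $0.7 - 0.2 \cdot
\text{age}$ (the observed direction and magnitude of the age decline, and
about 50% atypical at the center of the age mix); atypical bouts are
commissions with probability 31/33.

Effect sizes not printed anywhere were calibrated once, at design time:
`effect_sex = 2.4` and `effect_parity = 3.4` make the expected
female–male and multiparous–primiparous index contrasts match the
published robust-regression magnitudes (about 2.2 and 2.7 index units) at
the 36-individual design, and `bout_rate_base = 0.022` keeps counts low.
One trade-off is documented rather than hidden: at the observed mean of
1.86 bouts/individual, zero-truncation compresses count-driven index
contrasts well below the published coefficients, so matching the effect
magnitudes (which drive the inferential validation) puts the generator's
mean count near 2.7. The generator also does not emulate the
observation process (focal vs. *ad libitum* sampling), bout narratives, or
any age structure in category choice — passing recovery tests on this
generator shows the estimators work under the *assumed* structure, not
that real data satisfy it.

With a fixed seed the generator is byte-identical across runs and
platforms: every stochastic step draws a fixed number of variates per unit
(the zero-truncated Poisson uses a single inverse-CDF uniform per
individual precisely so the RNG stream does not depend on rejected draws).

## Validation problem sizes

The shipped tests validate: oracle equivalence on small instances (Huber
and logistic vs. iteratively refined grid minimization on 12–20-point
problems, to $10^{-3}$; exact U vs. full enumeration for pooled $n \le
10$; 1-D k-means vs. exhaustive contiguous search for $n \le 12$; REML vs.
ANOVA on balanced 10 x 5 designs, to $10^{-6}$); heavy-tailed recovery of
the regression design (500 replicates of $n = 36$ with $t_3$ noise:
median bias below 0.3, sign agreement at least 95% for sex and parity);
end-to-end generator recovery (200 pipeline replicates at the default
design for coefficient signs; REML ICC at 200 groups x 5 with
$\sigma^2_b/\sigma^2_w = 1/9$, recovered within ±0.03 of 0.10 as the mean
of 20 replicates, since a single replicate's sampling SD at that design is
itself about 0.028; logistic slope from about 2,000 generated bouts within
±0.05). These sizes were chosen so each check is decisive for the property
it tests.

## Known limitations

- The package analyzes coded bout tables; it does not code typicality from
  descriptions, compute inter-observer reliability, or handle the
  observation process.
- The composite index is the unweighted z-score sum by definition;
  PCA-based or reweighted composites are out of scope beyond the
  `metric4` switch.
- Clustering is exact 1-D k-means with elbow selection only; mixture
  models and silhouette/gap selection are deliberately absent.
- The mixed model is the one-way random intercept; no crossed or nested
  random effects, no bootstrap intervals, no multiple-testing machinery
  (the analysis it implements applies none).
- Exact reproduction of published regression coefficients additionally
  depends on unstated estimator conventions in the original stack (scale
  update scheme, SE variant); the conventions used here are stated above
  and exposed as arguments.
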