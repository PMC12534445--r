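# explorindex

Quantitative analysis of object use and exploration in immature wild
chimpanzees (and similar coded ethological bout data). The package takes two
CSV tables — one row per object-use *bout* (individual, age at bout, one of
seven ethogram categories, typical/atypical coding with omission/commission
modes) and one row per *individual* (sex, maternal parity, maternal ID,
observation hours) — and produces the study-style analysis end-to-end:

- **Exploration Index**: five per-individual metrics (bout total, category
  diversity, atypical proportion, bouts per observation hour, number of
  integer age points with object use), each z-transformed across individuals
  (sample SD), summed with equal weights:
  `EI_i = Σ_k (m_ki − mean(m_k)) / sd(m_k)`.
- **Explorer classes**: globally optimal one-dimensional k-means (dynamic
  programming over contiguous splits — deterministic, no random restarts),
  elbow selection of k by the maximal second difference of the WCSS curve,
  high/low labeling and a Mann-Whitney U comparison. Optimal 2-means splits
  of scalar data are threshold rules, so the high-group U always equals
  `n_high * n_low` (243 for a 9/27 split; 0 in the reverse orientation).
- **Inferential models, implemented from scratch and oracle-tested**:
  OLS; Huber M-estimator robust regression (IRLS, c = 1.345, MAD scale,
  sandwich SEs, normal CIs) of `index ~ sex + parity + central_age`;
  bout-level logistic regression of atypicality on age (Newton-Raphson with
  step-halving and separation detection); Mann-Whitney U with an exact
  enumeration null for pooled n ≤ 20; one-way random-intercept variance
  components (profiled REML plus ANOVA cross-check) giving the intraclass
  correlation across maternal siblings.
- **Data machinery**: validated CSV I/O with classed, row-citing errors; a
  deterministic in-study fixture (`table1_fixture()`, 67 bouts / 36
  individuals reproducing every published aggregate); a seeded synthetic
  generator (`simulate_dataset()`) with sex/parity effects, maternal
  clustering and a logit-linear age decline of atypicality; and a pipeline
  (`run_pipeline()`, `render_report()`) emitting stable JSON or markdown
  reports. A thin CLI lives at `inst/cli/explorindex.R`.

## Worked example

```r
library(explorindex)

ds <- table1_fixture()          # the in-study 67-bout accounting
typicality_breakdown(ds)
#> <explor_typicality> 34 typical / 33 atypical (49.3%)
#>   atypical: 2 omission, 31 commission (93.9% of atypical)
#>   atypical share: age <= 4: 53.6%; age > 4: 27.3%

prof <- exploration_profiles(ds)   # five metrics + z-scores + index
round(mean(prof$total_bouts), 2)
#> [1] 1.86

partition_explorers(prof)
#> <explor_clusters> k = 2
#>  cluster size      mean       sd       min       max
#>      low   24 -2.069011 1.442422 -3.765905 0.1079933
#>     high   12  4.138023 2.071028  1.514279 8.0232644
#>   Mann-Whitney U (high orientation) = 288, p = 1.47e-06
```

Half the bouts (49.3%) diverge from adult-typical forms, and nearly all
atypical uses are commissions (novel/modified uses) rather than omissions;
atypicality is about twice as common in bouts by younger (≤ 4 y) as by older
immatures. The elbow method picks two explorer classes; with this fixture's
synthetic per-individual attributes the split is 12 high / 24 low, and the
perfect rank separation forced by contiguity gives U = 12 × 24 = 288.
On the bimodal 9/27 design the same machinery yields U = 243:

```r
partition_explorers(simulate_bimodal_explorers(n_high = 9, n_low = 27,
                                               gap = 6, seed = 3))
#> <explor_clusters> k = 2
#>  cluster size      mean        sd       min      max
#>      low   27 -0.251841 0.8001586 -1.666475 1.267369
#>     high    9  6.374801 0.7321083  4.863218 7.012067
#>   Mann-Whitney U (high orientation) = 243, p = 9.85e-06
```

Regression, end to end, on any dataset:

```r
r <- analyze_dataset(ds)
r$huber_fit$value      # index ~ sex + parity + central_age, Huber M-estimator
cat(render_report(r, "markdown"))
```

Note that regression coefficients computed from the fixture characterize the
fixture: the per-individual attributes they consume (sex of unnamed
subjects, parity, hours) are synthetic placeholders for values the source
tables do not print (see the methods vignette,
`vignettes/exploration-index-methods.Rmd`).

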