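# melkin

Toolkit for the quantitative questions that arise when testing whether a
single oncogenic lesion can initiate a tumor in vivo — built around mouse
melanoma models in which a Cre-conditional *Braf* allele is activated in
melanocytes and animals are watched for tumors:

* **Initiation kinetics.** If initiation is one random event with constant
  probability per unit time, tumor-free survival declines as a single
  exponential, S(t) = exp(−λ·(t − t₀)₊), with a detection lag t₀. The
  package fits this model to right-censored survival tables and extracts
  the initiation half-time t₁/₂ = ln 2 / λ from the tail slope of the log
  Kaplan-Meier curve (or by shifted-exponential maximum likelihood).
* **Tumor purity from loxP junctions.** Bulk DNA from a tumor mixes
  recombined tumor-lineage cells with stroma. Reads spanning the 34-bp
  loxP core are classified into unrecombined 5′ (U₅), unrecombined 3′
  (U₃) and recombined (R) junctions by their flanking context, and the
  recombined-cell fraction is ρ̂ = R / (R + (U₅+U₃)/2) — the halving
  corrects for unrecombined cells carrying two loxP sites where recombined
  cells carry one. Percentile-bootstrap intervals included.
* **Mutation-detection power.** A clonal heterozygous mutation in a sample
  of purity φ appears at allele fraction f = φ/2; the probability that a
  site covered C times shows no supporting read is (1−f)^C (general
  minimum-read thresholds use the binomial tail). This quantifies whether
  a shared driver mutation could have been missed at a given coverage.
* **Gene-signature membership scores.** UMI counts are converted to
  analytic Pearson residuals r = (x−μ)/√(μ+c²μ²) under a biological-CV
  noise model (θ = 1/c²), clipped at ±√n_cells, z-scored per gene, and
  averaged per cell over a signature's genes; plus Euclidean distances
  between cluster centroids in embedding space.

Each stage has a seeded synthetic-data generator (exponential-waiting-time
cohorts with lag and censoring, loxP junction read libraries at a known
cell-fraction mix, negative-binomial count matrices with planted
signatures) whose truth records make every estimate checkable end to end.

## Worked example

```r
library(melkin)

# Power: could a driver mutation hide in a 19%-pure tumor at 40X?
p_miss(coverage = 40, tumor_fraction = 0.19)
#> Mutation detection at 40X coverage (tumor fraction 0.19, allele fraction 0.095):
#>   P(miss)   = 0.01845 (1.8%)
#>   P(detect) = 0.9816

# Kinetics: simulate a cohort with a 15-week half-time and recover it
sim <- simulate_incidence_cohort(cohort_spec(
  500, half_time_weeks = 15, lag_weeks = 4, followup_weeks = 80, seed = 2
))
fit_single_hit(sim$table)
#> Single-hit initiation kinetics fit (log-linear-tail)
#>   rate lambda   : 0.04361 / week (SE 0.00217)
#>   half-time t1/2: 15.89 weeks [14.48, 17.61] (95% CI)
#>   detection lag : 4.01 weeks; events: 479; window: [4.00995, 80]

# Purity: classify a simulated junction library at rho_true = 0.36
cfg <- random_loxp_config(seed = 5)
lib <- simulate_loxp_library(
  loxp_library_spec(rho_true = 0.36, n_cells_sampled = 100, seed = 7), cfg
)
counts <- classify_reads(lib$reads, cfg)
estimate_purity(counts, seed = 1)
#> Recombined-cell fraction (tumor purity): 0.340 [0.253, 0.427] (166 informative reads)
```

The half-time lands within the fit's confidence interval of the simulated
15 weeks; the purity estimate recovers the simulated recombined-cell
fraction (34 recombined cells among 100) exactly, with an interval
reflecting ~150 informative reads — the depth at which this assay is
typically run.

Signature scoring follows the same pattern: `pearson_residuals()` →
`standardize_residuals()` → `membership_score()`, with
`simulate_count_matrix()` providing planted-signature test data; see the
methods vignette (`vignettes/melkin-methods.Rmd`) for the models and
design choices, and `inst/extdata/demo-config.yaml` +
`run_pipeline()` / `melkin_cli()` for the end-to-end pipeline.

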