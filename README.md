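# recruitnet

Time-resolved AP-MS interactor detection and co-recruitment network
inference.

## What this solves, and for whom

Affinity purification–mass spectrometry (AP-MS) experiments that profile a
tagged bait protein over a stimulation time course — against matched
wild-type control pulldowns — produce a protein × run table of label-free
intensities riddled with non-specific background and missing values. This
package is for proteomics analysts who want to go from that table to:

1. a list of **specific interactors** per time point,
2. **recruitment kinetics** per interactor, and
3. a **co-recruitment network** whose edges predict physical
   protein–protein interactions (PPIs), benchmarked against a curated
   reference interaction list.

It also ships a synthetic-data generator with planted ground truth
(specific preys, kinetic modules, contaminants, intensity-dependent
missingness), so the whole pipeline is testable without raw MS data.

## The statistics at the core

**Detection.** At each time point *t*, bait and control log₁₀ intensities
are compared by enrichment and one-way ANOVA:

    r(t) = 10^(⟨log₁₀ I⟩_bait − ⟨log₁₀ I⟩_control),   P(t) from a two-group F-test.

A protein is selected when P(t) < P\* (default 0.001, or 0.005 for a
lower-powered duplicate design) and r(t) > 2. Selection is repeated over
200 bootstrap resamples of the run values within each (protein, time,
group); `P(Detection)` is the selecting fraction, and a specific interactor
needs `P(Detection)` ≥ 0.9 at some time point. Missing values are first
imputed from the control background: Normal(μ₀, σ₀) on the log scale with
μ₀ the 5th percentile of per-protein mean control intensities and σ₀ the
mean per-protein control SD.

**Co-recruitment.** After bait normalization (constant bait intensity per
run) and per-biological-replicate max normalization of technical-replicate
means, each interactor has a recruitment profile in [0, 1] over time. For
every pair (i, j), the Pearson coefficient and its t-distribution p-value
are averaged over 1,000 bootstrap resamples of the paired profile points,
giving R_ij and P_ij. Network edges require

    P_ij < α / (N(N−1)/2),   α = 5 × 10⁻⁵  (Bonferroni over all pairs),

with a high-confidence flag at R_ij > 0.8. K-means on the correlation
matrix rows groups interactors into kinetic modules.

**Benchmarking.** Precision = validated/predicted edges; the random-network
baseline is 2K/(N(N−1)) for K reference edges among N nodes; first-neighbor
and distance-stratified validation quantify how predictive network
proximity is of membership in an independent interactor set.

## Worked example

```r
library(recruitnet)

sim <- simulate_experiment(sim_config(seed = 1))     # 241 proteins x 90 runs
res <- run_pipeline(sim$intensities, sim$design, bait = "BAIT",
                    reference = truth_reference_list(sim$truth, 1, seed = 1),
                    seed = 1)

res$detection
#> detection_result: 241 proteins, 5 time points; 38 specific interactors (bait BAIT excluded)

interactors_per_time(res$detection)
#>   time_s n_interactors
#> 1      0             0
#> 2     30            18
#> 3    120            23
#> 4    300            23
#> 5    600            18

detection_recovery(res$detection, sim$truth)[c("sensitivity", "fdp")]
#> $sensitivity [1] 0.95    $fdp [1] 0

res$benchmark
#> complete network: 38 nodes, 13 predicted edges, 13 validated (precision 1; random baseline 0.23 over 162 reference edges)
#> high-confidence network: 38 nodes, 13 predicted edges, 13 validated (precision 1; random baseline 0.23 over 162 reference edges)
```

Reading: of 40 planted specific preys, 38 are recovered with no false
discoveries; no interactor is called in the unstimulated condition because
planted recruitment starts below the twofold threshold there and rises
after stimulation. The α = 5 × 10⁻⁵ Bonferroni network keeps only the
cleanest co-recruitment edges — all 13 predicted edges are true planted
pairs (precision 1 against a full-recall reference, four times the 0.23
random baseline), at the cost of recall; see the vignette's limitations
section for the quantitative reason.

The numbered scripts in `analysis/` (`01_simulate.R` … `04_benchmark.R`)
run the same stages as a narrative workflow over two simulated bait designs
(triplicate and duplicate technical replication) and write all tables under
`results/`.

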