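# tfdep

Is a stimulus-induced transcriptional program dependent on one transcription
factor? `tfdep` answers that question for two-background RNA-seq designs —
the same cells, with and without the regulator (e.g. wild-type vs knockout
mast cells activated through the IgE receptor), each profiled unstimulated
and stimulated.

The package is written for transcriptomics analysts: every user-facing
function takes a data frame and returns a tibble, so stages chain with the
pipe, and fitted results have `tidy()`, `glance()` and `autoplot()` methods.

## The method

For each gene *g* induced in background 1, build the dependence point

> x<sub>g</sub> = log2FC<sub>bg1</sub>(stim/unstim),  y<sub>g</sub> =
> x<sub>g</sub> − log2FC<sub>bg2</sub>(stim/unstim)

If the regulator is irrelevant, y scatters around 0 and the OLS slope of the
points above (or below) y = 0 tends to zero. If induction depends entirely on
the regulator, y = x for every gene: slope 1, intercept 0, r² = 1. Real data
sit in between; each side of the plot is tested for a significantly non-zero
slope and cleaned with an iterative filter that keeps exactly the points
within *k* robust standard deviations (1.4826 × median absolute distance) of
the current fit, by perpendicular (Euclidean) point-to-line distance,
refitting until the inclusion set stabilises. Genes surviving the filter on a
significant side are *dependent* (impaired above the line, enhanced below);
the rest are *independent*.

Around that core the package provides:

* `simulate_experiment()` — negative-binomial simulator (mean μ, variance
  μ + φμ²; φ = 0 gives an exact noise-free mode) with per-gene ground truth,
  so everything is testable without external data;
* `normalize_expression()`, `fpkm_to_tpm()`, `counts_to_cpm()`,
  `counts_to_fpkm()` — unit conversions (TPM columns sum to 10⁶);
* `induction_test()` — per-background log2 fold changes (median-centred to
  remove library-composition bias), Welch tests on log2 values, BH
  adjustment, and 2-fold / 0.5-fold classification (1.5 / 0.66 preset
  available);
* `dependence_analysis()` — the dependence regression above;
* `enrich()`, `read_gmt()` — hypergeometric gene-set enrichment with
  Bonferroni adjustment;
* `run_full_pipeline()` — file-to-file orchestration with a run manifest.

## Worked example

```r
library(tfdep)
library(dplyr)

sim <- simulate_experiment(
  n_genes = 1000, n_replicates = 4, frac_induced = 0.2,
  frac_dependent_impaired = 0.8, dispersion = 0.05, seed = 42
)
cpm   <- normalize_expression(sim$counts, from = "counts", to = "cpm")
de_wt <- induction_test(cpm, sim$design, background = "WT")
de_ko <- induction_test(cpm, sim$design, background = "KO")
dep   <- dependence_analysis(de_wt, de_ko, subset = "up")
glance(dep)
#> # A tibble: 2 × 9
#>   side  slope intercept r_squared spearman_rho   bias_p n_points n_iterations converged
#>   <chr> <dbl>     <dbl>     <dbl>        <dbl>    <dbl>    <int>        <int> <lgl>
#> 1 above 0.995    0.0331     0.750        0.849 8.06e-36      115            3 TRUE
#> 2 below 0.218   -0.643      0.338        0.499 2.93e- 2       14            3 TRUE

count(tidy(dep), call)
#> # A tibble: 3 × 2
#>   call                   n
#>   <chr>              <int>
#> 1 dependent_enhanced    14
#> 2 dependent_impaired   115
#> 3 independent           19
```

Reading the numbers: 148 genes passed the 2-fold induction screen in the
"wild-type" background and entered the plot. The above side carries the
signal — slope ≈ 1 with bias p ≈ 10⁻³⁶ — and its 115 surviving genes are
called impaired; in this simulation all 115 are truly dependent (precision
1.00). The below side illustrates why the bias test matters: its 14 points
are bystanders that scraped under α = 0.05 (p = 0.029), a borderline false
positive — at small n, treat a side whose p sits near α with suspicion.
`autoplot(dep)` draws the dependence plot with the fitted lines.

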