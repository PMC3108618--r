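# pitcherwebs

Trophic diversity and maximum-likelihood path analysis for the
*Sarracenia purpurea* inquiline food web.

The water-filled leaves of the northern pitcher plant host a complete,
five-trophic-level "brown" food web — bacteria, protozoa, a rotifer, a
mite, a copepod, mosquito and midge larvae — that decomposes captured
insect prey. `pitcherwebs` is for ecologists studying how species richness
and food-web structure drive that ecosystem function. It provides, as
tested reusable components:

* **Trophic diversity (TD).** Species are clustered hierarchically by
  their rows of a symmetric binary interaction matrix ($a_{ij} = 1$ when
  species $i$ consumes or is consumed by species $j$); TD is the total
  branch length of the dendrogram, standardized to $[0,1]$ by min–max over
  the enumerated webs. Distance and linkage (Euclidean/Jaccard ×
  UPGMA/Ward/single/complete) are selected by cophenetic correlation.
* **TD-stratified experimental design.** Exhaustive enumeration of all
  $2^9$ consumer combinations, seven equal-width TD levels per richness
  treatment, and a randomized 70-web design table (10 richness levels × 7
  replicates).
* **Observed-variable path analysis.** A plain-text model DSL
  (`x -> y`, `a <-> b`), implied covariance
  $\Sigma(\theta) = (I-B)^{-1}\Psi(I-B)^{-\top}$, ML fitting of
  $F_{ML} = \ln|\Sigma| + \mathrm{tr}(S\Sigma^{-1}) - \ln|S| - p$ with
  $\chi^2 = (N-1)F_{ML}$, CFI against the independence baseline,
  $BIC = \chi^2 - df\,\ln N$, standardized coefficients, outcome $R^2$,
  and ΔBIC model ranking. `build_paper_models()` constructs the full a
  priori candidate set: 12 sampling-effect models and 4 food-web models
  (indirect/combined top-down cascade and full-web), each with and without
  an initial-ant-mass path — 32 specifications.
* **Synthetic experiments.** A seeded generator that draws per-web
  abundances and percent decomposition from the linear structural system
  the analysis assumes, including contaminant establishment and final-TD
  recomputation, plus `parameter_recovery()` for bias/RMSE/Wald-coverage
  studies.
* **Univariate analyses.** Polynomial OLS with overall F tests and the
  pooled two-sample t test.

The shipped 13-taxon interaction matrix is a synthetic reconstruction
assembled from well-documented trophic links of the system (see the
vignette); substitute your own matrix with `read_interaction_matrix()`.

## Worked example

```r
library(pitcherwebs)

m <- sarracenia_web()
head(as.data.frame(select_method(m)), 3)
#>      metric  linkage cophenetic_r
#> 1 euclidean    upgma    0.9892590
#> 2 euclidean complete    0.9875584
#> 3   jaccard    upgma    0.9870006
```

Euclidean distance + UPGMA linkage represents the trophic distance matrix
best (cophenetic correlation 0.989), so TD is measured on that dendrogram:

```r
trophic_diversity(m, c("mosquito", "midge", "rotifer"))
#> Trophic diversity (recluster, euclidean+upgma, basal taxa included)
#>   composition: mosquito, midge, rotifer
#>   raw branch length: 13.41763
```

An end-to-end synthetic run — design, simulation, covariance, all 32
models, ranking, regressions:

```r
res <- run_pipeline(run_config(output_dir = "run1", seed = 1))
head(res$ranking[, c("model", "chisq", "df", "p", "cfi", "bic", "delta_bic", "r2")], 5)
#>                       model chisq df       p   cfi   bic delta_bic    r2
#> 1 indirect_full_web_antmass  29.4 19 0.06020 0.917 -51.3       0.0 0.795
#> 2 combined_full_web_antmass  28.2 16 0.02994 0.903 -39.8      11.6 0.798
#> 3         indirect_full_web  28.0 13 0.00917 0.881 -27.3      24.1 0.783
#> 4 indirect_top_down_antmass  12.7  8 0.12092 0.939 -21.2      30.1 0.522
#> 5         combined_full_web  26.5 10 0.00317 0.869 -16.0      35.3 0.787
```

Under the generator's default truth (an active mosquito–protozoa–
decomposition cascade plus midge and ant-mass effects), the indirect full
food-web model with ant mass attains the minimum BIC, with ΔBIC > 6 to the
runner-up — i.e. sole strong support — and explains ~80% of decomposition
variance in this synthetic world. The accompanying quadratic regression of
decomposition on final richness is

```r
res$regressions$richness_quadratic
#> Polynomial OLS (degree 2, n = 70): F(2, 67) = 11.32, p = 5.83e-05, R^2 = 0.253
```

with the F degrees of freedom (2, 67) fixed by the 70-web design.

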