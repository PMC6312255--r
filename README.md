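# radOmics

Integrative dose-response analysis of paired cardiac proteome and
transcriptome data from radiation-exposed cohorts.

## The problem

In occupational radiation cohorts, lifetime external gamma dose and age
are strongly correlated (Spearman ρ ≈ 0.7): a worker with a higher
accumulated dose is, almost by construction, older. Any naive
differential analysis of post-mortem tissue therefore confounds
radiation effects with ageing. `radOmics` implements the statistical
machinery to untangle them and to cross-validate proteomic findings
against a small paired RNA-seq experiment:

* **Confounder deconvolution** — per protein, Box-Cox transformation
  followed by backward stepwise AIC selection over
  {dose, age, dose × age, BMI} on standardized covariates, and
  classification into *dose-only*, *age-only*, *dose-and-age*, *bmi* or
  *none* from the significant terms of the final model.
* **Dose-group differential analysis** — Kruskal-Wallis screening
  (exact for tiny samples) with Storey q-values
  (π̂₀ = min(1, #{p > λ}/(m(1−λ))), λ = 0.5), Dunnett many-to-one
  post-hoc comparisons against the unexposed controls (multivariate-t,
  quasi-Monte-Carlo, seeded), and classification of each significant
  protein's dose-response shape: monotone *up*/*down* versus
  non-monotone *∪* / *∩* patterns via the quadratic contrast over
  ordered group means.
* **Transcript differential expression** — a minimal, fully specified
  negative-binomial Wald pipeline for the 2-control-vs-2-high-dose
  design: <15-total-count filter, median-of-ratios size factors,
  conservatively moderated method-of-moments dispersions, per-gene NB
  GLM, BH correction.
* **Integration** — per gene–protein pair (minimum-p gene for
  multi-gene proteins), Fisher's combined probability
  X = −2(ln p₁ + ln p₂) ~ χ²₄, survival e^(−X/2)(1 + X/2), one BH
  correction across pairs, and direction-coherence accounting; plus the
  *restrictive* comparator (both layers independently significant at
  0.05) and gene-set over-representation for both feature lists.
* **A synthetic-cohort generator** — the full study design (3/6/10/10
  samples, dose–age copula, planted effect categories including ∪/∩
  shapes, paired NB transcriptome with direction-coherent effects) with
  ground-truth labels, so every statistical property is testable as
  planted-structure recovery.

Data are held in a `RadStudy` S4 container wrapping two
`SummarizedExperiment` objects (proteome and transcriptome), the
gene–protein feature map and GMT gene sets.

## Worked example

```r
library(radOmics)

study <- simulateStudy(seed = 7, nProteins = 120, nGenes = 600)
study
#> RadStudy
#>   proteome:      120 proteins x 29 samples
#>   transcriptome: 600 genes x 4 samples
#>   dose groups:   control=3 low=6 medium=10 high=10
#>   feature map:   92 gene-protein pairs
#>   gene sets:     13
#>   ground truth:  present (simulated study)

res <- runStudy(study)
res$summary$dose_age_spearman
#> 0.76248
res$summary$deconvolution_counts
#> dose_only=39 age_only=14 dose_age=21 bmi=4 none=42
res$summary$shape_counts
#> up=33 down=21 u_shape=5 cap_shape=3 flat=58
res$summary$integrative_pairs; res$summary$restrictive_pairs
#> 38
#> 25
res$summary$coherence
#> 0.789474
```

Reading the output: the cohort realizes a dose–age rank correlation of
0.76; of 120 proteins, 39 are classified dose-only and 14 age-only; 62
proteins pass the Kruskal-Wallis screen at q ≤ 0.05, of which 8 show a
non-monotone (∪/∩) dose response; Fisher integration finds 38
significant gene–protein pairs where the restrictive
both-layers-significant rule finds 25, and 79% of the significant
integrated pairs are direction-coherent between protein and transcript.

To run on your own files (tab-separated matrices, metadata, two-column
gene–protein map, GMT sets):

```r
study <- readStudy("abundance.tsv", "metadata.tsv", "counts.tsv",
                   "map.tsv", "sets.gmt", config = radConfig(seed = 1))
res <- runStudy(study, outDir = "results/")
```

or from a shell via the wrapper in `inst/scripts/radomics-run.R`.

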