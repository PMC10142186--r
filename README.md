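# venomdiv

Do snakes with more diverse diets have more diverse venoms — and if so, is
the association carried by the *number* of toxin families or by the
*evenness* of their abundances?

`venomdiv` is an R package plus a numbered analysis workflow for answering
that question with compositional data and phylogenetic comparative methods.
It is aimed at venom biologists and evolutionary ecologists working with
quantitative venomics tables (percent relative abundance per toxin protein
family, from proteomes or transcriptomes) and diet record tables (prey
record counts per prey family/order), together with a posterior sample of
dated phylogenies.

## What it computes

**Diversity indices.** Both diet and venom composition are summarized by
Shannon's index *H* = −Σ pᵢ ln pᵢ (nats; weights richness, sensitive to
rare categories) and the Gini–Simpson index *D* = 1 − Σ pᵢ² (weights
evenness, sensitive to dominant categories). Contrasting the two separates
"more toxin families" from "a more even spread of toxin families".

**Data cleaning.** Venomic records whose reported percent totals fall
outside [90%, 110%] are removed (rounding leeway around 100%), survivors
renormalized; species with fewer than 5 prey records at a taxonomic level
are excluded from that level's diet dataset.

**Phylogeny.** `mcc_tree()` selects the maximum clade credibility tree
from a sample (sum of log clade frequencies, own branch lengths, ties by
file order); `prune_to_taxa()` restricts it to the study species while
preserving root-to-tip depths; `bm_covariance()` builds the Brownian-motion
covariance matrix C (Cᵢⱼ = shared root-to-MRCA branch length).

**The regression.** Venom diversity is regressed on diet diversity under a
bivariate Brownian measurement-error model: stacked species means
z = (x̄, ȳ) are Gaussian with covariance

```
V = | σx²·C + Dx   σxy·C      |
    | σxy·C        σy²·C + Dy |
```

where Dy carries pooled within-species (among-record) variance divided by
the number of records per species. The evolutionary slope is
b₁ = σxy/σx², the intercept b₀ = a_y − b₁·a_x. The diet effect is tested by
a likelihood-ratio test (df = 1) against the σxy = 0 "intercept-only"
model, with each analysis repeated over 100 randomized starts (means of
estimates, maxima of log-likelihoods). Welch t-tests check for systematic
proteome/transcriptome differences.

**Synthetic data.** `synthetic_scenario()` + `write_scenario_bundle()`
generate complete input bundles (tree, venom CSV, diet CSV, ground-truth
JSON) with known slope: Dirichlet compositions whose *expected* index
matches each species' venom diversity, and multinomial diet counts matching
its diet diversity. Every stage of the pipeline is tested against these.

## Worked example

```r
library(venomdiv)

# a synthetic study: 60 species, 1-4 venomic records each, true slope 0.15
scenario <- synthetic_scenario(seed = 20260926)
bundle <- write_scenario_bundle(scenario, "results/bundle")

cfg <- pipeline_config(
  venom = "results/bundle/venom.csv",
  diet  = "results/bundle/diet.csv",
  trees = "results/bundle/tree.nwk",
  n_runs = 100, seed = 20260926, outdir = "results")
res <- run_pipeline(cfg)
print(res)
```

which prints:

```
<pipeline_result> 160 records across 60 species
        Index    logLik Coefficient Intercept logLik_intercept_only         LR         p
1 Shannon (F) -46.16642  0.05481145 1.1855849             -46.30620 0.27955828 0.5969909
2 Simpson (F)  54.56699  0.02140404 0.5869335              54.54250 0.04898481 0.8248393
3 Shannon (O) -24.87342  0.04827563 1.2198536             -24.94872 0.15059186 0.6979704
4 Simpson (O)  67.02451  0.02377531 0.5910176              66.99131 0.06640975 0.7966378
```

One row per (index, diet taxonomic level) analysis: full-model
log-likelihood, mean slope and intercept across the 100 restarts,
intercept-only log-likelihood, likelihood ratio, and χ²₁ p-value. All four
analyses estimate a positive diet effect, but none is significant on this
particular draw: with a true slope of 0.15 against the default Brownian and
within-species noise, a single 60-species dataset has modest power, and the
slope estimate itself is noisy (here 0.055 on the Shannon/family row).
That is not a defect of the estimator — `analysis/04_calibration.R` shows
that across repeated datasets the null is rejected at close to the nominal
5% rate (0.060 over 100 null datasets) and the slope is recovered without
bias (mean 0.142, Monte-Carlo SE 0.018, truth 0.15). On real data a
positive Simpson coefficient alongside a negative Shannon coefficient would
indicate the diet–venom association runs through evenness rather than
richness.

The numbered drivers reproduce the full workflow from scratch:

```sh
Rscript analysis/01_simulate.R     # generate the study bundle
Rscript analysis/02_diversity.R    # clean + per-record diversity table
Rscript analysis/03_regression.R   # MCC tree, 4 regressions, report.tsv
Rscript analysis/04_calibration.R  # null calibration + slope recovery
```

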