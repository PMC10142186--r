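---
title: "Diet diversity and venom diversity: model, assumptions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diet diversity and venom diversity: model, assumptions, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomdiv)
```

## The question and the quantities

Snake venoms are mixtures of toxin protein families, and quantitative
venomics reports the relative abundance of each family in a venom. Diet
databases report counts of prey records per prey taxon. Both sides are
compositional, so both can be summarized by the same ecological diversity
indices:

* **Shannon index** $H = -\sum_{i=1}^{R} p_i \ln p_i$ (nats), which weights
  the richness component of diversity and responds most to rare categories;
* **Gini–Simpson index** $D = 1 - \sum_{i=1}^{R} p_i^2$, which weights
  evenness and responds most to the dominant categories.

$p_i$ is the proportion of the venom (or diet) in the $i$-th toxin family
(or prey taxon) and $R$ the number of categories. The scientific question is
whether species with more diverse diets have more diverse venoms, and — by
contrasting the two indices — whether any association runs through richness
or through evenness.

## Data model and cleaning

A *venomic record* is one proteomic or transcriptomic profile of one species
from one study; species typically have several records. Reported percent
totals can exceed 100% (rounding) or fall short (unreported fractions).
Records are removed when the reported total is above 110% or below 90%; the
upper cap allows modest rounding leeway above 100%, and the symmetric lower
floor is this package's own choice — a profile totalling 60% is as
unreliable as one totalling 140%. Both thresholds are arguments of
`clean_venom_profiles()`. Survivors are renormalized to sum to one, which
preserves component ratios; whether to renormalize at all is a judgment
call, and we take the view that the reported proportions are correct up to
a scale error. Raw totals are kept on each profile for audit.

Diet records are pooled per species and aggregated at family or order
level separately; species with fewer than five prey records at a level are
excluded at that level, so a diet diversity value is never driven by a
couple of isolated records. Diet diversity is computed once per species
from the pooled counts and attached to every venomic record of that
species: diet is a species-level trait here, while venom diversity is
observed per record.

## Phylogeny

Dated trees come as a posterior sample. `mcc_tree()` selects the maximum
clade credibility tree: each tree is scored by the sum over its non-trivial
clades of the log of that clade's frequency in the sample (equivalently,
the product of clade credibilities is maximized), clades being tip-label
sets irrespective of branch lengths. The selected tree keeps its own branch
lengths — no averaging across the sample — and ties break by file order.
The tree is then pruned to the species present in the data
(`prune_to_taxa()`, which preserves tip-to-tip path lengths), and
`bm_covariance()` builds the Brownian-motion covariance matrix $C$ with
$C_{ij}$ the root-to-MRCA distance of tips $i$ and $j$. Unrooted input is
rejected rather than midpoint-rooted, because rooting changes $C$ and dated
posteriors are rooted by construction. No further covariance transforms
(Pagel's $\lambda$, OU) are offered: the regression model below assumes
plain Brownian motion.

## The regression model

Let $x_s$ be diet diversity and $y_s$ venom diversity of species $s$, both
on an index scale. The model treats $(x, y)$ as a bivariate Brownian motion
on the tree with rate matrix
$\Sigma = \begin{pmatrix} \sigma_x^2 & \sigma_{xy} \\ \sigma_{xy} & \sigma_y^2 \end{pmatrix}$
around phylogenetic means $(a_x, a_y)$, observed with sampling error.
Stacking the observed species means $z = (\bar x, \bar y)$,

$$ z \sim \mathcal{N}\!\left( (a_x \mathbf{1}, a_y \mathbf{1}),\;
   \begin{pmatrix} \sigma_x^2 C + D_x & \sigma_{xy} C \\
                   \sigma_{xy} C & \sigma_y^2 C + D_y \end{pmatrix} \right) $$

with $D_x$, $D_y$ diagonal sampling variances. The evolutionary regression
of $y$ on $x$ has slope $b_1 = \sigma_{xy}/\sigma_x^2$ and intercept
$b_0 = a_y - b_1 a_x$. The null "intercept-only" model constrains
$\sigma_{xy} = 0$ (hence $b_1 = 0$), and the diet effect is tested by a
likelihood-ratio test with one degree of freedom.

**Within-species variance.** Replicate venomic records of a species are
treated as independent noisy observations of its trait:
`summarize_replicates()` computes species means and a *pooled*
within-species variance $\hat\sigma_w^2 = \sum_s \sum_j (y_{sj}-\bar
y_s)^2 / \sum_s (m_s - 1)$, assigning species $s$ the sampling variance
$\hat\sigma_w^2 / m_s$. Pooling is deliberate: per-species variances from
2–4 records are far too unstable to plug in individually, and species with
a single record still need a value. Diet diversity gets sampling variance 0
by default, since it is computed once per species from pooled records; the
field is writable in the `species_summary` should a resampling variance for
diet ever be wanted.

**Estimation.** The likelihood is maximized by ML (not REML — the LRT
compares models differing in a covariance parameter, so ML log-likelihoods
are required). The search is parameterized as $(\log \sigma_x^2, \log
\sigma_y^2, \operatorname{atanh}\rho)$ with $\sigma_{xy} = \rho
\sigma_x \sigma_y$, which keeps $\Sigma$ positive definite by construction;
the two phylogenetic means are profiled out analytically (their ML values
given the covariance parameters solve a 2-parameter GLS), which reduces the
search to three dimensions — the profiled optimum is the joint ML optimum,
and in our experience this is substantially more robust than searching all
five parameters. Each start runs a derivative-free Nelder–Mead pass
followed by a BFGS polish (finite-difference gradients, relative objective
tolerance 1e-12): the simplex stage is immune to the likelihood cliff at
the positive-definiteness boundary, and the quasi-Newton stage sharpens the
optimum. A non-positive-definite covariance during the search yields
$-\infty$ rather than an error so that multi-start exploration can
continue.

**Restarts.** Convergence can be sensitive to starting conditions when
variance parameters sit near boundaries, so each analysis is repeated
(100 times by default) with randomized starts: log-rates drawn uniformly
within $\pm 1$ of the empirical GLS rates, $\operatorname{atanh}\rho$
uniform on $(-1, 1)$. Across converged runs the slope and intercept are
reported as *means*, while the log-likelihoods entering the LRT are the
per-model *maxima* — the best optimum found is the right input to a
likelihood-ratio test, whereas averaging estimates summarizes run-to-run
stability. Mean log-likelihoods are available behind
`use_mean_loglik = TRUE` as a sensitivity check. Child seeds for every run
derive deterministically from the pipeline seed, so any subset of runs
reproduces exactly. No multiple-testing correction is applied across the
four (index × level) analyses; they are reported side by side.

**Method heterogeneity.** Proteome- and transcriptome-derived records are
pooled in the main analysis; `welch_t_test()` (two-sided, unequal-variance,
Welch–Satterthwaite df) checks whether the two methods differ systematically
in the diversity they report.

## The synthetic-data generator

`synthetic_scenario()` fixes the study conditions; everything downstream is
a deterministic function of it. The generator emulates:

* an ultrametric dated phylogeny (Yule with birth rate 1 by default, or a
  star tree, or a fixed Newick string);
* species-level traits from exact branch-wise Brownian simulation — diet
  diversity $x$ with rate $\sigma_x^2$ from a root value, venom diversity
  $y = b_0 + b_1 x + \varepsilon$ with a Brownian residual;
* per-species venomic records (1–4 by default, matching the roughly 3:1
  record:species ratio of multi-study venomics compilations): each record
  is a symmetric Dirichlet composition over 12 toxin families whose
  concentration is solved so the record's *expected* index equals the
  species value plus Gaussian per-record noise (SD 0.15 nats). Within-
  species variance is therefore real compositional scatter, not additive
  noise on the index scale. The solve uses closed forms for the expected
  indices of a symmetric Dirichlet: $E[H] = \psi(K\alpha + 1) -
  \psi(\alpha + 1)$ and $E[D] = \frac{K-1}{K}\,\frac{K\alpha}{K\alpha+1}$
  (`expected_dirichlet_index()`, inverted by `solve_concentration()`);
* diet tables as multinomial draws (10–200 records per species, mirroring
  the skew of per-species record counts in diet databases) over a
  geometric-series abundance profile whose index equals the species' diet
  diversity; 15 prey families are nested two-per-order so both taxonomic
  levels are populated.

Traits are simulated directly on the index scale, since that is the scale
the regression uses. Default rates and intercept ($b_0 = 1$, $\sigma_x^2 =
0.06$, $\sigma_{y\cdot x}^2 = 0.03$, root diet diversity 1.5 nats, true
slope 0.15 — the magnitude of coefficients such analyses report) are sized
so traits stay well inside the attainable range $(0, \ln K)$: values are
clipped into that range as a safeguard and clips are logged, but routine
clipping would distort the generative regression, so the defaults make it
rare. Venom Shannon diversity of 1–2 nats is also the realistic range for
snake venoms.

What the generator does *not* emulate: real toxin-family identities or
snake taxonomy, correlation between proteome and transcriptome methods for
the same species, taxonomically structured diets, or isoform-level
diversity within toxin families. Passing tests therefore show that the
pipeline recovers what it assumes — a Brownian bivariate trait process
observed through compositional records — not that real venom evolution
follows that process.

One known bias is inherited from real data too: plug-in diversity indices
computed from a finite number of diet records slightly underestimate the
true diversity and add noise to $x$, attenuating the estimated slope. With
the default 10–200 records per species the effect is small (end-to-end
recovery of $b_1 = 0.15$ is within Monte-Carlo error), but it grows as
record counts shrink — one reason the minimum-record filter exists.

## Numerical choices and degenerate inputs

* Indices renormalize their input internally and reject all-zero or
  negative vectors; zero components contribute zero.
* Shannon values are in nats (natural log) throughout.
* The likelihood returns $-\infty$ (never an error) for non-PD covariances;
  fits that never find a finite optimum are flagged `converged = FALSE`.
* A likelihood ratio in $(-10^{-6}, 0)$ is clamped to zero with a warning;
  anything more negative is an error, because the full model cannot truly
  fit worse than its nested null.
* MCC ties break by file order; trees with a single tip or star topologies
  are legal inputs everywhere (a star tree makes the fit collapse to
  ordinary least squares, which the tests exploit as an oracle).
* Duplicate (record, toxin family) rows are an error, not silently summed:
  venomic tables should be unique per family, and silent summing would mask
  data-entry faults.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on generated data:
null calibration uses 100–200 datasets of 40 species with 5-start fits;
slope recovery uses 100 datasets of 50 species; likelihood oracle checks
use 50 instances of up to 6 species against a dense eigendecomposition
route; MCC selection is checked against brute-force clade tabulation on 50
samples of up to 20 trees and 8 tips. These sizes give Monte-Carlo error
well below the effect sizes being checked while keeping a full run to a few
minutes.

## Limitations

* The within-species variance treatment (pooled, plugged in) is one
  defensible reading of measurement-error phylogenetic regression; jointly
  estimating within-species variance is a model variant this package does
  not implement.
* No Ornstein–Uhlenbeck or $\lambda$-transformed covariance alternatives;
  if traits are strongly constrained, Brownian rates and hence the slope
  may be misestimated.
* Exact-label matching between tree tips and tables (after
  underscore/space normalization); taxonomic synonymy must be resolved
  upstream.
* The LRT relies on the asymptotic $\chi^2_1$ null; at a few dozen species
  the simulation-based calibration in the tests is the evidence that the
  nominal level holds at this size.
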