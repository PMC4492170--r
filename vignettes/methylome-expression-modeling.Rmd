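---
title: "Modeling gene expression from DNA methylation with methylex"
author: "methylex maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling gene expression from DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylex)
```

## The problem

Plant genomes carry cytosine methylation in three sequence contexts —
CG, CHG and CHH, where H is any base but G — maintained by distinct
enzymatic pathways and distributed very differently over gene bodies,
regulatory flanks, repeats and inter-genic space. How this methylation
relates to transcription is not a single monotone association: gene-body
CG methylation in particular shows an intermediate optimum and strong
interactions with gene size. `methylex` implements a complete pipeline
for studying these relationships in any species with a whole-genome
bisulfite data set:

1. **Summarization.** Per-cytosine methylated/unmethylated read counts
   are pooled into percent methylation per context over genome windows,
   per-gene regions (1 kb up-stream of the TSS, the transcribed body,
   the first 500 bp of the body, 1 kb down-stream of the transcript
   end), repeats, and TSS-anchored metaprofile bins.
2. **Modeling.** Twelve per-gene predictors — nine region-by-context
   methylation levels plus summed exon length, summed intron length and
   exon count — are Z-standardized and related to log gene expression
   through a polynomial model with all interactions up to total degree
   3 (454 candidate monomials), selected by greedy forward search under
   the Bayesian information criterion and validated by k-fold
   cross-validation.
3. **Surface analysis.** The fitted multivariate cubic is interrogated
   analytically: conditional univariate profiles in one predictor,
   their local maxima/minima and inflection points, and conversion
   between standardized units and raw percent methylation.
4. **Enrichment.** Fisher's exact test contrasts GO-term membership in
   the top decile of gene-body CG methylation against the remaining
   transcriptome.

A reference 28-term model of log expression (29 fitted factors with the
intercept) ships with the package (`publishedModel()`), together with
the simplified nested family `textModel(1:6)` that builds the gene-body
CG cubic up term by term and reproduces its documented stationary
points, e.g. a local expression maximum at standardized methylation
−0.35 under the quadratic model and −0.435 under the cubic.

## Statistical conventions

* **Pooling.** Percent methylation is always read-count-weighted:
  100 × Σ methylated / Σ (methylated + unmethylated) over the covered
  cytosines of a region. This is robust at low coverage and matches the
  per-residue count semantics of bisulfite mappers. A per-site-mean
  mode (`perSite = TRUE`) is provided for sensitivity analysis; the two
  differ whenever coverage varies across sites.
* **Strands.** Cytosines are counted per residue; CG sites are not
  collapsed across strands. Sites whose context cannot be determined
  (chromosome ends, ambiguous bases) are excluded everywhere.
* **Coordinates.** All genomic containers are Bioconductor `GRanges`
  (1-based, inclusive). GFF3 input maps directly; BED input/output is
  converted from/to its 0-based half-open convention at the boundary.
* **Region definitions.** The gene body is the transcribed span,
  introns included. The down-stream anchor is the annotated transcript
  end (a proxy for the 3′ UTR end, which many annotations lack).
  Flanks are truncated at contig edges and are *not* masked for
  overlap with neighbouring genes. Genes lacking expression or any
  region value are dropped listwise from the model feature table only.
* **Standardization** uses the sample SD (n − 1). Expression is logged
  in base 10 by default (`logBase` is configurable; the reference
  analysis does not fix a base, and surface *shapes* are unaffected).
* **Model fitting.** The model has fixed effects only, so restricted
  maximum likelihood and ordinary least squares coincide; the package
  fits OLS and computes the Gaussian-likelihood BIC (`n` = rows,
  parameters = coefficients + error variance). Forward stepwise
  selection adds the candidate that most lowers BIC and stops when no
  candidate lowers it; a bidirectional mode (`direction = "both"`) adds
  backward deletion passes. Candidates are scanned in a fixed order
  (total degree, then lexicographic exponents) and ties below 1e-9 take
  the earliest candidate, making selection fully deterministic.
  Marginality is not enforced — a cubic term may enter without its
  quadratic — because the reference model itself contains such sets.
* **Contrast test.** Region contrasts (e.g. first 500 bp vs up-stream)
  use a two-proportion z-test on pooled counts, without continuity
  correction; the reference analysis names no test, so the choice is
  documented here and isolated in `regionContrast()`.
* **Enrichment.** Two-sided Fisher exact p-values per GO term with
  Benjamini–Hochberg adjustment reported alongside the raw values;
  unannotated genes stay in the universe (they inform the
  "without-term" cells). The top fraction takes values strictly above
  the quantile threshold, so a fully tied measure yields an empty set.

## The synthetic data generator

No public accession exists for the reference methylome, so the package
ships a first-class generator (`simulateBundle()`) whose defaults *are*
the study conditions; every pipeline stage can be exercised and
validated against known ground truth without downloads.

* **Genome and genes.** I.i.d. bases at GC 0.36 on four 6 Mb
  chromosomes; 5000 non-overlapping genes (exon count 1 + Poisson(2.5),
  log-normal exon/intron lengths, transcribed length ≥ 1 kb) separated
  by gaps of at least 2.1 kb so that every 1 kb flank is inter-genic;
  labelled repeat copies scattered into the remaining gaps; an
  unmethylated 48.5 kb spike-in chromosome ("lambda").
* **Methylation.** Region/context mean levels follow the reference
  proportions (gene body 0.56/0.038/0.012 for CG/CHG/CHH, first 500 bp
  0.28/0.032/0.019, up-stream 0.35/0.11/0.027, inter-genic
  0.75/0.45/0.072, repeats 0.73/0.36/0.063). The reference table has no
  down-stream row, so down-stream flanks default to the up-stream
  levels. Each gene draws a 9-dimensional latent propensity vector from
  a Gaussian copula mapped through beta quantiles (precision 12) onto
  these means; the copula's latent correlations are moment-matched
  (Hermite-expansion NORTA calibration) so that the *configured* matrix
  — CHG–CHH 0.70 within regions, body-CG vs up-stream-CG 0.14, mildly
  negative flank-CHH vs body-CG, 0.18 elsewhere — is attained by the
  beta-scale propensities themselves. The first 500 bp of each body
  uses its own (lower) target with the remainder compensated so the
  whole-body mean is preserved, which imposes the TSS dip. Per-cytosine
  counts are beta-binomial (site precision 20) around the gene-region
  mean at a negative-binomial depth with mean 19 and median 6 (size
  0.35); zero-depth sites are unobserved. Spike-in cytosines are
  methylated only at the conversion-failure rate 0.006.
* **Expression.** Log expression is the reference 28-term model
  evaluated on the standardized *measured* region table plus Gaussian
  noise with SD 0.64 (the reference residual error). Generating from
  measured features rather than latent ones means refitting the known
  term set is an unbiased recovery problem rather than an
  errors-in-variables one — which is exactly what the recovery tests
  assert. Alternatively `signalFraction = 0.20` calibrates the noise so
  the model explains 20 % of the variance, matching the reference
  explanatory power. A configurable GO term is planted among top-decile
  gene-body-CG genes at odds ratio 4.
* **What it does not emulate.** Sequence-dependent methylation motifs,
  smoothly varying methylation along chromosomes (centromeric
  gradients), read-level artefacts (mapping bias, incomplete
  conversion outside the spike-in), TE family evolution, and biological
  coupling between methylation and expression beyond the generating
  polynomial. Passing recovery tests therefore demonstrates the
  *pipeline's* correctness under the stated statistical structure, not
  that real methylomes obey it.

## Numerical choices and degenerate inputs

* Stationary points classify roots of the profile derivative by the
  second derivative; saddle points (zero second derivative, e.g. the
  flat point of a pure cubic) are excluded. Locations are reported at
  full precision; printed reference values are truncated to two
  decimals, so comparisons in the tests use ±0.01.
* Rank-deficient designs are an error naming the collinear terms, not a
  silent drop. Stepwise selection skips candidates whose residual norm
  collapses below 1e-10 × n after orthogonalization.
* Empty candidate lists and all-tied top fractions return degenerate
  results (intercept-only model; empty set) with explicit warnings.
* A latent correlation target that exceeds the Fréchet bound of its
  beta margins is an error ("infeasible correlation target"); a matched
  matrix that loses positive definiteness is repaired by eigenvalue
  clipping at 1e-6 and rescaling to unit diagonal.
* Windows, profile bins and regions retain final partial intervals and
  truncate at contig boundaries rather than erroring.

## Problem sizes in the test suite

Unit tests run on in-memory fixtures of hundreds to thousands of sites
and a shared 250-gene / 2 Mb bundle. The acceptance suite additionally
runs the generator's default conditions — 5000 genes on 24 Mb, about
four million cytosine records — once, in roughly a minute, and asserts
coefficient recovery (≥ 90 % of the 28 reference coefficients within 3
standard errors), calibrated explanatory power (fitted R² in
[0.15, 0.25]), exact stepwise support recovery at n = 2000, and
conservation/determinism invariants. These sizes were chosen so the
asymptotics that the assertions rely on (normality of OLS estimates,
3-SE coverage) are comfortably in force while the suite stays fast.

## Known limitations

* The published-model transcription maps the reference analysis's "Percent CG"
  predictor to gene-body CG methylation; this is supported by its cubic
  and interaction coefficients matching the simplified text model, but
  it is an interpretation.
* Two worked values in the reference analysis's f⁵/f⁶ discussion (maxima at −0.05
  and 0.07/0.90) cannot be reproduced from the printed coefficients at
  any rounding; the package reproduces the coefficient algebra, and its
  grid-search oracle confirms the package's own stationary points, so
  those printed values are not used as checks.
* The reference analysis's ANOVA table prints an F that differs slightly from the
  ratio of its printed mean squares; neither value is asserted.
* Stepwise selection on real data is order-deterministic but, like all
  greedy searches, not guaranteed to find the global BIC optimum.
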