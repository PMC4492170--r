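# methylex

Summarize whole-genome bisulfite methylomes and model their effect on
gene expression.

`methylex` is for epigenomics researchers who have (i) per-cytosine
methylated/unmethylated read counts from a bisulfite experiment, (ii)
gene models, and (iii) per-gene expression values, and who want to go
beyond rank-based association: it quantifies CG/CHG/CHH methylation over
genome windows, gene regions (1 kb up-stream of the TSS, the transcribed
body, its first 500 bp, 1 kb down-stream), transposable elements and
TSS-anchored metaprofiles, then fits and dissects a polynomial model of
log gene expression.

## The model

For each gene, twelve predictors are Z-standardized: percent methylation
by context in the body (*m<sub>cg</sub>, m<sub>chg</sub>,
m<sub>chh</sub>*), up-stream (*u<sub>·</sub>*) and down-stream
(*d<sub>·</sub>*) regions, plus summed exon length *l<sub>exon</sub>*,
summed intron length *l<sub>intron</sub>* and exon count
*n<sub>exon</sub>*. Log expression is regressed on monomials of these
predictors up to total degree 3 — 454 candidate terms — selected by
greedy forward search under the Bayesian information criterion, with
k-fold cross-validated out-of-sample R². The fitted surface is then
interrogated analytically: fixing all but one predictor collapses the
model to a univariate cubic

log *GE* = c₀ + c₁ *m* + c₂ *m*² + c₃ *m*³,

whose stationary points (roots of c₁ + 2c₂ *m* + 3c₃ *m*² classified by
the second derivative) locate the methylation level of peak predicted
expression, and whose inflection point sits at −c₂/(3c₃). A reference
28-term model ships in `publishedModel()`, and `textModel(1:6)` builds
its simplified gene-body-CG family term by term. Fisher-exact GO
enrichment of the top methylation decile and one-way chromosome ANOVAs
complete the analysis. A seed-deterministic synthetic-data generator
(`simulateBundle()`) emulates the study conditions — region methylation
levels, inter-context correlations, a TSS methylation dip, long-tailed
read depth, an unmethylated spike-in — so the whole pipeline is testable
without external data.

## Worked example

```r
library(methylex)

## a synthetic input bundle: genome, genes, repeats, cytosine counts,
## expression, GO annotations (seed-deterministic)
cfg <- syntheticConfig(seed = 42, geneCount = 400L,
                       chromLengths = c(chr1 = 1.6e6, chr2 = 1.6e6))
bundle <- simulateBundle(cfg)

globalLevels(bundle$track)
#>   context   percent methylated    total
#> 1      CG 59.844906    2431319  4062700
#> 2     CHG 27.519081     913041  3317847
#> 3     CHH  4.879486     730839 14977787
#> 4   total 18.226756    4075199 22358334

conversionEfficiency(bundle$track, "lambda")
#> [1] 0.994155
```

Genome-wide methylation is highest in CG context and lowest in CHH, and
the unmethylated spike-in shows 99.4 % bisulfite conversion. Fitting the
reference 28-term set to the bundle's region table:

```r
ft  <- buildFeatureTable(bundle$regionTable)   # Z-standardized, log10 GE
fit <- fitOls(ft, modelTerms(publishedModel()))
fit
#> ModelFit: n=400, 28 terms; R2=0.3237 (adj 0.2726), RMSE=0.6849, BIC=982.1
#>   ANOVA: SS model 83.306 (df 28), SS error 174.056 (df 371), F=6.34

round(conditionalProfile(fit@spec, "m_cg"), 4)
#>      c0      c1      c2      c3
#>  2.5855 -0.0244 -0.1091 -0.0444
```

The conditional profile of gene-body CG methylation (all other
predictors at their means) is a concave cubic. Its analytic stationary
points for the simplified reference model:

```r
stationaryPoints(textModel(3))
#>     location type    value
#> 1 -1.7869736  min 2.586950
#> 2 -0.4352486  max 2.623997

zToPercent(-0.4352486)   # back to raw percent methylation
#> [1] 45.55403
```

Predicted expression peaks at standardized gene-body CG methylation
−0.435, i.e. about 46 % raw methylation — moderately methylated gene
bodies are associated with the highest expression, and both hypo- and
hyper-methylated bodies with less.

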