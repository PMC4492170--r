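## Central S4 containers.

#' Canonical predictor names of the expression model
#'
#' The twelve gene-level predictors: percent methylation by context in the
#' gene body (`m_*`), up-stream 1 kb (`u_*`) and down-stream 1 kb (`d_*`),
#' plus gene architecture (summed exon length, summed intron length, exon
#' count).
#'
#' @return Character vector of length 12.
#' @export
#' @examples
#' predictorNames()
predictorNames <- function() {
  c("m_cg", "m_chg", "m_chh",
    "u_cg", "u_chg", "u_chh",
    "d_cg", "d_chg", "d_chh",
    "l_exon", "l_intron", "n_exon")
}

.CONTEXTS <- c("CG", "CHG", "CHH")

#' MethylationTrack: per-cytosine methylation counts
#'
#' Holds one record per cytosine residue (per strand, residues are not
#' collapsed across strands) with methylated/unmethylated read counts and
#' sequence context, as a width-1 `GRanges` sorted by position, plus an
#' optional attached genome.
#'
#' @slot sites `GRanges` of width 1 with metadata columns `context`
#'   (`"CG"`, `"CHG"` or `"CHH"`), `mCount` and `uCount` (non-negative
#'   integer read counts supporting the methylated / unmethylated state).
#' @slot genome A `DNAStringSet` or `NULL`.
#' @export
setClass("MethylationTrack",
  slots = c(sites = "GRanges", genome = "ANY"))

setValidity("MethylationTrack", function(object) {
  s <- object@sites
  mc <- S4Vectors::mcols(s)
  need <- c("context", "mCount", "uCount")
  if (!all(need %in% colnames(mc)))
    return(paste("sites must carry metadata columns:",
                 paste(need, collapse = ", ")))
  if (length(s) && !all(mc$context %in% .CONTEXTS))
    return("context must be one of CG, CHG, CHH")
  if (length(s) && (any(mc$mCount < 0) || any(mc$uCount < 0)))
    return("read counts must be non-negative")
  if (length(s) && any(GenomicRanges::width(s) != 1))
    return("sites must have width 1")
  g <- object@genome
  if (!is.null(g)) {
    if (!is(g, "DNAStringSet"))
      return("genome must be a DNAStringSet or NULL")
    chr <- as.character(GenomeInfoDb::seqnames(s))
    bad <- !(chr %in% names(g))
    if (any(bad))
      return(paste0("sites on chromosomes absent from the genome: ",
                    paste(unique(chr[bad]), collapse = ", ")))
    lim <- stats::setNames(BiocGenerics::width(g), names(g))
    if (length(s) && any(GenomicRanges::start(s) > lim[chr]))
      return("site positions exceed chromosome lengths")
  }
  TRUE
})

#' Construct a MethylationTrack
#'
#' @param sites `GRanges` with metadata columns `context`, `mCount`,
#'   `uCount`; records are sorted by (chromosome, position).
#' @param genome Optional `DNAStringSet` the positions refer to.
#' @return A [MethylationTrack-class] object.
#' @export
MethylationTrack <- function(sites, genome = NULL) {
  if (length(sites))
    sites <- sites[order(as.character(GenomeInfoDb::seqnames(sites)),
                         GenomicRanges::start(sites))]
  new("MethylationTrack", sites = sites, genome = genome)
}

#' @describeIn MethylationTrack-class The underlying per-cytosine `GRanges`.
#' @param track,object A `MethylationTrack`.
#' @export
trackSites <- function(track) track@sites

#' @describeIn MethylationTrack-class The attached genome (or `NULL`).
#' @export
trackGenome <- function(track) track@genome

#' @export
setMethod("show", "MethylationTrack", function(object) {
  s <- object@sites
  cat("MethylationTrack with", length(s), "cytosine records on",
      length(unique(as.character(GenomeInfoDb::seqnames(s)))),
      "chromosome(s)\n")
  if (length(s)) {
    tab <- table(S4Vectors::mcols(s)$context)
    cat("  context counts:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  cat("  genome attached:", !is.null(object@genome), "\n")
})

#' RegionMethylationTable: per-gene region/context methylation summaries
#'
#' A `data.frame`-backed table with one row per gene holding pooled percent
#' methylation for each region x context combination, first-500-bp levels,
#' gene architecture, and (optionally) expression. Percent columns are in
#' [0, 100] or `NA` where a region holds no covered cytosine.
#'
#' Columns: `gene_id`, `chromosome`, `strand`, the nine predictors
#' `m_cg, m_chg, m_chh, u_cg, u_chg, u_chh, d_cg, d_chg, d_chh`,
#' `first500_cg, first500_chg, first500_chh`, `l_exon`, `l_intron`,
#' `n_exon`, and `expression` (`NA` when not attached).
#'
#' @export
setClass("RegionMethylationTable", contains = "data.frame")

setValidity("RegionMethylationTable", function(object) {
  need <- c("gene_id", "chromosome", "strand", predictorNames(),
            "first500_cg", "first500_chg", "first500_chh", "expression")
  miss <- setdiff(need, colnames(object))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  pct <- c("m_cg", "m_chg", "m_chh", "u_cg", "u_chg", "u_chh",
           "d_cg", "d_chg", "d_chh",
           "first500_cg", "first500_chg", "first500_chh")
  for (p in pct) {
    v <- object[[p]]
    if (any(!is.na(v) & (v < 0 | v > 100)))
      return(paste0("percent column out of [0,100]: ", p))
  }
  if (any(object$l_exon < 1) || any(object$n_exon < 1) ||
      any(object$l_intron < 0))
    return("invalid gene architecture (l_exon>=1, l_intron>=0, n_exon>=1)")
  if (anyDuplicated(object$gene_id))
    return("duplicate gene_id")
  TRUE
})

#' Drop a RegionMethylationTable to a plain data.frame
#'
#' @param x A [RegionMethylationTable-class].
#' @param row.names,optional,... Ignored (base signature).
#' @return A plain `data.frame` with the same columns.
#' @export
setMethod("as.data.frame", "RegionMethylationTable",
  function(x, row.names = NULL, optional = FALSE, ...) {
    out <- x@.Data
    names(out) <- x@names
    attr(out, "row.names") <- x@row.names
    class(out) <- "data.frame"
    out
  })

#' FeatureTable: standardized model inputs
#'
#' Row-complete, Z-standardized predictor matrix and log-expression
#' response, with the standardization constants retained so raw values can
#' be recovered and new data mapped onto the same scale.
#'
#' @slot x Numeric matrix (genes x predictors), each column mean 0, SD 1.
#' @slot y Numeric response, log expression.
#' @slot center,scale Named per-predictor raw mean and SD.
#' @slot geneIds Character row identifiers.
#' @slot logBase Base of the logarithm applied to expression.
#' @export
setClass("FeatureTable",
  slots = c(x = "matrix", y = "numeric", center = "numeric",
            scale = "numeric", geneIds = "character", logBase = "numeric"))

setValidity("FeatureTable", function(object) {
  if (nrow(object@x) != length(object@y))
    return("x and y dimensions disagree")
  if (is.null(colnames(object@x)))
    return("x must have predictor column names")
  if (length(object@center) != ncol(object@x) ||
      length(object@scale) != ncol(object@x))
    return("center/scale must match predictor count")
  if (anyNA(object@x) || anyNA(object@y))
    return("feature table must be complete (no NA)")
  z <- colMeans(object@x)
  s <- apply(object@x, 2, stats::sd)
  if (any(abs(z) > 1e-8) || any(abs(s - 1) > 1e-8))
    return("columns of x must be standardized (mean 0, SD 1)")
  TRUE
})

#' @export
setMethod("show", "FeatureTable", function(object) {
  cat("FeatureTable:", nrow(object@x), "genes x", ncol(object@x),
      "standardized predictors (log base", object@logBase, "response)\n")
})

#' PolynomialModelSpec: a polynomial model as exponent vectors
#'
#' Represents intercept + sum of monomial terms; each term is an exponent
#' vector over the predictors with total degree between 1 and 3, paired
#' with a coefficient (and optionally its standard error, t and p).
#'
#' @slot intercept Numeric scalar (may be `NA` when unset).
#' @slot exponents Integer matrix, terms x predictors, with predictor
#'   column names; rows are distinct, total degree in 1..3.
#' @slot coefficients,se,tvalue,pvalue Numeric per-term statistics
#'   (`se`/`tvalue`/`pvalue` may be `NA`).
#' @export
setClass("PolynomialModelSpec",
  slots = c(intercept = "numeric", exponents = "matrix",
            coefficients = "numeric", se = "numeric",
            tvalue = "numeric", pvalue = "numeric"))

setValidity("PolynomialModelSpec", function(object) {
  e <- object@exponents
  if (nrow(e)) {
    if (is.null(colnames(e))) return("exponents must have predictor names")
    deg <- rowSums(e)
    if (any(deg < 1)) return("every term must be non-constant")
    if (any(deg > 3)) return("total degree must be <= 3")
    if (any(e < 0) || any(e != round(e)))
      return("exponents must be non-negative integers")
    if (anyDuplicated(apply(e, 1, paste, collapse = ",")))
      return("duplicate exponent vectors")
  }
  k <- nrow(e)
  if (length(object@coefficients) != k)
    return("one coefficient per term required")
  for (s in c("se", "tvalue", "pvalue"))
    if (length(slot(object, s)) != k)
      return(paste(s, "must have one entry per term"))
  if (length(object@intercept) != 1)
    return("intercept must be a scalar")
  TRUE
})

#' Construct a PolynomialModelSpec
#'
#' @param exponents Integer matrix (terms x predictors) with column names.
#' @param coefficients Numeric vector, one per term.
#' @param intercept Scalar intercept (`NA` to leave unset).
#' @param se,tvalue,pvalue Optional per-term statistics.
#' @return A [PolynomialModelSpec-class].
#' @export
PolynomialModelSpec <- function(exponents, coefficients, intercept = NA_real_,
                                se = NULL, tvalue = NULL, pvalue = NULL) {
  exponents <- as.matrix(exponents)
  storage.mode(exponents) <- "integer"
  k <- nrow(exponents)
  blank <- rep(NA_real_, k)
  new("PolynomialModelSpec", intercept = as.numeric(intercept),
      exponents = exponents, coefficients = as.numeric(coefficients),
      se = if (is.null(se)) blank else as.numeric(se),
      tvalue = if (is.null(tvalue)) blank else as.numeric(tvalue),
      pvalue = if (is.null(pvalue)) blank else as.numeric(pvalue))
}

#' Human-readable term labels for a polynomial model
#' @param spec A `PolynomialModelSpec`.
#' @return Character vector, e.g. `"m_cg^2:l_exon"`.
#' @export
termLabels <- function(spec) {
  e <- spec@exponents
  apply(e, 1, function(row) {
    on <- which(row > 0)
    paste(ifelse(row[on] == 1, colnames(e)[on],
                 paste0(colnames(e)[on], "^", row[on])), collapse = ":")
  })
}

#' @describeIn PolynomialModelSpec-class Exponent matrix of the terms.
#' @param spec A `PolynomialModelSpec`.
#' @export
modelTerms <- function(spec) spec@exponents

#' @describeIn PolynomialModelSpec-class Number of fitted factors,
#'   counting the intercept when it is set.
#' @export
nFactors <- function(spec) nrow(spec@exponents) + !is.na(spec@intercept)

#' @export
setMethod("coef", "PolynomialModelSpec", function(object, ...) {
  stats::setNames(object@coefficients, termLabels(object))
})

#' @export
setMethod("show", "PolynomialModelSpec", function(object) {
  cat("PolynomialModelSpec with", nrow(object@exponents), "terms over",
      ncol(object@exponents), "predictors; intercept =",
      format(object@intercept), "\n")
  lab <- termLabels(object)
  o <- order(-abs(object@coefficients))
  n <- min(6L, length(lab))
  for (i in head(o, n))
    cat(sprintf("  %-28s % .4f\n", lab[i], object@coefficients[i]))
  if (length(lab) > n) cat("  ...\n")
})

#' ModelFit: least-squares fit summary
#'
#' The ANOVA decomposition, fit statistics and Gaussian BIC of an ordinary
#' least-squares polynomial fit.
#'
#' @slot spec Fitted [PolynomialModelSpec-class] (with intercept and
#'   per-term statistics filled in).
#' @slot n Number of rows fitted.
#' @slot ssModel,ssError,ssTotal Sums of squares; model + error = total.
#' @slot dfModel,dfError Degrees of freedom.
#' @slot fStatistic,r2,adjR2,rmse,bic,responseMean Fit statistics; `rmse`
#'   is the residual standard error sqrt(SSE/dfError).
#' @export
setClass("ModelFit",
  slots = c(spec = "PolynomialModelSpec", n = "integer",
            ssModel = "numeric", ssError = "numeric", ssTotal = "numeric",
            dfModel = "integer", dfError = "integer",
            fStatistic = "numeric", r2 = "numeric", adjR2 = "numeric",
            rmse = "numeric", bic = "numeric", responseMean = "numeric"))

setValidity("ModelFit", function(object) {
  tot <- object@ssModel + object@ssError
  if (object@ssTotal > 0 &&
      abs(tot - object@ssTotal) > 1e-8 * max(1, object@ssTotal))
    return("SS_model + SS_error must equal SS_total")
  TRUE
})

#' @export
setMethod("show", "ModelFit", function(object) {
  cat(sprintf(
    "ModelFit: n=%d, %d terms; R2=%.4f (adj %.4f), RMSE=%.4f, BIC=%.1f\n",
    object@n, object@dfModel, object@r2, object@adjR2, object@rmse,
    object@bic))
  cat(sprintf("  ANOVA: SS model %.3f (df %d), SS error %.3f (df %d), F=%.2f\n",
              object@ssModel, object@dfModel, object@ssError,
              object@dfError, object@fStatistic))
})
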