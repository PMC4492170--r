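## Synthetic input bundles: genome, gene models, repeats, per-cytosine
## methylation counts, expression and GO annotations with the statistical
## structure the analysis assumes. Methylation is generated at region
## resolution: each gene draws a 9-dimensional latent propensity vector
## from a Gaussian copula, mapped through beta quantiles onto the
## configured region/context mean levels; per-cytosine counts are then
## beta-binomial around the gene-region mean with a long-tailed
## (negative-binomial) read depth.

#' Default latent correlation matrix of the nine methylation measures
#'
#' Gene-level target correlations among the nine region x context
#' methylation propensities: strong CHG-CHH coupling within each region
#' (0.70), weak coupling of up-stream CG with gene-body CG (0.14),
#' slightly negative flank-CHH vs body-CG correlations, and mildly
#' positive correlations elsewhere. Positive definite by construction.
#'
#' @return 9 x 9 correlation matrix over
#'   `m_cg, m_chg, m_chh, u_cg, u_chg, u_chh, d_cg, d_chg, d_chh`.
#' @export
defaultLatentCorrelation <- function() {
  nm <- c("m_cg", "m_chg", "m_chh", "u_cg", "u_chg", "u_chh",
          "d_cg", "d_chg", "d_chh")
  R <- diag(9); dimnames(R) <- list(nm, nm)
  set2 <- function(a, b, v) { R[a, b] <<- v; R[b, a] <<- v }
  set2("m_chg", "m_chh", 0.70); set2("u_chg", "u_chh", 0.70)
  set2("d_chg", "d_chh", 0.70)
  set2("m_cg", "m_chg", 0.30); set2("m_cg", "m_chh", 0.25)
  set2("u_cg", "u_chg", 0.35); set2("u_cg", "u_chh", 0.30)
  set2("d_cg", "d_chg", 0.35); set2("d_cg", "d_chh", 0.30)
  set2("u_cg", "d_cg", 0.40); set2("u_chg", "d_chg", 0.45)
  set2("u_chh", "d_chh", 0.45)
  set2("m_cg", "u_cg", 0.14); set2("m_cg", "d_cg", 0.14)
  set2("m_chg", "u_chg", 0.35); set2("m_chg", "d_chg", 0.35)
  set2("m_chh", "u_chh", 0.35); set2("m_chh", "d_chh", 0.35)
  set2("m_cg", "u_chh", -0.05); set2("m_cg", "d_chh", -0.05)
  for (i in 1:8) for (j in (i + 1):9)
    if (R[i, j] == 0) R[i, j] <- R[j, i] <- 0.18
  R
}

#' Default region/context mean methylation targets
#'
#' Proportion of methylated read observations by genomic region and
#' sequence context: gene bodies 0.56/0.038/0.012 (CG/CHG/CHH), first
#' 500 bp of the body 0.28/0.032/0.019, up-stream regulatory 0.35/0.11/
#' 0.027, inter-genic 0.75/0.45/0.072, transposable elements
#' 0.73/0.36/0.063. Down-stream flanks default to the up-stream levels.
#'
#' @return 6 x 3 numeric matrix (rows `body`, `first500`, `upstream`,
#'   `downstream`, `intergenic`, `te`; columns `CG`, `CHG`, `CHH`).
#' @export
defaultMethTargets <- function() {
  m <- rbind(body = c(0.56, 0.038, 0.012),
             first500 = c(0.28, 0.032, 0.019),
             upstream = c(0.35, 0.11, 0.027),
             downstream = c(0.35, 0.11, 0.027),
             intergenic = c(0.75, 0.45, 0.072),
             te = c(0.73, 0.36, 0.063))
  colnames(m) <- c("CG", "CHG", "CHH")
  m
}

.defaultTeFamilies <- function() {
  data.frame(
    family = c("Helitron1", "MITE1", "Copia1", "MULE1", "Gypsy1",
               "hAT1", "LARD1", "SINE1"),
    minLen = c(400, 120, 800, 200, 900, 150, 600, 120),
    maxLen = c(1400, 400, 1500, 700, 1500, 500, 1200, 350),
    weight = c(0.30, 0.20, 0.12, 0.12, 0.08, 0.08, 0.05, 0.05))
}

#' SyntheticConfig: all generator parameters
#'
#' Complete parameterization of the synthetic input bundle; the seed
#' fully determines every output. See [syntheticConfig()] for the
#' defaults and their rationale.
#'
#' @export
setClass("SyntheticConfig",
  slots = c(seed = "numeric", chromLengths = "numeric",
            gcFraction = "numeric", geneCount = "integer",
            exonCountLambda = "numeric",
            exonLengthMeanLog = "numeric", exonLengthSdLog = "numeric",
            intronLengthMeanLog = "numeric", intronLengthSdLog = "numeric",
            minBodyLength = "numeric", gapRange = "numeric",
            teFamilies = "data.frame", teProbability = "numeric",
            methTargets = "matrix", latentCorrelation = "matrix",
            geneConcentration = "numeric", siteConcentration = "numeric",
            depthMean = "numeric", depthSize = "numeric",
            spikein = "logical", spikeinLength = "numeric",
            conversionFailure = "numeric",
            expressionModel = "PolynomialModelSpec",
            residualSD = "numeric", signalFraction = "numeric",
            logBase = "numeric", goTermCount = "integer",
            goTermRateRange = "numeric", plantedTerm = "character",
            plantedOddsRatio = "numeric", plantedBaseRate = "numeric"))

setValidity("SyntheticConfig", function(object) {
  if (any(object@chromLengths < 1e4))
    return("chromosome lengths must be at least 10 kb")
  if (any(object@methTargets < 0) || any(object@methTargets > 1))
    return("methylation targets must lie in [0, 1]")
  R <- object@latentCorrelation
  if (!isSymmetric(unname(R)))
    return("latent correlation matrix must be symmetric")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    return("latent correlation matrix must be positive semi-definite")
  if (object@conversionFailure < 0 || object@conversionFailure > 1)
    return("conversionFailure must be in [0, 1]")
  TRUE
})

#' Construct a synthetic-bundle configuration
#'
#' Defaults emulate the reference study's conditions: region/context mean
#' methylation from [defaultMethTargets()], read depth negative-binomial
#' with mean 19 and median 6 (size 0.35), bisulfite conversion failure
#' 0.006 (99.4 % efficiency), expression generated from
#' [publishedModel()] with residual SD 0.64 on the log scale, and 5000
#' genes on four 6 Mb chromosomes.
#'
#' @param seed Integer master seed (fully determines the bundle).
#' @param geneCount Number of genes.
#' @param chromLengths Named chromosome lengths (bp).
#' @param gcFraction Genome GC content.
#' @param exonCountLambda Exon count is 1 + Poisson(lambda).
#' @param exonLengthMeanLog,exonLengthSdLog,intronLengthMeanLog,intronLengthSdLog
#'   Log-normal exon/intron length parameters (bp).
#' @param minBodyLength Minimum transcribed length; shorter draws are
#'   extended so the first-500-bp sub-region is always proper.
#' @param gapRange Uniform range of the gap preceding each gene (bp);
#'   at least 2 kb so 1 kb flanks never overlap neighbouring genes.
#' @param teFamilies Repeat family table (family, minLen, maxLen, weight).
#' @param teProbability Probability an inter-genic gap hosts a repeat.
#' @param methTargets Region x context mean methylation matrix.
#' @param latentCorrelation 9 x 9 gene-level latent correlation matrix.
#' @param geneConcentration Beta precision of gene-level propensities
#'   (larger = less gene-to-gene spread around the region mean).
#' @param siteConcentration Beta precision of per-site levels around the
#'   gene-region mean (beta-binomial overdispersion).
#' @param depthMean,depthSize Negative-binomial read depth parameters.
#' @param spikein,spikeinLength Append an unmethylated spike-in
#'   chromosome (`"lambda"`) of this length.
#' @param conversionFailure Probability an unmethylated cytosine is read
#'   as methylated.
#' @param expressionModel [PolynomialModelSpec-class] generating log
#'   expression from the standardized measured features.
#' @param residualSD Gaussian noise SD on log expression.
#' @param signalFraction If set (in (0,1)), overrides `residualSD` so
#'   that var(signal)/var(total) equals this fraction.
#' @param logBase Expression is `logBase^y`.
#' @param goTermCount,goTermRateRange Number of GO terms and the uniform
#'   range of their per-gene annotation rates.
#' @param plantedTerm,plantedOddsRatio,plantedBaseRate A GO term planted
#'   at this odds ratio among top-decile gene-body-CG genes.
#' @return A validated [SyntheticConfig-class].
#' @export
syntheticConfig <- function(seed = 1L,
                            geneCount = 5000L,
                            chromLengths = stats::setNames(
                              rep(6e6, 4), paste0("chr", 1:4)),
                            gcFraction = 0.36,
                            exonCountLambda = 2.5,
                            exonLengthMeanLog = log(220),
                            exonLengthSdLog = 0.55,
                            intronLengthMeanLog = log(180),
                            intronLengthSdLog = 0.65,
                            minBodyLength = 1000,
                            gapRange = c(2100, 3500),
                            teFamilies = .defaultTeFamilies(),
                            teProbability = 0.4,
                            methTargets = defaultMethTargets(),
                            latentCorrelation = defaultLatentCorrelation(),
                            geneConcentration = 12,
                            siteConcentration = 20,
                            depthMean = 19, depthSize = 0.35,
                            spikein = TRUE, spikeinLength = 48502,
                            conversionFailure = 0.006,
                            expressionModel = publishedModel(),
                            residualSD = 0.64,
                            signalFraction = NA_real_,
                            logBase = 10,
                            goTermCount = 40L,
                            goTermRateRange = c(0.02, 0.25),
                            plantedTerm = "GO:planted",
                            plantedOddsRatio = 4,
                            plantedBaseRate = 0.10) {
  new("SyntheticConfig", seed = seed, chromLengths = chromLengths,
      gcFraction = gcFraction, geneCount = as.integer(geneCount),
      exonCountLambda = exonCountLambda,
      exonLengthMeanLog = exonLengthMeanLog,
      exonLengthSdLog = exonLengthSdLog,
      intronLengthMeanLog = intronLengthMeanLog,
      intronLengthSdLog = intronLengthSdLog,
      minBodyLength = minBodyLength, gapRange = gapRange,
      teFamilies = teFamilies, teProbability = teProbability,
      methTargets = methTargets, latentCorrelation = latentCorrelation,
      geneConcentration = geneConcentration,
      siteConcentration = siteConcentration,
      depthMean = depthMean, depthSize = depthSize,
      spikein = spikein, spikeinLength = spikeinLength,
      conversionFailure = conversionFailure,
      expressionModel = expressionModel,
      residualSD = residualSD, signalFraction = signalFraction,
      logBase = logBase, goTermCount = as.integer(goTermCount),
      goTermRateRange = goTermRateRange, plantedTerm = plantedTerm,
      plantedOddsRatio = plantedOddsRatio,
      plantedBaseRate = plantedBaseRate)
}

#' @export
setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig: seed", object@seed, "|", object@geneCount,
      "genes on", length(object@chromLengths), "chromosome(s) totalling",
      round(sum(object@chromLengths) / 1e6, 1), "Mb\n")
})

#' Generate a random genome
#'
#' I.i.d. bases at the configured GC fraction, one sequence per
#' configured chromosome, plus an unmethylated spike-in chromosome
#' (`"lambda"`) when enabled.
#'
#' @param config A [SyntheticConfig-class].
#' @return A named `DNAStringSet`.
#' @export
generateGenome <- function(config) {
  set.seed(config@seed + 1L)
  gc <- config@gcFraction
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  codes <- utf8ToInt("ACGT")
  rseq <- function(L, p) intToUtf8(codes[sample.int(4, L, replace = TRUE,
                                                    prob = p)])
  seqs <- vapply(config@chromLengths, rseq, character(1), p = prob)
  if (config@spikein)
    seqs <- c(seqs, lambda = rseq(config@spikeinLength, rep(0.25, 4)))
  Biostrings::DNAStringSet(seqs)
}

## Draw one gene structure: exon widths and intron widths.
.drawStructure <- function(config) {
  nEx <- 1L + stats::rpois(1, config@exonCountLambda)
  ex <- pmax(50, round(stats::rlnorm(nEx, config@exonLengthMeanLog,
                                     config@exonLengthSdLog)))
  inr <- if (nEx > 1)
    pmax(60, round(stats::rlnorm(nEx - 1, config@intronLengthMeanLog,
                                 config@intronLengthSdLog)))
  else numeric(0)
  short <- config@minBodyLength - (sum(ex) + sum(inr))
  if (short > 0) ex[nEx] <- ex[nEx] + short
  list(exons = ex, introns = inr)
}

#' Generate gene models and repeats
#'
#' Places non-overlapping genes sequentially along the chromosomes with
#' inter-genic gaps wide enough that every 1 kb flank stays inter-genic,
#' and scatters labelled repeat copies into the remaining gaps.
#'
#' @param genome `DNAStringSet` from [generateGenome()].
#' @param config A [SyntheticConfig-class].
#' @return List with `genes` (named `GRangesList` of exons) and `repeats`
#'   (`GRanges` with a `family` column).
#' @export
generateGenes <- function(genome, config) {
  set.seed(config@seed + 2L)
  chroms <- names(config@chromLengths)
  lens <- config@chromLengths
  nGenes <- config@geneCount
  ids <- sprintf("gene%05d", seq_len(nGenes))
  teRows <- list()
  fam <- config@teFamilies
  exChrom <- character(0); exStartAll <- numeric(0)
  exWidthAll <- numeric(0); exStrand <- character(0); exGene <- integer(0)
  ci <- 1L
  cursor <- 1000
  placed <- 0L
  while (placed < nGenes) {
    if (ci > length(chroms))
      stop("genome too small for the requested gene count (placed ",
           placed, " of ", nGenes, ")")
    st <- .drawStructure(config)
    body <- sum(st$exons) + sum(st$introns)
    gap <- stats::runif(1, config@gapRange[1], config@gapRange[2])
    start <- round(cursor + gap)
    end <- start + body - 1
    if (end + 1000 > lens[ci]) {   # no room left on this chromosome
      ci <- ci + 1L
      cursor <- 1000
      next
    }
    ## repeat in the inter-genic part of the gap (outside both flanks)
    gapLo <- cursor + 1001
    gapHi <- start - 1001
    if (gapHi - gapLo > 150 && stats::runif(1) < config@teProbability) {
      fi <- sample(nrow(fam), 1, prob = fam$weight)
      teLen <- round(stats::runif(1, fam$minLen[fi], fam$maxLen[fi]))
      if (gapLo + teLen - 1 <= gapHi) {
        teStart <- round(stats::runif(1, gapLo, gapHi - teLen + 1))
        teRows[[length(teRows) + 1L]] <- data.frame(
          chrom = chroms[ci], start = teStart, end = teStart + teLen - 1,
          family = fam$family[fi])
      }
    }
    placed <- placed + 1L
    strandG <- sample(c("+", "-"), 1)
    exStart <- start + cumsum(c(0, head(st$exons, -1) +
                                  if (length(st$introns)) st$introns else 0))
    nEx <- length(st$exons)
    exChrom <- c(exChrom, rep(chroms[ci], nEx))
    exStartAll <- c(exStartAll, exStart)
    exWidthAll <- c(exWidthAll, st$exons)
    exStrand <- c(exStrand, rep(strandG, nEx))
    exGene <- c(exGene, rep(placed, nEx))
    cursor <- end
  }
  exGr <- GenomicRanges::GRanges(
    exChrom, IRanges::IRanges(exStartAll, width = exWidthAll),
    strand = exStrand)
  genes <- GenomicRanges::split(exGr, factor(ids[exGene], levels = ids))
  repeats <- if (length(teRows)) {
    df <- do.call(rbind, teRows)
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start, df$end))
    gr$family <- df$family
    gr
  } else {
    gr <- GenomicRanges::GRanges()
    gr$family <- character(0)
    gr
  }
  list(genes = genes, repeats = repeats)
}

## Gauss-Hermite nodes/weights for E[f(Z)], Z ~ N(0,1) (probabilists'
## scaling), by Golub-Welsch on the Jacobi matrix.
.gaussHermiteProb <- function(n) {
  k <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- sqrt(k)
  J[cbind(k + 1, k)] <- sqrt(k)
  e <- eigen(J, symmetric = TRUE)
  list(z = e$values, w = e$vectors[1, ]^2)
}

## Latent Gaussian correlation that yields a target Pearson correlation
## after mapping each margin through qbeta(pnorm(z), a, b): the Hermite
## expansion X(Z) = sum_k a_k He_k(Z)/k! gives
## cov(X, Y)(rho) = sum_k a_k b_k rho^k / k!, solved for rho by uniroot.
.matchedRho <- function(sh1, sh2, target, gh, m = 20L) {
  if (target == 0) return(0)
  x <- stats::qbeta(stats::pnorm(gh$z), sh1[1], sh1[2])
  y <- stats::qbeta(stats::pnorm(gh$z), sh2[1], sh2[2])
  H <- matrix(0, length(gh$z), m + 1)
  H[, 1] <- 1; H[, 2] <- gh$z
  for (k in 2:m) H[, k + 1] <- gh$z * H[, k] - (k - 1) * H[, k - 1]
  ax <- colSums(gh$w * x * H)[-1]
  ay <- colSums(gh$w * y * H)[-1]
  fct <- factorial(seq_len(m))
  sx <- sqrt(sum(ax^2 / fct)); sy <- sqrt(sum(ay^2 / fct))
  f <- function(r) sum(ax * ay / fct * r^seq_len(m)) / (sx * sy) - target
  if ((target > 0 && f(0.9999) < 0) || (target < 0 && f(-0.9999) > 0))
    stop("infeasible correlation target ", target,
         " for the configured beta margins")
  stats::uniroot(f, c(-0.9999, 0.9999), tol = 1e-9)$root
}

## Adjust the whole 9 x 9 target matrix; repair to the nearest positive
## definite matrix by eigenvalue clipping if matching breaks PSD-ness.
.matchedLatentCorrelation <- function(Rtarget, shapes) {
  gh <- .gaussHermiteProb(64L)
  R <- diag(nrow(Rtarget))
  dimnames(R) <- dimnames(Rtarget)
  for (i in seq_len(nrow(R) - 1)) for (j in (i + 1):nrow(R))
    R[i, j] <- R[j, i] <- .matchedRho(shapes[[i]], shapes[[j]],
                                      Rtarget[i, j], gh)
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    lam <- pmax(ev$values, 1e-6)
    R <- ev$vectors %*% diag(lam) %*% t(ev$vectors)
    d <- sqrt(diag(R))
    R <- R / outer(d, d)
  }
  R
}

#' Generate per-cytosine methylation counts
#'
#' Every cytosine residue (both strands) with a defined context receives
#' a negative-binomial read depth; zero-depth sites are unobserved. Gene
#' regions draw correlated gene-level propensities through a Gaussian
#' copula mapped to beta quantiles around the configured region means;
#' the first 500 bp of each body uses its own (lower) target with the
#' remainder of the body compensated so the whole-body mean is preserved.
#' Repeats and inter-genic sites use their own targets; spike-in
#' cytosines are methylated only at the conversion-failure rate.
#'
#' @param genome `DNAStringSet`.
#' @param genes Named `GRangesList` of exons.
#' @param repeats `GRanges` with `family`.
#' @param config A [SyntheticConfig-class].
#' @return A [MethylationTrack-class] with the genome attached, plus the
#'   gene-level propensity matrix as attribute `"propensities"`.
#' @export
generateMethylation <- function(genome, genes, repeats, config) {
  set.seed(config@seed + 3L)
  arch <- geneArchitecture(genes)
  tg <- config@methTargets
  nu <- config@geneConcentration
  kap <- config@siteConcentration
  ## gene-level latent propensities via a Gaussian copula whose latent
  ## correlations are moment-matched so the configured values are the
  ## Pearson correlations of the beta-scale propensities themselves
  R <- config@latentCorrelation
  shapes <- lapply(colnames(R), function(nm) {
    reg <- switch(substr(nm, 1, 1), m = "body", u = "upstream",
                  d = "downstream")
    ctx <- toupper(sub("^[mud]_", "", nm))
    m <- tg[reg, ctx]
    c(m * nu, (1 - m) * nu)
  })
  Rlat <- .matchedLatentCorrelation(R, shapes)
  Z <- MASS::mvrnorm(nrow(arch), mu = rep(0, 9), Sigma = Rlat)
  U <- stats::pnorm(Z)
  colnames(U) <- colnames(R)
  qb <- function(u, m) stats::qbeta(u, m * nu, (1 - m) * nu)
  ctxs <- c("CG", "CHG", "CHH")
  P <- list()   # P[[region]][gene, ctx]
  for (reg in c("upstream", "body", "downstream")) {
    pre <- switch(reg, upstream = "u_", body = "m_", downstream = "d_")
    P[[reg]] <- sapply(seq_along(ctxs), function(j)
      qb(U[, paste0(pre, tolower(ctxs[j]))], tg[reg, ctxs[j]]))
  }
  P$first500 <- sapply(seq_along(ctxs), function(j)
    qb(U[, paste0("m_", tolower(ctxs[j]))], tg["first500", ctxs[j]]))
  bodyLen <- arch$end - arch$start + 1
  fw <- pmin(500, bodyLen)
  P$bodyrest <- sapply(seq_along(ctxs), function(j) {
    pr <- (bodyLen * P$body[, j] - fw * P$first500[, j]) /
      pmax(bodyLen - fw, 1)
    pmin(pmax(pr, 1e-4), 1 - 1e-4)
  })
  for (nmr in names(P)) colnames(P[[nmr]]) <- ctxs
  ## disjoint generation regions
  plus <- arch$strand == "+"
  restS <- ifelse(plus, arch$start + fw, arch$start)
  restE <- ifelse(plus, arch$end, arch$end - fw)
  regList <- list(
    upstream = data.frame(chrom = arch$chromosome,
                          start = pmax(ifelse(plus, arch$start - 1000,
                                              arch$end + 1), 1),
                          end = ifelse(plus, arch$start - 1,
                                       arch$end + 1000), gene = seq_len(nrow(arch))),
    first500 = data.frame(chrom = arch$chromosome,
                          start = ifelse(plus, arch$start, arch$end - fw + 1),
                          end = ifelse(plus, arch$start + fw - 1, arch$end),
                          gene = seq_len(nrow(arch))),
    bodyrest = data.frame(chrom = arch$chromosome, start = restS,
                          end = restE, gene = seq_len(nrow(arch))),
    downstream = data.frame(chrom = arch$chromosome,
                            start = pmax(ifelse(plus, arch$end + 1,
                                                arch$start - 1000), 1),
                            end = ifelse(plus, arch$end + 1000,
                                         arch$start - 1),
                            gene = seq_len(nrow(arch))))
  regDf <- do.call(rbind, Map(function(d, nmr) {
    d$region <- nmr; d
  }, regList, names(regList)))
  regDf <- regDf[regDf$end >= regDf$start, , drop = FALSE]
  regGr <- GenomicRanges::GRanges(regDf$chrom,
                                  IRanges::IRanges(regDf$start, regDf$end))
  ## enumerate cytosine sites chromosome by chromosome
  siteAcc <- vector("list", length(genome))
  for (ci in seq_along(genome)) {
    chr <- names(genome)[ci]
    sites <- .cytosineSites(as.character(genome[[ci]]))
    if (!nrow(sites)) next
    depth <- stats::rnbinom(nrow(sites), size = config@depthSize,
                            mu = config@depthMean)
    keep <- depth > 0
    sites <- sites[keep, , drop = FALSE]
    sites$depth <- depth[keep]
    sites$chrom <- chr
    siteAcc[[ci]] <- sites
  }
  sites <- do.call(rbind, siteAcc)
  rownames(sites) <- NULL
  n <- nrow(sites)
  siteGr <- GenomicRanges::GRanges(sites$chrom,
                                   IRanges::IRanges(sites$position, width = 1))
  pm <- rep(NA_real_, n)
  isSpike <- sites$chrom == "lambda"
  ## gene regions
  ov <- GenomicRanges::findOverlaps(siteGr, regGr)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  ctxIdx <- match(sites$context, ctxs)
  ## per-(region row, context) propensity lookup
  regP <- matrix(NA_real_, nrow(regDf), 3)
  for (nmr in names(regList)) {
    rws <- which(regDf$region == nmr)
    regP[rws, ] <- P[[nmr]][regDf$gene[rws], , drop = FALSE]
  }
  pm[qh] <- regP[cbind(sh, ctxIdx[qh])]
  ## repeats
  if (length(repeats)) {
    pte <- sapply(seq_along(ctxs), function(j)
      stats::rbeta(length(repeats), tg["te", ctxs[j]] * nu,
                   (1 - tg["te", ctxs[j]]) * nu))
    ovT <- GenomicRanges::findOverlaps(siteGr, repeats)
    qt <- S4Vectors::queryHits(ovT); st <- S4Vectors::subjectHits(ovT)
    pm[qt] <- pte[cbind(st, ctxIdx[qt])]
  }
  ## inter-genic background
  bg <- is.na(pm) & !isSpike
  pm[bg] <- tg["intergenic", ctxs][ctxIdx[bg]]
  ## site-level beta-binomial counts
  m <- integer(n)
  gen <- !isSpike
  pSite <- stats::rbeta(sum(gen), pm[gen] * kap, (1 - pm[gen]) * kap)
  m[gen] <- stats::rbinom(sum(gen), sites$depth[gen], pSite)
  if (any(isSpike))
    m[isSpike] <- stats::rbinom(sum(isSpike), sites$depth[isSpike],
                                config@conversionFailure)
  gr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$position, width = 1),
                               strand = sites$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    context = sites$context, mCount = as.integer(m),
    uCount = as.integer(sites$depth - m))
  track <- MethylationTrack(gr, genome)
  prop <- do.call(cbind, lapply(names(P), function(nmr) {
    colnames(P[[nmr]]) <- paste(nmr, ctxs, sep = "_"); P[[nmr]]
  }))
  rownames(prop) <- arch$gene_id
  attr(track, "propensities") <- prop
  track
}

#' Generate expression and GO annotations from a region table
#'
#' Log expression is the configured polynomial model evaluated on the
#' Z-standardized measured predictors plus Gaussian noise; expression is
#' `logBase^y`. Genes with incomplete predictors receive no expression
#' value. GO terms are assigned at per-term uniform rates, with one
#' planted term over-represented among top-decile gene-body-CG genes at
#' the configured odds ratio.
#'
#' @param table A [RegionMethylationTable-class] (expression not needed).
#' @param config A [SyntheticConfig-class].
#' @return List with `expression` (named vector), `annotations`
#'   (`data.frame` gene_id/term) and `truth` (signal, residual SD used,
#'   planted term and its focal set, generating model).
#' @export
generateExpression <- function(table, config) {
  set.seed(config@seed + 4L)
  df <- as.data.frame(table)
  x <- as.matrix(df[, predictorNames()])
  ok <- stats::complete.cases(x)
  xs <- scale(x[ok, , drop = FALSE])
  signal <- predict(config@expressionModel, xs)
  sdRes <- if (!is.na(config@signalFraction)) {
    f <- config@signalFraction
    stats::sd(signal) * sqrt((1 - f) / f)
  } else config@residualSD
  y <- signal + stats::rnorm(sum(ok), 0, sdRes)
  expression <- stats::setNames(config@logBase^y, df$gene_id[ok])
  ## GO annotations
  ids <- df$gene_id
  rates <- stats::runif(config@goTermCount, config@goTermRateRange[1],
                        config@goTermRateRange[2])
  terms <- sprintf("GO:%04d", seq_len(config@goTermCount))
  ann <- lapply(seq_along(terms), function(i) {
    hit <- stats::runif(length(ids)) < rates[i]
    if (any(hit)) data.frame(gene_id = ids[hit], term = terms[i]) else NULL
  })
  top <- tryCatch(topFraction(table, "m_cg", 0.10),
                  error = function(e) character(0))
  q <- config@plantedBaseRate
  orr <- config@plantedOddsRatio
  pFocal <- orr * q / (1 - q + orr * q)
  pr <- ifelse(ids %in% top, pFocal, q)
  hit <- stats::runif(length(ids)) < pr
  if (any(hit))
    ann[[length(ann) + 1L]] <- data.frame(gene_id = ids[hit],
                                          term = config@plantedTerm)
  annotations <- do.call(rbind, ann)
  rownames(annotations) <- NULL
  list(expression = expression,
       annotations = annotations,
       truth = list(signal = stats::setNames(signal, df$gene_id[ok]),
                    residualSD = sdRes, plantedTerm = config@plantedTerm,
                    plantedFocal = top, model = config@expressionModel))
}

#' Generate a complete synthetic input bundle
#'
#' Runs the whole generator: genome, gene models and repeats, cytosine
#' counts, region summarization, expression and GO annotations. With
#' `dir` set, writes the bundle as plain-text files (genome.fa,
#' genes.gff3, repeats.bed, cytosines.tsv, expression.tsv, go.tsv,
#' truth.json).
#'
#' @param config A [SyntheticConfig-class].
#' @param dir Optional output directory (created if needed).
#' @return List with `genome`, `genes`, `repeats`, `track`,
#'   `regionTable` (expression attached), `expression`, `annotations`,
#'   `truth`.
#' @export
simulateBundle <- function(config = syntheticConfig(), dir = NULL) {
  genome <- generateGenome(config)
  gg <- generateGenes(genome, config)
  track <- generateMethylation(genome, gg$genes, gg$repeats, config)
  rt <- regionMethylation(track, gg$genes)
  ge <- generateExpression(rt, config)
  rdf <- as.data.frame(rt)
  rdf$expression <- unname(ge$expression[rdf$gene_id])
  rt <- new("RegionMethylationTable", rdf)
  bundle <- list(genome = genome, genes = gg$genes, repeats = gg$repeats,
                 track = track, regionTable = rt,
                 expression = ge$expression, annotations = ge$annotations,
                 truth = ge$truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"))
    writeGenesGFF3(gg$genes, file.path(dir, "genes.gff3"))
    writeRepeatBed(gg$repeats, file.path(dir, "repeats.bed"))
    writeCytosineTable(track, file.path(dir, "cytosines.tsv"))
    writeExpressionTable(ge$expression, file.path(dir, "expression.tsv"))
    writeGoAnnotations(ge$annotations, file.path(dir, "go.tsv"))
    jsonlite::write_json(
      list(seed = config@seed,
           residualSD = ge$truth$residualSD,
           plantedTerm = ge$truth$plantedTerm,
           intercept = config@expressionModel@intercept,
           coefficients = as.list(coef(config@expressionModel)),
           signal = as.list(ge$truth$signal)),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  bundle
}
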