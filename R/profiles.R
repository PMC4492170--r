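## TSS metaprofiles, region contrasts, correlation matrix, chromosome ANOVA.

#' TSS-anchored methylation metaprofile
#'
#' Pools cytosine counts into fixed-width bins of position relative to the
#' transcription start site, oriented by gene strand (negative positions
#' are up-stream of the TSS; minus-strand genes are flipped so their 5'
#' flank maps to negative positions). By default counts are pooled across
#' genes within a bin; `perGene = TRUE` instead averages per-gene percent
#' values per bin.
#'
#' @param track A [MethylationTrack-class].
#' @param genes Named `GRangesList` of exons per gene.
#' @param bin Bin width in bp (default 100).
#' @param flank Half-width of the profiled window in bp (default 2000);
#'   bins tile [-flank, flank).
#' @param perGene Average per-gene percentages instead of pooling counts.
#' @return `data.frame` with `binStart` (bin's first position relative to
#'   the TSS), `context`, `percent`, `methylated`, `total`.
#' @export
tssProfile <- function(track, genes, bin = 100L, flank = 2000L,
                       perGene = FALSE) {
  stopifnot(length(genes) >= 1)
  arch <- geneArchitecture(genes)
  s <- trackSites(track)
  pos <- GenomicRanges::start(s)
  chrom <- as.character(GenomeInfoDb::seqnames(s))
  mc <- S4Vectors::mcols(s)
  nb <- 2L * (flank %/% bin)
  binStarts <- seq(-flank, flank - bin, by = bin)
  byChrom <- split(seq_along(pos), chrom)
  acc <- list()
  for (gi in seq_len(nrow(arch))) {
    k <- byChrom[[arch$chromosome[gi]]]
    if (is.null(k)) next
    rel <- if (arch$strand[gi] == "+") pos[k] - arch$tss[gi]
           else arch$tss[gi] - pos[k]
    inw <- rel >= -flank & rel < flank
    if (!any(inw)) next
    k <- k[inw]; rel <- rel[inw]
    acc[[length(acc) + 1L]] <- data.frame(
      gene = gi, b = (rel + flank) %/% bin + 1L,
      ctx = mc$context[k], m = mc$mCount[k],
      t = mc$mCount[k] + mc$uCount[k])
  }
  hits <- if (length(acc)) do.call(rbind, acc) else
    data.frame(gene = integer(0), b = integer(0), ctx = character(0),
               m = numeric(0), t = numeric(0))
  out <- expand.grid(binStart = binStarts, context = .CONTEXTS,
                     stringsAsFactors = FALSE)
  out$percent <- NA_real_; out$methylated <- 0; out$total <- 0
  for (j in seq_along(.CONTEXTS)) {
    h <- hits[hits$ctx == .CONTEXTS[j] & hits$t > 0, , drop = FALSE]
    if (!nrow(h)) next
    rows <- (j - 1L) * nb + seq_len(nb)
    msum <- rowsum(h$m, h$b); tsum <- rowsum(h$t, h$b)
    bi <- as.integer(rownames(msum))
    out$methylated[rows[bi]] <- msum[, 1]
    out$total[rows[bi]] <- tsum[, 1]
    if (perGene) {
      ## pool within gene x bin first, then average across genes
      gb <- paste(h$gene, h$b)
      gm <- rowsum(h$m, gb); gt <- rowsum(h$t, gb)
      gbin <- as.integer(sub("^\\S+ ", "", rownames(gm)))
      gpct <- 100 * gm[, 1] / gt[, 1]
      mm <- tapply(gpct, gbin, mean)
      out$percent[rows[as.integer(names(mm))]] <- as.numeric(mm)
    } else {
      out$percent[rows[bi]] <- 100 * msum[, 1] / tsum[, 1]
    }
  }
  out
}

#' Contrast pooled methylation between two gene regions
#'
#' Pools (methylated, total) read counts over all genes for each of two
#' regions and applies a two-proportion z-test (pooled-variance, no
#' continuity correction) in the given sequence context.
#'
#' @param track A [MethylationTrack-class].
#' @param genes Named `GRangesList` of exons per gene.
#' @param regionA,regionB One of `"upstream"`, `"body"`, `"first500"`,
#'   `"downstream"`.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param flank,first Region widths, see [defineRegions()].
#' @return List with `proportionA`, `proportionB`, `difference`
#'   (A - B, percentage points), `zValue`, `pValue` (two-sided) and
#'   `direction`.
#' @export
regionContrast <- function(track, genes, regionA, regionB, context,
                           flank = 1000L, first = 500L) {
  stopifnot(context %in% .CONTEXTS)
  choices <- c("upstream", "body", "first500", "downstream")
  stopifnot(regionA %in% choices, regionB %in% choices)
  g <- trackGenome(track)
  sl <- if (!is.null(g)) stats::setNames(BiocGenerics::width(g), names(g))
        else NULL
  regs <- defineRegions(genes, flank = flank, first = first,
                        seqlengths = sl)
  pooled <- .poolByRegion(trackSites(track), regs)
  tot <- function(reg, mat) sum(mat[regs$region == reg, context])
  mA <- tot(regionA, pooled$m); tA <- tot(regionA, pooled$t)
  mB <- tot(regionB, pooled$m); tB <- tot(regionB, pooled$t)
  if (tA == 0 || tB == 0)
    stop("zero total read count in region ",
         if (tA == 0) regionA else regionB)
  pA <- mA / tA; pB <- mB / tB
  pPool <- (mA + mB) / (tA + tB)
  se <- sqrt(pPool * (1 - pPool) * (1 / tA + 1 / tB))
  z <- if (se == 0) 0 else (pA - pB) / se
  list(proportionA = pA, proportionB = pB,
       difference = 100 * (pA - pB), zValue = z,
       pValue = 2 * stats::pnorm(-abs(z)),
       direction = if (pA > pB) "A > B" else if (pA < pB) "A < B" else "equal")
}

#' Pairwise correlations of the nine region x context measures
#'
#' Pearson correlations across genes between gene body, up-stream and
#' down-stream methylation in each context, using pairwise-complete
#' observations, with per-pair sample size and p-value.
#'
#' @param table A [RegionMethylationTable-class].
#' @return List of 9 x 9 matrices `r`, `n`, `p`. Measures with zero
#'   variance get `NA` rows/columns with a warning.
#' @export
methylationCorrelations <- function(table) {
  meas <- c("m_cg", "m_chg", "m_chh", "u_cg", "u_chg", "u_chh",
            "d_cg", "d_chg", "d_chh")
  x <- as.matrix(as.data.frame(table)[, meas])
  if (sum(stats::complete.cases(x)) < 3)
    stop("need at least 3 genes with complete methylation measures")
  v <- apply(x, 2, stats::var, na.rm = TRUE)
  degenerate <- !is.na(v) & v == 0
  if (any(degenerate))
    warning("zero-variance measure(s): ",
            paste(meas[degenerate], collapse = ", "))
  r <- matrix(NA_real_, 9, 9, dimnames = list(meas, meas))
  nmat <- r; pmat <- r
  for (i in 1:9) for (j in i:9) {
    ok <- !is.na(x[, i]) & !is.na(x[, j])
    nmat[i, j] <- nmat[j, i] <- sum(ok)
    if (degenerate[i] || degenerate[j]) next
    if (i == j) { r[i, i] <- 1; pmat[i, i] <- 0; next }
    if (sum(ok) >= 3) {
      ct <- stats::cor.test(x[ok, i], x[ok, j])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      pmat[i, j] <- pmat[j, i] <- ct$p.value
    }
  }
  list(r = r, n = nmat, p = pmat)
}

#' One-way ANOVA of methylation and expression across chromosomes
#'
#' Fits a fixed-effects one-way ANOVA with chromosome as the factor for
#' each of log expression and gene-body CG/CHG/CHH methylation.
#'
#' @param table A [RegionMethylationTable-class] with expression attached.
#' @param logBase Base for the expression log transform (default 10);
#'   zero-expression genes are dropped from the expression response.
#' @return `data.frame` with `response`, `fStatistic`, `df1`, `df2`,
#'   `pValue`.
#' @export
chromosomeAnova <- function(table, logBase = 10) {
  df <- as.data.frame(table)
  chromCounts <- table(df$chromosome)
  if (length(chromCounts) < 2)
    stop("need at least 2 chromosomes for a chromosome ANOVA")
  if (any(chromCounts < 2))
    stop("every chromosome needs at least 2 genes")
  df$log_expression <- ifelse(!is.na(df$expression) & df$expression > 0,
                              log(df$expression, base = logBase), NA)
  responses <- c("log_expression", "m_cg", "m_chg", "m_chh")
  out <- data.frame(response = responses, fStatistic = NA_real_,
                    df1 = NA_integer_, df2 = NA_integer_,
                    pValue = NA_real_)
  for (i in seq_along(responses)) {
    y <- df[[responses[i]]]
    ok <- !is.na(y)
    fit <- stats::aov(y[ok] ~ factor(df$chromosome[ok]))
    a <- stats::anova(fit)
    out$fStatistic[i] <- a$`F value`[1]
    out$df1[i] <- a$Df[1]
    out$df2[i] <- a$Df[2]
    out$pValue[i] <- a$`Pr(>F)`[1]
  }
  out
}
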