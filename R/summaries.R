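## Genome-scale methylation summaries.

## Pooled (count-weighted) or per-site-mean percent methylation for a set
## of records. Returns NA when nothing is covered.
.percentMeth <- function(mCount, uCount, perSite = FALSE, minCoverage = 1L) {
  tot <- mCount + uCount
  keep <- tot >= minCoverage
  if (!any(keep)) return(NA_real_)
  if (perSite) mean(100 * mCount[keep] / tot[keep])
  else 100 * sum(mCount[keep]) / sum(tot[keep])
}

#' Genome-wide percent methylation by context
#'
#' Percent methylation is pooled over read observations:
#' 100 x sum(methylated) / sum(methylated + unmethylated) across covered
#' cytosines, per context and pooled over all contexts. A per-site-mean
#' mode (mean of per-cytosine fractions) is available for sensitivity
#' analysis; the two differ whenever coverage varies across sites.
#'
#' @param track A [MethylationTrack-class].
#' @param perSite Average per-site fractions instead of pooling counts.
#' @param minCoverage Minimum reads for a cytosine to be included.
#' @return `data.frame` with columns `context` (`CG`, `CHG`, `CHH`,
#'   `total`), `percent`, `methylated`, `total` (read observations).
#'   Contexts with no covered cytosine get `NA` percent with a warning.
#' @export
globalLevels <- function(track, perSite = FALSE, minCoverage = 1L) {
  s <- trackSites(track)
  if (!length(s)) stop("empty methylation track")
  mc <- S4Vectors::mcols(s)
  out <- data.frame(context = c(.CONTEXTS, "total"),
                    percent = NA_real_, methylated = 0, total = 0)
  for (i in seq_along(.CONTEXTS)) {
    k <- mc$context == .CONTEXTS[i]
    out$percent[i] <- .percentMeth(mc$mCount[k], mc$uCount[k],
                                   perSite, minCoverage)
    out$methylated[i] <- sum(mc$mCount[k])
    out$total[i] <- sum(mc$mCount[k] + mc$uCount[k])
  }
  out$percent[4] <- .percentMeth(mc$mCount, mc$uCount, perSite, minCoverage)
  out$methylated[4] <- sum(mc$mCount)
  out$total[4] <- sum(mc$mCount + mc$uCount)
  if (anyNA(out$percent))
    warning("context(s) with no covered cytosine: ",
            paste(out$context[is.na(out$percent)], collapse = ", "))
  out
}

#' Windowed percent methylation across the genome
#'
#' Tiles each chromosome with non-overlapping windows (the final partial
#' window is retained) and reports pooled percent methylation per context
#' and over all contexts for each window.
#'
#' @inheritParams globalLevels
#' @param windowSize Window width in bp (default 1000).
#' @return `data.frame` with `chromosome`, `start`, `end` (1-based
#'   inclusive), `pct_cg`, `pct_chg`, `pct_chh`, `pct_total`, and per
#'   context read-observation totals `reads_cg`, `reads_chg`, `reads_chh`.
#'   Windows with no covered cytosine in a context have `NA` percent.
#' @export
windowMethylation <- function(track, windowSize = 1000L, perSite = FALSE,
                              minCoverage = 1L) {
  stopifnot(windowSize >= 1)
  s <- trackSites(track)
  if (!length(s)) stop("empty methylation track")
  chrom <- as.character(GenomeInfoDb::seqnames(s))
  g <- trackGenome(track)
  lens <- if (!is.null(g)) stats::setNames(BiocGenerics::width(g), names(g))
          else tapply(GenomicRanges::start(s), chrom, max)
  chrs <- if (!is.null(g)) names(g) else sort(unique(chrom))
  res <- vector("list", length(chrs))
  mc <- S4Vectors::mcols(s)
  pos <- GenomicRanges::start(s)
  for (ci in seq_along(chrs)) {
    chr <- chrs[ci]
    L <- as.integer(lens[[chr]])
    nw <- ceiling(L / windowSize)
    starts <- (seq_len(nw) - 1L) * windowSize + 1L
    ends <- pmin(starts + windowSize - 1L, L)
    df <- data.frame(chromosome = chr, start = starts, end = ends,
                     pct_cg = NA_real_, pct_chg = NA_real_,
                     pct_chh = NA_real_, pct_total = NA_real_,
                     reads_cg = 0, reads_chg = 0, reads_chh = 0)
    k <- chrom == chr
    if (any(k)) {
      w <- (pos[k] - 1L) %/% windowSize + 1L
      ctx <- mc$context[k]
      m <- mc$mCount[k]; u <- mc$uCount[k]
      for (j in seq_along(.CONTEXTS)) {
        sel <- ctx == .CONTEXTS[j]
        if (any(sel)) {
          byw <- split(seq_len(sum(k))[sel], w[sel])
          widx <- as.integer(names(byw))
          pcol <- paste0("pct_", tolower(.CONTEXTS[j]))
          rcol <- paste0("reads_", tolower(.CONTEXTS[j]))
          df[[pcol]][widx] <- vapply(byw, function(ii)
            .percentMeth(m[ii], u[ii], perSite, minCoverage), numeric(1))
          df[[rcol]][widx] <- vapply(byw, function(ii)
            sum(m[ii] + u[ii]), numeric(1))
        }
      }
      byw <- split(seq_len(sum(k)), w)
      widx <- as.integer(names(byw))
      df$pct_total[widx] <- vapply(byw, function(ii)
        .percentMeth(m[ii], u[ii], perSite, minCoverage), numeric(1))
    }
    res[[ci]] <- df
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Bisulfite conversion efficiency from an unmethylated spike-in
#'
#' The spike-in control (e.g. unmethylated lambda DNA) carries no true
#' methylation, so every methylated call on it is a conversion failure.
#' Efficiency is 1 - sum(methylated) / sum(total) pooled over all contexts
#' on the spike-in chromosome.
#'
#' @param track A [MethylationTrack-class].
#' @param spikein Name of the spike-in chromosome.
#' @return Fraction in [0, 1].
#' @export
conversionEfficiency <- function(track, spikein = "lambda") {
  s <- trackSites(track)
  k <- as.character(GenomeInfoDb::seqnames(s)) == spikein
  if (!any(k))
    stop("spike-in chromosome not present in track: ", spikein)
  mc <- S4Vectors::mcols(s)[k, , drop = FALSE]
  tot <- sum(mc$mCount + mc$uCount)
  if (tot == 0) stop("spike-in chromosome has zero coverage")
  1 - sum(mc$mCount) / tot
}
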