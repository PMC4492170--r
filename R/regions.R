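## Per-gene region definitions and methylation summarization.

#' Define stranded gene regions
#'
#' For each gene the up-stream region is the `flank` bp 5' of the
#' transcription start site, the gene body is the transcribed span
#' (introns included), the down-stream region is the `flank` bp 3' of the
#' transcript end, and the first-500 bp sub-region is the body's first
#' `min(first, body length)` bases from the TSS. Orientation follows the
#' gene's strand; flanks are truncated at chromosome boundaries (never an
#' error).
#'
#' @param genes Named `GRangesList` of exons per gene.
#' @param flank Flank width in bp (default 1000).
#' @param first Width of the initial gene-body sub-region (default 500).
#' @param seqlengths Optional named vector of chromosome lengths used to
#'   truncate down-stream flanks; when omitted, flanks are only truncated
#'   at position 1.
#' @return `GRanges` with metadata columns `gene_id` and `region`
#'   (`upstream`, `body`, `first500`, `downstream`). Zero-width truncated
#'   flanks are dropped.
#' @export
defineRegions <- function(genes, flank = 1000L, first = 500L,
                          seqlengths = NULL) {
  arch <- geneArchitecture(genes)
  n <- nrow(arch)
  plus <- arch$strand == "+"
  s <- arch$start; e <- arch$end
  up_s <- ifelse(plus, s - flank, e + 1)
  up_e <- ifelse(plus, s - 1, e + flank)
  dn_s <- ifelse(plus, e + 1, s - flank)
  dn_e <- ifelse(plus, e + flank, s - 1)
  bodyLen <- e - s + 1
  fw <- pmin(first, bodyLen)
  f_s <- ifelse(plus, s, e - fw + 1)
  f_e <- ifelse(plus, s + fw - 1, e)
  df <- data.frame(
    chromosome = rep(arch$chromosome, 4),
    start = c(up_s, s, f_s, dn_s),
    end = c(up_e, e, f_e, dn_e),
    strand = rep(arch$strand, 4),
    gene_id = rep(arch$gene_id, 4),
    region = rep(c("upstream", "body", "first500", "downstream"), each = n))
  ## truncate at contig edges
  df$start <- pmax(df$start, 1)
  if (!is.null(seqlengths)) {
    lim <- seqlengths[df$chromosome]
    df$end <- pmin(df$end, lim)
  }
  df <- df[df$end >= df$start, , drop = FALSE]
  GenomicRanges::GRanges(df$chromosome,
                         IRanges::IRanges(df$start, df$end),
                         strand = df$strand,
                         gene_id = df$gene_id, region = df$region)
}

## Pool mCount/total by (region index, context) over a site/region overlap.
## Returns matrices [length(regions) x 3] of methylated and total counts.
.poolByRegion <- function(sites, regions) {
  ov <- GenomicRanges::findOverlaps(sites, regions, ignore.strand = TRUE)
  si <- S4Vectors::queryHits(ov)
  ri <- S4Vectors::subjectHits(ov)
  mc <- S4Vectors::mcols(sites)
  ctx <- match(mc$context[si], .CONTEXTS)
  code <- (ri - 1L) * 3L + ctx
  msum <- rowsum(as.numeric(mc$mCount[si]), code)
  tsum <- rowsum(as.numeric(mc$mCount[si] + mc$uCount[si]), code)
  idx <- as.integer(rownames(msum))
  M <- matrix(0, nrow = length(regions), ncol = 3,
              dimnames = list(NULL, .CONTEXTS))
  TT <- M
  M[cbind((idx - 1L) %/% 3L + 1L, (idx - 1L) %% 3L + 1L)] <- msum[, 1]
  TT[cbind((idx - 1L) %/% 3L + 1L, (idx - 1L) %% 3L + 1L)] <- tsum[, 1]
  list(m = M, t = TT)
}

#' Per-gene region x context methylation table
#'
#' Computes pooled percent methylation for each gene in the up-stream
#' flank, gene body, first 500 bp of the body, and down-stream flank, for
#' each sequence context, plus gene-architecture covariates. Both strands'
#' cytosines inside a region are pooled. Genes without any covered
#' cytosine in a region get `NA` there.
#'
#' @param track A [MethylationTrack-class].
#' @param genes Named `GRangesList` of exons per gene.
#' @param expression Optional named numeric vector of per-gene expression;
#'   genes absent from it get `NA` expression.
#' @param flank,first Region widths, see [defineRegions()].
#' @return A [RegionMethylationTable-class].
#' @export
regionMethylation <- function(track, genes, expression = NULL,
                              flank = 1000L, first = 500L) {
  s <- trackSites(track)
  arch <- geneArchitecture(genes)
  trackChr <- unique(as.character(GenomeInfoDb::seqnames(s)))
  miss <- setdiff(unique(arch$chromosome), trackChr)
  if (length(miss) == length(unique(arch$chromosome)))
    stop("no gene chromosome matches the track; unmatched: ",
         paste(miss, collapse = ", "))
  g <- trackGenome(track)
  sl <- if (!is.null(g)) stats::setNames(BiocGenerics::width(g), names(g))
        else NULL
  regs <- defineRegions(genes, flank = flank, first = first,
                        seqlengths = sl)
  pooled <- .poolByRegion(s, regs)
  pct <- 100 * pooled$m / pooled$t   # NaN where total == 0
  pct[pooled$t == 0] <- NA_real_
  key <- paste(regs$gene_id, regs$region)
  getCol <- function(region, ctx) {
    i <- match(paste(arch$gene_id, region), key)
    out <- rep(NA_real_, nrow(arch))
    ok <- !is.na(i)
    out[ok] <- pct[i[ok], ctx]
    out
  }
  tab <- data.frame(
    gene_id = arch$gene_id, chromosome = arch$chromosome,
    strand = arch$strand,
    m_cg = getCol("body", "CG"), m_chg = getCol("body", "CHG"),
    m_chh = getCol("body", "CHH"),
    u_cg = getCol("upstream", "CG"), u_chg = getCol("upstream", "CHG"),
    u_chh = getCol("upstream", "CHH"),
    d_cg = getCol("downstream", "CG"), d_chg = getCol("downstream", "CHG"),
    d_chh = getCol("downstream", "CHH"),
    first500_cg = getCol("first500", "CG"),
    first500_chg = getCol("first500", "CHG"),
    first500_chh = getCol("first500", "CHH"),
    l_exon = arch$l_exon, l_intron = arch$l_intron, n_exon = arch$n_exon,
    expression = NA_real_, row.names = NULL)
  if (!is.null(expression))
    tab$expression <- unname(expression[tab$gene_id])
  new("RegionMethylationTable", tab)
}

#' Transposable-element methylation
#'
#' Repeats shorter than `minLength` bp are excluded. Percent methylation
#' is pooled per repeat copy and per family (family pooling aggregates the
#' raw counts of its member copies, not their percentages).
#'
#' @param track A [MethylationTrack-class].
#' @param repeats `GRanges` with a `family` metadata column.
#' @param minLength Minimum repeat length in bp (default 100).
#' @return List with `perRepeat` (chromosome, start, end, family, pct per
#'   context) and `perFamily` (family, copies, pooled pct per context)
#'   data frames.
#' @export
teMethylation <- function(track, repeats, minLength = 100L) {
  keep <- GenomicRanges::width(repeats) >= minLength
  repeats <- repeats[keep]
  s <- trackSites(track)
  pooled <- .poolByRegion(s, repeats)
  pct <- 100 * pooled$m / pooled$t
  pct[pooled$t == 0] <- NA_real_
  perRepeat <- data.frame(
    chromosome = as.character(GenomeInfoDb::seqnames(repeats)),
    start = GenomicRanges::start(repeats),
    end = GenomicRanges::end(repeats),
    family = repeats$family,
    pct_cg = pct[, "CG"], pct_chg = pct[, "CHG"], pct_chh = pct[, "CHH"],
    row.names = NULL)
  fams <- sort(unique(repeats$family))
  fm <- rowsum(pooled$m, repeats$family)
  ft <- rowsum(pooled$t, repeats$family)
  fpct <- 100 * fm / ft
  fpct[ft == 0] <- NA_real_
  perFamily <- data.frame(
    family = rownames(fm),
    copies = as.integer(table(repeats$family)[rownames(fm)]),
    pct_cg = fpct[, "CG"], pct_chg = fpct[, "CHG"],
    pct_chh = fpct[, "CHH"], row.names = NULL)
  perFamily <- perFamily[order(-perFamily$copies), ]
  rownames(perFamily) <- NULL
  list(perRepeat = perRepeat, perFamily = perFamily)
}
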