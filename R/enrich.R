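## GO-term enrichment in highly methylated genes.

#' Genes in the top fraction of a methylation measure
#'
#' Returns genes whose measure lies strictly above the (1 - fraction)
#' quantile; ties exactly at the threshold are excluded, so when all
#' values are equal the set is empty (with a warning).
#'
#' @param table A [RegionMethylationTable-class].
#' @param measure Column to rank by (default gene-body CG methylation).
#' @param fraction Top fraction in (0, 1) (default 0.10).
#' @return Character vector of gene ids.
#' @export
topFraction <- function(table, measure = "m_cg", fraction = 0.10) {
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must be in (0, 1)")
  df <- as.data.frame(table)
  if (!measure %in% colnames(df)) stop("unknown measure: ", measure)
  v <- df[[measure]]
  ok <- !is.na(v)
  if (sum(ok) < 10)
    stop("measure must be non-missing for at least 10 genes")
  thr <- stats::quantile(v[ok], 1 - fraction, names = FALSE)
  ids <- df$gene_id[ok & v > thr]
  if (!length(ids))
    warning("top fraction is empty (all values tie at the threshold)")
  ids
}

#' Fisher's exact test of GO-term enrichment
#'
#' For each GO term, tests the 2x2 table of (focal vs background) x
#' (annotated vs not) with a two-sided Fisher's exact test. Genes with no
#' annotation stay in the universe and inform the "without term" cells.
#' The odds ratio reported is the sample cross-product ratio
#' (a d)/(b c); the Benjamini-Hochberg adjusted p is reported alongside
#' the raw p.
#'
#' @param focal Character vector of focal gene ids (subset of universe).
#' @param universe Character vector of all gene ids under consideration.
#' @param annotations `data.frame` with columns `gene_id`, `term`.
#' @return `data.frame` per term: the four 2x2 cell counts
#'   (`focalWith`, `focalWithout`, `restWith`, `restWithout`),
#'   `oddsRatio`, `pValue`, `pAdjust`, `direction`
#'   (`"enriched"`/`"depleted"`/`"none"`). Terms annotating no gene in the
#'   universe are skipped with a message.
#' @export
goFisher <- function(focal, universe, annotations) {
  focal <- unique(focal); universe <- unique(universe)
  if (!all(focal %in% universe))
    stop("focal set must be a subset of the universe")
  ann <- annotations[annotations$gene_id %in% universe, , drop = FALSE]
  terms <- sort(unique(annotations$term))
  skipped <- setdiff(terms, unique(ann$term))
  if (length(skipped))
    message("skipping ", length(skipped),
            " term(s) annotating no gene in the universe")
  terms <- setdiff(terms, skipped)
  nFocal <- length(focal)
  nRest <- length(universe) - nFocal
  byTerm <- split(ann$gene_id, ann$term)
  res <- lapply(terms, function(tm) {
    withTerm <- unique(byTerm[[tm]])
    a <- sum(withTerm %in% focal)
    b <- nFocal - a
    cc <- length(withTerm) - a
    d <- nRest - cc
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2),
                            alternative = "two.sided")$p.value
    or <- if (b == 0 || cc == 0) {
      if (a == 0 || d == 0) 1 else Inf
    } else (a * d) / (b * cc)
    data.frame(term = tm, focalWith = a, focalWithout = b,
               restWith = cc, restWithout = d,
               oddsRatio = or, pValue = p)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(term = character(0), focalWith = integer(0),
                      focalWithout = integer(0), restWith = integer(0),
                      restWithout = integer(0), oddsRatio = numeric(0),
                      pValue = numeric(0), pAdjust = numeric(0),
                      direction = character(0)))
  out$pAdjust <- stats::p.adjust(out$pValue, method = "BH")
  out$direction <- ifelse(out$oddsRatio > 1, "enriched",
                          ifelse(out$oddsRatio < 1, "depleted", "none"))
  rownames(out) <- NULL
  out[order(out$pValue), ]
}
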