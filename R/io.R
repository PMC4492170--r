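## Readers and writers for the plain-text formats the pipeline touches.
## The per-cytosine table is a fixed 6-column TSV (no header):
##   chromosome, position (1-based), strand, context, count_methylated,
##   count_unmethylated
## mirroring common bisulfite cytosine-report exports.

#' Read a per-cytosine methylation count table
#'
#' @param path Path to a 6-column headerless TSV: chromosome, 1-based
#'   position, strand (+/-), context (CG/CHG/CHH), methylated read count,
#'   unmethylated read count.
#' @param genome Optional `DNAStringSet`. When supplied, each record's
#'   context (and the presence of a cytosine at the stated position and
#'   strand) is validated against the sequence; the first disagreement
#'   raises an error.
#' @return A [MethylationTrack-class], records sorted by
#'   (chromosome, position). An empty file yields an empty track with a
#'   warning.
#' @export
readCytosineTable <- function(path, genome = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty cytosine table: ", path)
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      context = character(0), mCount = integer(0), uCount = integer(0))
    return(MethylationTrack(gr, genome))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L))
    stop("malformed cytosine table line ", which(nf != 6L)[1],
         ": expected 6 tab-separated fields, found ", nf[nf != 6L][1])
  m <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  cm <- suppressWarnings(as.integer(m[, 5]))
  cu <- suppressWarnings(as.integer(m[, 6]))
  bad <- which(is.na(pos) | pos < 1L | is.na(cm) | cm < 0L |
               is.na(cu) | cu < 0L |
               !(m[, 3] %in% c("+", "-")) | !(m[, 4] %in% .CONTEXTS))
  if (length(bad))
    stop("malformed cytosine table line ", bad[1], ": ", lines[bad[1]])
  gr <- GenomicRanges::GRanges(m[, 1], IRanges::IRanges(pos, width = 1),
                               strand = m[, 3])
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    context = m[, 4], mCount = cm, uCount = cu)
  if (!is.null(genome)) {
    ctx <- classifyContext(genome, as.character(GenomeInfoDb::seqnames(gr)),
                           GenomicRanges::start(gr),
                           as.character(BiocGenerics::strand(gr)))
    off <- which(ctx != S4Vectors::mcols(gr)$context)
    if (length(off)) {
      i <- off[1]
      stop("context disagrees with genome at ",
           as.character(GenomeInfoDb::seqnames(gr))[i], ":",
           GenomicRanges::start(gr)[i], " (claimed ",
           S4Vectors::mcols(gr)$context[i], ", sequence gives ", ctx[i],
           "); ", length(off), " offending record(s) in total")
    }
  }
  MethylationTrack(gr, genome)
}

#' Write a per-cytosine methylation count table
#'
#' Inverse of [readCytosineTable()]; emits the canonical 6-column TSV.
#'
#' @param track A [MethylationTrack-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeCytosineTable <- function(track, path) {
  s <- trackSites(track)
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(s)),
    pos = GenomicRanges::start(s),
    strand = as.character(BiocGenerics::strand(s)),
    context = S4Vectors::mcols(s)$context,
    mCount = S4Vectors::mcols(s)$mCount,
    uCount = S4Vectors::mcols(s)$uCount)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon features. One gene model is built per `gene`
#' feature using its first `mRNA` child in file order (the pipeline carries
#' one expression value per gene, so a single isoform is kept). GFF3
#' 1-based inclusive coordinates map directly onto `GRanges`.
#'
#' @param path Path to a GFF3 file.
#' @return A named `GRangesList`, one element per gene holding its exons
#'   sorted in genomic order; names are gene IDs.
#' @export
readGFF3Genes <- function(path) {
  gr <- rtracklayer::import(path)
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  if (!length(genes)) stop("no gene features in ", path)
  if (any(is.na(genes$ID)) || any(!nzchar(genes$ID)))
    stop("gene feature without an ID attribute in ", path)
  mrna <- gr[type == "mRNA"]
  exon <- gr[type == "exon"]
  mrnaParent <- as.character(S4Vectors::unstrsplit(mrna$Parent, ","))
  exonParent <- as.character(S4Vectors::unstrsplit(exon$Parent, ","))
  out <- vector("list", length(genes))
  names(out) <- genes$ID
  for (i in seq_along(genes)) {
    gid <- genes$ID[i]
    mi <- which(mrnaParent == gid)
    if (!length(mi))
      stop("gene ", gid, " has no mRNA child")
    tx <- mrna[mi[1]]
    ex <- exon[exonParent == as.character(tx$ID)]
    if (!length(ex))
      stop("gene ", gid, " has an mRNA with no exon children")
    if (any(GenomicRanges::start(ex) < GenomicRanges::start(genes[i])) ||
        any(GenomicRanges::end(ex) > GenomicRanges::end(genes[i])))
      stop("exon outside gene span for gene ", gid)
    ex <- ex[order(GenomicRanges::start(ex))]
    S4Vectors::mcols(ex) <- NULL
    out[[i]] <- ex
  }
  GenomicRanges::GRangesList(out)
}

#' Write gene models as GFF3
#'
#' Emits a canonical gene/mRNA/exon hierarchy (one mRNA per gene) that
#' [readGFF3Genes()] reads back to an identical structure.
#'
#' @param genes Named `GRangesList` of exons per gene.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeGenesGFF3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (gid in names(genes)) {
    ex <- genes[[gid]]
    chr <- as.character(GenomeInfoDb::seqnames(ex))[1]
    str <- as.character(BiocGenerics::strand(ex))[1]
    s <- min(GenomicRanges::start(ex)); e <- max(GenomicRanges::end(ex))
    tid <- paste0(gid, ".1")
    writeLines(c(
      paste(chr, "methylex", "gene", s, e, ".", str, ".",
            paste0("ID=", gid), sep = "\t"),
      paste(chr, "methylex", "mRNA", s, e, ".", str, ".",
            paste0("ID=", tid, ";Parent=", gid), sep = "\t"),
      vapply(seq_along(ex), function(j)
        paste(chr, "methylex", "exon", GenomicRanges::start(ex)[j],
              GenomicRanges::end(ex)[j], ".", str, ".",
              paste0("ID=", tid, ".exon", j, ";Parent=", tid), sep = "\t"),
        character(1))), con)
  }
  invisible(path)
}

#' Gene architecture summaries
#'
#' @param genes Named `GRangesList` of exons per gene.
#' @return `data.frame` with `gene_id`, `chromosome`, `strand`, `start`,
#'   `end` (gene span, 1-based inclusive), `l_exon` (summed exon length),
#'   `l_intron` (span minus exons), `n_exon`, and `tss` (transcription
#'   start: span start on `+`, span end on `-`).
#' @export
geneArchitecture <- function(genes) {
  if (!length(genes)) stop("no genes")
  n <- length(genes)
  cnt <- lengths(genes)
  if (any(cnt < 1)) stop("every gene needs at least one exon")
  ex <- unlist(genes, use.names = FALSE)
  gidx <- rep.int(seq_len(n), cnt)
  first <- cumsum(cnt) - cnt + 1L
  f <- factor(gidx, levels = seq_len(n))
  stAll <- GenomicRanges::start(ex)
  enAll <- GenomicRanges::end(ex)
  st <- as.numeric(tapply(stAll, f, min))
  en <- as.numeric(tapply(enAll, f, max))
  lex <- as.numeric(rowsum(GenomicRanges::width(ex), gidx)[as.character(seq_len(n)), ])
  strands <- as.character(BiocGenerics::strand(ex))[first]
  chrom <- as.character(GenomeInfoDb::seqnames(ex))[first]
  span <- en - st + 1
  data.frame(
    gene_id = names(genes), chromosome = chrom, strand = strands,
    start = st, end = en, l_exon = lex, l_intron = span - lex,
    n_exon = lengths(genes),
    tss = ifelse(strands == "+", st, en),
    row.names = NULL)
}

#' Read a two-column expression table
#'
#' @param path Headerless TSV: gene id, non-negative expression value.
#' @return Named numeric vector.
#' @export
readExpressionTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("gene_id", "expression"),
                          colClasses = c("character", "character"))
  val <- suppressWarnings(as.numeric(df$expression))
  if (anyNA(val))
    stop("non-numeric expression value for gene ",
         df$gene_id[which(is.na(val))[1]])
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup))
    stop("duplicate gene id in expression table: ", dup[1])
  if (any(val < 0))
    stop("negative expression value for gene ",
         df$gene_id[which(val < 0)[1]])
  stats::setNames(val, df$gene_id)
}

#' Write a two-column expression table
#' @param expression Named numeric vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeExpressionTable <- function(expression, path) {
  df <- data.frame(gene_id = names(expression),
                   expression = format(unname(expression), trim = TRUE,
                                       scientific = FALSE, digits = 15))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read repeat intervals from BED
#'
#' BED uses 0-based half-open coordinates; they are converted to the
#' 1-based inclusive `GRanges` convention on read.
#'
#' @param path BED file with at least 4 columns: chromosome, start, end,
#'   name. The name column carries the repeat family label.
#' @return `GRanges` with a `family` metadata column.
#' @export
readRepeatBed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "integer", "integer",
                                         "character"))
  gr <- GenomicRanges::GRanges(df[[1]],
                               IRanges::IRanges(df[[2]] + 1L, df[[3]]))
  gr$family <- df[[4]]
  gr
}

#' Write repeat intervals as BED (0-based half-open)
#' @param repeats `GRanges` with a `family` metadata column.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeRepeatBed <- function(repeats, path) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(repeats)),
                   start = GenomicRanges::start(repeats) - 1L,
                   end = GenomicRanges::end(repeats),
                   name = repeats$family)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene-to-GO-term annotations
#' @param path Headerless two-column TSV: gene id, GO term (one pair per
#'   row; genes may appear on several rows or not at all).
#' @return `data.frame` with columns `gene_id`, `term`.
#' @export
readGoAnnotations <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE,
                    col.names = c("gene_id", "term"),
                    colClasses = c("character", "character"))
}

#' Write gene-to-GO-term annotations
#' @param annotations `data.frame` with columns `gene_id`, `term`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeGoAnnotations <- function(annotations, path) {
  utils::write.table(annotations[, c("gene_id", "term")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
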