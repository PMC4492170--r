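# Builders for small in-memory fixtures.

# Track from a plain data.frame (chrom, pos, strand, context, m, u).
mkTrack <- function(df, genome = NULL) {
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$pos, width = 1),
                               strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    context = df$context, mCount = as.integer(df$m),
    uCount = as.integer(df$u))
  MethylationTrack(gr, genome)
}

# One gene as a GRanges of exons; exons = list of c(start, end), 1-based.
mkGene <- function(chrom, exons, strand = "+") {
  st <- vapply(exons, `[`, numeric(1), 1)
  en <- vapply(exons, `[`, numeric(1), 2)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(st, en), strand = strand)
}

mkGenes <- function(...) {
  GenomicRanges::GRangesList(list(...))
}

# Every cytosine of a genome covered with the given counts.
uniformTrack <- function(genome, m = 1L, u = 1L) {
  acc <- lapply(names(genome), function(chr) {
    seq <- as.character(genome[[chr]])
    ch <- strsplit(seq, "")[[1]]
    pos <- c(which(ch == "C"), which(ch == "G"))
    strand <- rep(c("+", "-"), c(sum(ch == "C"), sum(ch == "G")))
    ctx <- classifyContext(genome, rep(chr, length(pos)), pos, strand)
    keep <- ctx != "undefined"
    data.frame(chrom = chr, pos = pos[keep], strand = strand[keep],
               context = ctx[keep], m = m, u = u)
  })
  mkTrack(do.call(rbind, acc), genome)
}

# A small region table with arbitrary but valid content.
mkRegionTable <- function(n = 40, seed = 7) {
  set.seed(seed)
  df <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n)),
    chromosome = rep(c("chr1", "chr2"), length.out = n),
    strand = rep(c("+", "-"), length.out = n),
    m_cg = runif(n, 20, 90), m_chg = runif(n, 0, 20),
    m_chh = runif(n, 0, 5),
    u_cg = runif(n, 10, 70), u_chg = runif(n, 0, 30),
    u_chh = runif(n, 0, 10),
    d_cg = runif(n, 10, 70), d_chg = runif(n, 0, 30),
    d_chh = runif(n, 0, 10),
    first500_cg = runif(n, 5, 60), first500_chg = runif(n, 0, 15),
    first500_chh = runif(n, 0, 6),
    l_exon = round(runif(n, 300, 3000)),
    l_intron = round(runif(n, 0, 2000)),
    n_exon = sample(1:8, n, replace = TRUE),
    expression = round(10^rnorm(n, 2, 0.7), 3))
  new("RegionMethylationTable", df)
}
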