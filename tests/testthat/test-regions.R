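test_that("region definitions mirror by strand and truncate at edges", {
  genes <- mkGenes(plus = mkGene("chr1", list(c(5001, 7000)), "+"),
                   minus = mkGene("chr1", list(c(5001, 7000)), "-"),
                   edge = mkGene("chr1", list(c(301, 1300)), "+"))
  names(genes) <- c("plus", "minus", "edge")
  regs <- defineRegions(genes, seqlengths = c(chr1 = 10000))
  get <- function(id, reg) {
    r <- regs[regs$gene_id == id & regs$region == reg]
    c(GenomicRanges::start(r), GenomicRanges::end(r))
  }
  expect_equal(get("plus", "upstream"), c(4001, 5000))
  expect_equal(get("plus", "body"), c(5001, 7000))
  expect_equal(get("plus", "downstream"), c(7001, 8000))
  expect_equal(get("plus", "first500"), c(5001, 5500))
  ## minus strand: 5' flank is genomically to the right
  expect_equal(get("minus", "upstream"), c(7001, 8000))
  expect_equal(get("minus", "downstream"), c(4001, 5000))
  expect_equal(get("minus", "first500"), c(6501, 7000))
  ## upstream flank truncated at the contig start: length 300
  expect_equal(get("edge", "upstream"), c(1, 300))
})

test_that("first-500 sub-region never exceeds the body", {
  genes <- mkGenes(short = mkGene("chr1", list(c(1001, 1300)), "+"))
  names(genes) <- "short"
  regs <- defineRegions(genes)
  f <- regs[regs$region == "first500"]
  expect_equal(GenomicRanges::width(f), 300L)
})

test_that("region methylation pools counts and fills architecture", {
  genes <- mkGenes(g1 = mkGene("chr1", list(c(1001, 1800)), "+"))
  names(genes) <- "g1"
  ## 4 CG sites in the body, pooled 4 methylated / 4 unmethylated
  tr <- mkTrack(data.frame(chrom = "chr1",
                           pos = c(1100, 1200, 1600, 1700),
                           strand = "+", context = "CG",
                           m = c(2, 0, 1, 1), u = c(0, 2, 1, 1)))
  rt <- regionMethylation(tr, genes)
  expect_s4_class(rt, "RegionMethylationTable")
  expect_equal(rt$m_cg, 50)
  expect_equal(rt$l_exon, 800)
  expect_equal(rt$l_intron, 0)
  expect_equal(rt$n_exon, 1L)
  ## nothing upstream -> missing
  expect_true(is.na(rt$u_cg))
})

test_that("region table matches per-site brute force for random genes", {
  set.seed(21)
  geneStarts <- seq(3000, 60000, by = 4000)
  gl <- lapply(seq_along(geneStarts), function(i) {
    mkGene("chr1", list(c(geneStarts[i], geneStarts[i] + 1499)),
           sample(c("+", "-"), 1))
  })
  genes <- GenomicRanges::GRangesList(gl)
  names(genes) <- sprintf("g%02d", seq_along(gl))
  n <- 3000
  df <- data.frame(chrom = "chr1", pos = sort(sample(1:65000, n)),
                   strand = sample(c("+", "-"), n, TRUE),
                   context = sample(c("CG", "CHG", "CHH"), n, TRUE,
                                    prob = c(0.3, 0.2, 0.5)),
                   m = rpois(n, 2), u = rpois(n, 3))
  tr <- mkTrack(df)
  rt <- regionMethylation(tr, genes)
  arch <- geneArchitecture(genes)
  for (i in sample(nrow(arch), 8)) {
    s <- arch$start[i]; e <- arch$end[i]; plus <- arch$strand[i] == "+"
    expect_equal(rt$m_cg[i], oraclePercent(df, "chr1", s, e, "CG"))
    upLo <- if (plus) s - 1000 else e + 1
    upHi <- if (plus) s - 1 else e + 1000
    expect_equal(rt$u_chh[i], oraclePercent(df, "chr1", upLo, upHi, "CHH"))
    fLo <- if (plus) s else e - 499
    fHi <- if (plus) s + 499 else e
    expect_equal(rt$first500_chg[i],
                 oraclePercent(df, "chr1", fLo, fHi, "CHG"))
  }
})

test_that("first-500 and remainder counts combine exactly to the body", {
  set.seed(8)
  genes <- mkGenes(g1 = mkGene("chr1", list(c(2001, 4000)), "+"),
                   g2 = mkGene("chr1", list(c(9001, 11000)), "-"))
  names(genes) <- c("g1", "g2")
  n <- 1500
  df <- data.frame(chrom = "chr1", pos = sort(sample(1:12000, n)),
                   strand = sample(c("+", "-"), n, TRUE),
                   context = "CG", m = rpois(n, 2), u = rpois(n, 2))
  tr <- mkTrack(df)
  rt <- regionMethylation(tr, genes)
  arch <- geneArchitecture(genes)
  for (i in 1:2) {
    s <- arch$start[i]; e <- arch$end[i]; plus <- arch$strand[i] == "+"
    fLo <- if (plus) s else e - 499
    fHi <- if (plus) s + 499 else e
    rLo <- if (plus) s + 500 else s
    rHi <- if (plus) e else e - 500
    inB <- df$pos >= s & df$pos <= e
    inF <- df$pos >= fLo & df$pos <= fHi
    inR <- df$pos >= rLo & df$pos <= rHi
    mF <- sum(df$m[inF]); tF <- sum(df$m[inF] + df$u[inF])
    mR <- sum(df$m[inR]); tR <- sum(df$m[inR] + df$u[inR])
    ## counts partition exactly: body = first500 + remainder
    expect_equal(sum(df$m[inB]), mF + mR)
    expect_equal(rt$m_cg[i], 100 * (mF + mR) / (tF + tR))
  }
})

test_that("chromosome mismatch between track and genes is an error", {
  genes <- mkGenes(g1 = mkGene("scaffold_9", list(c(1001, 2000)), "+"))
  names(genes) <- "g1"
  tr <- mkTrack(data.frame(chrom = "chr1", pos = 1, strand = "+",
                           context = "CG", m = 1, u = 1))
  expect_error(regionMethylation(tr, genes), "scaffold_9")
})

test_that("repeats shorter than 100 bp are excluded from TE summaries", {
  reps <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1001, 2001, 3001), width = c(80, 150, 200)))
  reps$family <- c("famA", "famA", "famB")
  tr <- mkTrack(data.frame(chrom = "chr1",
                           pos = c(1010, 2010, 2020, 3010, 3020),
                           strand = "+", context = "CG",
                           m = c(5, 1, 3, 1, 1), u = c(0, 1, 1, 0, 0)))
  te <- teMethylation(tr, reps)
  expect_equal(nrow(te$perRepeat), 2L)   # the 80 bp copy is gone
  ## famA keeps only its long copy: counts 1/1 + 3/1 pooled -> 66.7 %
  a <- te$perFamily[te$perFamily$family == "famA", ]
  expect_equal(a$copies, 1L)
  expect_equal(a$pct_cg, 100 * 4 / 6, tolerance = 1e-12)
})

test_that("family aggregates equal pooling of member copy counts", {
  set.seed(4)
  starts <- seq(1000, 20000, by = 1000)
  reps <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(starts, width = 300))
  reps$family <- sample(c("f1", "f2", "f3"), length(starts), TRUE)
  n <- 800
  df <- data.frame(chrom = "chr1", pos = sort(sample(1:21000, n)),
                   strand = "+",
                   context = sample(c("CG", "CHG", "CHH"), n, TRUE),
                   m = rpois(n, 2), u = rpois(n, 2))
  tr <- mkTrack(df)
  te <- teMethylation(tr, reps)
  for (f in unique(reps$family)) {
    members <- which(reps$family == f)
    mm <- 0; tt <- 0
    for (i in members) {
      lo <- GenomicRanges::start(reps)[i]; hi <- GenomicRanges::end(reps)[i]
      sel <- df$pos >= lo & df$pos <= hi & df$context == "CG"
      mm <- mm + sum(df$m[sel]); tt <- tt + sum(df$m[sel] + df$u[sel])
    }
    got <- te$perFamily$pct_cg[te$perFamily$family == f]
    expect_equal(got, if (tt == 0) NA_real_ else 100 * mm / tt)
  }
})
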