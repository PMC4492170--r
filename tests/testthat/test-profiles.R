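test_that("a uniform track gives a flat TSS profile", {
  set.seed(2)
  g <- Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 12000, replace = TRUE), collapse = "")))
  tr <- uniformTrack(g)
  genes <- mkGenes(g1 = mkGene("chr1", list(c(5001, 8000)), "+"))
  names(genes) <- "g1"
  pr <- tssProfile(tr, genes, bin = 500, flank = 2000)
  expect_true(all(pr$percent[pr$total > 0] == 50))
  ## bins tile [-flank, flank)
  expect_equal(sort(unique(pr$binStart)), seq(-2000, 1500, by = 500))
})

test_that("minus-strand genes give the mirror of the plus-strand profile", {
  set.seed(9)
  n <- 2000
  df <- data.frame(chrom = "chr1", pos = sample(1:20000, n),
                   strand = "+", context = "CG",
                   m = rpois(n, 2), u = rpois(n, 2))
  trP <- mkTrack(df)
  ## mirror the whole layout around position 10000
  dfM <- df; dfM$pos <- 20001L - df$pos
  trM <- mkTrack(dfM)
  genesP <- mkGenes(g = mkGene("chr1", list(c(8001, 12000)), "+"))
  names(genesP) <- "g"
  genesM <- mkGenes(g = mkGene("chr1", list(c(8001, 12000)), "-"))
  names(genesM) <- "g"
  pP <- tssProfile(trP, genesP, bin = 250, flank = 1500)
  pM <- tssProfile(trM, genesM, bin = 250, flank = 1500)
  ## mirroring both the track and the gene strand preserves every
  ## TSS-relative offset, so the oriented profiles coincide exactly
  expect_equal(pM$percent, pP$percent)
  expect_equal(pM$total, pP$total)
})

test_that("an imposed first-500bp dip puts the profile minimum there", {
  set.seed(5)
  starts <- seq(5000, 95000, by = 6000)
  gl <- lapply(starts, function(s) mkGene("chr1", list(c(s, s + 2999)), "+"))
  genes <- GenomicRanges::GRangesList(gl)
  names(genes) <- sprintf("g%02d", seq_along(gl))
  pos <- sort(sample(1:100000, 20000))
  inDip <- vapply(pos, function(p)
    any(p >= starts & p <= starts + 499), logical(1))
  depth <- 10L
  m <- rbinom(length(pos), depth, ifelse(inDip, 0.15, 0.55))
  tr <- mkTrack(data.frame(chrom = "chr1", pos = pos, strand = "+",
                           context = "CG", m = m, u = depth - m))
  pr <- tssProfile(tr, genes, bin = 100, flank = 2000)
  cg <- pr[pr$context == "CG" & pr$total > 0, ]
  minBin <- cg$binStart[which.min(cg$percent)]
  expect_gte(minBin, 0)
  expect_lt(minBin, 500)
})

test_that("region contrast reproduces the textbook two-proportion z", {
  genes <- mkGenes(g = mkGene("chr1", list(c(2001, 4000)), "+"))
  names(genes) <- "g"
  ## 100 reads in each region: 50/100 upstream vs 60/100 body
  tr <- mkTrack(data.frame(
    chrom = "chr1", pos = c(1500, 2500),
    strand = "+", context = "CG", m = c(50, 60), u = c(50, 40)))
  rc <- regionContrast(tr, genes, "upstream", "body", "CG")
  pPool <- 110 / 200
  zHand <- (0.5 - 0.6) / sqrt(pPool * (1 - pPool) * (1 / 100 + 1 / 100))
  expect_equal(rc$zValue, zHand, tolerance = 1e-12)
  expect_equal(rc$pValue, 2 * pnorm(-abs(zHand)), tolerance = 1e-12)
  expect_equal(rc$difference, -10)
})

test_that("identical proportions give p near 1; extreme ones vanish", {
  genes <- mkGenes(g = mkGene("chr1", list(c(2001, 4000)), "+"))
  names(genes) <- "g"
  trSame <- mkTrack(data.frame(chrom = "chr1", pos = c(1500, 2500),
                               strand = "+", context = "CG",
                               m = c(30, 30), u = c(70, 70)))
  rcSame <- regionContrast(trSame, genes, "upstream", "body", "CG")
  expect_equal(rcSame$pValue, 1)
  expect_equal(rcSame$difference, 0)
  trFar <- mkTrack(data.frame(chrom = "chr1", pos = c(1500, 2500),
                              strand = "+", context = "CG",
                              m = c(900, 100), u = c(100, 900)))
  rcFar <- regionContrast(trFar, genes, "upstream", "body", "CG")
  expect_equal(rcFar$difference, 80)
  expect_lt(rcFar$pValue, 1e-10)
  trEmpty <- mkTrack(data.frame(chrom = "chr1", pos = 2500, strand = "+",
                                context = "CG", m = 1, u = 1))
  expect_error(regionContrast(trEmpty, genes, "upstream", "body", "CG"),
               "zero total")
})

test_that("correlation matrix is symmetric with unit diagonal", {
  rt <- mkRegionTable(60)
  cc <- methylationCorrelations(rt)
  expect_equal(cc$r, t(cc$r))
  expect_equal(unname(diag(cc$r)), rep(1, 9))
  ## duplicated measure correlates at exactly 1
  df <- as.data.frame(rt)
  df$m_chg <- df$m_cg
  cc2 <- methylationCorrelations(new("RegionMethylationTable", df))
  expect_equal(cc2$r["m_cg", "m_chg"], 1)
})

test_that("pairwise r matches the closed-form Pearson formula", {
  x <- c(1, 4, 2, 8, 5)
  y <- c(2, 3, 7, 6, 9)
  rHand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  df <- as.data.frame(mkRegionTable(5))
  df$m_cg <- x; df$m_chg <- y
  cc <- methylationCorrelations(new("RegionMethylationTable", df))
  expect_equal(cc$r["m_cg", "m_chg"], rHand, tolerance = 1e-12)
  expect_equal(cc$n["m_cg", "m_chg"], 5)
})

test_that("zero-variance measures are flagged and dropped", {
  df <- as.data.frame(mkRegionTable(30))
  df$d_chh <- 5
  expect_warning(cc <- methylationCorrelations(
    new("RegionMethylationTable", df)), "d_chh")
  expect_true(all(is.na(cc$r["d_chh", setdiff(colnames(cc$r), "d_chh")])))
})

test_that("two-chromosome ANOVA reduces to the squared t statistic", {
  set.seed(14)
  df <- as.data.frame(mkRegionTable(40))
  df$chromosome <- rep(c("chr1", "chr2"), each = 20)
  out <- chromosomeAnova(new("RegionMethylationTable", df))
  tt <- t.test(m_cg ~ chromosome, data = df, var.equal = TRUE)
  expect_equal(out$fStatistic[out$response == "m_cg"],
               unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(out$df1[1], 1L)
})

test_that("a shifted chromosome produces a decisive ANOVA signal", {
  set.seed(15)
  df <- as.data.frame(mkRegionTable(120, seed = 15))
  df$chromosome <- rep(c("chr1", "chr2", "chr3"), each = 40)
  sdv <- sd(df$m_cg)
  df$m_cg <- pmin(df$m_cg + ifelse(df$chromosome == "chr3", 5 * sdv, 0), 100)
  out <- chromosomeAnova(new("RegionMethylationTable", df))
  expect_lt(out$pValue[out$response == "m_cg"], 1e-6)
  ## a single chromosome cannot be contrasted
  df1 <- df; df1$chromosome <- "chr1"
  expect_error(chromosomeAnova(new("RegionMethylationTable", df1)),
               "at least 2 chromosomes")
})

test_that("null chromosome ANOVA keeps F near 1 across replicates", {
  set.seed(16)
  fs <- replicate(30, {
    y <- rnorm(90)
    chrom <- rep(c("a", "b", "c"), each = 30)
    a <- anova(aov(y ~ factor(chrom)))
    a$`F value`[1]
  })
  ## mean of F_{2,87} is df2/(df2-2) ~ 1.02
  expect_lt(abs(mean(fs) - 87 / 85), 0.35)
})
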