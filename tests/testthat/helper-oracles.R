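# Independent oracles, deliberately written without reusing package code
# paths: exhaustive hypergeometric tail summation, dense grid search, and
# per-site brute-force percent recomputation.

# Two-sided Fisher p for a 2x2 table by enumerating the hypergeometric
# support and summing all outcomes no more probable than the observed one.
oracleFisherP <- function(a, b, cc, d) {
  white <- a + cc          # genes carrying the term
  black <- b + d
  drawn <- a + b           # focal set size
  ks <- max(0, drawn - black):min(drawn, white)
  probs <- stats::dhyper(ks, white, black, drawn)
  pObs <- stats::dhyper(a, white, black, drawn)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Interior local maxima of a polynomial profile on a dense grid
# (boundary points excluded so a cubic's divergence does not mask the
# local structure).
oracleGridLocalMax <- function(coefs, lo = -5, hi = 5, step = 1e-4) {
  xs <- seq(lo, hi, by = step)
  v <- numeric(length(xs))
  coefs <- unname(coefs)
  for (i in seq_along(coefs)) v <- v + coefs[i] * xs^(i - 1)
  n <- length(v)
  mid <- 2:(n - 1)
  hits <- mid[v[mid] > v[mid - 1] & v[mid] >= v[mid + 1]]
  xs[hits]
}

# Pooled percent methylation over an interval recomputed record by record
# from a plain data.frame (chrom, pos, strand, context, m, u).
oraclePercent <- function(df, chrom, lo, hi, context = NULL) {
  sm <- 0; st <- 0
  for (i in seq_len(nrow(df))) {
    if (df$chrom[i] != chrom) next
    if (df$pos[i] < lo || df$pos[i] > hi) next
    if (!is.null(context) && df$context[i] != context) next
    sm <- sm + df$m[i]
    st <- st + df$m[i] + df$u[i]
  }
  if (st == 0) NA_real_ else 100 * sm / st
}

# Trinucleotide context by direct rule application on a 3-character string
# read 5'->3' on the site's own strand.
oracleContext <- function(tri) {
  b <- strsplit(tri, "")[[1]]
  if (b[1] != "C") stop("not a cytosine")
  if (length(b) < 2 || !(b[2] %in% c("A", "C", "G", "T"))) return("undefined")
  if (b[2] == "G") return("CG")
  if (length(b) < 3 || !(b[3] %in% c("A", "C", "G", "T"))) return("undefined")
  if (b[3] == "G") return("CHG")
  "CHH"
}

revComp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}
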