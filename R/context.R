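#' Classify the sequence context of cytosines
#'
#' A cytosine's context is determined by the two bases immediately 3' of it
#' on its own strand: CG when the next base is G, otherwise CHG when the
#' base two positions away is G, otherwise CHH (H = A, C or T). Sites with
#' fewer than two downstream bases, or with an ambiguous (non-ACGT)
#' downstream base, are `"undefined"` and are excluded from all summaries.
#'
#' @param genome A `DNAStringSet` (names are chromosome names).
#' @param chromosome Character vector of chromosome names.
#' @param position Integer vector of 1-based positions.
#' @param strand Character vector, `"+"` or `"-"`. On the minus strand the
#'   site must be a G in the reference (a C on its own strand) and the
#'   downstream bases are read towards lower coordinates, complemented.
#' @return Character vector: `"CG"`, `"CHG"`, `"CHH"` or `"undefined"`.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr = "ACGT"))
#' classifyContext(g, "chr", 2L, "+")   # "CG"
#' classifyContext(g, "chr", 3L, "-")   # "CG" (CG is strand-symmetric)
#' @export
classifyContext <- function(genome, chromosome, position, strand) {
  stopifnot(is(genome, "DNAStringSet"))
  n <- max(length(chromosome), length(position), length(strand))
  chromosome <- rep_len(as.character(chromosome), n)
  position <- rep_len(as.integer(position), n)
  strand <- rep_len(as.character(strand), n)
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  bad <- !(chromosome %in% names(genome))
  if (any(bad))
    stop("unknown chromosome: ", paste(unique(chromosome[bad]), collapse = ", "))
  out <- character(n)
  for (chr in unique(chromosome)) {
    idx <- which(chromosome == chr)
    seq <- as.character(genome[[chr]])
    len <- nchar(seq)
    pos <- position[idx]
    if (any(pos < 1L | pos > len))
      stop("position outside chromosome ", chr)
    out[idx] <- .contextFromString(seq, len, pos, strand[idx])
  }
  out
}

## Core per-chromosome classification on a plain character sequence.
.contextFromString <- function(seq, len, pos, strand) {
  base <- substring(seq, pos, pos)
  plus <- strand == "+"
  if (any(plus & base != "C") || any(!plus & base != "G"))
    stop("base at position is not a cytosine on the requested strand ",
         "(first offender: position ",
         pos[which((plus & base != "C") | (!plus & base != "G"))[1]], ")")
  n1 <- ifelse(plus,
               ifelse(pos + 1L <= len, substring(seq, pos + 1L, pos + 1L), ""),
               ifelse(pos - 1L >= 1L, substring(seq, pos - 1L, pos - 1L), ""))
  n2 <- ifelse(plus,
               ifelse(pos + 2L <= len, substring(seq, pos + 2L, pos + 2L), ""),
               ifelse(pos - 2L >= 1L, substring(seq, pos - 2L, pos - 2L), ""))
  ## on the minus strand the downstream base is read complemented
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n1[!plus] <- ifelse(n1[!plus] %in% names(comp), comp[n1[!plus]], n1[!plus])
  n2[!plus] <- ifelse(n2[!plus] %in% names(comp), comp[n2[!plus]], n2[!plus])
  ok1 <- n1 %in% c("A", "C", "G", "T")
  ok2 <- n2 %in% c("A", "C", "G", "T")
  out <- rep("undefined", length(pos))
  cg <- ok1 & n1 == "G"
  chg <- ok1 & !cg & ok2 & n2 == "G"
  chh <- ok1 & ok2 & n1 != "G" & n2 != "G"
  out[cg] <- "CG"
  out[chg] <- "CHG"
  out[chh] <- "CHH"
  out
}

## All cytosine sites (both strands) of one chromosome string, with context.
## Returns data.frame(position, strand, context), undefined sites dropped.
## Vectorized with logical indexing (no per-site calls) so whole
## chromosomes scan in one pass.
.cytosineSites <- function(seq) {
  len <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pad <- c(ch, "N", "N")   # sentinels past both chromosome ends
  classify <- function(pos, n1, n2) {
    ok1 <- n1 %in% c("A", "C", "G", "T")
    ok2 <- n2 %in% c("A", "C", "G", "T")
    ctx <- rep("undefined", length(pos))
    isCG <- ok1 & n1 == "G"
    ctx[isCG] <- "CG"
    rest <- ok1 & !isCG & ok2
    ctx[rest & n2 == "G"] <- "CHG"
    ctx[rest & n2 != "G"] <- "CHH"
    ctx
  }
  posP <- which(ch == "C")
  ctxP <- classify(posP, pad[posP + 1L], pad[posP + 2L])
  posM <- which(ch == "G")
  ## downstream on the minus strand runs leftwards, complemented:
  ## the complement of the reference base equals G iff the base is C
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n1 <- pad[ifelse(posM >= 2L, posM - 1L, len + 1L)]
  n2 <- pad[ifelse(posM >= 3L, posM - 2L, len + 1L)]
  cmpl <- function(x) {
    out <- unname(comp[x])
    out[is.na(out)] <- "N"
    out
  }
  ctxM <- classify(posM, cmpl(n1), cmpl(n2))
  df <- data.frame(
    position = c(posP, posM),
    strand = rep(c("+", "-"), c(length(posP), length(posM))),
    context = c(ctxP, ctxM))
  df <- df[df$context != "undefined", , drop = FALSE]
  df <- df[order(df$position), , drop = FALSE]
  rownames(df) <- NULL
  df
}
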