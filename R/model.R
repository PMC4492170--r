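## Feature construction, monomial enumeration, OLS fitting, BIC stepwise
## selection and k-fold cross-validation.

#' Build a standardized feature table from raw predictors
#'
#' Rows with any missing value are dropped, then each predictor column is
#' Z-standardized (sample SD, n-1 denominator) so that 0 is the column
#' mean and units are standard deviations.
#'
#' @param x Numeric matrix or data.frame of raw predictors with column
#'   names.
#' @param y Numeric response (already on its final scale).
#' @param geneIds Optional row identifiers.
#' @param logBase Recorded log base of the response (metadata only here).
#' @return A [FeatureTable-class].
#' @export
featureTable <- function(x, y, geneIds = NULL, logBase = 10) {
  x <- as.matrix(x)
  if (is.null(geneIds)) geneIds <- as.character(seq_len(nrow(x)))
  ok <- stats::complete.cases(x) & !is.na(y)
  x <- x[ok, , drop = FALSE]; y <- y[ok]; geneIds <- geneIds[ok]
  if (nrow(x) < 3) stop("fewer than 3 complete rows")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0))
    stop("zero-variance predictor(s): ",
         paste(colnames(x)[scl == 0], collapse = ", "))
  xs <- scale(x, center = ctr, scale = scl)
  attr(xs, "scaled:center") <- NULL
  attr(xs, "scaled:scale") <- NULL
  new("FeatureTable", x = xs, y = as.numeric(y), center = ctr, scale = scl,
      geneIds = geneIds, logBase = logBase)
}

#' Standardized model inputs from a region methylation table
#'
#' Takes the twelve predictors (nine region x context percent methylation
#' measures plus exon length, intron length and exon count) and log
#' expression as the response. Genes with zero expression (log undefined)
#' or any missing predictor are excluded, with a message stating how many.
#'
#' @param table A [RegionMethylationTable-class] with expression attached.
#' @param logBase Base of the expression logarithm (default 10).
#' @return A [FeatureTable-class] with the 12 canonical predictors.
#' @export
buildFeatureTable <- function(table, logBase = 10) {
  df <- as.data.frame(table)
  x <- as.matrix(df[, predictorNames()])
  expr <- df$expression
  zero <- !is.na(expr) & expr == 0
  if (any(zero))
    message(sum(zero), " gene(s) with zero expression excluded")
  expr[zero] <- NA
  y <- ifelse(is.na(expr), NA, log(expr, base = logBase))
  dropped <- sum(!(stats::complete.cases(x) & !is.na(y)))
  if (dropped)
    message(dropped, " of ", nrow(df),
            " gene(s) dropped for missing predictor or response")
  featureTable(x, y, geneIds = df$gene_id, logBase = logBase)
}

#' Recover raw predictor values from standardized ones
#' @param ft A [FeatureTable-class].
#' @return Numeric matrix on the raw predictor scale.
#' @export
unstandardize <- function(ft) {
  sweep(sweep(ft@x, 2, ft@scale, "*"), 2, ft@center, "+")
}

#' Enumerate all candidate monomials up to a total degree
#'
#' All distinct non-constant monomials in `n` predictors with total degree
#' at most `maxDegree`; their number is choose(n + d, d) - 1. Terms are
#' ordered by total degree, then lexicographically by the sorted predictor
#' index multiset, which fixes the deterministic scan order of stepwise
#' selection.
#'
#' @param n Number of predictors (default 12) or a character vector of
#'   predictor names.
#' @param maxDegree Maximum total degree (default 3).
#' @return Integer matrix, terms x predictors, with predictor column
#'   names.
#' @examples
#' nrow(enumerateTerms(12, 3))   # 454
#' @export
enumerateTerms <- function(n = predictorNames(), maxDegree = 3L) {
  nms <- if (is.character(n)) n else paste0("x", seq_len(n))
  if (is.character(n)) n <- length(n)
  stopifnot(n >= 1, maxDegree >= 1)
  rows <- list()
  for (d in seq_len(maxDegree)) {
    ## multisets of size d from n predictors, lexicographic
    combs <- .multisets(n, d)
    for (k in seq_len(nrow(combs))) {
      e <- integer(n)
      for (i in combs[k, ]) e[i] <- e[i] + 1L
      rows[[length(rows) + 1L]] <- e
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- nms
  m
}

## All non-decreasing index tuples of length d from 1..n (multisets).
.multisets <- function(n, d) {
  if (d == 1) return(matrix(seq_len(n), ncol = 1))
  sub <- .multisets(n, d - 1)
  out <- list()
  for (i in seq_len(n)) {
    keep <- sub[, 1] >= i
    if (any(keep))
      out[[i]] <- cbind(i, sub[keep, , drop = FALSE])
  }
  do.call(rbind, out)
}

## Design matrix (without intercept) for a term set.
.designMatrix <- function(x, terms) {
  if (!nrow(terms)) return(matrix(numeric(0), nrow = nrow(x), ncol = 0))
  miss <- setdiff(colnames(terms)[colSums(terms) > 0], colnames(x))
  if (length(miss))
    stop("predictor(s) absent from feature table: ",
         paste(miss, collapse = ", "))
  D <- matrix(1, nrow(x), nrow(terms))
  for (j in seq_len(nrow(terms))) {
    on <- which(terms[j, ] > 0)
    for (k in on)
      D[, j] <- D[, j] * x[, colnames(terms)[k]]^terms[j, k]
  }
  D
}

## Gaussian BIC from a residual sum of squares, matching stats::BIC on lm:
## npar = nCoef coefficients + 1 for sigma.
.gaussianBic <- function(n, sse, nCoef) {
  n * (log(2 * pi) + log(sse / n) + 1) + log(n) * (nCoef + 1)
}

#' Ordinary least squares fit of a polynomial term set
#'
#' Fits intercept + the given monomial terms by least squares and reports
#' the full ANOVA decomposition, fit statistics and Gaussian BIC
#' (likelihood-based, n = number of rows).
#'
#' @param ft A [FeatureTable-class].
#' @param terms Integer exponent matrix (terms x predictors), e.g. rows of
#'   [enumerateTerms()].
#' @return A [ModelFit-class].
#' @export
fitOls <- function(ft, terms) {
  terms <- as.matrix(terms)
  n <- nrow(ft@x)
  p <- nrow(terms) + 1L
  if (n <= p)
    stop("rows (", n, ") must exceed number of parameters (", p, ")")
  X <- cbind(`(Intercept)` = 1, .designMatrix(ft@x, terms))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    lab <- c("(Intercept)",
             termLabels(PolynomialModelSpec(terms, rep(0, nrow(terms)))))
    dropped <- lab[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }
  cf <- qr.coef(qrX, ft@y)
  res <- ft@y - drop(X %*% cf)
  sse <- sum(res^2)
  sst <- sum((ft@y - mean(ft@y))^2)
  ssm <- sst - sse
  dfM <- p - 1L; dfE <- n - p
  sigma2 <- sse / dfE
  xtxInv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(xtxInv) * sigma2)
  tv <- cf / se
  pv <- 2 * stats::pt(-abs(tv), dfE)
  spec <- PolynomialModelSpec(terms, cf[-1], intercept = cf[1],
                              se = se[-1], tvalue = tv[-1], pvalue = pv[-1])
  new("ModelFit", spec = spec, n = n,
      ssModel = ssm, ssError = sse, ssTotal = sst,
      dfModel = dfM, dfError = dfE,
      fStatistic = if (dfM > 0) (ssm / dfM) / sigma2 else NA_real_,
      r2 = ssm / sst, adjR2 = 1 - (sse / dfE) / (sst / (n - 1)),
      rmse = sqrt(sigma2), bic = .gaussianBic(n, sse, p),
      responseMean = mean(ft@y))
}

#' Forward stepwise term selection by BIC
#'
#' Greedy forward selection over a candidate monomial set: at each step
#' the candidate whose addition most lowers the Gaussian BIC enters;
#' selection stops when no addition lowers it. With
#' `direction = "both"`, each addition is followed by backward passes
#' removing any term whose deletion lowers BIC. The scan order (candidates
#' sorted by total degree, then lexicographic exponent vector) makes the
#' procedure deterministic; BIC ties below 1e-9 resolve to the
#' earliest-scanned candidate. Marginality is not enforced: a cubic term
#' can enter without its lower-order relatives.
#'
#' @param ft A [FeatureTable-class].
#' @param candidates Exponent matrix of candidate terms (default: all
#'   degree-<=3 monomials of the table's predictors).
#' @param direction `"forward"` (default) or `"both"`.
#' @param maxTerms Optional cap on selected model size.
#' @return List with `fit` (a [ModelFit-class] of the selected model) and
#'   `spec` (its [PolynomialModelSpec-class]). An empty candidate set
#'   yields the intercept-only model with a warning.
#' @export
stepwiseBic <- function(ft, candidates = enumerateTerms(colnames(ft@x)),
                        direction = c("forward", "both"),
                        maxTerms = Inf) {
  direction <- match.arg(direction)
  candidates <- as.matrix(candidates)
  n <- nrow(ft@x)
  y <- ft@y
  emptyTerms <- matrix(integer(0), nrow = 0, ncol = ncol(ft@x),
                       dimnames = list(NULL, colnames(ft@x)))
  if (!nrow(candidates)) {
    warning("empty candidate list; returning intercept-only model")
    return(.interceptOnlyFit(ft, emptyTerms))
  }
  ## canonical deterministic order: degree, then lexicographic exponents
  ord <- do.call(order, c(list(rowSums(candidates)),
                          lapply(seq_len(ncol(candidates)),
                                 function(j) -candidates[, j])))
  candidates <- candidates[ord, , drop = FALSE]
  D <- .designMatrix(ft@x, candidates)
  ## residualize everything against the intercept once
  r <- y - mean(y)
  Z <- sweep(D, 2, colMeans(D))
  active <- integer(0)
  alive <- rep(TRUE, ncol(D))
  sse <- sum(r^2)
  bicCur <- .gaussianBic(n, sse, 1L)
  tol <- 1e-9
  repeat {
    if (length(active) >= maxTerms || !any(alive)) break
    zz <- colSums(Z^2)
    usable <- alive & zz > 1e-10 * n
    if (!any(usable)) break
    zr <- as.numeric(crossprod(Z, r))
    gain <- ifelse(usable, zr^2 / zz, -Inf)
    sseNew <- sse - gain
    k <- length(active) + 2L   # intercept + active + candidate
    bicNew <- .gaussianBic(n, pmax(sseNew, 1e-300), k)
    best <- which(bicNew <= min(bicNew) + tol)[1]
    if (!is.finite(bicNew[best]) || bicNew[best] >= bicCur - 0) break
    ## orthogonalize the chosen column into the basis, update residuals
    q <- Z[, best] / sqrt(zz[best])
    r <- r - q * sum(q * r)
    Z <- Z - outer(q, as.numeric(crossprod(Z, q)))
    active <- c(active, best)
    alive[best] <- FALSE
    sse <- sum(r^2)
    bicCur <- .gaussianBic(n, sse, length(active) + 1L)
    if (direction == "both" && length(active) > 1) {
      repeat {
        drops <- vapply(seq_along(active), function(i) {
          keep <- candidates[active[-i], , drop = FALSE]
          f <- try(fitOls(ft, keep), silent = TRUE)
          if (inherits(f, "try-error")) Inf else f@bic
        }, numeric(1))
        if (min(drops) < bicCur - tol) {
          i <- which.min(drops)
          alive[active[i]] <- TRUE
          active <- active[-i]
          ## rebuild the orthogonal state from scratch after a removal
          r <- y - mean(y)
          Z <- sweep(D, 2, colMeans(D))
          for (a in active) {
            q <- Z[, a] / sqrt(sum(Z[, a]^2))
            r <- r - q * sum(q * r)
            Z <- Z - outer(q, as.numeric(crossprod(Z, q)))
          }
          sse <- sum(r^2)
          bicCur <- .gaussianBic(n, sse, length(active) + 1L)
        } else break
      }
    }
  }
  if (!length(active)) {
    warning("no candidate term lowers BIC; returning intercept-only model")
    return(.interceptOnlyFit(ft, emptyTerms))
  }
  terms <- candidates[active, , drop = FALSE]
  fit <- fitOls(ft, terms)
  list(fit = fit, spec = fit@spec)
}

.interceptOnlyFit <- function(ft, emptyTerms) {
  n <- length(ft@y)
  sst <- sum((ft@y - mean(ft@y))^2)
  spec <- PolynomialModelSpec(emptyTerms, numeric(0),
                              intercept = mean(ft@y))
  fit <- new("ModelFit", spec = spec, n = n,
             ssModel = 0, ssError = sst, ssTotal = sst,
             dfModel = 0L, dfError = n - 1L, fStatistic = NA_real_,
             r2 = 0, adjR2 = 0, rmse = sqrt(sst / (n - 1)),
             bic = .gaussianBic(n, sst, 1L), responseMean = mean(ft@y))
  list(fit = fit, spec = spec)
}

#' k-fold cross-validated out-of-sample R-squared
#'
#' Randomly partitions rows into k folds of near-equal size (sizes differ
#' by at most 1), fits the given term set on k-1 folds and evaluates
#' 1 - SSE/SST on the held-out fold (SST about the held-out mean).
#'
#' @param ft A [FeatureTable-class].
#' @param terms Exponent matrix of model terms.
#' @param k Number of folds (default 3).
#' @param seed Optional integer; fixes the fold assignment.
#' @return List with `foldR2` (length k), `minR2`, `meanR2` and `folds`
#'   (the row assignment).
#' @export
kfoldCv <- function(ft, terms, k = 3L, seed = NULL) {
  terms <- as.matrix(terms)
  n <- nrow(ft@x)
  stopifnot(k >= 2)
  if (n < k * (nrow(terms) + 2))
    stop("insufficient rows (", n, ") for ", k, "-fold CV with ",
         nrow(terms), " terms")
  if (!is.null(seed)) set.seed(seed)
  folds <- sample(rep(seq_len(k), length.out = n))
  X <- cbind(1, .designMatrix(ft@x, terms))
  r2 <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    cf <- stats::lm.fit(X[tr, , drop = FALSE], ft@y[tr])$coefficients
    if (anyNA(cf)) stop("rank-deficient design in fold ", f)
    pred <- drop(X[!tr, , drop = FALSE] %*% cf)
    yte <- ft@y[!tr]
    r2[f] <- 1 - sum((yte - pred)^2) / sum((yte - mean(yte))^2)
  }
  list(foldR2 = r2, minR2 = min(r2), meanR2 = mean(r2), folds = folds)
}

#' Predict log expression from a polynomial model
#'
#' Evaluates intercept + sum(coefficient x product(predictor^exponent))
#' on standardized features.
#'
#' @param object A [PolynomialModelSpec-class].
#' @param newdata Matrix or data.frame of standardized predictor values
#'   containing every predictor the model uses.
#' @param ... Ignored.
#' @return Numeric vector of predicted log expression.
#' @export
setMethod("predict", "PolynomialModelSpec", function(object, newdata, ...) {
  x <- as.matrix(newdata)
  used <- colnames(object@exponents)[colSums(object@exponents) > 0]
  miss <- setdiff(used, colnames(x))
  if (length(miss))
    stop("missing predictor(s): ", paste(miss, collapse = ", "))
  if (anyNA(x[, used, drop = FALSE]))
    stop("NA in required predictor(s)")
  icpt <- if (is.na(object@intercept)) 0 else object@intercept
  if (!nrow(object@exponents)) return(rep(icpt, nrow(x)))
  D <- .designMatrix(x, object@exponents)
  drop(icpt + D %*% object@coefficients)
})
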