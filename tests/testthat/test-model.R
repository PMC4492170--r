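test_that("standardization maps {10,20,30} to {-1,0,1} with sample SD", {
  x <- cbind(a = c(10, 20, 30), b = c(5, 9, 1))
  ft <- featureTable(x, y = c(1, 2, 3))
  expect_equal(unname(ft@x[, "a"]), c(-1, 0, 1))
  expect_equal(unname(ft@center["a"]), 20)
  expect_equal(unname(ft@scale["a"]), 10)
})

test_that("zero-expression genes are excluded before the log transform", {
  df <- as.data.frame(mkRegionTable(30))
  df$expression[c(3, 17)] <- 0
  expect_message(
    expect_message(
      ft <- buildFeatureTable(new("RegionMethylationTable", df)),
      "zero expression"),
    "dropped")
  expect_equal(nrow(ft@x), 28L)
  expect_false(any(ft@geneIds %in% df$gene_id[c(3, 17)]))
  expect_equal(ft@y, log10(df$expression[-c(3, 17)]))
})

test_that("standardize-then-invert recovers raw values", {
  rt <- mkRegionTable(50)
  ft <- buildFeatureTable(rt)
  raw <- unstandardize(ft)
  orig <- as.matrix(as.data.frame(rt)[, predictorNames()])
  expect_equal(raw, orig[match(ft@geneIds, rt$gene_id), ],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("fewer than 3 complete rows is an error", {
  expect_error(featureTable(cbind(a = c(1, 2), b = c(3, 4)), c(1, 2)),
               "fewer than 3")
})

test_that("monomial enumeration yields C(n+d,d)-1 ordered terms", {
  expect_equal(nrow(enumerateTerms(1, 1)), 1L)
  e22 <- enumerateTerms(2, 2)
  expect_equal(nrow(e22), 5L)
  ## exhaustive listing oracle for two predictors, degree <= 2
  want <- rbind(c(1, 0), c(0, 1), c(2, 0), c(1, 1), c(0, 2))
  key <- function(m) sort(apply(m, 1, paste, collapse = ","))
  expect_equal(key(e22), key(want))
  for (n in c(3, 5)) for (d in c(2, 3))
    expect_equal(nrow(enumerateTerms(n, d)), choose(n + d, d) - 1)
  expect_false(anyDuplicated(apply(enumerateTerms(4, 3), 1,
                                   paste, collapse = ",")) > 0)
})

test_that("exact linear data fits with R2 = 1 and zero error SS", {
  x <- cbind(x1 = seq(-2, 2, length.out = 40))
  ft <- featureTable(x, y = 2 * scale(x[, 1])[, 1] + 1)
  fit <- fitOls(ft, rbind(c(x1 = 1L)))
  expect_equal(fit@r2, 1)
  expect_equal(fit@ssError, 0, tolerance = 1e-20)
  expect_equal(unname(fit@spec@coefficients), 2)
  expect_equal(fit@spec@intercept, 1)
})

test_that("coefficients on an orthogonal design equal cov/var ratios", {
  ## build exactly orthogonal standardized columns: centre first so the
  ## orthonormal basis stays orthogonal to the intercept, then rescale
  set.seed(31)
  raw <- scale(matrix(rnorm(60 * 3), 60), scale = FALSE)
  raw <- scale(qr.Q(qr(raw)))
  colnames(raw) <- c("a", "b", "c")
  y <- rnorm(60)
  ft <- featureTable(raw, y)
  fit <- fitOls(ft, diag(3L) |> `colnames<-`(c("a", "b", "c")))
  byHand <- vapply(1:3, function(j)
    sum(ft@x[, j] * (y - mean(y))) / sum(ft@x[, j]^2), numeric(1))
  expect_equal(unname(fit@spec@coefficients), byHand, tolerance = 1e-10)
})

test_that("duplicate terms produce a rank-deficiency error", {
  ft <- featureTable(cbind(a = rnorm(20), b = rnorm(20)), rnorm(20))
  dup <- rbind(c(a = 1L, b = 0L), c(a = 1L, b = 0L))
  expect_error(fitOls(ft, dup), "duplicate|collinear")
})

test_that("ANOVA decomposition conserves sums of squares", {
  set.seed(33)
  for (rep in 1:5) {
    x <- matrix(rnorm(200 * 4), 200)
    colnames(x) <- paste0("x", 1:4)
    ft <- featureTable(x, rnorm(200) + x[, 1])
    fit <- fitOls(ft, enumerateTerms(paste0("x", 1:4), 2))
    expect_equal(fit@ssModel + fit@ssError, fit@ssTotal,
                 tolerance = 1e-10)
    expect_equal(fit@r2, fit@ssModel / fit@ssTotal)
  }
})

test_that("reported BIC matches the Gaussian likelihood BIC of lm", {
  set.seed(34)
  x <- matrix(rnorm(100 * 2), 100, dimnames = list(NULL, c("a", "b")))
  y <- x[, 1] - 0.5 * x[, 2] + rnorm(100)
  ft <- featureTable(x, y)
  terms <- rbind(c(a = 1L, b = 0L), c(a = 0L, b = 1L),
                 c(a = 1L, b = 1L))
  fit <- fitOls(ft, terms)
  D <- cbind(ft@x, ab = ft@x[, 1] * ft@x[, 2])
  ref <- lm(ft@y ~ D)
  expect_equal(fit@bic, BIC(ref), tolerance = 1e-8)
  expect_equal(fit@rmse, summary(ref)$sigma, tolerance = 1e-10)
  expect_equal(unname(fit@spec@se),
               unname(summary(ref)$coefficients[-1, 2]), tolerance = 1e-10)
})

test_that("a useless extra term raises BIC", {
  set.seed(35)
  x <- matrix(rnorm(500 * 3), 500, dimnames = list(NULL, c("a", "b", "c")))
  y <- x[, 1] + rnorm(500)
  ft <- featureTable(x, y)
  base <- fitOls(ft, rbind(c(a = 1L, b = 0L, c = 0L)))
  ## c is independent noise; with n >> e^2 the log(n) penalty dominates
  ## the expected unit chi-square improvement
  more <- fitOls(ft, rbind(c(a = 1L, b = 0L, c = 0L),
                           c(a = 0L, b = 0L, c = 1L)))
  expect_gt(more@bic, base@bic)
})

test_that("forward stepwise recovers a planted two-predictor support", {
  set.seed(36)
  n <- 2000
  x <- matrix(rnorm(n * 10), n, dimnames = list(NULL, paste0("x", 1:10)))
  y <- 3 * scale(x[, 1])[, 1] - 2 * scale(x[, 2])[, 1] + rnorm(n, 0, 0.5)
  ft <- featureTable(x, y)
  sel <- stepwiseBic(ft, enumerateTerms(paste0("x", 1:10), 1))
  lab <- sort(termLabels(sel$spec))
  expect_equal(lab, c("x1", "x2"))
  expect_equal(unname(sel$spec@coefficients[order(termLabels(sel$spec))]),
               c(3, -2), tolerance = 0.1)
})

test_that("stepwise on pure noise stays at or near the intercept", {
  ## with 50 candidates at n = 1000 a term enters only when its
  ## chi-square improvement beats log(n) ~ 6.9, so selections are rare
  ## and never large
  sizes <- vapply(1:8, function(s) {
    set.seed(400 + s)
    x <- matrix(rnorm(1000 * 50), 1000,
                dimnames = list(NULL, paste0("x", 1:50)))
    ft <- featureTable(x, rnorm(1000))
    sel <- suppressWarnings(
      stepwiseBic(ft, enumerateTerms(paste0("x", 1:50), 1)))
    nrow(sel$spec@exponents)
  }, numeric(1))
  expect_gte(sum(sizes == 0), 4)
  expect_true(all(sizes <= 2))
})

test_that("a single perfect predictor beats the intercept-only BIC", {
  x <- cbind(a = rnorm(50))
  ft <- featureTable(x, 2 * scale(x[, 1])[, 1])
  sel <- stepwiseBic(ft, rbind(c(a = 1L)))
  expect_equal(nrow(sel$spec@exponents), 1L)
  n <- 50
  sst <- sum((ft@y - mean(ft@y))^2)
  bic0 <- n * (log(2 * pi) + log(sst / n) + 1) + log(n) * 2
  expect_lt(sel$fit@bic, bic0)
  ## empty candidate set falls back to the intercept with a warning
  empty <- matrix(integer(0), 0, 1, dimnames = list(NULL, "a"))
  expect_warning(s0 <- stepwiseBic(ft, empty), "intercept-only")
  expect_equal(nrow(s0$spec@exponents), 0L)
})

test_that("cross-validation is seed-reproducible and exact on noiseless data", {
  set.seed(38)
  x <- matrix(rnorm(300 * 3), 300, dimnames = list(NULL, c("a", "b", "c")))
  yLin <- drop(scale(x) %*% c(1, -1, 0.5))
  ft <- featureTable(x, yLin)
  terms <- enumerateTerms(c("a", "b", "c"), 1)
  cv1 <- kfoldCv(ft, terms, k = 3, seed = 7)
  cv2 <- kfoldCv(ft, terms, k = 3, seed = 7)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$foldR2, cv2$foldR2)
  expect_equal(cv1$foldR2, rep(1, 3), tolerance = 1e-10)
  ## fold sizes differ by at most one
  expect_lte(diff(range(table(cv1$folds))), 1)
})

test_that("cross-validated R2 of pure noise is not positive", {
  set.seed(39)
  r2s <- replicate(10, {
    x <- matrix(rnorm(150 * 4), 150, dimnames = list(NULL, paste0("x", 1:4)))
    ft <- featureTable(x, rnorm(150))
    kfoldCv(ft, enumerateTerms(paste0("x", 1:4), 1), k = 3)$meanR2
  })
  expect_lt(mean(r2s), 0.02)
})

test_that("prediction is linear and matches brute-force term evaluation", {
  spec <- publishedModel()
  set.seed(40)
  for (i in 1:20) {
    v <- stats::setNames(rnorm(12), predictorNames())
    byHand <- spec@intercept
    for (j in seq_len(nrow(spec@exponents)))
      byHand <- byHand + spec@coefficients[j] * prod(v^spec@exponents[j, ])
    got <- predict(spec, matrix(v, 1, dimnames = list(NULL, names(v))))
    expect_equal(got, byHand, tolerance = 1e-12)
  }
  ## degree-1-only model: doubling features doubles (prediction - intercept)
  lin <- PolynomialModelSpec(diag(3L) |> `colnames<-`(c("a", "b", "c")),
                             c(1, -2, 0.5), intercept = 4)
  v <- matrix(c(1, 2, 3), 1, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(predict(lin, 2 * v) - 4, 2 * (predict(lin, v) - 4))
  expect_error(predict(lin, v[, 1:2, drop = FALSE]), "missing predictor")
})
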