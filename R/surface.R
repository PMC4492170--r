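## Response-surface analysis of the fitted polynomial: the published
## 28-term model, the simplified nested cubics in gene-body CG
## methylation, conditional profiles, stationary/inflection points, and
## Z <-> percent conversion.

#' The published 28-term expression model
#'
#' The reference cubic polynomial relating Z-standardized methylation and
#' gene-architecture predictors to log gene expression: 28 monomial terms
#' plus an intercept (29 fitted factors). Coefficients, standard errors
#' and t statistics are the published estimates; the predictor written
#' "Percent CG" in the source is gene-body CG methylation (`m_cg`), whose
#' cubic and up-stream-CHH interaction coefficients match the simplified
#' text model.
#'
#' @param intercept Intercept on the log-expression scale (default 2.61,
#'   the simplified model's constant; pass `NA` to leave it unset —
#'   surface shapes do not depend on it).
#' @return A [PolynomialModelSpec-class] over the 12 canonical predictors.
#' @examples
#' nFactors(publishedModel())   # 29
#' @export
publishedModel <- function(intercept = 2.61) {
  p <- predictorNames()
  term <- function(...) {
    e <- integer(12); names(e) <- p
    v <- list(...)
    for (nm in names(v)) e[nm] <- v[[nm]]
    e
  }
  rows <- list(
    ## positive terms
    list(term(l_intron = 1),               0.3472, 0.0117,  29.75),
    list(term(m_chg = 2),                  0.0874, 0.0082,  10.64),
    list(term(n_exon = 1, l_intron = 1),   0.0793, 0.0081,   9.74),
    list(term(l_exon = 1),                 0.0767, 0.0102,   7.55),
    list(term(l_exon = 1, l_intron = 1),   0.0553, 0.0070,   7.86),
    list(term(m_cg = 1, l_exon = 1),       0.0392, 0.0089,   4.40),
    list(term(m_cg = 2, l_exon = 1),       0.0303, 0.0069,   4.37),
    list(term(u_chh = 1),                  0.0275, 0.0055,   4.99),
    list(term(m_cg = 1, m_chh = 1),        0.0244, 0.0064,   3.78),
    list(term(d_chh = 1),                  0.0185, 0.0050,   3.69),
    list(term(u_chh = 1, m_cg = 1),        0.0167, 0.0051,   3.28),
    list(term(l_intron = 3),               0.0105, 0.0007,  14.40),
    list(term(l_exon = 2, n_exon = 1),     0.0074, 0.0009,   8.19),
    ## negative terms
    list(term(m_chg = 1),                 -0.3273, 0.0197, -16.58),
    list(term(l_intron = 2),              -0.1611, 0.0076, -21.18),
    list(term(m_cg = 2),                  -0.0980, 0.0092, -10.62),
    list(term(m_cg = 1),                  -0.0720, 0.0118,  -6.09),
    list(term(l_exon = 1, n_exon = 1),    -0.0662, 0.0076,  -8.72),
    list(term(m_chh = 1),                 -0.0451, 0.0076,  -5.93),
    list(term(n_exon = 1),                -0.0308, 0.0112,  -2.75),
    list(term(m_cg = 3),                  -0.0277, 0.0059,  -4.73),
    list(term(u_cg = 1),                  -0.0274, 0.0054,  -5.06),
    list(term(l_exon = 2),                -0.0205, 0.0033,  -6.28),
    list(term(m_chg = 1, l_exon = 1),     -0.0198, 0.0058,  -3.41),
    list(term(u_cg = 1, u_chh = 1),       -0.0188, 0.0058,  -3.23),
    list(term(u_cg = 1, m_cg = 1),        -0.0170, 0.0052,  -3.28),
    list(term(l_exon = 1, l_intron = 1, n_exon = 1),
                                          -0.0118, 0.0016,  -7.21),
    list(term(m_chg = 3),                 -0.0063, 0.0008,  -7.95))
  e <- do.call(rbind, lapply(rows, `[[`, 1))
  colnames(e) <- p
  PolynomialModelSpec(e,
                      coefficients = vapply(rows, `[[`, numeric(1), 2),
                      intercept = intercept,
                      se = vapply(rows, `[[`, numeric(1), 3),
                      tvalue = vapply(rows, `[[`, numeric(1), 4))
}

#' Simplified nested cubic models of gene-body CG methylation
#'
#' The simplified model family f1..f6: a univariate cubic in standardized
#' gene-body CG methylation (`m_cg`) built up term by term. Level 1 is
#' the linear model log(GE) = 2.61 - 0.07 m_cg; level 2 adds the
#' quadratic -0.10 m_cg^2; level 3 the cubic -0.03 m_cg^3; level 4 the
#' up-stream CG interaction -0.02 m_cg u_cg; level 5 the three positive
#' interactions m_cg (0.02 u_chh + 0.02 m_chh + 0.04 l_exon); level 6 the
#' quadratic interaction 0.03 m_cg^2 l_exon. Interaction partners are
#' supplied in Z units and folded into the cubic's coefficients.
#'
#' @param level Integer 1..6.
#' @param u_cg,u_chh,m_chh,l_exon Fixed standardized values of the
#'   interaction partners (used only at/above their introduction level).
#' @param includeExonEffects At level 6, also add the independent exon
#'   terms 0.08 l_exon - 0.02 l_exon^2 to the constant.
#' @return Named numeric vector `c(c0, c1, c2, c3)`: the conditional
#'   cubic's coefficients.
#' @examples
#' textModel(3, u_cg = 1)   # c(2.61, -0.09, -0.10, -0.03)
#' @export
textModel <- function(level, u_cg = 0, u_chh = 0, m_chh = 0, l_exon = 0,
                      includeExonEffects = FALSE) {
  if (!(is.numeric(level) && length(level) == 1 && level %in% 1:6))
    stop("level must be an integer in 1..6")
  c0 <- 2.61
  c1 <- -0.07
  c2 <- 0; c3 <- 0
  if (level >= 2) c2 <- -0.10
  if (level >= 3) c3 <- -0.03
  if (level >= 4) c1 <- c1 - 0.02 * u_cg
  if (level >= 5) c1 <- c1 + 0.02 * u_chh + 0.02 * m_chh + 0.04 * l_exon
  if (level >= 6) {
    c2 <- c2 + 0.03 * l_exon
    if (includeExonEffects) c0 <- c0 + 0.08 * l_exon - 0.02 * l_exon^2
  }
  c(c0 = c0, c1 = c1, c2 = c2, c3 = c3)
}

#' Evaluate a univariate polynomial profile
#' @param coefs Numeric coefficients in increasing power order
#'   (c0, c1, c2, ...).
#' @param x Points at which to evaluate.
#' @return Numeric vector.
#' @export
evaluateProfile <- function(coefs, x) {
  coefs <- unname(coefs)
  out <- numeric(length(x))
  for (i in seq_along(coefs)) out <- out + coefs[i] * x^(i - 1)
  out
}

#' Stationary points of a cubic profile
#'
#' Real roots of the derivative c1 + 2 c2 x + 3 c3 x^2, classified by the
#' second derivative: local maxima (negative), local minima (positive);
#' saddle points (zero second derivative, e.g. the flat point of a pure
#' cubic) are excluded.
#'
#' @param coefs Numeric vector `c(c0, c1[, c2[, c3]])`.
#' @return `data.frame` with `location`, `type` (`"max"`/`"min"`) and
#'   `value` (profile height at the point); zero rows when the derivative
#'   has no real root. Constant profiles are an error.
#' @examples
#' stationaryPoints(c(2.61, -0.07, -0.10))        # maximum at -0.35
#' stationaryPoints(c(2.61, -0.07, -0.10, -0.03)) # maximum at -0.4353
#' @export
stationaryPoints <- function(coefs) {
  coefs <- c(coefs, rep(0, max(0, 4 - length(coefs))))[1:4]
  c1 <- coefs[2]; c2 <- coefs[3]; c3 <- coefs[4]
  if (c1 == 0 && c2 == 0 && c3 == 0)
    stop("constant profile has no stationary-point structure")
  roots <- if (c3 != 0) {
    disc <- (2 * c2)^2 - 4 * (3 * c3) * c1
    if (disc < 0) numeric(0)
    else (-2 * c2 + c(-1, 1) * sqrt(disc)) / (2 * 3 * c3)
  } else if (c2 != 0) {
    -c1 / (2 * c2)
  } else numeric(0)   # linear: no stationary point
  if (!length(roots))
    return(data.frame(location = numeric(0), type = character(0),
                      value = numeric(0)))
  second <- 2 * c2 + 6 * c3 * roots
  keep <- second != 0
  roots <- roots[keep]; second <- second[keep]
  o <- order(roots)
  data.frame(location = roots[o],
             type = ifelse(second[o] < 0, "max", "min"),
             value = evaluateProfile(coefs, roots[o]))
}

#' Inflection point of a cubic profile
#'
#' Where the second derivative 2 c2 + 6 c3 x changes sign:
#' x = -c2 / (3 c3). Quadratic or lower profiles have none.
#'
#' @param coefs Numeric vector `c(c0, c1, c2, c3)`.
#' @return The location, or `NA` when `c3 = 0`.
#' @export
inflectionPoint <- function(coefs) {
  coefs <- c(coefs, rep(0, max(0, 4 - length(coefs))))[1:4]
  if (coefs[4] == 0) return(NA_real_)
  -coefs[3] / (3 * coefs[4])
}

#' Raw-scale anchors for standardized methylation predictors
#'
#' Per-predictor raw mean and SD implied by the printed (Z, percent)
#' anchor pairs of the reference analysis: gene-body CG methylation
#' (-1 -> 32 %, +1 -> 80 %, hence mean 56 %, SD 24 %) and up-stream CG
#' methylation (-1 -> 24.1 %, +1 -> 82 %).
#'
#' @return `data.frame` with `predictor`, `mean`, `sd` (percent units).
#' @export
scaleAnchors <- function() {
  data.frame(predictor = c("m_cg", "u_cg"),
             mean = c((32 + 80) / 2, (24.1 + 82) / 2),
             sd = c((80 - 32) / 2, (82 - 24.1) / 2))
}

#' Convert between Z units and percent methylation
#'
#' Affine map percent = mean + sd * z using per-predictor anchors.
#'
#' @param z,percent Values to convert.
#' @param predictor Predictor name (must have anchors).
#' @param anchors Anchor table, see [scaleAnchors()].
#' @return Numeric vector.
#' @export
zToPercent <- function(z, predictor = "m_cg", anchors = scaleAnchors()) {
  i <- match(predictor, anchors$predictor)
  if (is.na(i)) stop("no scale anchors for predictor: ", predictor)
  anchors$mean[i] + anchors$sd[i] * z
}

#' @rdname zToPercent
#' @export
percentToZ <- function(percent, predictor = "m_cg",
                       anchors = scaleAnchors()) {
  i <- match(predictor, anchors$predictor)
  if (is.na(i)) stop("no scale anchors for predictor: ", predictor)
  (percent - anchors$mean[i]) / anchors$sd[i]
}

#' Conditional cubic profile of one predictor in a polynomial model
#'
#' Collapses a multivariate polynomial model to a univariate cubic in one
#' free predictor by substituting fixed standardized values for every
#' other predictor. The reduction is algebraically exact: evaluating the
#' profile at any free value equals evaluating the full model with that
#' value substituted.
#'
#' @param spec A [PolynomialModelSpec-class].
#' @param free Name of the free predictor (must appear in the model).
#' @param fixed Named numeric vector of standardized values for other
#'   predictors; unnamed predictors default to 0 (their mean).
#' @return Named numeric vector `c(c0, c1, c2, c3)`.
#' @examples
#' conditionalProfile(publishedModel(), "m_cg")
#' @export
conditionalProfile <- function(spec, free, fixed = numeric(0)) {
  e <- spec@exponents
  if (!(free %in% colnames(e)) || all(e[, free] == 0))
    stop("free predictor absent from model: ", free)
  others <- setdiff(colnames(e), free)
  vals <- stats::setNames(rep(0, length(others)), others)
  if (length(fixed)) {
    unknown <- setdiff(names(fixed), others)
    if (length(unknown))
      stop("fixed values for unknown predictor(s): ",
           paste(unknown, collapse = ", "))
    vals[names(fixed)] <- fixed
  }
  cc <- c(c0 = if (is.na(spec@intercept)) 0 else spec@intercept,
          c1 = 0, c2 = 0, c3 = 0)
  for (j in seq_len(nrow(e))) {
    k <- e[j, free]
    contrib <- spec@coefficients[j] *
      prod(vals^e[j, others])
    cc[k + 1L] <- cc[k + 1L] + contrib
  }
  cc
}
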