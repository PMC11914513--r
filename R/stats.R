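#' Tail probabilities via the regularized incomplete beta function
#'
#' `pFromT` is the two-sided tail probability of a t statistic; `pFromF` the
#' upper tail probability of an F statistic. Both are evaluated through the
#' regularized incomplete beta function.
#'
#' @param t,f test statistic.
#' @param df,df1,df2 degrees of freedom.
#' @return A probability in \[0, 1\].
#' @examples
#' pFromT(0, 10)    # 1
#' pFromF(0, 3, 20) # 1
#' @export
pFromT <- function(t, df) {
  if (df <= 0) stop("df must be positive")
  ## two-sided: P(|T| >= |t|) = I_{df/(df+t^2)}(df/2, 1/2)
  stats::pbeta(df / (df + t^2), df / 2, 0.5)
}

#' @rdname pFromT
#' @export
pFromF <- function(f, df1, df2) {
  if (df1 <= 0 || df2 <= 0) stop("degrees of freedom must be positive")
  if (f < 0) stop("F statistic must be non-negative")
  ## upper tail: P(F >= f) = I_{df2/(df2 + df1 f)}(df2/2, df1/2)
  stats::pbeta(df2 / (df2 + df1 * f), df2 / 2, df1 / 2)
}

#' Two-sample t test (pooled variance)
#'
#' Classical two-sided two-sample t test with pooled variance:
#' t = (mean(a) - mean(b)) / sqrt(s2p (1/na + 1/nb)) with
#' s2p = ((na-1) s2a + (nb-1) s2b) / (na + nb - 2) and df = na + nb - 2.
#' A Welch variant (Satterthwaite df) is available via `pooled = FALSE`.
#'
#' @param a,b numeric value vectors (each length >= 2).
#' @param pooled use the pooled-variance statistic (default) or Welch.
#' @param testName label stored in the result.
#' @return A [StatResult].
#' @examples
#' twoSampleT(c(1, 2, 3), c(2, 3, 4))   # t = -1.2247, df = 4
#' @export
twoSampleT <- function(a, b, pooled = TRUE, testName = "two-sample t") {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  if (pooled) {
    s2p <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    if (s2p <= 0) {
      if (mean(a) == mean(b))
        return(new("StatResult", statistic = 0, df = na + nb - 2,
                   pValue = 1, testName = testName,
                   nPerGroup = c(na, nb)))
      stop("zero pooled variance with unequal means: degenerate t test")
    }
    t <- (mean(a) - mean(b)) / sqrt(s2p * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se2 <- va / na + vb / nb
    if (se2 <= 0) stop("zero variance: degenerate t test")
    t <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  new("StatResult", statistic = t, df = df, pValue = pFromT(t, df),
      testName = testName, nPerGroup = c(na, nb))
}

#' One-way ANOVA
#'
#' F test across k groups from the defining sums of squares:
#' F = (SSB / (k - 1)) / (SSW / (N - k)), with SSB the between-group and SSW
#' the within-group sum of squares.
#'
#' @param groups list of numeric vectors, one per group (k >= 2, each
#'   nonempty, total N > k).
#' @param testName label stored in the result.
#' @return A [StatResult] with `df = c(k - 1, N - k)`.
#' @examples
#' oneWayAnova(list(c(1, 2), c(3, 4)))   # F = 8, df = (1, 2)
#' @export
oneWayAnova <- function(groups, testName = "one-way ANOVA") {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, as.numeric)
  if (any(lengths(groups) == 0)) stop("all groups must be nonempty")
  k <- length(groups)
  N <- sum(lengths(groups))
  if (N <= k) stop("need more observations than groups")
  grand <- mean(unlist(groups))
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw <= 0) {
    if (ssb == 0)
      return(new("StatResult", statistic = 0, df = c(k - 1, N - k),
                 pValue = 1, testName = testName,
                 nPerGroup = as.integer(lengths(groups))))
    stop("zero within-group sum of squares: degenerate ANOVA")
  }
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  new("StatResult", statistic = f, df = c(k - 1, N - k),
      pValue = pFromF(f, k - 1, N - k), testName = testName,
      nPerGroup = as.integer(lengths(groups)))
}

## residual sum of squares of the least-squares fit of y on design X
rssFit <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Two-way main-effects ANOVA (Type II, unbalanced)
#'
#' Main-effects F tests for `value ~ factorA + factorB` on a possibly
#' unbalanced design, with Type II sums of squares: each main effect is the
#' residual-sum-of-squares reduction from adding that factor to the model
#' already containing the other. With the default `errorModel = "additive"`
#' the error term is the additive model's residual with
#' df = N - 1 - (a - 1) - (b - 1); with `errorModel = "full"` the error is
#' the residual of the model including the interaction (df = N - ab for
#' complete designs), the convention used by some ANOVA software even when
#' only main effects are reported. Cells empty in either factor combination
#' should be removed by the caller (as [eccentricityBins()] reports them);
#' levels absent from the data are dropped automatically.
#'
#' @param values numeric response values.
#' @param factorA,factorB factors (coerced) of the two main effects, e.g.
#'   visual field and eccentricity bin.
#' @param errorModel "additive" or "full" (see above).
#' @param testNames labels for the two per-factor results.
#' @return A list of two [StatResult]s, one per main effect, in the order
#'   (factorA, factorB).
#' @examples
#' v <- c(1, 2, 1, 2, 3, 4, 3, 4)
#' f <- rep(c("U", "L"), each = 4)
#' e <- rep(c("e1", "e1", "e2", "e2"), 2)
#' twoWayAnovaMainEffects(v, f, e)   # F_field = 20 with df (1, 5)
#' @export
twoWayAnovaMainEffects <- function(values, factorA, factorB,
                                   errorModel = c("additive", "full"),
                                   testNames = c("two-way ANOVA: factor A",
                                                 "two-way ANOVA: factor B")) {
  errorModel <- match.arg(errorModel)
  y <- as.numeric(values)
  fa <- droplevels(as.factor(factorA))
  fb <- droplevels(as.factor(factorB))
  stopifnot(length(fa) == length(y), length(fb) == length(y))
  a <- nlevels(fa); b <- nlevels(fb)
  if (a < 2 || b < 2)
    stop("each factor needs at least 2 levels after dropping empty cells")
  N <- length(y)
  Xab <- stats::model.matrix(~ fa + fb)
  Xa <- stats::model.matrix(~ fa)
  Xb <- stats::model.matrix(~ fb)
  rssAdd <- rssFit(Xab, y)
  ssA <- max(rssFit(Xb, y) - rssAdd, 0)   # factor A adjusted for B
  ssB <- max(rssFit(Xa, y) - rssAdd, 0)   # factor B adjusted for A
  if (errorModel == "additive") {
    dfe <- N - 1 - (a - 1) - (b - 1)
    rssErr <- rssAdd
  } else {
    Xint <- stats::model.matrix(~ fa * fb)
    dfe <- N - qr(Xint)$rank
    rssErr <- rssFit(Xint, y)
  }
  if (dfe <= 0) stop("no error degrees of freedom left")
  if (rssErr <= 0) stop("zero error sum of squares: degenerate ANOVA")
  mse <- rssErr / dfe
  fA <- (ssA / (a - 1)) / mse
  fB <- (ssB / (b - 1)) / mse
  list(new("StatResult", statistic = fA, df = c(a - 1, dfe),
           pValue = pFromF(fA, a - 1, dfe), testName = testNames[1],
           nPerGroup = as.integer(table(fa))),
       new("StatResult", statistic = fB, df = c(b - 1, dfe),
           pValue = pFromF(fB, b - 1, dfe), testName = testNames[2],
           nPerGroup = as.integer(table(fb))))
}

#' Field comparison and topography statistics of a measurement table
#'
#' Convenience wrappers over the measurement table: `fieldTTest` compares the
#' upper against the lower visual-field group with the pooled two-sample t
#' test (upper first, so a more negative upper field gives a negative t);
#' `directionOneWay` runs the one-way ANOVA across all retained angular
#' direction bins; `fieldByBinAnova` runs the Type II two-way main-effects
#' ANOVA of field x bin, dropping bins missing from either field.
#'
#' @param measurements a [sessionMeasurements()] table.
#' @param testName label for the result.
#' @return A [StatResult] (a list of two for `fieldByBinAnova`).
#' @export
fieldTTest <- function(measurements, testName = "upper vs lower field t") {
  u <- measurements$value[measurements$field == "upper"]
  l <- measurements$value[measurements$field == "lower"]
  twoSampleT(u, l, testName = testName)
}

#' @rdname fieldTTest
#' @inheritParams directionBins
#' @export
directionOneWay <- function(measurements, widthDeg = 20, stepDeg = 10,
                            minN = 10,
                            testName = "one-way ANOVA across direction bins") {
  groups <- directionBinGroups(measurements, widthDeg, stepDeg, minN)
  if (length(groups) < 2) stop("fewer than 2 retained direction bins")
  oneWayAnova(groups, testName = testName)
}

#' @rdname fieldTTest
#' @param by "eccentricity" (non-overlapping eccentricity bins) or
#'   "direction" (non-overlapping |direction| bins of width `stepDeg`... the
#'   two-way design uses non-overlapping bins so each session enters once).
#' @param edgesDeg bin edges for the chosen dimension.
#' @export
fieldByBinAnova <- function(measurements, by = c("eccentricity", "direction"),
                            edgesDeg = NULL) {
  by <- match.arg(by)
  if (is.null(edgesDeg))
    edgesDeg <- if (by == "eccentricity") c(0, 2, 5, 10, 30)
    else c(0, 30, 60, 90)
  v <- if (by == "eccentricity") measurements$eccentricity_deg
  else abs(measurements$direction_deg)
  keep <- v >= edgesDeg[1] & v < edgesDeg[length(edgesDeg)]
  m <- measurements[keep, , drop = FALSE]
  bin <- findInterval(if (by == "eccentricity") m$eccentricity_deg
                      else abs(m$direction_deg), edgesDeg)
  ## drop bins with data from only one field (no cross-field comparison there)
  tab <- table(m$field, bin)
  good <- colnames(tab)[apply(tab > 0, 2, all)]
  sel <- bin %in% as.integer(good)
  m <- m[sel, , drop = FALSE]; bin <- bin[sel]
  twoWayAnovaMainEffects(m$value, m$field, bin,
                         testNames = c("two-way ANOVA: visual field",
                                       sprintf("two-way ANOVA: %s bin", by)))
}
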