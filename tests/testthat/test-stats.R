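test_that("pooled t test reproduces hand-derived examples", {
  r <- twoSampleT(c(1, 2, 3), c(2, 3, 4))
  expect_equal(statistic(r), -1.224745, tolerance = 1e-6)
  expect_equal(degreesOfFreedom(r), 4)
  expect_equal(pValue(r), 0.2878641, tolerance = 1e-6)

  r2 <- twoSampleT(c(1, 3), c(2, 6))   # means 2, 4; pooled s2 = 5
  expect_equal(statistic(r2), -0.8944272, tolerance = 1e-6)
  expect_equal(degreesOfFreedom(r2), 2)

  same <- twoSampleT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(statistic(same), 0)
  expect_equal(pValue(same), 1)

  expect_error(twoSampleT(c(1, 1), c(2, 2)), "degenerate")
  expect_error(twoSampleT(1, c(1, 2)), "at least 2")
})

test_that("one-way ANOVA reproduces hand-derived examples", {
  r <- oneWayAnova(list(c(1, 2), c(3, 4)))   # SSB = 4, SSW = 1
  expect_equal(statistic(r), 8)
  expect_equal(degreesOfFreedom(r), c(1, 2))

  flat <- oneWayAnova(list(c(1, 2), c(1, 2)))
  expect_equal(statistic(flat), 0)
  expect_equal(pValue(flat), 1)

  # 12 groups totalling 351 values give df = (11, 339)
  set.seed(30)
  sizes <- c(rep(29, 9), 30, 30, 30)
  stopifnot(sum(sizes) == 351)
  g <- lapply(sizes, rnorm)
  r12 <- oneWayAnova(g)
  expect_equal(degreesOfFreedom(r12), c(11, 339))

  expect_error(oneWayAnova(list(1:3)), "2")
  # zero within-group variance with distinct means is degenerate
  expect_error(oneWayAnova(list(c(1, 1), c(2, 2))), "degenerate")
  # zero variance and equal means is the trivial null
  expect_equal(statistic(oneWayAnova(list(c(1, 1), c(1, 1)))), 0)
})

test_that("two-way Type II main effects match the balanced hand example", {
  v <- c(1, 2, 1, 2, 3, 4, 3, 4)
  f <- rep(c("U", "L"), each = 4)
  e <- rep(c("e1", "e1", "e2", "e2"), 2)
  res <- twoWayAnovaMainEffects(v, f, e)
  expect_equal(statistic(res[[1]]), 20)       # SSA = 8, SSE = 2, df (1, 5)
  expect_equal(degreesOfFreedom(res[[1]]), c(1, 5))
  expect_equal(statistic(res[[2]]), 0)

  # no effects: within-cell jitter only
  set.seed(31)
  v2 <- rnorm(40)
  f2 <- rep(c("U", "L"), 20)
  e2 <- rep(c("a", "b", "c", "d"), 10)
  res2 <- twoWayAnovaMainEffects(v2, f2, e2)
  expect_gt(pValue(res2[[1]]), 0.001)

  # additive error df: N - 1 - (a-1) - (b-1)
  set.seed(32)
  f3 <- sample(c("U", "L"), 193, replace = TRUE)
  e3 <- sample(letters[1:4], 193, replace = TRUE)
  res3 <- twoWayAnovaMainEffects(rnorm(193), f3, e3)
  expect_equal(degreesOfFreedom(res3[[1]]), c(1, 188))
  # with the interaction kept in the error term (2 x 4 design, N = 193)
  # the error df drops to N - a*b = 185
  res4 <- twoWayAnovaMainEffects(rnorm(193), f3, e3, errorModel = "full")
  expect_equal(degreesOfFreedom(res4[[1]]), c(1, 185))
  expect_equal(degreesOfFreedom(res4[[2]]), c(3, 185))

  expect_error(twoWayAnovaMainEffects(1:4, rep("U", 4), c("a", "a", "b", "b")),
               "2 levels")
})

test_that("t and F agree with the base-R oracles on random data", {
  set.seed(33)
  for (i in 1:300) {
    a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1), mean = runif(1, -1, 1))
    mine <- twoSampleT(a, b)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(statistic(mine), unname(ref$statistic), tolerance = 1e-10)
    expect_equal(pValue(mine), ref$p.value, tolerance = 1e-10)

    k <- sample(2:5, 1)
    g <- lapply(seq_len(k), function(j) rnorm(sample(3:8, 1), mean = j / 3))
    mineF <- oneWayAnova(g)
    df <- data.frame(y = unlist(g),
                     grp = factor(rep(seq_len(k), lengths(g))))
    refF <- stats::anova(stats::lm(y ~ grp, df))
    expect_equal(statistic(mineF), refF$`F value`[1], tolerance = 1e-10)
    expect_equal(pValue(mineF), refF$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("Type II two-way results agree with the car oracle when available", {
  skip_if_not_installed("car")
  set.seed(34)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    f <- factor(sample(c("U", "L"), n, replace = TRUE))
    e <- factor(sample(letters[1:sample(2:4, 1)], n, replace = TRUE))
    if (nlevels(droplevels(f)) < 2 || nlevels(droplevels(e)) < 2) next
    y <- rnorm(n) + as.numeric(f) * runif(1, 0, 1)
    mine <- twoWayAnovaMainEffects(y, f, e)
    ref <- car::Anova(stats::lm(y ~ f + e), type = 2)
    expect_equal(statistic(mine[[1]]), ref$`F value`[1], tolerance = 1e-9)
    expect_equal(statistic(mine[[2]]), ref$`F value`[2], tolerance = 1e-9)
    expect_equal(pValue(mine[[1]]), ref$`Pr(>F)`[1], tolerance = 1e-9)
    # with the interaction kept in the error term
    if (all(table(f, e) > 0)) {
      mineF <- twoWayAnovaMainEffects(y, f, e, errorModel = "full")
      refF <- car::Anova(stats::lm(y ~ f * e), type = 2)
      expect_equal(statistic(mineF[[1]]), refF$`F value`[1], tolerance = 1e-9)
      expect_equal(statistic(mineF[[2]]), refF$`F value`[2], tolerance = 1e-9)
    }
  }
})

test_that("two-group one-way ANOVA satisfies F = t squared", {
  set.seed(35)
  for (i in 1:50) {
    a <- rnorm(sample(3:10, 1)); b <- rnorm(sample(3:10, 1), 0.5)
    tt <- twoSampleT(a, b)
    ff <- oneWayAnova(list(a, b))
    expect_equal(statistic(ff), statistic(tt)^2, tolerance = 1e-9)
    expect_equal(pValue(ff), pValue(tt), tolerance = 1e-9)
  }
})

test_that("tail probabilities match the t and F distributions", {
  expect_equal(pFromT(0, 7), 1)
  expect_equal(pFromF(0, 3, 10), 1)
  set.seed(36)
  for (i in 1:50) {
    t <- rnorm(1, sd = 2); df <- sample(1:50, 1)
    expect_equal(pFromT(t, df), 2 * stats::pt(-abs(t), df), tolerance = 1e-12)
    f <- rexp(1); d1 <- sample(1:10, 1); d2 <- sample(2:50, 1)
    expect_equal(pFromF(f, d1, d2), stats::pf(f, d1, d2, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # monotone decreasing in |t| and in F
  ts <- seq(0, 5, by = 0.25)
  expect_true(all(diff(vapply(ts, pFromT, numeric(1), df = 10)) < 0))
  fs <- seq(0, 10, by = 0.5)
  expect_true(all(diff(vapply(fs, pFromF, numeric(1), df1 = 3, df2 = 20)) < 0))
  expect_error(pFromT(1, 0), "positive")
  expect_error(pFromF(-1, 1, 1), "non-negative")
})

test_that("field t tests put the upper group first", {
  m <- data.frame(field = rep(c("upper", "lower"), each = 4),
                  value = c(-3, -3.1, -2.9, -3, -1, -1.1, -0.9, -1))
  r <- fieldTTest(m)
  expect_lt(statistic(r), 0)   # more negative upper field => negative t
  expect_equal(r@nPerGroup, c(4L, 4L))
})
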