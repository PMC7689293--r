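# Univariable MR estimators against independent closed-form / brute-force /
# Monte-Carlo oracles.

test_that("Wald ratio and its first-order SE", {
  est <- waldRatio(0.1, 0.2, 0.01, 0.02)
  expect_equal(estBeta(est), 2)
  expect_equal(estSE(est), 0.2)
  est0 <- waldRatio(0.1, 0, 0.01, 0.02)
  expect_equal(estBeta(est0), 0)
  expect_equal(estSE(est0), 0.2)
  expect_error(waldRatio(0, 0.1, 0.01, 0.02), "undefined")
})

test_that("Wald SE matches a Monte-Carlo oracle for strong instruments", {
  # |bx|/se_x = 20 > 10: first-order SE within 5% of the simulated SD
  bx <- 0.2; by <- 0.1; sx <- 0.01; sy <- 0.02
  sim <- withSeed(404, {
    bxs <- rnorm(1e6, bx, sx); bys <- rnorm(1e6, by, sy)
    sd(bys / bxs)
  })
  expect_equal(estSE(waldRatio(bx, by, sx, sy)), sim, tolerance = 0.05)
})

test_that("IVW equals the closed-form weighted least squares oracle", {
  set.seed(31)
  for (k in c(3, 8)) {
    bx <- rnorm(k, 0.1, 0.05); by <- 0.4 * bx + rnorm(k, 0, 0.01)
    sy <- runif(k, 0.01, 0.03)
    h <- toyHarmonized(bx, by, sy = sy)
    w <- 1 / sy^2
    oracle <- sum(w * bx * by) / sum(w * bx^2)
    fit <- lm(by ~ 0 + bx, weights = w)   # independent solve
    expect_equal(estBeta(mrIVW(h)), oracle, tolerance = 1e-12)
    expect_equal(estBeta(mrIVW(h)), unname(coef(fit)), tolerance = 1e-12)
    # fixed-effects SE never exceeds multiplicative random-effects SE
    expect_lte(estSE(mrIVW(h, "fixed")), estSE(mrIVW(h)))
  }
})

test_that("IVW degenerate homogeneity and k=1 guard", {
  bx <- c(0.1, 0.2, 0.3); r <- 1.7
  h <- toyHarmonized(bx, r * bx)
  est <- mrIVW(h)
  expect_equal(estBeta(est), r)
  q <- cochranQ(h, est)
  expect_equal(q@Q, 0, tolerance = 1e-20)
  expect_equal(q@pvalue, 1)
  h1 <- toyHarmonized(0.1, 0.05)
  expect_error(mrIVW(h1), "waldRatio")
})

test_that("weighted median follows the midpoint interpolation rule", {
  # equal weights, ratios {1,2,9}: cumulative midpoints {1/6,1/2,5/6}
  h <- toyHarmonized(bx = c(1, 1, 1), by = c(1, 2, 9))
  expect_equal(estBeta(mrWeightedMedian(h, nBoot = 10)), 2)
  # all ratios equal
  h2 <- toyHarmonized(bx = c(0.1, 0.2, 0.4), by = c(0.15, 0.3, 0.6),
                      sy = c(0.02, 0.04, 0.08))
  expect_equal(estBeta(mrWeightedMedian(h2, nBoot = 10)), 1.5)
  # two-point interpolation: 50/50 weight on ratios 0 and 4 -> 2
  h3 <- toyHarmonized(bx = c(1, 1, 2, 2), by = c(0, 0, 8, 8),
                      sy = c(0.1, 0.1, 0.2, 0.2))
  expect_equal(estBeta(mrWeightedMedian(h3, nBoot = 10)), 2)
})

test_that("weighted median equals brute force on exhaustive small instruments", {
  # independent implementation of the interpolation rule
  bruteMedian <- function(r, w) {
    o <- order(r); r <- r[o]; w <- w[o] / sum(w)
    cw <- cumsum(w) - w / 2
    if (0.5 <= cw[1]) return(r[1])
    if (0.5 >= cw[length(r)]) return(r[length(r)])
    i <- max(which(cw < 0.5))
    r[i] + (r[i + 1] - r[i]) * (0.5 - cw[i]) / (cw[i + 1] - cw[i])
  }
  set.seed(77)
  for (k in 3:5) {
    for (rep in 1:40) {
      bx <- rnorm(k, 0.2, 0.1); bx[abs(bx) < 0.02] <- 0.05
      by <- rnorm(k, 0.1, 0.1)
      sy <- runif(k, 0.01, 0.05)
      h <- toyHarmonized(bx, by, sy = sy)
      w <- (abs(bx) / sy)^2
      expect_equal(estBeta(mrWeightedMedian(h, nBoot = 2)),
                   bruteMedian(by / bx, w), tolerance = 1e-12)
    }
  }
})

test_that("weighted median is stable under duplicating every SNP", {
  # With equal weights and an odd count, 0.5 falls inside the duplicated
  # middle value's span, so duplication is exactly neutral.
  h <- toyHarmonized(c(1, 1, 1), c(1, 2, 9))
  hd <- toyHarmonized(rep(c(1, 1, 1), 2), rep(c(1, 2, 9), 2))
  expect_equal(estBeta(mrWeightedMedian(hd, nBoot = 2)),
               estBeta(mrWeightedMedian(h, nBoot = 2)))
  # In general the midpoint-interpolation knots move by half a weight, so
  # duplication shifts the estimate by at most the local knot spacing.
  bx <- c(0.1, 0.2, 0.3); by <- c(0.05, 0.12, 0.2)
  h2 <- toyHarmonized(bx, by)
  h2d <- toyHarmonized(rep(bx, 2), rep(by, 2), sy = rep(0.02, 6))
  r <- sort(by / bx)
  expect_lt(abs(estBeta(mrWeightedMedian(h2d, nBoot = 2)) -
                estBeta(mrWeightedMedian(h2, nBoot = 2))),
            max(diff(r)))
})

test_that("MR-Egger equals an independent weighted LS solve", {
  set.seed(13)
  k <- 5
  bx <- abs(rnorm(k, 0.15, 0.05))
  by <- 0.02 + 0.5 * bx + rnorm(k, 0, 0.005)
  sy <- runif(k, 0.01, 0.02)
  h <- toyHarmonized(bx, by, sy = sy)
  egg <- mrEgger(h)
  X <- cbind(1, bx); W <- diag(1 / sy^2)
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% by)   # normal equations
  expect_equal(egg@intercept, beta[1], tolerance = 1e-10)
  expect_equal(estBeta(egg@slope), beta[2], tolerance = 1e-10)
})

test_that("adding a constant to outcome betas shifts only the intercept", {
  set.seed(14)
  bx <- abs(rnorm(6, 0.2, 0.05)); by <- 0.3 * bx + rnorm(6, 0, 0.01)
  h1 <- toyHarmonized(bx, by)
  h2 <- toyHarmonized(bx, by + 0.05)
  e1 <- mrEgger(h1); e2 <- mrEgger(h2)
  expect_equal(e2@intercept - e1@intercept, 0.05, tolerance = 1e-10)
  expect_equal(estBeta(e2@slope), estBeta(e1@slope), tolerance = 1e-10)
})

test_that("Egger with the intercept constrained to zero is IVW", {
  set.seed(15)
  bx <- abs(rnorm(7, 0.2, 0.08)); by <- 0.25 * bx + rnorm(7, 0, 0.02)
  sy <- runif(7, 0.01, 0.03)
  h <- toyHarmonized(bx, by, sy = sy)
  constrained <- lm(by ~ 0 + bx, weights = 1 / sy^2)
  expect_equal(estBeta(mrIVW(h, "fixed")), unname(coef(constrained)),
               tolerance = 1e-12)
})

test_that("Cochran's Q hand cases and simulation calibration", {
  # k=2, unit Wald weights, ratios at +/- d around the estimate: Q = 2 d^2
  d <- 0.3; m <- 1
  h <- toyHarmonized(bx = c(1, 1), by = c(m + d, m - d), sy = c(1, 1))
  est <- mrIVW(h, "fixed")
  expect_equal(estBeta(est), m)
  expect_equal(cochranQ(h, est)@Q, 2 * d^2, tolerance = 1e-12)

  # homogeneous simulated data: Q/(k-1) averages about 1
  qn <- withSeed(88, vapply(1:200, function(i) {
    k <- 20
    bx <- rnorm(k, 0.3, 0.02)          # measured nearly without error
    by <- rnorm(k, 0.4 * bx, 0.02)
    h <- toyHarmonized(bx, by, sx = rep(1e-6, k), sy = rep(0.02, k))
    cochranQ(h, mrIVW(h, "fixed"))@Q / (k - 1)
  }, 0))
  expect_equal(mean(qn), 1, tolerance = 0.05)
})

test_that("odds-ratio conversions follow the doubling convention", {
  expect_equal(unname(toOddsRatio(0, exposureType = "binary")["or"]), 1)
  expect_equal(unname(toOddsRatio(0, exposureType = "continuous")["or"]), 1)
  expect_equal(unname(toOddsRatio(1, exposureType = "binary")["or"]), 2)
  expect_equal(unname(toOddsRatio(1, exposureType = "continuous")["or"]),
               exp(1))
  # monotone, order-preserving on CI endpoints
  o <- toOddsRatio(0.5, 0.1, 0.9, "binary")
  expect_lt(o[["ci_low"]], o[["or"]])
  expect_lt(o[["or"]], o[["ci_high"]])
  est <- waldRatio(0.1, 0.05, 0.01, 0.01, exposureType = "continuous")
  expect_equal(est@or, exp(estBeta(est)))
})

test_that("the combined battery reports one row per method", {
  set.seed(16)
  bx <- rnorm(10, 0.2, 0.05); by <- 0.3 * bx + rnorm(10, 0, 0.01)
  h <- toyHarmonized(bx, by)
  out <- mrAll(h, nBoot = 50, seed = 2)
  expect_equal(out$table$method,
               c("ivw_re", "weighted_median", "egger_slope"))
  expect_true(all(is.finite(out$table$or)))
  expect_s4_class(out$q, "QResult")
})
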