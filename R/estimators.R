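## Two-sample MR estimators, heterogeneity/pleiotropy diagnostics and
## effect-scale conversions.

.hsCheck <- function(h, kmin) {
  stopifnot(is(h, "HarmonizedSet"))
  if (nrow(h@snps) < kmin)
    stop("need at least ", kmin, " SNPs (", nrow(h@snps), " available)",
         if (kmin == 2) "; use waldRatio() for a single SNP" else "")
  invisible(h)
}

#' Wald ratio causal estimate for a single SNP
#'
#' \eqn{\beta = b_y/b_x} with first-order standard error
#' \eqn{se_y/|b_x|}.
#'
#' @param bx,by exposure and outcome per-allele effects.
#' @param seX,seY their standard errors (seX kept for interface symmetry;
#'   the first-order SE ignores it, which is accurate for strong
#'   instruments).
#' @param exposureType "binary" or "continuous" (drives the OR scale).
#' @return An [MREstimate-class].
#' @export
waldRatio <- function(bx, by, seX, seY, exposureType = "binary") {
  if (bx == 0) stop("bx = 0: Wald ratio undefined")
  .mrEstimate("wald", beta = by / bx, se = seY / abs(bx), nSnps = 1L,
              exposureType = exposureType)
}

#' Inverse-variance-weighted MR estimate
#'
#' Weighted regression of outcome betas on exposure betas through the origin
#' with weights \eqn{1/se_y^2}: \eqn{\hat\beta = \sum w b_x b_y / \sum w
#' b_x^2}. The fixed-effects SE is \eqn{\sqrt{1/\sum w b_x^2}}; the
#' multiplicative random-effects model (the default, matching the study's
#' random-effects choice) inflates it by \eqn{\max(1, \sqrt{Q/(k-1)})}.
#'
#' @param h a [HarmonizedSet-class] with >= 2 SNPs.
#' @param model "multiplicative_random" (default) or "fixed".
#' @return An [MREstimate-class] (method `ivw_re` or `ivw_fixed`).
#' @export
mrIVW <- function(h, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  .hsCheck(h, 2L)
  bx <- h@exposureBeta[, 1]; by <- h@outcomeBeta; w <- 1 / h@outcomeSE^2
  k <- length(bx)
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se <- sqrt(1 / sum(w * bx^2))
  Q <- sum(w * (by - beta * bx)^2)
  if (model == "multiplicative_random")
    se <- se * max(1, sqrt(Q / (k - 1)))
  .mrEstimate(if (model == "fixed") "ivw_fixed" else "ivw_re",
              beta = beta, se = se, nSnps = k,
              exposureType = h@exposureTypes[1])
}

## Weighted median by midpoint-convention interpolation: sort ratios, weights
## normalized; the estimate is the ratio value at cumulative weight 0.5 where
## the cumulative weight of ratio i is sum(w[1..i]) - w[i]/2.
.weightedMedian <- function(values, weights) {
  o <- order(values)
  v <- values[o]; w <- weights[o] / sum(weights)
  cw <- cumsum(w) - w / 2
  if (0.5 <= cw[1]) return(v[1])
  if (0.5 >= cw[length(cw)]) return(v[length(cw)])
  approx(cw, v, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median MR estimate
#'
#' Per-SNP Wald ratios weighted by their inverse variance; consistent when
#' at least half of the weight comes from valid instruments. The SE comes
#' from a seeded parametric bootstrap resampling `bx` and `by` from their
#' standard errors.
#'
#' @param h a [HarmonizedSet-class] with >= 3 SNPs.
#' @param nBoot bootstrap replicates (default 5000).
#' @param seed RNG seed for the bootstrap.
#' @return An [MREstimate-class].
#' @export
mrWeightedMedian <- function(h, nBoot = 5000, seed = 1L) {
  .hsCheck(h, 3L)
  if (nBoot < 1) stop("nBoot must be >= 1")
  bx <- h@exposureBeta[, 1]; by <- h@outcomeBeta
  sx <- h@exposureSE[, 1]; sy <- h@outcomeSE
  ratio <- by / bx
  w <- 1 / (sy / abs(bx))^2
  beta <- .weightedMedian(ratio, w)
  k <- length(bx)
  bootEst <- withSeed(seed, vapply(seq_len(nBoot), function(b) {
    bxb <- rnorm(k, bx, sx); byb <- rnorm(k, by, sy)
    ok <- bxb != 0
    rb <- byb[ok] / bxb[ok]
    wb <- (abs(bxb[ok]) / sy[ok])^2
    .weightedMedian(rb, wb)
  }, 0))
  se <- sd(bootEst)
  .mrEstimate("weighted_median", beta = beta, se = se, nSnps = k,
              exposureType = h@exposureTypes[1])
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded internals (bootstraps,
#' simulators) do not perturb the session stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' MR-Egger regression
#'
#' Rows are first oriented so every exposure beta is non-negative (the
#' estimator is not invariant to allele coding), then outcome betas are
#' regressed on exposure betas with a free intercept and weights
#' \eqn{1/se_y^2}. A nonzero intercept indicates directional horizontal
#' pleiotropy. Inference uses the t distribution with k-2 df and the same
#' multiplicative residual inflation (floored at 1) as the IVW model.
#'
#' @param h a [HarmonizedSet-class] with >= 3 SNPs.
#' @return An [EggerResult-class].
#' @export
mrEgger <- function(h) {
  .hsCheck(h, 3L)
  bx <- h@exposureBeta[, 1]; by <- h@outcomeBeta; sy <- h@outcomeSE
  flip <- bx < 0
  bx[flip] <- -bx[flip]; by[flip] <- -by[flip]
  w <- 1 / sy^2
  k <- length(bx)
  fit <- lm(by ~ bx, weights = w)
  sm <- summary(fit)
  infl <- max(1, sm$sigma)          # residual-variance inflation, floored
  cf <- coef(sm)
  slopeSE <- cf["bx", "Std. Error"] / sm$sigma * infl
  intSE <- cf["(Intercept)", "Std. Error"] / sm$sigma * infl
  slope <- .mrEstimate("egger_slope", beta = cf["bx", "Estimate"],
                       se = slopeSE, nSnps = k, df = k - 2,
                       exposureType = h@exposureTypes[1])
  int <- cf["(Intercept)", "Estimate"]
  new("EggerResult", slope = slope, intercept = int, interceptSE = intSE,
      interceptPvalue = 2 * pt(-abs(int / intSE), df = k - 2))
}

#' Cochran's Q heterogeneity test
#'
#' \eqn{Q = \sum w_i (ratio_i - \hat\beta)^2} with first-order Wald weights
#' \eqn{w_i = b_{x,i}^2/se_{y,i}^2}; p from chi-square with k-1 df.
#'
#' @param h a [HarmonizedSet-class] with >= 2 SNPs.
#' @param est the [MREstimate-class] whose pooled estimate is tested
#'   (typically IVW).
#' @return A [QResult-class].
#' @export
cochranQ <- function(h, est) {
  .hsCheck(h, 2L)
  stopifnot(is(est, "MREstimate"))
  bx <- h@exposureBeta[, 1]; by <- h@outcomeBeta; sy <- h@outcomeSE
  ratio <- by / bx
  w <- bx^2 / sy^2
  Q <- sum(w * (ratio - est@beta)^2)
  k <- length(bx)
  new("QResult", Q = Q, df = as.integer(k - 1),
      pvalue = pchisq(Q, df = k - 1, lower.tail = FALSE))
}

#' Convert a log-scale causal estimate to the odds-ratio scale
#'
#' Binary exposures: `OR = exp(ln(2) * beta)`, the change in outcome odds per
#' 2-fold increase in exposure odds. Continuous exposures: `OR = exp(beta)`,
#' per SD of exposure. CI endpoints map through the same monotone transform.
#'
#' @param x an [MREstimate-class], or a numeric beta.
#' @param ciLow,ciHigh CI endpoints when `x` is numeric.
#' @param exposureType "binary" or "continuous" when `x` is numeric.
#' @return The [MREstimate-class] with OR slots filled, or a named numeric
#'   vector (or, ci_low, ci_high).
#' @export
toOddsRatio <- function(x, ciLow = NA_real_, ciHigh = NA_real_,
                        exposureType = c("binary", "continuous")) {
  if (is(x, "MREstimate")) {
    o <- toOddsRatio(x@beta, x@ciLow, x@ciHigh, x@exposureType)
    x@or <- o[["or"]]; x@orCiLow <- o[["ci_low"]]; x@orCiHigh <- o[["ci_high"]]
    return(x)
  }
  exposureType <- match.arg(exposureType)
  f <- if (exposureType == "binary") function(b) exp(log(2) * b) else exp
  c(or = f(x), ci_low = f(ciLow), ci_high = f(ciHigh))
}

#' Run the standard univariable MR battery on a harmonized set
#'
#' IVW (random effects), weighted median, MR-Egger and Cochran's Q in one
#' call; the summary table matches common two-sample MR reporting.
#'
#' @param h a [HarmonizedSet-class] with >= 3 SNPs.
#' @param nBoot,seed weighted-median bootstrap settings.
#' @return list(ivw, median, egger, q, table) where `table` has one row per
#'   method.
#' @export
mrAll <- function(h, nBoot = 5000, seed = 1L) {
  ivw <- mrIVW(h)
  med <- mrWeightedMedian(h, nBoot = nBoot, seed = seed)
  egg <- mrEgger(h)
  q <- cochranQ(h, ivw)
  tab <- rbind(as.data.frame(ivw), as.data.frame(med),
               as.data.frame(egg@slope))
  tab$exposure <- h@exposureNames[1]
  tab$outcome <- h@outcomeName
  list(ivw = ivw, median = med, egger = egg, q = q, table = tab)
}
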