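## MR-Steiger: infer causal direction from instrument variance explained.

## Observed-scale r2 for one trait across instrument SNPs. Continuous traits
## use the variance-explained formula; binary traits use the z-score
## approximation r2 ~ z^2/(z^2 + n) (observed scale; no liability
## conversion).
.traitR2 <- function(beta, se, eaf, n, type) {
  if (type == "continuous") {
    sum(varianceExplained(beta, se, eaf, n))
  } else {
    z <- beta / se
    sum(z^2 / (z^2 + n))
  }
}

#' MR-Steiger directionality test
#'
#' Compares the instrument's aggregate variance explained in the exposure
#' with that in the outcome. The causal direction is called "correct"
#' (exposure to outcome) when `r2_exposure > r2_outcome`; the z statistic is
#' Steiger's test for two correlations, applying the Fisher transform to
#' \eqn{\sqrt{r^2}} of each trait with its own sample size.
#'
#' The sensitivity ratio perturbs both traits' r2 over a grid of
#' hypothetical measurement-reliability multipliers (observed r2 divided by
#' the reliability) and reports the ratio of grid volume supporting the
#' called direction to the volume opposing it; `+Inf` when no point opposes.
#'
#' @param h a [HarmonizedSet-class] (instrument SNPs only).
#' @param nExp,nOut sample sizes; default from the harmonized tables.
#' @param reliabilityGrid multipliers in (0,1] applied to each trait
#'   (default `seq(0.5, 1, 0.1)`, a 36-point grid).
#' @return A [SteigerResult-class].
#' @export
steigerTest <- function(h, nExp = NULL, nOut = NULL,
                        reliabilityGrid = seq(0.5, 1, 0.1)) {
  stopifnot(is(h, "HarmonizedSet"))
  if (is.null(nExp)) nExp <- h@exposureN[1]
  if (is.null(nOut)) nOut <- h@outcomeN
  r2x <- .traitR2(h@exposureBeta[, 1], h@exposureSE[, 1],
                  h@exposureEAF[, 1], nExp, h@exposureTypes[1])
  r2y <- .traitR2(h@outcomeBeta, h@outcomeSE, h@outcomeEAF, nOut,
                  h@outcomeType)
  r2x <- min(r2x, 1 - 1e-12); r2y <- min(r2y, 1 - 1e-12)

  fisher <- function(r) atanh(r)
  z <- (fisher(sqrt(r2x)) - fisher(sqrt(r2y))) /
    sqrt(1 / (nExp - 3) + 1 / (nOut - 3))
  p <- 2 * pnorm(-abs(z))

  if (r2x == r2y) {
    warning("r2_exposure equals r2_outcome: direction undefined")
    direction <- NA
  } else direction <- r2x > r2y

  grid <- expand.grid(rx = reliabilityGrid, ry = reliabilityGrid)
  adjX <- pmin(r2x / grid$rx, 1)
  adjY <- pmin(r2y / grid$ry, 1)
  support <- if (isTRUE(direction)) adjX > adjY else adjY > adjX
  oppose <- if (isTRUE(direction)) adjX < adjY else adjY < adjX
  ratio <- if (is.na(direction)) NA_real_
           else if (sum(oppose) == 0) Inf
           else sum(support) / sum(oppose)

  new("SteigerResult", r2Exposure = r2x, r2Outcome = r2y,
      correctDirection = direction, z = z,
      pvalue = if (r2x == r2y) 1 else p, sensitivityRatio = ratio)
}
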