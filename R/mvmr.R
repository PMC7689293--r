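## Multivariable MR (direct effects conditional on a mediator) and
## total/direct mediation reporting.

#' Multivariable MR fit
#'
#' Weighted multiple regression of outcome betas on the matrix of exposure
#' betas with no intercept and weights \eqn{1/se_y^2}. Standard errors use
#' the weighted-regression covariance with multiplicative residual inflation
#' floored at 1 (the same convention as [mrIVW()]). With a single exposure
#' this reproduces univariable IVW exactly.
#'
#' A Sanderson-style conditional instrument-strength diagnostic is reported
#' per exposure: the heterogeneity of that exposure's betas about their
#' weighted projection on the other exposures, scaled by its exposure
#' standard errors and divided by the residual degrees of freedom. It is a
#' diagnostic only; nothing is gated on it.
#'
#' @param h a [HarmonizedSet-class]; `k` must exceed the number of
#'   exposures.
#' @return An [MVMRResult-class].
#' @export
mvmrFit <- function(h) {
  stopifnot(is(h, "HarmonizedSet"))
  X <- h@exposureBeta
  y <- h@outcomeBeta
  w <- 1 / h@outcomeSE^2
  k <- nrow(X); p <- ncol(X)
  if (k < p + 1) stop("need more SNPs than exposures (k=", k, ", p=", p, ")")

  ## An exposure with no genetic associations at all cannot be conditioned
  ## on: its column is dropped from the solve and reported as NA, so the
  ## remaining exposures reduce to the nested (e.g. univariable IVW) model.
  zero <- apply(X, 2, function(col) all(col == 0))
  if (any(zero)) {
    warning("exposure(s) with all-zero betas excluded from the design: ",
            paste(h@exposureNames[zero], collapse = ", "))
    sub <- initialize(h,
      exposureBeta = X[, !zero, drop = FALSE],
      exposureSE = h@exposureSE[, !zero, drop = FALSE],
      exposureEAF = h@exposureEAF[, !zero, drop = FALSE],
      exposureNames = h@exposureNames[!zero],
      exposureTypes = h@exposureTypes[!zero],
      exposureN = h@exposureN[!zero])
    fitSub <- mvmrFit(sub)
    pad <- function(v) {
      out <- setNames(rep(NA_real_, p), h@exposureNames)
      out[names(v)] <- v
      out
    }
    return(new("MVMRResult", exposures = h@exposureNames,
               beta = pad(fitSub@beta), se = pad(fitSub@se),
               pvalue = pad(fitSub@pvalue), or = pad(fitSub@or),
               orCiLow = pad(fitSub@orCiLow), orCiHigh = pad(fitSub@orCiHigh),
               k = fitSub@k, conditionalF = pad(fitSub@conditionalF),
               exposureTypes = h@exposureTypes))
  }

  qrX <- qr(sqrt(w) * X)
  if (qrX$rank < p) {
    cors <- stats::cor(X)
    pair <- which(abs(cors) == max(abs(cors[upper.tri(cors)])), arr.ind = TRUE)
    pair <- pair[pair[, 1] < pair[, 2], , drop = FALSE][1, ]
    stop("rank-deficient design: exposure betas collinear (",
         h@exposureNames[pair[1]], " vs ", h@exposureNames[pair[2]], ")")
  }
  XtWX <- crossprod(X, w * X)
  XtWy <- crossprod(X, w * y)
  beta <- drop(solve(XtWX, XtWy))
  resid <- y - drop(X %*% beta)
  sigma2 <- max(1, sum(w * resid^2) / (k - p))
  covB <- sigma2 * solve(XtWX)
  se <- sqrt(diag(covB))
  pv <- 2 * pnorm(-abs(beta / se))
  zc <- qnorm(0.975)

  condF <- vapply(seq_len(p), function(j) {
    wx <- 1 / h@exposureSE[, j]^2
    if (p == 1) {
      q <- sum(wx * X[, 1]^2) / k       # unconditional mean chi-square
    } else {
      others <- X[, -j, drop = FALSE]
      fit <- lm(X[, j] ~ 0 + others, weights = wx)
      q <- sum(wx * residuals(fit)^2) / (k - (p - 1))
    }
    q
  }, 0)

  ors <- vapply(seq_len(p), function(j)
    toOddsRatio(beta[j], beta[j] - zc * se[j], beta[j] + zc * se[j],
                h@exposureTypes[j]), numeric(3))
  nm <- h@exposureNames
  new("MVMRResult", exposures = nm,
      beta = setNames(beta, nm), se = setNames(se, nm),
      pvalue = setNames(pv, nm),
      or = setNames(ors[1, ], nm), orCiLow = setNames(ors[2, ], nm),
      orCiHigh = setNames(ors[3, ], nm),
      k = as.integer(k), conditionalF = setNames(condF, nm),
      exposureTypes = h@exposureTypes)
}

#' Pair total and direct effects into a mediation report
#'
#' The total effect is the univariable MR estimate; the direct effect is the
#' exposure's multivariable (mediator-conditional) estimate. Both are also
#' expressed as percent increase in outcome odds per 2-fold increase in
#' exposure odds, `100*(exp(ln2*beta) - 1)`, with CIs by transforming the
#' interval endpoints. No indirect effect is computed for binary outcomes:
#' odds ratios are noncollapsible, so total minus direct does not identify a
#' mediated path.
#'
#' @param total an [MREstimate-class] (univariable, total effect).
#' @param mvmr an [MVMRResult-class] containing `exposureName`.
#' @param exposureName which exposure's direct effect to pair.
#' @param outcomeType "binary" or "continuous".
#' @return A [MediationResult-class].
#' @export
mediate <- function(total, mvmr, exposureName,
                    outcomeType = c("binary", "continuous")) {
  outcomeType <- match.arg(outcomeType)
  stopifnot(is(total, "MREstimate"), is(mvmr, "MVMRResult"))
  if (!exposureName %in% mvmr@exposures)
    stop("exposure '", exposureName, "' not in the MVMR fit (has: ",
         paste(mvmr@exposures, collapse = ", "), ")")
  zc <- qnorm(0.975)
  db <- mvmr@beta[[exposureName]]
  dse <- mvmr@se[[exposureName]]
  pct <- function(b) 100 * (exp(log(2) * b) - 1)
  reason <- if (outcomeType == "binary")
    "noncollapsible binary outcome" else
    "not computed; report total - direct path product externally"
  new("MediationResult", exposure = exposureName, total = total,
      directBeta = db, directSE = dse,
      directPvalue = mvmr@pvalue[[exposureName]],
      directCiLow = db - zc * dse, directCiHigh = db + zc * dse,
      totalPercent = pct(total@beta),
      totalPercentCi = c(pct(total@ciLow), pct(total@ciHigh)),
      directPercent = pct(db),
      directPercentCi = c(pct(db - zc * dse), pct(db + zc * dse)),
      indirectAbsentReason = reason)
}

#' Mediation report as a one-row data.frame
#' @param m a [MediationResult-class].
#' @return data.frame with total/direct betas, ORs and percent forms.
#' @export
mediationTable <- function(m) {
  stopifnot(is(m, "MediationResult"))
  data.frame(exposure = m@exposure,
             total_b = m@total@beta, total_or = m@total@or,
             total_or_lci = m@total@orCiLow, total_or_uci = m@total@orCiHigh,
             total_pct = m@totalPercent,
             total_pct_lci = m@totalPercentCi[1],
             total_pct_uci = m@totalPercentCi[2],
             direct_b = m@directBeta, direct_se = m@directSE,
             direct_p = m@directPvalue,
             direct_pct = m@directPercent,
             direct_pct_lci = m@directPercentCi[1],
             direct_pct_uci = m@directPercentCi[2],
             indirect = m@indirectAbsentReason)
}
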