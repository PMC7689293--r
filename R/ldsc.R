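## Simplified bivariate LD score regression: heritability and genetic
## correlation from per-SNP z-scores and an explicit LD reference.

#' Compute per-SNP LD scores from an LD reference
#'
#' \eqn{\ell_j = 1 + \sum_{i \ne j} r^2(i, j)} over pairs present in the
#' reference (the self term contributes the 1). SNPs absent from the
#' reference receive \eqn{\ell_j = 1} with a warning.
#'
#' @param ld an [LDReference-class].
#' @param snpIds SNPs to score, in genome order.
#' @return An [LDScoreTable-class].
#' @export
computeLDScores <- function(ld, snpIds) {
  stopifnot(is(ld, "LDReference"))
  scores <- setNames(rep(1, length(snpIds)), snpIds)
  p <- ld@pairs
  if (nrow(p)) {
    inset <- p$snp_a %in% snpIds & p$snp_b %in% snpIds
    p <- p[inset, , drop = FALSE]
    add <- tapply(c(p$r2, p$r2), c(p$snp_a, p$snp_b), sum)
    hit <- intersect(names(add), snpIds)
    scores[hit] <- scores[hit] + add[hit]
    covered <- unique(c(ld@pairs$snp_a, ld@pairs$snp_b))
    nAbsent <- sum(!snpIds %in% covered)
    if (nAbsent > 0)
      warning(nAbsent, " SNP(s) absent from the LD reference; scores set to 1")
  }
  new("LDScoreTable", scores = scores, M = length(snpIds))
}

## Single weighted regression of y on ell used by both h2 and rg fits.
.ldscFit <- function(y, ell, w) {
  W <- w / sum(w)
  mx <- sum(W * ell); my <- sum(W * y)
  sxx <- sum(W * (ell - mx)^2)
  ## constant LD scores carry no information: slope 0, intercept the mean
  slope <- if (sxx < 1e-12) 0 else sum(W * (ell - mx) * (y - my)) / sxx
  list(slope = slope, intercept = my - slope * mx)
}

#' Heritability by LD score regression
#'
#' Regresses squared z-scores on LD scores; `h2 = slope * M / n`. Weights
#' are \eqn{1/(2 (1 + n h^2 \ell / M)^2)}, initialized at h2 = 0 and updated
#' by one re-weighting iteration. Negative fitted h2 is clipped to 0 with a
#' warning.
#'
#' @param z2 per-SNP squared z statistics (genome order, >= 200 SNPs).
#' @param n GWAS sample size.
#' @param ldscores an [LDScoreTable-class] aligned to `z2`.
#' @return list(h2, intercept, slope).
#' @export
h2Regression <- function(z2, n, ldscores) {
  stopifnot(is(ldscores, "LDScoreTable"), length(z2) == ldscores@M)
  if (length(z2) < 200) stop("need at least 200 SNPs")
  ell <- unname(ldscores@scores)
  M <- ldscores@M
  fit <- .ldscFit(z2, ell, rep(1, M))
  h2 <- max(0, fit$slope * M / n)
  w <- 1 / (2 * (1 + n * h2 * ell / M)^2)
  fit <- .ldscFit(z2, ell, w)
  h2 <- fit$slope * M / n
  if (h2 < 0) {
    warning("negative fitted h2 clipped to 0")
    h2 <- 0
  }
  list(h2 = h2, intercept = fit$intercept, slope = fit$slope)
}

.rgPoint <- function(z1, z2, n1, n2, ell, M, w1, w2, wx) {
  f1 <- .ldscFit(z1^2, ell, w1)
  f2 <- .ldscFit(z2^2, ell, w2)
  fx <- .ldscFit(z1 * z2, ell, wx)
  h21 <- f1$slope * M / n1
  h22 <- f2$slope * M / n2
  rhog <- fx$slope * M / sqrt(n1 * n2)
  rg <- if (h21 <= 0 || h22 <= 0) NA_real_ else rhog / sqrt(h21 * h22)
  list(h21 = h21, h22 = h22, rg = rg,
       int1 = f1$intercept, int2 = f2$intercept, gcovInt = fx$intercept)
}

#' Bivariate LD score regression genetic correlation
#'
#' Regresses the per-SNP z-score product on LD scores to estimate the
#' genetic covariance (`slope * M / sqrt(n1 n2)`), normalizes by the two
#' heritabilities from [h2Regression()], clips to \[-1, 1\], and attaches a
#' delete-one block jackknife SE over contiguous SNP blocks. Samples are
#' assumed non-overlapping, so the cross-product intercept is reported but
#' not modelled.
#'
#' @param z1,z2 per-SNP z statistics on the shared SNP set (genome order).
#' @param n1,n2 sample sizes.
#' @param ldscores an [LDScoreTable-class] aligned to the z vectors.
#' @param nBlocks jackknife blocks (default 200, reduced to
#'   `floor(M/25)` when fewer SNPs; at least 20).
#' @return An [RgResult-class].
#' @export
rgRegression <- function(z1, z2, n1, n2, ldscores, nBlocks = 200) {
  stopifnot(is(ldscores, "LDScoreTable"),
            length(z1) == ldscores@M, length(z2) == ldscores@M)
  M <- ldscores@M
  nBlocks <- min(nBlocks, max(20L, floor(M / 25)))
  if (M < 20 * 10) stop("too few SNPs for a stable jackknife")
  ell <- unname(ldscores@scores)

  ## one re-weighting iteration as in the univariate fit
  pre1 <- h2Regression(z1^2, n1, ldscores)
  pre2 <- h2Regression(z2^2, n2, ldscores)
  w1 <- 1 / (2 * (1 + n1 * max(0, pre1$h2) * ell / M)^2)
  w2 <- 1 / (2 * (1 + n2 * max(0, pre2$h2) * ell / M)^2)
  wx <- sqrt(w1 * w2)

  full <- .rgPoint(z1, z2, n1, n2, ell, M, w1, w2, wx)
  if (!is.finite(full$rg)) {
    warning("non-positive h2 for one trait: rg undefined")
    return(new("RgResult", h2Trait1 = full$h21, h2Trait2 = full$h22,
               rg = NA_real_, seRg = NA_real_, z = NA_real_,
               pvalue = NA_real_,
               intercepts = c(int1 = full$int1, int2 = full$int2,
                              gcovInt = full$gcovInt),
               nBlocks = as.integer(nBlocks)))
  }
  blockId <- ceiling(seq_along(z1) / (M / nBlocks))
  loo <- vapply(seq_len(nBlocks), function(b) {
    keep <- blockId != b
    v <- .rgPoint(z1[keep], z2[keep], n1, n2, ell[keep], sum(keep),
                  w1[keep], w2[keep], wx[keep])
    if (is.finite(v$rg)) v$rg else full$rg
  }, 0)
  nb <- length(loo)
  seJk <- sqrt((nb - 1) / nb * sum((loo - mean(loo))^2))
  rg <- max(-1, min(1, full$rg))
  z <- rg / seJk
  new("RgResult", h2Trait1 = full$h21, h2Trait2 = full$h22, rg = rg,
      seRg = seJk, z = z, pvalue = 2 * pnorm(-abs(z)),
      intercepts = c(int1 = full$int1, int2 = full$int2,
                     gcovInt = full$gcovInt),
      nBlocks = as.integer(nb))
}

#' One-row rg summary table (LDSC-style columns)
#' @param res an [RgResult-class].
#' @param p1,p2 trait labels.
#' @return data.frame with columns p1, p2, rg, se, z, p, h2_obs1, h2_obs2,
#'   h2_int1, h2_int2, gcov_int.
#' @export
rgTable <- function(res, p1 = "trait1", p2 = "trait2") {
  stopifnot(is(res, "RgResult"))
  data.frame(p1 = p1, p2 = p2, rg = res@rg, se = res@seRg, z = res@z,
             p = res@pvalue, h2_obs1 = res@h2Trait1, h2_obs2 = res@h2Trait2,
             h2_int1 = res@intercepts[["int1"]],
             h2_int2 = res@intercepts[["int2"]],
             gcov_int = res@intercepts[["gcovInt"]])
}
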