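## Individual-level MR: polygenic scores, Nagelkerke pseudo-R2, and
## two-stage predictor substitution with a mediator channel.

#' Polygenic score from a weight table
#'
#' `score_i = sum_j w_j dosage_ij`, with dosages aligned to each weight's
#' effect allele (a swapped allele contributes `2 - dosage`). Weight SNPs
#' absent from the cohort are dropped with a warning; more than `maxMissing`
#' missing is fatal.
#'
#' @param cohort a [Cohort-class].
#' @param prs data.frame (snp_id, effect_allele, weight) from [prsModel()].
#' @param maxMissing maximum tolerated missing fraction (default 0.2).
#' @return numeric per-individual score vector.
#' @export
scoreCohort <- function(cohort, prs, maxMissing = 0.2) {
  stopifnot(is(cohort, "Cohort"),
            all(c("snp_id", "effect_allele", "weight") %in% names(prs)))
  idx <- match(prs$snp_id, cohort@snps$snp_id)
  missing <- is.na(idx)
  if (mean(missing) > maxMissing)
    stop("more than ", round(100 * maxMissing),
         "% of PRS SNPs missing from the cohort")
  if (any(missing))
    warning(sum(missing), " PRS SNP(s) missing from the cohort; dropped")
  prs <- prs[!missing, , drop = FALSE]
  idx <- idx[!missing]
  G <- cohort@dosages[, idx, drop = FALSE]
  cohortEA <- cohort@snps$effect_allele[idx]
  w <- prs$weight
  swapped <- prs$effect_allele != cohortEA
  ## dosage of the weight's effect allele is 2 - dosage when labels disagree
  base <- as.vector(G %*% ifelse(swapped, -w, w))
  base + 2 * sum(w[swapped])
}

#' Nagelkerke's pseudo-R2 for nested logistic models
#'
#' \eqn{R^2 = [1 - \exp((2/n)(\ell_0 - \ell_1))] / [1 - \exp((2/n)\ell_0)]}
#' from the maximized log-likelihoods of the null and full models.
#'
#' @param y binary response vector.
#' @param full data.frame/matrix of covariates for the full model.
#' @param null data.frame/matrix of covariates for the null model (subset of
#'   `full`); NULL for the intercept-only null.
#' @return numeric scalar in \[0, 1\].
#' @export
nagelkerkeR2 <- function(y, full, null = NULL) {
  n <- length(y)
  dfull <- data.frame(y = y, full)
  m1 <- glm(y ~ ., data = dfull, family = binomial())
  m0 <- if (is.null(null)) glm(y ~ 1, family = binomial()) else
    glm(y ~ ., data = data.frame(y = y, null), family = binomial())
  if (!m1$converged || any(fitted(m1) < 1e-10 | fitted(m1) > 1 - 1e-10))
    warning("possible separation in the full logistic model")
  l1 <- as.numeric(logLik(m1)); l0 <- as.numeric(logLik(m0))
  r2 <- (1 - exp((2 / n) * (l0 - l1))) / (1 - exp((2 / n) * l0))
  max(0, min(1, r2))
}

.covarNames <- c("age", "sex", "pc1", "pc2", "pc3", "pc4", "pc5")

.glmRow <- function(fit, term) {
  cf <- summary(fit)$coefficients
  if (!term %in% rownames(cf) || is.na(coef(fit)[term]))
    return(c(beta = NA_real_, se = NA_real_, p = NA_real_))
  c(beta = cf[term, 1], se = cf[term, 2], p = cf[term, 4])
}

#' Two-stage predictor substitution (2SPS)
#'
#' Stage 1 regresses the exposure (logistic for binary smoking status,
#' adjusted for age, sex and five PCs) on the polygenic score and carries
#' the fitted probabilities forward. Stage 2 regresses the outcome
#' (logistic for binary outcomes, linear for BMI) on the predicted exposure
#' plus covariates: its coefficient is the total effect. When
#' `bmiWeights` is supplied, a second stage-1 linear model predicts
#' standardized BMI from the mediator-by-exposure-SNPs score, and stage 2
#' includes both predicted exposure (direct effect) and predicted BMI. A
#' linear-model instrument F below `fGate` (default 10, the conventional
#' weak-instrument guard) aborts before stage 2.
#'
#' Effect conversions follow the binary-exposure convention: outcome odds
#' ratios per 2-fold increase in exposure odds, `exp(ln2 * beta)`; for the
#' BMI outcome the absolute change per 2-fold exposure odds is
#' `ln(2) * beta` on the kg/m2 scale.
#'
#' @param cohort a [Cohort-class].
#' @param smokingPrs PRS weight table for the exposure.
#' @param outcome "t2d", "cad" or "bmi".
#' @param bmiWeights optional PRS weight table (same SNPs, mediator-derived
#'   weights) enabling the mediator-adjusted model.
#' @param fGate weak-instrument threshold on the stage-1 F (default 10).
#' @return A [TwoStageResult-class].
#' @export
twoStage <- function(cohort, smokingPrs, outcome = c("t2d", "cad", "bmi"),
                     bmiWeights = NULL, fGate = 10) {
  outcome <- match.arg(outcome)
  stopifnot(is(cohort, "Cohort"))
  ph <- cohort@phenotypes
  cv <- cohort@covariates[, .covarNames]
  score <- scoreCohort(cohort, smokingPrs)

  ## stage 1: exposure on score + covariates
  d1 <- data.frame(y = ph$smoking_ever, score = score, cv)
  s1 <- glm(y ~ ., data = d1, family = binomial())
  s1row <- .glmRow(s1, "score")
  ## instrument F from the partial linear fit (standard 2SLS diagnostic)
  lin <- lm(y ~ ., data = d1)
  lin0 <- lm(y ~ . - score, data = d1)
  an <- stats::anova(lin0, lin)
  f1 <- an$F[2]
  nag <- nagelkerkeR2(ph$smoking_ever, d1[, -1, drop = FALSE],
                      cv)
  if (!is.finite(f1) || f1 < fGate)
    stop(sprintf(
      "weak instrument: stage-1 F = %.2f < %g; refusing stage 2",
      if (is.finite(f1)) f1 else 0, fGate))
  predSmk <- fitted(s1)

  yOut <- switch(outcome, t2d = ph$t2d, cad = ph$cad, bmi = ph$bmi)
  binaryOut <- outcome != "bmi"
  fitStage2 <- function(df) {
    if (binaryOut) glm(y ~ ., data = df, family = binomial())
    else lm(y ~ ., data = df)
  }
  fTot <- fitStage2(data.frame(y = yOut, pred_smoking = predSmk, cv))
  if (binaryOut && !fTot$converged)
    stop("stage-2 model did not converge (outcome ", outcome, ")")
  tot <- .glmRow(fTot, "pred_smoking")

  adj <- c(beta = NA_real_, se = NA_real_, p = NA_real_)
  med <- c(beta = NA_real_, se = NA_real_, p = NA_real_)
  if (!is.null(bmiWeights)) {
    bmiScore <- scoreCohort(cohort, bmiWeights)
    dB <- data.frame(y = ph$bmi_std, score = bmiScore, cv)
    sB <- lm(y ~ ., data = dB)
    predBmi <- fitted(sB)
    ## predicted mediator listed last so that a degenerate score (collinear
    ## with the covariates) is the term aliased out of the fit
    fAdj <- fitStage2(data.frame(y = yOut, pred_smoking = predSmk,
                                 cv, pred_bmi = predBmi))
    adj <- .glmRow(fAdj, "pred_smoking")
    med <- .glmRow(fAdj, "pred_bmi")
    if (is.na(adj["beta"]))
      stop("stage-2 adjusted model rank-deficient for pred_smoking")
    if (is.na(med["beta"])) {
      ## degenerate mediator score (e.g. all-zero weights): predicted BMI is
      ## collinear with the covariates, so the adjusted model collapses onto
      ## the total-effect model
      warning("predicted BMI collinear with covariates; adjusted model ",
              "equals the total-effect model")
    }
  }

  orize <- function(rw) {
    if (is.na(rw["beta"])) return(c(NA_real_, NA_real_, NA_real_))
    zc <- qnorm(0.975)
    unname(toOddsRatio(rw[["beta"]], rw[["beta"]] - zc * rw[["se"]],
                       rw[["beta"]] + zc * rw[["se"]], "binary"))
  }
  orT <- orize(tot); orA <- orize(adj)
  new("TwoStageResult",
      stage1Beta = s1row[["beta"]], stage1SE = s1row[["se"]],
      stage1P = s1row[["p"]], stage1F = f1, nagelkerkeR2 = nag,
      totalBeta = tot[["beta"]], totalSE = tot[["se"]],
      totalP = tot[["p"]], totalOr = orT[1], totalOrCi = orT[2:3],
      adjustedBeta = adj[["beta"]], adjustedSE = adj[["se"]],
      adjustedP = adj[["p"]], adjustedOr = orA[1], adjustedOrCi = orA[2:3],
      mediatorBeta = med[["beta"]], mediatorSE = med[["se"]],
      mediatorP = med[["p"]],
      outcome = outcome, outcomeType = if (binaryOut) "binary" else
        "continuous")
}

#' Absolute BMI change per 2-fold exposure odds
#'
#' For a linear stage-2 model on the kg/m2 scale, the absolute change per
#' 2-fold increase in exposure odds is `ln(2) * beta`.
#'
#' @param beta stage-2 linear coefficient (kg/m2 per unit predicted
#'   exposure).
#' @return numeric, kg/m2 per 2-fold exposure odds.
#' @export
bmiPerDoubling <- function(beta) log(2) * beta
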