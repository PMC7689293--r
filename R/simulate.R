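## Synthetic cohorts and derived GWAS summary statistics under a known
## causal mediation model: smoking -> BMI -> {T2D, CAD} with direct smoking
## paths. Every test fixture in the package derives from this module.

## Upper-orthant probability P(z1 > a, z2 > b) for a standard bivariate
## normal with correlation rho, by one-dimensional quadrature.
.biNormUpper <- function(a, b, rho) {
  if (abs(rho) < 1e-12) return(pnorm(a, lower.tail = FALSE) *
                               pnorm(b, lower.tail = FALSE))
  stats::integrate(function(x)
    stats::dnorm(x) * pnorm((rho * x - b) / sqrt(1 - rho^2)),
    lower = a, upper = Inf, rel.tol = 1e-9)$value
}

## Dosage-scale correlation implied by the single-latent Gaussian copula at
## latent correlation rho and minor allele frequency p (HWE thresholds).
.dosageCorr <- function(rho, p) {
  if (abs(rho) < 1e-12) return(0)
  t0 <- qnorm((1 - p)^2); t2 <- qnorm(1 - p^2)
  thr <- c(t0, t2)
  cv <- 0
  for (a in thr) for (b in thr)
    cv <- cv + .biNormUpper(a, b, rho) -
      pnorm(a, lower.tail = FALSE) * pnorm(b, lower.tail = FALSE)
  cv / (2 * p * (1 - p))
}

#' Construct the generating truth for the synthetic cohort model
#'
#' Defaults encode the study conditions the pipeline is validated against:
#' smoking initiation as a liability-threshold binary trait (prevalence
#' 0.45), BMI continuous, T2D/CAD logistic with prevalences 0.20/0.15;
#' 60 causal SNPs per trait (disjoint blocks, normally distributed effects
#' averaging 0.4% of liability/phenotype variance each, so h2 ~ 0.24);
#' block LD of size 10 with adjacent dosage r2 = 0.3 decaying geometrically.
#' Path coefficients (per smoking-status unit / per BMI SD):
#' `SB = 0.8`, `BT = ln(2.5)`, `ST = 0`, `BC = 0.35`, `SC = 0.66` — chosen
#' to land the synthetic total/direct odds ratios near the motivating
#' study's reported values (see the methods vignette).
#'
#' @param M number of SNPs.
#' @param blockSize SNPs per LD block.
#' @param r2Adjacent dosage r2 between adjacent SNPs in a block.
#' @param nCausalSmk,nCausalBmi causal SNPs per trait.
#' @param h2Smk,h2Bmi variance explained by causal SNPs on the smoking
#'   liability / BMI scale.
#' @param theta named path coefficients (SB, BT, ST, BC, SC).
#' @param prevalence named trait prevalences (smoking, t2d, cad).
#' @param pleiotropy list(fraction, mean, sd): fraction of smoking causal
#'   SNPs given direct outcome effects (directional when mean != 0).
#' @param mafRange minor-allele-frequency range (uniform draw).
#' @param seed integer seed for the per-SNP parameters.
#' @return A [SimulationTruth-class].
#' @export
simulationTruth <- function(M = 2000, blockSize = 10, r2Adjacent = 0.3,
                            nCausalSmk = 60, nCausalBmi = 60,
                            h2Smk = 0.24, h2Bmi = 0.24,
                            theta = c(SB = 0.8, BT = log(2.5), ST = 0,
                                      BC = 0.35, SC = 0.66),
                            prevalence = c(smoking = 0.45, t2d = 0.20,
                                           cad = 0.15),
                            pleiotropy = list(fraction = 0, mean = 0,
                                              sd = 0),
                            mafRange = c(0.05, 0.5), seed = 42L) {
  stopifnot(M %% blockSize == 0)
  nBlocks <- M / blockSize
  stopifnot(nCausalSmk + nCausalBmi <= nBlocks)
  withSeed(seed, {
    maf <- runif(M, mafRange[1], mafRange[2])
    ## one causal SNP per block, disjoint blocks per trait
    blocks <- sample(nBlocks, nCausalSmk + nCausalBmi)
    posInBlock <- sample(blockSize, nCausalSmk + nCausalBmi, replace = TRUE)
    causal <- (blocks - 1) * blockSize + posInBlock
    cSmk <- causal[seq_len(nCausalSmk)]
    cBmi <- causal[nCausalSmk + seq_len(nCausalBmi)]

    drawGamma <- function(idx, h2) {
      g <- numeric(M)
      raw <- rnorm(length(idx))
      het <- 2 * maf[idx] * (1 - maf[idx])
      ## scale so the summed variance contribution is exactly h2
      g[idx] <- raw / sqrt(sum(raw^2 * het) / h2)
      g
    }
    gammaSmk <- drawGamma(cSmk, h2Smk)
    gammaBmi <- drawGamma(cBmi, h2Bmi)

    bases <- c("A", "C", "G", "T")
    ea <- sample(bases, M, replace = TRUE)
    oa <- vapply(ea, function(a) sample(setdiff(bases, a), 1), "")

    ## calibrate the latent correlation so the *dosage* r2 between adjacent
    ## SNPs hits r2Adjacent at the average maf; record what the copula then
    ## implies at larger lags (approximately geometric decay)
    pbar <- mean(maf)
    rho <- if (r2Adjacent <= 0) 0 else
      uniroot(function(r) .dosageCorr(r, pbar) - sqrt(r2Adjacent),
              c(1e-6, 0.9999), tol = 1e-7)$root
    lagR2 <- vapply(seq_len(blockSize - 1),
                    function(d) .dosageCorr(rho^d, pbar)^2, 0)

    new("SimulationTruth", M = as.integer(M),
        blockSize = as.integer(blockSize),
        rho = rho, lagR2 = lagR2, maf = maf,
        gammaSmk = gammaSmk, gammaBmi = gammaBmi,
        theta = theta, prevalence = prevalence, pleiotropy = pleiotropy,
        positions = as.integer(seq_len(M) * 5000L),
        chrom = rep("1", M),
        alleles = data.frame(effect_allele = unname(ea),
                             other_allele = unname(oa),
                             stringsAsFactors = FALSE),
        seed = as.integer(seed))
  })
}

## Latent AR(1) Gaussians per block, thresholded to Hardy-Weinberg genotype
## dosages via a Gaussian copula. One shared Cholesky per block keeps this a
## single large matrix product.
.simDosages <- function(truth, n) {
  M <- truth@M; bs <- truth@blockSize
  nBlocks <- M / bs
  R <- truth@rho^abs(outer(seq_len(bs), seq_len(bs), "-"))
  L <- chol(R)               # R = t(L) %*% L
  ## SNP-major layout: columns of E are (block, individual) pairs with block
  ## fastest, so flattening the first two array dims restores genome order.
  E <- matrix(rnorm(n * M), bs, nBlocks * n)
  Zm <- matrix(crossprod(L, E), M, n)
  p <- truth@maf
  t0 <- qnorm((1 - p)^2)   # below: zero copies
  t2 <- qnorm(1 - p^2)     # above: two copies
  G <- t((Zm > t0) + (Zm > t2))   # thresholds recycle down SNP-major cols
  storage.mode(G) <- "double"
  colnames(G) <- paste0("rs", seq_len(M))
  G
}

.solveIntercept <- function(eta, prev) {
  f <- function(a) mean(plogis(a + eta)) - prev
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0)
    stop("unreachable prevalence ", prev, " given the linear predictor")
  uniroot(f, c(lo, hi), tol = 1e-8)$root
}

#' Simulate an individual-level cohort from a SimulationTruth
#'
#' Dosages follow the truth's block LD; smoking is a thresholded liability
#' `G gamma_smk + N(0, 1 - h2)`; BMI is `theta_SB smoking + G gamma_bmi +
#' noise` (reported both standardized and on a kg/m2 scale with mean 28,
#' SD 4.7); T2D and CAD are Bernoulli with logistic linear predictors
#' `alpha + theta_B* bmi_std + theta_S* smoking + pleiotropy + nuisance`,
#' with alpha solved so the target prevalence is met. Age, sex and five PCs
#' are simulated independently with small nuisance effects on all traits.
#'
#' @param truth a [SimulationTruth-class].
#' @param n cohort size (>= 100).
#' @param seed integer seed.
#' @return A [Cohort-class].
#' @export
simulateCohort <- function(truth, n, seed = 1L) {
  stopifnot(is(truth, "SimulationTruth"), n >= 100)
  withSeed(seed, {
    G <- .simDosages(truth, n)
    age <- rnorm(n, 60, 10)
    sex <- rbinom(n, 1, 0.5)
    pcs <- matrix(rnorm(n * 5, 0, 1), n, 5,
                  dimnames = list(NULL, paste0("pc", 1:5)))
    ageStd <- (age - 60) / 10

    h2 <- sum(truth@gammaSmk^2 * 2 * truth@maf * (1 - truth@maf))
    liab <- drop(G %*% truth@gammaSmk) + 0.05 * ageStd + 0.05 * pcs[, 1] +
      rnorm(n, 0, sqrt(max(0.05, 1 - h2 - 0.005)))
    smoking <- as.numeric(liab > quantile(liab,
                                          1 - truth@prevalence[["smoking"]]))

    th <- truth@theta
    bmiGen <- drop(G %*% truth@gammaBmi)
    h2b <- sum(truth@gammaBmi^2 * 2 * truth@maf * (1 - truth@maf))
    bmiRaw <- th[["SB"]] * smoking + bmiGen + 0.1 * ageStd +
      0.05 * pcs[, 2] + rnorm(n, 0, sqrt(max(0.05, 1 - h2b - 0.0125)))
    bmiStd <- (bmiRaw - mean(bmiRaw)) / sd(bmiRaw)
    bmi <- 28 + 4.7 * bmiStd

    ## optional directional pleiotropy: direct SNP effects on the outcomes
    pleio <- numeric(n)
    pl <- truth@pleiotropy
    if (pl$fraction > 0) {
      idx <- which(truth@gammaSmk != 0)
      idx <- idx[seq_len(ceiling(pl$fraction * length(idx)))]
      alpha <- rnorm(length(idx), pl$mean, pl$sd)
      pleio <- drop(G[, idx, drop = FALSE] %*% alpha)
    }

    mkBinary <- function(etaCore, prev) {
      eta <- etaCore + 0.2 * ageStd + 0.1 * sex + 0.05 * pcs[, 3]
      a <- .solveIntercept(eta, prev)
      rbinom(n, 1, plogis(a + eta))
    }
    t2d <- mkBinary(th[["BT"]] * bmiStd + th[["ST"]] * smoking + pleio,
                    truth@prevalence[["t2d"]])
    cad <- mkBinary(th[["BC"]] * bmiStd + th[["SC"]] * smoking + pleio,
                    truth@prevalence[["cad"]])

    snps <- data.frame(snp_id = colnames(G), chrom = truth@chrom,
                       pos = truth@positions,
                       effect_allele = truth@alleles$effect_allele,
                       other_allele = truth@alleles$other_allele,
                       maf = truth@maf, stringsAsFactors = FALSE)
    new("Cohort", dosages = G, snps = snps,
        phenotypes = data.frame(smoking_ever = smoking, bmi = bmi,
                                bmi_std = bmiStd, t2d = t2d, cad = cad),
        covariates = data.frame(age = age, sex = sex, pcs))
  })
}

#' Covariate-adjusted GWAS scan of one trait
#'
#' Linear regression for continuous traits; for binary traits a one-step
#' score/Wald approximation from the covariate-only null logistic model
#' (weighted projection of each SNP on the covariates, then
#' `beta_j = g'(y - mu) / (g' W g)`), the standard fast approximation for
#' biobank-scale scans. Adjusted for age, sex and five PCs. Monomorphic
#' SNPs are dropped with a warning.
#'
#' @param cohort a [Cohort-class].
#' @param trait one of "smoking_ever", "bmi_std", "bmi", "t2d", "cad" (or
#'   any phenotype column).
#' @param traitType override the binary/continuous guess from the values.
#' @return A [SummaryStats-class].
#' @export
gwasScan <- function(cohort, trait, traitType = NULL) {
  stopifnot(is(cohort, "Cohort"))
  if (!trait %in% names(cohort@phenotypes))
    stop("unknown trait: ", trait)
  y <- cohort@phenotypes[[trait]]
  if (is.null(traitType))
    traitType <- if (all(y %in% c(0, 1))) "binary" else "continuous"
  G <- cohort@dosages
  n <- nrow(G)
  keep <- which(.colSds(G) > 0)
  if (length(keep) < ncol(G))
    warning(ncol(G) - length(keep), " monomorphic SNP(s) dropped")
  G <- G[, keep, drop = FALSE]
  C <- cbind(1, as.matrix(cohort@covariates[, .covarNames]))

  if (traitType == "binary") {
    null <- glm.fit(C, y, family = binomial())
    mu <- null$fitted.values
    w <- mu * (1 - mu)
    CtWC <- crossprod(C, C * w)
    T1 <- crossprod(C, G * w)                       # q x M
    den <- colSums(G * G * w) - colSums(T1 * solve(CtWC, T1))
    num <- drop(crossprod(G, y - mu))
    beta <- num / den
    se <- 1 / sqrt(den)
  } else {
    CtC <- crossprod(C)
    T1 <- crossprod(C, G)
    den <- colSums(G * G) - colSums(T1 * solve(CtC, T1))
    yr <- y - drop(C %*% solve(CtC, crossprod(C, y)))
    num <- drop(crossprod(G, yr))
    beta <- num / den
    rss <- sum(yr^2) - beta^2 * den
    sigma2 <- rss / (n - ncol(C) - 1)
    se <- sqrt(sigma2 / den)
  }
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  d <- data.frame(snp_id = colnames(G),
                  chrom = cohort@snps$chrom[keep],
                  pos = cohort@snps$pos[keep],
                  effect_allele = cohort@snps$effect_allele[keep],
                  other_allele = cohort@snps$other_allele[keep],
                  eaf = colMeans(G) / 2, beta = beta, se = se,
                  pvalue = pmax(p, .Machine$double.xmin), n = n,
                  stringsAsFactors = FALSE)
  SummaryStats(d, traitName = trait, traitType = traitType)
}

.colSds <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sqrt((colSums(x^2) - n * mu^2) / (n - 1))
}

#' LDReference implied by the truth's block structure
#' @param truth a [SimulationTruth-class].
#' @param minR2 pairs below this r2 are omitted (default 0.005).
#' @return An [LDReference-class].
#' @export
truthLDReference <- function(truth, minR2 = 0.005) {
  bs <- truth@blockSize
  nBlocks <- truth@M / bs
  ij <- which(upper.tri(matrix(0, bs, bs)), arr.ind = TRUE)
  r2 <- truth@lagR2[abs(ij[, 1] - ij[, 2])]
  keep <- r2 >= minR2
  ij <- ij[keep, , drop = FALSE]; r2 <- r2[keep]
  offs <- rep((seq_len(nBlocks) - 1) * bs, each = nrow(ij))
  pairs <- data.frame(
    snp_a = paste0("rs", offs + ij[, 1]),
    snp_b = paste0("rs", offs + ij[, 2]),
    r2 = rep(r2, nBlocks), stringsAsFactors = FALSE)
  LDReference(pairs, windowBp = 250000)
}

#' Two-sample GWAS summary statistics from non-overlapping cohorts
#'
#' Simulates two independent cohorts from one truth; exposure GWAS
#' (smoking, BMI) come from cohort A and outcome GWAS (T2D, CAD) from
#' cohort B, emulating non-overlapping two-sample MR. Identical seeds are
#' permitted deliberately (sample-overlap bias demonstrations) but warned
#' about.
#'
#' @param truth a [SimulationTruth-class].
#' @param nExposure,nOutcome cohort sizes.
#' @param seedExposure,seedOutcome cohort seeds.
#' @param exposureTraits,outcomeTraits phenotype columns to scan.
#' @return list(exposure = named list of SummaryStats, outcome = named list
#'   of SummaryStats, ld = LDReference, ldscores = LDScoreTable).
#' @export
makeTwoSample <- function(truth, nExposure = 20000, nOutcome = 20000,
                          seedExposure = 1L, seedOutcome = 2L,
                          exposureTraits = c("smoking_ever", "bmi_std"),
                          outcomeTraits = c("t2d", "cad")) {
  if (seedExposure == seedOutcome)
    warning("identical seeds: the two samples overlap completely ",
            "(deliberate overlap-bias scenario)")
  cohA <- simulateCohort(truth, nExposure, seed = seedExposure)
  expo <- lapply(exposureTraits, function(tr) gwasScan(cohA, tr))
  names(expo) <- exposureTraits
  rm(cohA); gc(FALSE)
  cohB <- simulateCohort(truth, nOutcome, seed = seedOutcome)
  outc <- lapply(outcomeTraits, function(tr) gwasScan(cohB, tr))
  names(outc) <- outcomeTraits
  rm(cohB); gc(FALSE)
  ld <- truthLDReference(truth)
  list(exposure = expo, outcome = outc, ld = ld,
       ldscores = computeLDScores(ld, paste0("rs", seq_len(truth@M))))
}

#' Summary-level two-sample MR simulator
#'
#' Draws instrument-level summary statistics directly: true exposure effects
#' `bx ~ N(bxMean, bxSd)` (random signs), outcome effects `by = ratio * bx +
#' alpha` with per-SNP pleiotropy `alpha ~ N(pleioMean, pleioSd)`, and
#' sampling noise on both. Cheap enough for large replicate calibrations
#' (Egger null calibration, Steiger direction sweeps).
#'
#' @param k instruments.
#' @param ratio true causal slope.
#' @param bxMean,bxSd distribution of true exposure effects.
#' @param seX,seY sampling standard errors.
#' @param pleioMean,pleioSd directional/balanced pleiotropy; the direct
#'   outcome effect is attached to the exposure-increasing allele (the
#'   coding under which the MR-Egger intercept estimates its mean).
#' @param nExp,nOut sample sizes recorded in the tables.
#' @param eaf effect-allele frequency recorded in the tables.
#' @param seed integer seed.
#' @return A [HarmonizedSet-class] ready for the estimators.
#' @export
simulateSummaryMR <- function(k = 100, ratio = 0.2, bxMean = 0.08,
                              bxSd = 0.02, seX = 0.01, seY = 0.015,
                              pleioMean = 0, pleioSd = 0,
                              nExp = 1e5, nOut = 1e5, eaf = 0.3,
                              seed = 1L) {
  withSeed(seed, {
    bx <- (bxMean + rnorm(k, 0, bxSd)) * sample(c(-1, 1), k, replace = TRUE)
    alpha <- if (pleioMean != 0 || pleioSd > 0)
      rnorm(k, pleioMean, pleioSd) else numeric(k)
    bxHat <- rnorm(k, bx, seX)
    byHat <- rnorm(k, ratio * bx + sign(bx) * alpha, seY)
    ids <- paste0("rs", seq_len(k))
    snps <- data.frame(snp_id = ids, chrom = "1",
                       pos = seq_len(k) * 1000000L,
                       effect_allele = "A", other_allele = "G",
                       stringsAsFactors = FALSE)
    new("HarmonizedSet", snps = snps,
        exposureBeta = matrix(bxHat, k, 1),
        exposureSE = matrix(rep(seX, k), k, 1),
        exposureEAF = matrix(rep(eaf, k), k, 1),
        outcomeBeta = byHat, outcomeSE = rep(seY, k),
        outcomeEAF = rep(eaf, k),
        exposureNames = "exposure", exposureTypes = "continuous",
        outcomeName = "outcome", outcomeType = "continuous",
        exposureN = nExp, outcomeN = nOut,
        action = rep("kept", k),
        audit = data.frame(snp_id = ids, action = "kept",
                           stringsAsFactors = FALSE))
  })
}

#' Correlated z-scores under the LD score regression model
#'
#' Draws infinitesimal true effects for two traits with genetic correlation
#' `rg` and heritabilities `h2`, then per-block z-scores `z = sqrt(n) R beta
#' + chol(R) e` under the truth's block LD. Used for genetic-correlation
#' recovery experiments without individual-level simulation.
#'
#' @param truth a [SimulationTruth-class] (block structure and M reused).
#' @param n1,n2 sample sizes.
#' @param h2_1,h2_2 heritabilities.
#' @param rg genetic correlation of per-SNP effects.
#' @param seed integer seed.
#' @return list(z1, z2) aligned to `paste0("rs", 1:M)`.
#' @export
simulateZscores <- function(truth, n1 = 20000, n2 = 20000, h2_1 = 0.3,
                            h2_2 = 0.3, rg = 0.25, seed = 1L) {
  withSeed(seed, {
    M <- truth@M; bs <- truth@blockSize
    nBlocks <- M / bs
    ## z-scores track the dosage-scale correlation, not the latent one
    lag <- abs(outer(seq_len(bs), seq_len(bs), "-"))
    R <- matrix(sqrt(c(1, truth@lagR2))[lag + 1], bs, bs)
    L <- chol(R)
    s1 <- sqrt(h2_1 / M); s2 <- sqrt(h2_2 / M)
    b1 <- rnorm(M, 0, s1)
    b2 <- if (s1 > 0 && rg != 0)
      rg * (s2 / s1) * b1 + rnorm(M, 0, s2 * sqrt(max(0, 1 - rg^2)))
    else rnorm(M, 0, s2)
    B1 <- matrix(b1, bs, nBlocks); B2 <- matrix(b2, bs, nBlocks)
    E1 <- matrix(rnorm(M), bs, nBlocks); E2 <- matrix(rnorm(M), bs, nBlocks)
    z1 <- sqrt(n1) * (R %*% B1) + t(L) %*% E1
    z2 <- sqrt(n2) * (R %*% B2) + t(L) %*% E2
    list(z1 = as.vector(z1), z2 = as.vector(z2))
  })
}
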