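#' @import methods
#' @importFrom stats approx coef glm glm.fit lm logLik median pchisq pnorm
#'   pt qnorm qt rbinom rnorm runif sd setNames uniroot binomial plogis
#'   quantile residuals fitted anova cor
#' @importFrom utils head modifyList
NULL

VALID_BASES <- c("A", "C", "G", "T")

## ---------------------------------------------------------------------------
## SummaryStats: one trait's per-SNP GWAS association table
## ---------------------------------------------------------------------------

#' SummaryStats: GWAS summary statistics for one trait
#'
#' Container for a validated per-SNP association table. `beta` is the
#' per-effect-allele association: a log odds ratio for binary traits, an
#' effect in phenotype standard deviation units for continuous traits.
#'
#' @slot data data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`.
#' @slot traitName character scalar.
#' @slot traitType `"binary"` or `"continuous"`.
#' @export
setClass("SummaryStats",
  representation(data = "data.frame", traitName = "character",
                 traitType = "character"))

SUMSTATS_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pvalue", "n")

setValidity("SummaryStats", function(object) {
  d <- object@data
  msgs <- character()
  if (!all(SUMSTATS_COLS %in% names(d)))
    return(paste("missing columns:",
                 paste(setdiff(SUMSTATS_COLS, names(d)), collapse = ", ")))
  if (nrow(d) == 0) msgs <- c(msgs, "empty summary statistics table")
  if (anyDuplicated(d$snp_id)) msgs <- c(msgs, "duplicate snp_id values")
  if (!all(d$effect_allele %in% VALID_BASES) ||
      !all(d$other_allele %in% VALID_BASES))
    msgs <- c(msgs, "alleles must be single bases A/C/G/T")
  if (any(d$effect_allele == d$other_allele))
    msgs <- c(msgs, "effect_allele equals other_allele for some rows")
  if (any(!is.finite(d$se)) || any(d$se <= 0))
    msgs <- c(msgs, "se must be finite and > 0")
  if (any(d$eaf <= 0) || any(d$eaf >= 1))
    msgs <- c(msgs, "eaf must lie strictly in (0,1)")
  if (any(d$pvalue <= 0) || any(d$pvalue > 1))
    msgs <- c(msgs, "pvalue must lie in (0,1]")
  if (any(d$n <= 0)) msgs <- c(msgs, "n must be positive")
  if (!object@traitType %in% c("binary", "continuous"))
    msgs <- c(msgs, "traitType must be 'binary' or 'continuous'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SummaryStats object from a data.frame
#'
#' Rows violating the table invariants (non-ACGT or identical alleles,
#' non-positive `se`, `eaf` outside (0,1), p outside (0,1], duplicated
#' `snp_id`) are dropped with a message giving the count per reason.
#'
#' @param data data.frame carrying the columns listed in
#'   [SummaryStats-class].
#' @param traitName trait label.
#' @param traitType `"binary"` or `"continuous"`.
#' @return A validated `SummaryStats` object.
#' @export
SummaryStats <- function(data, traitName = "trait",
                         traitType = c("binary", "continuous")) {
  traitType <- match.arg(traitType)
  missing <- setdiff(SUMSTATS_COLS, names(data))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  d <- as.data.frame(data)[, SUMSTATS_COLS]
  d$snp_id <- as.character(d$snp_id)
  d$chrom <- sub("^chr", "", as.character(d$chrom))
  d$pos <- as.integer(d$pos)
  d$effect_allele <- toupper(as.character(d$effect_allele))
  d$other_allele <- toupper(as.character(d$other_allele))
  for (cc in c("eaf", "beta", "se", "pvalue", "n"))
    d[[cc]] <- as.numeric(d[[cc]])

  drop_count <- function(bad, why) {
    nb <- sum(bad, na.rm = TRUE)
    if (nb > 0) message(nb, " row(s) dropped: ", why)
    bad & !is.na(bad)
  }
  bad <- drop_count(!(d$effect_allele %in% VALID_BASES) |
                    !(d$other_allele %in% VALID_BASES) |
                    d$effect_allele == d$other_allele,
                    "invalid alleles (non-SNP or monoallelic)")
  bad <- bad | drop_count(!is.finite(d$se) | d$se <= 0, "se not positive")
  bad <- bad | drop_count(!is.finite(d$eaf) | d$eaf <= 0 | d$eaf >= 1,
                          "eaf outside (0,1)")
  bad <- bad | drop_count(!is.finite(d$beta), "non-finite beta")
  bad <- bad | drop_count(!is.finite(d$pvalue) | d$pvalue <= 0 | d$pvalue > 1,
                          "pvalue outside (0,1]")
  bad <- bad | drop_count(!is.finite(d$n) | d$n <= 0, "n not positive")
  bad <- bad | is.na(bad)
  d <- d[!bad, , drop = FALSE]
  dup <- duplicated(d$snp_id)
  if (any(dup)) {
    message(sum(dup), " row(s) dropped: duplicate snp_id")
    d <- d[!dup, , drop = FALSE]
  }
  if (nrow(d) == 0) stop("no rows left after validation")
  rownames(d) <- NULL
  new("SummaryStats", data = d, traitName = traitName, traitType = traitType)
}

## ---------------------------------------------------------------------------
## HarmonizedSet: exposure(s) and outcome aligned to a common effect allele
## ---------------------------------------------------------------------------

#' HarmonizedSet: allele-aligned exposure/outcome effect table
#'
#' The instrument actually fed to the estimators. Exposure effects are stored
#' as k x p matrices (p = number of exposures) so univariable and
#' multivariable MR share one container. Every retained row expresses all
#' effects for the same effect allele.
#'
#' @slot snps data.frame (snp_id, chrom, pos, effect_allele, other_allele).
#' @slot exposureBeta,exposureSE,exposureEAF numeric matrices, one column per
#'   exposure.
#' @slot outcomeBeta,outcomeSE,outcomeEAF numeric vectors.
#' @slot exposureNames,exposureTypes,outcomeName,outcomeType character.
#' @slot exposureN,outcomeN numeric sample sizes (per exposure / outcome).
#' @slot action harmonization action for retained rows ("kept"/"flipped").
#' @slot audit data.frame (snp_id, action) over the full snp_id intersection,
#'   including dropped rows.
#' @export
setClass("HarmonizedSet",
  representation(snps = "data.frame",
                 exposureBeta = "matrix", exposureSE = "matrix",
                 exposureEAF = "matrix",
                 outcomeBeta = "numeric", outcomeSE = "numeric",
                 outcomeEAF = "numeric",
                 exposureNames = "character", exposureTypes = "character",
                 outcomeName = "character", outcomeType = "character",
                 exposureN = "numeric", outcomeN = "numeric",
                 action = "character", audit = "data.frame"))

setValidity("HarmonizedSet", function(object) {
  k <- nrow(object@snps)
  p <- length(object@exposureNames)
  msgs <- character()
  if (nrow(object@exposureBeta) != k || ncol(object@exposureBeta) != p)
    msgs <- c(msgs, "exposureBeta dimensions disagree with snps/exposureNames")
  if (length(object@outcomeBeta) != k)
    msgs <- c(msgs, "outcomeBeta length disagrees with snps")
  if (any(object@outcomeSE <= 0) || any(object@exposureSE <= 0))
    msgs <- c(msgs, "standard errors must be positive")
  if (!all(object@action %in% c("kept", "flipped")))
    msgs <- c(msgs, "retained actions must be kept/flipped")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## LD reference and instruments
## ---------------------------------------------------------------------------

#' LDReference: sparse pairwise r-squared map
#'
#' Symmetric sparse map of linkage disequilibrium between SNP pairs, defined
#' within a stated window. `r2(a, a) = 1` is implicit and unlisted pairs are
#' taken as r2 = 0.
#'
#' @slot pairs data.frame (snp_a, snp_b, r2).
#' @slot windowBp window within which the map is defined, in base pairs.
#' @export
setClass("LDReference",
  representation(pairs = "data.frame", windowBp = "numeric"))

setValidity("LDReference", function(object) {
  p <- object@pairs
  if (!all(c("snp_a", "snp_b", "r2") %in% names(p)))
    return("pairs needs columns snp_a, snp_b, r2")
  if (nrow(p) && (any(p$r2 < 0) || any(p$r2 > 1)))
    return("r2 values must lie in [0,1]")
  TRUE
})

#' Construct an LDReference
#'
#' @param pairs data.frame with columns `snp_a`, `snp_b`, `r2`. Stored
#'   symmetrically; self-pairs are dropped.
#' @param windowBp window (bp) within which the reference is defined.
#' @return An `LDReference`.
#' @export
LDReference <- function(pairs, windowBp = 250000) {
  pairs <- as.data.frame(pairs)
  names(pairs)[1:3] <- c("snp_a", "snp_b", "r2")
  pairs$snp_a <- as.character(pairs$snp_a)
  pairs$snp_b <- as.character(pairs$snp_b)
  pairs <- pairs[pairs$snp_a != pairs$snp_b, , drop = FALSE]
  rownames(pairs) <- NULL
  new("LDReference", pairs = pairs, windowBp = as.numeric(windowBp))
}

#' Read an LD reference from a 3-column TSV (snp_a, snp_b, r2)
#' @param path file path.
#' @param windowBp window (bp) the file was computed within.
#' @return An `LDReference`.
#' @export
readLDReference <- function(path, windowBp = 250000) {
  LDReference(.freadAny(path), windowBp = windowBp)
}

#' InstrumentSet: SNPs retained by clumping, with strength diagnostics
#'
#' @slot snpIds ordered (by ascending p) retained SNP ids.
#' @slot r2PerSnp per-SNP variance explained in the exposure.
#' @slot r2Total summed variance explained.
#' @slot fStat F-statistic \eqn{[(n-k-1)/k] r^2/(1-r^2)}.
#' @slot nExposure exposure GWAS sample size used for F.
#' @slot k number of retained SNPs.
#' @slot assignments data.frame (snp_id, index_snp) attributing every removed
#'   candidate to the retained index SNP that absorbed it.
#' @export
setClass("InstrumentSet",
  representation(snpIds = "character", r2PerSnp = "numeric",
                 r2Total = "numeric", fStat = "numeric",
                 nExposure = "numeric", k = "integer",
                 assignments = "data.frame"))

setValidity("InstrumentSet", function(object) {
  if (object@k < 1L) return("k must be >= 1")
  if (length(object@snpIds) != object@k) return("snpIds length != k")
  TRUE
})

## ---------------------------------------------------------------------------
## Estimator results
## ---------------------------------------------------------------------------

#' MREstimate: a causal effect estimate on the log scale
#'
#' `beta` is on the log scale per unit of the exposure's association scale
#' (per log-odds unit for binary exposures, per SD for continuous ones).
#' `or`/`orCiLow`/`orCiHigh` hold the odds-ratio form: per 2-fold increase in
#' exposure odds for binary exposures, per SD for continuous exposures.
#'
#' @slot method one of wald, ivw_fixed, ivw_re, weighted_median, egger_slope.
#' @slot beta,se,ciLow,ciHigh,pvalue estimate and inference.
#' @slot nSnps number of SNPs used.
#' @slot or,orCiLow,orCiHigh odds-ratio-scale form (NA until converted).
#' @slot exposureType "binary" or "continuous" (drives the OR conversion).
#' @export
setClass("MREstimate",
  representation(method = "character", beta = "numeric", se = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", pvalue = "numeric",
                 nSnps = "integer", or = "numeric", orCiLow = "numeric",
                 orCiHigh = "numeric", exposureType = "character"))

setValidity("MREstimate", function(object) {
  if (is.finite(object@ciLow) && is.finite(object@ciHigh) &&
      !(object@ciLow <= object@beta && object@beta <= object@ciHigh))
    return("confidence interval does not bracket the estimate")
  TRUE
})

.mrEstimate <- function(method, beta, se, nSnps, pvalue = NULL, df = NULL,
                        exposureType = "binary", level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  if (is.null(pvalue)) {
    stat <- beta / se
    pvalue <- if (is.null(df)) 2 * pnorm(-abs(stat)) else
      2 * pt(-abs(stat), df = df)
  }
  crit <- if (is.null(df)) z else qt(1 - (1 - level) / 2, df = df)
  est <- new("MREstimate", method = method, beta = beta, se = se,
             ciLow = beta - crit * se, ciHigh = beta + crit * se,
             pvalue = max(min(pvalue, 1), .Machine$double.xmin),
             nSnps = as.integer(nSnps),
             or = NA_real_, orCiLow = NA_real_, orCiHigh = NA_real_,
             exposureType = exposureType)
  toOddsRatio(est)
}

#' EggerResult: MR-Egger slope and intercept
#' @slot slope an [MREstimate-class] for the causal slope.
#' @slot intercept,interceptSE,interceptPvalue intercept inference; a nonzero
#'   intercept indicates directional horizontal pleiotropy.
#' @export
setClass("EggerResult",
  representation(slope = "MREstimate", intercept = "numeric",
                 interceptSE = "numeric", interceptPvalue = "numeric"))

#' QResult: Cochran's Q heterogeneity test
#' @slot Q statistic; @slot df degrees of freedom (k-1); @slot pvalue
#'   chi-square upper tail.
#' @export
setClass("QResult",
  representation(Q = "numeric", df = "integer", pvalue = "numeric"))

setValidity("QResult", function(object)
  if (object@Q < 0) "Q must be >= 0" else TRUE)

#' MVMRResult: multivariable MR direct effects
#' @slot exposures exposure names (design-matrix columns).
#' @slot beta,se,pvalue named per-exposure direct effects (log scale).
#' @slot or,orCiLow,orCiHigh per-exposure odds-ratio forms.
#' @slot k number of SNPs; @slot conditionalF Sanderson-style conditional
#'   instrument-strength diagnostic per exposure.
#' @slot exposureTypes per-exposure "binary"/"continuous".
#' @export
setClass("MVMRResult",
  representation(exposures = "character", beta = "numeric", se = "numeric",
                 pvalue = "numeric", or = "numeric", orCiLow = "numeric",
                 orCiHigh = "numeric", k = "integer",
                 conditionalF = "numeric", exposureTypes = "character"))

setValidity("MVMRResult", function(object) {
  p <- length(object@exposures)
  if (length(object@beta) != p) return("beta length != number of exposures")
  if (object@k <= p) return("k must exceed the number of exposures")
  TRUE
})

#' MediationResult: paired total and direct effects
#'
#' Total effect comes from univariable MR, direct effect from multivariable
#' MR conditional on the mediator. For binary outcomes the indirect effect is
#' deliberately not populated: odds ratios are noncollapsible, so
#' difference/product decompositions are not valid.
#'
#' @slot exposure exposure name.
#' @slot total an [MREstimate-class].
#' @slot directBeta,directSE,directPvalue,directCiLow,directCiHigh direct
#'   effect (log scale).
#' @slot totalPercent,totalPercentCi,directPercent,directPercentCi percent
#'   increase per 2-fold exposure odds, `100*(exp(ln2*beta)-1)`.
#' @slot indirectAbsentReason why no indirect effect is reported.
#' @export
setClass("MediationResult",
  representation(exposure = "character", total = "MREstimate",
                 directBeta = "numeric", directSE = "numeric",
                 directPvalue = "numeric", directCiLow = "numeric",
                 directCiHigh = "numeric",
                 totalPercent = "numeric", totalPercentCi = "numeric",
                 directPercent = "numeric", directPercentCi = "numeric",
                 indirectAbsentReason = "character"))

#' SteigerResult: causal direction inference
#' @slot r2Exposure,r2Outcome instrument variance explained per trait.
#' @slot correctDirection TRUE when r2Exposure > r2Outcome (NA when tied).
#' @slot z,pvalue Steiger's z comparing the two correlations.
#' @slot sensitivityRatio ratio of reliability-grid volume supporting the
#'   called direction to the volume opposing it (+Inf when unopposed).
#' @export
setClass("SteigerResult",
  representation(r2Exposure = "numeric", r2Outcome = "numeric",
                 correctDirection = "logical", z = "numeric",
                 pvalue = "numeric", sensitivityRatio = "numeric"))

setValidity("SteigerResult", function(object) {
  ok <- object@r2Exposure >= 0 && object@r2Exposure < 1 &&
    object@r2Outcome >= 0 && object@r2Outcome < 1
  if (!ok) return("r2 values must lie in [0,1)")
  TRUE
})

## ---------------------------------------------------------------------------
## LDSC
## ---------------------------------------------------------------------------

#' LDScoreTable: per-SNP LD scores
#' @slot scores named numeric, `l_j = 1 + sum of r2 with windowed neighbours`.
#' @slot M number of SNPs.
#' @export
setClass("LDScoreTable",
  representation(scores = "numeric", M = "integer"))

setValidity("LDScoreTable", function(object) {
  if (any(object@scores < 1 - 1e-9)) return("LD scores must be >= 1")
  if (any(!is.finite(object@scores))) return("LD scores must be finite")
  TRUE
})

#' RgResult: bivariate LD score regression genetic correlation
#' @slot h2Trait1,h2Trait2 heritability estimates.
#' @slot rg genetic correlation, clipped to \[-1, 1\].
#' @slot seRg delete-one block jackknife SE.
#' @slot z,pvalue normal-theory test of rg = 0.
#' @slot intercepts named: int1, int2 (univariate), gcovInt (cross-product).
#' @slot nBlocks jackknife blocks used.
#' @export
setClass("RgResult",
  representation(h2Trait1 = "numeric", h2Trait2 = "numeric", rg = "numeric",
                 seRg = "numeric", z = "numeric", pvalue = "numeric",
                 intercepts = "numeric", nBlocks = "integer"))

## ---------------------------------------------------------------------------
## Individual-level data
## ---------------------------------------------------------------------------

#' Cohort: individual-level dosages, phenotypes and covariates
#' @slot dosages individuals x SNPs matrix, values in \[0,2\] counting the
#'   effect allele; colnames are snp_ids.
#' @slot snps data.frame (snp_id, chrom, pos, effect_allele, other_allele,
#'   maf).
#' @slot phenotypes data.frame: smoking_ever {0,1}, bmi (kg/m2), bmi_std,
#'   t2d {0,1}, cad {0,1} (optional lifetime_smoking).
#' @slot covariates data.frame: age, sex {0,1}, pc1..pc5.
#' @export
setClass("Cohort",
  representation(dosages = "matrix", snps = "data.frame",
                 phenotypes = "data.frame", covariates = "data.frame"))

setValidity("Cohort", function(object) {
  n <- nrow(object@dosages)
  msgs <- character()
  if (nrow(object@phenotypes) != n || nrow(object@covariates) != n)
    msgs <- c(msgs, "phenotype/covariate rows must equal dosage rows")
  if (ncol(object@dosages) != nrow(object@snps))
    msgs <- c(msgs, "snps rows must equal dosage columns")
  if (anyNA(object@dosages)) msgs <- c(msgs, "missing dosages not allowed")
  if (length(msgs)) msgs else TRUE
})

#' TwoStageResult: two-stage predictor substitution estimates
#' @slot stage1Beta,stage1SE,stage1P effect of the PRS on the exposure.
#' @slot stage1F linear-model instrument F-statistic (weak-instrument guard).
#' @slot nagelkerkeR2 PRS pseudo-R2 on the exposure (binary stage 1).
#' @slot totalBeta,totalSE,totalP,totalOr,totalOrCi stage-2 effect of
#'   predicted exposure without the mediator channel (total effect).
#' @slot adjustedBeta,adjustedSE,adjustedP,adjustedOr,adjustedOrCi predicted
#'   exposure effect with predicted mediator in the model (direct effect).
#' @slot mediatorBeta,mediatorSE,mediatorP predicted-mediator coefficient.
#' @slot outcome,outcomeType outcome name and type.
#' @export
setClass("TwoStageResult",
  representation(stage1Beta = "numeric", stage1SE = "numeric",
                 stage1P = "numeric", stage1F = "numeric",
                 nagelkerkeR2 = "numeric",
                 totalBeta = "numeric", totalSE = "numeric",
                 totalP = "numeric", totalOr = "numeric",
                 totalOrCi = "numeric",
                 adjustedBeta = "numeric", adjustedSE = "numeric",
                 adjustedP = "numeric", adjustedOr = "numeric",
                 adjustedOrCi = "numeric",
                 mediatorBeta = "numeric", mediatorSE = "numeric",
                 mediatorP = "numeric",
                 outcome = "character", outcomeType = "character"))

## ---------------------------------------------------------------------------
## Simulation truth
## ---------------------------------------------------------------------------

#' SimulationTruth: generating parameters for the synthetic cohort model
#'
#' Encodes the structural model smoking -> BMI -> {T2D, CAD} with direct
#' smoking paths. Binary traits are generated on the logistic scale (so GWAS
#' log odds ratios are the natural effect scale); smoking initiation uses a
#' liability threshold so polygenic-score-on-liability scenarios exist.
#'
#' @slot M number of SNPs; @slot blockSize LD block size; @slot rho latent
#'   adjacent-SNP correlation (adjacent dosage r2 ~ rho^2, geometric decay).
#' @slot maf per-SNP minor allele frequencies.
#' @slot gammaSmk,gammaBmi per-SNP effects on smoking liability / BMI (SD).
#' @slot theta named path coefficients: SB (smoking->BMI, SD per status
#'   unit), BT (BMI->T2D log-odds per SD), ST (smoking->T2D direct), BC
#'   (BMI->CAD), SC (smoking->CAD direct).
#' @slot lagR2 dosage-scale r2 per within-block lag implied by the
#'   calibrated latent correlation (this is what the emitted LD reference
#'   reports).
#' @slot prevalence named: smoking, t2d, cad.
#' @slot pleiotropy list(fraction, mean, sd): fraction of instrument SNPs
#'   given direct outcome effects, with directional mean and spread.
#' @slot positions,chrom genomic coordinates; @slot alleles data.frame
#'   (effect_allele, other_allele); @slot seed integer seed the per-SNP
#'   parameters were drawn with.
#' @export
setClass("SimulationTruth",
  representation(M = "integer", blockSize = "integer", rho = "numeric",
                 lagR2 = "numeric",
                 maf = "numeric", gammaSmk = "numeric", gammaBmi = "numeric",
                 theta = "numeric", prevalence = "numeric",
                 pleiotropy = "list", positions = "integer",
                 chrom = "character", alleles = "data.frame",
                 seed = "integer"))

setValidity("SimulationTruth", function(object) {
  msgs <- character()
  if (any(object@prevalence <= 0) || any(object@prevalence >= 1))
    msgs <- c(msgs, "prevalences must lie in (0,1)")
  if (length(object@maf) != object@M)
    msgs <- c(msgs, "maf length must equal M")
  if (!all(c("SB", "BT", "ST", "BC", "SC") %in% names(object@theta)))
    msgs <- c(msgs, "theta needs entries SB, BT, ST, BC, SC")
  if (length(msgs)) msgs else TRUE
})
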