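## Generics and simple accessors / show methods.

#' SNP identifiers of an object
#' @param x a SummaryStats, HarmonizedSet, InstrumentSet or Cohort.
#' @return character vector of snp_ids.
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname snpIds
#' @export
setMethod("snpIds", "SummaryStats", function(x) x@data$snp_id)
#' @rdname snpIds
#' @export
setMethod("snpIds", "HarmonizedSet", function(x) x@snps$snp_id)
#' @rdname snpIds
#' @export
setMethod("snpIds", "InstrumentSet", function(x) x@snpIds)
#' @rdname snpIds
#' @export
setMethod("snpIds", "Cohort", function(x) x@snps$snp_id)

#' Number of SNPs in an object
#' @param x a container holding per-SNP rows.
#' @return integer count.
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))
#' @rdname nSnps
#' @export
setMethod("nSnps", "SummaryStats", function(x) nrow(x@data))
#' @rdname nSnps
#' @export
setMethod("nSnps", "HarmonizedSet", function(x) nrow(x@snps))
#' @rdname nSnps
#' @export
setMethod("nSnps", "InstrumentSet", function(x) length(x@snpIds))
#' @rdname nSnps
#' @export
setMethod("nSnps", "MREstimate", function(x) x@nSnps)

#' Trait name of a SummaryStats table
#' @param x a SummaryStats.
#' @return character scalar.
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))
#' @rdname traitName
#' @export
setMethod("traitName", "SummaryStats", function(x) x@traitName)

#' Trait type ("binary"/"continuous")
#' @param x a SummaryStats.
#' @return character scalar.
#' @export
setGeneric("traitType", function(x) standardGeneric("traitType"))
#' @rdname traitType
#' @export
setMethod("traitType", "SummaryStats", function(x) x@traitType)

#' Point estimate (log scale)
#' @param x an MREstimate.
#' @return numeric scalar.
#' @export
setGeneric("estBeta", function(x) standardGeneric("estBeta"))
#' @rdname estBeta
#' @export
setMethod("estBeta", "MREstimate", function(x) x@beta)

#' Standard error of the point estimate
#' @param x an MREstimate.
#' @return numeric scalar.
#' @export
setGeneric("estSE", function(x) standardGeneric("estSE"))
#' @rdname estSE
#' @export
setMethod("estSE", "MREstimate", function(x) x@se)

#' P-value of the point estimate
#' @param x an MREstimate.
#' @return numeric scalar.
#' @export
setGeneric("estPvalue", function(x) standardGeneric("estPvalue"))
#' @rdname estPvalue
#' @export
setMethod("estPvalue", "MREstimate", function(x) x@pvalue)

#' Confidence interval of the point estimate
#' @param x an MREstimate.
#' @return numeric length-2 vector (low, high) on the log scale.
#' @export
setGeneric("estCi", function(x) standardGeneric("estCi"))
#' @rdname estCi
#' @export
setMethod("estCi", "MREstimate", function(x) c(x@ciLow, x@ciHigh))

#' @describeIn SummaryStats-class coerce to data.frame
#' @param x a SummaryStats.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "SummaryStats", function(x, ...) x@data)

#' @describeIn HarmonizedSet-class coerce to a flat data.frame (one block of
#'   columns per exposure, suffixed with the exposure name)
#' @param x a HarmonizedSet.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "HarmonizedSet", function(x, ...) {
  d <- x@snps
  for (j in seq_along(x@exposureNames)) {
    nm <- x@exposureNames[j]
    d[[paste0("beta.", nm)]] <- x@exposureBeta[, j]
    d[[paste0("se.", nm)]] <- x@exposureSE[, j]
    d[[paste0("eaf.", nm)]] <- x@exposureEAF[, j]
  }
  d$beta.outcome <- x@outcomeBeta
  d$se.outcome <- x@outcomeSE
  d$eaf.outcome <- x@outcomeEAF
  d$action <- x@action
  d
})

#' @describeIn MREstimate-class one-row data.frame summary
#' @param x an MREstimate.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "MREstimate", function(x, ...)
  data.frame(method = x@method, nsnp = x@nSnps, b = x@beta, se = x@se,
             ci_low = x@ciLow, ci_high = x@ciHigh, p = x@pvalue,
             or = x@or, or_lci95 = x@orCiLow, or_uci95 = x@orCiHigh))

setMethod("show", "SummaryStats", function(object) {
  cat("SummaryStats: ", object@traitName, " (", object@traitType, "), ",
      nrow(object@data), " SNPs\n", sep = "")
  print(head(object@data, 4))
  if (nrow(object@data) > 4) cat("...\n")
})

setMethod("show", "HarmonizedSet", function(object) {
  cat("HarmonizedSet: ", paste(object@exposureNames, collapse = " + "),
      " -> ", object@outcomeName, "\n", sep = "")
  cat("  retained SNPs: ", nrow(object@snps), "\n", sep = "")
  tab <- table(object@audit$action)
  cat("  actions: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "InstrumentSet", function(object) {
  cat("InstrumentSet: k=", object@k,
      sprintf(", total R2=%.4g, F=%.1f (n=%g)\n", object@r2Total,
              object@fStat, object@nExposure), sep = "")
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MREstimate [%s] k=%d: b=%.4g (se %.3g), p=%.3g\n",
              object@method, object@nSnps, object@beta, object@se,
              object@pvalue))
  if (is.finite(object@or))
    cat(sprintf("  OR %s = %.3f (95%% CI %.3f-%.3f)\n",
                if (object@exposureType == "binary")
                  "per 2-fold exposure odds" else "per SD",
                object@or, object@orCiLow, object@orCiHigh))
})

setMethod("show", "EggerResult", function(object) {
  cat("MR-Egger\n  slope: ")
  show(object@slope)
  cat(sprintf("  intercept: %.4g (se %.3g), p=%.3g\n", object@intercept,
              object@interceptSE, object@interceptPvalue))
})

setMethod("show", "QResult", function(object)
  cat(sprintf("Cochran's Q = %.3f, df = %d, p = %.3g\n", object@Q,
              object@df, object@pvalue)))

setMethod("show", "MVMRResult", function(object) {
  cat("MVMRResult, k=", object@k, " SNPs\n", sep = "")
  print(data.frame(exposure = object@exposures, b = object@beta,
                   se = object@se, p = object@pvalue, or = object@or,
                   cond_F = object@conditionalF, row.names = NULL))
})

setMethod("show", "MediationResult", function(object) {
  cat("MediationResult for ", object@exposure, "\n  total:  ", sep = "")
  cat(sprintf("b=%.4g, %%change=%.1f%% (CI %.1f%% to %.1f%%)\n",
              object@total@beta, object@totalPercent,
              object@totalPercentCi[1], object@totalPercentCi[2]))
  cat(sprintf("  direct: b=%.4g, %%change=%.1f%% (CI %.1f%% to %.1f%%)\n",
              object@directBeta, object@directPercent,
              object@directPercentCi[1], object@directPercentCi[2]))
  cat("  indirect effect not reported:", object@indirectAbsentReason, "\n")
})

setMethod("show", "SteigerResult", function(object) {
  cat(sprintf("MR-Steiger: r2_exposure=%.4g, r2_outcome=%.4g\n",
              object@r2Exposure, object@r2Outcome))
  cat(sprintf("  correct direction: %s, z=%.2f, p=%.3g, sensitivity=%.3g\n",
              object@correctDirection, object@z, object@pvalue,
              object@sensitivityRatio))
})

setMethod("show", "RgResult", function(object) {
  cat(sprintf("LDSC rg = %.3f (se %.3f), p = %.3g\n", object@rg,
              object@seRg, object@pvalue))
  cat(sprintf("  h2: %.3f / %.3f; intercepts: %.3f / %.3f; gcov int %.3f\n",
              object@h2Trait1, object@h2Trait2, object@intercepts["int1"],
              object@intercepts["int2"], object@intercepts["gcovInt"]))
})

setMethod("show", "Cohort", function(object) {
  cat("Cohort: ", nrow(object@dosages), " individuals x ",
      ncol(object@dosages), " SNPs\n", sep = "")
  cat("  phenotypes:", paste(names(object@phenotypes), collapse = ", "), "\n")
})

setMethod("show", "TwoStageResult", function(object) {
  cat("TwoStageResult (outcome: ", object@outcome, ")\n", sep = "")
  cat(sprintf("  stage 1: b=%.4g (p=%.3g), F=%.1f, Nagelkerke R2=%.4g\n",
              object@stage1Beta, object@stage1P, object@stage1F,
              object@nagelkerkeR2))
  cat(sprintf("  total:    b=%.4g (se %.3g), p=%.3g, OR=%.3f\n",
              object@totalBeta, object@totalSE, object@totalP,
              object@totalOr))
  if (is.finite(object@adjustedBeta))
    cat(sprintf("  adjusted: b=%.4g (se %.3g), p=%.3g, OR=%.3f\n",
                object@adjustedBeta, object@adjustedSE, object@adjustedP,
                object@adjustedOr))
})

setMethod("show", "SimulationTruth", function(object) {
  cat("SimulationTruth: M=", object@M, ", block size ", object@blockSize,
      ", causal SNPs smoking/BMI = ", sum(object@gammaSmk != 0), "/",
      sum(object@gammaBmi != 0), "\n", sep = "")
  cat("  theta:", paste(names(object@theta), signif(object@theta, 3),
                        sep = "=", collapse = ", "), "\n")
})
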