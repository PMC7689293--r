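# Shared fixtures, all built in code.

withr_local_tempfile <- function() tempfile(fileext = ".tsv")

# A tiny deterministic summary-statistics data.frame.
toySumstatsDf <- function(k = 5, beta = NULL, se = NULL, eaf = NULL,
                          ea = NULL, oa = NULL, p = NULL, n = 50000) {
  data.frame(
    snp_id = paste0("rs", seq_len(k)),
    chrom = "1",
    pos = seq_len(k) * 100000L,
    effect_allele = if (is.null(ea)) rep_len(c("A", "C", "G", "T"), k) else ea,
    other_allele = if (is.null(oa)) rep_len(c("G", "T", "A", "C"), k) else oa,
    eaf = if (is.null(eaf)) seq(0.2, 0.4, length.out = k) else eaf,
    beta = if (is.null(beta)) seq(0.05, 0.15, length.out = k) else beta,
    se = if (is.null(se)) rep(0.01, k) else se,
    pvalue = if (is.null(p)) rep(1e-10, k) else p,
    n = n, stringsAsFactors = FALSE)
}

toySumstats <- function(..., traitName = "trait", traitType = "binary") {
  SummaryStats(toySumstatsDf(...), traitName = traitName,
               traitType = traitType)
}

# HarmonizedSet built directly from effect vectors (single exposure).
toyHarmonized <- function(bx, by, sx = rep(0.01, length(bx)),
                          sy = rep(0.02, length(bx)),
                          exposureType = "binary",
                          outcomeType = "binary",
                          nExp = 1e5, nOut = 1e5) {
  k <- length(bx)
  ids <- paste0("rs", seq_len(k))
  new("HarmonizedSet",
      snps = data.frame(snp_id = ids, chrom = "1", pos = seq_len(k) * 1e5L,
                        effect_allele = "A", other_allele = "G",
                        stringsAsFactors = FALSE),
      exposureBeta = matrix(bx, k, 1), exposureSE = matrix(sx, k, 1),
      exposureEAF = matrix(rep(0.3, k), k, 1),
      outcomeBeta = by, outcomeSE = sy, outcomeEAF = rep(0.3, k),
      exposureNames = "exposure", exposureTypes = exposureType,
      outcomeName = "outcome", outcomeType = outcomeType,
      exposureN = nExp, outcomeN = nOut, action = rep("kept", k),
      audit = data.frame(snp_id = ids, action = "kept",
                         stringsAsFactors = FALSE))
}

# Multi-exposure harmonized set from matrices.
toyHarmonizedMulti <- function(X, y, sy = rep(0.02, length(y)),
                               SX = matrix(0.01, nrow(X), ncol(X)),
                               exposureTypes = rep("binary", ncol(X))) {
  k <- nrow(X); p <- ncol(X)
  ids <- paste0("rs", seq_len(k))
  nms <- paste0("exp", seq_len(p))
  new("HarmonizedSet",
      snps = data.frame(snp_id = ids, chrom = "1", pos = seq_len(k) * 1e5L,
                        effect_allele = "A", other_allele = "G",
                        stringsAsFactors = FALSE),
      exposureBeta = `colnames<-`(X, nms), exposureSE = SX,
      exposureEAF = matrix(0.3, k, p),
      outcomeBeta = y, outcomeSE = sy, outcomeEAF = rep(0.3, k),
      exposureNames = nms, exposureTypes = exposureTypes,
      outcomeName = "outcome", outcomeType = "binary",
      exposureN = rep(1e5, p), outcomeN = 1e5, action = rep("kept", k),
      audit = data.frame(snp_id = ids, action = "kept",
                         stringsAsFactors = FALSE))
}

# Small cohort truth: few strong causal SNPs so instruments are detectable
# at modest n in unit tests.
smallTruth <- function(seed = 11, M = 500, ...) {
  nc <- min(20L, (M %/% 10L) %/% 3L)   # causal loci fit in distinct blocks
  simulationTruth(M = M, nCausalSmk = nc, nCausalBmi = nc,
                  h2Smk = 0.3, h2Bmi = 0.3, seed = seed, ...)
}

# Memoized medium two-sample fixture shared by several test files.
.fixtureCache <- new.env(parent = emptyenv())
sharedTwoSample <- function() {
  if (is.null(.fixtureCache$ts)) {
    truth <- smallTruth(seed = 21)
    .fixtureCache$truth <- truth
    .fixtureCache$ts <- suppressWarnings(
      makeTwoSample(truth, nExposure = 8000, nOutcome = 8000,
                    seedExposure = 31, seedOutcome = 32))
  }
  list(truth = .fixtureCache$truth, ts = .fixtureCache$ts)
}
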