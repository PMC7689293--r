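## Readers/writers and allele harmonization for GWAS summary statistics.

.complement <- c(A = "T", C = "G", G = "C", T = "A")

## fread with transparent gzip support via a connection (no R.utils needed)
.freadAny <- function(path) {
  if (grepl("\\.b?gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    data.table::fread(text = readLines(con), data.table = FALSE)
  } else data.table::fread(path, data.table = FALSE)
}

.isPalindromic <- function(a1, a2) .complement[a1] == a2

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab- or whitespace-delimited table with a header (gzip supported
#' transparently), maps columns to the canonical schema and validates rows.
#' Rows violating invariants are dropped with a logged count; missing mapped
#' columns are fatal.
#'
#' @param path file path.
#' @param columnMap named character vector mapping canonical names
#'   (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pvalue`, `n`) to the file's column names. Canonical names
#'   absent from the map are assumed to appear verbatim in the file.
#' @param traitName trait label.
#' @param traitType `"binary"` or `"continuous"`.
#' @return A [SummaryStats-class] object.
#' @export
readSumstats <- function(path, columnMap = character(),
                         traitName = "trait",
                         traitType = c("binary", "continuous")) {
  traitType <- match.arg(traitType)
  raw <- .freadAny(path)
  map <- setNames(SUMSTATS_COLS, SUMSTATS_COLS)
  if (length(columnMap)) map[names(columnMap)] <- columnMap
  missing <- map[!map %in% names(raw)]
  if (length(missing))
    stop("column(s) not found in ", path, ": ",
         paste(sprintf("%s (mapped to '%s')", missing, names(missing)),
               collapse = ", "))
  d <- raw[, unname(map)]
  names(d) <- names(map)
  SummaryStats(d, traitName = traitName, traitType = traitType)
}

#' Write summary statistics as TSV
#' @param x a [SummaryStats-class].
#' @param path output path (".gz" suffix compresses).
#' @return `path`, invisibly.
#' @export
writeSumstats <- function(x, path) {
  stopifnot(is(x, "SummaryStats"))
  data.table::fwrite(x@data, path, sep = "\t")
  invisible(path)
}

## Align one outcome-style table to reference alleles. Returns list with
## per-row action and flipped beta/eaf. Vectorized truth table:
##  - labels equal            -> kept
##  - labels swapped          -> flipped (beta -> -beta, eaf -> 1 - eaf)
##  - complement equal/swapped-> strand difference, resolved the same way
##  - palindromic             -> frequency-resolved (drop near 0.5)
##  - anything else           -> dropped_mismatch
.alignAlleles <- function(refEA, refOA, ea, oa, beta, eaf, refEAF, window) {
  n <- length(refEA)
  action <- rep("dropped_mismatch", n)
  pal <- .isPalindromic(refEA, refOA)

  same <- ea == refEA & oa == refOA
  swap <- ea == refOA & oa == refEA
  csame <- .complement[ea] == refEA & .complement[oa] == refOA
  cswap <- .complement[ea] == refOA & .complement[oa] == refEA

  action[!pal & same] <- "kept"
  action[!pal & !same & swap] <- "flipped"
  action[!pal & !same & !swap & csame] <- "kept"
  action[!pal & !same & !swap & !csame & cswap] <- "flipped"

  ## Palindromic: labels cannot resolve strand; use allele frequencies.
  ## Drop when either frequency falls inside [0.5 - w, 0.5 + w]; otherwise
  ## orient so both frequencies indicate the same allele side.
  ambiguous <- pal & (abs(refEAF - 0.5) <= window | abs(eaf - 0.5) <= window)
  action[pal & (same | swap | csame | cswap) & ambiguous] <-
    "dropped_palindromic"
  resolvable <- pal & (same | swap | csame | cswap) & !ambiguous
  sameSide <- (refEAF < 0.5) == (eaf < 0.5)
  action[resolvable & sameSide] <- "kept"
  action[resolvable & !sameSide] <- "flipped"

  flip <- action == "flipped"
  beta[flip] <- -beta[flip]
  eaf[flip] <- 1 - eaf[flip]
  list(action = action, beta = beta, eaf = eaf)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Intersects tables on `snp_id` and expresses all effects for the exposure's
#' effect allele. Swapped alleles negate the outcome beta and complement the
#' allele frequency; strand flips are resolved through allele complements;
#' palindromic (A/T, C/G) SNPs are kept only when both allele frequencies lie
#' outside `0.5 +/- palindromeEafWindow` and imply the same orientation, and
#' are dropped otherwise. Allele sets matching no orientation are dropped as
#' mismatches. With a list of exposures, all tables are aligned to the first
#' exposure's alleles and the SNP intersection across all of them is used
#' (the multivariable MR design).
#'
#' @param exposure a [SummaryStats-class] or a list of them.
#' @param outcome a [SummaryStats-class].
#' @param palindromeEafWindow half-width w of the ambiguity window around
#'   0.5; must lie in \[0, 0.5).
#' @return A [HarmonizedSet-class].
#' @export
harmonize <- function(exposure, outcome, palindromeEafWindow = 0.08) {
  stopifnot(palindromeEafWindow >= 0, palindromeEafWindow < 0.5)
  exposures <- if (is(exposure, "SummaryStats")) list(exposure) else exposure
  stopifnot(length(exposures) >= 1,
            all(vapply(exposures, is, TRUE, "SummaryStats")),
            is(outcome, "SummaryStats"))

  ids <- Reduce(intersect, c(lapply(exposures, snpIds), list(snpIds(outcome))))
  if (length(ids) == 0) stop("empty snp_id intersection")

  ref <- exposures[[1]]@data
  ref <- ref[match(ids, ref$snp_id), ]
  p <- length(exposures)
  k0 <- length(ids)
  eb <- es <- ef <- matrix(NA_real_, k0, p)
  eb[, 1] <- ref$beta; es[, 1] <- ref$se; ef[, 1] <- ref$eaf
  actions <- matrix("kept", k0, p + 1)

  alignOne <- function(tab) {
    d <- tab@data[match(ids, tab@data$snp_id), ]
    .alignAlleles(ref$effect_allele, ref$other_allele,
                  d$effect_allele, d$other_allele,
                  d$beta, d$eaf, ref$eaf, palindromeEafWindow)
  }
  if (p > 1) for (j in 2:p) {
    al <- alignOne(exposures[[j]])
    d <- exposures[[j]]@data[match(ids, exposures[[j]]@data$snp_id), ]
    eb[, j] <- al$beta; es[, j] <- d$se; ef[, j] <- al$eaf
    actions[, j] <- al$action
  }
  alo <- alignOne(outcome)
  d <- outcome@data[match(ids, outcome@data$snp_id), ]
  ob <- alo$beta; os <- d$se; oe <- alo$eaf
  actions[, p + 1] <- alo$action

  ## A row survives only if every table harmonized; record the first failure.
  rowAction <- apply(actions, 1, function(a) {
    bad <- a[!a %in% c("kept", "flipped")]
    if (length(bad)) bad[1] else if (any(a == "flipped")) "flipped" else "kept"
  })
  keep <- rowAction %in% c("kept", "flipped")
  audit <- data.frame(snp_id = ids, action = rowAction,
                      stringsAsFactors = FALSE)
  if (!any(keep)) stop("all rows dropped during harmonization")

  new("HarmonizedSet",
      snps = data.frame(snp_id = ids, chrom = ref$chrom, pos = ref$pos,
                        effect_allele = ref$effect_allele,
                        other_allele = ref$other_allele,
                        stringsAsFactors = FALSE)[keep, , drop = FALSE],
      exposureBeta = eb[keep, , drop = FALSE],
      exposureSE = es[keep, , drop = FALSE],
      exposureEAF = ef[keep, , drop = FALSE],
      outcomeBeta = ob[keep], outcomeSE = os[keep], outcomeEAF = oe[keep],
      exposureNames = vapply(exposures, traitName, ""),
      exposureTypes = vapply(exposures, traitType, ""),
      outcomeName = traitName(outcome), outcomeType = traitType(outcome),
      exposureN = vapply(exposures, function(e) stats::median(e@data$n), 0),
      outcomeN = stats::median(outcome@data$n),
      action = rowAction[keep], audit = audit)
}

#' Restrict a HarmonizedSet to a set of SNPs
#' @param h a [HarmonizedSet-class].
#' @param ids snp_ids to retain (order preserved from `h`).
#' @return A [HarmonizedSet-class].
#' @export
subsetSnps <- function(h, ids) {
  stopifnot(is(h, "HarmonizedSet"))
  keep <- h@snps$snp_id %in% ids
  if (!any(keep)) stop("no overlapping SNPs")
  initialize(h, snps = h@snps[keep, , drop = FALSE],
             exposureBeta = h@exposureBeta[keep, , drop = FALSE],
             exposureSE = h@exposureSE[keep, , drop = FALSE],
             exposureEAF = h@exposureEAF[keep, , drop = FALSE],
             outcomeBeta = h@outcomeBeta[keep],
             outcomeSE = h@outcomeSE[keep],
             outcomeEAF = h@outcomeEAF[keep],
             action = h@action[keep],
             audit = h@audit[h@audit$snp_id %in% ids, , drop = FALSE])
}

#' Write a HarmonizedSet as TSV (with its `action` column)
#' @param h a [HarmonizedSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHarmonized <- function(h, path) {
  stopifnot(is(h, "HarmonizedSet"))
  data.table::fwrite(as.data.frame(h), path, sep = "\t")
  invisible(path)
}
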