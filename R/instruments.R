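## Instrument construction: p-value thresholding, greedy LD clumping,
## variance explained and F-statistics, PRS weight tables.

#' Per-SNP variance explained in the exposure
#'
#' \eqn{r^2_j = \beta^2 2p(1-p) / [\beta^2 2p(1-p) + se^2 2p(1-p) n]}.
#' The instrument total R2 is the sum over retained SNPs.
#'
#' @param beta,se per-allele effect and its standard error.
#' @param eaf effect-allele frequency, strictly inside (0,1).
#' @param n exposure GWAS sample size (> 1).
#' @return numeric vector of per-SNP r2 values.
#' @export
varianceExplained <- function(beta, se, eaf, n) {
  stopifnot(all(is.finite(beta)), all(is.finite(se)), all(is.finite(n)),
            all(n > 1))
  if (any(eaf <= 0 | eaf >= 1))
    stop("monomorphic SNP: eaf must lie strictly in (0,1)")
  het <- 2 * eaf * (1 - eaf)
  (beta^2 * het) / (beta^2 * het + se^2 * het * n)
}

#' Instrument F-statistic (mRnd convention)
#'
#' \eqn{F = [(n-k-1)/k] \cdot r^2/(1-r^2)}. Values above 10 are the
#' conventional guard against weak-instrument bias.
#'
#' @param r2Total total variance explained, in \[0,1).
#' @param n exposure sample size (> k+1).
#' @param k number of instrument SNPs (>= 1).
#' @return numeric scalar.
#' @export
fStatistic <- function(r2Total, n, k) {
  stopifnot(k >= 1, n > k + 1)
  if (r2Total >= 1) stop("r2Total must be < 1")
  if (r2Total < 0) stop("r2Total must be >= 0")
  ((n - k - 1) / k) * (r2Total / (1 - r2Total))
}

## Fast neighbour lookup: named list snp -> data.frame(other, r2)
.ldNeighbours <- function(ld) {
  p <- ld@pairs
  if (nrow(p) == 0) return(list())
  both <- data.frame(a = c(p$snp_a, p$snp_b), b = c(p$snp_b, p$snp_a),
                     r2 = c(p$r2, p$r2), stringsAsFactors = FALSE)
  split(both[c("b", "r2")], both$a)
}

#' Greedy LD clumping of genome-wide significant SNPs
#'
#' Candidates passing `pThreshold` are sorted by ascending p (ties broken by
#' chromosome then position); the best remaining SNP is retained and all
#' unretained candidates on the same chromosome within `windowBp` with
#' `r2 >= r2Threshold` against it are removed and attributed to it.
#'
#' @param sumstats a [SummaryStats-class] for the exposure.
#' @param ld an [LDReference-class].
#' @param pThreshold significance threshold (default genome-wide, 5e-8).
#' @param r2Threshold LD pruning threshold (default 0.01).
#' @param windowBp window radius in bp (default 250000): SNPs with
#'   `|pos_a - pos_b| <= windowBp` on the same chromosome are in range.
#' @return An [InstrumentSet-class]; per-SNP r2 from [varianceExplained()],
#'   F from [fStatistic()].
#' @export
clump <- function(sumstats, ld, pThreshold = 5e-8, r2Threshold = 0.01,
                  windowBp = 250000) {
  stopifnot(is(sumstats, "SummaryStats"), is(ld, "LDReference"))
  d <- sumstats@data
  cand <- d[d$pvalue < pThreshold, , drop = FALSE]
  if (nrow(cand) == 0) {
    near <- sum(d$pvalue < pThreshold * 100)
    stop("no SNP passes p < ", format(pThreshold), " (", near,
         " within two orders of magnitude)")
  }
  ord <- order(cand$pvalue, cand$chrom, cand$pos)
  cand <- cand[ord, ]
  nb <- .ldNeighbours(ld)
  status <- rep("free", nrow(cand))  # free | retained | removed
  index_of <- rep(NA_character_, nrow(cand))
  pos <- setNames(cand$pos, cand$snp_id)
  chr <- setNames(cand$chrom, cand$snp_id)
  rowOf <- setNames(seq_len(nrow(cand)), cand$snp_id)

  for (i in seq_len(nrow(cand))) {
    if (status[i] != "free") next
    status[i] <- "retained"
    id <- cand$snp_id[i]
    friends <- nb[[id]]
    if (is.null(friends)) next
    hit <- friends$b[friends$r2 >= r2Threshold]
    hit <- hit[hit %in% names(rowOf)]
    if (!length(hit)) next
    inWindow <- chr[hit] == chr[id] & abs(pos[hit] - pos[id]) <= windowBp
    hit <- hit[inWindow]
    rows <- rowOf[hit]
    rows <- rows[status[rows] == "free"]
    status[rows] <- "removed"
    index_of[rows] <- id
  }
  kept <- cand[status == "retained", ]
  r2 <- varianceExplained(kept$beta, kept$se, kept$eaf, kept$n)
  names(r2) <- kept$snp_id
  n <- stats::median(kept$n)
  r2tot <- sum(r2)
  new("InstrumentSet", snpIds = kept$snp_id, r2PerSnp = r2,
      r2Total = r2tot, fStat = fStatistic(r2tot, n, nrow(kept)),
      nExposure = n, k = nrow(kept),
      assignments = data.frame(
        snp_id = cand$snp_id[status == "removed"],
        index_snp = index_of[status == "removed"],
        stringsAsFactors = FALSE))
}

#' Build a PRS weight table for an instrument
#'
#' Weights come either from the exposure's own GWAS (default) or from a
#' second trait's GWAS harmonized to the exposure's effect alleles — the
#' "mediator-by-exposure-SNPs" construction used to carry a predicted
#' mediator into stage-2 models.
#'
#' @param instrument an [InstrumentSet-class].
#' @param exposure the [SummaryStats-class] the instrument was built from.
#' @param weightsFrom optional [SummaryStats-class] supplying the weights
#'   (harmonized to the exposure alleles; flipped alleles negate the weight).
#' @param maxMissing maximum tolerated fraction of instrument SNPs absent
#'   from the weight source (default 0.2); beyond it, fatal.
#' @return data.frame (snp_id, effect_allele, weight).
#' @export
prsModel <- function(instrument, exposure, weightsFrom = NULL,
                     maxMissing = 0.2) {
  stopifnot(is(instrument, "InstrumentSet"), is(exposure, "SummaryStats"))
  d <- exposure@data[match(instrument@snpIds, exposure@data$snp_id), ]
  if (anyNA(d$snp_id)) stop("instrument SNPs missing from exposure table")
  if (is.null(weightsFrom))
    return(data.frame(snp_id = d$snp_id, effect_allele = d$effect_allele,
                      weight = d$beta, stringsAsFactors = FALSE))
  stopifnot(is(weightsFrom, "SummaryStats"))
  expoSub <- SummaryStats(d, traitName = exposure@traitName,
                          traitType = exposure@traitType)
  h <- harmonize(expoSub, weightsFrom)
  nMissing <- length(instrument@snpIds) - nrow(h@snps)
  if (nMissing > 0)
    message(nMissing, " instrument SNP(s) missing/unharmonizable in the ",
            "weight source; dropped")
  if (nMissing / length(instrument@snpIds) > maxMissing)
    stop("more than ", round(100 * maxMissing), "% of instrument SNPs ",
         "missing from the weight source")
  data.frame(snp_id = h@snps$snp_id, effect_allele = h@snps$effect_allele,
             weight = h@outcomeBeta, stringsAsFactors = FALSE)
}

#' Write an InstrumentSet (or PRS table) as TSV
#' @param x an [InstrumentSet-class] or PRS weight data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeInstruments <- function(x, path) {
  d <- if (is(x, "InstrumentSet"))
    data.frame(snp_id = x@snpIds, r2 = x@r2PerSnp[x@snpIds],
               row.names = NULL)
  else as.data.frame(x)
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}
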