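# Reading, validation and allele harmonization of summary statistics.

test_that("reading a toy TSV round-trips and maps columns", {
  d <- toySumstatsDf(3)
  path <- withr_local_tempfile()
  names(d)[names(d) == "beta"] <- "b_est"
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  ss <- readSumstats(path, columnMap = c(beta = "b_est"),
                     traitName = "smk", traitType = "binary")
  expect_s4_class(ss, "SummaryStats")
  expect_equal(nSnps(ss), 3)
  expect_equal(ss@data$beta, toySumstatsDf(3)$beta)
  expect_equal(traitName(ss), "smk")
})

test_that("gzip-compressed tables read transparently", {
  d <- toySumstatsDf(4)
  path <- tempfile(fileext = ".tsv.gz")
  data.table::fwrite(d, path, sep = "\t")
  ss <- readSumstats(path, traitName = "smk")
  expect_equal(nSnps(ss), 4)
  expect_equal(ss@data$beta, d$beta)
})

test_that("invalid rows are dropped with a message; empty result is fatal", {
  d <- toySumstatsDf(4)
  d$se[2] <- 0
  expect_message(ss <- SummaryStats(d), "se not positive")
  expect_equal(nSnps(ss), 3)
  expect_false("rs2" %in% snpIds(ss))

  d2 <- toySumstatsDf(2)
  d2$se <- 0
  expect_error(suppressMessages(SummaryStats(d2)), "no rows left")
})

test_that("a missing mapped column is a fatal error naming the column", {
  d <- toySumstatsDf(3)
  d$eaf <- NULL
  path <- withr_local_tempfile()
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(readSumstats(path), "eaf")
  expect_error(SummaryStats(d), "eaf")
})

test_that("duplicate ids, indels and monoallelic rows are rejected", {
  d <- toySumstatsDf(4)
  d$snp_id[2] <- "rs1"
  expect_message(ss <- SummaryStats(d), "duplicate")
  expect_equal(nSnps(ss), 3)

  d <- toySumstatsDf(3)
  d$effect_allele[1] <- "AT"    # indel-like
  d$other_allele[2] <- d$effect_allele[2]
  expect_message(ss <- SummaryStats(d), "invalid alleles")
  expect_equal(nSnps(ss), 1)
})

# Hand-written truth table over allele configurations, non-palindromic ref
# (A/G) and palindromic ref (A/T), crossed with eaf placement.
test_that("harmonization follows the allele/frequency truth table", {
  mk <- function(ea, oa, eaf, beta = 0.05) {
    d <- toySumstatsDf(1, ea = ea, oa = oa, eaf = eaf, beta = beta)
    SummaryStats(d, traitType = "binary")
  }
  expo <- mk("A", "G", 0.3, beta = 0.1)
  cases <- list(
    list(ea = "A", oa = "G", eaf = 0.3, action = "kept",    b = 0.05),
    list(ea = "G", oa = "A", eaf = 0.7, action = "flipped", b = -0.05),
    list(ea = "T", oa = "C", eaf = 0.3, action = "kept",    b = 0.05),
    list(ea = "C", oa = "T", eaf = 0.7, action = "flipped", b = -0.05),
    list(ea = "A", oa = "C", eaf = 0.3, action = "dropped_mismatch"))
  for (cs in cases) {
    out <- mk(cs$ea, cs$oa, cs$eaf)
    if (grepl("dropped", cs$action)) {
      expect_error(harmonize(expo, out), "all rows dropped")
    } else {
      h <- harmonize(expo, out)
      expect_equal(unname(h@action), cs$action)
      expect_equal(unname(h@outcomeBeta), cs$b)
    }
  }

  # palindromic reference: frequency decides orientation, window drops
  expoP <- mk("A", "T", 0.2, beta = 0.1)
  h <- harmonize(expoP, mk("A", "T", 0.2), palindromeEafWindow = 0.08)
  expect_equal(unname(h@action), "kept")
  h <- harmonize(expoP, mk("A", "T", 0.8), palindromeEafWindow = 0.08)
  expect_equal(unname(h@action), "flipped")
  expect_equal(unname(h@outcomeBeta), -0.05)
  expect_equal(unname(h@outcomeEAF), 0.2)
  # swapped labels but same frequency side: strand flip, net kept
  h <- harmonize(expoP, mk("T", "A", 0.2), palindromeEafWindow = 0.08)
  expect_equal(unname(h@action), "kept")
  # ambiguous frequency: dropped whatever the labels say
  expoQ <- mk("A", "T", 0.49, beta = 0.1)
  expect_error(harmonize(expoQ, mk("A", "T", 0.49),
                         palindromeEafWindow = 0.08),
               "all rows dropped")
})

test_that("palindrome window boundary respects w", {
  mk <- function(eaf) SummaryStats(toySumstatsDf(1, ea = "C", oa = "G",
                                                 eaf = eaf))
  # eaf = 0.40 is outside the 0.42-0.58 window, 0.43 inside
  expect_equal(unname(harmonize(mk(0.40), mk(0.40))@action), "kept")
  expect_error(harmonize(mk(0.43), mk(0.43)), "all rows dropped")
})

test_that("sign flip preserves |beta| and the p-value exactly", {
  expo <- toySumstats(3)
  d <- toySumstatsDf(3)
  tmp <- d$effect_allele; d$effect_allele <- d$other_allele
  d$other_allele <- tmp
  d$eaf <- 1 - d$eaf
  out <- SummaryStats(d, traitName = "out")
  h <- harmonize(expo, out)
  expect_equal(unname(h@action), rep("flipped", 3))
  expect_equal(abs(h@outcomeBeta), abs(toySumstatsDf(3)$beta))
  expect_equal(h@outcomeEAF, toySumstatsDf(3)$eaf)
})

test_that("harmonization is idempotent (flipping is an involution)", {
  set.seed(5)
  k <- 40
  bases <- list(c("A", "G"), c("C", "T"), c("A", "T"), c("C", "G"))
  pick <- sample(4, k, replace = TRUE)
  ea <- vapply(pick, function(i) bases[[i]][1], "")
  oa <- vapply(pick, function(i) bases[[i]][2], "")
  eaf <- runif(k, 0.05, 0.95)
  expo <- SummaryStats(toySumstatsDf(k, ea = ea, oa = oa, eaf = eaf,
                                     beta = rnorm(k, 0, 0.05)))
  # outcome with randomly swapped labels
  swap <- as.logical(rbinom(k, 1, 0.5))
  d <- toySumstatsDf(k, ea = ifelse(swap, oa, ea),
                     oa = ifelse(swap, ea, oa),
                     eaf = ifelse(swap, 1 - eaf, eaf),
                     beta = rnorm(k, 0, 0.05))
  out <- SummaryStats(d, traitName = "out")
  h1 <- harmonize(expo, out)
  # re-express the harmonized outcome as a SummaryStats and harmonize again
  df1 <- as.data.frame(h1)
  d2 <- data.frame(snp_id = df1$snp_id, chrom = df1$chrom, pos = df1$pos,
                   effect_allele = df1$effect_allele,
                   other_allele = df1$other_allele,
                   eaf = df1$eaf.outcome,
                   beta = df1$beta.outcome, se = 0.01, pvalue = 1e-5,
                   n = 50000)
  h2 <- harmonize(expo, SummaryStats(d2, traitName = "out"))
  expect_equal(unname(h2@action), rep("kept", nrow(d2)))
  expect_equal(h2@outcomeBeta, h1@outcomeBeta[h1@snps$snp_id %in%
                                                h2@snps$snp_id])
})

test_that("multi-exposure harmonization aligns all tables to exposure 1", {
  e1 <- toySumstats(4, traitName = "smk")
  d <- toySumstatsDf(4)
  tmp <- d$effect_allele; d$effect_allele <- d$other_allele
  d$other_allele <- tmp; d$eaf <- 1 - d$eaf; d$beta <- -d$beta
  e2 <- SummaryStats(d, traitName = "bmi", traitType = "continuous")
  out <- toySumstats(4, traitName = "t2d")
  h <- harmonize(list(e1, e2), out)
  expect_equal(h@exposureNames, c("smk", "bmi"))
  # e2 was stored with flipped coding; after alignment both agree
  expect_equal(h@exposureBeta[, 1], h@exposureBeta[, 2])
})

test_that("HarmonizedSet serializes with its action column", {
  h <- toyHarmonized(bx = c(0.1, 0.2, 0.3), by = c(0.05, 0.1, 0.15))
  path <- withr_local_tempfile()
  writeHarmonized(h, path)
  back <- read.delim(path)
  expect_equal(back$action, rep("kept", 3))
  expect_equal(back$beta.outcome, h@outcomeBeta)
})
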