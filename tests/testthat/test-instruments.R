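# Clumping, variance explained, F-statistics, PRS weight tables.

test_that("variance explained matches the closed form and is monotone", {
  expect_equal(varianceExplained(0, 0.01, 0.3, 1e4), 0)
  # beta=0.1, se=0.01, p=0.5, n=1e4: r2 = 0.01/(0.01 + 1) (heterozygosity
  # cancels between numerator and denominator)
  expect_equal(varianceExplained(0.1, 0.01, 0.5, 1e4), 0.01 / 1.01,
               tolerance = 1e-12)
  expect_lt(varianceExplained(0.1, 0.02, 0.5, 1e4),
            varianceExplained(0.1, 0.01, 0.5, 1e4))
  expect_error(varianceExplained(0.1, 0.01, 1, 1e4), "monomorphic")
})

test_that("F-statistic follows the mRnd convention", {
  expect_equal(fStatistic(0, 1000, 10), 0)
  expect_equal(fStatistic(0.01, 1000, 10),
               (989 / 10) * (0.01 / 0.99), tolerance = 1e-12)
  expect_lt(fStatistic(0.01, 1000, 10), fStatistic(0.02, 1000, 10))
  expect_error(fStatistic(1, 1000, 10), "< 1")
})

test_that("clumping keeps all SNPs in linkage equilibrium", {
  ss <- toySumstats(5, p = c(1e-10, 1e-9, 1e-12, 1e-11, 1e-8))
  ld <- LDReference(data.frame(snp_a = character(), snp_b = character(),
                               r2 = numeric()))
  inst <- clump(ss, ld)
  expect_setequal(snpIds(inst), paste0("rs", 1:5))
  # ordered by ascending p
  expect_equal(snpIds(inst)[1], "rs3")
})

test_that("the stronger of two linked SNPs dominates", {
  d <- toySumstatsDf(2, p = c(1e-10, 1e-9))
  d$pos <- c(100000L, 110000L)   # 10 kb apart
  ss <- SummaryStats(d)
  ld <- LDReference(data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.5))
  inst <- clump(ss, ld)
  expect_equal(snpIds(inst), "rs1")
  expect_equal(inst@assignments$index_snp, "rs1")
  expect_equal(inst@assignments$snp_id, "rs2")
})

test_that("no significant SNP is a fatal error with near-miss count", {
  ss <- toySumstats(3, p = c(1e-7, 1e-6, 0.5))
  ld <- LDReference(data.frame(snp_a = character(), snp_b = character(),
                               r2 = numeric()))
  expect_error(clump(ss, ld), "no SNP passes")
})

test_that("greedy output satisfies the clumping postconditions (brute check)", {
  # 6-SNP toy with a hand-specified LD structure
  d <- toySumstatsDf(6, p = c(1e-12, 1e-10, 1e-11, 1e-9, 1e-13, 1e-8))
  d$pos <- c(1e5, 1.5e5, 2e5, 9e5, 9.5e5, 1.1e6)
  ss <- SummaryStats(d)
  pairs <- data.frame(
    snp_a = c("rs1", "rs1", "rs2", "rs4", "rs5"),
    snp_b = c("rs2", "rs3", "rs3", "rs5", "rs6"),
    r2    = c(0.80, 0.05, 0.30, 0.60, 0.90))
  ld <- LDReference(pairs)
  inst <- clump(ss, ld, r2Threshold = 0.1, windowBp = 250000)

  lookup <- function(a, b) {
    hit <- (pairs$snp_a == a & pairs$snp_b == b) |
      (pairs$snp_a == b & pairs$snp_b == a)
    if (any(hit)) pairs$r2[hit] else 0
  }
  kept <- snpIds(inst)
  pos <- setNames(d$pos, d$snp_id)
  # postcondition 1: retained SNPs pairwise below threshold within window
  for (a in kept) for (b in kept) if (a != b &&
      abs(pos[a] - pos[b]) <= 250000)
    expect_lt(lookup(a, b), 0.1)
  # postcondition 2: every removed SNP is linked to a retained SNP with a
  # smaller (or tie-broken) p-value
  pv <- setNames(d$pvalue, d$snp_id)
  for (i in seq_len(nrow(inst@assignments))) {
    rem <- inst@assignments$snp_id[i]
    idx <- inst@assignments$index_snp[i]
    expect_gte(lookup(rem, idx), 0.1)
    expect_lte(pv[idx], pv[rem])
    expect_lte(abs(pos[rem] - pos[idx]), 250000)
  }
  # rs5 (best p) retained; rs4, rs6 removed through it
  expect_true("rs5" %in% kept)
  expect_false(any(c("rs4", "rs6") %in% kept))
  # rs1-rs3 weakly linked (0.05 < 0.1): both kept, rs2 absorbed by rs1
  expect_true(all(c("rs1", "rs3") %in% kept))
})

test_that("clumping is invariant to input row order", {
  set.seed(9)
  d <- toySumstatsDf(30, p = 10^-runif(30, 8, 20))
  d$pos <- sort(sample.int(3e6, 30))
  pairs <- data.frame(snp_a = d$snp_id[1:29], snp_b = d$snp_id[2:30],
                      r2 = runif(29))
  ld <- LDReference(pairs)
  i1 <- clump(SummaryStats(d), ld)
  i2 <- clump(SummaryStats(d[sample.int(30), ]), ld)
  expect_equal(snpIds(i1), snpIds(i2))
})

test_that("equal p-values break ties by genomic position", {
  d <- toySumstatsDf(2, p = c(1e-10, 1e-10))
  d$pos <- c(200000L, 100000L)
  ld <- LDReference(data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.9))
  inst <- clump(SummaryStats(d), ld)
  expect_equal(snpIds(inst), "rs2")   # lower position wins
})

test_that("window semantics are a radius on the same chromosome", {
  d <- toySumstatsDf(2, p = c(1e-10, 1e-9))
  d$pos <- c(100000L, 360000L)        # 260 kb apart: outside the radius
  ld <- LDReference(data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.9))
  expect_equal(snpIds(clump(SummaryStats(d), ld)), c("rs1", "rs2"))
  d$pos <- c(100000L, 340000L)        # 240 kb: inside
  expect_equal(snpIds(clump(SummaryStats(d), ld)), "rs1")
})

test_that("PRS weights come from the exposure or a harmonized second GWAS", {
  ss <- toySumstats(5, traitName = "smk")
  ld <- LDReference(data.frame(snp_a = character(), snp_b = character(),
                               r2 = numeric()))
  inst <- clump(ss, ld)
  w <- prsModel(inst, ss)
  expect_equal(w$weight[match(snpIds(ss), w$snp_id)], ss@data$beta)

  # second-trait weights with flipped allele labels negate the weight
  d <- toySumstatsDf(5, beta = rep(0.2, 5))
  tmp <- d$effect_allele; d$effect_allele <- d$other_allele
  d$other_allele <- tmp; d$eaf <- 1 - d$eaf
  bmi <- SummaryStats(d, traitName = "bmi", traitType = "continuous")
  w2 <- prsModel(inst, ss, weightsFrom = bmi)
  expect_equal(unname(w2$weight), rep(-0.2, 5))
  expect_equal(w2$effect_allele,
               ss@data$effect_allele[match(w2$snp_id, ss@data$snp_id)])

  # excessive missingness is fatal
  bmiShort <- SummaryStats(toySumstatsDf(5)[1:2, ], traitName = "bmi")
  expect_error(suppressMessages(prsModel(inst, ss, weightsFrom = bmiShort)),
               "missing from the weight source")
})

test_that("instrument strength on synthetic data clears the F > 10 guard", {
  fx <- sharedTwoSample()
  inst <- clump(fx$ts$exposure$smoking_ever, fx$ts$ld)
  expect_gt(inst@fStat, 10)
  expect_gte(inst@k, 5)
  # one retained SNP per causal block: retained SNPs in distinct blocks
  blockOf <- (as.integer(sub("rs", "", snpIds(inst))) - 1) %/%
    fx$truth@blockSize
  expect_equal(anyDuplicated(blockOf), 0L)
})
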