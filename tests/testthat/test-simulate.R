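# The synthetic cohort generator: determinism, calibration, and the GWAS
# scan against a per-SNP glm oracle.

test_that("identical config and seed give byte-identical cohorts", {
  truth <- smallTruth(seed = 81, M = 200)
  c1 <- simulateCohort(truth, 500, seed = 82)
  c2 <- simulateCohort(truth, 500, seed = 82)
  expect_identical(c1@dosages, c2@dosages)
  expect_identical(c1@phenotypes, c2@phenotypes)
  c3 <- simulateCohort(truth, 500, seed = 83)
  expect_false(identical(c1@dosages, c3@dosages))
})

test_that("binary trait prevalences land within one percentage point", {
  truth <- simulationTruth(M = 200, nCausalSmk = 10, nCausalBmi = 10,
                           seed = 84)
  coh <- simulateCohort(truth, 50000, seed = 85)
  ph <- coh@phenotypes
  expect_lt(abs(mean(ph$smoking_ever) - 0.45), 0.01)
  expect_lt(abs(mean(ph$t2d) - 0.20), 0.01)
  expect_lt(abs(mean(ph$cad) - 0.15), 0.01)
})

test_that("an unreachable prevalence is a fatal error", {
  truth <- simulationTruth(M = 200, nCausalSmk = 10, nCausalBmi = 10,
                           prevalence = c(smoking = 0.45, t2d = 1e-30,
                                          cad = 0.15), seed = 86)
  expect_error(suppressWarnings(simulateCohort(truth, 500, seed = 86)),
               "unreachable prevalence")
})

test_that("the smoking -> BMI path shows up at its injected size", {
  truth <- smallTruth(seed = 87, M = 200)
  diffs <- vapply(1:5, function(i) {
    coh <- simulateCohort(truth, 10000, seed = 870 + i)
    ph <- coh@phenotypes
    mean(ph$bmi_std[ph$smoking_ever == 1]) -
      mean(ph$bmi_std[ph$smoking_ever == 0])
  }, 0)
  # theta_SB = 0.8 on the pre-standardization scale; after standardization
  # (total SD ~ sqrt(1 + 0.25*0.8^2) ~ 1.077) expect ~0.74, plus a small
  # genetic-correlation contribution through shared liability
  expect_gt(mean(diffs), 0.5)
  expect_lt(abs(mean(diffs) - 0.8 / sqrt(1 + 0.2475 * 0.64)), 0.1)
})

test_that("a global-null truth yields calibrated null associations", {
  truth <- simulationTruth(M = 400, nCausalSmk = 0, nCausalBmi = 0,
                           theta = c(SB = 0, BT = 0, ST = 0, BC = 0,
                                     SC = 0), seed = 88)
  coh <- simulateCohort(truth, 4000, seed = 89)
  gw <- gwasScan(coh, "bmi_std")
  expect_lt(abs(mean(gw@data$pvalue < 0.05) - 0.05), 0.025)
  gwb <- gwasScan(coh, "t2d")
  expect_lt(abs(mean(gwb@data$pvalue < 0.05) - 0.05), 0.025)
  # trait-trait: smoking and t2d unrelated
  expect_gt(t.test(coh@phenotypes$t2d ~ coh@phenotypes$smoking_ever)$p.value,
            0.01)
})

test_that("eaf is exactly the mean dosage over two", {
  truth <- smallTruth(seed = 90, M = 200)
  coh <- simulateCohort(truth, 1000, seed = 91)
  gw <- gwasScan(coh, "bmi_std")
  expect_equal(gw@data$eaf, unname(colMeans(coh@dosages) / 2))
  expect_equal(gw@data$n, rep(1000, 200))
})

test_that("the fast scan matches per-SNP glm fits", {
  truth <- smallTruth(seed = 92, M = 60)
  coh <- simulateCohort(truth, 4000, seed = 93)
  cv <- coh@covariates
  # continuous trait: exact equality with lm (same projection algebra)
  gw <- gwasScan(coh, "bmi_std")
  idx <- c(3, 17, 41)
  for (j in idx) {
    fit <- lm(coh@phenotypes$bmi_std ~ coh@dosages[, j] + age + sex +
                pc1 + pc2 + pc3 + pc4 + pc5, data = cv)
    expect_equal(gw@data$beta[j], unname(coef(fit)[2]), tolerance = 1e-8)
    expect_equal(gw@data$se[j],
                 unname(sqrt(diag(vcov(fit)))[2]), tolerance = 1e-6)
  }
  # binary trait: one-step score approximation within ~3% of full IRLS
  gwb <- gwasScan(coh, "smoking_ever")
  for (j in idx) {
    fit <- glm(coh@phenotypes$smoking_ever ~ coh@dosages[, j] + age + sex +
                 pc1 + pc2 + pc3 + pc4 + pc5, data = cv,
               family = binomial())
    expect_equal(gwb@data$beta[j], unname(coef(fit)[2]), tolerance = 0.03)
    expect_equal(gwb@data$se[j],
                 unname(sqrt(diag(vcov(fit)))[2]), tolerance = 0.03)
  }
})

test_that("injected effects are recovered with nominal CI coverage", {
  truth <- smallTruth(seed = 94, M = 100)
  causal <- which(truth@gammaBmi != 0)
  covered <- withSeed(95, unlist(lapply(1:10, function(i) {
    coh <- simulateCohort(truth, 6000, seed = 940 + i)
    gw <- gwasScan(coh, "bmi_std")
    lo <- gw@data$beta - 1.96 * gw@data$se
    hi <- gw@data$beta + 1.96 * gw@data$se
    # per-SNP marginal truth includes LD with block neighbours; causal SNPs
    # are alone in their blocks, so the marginal effect is gamma itself
    # (up to the post-standardization rescaling of BMI)
    sdB <- sqrt(1 + 0.2475 * truth@theta[["SB"]]^2)
    (truth@gammaBmi[causal] / sdB >= lo[causal]) &
      (truth@gammaBmi[causal] / sdB <= hi[causal])
  })))
  expect_gt(mean(covered), 0.90)
  expect_lt(mean(covered), 0.99)
})

test_that("two-sample generation is reproducible and guards its edges", {
  truth0 <- simulationTruth(M = 200, nCausalSmk = 0, nCausalBmi = 10,
                            seed = 96)
  expect_warning(
    ts <- makeTwoSample(truth0, 500, 500, seedExposure = 7,
                        seedOutcome = 7),
    "overlap")
  # zero-instrument truth: clumping must fail loudly
  expect_error(clump(ts$exposure$smoking_ever, ts$ld), "no SNP passes")
})

test_that("LD reference from the truth matches empirical dosage LD", {
  fx <- sharedTwoSample()
  truth <- fx$truth
  coh <- simulateCohort(truth, 8000, seed = 97)
  G <- coh@dosages[, 1:10]
  emp <- cor(G)
  # adjacent r2 near the calibrated target, well above the clump threshold
  adj <- mean(vapply(1:9, function(i) emp[i, i + 1]^2, 0))
  expect_gt(adj, 0.15)
  expect_lt(abs(adj - truth@lagR2[1]), 0.15)
  # cross-block independence
  expect_lt(abs(cor(coh@dosages[, 10], coh@dosages[, 11])), 0.05)
})
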