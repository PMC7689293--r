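## Pipeline orchestration: univariable MR -> MVMR -> mediation -> Steiger ->
## genetic correlation -> optional individual-level 2SPS, from one config.

.asSumstats <- function(x, role) {
  if (is(x, "SummaryStats")) return(x)
  if (is.list(x) && !is.null(x$path))
    return(readSumstats(x$path,
                        columnMap = unlist(x$columnMap %||% list()),
                        traitName = x$traitName %||% role,
                        traitType = x$traitType %||% "binary"))
  stop("cannot interpret ", role, " input")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate and normalize a pipeline configuration
#'
#' A config is a named list (or YAML file path) with entries: `exposure`,
#' `mediator` (optional), `outcome` — each a SummaryStats or
#' `list(path, columnMap, traitName, traitType)`; `ld` (LDReference or
#' 3-column TSV path); thresholds `pThreshold`, `r2Threshold`, `windowBp`,
#' `palindromeEafWindow`; estimator settings `nBoot`; optional `cohort`
#' ([Cohort-class]) plus `bmiWeightsFrom` for 2SPS; `outDir`; `seed`.
#'
#' @param config named list or YAML path.
#' @return normalized config list.
#' @export
pipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$exposure),
            !is.null(config$outcome), !is.null(config$ld))
  defaults <- list(pThreshold = 5e-8, r2Threshold = 0.01, windowBp = 250000,
                   palindromeEafWindow = 0.08, nBoot = 1000, seed = 1L,
                   outDir = NULL, cohort = NULL, mediator = NULL,
                   bmiWeightsFrom = NULL)
  config <- modifyList(defaults, config)
  stopifnot(config$pThreshold > 0, config$pThreshold < 1,
            config$r2Threshold > 0, config$r2Threshold <= 1,
            config$windowBp > 0)
  if (is.character(config$ld)) config$ld <- readLDReference(config$ld)
  config
}

.writeTsv <- function(d, dir, name) {
  if (!is.null(dir)) data.table::fwrite(d, file.path(dir, name), sep = "\t")
}

#' Run the full mediation-MR pipeline
#'
#' Stages, mirroring the analysis order of the motivating study: instrument
#' construction by clumping; univariable MR of exposure on outcome (IVW
#' random effects, weighted median, MR-Egger, Cochran's Q); exposure on
#' mediator; multivariable MR of exposure + mediator on outcome with
#' mediation (total/direct) reporting; MR-Steiger between exposure and
#' mediator; LD-score genetic correlation between exposure and outcome;
#' optional individual-level 2SPS when a cohort is supplied. Writes
#' forest-plot-ready TSVs, a machine-readable JSON of all estimates and a
#' run log into `outDir` when given.
#'
#' @param config see [pipelineConfig()].
#' @return list with elements instruments, mr, mediatorMr, mvmr, mediation,
#'   steiger, rg, twostage (NULL without a cohort), tables (data.frames as
#'   written) — invisibly.
#' @export
runPipeline <- function(config) {
  cfg <- pipelineConfig(config)
  if (!is.null(cfg$outDir) && !dir.exists(cfg$outDir))
    dir.create(cfg$outDir, recursive = TRUE)
  logLines <- c(sprintf("mrmediate %s", as.character(utils::packageVersion("mrmediate"))),
                sprintf("R %s", getRversion()),
                sprintf("seed %d", cfg$seed),
                sprintf("thresholds p<%g r2<%g window %d bp",
                        cfg$pThreshold, cfg$r2Threshold, cfg$windowBp))
  stage <- "read"
  res <- list()
  tryCatch({
    expo <- .asSumstats(cfg$exposure, "exposure")
    outc <- .asSumstats(cfg$outcome, "outcome")
    medi <- if (!is.null(cfg$mediator)) .asSumstats(cfg$mediator, "mediator")

    stage <- "instruments"
    instExp <- clump(expo, cfg$ld, cfg$pThreshold, cfg$r2Threshold,
                     cfg$windowBp)
    res$instruments <- list(exposure = instExp)
    instTab <- data.frame(trait = traitName(expo), k = instExp@k,
                          r2_total = instExp@r2Total, F = instExp@fStat)

    stage <- "harmonize"
    hExpOut <- subsetSnps(harmonize(expo, outc, cfg$palindromeEafWindow),
                          snpIds(instExp))
    res$harmonization <- hExpOut@audit

    stage <- "mr"
    mr <- mrAll(hExpOut, nBoot = cfg$nBoot, seed = cfg$seed)
    res$mr <- mr
    diag <- data.frame(Q = mr$q@Q, Q_df = mr$q@df, Q_p = mr$q@pvalue,
                       egger_intercept = mr$egger@intercept,
                       egger_intercept_p = mr$egger@interceptPvalue)

    medTab <- rgTab <- steigTab <- mvmrTab <- mediationTab <- NULL
    if (!is.null(cfg$mediator)) {
      stage <- "mediator_mr"
      instMed <- clump(medi, cfg$ld, cfg$pThreshold, cfg$r2Threshold,
                       cfg$windowBp)
      res$instruments$mediator <- instMed
      instTab <- rbind(instTab,
                       data.frame(trait = traitName(medi), k = instMed@k,
                                  r2_total = instMed@r2Total,
                                  F = instMed@fStat))
      hExpMed <- subsetSnps(harmonize(expo, medi, cfg$palindromeEafWindow),
                            snpIds(instExp))
      res$mediatorMr <- mrAll(hExpMed, nBoot = cfg$nBoot, seed = cfg$seed)
      medTab <- res$mediatorMr$table

      stage <- "mvmr"
      ## union instrument, jointly re-clumped to stay LD-independent
      unionIds <- union(snpIds(instExp), snpIds(instMed))
      combined <- expo@data[expo@data$snp_id %in% unionIds, ]
      combined$pvalue <- pmin(
        combined$pvalue,
        medi@data$pvalue[match(combined$snp_id, medi@data$snp_id)],
        na.rm = TRUE)
      comboSs <- SummaryStats(combined, "union", traitType(expo))
      instUnion <- clump(comboSs, cfg$ld, pThreshold = 1,
                         r2Threshold = cfg$r2Threshold,
                         windowBp = cfg$windowBp)
      hMv <- subsetSnps(
        harmonize(list(expo, medi), outc, cfg$palindromeEafWindow),
        snpIds(instUnion))
      mv <- mvmrFit(hMv)
      res$mvmr <- mv
      mvmrTab <- data.frame(exposure = mv@exposures, b = mv@beta,
                            se = mv@se, p = mv@pvalue, or = mv@or,
                            or_lci95 = mv@orCiLow, or_uci95 = mv@orCiHigh,
                            cond_F = mv@conditionalF, k = mv@k,
                            row.names = NULL)

      stage <- "mediation"
      med <- mediate(mr$ivw, mv, traitName(expo),
                     outcomeType = traitType(outc))
      res$mediation <- med
      mediationTab <- mediationTable(med)

      stage <- "steiger"
      res$steiger <- steigerTest(hExpMed)
      steigTab <- data.frame(
        r2_exposure = res$steiger@r2Exposure,
        r2_outcome = res$steiger@r2Outcome,
        correct_direction = res$steiger@correctDirection,
        z = res$steiger@z, p = res$steiger@pvalue,
        sensitivity = res$steiger@sensitivityRatio)
    }

    stage <- "rg"
    shared <- intersect(snpIds(expo), snpIds(outc))
    if (length(shared) >= 200) {
      e <- expo@data[match(shared, expo@data$snp_id), ]
      o <- outc@data[match(shared, outc@data$snp_id), ]
      scores <- computeLDScores(cfg$ld, shared)
      rg <- rgRegression(e$beta / e$se, o$beta / o$se,
                         stats::median(e$n), stats::median(o$n), scores)
      res$rg <- rg
      rgTab <- rgTable(rg, traitName(expo), traitName(outc))
    }

    stage <- "twostage"
    if (!is.null(cfg$cohort)) {
      prs <- prsModel(instExp, expo)
      bmiW <- if (!is.null(cfg$bmiWeightsFrom))
        prsModel(instExp, expo, weightsFrom = cfg$bmiWeightsFrom)
      res$twostage <- twoStage(cfg$cohort, prs,
                               outcome = cfg$twostageOutcome %||% "t2d",
                               bmiWeights = bmiW)
      ts <- res$twostage
      res$twostageTable <- data.frame(
        outcome = ts@outcome, stage1_F = ts@stage1F,
        nagelkerke_r2 = ts@nagelkerkeR2,
        total_b = ts@totalBeta, total_p = ts@totalP, total_or = ts@totalOr,
        direct_b = ts@adjustedBeta, direct_p = ts@adjustedP,
        direct_or = ts@adjustedOr)
    }

    stage <- "write"
    tables <- list(instruments = instTab, mr = mr$table,
                   mr_diagnostics = diag, mediator_mr = medTab,
                   mvmr = mvmrTab, mediation = mediationTab,
                   steiger = steigTab, rg = rgTab,
                   twostage = res$twostageTable,
                   harmonization_audit = res$harmonization)
    tables <- tables[!vapply(tables, is.null, TRUE)]
    res$tables <- tables
    if (!is.null(cfg$outDir)) {
      for (nm in names(tables)) .writeTsv(tables[[nm]], cfg$outDir,
                                          paste0(nm, ".tsv"))
      flat <- lapply(tables, function(t)
        lapply(as.list(t), function(col) unname(col)))
      jsonlite::write_json(flat, file.path(cfg$outDir, "estimates.json"),
                           auto_unbox = TRUE, digits = NA)
      logLines <- c(logLines,
                    sprintf("config sha %s",
                            substr(digestConfig(cfg), 1, 12)),
                    paste("stages completed:",
                          paste(names(tables), collapse = ", ")))
      writeLines(logLines, file.path(cfg$outDir, "run.log"))
    }
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

## Stable fingerprint of the run settings (no external digest dependency:
## sum of a serialized config through a small rolling hash).
digestConfig <- function(cfg) {
  keep <- cfg[c("pThreshold", "r2Threshold", "windowBp",
                "palindromeEafWindow", "nBoot", "seed")]
  raw <- serialize(keep, NULL)
  h <- 0
  for (b in as.integer(raw)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x%04x", h, length(raw) %% 65536)
}

#' One-command synthetic demonstration of the full pipeline
#'
#' Simulates a two-sample data set from the default [simulationTruth()]
#' (smoking -> BMI -> {T2D, CAD}), then runs [runPipeline()] with smoking as
#' exposure, BMI as mediator and the chosen outcome, optionally adding an
#' individual-level cohort for the 2SPS stage.
#'
#' @param seed master seed; cohort seeds derive from it.
#' @param outcome "t2d" or "cad".
#' @param n per-cohort sample size.
#' @param M SNP count (multiple of the block size).
#' @param withCohort also simulate a third, independent cohort and run the
#'   2SPS stage.
#' @param nCohort size of that cohort.
#' @param outDir optional output directory for the report bundle.
#' @return the [runPipeline()] result list, invisibly.
#' @export
pipelineDemo <- function(seed = 1L, outcome = c("t2d", "cad"), n = 20000,
                         M = 2000, withCohort = FALSE, nCohort = 20000,
                         outDir = NULL) {
  outcome <- match.arg(outcome)
  truth <- simulationTruth(M = M, seed = seed + 1000L)
  ts <- makeTwoSample(truth, nExposure = n, nOutcome = n,
                      seedExposure = seed * 2L + 1L,
                      seedOutcome = seed * 2L + 2L)
  cohort <- if (withCohort)
    simulateCohort(truth, nCohort, seed = seed * 2L + 3L)
  cfg <- list(exposure = ts$exposure$smoking_ever,
              mediator = ts$exposure$bmi_std,
              outcome = ts$outcome[[outcome]],
              ld = ts$ld, seed = seed, outDir = outDir,
              cohort = cohort,
              bmiWeightsFrom = if (withCohort) ts$exposure$bmi_std,
              twostageOutcome = outcome)
  runPipeline(cfg)
}
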