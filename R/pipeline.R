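#' Greedy unrelated-subsample construction
#'
#' Iteratively drops the individual with the most remaining relationships at
#' or above the kinship cutoff (ties broken by a seeded random choice) until
#' no related pair remains, which retains close to the maximal number of
#' individuals.
#'
#' @param cohort cohort data.frame.
#' @param pairs kinship pairs data.frame (`ID1`, `ID2`, `Kinship`).
#' @param cutoff kinship cutoff (default 0.088, second-degree relationships).
#' @param seed integer seed for tie-breaking.
#' @return The cohort restricted to the retained individuals.
#' @export
filterUnrelated <- function(cohort, pairs, cutoff = 0.088, seed = 1L) {
  rel <- pairs[pairs$Kinship >= cutoff &
                 pairs$ID1 %in% cohort$individual_id &
                 pairs$ID2 %in% cohort$individual_id, , drop = FALSE]
  if (nrow(rel) == 0) return(cohort)
  set.seed(seed)
  drop <- character()
  edges <- rel[, c("ID1", "ID2")]
  repeat {
    if (nrow(edges) == 0) break
    deg <- table(c(edges$ID1, edges$ID2))
    top <- names(deg)[deg == max(deg)]
    victim <- if (length(top) == 1) top else sample(top, 1L)
    drop <- c(drop, victim)
    edges <- edges[edges$ID1 != victim & edges$ID2 != victim, , drop = FALSE]
  }
  message(length(drop), " individual(s) removed to break ", nrow(rel),
          " related pair(s) at kinship >= ", cutoff)
  cohort[!(cohort$individual_id %in% drop), , drop = FALSE]
}

.applyFilters <- function(cohort, filters, pairs = NULL, cutoff = 0.088,
                          seed = 1L) {
  n0 <- nrow(cohort)
  if (!is.null(filters$sex))
    cohort <- cohort[cohort$sex %in% filters$sex, , drop = FALSE]
  if (!is.null(filters$birthYearRange)) {
    r <- filters$birthYearRange
    cohort <- cohort[cohort$birth_year >= r[1] & cohort$birth_year <= r[2], ,
                     drop = FALSE]
  }
  if (isTRUE(filters$unrelatedOnly) && !is.null(pairs))
    cohort <- filterUnrelated(cohort, pairs, cutoff, seed)
  if (nrow(cohort) < n0)
    message("subcohort filters: ", n0, " -> ", nrow(cohort), " individuals")
  cohort
}

.writeStage <- function(df, dir, name, cfg) {
  path <- file.path(dir, paste0(name, ".tsv"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# stage: %s (migsel %s)", name,
            as.character(utils::packageVersion("migsel"))),
    sprintf("# seed: %s", format(cfg$seed)),
    sprintf("# config_hash: %s", cfg$.hash)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.vcRow <- function(vc, extra = list()) {
  base <- data.frame(
    score = vc@scoreName, factor = vc@groupFactor, n = vc@n,
    kGroups = vc@kGroups, ssBetween = vc@ssBetween, ssWithin = vc@ssWithin,
    varCounty = vc@varCounty, fStat = vc@fStat, pAnova = vc@pAnova,
    pBonferroni = vc@pBonferroni, degenerate = vc@degenerate,
    stringsAsFactors = FALSE)
  if (length(extra)) base <- cbind(base, as.data.frame(extra))
  base
}

.regRows <- function(rr) {
  cbind(data.frame(model = rr@model, nCases = rr@nCases,
                   nControls = rr@nControls, sigmaRanef = rr@sigmaRanef,
                   stringsAsFactors = FALSE),
        resultTable(rr))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on the configured inputs
#' (or on a [SyntheticCohort-class] passed directly): covariate adjustment of
#' all scores, the per-score `Var_county` statistics for birth and residence
#' county with the joint-factor gain test and Bonferroni correction, the
#' sibling design (sibship construction, harmonization, deviations,
#' `Var_county` on deviations with its empirical null), the migration-group
#' and county contrasts, and the migration logistic regressions. Every output
#' TSV carries the seed and a config hash in comment headers.
#'
#' @param config list from [readRunConfig()], or a YAML path. Alternatively
#'   supply `synthetic` and a minimal config list.
#' @param synthetic optional [SyntheticCohort-class] used instead of file
#'   inputs.
#' @return Invisibly, a named list of the stage results; files are written
#'   under `config$outputDir`.
#' @export
runPipeline <- function(config, synthetic = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  cfg <- config
  if (is.null(cfg$stages)) cfg$stages <- list()
  stageOn <- function(s) !identical(cfg$stages[[s]], FALSE)
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  # hash the analysis-relevant settings only, so reruns into a different
  # directory are recognizably the same configuration
  cfg$.hash <- digest_ish(cfg[setdiff(names(cfg), c("outputDir", ".hash"))])

  log <- file.path(cfg$outputDir, "pipeline.log")
  logLine <- function(...) cat(..., "\n", sep = "", file = log, append = TRUE)
  cat("", file = log)
  logLine("migsel pipeline, seed ", format(cfg$seed), ", config hash ",
          cfg$.hash)

  res <- list()
  stage <- "inputs"
  tryCatch({
    if (!is.null(synthetic)) {
      cohort <- cohortTable(synthetic)
      scores <- scoreMatrix(synthetic)
      pcs <- pcMatrix(synthetic)
      pairs <- kinshipPairs(synthetic)
      vocab <- unique(c(cohort$pob_county, cohort$por_county))
      if (is.null(cfg$cityCounties))
        cfg$cityCounties <- truthRecord(synthetic)$config@cityCounties
    } else {
      vocab <- cfg$countyVocabulary
      cohort <- readCohort(cfg$inputs$cohort, vocab)
      scores <- readEigenvec(cfg$inputs$scores)
      pcs <- if (!is.null(cfg$inputs$pcs)) readEigenvec(cfg$inputs$pcs)
      pairs <- if (!is.null(cfg$inputs$kinship)) readKin0(cfg$inputs$kinship)
    }
    cityC <- unlist(cfg$cityCounties)
    if (is.null(names(cityC))) names(cityC) <- c("CityA", "CityB")
    scheme <- areaScheme(cityC, level = "county")
    cohort <- .applyFilters(cohort, cfg$filters, pairs,
                            cfg$kinshipCutoff, cfg$seed)
    keep <- cohort$individual_id
    scores <- scores[rownames(scores) %in% keep, , drop = FALSE]
    logLine("inputs: ", nrow(cohort), " individuals, ", ncol(scores),
            " scores")

    stage <- "adjust"
    adj <- scores
    if (stageOn("adjust")) {
      adj <- adjustScores(scores, cohort, pcs, nPCs = cfg$nPCs)
      prov <- attr(adj, "adjustment")
      .writeStage(data.frame(key = c("covariates", "nPCs", "driver"),
                             value = c(paste(prov$covariates, collapse = ","),
                                       prov$nPCs, prov$driver)),
                  cfg$outputDir, "adjustment_provenance", cfg)
      res$adjusted <- adj
      logLine("adjust: ", prov$nPCs, " PCs regressed out")
    }

    if (stageOn("varcounty")) {
      stage <- "varcounty"
      m <- cfg$bonferroniTests$scores
      rows <- list()
      for (s in colnames(adj)) {
        v <- adj[, s]
        ids <- rownames(adj)
        ci <- match(ids, cohort$individual_id)
        for (fac in c("POB", "POR")) {
          lab <- if (fac == "POB") cohort$pob_county[ci] else
            cohort$por_county[ci]
          vc <- varCounty(v, lab, scoreName = s, groupFactor = fac)
          vc@pBonferroni <- bonferroniAdjust(vc@pAnova, m)
          rows[[paste(s, fac)]] <- .vcRow(vc)
        }
        res$gain[[s]] <- jointGainTest(v, cohort$pob_county[ci],
                                       cohort$por_county[ci])
      }
      res$varcounty <- do.call(rbind, rows)
      .writeStage(res$varcounty, cfg$outputDir, "varcounty", cfg)
      .writeStage(do.call(rbind, lapply(names(res$gain), function(s)
        cbind(score = s, res$gain[[s]]))), cfg$outputDir,
        "varcounty_gain", cfg)
      logLine("varcounty: ", nrow(res$varcounty), " rows")
    }

    if (stageOn("sibling") && !is.null(pairs)) {
      stage <- "sibling"
      sib <- harmonizeByPob(buildSibships(pairs), cohort)
      memb <- sibshipMembers(sib)
      .writeStage(data.frame(
        sibship_id = rep(names(memb), lengths(memb)),
        individual_id = unlist(memb, use.names = FALSE),
        pob = rep(sibshipPOB(sib), lengths(memb))),
        cfg$outputDir, "sibships", cfg)
      por <- structure(cohort$por_county, names = cohort$individual_id)
      nullDist <- empiricalNull(sib, por, nSims = cfg$nNullSims,
                                seed = cfg$seed)
      writeLines(format(nullStats(nullDist), digits = 17),
                 file.path(cfg$outputDir, "sibling_null.txt"))
      rows <- list()
      for (s in colnames(adj)) {
        dev <- centerWithinSibship(structure(adj[, s],
                                             names = rownames(adj)), sib)
        lab <- por[names(dev)]
        vc <- siblingVarCounty(dev, lab, scoreName = s)
        pEmp <- empiricalP(nullDist, vc)
        rows[[s]] <- .vcRow(vc, list(
          pEmpirical = pEmp,
          pEmpiricalBonf = bonferroniAdjust(pEmp,
                                            cfg$bonferroniTests$scores)))
      }
      res$sibling <- do.call(rbind, rows)
      res$sibships <- sib
      res$siblingNull <- nullDist
      .writeStage(res$sibling, cfg$outputDir, "sibling_varcounty", cfg)
      logLine("sibling: ", length(memb), " sibships, null of ",
              cfg$nNullSims, " sims")
    }

    if (stageOn("contrasts")) {
      stage <- "contrasts"
      driver <- colnames(adj)[1]
      v <- structure(adj[, driver], names = rownames(adj))
      ci <- match(rownames(adj), cohort$individual_id)
      pobA <- assignArea(cohort$pob_county[ci], cohort$pob_city_flag[ci],
                         scheme)
      porA <- assignArea(cohort$por_county[ci], cohort$por_city_flag[ci],
                         scheme)
      grp <- classifyMigrationGroup(pobA, porA)
      res$groups <- groupStats(v, grp)
      .writeStage(res$groups, cfg$outputDir, "migration_groups", cfg)
      res$countyMeans <- countyMeansAndDelta(v, cohort)
      .writeStage(res$countyMeans, cfg$outputDir, "county_means", cfg)
      res$destination <- destinationContrastByOrigin(v, cohort, scheme)
      if (!is.null(res$destination))
        .writeStage(res$destination, cfg$outputDir,
                    "destination_contrast", cfg)
      edges <- cfg$birthYearBins
      if (is.null(edges)) {
        r <- range(cohort$birth_year)
        inner <- seq(ceiling(r[1] / 10) * 10 + 10,
                     floor(r[2] / 10) * 10 - 10, by = 10)
        edges <- sort(unique(c(r[1], inner[inner > r[1] & inner <= r[2]],
                               r[2] + 1)))
      }
      res$trend <- birthCohortTrend(v, cohort, edges, scheme)
      .writeStage(res$trend, cfg$outputDir, "birth_cohort_trend", cfg)
      logLine("contrasts: driver score ", driver)
    }

    if (stageOn("regression")) {
      stage <- "regression"
      driver <- colnames(adj)[1]
      v <- structure(adj[, driver], names = rownames(adj))
      pheno <- defineMigrationPhenotype(cohort, scheme)
      fits <- list(population_fixed =
                     fitPopulationLogistic(pheno, v, cohort))
      if (!is.null(res$sibships)) {
        fits$within_between_fixed <-
          fitWithinBetweenLogistic(pheno, v, res$sibships, cohort)
        fits$within_between_mixed <- tryCatch(
          fitWithinBetweenLogistic(pheno, v, res$sibships, cohort,
                                   mixed = TRUE),
          error = function(e) NULL)
      }
      if ("ea_years" %in% names(cohort)) {
        ea <- structure(cohort$ea_years, names = cohort$individual_id)
        fits$population_fixed_ea_years <-
          fitJointWithEA(pheno, v, ea, cohort, eaType = "years")
      }
      res$regression <- do.call(rbind, lapply(fits[!vapply(fits, is.null,
                                                           logical(1))],
                                              .regRows))
      .writeStage(res$regression, cfg$outputDir, "migration_regression", cfg)
      logLine("regression: ", length(fits), " model variants")
    }
    logLine("pipeline complete")
  }, error = function(e) {
    marker <- file.path(cfg$outputDir, "FAILED")
    writeLines(paste0("stage '", stage, "' failed: ", conditionMessage(e)),
               marker)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

# dependency-free stable hash of a configuration list; only used to stamp
# output headers so reruns with the same settings are recognizable
digest_ish <- function(x) {
  s <- paste(utils::capture.output(utils::str(x)), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 1e9
  sprintf("%09d", h)
}
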