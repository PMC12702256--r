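#' Define the ORE-to-city migration phenotype
#'
#' The binary phenotype is specified only for individuals born in ORE:
#' controls (`y = 0`) still reside in ORE, cases (`y = 1`) reside in one of
#' the two cities proper. City-county residents outside the city proper, and
#' city-county residents with a missing city flag, are ineligible.
#'
#' @param cohort cohort data.frame.
#' @param scheme an [areaScheme()]; the case definition always uses the city
#'   proper, so the scheme is applied at city level.
#' @return data.frame `individual_id`, `y` (`NA` when ineligible),
#'   `eligible`; case/control counts are reported via `message()`.
#' @export
defineMigrationPhenotype <- function(cohort, scheme) {
  citySc <- areaScheme(scheme$cityCounties, level = "city")
  pobArea <- assignArea(cohort$pob_county, cohort$pob_city_flag,
                        areaScheme(scheme$cityCounties, level = "county"))
  porArea <- assignArea(cohort$por_county, cohort$por_city_flag, citySc)
  bornOre <- pobArea == "ORE"
  y <- rep(NA_integer_, nrow(cohort))
  y[bornOre & !is.na(porArea) & porArea == "ORE"] <- 0L
  y[bornOre & !is.na(porArea) & porArea != "ORE"] <- 1L
  eligible <- !is.na(y)
  message(sum(y == 1L, na.rm = TRUE), " cases / ",
          sum(y == 0L, na.rm = TRUE), " controls; ",
          sum(!eligible), " ineligible")
  data.frame(individual_id = cohort$individual_id, y = y,
             eligible = eligible, stringsAsFactors = FALSE)
}

.coefTable <- function(est, se) {
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             z = unname(z), p = unname(p), or = exp(unname(est)),
             orLow = exp(unname(est) - 1.96 * unname(se)),
             orHigh = exp(unname(est) + 1.96 * unname(se)),
             stringsAsFactors = FALSE)
}

.checkSeparation <- function(fit) {
  mu <- stats::fitted(fit)
  if (all(mu < 1e-8 | mu > 1 - 1e-8))
    stop("complete separation: all fitted probabilities at 0/1; ",
         "largest |coefficient| = ", signif(max(abs(stats::coef(fit))), 3))
  invisible(TRUE)
}

.fitLogistic <- function(df, formulaFixed, formulaMixed, mixed, model) {
  if (length(unique(df$y)) < 2)
    stop("phenotype has no variation (need at least 1 case and 1 control)")
  sigma <- NA_real_
  if (mixed) {
    fit <- tryCatch(
      lme4::glmer(formulaMixed, data = df, family = stats::binomial(),
                  nAGQ = 10L,
                  control = lme4::glmerControl(calc.derivs = FALSE)),
      error = function(e)
        lme4::glmer(formulaMixed, data = df, family = stats::binomial(),
                    nAGQ = 1L,
                    control = lme4::glmerControl(calc.derivs = FALSE)))
    sm <- summary(fit)$coefficients
    est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
    sigma <- sqrt(unname(lme4::VarCorr(fit)$sibship[1, 1]))
    conv <- length(fit@optinfo$conv$lme4) == 0
  } else {
    fit <- stats::glm(formulaFixed, data = df, family = stats::binomial())
    if (!fit$converged)
      stop("logistic fit did not converge after ", fit$iter, " iterations")
    .checkSeparation(fit)
    sm <- summary(fit)$coefficients
    est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
    conv <- fit$converged
  }
  new("RegressionResult", coefficients = .coefTable(est, se),
      model = model, nCases = as.integer(sum(df$y == 1)),
      nControls = as.integer(sum(df$y == 0)), nObs = nrow(df),
      sigmaRanef = sigma, converged = conv)
}

.eaColumns <- function(df, ea, eaType) {
  if (eaType == "years") {
    if (length(unique(ea[!is.na(ea)])) < 2) {
      warning("EA covariate is constant; dropped from the model")
      return(df)
    }
    df$eaYears <- ea
  } else {
    f <- factor(ea)
    if (nlevels(f) < 2) {
      warning("EA covariate is constant; dropped from the model")
      return(df)
    }
    # lowest category is the reference
    bad <- vapply(levels(f), function(l) {
      yy <- df$y[f == l]
      length(unique(yy)) < 2
    }, logical(1))
    if (any(bad))
      warning("EA categor(ies) with no cases or no controls: ",
              paste(levels(f)[bad], collapse = ", "),
              "; fit proceeds, their dummies may be unstable")
    df$eaCat <- f
  }
  df
}

.assembleData <- function(pheno, score, cohort, covariates, ea = NULL,
                          eaType = "years") {
  keep <- pheno$eligible
  ids <- pheno$individual_id[keep]
  df <- data.frame(individual_id = ids, y = pheno$y[keep],
                   score = as.numeric(score[match(ids, names(score))]),
                   stringsAsFactors = FALSE)
  if (length(covariates)) {
    ci <- match(ids, cohort$individual_id)
    for (cv in covariates) df[[cv]] <- cohort[[cv]][ci]
  }
  if (!is.null(ea)) df <- .eaColumns(df, ea[match(ids, names(ea))], eaType)
  ok <- stats::complete.cases(df)
  if (any(!ok)) message(sum(!ok), " row(s) dropped from the model (missing)")
  df[ok, , drop = FALSE]
}

#' Population-level logistic regression of migration on a score
#'
#' Maximum-likelihood logistic regression of the ORE-to-city migration
#' phenotype on a polygenic score plus demographic covariates (sex and age by
#' default), reported as log-odds, odds ratios, Wald 95% CIs and p-values.
#' The mixed variant adds a sibship random intercept estimated by adaptive
#' Gauss-Hermite quadrature (10 nodes; Laplace fallback).
#'
#' @param pheno data.frame from [defineMigrationPhenotype()].
#' @param score named numeric vector (adjusted, standardized score).
#' @param cohort cohort data.frame supplying the covariates.
#' @param covariates character vector of cohort columns (default sex, age).
#' @param mixed logical; add a sibship random intercept.
#' @param sibships harmonized [SibshipSet-class], required when `mixed`;
#'   individuals outside any sibship form singleton groups.
#' @param ea optional named EA vector added as a covariate.
#' @param eaType `"years"` (linear) or `"categorical"` (dummies, lowest
#'   category as reference).
#' @return A [RegressionResult-class].
#' @export
fitPopulationLogistic <- function(pheno, score, cohort,
                                  covariates = c("sex", "age"),
                                  mixed = FALSE, sibships = NULL,
                                  ea = NULL, eaType = c("years", "categorical")) {
  eaType <- match.arg(eaType)
  df <- .assembleData(pheno, score, cohort, covariates, ea, eaType)
  covTerms <- intersect(c(covariates, "eaYears", "eaCat"), names(df))
  rhs <- paste(c("score", covTerms), collapse = " + ")
  if (mixed) {
    if (is.null(sibships)) stop("mixed model requires sibships")
    ix <- .sibIndex(sibships)
    sibId <- ix$sib[match(df$individual_id, ix$ids)]
    single <- is.na(sibId)
    sibId[single] <- max(0L, ix$sib) + seq_len(sum(single))
    df$sibship <- factor(sibId)
  }
  .fitLogistic(df,
               stats::as.formula(paste("y ~", rhs)),
               stats::as.formula(paste("y ~", rhs, "+ (1 | sibship)")),
               mixed,
               paste0("population ", if (mixed) "mixed" else "fixed",
                      "-effects logistic",
                      if (!is.null(ea)) paste0(" + EA (", eaType, ")") else ""))
}

#' Within/between-sibship logistic regression
#'
#' Decomposes the score effect on migration into a within-sibship coefficient
#' on the deviation from the sibship mean (the mean includes the individual)
#' and a between-sibship coefficient on the sibship mean. The within-family
#' estimate is free of genotype-environment correlation and parental
#' indirect-effect confounding. Fixed- and mixed-effects (sibship random
#' intercept) variants are available.
#'
#' @inheritParams fitPopulationLogistic
#' @param sibships harmonized [SibshipSet-class]; only sibship members enter.
#' @return A [RegressionResult-class] with terms `scoreDev` (within) and
#'   `scoreMean` (between).
#' @export
fitWithinBetweenLogistic <- function(pheno, score, sibships, cohort,
                                     covariates = c("sex", "age"),
                                     mixed = FALSE, ea = NULL,
                                     eaType = c("years", "categorical")) {
  eaType <- match.arg(eaType)
  ix <- .sibIndex(sibships)
  inSib <- pheno$individual_id %in% ix$ids
  ph <- pheno[inSib & pheno$eligible, , drop = FALSE]
  df <- .assembleData(ph, score, cohort, covariates, ea, eaType)
  sib <- ix$sib[match(df$individual_id, ix$ids)]
  sMean <- (rowsum(df$score, sib)[, 1] /
              tabulate(sib)[sort(unique(sib))])[match(sib, sort(unique(sib)))]
  df$scoreDev <- df$score - sMean
  df$scoreMean <- sMean
  df$sibship <- factor(sib)
  disc <- tapply(df$y, df$sibship, function(y) length(unique(y)) > 1)
  if (sum(disc, na.rm = TRUE) < 2)
    stop("need >= 2 sibships discordant on the phenotype ",
         "(within-sibship effect unidentifiable)")
  if (max(df$scoreMean) - min(df$scoreMean) == 0)
    stop("all sibship means are equal; between term collinear with intercept")
  covTerms <- intersect(c(covariates, "eaYears", "eaCat"), names(df))
  rhs <- paste(c("scoreDev", "scoreMean", covTerms), collapse = " + ")
  .fitLogistic(df,
               stats::as.formula(paste("y ~", rhs)),
               stats::as.formula(paste("y ~", rhs, "+ (1 | sibship)")),
               mixed,
               paste0("within/between-sibship ",
                      if (mixed) "mixed" else "fixed", "-effects logistic",
                      if (!is.null(ea)) paste0(" + EA (", eaType, ")") else ""))
}

#' Joint model: score and educational attainment
#'
#' Refits the population or within/between migration model with the EA
#' phenotype added as a covariate (years of education, or the reported
#' categories as dummies with the lowest as reference), so the attenuation of
#' the score coefficient can be read off against the EA-free model.
#'
#' @inheritParams fitPopulationLogistic
#' @param ea named numeric (years) or factor-like (categories) EA vector.
#' @param level `"population"` or `"within_between"`.
#' @param sibships required for `"within_between"` and for mixed fits.
#' @return A [RegressionResult-class].
#' @export
fitJointWithEA <- function(pheno, score, ea, cohort,
                           eaType = c("years", "categorical"),
                           level = c("population", "within_between"),
                           covariates = c("sex", "age"),
                           mixed = FALSE, sibships = NULL) {
  eaType <- match.arg(eaType)
  level <- match.arg(level)
  if (level == "population") {
    fitPopulationLogistic(pheno, score, cohort, covariates, mixed, sibships,
                          ea = ea, eaType = eaType)
  } else {
    fitWithinBetweenLogistic(pheno, score, sibships, cohort, covariates,
                             mixed, ea = ea, eaType = eaType)
  }
}

#' Pick one random member per sibship
#'
#' Utility for fixed-effects comparability analyses: returns the ids of one
#' seeded-random member from each sibship, so population models can be refit
#' on a sibling-derived but unrelated subsample.
#'
#' @param sibships a [SibshipSet-class].
#' @param seed integer seed.
#' @return Character vector of ids, one per sibship.
#' @export
pickOnePerSibship <- function(sibships, seed = 1L) {
  set.seed(seed)
  vapply(sibshipMembers(sibships), function(m) m[sample.int(length(m), 1L)],
         character(1))
}
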