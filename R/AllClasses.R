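#' @import methods
NULL

.checkProb <- function(p, what) {
  if (length(p) == 0 || any(!is.finite(p)) || any(p < 0))
    return(sprintf("%s must be a finite nonnegative vector", what))
  if (abs(sum(p) - 1) > 1e-12)
    return(sprintf("%s must sum to 1 (got %.15g)", what, sum(p)))
  NULL
}

#' Parameters of the synthetic-cohort generator
#'
#' Holds every knob of the generative model behind [simulateCohort()]:
#' sibship structure, county geography with two designated city counties,
#' the family/Mendelian decomposition of the latent genetic value, per-score
#' loadings on the single shared genetic component, the selective-migration
#' liability model, and the educational-attainment (EA) model. Construct with
#' [simConfig()], which supplies defaults emulating a national volunteer
#' biobank with genotype-dependent migration towards two major cities.
#'
#' @slot nSibships number of families drawn (size-1 families are unrelated
#'   singletons).
#' @slot sibshipSizeDist probability vector over sibship sizes `1..s_max`.
#' @slot nCounties number of counties (>= 3).
#' @slot countyLabels county vocabulary, length `nCounties`.
#' @slot cityCounties named character of length 2; values are county labels
#'   containing the two cities, names are the city names.
#' @slot countyWeights probability of each county as place of birth.
#' @slot varFamily,varMendelian variance of the family-level genetic value and
#'   of the within-family (Mendelian segregation) deviation; the sib-sib
#'   correlation of the true genetic value is
#'   `varFamily / (varFamily + varMendelian)`.
#' @slot scoreLoadings named loadings of each polygenic score on the shared
#'   genetic component g.
#' @slot scoreIdioVar idiosyncratic variance per score (same names).
#' @slot pcCountyShift matrix (`nCounties` x number of PCs) of county-of-birth
#'   mean offsets for the simulated principal components.
#' @slot pcNoiseSD individual-level SD around the county PC mean.
#' @slot migIntercepts baseline log-odds (vs staying) of moving to city A and
#'   city B for ORE-born individuals; `-Inf` disables a destination.
#' @slot oreIntercept baseline log-odds of a city-born individual moving to ORE.
#' @slot migBetaG log-odds of city migration per SD of the true genetic value.
#' @slot migVarEnv variance of the family-environment term shared by sibs in
#'   the migration liability.
#' @slot migEnvLoading loading of the family genetic value on the family
#'   environment term; positive values make the between-family effect exceed
#'   the within-family effect, as observed in real cohorts.
#' @slot migWithinBetween optional `c(betaWithin, betaBetween)`; when length 2
#'   the city log-odds are `bw*(g - gbar_j) + bb*gbar_j` instead of the
#'   `migBetaG` parameterization, giving an exact within/between truth.
#' @slot withinOreMoveRate probability that an ORE-born stayer is reassigned
#'   to a different ORE county (moves within ORE are ignored downstream).
#' @slot cityProperShare probability that a city-county birth/residence is in
#'   the city proper (sets the city flags).
#' @slot eaBetaG,eaVarFam,eaVarNoise generative coefficients of years of
#'   education on the EA genetic value, family environment and noise.
#' @slot eaGeneticCor genetic correlation between the EA genetic value and the
#'   migration-driving genetic value g.
#' @slot eaYearsScale years of education per liability SD.
#' @slot eaThreshold years cut-off defining the binary degree phenotype.
#' @slot demogEffects list with scalars `sex` and `age`: additive demographic
#'   effects applied to every raw score (age centred at 50).
#' @slot nDecoyPairs number of non-sibling kinship pairs emitted outside the
#'   sibling window.
#' @slot kinshipNoiseSD SD of the noise around 0.25 for sib-pair kinship.
#' @slot seed integer seed; identical config + seed gives byte-identical output.
#' @seealso [simConfig()], [simulateCohort()]
#' @export
setClass("SimulationConfig",
  representation(
    nSibships = "numeric", sibshipSizeDist = "numeric",
    nCounties = "numeric", countyLabels = "character",
    cityCounties = "character", countyWeights = "numeric",
    varFamily = "numeric", varMendelian = "numeric",
    scoreLoadings = "numeric", scoreIdioVar = "numeric",
    pcCountyShift = "matrix", pcNoiseSD = "numeric",
    migIntercepts = "numeric", oreIntercept = "numeric",
    migBetaG = "numeric", migVarEnv = "numeric", migEnvLoading = "numeric",
    migWithinBetween = "numeric",
    withinOreMoveRate = "numeric", cityProperShare = "numeric",
    eaBetaG = "numeric", eaVarFam = "numeric", eaVarNoise = "numeric",
    eaGeneticCor = "numeric", eaYearsScale = "numeric", eaThreshold = "numeric",
    demogEffects = "list",
    nDecoyPairs = "numeric", kinshipNoiseSD = "numeric",
    seed = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  add <- function(m) if (!is.null(m)) msgs <<- c(msgs, m)
  add(.checkProb(object@sibshipSizeDist, "sibshipSizeDist"))
  add(.checkProb(object@countyWeights, "countyWeights"))
  if (object@nCounties < 3)
    add("nCounties must be >= 3 (two city counties plus at least one ORE county)")
  if (length(object@countyLabels) != object@nCounties)
    add("countyLabels length must equal nCounties")
  if (anyDuplicated(object@countyLabels))
    add("countyLabels must be unique")
  if (length(object@cityCounties) != 2 ||
      !all(object@cityCounties %in% object@countyLabels))
    add("cityCounties must name exactly 2 labels drawn from countyLabels")
  if (length(object@countyWeights) != object@nCounties)
    add("countyWeights length must equal nCounties")
  for (v in c("varFamily", "varMendelian", "migVarEnv", "eaVarFam",
              "eaVarNoise", "pcNoiseSD", "kinshipNoiseSD")) {
    if (any(slot(object, v) < 0)) add(sprintf("%s must be >= 0", v))
  }
  if (length(object@scoreLoadings) == 0 || is.null(names(object@scoreLoadings)))
    add("scoreLoadings must be a named numeric vector")
  if (!identical(names(object@scoreLoadings), names(object@scoreIdioVar)))
    add("scoreIdioVar must carry the same names as scoreLoadings")
  if (any(object@scoreIdioVar < 0)) add("scoreIdioVar must be >= 0")
  if (nrow(object@pcCountyShift) != object@nCounties)
    add("pcCountyShift must have one row per county")
  if (length(object@migIntercepts) != 2)
    add("migIntercepts must have length 2 (city A, city B)")
  if (!(length(object@migWithinBetween) %in% c(0L, 2L)))
    add("migWithinBetween must be empty or c(betaWithin, betaBetween)")
  if (object@withinOreMoveRate < 0 || object@withinOreMoveRate > 1)
    add("withinOreMoveRate must lie in [0, 1]")
  if (object@cityProperShare < 0 || object@cityProperShare > 1)
    add("cityProperShare must lie in [0, 1]")
  if (abs(object@eaGeneticCor) > 1)
    add("eaGeneticCor must lie in [-1, 1]")
  if (!all(c("sex", "age") %in% names(object@demogEffects)))
    add("demogEffects must contain elements 'sex' and 'age'")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' A simulated cohort with its generating truth
#'
#' Returned by [simulateCohort()]. Bundles the cohort table, the score and PC
#' matrices (rows named by individual id), the pairwise kinship list, and a
#' truth record holding the generator's latent quantities. The truth record is
#' for validation only and is never consumed by the analysis functions.
#'
#' @slot cohort data.frame, one row per individual (see [readCohort()] for the
#'   column contract).
#' @slot scores numeric matrix, individuals x scores.
#' @slot pcs numeric matrix, individuals x principal components.
#' @slot kinship data.frame with columns `ID1`, `ID2`, `Kinship`.
#' @slot truth list: true effect sizes, per-individual genetic value `g`,
#'   sibship assignment, and the config used.
#' @export
setClass("SyntheticCohort",
  representation(cohort = "data.frame", scores = "matrix", pcs = "matrix",
                 kinship = "data.frame", truth = "list")
)

setValidity("SyntheticCohort", function(object) {
  ids <- object@cohort$individual_id
  if (anyDuplicated(ids)) return("individual ids must be unique")
  if (!identical(rownames(object@scores), ids))
    return("score matrix rows must align with the cohort")
  TRUE
})

#' Disjoint sibships derived from kinship pairs
#'
#' Connected components of the graph of retained kinship pairs (see
#' [buildSibships()]), optionally harmonized so that every sibship shares a
#' single county of birth ([harmonizeByPob()]). Every sibship has >= 2 members.
#'
#' @slot members named list; each element is a character vector of member ids.
#' @slot pob shared county of birth per sibship (`NA` before harmonization).
#' @export
setClass("SibshipSet",
  representation(members = "list", pob = "character")
)

setValidity("SibshipSet", function(object) {
  if (length(object@members) != length(object@pob))
    return("one pob entry per sibship required")
  sizes <- lengths(object@members)
  if (any(sizes < 2)) return("every sibship must have >= 2 members")
  all_ids <- unlist(object@members, use.names = FALSE)
  if (anyDuplicated(all_ids)) return("sibships must be disjoint")
  TRUE
})

#' Between-county variance partition of one variable
#'
#' Result of [varCounty()] or [siblingVarCounty()]: the sums of squares
#' between and within counties, the statistic `SSB / (SSB + SSW)`, and the
#' one-way ANOVA F test.
#'
#' @slot scoreName variable label.
#' @slot groupFactor grouping factor label, typically `"POB"` or `"POR"`.
#' @slot ssBetween,ssWithin between- and within-group sums of squares.
#' @slot varCounty the statistic `SSB / (SSB + SSW)`, in `[0, 1]`.
#' @slot n,kGroups sample size and number of non-empty groups.
#' @slot fStat,df,pAnova F statistic, its `(k-1, n-k)` degrees of freedom and
#'   ANOVA p-value.
#' @slot pBonferroni Bonferroni-adjusted p for a declared test count (`NA`
#'   until [bonferroniAdjust()] is applied).
#' @slot degenerate TRUE when total SS is zero and the statistic is defined
#'   as 0 by convention.
#' @export
setClass("VarCountyResult",
  representation(scoreName = "character", groupFactor = "character",
                 ssBetween = "numeric", ssWithin = "numeric",
                 varCounty = "numeric", n = "integer", kGroups = "integer",
                 fStat = "numeric", df = "numeric", pAnova = "numeric",
                 pBonferroni = "numeric", degenerate = "logical")
)

setValidity("VarCountyResult", function(object) {
  if (!is.na(object@varCounty) &&
      (object@varCounty < -1e-12 || object@varCounty > 1 + 1e-12))
    return("varCounty must lie in [0, 1]")
  TRUE
})

#' Simulated null distribution of the sibling-design statistic
#'
#' Null distribution of `Var_county` computed on iid standard-normal variables
#' pushed through the same within-sibship centering and grouping as the real
#' scores (see [empiricalNull()]). The empirical p-value of an observed
#' statistic is `(r + 1) / (nSims + 1)` with `r` the number of null statistics
#' strictly greater than it ([empiricalP()]).
#'
#' @slot nSims number of simulated variables.
#' @slot seed seed used.
#' @slot stats the `nSims` simulated `Var_county` values.
#' @export
setClass("EmpiricalNull",
  representation(nSims = "integer", seed = "numeric", stats = "numeric")
)

setValidity("EmpiricalNull", function(object) {
  if (length(object@stats) != object@nSims)
    return("stats must hold exactly nSims values")
  TRUE
})

#' Logistic-regression result for the migration phenotype
#'
#' Coefficient table of a population-level or within/between-sibship logistic
#' model of city migration, with odds ratios, Wald 95% intervals and p-values;
#' mixed variants carry the sibship random-intercept SD.
#'
#' @slot coefficients data.frame with columns `term`, `estimate`, `se`, `z`,
#'   `p`, `or`, `orLow`, `orHigh`.
#' @slot model description of the fitted variant.
#' @slot nCases,nControls,nObs counts of cases, controls and fitted rows.
#' @slot sigmaRanef random-intercept SD (`NA` for fixed-effects fits).
#' @slot converged logical convergence flag.
#' @export
setClass("RegressionResult",
  representation(coefficients = "data.frame", model = "character",
                 nCases = "integer", nControls = "integer", nObs = "integer",
                 sigmaRanef = "numeric", converged = "logical")
)

setValidity("RegressionResult", function(object) {
  cc <- object@coefficients
  need <- c("term", "estimate", "se", "z", "p", "or", "orLow", "orHigh")
  if (!all(need %in% names(cc)))
    return("coefficient table is missing required columns")
  ok <- stats::complete.cases(cc[, c("or", "orLow", "orHigh")])
  if (any(cc$or[ok] <= 0)) return("odds ratios must be positive")
  if (any(cc$orLow[ok] > cc$or[ok] | cc$orHigh[ok] < cc$or[ok]))
    return("confidence interval must contain the odds ratio")
  TRUE
})
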