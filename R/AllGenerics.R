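#' Accessors for migsel S4 containers
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `cohortTable()`, `scoreMatrix()`, `pcMatrix()`, `kinshipPairs()` and
#' `truthRecord()` unpack a [SyntheticCohort-class]; `sibshipMembers()` and
#' `sibshipPOB()` a [SibshipSet-class]; `varCountyStat()`, `ssBetween()`,
#' `ssWithin()` and `pValue()` a [VarCountyResult-class]; `nullStats()` an
#' [EmpiricalNull-class]; `resultTable()` and `oddsRatios()` a
#' [RegressionResult-class].
#'
#' @param x the object.
#' @return The corresponding slot content (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cohortTable", function(x) standardGeneric("cohortTable"))
#' @rdname accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))
#' @rdname accessors
#' @export
setGeneric("pcMatrix", function(x) standardGeneric("pcMatrix"))
#' @rdname accessors
#' @export
setGeneric("kinshipPairs", function(x) standardGeneric("kinshipPairs"))
#' @rdname accessors
#' @export
setGeneric("truthRecord", function(x) standardGeneric("truthRecord"))
#' @rdname accessors
#' @export
setGeneric("sibshipMembers", function(x) standardGeneric("sibshipMembers"))
#' @rdname accessors
#' @export
setGeneric("sibshipPOB", function(x) standardGeneric("sibshipPOB"))
#' @rdname accessors
#' @export
setGeneric("varCountyStat", function(x) standardGeneric("varCountyStat"))
#' @rdname accessors
#' @export
setGeneric("ssBetween", function(x) standardGeneric("ssBetween"))
#' @rdname accessors
#' @export
setGeneric("ssWithin", function(x) standardGeneric("ssWithin"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("nullStats", function(x) standardGeneric("nullStats"))
#' @rdname accessors
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))
#' @rdname accessors
#' @export
setGeneric("oddsRatios", function(x) standardGeneric("oddsRatios"))

#' @rdname accessors
#' @export
setMethod("cohortTable", "SyntheticCohort", function(x) x@cohort)
#' @rdname accessors
#' @export
setMethod("scoreMatrix", "SyntheticCohort", function(x) x@scores)
#' @rdname accessors
#' @export
setMethod("pcMatrix", "SyntheticCohort", function(x) x@pcs)
#' @rdname accessors
#' @export
setMethod("kinshipPairs", "SyntheticCohort", function(x) x@kinship)
#' @rdname accessors
#' @export
setMethod("truthRecord", "SyntheticCohort", function(x) x@truth)

#' @rdname accessors
#' @export
setMethod("sibshipMembers", "SibshipSet", function(x) x@members)
#' @rdname accessors
#' @export
setMethod("sibshipPOB", "SibshipSet", function(x) x@pob)

#' @rdname accessors
#' @export
setMethod("varCountyStat", "VarCountyResult", function(x) x@varCounty)
#' @rdname accessors
#' @export
setMethod("ssBetween", "VarCountyResult", function(x) x@ssBetween)
#' @rdname accessors
#' @export
setMethod("ssWithin", "VarCountyResult", function(x) x@ssWithin)
#' @rdname accessors
#' @export
setMethod("pValue", "VarCountyResult", function(x) x@pAnova)

#' @rdname accessors
#' @export
setMethod("nullStats", "EmpiricalNull", function(x) x@stats)

#' @rdname accessors
#' @export
setMethod("resultTable", "RegressionResult", function(x) x@coefficients)
#' @rdname accessors
#' @export
setMethod("oddsRatios", "RegressionResult", function(x) {
  cc <- x@coefficients
  structure(cc$or, names = cc$term)
})

#' @importFrom methods show slot slotNames new validObject is
NULL

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nSibships, "sibships,",
      object@nCounties, "counties (cities:",
      paste(sprintf("%s=%s", names(object@cityCounties), object@cityCounties),
            collapse = ", "), ")\n")
  cat("  scores:", paste(names(object@scoreLoadings), collapse = ", "), "\n")
  if (length(object@migWithinBetween) == 2) {
    cat(sprintf("  migration: betaWithin=%.3g betaBetween=%.3g\n",
                object@migWithinBetween[1], object@migWithinBetween[2]))
  } else {
    cat(sprintf("  migration: betaG=%.3g envLoading=%.3g varEnv=%.3g\n",
                object@migBetaG, object@migEnvLoading, object@migVarEnv))
  }
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", nrow(object@cohort), "individuals,",
      ncol(object@scores), "scores,", ncol(object@pcs), "PCs,",
      nrow(object@kinship), "kinship pairs\n")
})

setMethod("show", "SibshipSet", function(object) {
  sizes <- lengths(object@members)
  cat("SibshipSet:", length(sizes), "sibships,", sum(sizes), "individuals",
      sprintf("(sizes %d..%d)", if (length(sizes)) min(sizes) else 0L,
              if (length(sizes)) max(sizes) else 0L), "\n")
  if (all(is.na(object@pob))) cat("  not yet harmonized by county of birth\n")
})

setMethod("show", "VarCountyResult", function(object) {
  cat(sprintf("VarCountyResult [%s ~ %s]: Var_county = %.4g (SSB=%.4g, SSW=%.4g)\n",
              object@scoreName, object@groupFactor, object@varCounty,
              object@ssBetween, object@ssWithin))
  cat(sprintf("  n=%d, k=%d, F=%.4g, p=%.3g%s%s\n", object@n, object@kGroups,
              object@fStat, object@pAnova,
              if (!is.na(object@pBonferroni))
                sprintf(", p_Bonf=%.3g", object@pBonferroni) else "",
              if (object@degenerate) " [degenerate: zero total SS]" else ""))
})

setMethod("show", "EmpiricalNull", function(object) {
  cat(sprintf("EmpiricalNull: %d simulated Var_county values (seed %s), range [%.3g, %.3g]\n",
              object@nSims, format(object@seed), min(object@stats),
              max(object@stats)))
})

setMethod("show", "RegressionResult", function(object) {
  cat("RegressionResult:", object@model, "\n")
  cat(sprintf("  %d cases / %d controls (n=%d)%s%s\n",
              object@nCases, object@nControls, object@nObs,
              if (!is.na(object@sigmaRanef))
                sprintf(", sibship ranef SD=%.3g", object@sigmaRanef) else "",
              if (!object@converged) " [NOT CONVERGED]" else ""))
  cc <- object@coefficients
  print(data.frame(term = cc$term, OR = round(cc$or, 3),
                   ci = sprintf("[%.3f; %.3f]", cc$orLow, cc$orHigh),
                   p = signif(cc$p, 3)), row.names = FALSE)
})
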