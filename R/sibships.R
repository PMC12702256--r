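#' Build sibships from pairwise kinship estimates
#'
#' Retains kinship pairs inside the full-sibling window
#' `lower < kinship < upper` (defaults 0.177 and 0.354) and returns the
#' connected components of the retained pair graph as sibships: the sib
#' relation is taken as transitive, so any chain of sib pairs merges into one
#' sibship.
#'
#' @param pairs data.frame with columns `ID1`, `ID2`, `Kinship` (kin0-style;
#'   see [readKin0()]).
#' @param lower,upper open kinship window for full siblings.
#' @return A [SibshipSet-class] with `NA` birth counties (call
#'   [harmonizeByPob()] next).
#' @examples
#' p <- data.frame(ID1 = c("A", "B", "D"), ID2 = c("B", "C", "E"),
#'                 Kinship = c(0.25, 0.25, 0.40))
#' sibshipMembers(buildSibships(p))   # {A,B,C}; D-E excluded (0.40 > 0.354)
#' @export
buildSibships <- function(pairs, lower = 0.177, upper = 0.354) {
  stopifnot(all(c("ID1", "ID2", "Kinship") %in% names(pairs)))
  if (!(0 < lower && lower < upper))
    stop("thresholds must satisfy 0 < lower < upper")
  if (any(pairs$ID1 == pairs$ID2)) stop("self-pairs are not allowed")
  keep <- pairs$Kinship > lower & pairs$Kinship < upper
  kept <- pairs[keep, , drop = FALSE]
  if (nrow(kept) == 0) {
    warning("no kinship pair falls in the sibling window (", lower, ", ",
            upper, "); empty sibship set")
    return(new("SibshipSet", members = list(), pob = character()))
  }
  g <- igraph::graph_from_data_frame(kept[, c("ID1", "ID2")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  ids <- igraph::V(g)$name
  members <- split(ids, comp$membership)
  names(members) <- sprintf("S%05d", seq_along(members))
  new("SibshipSet", members = members,
      pob = rep(NA_character_, length(members)))
}

#' Enforce the shared-birthplace rule on sibships
#'
#' Partitions every sibship by county of birth: subgroups of two or more
#' members with the same POB become (possibly new) sibships, while members
#' whose POB is unique within their sibship are dropped, since their deviation
#' from a size-1 sibship mean is identically zero and contributes nothing.
#'
#' @param sibships a [SibshipSet-class] from [buildSibships()].
#' @param cohort cohort data.frame with `individual_id` and `pob_county`.
#' @return A [SibshipSet-class] with the shared `pob` filled per sibship.
#' @export
harmonizeByPob <- function(sibships, cohort) {
  members <- sibshipMembers(sibships)
  allIds <- unlist(members, use.names = FALSE)
  pos <- match(allIds, cohort$individual_id)
  if (anyNA(pos))
    stop("sibship member(s) missing from cohort: ",
         paste(utils::head(allIds[is.na(pos)], 10), collapse = ", "))
  pobAll <- structure(cohort$pob_county[pos], names = allIds)
  outMembers <- list()
  outPob <- character()
  for (memb in members) {
    groups <- split(memb, pobAll[memb])
    for (cty in names(groups)) {
      if (length(groups[[cty]]) >= 2) {
        outMembers[[length(outMembers) + 1L]] <- groups[[cty]]
        outPob <- c(outPob, cty)
      }
    }
  }
  names(outMembers) <- if (length(outMembers))
    sprintf("S%05d", seq_along(outMembers)) else character()
  new("SibshipSet", members = outMembers, pob = outPob)
}

# integer sibship index per member id, plus aligned bookkeeping
.sibIndex <- function(sibships) {
  members <- sibshipMembers(sibships)
  ids <- unlist(members, use.names = FALSE)
  list(ids = ids,
       sib = rep.int(seq_along(members), lengths(members)),
       sizes = lengths(members))
}

#' Deviations from the sibship mean
#'
#' Subtracts from each sibship member's value the mean over the whole sibship
#' (the mean includes the individual, regardless of sibship size). Only
#' members of a sibship receive deviations; sibships containing a missing
#' value are excluded entirely and reported.
#'
#' @param values named numeric vector covering the sibship members.
#' @param sibships a [SibshipSet-class] (harmonized by POB for downstream use).
#' @return Named numeric vector of deviations, one entry per retained member;
#'   the retained sibship index is attached as attribute `"sibship"`.
#' @examples
#' s <- new("SibshipSet", members = list(S1 = c("a", "b")), pob = "X")
#' centerWithinSibship(c(a = 2, b = 4), s)   # -1, +1
#' @export
centerWithinSibship <- function(values, sibships) {
  ix <- .sibIndex(sibships)
  v <- values[match(ix$ids, names(values))]
  sibNA <- unique(ix$sib[is.na(v)])
  if (length(sibNA)) {
    message(length(sibNA),
            " sibship(s) excluded from centering (missing values)")
    keep <- !(ix$sib %in% sibNA)
    ix$ids <- ix$ids[keep]; ix$sib <- ix$sib[keep]; v <- v[keep]
  }
  if (!length(v)) return(structure(numeric(0), sibship = integer(0)))
  m <- (rowsum(v, ix$sib)[, 1] / tabulate(ix$sib)[sort(unique(ix$sib))])
  dev <- v - m[match(ix$sib, sort(unique(ix$sib)))]
  structure(dev, names = ix$ids, sibship = ix$sib)
}

#' Variance partition of sibship deviations by county
#'
#' Applies the `Var_county` statistic to within-sibship deviations, grouped by
#' county of residence (or, as a design check, by county of birth, where the
#' statistic is exactly zero because every sibship is POB-homogeneous and
#' centered). All-zero deviations give a degenerate result with statistic 0.
#'
#' @param deviations named vector from [centerWithinSibship()].
#' @param labels county labels aligned with `deviations` (either named, or in
#'   the same order).
#' @param scoreName,groupFactor labels stored in the result.
#' @details When every sibship lies entirely inside one group -- as it does
#'   when grouping by the shared county of birth -- each group total of the
#'   deviations is a sum of whole-sibship sums, all of which vanish by
#'   construction, so the between-group sum of squares is identically zero.
#'   This identity is applied exactly (SSB = 0, statistic = 0) rather than
#'   left to floating-point cancellation.
#' @return A [VarCountyResult-class].
#' @export
siblingVarCounty <- function(deviations, labels, scoreName = "deviation",
                             groupFactor = "POR") {
  if (!is.null(names(labels)))
    labels <- labels[match(names(deviations), names(labels))]
  sib <- attr(deviations, "sibship")
  if (!is.null(sib)) {
    homogeneous <- all(vapply(split(labels, sib),
                              function(l) length(unique(l)) == 1L,
                              logical(1)))
    if (homogeneous) {
      ssw <- sum(as.numeric(deviations)^2)
      k <- length(unique(labels))
      n <- length(deviations)
      return(new("VarCountyResult", scoreName = scoreName,
                 groupFactor = groupFactor, ssBetween = 0, ssWithin = ssw,
                 varCounty = 0, n = as.integer(n), kGroups = as.integer(k),
                 fStat = 0, df = c(k - 1, n - k), pAnova = 1,
                 pBonferroni = NA_real_, degenerate = ssw == 0))
    }
  }
  varCounty(as.numeric(deviations), labels, scoreName = scoreName,
            groupFactor = groupFactor)
}

#' Simulated empirical null for the sibling-design statistic
#'
#' Under the sibling design the statistic does not follow the standard ANOVA
#' F distribution, so significance is judged against a simulation null: each
#' simulation draws one independent standard-normal value per individual,
#' pushes it through the same within-sibship centering and county grouping as
#' the real scores, and records `Var_county`. The null depends only on the
#' sibship/label structure and is therefore computed once and reused across
#' all scores.
#'
#' @param sibships harmonized [SibshipSet-class].
#' @param porLabels named county-of-residence labels covering all members.
#' @param nSims number of simulated variables (default 10140).
#' @param seed integer seed; fixed seed gives a deterministic null.
#' @return An [EmpiricalNull-class].
#' @seealso [empiricalP()]
#' @export
empiricalNull <- function(sibships, porLabels, nSims = 10140, seed = 1L) {
  if (nSims < 1) stop("nSims must be >= 1")
  ix <- .sibIndex(sibships)
  n <- length(ix$ids)
  if (n == 0) stop("empty sibship set")
  por <- porLabels[match(ix$ids, names(porLabels))]
  if (anyNA(por)) stop("porLabels must cover every sibship member")
  porF <- factor(por)
  set.seed(seed)
  out <- numeric(nSims)
  done <- 0L
  batch <- max(1L, min(nSims, floor(5e6 / n)))
  while (done < nSims) {
    b <- min(batch, nSims - done)
    x <- matrix(stats::rnorm(n * b), n, b)
    devs <- x - (rowsum(x, ix$sib) / ix$sizes)[ix$sib, , drop = FALSE]
    # deviations sum to zero within sibship, so the grand mean is exactly 0
    sst <- colSums(devs^2)
    grp <- rowsum(devs, porF)
    ng <- tabulate(porF)
    ssb <- colSums(grp^2 / ng)
    out[done + seq_len(b)] <- ifelse(sst == 0, 0, ssb / sst)
    done <- done + b
  }
  new("EmpiricalNull", nSims = as.integer(nSims), seed = seed, stats = out)
}

#' Empirical p-value against a simulated null
#'
#' `p = (r + 1) / (nSims + 1)` where `r` is the number of null statistics
#' strictly greater than the observed one; a statistic exceeding every null
#' value gets the smallest attainable p, `1 / (nSims + 1)`.
#'
#' @param null an [EmpiricalNull-class].
#' @param statistic observed `Var_county` (a number or a
#'   [VarCountyResult-class]).
#' @return The empirical p-value.
#' @examples
#' nl <- new("EmpiricalNull", nSims = 4L, seed = 1, stats = c(.1, .2, .3, .4))
#' empiricalP(nl, 0.35)   # (1+1)/(4+1)
#' @export
empiricalP <- function(null, statistic) {
  stopifnot(is(null, "EmpiricalNull"))
  if (is(statistic, "VarCountyResult")) statistic <- varCountyStat(statistic)
  r <- sum(nullStats(null) > statistic)
  (r + 1) / (null@nSims + 1)
}
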