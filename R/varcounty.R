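#' Proportion of variance explained by county grouping
#'
#' The variance-partition statistic `Var_county = SSB / (SSB + SSW)`, where
#' `SSB = sum_c n_c (ybar_c - ybar)^2` is the between-county sum of squares
#' and `SSW = sum_c sum_i (y_ci - ybar_c)^2` the within-county sum. The
#' statistic equals the R-squared of the one-way dummy-coded linear model;
#' significance comes from the one-way ANOVA F test with `(k - 1, n - k)`
#' degrees of freedom.
#'
#' When the total sum of squares is zero (constant input) the statistic is
#' defined as 0 and the result is flagged degenerate with `p = 1`.
#'
#' @param values numeric vector (missing entries dropped pairwise with their
#'   labels).
#' @param labels county labels, same length as `values`.
#' @param scoreName,groupFactor labels stored in the result.
#' @return A [VarCountyResult-class].
#' @examples
#' r <- varCounty(c(1, 2, 3, 4), c("A", "A", "B", "B"))
#' varCountyStat(r)   # 0.8: SSB = 4, SSW = 1
#' @export
varCounty <- function(values, labels, scoreName = "value",
                      groupFactor = "county") {
  if (length(values) != length(labels))
    stop("values and labels must have equal length")
  bad <- which(is.na(labels) | labels == "")
  if (length(bad))
    stop("empty/missing county label at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  ok <- !is.na(values)
  y <- values[ok]
  f <- factor(labels[ok])
  k <- nlevels(f)
  n <- length(y)
  if (k < 2) stop("need at least 2 non-empty groups (got ", k, ")")
  if (n <= k) stop("need more observations than groups")
  gm <- tapply(y, f, mean)
  nc <- tabulate(f)
  ssb <- sum(nc * (gm - mean(y))^2)
  ssw <- sum((y - gm[f])^2)
  tot <- ssb + ssw
  degenerate <- tot == 0
  vc <- if (degenerate) 0 else ssb / tot
  fstat <- if (degenerate || ssw == 0) {
    if (degenerate) 0 else Inf
  } else (ssb / (k - 1)) / (ssw / (n - k))
  p <- if (degenerate) 1 else
    stats::pf(fstat, k - 1, n - k, lower.tail = FALSE)
  new("VarCountyResult", scoreName = scoreName, groupFactor = groupFactor,
      ssBetween = ssb, ssWithin = ssw, varCounty = vc,
      n = as.integer(n), kGroups = as.integer(k), fStat = fstat,
      df = c(k - 1, n - k), pAnova = p, pBonferroni = NA_real_,
      degenerate = degenerate)
}

#' Bonferroni correction for a declared number of tests
#'
#' Element-wise `min(1, m * p)` via [stats::p.adjust()], with `m` the declared
#' family size (e.g. 100 PCs or 169 polygenic scores), which may exceed the
#' number of p-values supplied.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param m declared test count, `m >= length(p)`.
#' @return Adjusted p-values.
#' @examples
#' bonferroniAdjust(1e-4, 100)          # 0.01
#' bonferroniAdjust(3 / 10141, 169)     # ~0.05
#' @export
bonferroniAdjust <- function(p, m) {
  if (length(m) != 1 || !is.finite(m) || m <= 0)
    stop("m must be a single positive test count")
  if (m < length(p)) stop("m must be at least the number of p-values")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "bonferroni", n = m)
}

.gaussLogLik <- function(fit) {
  # ML (not REML) Gaussian log-likelihood of an lm-style residual vector
  r <- stats::resid(fit)
  n <- length(r)
  -n / 2 * (log(2 * pi) + log(sum(r^2) / n) + 1)
}

#' Joint-factor gain test for birth vs residence county
#'
#' Tests whether county of birth and county of residence together explain
#' significantly more variance than either factor alone. Fits the Gaussian
#' linear models `values ~ POB`, `values ~ POR` and `values ~ POB + POR`
#' (dummy coding) and compares the joint model to each single-factor model by
#' the likelihood-ratio chi-square `-2 * delta logLik` with degrees of freedom
#' equal to the number of estimable parameters added. Also reports which
#' factor is the weaker predictor (smaller single-factor `Var_county`), the
#' rule used when annotating per-score displays.
#'
#' @param values numeric vector.
#' @param pobLabels,porLabels county label vectors.
#' @return A one-row data.frame with the single-factor statistics, both gain
#'   chi-squares with df and p-values, the weaker factor, and a flag set when
#'   the two label vectors are identical (gain 0 by construction).
#' @examples
#' set.seed(1)
#' pob <- sample(LETTERS[1:4], 200, TRUE)
#' por <- sample(LETTERS[1:4], 200, TRUE)
#' y <- rnorm(200) + (por == "A")
#' jointGainTest(y, pob, por)
#' @export
jointGainTest <- function(values, pobLabels, porLabels) {
  ok <- !is.na(values)
  y <- values[ok]
  pob <- factor(pobLabels[ok])
  por <- factor(porLabels[ok])
  vcB <- varCounty(y, as.character(pob), groupFactor = "POB")
  vcR <- varCounty(y, as.character(por), groupFactor = "POR")
  identicalLabels <- identical(as.character(pob), as.character(por))
  fitB <- stats::lm(y ~ pob)
  fitR <- stats::lm(y ~ por)
  fitJ <- stats::lm(y ~ pob + por)
  llB <- .gaussLogLik(fitB); llR <- .gaussLogLik(fitR)
  llJ <- .gaussLogLik(fitJ)
  dfJ <- fitJ$rank
  chiB <- max(0, -2 * (llB - llJ))
  chiR <- max(0, -2 * (llR - llJ))
  dfGainB <- dfJ - fitB$rank
  dfGainR <- dfJ - fitR$rank
  pGainB <- if (dfGainB > 0)
    stats::pchisq(chiB, dfGainB, lower.tail = FALSE) else 1
  pGainR <- if (dfGainR > 0)
    stats::pchisq(chiR, dfGainR, lower.tail = FALSE) else 1
  if (identicalLabels) { chiB <- chiR <- 0; pGainB <- pGainR <- 1 }
  data.frame(
    varCountyPOB = varCountyStat(vcB), varCountyPOR = varCountyStat(vcR),
    chisqGainOverPOB = chiB, dfGainOverPOB = dfGainB, pGainOverPOB = pGainB,
    chisqGainOverPOR = chiR, dfGainOverPOR = dfGainR, pGainOverPOR = pGainR,
    weakerFactor = if (varCountyStat(vcB) <= varCountyStat(vcR)) "POB" else "POR",
    identicalLabels = identicalLabels,
    stringsAsFactors = FALSE)
}

#' Paired bootstrap for the POB-POR difference in Var_county
#'
#' Resamples individuals with replacement and recomputes `Var_county` under
#' both groupings, giving a bootstrap distribution of the difference
#' `Var_county(POB) - Var_county(POR)` for one score. This backs statements
#' that one grouping explains significantly more variance than the other.
#'
#' @param values numeric vector.
#' @param pobLabels,porLabels county labels.
#' @param nBoot number of resamples.
#' @param seed integer seed.
#' @return List with the observed difference, the bootstrap differences, a
#'   percentile 95% CI and a two-sided bootstrap p-value for difference 0.
#' @export
varCountyDiffBootstrap <- function(values, pobLabels, porLabels,
                                   nBoot = 1000, seed = 1L) {
  ok <- !is.na(values)
  y <- values[ok]; pob <- pobLabels[ok]; por <- porLabels[ok]
  obs <- varCountyStat(varCounty(y, pob)) - varCountyStat(varCounty(y, por))
  set.seed(seed)
  boot <- vapply(seq_len(nBoot), function(i) {
    idx <- sample.int(length(y), replace = TRUE)
    varCountyStat(varCounty(y[idx], pob[idx])) -
      varCountyStat(varCounty(y[idx], por[idx]))
  }, numeric(1))
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  p <- 2 * min(mean(boot <= 0), mean(boot >= 0))
  list(observed = obs, boot = boot, ci95 = ci, p = min(1, p))
}
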