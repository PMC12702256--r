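#' Demographic covariate design for score adjustment
#'
#' Builds the covariate design used before every analysis: intercept, sex,
#' age, sex x age interaction and age squared, aligned with the cohort rows.
#' Rows with missing sex or age are excluded and reported.
#'
#' @param cohort cohort data.frame with columns `individual_id`, `sex`, `age`.
#' @return Numeric matrix with columns `intercept`, `sex`, `age`, `sexAge`,
#'   `ageSq` and rownames the retained individual ids; the excluded ids are
#'   attached as attribute `"excluded"`.
#' @examples
#' co <- data.frame(individual_id = c("a", "b"), sex = c(1, 0), age = c(10, 20))
#' buildCovariates(co)
#' @export
buildCovariates <- function(cohort) {
  stopifnot(all(c("individual_id", "sex", "age") %in% names(cohort)))
  ok <- !is.na(cohort$sex) & !is.na(cohort$age)
  if (!any(ok)) {
    stop("no rows with non-missing sex and age; excluded ids: ",
         paste(utils::head(cohort$individual_id, 10), collapse = ", "),
         if (nrow(cohort) > 10) ", ..." else "")
  }
  if (any(!ok)) {
    message(sum(!ok), " row(s) dropped from the covariate design ",
            "(missing sex or age)")
  }
  x <- cohort[ok, ]
  out <- cbind(intercept = 1, sex = x$sex, age = x$age,
               sexAge = x$sex * x$age, ageSq = x$age^2)
  rownames(out) <- x$individual_id
  attr(out, "excluded") <- cohort$individual_id[!ok]
  out
}

#' Residualize and standardize a variable
#'
#' Ordinary least-squares residuals of `values` on the covariate design,
#' optionally augmented with principal-component columns and with a driver
#' score to be regressed out, then divided by their standard deviation. This
#' is the adjustment applied to every polygenic score and to quantitative
#' phenotypes before analysis: residuals are exactly orthogonal to every
#' fitted column and come back with mean 0 and SD 1.
#'
#' Rows are matched by name; rows missing any fitted column or the value are
#' dropped (complete-case) and returned as `NA`, with a message.
#'
#' @param values named numeric vector.
#' @param covariates design matrix from [buildCovariates()] (or any numeric
#'   matrix with an intercept column and rownames).
#' @param pcs optional PC matrix (rownames = ids); use `nPCs` to truncate.
#' @param driver optional named numeric vector (e.g. the EA score) regressed
#'   out along with the covariates.
#' @param nPCs number of leading PC columns used (default all supplied; the
#'   conventional full adjustment uses the top 100).
#' @param refIds optional ids of a reference subsample; when supplied the
#'   centering/scaling constants are taken from the residuals of that
#'   subsample instead of the analysis sample.
#' @return Named numeric vector aligned with `values` (dropped rows `NA`).
#' @examples
#' set.seed(1)
#' co <- data.frame(individual_id = sprintf("i%03d", 1:100),
#'                  sex = rbinom(100, 1, 0.5), age = runif(100, 20, 80))
#' x <- structure(rnorm(100), names = co$individual_id)
#' adj <- residualize(x, buildCovariates(co))
#' round(c(mean(adj), sd(adj)), 10)
#' @export
residualize <- function(values, covariates, pcs = NULL, driver = NULL,
                        nPCs = NULL, refIds = NULL) {
  if (is.null(names(values))) stop("values must be named by individual id")
  design <- covariates
  if (!is.null(pcs)) {
    if (!is.null(nPCs)) pcs <- pcs[, seq_len(min(nPCs, ncol(pcs))), drop = FALSE]
    design <- cbind(design, pcs[match(rownames(design), rownames(pcs)), ,
                                drop = FALSE])
  }
  if (!is.null(driver)) {
    if (length(unique(driver[!is.na(driver)])) < 2)
      stop("driver is constant and cannot be regressed out")
    design <- cbind(design, driver = driver[match(rownames(design),
                                                  names(driver))])
  }
  y <- values[match(rownames(design), names(values))]
  ok <- stats::complete.cases(design) & !is.na(y)
  if (sum(ok) < ncol(design) + 2)
    stop("need at least 2 more rows than fitted columns (",
         sum(ok), " complete rows for ", ncol(design), " columns)")
  if (any(!ok))
    message(sum(!ok), " row(s) dropped in residualization (missing data)")
  X <- design[ok, , drop = FALSE]
  # drop duplicated constant columns before the rank check
  constIdx <- which(apply(X, 2, function(v) max(v) - min(v) == 0))
  if (length(constIdx) > 1) X <- X[, -constIdx[-1], drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  res <- qr.resid(qrX, y[ok])
  if (is.null(refIds)) {
    s <- stats::sd(res)
    ctr <- mean(res)
  } else {
    inRef <- rownames(X) %in% refIds
    if (sum(inRef) < 2) stop("reference subsample has fewer than 2 fitted rows")
    s <- stats::sd(res[inRef])
    ctr <- mean(res[inRef])
  }
  if (s <= 1e-10 * max(1, stats::sd(y[ok])))
    stop("residuals have zero variance; nothing left to standardize")
  out <- rep(NA_real_, length(values))
  names(out) <- names(values)
  out[match(rownames(X), names(out))] <- (res - ctr) / s
  out
}

#' Adjust every column of a score matrix
#'
#' Applies [residualize()] column-wise: each score is regressed on the
#' demographic design, the top `nPCs` principal components and optionally a
#' driver score, then standardized. The returned matrix carries the
#' adjustment provenance as attribute `"adjustment"`.
#'
#' @param scores individuals x scores matrix with rownames.
#' @param cohort cohort data.frame (for [buildCovariates()]).
#' @param pcs optional PC matrix.
#' @param nPCs number of leading PCs regressed out (default 100, capped at
#'   the number supplied).
#' @param driver optional driver score name (column of `scores`) or named
#'   vector; when a column name is given that column is adjusted first
#'   (without the driver) and then regressed out of the remaining scores.
#' @param refIds optional reference subsample for standardization.
#' @return Adjusted matrix of the same shape (dropped rows `NA`).
#' @examples
#' syn <- simulateCohort(simConfig(nSibships = 300, seed = 3))
#' adj <- adjustScores(scoreMatrix(syn), cohortTable(syn), pcMatrix(syn))
#' round(colMeans(adj), 10)
#' @export
adjustScores <- function(scores, cohort, pcs = NULL, nPCs = 100,
                         driver = NULL, refIds = NULL) {
  cov <- buildCovariates(cohort)
  driverVec <- NULL
  driverName <- NULL
  if (!is.null(driver)) {
    if (is.character(driver) && length(driver) == 1) {
      stopifnot(driver %in% colnames(scores))
      driverName <- driver
      driverVec <- residualize(scores[, driver], cov, pcs = pcs, nPCs = nPCs,
                               refIds = refIds)
    } else {
      driverVec <- driver
    }
  }
  out <- scores
  out[] <- NA_real_
  for (j in colnames(scores)) {
    v <- scores[, j]
    useDriver <- if (!is.null(driverName) && j == driverName) NULL else driverVec
    out[, j] <- residualize(v, cov, pcs = pcs, driver = useDriver,
                            nPCs = nPCs, refIds = refIds)[rownames(scores)]
  }
  attr(out, "adjustment") <- list(
    covariates = colnames(cov),
    nPCs = if (is.null(pcs)) 0L else min(nPCs, ncol(pcs)),
    driver = if (is.null(driverName)) {
      if (is.null(driverVec)) NA_character_ else "external"
    } else driverName)
  out
}
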