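#' Area scheme: counties to three migration areas
#'
#' Maps counties (plus the city flags) onto three areas: the two city areas
#' and ORE ("other regions"). At the `county` level the whole city county
#' belongs to its city area; at the `city` level only individuals flagged as
#' being in the city proper count as the city area, and residents/natives of
#' a city county outside the city proper are undefined under the scheme (such
#' rows are dropped by the classifiers).
#'
#' @param cityCounties named length-2 character vector: names are the city
#'   (area) names, values the county labels containing them.
#' @param level `"county"` or `"city"`.
#' @return An object of class `"areaScheme"` used by [assignArea()] and
#'   friends.
#' @examples
#' sc <- areaScheme(c(Tallinn = "C01", Tartu = "C02"))
#' @export
areaScheme <- function(cityCounties, level = c("county", "city")) {
  level <- match.arg(level)
  stopifnot(length(cityCounties) == 2, !is.null(names(cityCounties)))
  structure(list(cityCounties = cityCounties, level = level,
                 areas = names(cityCounties)),
            class = "areaScheme")
}

#' Assign each individual to a migration area
#'
#' @param county county labels.
#' @param cityFlag logical city-proper flags (required at `city` level).
#' @param scheme an [areaScheme()].
#' @return Character vector of area names (`"ORE"` or a city name); `NA` when
#'   the area is undefined under a city-level scheme.
#' @export
assignArea <- function(county, cityFlag = NULL, scheme) {
  m <- match(county, scheme$cityCounties)
  area <- ifelse(is.na(m), "ORE", scheme$areas[m])
  if (scheme$level == "city") {
    inCityCounty <- !is.na(m)
    flag <- if (is.null(cityFlag)) rep(NA, length(county)) else cityFlag
    area[inCityCounty & (is.na(flag) | !flag)] <- NA_character_
  }
  area
}

#' Classify individuals into the nine migration-profile groups
#'
#' Combines place-of-birth and place-of-residence areas into the 3 x 3
#' taxonomy: three stayer groups (`"<area> stayer"`) and six migrant groups
#' (`"<from>→<to>"`). Moves within one area -- for instance between two
#' ORE counties -- are ignored and collapse to the stayer label.
#'
#' @param pobArea,porArea area vectors from [assignArea()].
#' @return Factor with the nine labels; `NA` where either area is undefined.
#' @examples
#' classifyMigrationGroup("ORE", "Tallinn")   # "ORE→Tallinn"
#' classifyMigrationGroup("ORE", "ORE")       # "ORE stayer"
#' @export
classifyMigrationGroup <- function(pobArea, porArea) {
  lab <- ifelse(is.na(pobArea) | is.na(porArea), NA_character_,
                ifelse(pobArea == porArea, paste(pobArea, "stayer"),
                       paste0(pobArea, "→", porArea)))
  areas <- unique(stats::na.omit(c(pobArea, porArea)))
  lev <- c(paste(areas, "stayer"),
           as.vector(outer(areas, areas, function(a, b)
             ifelse(a == b, NA, paste0(a, "→", b)))))
  factor(lab, levels = stats::na.omit(lev))
}

.zContrast <- function(mean1, se1, mean2 = 0, se2 = 0) {
  d <- mean1 - mean2
  se <- sqrt(se1^2 + se2^2)
  # a zero difference is never evidence against the null, even at zero SE
  z <- ifelse(d == 0, 0, d / se)
  list(delta = d, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Per-group means with Z-tests and FDR
#'
#' For each group: `n`, mean, standard error, 95% CI, the Z statistic of the
#' mean against zero with its two-sided normal p-value, and the
#' Benjamini-Hochberg q-value across the groups tested. Intended for
#' adjusted, standardized values, where "different from zero" means different
#' from the cohort average. Groups of size 1 are reported with `NA` standard
#' errors and excluded from testing.
#'
#' @param values numeric vector.
#' @param groups factor/character of group labels aligned with `values`.
#' @return data.frame with one row per group: `group`, `n`, `mean`, `se`,
#'   `ciLow`, `ciHigh`, `z`, `p`, `q`.
#' @examples
#' groupStats(c(1, 3), c("g", "g"))   # mean 2, se 1, z 2
#' @export
groupStats <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  v <- values[ok]; f <- factor(groups[ok])
  n <- as.integer(table(f))
  m <- as.numeric(tapply(v, f, mean))
  s <- as.numeric(tapply(v, f, stats::sd))
  se <- s / sqrt(n)
  se[n < 2] <- NA_real_
  z <- ifelse(m == 0, 0, m / se)
  p <- 2 * stats::pnorm(-abs(z))
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  data.frame(group = levels(f), n = n, mean = m, se = se,
             ciLow = m - 1.96 * se, ciHigh = m + 1.96 * se,
             z = z, p = p, q = q, stringsAsFactors = FALSE)
}

#' County means by birth and residence, and their difference
#'
#' For every county: the mean of the value over individuals born there, the
#' mean over individuals residing there, and the migration-driven change
#' `delta = resident mean - born mean`, each with a 95% CI, a Z-test against
#' zero and an FDR mark within its own family of tests.
#'
#' @param values named numeric vector (named by individual id).
#' @param cohort cohort data.frame.
#' @return data.frame with one row per county; counties lacking individuals
#'   under a factor carry `NA` and are flagged in the `missing` column.
#' @export
countyMeansAndDelta <- function(values, cohort) {
  v <- values[match(cohort$individual_id, names(values))]
  counties <- sort(unique(c(cohort$pob_county, cohort$por_county)))
  born <- groupStats(v, factor(cohort$pob_county, levels = counties))
  res <- groupStats(v, factor(cohort$por_county, levels = counties))
  bi <- match(counties, born$group)
  ri <- match(counties, res$group)
  d <- .zContrast(res$mean[ri], res$se[ri], born$mean[bi], born$se[bi])
  out <- data.frame(
    county = counties,
    nBorn = born$n[bi], meanBorn = born$mean[bi], seBorn = born$se[bi],
    pBorn = born$p[bi], qBorn = born$q[bi],
    nResident = res$n[ri], meanResident = res$mean[ri],
    seResident = res$se[ri], pResident = res$p[ri], qResident = res$q[ri],
    delta = d$delta, seDelta = d$se,
    deltaCiLow = d$delta - 1.96 * d$se, deltaCiHigh = d$delta + 1.96 * d$se,
    zDelta = d$z, pDelta = d$p, stringsAsFactors = FALSE)
  out$qDelta <- NA_real_
  okd <- !is.na(out$pDelta)
  out$qDelta[okd] <- stats::p.adjust(out$pDelta[okd], method = "BH")
  out$missing <- is.na(out$meanBorn) | is.na(out$meanResident)
  if (any(out$missing))
    message(sum(out$missing), " county record(s) incomplete under a factor")
  out
}

#' City-destination contrast by county of origin
#'
#' For each origin county, the mean value of individuals born there and now
#' residing in the first city minus the mean of those born there and residing
#' in the second city (city proper in both cases), with a two-sample Welch-Z
#' test and FDR across origins. Individuals born in either city proper are
#' excluded from every origin county.
#'
#' @param values named numeric vector.
#' @param cohort cohort data.frame.
#' @param scheme an [areaScheme()] (its two city names order the contrast:
#'   first minus second).
#' @return data.frame, one row per origin county with migrants to at least one
#'   destination; contrasts lacking a destination are flagged `undefined`.
#' @export
destinationContrastByOrigin <- function(values, cohort, scheme) {
  v <- values[match(cohort$individual_id, names(values))]
  citySc <- areaScheme(scheme$cityCounties, level = "city")
  porArea <- assignArea(cohort$por_county, cohort$por_city_flag, citySc)
  pobArea <- assignArea(cohort$pob_county, cohort$pob_city_flag, citySc)
  bornInCity <- !is.na(pobArea) & pobArea != "ORE"
  eligible <- !bornInCity & !is.na(porArea) & porArea != "ORE" & !is.na(v)
  a1 <- citySc$areas[1]; a2 <- citySc$areas[2]
  origins <- sort(unique(cohort$pob_county[eligible]))
  rows <- lapply(origins, function(cty) {
    sel <- eligible & cohort$pob_county == cty
    x1 <- v[sel & porArea == a1]
    x2 <- v[sel & porArea == a2]
    if (length(x1) < 2 || length(x2) < 2) {
      return(data.frame(origin = cty, n1 = length(x1), n2 = length(x2),
                        contrast = NA_real_, se = NA_real_, z = NA_real_,
                        p = NA_real_, undefined = TRUE,
                        stringsAsFactors = FALSE))
    }
    ct <- .zContrast(mean(x1), stats::sd(x1) / sqrt(length(x1)),
                     mean(x2), stats::sd(x2) / sqrt(length(x2)))
    data.frame(origin = cty, n1 = length(x1), n2 = length(x2),
               contrast = ct$delta, se = ct$se, z = ct$z, p = ct$p,
               undefined = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$q <- NA_real_
  okp <- !is.na(out$p)
  out$q[okp] <- stats::p.adjust(out$p[okp], method = "BH")
  names(out)[names(out) %in% c("n1", "n2")] <-
    c(paste0("n", a1), paste0("n", a2))
  out
}

#' Birth-cohort trends in city/ORE contrasts
#'
#' Groups individuals into half-open birth-year bins `[lo, hi)` and computes
#' per bin: (a) the mean value of individuals born in the cities vs born in
#' ORE, and (b) among the ORE-born, the mean of stayers vs ORE-to-city
#' migrants, each pair compared by a two-sample Welch-Z test. Edge bins may
#' be wider than the interior ones to keep the oldest and youngest cohorts
#' populated.
#'
#' @param values named numeric vector.
#' @param cohort cohort data.frame.
#' @param binEdges increasing numeric vector of bin edges covering the
#'   birth-year range.
#' @param scheme an [areaScheme()].
#' @return data.frame with one row per bin and contrast (`contrast` is
#'   `"bornCityVsORE"` or `"migrantVsStayer"`), with both group means, the
#'   difference, Z and p; empty cells give `NA`.
#' @export
birthCohortTrend <- function(values, cohort, binEdges, scheme) {
  v <- values[match(cohort$individual_id, names(values))]
  pobArea <- assignArea(cohort$pob_county, cohort$pob_city_flag, scheme)
  porArea <- assignArea(cohort$por_county, cohort$por_city_flag, scheme)
  bin <- cut(cohort$birth_year, breaks = binEdges, right = FALSE,
             include.lowest = FALSE, dig.lab = 5)
  bornCity <- !is.na(pobArea) & pobArea != "ORE"
  bornOre <- !is.na(pobArea) & pobArea == "ORE"
  migrant <- bornOre & !is.na(porArea) & porArea != "ORE"
  stayer <- bornOre & !is.na(porArea) & porArea == "ORE"
  one <- function(binLev, selA, selB, label, nameA, nameB) {
    sA <- !is.na(bin) & bin == binLev & selA & !is.na(v)
    sB <- !is.na(bin) & bin == binLev & selB & !is.na(v)
    if (sum(sA) < 2 || sum(sB) < 2) {
      return(data.frame(bin = binLev, contrast = label,
                        nA = sum(sA), nB = sum(sB),
                        meanA = NA_real_, meanB = NA_real_, diff = NA_real_,
                        se = NA_real_, z = NA_real_, p = NA_real_,
                        groupA = nameA, groupB = nameB,
                        stringsAsFactors = FALSE))
    }
    ct <- .zContrast(mean(v[sA]), stats::sd(v[sA]) / sqrt(sum(sA)),
                     mean(v[sB]), stats::sd(v[sB]) / sqrt(sum(sB)))
    data.frame(bin = binLev, contrast = label, nA = sum(sA), nB = sum(sB),
               meanA = mean(v[sA]), meanB = mean(v[sB]), diff = ct$delta,
               se = ct$se, z = ct$z, p = ct$p,
               groupA = nameA, groupB = nameB, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(
    lapply(levels(bin), one, selA = bornCity, selB = bornOre,
           label = "bornCityVsORE", nameA = "born city", nameB = "born ORE"),
    lapply(levels(bin), one, selA = migrant, selB = stayer,
           label = "migrantVsStayer", nameA = "ORE→city",
           nameB = "ORE stayer")))
  out
}
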