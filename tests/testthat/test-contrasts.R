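test_that("migration groups follow the 3x3 taxonomy with within-area moves collapsed", {
  sch <- defaultScheme()
  expect_equal(assignArea(c("C01", "C02", "C07"), scheme = sch),
               c("Tallinn", "Tartu", "ORE"))
  expect_equal(as.character(classifyMigrationGroup("ORE", "Tallinn")),
               "ORE→Tallinn")
  # a move between two ORE counties is a stay under the taxonomy
  a1 <- assignArea("C05", scheme = sch); a2 <- assignArea("C09", scheme = sch)
  expect_equal(as.character(classifyMigrationGroup(a1, a2)), "ORE stayer")
  expect_equal(as.character(classifyMigrationGroup("Tallinn", "Tartu")),
               "Tallinn→Tartu")
  # city-level scheme: a city-county resident outside the city proper is
  # undefined and the classification propagates NA
  citySch <- areaScheme(c(Tallinn = "C01", Tartu = "C02"), level = "city")
  expect_true(is.na(assignArea("C01", FALSE, citySch)))
  expect_true(is.na(classifyMigrationGroup(NA_character_, "ORE")))
})

test_that("nine group labels partition the classified individuals", {
  syn <- simulateCohort(tinyConfig(seed = 33))
  co <- cohortTable(syn)
  sch <- defaultScheme()
  grp <- classifyMigrationGroup(
    assignArea(co$pob_county, co$pob_city_flag, sch),
    assignArea(co$por_county, co$por_city_flag, sch))
  expect_lte(nlevels(grp), 9)
  expect_equal(sum(table(grp)), sum(!is.na(grp)))
  expect_equal(sum(!is.na(grp)), nrow(co))   # county level defines everyone
})

test_that("group statistics match the hand normal-tail computation", {
  g <- groupStats(c(1, 3), c("g", "g"))
  expect_equal(g$mean, 2)
  expect_equal(g$se, 1)
  expect_equal(g$z, 2)
  expect_equal(g$p, 2 * pnorm(-2), tolerance = 1e-12)
  expect_equal(g$ciLow, 2 - 1.96)

  gz <- groupStats(rep(0, 10), rep(c("a", "b"), 5))
  expect_equal(gz$p, c(1, 1))

  g1 <- groupStats(c(1, 2, 3), c("a", "a", "b"))
  expect_true(is.na(g1$se[g1$group == "b"]))
  expect_true(is.na(g1$q[g1$group == "b"]))
})

test_that("population-weighted mean of group means is the cohort mean", {
  syn <- simulateCohort(tinyConfig(seed = 35))
  co <- cohortTable(syn)
  adj <- adjustScores(scoreMatrix(syn), co, pcMatrix(syn))
  sch <- defaultScheme()
  v <- adj[, "PGS_EA"]
  grp <- classifyMigrationGroup(
    assignArea(co$pob_county, co$pob_city_flag, sch),
    assignArea(co$por_county, co$por_city_flag, sch))
  gs <- groupStats(v, grp)
  expect_equal(sum(gs$n * gs$mean) / sum(gs$n), 0, tolerance = 1e-8)
})

test_that("county means and the migration delta recompute by brute force", {
  syn <- simulateCohort(tinyConfig(seed = 37))
  co <- cohortTable(syn)
  v <- structure(rnorm(nrow(co)), names = co$individual_id)
  cm <- countyMeansAndDelta(v, co)
  for (cty in cm$county[1:5]) {
    expect_equal(cm$meanBorn[cm$county == cty],
                 mean(v[co$individual_id[co$pob_county == cty]]),
                 tolerance = 1e-12)
    expect_equal(cm$meanResident[cm$county == cty],
                 mean(v[co$individual_id[co$por_county == cty]]),
                 tolerance = 1e-12)
  }
  expect_equal(cm$delta, cm$meanResident - cm$meanBorn, tolerance = 1e-12)

  # without migration the delta vanishes everywhere
  synStay <- simulateCohort(tinyConfig(
    migIntercepts = c(-Inf, -Inf), oreIntercept = -Inf,
    withinOreMoveRate = 0, seed = 39))
  cs <- countyMeansAndDelta(
    structure(rnorm(nrow(cohortTable(synStay))),
              names = cohortTable(synStay)$individual_id),
    cohortTable(synStay))
  expect_equal(cs$delta, rep(0, nrow(cs)), tolerance = 1e-12)
  expect_equal(cs$pDelta, rep(1, nrow(cs)))
})

test_that("high-value out-migration depresses the origin counties' delta", {
  syn <- simulateCohort(simConfig(seed = 41))
  co <- cohortTable(syn)
  adj <- adjustScores(scoreMatrix(syn), co, pcMatrix(syn))
  cm <- countyMeansAndDelta(
    structure(adj[, "PGS_EA"], names = rownames(adj)), co)
  ore <- setdiff(cm$county, c("C01", "C02"))
  # the capital county gains, most ORE counties lose
  expect_gt(cm$delta[cm$county == "C01"], 0)
  expect_lt(cm$pDelta[cm$county == "C01"], 0.05)
  expect_gt(mean(cm$delta[cm$county %in% ore] < 0), 0.7)
})

test_that("destination contrast excludes the city-born and recovers a built-in shift", {
  sch <- defaultScheme()
  set.seed(43)
  nPer <- 60
  ids <- sprintf("d%03d", 1:(4 * nPer))
  co <- handCohort(
    ids,
    pob = rep(c("C05", "C05", "C01", "C02"), each = nPer),
    por = rep(c("C01", "C02", "C01", "C02"), each = nPer),
    porFlag = TRUE)
  co$pob_city_flag <- rep(c(FALSE, FALSE, TRUE, TRUE), each = nPer)
  v <- structure(c(rnorm(nPer, 0.5), rnorm(nPer, 0),
                   rnorm(nPer, 9), rnorm(nPer, 9)), names = ids)
  dc <- destinationContrastByOrigin(v, co, sch)
  expect_equal(nrow(dc), 1)             # only C05 is a valid origin
  expect_equal(dc$origin, "C05")
  expect_equal(dc$contrast, 0.5, tolerance = 3 * dc$se)
  expect_false(any(dc$origin %in% c("C01", "C02")))
})

test_that("birth-year bins are half-open and trends come out per bin", {
  sch <- defaultScheme()
  set.seed(45)
  n <- 400
  ids <- sprintf("t%03d", 1:n)
  bornCity <- rep(c(TRUE, FALSE), n / 2)
  years <- rep(c(1945, 1949, 1955, 1965), each = n / 4)
  co <- handCohort(ids, pob = ifelse(bornCity, "C01", "C08"),
                   por = ifelse(bornCity, "C01", "C08"))
  co$birth_year <- years
  co$pob_city_flag <- bornCity
  co$por_city_flag <- bornCity
  # contrast between city-born and ORE-born grows across bins
  shift <- (years - 1940) / 25
  v <- structure(rnorm(n, ifelse(bornCity, shift, 0)), names = ids)
  tr <- birthCohortTrend(v, co, c(1940, 1950, 1960, 1970), sch)
  born <- tr[tr$contrast == "bornCityVsORE", ]
  expect_equal(nrow(born), 3)
  # 1949 falls in the [1940,1950) bin together with 1945
  expect_equal(born$nA[1] + born$nB[1], sum(years < 1950))
  expect_equal(cor(seq_len(3), born$diff, method = "spearman"), 1)
})
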