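test_that("migration phenotype eligibility follows the case/control definition", {
  sch <- defaultScheme()
  co <- handCohort(
    c("a", "b", "c", "d", "e"),
    pob = c("C05", "C05", "C01", "C05", "C05"),
    por = c("C01", "C05", "C01", "C02", "C01"))
  co$por_city_flag <- c(TRUE, FALSE, TRUE, FALSE, NA)
  ph <- suppressMessages(defineMigrationPhenotype(co, sch))
  expect_equal(ph$y[ph$individual_id == "a"], 1L)   # ORE -> Tallinn city
  expect_equal(ph$y[ph$individual_id == "b"], 0L)   # ORE stayer
  expect_false(ph$eligible[ph$individual_id == "c"])  # born in a city county
  # city-county resident outside the city proper, or with a missing flag,
  # is neither case nor control
  expect_false(ph$eligible[ph$individual_id == "d"])
  expect_false(ph$eligible[ph$individual_id == "e"])
})

test_that("population fit recovers the generating log-odds on the true value", {
  cfg <- simConfig(nSibships = 17000, migVarEnv = 0, migEnvLoading = 0,
                   seed = 47)
  syn <- simulateCohort(cfg)
  co <- cohortTable(syn)
  g <- truthRecord(syn)$g
  ph <- suppressMessages(defineMigrationPhenotype(co, defaultScheme()))
  fit <- fitPopulationLogistic(ph, g, co)
  cc <- resultTable(fit)
  row <- cc[cc$term == "score", ]
  expect_lt(abs(row$estimate - 0.23), 2 * row$se)
  expect_gt(fit@nObs, 10000)   # the ORE-born eligible subset of ~30k simulated
})

test_that("degenerate phenotypes and separation are rejected", {
  sch <- defaultScheme()
  n <- 40
  co <- handCohort(sprintf("y%02d", 1:n), rep("C05", n), rep("C05", n))
  ph <- suppressMessages(defineMigrationPhenotype(co, sch))
  v <- structure(rnorm(n), names = co$individual_id)
  expect_error(fitPopulationLogistic(ph, v, co), "no variation")
})

test_that("within/between terms are the centered deviation and the sibship mean", {
  # sibship scores {1, -1}: deviations +/-1, sibship mean 0; with both
  # means equal the between term is collinear with the intercept
  sch <- defaultScheme()
  n <- 40
  ids <- sprintf("w%02d", 1:n)
  co <- handCohort(ids, rep("C05", n),
                   rep(c("C05", "C01"), n / 2), porFlag = rep(c(FALSE, TRUE), n / 2))
  s <- new("SibshipSet",
           members = split(ids, rep(1:(n / 2), each = 2)),
           pob = rep("C05", n / 2))
  ph <- suppressMessages(defineMigrationPhenotype(co, sch))
  v <- structure(rep(c(1, -1), n / 2), names = ids)
  expect_error(fitWithinBetweenLogistic(ph, v, s, co), "collinear")
})

test_that("within-sibship effect is unidentifiable without discordant sibships", {
  sch <- defaultScheme()
  n <- 20
  ids <- sprintf("c%02d", 1:n)
  co <- handCohort(ids, rep("C05", n), rep("C05", n))   # nobody migrates
  s <- new("SibshipSet", members = split(ids, rep(1:(n / 2), each = 2)),
           pob = rep("C05", n / 2))
  ph <- suppressMessages(defineMigrationPhenotype(co, sch))
  v <- structure(rnorm(n), names = ids)
  expect_error(fitWithinBetweenLogistic(ph, v, s, co), "no variation|discordant")
})

test_that("within and between log-odds are recovered from the generator truth", {
  cfg <- simConfig(nSibships = 5000, sibshipSizeDist = c(0, 0.6, 0.3, 0.1),
                   migWithinBetween = c(0.2, 0.4), migVarEnv = 0, seed = 49)
  syn <- simulateCohort(cfg)
  co <- cohortTable(syn)
  sib <- harmonizeByPob(buildSibships(kinshipPairs(syn)), co)
  ph <- suppressMessages(defineMigrationPhenotype(co, defaultScheme()))
  fit <- fitWithinBetweenLogistic(ph, truthRecord(syn)$g, sib, co)
  cc <- resultTable(fit)
  w <- cc[cc$term == "scoreDev", ]
  b <- cc[cc$term == "scoreMean", ]
  expect_lt(abs(w$estimate - 0.2), 2 * w$se)
  expect_lt(abs(b$estimate - 0.4), 2 * b$se)
})

test_that("mixed and fixed estimates agree when family variance is absent", {
  cfg <- simConfig(nSibships = 2500, sibshipSizeDist = c(0, 1),
                   migWithinBetween = c(0.25, 0.25), migVarEnv = 0, seed = 51)
  syn <- simulateCohort(cfg)
  co <- cohortTable(syn)
  sib <- harmonizeByPob(buildSibships(kinshipPairs(syn)), co)
  ph <- suppressMessages(defineMigrationPhenotype(co, defaultScheme()))
  g <- truthRecord(syn)$g
  fx <- fitWithinBetweenLogistic(ph, g, sib, co)
  mx <- fitWithinBetweenLogistic(ph, g, sib, co, mixed = TRUE)
  for (term in c("scoreDev", "scoreMean")) {
    eF <- resultTable(fx)$estimate[resultTable(fx)$term == term]
    eM <- resultTable(mx)$estimate[resultTable(mx)$term == term]
    expect_lt(abs(eM - eF) / abs(eF), 1e-3)
  }
  expect_lt(mx@sigmaRanef, 0.1)
})

test_that("EA covariates attenuate a fully mediated score effect", {
  # migration generated from the EA phenotype alone: conditioning on EA
  # must pull the score's odds ratio towards 1
  sch <- defaultScheme()
  set.seed(53)
  attenuated <- vapply(1:20, function(i) {
    n <- 4000
    ids <- sprintf("m%05d", 1:n)
    score <- rnorm(n)
    eaYears <- 13 + 2 * score + rnorm(n, 0, 2)
    eta <- -1 + 0.5 * scale(eaYears)[, 1]
    mig <- rbinom(n, 1, plogis(eta)) == 1
    co <- handCohort(ids, rep("C05", n),
                     ifelse(mig, "C01", "C05"), porFlag = mig)
    co$sex <- rbinom(n, 1, 0.5); co$age <- runif(n, 20, 80)
    co$ea_years <- eaYears
    ph <- suppressMessages(defineMigrationPhenotype(co, sch))
    v <- structure(score, names = ids)
    ea <- structure(eaYears, names = ids)
    orBare <- oddsRatios(fitPopulationLogistic(ph, v, co))[["score"]]
    orEA <- oddsRatios(fitJointWithEA(ph, v, ea, co, eaType = "years"))[["score"]]
    abs(log(orEA)) < abs(log(orBare))
  }, logical(1))
  expect_lt(binom.test(sum(attenuated), 20, alternative = "greater")$p.value,
            0.01)
})

test_that("constant or degenerate EA covariates degrade gracefully", {
  sch <- defaultScheme()
  set.seed(55)
  n <- 500
  ids <- sprintf("e%04d", 1:n)
  mig <- rbinom(n, 1, 0.3) == 1
  co <- handCohort(ids, rep("C05", n), ifelse(mig, "C01", "C05"),
                   porFlag = mig)
  co$sex <- rbinom(n, 1, 0.5); co$age <- runif(n, 20, 80)
  ph <- suppressMessages(defineMigrationPhenotype(co, sch))
  v <- structure(rnorm(n), names = ids)
  eaConst <- structure(rep(12, n), names = ids)
  expect_warning(fitC <- fitJointWithEA(ph, v, eaConst, co, eaType = "years"),
                 "constant")
  fit0 <- fitPopulationLogistic(ph, v, co)
  expect_equal(resultTable(fitC)$estimate, resultTable(fit0)$estimate,
               tolerance = 1e-12)

  eaCat <- structure(ifelse(mig, "high", sample(c("low", "high"), n, TRUE)),
                     names = ids)
  expect_warning(fitJointWithEA(ph, v, eaCat, co, eaType = "categorical"),
                 "no cases or no controls")
})

test_that("odds ratios are invariant to affine covariate rescaling", {
  syn <- simulateCohort(tinyConfig(nSibships = 1500, seed = 57))
  co <- cohortTable(syn)
  ph <- suppressMessages(defineMigrationPhenotype(co, defaultScheme()))
  v <- structure(scoreMatrix(syn)[, "PGS_EA"], names = co$individual_id)
  or1 <- oddsRatios(fitPopulationLogistic(ph, v, co))[["score"]]
  co2 <- co; co2$age <- co2$age / 10 + 3
  or2 <- oddsRatios(fitPopulationLogistic(ph, v, co2))[["score"]]
  expect_equal(or1, or2, tolerance = 1e-8)
})

test_that("Wald p-values are uniform under score permutation", {
  syn <- simulateCohort(simConfig(nSibships = 3000, seed = 59))
  co <- cohortTable(syn)
  ph <- suppressMessages(defineMigrationPhenotype(co, defaultScheme()))
  v <- structure(scoreMatrix(syn)[, "PGS_EA"], names = co$individual_id)
  set.seed(61)
  p <- replicate(500, {
    vp <- structure(sample(as.numeric(v)), names = names(v))
    cc <- resultTable(fitPopulationLogistic(ph, vp, co))
    cc$p[cc$term == "score"]
  })
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("sibling-subsample fixed estimates agree with the unrelated subsample", {
  syn <- simulateCohort(simConfig(nSibships = 8000, seed = 63))
  co <- cohortTable(syn)
  sib <- harmonizeByPob(buildSibships(kinshipPairs(syn)), co)
  ph <- suppressMessages(defineMigrationPhenotype(co, defaultScheme()))
  v <- structure(scoreMatrix(syn)[, "PGS_EA"], names = co$individual_id)

  unrel <- suppressMessages(filterUnrelated(co, kinshipPairs(syn), seed = 2))
  phU <- ph[ph$individual_id %in% unrel$individual_id, ]
  fitU <- fitPopulationLogistic(phU, v, unrel)

  onePer <- pickOnePerSibship(sib, seed = 3)
  coS <- co[co$individual_id %in% onePer, ]
  phS <- ph[ph$individual_id %in% onePer, ]
  fitS <- fitPopulationLogistic(phS, v, coS)

  rU <- resultTable(fitU); rS <- resultTable(fitS)
  sU <- rU[rU$term == "score", ]; sS <- rS[rS$term == "score", ]
  expect_lt(max(sU$orLow, sS$orLow), min(sU$orHigh, sS$orHigh))  # CIs overlap
})
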