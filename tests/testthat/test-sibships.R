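test_that("sibships are connected components inside the kinship window", {
  p <- data.frame(ID1 = c("A", "B", "D", "F"),
                  ID2 = c("B", "C", "E", "G"),
                  Kinship = c(0.25, 0.25, 0.40, 0.10))
  s <- buildSibships(p)
  memb <- sibshipMembers(s)
  expect_length(memb, 1)
  expect_setequal(memb[[1]], c("A", "B", "C"))   # chain merges transitively

  # window is open: boundary values are excluded
  pb <- data.frame(ID1 = c("A", "C"), ID2 = c("B", "D"),
                   Kinship = c(0.177, 0.354))
  expect_warning(s2 <- buildSibships(pb), "sibling window")
  expect_length(sibshipMembers(s2), 0)

  expect_error(buildSibships(data.frame(ID1 = "A", ID2 = "A",
                                        Kinship = 0.25)), "self-pairs")
})

test_that("the shared-birthplace rule splits and drops as specified", {
  s <- new("SibshipSet", members = list(S1 = c("A", "B", "C")),
           pob = NA_character_)
  co <- handCohort(c("A", "B", "C"), c("X", "X", "Y"), c("X", "X", "Y"))
  h <- harmonizeByPob(s, co)
  expect_length(sibshipMembers(h), 1)
  expect_setequal(sibshipMembers(h)[[1]], c("A", "B"))
  expect_equal(sibshipPOB(h), "X")

  co2 <- handCohort(c("A", "B", "C"), c("X", "X", "X"), c("X", "X", "X"))
  h2 <- harmonizeByPob(s, co2)
  expect_setequal(sibshipMembers(h2)[[1]], c("A", "B", "C"))

  co3 <- handCohort(c("A", "B", "C"), c("X", "Y", "Z"), c("X", "Y", "Z"))
  h3 <- harmonizeByPob(s, co3)
  expect_length(sibshipMembers(h3), 0)   # all singletons dropped

  expect_error(harmonizeByPob(s, co3[1:2, ]), "missing from cohort")
})

test_that("within-sibship centering subtracts the inclusive mean", {
  s <- new("SibshipSet", members = list(S1 = c("a", "b"), S2 = c("c", "d", "e")),
           pob = c("X", "Y"))
  d <- centerWithinSibship(c(a = 2, b = 4, c = 1, d = 1, e = 1), s)
  expect_equal(unname(d[c("a", "b")]), c(-1, 1))
  expect_equal(unname(d[c("c", "d", "e")]), c(0, 0, 0))

  set.seed(3)
  v <- structure(rnorm(5), names = letters[1:5])
  d2 <- centerWithinSibship(v, s)
  sums <- tapply(d2, attr(d2, "sibship"), sum)
  expect_lt(max(abs(sums)), 1e-12)

  vNA <- v; vNA["c"] <- NA
  expect_message(d3 <- centerWithinSibship(vNA, s), "excluded")
  expect_setequal(names(d3), c("a", "b"))
})

test_that("deviations grouped by birth county give exactly zero variance", {
  syn <- simulateCohort(tinyConfig(seed = 19))
  co <- cohortTable(syn)
  sib <- harmonizeByPob(buildSibships(kinshipPairs(syn)), co)
  v <- structure(scoreMatrix(syn)[, "PGS_EA"], names = co$individual_id)
  dev <- centerWithinSibship(v, sib)
  pob <- structure(co$pob_county, names = co$individual_id)
  r <- siblingVarCounty(dev, pob[names(dev)], groupFactor = "POB")
  expect_identical(varCountyStat(r), 0)
  expect_identical(ssBetween(r), 0)
})

test_that("sibling statistic on residence matches the brute-force oracle", {
  # 4 sibships of 2; one sib of each pair moves to a shared destination
  # carrying a +delta deviation
  ids <- sprintf("m%02d", 1:8)
  s <- new("SibshipSet",
           members = list(S1 = ids[1:2], S2 = ids[3:4],
                          S3 = ids[5:6], S4 = ids[7:8]),
           pob = rep("X", 4))
  v <- structure(c(1, 2, 0, 1.4, -1, 0.1, 2, 2.8), names = ids)
  dev <- centerWithinSibship(v, s)
  por <- structure(rep(c("X", "CITY"), 4), names = ids)  # 2nd sib moved
  r <- siblingVarCounty(dev, por)
  o <- bruteVarCounty(as.numeric(dev), por[names(dev)])
  expect_gt(varCountyStat(r), 0)
  expect_equal(varCountyStat(r), o$stat, tolerance = 1e-12)

  zeros <- structure(rep(0, 8), names = ids, sibship = rep(1:4, each = 2))
  rz <- siblingVarCounty(zeros, por)
  expect_equal(varCountyStat(rz), 0)
  expect_true(rz@degenerate)
})

test_that("empirical p follows the (r+1)/(n+1) rule with strict exceedance", {
  nl <- new("EmpiricalNull", nSims = 4L, seed = 1,
            stats = c(0.1, 0.2, 0.3, 0.4))
  expect_equal(empiricalP(nl, 0.5), 1 / 5)    # exceeds all null values
  expect_equal(empiricalP(nl, -1), 1)         # below all null values
  expect_equal(empiricalP(nl, 0.25), 3 / 5)
  expect_equal(empiricalP(nl, 0.3), 2 / 5)    # ties do not count as exceedance
})

test_that("the simulated null is deterministic and reusable across scores", {
  syn <- simulateCohort(tinyConfig(seed = 23))
  co <- cohortTable(syn)
  sib <- harmonizeByPob(buildSibships(kinshipPairs(syn)), co)
  por <- structure(co$por_county, names = co$individual_id)
  n1 <- empiricalNull(sib, por, nSims = 150, seed = 5)
  n2 <- empiricalNull(sib, por, nSims = 150, seed = 5)
  expect_identical(nullStats(n1), nullStats(n2))
  n3 <- empiricalNull(sib, por, nSims = 150, seed = 6)
  expect_false(identical(nullStats(n1), nullStats(n3)))
  expect_true(all(nullStats(n1) >= 0 & nullStats(n1) <= 1))
})

test_that("null statistics match the sibling statistic computed directly", {
  # one simulated variable pushed through the public path must be
  # distributed like the internal vectorized null
  syn <- simulateCohort(tinyConfig(nSibships = 200, seed = 29))
  co <- cohortTable(syn)
  sib <- harmonizeByPob(buildSibships(kinshipPairs(syn)), co)
  por <- structure(co$por_county, names = co$individual_id)
  nl <- empiricalNull(sib, por, nSims = 400, seed = 7)
  set.seed(101)
  direct <- replicate(400, {
    ix <- unlist(sibshipMembers(sib), use.names = FALSE)
    v <- structure(rnorm(length(ix)), names = ix)
    varCountyStat(siblingVarCounty(centerWithinSibship(v, sib), por[ix]))
  })
  expect_gt(suppressWarnings(
    ks.test(nullStats(nl), direct))$p.value, 0.01)
})
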