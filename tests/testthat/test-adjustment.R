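test_that("covariate design holds intercept, sex, age, interaction, age^2", {
  co <- handCohort(c("a", "b"), c("X", "X"), c("X", "X"))
  co$sex <- c(1L, 0L); co$age <- c(10, 20)
  d <- buildCovariates(co)
  expect_equal(unname(d["a", ]), c(1, 1, 10, 10, 100))
  expect_equal(unname(d["b", ]), c(1, 0, 20, 0, 400))
})

test_that("missing demographics are excluded and reported", {
  co <- handCohort(letters[1:4], rep("X", 4), rep("X", 4))
  co$age[2] <- NA
  expect_message(d <- buildCovariates(co), "dropped")
  expect_equal(rownames(d), c("a", "c", "d"))
  expect_equal(attr(d, "excluded"), "b")
  co$age <- NA
  expect_error(buildCovariates(co), "no rows")
})

test_that("residualizing a covariate itself leaves nothing to standardize", {
  co <- handCohort(sprintf("i%02d", 1:30), rep("X", 30), rep("X", 30))
  co$sex <- rep(0:1, 15); co$age <- runif(30, 20, 80)
  d <- buildCovariates(co)
  v <- structure(d[, "age"], names = rownames(d))
  expect_error(residualize(v, d), "zero variance")
})

test_that("a variable independent of the design survives adjustment", {
  set.seed(41)
  n <- 10000
  co <- handCohort(sprintf("i%05d", 1:n), rep("X", n), rep("X", n))
  co$sex <- rbinom(n, 1, 0.5); co$age <- runif(n, 18, 90)
  d <- buildCovariates(co)
  v <- structure(rnorm(n), names = co$individual_id)
  adj <- residualize(v, d)
  expect_gt(cor(adj, v), 0.99)
  expect_equal(mean(adj), 0, tolerance = 1e-10)
  expect_equal(sd(adj), 1, tolerance = 1e-10)
})

test_that("driver adjustment removes the shared component", {
  set.seed(42)
  n <- 10000
  co <- handCohort(sprintf("i%05d", 1:n), rep("X", n), rep("X", n))
  co$sex <- rbinom(n, 1, 0.5); co$age <- runif(n, 18, 90)
  d <- buildCovariates(co)
  a <- structure(rnorm(n), names = co$individual_id)
  b <- 0.8 * a + rnorm(n) * 0.6
  adjB <- residualize(b, d, driver = a)
  expect_lt(cor(adjB, a)^2, 1e-3)
  expect_error(residualize(b, d, driver = structure(rep(1, n), names = names(a))),
               "constant")
})

test_that("residuals are orthogonal to every fitted column", {
  set.seed(43)
  n <- 500
  co <- handCohort(sprintf("i%03d", 1:n), rep("X", n), rep("X", n))
  co$sex <- rbinom(n, 1, 0.5); co$age <- runif(n, 18, 90)
  d <- buildCovariates(co)
  pcs <- matrix(rnorm(n * 3), n, 3,
                dimnames = list(co$individual_id, paste0("PC", 1:3)))
  v <- structure(rnorm(n) + 0.2 * co$age / 10 + 0.5 * pcs[, 1],
                 names = co$individual_id)
  adj <- residualize(v, d, pcs = pcs)
  X <- cbind(d, pcs)
  dots <- abs(crossprod(X, adj)) / (sqrt(colSums(X^2)) * sqrt(sum(adj^2)))
  expect_lt(max(dots), 1e-8)
})

test_that("adjustment is idempotent and order-invariant", {
  set.seed(44)
  n <- 300
  co <- handCohort(sprintf("i%03d", 1:n), rep("X", n), rep("X", n))
  co$sex <- rbinom(n, 1, 0.5); co$age <- runif(n, 18, 90)
  d <- buildCovariates(co)
  v <- structure(rnorm(n) + co$age / 40, names = co$individual_id)
  a1 <- residualize(v, d)
  a2 <- residualize(a1, d)
  expect_lt(max(abs(a1 - a2)), 1e-10)

  perm <- sample(n)
  aPerm <- residualize(v[perm], d[perm, ])
  expect_equal(aPerm[names(a1)], a1, tolerance = 1e-12)
})

test_that("rank-deficient designs are rejected with the offending column", {
  set.seed(45)
  n <- 50
  co <- handCohort(sprintf("i%02d", 1:n), rep("X", n), rep("X", n))
  co$sex <- rbinom(n, 1, 0.5); co$age <- runif(n, 18, 90)
  d <- buildCovariates(co)
  d2 <- cbind(d, ageCopy = d[, "age"])
  v <- structure(rnorm(n), names = co$individual_id)
  expect_error(residualize(v, d2), "rank deficient")
})

test_that("matrix-level adjustment standardizes every score", {
  syn <- simulateCohort(tinyConfig(seed = 9))
  adj <- adjustScores(scoreMatrix(syn), cohortTable(syn), pcMatrix(syn))
  expect_equal(unname(colMeans(adj)), rep(0, ncol(adj)), tolerance = 1e-10)
  expect_equal(unname(apply(adj, 2, sd)), rep(1, ncol(adj)),
               tolerance = 1e-10)
  prov <- attr(adj, "adjustment")
  expect_equal(prov$nPCs, 4L)
})

test_that("driver-score adjustment decorrelates the other scores from it", {
  syn <- simulateCohort(simConfig(nSibships = 3000, seed = 10))
  adj <- adjustScores(scoreMatrix(syn), cohortTable(syn), pcMatrix(syn),
                      driver = "PGS_EA")
  driver <- residualize(
    structure(scoreMatrix(syn)[, "PGS_EA"],
              names = rownames(scoreMatrix(syn))),
    buildCovariates(cohortTable(syn)), pcs = pcMatrix(syn))
  for (s in setdiff(colnames(adj), "PGS_EA"))
    expect_lt(cor(adj[, s], driver)^2, 1e-3)
})
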