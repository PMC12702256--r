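#' Build a simulation configuration
#'
#' Constructs a validated [SimulationConfig-class]. The defaults describe the
#' cohort structure the analysis assumes: 15 counties of which two contain the
#' major cities, sibships sharing a county of birth with true-genetic-value
#' sib-sib correlation 0.5, several intercorrelated polygenic scores driven by
#' one shared genetic component (the educational-attainment score carrying the
#' largest loading), migration towards the cities with odds increasing by
#' roughly 1.2-1.3 per SD of the genetic value, and a years-of-education
#' phenotype whose genetic value is correlated 0.8 with the migration-driving
#' component.
#'
#' @param nSibships number of families (size-1 families are singletons).
#' @param sibshipSizeDist probability vector over sibship sizes 1..s_max.
#' @param nCounties,countyLabels,cityCounties,countyWeights county geography;
#'   `cityCounties` is a named length-2 character vector (names = city names,
#'   values = county labels).
#' @param varFamily,varMendelian variance decomposition of the latent genetic
#'   value g.
#' @param scoreLoadings,scoreIdioVar named per-score loading on g and
#'   idiosyncratic variance; the default idiosyncratic variance
#'   `1 - loading^2` gives unit-variance raw scores.
#' @param pcCountyShift,pcNoiseSD county-of-birth mean offsets for the PCs and
#'   the individual noise SD.
#' @param migIntercepts,oreIntercept,migBetaG,migVarEnv,migEnvLoading,migWithinBetween
#'   migration liability model; see [SimulationConfig-class].
#' @param withinOreMoveRate,cityProperShare residual geography knobs.
#' @param eaBetaG,eaVarFam,eaVarNoise,eaGeneticCor,eaYearsScale,eaThreshold
#'   educational-attainment model.
#' @param demogEffects list with scalars `sex` and `age` added to every raw
#'   score (age centred at 50).
#' @param nDecoyPairs,kinshipNoiseSD kinship-list realism knobs.
#' @param seed integer seed.
#' @return A [SimulationConfig-class] object; invalid settings are rejected
#'   with the violated invariant named.
#' @examples
#' cfg <- simConfig(nSibships = 200, seed = 7)
#' cfg
#' @export
simConfig <- function(nSibships = 12000,
                      sibshipSizeDist = c(0.45, 0.40, 0.11, 0.04),
                      nCounties = 15,
                      countyLabels = sprintf("C%02d", seq_len(nCounties)),
                      cityCounties = c(Tallinn = countyLabels[1],
                                       Tartu = countyLabels[2]),
                      countyWeights = NULL,
                      varFamily = 0.5, varMendelian = 0.5,
                      scoreLoadings = c(PGS_EA = 0.95, PGS_cognition = 0.7,
                                        PGS_income = 0.6, PGS_openness = 0.45,
                                        PGS_smoking = -0.4, PGS_bmi = -0.25),
                      scoreIdioVar = pmax(0, 1 - scoreLoadings^2),
                      pcCountyShift = NULL, pcNoiseSD = 1,
                      migIntercepts = c(-1.4, -2.2), oreIntercept = -2.5,
                      migBetaG = 0.23, migVarEnv = 0.2, migEnvLoading = 0.12,
                      migWithinBetween = numeric(),
                      withinOreMoveRate = 0.05, cityProperShare = 0.8,
                      eaBetaG = 0.55, eaVarFam = 0.35, eaVarNoise = 0.45,
                      eaGeneticCor = 0.8, eaYearsScale = 2.6, eaThreshold = 16,
                      demogEffects = list(sex = 0.1, age = -0.004),
                      nDecoyPairs = 500, kinshipNoiseSD = 0.012,
                      seed = 1L) {
  if (is.null(countyWeights)) {
    # two dominant city counties, remaining mass spread unevenly over ORE
    w <- c(0.30, 0.12, 0.58 * rev(seq_len(nCounties - 2)) /
             sum(seq_len(nCounties - 2)))
    countyWeights <- w / sum(w)
  }
  if (is.null(pcCountyShift)) {
    pcCountyShift <- cbind(
      seq(-0.5, 0.5, length.out = nCounties),
      rep_len(c(-0.3, 0.3), nCounties),
      0, 0)
    colnames(pcCountyShift) <- paste0("PC", 1:4)
  }
  names(scoreIdioVar) <- names(scoreLoadings)
  new("SimulationConfig",
      nSibships = nSibships, sibshipSizeDist = sibshipSizeDist,
      nCounties = nCounties, countyLabels = countyLabels,
      cityCounties = cityCounties, countyWeights = countyWeights,
      varFamily = varFamily, varMendelian = varMendelian,
      scoreLoadings = scoreLoadings, scoreIdioVar = scoreIdioVar,
      pcCountyShift = pcCountyShift, pcNoiseSD = pcNoiseSD,
      migIntercepts = migIntercepts, oreIntercept = oreIntercept,
      migBetaG = migBetaG, migVarEnv = migVarEnv,
      migEnvLoading = migEnvLoading, migWithinBetween = migWithinBetween,
      withinOreMoveRate = withinOreMoveRate, cityProperShare = cityProperShare,
      eaBetaG = eaBetaG, eaVarFam = eaVarFam, eaVarNoise = eaVarNoise,
      eaGeneticCor = eaGeneticCor, eaYearsScale = eaYearsScale,
      eaThreshold = eaThreshold, demogEffects = demogEffects,
      nDecoyPairs = nDecoyPairs, kinshipNoiseSD = kinshipNoiseSD,
      seed = seed)
}

# softmax draw over destinations given a matrix of log-odds vs staying
.drawDestination <- function(logOdds) {
  expo <- cbind(1, exp(logOdds))
  expo[is.na(expo)] <- 0
  p <- expo / rowSums(expo)
  u <- stats::runif(nrow(p))
  dest <- integer(nrow(p))
  cum <- p[, 1]
  dest[u <= cum] <- 1L
  for (j in 2:ncol(p)) {
    sel <- dest == 0L & u <= (cum <- cum + p[, j])
    dest[sel] <- j
  }
  dest[dest == 0L] <- ncol(p)
  dest
}

#' Simulate a cohort with genotype-dependent migration
#'
#' Generates a full synthetic input set: cohort table, score matrix, PC
#' matrix, kinship pair list, and a truth record. Sibships share a county of
#' birth; each draws a family genetic value `~ N(0, varFamily)` to which each
#' member adds an independent Mendelian deviation `~ N(0, varMendelian)`.
#' Every score loads on the single shared genetic value g. Residence is drawn
#' from a multinomial over staying and the two cities whose log-odds increase
#' in g (both city destinations share the genetic term, so the case/control
#' log-odds of reaching either city is exactly linear in g); a family
#' environment term shared by sibs adds family-level liability variance.
#' Years of education depend on a second genetic value correlated
#' `eaGeneticCor` with g. All within-sibship kinship pairs are emitted around
#' 0.25, plus decoy pairs outside the sibling window. Identical config and
#' seed give byte-identical output.
#'
#' @param config a [SimulationConfig-class].
#' @return A [SyntheticCohort-class].
#' @examples
#' syn <- simulateCohort(simConfig(nSibships = 300, seed = 2))
#' syn
#' head(cohortTable(syn))
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)

  smax <- length(config@sibshipSizeDist)
  sizes <- sample.int(smax, config@nSibships, replace = TRUE,
                      prob = config@sibshipSizeDist)
  nSib <- config@nSibships
  n <- sum(sizes)
  sib <- rep.int(seq_len(nSib), sizes)
  id <- sprintf("I%06d", seq_len(n))

  # latent genetic values: shared migration-driving component g and an EA
  # component correlated eaGeneticCor with it, same family/Mendelian split
  gFam <- stats::rnorm(nSib, 0, sqrt(config@varFamily))
  gDev <- stats::rnorm(n, 0, sqrt(config@varMendelian))
  g <- gFam[sib] + gDev
  rg <- config@eaGeneticCor
  gFam2 <- stats::rnorm(nSib, 0, sqrt(config@varFamily))
  gDev2 <- stats::rnorm(n, 0, sqrt(config@varMendelian))
  gEA <- rg * g + sqrt(1 - rg^2) * (gFam2[sib] + gDev2)

  # demography and place of birth (shared within sibship)
  sex <- stats::rbinom(n, 1L, 0.5)
  age <- floor(stats::runif(n, 18, 91))
  birthYear <- 2022L - age
  sibCounty <- sample(config@countyLabels, nSib, replace = TRUE,
                      prob = config@countyWeights)
  pob <- sibCounty[sib]
  cityA <- config@cityCounties[[1]]
  cityB <- config@cityCounties[[2]]
  bornCity <- pob %in% c(cityA, cityB)
  pobCityFlag <- bornCity & stats::runif(n) < config@cityProperShare

  # migration liability
  if (length(config@migWithinBetween) == 2) {
    gbar <- (rowsum(g, sib)[, 1] / sizes)[sib]
    eta <- config@migWithinBetween[1] * (g - gbar) +
      config@migWithinBetween[2] * gbar
    envU <- stats::rnorm(nSib, 0, sqrt(config@migVarEnv))
    eta <- eta + envU[sib]
  } else {
    envU <- stats::rnorm(nSib, 0, sqrt(config@migVarEnv))
    eta <- config@migBetaG * g + (config@migEnvLoading * gFam + envU)[sib]
  }

  por <- pob
  porCityFlag <- pobCityFlag
  oreLabels <- setdiff(config@countyLabels, c(cityA, cityB))
  oreW <- config@countyWeights[match(oreLabels, config@countyLabels)]

  idxOre <- which(!bornCity)
  if (length(idxOre)) {
    lo <- cbind(config@migIntercepts[1] + eta[idxOre],
                config@migIntercepts[2] + eta[idxOre])
    dest <- .drawDestination(lo)        # 1=stay, 2=cityA, 3=cityB
    por[idxOre[dest == 2L]] <- cityA
    por[idxOre[dest == 3L]] <- cityB
    porCityFlag[idxOre[dest != 1L]] <- TRUE
    # within-ORE moves: ignored by the area taxonomy but exercised here
    stay <- idxOre[dest == 1L]
    if (config@withinOreMoveRate > 0 && length(oreLabels) > 1) {
      mv <- stay[stats::runif(length(stay)) < config@withinOreMoveRate]
      if (length(mv)) {
        newC <- sample(oreLabels, length(mv), replace = TRUE, prob = oreW)
        same <- newC == pob[mv]
        while (any(same)) {   # force a genuine county change
          newC[same] <- sample(oreLabels, sum(same), replace = TRUE, prob = oreW)
          same <- newC == pob[mv]
        }
        por[mv] <- newC
      }
    }
  }
  idxCity <- which(bornCity)
  if (length(idxCity)) {
    other <- ifelse(pob[idxCity] == cityA, cityB, cityA)
    interceptOther <- ifelse(pob[idxCity] == cityA,
                             config@migIntercepts[2], config@migIntercepts[1])
    lo <- cbind(interceptOther + eta[idxCity],
                config@oreIntercept - eta[idxCity])
    dest <- .drawDestination(lo)        # 1=stay, 2=other city, 3=ORE
    sel2 <- dest == 2L
    por[idxCity[sel2]] <- other[sel2]
    porCityFlag[idxCity[sel2]] <- TRUE
    sel3 <- dest == 3L
    if (any(sel3)) {
      por[idxCity[sel3]] <- sample(oreLabels, sum(sel3), replace = TRUE,
                                   prob = oreW)
      porCityFlag[idxCity[sel3]] <- FALSE
    }
  }

  # scores: one shared genetic component plus idiosyncratic noise and
  # optional demographic effects
  k <- length(config@scoreLoadings)
  noise <- matrix(stats::rnorm(n * k), n, k) %*%
    diag(sqrt(config@scoreIdioVar), k)
  scores <- outer(g, config@scoreLoadings) + noise +
    config@demogEffects$sex * sex + config@demogEffects$age * (age - 50)
  dimnames(scores) <- list(id, names(config@scoreLoadings))

  # PCs: county-of-birth mean shift plus individual noise
  m <- ncol(config@pcCountyShift)
  pcs <- config@pcCountyShift[match(pob, config@countyLabels), , drop = FALSE] +
    matrix(stats::rnorm(n * m, 0, config@pcNoiseSD), n, m)
  dimnames(pcs) <- list(id, colnames(config@pcCountyShift))

  # educational attainment
  eaFam <- stats::rnorm(nSib, 0, sqrt(config@eaVarFam))
  eaLiab <- config@eaBetaG * gEA + eaFam[sib] +
    stats::rnorm(n, 0, sqrt(config@eaVarNoise))
  eaYears <- pmax(4, 13 + config@eaYearsScale * eaLiab)
  eaDegree <- as.integer(eaYears >= config@eaThreshold)

  cohort <- data.frame(
    individual_id = id, sex = sex, age = age, birth_year = birthYear,
    pob_county = pob, por_county = por,
    pob_city_flag = pobCityFlag, por_city_flag = porCityFlag,
    ea_years = eaYears, ea_degree = eaDegree,
    stringsAsFactors = FALSE)

  # kinship: all within-sibship pairs near 0.25, then decoys outside the window
  multi <- which(sizes >= 2)
  pr1 <- integer(0); pr2 <- integer(0)
  if (length(multi)) {
    start <- cumsum(c(0L, sizes))[seq_len(nSib)]
    pairs <- lapply(multi, function(s) {
      members <- start[s] + seq_len(sizes[s])
      cmb <- utils::combn(members, 2L)
      list(cmb[1, ], cmb[2, ])
    })
    pr1 <- unlist(lapply(pairs, `[[`, 1L))
    pr2 <- unlist(lapply(pairs, `[[`, 2L))
  }
  kin <- 0.25 + stats::rnorm(length(pr1), 0, config@kinshipNoiseSD)
  kin <- pmin(pmax(kin, 0.178), 0.353)
  kinship <- data.frame(ID1 = id[pr1], ID2 = id[pr2], Kinship = kin,
                        stringsAsFactors = FALSE)
  if (config@nDecoyPairs > 0 && nSib >= 2) {
    d1 <- sample.int(n, config@nDecoyPairs, replace = TRUE)
    d2 <- sample.int(n, config@nDecoyPairs, replace = TRUE)
    ok <- sib[d1] != sib[d2]
    d1 <- d1[ok]; d2 <- d2[ok]
    swap <- d1 > d2
    tmp <- d1[swap]; d1[swap] <- d2[swap]; d2[swap] <- tmp
    dup <- duplicated(cbind(d1, d2))
    d1 <- d1[!dup]; d2 <- d2[!dup]
    nd <- length(d1)
    low <- stats::runif(nd, 0.01, 0.17)
    high <- stats::runif(nd, 0.36, 0.45)
    dkin <- ifelse(seq_len(nd) %% 2 == 0, high, low)
    kinship <- rbind(kinship,
                     data.frame(ID1 = id[d1], ID2 = id[d2], Kinship = dkin,
                                stringsAsFactors = FALSE))
  }

  if (length(config@migWithinBetween) == 2) {
    betaW <- config@migWithinBetween[1]
    betaB <- config@migWithinBetween[2]
  } else {
    betaW <- config@migBetaG
    # approximate: marginalizes the family environment over the family mean
    # (size-2 regression of gFam on the sibship mean), exact when
    # migEnvLoading == 0
    betaB <- config@migBetaG + config@migEnvLoading * config@varFamily /
      (config@varFamily + config@varMendelian / 2)
  }
  truth <- list(
    migBetaG = if (length(config@migWithinBetween) == 2)
      NA_real_ else config@migBetaG,
    betaWithinTrue = betaW, betaBetweenTrue = betaB,
    eaGeneticCor = config@eaGeneticCor,
    g = structure(g, names = id),
    gFam = gFam, sibship = structure(sib, names = id),
    config = config)

  new("SyntheticCohort", cohort = cohort, scores = scores, pcs = pcs,
      kinship = kinship, truth = truth)
}
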