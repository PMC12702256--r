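# small, fast configurations used across test files

tinyConfig <- function(nSibships = 400, seed = 1L, ...) {
  simConfig(nSibships = nSibships, nDecoyPairs = 50, seed = seed, ...)
}

# a cohort data.frame built by hand, for tests that need full control
handCohort <- function(ids, pob, por, pobFlag = FALSE, porFlag = FALSE,
                       sex = 0L, age = 40, birthYear = 1970) {
  n <- length(ids)
  data.frame(individual_id = ids,
             sex = rep_len(sex, n), age = rep_len(age, n),
             birth_year = rep_len(birthYear, n),
             pob_county = pob, por_county = por,
             pob_city_flag = rep_len(pobFlag, n),
             por_city_flag = rep_len(porFlag, n),
             stringsAsFactors = FALSE)
}

# brute-force two-loop sums-of-squares oracle for the variance partition
bruteVarCounty <- function(values, labels) {
  grand <- mean(values)
  ssb <- 0; ssw <- 0
  for (g in unique(labels)) {
    grp <- values[labels == g]
    ssb <- ssb + length(grp) * (mean(grp) - grand)^2
    for (x in grp) ssw <- ssw + (x - mean(grp))^2
  }
  list(ssb = ssb, ssw = ssw, stat = ssb / (ssb + ssw))
}

defaultScheme <- function() areaScheme(c(Tallinn = "C01", Tartu = "C02"))
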