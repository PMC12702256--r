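# Example run configuration for migsel::runPipeline().
# Point the inputs at files written by the `simulate` CLI subcommand (or at
# your own cohort in the same dialects).
inputs:
  cohort: migsel-sim/cohort.tsv
  scores: migsel-sim/scores.eigenvec
  pcs: migsel-sim/pcs.eigenvec
  kinship: migsel-sim/kinship.kin0
cityCounties:
  Tallinn: C01
  Tartu: C02
countyVocabulary: [C01, C02, C03, C04, C05, C06, C07, C08,
                   C09, C10, C11, C12, C13, C14, C15]
stages:
  adjust: true
  varcounty: true
  sibling: true
  contrasts: true
  regression: true
nPCs: 100
nNullSims: 10140
bonferroniTests:
  scores: 169
  pcs: 100
kinshipCutoff: 0.088
filters: {}
seed: 1
outputDir: migsel-results
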