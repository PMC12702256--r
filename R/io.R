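.requiredCohortCols <- c("individual_id", "sex", "age", "birth_year",
                         "pob_county", "por_county")

#' Read and write the cohort table
#'
#' The cohort table is tab-separated with a header and one row per
#' individual: `individual_id`, `sex` (0/1), `age`, `birth_year`,
#' `pob_county`, `por_county`, optional `pob_city_flag`/`por_city_flag`
#' (logical), `ea_years`, `ea_degree`. `readCohort()` validates ids for
#' uniqueness and, when a county vocabulary is supplied, rejects unknown
#' county labels with their row numbers.
#'
#' @param path file path.
#' @param countyVocabulary optional character vector of valid county labels.
#' @return `readCohort()`: validated data.frame. `writeCohort()`: the path,
#'   invisibly.
#' @export
readCohort <- function(path, countyVocabulary = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  if (file.size(path) == 0) stop("cohort file is empty: ", path)
  x <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(x) == 0) stop("cohort file has a header but no rows: ", path)
  missingCols <- setdiff(.requiredCohortCols, names(x))
  if (length(missingCols))
    stop("cohort file is missing required column(s): ",
         paste(missingCols, collapse = ", "))
  if (anyDuplicated(x$individual_id))
    stop("duplicate individual ids in cohort file")
  if (!is.null(countyVocabulary)) {
    badB <- which(!(x$pob_county %in% countyVocabulary))
    badR <- which(!(x$por_county %in% countyVocabulary))
    if (length(badB) || length(badR))
      stop("unknown county label(s); offending rows: ",
           paste(utils::head(sort(unique(c(badB, badR))), 20),
                 collapse = ", "))
  }
  for (fl in c("pob_city_flag", "por_city_flag"))
    if (fl %in% names(x)) x[[fl]] <- as.logical(x[[fl]])
  x
}

#' @rdname readCohort
#' @param cohort data.frame to write.
#' @export
writeCohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write score/PC matrices in the eigenvec dialect
#'
#' Whitespace-delimited files whose first two columns are family and
#' individual id (`FID IID`) followed by numeric columns; a header line is
#' optional and auto-detected by a non-numeric third field.
#'
#' @param path file path.
#' @param columnNames names for the numeric columns when the file has no
#'   header (default `V1`, `V2`, ...).
#' @return `readEigenvec()`: numeric matrix with individual ids as rownames.
#'   `writeEigenvec()`: the path, invisibly.
#' @export
readEigenvec <- function(path, columnNames = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- strsplit(trimws(readLines(path, n = 1L)), "[ \t]+")[[1]]
  hasHeader <- length(first) >= 3 && is.na(suppressWarnings(
    as.numeric(first[3])))
  x <- utils::read.table(path, header = hasHeader, stringsAsFactors = FALSE)
  ids <- as.character(x[[2]])
  m <- as.matrix(x[, -(1:2), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (!hasHeader) {
    colnames(m) <- if (is.null(columnNames))
      paste0("V", seq_len(ncol(m))) else columnNames
  }
  m
}

#' @rdname readEigenvec
#' @param m matrix with rownames (ids); the family id column is written equal
#'   to the individual id.
#' @param header write a header line (default FALSE, the plain dialect).
#' @export
writeEigenvec <- function(m, path, header = FALSE) {
  df <- data.frame(FID = rownames(m), IID = rownames(m), m,
                   check.names = FALSE)
  utils::write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE,
                     col.names = header)
  invisible(path)
}

#' Read and write kinship pairs in the kin0 dialect
#'
#' Tab- or space-delimited with a header containing at least `ID1`, `ID2`
#' and `Kinship` (extra columns are ignored on read).
#'
#' @param path file path.
#' @return `readKin0()`: data.frame `ID1`, `ID2`, `Kinship`.
#'   `writeKin0()`: the path, invisibly.
#' @export
readKin0 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("ID1", "ID2", "Kinship")
  if (!all(need %in% names(x)))
    stop("kin0 file must contain columns ID1, ID2, Kinship")
  x[, need]
}

#' @rdname readKin0
#' @param pairs data.frame with `ID1`, `ID2`, `Kinship`.
#' @export
writeKin0 <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write and read a truth record
#'
#' Scalar truths are stored as a `key<TAB>value` text file; the
#' per-individual genetic values and sibship assignment go to a sidecar TSV
#' at `<path>.g.tsv`.
#'
#' @param truth truth list from [simulateCohort()].
#' @param path file path for the key-value file.
#' @return `writeTruth()`: the path, invisibly. `readTruth()`: a list with
#'   the scalar entries and, when present, the per-individual table `g`.
#' @export
writeTruth <- function(truth, path) {
  scalars <- truth[vapply(truth, function(x)
    is.numeric(x) && length(x) == 1, logical(1))]
  writeLines(sprintf("%s\t%.17g", names(scalars), unlist(scalars)), path)
  if (!is.null(truth$g)) {
    utils::write.table(
      data.frame(individual_id = names(truth$g), g = as.numeric(truth$g),
                 sibship = as.integer(truth$sibship[names(truth$g)])),
      paste0(path, ".g.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  kv <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  out <- as.list(structure(kv[[2]], names = kv[[1]]))
  gPath <- paste0(path, ".g.tsv")
  if (file.exists(gPath)) out$g <- utils::read.delim(gPath)
  out
}

#' Read a run configuration
#'
#' YAML run configuration for [runPipeline()]: input paths, county vocabulary
#' with the two city counties, per-stage toggles, subcohort filters, declared
#' test counts for the Bonferroni correction, seeds and the output directory.
#' Referenced input files must exist.
#'
#' @param path YAML file path.
#' @return Named list with defaults filled in.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    stages = list(adjust = TRUE, varcounty = TRUE, sibling = TRUE,
                  contrasts = TRUE, regression = TRUE),
    nPCs = 100, bonferroniTests = list(scores = 169, pcs = 100),
    nNullSims = 10140, seed = 1L, kinshipCutoff = 0.088,
    filters = list(), outputDir = "migsel-results")
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) {
      cfg[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]])) {
      for (k in names(defaults[[nm]]))
        if (is.null(cfg[[nm]][[k]])) cfg[[nm]][[k]] <- defaults[[nm]][[k]]
    }
  }
  for (p in c("cohort", "scores", "pcs", "kinship")) {
    if (!is.null(cfg$inputs[[p]]) && !file.exists(cfg$inputs[[p]]))
      stop("configured input file does not exist: ", cfg$inputs[[p]])
  }
  cfg
}
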