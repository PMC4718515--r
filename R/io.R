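#' Read a LINKAGE-style pedigree file
#'
#' Whitespace- or tab-delimited columns `FID IID FATHER MOTHER SEX`, with
#' optional `HOUSEHOLD` and `PROBAND` columns. `0` or `NA` denote missing
#' parents/households; sex is coded 1 = male, 2 = female. A header line is
#' detected automatically.
#'
#' @param path File path.
#' @return A validated `ped_tbl` (see [build_pedigree()]).
#' @export
read_pedigree_file <- function(path) {
  if (!file.exists(path)) abort(paste0("pedigree file not found: ", path))
  first <- readLines(path, n = 1)
  has_header <- grepl("FID|IID", toupper(first))
  raw <- tryCatch(
    utils::read.table(path, header = has_header, stringsAsFactors = FALSE,
                      colClasses = "character", comment.char = "#"),
    error = function(e) abort(paste0("cannot parse pedigree file: ", conditionMessage(e))))
  if (ncol(raw) < 5) abort("pedigree file needs at least 5 columns (FID IID FATHER MOTHER SEX)")
  nm <- c("fid", "id", "father", "mother", "sex", "household", "proband")
  names(raw)[seq_len(min(ncol(raw), 7))] <- nm[seq_len(min(ncol(raw), 7))]
  tryCatch(
    build_pedigree(raw),
    error = function(e) {
      msg <- conditionMessage(e)
      bad <- regmatches(msg, regexpr("[A-Za-z0-9_]+$", msg))
      line <- if (length(bad) == 1 && bad %in% raw$id)
        which(raw$id == bad)[1] + has_header else NA
      abort(paste0(msg, if (!is.na(line)) paste0(" (file line ", line, ")")))
    })
}

#' Write a pedigree in LINKAGE-style format
#'
#' @param ped A `ped_tbl`.
#' @param path Output path (TSV with header, sex coded 1/2, missing parents
#'   and households as 0).
#' @return `path`, invisibly.
#' @export
write_pedigree_file <- function(ped, path) {
  stopifnot(inherits(ped, "ped_tbl"))
  out <- data.frame(
    FID = ped$fid, IID = ped$id,
    FATHER = ifelse(is.na(ped$father), "0", ped$father),
    MOTHER = ifelse(is.na(ped$mother), "0", ped$mother),
    SEX = ifelse(ped$sex == "male", 1L, 2L),
    HOUSEHOLD = ifelse(is.na(ped$household), "0", ped$household),
    PROBAND = as.integer(ped$proband)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Plain CSV or TSV (by extension) with a header; must contain `fid` and
#' `id` columns.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) abort(paste0("phenotype file not found: ", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  if (!all(c("fid", "id") %in% names(d))) {
    abort("phenotype table must contain `fid` and `id` columns")
  }
  d$fid <- as.character(d$fid); d$id <- as.character(d$id)
  tibble::as_tibble(d)
}

#' Read a genotype matrix
#'
#' TSV with SNP ids in the first column and one column per individual;
#' values are allele counts 0/1/2 or imputed dosages.
#'
#' @param path File path.
#' @return Numeric matrix, SNPs in rows.
#' @export
read_genotype_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("genotype file not found: ", path))
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  g <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(g) <- "double"
  rownames(g) <- as.character(d[[1]])
  g
}

#' Write a genotype matrix as TSV
#' @param genotypes SNP-by-individual matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(genotypes, path) {
  out <- data.frame(snp = rownames(genotypes), genotypes, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export nonzero relationship coefficients as long-format TSV
#'
#' @param kin Matrix from [kinship_matrix()].
#' @param path Output path (columns `id1`, `id2`, `two_phi`).
#' @return `path`, invisibly.
#' @export
write_kinship_tsv <- function(kin, path) {
  utils::write.table(kinship_pairs(kin), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON record of the seed, package version and configuration that produced a
#' set of outputs, for reproducibility audits.
#'
#' @param path Output path.
#' @param seed Seed used.
#' @param config Named list of configuration values.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, seed, config = list()) {
  manifest <- list(
    package = "pedvc",
    version = as.character(utils::packageVersion("pedvc")),
    r_version = R.version.string,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    config_hash = config_hash(c(list(seed = seed), config))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  # rolling polynomial hash mod a Mersenne prime: locale-independent,
  # no extra dependencies, stable across sessions
  h <- 0
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}
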