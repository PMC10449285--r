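# Readers and writers for the pipeline's delimited formats.

PHENO_REQUIRED <- c("person_id", "family_id", "cohort_id", "sex",
                    "birth_year", "site", "exam_age",
                    "TG", "HDL_C", "LDL_C", "TC")

#' Read a phenotype table
#'
#' Reads a tab-separated long-format phenotype file (one row per
#' person-exam) and validates the schema: required identifier and lipid
#' columns, numeric lipids, 0/1 event indicators, and strictly increasing
#' exam ages within person.  Errors name the offending column or row.
#'
#' @param path file path.
#' @return A validated data.frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_phenotypes(df, context = path)
}

validate_phenotypes <- function(df, context = "phenotype table") {
  missing_cols <- setdiff(PHENO_REQUIRED, names(df))
  if (length(missing_cols))
    stop(context, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  for (cn in c("exam_age", "TG", "HDL_C", "LDL_C", "TC")) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1L]
      stop(sprintf("%s: column %s is not numeric (see row %d)",
                   context, cn, bad))
    }
  }
  for (cn in c("TG", "HDL_C", "LDL_C", "TC")) {
    neg <- which(df[[cn]] <= 0)
    if (length(neg))
      stop(sprintf("%s: non-positive %s at row %d", context, cn, neg[1L]))
  }
  ind_cols <- grep("^event_ind_", names(df), value = TRUE)
  for (cn in ind_cols) {
    bad <- which(!df[[cn]] %in% c(0L, 1L) & !is.na(df[[cn]]))
    if (length(bad))
      stop(sprintf("%s: %s must be 0/1 (see row %d)", context, cn,
                   bad[1L]))
  }
  o <- order(df$person_id, df$exam_age)
  same <- df$person_id[o][-1] == df$person_id[o][-length(o)]
  dup <- which(same & diff(df$exam_age[o]) <= 0)
  if (length(dup))
    stop(sprintf("%s: exam_age not strictly increasing within person %s",
                 context, df$person_id[o][dup[1L]]))
  df
}

#' Write a phenotype table as TSV
#'
#' @param pheno data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a genotype dosage table
#'
#' Expects a tab-separated file with a `person_id` column followed by one
#' dosage column per SNP (values 0, 1, 2 or NA).  Invalid dosages are
#' reported with their row and column.
#'
#' @param path file path.
#' @return A [genotype_matrix].
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (names(df)[1] != "person_id")
    stop(path, ": first column must be person_id")
  snps <- names(df)[-1]
  if (!length(snps)) stop(path, ": no SNP columns")
  d <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!(d %in% c(0, 1, 2)) & !is.na(d), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("%s: invalid dosage %s at row %d, SNP %s", path,
                 format(d[bad[1, 1], bad[1, 2]]), bad[1, 1],
                 snps[bad[1, 2]]))
  genotype_matrix(d, person_ids = df$person_id, snp_ids = snps)
}

#' Write a genotype matrix as a dosage TSV
#'
#' @param gm a [genotype_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  df <- data.frame(person_id = gm$person_ids, gm$dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read genotypes for selected SNPs from a VCF
#'
#' Extracts GT fields for the listed SNP ids from a VCF file (biallelic
#' records only) and converts them to alternate-allele dosages.  Requires
#' the `vcfR` package.
#'
#' @param path VCF file path (plain or bgzipped).
#' @param snp_ids SNP ids (VCF ID column values) to extract.
#' @return A [genotype_matrix] of alternate-allele dosages.
#' @export
read_genotypes_vcf <- function(path, snp_ids) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("package 'vcfR' is required for VCF input")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ids <- vcfR::getID(v)
  alt <- vcfR::getALT(v)
  keep <- ids %in% snp_ids & !grepl(",", alt)
  if (!any(keep)) stop("none of the requested SNPs found as biallelic records")
  gt <- vcfR::extract.gt(v[keep, ], element = "GT")
  dos <- apply(gt, c(1, 2), function(x) {
    if (is.na(x)) return(NA_integer_)
    al <- strsplit(x, "[/|]")[[1]]
    if (length(al) != 2 || any(!al %in% c("0", "1"))) return(NA_integer_)
    sum(al == "1")
  })
  genotype_matrix(t(dos), person_ids = colnames(gt),
                  snp_ids = rownames(gt))
}

#' Write association/mediation result rows as TSV
#'
#' @param rows data.frame of results.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
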