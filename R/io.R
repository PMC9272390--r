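# File dialects: every table the package reads or writes is tab-separated
# UTF-8 with one header row and "NA" as the missing token, matching GWAS
# summary-file norms. Sex is coded 0 = male, 1 = female.
dialects <- list(
  `cohort-tsv` = c("id"),
  `geno-tsv` = c("id"),
  `weights-tsv` = c("snp_id", "effect_allele", "other_allele", "weight"),
  `sumstats-tsv` = c("snp", "effect_allele", "other_allele",
                     "beta_x", "se_x", "beta_y", "se_y"),
  `gwas-tsv` = c("snp", "effect_allele", "other_allele", "beta", "se"),
  `results-tsv` = c("model_kind", "exposure", "outcome", "stratum", "n",
                    "beta", "se", "ci_low", "ci_high", "p")
)

#' Read a tab-separated analysis table
#'
#' Reads one of the package's TSV dialects, validating that the dialect's
#' required columns are present. Missing values are the "NA" token or an
#' empty cell.
#'
#' @param path File path.
#' @param dialect One of `"cohort-tsv"`, `"geno-tsv"`, `"weights-tsv"`,
#'   `"sumstats-tsv"`, `"gwas-tsv"`, `"results-tsv"`.
#' @return data.frame (for `"geno-tsv"`, a numeric dosage matrix with IDs
#'   as row names).
#' @export
read_table <- function(path, dialect = names(dialects)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         na.strings = c("NA", ""), check.names = FALSE,
                         stringsAsFactors = FALSE)
  need <- dialects[[dialect]]
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  message("read ", nrow(d), " rows from ", path, " [", dialect, "]")
  if (dialect == "geno-tsv") {
    G <- data.matrix(d[setdiff(names(d), "id")])
    rownames(G) <- as.character(d$id)
    return(G)
  }
  d
}

#' Write a tab-separated analysis table
#'
#' @param x data.frame, or a dosage matrix for `"geno-tsv"`.
#' @param path Output path.
#' @param dialect Dialect name; the required-column schema is checked
#'   before writing.
#' @export
write_table <- function(x, path, dialect = names(dialects)) {
  dialect <- match.arg(dialect)
  if (dialect == "geno-tsv" && is.matrix(x))
    x <- data.frame(id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  miss <- setdiff(dialects[[dialect]], names(x))
  if (length(miss))
    stop("refusing to write ", dialect, " without column(s): ",
         paste(miss, collapse = ", "))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Emits the genotype dosage TSV, phenotype TSV, the two SNP-weight TSVs
#' and a truth JSON holding every generative coefficient.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genotypes = file.path(dir, "genotypes.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    weights_bmi = file.path(dir, "weights_bmi.tsv"),
    weights_whr = file.path(dir, "weights_whr.tsv"),
    truth = file.path(dir, "truth.json"))
  write_table(cohort$genotypes, paths["genotypes"], "geno-tsv")
  write_table(cohort$phenotypes, paths["phenotypes"], "cohort-tsv")
  write_table(cohort$weights_bmi, paths["weights_bmi"], "weights-tsv")
  write_table(cohort$weights_whr, paths["weights_whr"], "weights-tsv")
  jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Join phenotypes with risk scores into an analysis cohort
#'
#' Inner join on the shared ID column, with an optional eligibility
#' filter requiring at least one non-missing outcome. Join losses are
#' logged; duplicate IDs are an error.
#'
#' @param phenotypes data.frame with an `id` column.
#' @param scores data.frame with `id` plus score columns (e.g. from
#'   [build_grs()], renamed as needed).
#' @param require_outcomes Optional character vector of outcome columns;
#'   rows missing all of them are dropped (the "eligible for >= 1
#'   analysis" rule).
#' @return Merged data.frame.
#' @export
merge_cohort <- function(phenotypes, scores, require_outcomes = NULL) {
  for (d in list(phenotypes, scores))
    if (!"id" %in% names(d)) stop("both tables need an 'id' column")
  if (anyDuplicated(phenotypes$id)) stop("duplicate IDs in phenotypes")
  if (anyDuplicated(scores$id)) stop("duplicate IDs in scores")
  shared <- intersect(phenotypes$id, scores$id)
  if (length(shared) == 0L) stop("no shared IDs between phenotypes and scores")
  lost <- nrow(phenotypes) - length(shared)
  if (lost > 0L) message("merge_cohort: ", lost, " phenotype row(s) lost in join")
  out <- merge(phenotypes, scores, by = "id")
  if (!is.null(require_outcomes)) {
    oc <- intersect(require_outcomes, names(out))
    if (length(oc)) {
      keep <- rowSums(!is.na(out[oc])) >= 1L
      if (any(!keep))
        message("merge_cohort: dropping ", sum(!keep),
                " row(s) with no non-missing outcome")
      out <- out[keep, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out
}

#' Read allele dosages from a VCF file
#'
#' Uses the DS FORMAT field when present, otherwise computes dosage from
#' GT (count of ALT alleles; half-calls and missing genotypes become
#' missing). The ALT allele is the effect allele.
#'
#' @param path Path to a VCF file.
#' @return Numeric dosage matrix, samples in rows, variants in columns
#'   (named by ID); attribute `"alleles"` is a data.frame of snp_id,
#'   effect_allele (ALT), other_allele (REF).
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf_dosages needs the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ids <- v@fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(v@fix[, "CHROM"], ":", v@fix[, "POS"])[is.na(ids) | ids == "."]
  fmt <- v@gt[, 1L]
  has_ds <- all(grepl("DS", fmt, fixed = TRUE))
  if (has_ds) {
    D <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(g) {
      if (is.na(g)) return(NA_real_)
      al <- strsplit(g, "[/|]")[[1]]
      if (any(al == ".")) return(NA_real_) # half-call
      sum(al != "0")
    }
    D <- apply(gt, c(1, 2), count_alt)
  }
  out <- t(D)
  colnames(out) <- ids
  attr(out, "alleles") <- data.frame(
    snp_id = ids, effect_allele = v@fix[, "ALT"],
    other_allele = v@fix[, "REF"], stringsAsFactors = FALSE)
  out
}
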