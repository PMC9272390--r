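#' Build a genetic risk score from dosages and SNP weights
#'
#' Standard scoring: each individual's score is the effect-allele dosage
#' multiplied by its per-allele weight, summed over SNPs and divided by
#' the number of SNPs used, so the score reflects the average per-SNP
#' effect on the exposure. Weight SNPs absent from the genotype matrix
#' are excluded and counted; if the absent fraction exceeds
#' `allow_missing` an error is raised. Dosages are assumed already
#' aligned to the weight file's effect alleles (alignment of external
#' summary files is the harmoniser's job, see [harmonise_sumstats()]).
#'
#' @param geno Numeric matrix of effect-allele dosages in [0, 2],
#'   individuals in rows (row names are IDs), SNPs in columns.
#' @param weights data.frame with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `weight`.
#' @param allow_missing Maximum tolerated fraction of weight SNPs absent
#'   from the genotype matrix (default 0).
#' @param na_action How to treat missing dosages: `"average"` computes
#'   each individual's score over their observed SNPs (per-individual
#'   denominator), `"error"` refuses missing dosages.
#' @return data.frame with columns `id` and `score`, attribute
#'   `n_snps_used` giving the number of scored SNPs.
#' @export
build_grs <- function(geno, weights, allow_missing = 0,
                      na_action = c("average", "error")) {
  na_action <- match.arg(na_action)
  req <- c("snp_id", "weight")
  if (!all(req %in% names(weights)))
    stop("weights must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(weights$snp_id))
    stop("duplicate SNP in weights: ",
         paste(unique(weights$snp_id[duplicated(weights$snp_id)]), collapse = ", "))
  present <- weights$snp_id %in% colnames(geno)
  if (!any(present)) stop("no weight SNPs present in the genotype matrix")
  frac_missing <- mean(!present)
  if (frac_missing > allow_missing)
    stop(sprintf("%d of %d weight SNPs (%.1f%%) absent from genotypes exceeds allow_missing = %g",
                 sum(!present), length(present), 100 * frac_missing, allow_missing))
  w <- weights$weight[present]
  D <- geno[, weights$snp_id[present], drop = FALSE]
  if (any(D < 0 | D > 2, na.rm = TRUE)) stop("dosages outside [0, 2]")
  if (anyNA(D) && na_action == "error")
    stop("missing dosages present and na_action = 'error'")
  m_i <- rowSums(!is.na(D))
  if (any(m_i == 0L)) stop("some individuals have no observed scored SNPs")
  contrib <- sweep(D, 2L, w, `*`)
  score <- rowSums(contrib, na.rm = TRUE) / m_i
  out <- data.frame(id = rownames(geno), score = score,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_snps_used") <- ncol(D)
  out
}

#' Correlation between two risk scores
#'
#' Pearson correlation of two scores on the intersection of their
#' individual IDs.
#'
#' @param score_a,score_b data.frames as returned by [build_grs()].
#' @return Pearson correlation coefficient.
#' @export
grs_correlation <- function(score_a, score_b) {
  shared <- intersect(score_a$id, score_b$id)
  if (length(shared) < 3L) stop("fewer than 3 shared individuals")
  stats::cor(score_a$score[match(shared, score_a$id)],
             score_b$score[match(shared, score_b$id)])
}
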