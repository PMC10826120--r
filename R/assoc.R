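#' Basic allelic chi-square association test
#'
#' For each SNP, counts allele-1 and allele-2 copies separately in cases and
#' controls (each non-missing genotype contributes two alleles; individuals
#' missing the genotype are dropped for that SNP) and computes the Pearson
#' chi-square statistic on the resulting 2x2 table without continuity
#' correction, referred to a chi-square distribution with 1 degree of freedom.
#' Monomorphic SNPs get `chisq = 0`, `p = 1`. This reproduces the basic
#' allelic association test used as a single-locus dimension-reduction filter.
#'
#' @param cohort A [geno_cohort] with at least one case and one control.
#' @param snp_ids Optional character vector; default all SNPs.
#' @return A tibble with one row per SNP: `snp_id`, `chrom`, allele counts
#'   `a1_case`, `a2_case`, `a1_control`, `a2_control`, `chisq`, `p_value`.
#'   SNPs with no non-missing genotype in one stratum get `NA` statistics with
#'   a warning.
#' @export
allelic_assoc <- function(cohort, snp_ids = NULL) {
  stopifnot(inherits(cohort, "geno_cohort"))
  status <- cohort_status(cohort)
  if (!any(status == 1L) || !any(status == 0L)) {
    stop("cohort must contain both cases and controls", call. = FALSE)
  }
  if (!is.null(snp_ids)) cohort <- subset_snps(cohort, snp_ids)
  g <- genotypes(cohort)
  gc_case <- g[status == 1L, , drop = FALSE]
  gc_ctrl <- g[status == 0L, , drop = FALSE]

  n1 <- colSums(!is.na(gc_case))     # non-missing individuals per stratum
  n0 <- colSums(!is.na(gc_ctrl))
  a <- colSums(gc_case, na.rm = TRUE)          # A1 copies in cases
  b <- 2 * n1 - a                              # A2 copies in cases
  c_ <- colSums(gc_ctrl, na.rm = TRUE)
  d <- 2 * n0 - c_

  n <- a + b + c_ + d
  det <- a * d - b * c_
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  chisq <- ifelse(denom > 0, n * det^2 / denom, 0)
  p <- ifelse(denom > 0, stats::pchisq(chisq, 1, lower.tail = FALSE), 1)

  undefined <- n1 == 0 | n0 == 0
  if (any(undefined)) {
    warning(sum(undefined),
            " SNP(s) with all genotypes missing in one stratum: statistics NA",
            call. = FALSE)
    chisq[undefined] <- NA_real_
    p[undefined] <- NA_real_
  }
  tibble::tibble(
    snp_id = snp_meta(cohort)$snp_id,
    chrom = snp_meta(cohort)$chrom,
    a1_case = as.integer(a), a2_case = as.integer(b),
    a1_control = as.integer(c_), a2_control = as.integer(d),
    chisq = as.numeric(chisq), p_value = as.numeric(p)
  )
}

#' Allelic test for a single SNP
#'
#' Single-SNP form of [allelic_assoc()]; errors (rather than warning) when
#' the test is undefined because one stratum has no non-missing genotypes.
#'
#' @inheritParams allelic_assoc
#' @param snp_id One SNP id.
#' @return A one-row tibble as in [allelic_assoc()].
#' @export
allelic_test <- function(cohort, snp_id) {
  stopifnot(length(snp_id) == 1L)
  res <- suppressWarnings(allelic_assoc(cohort, snp_id))
  if (is.na(res$chisq)) {
    stop("allelic test undefined for ", snp_id,
         ": all genotypes missing in one stratum", call. = FALSE)
  }
  res
}

#' Filter SNPs by allelic-test p-value
#'
#' Returns the ids of SNPs whose allelic p-value is strictly below `alpha`
#' (the boundary is excluded), ordered by ascending p-value — the
#' single-locus dimension-reduction step preceding multivariate modeling.
#'
#' @param results Tibble from [allelic_assoc()].
#' @param alpha Significance threshold (default 0.01).
#' @return Character vector of SNP ids.
#' @export
filter_by_p <- function(results, alpha = 0.01) {
  stopifnot(is.data.frame(results), nrow(results) > 0)
  keep <- !is.na(results$p_value) & results$p_value < alpha
  kept <- results[keep, , drop = FALSE]
  kept$snp_id[order(kept$p_value)]
}

#' Write an allelic association table as TSV
#'
#' Column layout mirrors the `.assoc` output of standard GWAS tooling:
#' `SNP`, `CHR`, allele counts, `CHISQ`, `P`.
#'
#' @param results Tibble from [allelic_assoc()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_assoc_tsv <- function(results, path) {
  out <- data.frame(
    SNP = results$snp_id, CHR = results$chrom,
    A1_CASE = results$a1_case, A2_CASE = results$a2_case,
    A1_CTRL = results$a1_control, A2_CTRL = results$a2_control,
    CHISQ = results$chisq, P = results$p_value
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
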