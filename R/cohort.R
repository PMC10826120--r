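#' Construct a case-control genotype cohort
#'
#' Bundles an individuals-by-SNPs genotype matrix (0/1/2 = count of allele-1
#' copies, `NA` = missing) with per-SNP metadata and a binary disease status
#' per individual (0 = control, 1 = case).
#'
#' @param genotypes Integer matrix, individuals in rows, SNPs in columns;
#'   values in `{0, 1, 2, NA}`.
#' @param snp_meta Tibble/data frame with one row per SNP and columns
#'   `chrom`, `snp_id`, `pos`, `allele1`, `allele2`. `snp_id`s must be unique.
#' @param ind_ids Character vector of unique individual ids (one per row).
#' @param status Integer vector of disease status per individual, 0 = control,
#'   1 = case.
#' @return An object of class `geno_cohort`.
#' @export
geno_cohort <- function(genotypes, snp_meta, ind_ids, status) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  snp_meta <- tibble::as_tibble(snp_meta)
  ind_ids <- as.character(ind_ids)
  status <- as.integer(status)
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  }
  need <- c("chrom", "snp_id", "pos", "allele1", "allele2")
  if (!all(need %in% names(snp_meta))) {
    stop("`snp_meta` needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(snp_meta) != ncol(genotypes)) {
    stop("`snp_meta` rows must match genotype columns", call. = FALSE)
  }
  if (length(ind_ids) != nrow(genotypes)) {
    stop("`ind_ids` must match genotype rows", call. = FALSE)
  }
  if (anyDuplicated(snp_meta$snp_id)) stop("duplicated snp ids", call. = FALSE)
  if (anyDuplicated(ind_ids)) stop("duplicated individual ids", call. = FALSE)
  if (length(status) != nrow(genotypes) || !all(status %in% 0:1)) {
    stop("`status` must be 0/1, one per individual", call. = FALSE)
  }
  colnames(genotypes) <- snp_meta$snp_id
  rownames(genotypes) <- ind_ids
  structure(
    list(genotypes = genotypes, snp_meta = snp_meta,
         ind_ids = ind_ids, status = status),
    class = "geno_cohort"
  )
}

#' Genotype matrix of a cohort
#' @param cohort A [geno_cohort].
#' @return Integer matrix, individuals by SNPs.
#' @export
genotypes <- function(cohort) cohort$genotypes

#' Per-SNP metadata of a cohort
#' @param cohort A [geno_cohort].
#' @return Tibble with one row per SNP.
#' @export
snp_meta <- function(cohort) cohort$snp_meta

#' Disease status vector of a cohort (0 = control, 1 = case)
#' @param cohort A [geno_cohort].
#' @return Integer vector.
#' @export
cohort_status <- function(cohort) cohort$status

#' Ground truth of a simulated cohort
#'
#' For cohorts produced by [simulate_cohort()], the planted-signal record:
#' ids of marginal-effect SNPs and the id triplets of planted penetrance
#' triplets. `NULL` for cohorts read from disk.
#'
#' @param cohort A [geno_cohort].
#' @return A list with elements `marginal` and `triplets`, or `NULL`.
#' @export
planted_truth <- function(cohort) attr(cohort, "truth", exact = TRUE)

#' @export
print.geno_cohort <- function(x, ...) {
  cat(sprintf(
    "<geno_cohort> %d individuals (%d cases / %d controls) x %d SNPs; %.2f%% missing\n",
    nrow(x$genotypes), sum(x$status == 1L), sum(x$status == 0L),
    ncol(x$genotypes), 100 * mean(is.na(x$genotypes))
  ))
  invisible(x)
}

#' @export
dim.geno_cohort <- function(x) dim(x$genotypes)

#' Subset a cohort to named SNPs
#'
#' Returns the cohort restricted to `snp_ids`, with columns (and metadata
#' rows) in the requested order.
#'
#' @param cohort A [geno_cohort].
#' @param snp_ids Character vector of SNP ids; all must be present.
#' @return A [geno_cohort] with `length(snp_ids)` SNPs.
#' @export
subset_snps <- function(cohort, snp_ids) {
  stopifnot(inherits(cohort, "geno_cohort"))
  snp_ids <- as.character(snp_ids)
  idx <- match(snp_ids, cohort$snp_meta$snp_id)
  if (anyNA(idx)) {
    stop("unknown SNP id(s): ", paste(snp_ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  out <- geno_cohort(
    cohort$genotypes[, idx, drop = FALSE],
    cohort$snp_meta[idx, , drop = FALSE],
    cohort$ind_ids,
    cohort$status
  )
  attr(out, "truth") <- attr(cohort, "truth", exact = TRUE)
  out
}

#' Long-format genotype table
#'
#' Debugging/export view of a cohort as a tidy tibble with one row per
#' individual-SNP combination.
#'
#' @param cohort A [geno_cohort].
#' @return Tibble with columns `ind_id`, `status`, `snp_id`, `genotype`.
#' @export
geno_long <- function(cohort) {
  stopifnot(inherits(cohort, "geno_cohort"))
  g <- cohort$genotypes
  tibble::tibble(
    ind_id = rep(cohort$ind_ids, times = ncol(g)),
    status = rep(cohort$status, times = ncol(g)),
    snp_id = rep(colnames(g), each = nrow(g)),
    genotype = as.integer(g)
  )
}

#' Write a cohort's genotype table to TSV
#'
#' @param cohort A [geno_cohort].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_geno_tsv <- function(cohort, path) {
  utils::write.table(
    geno_long(cohort), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
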