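#' Read PLINK 1 binary genotype data
#'
#' Reads a PLINK 1 BED/BIM/FAM file set (SNP-major, magic bytes
#' `0x6C 0x1B 0x01`) into a [geno_cohort]. Genotype codes count copies of the
#' BIM allele-1 (A1): the two-bit fields decode as `00` = homozygous A1 (code
#' 2), `10` = heterozygous (code 1), `11` = homozygous A2 (code 0), `01` =
#' missing (`NA`). FAM phenotypes follow the PLINK convention 1 = control,
#' 2 = case; individuals with phenotype `-9` or `0` (missing) are dropped with
#' a warning, since every downstream statistic is case/control stratified.
#'
#' @param prefix Path prefix; `<prefix>.bed/.bim/.fam` are read. Alternatively
#'   give the three paths explicitly.
#' @param bed,bim,fam Explicit file paths (override `prefix`).
#' @return A [geno_cohort].
#' @export
read_plink <- function(prefix = NULL, bed = NULL, bim = NULL, fam = NULL) {
  if (!is.null(prefix)) {
    bed <- bed %||% paste0(prefix, ".bed")
    bim <- bim %||% paste0(prefix, ".bim")
    fam <- fam %||% paste0(prefix, ".fam")
  }
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  }

  bim_df <- utils::read.table(
    bim, header = FALSE, colClasses = c("character", "character", "numeric",
                                        "integer", "character", "character"),
    col.names = c("chrom", "snp_id", "cm", "pos", "allele1", "allele2")
  )
  fam_df <- utils::read.table(
    fam, header = FALSE,
    col.names = c("fid", "iid", "pat", "mat", "sex", "pheno")
  )
  n_ind <- nrow(fam_df)
  n_snp <- nrow(bim_df)

  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK 1 .bed file (bad magic bytes)", call. = FALSE)
  }
  if (raw[3] != as.raw(0x01)) {
    stop("only SNP-major PLINK 1 .bed files are supported", call. = FALSE)
  }
  bpv <- ceiling(n_ind / 4)          # bytes per variant
  payload <- raw[-(1:3)]
  if (length(payload) != n_snp * bpv) {
    stop(sprintf(".bed payload has %d bytes, expected %d (%d SNPs x %d bytes)",
                 length(payload), n_snp * bpv, n_snp, bpv), call. = FALSE)
  }

  geno <- matrix(NA_integer_, nrow = n_ind, ncol = n_snp)
  if (n_snp > 0L && n_ind > 0L) {
    codes <- .plink_decode_bytes(payload)             # 4 codes per byte
    codes <- matrix(codes, nrow = 4L * bpv, ncol = n_snp)
    geno <- codes[seq_len(n_ind), , drop = FALSE]
  }

  pheno <- fam_df$pheno
  ok_codes <- pheno %in% c(1, 2, -9, 0)
  if (!all(ok_codes)) {
    stop("unsupported FAM phenotype code(s): ",
         paste(unique(pheno[!ok_codes]), collapse = ", "),
         " (expected 1/2 with -9/0 for missing)", call. = FALSE)
  }
  keep <- pheno %in% c(1, 2)
  if (any(!keep)) {
    warning(sum(!keep), " individual(s) with missing phenotype dropped",
            call. = FALSE)
  }
  geno_cohort(
    geno[keep, , drop = FALSE],
    bim_df[, c("chrom", "snp_id", "pos", "allele1", "allele2")],
    ind_ids = paste(fam_df$fid, fam_df$iid, sep = "_")[keep],
    status = as.integer(pheno[keep] == 2)
  )
}

# Decode a vector of raw bytes into genotype codes, 4 two-bit fields per byte,
# least-significant bits first: 00 -> 2 (hom A1), 01 -> NA (missing),
# 10 -> 1 (het), 11 -> 0 (hom A2). Lookup-table based for speed.
.plink_decode_bytes <- function(raw_bytes) {
  map <- c(2L, NA_integer_, 1L, 0L)
  v <- 0:255
  lut <- rbind(
    map[bitwAnd(v, 3L) + 1L],
    map[bitwAnd(bitwShiftR(v, 2L), 3L) + 1L],
    map[bitwAnd(bitwShiftR(v, 4L), 3L) + 1L],
    map[bitwAnd(bitwShiftR(v, 6L), 3L) + 1L]
  )
  as.integer(lut[, as.integer(raw_bytes) + 1L])
}

#' Write PLINK 1 binary genotype data
#'
#' Writes a [geno_cohort] as a PLINK 1 BED/BIM/FAM file set (SNP-major).
#' Inverse of [read_plink()]: `read_plink()` of the written files reproduces
#' the genotype codes and status labels bit-exactly.
#'
#' @param cohort A [geno_cohort].
#' @param prefix Output path prefix; `<prefix>.bed/.bim/.fam` are created.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(cohort, prefix) {
  stopifnot(inherits(cohort, "geno_cohort"))
  g <- cohort$genotypes
  n_ind <- nrow(g)
  n_snp <- ncol(g)

  meta <- cohort$snp_meta
  bim_lines <- sprintf("%s\t%s\t0\t%d\t%s\t%s",
                       meta$chrom, meta$snp_id, meta$pos,
                       meta$allele1, meta$allele2)
  fam_lines <- sprintf("%s\t%s\t0\t0\t0\t%d",
                       cohort$ind_ids, cohort$ind_ids,
                       ifelse(cohort$status == 1L, 2L, 1L))
  writeLines(bim_lines, paste0(prefix, ".bim"))
  writeLines(fam_lines, paste0(prefix, ".fam"))

  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  if (n_snp > 0L && n_ind > 0L) {
    # genotype code -> two-bit field: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
    bits <- matrix(1L, nrow = 4L * ceiling(n_ind / 4), ncol = n_snp)
    fld <- c(3L, 2L, 0L)[g + 1L]   # for codes 0,1,2
    fld[is.na(fld)] <- 1L
    bits[seq_len(n_ind), ] <- fld
    # padding individuals (beyond n_ind) are written as 00 per PLINK practice
    if (nrow(bits) > n_ind) bits[(n_ind + 1L):nrow(bits), ] <- 0L
    dim(bits) <- c(4L, length(bits) / 4L)
    bytes <- bits[1L, ] + bitwShiftL(bits[2L, ], 2L) +
      bitwShiftL(bits[3L, ], 4L) + bitwShiftL(bits[4L, ], 6L)
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
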