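#' Triplet-stage configuration
#'
#' Thresholds and permutation settings for the three-way interaction
#' prioritization cascade: the chi-square screen on the IIG statistic, the
#' two-way information-gain exclusion, the linkage-disequilibrium exclusion
#' and the label-shuffling permutation test.
#'
#' @param triplet_alpha Chi-square screen threshold on the IIG p-value.
#' @param pair_alpha Threshold for the two-way IG exclusion: a triplet is
#'   dropped when any of its three pairs has a significant two-way gain.
#' @param ld_r2_max Genotype-correlation `r^2` above which a pair counts as
#'   being in strong linkage disequilibrium.
#' @param n_perm Number of label permutations (1000 at the scale of a few
#'   thousand subjects; 10000 when many triplets survive).
#' @param perm_alpha Permutation p-value threshold for the final report (0.05,
#'   or 0.01 when the surviving triplet count is large).
#' @param reference Reference stratum for the "general population" information
#'   term: `"controls"` (default) or `"pooled"`.
#' @param seed Integer seed for the permutation draws.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(triplet_alpha = 0.05,
                            pair_alpha = 0.05,
                            ld_r2_max = 0.8,
                            n_perm = 1000L,
                            perm_alpha = 0.05,
                            reference = c("controls", "pooled"),
                            seed = 1L) {
  stopifnot(triplet_alpha >= 0, triplet_alpha <= 1,
            pair_alpha >= 0, pair_alpha <= 1,
            ld_r2_max >= 0, ld_r2_max <= 1,
            n_perm >= 1, perm_alpha >= 0, perm_alpha <= 1)
  structure(
    list(triplet_alpha = triplet_alpha, pair_alpha = pair_alpha,
         ld_r2_max = ld_r2_max, n_perm = as.integer(n_perm),
         perm_alpha = perm_alpha, reference = match.arg(reference),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Enumerate unordered SNP triplets
#'
#' All `choose(m, 3)` unordered combinations of the given ids, in
#' lexicographic order of positions in the input.
#'
#' @param snp_ids Character vector of at least 3 SNP ids.
#' @return Tibble with columns `snp1`, `snp2`, `snp3`.
#' @export
enumerate_triplets <- function(snp_ids) {
  snp_ids <- as.character(snp_ids)
  if (length(snp_ids) < 3L) {
    stop("need at least 3 SNP ids to form triplets", call. = FALSE)
  }
  cmb <- utils::combn(snp_ids, 3L)
  tibble::tibble(snp1 = cmb[1, ], snp2 = cmb[2, ], snp3 = cmb[3, ])
}

# Per-triplet precomputation: the 1..27 cell index over individuals with
# complete genotypes at the three SNPs. Reused across label permutations.
.triplet_cells <- function(g, idx3) {
  g1 <- g[, idx3[1]]; g2 <- g[, idx3[2]]; g3 <- g[, idx3[3]]
  complete <- which(!(is.na(g1) | is.na(g2) | is.na(g3)))
  list(cell = g1[complete] + g2[complete] * 3L + g3[complete] * 9L + 1L,
       complete = complete)
}

.pair_cells <- function(g, idx2) {
  g1 <- g[, idx2[1]]; g2 <- g[, idx2[2]]
  complete <- which(!(is.na(g1) | is.na(g2)))
  list(cell = g1[complete] + g2[complete] * 3L + 1L, complete = complete)
}

#' Screen triplets by the three-way interaction-information statistic
#'
#' Computes, for every candidate triplet, the interaction information gain
#' IIG (case minus reference), its variance normalizer `Lambda`, the test
#' statistic `T = IIG^2 / Lambda` and the chi-square(1 df) p-value, and flags
#' triplets passing `p < triplet_alpha`. Triplets for which a disease stratum
#' has no complete genotypes are skipped with a message.
#'
#' @param cohort A [geno_cohort].
#' @param triplets Tibble with columns `snp1`, `snp2`, `snp3` (e.g. from
#'   [enumerate_triplets()]); default: all triplets of the cohort's SNPs.
#' @param cfg A [pipeline_config].
#' @return Tibble with one row per evaluated triplet: the three ids, `iig`,
#'   `lambda`, `t_stat`, `p_chi2`, `direction` (`"positive"`, `"negative"` or
#'   `"zero"`), `pass_screen` and `excluded_reason` (initialized `"none"`).
#' @export
screen_triplets <- function(cohort, triplets = NULL,
                            cfg = pipeline_config()) {
  stopifnot(inherits(cohort, "geno_cohort"), inherits(cfg, "pipeline_config"))
  if (is.null(triplets)) triplets <- enumerate_triplets(snp_meta(cohort)$snp_id)
  g <- genotypes(cohort)
  status <- cohort_status(cohort)
  ids <- snp_meta(cohort)$snp_id

  rows <- purrr::pmap(triplets[, c("snp1", "snp2", "snp3")],
                      function(snp1, snp2, snp3) {
    idx3 <- match(c(snp1, snp2, snp3), ids)
    if (anyNA(idx3)) stop("unknown SNP id in triplet", call. = FALSE)
    tc <- .triplet_cells(g, idx3)
    st <- status[tc$complete]
    cc <- tabulate(tc$cell[st == 1L], 27L)
    ct <- tabulate(tc$cell[st == 0L], 27L)
    if (sum(cc) == 0L || sum(ct) == 0L) {
      message("triplet ", paste(c(snp1, snp2, snp3), collapse = "/"),
              " skipped: empty disease stratum")
      return(NULL)
    }
    s <- .gain_stat(cc, ct, 3L, reference = cfg$reference)
    tibble::tibble(
      snp1 = snp1, snp2 = snp2, snp3 = snp3,
      iig = s[["gain"]], lambda = s[["lambda"]],
      t_stat = s[["t_stat"]], p_chi2 = s[["p_chi2"]]
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(
      snp1 = character(), snp2 = character(), snp3 = character(),
      iig = numeric(), lambda = numeric(), t_stat = numeric(),
      p_chi2 = numeric(), direction = character(), pass_screen = logical(),
      excluded_reason = character()
    ))
  }
  out$direction <- dplyr::case_when(
    out$iig > 0 ~ "positive",
    out$iig < 0 ~ "negative",
    TRUE ~ "zero"
  )
  out$pass_screen <- out$p_chi2 < cfg$triplet_alpha
  out$excluded_reason <- "none"
  out
}

#' Exclude triplets explained by two-way information gain
#'
#' For each screened-in triplet, tests the two-way information gain of its
#' three SNP pairs; when any pair is significant at `pair_alpha` the triplet
#' is flagged `excluded_reason = "pairwise_2way"` — the three-way signal is
#' then not attributable purely to the triple. The three pair p-values are
#' recorded as `p_pair12`, `p_pair13`, `p_pair23`.
#'
#' @param results Tibble from [screen_triplets()].
#' @param cohort The same [geno_cohort].
#' @param cfg A [pipeline_config].
#' @return `results` with pair p-value columns and updated `excluded_reason`.
#' @export
pairwise_exclusion <- function(results, cohort, cfg = pipeline_config()) {
  stopifnot(is.data.frame(results), inherits(cohort, "geno_cohort"))
  g <- genotypes(cohort)
  status <- cohort_status(cohort)
  ids <- snp_meta(cohort)$snp_id

  pair_p <- function(a, b) {
    pc <- .pair_cells(g, match(c(a, b), ids))
    st <- status[pc$complete]
    cc <- tabulate(pc$cell[st == 1L], 9L)
    ct <- tabulate(pc$cell[st == 0L], 9L)
    if (sum(cc) == 0L || sum(ct) == 0L) return(NA_real_)
    .gain_stat(cc, ct, 2L, reference = cfg$reference)[["p_chi2"]]
  }
  # distinct pairs across all triplets, each tested once
  active <- which(results$pass_screen)
  results$p_pair12 <- NA_real_
  results$p_pair13 <- NA_real_
  results$p_pair23 <- NA_real_
  if (length(active)) {
    pairs <- unique(rbind(
      as.matrix(results[active, c("snp1", "snp2")]),
      as.matrix(results[active, c("snp1", "snp3")]),
      as.matrix(results[active, c("snp2", "snp3")])
    ))
    pvals <- apply(pairs, 1, function(p) pair_p(p[1], p[2]))
    key <- paste(pairs[, 1], pairs[, 2])
    lookup <- stats::setNames(pvals, key)
    results$p_pair12[active] <-
      lookup[paste(results$snp1[active], results$snp2[active])]
    results$p_pair13[active] <-
      lookup[paste(results$snp1[active], results$snp3[active])]
    results$p_pair23[active] <-
      lookup[paste(results$snp2[active], results$snp3[active])]
    minp <- pmin(results$p_pair12[active], results$p_pair13[active],
                 results$p_pair23[active], na.rm = TRUE)
    hit <- active[!is.na(minp) & minp < cfg$pair_alpha]
    results$excluded_reason[hit] <- "pairwise_2way"
  }
  results
}

#' Genotype-correlation r-squared between two SNPs
#'
#' Composite linkage-disequilibrium measure: the squared Pearson correlation
#' of the 0/1/2 genotype codes over individuals non-missing at both SNPs.
#' A zero-variance SNP yields 0 with a warning.
#'
#' @param cohort A [geno_cohort].
#' @param snp_a,snp_b SNP ids.
#' @return `r^2` in `[0, 1]`.
#' @export
geno_r2 <- function(cohort, snp_a, snp_b) {
  g <- genotypes(subset_snps(cohort, c(snp_a, snp_b)))
  ok <- stats::complete.cases(g)
  x <- g[ok, 1]; y <- g[ok, 2]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero-variance SNP in LD pair (", snp_a, ", ", snp_b,
            "); r^2 treated as 0", call. = FALSE)
    return(0)
  }
  stats::cor(x, y)^2
}

#' Exclude triplets containing a pair in strong linkage disequilibrium
#'
#' Flags `excluded_reason = "ld_pair"` for any screened-in, not otherwise
#' excluded triplet in which some pair's genotype-correlation `r^2` exceeds
#' `ld_r2_max`. The maximum pairwise `r^2` is recorded as `r2_max`.
#'
#' @inheritParams pairwise_exclusion
#' @return `results` with an `r2_max` column and updated `excluded_reason`.
#' @export
ld_exclusion <- function(results, cohort, cfg = pipeline_config()) {
  stopifnot(is.data.frame(results), inherits(cohort, "geno_cohort"))
  results$r2_max <- NA_real_
  active <- which(results$pass_screen)
  for (i in active) {
    r2 <- max(
      geno_r2(cohort, results$snp1[i], results$snp2[i]),
      geno_r2(cohort, results$snp1[i], results$snp3[i]),
      geno_r2(cohort, results$snp2[i], results$snp3[i])
    )
    results$r2_max[i] <- r2
    if (r2 > cfg$ld_r2_max && results$excluded_reason[i] == "none") {
      results$excluded_reason[i] <- "ld_pair"
    }
  }
  results
}

#' Permutation test of surviving triplets
#'
#' Validates the chi-square screen by label shuffling: disease status is
#' randomly permuted `n_perm` times (one shared shuffle per iteration scores
#' all triplets) and the IIG test statistic is recomputed each time. The
#' permutation p-value uses the add-one rule
#' `p = (1 + #(T_perm >= T_obs)) / (1 + n_perm)`; triplets with
#' `p_perm < perm_alpha` are flagged `significant`.
#'
#' @inheritParams pairwise_exclusion
#' @return `results` with `p_perm` and `significant` columns (set only for
#'   triplets that passed the screen and both exclusions).
#' @export
permutation_test <- function(results, cohort, cfg = pipeline_config()) {
  stopifnot(is.data.frame(results), inherits(cohort, "geno_cohort"))
  if (cfg$n_perm < 1L) stop("`n_perm` must be at least 1", call. = FALSE)
  g <- genotypes(cohort)
  status <- cohort_status(cohort)
  ids <- snp_meta(cohort)$snp_id

  results$p_perm <- NA_real_
  results$significant <- NA
  active <- which(results$pass_screen & results$excluded_reason == "none")
  if (!length(active)) return(results)

  cells <- lapply(active, function(i) {
    .triplet_cells(g, match(c(results$snp1[i], results$snp2[i],
                              results$snp3[i]), ids))
  })
  t_obs <- results$t_stat[active]

  set.seed(cfg$seed)
  exceed <- integer(length(active))
  for (b in seq_len(cfg$n_perm)) {
    perm <- sample(status)
    for (j in seq_along(active)) {
      st <- perm[cells[[j]]$complete]
      cc <- tabulate(cells[[j]]$cell[st == 1L], 27L)
      ct <- tabulate(cells[[j]]$cell[st == 0L], 27L)
      if (sum(cc) == 0L || sum(ct) == 0L) next
      tb <- .gain_stat(cc, ct, 3L, reference = cfg$reference)[["t_stat"]]
      if (tb >= t_obs[j]) exceed[j] <- exceed[j] + 1L
    }
  }
  results$p_perm[active] <- (1 + exceed) / (1 + cfg$n_perm)
  results$significant[active] <- results$p_perm[active] < cfg$perm_alpha
  results
}

#' Unique SNPs across triplet results
#'
#' Sorted distinct SNP ids over the triplet rows, optionally restricted to
#' triplets flagged significant.
#'
#' @param results Tibble with `snp1`, `snp2`, `snp3` (and `significant` when
#'   `only_significant = TRUE`).
#' @param only_significant Restrict to rows with `significant == TRUE`.
#' @return Sorted character vector of distinct SNP ids.
#' @export
unique_snps <- function(results, only_significant = FALSE) {
  stopifnot(is.data.frame(results))
  if (only_significant) {
    results <- results[!is.na(results$significant) & results$significant, ,
                       drop = FALSE]
  }
  sort(unique(c(results$snp1, results$snp2, results$snp3)))
}

#' Run the full prioritization pipeline
#'
#' End-to-end cascade on a cohort (or a PLINK fileset prefix): single-locus
#' allelic chi-square filter, two-step random-forest selection, triplet
#' enumeration, three-way interaction-information screen, two-way
#' information-gain exclusion, linkage-disequilibrium exclusion and
#' label-shuffling permutation validation. Any stage that leaves too few SNPs
#' (or no surviving triplet) terminates the cascade cleanly, recording the
#' stage that stopped it.
#'
#' @param cohort A [geno_cohort], or a character path prefix of a PLINK
#'   BED/BIM/FAM fileset.
#' @param assoc_alpha Allelic-filter threshold (default 0.01). `NULL` skips
#'   the allelic filter — appropriate when the signal of interest is purely
#'   epistatic, since a pure third-order signal has no single-locus
#'   association for the filter to find.
#' @param rf An [rf_config].
#' @param triplets A [pipeline_config].
#' @param out_dir Optional directory; per-stage TSVs and a JSON run summary
#'   are written there.
#' @return An object of class `wii_pipeline`: list with `assoc`,
#'   `assoc_kept`, `rf` (an `rf_selection` or `NULL`), `triplets` (full
#'   per-triplet tibble), `report` (significant triplets only, Table-style),
#'   `stopped_at` (`NA` or the stage name) and the configs used.
#' @export
run_pipeline <- function(cohort,
                         assoc_alpha = 0.01,
                         rf = rf_config(),
                         triplets = pipeline_config(),
                         out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_plink(cohort)
  stopifnot(inherits(cohort, "geno_cohort"))

  res <- list(assoc = NULL, assoc_kept = NULL, rf = NULL, triplets = NULL,
              report = NULL, stopped_at = NA_character_,
              config = list(assoc_alpha = assoc_alpha, rf = rf,
                            triplets = triplets))
  class(res) <- "wii_pipeline"
  empty_report <- tibble::tibble(
    snp1 = character(), snp2 = character(), snp3 = character(),
    iig = numeric(), t_stat = numeric(), p_chi2 = numeric(),
    p_perm = numeric(), direction = character()
  )
  res$report <- empty_report

  # stage 1: allelic filter
  if (!is.null(assoc_alpha)) {
    res$assoc <- allelic_assoc(cohort)
    res$assoc_kept <- filter_by_p(res$assoc, assoc_alpha)
    if (length(res$assoc_kept) < 3L) {
      res$stopped_at <- "assoc_filter"
      return(.finish_pipeline(res, out_dir))
    }
    cohort <- subset_snps(cohort, res$assoc_kept)
  } else {
    res$assoc_kept <- snp_meta(cohort)$snp_id
  }

  # stage 2: two-step random forest
  res$rf <- two_step_select(cohort, rf)
  if (length(res$rf$selected_ids) < 3L) {
    res$stopped_at <- "rf_prioritizer"
    return(.finish_pipeline(res, out_dir))
  }
  cohort <- subset_snps(cohort, res$rf$selected_ids)

  # stage 3: triplet cascade
  scr <- screen_triplets(cohort, cfg = triplets)
  scr <- pairwise_exclusion(scr, cohort, triplets)
  scr <- ld_exclusion(scr, cohort, triplets)
  surviving <- scr$pass_screen & scr$excluded_reason == "none"
  res$triplets <- scr
  if (!any(surviving)) {
    res$stopped_at <- "triplet_screen"
    return(.finish_pipeline(res, out_dir))
  }
  scr <- permutation_test(scr, cohort, triplets)
  res$triplets <- scr

  sig <- !is.na(scr$significant) & scr$significant
  res$report <- scr[sig, c("snp1", "snp2", "snp3", "iig", "t_stat",
                           "p_chi2", "p_perm", "direction"), drop = FALSE]
  res$report <- res$report[order(res$report$p_perm, res$report$p_chi2), ,
                           drop = FALSE]
  .finish_pipeline(res, out_dir)
}

.finish_pipeline <- function(res, out_dir) {
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(res$assoc)) {
      write_assoc_tsv(res$assoc, file.path(out_dir, "assoc.tsv"))
    }
    if (!is.null(res$rf)) {
      utils::write.table(
        generics::tidy(res$rf), file.path(out_dir, "rf_selection.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
    }
    if (!is.null(res$triplets)) {
      utils::write.table(
        res$triplets, file.path(out_dir, "triplets.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
    }
    utils::write.table(
      res$report, file.path(out_dir, "report.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    jsonlite::write_json(
      generics::glance(res), file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  res
}

#' @export
print.wii_pipeline <- function(x, ...) {
  cat("<wii_pipeline>\n")
  if (!is.na(x$stopped_at)) {
    cat("  stopped early at stage:", x$stopped_at, "\n")
  }
  cat(sprintf("  allelic filter kept : %s SNPs\n",
              if (is.null(x$assoc_kept)) "all" else length(x$assoc_kept)))
  if (!is.null(x$rf)) {
    cat(sprintf("  RF selection kept   : %d SNPs\n",
                length(x$rf$selected_ids)))
  }
  if (!is.null(x$triplets)) {
    cat(sprintf("  triplets screened   : %d (passed: %d)\n",
                nrow(x$triplets), sum(x$triplets$pass_screen)))
  }
  cat(sprintf("  significant triplets: %d\n", nrow(x$report)))
  invisible(x)
}
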