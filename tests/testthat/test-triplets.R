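test_that("triplet enumeration is complete, ordered and duplicate-free", {
  expect_equal(nrow(enumerate_triplets(c("a", "b", "c"))), 1L)
  tr <- enumerate_triplets(sprintf("s%02d", 1:5))
  expect_equal(nrow(tr), choose(5, 3))
  expect_false(any(duplicated(tr)))
  # within each row ids keep input order
  expect_true(all(tr$snp1 < tr$snp2 & tr$snp2 < tr$snp3))
  expect_equal(nrow(enumerate_triplets(sprintf("s%02d", 1:36))), 7140L)
  expect_error(enumerate_triplets(c("a", "b")), "at least 3")
})

test_that("screening reports signed IIG, chi-square p and direction per triplet", {
  co <- fixture_small()
  scr <- screen_triplets(co, cfg = pipeline_config(triplet_alpha = 0.05))
  expect_equal(nrow(scr), choose(12, 3))
  expect_true(all(scr$t_stat >= 0))
  expect_true(all(scr$p_chi2 >= 0 & scr$p_chi2 <= 1))
  expect_identical(scr$direction, ifelse(scr$iig > 0, "positive",
                                         ifelse(scr$iig < 0, "negative", "zero")))
  expect_true(all(scr$excluded_reason == "none"))
  # cross-check one triplet against the exported single-tuple test
  row <- scr[5, ]
  ref <- ig_test(co, c(row$snp1, row$snp2, row$snp3))
  expect_equal(row$iig, ref$gain, tolerance = 1e-12)
  expect_equal(row$t_stat, ref$t_stat, tolerance = 1e-9)
})

test_that("a planted pure pairwise signal triggers the two-way exclusion", {
  # penetrance varying with the parity of SNPs 1+2 only: a pure 2-way effect
  tab <- array(0, c(3, 3, 3))
  g <- expand.grid(0:2, 0:2, 0:2)
  tab[] <- 0.15 + 0.12 * (-1)^(g[[1]] + g[[2]])
  pt <- penetrance_triplet(c(0.5, 0.5, 0.5), tab)
  spec <- simulation_spec(1500, 1500, planted_triplets = list(pt),
                          baseline_prevalence = 0.15, seed = 404)
  co <- simulate_cohort(spec)
  cfg <- pipeline_config(triplet_alpha = 1, pair_alpha = 0.05)
  scr <- screen_triplets(co, cfg = cfg)
  scr <- pairwise_exclusion(scr, co, cfg)
  expect_equal(scr$excluded_reason, "pairwise_2way")
  expect_lt(scr$p_pair12, 0.05)

  # pair_alpha = 0 excludes nothing (vacuous threshold)
  scr0 <- pairwise_exclusion(screen_triplets(co, cfg = cfg), co,
                             pipeline_config(triplet_alpha = 1, pair_alpha = 0))
  expect_true(all(scr0$excluded_reason == "none"))
})

test_that("pure parity triplets pass the pairwise exclusion in most replicates", {
  nonsig <- 0L
  for (s in 1:6) {
    spec <- simulation_spec(1500, 1500,
      planted_triplets = list(make_parity_penetrance(base = 0.1, effect = 0.08)),
      baseline_prevalence = 0.1, seed = 6000 + s)
    co <- simulate_cohort(spec)
    cfg <- pipeline_config(triplet_alpha = 1)
    scr <- pairwise_exclusion(screen_triplets(co, cfg = cfg), co, cfg)
    nonsig <- nonsig + sum(c(scr$p_pair12, scr$p_pair13, scr$p_pair23) >= 0.05)
  }
  # 18 pair tests, all null by the purity construction
  expect_gte(nonsig, 14L)
})

test_that("LD exclusion flags duplicated and correlated SNPs but not independent ones", {
  spec <- simulation_spec(500, 500, n_background_snps = 30,
                          ld_blocks = list(list(block_size = 2, r = 0.95)),
                          baseline_prevalence = 0.5, seed = 12)
  co <- simulate_cohort(spec)
  cfg <- pipeline_config(triplet_alpha = 1, ld_r2_max = 0.8)

  # independent background SNPs: no exclusions over 100 triplets
  ids <- snp_meta(co)$snp_id[1:30]
  set.seed(2)
  some <- enumerate_triplets(ids)[sample(choose(30, 3), 100), ]
  scr <- ld_exclusion(screen_triplets(co, some, cfg), co, cfg)
  expect_true(all(scr$excluded_reason == "none"))
  expect_true(all(scr$r2_max < 0.8))

  # the LD-block pair is excluded (genotype r^2 of a thresholded latent pair
  # at r = 0.95 settles near 0.6, so the configurable threshold is set below)
  trip <- tibble::tibble(snp1 = "ld1_01", snp2 = "ld1_02", snp3 = "bg0001")
  cfg_ld <- pipeline_config(triplet_alpha = 1, ld_r2_max = 0.5)
  scr2 <- ld_exclusion(screen_triplets(co, trip, cfg_ld), co, cfg_ld)
  expect_identical(scr2$excluded_reason, "ld_pair")
  expect_gt(scr2$r2_max, 0.5)

  # a duplicated SNP column gives r^2 = 1
  g <- genotypes(co)
  g2 <- cbind(g[, 1:2], dup = g[, 1])
  co_dup <- geno_cohort(
    g2, tibble::tibble(chrom = "1", snp_id = c("s1", "s2", "dup"),
                       pos = 1:3, allele1 = "A", allele2 = "G"),
    ind_ids = cohort_status(co) |> seq_along() |> sprintf(fmt = "i%04d"),
    status = cohort_status(co)
  )
  scr3 <- ld_exclusion(screen_triplets(co_dup, cfg = cfg), co_dup, cfg)
  expect_identical(scr3$excluded_reason, "ld_pair")
  expect_equal(scr3$r2_max, 1)
})

test_that("permutation p-values respect add-one bounds and flag T = 0 as null", {
  co <- fixture_small()
  cfg <- pipeline_config(triplet_alpha = 1, n_perm = 50, perm_alpha = 0.05,
                         seed = 33)
  scr <- screen_triplets(co, enumerate_triplets(snp_meta(co)$snp_id[1:5]),
                         cfg = cfg)
  scr$t_stat[1] <- 0   # degenerate observed statistic
  out <- permutation_test(scr, co, cfg)
  expect_equal(out$p_perm[1], 1)
  expect_true(all(out$p_perm >= 1 / 51 & out$p_perm <= 1))
  # identical seed -> identical permutation p-values
  out2 <- permutation_test(scr, co, cfg)
  expect_identical(out$p_perm, out2$p_perm)
})

test_that("unique SNP counting matches a set oracle and the significance filter", {
  set.seed(14)
  ids <- sprintf("rs%03d", 1:30)
  res <- tibble::tibble(
    snp1 = sample(ids, 20, TRUE), snp2 = sample(ids, 20, TRUE),
    snp3 = sample(ids, 20, TRUE),
    significant = sample(c(TRUE, FALSE, NA), 20, TRUE)
  )
  expect_identical(unique_snps(res),
                   sort(unique(c(res$snp1, res$snp2, res$snp3))))
  sig <- res[!is.na(res$significant) & res$significant, ]
  expect_identical(unique_snps(res, only_significant = TRUE),
                   sort(unique(c(sig$snp1, sig$snp2, sig$snp3))))
  expect_identical(unique_snps(res[0, ]), character(0))
})

test_that("the published triplet tables yield 19 and 26 unique SNPs", {
  genada <- read.delim(system.file("extdata", "genada_triplets.tsv",
                                   package = "threewii"))
  adni <- read.delim(system.file("extdata", "adni_triplets.tsv",
                                 package = "threewii"))
  expect_equal(nrow(genada), 8L)
  expect_equal(nrow(adni), 17L)
  expect_equal(length(unique_snps(genada)), 19L)
  expect_equal(length(unique_snps(adni)), 26L)
})

test_that("the end-to-end pipeline is deterministic and writes its reports", {
  co <- fixture_small()
  rfc <- rf_config(ntree_grid = 60L, mtry_grid = c(3L),
                   importance_permutations = 10L, seed = 7)
  plc <- pipeline_config(n_perm = 60L, seed = 7)
  out_dir <- tempfile()
  r1 <- suppressWarnings(run_pipeline(co, assoc_alpha = NULL, rf = rfc,
                                      triplets = plc, out_dir = out_dir))
  r2 <- suppressWarnings(run_pipeline(co, assoc_alpha = NULL, rf = rfc,
                                      triplets = plc))
  expect_identical(r1$report, r2$report)
  expect_identical(r1$rf$selected_ids, r2$rf$selected_ids)
  expect_true(file.exists(file.path(out_dir, "report.tsv")))
  expect_true(file.exists(file.path(out_dir, "summary.json")))
  gl <- glance(r1)
  expect_equal(gl$n_unique_snps, length(unique_snps(r1$report)))

  # monotone bookkeeping: everything in the report survived every stage
  if (nrow(r1$report) > 0) {
    tr <- tidy(r1)
    key <- paste(tr$snp1, tr$snp2, tr$snp3)
    rep_key <- paste(r1$report$snp1, r1$report$snp2, r1$report$snp3)
    rows <- tr[match(rep_key, key), ]
    expect_true(all(rows$pass_screen))
    expect_true(all(rows$excluded_reason == "none"))
    expect_true(all(rows$p_perm < plc$perm_alpha))
  }
})

test_that("a cascade with no surviving stage terminates cleanly", {
  co <- random_cohort(60, 10, missing_rate = 0, seed = 21)
  r <- run_pipeline(co, assoc_alpha = 1e-6)
  expect_identical(r$stopped_at, "assoc_filter")
  expect_equal(nrow(r$report), 0L)
  expect_identical(glance(r)$stopped_at, "assoc_filter")
})
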