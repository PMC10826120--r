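#' Penetrance-table triplet specification
#'
#' A planted three-SNP disease signal: three minor-allele frequencies and a
#' 27-entry penetrance table `f(g1, g2, g3) = P(D = 1 | genotypes)`. When
#' `purity = TRUE` the constructor verifies that the table carries no
#' lower-order signal: marginalized over any one or two of the SNPs under
#' Hardy-Weinberg genotype frequencies, the penetrance is constant across
#' genotype classes (tolerance `1e-12`).
#'
#' @param mafs Numeric vector of three minor-allele frequencies in (0, 0.5].
#' @param penetrance Numeric `3 x 3 x 3` array (or length-27 vector) of
#'   disease probabilities, indexed by allele-1 dosage (0, 1, 2) of each SNP.
#' @param purity Logical; require (and check) zeroed lower-order effects.
#' @return An object of class `penetrance_triplet`.
#' @export
penetrance_triplet <- function(mafs, penetrance, purity = FALSE) {
  mafs <- as.numeric(mafs)
  if (length(mafs) != 3L || any(mafs <= 0) || any(mafs > 0.5)) {
    stop("`mafs` must be three frequencies in (0, 0.5]", call. = FALSE)
  }
  if (is.null(dim(penetrance))) penetrance <- array(penetrance, dim = c(3, 3, 3))
  if (!all(dim(penetrance) == 3L)) {
    stop("`penetrance` must be a 3 x 3 x 3 table", call. = FALSE)
  }
  if (any(penetrance < 0) || any(penetrance > 1)) {
    stop("penetrance entries must be probabilities in [0, 1]", call. = FALSE)
  }
  if (purity) {
    hw <- lapply(mafs, .hwe_probs)
    # single-SNP marginals
    for (j in 1:3) {
      others <- setdiff(1:3, j)
      wgt <- outer(hw[[others[1]]], hw[[others[2]]])
      marg <- apply(penetrance, j, function(sl) sum(sl * wgt))
      if (diff(range(marg)) > 1e-12) {
        stop("penetrance table is not pure: single-SNP marginal varies",
             call. = FALSE)
      }
    }
    # pairwise marginals
    for (j in 1:3) {
      pair <- setdiff(1:3, j)
      marg <- apply(penetrance, pair, function(sl) sum(sl * hw[[j]]))
      if (diff(range(marg)) > 1e-12) {
        stop("penetrance table is not pure: pairwise marginal varies",
             call. = FALSE)
      }
    }
  }
  structure(list(mafs = mafs, penetrance = penetrance, purity = purity),
            class = "penetrance_triplet")
}

# HWE genotype probabilities for allele-1 dosage 0, 1, 2 at frequency p.
.hwe_probs <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)

#' Parity penetrance table: an exactly pure third-order signal
#'
#' Builds the penetrance table
#' `f(g1, g2, g3) = base + effect * (-1)^(g1 + g2 + g3)`.
#' At minor-allele frequency 0.5 the expectation of `(-1)^g` over HWE genotype
#' frequencies (0.25, 0.5, 0.25) is exactly zero, so every single-SNP and
#' pairwise marginal penetrance equals `base`: the disease association is
#' carried purely by the three-way genotype parity.
#'
#' @param mafs Three minor-allele frequencies; must all be 0.5 for the purity
#'   guarantee (the default).
#' @param base Baseline penetrance.
#' @param effect Parity effect size; `base - effect` and `base + effect` must
#'   lie in `[0, 1]`.
#' @return A pure [penetrance_triplet].
#' @examples
#' pt <- make_parity_penetrance(base = 0.1, effect = 0.05)
#' range(pt$penetrance)  # 0.05 0.15
#' @export
make_parity_penetrance <- function(mafs = c(0.5, 0.5, 0.5), base = 0.1,
                                   effect = 0.05) {
  if (base - abs(effect) < 0 || base + abs(effect) > 1) {
    stop("`base` +/- `effect` must stay within [0, 1]", call. = FALSE)
  }
  g <- expand.grid(g1 = 0:2, g2 = 0:2, g3 = 0:2)
  f <- base + effect * (-1)^(g$g1 + g$g2 + g$g3)
  penetrance_triplet(mafs, array(f, dim = c(3, 3, 3)),
                     purity = all(mafs == 0.5))
}

#' Specification of a synthetic case-control cohort
#'
#' Fully parameterizes a simulated genotype study: cohort sizes, background
#' SNPs under Hardy-Weinberg equilibrium, optional linkage-disequilibrium
#' blocks, marginal single-SNP disease effects, planted penetrance triplets,
#' genotype missingness and the RNG seed.
#'
#' @param n_cases,n_controls Positive integers; the cohort is ascertained to
#'   these exact counts by rejection sampling.
#' @param n_background_snps Number of independent null SNPs.
#' @param maf_range Range `(low, high)` in (0, 0.5] from which background
#'   minor-allele frequencies are drawn uniformly.
#' @param ld_blocks List of `list(block_size =, r =)` entries; each block adds
#'   `block_size` SNPs whose latent haplotype Gaussians share pairwise
#'   correlation `r`.
#' @param marginal_effects List of `list(maf =, rr = c(r1, r2))` entries: a
#'   SNP with genotype relative risks `(1, r1, r2)` on the disease odds.
#' @param planted_triplets List of [penetrance_triplet] objects.
#' @param baseline_prevalence Disease probability for a genotype with no
#'   planted effect.
#' @param missing_rate Probability that any genotype call is set missing.
#' @param seed Integer RNG seed; identical specs give identical cohorts.
#' @param max_attempts Cap on rejection-sampling batches before aborting.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_cases, n_controls,
                            n_background_snps = 0L,
                            maf_range = c(0.05, 0.5),
                            ld_blocks = list(),
                            marginal_effects = list(),
                            planted_triplets = list(),
                            baseline_prevalence = 0.1,
                            missing_rate = 0,
                            seed = 1L,
                            max_attempts = 1000L) {
  stopifnot(n_cases > 0, n_controls > 0, n_background_snps >= 0)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("`maf_range` must lie within (0, 0.5]", call. = FALSE)
  }
  stopifnot(baseline_prevalence >= 0, baseline_prevalence <= 1,
            missing_rate >= 0, missing_rate <= 1)
  for (t in planted_triplets) stopifnot(inherits(t, "penetrance_triplet"))
  ld_blocks <- lapply(ld_blocks, function(b) {
    stopifnot(b$block_size >= 2, b$r >= 0, b$r < 1)
    list(block_size = as.integer(b$block_size), r = as.numeric(b$r))
  })
  for (m in marginal_effects) stopifnot(m$maf > 0, m$maf <= 0.5,
                                        length(m$rr) == 2L, all(m$rr > 0))
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         n_background_snps = as.integer(n_background_snps),
         maf_range = maf_range, ld_blocks = ld_blocks,
         marginal_effects = marginal_effects,
         planted_triplets = planted_triplets,
         baseline_prevalence = baseline_prevalence,
         missing_rate = missing_rate, seed = as.integer(seed),
         max_attempts = as.integer(max_attempts)),
    class = "simulation_spec"
  )
}

#' Simulate a case-control genotype cohort with known ground truth
#'
#' Draws genotypes under Hardy-Weinberg equilibrium (LD blocks via correlated
#' latent haplotype Gaussians thresholded at the allele frequency), assigns
#' disease status from a log-odds additive combination of the baseline
#' prevalence, per-SNP genotype relative risks and planted penetrance-table
#' deviations, and rejection-samples individuals until exactly `n_cases`
#' cases and `n_controls` controls are retained. With a single pure planted
#' triplet and no marginal effects the disease probability is exactly the
#' planted penetrance, so lower-order association is null by construction.
#'
#' @param spec A [simulation_spec].
#' @return A [geno_cohort] (cases first, then controls) whose `planted_truth()`
#'   records the ids of marginal-effect SNPs and planted triplets.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)

  # --- SNP layout -----------------------------------------------------------
  n_bg <- spec$n_background_snps
  bg_maf <- stats::runif(n_bg, spec$maf_range[1], spec$maf_range[2])
  ld_sizes <- vapply(spec$ld_blocks, `[[`, integer(1), "block_size")
  # one MAF per block: tightly linked SNPs share allele frequencies, and equal
  # thresholds limit the attenuation of the latent correlation
  ld_maf <- lapply(ld_sizes, function(k)
    rep(stats::runif(1, spec$maf_range[1], spec$maf_range[2]), k))
  marg_maf <- vapply(spec$marginal_effects, `[[`, numeric(1), "maf")
  trip_maf <- unlist(lapply(spec$planted_triplets, `[[`, "mafs"))

  ids <- c(
    if (n_bg) sprintf("bg%04d", seq_len(n_bg)),
    unlist(lapply(seq_along(ld_sizes), function(b)
      sprintf("ld%d_%02d", b, seq_len(ld_sizes[b])))),
    if (length(marg_maf)) sprintf("marg%02d", seq_along(marg_maf)),
    unlist(lapply(seq_along(spec$planted_triplets), function(t)
      sprintf("trip%d_%s", t, c("a", "b", "c"))))
  )
  mafs <- c(bg_maf, unlist(ld_maf), marg_maf, trip_maf)
  n_snp <- length(ids)
  if (n_snp == 0L) stop("the simulation has no SNPs", call. = FALSE)

  marg_idx <- match(if (length(marg_maf)) sprintf("marg%02d", seq_along(marg_maf)), ids)
  trip_idx <- lapply(seq_along(spec$planted_triplets), function(t)
    match(sprintf("trip%d_%s", t, c("a", "b", "c")), ids))

  draw_batch <- function(m) {
    g <- matrix(stats::rbinom(m * n_snp, 2L, rep(mafs, each = m)),
                nrow = m, ncol = n_snp)
    # overwrite LD-block columns with correlated-latent draws
    off <- n_bg
    for (b in seq_along(ld_sizes)) {
      k <- ld_sizes[b]; r <- spec$ld_blocks[[b]]$r
      blk <- matrix(0L, m, k)
      for (h in 1:2) {  # two haplotypes per individual
        common <- stats::rnorm(m)
        z <- sqrt(r) * common +
          sqrt(1 - r) * matrix(stats::rnorm(m * k), m, k)
        blk <- blk + (z < matrix(stats::qnorm(ld_maf[[b]]), m, k, byrow = TRUE))
      }
      g[, off + seq_len(k)] <- blk
      off <- off + k
    }
    g
  }

  disease_prob <- function(g) {
    eta <- rep(stats::qlogis(spec$baseline_prevalence), nrow(g))
    for (j in seq_along(marg_idx)) {
      rr <- c(1, spec$marginal_effects[[j]]$rr)
      eta <- eta + log(rr[g[, marg_idx[j]] + 1L])
    }
    for (t in seq_along(trip_idx)) {
      f <- spec$planted_triplets[[t]]$penetrance
      ft <- f[cbind(g[, trip_idx[[t]][1]] + 1L,
                    g[, trip_idx[[t]][2]] + 1L,
                    g[, trip_idx[[t]][3]] + 1L)]
      eta <- eta + stats::qlogis(ft) - stats::qlogis(spec$baseline_prevalence)
    }
    stats::plogis(eta)
  }

  # --- rejection sampling to exact case/control quotas ----------------------
  cases <- matrix(NA_integer_, 0L, n_snp)
  controls <- matrix(NA_integer_, 0L, n_snp)
  prev <- max(min(spec$baseline_prevalence, 1 - 1e-6), 1e-6)
  batch <- min(50000L, max(200L, ceiling(1.4 * max(spec$n_cases / prev,
                                                   spec$n_controls / (1 - prev)))))
  attempts <- 0L
  while (nrow(cases) < spec$n_cases || nrow(controls) < spec$n_controls) {
    attempts <- attempts + 1L
    if (attempts > spec$max_attempts) {
      stop(sprintf(paste0(
        "could not reach %d cases / %d controls after %d batches ",
        "(have %d / %d); penetrance may be too extreme"),
        spec$n_cases, spec$n_controls, spec$max_attempts,
        nrow(cases), nrow(controls)), call. = FALSE)
    }
    g <- draw_batch(batch)
    d <- stats::rbinom(nrow(g), 1L, disease_prob(g))
    if (nrow(cases) < spec$n_cases) {
      cases <- rbind(cases, g[d == 1L, , drop = FALSE])
    }
    if (nrow(controls) < spec$n_controls) {
      controls <- rbind(controls, g[d == 0L, , drop = FALSE])
    }
  }
  g_all <- rbind(cases[seq_len(spec$n_cases), , drop = FALSE],
                 controls[seq_len(spec$n_controls), , drop = FALSE])
  status <- rep(c(1L, 0L), c(spec$n_cases, spec$n_controls))

  if (spec$missing_rate > 0) {
    mask <- stats::runif(length(g_all)) < spec$missing_rate
    g_all[mask] <- NA_integer_
  }

  meta <- tibble::tibble(
    chrom = "1", snp_id = ids, pos = seq_len(n_snp) * 1000L,
    allele1 = "A", allele2 = "G"
  )
  out <- geno_cohort(
    g_all, meta,
    ind_ids = sprintf("ind%05d", seq_len(nrow(g_all))),
    status = status
  )
  attr(out, "truth") <- list(
    marginal = if (length(marg_idx)) ids[marg_idx] else character(0),
    triplets = lapply(trip_idx, function(i) ids[i])
  )
  out
}

#' Deterministic toy cohort used across the test suite
#'
#' A fixed-seed 60-individual, 12-SNP cohort (30 cases, 30 controls; 9
#' background SNPs plus one planted parity triplet `trip1_a/b/c`). Repeated
#' calls return bit-identical objects.
#'
#' @return A [geno_cohort] of dimension 60 x 12.
#' @export
fixture_small <- function() {
  spec <- simulation_spec(
    n_cases = 30, n_controls = 30,
    n_background_snps = 9,
    planted_triplets = list(make_parity_penetrance(base = 0.3, effect = 0.2)),
    baseline_prevalence = 0.3,
    seed = 20240130L
  )
  simulate_cohort(spec)
}
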