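# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's estimator code paths.

# Entropy by direct log-sum over cells.
oracle_entropy <- function(counts) {
  p <- as.numeric(counts) / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

# MI as sum p log(p / (px py)).
oracle_mi <- function(joint) {
  joint <- as.matrix(joint)
  n <- sum(joint)
  p <- joint / n
  px <- rowSums(p); py <- colSums(p)
  tot <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) tot <- tot + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  }
  tot
}

# Interaction information via the entropy expansion, all terms from
# oracle_entropy.
oracle_ii <- function(joint3) {
  a <- array(as.numeric(joint3), dim = c(3, 3, 3))
  oracle_entropy(apply(a, 1, sum)) + oracle_entropy(apply(a, 2, sum)) +
    oracle_entropy(apply(a, 3, sum)) -
    oracle_entropy(apply(a, c(1, 2), sum)) -
    oracle_entropy(apply(a, c(1, 3), sum)) -
    oracle_entropy(apply(a, c(2, 3), sum)) +
    oracle_entropy(a)
}

# Pearson chi-square on a 2x2 table by explicit expected counts.
oracle_chisq_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - e)^2 / e)
}

# A random cohort for round-trip / property tests.
random_cohort <- function(n_ind, n_snp, missing_rate = 0.05, seed = 1) {
  set.seed(seed)
  g <- matrix(sample(c(0:2, NA), n_ind * n_snp, replace = TRUE,
                     prob = c(0.4, 0.3, 0.25, missing_rate)),
              nrow = n_ind)
  status <- sample(0:1, n_ind, replace = TRUE)
  if (all(status == status[1])) status[1] <- 1L - status[1]
  geno_cohort(
    g,
    tibble::tibble(chrom = "1", snp_id = sprintf("s%03d", seq_len(n_snp)),
                   pos = seq_len(n_snp), allele1 = "A", allele2 = "C"),
    ind_ids = sprintf("i%03d", seq_len(n_ind)),
    status = status
  )
}

# Cell-index tabulation for a triplet, independent of the package internals.
oracle_triplet_counts <- function(cohort, ids) {
  g <- genotypes(cohort)[, ids, drop = FALSE]
  st <- cohort_status(cohort)
  ok <- stats::complete.cases(g)
  cc <- array(0L, c(3, 3, 3)); ct <- array(0L, c(3, 3, 3))
  for (i in which(ok)) {
    idx <- g[i, ] + 1L
    if (st[i] == 1L) cc[idx[1], idx[2], idx[3]] <- cc[idx[1], idx[2], idx[3]] + 1L
    else ct[idx[1], idx[2], idx[3]] <- ct[idx[1], idx[2], idx[3]] + 1L
  }
  list(case = cc, control = ct)
}
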