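#' Plug-in Shannon entropy of a count table
#'
#' Maximum-likelihood ("plug-in") entropy in nats: `H = -sum(p * log(p))` with
#' `p = counts / sum(counts)` and the convention `0 * log(0) = 0`.
#'
#' @param counts Non-negative numeric vector, matrix or array of cell counts.
#' @return Entropy in nats (a single non-negative number).
#' @examples
#' entropy(c(1, 1, 1))        # log(3)
#' entropy(c(5, 0, 0))        # 0
#' @export
entropy <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || anyNA(counts)) {
    stop("`counts` must be non-negative and free of NA", call. = FALSE)
  }
  n <- sum(counts)
  if (n <= 0) stop("entropy is undefined for an all-zero count table", call. = FALSE)
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

#' Two-way mutual information from a joint count table
#'
#' Plug-in mutual information `I(X; Y) = H(X) + H(Y) - H(X, Y)` in nats,
#' computed from a joint contingency table of counts.
#'
#' @param joint Matrix of joint counts (rows = levels of X, columns = levels of Y).
#' @return Mutual information in nats (non-negative up to numerical tolerance).
#' @export
mutual_information <- function(joint) {
  joint <- as.matrix(joint)
  entropy(rowSums(joint)) + entropy(colSums(joint)) - entropy(joint)
}

#' Three-way interaction information from a joint count table
#'
#' Plug-in interaction information of three discrete variables,
#' `I(X; Y; Z) = I(X; Y) - I(X; Y | Z)`, equivalently
#' `H(X)+H(Y)+H(Z) - H(XY) - H(XZ) - H(YZ) + H(XYZ)`.
#' Under this (McGill) sign convention a positive value indicates redundancy
#' among the three variables and a negative value synergy — information carried
#' only by the full triple, the signature of a pure third-order genotype effect.
#' The statistic is invariant under permutation of the three axes.
#'
#' @param joint3 A 3-dimensional array of joint counts (or a vector of length
#'   `prod(dim)` interpreted as a `3 x 3 x 3` array for genotype data).
#' @return Signed interaction information in nats.
#' @export
interaction_information <- function(joint3) {
  if (is.null(dim(joint3))) {
    if (length(joint3) != 27L) {
      stop("`joint3` must be a 3-d array or a length-27 vector", call. = FALSE)
    }
    joint3 <- array(as.numeric(joint3), dim = c(3L, 3L, 3L))
  }
  if (length(dim(joint3)) != 3L) {
    stop("`joint3` must have exactly three dimensions", call. = FALSE)
  }
  h1 <- entropy(apply(joint3, 1L, sum))
  h2 <- entropy(apply(joint3, 2L, sum))
  h3 <- entropy(apply(joint3, 3L, sum))
  h12 <- entropy(apply(joint3, c(1L, 2L), sum))
  h13 <- entropy(apply(joint3, c(1L, 3L), sum))
  h23 <- entropy(apply(joint3, c(2L, 3L), sum))
  h123 <- entropy(joint3)
  h1 + h2 + h3 - h12 - h13 - h23 + h123
}

# ---- internal gradient ("score weight") machinery for the delta method -----

# Log-ratio gradient of MI with respect to each cell probability of a 2-d
# table: w_xy = log(p_xy / (p_x p_y)); constant offsets drop out of the
# variance. Empty cells get weight 0 (they carry no probability mass).
.mi_weights <- function(p) {
  px <- rowSums(p)
  py <- colSums(p)
  w <- matrix(0, nrow(p), ncol(p))
  nz <- p > 0
  w[nz] <- log(p[nz]) - (log(px)[row(p)[nz]] + log(py)[col(p)[nz]])
  w
}

# Gradient of the interaction information (redundancy-positive convention)
# with respect to each cell probability of a 3-d table:
# w_xyz = log(p_xy p_xz p_yz / (p_x p_y p_z p_xyz)), offsets dropped.
.ii_weights <- function(p) {
  p1 <- apply(p, 1L, sum); p2 <- apply(p, 2L, sum); p3 <- apply(p, 3L, sum)
  p12 <- apply(p, c(1L, 2L), sum)
  p13 <- apply(p, c(1L, 3L), sum)
  p23 <- apply(p, c(2L, 3L), sum)
  w <- array(0, dim = dim(p))
  idx <- which(p > 0, arr.ind = TRUE)
  w[p > 0] <- log(p12[idx[, c(1, 2), drop = FALSE]]) +
    log(p13[idx[, c(1, 3), drop = FALSE]]) +
    log(p23[idx[, c(2, 3), drop = FALSE]]) -
    log(p1[idx[, 1]]) - log(p2[idx[, 2]]) - log(p3[idx[, 3]]) -
    log(p[p > 0])
  w
}

# Weighted variance of a multinomial score: sum(p w^2) - (sum(p w))^2
.score_var <- function(p, w) {
  sum(p * w^2) - sum(p * w)^2
}

.info_fun <- function(k) if (k == 2L) mutual_information else interaction_information
.weight_fun <- function(k) if (k == 2L) .mi_weights else .ii_weights

#' Genotype-combination counts stratified by disease status
#'
#' Tabulates the joint genotype distribution of `k` SNPs (`k` in 1..3, i.e.
#' `3^k` cells) separately for cases and controls. Individuals with a missing
#' genotype at any of the `k` SNPs are dropped for this tuple (tuple-wise
#' deletion). This table is the sufficient statistic for every entropy-based
#' test in the package.
#'
#' @param cohort A [geno_cohort] with both cases and controls.
#' @param snp_ids Character vector of 1 to 3 SNP ids.
#' @return An object of class `stratified_counts` with elements `case_counts`
#'   and `control_counts` (arrays of dimension `rep(3, k)`), `snp_ids`,
#'   `n_case`, `n_control`.
#' @export
stratified_counts <- function(cohort, snp_ids) {
  stopifnot(inherits(cohort, "geno_cohort"))
  k <- length(snp_ids)
  if (k < 1L || k > 3L) stop("`snp_ids` must name 1 to 3 SNPs", call. = FALSE)
  g <- genotypes(subset_snps(cohort, snp_ids))
  complete <- rowSums(is.na(g)) == 0L
  # column-major cell index: the first SNP varies fastest, matching array()
  cell <- rep(1L, nrow(g))
  for (j in seq_len(k)) cell <- cell + g[, j] * 3L^(j - 1L)
  status <- cohort_status(cohort)
  cc <- tabulate(cell[complete & status == 1L], nbins = 3L^k)
  ct <- tabulate(cell[complete & status == 0L], nbins = 3L^k)
  if (sum(cc) == 0L || sum(ct) == 0L) {
    stop("a disease stratum has no complete genotypes for this tuple", call. = FALSE)
  }
  structure(
    list(
      k = k,
      case_counts = array(cc, dim = rep(3L, k)),
      control_counts = array(ct, dim = rep(3L, k)),
      snp_ids = snp_ids,
      n_case = sum(cc),
      n_control = sum(ct)
    ),
    class = "stratified_counts"
  )
}

#' @export
print.stratified_counts <- function(x, ...) {
  cat(sprintf(
    "<stratified_counts> %d-SNP tuple [%s]: %d cases, %d controls\n",
    x$k, paste(x$snp_ids, collapse = ", "), x$n_case, x$n_control
  ))
  invisible(x)
}

#' Case-versus-reference information gain (IG / IIG)
#'
#' For a SNP pair this is the information gain
#' `IG = I(X, Y | affected) - I(X, Y | reference)`; for a triplet it is the
#' interaction information gain
#' `IIG = I(X, Y, Z | affected) - I(X, Y, Z | reference)`.
#' The "general population" reference defaults to the control stratum;
#' `reference = "pooled"` uses cases and controls combined instead.
#' A positive gain means the affected group carries more of the (pairwise or
#' three-way) shared information than the reference group.
#'
#' @param stratified A [stratified_counts] object with `k` of 2 or 3.
#' @param reference `"controls"` (default) or `"pooled"`.
#' @return Signed gain in nats.
#' @export
info_gain <- function(stratified, reference = c("controls", "pooled")) {
  stopifnot(inherits(stratified, "stratified_counts"))
  reference <- match.arg(reference)
  if (stratified$k < 2L) stop("information gain needs a pair or triplet", call. = FALSE)
  f <- .info_fun(stratified$k)
  ref_counts <- switch(reference,
    controls = stratified$control_counts,
    pooled = stratified$case_counts + stratified$control_counts
  )
  f(stratified$case_counts) - f(ref_counts)
}

#' Delta-method variance normalizer for an information gain
#'
#' The normalization factor `Lambda` that turns an observed IG or IIG into a
#' chi-square(1 df) test statistic. It is the first-order (delta-method)
#' variance of the plug-in gain: each stratum contributes
#' `(1/N_s) * (sum(p w^2) - (sum(p w))^2)` where `w` is the analytic gradient
#' (log-ratio score weight) of the information term with respect to the cell
#' probabilities. By default (`weights = "null"`) the weights are evaluated at
#' the pooled case+control frequencies — the consistent estimate of the common
#' cell probabilities under the screening null hypothesis that genotypes are
#' independent of disease, which is what calibrates the chi-square(1 df)
#' screen. `weights = "stratum"` evaluates each stratum's gradient at its own
#' frequencies, the plain delta-method variance of the observed gain (it
#' tracks the bootstrap variance away from the null). A small-sample floor of
#' `1e-12` is applied.
#'
#' @inheritParams info_gain
#' @param weights `"null"` (default) to evaluate score weights at the pooled
#'   frequencies, `"stratum"` for per-stratum weights.
#' @return A positive variance (nats squared).
#' @export
lambda_variance <- function(stratified, reference = c("controls", "pooled"),
                            weights = c("null", "stratum")) {
  stopifnot(inherits(stratified, "stratified_counts"))
  reference <- match.arg(reference)
  weights <- match.arg(weights)
  if (stratified$k < 2L) stop("information gain needs a pair or triplet", call. = FALSE)
  .lambda_from_arrays(stratified$case_counts, stratified$control_counts,
                      stratified$k, reference, weights)
}

.lambda_from_arrays <- function(ca, co, k, reference, weights) {
  wf <- .weight_fun(k)
  n1 <- sum(ca); n0 <- sum(co); n <- n1 + n0
  p1 <- ca / n1
  p0 <- co / n0
  pp <- (ca + co) / n
  if (weights == "null") {
    wp <- wf(pp)
    w1 <- wp; w0 <- wp
  } else {
    w1 <- wf(p1); w0 <- wf(p0)
  }
  if (reference == "controls") {
    v <- .score_var(p1, w1) / n1 + .score_var(p0, w0) / n0
  } else {
    wp <- wf(pp)
    g1 <- w1 - (n1 / n) * wp     # d gain / d p_case
    g0 <- -(n0 / n) * wp         # d gain / d p_control
    v <- .score_var(p1, g1) / n1 + .score_var(p0, g0) / n0
  }
  max(v, 1e-12)
}

#' Information-gain test statistic and chi-square p-value
#'
#' Forms the one-dimensional test statistic `T = gain^2 / Lambda` and refers
#' it to a central chi-square distribution with 1 degree of freedom (upper
#' tail), the null distribution of the normalized IG/IIG when the markers are
#' independent of disease status.
#'
#' @param gain Signed information gain in nats (from [info_gain()]).
#' @param lambda_norm Positive variance normalizer (from [lambda_variance()]).
#' @return A list with `t_stat` and `p_chi2`.
#' @export
test_statistic <- function(gain, lambda_norm) {
  if (!is.numeric(lambda_norm) || lambda_norm <= 0) {
    stop("`lambda_norm` must be positive", call. = FALSE)
  }
  t_stat <- gain^2 / lambda_norm
  list(t_stat = t_stat, p_chi2 = chisq1_pvalue(t_stat))
}

#' Upper-tail chi-square(1 df) p-value
#'
#' The mapping from an information-gain test statistic to its p-value.
#'
#' @param t_stat Non-negative statistic value(s).
#' @return Upper-tail probabilities of the chi-square distribution with 1 df.
#' @examples
#' chisq1_pvalue(8.25)   # ~0.004
#' @export
chisq1_pvalue <- function(t_stat) {
  stats::pchisq(t_stat, df = 1, lower.tail = FALSE)
}

#' Full IG/IIG test for one SNP tuple
#'
#' Convenience wrapper chaining [stratified_counts()], [info_gain()],
#' [lambda_variance()] and [test_statistic()] for a pair or triplet.
#'
#' @inheritParams stratified_counts
#' @inheritParams info_gain
#' @return A one-row tibble with the gain, `lambda`, `t_stat` and `p_chi2`.
#' @export
ig_test <- function(cohort, snp_ids, reference = c("controls", "pooled")) {
  reference <- match.arg(reference)
  sc <- stratified_counts(cohort, snp_ids)
  gain <- info_gain(sc, reference)
  lam <- lambda_variance(sc, reference)
  ts <- test_statistic(gain, lam)
  tibble::tibble(
    snp_ids = list(snp_ids),
    gain = gain,
    lambda = lam,
    t_stat = ts$t_stat,
    p_chi2 = ts$p_chi2
  )
}

# Fast internal path used by the screening / permutation loops: takes raw
# count vectors (length 9 or 27) and returns gain, lambda, T and p without
# building a stratified_counts object.
.gain_stat <- function(case_counts, control_counts, k, reference = "controls",
                       weights = "null") {
  dims <- rep(3L, k)
  ca <- array(case_counts, dim = dims)
  co <- array(control_counts, dim = dims)
  f <- .info_fun(k)
  gain <- if (reference == "controls") f(ca) - f(co) else f(ca) - f(ca + co)
  lam <- .lambda_from_arrays(ca, co, k, reference, weights)
  t_stat <- gain^2 / lam
  c(gain = gain, lambda = lam, t_stat = t_stat,
    p_chi2 = stats::pchisq(t_stat, 1, lower.tail = FALSE))
}
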