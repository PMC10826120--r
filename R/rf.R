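#' Candidate mtry grid from the feature count
#'
#' Builds a tuning grid for the number of features tried per split from the
#' square root of the feature count and its "folds": the square root, its
#' successive halvings (`s/2, s/4, s/8, s/16`) and doublings
#' (`2s, 4s, 8s`), rounded, deduplicated, sorted and clipped to
#' `[1, n_features]`.
#'
#' @param n_features Positive integer.
#' @return Sorted integer vector of candidate `mtry` values.
#' @examples
#' auto_mtry_grid(100)  # contains 10 = sqrt(100)
#' @export
auto_mtry_grid <- function(n_features) {
  stopifnot(n_features >= 1)
  s <- sqrt(n_features)
  grid <- c(round(s / 2^(1:4)), round(s * 2^(0:3)))
  grid <- pmax(1L, pmin(as.integer(n_features), as.integer(grid)))
  sort(unique(grid))
}

#' Random-forest selection configuration
#'
#' Hyperparameters of the two-step random-forest SNP selection: the tuning
#' grids, cross-validation setup, permutation-importance settings and the
#' per-stage selection thresholds. Forests use gini-impurity splits and trees
#' of maximal size (no depth limit, node size 1), with class predictions by
#' majority vote.
#'
#' @param ntree_grid Integer vector of forest sizes to tune over.
#' @param mtry_grid Integer vector, or `"auto"` to derive the grid from the
#'   feature count via [auto_mtry_grid()].
#' @param cv_folds Number of stratified cross-validation folds.
#' @param importance_permutations Number of label permutations for the
#'   importance p-values.
#' @param stage1_alpha,stage2_alpha Selection thresholds on the importance
#'   p-value (or raw importance score, see `importance_threshold`) for the two
#'   stages; defaults are 0.05 ("95% confidence"), with 0.01 as the stricter
#'   stage-2 option for larger panels.
#' @param importance_threshold `"pvalue"` (default) interprets the alphas as
#'   permutation p-value cutoffs; `"raw"` as cutoffs on the importance score
#'   itself (selecting scores greater than the alpha).
#' @param seed Integer seed controlling folds, forests and permutations.
#' @return An object of class `rf_config`.
#' @export
rf_config <- function(ntree_grid = c(250L, 500L, 1000L),
                      mtry_grid = "auto",
                      cv_folds = 5L,
                      importance_permutations = 100L,
                      stage1_alpha = 0.05,
                      stage2_alpha = 0.05,
                      importance_threshold = c("pvalue", "raw"),
                      seed = 1L) {
  stopifnot(length(ntree_grid) >= 1, all(ntree_grid >= 1),
            cv_folds >= 2, importance_permutations >= 1,
            stage1_alpha > 0, stage2_alpha > 0)
  if (!identical(mtry_grid, "auto")) {
    stopifnot(length(mtry_grid) >= 1, all(mtry_grid >= 1))
  }
  structure(
    list(ntree_grid = as.integer(ntree_grid), mtry_grid = mtry_grid,
         cv_folds = as.integer(cv_folds),
         importance_permutations = as.integer(importance_permutations),
         stage1_alpha = stage1_alpha, stage2_alpha = stage2_alpha,
         importance_threshold = match.arg(importance_threshold),
         seed = as.integer(seed)),
    class = "rf_config"
  )
}

# Genotype matrix as an all-numeric data frame for ranger, with missing
# calls imputed to the per-SNP modal genotype (forests cannot split on NA).
.rf_frame <- function(cohort) {
  g <- genotypes(cohort)
  if (anyNA(g)) {
    for (j in seq_len(ncol(g))) {
      nas <- is.na(g[, j])
      if (any(nas)) {
        tab <- tabulate(g[!nas, j] + 1L, 3L)
        g[nas, j] <- which.max(tab) - 1L
      }
    }
  }
  df <- as.data.frame(g)
  names(df) <- colnames(genotypes(cohort))
  df
}

.fit_ranger <- function(df, y, mtry, ntree, seed, importance = "none") {
  ranger::ranger(
    x = df, y = y,
    num.trees = ntree, mtry = min(mtry, ncol(df)),
    splitrule = "gini", min.node.size = 1,
    importance = importance,
    num.threads = 1, seed = seed,
    verbose = FALSE
  )
}

# Stratified fold assignment: within each class, individuals are dealt to
# folds in a random order.
.stratified_folds <- function(status, k) {
  fold <- integer(length(status))
  for (cls in unique(status)) {
    idx <- which(status == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Tune random-forest hyperparameters by stratified cross-validation
#'
#' Grid search over `mtry` x `ntree` scored by the mean misclassification
#' error across stratified `cv_folds`-fold cross-validation. Ties are broken
#' in favor of the smaller `ntree`, then the smaller `mtry`.
#'
#' @param cohort A [geno_cohort] with both classes present.
#' @param cfg An [rf_config].
#' @return A list with `best_mtry`, `best_ntree`, `cv_error` and the full
#'   `grid` tibble of scores.
#' @export
tune_rf <- function(cohort, cfg = rf_config()) {
  stopifnot(inherits(cohort, "geno_cohort"), inherits(cfg, "rf_config"))
  status <- cohort_status(cohort)
  if (length(unique(status)) < 2L) {
    stop("tuning requires both cases and controls", call. = FALSE)
  }
  if (min(table(status)) < 2L * cfg$cv_folds) {
    stop("need at least 2 individuals per class per fold", call. = FALSE)
  }
  df <- .rf_frame(cohort)
  y <- factor(status, levels = c(0L, 1L))
  mtry_grid <- if (identical(cfg$mtry_grid, "auto")) {
    auto_mtry_grid(ncol(df))
  } else {
    sort(unique(pmin(as.integer(cfg$mtry_grid), ncol(df))))
  }

  set.seed(cfg$seed)
  fold <- .stratified_folds(status, cfg$cv_folds)
  grid <- tidyr::expand_grid(ntree = cfg$ntree_grid, mtry = mtry_grid)
  grid$cv_error <- purrr::pmap_dbl(grid, function(ntree, mtry) {
    errs <- vapply(seq_len(cfg$cv_folds), function(f) {
      tr <- fold != f
      fit <- .fit_ranger(df[tr, , drop = FALSE], y[tr], mtry, ntree,
                         seed = cfg$seed + f)
      pred <- stats::predict(fit, data = df[!tr, , drop = FALSE])$predictions
      mean(pred != y[!tr])
    }, numeric(1))
    mean(errs)
  })
  best <- grid[order(grid$cv_error, grid$ntree, grid$mtry), ][1, ]
  list(best_mtry = best$mtry, best_ntree = best$ntree,
       cv_error = best$cv_error, grid = grid)
}

#' Permutation-importance p-values for SNP features
#'
#' Fits a forest on the true labels to obtain each SNP's permutation
#' importance, then builds a per-SNP null distribution from `n_perm` forests
#' fit on label-shuffled data (whole-forest refits on permuted labels). The
#' p-value uses the add-one formula
#' `p = (1 + #(null importance >= observed)) / (1 + n_perm)`, which bounds p
#' away from zero.
#'
#' @param cohort A [geno_cohort].
#' @param mtry,ntree Forest hyperparameters (typically from [tune_rf()]).
#' @param n_perm Number of label permutations (>= 1).
#' @param seed Integer seed.
#' @return Tibble with `snp_id`, `importance`, `p_value`.
#' @export
importance_pvalues <- function(cohort, mtry, ntree, n_perm = 100L, seed = 1L) {
  stopifnot(inherits(cohort, "geno_cohort"))
  if (n_perm < 1L) stop("`n_perm` must be at least 1", call. = FALSE)
  df <- .rf_frame(cohort)
  y <- factor(cohort_status(cohort), levels = c(0L, 1L))

  obs <- .fit_ranger(df, y, mtry, ntree, seed = seed,
                     importance = "permutation")$variable.importance
  set.seed(seed)
  exceed <- integer(ncol(df))
  for (b in seq_len(n_perm)) {
    yb <- sample(y)
    imp_b <- .fit_ranger(df, yb, mtry, ntree, seed = seed + b,
                         importance = "permutation")$variable.importance
    exceed <- exceed + (imp_b >= obs)
  }
  tibble::tibble(
    snp_id = names(obs),
    importance = unname(obs),
    p_value = (1 + unname(exceed)) / (1 + n_perm)
  )
}

#' Two-step random-forest SNP selection
#'
#' Stage 1 tunes a forest on all SNPs, computes permutation-importance
#' p-values and keeps SNPs below `stage1_alpha`; stage 2 re-tunes on the kept
#' subset, recomputes importance p-values and keeps SNPs below
#' `stage2_alpha`. The first forest performs dimension reduction, the second
#' models and validates the reduced SNP set. If stage 1 retains fewer than 3
#' SNPs, stage 2 is skipped with a warning and the stage-1 set is returned
#' flagged.
#'
#' @param cohort A [geno_cohort] with at least 3 SNPs.
#' @param cfg An [rf_config].
#' @return An object of class `rf_selection`: list with `selected_ids`,
#'   per-stage tibbles (`stage1`, `stage2`), per-stage tuning parameters, and
#'   `stage2_skipped`.
#' @export
two_step_select <- function(cohort, cfg = rf_config()) {
  stopifnot(inherits(cohort, "geno_cohort"), inherits(cfg, "rf_config"))
  if (ncol(genotypes(cohort)) < 3L) {
    stop("two-step selection needs at least 3 SNPs", call. = FALSE)
  }

  run_stage <- function(co, alpha, seed) {
    tuned <- tune_rf(co, .with_seed(cfg, seed))
    imp <- importance_pvalues(
      co, tuned$best_mtry, tuned$best_ntree,
      n_perm = cfg$importance_permutations, seed = seed
    )
    imp$selected <- if (cfg$importance_threshold == "pvalue") {
      imp$p_value < alpha
    } else {
      imp$importance > alpha
    }
    list(tuned = tuned, table = imp)
  }

  s1 <- run_stage(cohort, cfg$stage1_alpha, cfg$seed)
  kept1 <- s1$table$snp_id[s1$table$selected]
  if (length(kept1) < 3L) {
    warning("stage 1 selected fewer than 3 SNPs; stage 2 skipped",
            call. = FALSE)
    return(structure(
      list(selected_ids = kept1,
           stage1 = s1$table, stage2 = NULL,
           stage1_params = s1$tuned[c("best_mtry", "best_ntree", "cv_error")],
           stage2_params = NULL,
           stage2_skipped = TRUE),
      class = "rf_selection"
    ))
  }

  s2 <- run_stage(subset_snps(cohort, kept1), cfg$stage2_alpha, cfg$seed + 1000L)
  structure(
    list(selected_ids = s2$table$snp_id[s2$table$selected],
         stage1 = s1$table, stage2 = s2$table,
         stage1_params = s1$tuned[c("best_mtry", "best_ntree", "cv_error")],
         stage2_params = s2$tuned[c("best_mtry", "best_ntree", "cv_error")],
         stage2_skipped = FALSE),
    class = "rf_selection"
  )
}

.with_seed <- function(cfg, seed) {
  cfg$seed <- as.integer(seed)
  cfg
}

#' @export
print.rf_selection <- function(x, ...) {
  cat(sprintf(
    "<rf_selection> %d SNP(s) selected (stage 2 %s)\n",
    length(x$selected_ids),
    if (x$stage2_skipped) "skipped" else "completed"
  ))
  invisible(x)
}
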