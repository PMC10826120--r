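#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a two-step random-forest selection
#'
#' One row per SNP and stage, with the permutation importance, its p-value
#' and the selection flag.
#'
#' @param x An `rf_selection` from [two_step_select()].
#' @param ... Unused.
#' @return A tibble with columns `stage`, `snp_id`, `importance`, `p_value`,
#'   `selected`.
#' @method tidy rf_selection
#' @export
tidy.rf_selection <- function(x, ...) {
  out <- dplyr::bind_rows(
    dplyr::mutate(x$stage1, stage = 1L),
    if (!is.null(x$stage2)) dplyr::mutate(x$stage2, stage = 2L)
  )
  dplyr::select(out, "stage", "snp_id", "importance", "p_value", "selected")
}

#' One-row summary of a two-step random-forest selection
#'
#' @param x An `rf_selection` from [two_step_select()].
#' @param ... Unused.
#' @return A one-row tibble with the tuned parameters of each stage, the
#'   cross-validation errors and selection counts.
#' @method glance rf_selection
#' @export
glance.rf_selection <- function(x, ...) {
  tibble::tibble(
    stage1_mtry = x$stage1_params$best_mtry,
    stage1_ntree = x$stage1_params$best_ntree,
    stage1_cv_error = x$stage1_params$cv_error,
    stage1_selected = sum(x$stage1$selected),
    stage2_mtry = if (is.null(x$stage2_params)) NA_integer_ else x$stage2_params$best_mtry,
    stage2_ntree = if (is.null(x$stage2_params)) NA_integer_ else x$stage2_params$best_ntree,
    stage2_cv_error = if (is.null(x$stage2_params)) NA_real_ else x$stage2_params$cv_error,
    stage2_skipped = x$stage2_skipped,
    n_selected = length(x$selected_ids)
  )
}

#' Tidy a pipeline run
#'
#' The per-triplet result table of a [run_pipeline()] run (empty when the
#' cascade stopped before the triplet stage).
#'
#' @param x A `wii_pipeline` object.
#' @param ... Unused.
#' @return A tibble with one row per evaluated triplet.
#' @method tidy wii_pipeline
#' @export
tidy.wii_pipeline <- function(x, ...) {
  if (is.null(x$triplets)) {
    return(tibble::tibble(snp1 = character(), snp2 = character(),
                          snp3 = character()))
  }
  tibble::as_tibble(x$triplets)
}

#' One-row summary of a pipeline run
#'
#' Stage-by-stage counts of the prioritization cascade.
#'
#' @param x A `wii_pipeline` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance wii_pipeline
#' @export
glance.wii_pipeline <- function(x, ...) {
  tr <- x$triplets
  tibble::tibble(
    n_snps_assoc = length(x$assoc_kept %||% character()),
    n_snps_rf = if (is.null(x$rf)) NA_integer_ else length(x$rf$selected_ids),
    n_triplets = if (is.null(tr)) 0L else nrow(tr),
    n_pass_screen = if (is.null(tr)) 0L else sum(tr$pass_screen),
    n_excluded_pairwise = if (is.null(tr)) 0L else sum(tr$excluded_reason == "pairwise_2way"),
    n_excluded_ld = if (is.null(tr)) 0L else sum(tr$excluded_reason == "ld_pair"),
    n_significant = nrow(x$report),
    n_unique_snps = length(unique_snps(x$report)),
    stopped_at = x$stopped_at
  )
}
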