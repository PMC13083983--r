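#' Train a radiomics predictive-vector (RPV) signature pipeline
#'
#' Chains the modelling stages on a training cohort, fitting every
#' data-dependent transform inside the training data only: optional ICC
#' reliability filtering (inter-observer >= 0.8, test-retest >= 0.9),
#' standardisation to zero mean / unit SD, ComBat batch harmonisation
#' across sites, Spearman relevance-redundancy reduction, and LASSO
#' logistic regression with cross-validated penalty.  The returned object
#' carries the frozen transforms plus a manifest recording what was fitted
#' on which cases, so held-out cohorts are scored without leakage via
#' [rpv_predict()].
#'
#' @param x Training feature matrix (cases x features).
#' @param y Binary training labels.
#' @param batch Optional site/scanner labels enabling ComBat.
#' @param rater2_x,retest_x Optional replicate feature tables (same cases)
#'   switching on inter-observer / test-retest ICC filtering.
#' @param icc_interobserver,icc_retest ICC retention cutoffs.
#' @param spearman_k,redundancy_threshold Spearman-stage controls.
#' @param n_folds,seed LASSO cross-validation controls.
#' @return An object of class `rpv_fit` with the frozen pipeline and the
#'   final `signature_model`.
#' @export
rpv_train <- function(x, y, batch = NULL, rater2_x = NULL, retest_x = NULL,
                      icc_interobserver = 0.8, icc_retest = 0.9,
                      spearman_k = 50L, redundancy_threshold = 0.9,
                      n_folds = 10L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  manifest <- list(seed = seed, n_train = nrow(x),
                   n_features_in = ncol(x), steps = character(0))

  keep <- colnames(x)
  icc_tables <- list()
  if (!is.null(rater2_x)) {
    fl <- filter_features(list(x, as.matrix(rater2_x)[rownames(x), , drop = FALSE]),
                          icc_interobserver)
    keep <- intersect(keep, fl$keep)
    icc_tables$interobserver <- fl$icc_table
    manifest$steps <- c(manifest$steps,
                        sprintf("icc_interobserver>=%.2f:%d", icc_interobserver,
                                length(keep)))
  }
  if (!is.null(retest_x)) {
    fl <- filter_features(list(x[, keep, drop = FALSE],
                               as.matrix(retest_x)[rownames(x), keep, drop = FALSE]),
                          icc_retest)
    keep <- intersect(keep, fl$keep)
    icc_tables$retest <- fl$icc_table
    manifest$steps <- c(manifest$steps,
                        sprintf("icc_retest>=%.2f:%d", icc_retest, length(keep)))
  }
  if (length(keep) < 2L) stop("fewer than 2 reliable features", call. = FALSE)

  std <- suppressWarnings(standardise(x[, keep, drop = FALSE]))
  xs <- std$x
  manifest$steps <- c(manifest$steps, sprintf("standardise:%d", ncol(xs)))

  combat <- NULL
  if (!is.null(batch) && length(unique(batch)) > 1L) {
    combat <- combat_fit(xs, batch)
    xs <- combat_apply(combat, xs, batch)
    manifest$steps <- c(manifest$steps, "combat")
  }

  selected <- spearman_redundancy_filter(xs, y, redundancy_threshold,
                                         spearman_k)
  xsel <- xs[, as.character(selected), drop = FALSE]
  manifest$steps <- c(manifest$steps, sprintf("spearman:%d", ncol(xsel)))

  model <- fit_lasso_logistic(xsel, y, n_folds = n_folds, seed = seed)
  manifest$steps <- c(manifest$steps,
                      sprintf("lasso:%d", length(model$selected_features)))

  structure(list(standardiser = std, combat = combat,
                 spearman_features = as.character(selected),
                 signature = model, icc_tables = icc_tables,
                 manifest = manifest),
            class = "rpv_fit")
}

#' @export
print.rpv_fit <- function(x, ...) {
  cat("<rpv_fit>", paste(x$manifest$steps, collapse = " -> "), "\n")
  invisible(x)
}

#' Score new cases with a trained pipeline
#'
#' Applies the frozen training transforms (training means/SDs, fit-time
#' ComBat batch parameters, the selected features and LASSO weights) to a
#' held-out feature table.
#'
#' @param fit An [rpv_train()] object.
#' @param x New feature matrix (cases x features).
#' @param batch Site labels for the new cases when the fit used ComBat;
#'   batches must have been seen at fit time.
#' @return data.frame from [rpv_score()]: linear predictor, probability,
#'   positive call.
#' @export
rpv_predict <- function(fit, x, batch = NULL) {
  xs <- standardise_apply(fit$standardiser, as.matrix(x))
  if (!is.null(fit$combat)) {
    if (is.null(batch)) stop("fit used ComBat; `batch` required", call. = FALSE)
    xs <- combat_apply(fit$combat, xs, batch)
  }
  rpv_score(fit$signature, xs[, fit$spearman_features, drop = FALSE])
}

#' Held-out signature AUC as a function of the phantom label effect
#'
#' For each label-effect amplitude, generates an independent training and
#' test cohort from the phantom at that effect size, extracts the full
#' feature catalogue, trains the standardise - ComBat - Spearman - LASSO
#' pipeline on the training cohort, and reports the held-out test AUC.
#' Used to verify that the pipeline's discrimination increases with the
#' true effect size.
#'
#' @param effects Numeric vector of `label_texture_effect` values (HU).
#' @param n_train,n_test Cohort sizes per effect size.
#' @param prevalence Label prevalence in both cohorts.
#' @param seed Integer seed; train/test cohorts use disjoint derived seeds.
#' @param catalogue Feature catalogue (default [feature_catalogue()]).
#' @return data.frame with columns `effect` and `auc`.
#' @export
auc_vs_effect <- function(effects, n_train = 100L, n_test = 60L,
                          prevalence = 0.5, seed = 1L,
                          catalogue = feature_catalogue()) {
  rows <- lapply(seq_along(effects), function(i) {
    ps <- phantom_spec(label_texture_effect = effects[i])
    tr <- generate_cohort(ps, cohort_spec(n_cases = n_train,
                                          prevalence = prevalence,
                                          seed = derive_seed(seed, 20L + i)))
    te <- generate_cohort(ps, cohort_spec(n_cases = n_test,
                                          prevalence = prevalence,
                                          seed = derive_seed(seed, 40L + i)))
    xtr <- extract_cohort(tr$cases, catalogue)
    xte <- extract_cohort(te$cases, catalogue)
    fit <- rpv_train(xtr, tr$cohort$label, batch = tr$cohort$site_id,
                     seed = derive_seed(seed, 60L + i))
    pred <- rpv_predict(fit, xte, batch = te$cohort$site_id)
    roc <- roc_analysis(pred$probability, te$cohort$label,
                        n_bootstrap = 100L, seed = derive_seed(seed, 80L + i))
    data.frame(effect = effects[i], auc = roc$auc)
  })
  do.call(rbind, rows)
}
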