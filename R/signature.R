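#' Spearman relevance ranking with redundancy elimination
#'
#' Ranks features by the absolute Spearman correlation of each feature with
#' the class label, then walks down the ranking keeping a feature only if
#' its absolute pairwise Spearman correlation with every already-kept
#' feature is at or below `redundancy_threshold`; at most `k` features are
#' retained.  Constant features (Spearman undefined) are dropped and
#' flagged.
#'
#' @param x Numeric matrix, cases x features.
#' @param y Binary labels (0/1).
#' @param redundancy_threshold Pairwise |rho| above which the lower-ranked
#'   feature of a pair is discarded (default 0.9).
#' @param k Maximum number of survivors (default 50).
#' @return Character vector of surviving feature names, with attributes
#'   `relevance` (named |rho| with the label) and `dropped_constant`.
#' @export
spearman_redundancy_filter <- function(x, y, redundancy_threshold = 0.9,
                                       k = 50L) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need >= 2 features", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  constant <- colnames(x)[sds == 0 | !is.finite(sds)]
  ok <- setdiff(colnames(x), constant)
  xr <- apply(x[, ok, drop = FALSE], 2, rank)
  yr <- rank(y)
  rel <- abs(stats::cor(xr, yr))[, 1]
  ord <- names(sort(rel, decreasing = TRUE))
  kept <- character(0)
  for (f in ord) {
    if (length(kept) >= k) break
    if (length(kept) > 0) {
      rho <- abs(stats::cor(xr[, f], xr[, kept, drop = FALSE]))
      if (any(rho > redundancy_threshold)) next
    }
    kept <- c(kept, f)
  }
  structure(kept, relevance = rel, dropped_constant = constant)
}

#' Fit an L1-penalised logistic signature
#'
#' LASSO logistic regression with the penalty chosen by cross-validated
#' binomial deviance (folds fixed by `seed`, so the fit is deterministic).
#' Features with non-zero coefficients at the selected penalty become the
#' signature; the default decision threshold is the Youden-optimal cutoff
#' on the training fitted probabilities.
#'
#' @param x Numeric matrix of (standardised) features, cases x features.
#' @param y Binary labels with both classes present.
#' @param lambda Optional penalty grid passed to \pkg{glmnet}.
#' @param n_folds Cross-validation folds (default 10).
#' @param seed Integer seed fixing fold assignment.
#' @param lambda_rule `"min"` (deviance-optimal, default) or `"1se"`.
#' @return An object of class `signature_model`: `selected_features`,
#'   `weights`, `intercept`, `lambda`, `decision_threshold`, and a training
#'   `manifest` (seed, folds, n, feature count).
#' @export
fit_lasso_logistic <- function(x, y, lambda = NULL, n_folds = 10L, seed = 1L,
                               lambda_rule = c("min", "1se")) {
  lambda_rule <- match.arg(lambda_rule)
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("labels contain a single class", call. = FALSE)
  foldid <- with_seed(seed, make_stratified_folds(y, n_folds))
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                          lambda = lambda, foldid = foldid,
                          type.measure = "deviance", standardize = FALSE)
  lam <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  beta <- as.matrix(stats::coef(cv, s = lam))[, 1]
  w <- beta[-1][beta[-1] != 0]
  intercept <- beta[1]
  lp <- intercept + as.vector(x[, names(w), drop = FALSE] %*% w)
  prob <- stats::plogis(lp)
  thr <- youden_threshold(prob, y)
  structure(list(selected_features = names(w), weights = w,
                 intercept = intercept, lambda = lam,
                 decision_threshold = thr,
                 manifest = list(seed = seed, n_folds = n_folds,
                                 n_cases = nrow(x), n_features = ncol(x),
                                 lambda_rule = lambda_rule)),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat("<signature_model>", length(x$selected_features),
      "features, lambda =", signif(x$lambda, 4),
      ", threshold =", signif(x$decision_threshold, 4), "\n")
  invisible(x)
}

# Stratified fold ids: classes split separately so every fold sees both.
make_stratified_folds <- function(y, n_folds) {
  foldid <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    foldid[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  foldid
}

# Youden-optimal probability cutoff (max sensitivity + specificity - 1);
# ties broken toward the smaller threshold.
youden_threshold <- function(prob, y) {
  cuts <- sort(unique(prob))
  if (length(cuts) > 1) {
    cuts <- c(cuts[1] - 1e-9, (cuts[-1] + cuts[-length(cuts)]) / 2)
  }
  j <- vapply(cuts, function(t) {
    mean(prob[y == 1] >= t) + mean(prob[y == 0] < t) - 1
  }, 0)
  cuts[which.max(j)]
}

#' Score cases with a fitted signature
#'
#' Linear predictor `intercept + sum(w_i x_i)` and its logistic-link
#' probability; the positive call compares the probability with the model's
#' decision threshold.  A missing signature feature raises an error naming
#' it.
#'
#' @param model A `signature_model`.
#' @param x Matrix (cases x features) or a single named feature vector.
#' @return data.frame with `linear_predictor`, `probability`, `positive`.
#' @export
rpv_score <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, 1L, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  missing <- setdiff(model$selected_features, colnames(x))
  if (length(missing)) {
    stop("missing signature feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lp <- model$intercept +
    as.vector(x[, model$selected_features, drop = FALSE] %*% model$weights)
  prob <- stats::plogis(lp)
  data.frame(linear_predictor = lp, probability = prob,
             positive = prob >= model$decision_threshold)
}

#' Serialise / restore a signature model as JSON
#'
#' @param model A `signature_model`.
#' @param path JSON file path.
#' @export
signature_to_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname signature_to_json
#' @export
signature_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$weights <- stats::setNames(as.numeric(obj$weights), obj$selected_features)
  structure(obj, class = "signature_model")
}

#' Benchmark selector x learner combinations
#'
#' Evaluates every dimensionality-reduction / learner pair on one shared
#' set of stratified cross-validation folds and reports the pooled
#' out-of-fold AUROC per cell with a bootstrap confidence interval.  The
#' winning cell is the AUROC argmax, ties broken toward fewer selected
#' features.
#'
#' @param x Feature matrix (standardised), cases x features.
#' @param y Binary labels.
#' @param selectors Subset of `"spearman"`, `"variance"`, `"pca"`, `"none"`.
#' @param learners Subset of `"lasso"`, `"enet"`, `"glm"`, `"rf"`, `"svm"`,
#'   `"dummy"` (majority-class chance baseline).
#' @param n_folds Shared stratified folds (default 5).
#' @param seed Seed fixing folds and any stochastic learner.
#' @param k Features retained by each selector.
#' @return An object of class `benchmark_grid`: data.frame with columns
#'   `selector`, `learner`, `auc`, `ci_low`, `ci_high`, `n_features`, plus
#'   attribute `best` (the winning cell).
#' @export
benchmark <- function(x, y,
                      selectors = c("spearman", "variance"),
                      learners = c("lasso", "glm", "rf"),
                      n_folds = 5L, seed = 1L, k = 25L) {
  x <- as.matrix(x); y <- as.integer(y)
  if (length(selectors) < 1L || length(learners) < 1L) {
    stop("need >= 1 selector and learner", call. = FALSE)
  }
  foldid <- with_seed(seed, make_stratified_folds(y, n_folds))
  grid <- expand.grid(selector = selectors, learner = learners,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    sel <- grid$selector[g]; lrn <- grid$learner[g]
    oof <- rep(NA_real_, length(y))
    nfeat <- integer(n_folds)
    for (f in seq_len(n_folds)) {
      tr <- foldid != f
      feats <- select_features(x[tr, , drop = FALSE], y[tr], sel, k)
      nfeat[f] <- length(feats$features)
      xtr <- feats$transform(x[tr, , drop = FALSE])
      xte <- feats$transform(x[!tr, , drop = FALSE])
      oof[!tr] <- fit_predict_learner(lrn, xtr, y[tr], xte,
                                      seed = derive_seed(seed, 100L + g * 10L + f))
    }
    roc <- roc_analysis(oof, y, n_bootstrap = 200L,
                        seed = derive_seed(seed, 7L))
    data.frame(selector = sel, learner = lrn, auc = roc$auc,
               ci_low = roc$auc_ci[1], ci_high = roc$auc_ci[2],
               n_features = round(mean(nfeat)), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  best <- res[order(-res$auc, res$n_features), ][1, ]
  structure(res, best = best, class = c("benchmark_grid", "data.frame"))
}

# Selector: returns selected feature names and a transform closure (identity
# subsetting for filters; projection for PCA).
select_features <- function(x, y, selector, k) {
  switch(selector,
    none = list(features = colnames(x), transform = function(m) m),
    spearman = {
      keep <- spearman_redundancy_filter(x, y, k = k)
      list(features = as.character(keep),
           transform = function(m) m[, as.character(keep), drop = FALSE])
    },
    variance = {
      v <- apply(x, 2, stats::var)
      keep <- names(sort(v, decreasing = TRUE))[seq_len(min(k, ncol(x)))]
      list(features = keep, transform = function(m) m[, keep, drop = FALSE])
    },
    pca = {
      pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
      d <- min(k, ncol(pc$rotation))
      list(features = paste0("PC", seq_len(d)),
           transform = function(m) {
             sweep(m, 2, pc$center) %*% pc$rotation[, seq_len(d), drop = FALSE]
           })
    },
    stop("unknown selector: ", selector, call. = FALSE)
  )
}

fit_predict_learner <- function(learner, xtr, ytr, xte, seed = 1L) {
  if (length(unique(ytr)) < 2L) stop("fold with a single class", call. = FALSE)
  switch(learner,
    lasso = ,
    enet = {
      alpha <- if (learner == "lasso") 1 else 0.5
      foldid <- with_seed(seed, make_stratified_folds(ytr, 5L))
      cv <- glmnet::cv.glmnet(xtr, ytr, family = "binomial", alpha = alpha,
                              foldid = foldid, standardize = FALSE)
      as.vector(stats::predict(cv, xte, s = cv$lambda.min, type = "response"))
    },
    glm = {
      df <- data.frame(y = ytr, xtr, check.names = TRUE)
      fit <- suppressWarnings(stats::glm(y ~ ., binomial(), df))
      as.vector(stats::predict(fit, data.frame(xte, check.names = TRUE),
                               type = "response"))
    },
    rf = {
      fit <- with_seed(seed,
        randomForest::randomForest(xtr, factor(ytr), ntree = 300))
      stats::predict(fit, xte, type = "prob")[, "1"]
    },
    svm = {
      fit <- with_seed(seed,
        e1071::svm(xtr, factor(ytr), kernel = "radial", probability = TRUE))
      attr(stats::predict(fit, xte, probability = TRUE), "probabilities")[, "1"]
    },
    dummy = rep(mean(ytr), nrow(xte)),
    stop("unknown learner: ", learner, call. = FALSE)
  )
}
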