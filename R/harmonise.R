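#' Standardise a feature table
#'
#' Centres each feature to mean zero and scales to unit (population) SD.
#' Zero-variance features are dropped with a warning record rather than
#' silently producing NaN.  The fitted means/SDs can be applied to new data
#' with [standardise_apply()] so test cohorts are transformed with the
#' training parameters.
#'
#' @param x Numeric matrix, cases x features (>= 2 cases).
#' @return An object of class `standardiser`: list with `x` (the
#'   standardised table), `center`, `scale`, `dropped` (names of constant
#'   features).
#' @export
standardise <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need >= 2 cases", call. = FALSE)
  ctr <- colMeans(x)
  sds <- sqrt(colMeans(sweep(x, 2, ctr)^2))
  dropped <- colnames(x)[sds == 0 | !is.finite(sds)]
  if (length(dropped)) {
    warning(length(dropped), " constant feature(s) dropped", call. = FALSE)
  }
  keep <- setdiff(colnames(x), dropped)
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2, ctr[keep]), 2, sds[keep], "/")
  structure(list(x = xs, center = ctr[keep], scale = sds[keep],
                 dropped = dropped),
            class = "standardiser")
}

#' @rdname standardise
#' @param object A fitted `standardiser`.
#' @param newdata Matrix with at least the fitted features as columns.
#' @return `standardise_apply` returns the transformed matrix (fitted
#'   features only, training means/SDs).
#' @export
standardise_apply <- function(object, newdata) {
  feats <- names(object$center)
  missing <- setdiff(feats, colnames(newdata))
  if (length(missing)) {
    stop("newdata lacks feature(s): ", paste(utils::head(missing, 5),
                                             collapse = ", "), call. = FALSE)
  }
  sweep(sweep(as.matrix(newdata)[, feats, drop = FALSE], 2, object$center),
        2, object$scale, "/")
}

#' Fit a ComBat empirical-Bayes batch-harmonisation model
#'
#' Location/scale batch-effect model with parametric empirical-Bayes
#' shrinkage: per feature, data are standardised by the batch-size-weighted
#' grand mean and pooled variance; per-batch location (normal prior) and
#' scale (inverse-gamma prior) effects are shrunk toward their priors by the
#' standard iterative conditional scheme, run to a convergence tolerance of
#' 1e-4 (an error is raised if it is not reached).  Unlike the single-shot
#' reference routine, the fitted model is frozen and can be applied to new
#' cases from known batches via [combat_apply()].
#'
#' @param x Numeric matrix, cases x features (typically already
#'   standardised); every batch needs >= 2 cases.
#' @param batch Batch labels, length `nrow(x)`.
#' @param parametric Only the parametric priors are implemented.
#' @param tol,max_iter Convergence control of the EB iteration.
#' @return An object of class `combat_model`: per-feature `alpha` (grand
#'   mean) and `sigma` (pooled SD), per-batch EB-shrunk `gamma_star` /
#'   `delta_star`, the prior hyper-parameters, and batch levels.
#' @export
combat_fit <- function(x, batch, parametric = TRUE, tol = 1e-4,
                       max_iter = 5000L) {
  if (!parametric) stop("only parametric priors are implemented", call. = FALSE)
  x <- as.matrix(x)
  batch <- as.character(batch)
  stopifnot(length(batch) == nrow(x))
  levels_b <- sort(unique(batch))
  n_b <- vapply(levels_b, function(b) sum(batch == b), 0L)
  if (any(n_b < 2L)) {
    stop("singleton batch(es): ", paste(levels_b[n_b < 2L], collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(x); G <- ncol(x)

  # grand location: batch-size-weighted mean of batch means; scale: pooled
  # within-batch (population) variance, i.e. residual variance of the
  # location/scale model, not variance around the grand mean
  batch_means <- t(vapply(levels_b, function(b) colMeans(x[batch == b, , drop = FALSE]),
                          numeric(G)))
  alpha <- colSums(batch_means * n_b) / n
  within_ss <- Reduce(`+`, lapply(seq_along(levels_b), function(bi) {
    xb <- x[batch == levels_b[bi], , drop = FALSE]
    colSums(sweep(xb, 2, batch_means[bi, ])^2)
  }))
  sigma2 <- within_ss / n
  if (any(sigma2 <= 0)) stop("zero-variance feature; standardise first", call. = FALSE)
  sigma <- sqrt(sigma2)
  z <- sweep(sweep(x, 2, alpha), 2, sigma, "/")

  gamma_hat <- t(vapply(levels_b, function(b) colMeans(z[batch == b, , drop = FALSE]),
                        numeric(G)))
  # population batch variances: with a single batch they are exactly 1 on the
  # pooled scale, so the EB prior degenerates and the adjustment is identity
  delta2_hat <- t(vapply(levels_b, function(b) {
    zb <- z[batch == b, , drop = FALSE]
    colMeans(sweep(zb, 2, colMeans(zb))^2)
  }, numeric(G)))

  # parametric EB hyper-priors per batch
  gamma_bar <- rowMeans(gamma_hat)
  tau2_bar <- apply(gamma_hat, 1, stats::var)
  m_d <- rowMeans(delta2_hat)
  s2_d <- apply(delta2_hat, 1, stats::var)
  a_prior <- (2 * s2_d + m_d^2) / s2_d
  b_prior <- (m_d * s2_d + m_d^3) / s2_d

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  for (bi in seq_along(levels_b)) {
    nb <- n_b[bi]
    zb <- z[batch == levels_b[bi], , drop = FALSE]
    if (s2_d[bi] < 1e-12 || !is.finite(a_prior[bi])) {
      # degenerate inverse-gamma prior: all batch variances identical, so the
      # posterior collapses to their common value; location shrinks likewise
      gamma_star[bi, ] <- if (tau2_bar[bi] < 1e-12) {
        rep(gamma_bar[bi], G)
      } else gamma_hat[bi, ]
      delta2_star[bi, ] <- rep(m_d[bi], G)
      next
    }
    g_old <- gamma_hat[bi, ]
    d_old <- delta2_hat[bi, ]
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      g_new <- (nb * tau2_bar[bi] * gamma_hat[bi, ] + d_old * gamma_bar[bi]) /
        (nb * tau2_bar[bi] + d_old)
      ss <- colSums(sweep(zb, 2, g_new)^2)
      d_new <- (0.5 * ss + b_prior[bi]) / (nb / 2 + a_prior[bi] - 1)
      delta <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                   abs(d_new - d_old) / (abs(d_old) + 1e-12))
      g_old <- g_new; d_old <- d_new
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged) {
      stop("ComBat EB iteration did not converge for batch ", levels_b[bi],
           call. = FALSE)
    }
    gamma_star[bi, ] <- g_old
    delta2_star[bi, ] <- d_old
  }
  # fit-time recentring so the batch-size-weighted grand mean of the adjusted
  # training data equals alpha exactly (EB shrinkage alone leaves a small
  # residual offset); frozen into the model like every other parameter
  delta_star <- sqrt(delta2_star)
  recentre <- -colSums((gamma_hat - gamma_star) / delta_star * n_b) / n
  structure(list(alpha = alpha, sigma = sigma, batches = levels_b,
                 n_per_batch = n_b, gamma_star = gamma_star,
                 delta_star = delta_star, recentre = recentre,
                 priors = list(gamma_bar = gamma_bar, tau2_bar = tau2_bar,
                               a = a_prior, b = b_prior),
                 features = colnames(x)),
            class = "combat_model")
}

#' Apply a fitted ComBat model
#'
#' Deterministic row-wise adjustment
#' `x_adj = sigma * ((x - alpha)/sigma - gamma*_batch) / delta*_batch + alpha`
#' using the frozen fit-time parameters.  Batches unseen at fit time raise
#' an error (no reference-free extrapolation).
#'
#' @param model A [combat_fit()] model.
#' @param x Matrix of cases x features (the model's features).
#' @param batch Batch labels for the rows of `x`.
#' @return The adjusted matrix.
#' @export
combat_apply <- function(model, x, batch) {
  x <- as.matrix(x)
  batch <- as.character(batch)
  stopifnot(length(batch) == nrow(x))
  unseen <- setdiff(unique(batch), model$batches)
  if (length(unseen)) {
    stop("batch(es) unseen at fit time: ", paste(unseen, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(model$features, colnames(x))
  if (length(missing)) {
    stop("missing feature(s): ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  x <- x[, model$features, drop = FALSE]
  z <- sweep(sweep(x, 2, model$alpha), 2, model$sigma, "/")
  out <- z
  for (bi in seq_along(model$batches)) {
    sel <- batch == model$batches[bi]
    if (!any(sel)) next
    out[sel, ] <- sweep(sweep(z[sel, , drop = FALSE], 2,
                              model$gamma_star[bi, ]),
                        2, model$delta_star[bi, ], "/")
  }
  out <- sweep(out, 2, model$recentre, "+")
  sweep(sweep(out, 2, model$sigma, "*"), 2, model$alpha, "+")
}

#' Serialise / restore a ComBat model as JSON
#'
#' @param model A `combat_model`.
#' @param path JSON file path.
#' @return `combat_model_from_json` returns the restored model.
#' @export
combat_model_to_json <- function(model, path) {
  obj <- unclass(model)
  obj$gamma_star <- as.data.frame(obj$gamma_star)
  obj$delta_star <- as.data.frame(obj$delta_star)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname combat_model_to_json
#' @export
combat_model_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$alpha <- stats::setNames(as.numeric(obj$alpha), obj$features)
  obj$sigma <- stats::setNames(as.numeric(obj$sigma), obj$features)
  obj$recentre <- stats::setNames(as.numeric(obj$recentre), obj$features)
  obj$gamma_star <- as.matrix(obj$gamma_star)
  obj$delta_star <- as.matrix(obj$delta_star)
  structure(obj, class = "combat_model")
}
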