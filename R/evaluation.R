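#' ROC analysis with bootstrap confidence intervals
#'
#' Empirical ROC curve with mid-rank tie handling, AUC by the trapezoidal
#' rule (equal to the Mann-Whitney concordance probability), the
#' Youden-optimal threshold, accuracy at that threshold, and percentile
#' bootstrap 95% confidence intervals for AUC and accuracy.
#'
#' @param scores Numeric predictor scores (higher = more positive).
#' @param labels Binary 0/1 labels; both classes must be present.
#' @param n_bootstrap Bootstrap replicates (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `auc_ci`, `youden_threshold`, `accuracy`,
#'   `accuracy_ci`.
#' @export
roc_analysis <- function(scores, labels, n_bootstrap = 2000L, seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes required", call. = FALSE)
  stopifnot(length(scores) == length(labels))

  curve <- roc_curve(scores, labels)
  auc <- auc_trapezoid(curve)
  thr <- youden_threshold(scores, labels)
  acc <- mean((scores >= thr) == (labels == 1))

  ci <- with_seed(seed, {
    reps <- vapply(seq_len(n_bootstrap), function(i) {
      idx <- sample.int(length(labels), replace = TRUE)
      if (length(unique(labels[idx])) < 2L) return(c(NA_real_, NA_real_))
      c(auc_trapezoid(roc_curve(scores[idx], labels[idx])),
        mean((scores[idx] >= thr) == (labels[idx] == 1)))
    }, numeric(2))
    list(auc = stats::quantile(reps[1, ], c(0.025, 0.975), na.rm = TRUE),
         acc = stats::quantile(reps[2, ], c(0.025, 0.975), na.rm = TRUE))
  })
  structure(list(thresholds = curve$thresholds,
                 sensitivity = curve$sens, specificity = curve$spec,
                 auc = auc, auc_ci = unname(ci$auc),
                 youden_threshold = thr, accuracy = acc,
                 accuracy_ci = unname(ci$acc),
                 n = length(labels)),
            class = "roc_result")
}

# Step ROC: thresholds descend through the unique scores; ties grouped so
# the trapezoid over the tie segment contributes the mid-rank area.
roc_curve <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- tapply(y, grp, sum)
  fp <- tapply(1 - y, grp, sum)
  ctp <- cumsum(tp); cfp <- cumsum(fp)
  P <- sum(labels); N <- length(labels) - P
  list(thresholds = c(Inf, unique(s)),
       sens = c(0, ctp / P),
       spec = c(1, 1 - cfp / N))
}

auc_trapezoid <- function(curve) {
  x <- 1 - curve$spec  # FPR ascending
  y <- curve$sens
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (95%% CI %.3f-%.3f), accuracy %.3f at threshold %.3g\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$accuracy, x$youden_threshold))
  invisible(x)
}

#' Univariable and multivariable logistic models
#'
#' Fits one univariable logistic regression per covariate (coefficient,
#' odds ratio, Wald 95% CI, p-value), then a multivariable model on the
#' covariates univariably significant at the 5% level.  Complete or
#' quasi-complete separation is detected (diverging coefficients) and the
#' affected coefficient flagged non-estimable rather than reported.
#'
#' @param data data.frame of covariates plus the outcome column.
#' @param outcome Name of the binary outcome column.
#' @param covariates Covariate column names (default: all others).
#' @param alpha Univariable inclusion threshold for the multivariable model.
#' @return List with `univariable` (data.frame), `multivariable`
#'   (data.frame or NULL), `model` (the multivariable `glm` or NULL).
#' @export
logistic_models <- function(data, outcome, covariates = NULL, alpha = 0.05) {
  if (is.null(covariates)) covariates <- setdiff(names(data), outcome)
  y <- data[[outcome]]
  if (length(unique(y)) != 2L) stop("outcome must be binary", call. = FALSE)

  tidy_glm <- function(fit) {
    sm <- summary(fit)$coefficients
    sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
    est <- sm[, 1]; se <- sm[, 2]
    sep <- abs(est) > 15 | se > 100  # separation / non-identifiability
    data.frame(term = rownames(sm),
               estimate = ifelse(sep, NA_real_, est),
               odds_ratio = ifelse(sep, NA_real_, exp(est)),
               ci_low = ifelse(sep, NA_real_, exp(est - 1.96 * se)),
               ci_high = ifelse(sep, NA_real_, exp(est + 1.96 * se)),
               p = ifelse(sep, NA_real_, sm[, 4]),
               separation = sep,
               row.names = NULL, stringsAsFactors = FALSE)
  }

  uni <- do.call(rbind, lapply(covariates, function(v) {
    fit <- suppressWarnings(
      stats::glm(stats::reformulate(v, outcome), binomial(), data))
    out <- tidy_glm(fit)
    out$covariate <- v
    out
  }))

  sig <- unique(uni$covariate[!is.na(uni$p) & uni$p < alpha])
  multi <- NULL; fit_m <- NULL
  if (length(sig) >= 1L) {
    fit_m <- suppressWarnings(
      stats::glm(stats::reformulate(sig, outcome), binomial(), data))
    multi <- tidy_glm(fit_m)
  }
  list(univariable = uni, multivariable = multi, model = fit_m)
}

#' Build a points-based nomogram from a fitted logistic model
#'
#' Maps each model term to a 0-100 points scale: a term's points are
#' proportional to `|beta| * (x - x_ref)`, with `x_ref` the end of the
#' term's observed range that minimises `beta * x`, and 100 points assigned
#' to the widest-spanning term.  Total points convert to predicted
#' probability through the logistic link on a lookup grid, so reading the
#' nomogram reproduces the model probability up to grid resolution.
#'
#' @param model A fitted binomial `glm` with >= 1 non-intercept term.
#' @param term_ranges Optional named list of `c(min, max)` per model column;
#'   defaults to the observed range in the model frame.
#' @param grid_size Lookup grid resolution (default 1000).
#' @return An object of class `nomogram_model`.
#' @export
build_nomogram <- function(model, term_ranges = NULL, grid_size = 1000L) {
  beta <- stats::coef(model)
  intercept <- beta["(Intercept)"]
  beta <- beta[names(beta) != "(Intercept)"]
  if (length(beta) < 1L) stop("model has no terms", call. = FALSE)
  mm <- stats::model.matrix(model)
  if (is.null(term_ranges)) {
    term_ranges <- lapply(names(beta), function(t) range(mm[, t]))
    names(term_ranges) <- names(beta)
  }
  span <- vapply(names(beta), function(t) {
    abs(beta[t]) * diff(range(term_ranges[[t]]))
  }, 0)
  degenerate <- names(span)[span == 0]
  if (length(degenerate)) {
    warning("dropped degenerate term(s): ", paste(degenerate, collapse = ", "),
            call. = FALSE)
    beta <- beta[setdiff(names(beta), degenerate)]
    span <- span[setdiff(names(span), degenerate)]
    if (!length(beta)) stop("all terms degenerate", call. = FALSE)
  }
  max_span <- max(span)
  ref <- vapply(names(beta), function(t) {
    r <- term_ranges[[t]]
    if (beta[t] >= 0) r[1] else r[2]  # zero-point end
  }, 0)
  base_lp <- intercept + sum(beta * ref)
  total_range <- c(0, sum(span) / max_span * 100)
  grid <- seq(total_range[1], total_range[2], length.out = grid_size)
  lookup_prob <- stats::plogis(base_lp + grid * max_span / 100)
  structure(list(beta = beta, intercept = intercept, ref = ref,
                 term_ranges = term_ranges[names(beta)],
                 max_span = max_span, points_grid = grid,
                 prob_grid = lookup_prob),
            class = "nomogram_model")
}

#' Score cases through a nomogram
#'
#' @param nomogram A [build_nomogram()] model.
#' @param newdata data.frame (or matrix) with the model-matrix columns.
#' @return data.frame with per-term points, `total_points`, and
#'   `probability` read off the lookup grid.
#' @export
nomogram_points <- function(nomogram, newdata) {
  nd <- as.data.frame(newdata)
  pts <- vapply(names(nomogram$beta), function(t) {
    100 * abs(nomogram$beta[t] * (nd[[t]] - nomogram$ref[t])) / nomogram$max_span
  }, numeric(nrow(nd)))
  pts <- matrix(pts, nrow = nrow(nd),
                dimnames = list(NULL, paste0("points_", names(nomogram$beta))))
  total <- rowSums(pts)
  prob <- stats::approx(nomogram$points_grid, nomogram$prob_grid,
                        xout = total, rule = 2)$y
  data.frame(pts, total_points = total, probability = prob,
             check.names = FALSE)
}

#' Survival stratification by a risk score
#'
#' Dichotomises scores by `cut_rule`, then compares the groups with a
#' Kaplan-Meier estimate, the log-rank test, and a univariable Cox
#' proportional-hazards model (hazard ratio of high vs low risk with a
#' Wald 95% CI).  A group in which no events occur leaves the Cox fit
#' flagged non-estimable while the KM curves are still returned.
#'
#' @param scores Numeric risk scores.
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators.
#' @param cut_rule `"median"`, or a numeric threshold (scores >= threshold
#'   are high risk).
#' @return An object of class `survival_result`: `group` (factor low/high),
#'   `km` (the `survfit`), `logrank_chisq`, `logrank_p`, `cox_hr`,
#'   `cox_ci`, `cox_estimable`.
#' @export
survival_stratification <- function(scores, times, events,
                                    cut_rule = "median") {
  if (any(times <= 0)) stop("times must be positive", call. = FALSE)
  events <- as.integer(events)
  cut <- if (identical(cut_rule, "median")) stats::median(scores) else
    as.numeric(cut_rule)
  group <- factor(ifelse(scores >= cut, "high", "low"),
                  levels = c("low", "high"))
  if (any(table(group) == 0L)) stop("empty risk group after cut", call. = FALSE)
  surv <- survival::Surv(times, events)
  km <- survival::survfit(surv ~ group)
  lr <- survival::survdiff(surv ~ group)
  lr_p <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
  estimable <- all(tapply(events, group, sum) > 0)
  if (estimable) {
    cox <- survival::coxph(surv ~ group)
    hr <- unname(exp(stats::coef(cox)))
    ci <- unname(exp(stats::confint(cox)))
  } else {
    cox <- NULL; hr <- NA_real_; ci <- c(NA_real_, NA_real_)
  }
  structure(list(group = group, cut = cut, km = km,
                 logrank_chisq = unname(lr$chisq), logrank_p = lr_p,
                 cox_hr = hr, cox_ci = ci, cox_estimable = estimable,
                 cox = cox),
            class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat(sprintf("<survival_result> log-rank p = %.3g; Cox HR = %s (95%% CI %.2f-%.2f)\n",
              x$logrank_p,
              if (x$cox_estimable) sprintf("%.2f", x$cox_hr) else "non-estimable",
              x$cox_ci[1], x$cox_ci[2]))
  invisible(x)
}

#' Cohort-comparison statistics
#'
#' Per-variable two-sided tests between two cohorts: Pearson chi-square
#' (without continuity correction) for categorical variables and the
#' Wilcoxon rank-sum test for continuous ones; one-way ANOVA is available
#' as an alternative continuous test.  Categorical cells with expected
#' count below 1 are annotated with a warning flag.
#'
#' @param table_a,table_b data.frames with the variables to compare.
#' @param variable_specs Named character vector mapping variable name to
#'   `"categorical"` or `"continuous"`.
#' @param continuous_test `"ranksum"` (default) or `"anova"`.
#' @return data.frame: variable, type, test, statistic, p, warning flag.
#' @export
cohort_comparison <- function(table_a, table_b, variable_specs,
                              continuous_test = c("ranksum", "anova")) {
  continuous_test <- match.arg(continuous_test)
  rows <- lapply(names(variable_specs), function(v) {
    type <- match.arg(variable_specs[[v]], c("categorical", "continuous"))
    a <- table_a[[v]]; b <- table_b[[v]]
    warn <- FALSE
    if (type == "categorical") {
      tab <- rbind(table(factor(a, levels = sort(unique(c(a, b))))),
                   table(factor(b, levels = sort(unique(c(a, b))))))
      tst <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      warn <- any(tst$expected < 1)
      stat <- unname(tst$statistic); p <- tst$p.value; test <- "chi-square"
    } else if (continuous_test == "ranksum") {
      tst <- stats::wilcox.test(a, b, exact = FALSE)
      stat <- unname(tst$statistic); p <- tst$p.value; test <- "rank-sum"
    } else {
      vals <- c(a, b)
      grp <- factor(rep(c("a", "b"), c(length(a), length(b))))
      tst <- stats::anova(stats::aov(vals ~ grp))
      stat <- tst$`F value`[1]; p <- tst$`Pr(>F)`[1]; test <- "anova"
    }
    data.frame(variable = v, type = type, test = test, statistic = stat,
               p = p, low_expected_count = warn, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
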