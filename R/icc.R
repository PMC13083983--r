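#' Two-way random, single-measures, absolute-agreement ICC
#'
#' ICC(2,1) from the two-way ANOVA decomposition of a subjects-by-raters
#' matrix:
#' \deqn{ICC = (MS_S - MS_E) / (MS_S + (k-1) MS_E + k (MS_R - MS_E) / n)}
#' where `MS_S`, `MS_R`, `MS_E` are the subject, rater and residual mean
#' squares, `n` the number of subjects and `k` the number of raters.  This
#' is the absolute-agreement form: a constant offset between raters lowers
#' it.  Variance components are reported truncated at zero.  A matrix with
#' zero total variance yields an explicit missing ICC.
#'
#' @param measurements Numeric matrix, subjects x raters, no missing cells;
#'   >= 2 subjects and >= 2 raters.
#' @param feature_name Optional label carried in the result.
#' @return An object of class `icc_result`: list with `feature_name`,
#'   `icc`, `var_subject`, `var_rater`, `var_error`, `n_subjects`,
#'   `n_raters`, `undefined` flag.
#' @export
icc_two_way_random <- function(measurements, feature_name = NA_character_) {
  m <- as.matrix(measurements)
  if (any(!is.finite(m))) stop("missing cells not allowed", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 raters", call. = FALSE)
  grand <- mean(m)
  rmean <- rowMeans(m)
  cmean <- colMeans(m)
  ss_s <- k * sum((rmean - grand)^2)
  ss_r <- n * sum((cmean - grand)^2)
  ss_e <- sum((m - outer(rmean, rep(1, k)) - outer(rep(1, n), cmean) + grand)^2)
  ms_s <- ss_s / (n - 1)
  ms_r <- ss_r / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  total <- ss_s + ss_r + ss_e
  undefined <- total < .Machine$double.eps * k * n
  icc <- if (undefined) NA_real_ else {
    (ms_s - ms_e) / (ms_s + (k - 1) * ms_e + k * (ms_r - ms_e) / n)
  }
  structure(list(feature_name = feature_name, icc = icc,
                 var_subject = max(0, (ms_s - ms_e) / k),
                 var_rater = max(0, (ms_r - ms_e) / n),
                 var_error = ms_e,
                 n_subjects = n, n_raters = k, undefined = undefined),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat("<icc_result> ICC(2,1) =",
      if (x$undefined) "undefined (zero variance)" else signif(x$icc, 4),
      sprintf("[n=%d, k=%d]\n", x$n_subjects, x$n_raters))
  invisible(x)
}

#' Reliability filtering of a feature catalogue
#'
#' Computes ICC(2,1) per feature across replicate feature tables (one table
#' per rater, or the test/retest pair) and keeps the features at or above
#' the threshold.  The analysis defaults follow the pipeline's cutoffs:
#' inter-observer 0.8, test-retest 0.9.
#'
#' @param tables List of >= 2 numeric matrices (cases x features) with
#'   identical row and column names: one per rater / repeat.
#' @param icc_threshold Retention cutoff on ICC.
#' @return List with `keep` (surviving feature names) and `icc_table`
#'   (data.frame: feature, icc, variance components, undefined flag).
#' @export
filter_features <- function(tables, icc_threshold = 0.8) {
  if (length(tables) < 2L) stop("need >= 2 replicate tables", call. = FALSE)
  ref <- colnames(tables[[1]])
  for (i in seq_along(tables)[-1]) {
    missing <- setdiff(ref, colnames(tables[[i]]))
    extra <- setdiff(colnames(tables[[i]]), ref)
    if (length(missing) || length(extra)) {
      stop("replicate tables misaligned; missing features: ",
           paste(utils::head(c(missing, extra), 5), collapse = ", "),
           call. = FALSE)
    }
    tables[[i]] <- tables[[i]][rownames(tables[[1]]), ref, drop = FALSE]
  }
  res <- lapply(ref, function(f) {
    m <- vapply(tables, function(tb) tb[, f], numeric(nrow(tables[[1]])))
    if (any(!is.finite(m))) {
      return(data.frame(feature = f, icc = NA_real_, var_subject = NA_real_,
                        var_rater = NA_real_, var_error = NA_real_,
                        undefined = TRUE, stringsAsFactors = FALSE))
    }
    r <- icc_two_way_random(m, f)
    data.frame(feature = f, icc = r$icc, var_subject = r$var_subject,
               var_rater = r$var_rater, var_error = r$var_error,
               undefined = r$undefined, stringsAsFactors = FALSE)
  })
  icc_table <- do.call(rbind, res)
  keep <- icc_table$feature[!icc_table$undefined &
                              icc_table$icc >= icc_threshold]
  list(keep = keep, icc_table = icc_table)
}
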