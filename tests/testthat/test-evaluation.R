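test_that("AUC equals exhaustive pair counting and handles ties like pROC", {
  r <- roc_analysis(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1),
                    n_bootstrap = 50, seed = 1)
  expect_equal(r$auc, 0.75)  # one discordant pair of four

  # perfect separation
  rp <- roc_analysis(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1),
                     n_bootstrap = 50, seed = 1)
  expect_equal(rp$auc, 1)
  expect_equal(rp$accuracy, 1)

  # Mann-Whitney concordance oracle with heavy ties, several draws
  for (s in 1:5) {
    set.seed(s)
    n <- 150
    scores <- sample(1:6, n, replace = TRUE)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    pos <- scores[y == 1]; neg <- scores[y == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(roc_analysis(scores, y, 10, 1)$auc, mean(cmp),
                 tolerance = 1e-12)
    expect_equal(roc_analysis(scores, y, 10, 1)$auc,
                 as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("null scores give chance-level AUC and calibrated CIs", {
  set.seed(40)
  scores <- rnorm(2000)
  y <- rbinom(2000, 1, 0.5)
  r <- roc_analysis(scores, y, n_bootstrap = 200, seed = 2)
  expect_gt(r$auc, 0.45); expect_lt(r$auc, 0.55)
  expect_true(r$auc_ci[1] < r$auc & r$auc < r$auc_ci[2])
  expect_error(roc_analysis(scores, rep(1, 2000)), "both classes")
})

test_that("logistic odds ratios match the 2x2 cross-product", {
  d <- data.frame(y = rep(c(1, 1, 0, 0), c(40, 10, 20, 20)),
                  x = rep(c(1, 0, 1, 0), c(40, 10, 20, 20)))
  lm_ <- logistic_models(d, "y")
  expect_equal(lm_$univariable$odds_ratio, 4, tolerance = 1e-6)

  # duplicating rows leaves point estimates unchanged
  d2 <- rbind(d, d)
  lm2 <- logistic_models(d2, "y")
  expect_equal(lm2$univariable$estimate, lm_$univariable$estimate,
               tolerance = 1e-8)

  # null covariate: CI covers 1
  set.seed(41)
  dn <- data.frame(y = rbinom(500, 1, 0.4), x = rnorm(500))
  lmn <- logistic_models(dn, "y")
  expect_true(lmn$univariable$ci_low < 1 & lmn$univariable$ci_high > 1)

  # complete separation is flagged non-estimable
  ds <- data.frame(y = rep(c(0, 1), each = 20), x = rep(c(0, 1), each = 20))
  lms <- logistic_models(ds, "y")
  expect_true(lms$univariable$separation)
  expect_true(is.na(lms$univariable$odds_ratio))
})

test_that("nomogram lookup reproduces model probabilities", {
  set.seed(42)
  n <- 400
  d <- data.frame(score = rnorm(n), sexM = rbinom(n, 1, 0.5),
                  age = rnorm(n, 65, 10))
  d$y <- rbinom(n, 1, plogis(-1 + 2 * d$score + 0.8 * d$sexM +
                               0.04 * (d$age - 65)))
  fit <- stats::glm(y ~ score + sexM + age, binomial(), d)
  nom <- build_nomogram(fit)

  # reference value scores zero points
  ref_case <- as.data.frame(as.list(nom$ref))
  expect_lt(max(as.matrix(nomogram_points(nom, ref_case)[
    , paste0("points_", names(nom$beta))])), 1e-10)

  nd <- d[sample(n, 100), ]
  got <- nomogram_points(nom, nd)$probability
  direct <- stats::predict(fit, nd, type = "response")
  expect_lt(max(abs(got - direct)), 0.005)

  # single-term model: nomogram == model everywhere on the range
  fit1 <- stats::glm(y ~ score, binomial(), d)
  nom1 <- build_nomogram(fit1, grid_size = 5000)
  p1 <- nomogram_points(nom1, d)$probability
  expect_lt(max(abs(p1 - stats::predict(fit1, d, type = "response"))), 0.002)
})

test_that("survival stratification recovers hazard ratios", {
  set.seed(43)
  n <- 300
  g <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.03 * 2^g)
  cens <- rexp(n, 0.0075)
  time <- pmin(t_ev, cens); ev <- as.integer(t_ev <= cens)
  sr <- survival_stratification(g, time, ev, cut_rule = 0.5)
  expect_gt(sr$cox_hr, 1.5); expect_lt(sr$cox_hr, 2.7)
  expect_lt(sr$logrank_p, 0.001)

  # stochastically ordered groups without censoring: KM curves do not cross
  t0 <- sort(rexp(100, 0.02)); t1 <- t0 / 2
  sr2 <- survival_stratification(rep(c(0, 1), each = 100), c(t0, t1),
                                 rep(1, 200), cut_rule = 0.5)
  sm <- summary(sr2$km)
  km_low <- sm$surv[sm$strata == "group=low"]
  km_high <- sm$surv[sm$strata == "group=high"]
  tt <- sort(unique(sm$time))
  step_at <- function(times, surv, t) {
    i <- findInterval(t, times); c(1, surv)[i + 1]
  }
  lo <- step_at(sm$time[sm$strata == "group=low"], km_low, tt)
  hi <- step_at(sm$time[sm$strata == "group=high"], km_high, tt)
  expect_true(all(lo >= hi - 1e-12))

  # a group with no events leaves Cox flagged, KM intact
  sr3 <- survival_stratification(rep(c(0, 1), each = 20),
                                 rexp(40, 0.05),
                                 rep(c(0, 1), each = 20), cut_rule = 0.5)
  expect_false(sr3$cox_estimable)
  expect_true(is.na(sr3$cox_hr))
  expect_s3_class(sr3$km, "survfit")
})

test_that("cohort comparison reproduces the printed sex contingency p-value", {
  a <- data.frame(sex = rep(c("F", "M"), c(130, 174)), age = rnorm(304, 67.6, 10.7))
  b <- data.frame(sex = rep(c("F", "M"), c(16, 35)), age = rnorm(51, 69.6, 8.1))
  cc <- cohort_comparison(a, b, c(sex = "categorical", age = "continuous"))
  expect_lt(abs(cc$p[cc$variable == "sex"] - 0.1268), 1e-3)
  expect_equal(cc$test, c("chi-square", "rank-sum"))

  # identical proportions: statistic 0, p 1
  u <- data.frame(g = rep(c("x", "y"), c(10, 10)))
  cc0 <- cohort_comparison(u, u, c(g = "categorical"))
  expect_equal(cc0$statistic, 0)
  expect_equal(cc0$p, 1)

  # ANOVA option for continuous variables
  cca <- cohort_comparison(a, b, c(age = "continuous"),
                           continuous_test = "anova")
  expect_equal(cca$test, "anova")
  expect_true(is.finite(cca$p))
})
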