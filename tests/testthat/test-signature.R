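test_that("Spearman filter ranks by relevance and prunes redundancy", {
  set.seed(30)
  n <- 100
  y <- rbinom(n, 1, 0.5)
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  x[, 1] <- y                       # noise-free label copy
  x[, 2] <- x[, 1]                  # exact duplicate
  keep <- spearman_redundancy_filter(x, y)
  expect_equal(as.character(keep)[1], "f1")
  expect_false(all(c("f1", "f2") %in% keep))  # one of the pair pruned

  # brute-force oracle on a hand-built 5-feature instance
  set.seed(31)
  base <- rnorm(80)
  xb <- cbind(a = base + rnorm(80, sd = 0.1),   # highly mutually correlated
              b = base + rnorm(80, sd = 0.1),
              c = rnorm(80),
              d = rnorm(80),
              e = base * -1 + rnorm(80, sd = 0.1))
  yb <- as.integer(base + rnorm(80, sd = 0.5) > 0)
  thr <- 0.8
  got <- as.character(spearman_redundancy_filter(xb, yb, thr, k = 5))
  # oracle: independent greedy elimination over the full rank-correlation table
  rel <- abs(apply(xb, 2, function(v) stats::cor(rank(v), rank(yb))))
  ord <- names(sort(rel, decreasing = TRUE))
  rho <- abs(stats::cor(apply(xb, 2, rank)))
  kept <- character(0)
  for (f in ord) {
    if (!length(kept) || all(rho[f, kept] <= thr)) kept <- c(kept, f)
  }
  expect_identical(got, kept)

  # constant features are flagged, not crashed on
  xc <- cbind(xb, k = rep(1, 80))
  expect_equal(attr(spearman_redundancy_filter(xc, yb), "dropped_constant"), "k")
})

test_that("LASSO shrinks fully at huge lambda and matches glm at zero", {
  set.seed(32)
  n <- 200
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  x <- qr.Q(qr(x)) * sqrt(n)        # orthonormalised columns (scaled)
  colnames(x) <- paste0("f", 1:4)
  y <- rbinom(n, 1, plogis(0.8 * x[, 1] - 0.5 * x[, 2]))

  big <- fit_lasso_logistic(x, y, lambda = c(50, 10), seed = 1)
  expect_equal(length(big$selected_features), 0L)

  small <- glmnet::glmnet(x, y, family = "binomial", lambda = 0,
                          standardize = FALSE, thresh = 1e-12)
  ref <- stats::glm(y ~ x, binomial())
  expect_equal(as.numeric(stats::coef(small)),
               as.numeric(stats::coef(ref)), tolerance = 1e-4)

  expect_error(fit_lasso_logistic(x, rep(1, n), seed = 1), "single class")
})

test_that("LASSO fits are deterministic and scoring is linear/consistent", {
  set.seed(33)
  n <- 150
  x <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, paste0("f", 1:20)))
  y <- rbinom(n, 1, plogis(1.5 * x[, 3]))
  m1 <- fit_lasso_logistic(x, y, seed = 9)
  m2 <- fit_lasso_logistic(x, y, seed = 9)
  expect_identical(m1$weights, m2$weights)

  sc <- rpv_score(m1, x)
  expect_equal(sc$probability,
               plogis(m1$intercept +
                        as.vector(x[, m1$selected_features, drop = FALSE] %*%
                                    m1$weights)),
               tolerance = 1e-12)
  # all-zero features give logistic(intercept)
  zero <- matrix(0, 1, 20, dimnames = list(NULL, colnames(x)))
  expect_equal(rpv_score(m1, zero)$probability, unname(plogis(m1$intercept)))
  # doubling one selected feature moves the linear predictor by w*x
  f <- m1$selected_features[1]
  x2 <- x; x2[, f] <- 2 * x2[, f]
  d <- rpv_score(m1, x2)$linear_predictor - sc$linear_predictor
  expect_equal(d, m1$weights[f] * x[, f], tolerance = 1e-12,
               ignore_attr = TRUE)

  bad <- x[, setdiff(colnames(x), f), drop = FALSE]
  expect_error(rpv_score(m1, bad), f)

  path <- withr::local_tempfile(fileext = ".json")
  signature_to_json(m1, path)
  m3 <- signature_from_json(path)
  expect_equal(rpv_score(m3, x)$probability, sc$probability, tolerance = 1e-12)
})

test_that("a planted informative feature is selected consistently", {
  hits <- vapply(1:50, function(s) {
    set.seed(400 + s)
    n <- 300
    x <- matrix(rnorm(n * 50), n, 50, dimnames = list(NULL, paste0("f", 1:50)))
    y <- rbinom(n, 1, 0.5)
    x[, 1] <- x[, 1] + 2 * y            # 2-SD effect on f1
    m <- fit_lasso_logistic(x, y, seed = s)
    "f1" %in% m$selected_features
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("the LASSO active set shrinks along increasing lambda", {
  set.seed(34)
  n <- 200
  x <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- rbinom(n, 1, plogis(x[, 1] + 0.5 * x[, 2]))
  lams <- exp(seq(log(0.2), log(0.001), length.out = 10))
  fit <- glmnet::glmnet(x, y, family = "binomial", lambda = lams,
                        standardize = FALSE)
  nz <- fit$df  # nonzero counts along the decreasing-lambda path
  expect_true(all(diff(nz) >= 0))
})

test_that("benchmark shares folds, ranks the strong cell first", {
  set.seed(35)
  n <- 120
  x <- matrix(rnorm(n * 30), n, 30, dimnames = list(NULL, paste0("f", 1:30)))
  y <- rbinom(n, 1, 0.5)
  x[, 1] <- x[, 1] + 2 * y
  g <- benchmark(x, y, selectors = c("spearman", "variance"),
                 learners = c("lasso", "dummy"), seed = 4)
  expect_s3_class(g, "benchmark_grid")
  dummy_auc <- g$auc[g$learner == "dummy"]
  expect_true(all(abs(dummy_auc - 0.5) < 0.12))
  best <- attr(g, "best")
  expect_gt(best$auc, 0.9)
  expect_false(best$learner == "dummy")
  # determinism
  g2 <- benchmark(x, y, selectors = c("spearman", "variance"),
                  learners = c("lasso", "dummy"), seed = 4)
  expect_equal(as.data.frame(g), as.data.frame(g2))
})
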