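test_that("standardisation maps to zero mean, unit population SD", {
  x <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "a"))
  s <- standardise(x)
  expect_equal(s$x[, 1], c(-1.224745, 0, 1.224745), tolerance = 1e-6)

  set.seed(20)
  m <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  s2 <- standardise(m)
  expect_lt(max(abs(colMeans(s2$x))), 1e-10)
  expect_lt(max(abs(sqrt(colMeans(s2$x^2)) - 1)), 1e-10)
  # idempotence
  s3 <- standardise(s2$x)
  expect_equal(s3$x, s2$x, tolerance = 1e-10)

  # the frozen transform uses training parameters on new data
  new <- m + 100
  applied <- standardise_apply(s2, new)
  expect_equal(applied, s2$x + 100 / matrix(s2$scale, 50, 4, byrow = TRUE),
               tolerance = 1e-10)

  m_const <- cbind(m, k = rep(2, 50))
  expect_warning(sc <- standardise(m_const), "constant")
  expect_equal(sc$dropped, "k")
})

test_that("ComBat removes planted location and scale batch effects", {
  set.seed(21)
  n <- 200; G <- 50
  x <- matrix(rnorm(2 * n * G), 2 * n, G,
              dimnames = list(NULL, paste0("f", 1:G)))
  b <- rep(c("A", "B"), each = n)
  x[b == "B", ] <- x[b == "B", ] * 3 + 2
  fit <- combat_fit(x, b)
  adj <- combat_apply(fit, x, b)
  dmean <- colMeans(adj[b == "A", ]) - colMeans(adj[b == "B", ])
  expect_lt(abs(mean(dmean)), 0.1)
  sd_ratio <- apply(adj[b == "A", ], 2, sd) / apply(adj[b == "B", ], 2, sd)
  expect_true(all(sd_ratio > 0.9 & sd_ratio < 1.1))
  # grand mean preserved and training application reproducible
  expect_lt(max(abs(colMeans(adj) - colMeans(x))), 1e-6)
  expect_identical(combat_apply(fit, x, b), adj)
  # row-wise map: permuting cases permutes outputs
  perm <- sample(nrow(x))
  expect_equal(combat_apply(fit, x[perm, ], b[perm]), adj[perm, ],
               tolerance = 1e-12)
})

test_that("ComBat agrees with the reference empirical-Bayes implementation", {
  set.seed(22)
  n <- 80; G <- 30
  x <- matrix(rnorm(2 * n * G), 2 * n, G,
              dimnames = list(paste0("s", 1:(2 * n)), paste0("f", 1:G)))
  b <- rep(c("A", "B"), each = n)
  x[b == "B", ] <- x[b == "B", ] * 1.5 + 1
  adj <- combat_apply(combat_fit(x, b), x, b)
  ref <- t(suppressMessages(sva::ComBat(t(x), batch = b)))
  expect_lt(max(abs(adj - ref)), 0.05)
})

test_that("ComBat degenerate and error cases", {
  set.seed(23)
  x1 <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  f1 <- combat_fit(x1, rep("A", 100))
  expect_lt(max(abs(combat_apply(f1, x1, rep("A", 100)) - x1)), 1e-8)

  expect_error(combat_fit(x1, c("A", rep("B", 99))), "singleton")
  f2 <- combat_fit(x1, rep(c("A", "B"), 50))
  expect_error(combat_apply(f2, x1, rep("C", 100)), "unseen")
})

test_that("balanced label effects survive harmonisation", {
  set.seed(24)
  n <- 100; G <- 20
  y <- rep(c(0, 1), n)           # balanced within each batch
  b <- rep(c("A", "B"), each = n)
  x <- matrix(rnorm(2 * n * G), 2 * n, G,
              dimnames = list(NULL, paste0("f", 1:G)))
  x[, 1] <- x[, 1] + 1.5 * y     # planted label effect on f1
  x[b == "B", ] <- x[b == "B", ] + 2
  adj <- combat_apply(combat_fit(x, b), x, b)
  eff_before <- mean(x[y == 1, 1]) - mean(x[y == 0, 1])
  eff_after <- mean(adj[y == 1, 1]) - mean(adj[y == 0, 1])
  expect_lt(abs(eff_after - eff_before) / abs(eff_before), 0.10)
})

test_that("ComBat models serialise to JSON and back", {
  set.seed(25)
  x <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, paste0("f", 1:4)))
  b <- rep(c("A", "B"), 50)
  fit <- combat_fit(x, b)
  path <- withr::local_tempfile(fileext = ".json")
  combat_model_to_json(fit, path)
  fit2 <- combat_model_from_json(path)
  expect_equal(combat_apply(fit2, x, b), combat_apply(fit, x, b),
               tolerance = 1e-12)
})
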