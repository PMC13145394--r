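test_that("intercept benchmarks: means, cold-start fallback, equivariance", {
  m <- fit_person_intercept(c(2, 4), c("a", "a"))
  expect_equal(predict(m, groups = "a"), 3)
  m <- fit_person_intercept(c(1, 1, 5, 7), c("A", "A", "B", "B"))
  expect_equal(predict(m, groups = c("A", "B")), c(1, 6))
  expect_equal(m$global_mean, 3.5)
  # unseen person falls back to the global mean
  expect_equal(predict(m, groups = "Z"), 3.5)
  expect_error(fit_global_intercept(numeric(0)))
  # affine equivariance: shifting y shifts every prediction
  y <- rnorm(20); g <- rep(c("A", "B"), 10)
  m1 <- fit_person_intercept(y, g)
  m2 <- fit_person_intercept(y + 2, g)
  expect_equal(predict(m2, groups = c("A", "B", "Z")),
               predict(m1, groups = c("A", "B", "Z")) + 2)
})

test_that("population learners recover simple structure", {
  set.seed(1)
  X <- matrix(rnorm(400), 200, 2)
  y <- 2 * X[, 1]
  m <- fit_population("linear", X, y)
  expect_equal(unname(coef(m$fit)["f1"]), 2, tolerance = 1e-8)
  # forest on constant outcome predicts the constant
  mf <- fit_population("forest", X, rep(3, 200))
  expect_equal(predict(mf, X), rep(3, 200))
  # ffnn lands within 2x of the linear oracle's MAE on held-out rows
  Xte <- matrix(rnorm(200), 100, 2); yte <- 2 * Xte[, 1]
  mn <- fit_population("ffnn", X, y, hyper = list(epochs = 500), seed = 2)
  mae_lin <- mean(abs(yte - predict(m, Xte)))
  mae_net <- mean(abs(yte - predict(mn, Xte)))
  expect_lt(mae_net, max(2 * mae_lin, 0.25))
  # non-finite features rejected
  Xb <- X; Xb[1, 1] <- NA
  expect_error(fit_population("linear", Xb, y), "impute")
})

test_that("MERF recovers intercepts and shrinks them correctly", {
  ds <- simulate_modeling_dataset(25, 40, sigma_b = 1, sigma_eps = 0.5,
                                  nonlinear = TRUE, seed = 3)
  truth <- attr(ds, "truth")
  m <- suppressWarnings(fit_merf(as.matrix(ds$X), ds$y, ds$groups,
                                 num.trees = 80, max_iter = 6, seed = 1))
  expect_gt(cor(m$intercepts[names(truth$b)], truth$b), 0.9)
  expect_gt(m$sigma2_b, 0.4)
  # known participant: prediction is forest output + intercept exactly
  Xn <- as.matrix(ds$X[1:5, ])
  base <- predict(m, Xn, groups = rep("ZZZ", 5))  # unseen -> forest only
  known <- predict(m, Xn, groups = rep(ds$groups[1], 5))
  expect_equal(known - base, rep(unname(m$intercepts[ds$groups[1]]), 5))
  # objective trace is non-increasing after iteration 2, up to the
  # declared refit-noise tolerance (5% of the total criterion drop)
  if (length(m$trace) >= 3) {
    tol <- 0.05 * (max(m$trace) - min(m$trace))
    expect_true(all(diff(m$trace[-1]) <= tol))
  }
})

test_that("MERF with a null intercept structure estimates near-zero b", {
  ds <- simulate_modeling_dataset(30, 40, sigma_b = 0, sigma_eps = 0.5,
                                  nonlinear = TRUE, seed = 4)
  m <- suppressWarnings(fit_merf(as.matrix(ds$X), ds$y, ds$groups,
                                 num.trees = 80, max_iter = 6, seed = 1))
  expect_lt(m$sigma2_b, 0.05)
  expect_lt(max(abs(m$intercepts)), 0.15)
})

test_that("forcing zero intercept variance collapses MERF onto the forest", {
  ds <- simulate_modeling_dataset(12, 20, sigma_b = 1, seed = 5)
  m <- suppressWarnings(fit_merf(as.matrix(ds$X), ds$y, ds$groups,
                                 num.trees = 50, max_iter = 3,
                                 sigma2_b_fixed = 0, seed = 2))
  expect_true(all(m$intercepts == 0))
  p1 <- predict(m, as.matrix(ds$X), ds$groups)
  p2 <- as.numeric(predict(m$forest,
                           data = setNames(ds$X, m$feature_names),
                           num.threads = 1)$predictions)
  expect_equal(p1, p2)
})

test_that("large clusters escape shrinkage: b approaches the residual mean", {
  # shrinkage factor s = sigma_b^2 / (sigma_b^2 + sigma_eps^2 / n_i) -> 1
  s <- function(n) 1 / (1 + 0.25 / n)
  expect_lt(s(5), s(500))
  expect_equal(s(1e6), 1, tolerance = 1e-5)
  ds <- simulate_modeling_dataset(10, 200, sigma_b = 1, sigma_eps = 0.5,
                                  seed = 6)
  truth <- attr(ds, "truth")
  m <- suppressWarnings(fit_merf(as.matrix(ds$X), ds$y, ds$groups,
                                 num.trees = 60, max_iter = 5, seed = 3))
  expect_equal(unname(m$intercepts[names(truth$b)]), unname(truth$b),
               tolerance = 0.15)
})

test_that("single-participant MERF degenerates to a forest with a warning", {
  ds <- simulate_modeling_dataset(1, 50, sigma_b = 0, seed = 7)
  expect_warning(
    mdl <- fit_merf(as.matrix(ds$X), ds$y, ds$groups, num.trees = 30,
                    max_iter = 1, seed = 1),
    "single participant")
  expect_s3_class(mdl, "merf_model")
})

test_that("embedding net separates two persons with planted offsets", {
  set.seed(8)
  X <- matrix(rnorm(200 * 3), 200, 3)
  ids <- rep(c("u1", "u2"), each = 100)
  y <- 0.5 * X[, 1] + ifelse(ids == "u2", 2, 0)
  m <- suppressWarnings(fit_embed_net(X, y, ids, d = 8,
                                      hyper = list(epochs = 400), seed = 1))
  Xp <- matrix(0, 1, 3)
  gap <- predict(m, Xp, "u2") - predict(m, Xp, "u1")
  expect_equal(gap, 2, tolerance = 0.4)
  # determinism
  m2 <- suppressWarnings(fit_embed_net(X, y, ids, d = 8,
                                       hyper = list(epochs = 400), seed = 1))
  expect_identical(m$params$W, m2$params$W)
  expect_identical(m$params$E, m2$params$E)
  expect_error(fit_embed_net(X, y, ids, d = 0), "positive")
})

test_that("embedding fine-tuning touches nothing but the new rows", {
  set.seed(9)
  X <- matrix(rnorm(300 * 3), 300, 3)
  ids <- rep(c("u1", "u2", "u3"), each = 100)
  off <- c(u1 = -1, u2 = 0, u3 = 1)
  y <- 0.5 * X[, 1] + off[ids]
  m <- suppressWarnings(fit_embed_net(X, y, ids, d = 8,
                                      hyper = list(epochs = 300), seed = 1))
  Xn <- matrix(rnorm(64 * 3), 64, 3)
  yn <- 0.5 * Xn[, 1] + 2
  m2 <- finetune_embeddings(m, Xn, yn, rep("new", 64))
  # freeze contract: weights and old rows bit-identical
  expect_identical(m2$params$W, m$params$W)
  expect_identical(m2$params$b, m$params$b)
  expect_identical(m2$params$E[seq_len(3), ], m$params$E)
  # adapted predictions beat cold start on the planted-offset user
  Xh <- matrix(rnorm(50 * 3), 50, 3)
  yh <- 0.5 * Xh[, 1] + 2
  cold <- mean(abs(yh - predict(m, Xh, rep("unseen", 50))))
  adapted <- mean(abs(yh - predict(m2, Xh, rep("new", 50))))
  expect_lt(adapted, cold)
  # overlapping ids rejected; empty adaptation warns and keeps the mean row
  expect_error(finetune_embeddings(m, Xn, yn, rep("u1", 64)), "disjoint")
  expect_warning(m3 <- finetune_embeddings(m, Xn[0, ], numeric(0),
                                           character(0)), "empty")
  expect_identical(m3$params$E, m$params$E)
})

test_that("zero-epoch fine-tuning equals the mean-embedding cold start", {
  set.seed(10)
  X <- matrix(rnorm(100 * 2), 100, 2)
  ids <- rep(c("a", "b"), each = 50)
  y <- X[, 1] + ifelse(ids == "b", 1, 0)
  m <- suppressWarnings(fit_embed_net(X, y, ids, d = 4,
                                      hyper = list(epochs = 200), seed = 2))
  m0 <- finetune_embeddings(m, X[1:10, ], y[1:10], rep("c", 10), epochs = 0)
  Xq <- matrix(rnorm(20), 10, 2)
  expect_equal(predict(m0, Xq, rep("c", 10)),
               predict(m, Xq, rep("zzz", 10)), tolerance = 1e-12)
})

test_that("models never consult labels at predict time", {
  # predictions on the same X are invariant to the test labels by API:
  # predict() takes no y. Spot-check the registry contract instead.
  reg <- model_registry()
  expect_setequal(names(reg),
                  c("global_intercept", "per_person_intercept", "lr", "rf",
                    "ffnn", "lr_ps", "rf_ps", "ffnn_ps", "merf", "merf_ps",
                    "ffnn_embedding"))
  expect_true(all(vapply(reg, function(s) is.function(s$fit), logical(1))))
  adapters <- names(Filter(function(s) !is.null(s$adapt), reg))
  expect_setequal(adapters, c("per_person_intercept", "ffnn_embedding"))
})
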