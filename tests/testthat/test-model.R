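# Small learnable regression fixture: force is a noisy linear function of
# the first feature; remaining features are distractors.
make_linear_fixture <- function(n = 100, p = 5, seed = 1, noise = 0.1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- 50 + 10 * X[, 1] + rnorm(n, sd = noise)
  list(X = X, y = y)
}

test_that("metrics match hand arithmetic and affine invariance", {
  m <- compute_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$rmse, 0)
  expect_equal(m$mape, 0)
  expect_equal(m$r, 1)

  m2 <- compute_metrics(c(1, 2), c(2, 4))
  expect_equal(m2$rmse, sqrt(0.5 * (1 + 4)))
  expect_equal(m2$mape, 1.0)

  y <- c(1, 3, 7, 2)
  m3 <- compute_metrics(y, 2.5 * y + 4)
  expect_equal(m3$r, 1)

  expect_error(compute_metrics(c(1, 1), c(1, 2)), "zero-variance")
  expect_error(compute_metrics(1, 1), "length")
  expect_warning(compute_metrics(c(0, 1, 2), c(1, 1, 2)), "zero target")
})

test_that("metrics consistency: zero RMSE iff zero MAPE iff exact match", {
  set.seed(2)
  y <- runif(20, 10, 100)
  exact <- compute_metrics(y, y)
  expect_true(exact$rmse == 0 && exact$mape == 0)
  off <- compute_metrics(y, y + 0.01)
  expect_true(off$rmse > 0 && off$mape > 0)
})

test_that("cross-validated SVR loss is deterministic and sane", {
  fx <- make_linear_fixture()
  sc <- fit_zscore(fx$X)
  X <- apply_zscore(sc, fx$X)
  y <- as.numeric(scale(fx$y))
  l1 <- svr_fitness(c(10, 2), X, y, seed = 3)
  l2 <- svr_fitness(c(10, 2), X, y, seed = 3)
  expect_identical(l1, l2)
  expect_gte(l1, 0)
  expect_error(svr_fitness(c(10, 2), X[1:10, ], y[1:10]), ">= 20")

  # sensible parameters beat degenerate ones on learnable data
  better <- 0L
  for (s in 1:20) {
    f <- make_linear_fixture(seed = 100 + s)
    Xs <- apply_zscore(fit_zscore(f$X), f$X)
    ys <- as.numeric(scale(f$y))
    if (svr_fitness(c(100, 5), Xs, ys, seed = s) <
        svr_fitness(c(0.001, 500), Xs, ys, seed = s)) better <- better + 1L
  }
  expect_gte(better, 19L)
})

test_that("tuning stays in bounds, beats random draws, and reproduces", {
  fx <- make_linear_fixture(n = 60)
  sc <- fit_zscore(fx$X)
  X <- apply_zscore(sc, fx$X)
  y <- as.numeric(scale(fx$y))
  ics <- ics_params(n_nests = 8, T = 8, lower = 0.001, upper = 500, seed = 5)
  t1 <- tune_svr(X, y, ics = ics, cv_seed = 5)
  expect_true(t1$config$C >= 0.001 && t1$config$C <= 500)
  expect_true(t1$config$sigma >= 0.001 && t1$config$sigma <= 500)

  t2 <- tune_svr(X, y, ics = ics, cv_seed = 5)
  expect_identical(t2$config$C, t1$config$C)
  expect_identical(t2$config$sigma, t1$config$sigma)

  # tuned loss <= best of 20 random draws under the same folds
  tuned_loss <- t1$trace$best_fitness
  set.seed(99)
  rand_losses <- replicate(20, svr_fitness(runif(2, 0.001, 500), X, y, seed = 5))
  expect_lte(tuned_loss, min(rand_losses))
  # ... and <= the best of its own initial population
  expect_lte(tuned_loss, t1$trace$trace[1])
})

test_that("fit_predict interpolates easy cases and inverts target scaling", {
  fx <- make_linear_fixture(n = 80, noise = 0.01)
  cfg <- svr_config(C = 100, sigma = 2, epsilon = 0.001)
  est <- fit_predict(cfg, fx$X, fx$y, fx$X)
  expect_gt(cor(est$predicted, fx$y), 0.99)
  expect_equal(mean(est$predicted), mean(fx$y), tolerance = 0.05)

  est2 <- fit_predict(cfg, fx$X, fx$y, fx$X)
  expect_identical(est$predicted, est2$predicted)

  bad <- fx$X
  colnames(bad) <- paste0("g", 1:5)
  expect_error(fit_predict(cfg, fx$X, fx$y, bad), "columns differ")
})

test_that("evaluation protocol splits 90/10, reproduces, and recovers signal", {
  fx <- make_linear_fixture(n = 100, p = 4, noise = 0.5)
  fm <- structure(list(features = fx$X, force = fx$y, channel_labels = NULL),
                  class = "feature_matrix")
  ics <- ics_params(n_nests = 6, T = 6, lower = 0.001, upper = 500)
  rep1 <- evaluate_protocol(fm, combination = NULL, ics = ics,
                            n_reps = 3, seed = 7)
  expect_identical(nrow(rep1$repetitions), 3L)
  expect_gt(rep1$mean["r"], 0.9)

  rep2 <- evaluate_protocol(fm, combination = NULL, ics = ics,
                            n_reps = 3, seed = 7)
  expect_identical(rep1$repetitions, rep2$repetitions)

  # 100 rows, split 0.9 -> 90 train / 10 test (verified via metric length
  # indirectly: a 400-row dataset gives 360/40)
  expect_identical(floor(0.9 * 400), 360)
  expect_error(evaluate_protocol(
    structure(list(features = fx$X[1:30, ], force = fx$y[1:30]),
              class = "feature_matrix"), NULL, ics = ics), ">= 50")
})

test_that("GRA-selected features beat noise-diluted full sets", {
  # half the columns carry signal, half are pure noise; selection by
  # relational degree should not hurt and typically helps
  set.seed(11)
  n <- 100
  x1 <- rnorm(n)
  y <- 40 + 10 * x1 + rnorm(n, sd = 0.3)
  X <- cbind(x1, matrix(rnorm(n * 5), n, 5))
  colnames(X) <- paste0("f", 1:6)
  fm <- structure(list(features = X, force = y, channel_labels = NULL),
                  class = "feature_matrix")
  ics <- ics_params(n_nests = 6, T = 6, lower = 0.001, upper = 500)
  rep_sel <- evaluate_protocol(fm, combination = "B", ics = ics,
                               n_reps = 5, seed = 3)
  rep_all <- evaluate_protocol(fm, combination = NULL, ics = ics,
                               n_reps = 5, seed = 3)
  expect_lte(rep_sel$mean["rmse"], rep_all$mean["rmse"] * 1.05)
  # selection keeps the informative columns
  expect_true(all(rep_sel$repetitions$n_features < 6))
})
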