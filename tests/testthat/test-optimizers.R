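test_that("Mantegna scale factor matches gamma-function arithmetic", {
  expect_equal(levy_phi(1.5), 0.6966, tolerance = 1e-4 / 0.6966)
  for (b in c(0.5, 1.0, 1.9)) expect_equal(levy_phi(b), oracle_levy_phi(b))
  expect_error(levy_phi(0.2), "beta")
  expect_error(levy_phi(2.5), "beta")
})

test_that("Levy steps are reproducible and heavy-tailed with index beta", {
  set.seed(1); s1 <- levy_step(5, 1.5)
  set.seed(1); s2 <- levy_step(5, 1.5)
  expect_identical(s1, s2)

  set.seed(2)
  draws <- abs(levy_phi(1.5) * rnorm(1e6) / abs(rnorm(1e6))^(1 / 1.5))
  expect_true(is.finite(median(draws)))
  # tail index from survival-function slope on the log-log scale
  qs <- quantile(draws, 1 - 10^seq(-1.5, -4, length.out = 12))
  surv <- vapply(qs, function(q) mean(draws > q), numeric(1))
  slope <- coef(lm(log(surv) ~ log(as.numeric(qs))))[2]
  expect_equal(unname(slope), -1.5, tolerance = 0.15 / 1.5)
})

test_that("Tent map follows its piecewise form and hazards are known", {
  expect_equal(tent_map(0.3), 0.6)
  expect_equal(tent_map(0.75), 0.5)
  expect_equal(tent_map(0.5), 1.0)
  expect_equal(tent_map(1.0), 0.0)
  expect_error(tent_map(1.2), "\\[0, 1\\]")
})

test_that("Tent iterates are uniform on [0, 1] (KS distance < 0.05)", {
  set.seed(3)
  u <- mmgforce:::tent_iterate(runif(1, 0.01, 0.99), 1e4)
  d <- suppressWarnings(ks.test(u, "punif"))$statistic
  expect_lt(unname(d), 0.05)
})

test_that("chaotic initialization respects bounds and the affine map", {
  p <- ics_params(n_nests = 20, lower = 0.001, upper = 500)
  for (s in 1:100) {
    set.seed(s)
    pos <- chaotic_init(p, 2)
    expect_true(all(pos >= 0.001 & pos <= 500))
  }
  # endpoints of the affine map
  expect_equal(0.001 + 0 * (500 - 0.001), 0.001)
  expect_equal(0.001 + 1 * (500 - 0.001), 500)
})

test_that("chaotic populations spread wider than iid uniform ones on average", {
  p <- ics_params(n_nests = 20, lower = 0, upper = 1)
  min_spread <- function(pos) min(dist(pos))
  diff_sum <- 0
  for (s in 1:100) {
    set.seed(s)
    chaotic <- min_spread(chaotic_init(p, 2))
    unif <- min_spread(matrix(runif(40), 20, 2))
    diff_sum <- diff_sum + (chaotic - unif)
  }
  expect_gt(diff_sum / 100, 0)
})

test_that("adaptive schedules hit their endpoints exactly and decay", {
  p <- ics_params(lower = 0.001, upper = 500)
  expect_identical(adaptive_a0(0, p), 0.2)
  expect_equal(adaptive_a0(p$T, p), 0.001, tolerance = 1e-12)
  expect_identical(adaptive_pa(0, p), 0.70)
  expect_identical(adaptive_pa(p$T, p), 0.10)
  expect_equal(adaptive_pa(p$T / 2, p), 0.1 + 0.6 * 0.25)

  grid <- 0:p$T
  a0 <- adaptive_a0(grid, p)
  expect_true(all(diff(a0) <= 1e-12))
  expect_true(all(a0 >= 0.001 - 1e-12 & a0 <= 0.2 + 1e-12))
  pa <- adaptive_pa(grid, p)
  expect_true(all(diff(pa) < 0))
  expect_true(all(pa >= 0.1 & pa <= 0.7))
  mid <- adaptive_a0(p$T / 2, p)
  expect_true(mid > 0.001 && mid < 0.2)
  expect_error(adaptive_a0(-1, p), "\\[0, T\\]")
  expect_error(adaptive_pa(p$T + 1, p), "\\[0, T\\]")
})

test_that("benchmark functions attain their printed minima", {
  expect_identical(benchmark_function("rosenbrock")$fn(c(1, 1)), 0)
  expect_identical(benchmark_function("griewank")$fn(c(0, 0)), 0)
  expect_identical(benchmark_function("schaffer")$fn(c(0, 0)), 0)
  f3 <- benchmark_function("cross_in_tray")
  expect_equal(f3$fn(c(1.3491, 1.3491)), -2.06261, tolerance = 1e-4 / 2.06261)
  for (nm in c("rosenbrock", "griewank", "cross_in_tray", "schaffer")) {
    bf <- benchmark_function(nm)
    expect_equal(bf$fn(bf$argmin), bf$minimum, tolerance = 1e-4)
  }
  expect_error(benchmark_function("sphere"), "arg")
})

test_that("parameter validation enforces the documented ranges", {
  expect_error(cs_params(beta = 2.5, lower = 0, upper = 1), "beta")
  expect_error(cs_params(pa = 1.2, lower = 0, upper = 1), "pa")
  expect_error(cs_params(lower = 1, upper = 0), "bound")
  expect_error(ics_params(amin = 0.3, amax = 0.2, lower = 0, upper = 1), "amin")
  expect_error(ics_params(pa_min = 0.8, pa_max = 0.7, lower = 0, upper = 1),
               "pa_min")
})

test_that("cuckoo search solves the sphere and keeps its contracts", {
  sphere <- function(x) sum(x^2)
  ok <- 0L
  for (s in 1:20) {
    p <- cs_params(n_nests = 20, T = 200, lower = -5, upper = 5, seed = s)
    res <- cs_search(sphere, p)
    if (res$best_fitness < 1e-4) ok <- ok + 1L
    expect_true(all(diff(res$trace) <= 0))             # elitism
    expect_true(all(abs(res$best_position) <= 5))      # bounds
    expect_lte(res$best_fitness, res$trace[1])
  }
  expect_gte(ok, 19L)

  p <- cs_params(n_nests = 10, T = 50, lower = -5, upper = 5, seed = 42)
  r1 <- cs_search(sphere, p)
  r2 <- cs_search(sphere, p)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best_position, r2$best_position)
})

test_that("improved search is deterministic under a fixed seed", {
  bf <- benchmark_function("rosenbrock")
  p <- ics_params(n_nests = 10, T = 50, lower = bf$lower, upper = bf$upper,
                  seed = 7)
  r1 <- ics_search(bf$fn, p)
  r2 <- ics_search(bf$fn, p)
  expect_identical(r1$trace, r2$trace)
  expect_true(all(diff(r1$trace) <= 0))
})

test_that("comparison harness summarizes runs with sane ordering", {
  tab <- compare_runs("ics", "schaffer", n_runs = 5, seed = 1,
                      n_nests = 10, T = 50)
  expect_identical(nrow(tab), 1L)
  expect_lte(tab$optimal, tab$average)
  expect_lte(tab$average, tab$worst)
  expect_gte(tab$sd, 0)
  runs <- attr(tab, "runs")$ics.schaffer
  expect_length(runs, 5)
  expect_equal(tab$average, mean(runs))
})
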