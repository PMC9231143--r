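# Cuckoo search (CS) and its improved variant (ICS) for bound-constrained
# minimization, plus the 2-D benchmark suite used to exercise them.
#
# CS follows the standard Levy-flight scheme: each nest proposes a move whose
# step is a Mantegna-generated Levy deviate scaled by a0 and by the distance
# to the current best nest; the proposal competes greedily against a randomly
# chosen host nest. A fraction Pa of nests is abandoned each generation and
# regenerated by a biased random walk. ICS replaces uniform initialization
# with Tent-map chaotic initialization and makes both a0 and Pa decay over
# the run (cosine-log and quadratic schedules).

#' Parameters for the cuckoo search optimizer
#'
#' @param n_nests Population size (number of host nests).
#' @param T Total number of iterations.
#' @param beta Levy distribution index; must lie in (0.3, 1.99].
#' @param pa Discovery (abandonment) probability, fixed over the run.
#' @param a0 Step-size control factor, fixed over the run.
#' @param lower,upper Per-dimension search bounds (recycled to dimension).
#' @param seed Integer RNG seed; \code{NULL} leaves the RNG state alone.
#'
#' @return An object of class \code{cs_params}.
#' @export
cs_params <- function(n_nests = 20L, T = 200L, beta = 1.5, pa = 0.25,
                      a0 = 0.01, lower, upper, seed = NULL) {
  stopifnot(n_nests >= 2L, T >= 1L)
  if (!(beta > 0.3 && beta <= 1.99))
    stop("'beta' must lie in (0.3, 1.99]", call. = FALSE)
  if (!(pa > 0 && pa < 1)) stop("'pa' must lie in (0, 1)", call. = FALSE)
  if (a0 <= 0) stop("'a0' must be positive", call. = FALSE)
  if (missing(lower) || missing(upper))
    stop("search bounds 'lower' and 'upper' are required", call. = FALSE)
  if (any(lower >= upper)) stop("each lower bound must be < upper bound", call. = FALSE)
  structure(list(n_nests = as.integer(n_nests), T = as.integer(T),
                 beta = beta, pa = pa, a0 = a0,
                 lower = as.numeric(lower), upper = as.numeric(upper),
                 seed = seed),
            class = "cs_params")
}

#' Parameters for the improved cuckoo search (ICS)
#'
#' Extends \code{\link{cs_params}} with the adaptive-schedule constants:
#' the step control decays from \code{amax} to \code{amin} under a
#' cosine-log schedule and the discovery probability decays quadratically
#' from \code{pa_max} to \code{pa_min}.
#'
#' @inheritParams cs_params
#' @param amin,amax Bounds of the adaptive step-control schedule.
#' @param pa_min,pa_max Bounds of the adaptive discovery-probability schedule.
#'
#' @return An object of class \code{ics_params} (inherits \code{cs_params}).
#' @export
ics_params <- function(n_nests = 20L, T = 200L, beta = 1.5,
                       amin = 0.001, amax = 0.2,
                       pa_min = 0.1, pa_max = 0.70,
                       lower, upper, seed = NULL) {
  if (amin >= amax) stop("'amin' must be < 'amax'", call. = FALSE)
  if (pa_min >= pa_max) stop("'pa_min' must be < 'pa_max'", call. = FALSE)
  p <- cs_params(n_nests = n_nests, T = T, beta = beta, pa = pa_max,
                 a0 = amax, lower = lower, upper = upper, seed = seed)
  p$amin <- amin; p$amax <- amax
  p$pa_min <- pa_min; p$pa_max <- pa_max
  class(p) <- c("ics_params", class(p))
  p
}

#' Mantegna scale factor for Levy-flight steps
#'
#' phi = { Gamma(1+beta) sin(pi beta / 2) /
#'         [ Gamma((1+beta)/2) beta 2^((beta-1)/2) ] }^(1/beta)
#'
#' @param beta Levy index in (0.3, 1.99].
#' @return The scalar scale factor.
#' @export
levy_phi <- function(beta) {
  if (!(beta > 0.3 && beta <= 1.99))
    stop("'beta' must lie in (0.3, 1.99]", call. = FALSE)
  num <- gamma(1 + beta) * sin(pi * beta / 2)
  den <- gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)
  (num / den)^(1 / beta)
}

#' Draw one Levy-flight step vector (Mantegna's method)
#'
#' Each coordinate is phi * mu / |v|^(1/beta) with mu, v standard normal,
#' giving steps with a power-law tail of index beta.
#'
#' @param dim Number of coordinates.
#' @param beta Levy index in (0.3, 1.99].
#' @return Numeric vector of length \code{dim}.
#' @export
levy_step <- function(dim, beta = 1.5) {
  phi <- levy_phi(beta)
  mu <- stats::rnorm(dim)
  v <- stats::rnorm(dim)
  phi * mu / abs(v)^(1 / beta)
}

#' Tent map on the unit interval
#'
#' x -> 2x for x <= 1/2, else 2(1 - x). Piecewise-linear chaotic map with
#' uniform invariant density, used to spread initial populations.
#'
#' @param x Value(s) in [0, 1].
#' @return Mapped value(s).
#' @export
tent_map <- function(x) {
  if (any(x < 0 | x > 1)) stop("tent map input must lie in [0, 1]", call. = FALSE)
  ifelse(x <= 0.5, 2 * x, 2 * (1 - x))
}

# The Tent orbit collapses on {0, 1/2, 1} and at the fixed point 2/3, and
# in double precision every orbit drains its mantissa into 0 within ~50
# steps. Nudge iterates off the unstable set and re-inject tiny seeded
# jitter each step so long sequences keep the map's uniform invariant
# density.
tent_iterate <- function(x0, n) {
  out <- numeric(n)
  x <- x0
  jitter <- stats::runif(n, -1e-9, 1e-9)
  for (i in seq_len(n)) {
    bad <- abs(x - c(0, 0.5, 1, 2 / 3)) < 1e-12
    if (any(bad)) x <- x + 1e-6
    x <- min(max(x + jitter[i], 0), 1)
    x <- tent_map(x)
    out[i] <- x
  }
  out
}

#' Tent-chaotic initial population
#'
#' Per dimension, iterates the Tent map from a random start in (0, 1) and
#' maps the chaotic sequence affinely onto the search bounds.
#'
#' @param params An \code{\link{ics_params}} object.
#' @param dim Problem dimension.
#' @return \code{n_nests x dim} matrix of positions inside the bounds.
#' @export
chaotic_init <- function(params, dim) {
  lo <- rep_len(params$lower, dim)
  hi <- rep_len(params$upper, dim)
  pos <- matrix(0, params$n_nests, dim)
  for (k in seq_len(dim)) {
    x0 <- stats::runif(1, 1e-6, 1 - 1e-6)
    u <- tent_iterate(x0, params$n_nests)
    pos[, k] <- lo[k] + u * (hi[k] - lo[k])
  }
  pos
}

#' Adaptive step-control schedule of the improved cuckoo search
#'
#' a0(t) = amin + 0.5 (amax - amin) (cos(log(1 + (e - 1) t / T) * pi) + 1),
#' with the natural logarithm, so a0(0) = amax and a0(T) = amin.
#'
#' @param t Iteration index in [0, T].
#' @param params An \code{\link{ics_params}} object.
#' @return Step control value in [amin, amax].
#' @export
adaptive_a0 <- function(t, params) {
  if (any(t < 0 | t > params$T)) stop("'t' must lie in [0, T]", call. = FALSE)
  params$amin + 0.5 * (params$amax - params$amin) *
    (cos(log(1 + (exp(1) - 1) * t / params$T) * pi) + 1)
}

#' Adaptive discovery-probability schedule of the improved cuckoo search
#'
#' Pa(t) = pa_min + (pa_max - pa_min) ((T - t) / T)^2, so Pa(0) = pa_max
#' and Pa(T) = pa_min: discovery pressure relaxes as the population matures.
#'
#' @inheritParams adaptive_a0
#' @return Discovery probability in [pa_min, pa_max].
#' @export
adaptive_pa <- function(t, params) {
  if (any(t < 0 | t > params$T)) stop("'t' must lie in [0, T]", call. = FALSE)
  params$pa_min + (params$pa_max - params$pa_min) * ((params$T - t) / params$T)^2
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

cs_engine <- function(objective, params, dim, init, a0_fun, pa_fun) {
  if (!is.null(params$seed)) set.seed(params$seed)
  lo <- rep_len(params$lower, dim)
  hi <- rep_len(params$upper, dim)
  n <- params$n_nests
  pos <- init()
  fit <- apply(pos, 1, objective)
  if (any(!is.finite(fit))) stop("objective returned non-finite value", call. = FALSE)
  ibest <- which.min(fit)
  best_x <- pos[ibest, ]
  best_f <- fit[ibest]
  trace <- numeric(params$T)

  for (t in seq_len(params$T)) {
    a0 <- a0_fun(t)
    pa <- pa_fun(t)
    # Levy-flight proposals, greedily compared against the proposing nest.
    for (i in seq_len(n)) {
      step <- a0 * levy_step(dim, params$beta) * (pos[i, ] - best_x)
      cand <- clamp(pos[i, ] + step, lo, hi)
      f <- objective(cand)
      if (!is.finite(f)) stop("objective returned non-finite value", call. = FALSE)
      if (f < fit[i]) {
        pos[i, ] <- cand
        fit[i] <- f
      }
    }
    # Discovery/abandonment: biased random walk toward the difference of two
    # random nests, applied per coordinate with a retention mask of
    # probability Pa (the reference formulation of the discovery operator),
    # accepted greedily.
    r1 <- sample.int(n, n, replace = TRUE)
    r2 <- sample.int(n, n, replace = TRUE)
    for (i in seq_len(n)) {
      keep <- stats::runif(dim) < pa
      cand <- pos[i, ] + stats::runif(1) * (pos[r1[i], ] - pos[r2[i], ]) *
        as.numeric(!keep)
      cand <- clamp(cand, lo, hi)
      f <- objective(cand)
      if (f < fit[i]) {
        pos[i, ] <- cand
        fit[i] <- f
      }
    }
    ibest <- which.min(fit)
    if (fit[ibest] < best_f) {
      best_f <- fit[ibest]
      best_x <- pos[ibest, ]
    }
    trace[t] <- best_f
  }
  structure(list(best_position = best_x, best_fitness = best_f,
                 trace = trace, seed = params$seed),
            class = "search_trace")
}

#' Cuckoo search minimization
#'
#' @param objective Function mapping a numeric position vector to a scalar.
#' @param params A \code{\link{cs_params}} object.
#' @param dim Problem dimension (default 2).
#' @return A \code{search_trace}: best position, best fitness, and the
#'   per-iteration best-fitness trace (non-increasing by elitism).
#' @export
cs_search <- function(objective, params, dim = 2L) {
  stopifnot(inherits(params, "cs_params"))
  cs_engine(objective, params, dim,
            init = function() {
              lo <- rep_len(params$lower, dim)
              hi <- rep_len(params$upper, dim)
              matrix(stats::runif(params$n_nests * dim, rep(lo, each = params$n_nests),
                                  rep(hi, each = params$n_nests)),
                     params$n_nests, dim)
            },
            a0_fun = function(t) params$a0,
            pa_fun = function(t) params$pa)
}

#' Improved cuckoo search minimization
#'
#' Identical to \code{\link{cs_search}} except that the initial population
#' is Tent-chaotic and the step control and discovery probability follow
#' the adaptive schedules \code{\link{adaptive_a0}} and
#' \code{\link{adaptive_pa}}.
#'
#' @param objective Function mapping a numeric position vector to a scalar.
#' @param params An \code{\link{ics_params}} object.
#' @param dim Problem dimension (default 2).
#' @return A \code{search_trace}; see \code{\link{cs_search}}.
#' @export
ics_search <- function(objective, params, dim = 2L) {
  stopifnot(inherits(params, "ics_params"))
  cs_engine(objective, params, dim,
            init = function() chaotic_init(params, dim),
            a0_fun = function(t) adaptive_a0(t, params),
            pa_fun = function(t) adaptive_pa(t, params))
}

#' Two-dimensional benchmark functions
#'
#' Returns one of four classic unconstrained test problems:
#' \describe{
#'   \item{rosenbrock}{100 (y - x^2)^2 + (x - 1)^2, bounds [-2.048, 2.048],
#'     minimum 0 at (1, 1).}
#'   \item{griewank}{(x^2 + y^2)/4000 - cos(x) cos(y / sqrt(2)) + 1,
#'     bounds [-600, 600], minimum 0 at the origin.}
#'   \item{cross_in_tray}{-1e-4 (|sin x sin y exp(|100 - r / pi|)| + 1)^0.1
#'     with r = sqrt(x^2 + y^2), bounds [-10, 10], minimum -2.06261 at the
#'     four points (+-1.3491, +-1.3491).}
#'   \item{schaffer}{0.5 + (sin^2(r) - 0.5) / (1 + 0.01 r^2)^2 with
#'     r^2 = x^2 + y^2, bounds [-10, 10], minimum 0 at the origin.}
#' }
#'
#' @param name One of \code{"rosenbrock"}, \code{"griewank"},
#'   \code{"cross_in_tray"}, \code{"schaffer"}.
#' @return A list with \code{name}, \code{fn}, \code{lower}, \code{upper},
#'   \code{minimum} (global minimum value) and \code{argmin} (one argmin).
#' @export
benchmark_function <- function(name = c("rosenbrock", "griewank",
                                        "cross_in_tray", "schaffer")) {
  name <- match.arg(name)
  switch(name,
    rosenbrock = list(
      name = name,
      fn = function(x) 100 * (x[2] - x[1]^2)^2 + (x[1] - 1)^2,
      lower = -2.048, upper = 2.048, minimum = 0, argmin = c(1, 1)),
    griewank = list(
      name = name,
      fn = function(x) sum(x^2) / 4000 - cos(x[1]) * cos(x[2] / sqrt(2)) + 1,
      lower = -600, upper = 600, minimum = 0, argmin = c(0, 0)),
    cross_in_tray = list(
      name = name,
      fn = function(x) {
        r <- sqrt(sum(x^2))
        -1e-4 * (abs(sin(x[1]) * sin(x[2]) * exp(abs(100 - r / pi))) + 1)^0.1
      },
      lower = -10, upper = 10, minimum = -2.06261,
      argmin = c(1.3491, 1.3491)),
    schaffer = list(
      name = name,
      fn = function(x) {
        r2 <- sum(x^2)
        0.5 + (sin(sqrt(r2))^2 - 0.5) / (1 + 0.01 * r2)^2
      },
      lower = -10, upper = 10, minimum = 0, argmin = c(0, 0)))
}

#' Repeated-run comparison of CS and ICS on the benchmark suite
#'
#' Runs each requested algorithm \code{n_runs} times on each requested
#' benchmark with seeds \code{seed + 0 .. n_runs - 1} and summarizes the
#' final best fitness per cell (optimal, worst, average, sample SD).
#'
#' @param algorithms Character subset of \code{c("cs", "ics")}.
#' @param functions Character subset of the benchmark names.
#' @param n_runs Number of independently seeded runs per cell.
#' @param seed Master seed; run r uses \code{seed + r - 1}.
#' @param n_nests,T Population size and iteration budget.
#' @return Data frame with one row per (algorithm, function) cell plus a
#'   \code{"runs"} attribute holding the raw final fitness values.
#' @export
compare_runs <- function(algorithms = c("cs", "ics"),
                         functions = c("rosenbrock", "griewank",
                                       "cross_in_tray", "schaffer"),
                         n_runs = 50L, seed = 1L,
                         n_nests = 20L, T = 200L) {
  stopifnot(all(algorithms %in% c("cs", "ics")), n_runs >= 2L)
  rows <- list()
  raw <- list()
  for (fn_name in functions) {
    bf <- benchmark_function(fn_name)
    for (algo in algorithms) {
      finals <- vapply(seq_len(n_runs), function(r) {
        s <- as.integer(seed) + r - 1L
        if (algo == "cs") {
          p <- cs_params(n_nests = n_nests, T = T,
                         lower = bf$lower, upper = bf$upper, seed = s)
          cs_search(bf$fn, p)$best_fitness
        } else {
          p <- ics_params(n_nests = n_nests, T = T,
                          lower = bf$lower, upper = bf$upper, seed = s)
          ics_search(bf$fn, p)$best_fitness
        }
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = algo, fn = fn_name,
        optimal = min(finals), worst = max(finals),
        average = mean(finals), sd = stats::sd(finals))
      raw[[paste(algo, fn_name, sep = ".")]] <- finals
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "runs") <- raw
  out
}
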