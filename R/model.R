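# Force-estimation model: epsilon-SVR with RBF kernel, its (C, sigma)
# tuning by the improved cuckoo search, and the repeated 90/10 evaluation
# protocol with RMSE / MAPE / Pearson-R metrics.
#
# The kernel is exp(-||u - w||^2 / (2 sigma^2)) with sigma the kernel
# width; the backing library parameterizes the RBF as exp(-gamma ||.||^2),
# so gamma = 1 / (2 sigma^2).

#' SVR configuration
#'
#' @param C Penalty coefficient, > 0.
#' @param sigma RBF kernel width, > 0.
#' @param epsilon Width of the insensitive tube (on Z-scored targets).
#' @return An \code{svr_config} list.
#' @export
svr_config <- function(C, sigma, epsilon = 0.01) {
  if (C <= 0 || sigma <= 0) stop("'C' and 'sigma' must be positive", call. = FALSE)
  structure(list(C = C, sigma = sigma, epsilon = epsilon), class = "svr_config")
}

svm_gamma <- function(sigma) 1 / (2 * sigma^2)

#' Regression metrics: RMSE, MAPE and Pearson correlation
#'
#' RMSE = sqrt(mean((yhat - y)^2)); MAPE = mean(|(yhat - y) / y|) over
#' nonzero targets (zero targets are excluded with a warning); R is the
#' Pearson correlation between predictions and truth.
#'
#' @param y_true Observed values, length >= 2.
#' @param y_pred Predicted values, same length.
#' @return Named list \code{rmse}, \code{mape}, \code{r}.
#' @export
compute_metrics <- function(y_true, y_pred) {
  n <- length(y_true)
  if (n < 2L || length(y_pred) != n)
    stop("'y_true' and 'y_pred' must have equal length >= 2", call. = FALSE)
  if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0)
    stop("correlation undefined for zero-variance inputs", call. = FALSE)
  nz <- y_true != 0
  if (!all(nz))
    warning(sprintf("MAPE: excluding %d zero target(s)", sum(!nz)), call. = FALSE)
  list(rmse = sqrt(mean((y_pred - y_true)^2)),
       mape = mean(abs((y_pred[nz] - y_true[nz]) / y_true[nz])),
       r = stats::cor(y_pred, y_true))
}

seeded_folds <- function(n, k, seed) {
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

#' Cross-validated SVR loss at one (C, sigma) position
#'
#' 5-fold cross-validated RMSE of an RBF epsilon-SVR on the training set,
#' with folds fixed by \code{seed}: the fitness the optimizer minimizes.
#' Solver failures return a large-penalty sentinel rather than an error so
#' the search can continue.
#'
#' @param position Numeric vector \code{c(C, sigma)}.
#' @param X Training feature matrix (Z-scored).
#' @param y Training targets (Z-scored).
#' @param k Number of folds.
#' @param seed Fold-assignment seed.
#' @param epsilon Insensitive-tube width.
#' @return Scalar loss (>= 0).
#' @export
svr_fitness <- function(position, X, y, k = 5L, seed = 1L, epsilon = 0.01) {
  if (nrow(X) < 20L) stop("training set must have >= 20 rows", call. = FALSE)
  folds <- seeded_folds(nrow(X), k, seed)
  pred <- numeric(length(y))
  for (f in seq_len(k)) {
    te <- folds == f
    fit <- tryCatch(
      e1071::svm(X[!te, , drop = FALSE], y[!te], type = "eps-regression",
                 kernel = "radial", cost = position[1],
                 gamma = svm_gamma(position[2]), epsilon = epsilon,
                 scale = FALSE),
      error = function(e) NULL)
    if (is.null(fit)) return(1e6)
    pred[te] <- stats::predict(fit, X[te, , drop = FALSE])
  }
  sqrt(mean((pred - y)^2))
}

#' Tune SVR hyperparameters with the improved cuckoo search
#'
#' Minimizes \code{\link{svr_fitness}} over the (C, sigma) box
#' [0.001, 500]^2 with \code{\link{ics_search}}.
#'
#' @param X Z-scored training features.
#' @param y Z-scored training targets.
#' @param ics An \code{\link{ics_params}} object; its bounds define the
#'   search box. Defaults to an 8-nest, 12-iteration budget, which is ample
#'   for the 2-D (C, sigma) landscape.
#' @param cv_seed Seed fixing the cross-validation folds.
#' @param epsilon Insensitive-tube width.
#' @return List with the chosen \code{config} (\code{svr_config}) and the
#'   search \code{trace}.
#' @export
tune_svr <- function(X, y,
                     ics = ics_params(n_nests = 8L, T = 12L,
                                      lower = 0.001, upper = 500),
                     cv_seed = 1L, epsilon = 0.01) {
  trace <- ics_search(function(p) svr_fitness(p, X, y, seed = cv_seed,
                                              epsilon = epsilon),
                      ics, dim = 2L)
  list(config = svr_config(trace$best_position[1], trace$best_position[2],
                           epsilon),
       trace = trace)
}

#' Fit an SVR and predict test-set force
#'
#' Features and targets are standardized with train-fitted scalers;
#' predictions are returned in the original force units.
#'
#' @param config An \code{svr_config}.
#' @param train_x,train_y Training features (matrix) and force targets (N).
#' @param test_x Test features with identical columns.
#' @return A \code{force_estimate}: \code{predicted} (N), the fitted model
#'   and the scalers used.
#' @export
fit_predict <- function(config, train_x, train_y, test_x) {
  if (!identical(colnames(train_x), colnames(test_x)))
    stop("train and test feature columns differ", call. = FALSE)
  fx <- fit_zscore(train_x)
  fy <- fit_zscore(matrix(train_y, dimnames = list(NULL, "force")))
  Xtr <- apply_zscore(fx, train_x)
  ytr <- as.numeric(apply_zscore(fy, matrix(train_y,
                                            dimnames = list(NULL, "force"))))
  fit <- e1071::svm(Xtr, ytr, type = "eps-regression", kernel = "radial",
                    cost = config$C, gamma = svm_gamma(config$sigma),
                    epsilon = config$epsilon, scale = FALSE)
  pz <- stats::predict(fit, apply_zscore(fx, test_x))
  pred <- as.numeric(invert_zscore(fy, matrix(pz, ncol = 1)))
  structure(list(predicted = pred, model = fit, config = config,
                 x_scaler = fx, y_scaler = fy),
            class = "force_estimate")
}

#' Repeated train/test evaluation of the GRA + ICS-SVR pipeline
#'
#' Per repetition: shuffle with the repetition seed, split 90/10, fit the
#' Z-score scalers on the training split only, run GRA on the training
#' split and select the requested combination, tune (C, sigma) with ICS,
#' fit, predict the held-out force and compute metrics. Both the split and
#' the optimizer are re-seeded every repetition, so the reported mean and
#' SD reflect the full pipeline variability.
#'
#' @param fm A \code{feature_matrix} (features + force).
#' @param combination Combination label \code{"A"}..\code{"E"}, or a
#'   precomputed \code{feature_combination}, or \code{NULL} to use all
#'   features.
#' @param ics \code{\link{ics_params}} for the hyperparameter search.
#' @param n_reps Number of repetitions.
#' @param split Training fraction.
#' @param seed Master seed; repetition i uses \code{seed + i - 1}.
#' @param rho GRA resolution coefficient.
#' @return An \code{evaluation_report}: per-repetition metrics, their
#'   mean and SD (n - 1 denominator), chosen (C, sigma) per repetition and
#'   the seeds used.
#' @export
evaluate_protocol <- function(fm, combination = "D",
                              ics = ics_params(n_nests = 8L, T = 12L,
                                               lower = 0.001, upper = 500),
                              n_reps = 10L, split = 0.9, seed = 1L,
                              rho = 0.5) {
  X <- fm$features
  y <- fm$force
  n <- nrow(X)
  if (n < 50L) stop("evaluation needs >= 50 rows", call. = FALSE)
  reps <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    rep_seed <- as.integer(seed) + i - 1L
    set.seed(rep_seed)
    ord <- sample.int(n)
    n_train <- floor(split * n)
    tr <- ord[seq_len(n_train)]
    te <- ord[(n_train + 1L):n]

    sel <- combination
    if (is.character(combination)) {
      fx <- fit_zscore(X[tr, , drop = FALSE])
      fy <- fit_zscore(matrix(y[tr], dimnames = list(NULL, "force")))
      gz <- relational_analysis(
        as.numeric(apply_zscore(fy, matrix(y[tr], dimnames = list(NULL, "force")))),
        apply_zscore(fx, X[tr, , drop = FALSE]),
        rho = rho, rows_are_sequences = FALSE)
      sel <- select_combination(gz, combination)
    }
    cols <- if (is.null(sel)) colnames(X) else sel$names
    Xtr <- X[tr, cols, drop = FALSE]
    Xte <- X[te, cols, drop = FALSE]

    fx <- fit_zscore(Xtr)
    fy <- fit_zscore(matrix(y[tr], dimnames = list(NULL, "force")))
    ics_i <- ics
    ics_i$seed <- rep_seed
    tuned <- tune_svr(apply_zscore(fx, Xtr),
                      as.numeric(apply_zscore(fy, matrix(y[tr],
                                                dimnames = list(NULL, "force")))),
                      ics = ics_i, cv_seed = rep_seed)
    est <- fit_predict(tuned$config, Xtr, y[tr], Xte)
    m <- compute_metrics(y[te], est$predicted)
    reps[[i]] <- list(seed = rep_seed, metrics = m, config = tuned$config,
                      n_features = length(cols), features = cols)
  }
  tab <- data.frame(
    rep = seq_len(n_reps),
    seed = vapply(reps, function(r) r$seed, numeric(1)),
    rmse = vapply(reps, function(r) r$metrics$rmse, numeric(1)),
    mape = vapply(reps, function(r) r$metrics$mape, numeric(1)),
    r = vapply(reps, function(r) r$metrics$r, numeric(1)),
    C = vapply(reps, function(r) r$config$C, numeric(1)),
    sigma = vapply(reps, function(r) r$config$sigma, numeric(1)),
    n_features = vapply(reps, function(r) r$n_features, numeric(1)))
  structure(list(
    repetitions = tab,
    mean = c(rmse = mean(tab$rmse), mape = mean(tab$mape), r = mean(tab$r)),
    sd = c(rmse = stats::sd(tab$rmse), mape = stats::sd(tab$mape),
           r = stats::sd(tab$r)),
    combination = if (is.character(combination)) combination
                  else if (is.null(combination)) "all" else combination$label,
    seed = seed),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> combination %s, %d repetition(s)\n",
              x$combination, nrow(x$repetitions)))
  cat(sprintf("  RMSE %.4f +/- %.4f N | MAPE %.4f +/- %.4f | R %.4f +/- %.4f\n",
              x$mean["rmse"], x$sd["rmse"], x$mean["mape"], x$sd["mape"],
              x$mean["r"], x$sd["r"]))
  invisible(x)
}
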