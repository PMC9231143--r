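# Gray relational analysis (GRA): similarity between the force reference
# sequence and each feature sequence via pointwise absolute differences.
# Both sides must share a scale, so the pipeline feeds GRA Z-scored
# sequences; the relational degree r_i in (0, 1] ranks features by how
# closely they track force.

#' Gray relational analysis of feature sequences against a reference
#'
#' For reference F(k) and comparison rows x_i(k), with difference
#' Delta_i(k) = |F(k) - x_i(k)| and global extremes taken jointly over all
#' i and k, the relational coefficient is
#' xi_i(k) = (min min Delta + rho max max Delta) /
#'           (Delta_i(k) + rho max max Delta),
#' and the relational degree r_i is the mean of xi_i(k) over k. A smaller
#' resolution coefficient rho sharpens discrimination (resolution is best
#' for rho <= 0.5463; the customary value 0.5 is the default).
#'
#' @param F Reference sequence (typically the Z-scored force), length n >= 2.
#' @param X Comparison matrix, m rows (features) x n columns, or n x m with
#'   \code{rows_are_sequences = FALSE} (the feature-matrix layout).
#' @param rho Resolution coefficient in (0, 1).
#' @param rows_are_sequences If \code{FALSE}, \code{X} columns are the
#'   feature sequences (windows x features layout).
#' @return A \code{gra_result}: \code{delta} and \code{xi} matrices
#'   (m x n), relational degrees \code{r} (named if \code{X} has names),
#'   \code{rho} and \code{feature_names}.
#' @export
relational_analysis <- function(F, X, rho = 0.5, rows_are_sequences = TRUE) {
  if (!(rho > 0 && rho < 1)) stop("'rho' must lie in (0, 1)", call. = FALSE)
  X <- as.matrix(X)
  if (!rows_are_sequences) X <- t(X)
  n <- length(F)
  if (n < 2L) stop("reference sequence needs length >= 2", call. = FALSE)
  if (ncol(X) != n)
    stop("sequence length mismatch between reference and comparisons",
         call. = FALSE)
  delta <- abs(sweep(X, 2, F, "-"))
  dmin <- min(delta)
  dmax <- max(delta)
  xi <- if (dmax == 0) {
    matrix(1, nrow(X), n)  # all sequences identical to the reference
  } else {
    (dmin + rho * dmax) / (delta + rho * dmax)
  }
  r <- rowMeans(xi)
  nm <- rownames(X)
  if (!is.null(nm)) names(r) <- nm
  structure(list(delta = delta, xi = xi, r = r, rho = rho,
                 feature_names = nm),
            class = "gra_result")
}

#' @export
print.gra_result <- function(x, ...) {
  cat(sprintf("<gra_result> %d feature(s) x %d points, rho = %g\n",
              nrow(x$xi), ncol(x$xi), x$rho))
  top <- sort(x$r, decreasing = TRUE)
  print(utils::head(round(top, 4), 10))
  invisible(x)
}

COMBINATION_THRESHOLDS <- c(A = 0.60, B = 0.75, C = 0.80, D = 0.85, E = 0.90)

#' Select a feature combination by relational-degree threshold
#'
#' Combinations are labeled by the lower bound on the relational degree:
#' A keeps features with r >= 0.60, B >= 0.75, C >= 0.80, D >= 0.85 and
#' E >= 0.90 (boundaries inclusive), so the selections nest
#' E within D within C within B within A.
#'
#' @param result A \code{\link{relational_analysis}} result.
#' @param label One of \code{"A"}..\code{"E"}.
#' @return A \code{feature_combination}: \code{label}, \code{threshold},
#'   selected \code{indices} and \code{names}.
#' @export
select_combination <- function(result, label = c("A", "B", "C", "D", "E")) {
  label <- match.arg(label)
  thr <- COMBINATION_THRESHOLDS[[label]]
  idx <- which(result$r >= thr)
  if (length(idx) == 0L)
    stop(sprintf("no features selected at threshold %.2f (combination %s)",
                 thr, label), call. = FALSE)
  structure(list(label = label, threshold = thr, indices = idx,
                 names = if (!is.null(names(result$r))) names(result$r)[idx]),
            class = "feature_combination")
}

#' Relational-degree ranking and combination membership tables
#'
#' \code{gra_ranking} returns the features ranked by relational degree;
#' \code{combination_table} flags membership of each feature in the five
#' threshold combinations.
#'
#' @param result A \code{gra_result}.
#' @return A data frame.
#' @export
gra_ranking <- function(result) {
  r <- result$r
  nm <- names(r) %||% paste0("feature_", seq_along(r))
  df <- data.frame(feature = nm, r = as.numeric(r))
  df[order(-df$r), , drop = FALSE]
}

#' @rdname gra_ranking
#' @export
combination_table <- function(result) {
  r <- result$r
  nm <- names(r) %||% paste0("feature_", seq_along(r))
  out <- data.frame(feature = nm, r = as.numeric(r))
  for (lab in names(COMBINATION_THRESHOLDS))
    out[[lab]] <- r >= COMBINATION_THRESHOLDS[[lab]]
  out
}
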