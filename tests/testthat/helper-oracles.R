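# Independent brute-force oracles used to cross-check the package
# implementations. These are deliberately naive (plain loops, direct
# definitions) and share no code with the implementations they verify.

# Zero crossings: strict sign changes, zero counted as positive.
oracle_zc <- function(x) {
  n <- length(x)
  cnt <- 0L
  for (k in 2:n) {
    s1 <- if (x[k - 1] >= 0) 1 else -1
    s2 <- if (x[k] >= 0) 1 else -1
    if (s1 != s2) cnt <- cnt + 1L
  }
  cnt
}

# Slope sign changes: (x_k - x_{k-1})(x_k - x_{k+1}) > 0.
oracle_ssc <- function(x) {
  n <- length(x)
  cnt <- 0L
  for (k in 2:(n - 1)) {
    if ((x[k] - x[k - 1]) * (x[k] - x[k + 1]) > 0) cnt <- cnt + 1L
  }
  cnt
}

# LZ76 exhaustive-history parse on a character vector of "0"/"1",
# with a naive O(n^2) substring scan (no regex machinery).
oracle_lz76 <- function(bits) {
  s <- as.integer(bits)
  n <- length(s)
  occurs_in_prefix <- function(from, to) {
    # does s[from..to] occur anywhere in s[1..to-1]?
    len <- to - from + 1L
    if (to - 1L < len) return(FALSE)
    for (st in 1:(to - len)) {
      if (all(s[st:(st + len - 1L)] == s[from:to])) return(TRUE)
    }
    FALSE
  }
  cnt <- 0L
  i <- 1L
  while (i <= n) {
    l <- 1L
    while (i + l - 1L <= n && occurs_in_prefix(i, i + l - 1L)) l <- l + 1L
    l <- min(l, n - i + 1L)
    cnt <- cnt + 1L
    i <- i + l
  }
  cnt
}

# Chebyshev distance between m-length templates starting at i and j.
oracle_cheb <- function(x, i, j, m) {
  d <- 0
  for (k in 0:(m - 1)) d <- max(d, abs(x[i + k] - x[j + k]))
  d
}

# Sample entropy straight from the definition: ordered pairs i != j over
# templates 1..n-m at lengths m and m+1.
oracle_sampen <- function(x, m, r) {
  n <- length(x)
  np <- n - m
  A <- 0; B <- 0
  for (i in 1:np) for (j in 1:np) {
    if (i == j) next
    if (oracle_cheb(x, i, j, m) <= r) {
      B <- B + 1
      if (oracle_cheb(x, i, j, m + 1) <= r) A <- A + 1
    }
  }
  if (A == 0 || B == 0) return(Inf)
  -log(A / B)
}

# Approximate entropy from the definition, self-match included.
oracle_apen <- function(x, m, r) {
  phi <- function(mm) {
    n <- length(x)
    nt <- n - mm + 1
    logs <- numeric(nt)
    for (i in 1:nt) {
      cnt <- 0
      for (j in 1:nt) if (oracle_cheb(x, i, j, mm) <= r) cnt <- cnt + 1
      logs[i] <- log(cnt / nt)
    }
    mean(logs)
  }
  phi(m) - phi(m + 1)
}

# Mantegna scale factor from the gamma-function arithmetic.
oracle_levy_phi <- function(beta) {
  (gamma(1 + beta) * sin(pi * beta / 2) /
     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

# Grey relational degrees computed element by element from the defining
# formulas, without vectorization tricks.
oracle_gra <- function(F, X, rho) {
  m <- nrow(X); n <- length(F)
  delta <- matrix(0, m, n)
  for (i in 1:m) for (k in 1:n) delta[i, k] <- abs(F[k] - X[i, k])
  dmin <- min(delta); dmax <- max(delta)
  r <- numeric(m)
  for (i in 1:m) {
    xi <- (dmin + rho * dmax) / (delta[i, ] + rho * dmax)
    r[i] <- mean(xi)
  }
  r
}
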