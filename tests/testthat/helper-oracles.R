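# Independent oracles used across the suite.  Each is a deliberately naive
# computation (enumeration, brute force, closed form) kept separate from the
# implementation paths it checks.

# Exhaustive active-set non-negative least squares: try every subset of
# columns, solve the unconstrained LS on it, keep feasible solutions, return
# the one with the smallest residual sum of squares.
nnls_exhaustive <- function(A, b) {
  p <- ncol(A)
  best_x <- rep(0, p)
  best_rss <- sum(b^2)
  for (mask in seq_len(2^p - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    As <- A[, S, drop = FALSE]
    coef <- tryCatch(qr.solve(As, b), error = function(e) NULL)
    if (is.null(coef) || any(coef < -1e-10)) next
    rss <- sum((b - As %*% pmax(coef, 0))^2)
    if (rss < best_rss - 1e-12) {
      best_rss <- rss
      best_x <- rep(0, p)
      best_x[S] <- pmax(coef, 0)
    }
  }
  best_x
}

# Closed-form Welch statistic and Satterthwaite df.
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Exact signed-rank p by full enumeration of the 2^n sign assignments,
# two-sided with the doubling convention.
signed_rank_enumeration <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  all_W <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    sum(r[signs])
  }, numeric(1))
  mu <- n * (n + 1) / 4
  p <- if (W > mu) 2 * mean(all_W >= W) else 2 * mean(all_W <= W)
  min(1, p)
}

# Explicit sums-of-squares two-way ANOVA for a balanced design.
balanced_two_way_oracle <- function(y, f1, f2) {
  f1 <- factor(f1); f2 <- factor(f2)
  n <- length(y)
  a <- nlevels(f1); b <- nlevels(f2)
  r <- n / (a * b)
  grand <- mean(y)
  m1 <- tapply(y, f1, mean)
  m2 <- tapply(y, f2, mean)
  mc <- tapply(y, interaction(f1, f2), mean)
  ss1 <- r * b * sum((m1 - grand)^2)
  ss2 <- r * a * sum((m2 - grand)^2)
  cellv <- mc[as.character(interaction(f1, f2))]
  ss_within <- sum((y - cellv)^2)
  ss_cells <- r * sum((mc - grand)^2)
  ss12 <- ss_cells - ss1 - ss2
  df1 <- a - 1; df2 <- b - 1; df12 <- df1 * df2
  dfe <- n - a * b
  mse <- ss_within / dfe
  list(F1 = (ss1 / df1) / mse, F2 = (ss2 / df2) / mse,
       F12 = (ss12 / df12) / mse, dfe = dfe)
}

# Tukey-Kramer adjusted p for one pair, straight from the studentized range
# distribution.
tukey_pair_oracle <- function(diff, mse, ni, nj, k_groups, df_err) {
  q <- abs(diff) / sqrt(mse / 2 * (1 / ni + 1 / nj))
  ptukey(q, k_groups, df_err, lower.tail = FALSE)
}

# Deterministic random trace for I/O and QC tests.
random_trace <- function(n, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(abs(rnorm(4 * n, 0, 0.02)), nrow = n)
    hit <- cbind(seq_len(n), sample(1:4, n, replace = TRUE))
    m[hit] <- pmax(0, rnorm(n, 1, 0.05))
    colnames(m) <- c("A", "C", "G", "T")
    trace_data(m)
  })
}

# Small-geometry decomposition config (K = 5) used by the oracle-equivalence
# tests; windows sized so the stacked window signal stays <= 60 positions.
small_cfg <- function(brk) {
  decomposition_config(max_indel = 5L,
                       align_window = c(brk - 40L, brk - 21L),
                       decomp_window = c(brk + 11L, brk + 60L))
}
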