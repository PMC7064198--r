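# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops, explicit formulas, explicit matrix
# inversion.

# A residual-set stand-in built directly from numeric components (bypasses
# residualize(); used where the test controls y and S exactly).
make_resid <- function(y, S) towge:::new_ge_residuals(y_res = y, S_res = as.matrix(S))

# Random Gaussian residual-set fixture.
random_resid <- function(n, p, seed) {
  set.seed(seed)
  make_resid(rnorm(n), matrix(rnorm(n * p), n, p))
}

# Direct, loop-based evaluation of the weighted score statistic
# n * (sum_i (y_i - ybar)(s_i - sbar))^2 / (sum (y - ybar)^2 sum (s - sbar)^2)
oracle_score <- function(y, S, w) {
  s <- as.numeric(as.matrix(S) %*% w)
  num <- 0
  for (i in seq_along(y)) num <- num + (y[i] - mean(y)) * (s[i] - mean(s))
  length(y) * num^2 / (sum((y - mean(y))^2) * sum((s - mean(s))^2))
}

# Per-column scores and sums of squares by explicit loops.
oracle_UV <- function(y, S) {
  S <- as.matrix(S)
  U <- V <- numeric(ncol(S))
  for (j in seq_len(ncol(S))) {
    sj <- S[, j]
    U[j] <- sum((y - mean(y)) * (sj - mean(sj)))
    V[j] <- sum((sj - mean(sj))^2)
  }
  list(U = U, V = V)
}

# Exact permutation p-value by full enumeration of all n! trait orders
# (feasible for n <= 7): fraction of orders whose statistic reaches the
# observed one, the identity order included.
perms_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-k]
      out[row, ] <- c(k, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

oracle_exact_perm_p <- function(y, S, stat_fun) {
  P <- perms_of(length(y))
  t0 <- stat_fun(y, S)
  hits <- 0L
  for (r in seq_len(nrow(P))) {
    if (stat_fun(y[P[r, ]], S) >= t0 - 1e-12) hits <- hits + 1L
  }
  hits / nrow(P)
}

# TOW statistic through the oracle components.
oracle_tow <- function(y, S) {
  uv <- oracle_UV(y, S)
  sum(uv$U^2 / uv$V)
}

# Replay the package's permutation stream: the engine draws, after
# set.seed(seed), B permutations as consecutive sample.int(n) calls.
replay_perms <- function(n, B, seed) {
  set.seed(seed)
  vapply(seq_len(B), function(b) sample.int(n), integer(n))
}

# Literal brute-force VW-TOW-GE: nested loops over the printed formulas,
# raw convention (strict >, divide by B), on a given shared permutation set.
oracle_vw <- function(y, S_rare, S_common, perms, K) {
  B <- ncol(perms)
  T_r <- T_c <- numeric(B + 1)
  T_r[1] <- oracle_tow(y, S_rare)
  T_c[1] <- oracle_tow(y, S_common)
  for (b in seq_len(B)) {
    yp <- y[perms[, b]]
    T_r[b + 1] <- oracle_tow(yp, S_rare)
    T_c[b + 1] <- oracle_tow(yp, S_common)
  }
  var_r <- var(T_r); var_c <- var(T_c)
  lambdas <- (0:K) / K
  p_lam <- matrix(NA_real_, K + 1, B + 1)
  for (k in seq_len(K + 1)) {
    Tl <- lambdas[k] * T_r / var_r + (1 - lambdas[k]) * T_c / var_c
    for (b in seq_len(B + 1)) {
      p_lam[k, b] <- sum(Tl > Tl[b]) / B
    }
  }
  p_min <- apply(p_lam, 2, min)
  sum(p_min < p_min[1]) / B
}

# Least-squares residuals by explicit normal equations (full-rank designs).
oracle_residuals <- function(v, X) {
  beta <- solve(t(X) %*% X) %*% t(X) %*% v
  as.numeric(v - X %*% beta)
}
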