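# Independent reference implementations used as oracles. These deliberately
# take the slow, literal route (explicit loops, enumeration) so they share
# no code path with the package.

# classic iterative NIPALS PLS1: returns first-component weights, scores,
# loadings and y-loading for column-centered X and centered y
oracle_pls1 <- function(X, y, max_iter = 500, tol = 1e-12) {
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  t_old <- rep(Inf, nrow(Xc))
  u <- yc
  for (i in seq_len(max_iter)) {
    w <- as.numeric(crossprod(Xc, u)) / sum(u^2)
    w <- w / sqrt(sum(w^2))
    t_new <- as.numeric(Xc %*% w)
    c_load <- sum(yc * t_new) / sum(t_new^2)
    u <- yc * c_load / c_load^2
    if (sqrt(sum((t_new - t_old)^2)) < tol) break
    t_old <- t_new
  }
  p_load <- as.numeric(crossprod(Xc, t_new)) / sum(t_new^2)
  list(w = w, scores = t_new, p = p_load, c = c_load)
}

# leave-one-out PRESS for one-component PLS1, computed by an explicit loop
oracle_loo_q2 <- function(X, y) {
  n <- nrow(X)
  press <- 0
  for (i in seq_len(n)) {
    Xt <- X[-i, , drop = FALSE]
    yt <- y[-i]
    mu <- colMeans(Xt)
    Xc <- sweep(Xt, 2, mu)
    yc <- yt - mean(yt)
    w <- as.numeric(crossprod(Xc, yc))
    w <- w / sqrt(sum(w^2))
    t_tr <- as.numeric(Xc %*% w)
    c_load <- sum(yc * t_tr) / sum(t_tr^2)
    t_i <- sum((X[i, ] - mu) * w)
    pred <- mean(yt) + t_i * c_load
    press <- press + (y[i] - pred)^2
  }
  1 - press / sum((y - mean(y))^2)
}

# upper-tail hypergeometric probability by exhaustive enumeration of draws
oracle_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  in_pathway <- draws <= K   # pathway members are ids 1..K
  mean(colSums(in_pathway) >= k)
}

# Pearson correlation via the raw covariance formula with explicit loops
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# closed-form three-phase saturating rise used to cross-check the OJIP
# generator (written out independently of ojip_ideal)
oracle_rise <- function(t, f_o, f_m, w, tau) {
  amp <- w[1] * (1 - exp(-t / tau[1])) +
    w[2] * (1 - exp(-t / tau[2])) +
    w[3] * (1 - exp(-t / tau[3]))
  f_o + (f_m - f_o) * amp
}

# small deterministic two-class matrix for OPLS tests
seeded_matrix <- function(seed, n = 6, p = 4, effect = 2) {
  set.seed(seed)
  y <- rep(c("A", "B"), each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  X[y == "B", 1] <- X[y == "B", 1] + effect
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = y)
}
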