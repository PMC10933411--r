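## Independent straight-loop reference implementation of the mean-field DCA
## chain (weights, frequencies, connected correlations, couplings, direct
## information). Deliberately written with explicit loops and no shared code
## with the package internals, so it can serve as an oracle for the
## vectorized / compiled production path.

ref_weights <- function(M, theta = 0.8) {
  n <- nrow(M); L <- ncol(M)
  w <- numeric(n)
  for (m in seq_len(n)) {
    cnt <- 0L
    for (mp in seq_len(n)) {
      matches <- 0L
      for (i in seq_len(L)) if (M[m, i] == M[mp, i]) matches <- matches + 1L
      if (matches / L >= theta) cnt <- cnt + 1L
    }
    w[m] <- 1 / cnt
  }
  list(weights = w, m_eff = sum(w))
}

ref_frequencies <- function(M, w, lam_frac = 0.5, q) {
  n <- nrow(M); L <- ncol(M)
  m_eff <- sum(w)
  lam <- lam_frac / (1 - lam_frac) * m_eff
  f1 <- matrix(0, L, q)
  for (i in seq_len(L))
    for (a in seq_len(q)) {
      s <- 0
      for (m in seq_len(n)) if (M[m, i] == a) s <- s + w[m]
      f1[i, a] <- (lam / q + s) / (lam + m_eff)
    }
  f2 <- matrix(0, L * q, L * q)
  for (i in seq_len(L)) for (j in seq_len(L)) for (a in seq_len(q))
    for (b in seq_len(q)) {
      if (i == j) {
        f2[(i - 1) * q + a, (j - 1) * q + b] <- if (a == b) f1[i, a] else 0
      } else {
        s <- 0
        for (m in seq_len(n)) if (M[m, i] == a && M[m, j] == b) s <- s + w[m]
        f2[(i - 1) * q + a, (j - 1) * q + b] <- (lam / q^2 + s) / (lam + m_eff)
      }
    }
  list(f1 = f1, f2 = f2)
}

ref_couplings <- function(f1, f2, q) {
  L <- nrow(f1)
  d <- L * (q - 1)
  C <- matrix(0, d, d)
  for (i in seq_len(L)) for (j in seq_len(L)) for (a in seq_len(q - 1))
    for (b in seq_len(q - 1)) {
      C[(i - 1) * (q - 1) + a, (j - 1) * (q - 1) + b] <-
        f2[(i - 1) * q + a, (j - 1) * q + b] - f1[i, a] * f1[j, b]
    }
  inv <- solve(C)
  E <- matrix(0, L * q, L * q)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i == j) next
    for (a in seq_len(q - 1)) for (b in seq_len(q - 1)) {
      E[(i - 1) * q + a, (j - 1) * q + b] <-
        -inv[(i - 1) * (q - 1) + a, (j - 1) * (q - 1) + b]
    }
  }
  Es <- matrix(0, L * q, L * q)
  for (r in seq_len(L * q)) for (s in seq_len(L * q))
    Es[r, s] <- (E[r, s] + E[s, r]) / 2
  Es
}

## Same iterative-proportional-fitting scheme as the production code, in
## straight loops; returns the DI and the fitted two-site distribution.
ref_di_pair <- function(E, f1, i, j, q, tol = 1e-4, max_iter = 500) {
  W <- matrix(0, q, q)
  for (a in seq_len(q)) for (b in seq_len(q))
    W[a, b] <- exp(E[(i - 1) * q + a, (j - 1) * q + b])
  mu1 <- rep(1 / q, q); mu2 <- rep(1 / q, q)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    n1 <- numeric(q)
    for (a in seq_len(q)) {
      sv <- 0
      for (b in seq_len(q)) sv <- sv + W[a, b] * mu2[b]
      n1[a] <- f1[i, a] / sv
    }
    n1 <- n1 / sum(n1)
    n2 <- numeric(q)
    for (b in seq_len(q)) {
      sv <- 0
      for (a in seq_len(q)) sv <- sv + W[a, b] * n1[a]
      n2[b] <- f1[j, b] / sv
    }
    n2 <- n2 / sum(n2)
    diff <- 0
    for (a in seq_len(q)) {
      diff <- max(diff, abs(n1[a] - mu1[a]), abs(n2[a] - mu2[a]))
    }
    mu1 <- n1; mu2 <- n2
    if (diff < tol) { converged <- TRUE; break }
  }
  P <- matrix(0, q, q)
  Z <- 0
  for (a in seq_len(q)) for (b in seq_len(q)) {
    P[a, b] <- W[a, b] * mu1[a] * mu2[b]
    Z <- Z + P[a, b]
  }
  d <- 0
  for (a in seq_len(q)) for (b in seq_len(q)) {
    pab <- P[a, b] / Z
    if (pab > 0) d <- d + pab * log(pab / (f1[i, a] * f1[j, b]))
  }
  list(di = d, P = P / Z, converged = converged)
}

ref_di <- function(E, f1, q, tol = 1e-4, max_iter = 500) {
  L <- nrow(f1)
  D <- matrix(0, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (j <= i) next
    D[i, j] <- ref_di_pair(E, f1, i, j, q, tol, max_iter)$di
    D[j, i] <- D[i, j]
  }
  D
}

ref_mfdca <- function(M, theta = 0.8, lam_frac = 0.5, q,
                      tol = 1e-4, max_iter = 500) {
  sw <- ref_weights(M, theta)
  fr <- ref_frequencies(M, sw$weights, lam_frac, q)
  E <- ref_couplings(fr$f1, fr$f2, q)
  list(weights = sw$weights, m_eff = sw$m_eff, f1 = fr$f1, f2 = fr$f2,
       couplings = E, di = ref_di(E, fr$f1, q, tol, max_iter))
}
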