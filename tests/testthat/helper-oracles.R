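# Independent oracles used across the suite. Each deliberately recomputes the
# target quantity by a different route than the package implementation.

# Bivariate normal CDF by slow 1D adaptive quadrature.
bvn_oracle <- function(h, k, rho) {
  if (rho == 0) return(pnorm(h) * pnorm(k))
  s <- sqrt(1 - rho^2)
  f <- function(x) dnorm(x) * pnorm((k - rho * x) / s)
  integrate(f, -Inf, h, rel.tol = 1e-13, abs.tol = 1e-13)$value
}

# Dense grid search of the two-step polychoric likelihood for an r x c table.
polychoric_grid_oracle <- function(tab, step = 1e-4) {
  n <- sum(tab)
  a <- qnorm(cumsum(rowSums(tab) / n))
  a <- a[is.finite(a)]
  b <- qnorm(cumsum(colSums(tab) / n))
  b <- b[is.finite(b)]
  A <- c(-Inf, a, Inf)
  B <- c(-Inf, b, Inf)
  ll <- function(r) {
    G <- outer(A, B, function(x, y) pbvnorm(x, y, r))
    P <- G[-1, -1, drop = FALSE] - G[-nrow(G), -1, drop = FALSE] -
      G[-1, -ncol(G), drop = FALSE] + G[-nrow(G), -ncol(G), drop = FALSE]
    sum(tab * log(pmax(P, 1e-12)))
  }
  rs <- seq(-0.999, 0.999, by = step)
  rs[which.max(vapply(rs, ll, numeric(1)))]
}

# Direct numerical maximization of the penalized glasso objective over the
# free entries of Theta (off-diagonal penalty only).
glasso_direct_oracle <- function(R, lambda) {
  p <- ncol(R)
  up <- which(upper.tri(R))
  unpack <- function(par) {
    Th <- diag(par[seq_len(p)])
    Th[up] <- par[-seq_len(p)]
    Th <- Th + t(Th) - diag(diag(Th))
    Th
  }
  obj <- function(par) {
    Th <- unpack(par)
    ev <- eigen(Th, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12) return(1e10)
    -(as.numeric(determinant(Th)$modulus) - sum(R * Th)) +
      2 * lambda * sum(abs(Th[up]))
  }
  start <- c(diag(solve(R)), solve(R)[up])
  o <- optim(start, obj, method = "BFGS",
             control = list(reltol = 1e-15, maxit = 5000))
  o <- optim(o$par, obj, method = "Nelder-Mead",
             control = list(reltol = 1e-15, maxit = 20000))
  unpack(o$par)
}

# Exhaustive simple-path enumeration for betweenness and closeness on a small
# weighted graph (distances 1/|w|; same disconnected-closeness convention as
# the package: scale by reachable/(p-1)).
brute_force_centrality <- function(W, tol = 1e-9) {
  p <- ncol(W)
  A <- abs(W)
  len <- ifelse(A > 1e-12, 1 / A, Inf)
  paths_between <- function(s, t) {
    out <- list()
    walk <- function(path, d) {
      v <- path[length(path)]
      if (v == t) {
        out[[length(out) + 1]] <<- list(path = path, d = d)
        return()
      }
      for (u in seq_len(p)) {
        if (is.finite(len[v, u]) && !(u %in% path)) {
          walk(c(path, u), d + len[v, u])
        }
      }
    }
    walk(s, 0)
    out
  }
  btw <- numeric(p)
  dist <- matrix(Inf, p, p)
  diag(dist) <- 0
  for (s in seq_len(p)) for (t in seq_len(p)) {
    if (s == t) next
    ps <- paths_between(s, t)
    if (!length(ps)) next
    ds <- vapply(ps, `[[`, numeric(1), "d")
    dmin <- min(ds)
    dist[s, t] <- dmin
    shortest <- ps[ds <= dmin + tol]
    sigma <- length(shortest)
    for (v in seq_len(p)) {
      if (v == s || v == t) next
      through <- sum(vapply(shortest, function(q) v %in% q$path, logical(1)))
      btw[v] <- btw[v] + through / sigma
    }
  }
  clo <- vapply(seq_len(p), function(i) {
    d <- dist[i, -i]
    fin <- is.finite(d)
    r <- sum(fin)
    if (r == 0 || sum(d[fin]) == 0) return(0)
    (r / (p - 1)) / sum(d[fin])
  }, numeric(1))
  list(betweenness = btw, closeness = clo)
}

# Exact partial correlations from a covariance matrix by Schur-complement
# residualization (regression route, independent of the -Theta/sqrt identity).
pcor_residual_oracle <- function(Sigma) {
  p <- ncol(Sigma)
  out <- diag(p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    k <- setdiff(seq_len(p), c(i, j))
    S11 <- Sigma[c(i, j), c(i, j)]
    S12 <- Sigma[c(i, j), k, drop = FALSE]
    S22 <- Sigma[k, k, drop = FALSE]
    Scond <- S11 - S12 %*% solve(S22, t(S12))
    out[i, j] <- out[j, i] <- Scond[1, 2] / sqrt(Scond[1, 1] * Scond[2, 2])
  }
  out
}

# Small synthetic study shared by several tests.
make_test_wave <- function(p = 5, n = 200, seed = 1, edge_prob = 0.4) {
  m <- make_true_network(p, edge_prob, weight_range = c(0.2, 0.4), seed = seed)
  sample_ordinal_wave(m, n, seed = seed + 1)
}
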