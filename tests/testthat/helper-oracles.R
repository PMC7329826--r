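# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, closed forms and
# direct formula transcriptions only.

# all-pairs shortest paths by Floyd-Warshall on a binary adjacency matrix
bf_shortest_paths <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Pearson correlation from its definition, no stats::cor
bf_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# inter-subject similarity by explicit enumeration of parcel pairs p < q
bf_intersubject <- function(z_i, z_j) {
  p <- ncol(z_i)
  vi <- c(); vj <- c()
  for (a in seq_len(p - 1)) for (b in (a + 1):p) {
    vi <- c(vi, z_i[a, b]); vj <- c(vj, z_j[a, b])
  }
  bf_pearson(vi, vj)
}

# signed asymmetric modularity recomputed directly from its definition
bf_signed_q <- function(w, memb, gamma = 1) {
  diag(w) <- 0
  wp <- pmax(w, 0); wn <- pmax(-w, 0)
  vp <- sum(wp); vn <- sum(wn)
  q_layer <- function(l, v) {
    if (v == 0) return(0)
    s <- unname(rowSums(l))
    tot <- 0
    for (i in seq_len(nrow(l))) for (j in seq_len(ncol(l)))
      if (memb[i] == memb[j]) tot <- tot + l[i, j] - gamma * s[i] * s[j] / v
    tot / v
  }
  q_layer(wp, vp) - vn / (vp + vn) * q_layer(wn, vn)
}

# restricted log-likelihood of the random-effects meta-analysis model,
# for a grid-search tau2 oracle
meta_reml_loglik <- function(tau2, yi, sei) {
  w <- 1 / (sei^2 + tau2)
  mu <- sum(w * yi) / sum(w)
  0.5 * (-sum(log(sei^2 + tau2)) - log(sum(w)) - sum(w * (yi - mu)^2))
}

bf_meta_tau2 <- function(yi, sei, upper = 2) {
  opt <- optimize(meta_reml_loglik, c(0, upper), yi = yi, sei = sei,
                  maximum = TRUE, tol = 1e-12)
  if (meta_reml_loglik(0, yi, sei) >= opt$objective) 0 else opt$maximum
}

# dense-matrix REML criterion for the dyadic LME (no eigen shortcut)
bf_dyad_reml_crit <- function(s2u, s2e, y, X, Z) {
  V <- s2e * diag(length(y)) + s2u * tcrossprod(Z)
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  as.numeric(determinant(V)$modulus + determinant(t(X) %*% Vi %*% X)$modulus +
               t(r) %*% Vi %*% r)
}

# small complete-dyad dataset generated from the exact crossed model
make_dyad_data <- function(n_subjects, beta0 = 0, beta1 = 0.5, s2u = 0.4,
                           s2e = 0.6, seed = 1) {
  set.seed(seed)
  ids <- sprintf("S%02d", seq_len(n_subjects))
  pr <- t(combn(ids, 2))
  nd <- nrow(pr)
  x <- rnorm(nd)
  Z <- matrix(0, nd, n_subjects, dimnames = list(NULL, ids))
  for (r in seq_len(nd)) {
    Z[r, pr[r, 1]] <- 1
    Z[r, pr[r, 2]] <- 1
  }
  u <- rnorm(n_subjects, 0, sqrt(s2u))
  y <- beta0 + beta1 * x + drop(Z %*% u) + rnorm(nd, 0, sqrt(s2e))
  list(data = data.frame(similarity = y, distance = x,
                         i = pr[, 1], j = pr[, 2], stringsAsFactors = FALSE),
       Z = Z, X = cbind(1, x))
}

# tiny deterministic roster fixture; ratings chosen by hand
toy_roster <- function() {
  m <- matrix(c(NA, 5, 4, 1,
                5, NA, 3, 2,
                4, 4, NA, 1,
                1, 5, 1, NA), 4, 4, byrow = TRUE,
              dimnames = list(c("a", "b", "c", "d"), c("a", "b", "c", "d")))
  roster_rating(m, cohort = "toy")
}

# undirected igraph-free modularity of the all-in-one partition
bf_single_community_q <- function(adj) {
  m <- sum(adj) / 2
  k <- rowSums(adj)
  sum(adj - outer(k, k) / (2 * m)) / (2 * m)
}
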