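#' Signed nodal strength
#'
#' Positive strength of node i is the sum of its positive edge weights,
#' negative strength the sum of magnitudes of its negative weights; the
#' masked diagonal contributes nothing.
#'
#' @param matrix weighted signed connectivity matrix (diagonal ignored).
#' @return List with numeric vectors `pos` and `neg`, named by parcel.
#' @export
nodal_strength <- function(matrix) {
  w <- as.matrix(matrix)
  diag(w) <- 0
  list(pos = rowSums(pmax(w, 0)), neg = rowSums(pmax(-w, 0)))
}

# Signed modularity matrix for the asymmetric objective
#   Q* = Q+ - v- / (v+ + v-) * Q-,
# where Q+/- are Newman modularities of the rectified positive/negative
# layers and v+/- their total weights (summed over the full matrix, both
# directions; the masked diagonal counts as zero weight).
signed_modularity_matrix <- function(w, gamma = 1,
                                     variant = c("asymmetric", "symmetric")) {
  variant <- match.arg(variant)
  diag(w) <- 0
  wp <- pmax(w, 0); wn <- pmax(-w, 0)
  vp <- sum(wp); vn <- sum(wn)
  if (vp + vn == 0) stop("all-zero connectivity matrix")
  Bp <- if (vp > 0) (wp - gamma * outer(rowSums(wp), rowSums(wp)) / vp) / vp else w * 0
  Bn <- if (vn > 0) (wn - gamma * outer(rowSums(wn), rowSums(wn)) / vn) / vn else w * 0
  lam <- switch(variant, asymmetric = vn / (vp + vn), symmetric = 1)
  Bp - lam * Bn
}

# one sweep-loop of greedy local moves on a dense symmetric modularity
# matrix; returns the community vector
louvain_local_moves <- function(B, seed) {
  m <- nrow(B)
  cm <- seq_len(m)
  sweep <- 0L
  repeat {
    sweep <- sweep + 1L
    moved <- FALSE
    ord <- with_seed(child_seed(seed, paste0("sweep", sweep)), sample.int(m))
    for (i in ord) {
      cur <- as.character(cm[i])
      s <- rowsum(B[i, ], cm)[, 1]       # i's tie to each community
      s[cur] <- s[cur] - B[i, i]         # exclude i itself from its community
      if (sum(cm == cm[i]) > 1L)         # allow retreat into a fresh singleton
        s[as.character(max(cm) + 1L)] <- 0
      best <- names(s)[which.max(s)]
      if (best != cur && s[best] > s[cur] + 1e-13) {
        cm[i] <- as.integer(best)
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  cm
}

# full multi-level Louvain on a dense modularity matrix; membership of the
# original nodes maximising sum_{c_i == c_j} B_ij
louvain_dense <- function(B, seed) {
  B <- (B + t(B)) / 2
  memb <- seq_len(nrow(B))
  cur_B <- B
  lvl <- 0L
  repeat {
    lvl <- lvl + 1L
    m <- nrow(cur_B)
    cm <- louvain_local_moves(cur_B, child_seed(seed, paste0("lvl", lvl)))
    cm <- match(cm, unique(cm))
    memb <- cm[memb]
    k <- max(cm)
    if (k == m) break
    agg <- matrix(0, k, k)
    for (a in seq_len(k)) {
      ia <- cm == a
      for (b in a:k) {
        agg[a, b] <- sum(cur_B[ia, cm == b, drop = FALSE])
        agg[b, a] <- agg[a, b]
      }
    }
    cur_B <- agg
  }
  memb
}

#' Louvain modularity of a signed weighted brain graph
#'
#' Community detection on the full signed connectome, maximising the
#' asymmetric signed objective `Q* = Q+ - v-/(v+ + v-) Q-`, which rewards
#' positive within-module weight fully but penalises negative within-module
#' weight only in proportion to its share of total weight. The symmetric
#' variant (`Q+ - Q-`) is available via `variant`.
#'
#' @param matrix signed weighted connectivity matrix (diagonal ignored).
#' @param gamma resolution parameter.
#' @param seed integer seed; restarts use derived child seeds, so results
#'   are deterministic given `seed`.
#' @param restarts number of seeded restarts, best Q* kept (ties broken by
#'   first occurrence).
#' @param variant `"asymmetric"` (default) or `"symmetric"` treatment of
#'   negative weights.
#' @return List of class `signed_modularity`: `modularity` (Q*),
#'   `membership` (named integer vector), `gamma`, `seed`, `restarts`,
#'   `variant`.
#' @export
signed_modularity <- function(matrix, gamma = 1, seed = 1, restarts = 10,
                              variant = c("asymmetric", "symmetric")) {
  variant <- match.arg(variant)
  w <- as.matrix(matrix)
  B <- signed_modularity_matrix(w, gamma, variant)
  best <- NULL
  for (r in seq_len(restarts)) {
    memb <- louvain_dense(B, child_seed(seed, paste0("restart/", r)))
    q <- sum(B[outer(memb, memb, "==")])
    if (is.null(best) || q > best$q + 1e-13) best <- list(q = q, memb = memb)
  }
  memb <- match(best$memb, unique(best$memb))
  names(memb) <- colnames(w)
  structure(list(modularity = best$q, membership = memb, gamma = gamma,
                 seed = seed, restarts = restarts, variant = variant),
            class = "signed_modularity")
}

#' @export
print.signed_modularity <- function(x, ...) {
  cat("Signed Louvain (", x$variant, "): Q* = ", round(x$modularity, 4), ", ",
      length(unique(x$membership)), " modules\n", sep = "")
  invisible(x)
}

#' Signed nodal diversity
#'
#' Normalised entropy of how a node's positive (negative) strength is
#' distributed over the modules of a partition:
#' `h_i = -(1/log m) * sum_u p_i(u) log p_i(u)` with `p_i(u)` the share of
#' node i's strength falling in module u and `0 log 0 := 0`. 0 means all
#' weight in one module, 1 means weight spread evenly over all m modules; a
#' node with no strength in a layer gets 0.
#'
#' @param matrix signed connectivity matrix.
#' @param partition module assignment per node (integer vector or a
#'   [signed_modularity()] object), with at least 2 modules.
#' @return List with vectors `pos` and `neg` in `[0, 1]`.
#' @export
nodal_diversity <- function(matrix, partition) {
  if (inherits(partition, "signed_modularity")) partition <- partition$membership
  w <- as.matrix(matrix)
  diag(w) <- 0
  m <- length(unique(partition))
  if (m < 2) stop("diversity needs a partition with at least 2 modules")
  ent <- function(layer) {
    s_mod <- t(rowsum(t(layer), partition))   # node x module strength
    tot <- rowSums(s_mod)
    p <- s_mod / ifelse(tot > 0, tot, 1)
    h <- -rowSums(ifelse(p > 0, p * log(p), 0)) / log(m)
    h[tot == 0] <- 0
    unname(h)
  }
  list(pos = ent(pmax(w, 0)), neg = ent(pmax(-w, 0)))
}

#' Per-subject nodal metric bundle
#'
#' Computes signed strength, signed modularity and diversity (on the
#' subject's own modularity partition) in one call.
#'
#' @param matrix connectivity matrix (signed, weighted).
#' @param gamma,seed,restarts forwarded to [signed_modularity()].
#' @return List of class `nodal_metrics`: `strength`, `diversity`,
#'   `modularity` (Q*), `partition`, `labels`.
#' @export
nodal_metrics <- function(matrix, gamma = 1, seed = 1, restarts = 10) {
  sm <- signed_modularity(matrix, gamma = gamma, seed = seed, restarts = restarts)
  div <- if (length(unique(sm$membership)) >= 2)
    nodal_diversity(matrix, sm)
  else list(pos = rep(0, ncol(matrix)), neg = rep(0, ncol(matrix)))
  structure(list(strength = nodal_strength(matrix), diversity = div,
                 modularity = sm$modularity, partition = sm$membership,
                 labels = colnames(matrix)),
            class = "nodal_metrics")
}

#' Dyadic similarity of graph metrics
#'
#' Strength and diversity similarity are the Pearson correlation of the two
#' subjects' per-node vectors (positive and negative parts concatenated by
#' default); modularity, a single value per subject, is compared by the
#' absolute difference of the two Q* values.
#'
#' @param metrics_i,metrics_j [nodal_metrics()] for the two subjects.
#' @param kind `"strength"`, `"diversity"` or `"modularity"`.
#' @param signs `"both"` (concatenate positive and negative vectors,
#'   default), `"pos"` or `"neg"`.
#' @return Scalar Pearson correlation, or absolute Q* difference.
#' @export
metric_similarity <- function(metrics_i, metrics_j,
                              kind = c("strength", "diversity", "modularity"),
                              signs = c("both", "pos", "neg")) {
  kind <- match.arg(kind)
  signs <- match.arg(signs)
  if (!identical(metrics_i$labels, metrics_j$labels))
    stop("parcel labels differ between subjects")
  if (kind == "modularity")
    return(abs(metrics_i$modularity - metrics_j$modularity))
  pick <- function(m) {
    v <- m[[if (kind == "strength") "strength" else "diversity"]]
    switch(signs, both = c(v$pos, v$neg), pos = v$pos, neg = v$neg)
  }
  stats::cor(pick(metrics_i), pick(metrics_j))
}
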