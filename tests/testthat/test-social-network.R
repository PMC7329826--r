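test_that("roster CSV round trip preserves ratings and validates input", {
  r <- toy_roster()
  p <- withr::local_tempfile(fileext = ".csv")
  write_roster(r, p)
  r2 <- load_roster(p, cohort = "toy")
  expect_equal(unclass(r2), unclass(r), ignore_attr = TRUE)
  expect_equal(sum(!is.na(r2)), 12)

  bad <- as.data.frame(unclass(r))
  bad[1, 2] <- 6
  pb <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, pb, na = "")
  expect_error(load_roster(pb), "out of 1..5")
})

test_that("non-participants (all-missing row/column) are dropped", {
  r <- toy_roster()
  m <- unclass(r)
  m <- cbind(m, e = NA)
  m <- rbind(m, e = NA)
  rownames(m)[5] <- "e"
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(m), p, na = "")
  r2 <- load_roster(p)
  expect_equal(nrow(r2), 4)
  expect_equal(attr(r2, "n_dropped"), 1)
  expect_false("e" %in% rownames(r2))
})

test_that("tie thresholding and reciprocity follow the rating rules", {
  r <- toy_roster()  # a<->b mutual 5s; a->c 4, c->a 4; b->c 3, c->b 4; d->b 5, b->d 2
  g4 <- build_social_graph(r, 4, "reciprocal")
  a <- g4$adjacency
  expect_equal(a["a", "b"], 1)  # mutual >= 4
  expect_equal(a["a", "c"], 1)  # 4 and 4
  expect_equal(a["b", "c"], 0)  # 3 one way
  expect_equal(a["b", "d"], 0)  # 2 one way
  gd <- build_social_graph(r, 4, "directed")
  expect_equal(gd$adjacency["c", "b"], 1)  # one arc survives
  expect_equal(gd$adjacency["b", "c"], 0)

  # saturation: all ratings 5 -> complete reciprocal graph
  m5 <- matrix(5L, 4, 4, dimnames = dimnames(unclass(r)))
  diag(m5) <- NA
  gc <- build_social_graph(roster_rating(m5), 4, "reciprocal")
  expect_equal(igraph::edge_density(gc$graph), 1)
})

test_that("threshold-5 and reciprocal graphs are nested in their supersets", {
  for (seed in 1:5) {
    cfg <- sim_config(n_students = 15, n_parcels = 4, seed = seed)
    r <- simulate_social_roster(cfg)
    a4 <- build_social_graph(r, 4, "reciprocal")$adjacency
    a5 <- build_social_graph(r, 5, "reciprocal")$adjacency
    d4 <- build_social_graph(r, 4, "directed")$adjacency
    expect_true(all(a5 <= a4))   # threshold 5 subgraph of threshold 4
    expect_true(all(a4 <= d4))   # reciprocal edges subset of directed arcs
  }
})

test_that("social distances match definitions and brute-force enumeration", {
  r <- toy_roster()
  g <- build_social_graph(r, 4, "reciprocal")
  d <- social_distance(g)
  expect_equal(d["a", "b"], 1)         # mutual tie
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_equal(d["b", "c"], 2)         # via a
  expect_error(social_distance(build_social_graph(r, 4, "directed")), "directed")

  # path graph on 5 nodes: diameter 4
  pm <- matrix(1L, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  for (k in 1:4) { pm[k, k + 1] <- 5L; pm[k + 1, k] <- 5L }
  diag(pm) <- NA
  dp <- social_distance(build_social_graph(roster_rating(pm), 4))
  expect_equal(dp["a", "e"], 4)
  expect_equal(max(dp), 4)

  # exhaustive: random graphs on <= 8 nodes vs Floyd-Warshall
  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(4:8, 1)
    adj <- matrix(rbinom(n * n, 1, 0.35), n, n)
    adj <- 1 * ((adj + t(adj)) > 0)
    diag(adj) <- 0
    ids <- paste0("s", seq_len(n))
    rm <- matrix(1L, n, n, dimnames = list(ids, ids))
    rm[adj == 1] <- 5L
    diag(rm) <- NA
    d1 <- social_distance(build_social_graph(roster_rating(rm), 4))
    expect_equal(unname(unclass(d1))[seq_len(n), seq_len(n)],
                 bf_shortest_paths(adj), ignore_attr = TRUE)
  }
})

test_that("triangle inequality and edge equivalence hold on generated graphs", {
  cfg <- sim_config(n_students = 20, n_parcels = 4, seed = 9)
  g <- build_social_graph(simulate_social_roster(cfg), 4)
  d <- social_distance(g)
  expect_equal(unclass(d), t(unclass(d)), ignore_attr = TRUE)
  expect_true(all((d == 1) == (g$adjacency == 1) | is.na(diag(nrow(d)))))
  fin <- is.finite(d)
  n <- nrow(d)
  for (k in seq_len(n))
    expect_true(all(d[fin] <= (outer(d[, k], d[k, ], "+"))[fin] + 1e-9))
})

test_that("Louvain finds planted structure and respects baselines", {
  # two disconnected 5-cliques: Q = 0.5 exactly
  ids <- paste0("v", 1:10)
  m <- matrix(1L, 10, 10, dimnames = list(ids, ids))
  m[1:5, 1:5] <- 5L
  m[6:10, 6:10] <- 5L
  diag(m) <- NA
  g <- build_social_graph(roster_rating(m), 4)
  part <- detect_communities(g, seed = 1, restarts = 10)
  expect_equal(length(unique(part$membership)), 2)
  expect_equal(part$modularity, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(part$membership[1:5])), 1)

  # complete graph: no structure, single community
  mc <- matrix(5L, 8, 8, dimnames = list(ids[1:8], ids[1:8]))
  diag(mc) <- NA
  pc <- detect_communities(build_social_graph(roster_rating(mc), 4),
                           seed = 1, restarts = 5)
  expect_equal(length(unique(pc$membership)), 1)

  # never below the single-community baseline
  for (seed in 1:5) {
    cfg <- sim_config(n_students = 16, n_parcels = 4, seed = seed)
    gs <- build_social_graph(simulate_social_roster(cfg), 4)
    p <- detect_communities(gs, seed = seed, restarts = 10)
    expect_gte(p$modularity, bf_single_community_q(gs$adjacency) - 1e-12)
  }
})

test_that("Louvain recovers planted 4-group rosters exactly", {
  cfg <- sim_config(n_students = 60, n_parcels = 4, p_in = 0.9, p_out = 0.02,
                    n_groups = 4, seed = 31)
  r <- simulate_social_roster(cfg)
  g <- build_social_graph(r, 4, "reciprocal")
  part <- detect_communities(g, seed = 2, restarts = 20)
  nmi <- igraph::compare(part$membership, attr(r, "groups"), method = "nmi")
  expect_equal(length(unique(part$membership)), 4)
  expect_equal(nmi, 1)
})

test_that("network summary metrics match hand enumeration", {
  # 4-cycle: diameter 2, mean path length 4/3, density 4/6
  ids <- paste0("n", 1:4)
  m <- matrix(1L, 4, 4, dimnames = list(ids, ids))
  m[1, 2] <- m[2, 1] <- m[2, 3] <- m[3, 2] <- m[3, 4] <- m[4, 3] <- m[1, 4] <- m[4, 1] <- 5L
  diag(m) <- NA
  g <- build_social_graph(roster_rating(m), 4)
  s <- network_summary(g, seed = 1)
  expect_equal(s$diameter, 2)
  expect_equal(s$mean_path_length, 4 / 3)
  expect_equal(s$density, 4 / 6)

  # directed arcs {a->b, b->a, a->c}: reciprocity 2/3
  md <- matrix(1L, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  md["a", "b"] <- 5L; md["b", "a"] <- 5L; md["a", "c"] <- 5L
  diag(md) <- NA
  dg <- build_social_graph(roster_rating(md), 4, "directed")
  expect_equal(igraph::reciprocity(dg$graph), 2 / 3)

  # star K_{1,4}: centre centrality 1, leaves equal and smaller
  ms <- matrix(1L, 5, 5, dimnames = list(paste0("s", 1:5), paste0("s", 1:5)))
  ms[1, 2:5] <- 5L; ms[2:5, 1] <- 5L
  diag(ms) <- NA
  ss <- network_summary(build_social_graph(roster_rating(ms), 4), seed = 1)
  ec <- ss$eigenvector_centrality
  expect_equal(unname(ec["s1"]), 1)
  expect_true(all(ec[-1] < 1))
  expect_equal(length(unique(round(ec[-1], 10))), 1)

  # complete graph sanity
  mc <- matrix(5L, 5, 5, dimnames = list(paste0("c", 1:5), paste0("c", 1:5)))
  diag(mc) <- NA
  rc <- roster_rating(mc)
  sc <- network_summary(build_social_graph(rc, 4),
                        build_social_graph(rc, 4, "directed"), seed = 1)
  expect_equal(sc$density, 1)
  expect_equal(sc$diameter, 1)
  expect_equal(sc$mean_path_length, 1)
  expect_equal(sc$reciprocity, 1)
})

test_that("dyad counting reproduces the closed form", {
  expect_equal(count_dyads(59), 1711)
  expect_equal(count_dyads(23), 253)
  expect_equal(count_dyads(2), 1)
  expect_error(count_dyads(1), "at least 2")
})

test_that("direct-tie proximity aggregates the two directed ratings", {
  r <- toy_roster()
  pairs <- rbind(c("a", "b"), c("a", "c"), c("d", "b"))
  expect_equal(direct_tie_distance(r, pairs), c(5, 4, 3.5))
  expect_equal(direct_tie_distance(r, pairs, rule = "min"), c(5, 4, 2))
  expect_equal(direct_tie_distance(r, pairs, rule = "max"), c(5, 4, 5))
  # ratings 5 and 3 -> mean 4; 1 and 1 -> 1
  m <- matrix(c(NA, 5L, 3L, NA), 2, 2, byrow = TRUE,
              dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(direct_tie_distance(roster_rating(m), rbind(c("x", "y"))), 4)
  m1 <- matrix(c(NA, 1L, 1L, NA), 2, 2, byrow = TRUE,
               dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(direct_tie_distance(roster_rating(m1), rbind(c("x", "y"))), 1)
  m2 <- m; m2[2, 1] <- NA
  expect_error(direct_tie_distance(roster_rating(m2), rbind(c("x", "y"))),
               "missing rating")
})
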