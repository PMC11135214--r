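test_that("edge partition enumerates intra and cross pairs exactly", {
  m <- matrix(0, 4, 4)
  m[upper.tri(m)] <- c(12, 13, 23, 14, 24, 34) # column-major upper triangle
  m <- m + t(m)
  parts <- edge_partition(m, c("A", "A", "B", "B"))
  expect_setequal(parts$intra, c(12, 34))
  expect_setequal(parts$cross, c(13, 23, 14, 24))

  all_a <- edge_partition(m, rep("A", 4))
  expect_length(all_a$cross, 0)
  expect_length(all_a$intra, 6)

  big <- edge_partition(diag(500), rep(c("A", "B"), each = 250))
  expect_length(big$intra, 2 * (250 * 249 / 2))
  expect_length(big$cross, 250 * 250)
  expect_length(c(big$intra, big$cross), 500 * 499 / 2)
})

test_that("mean relative edge strength normalizes by the strongest edge", {
  m <- matrix(0, 4, 4)
  m[1, 2] <- 2.0
  m[3, 4] <- 1.0
  m[1, 3] <- -1.0
  m[2, 4] <- -1.0
  m <- m + t(m)
  mr <- mean_relative_edge_strength(m, c("A", "A", "B", "B"))
  expect_equal(mr$mean_rel_intra, 0.75)
  expect_equal(mr$mean_rel_cross, -0.25)
  mr_scaled <- mean_relative_edge_strength(5.5 * m, c("A", "A", "B", "B"))
  expect_equal(mr_scaled, mr)
  expect_error(mean_relative_edge_strength(diag(4), c("A", "A", "B", "B")),
               "zero")
})

test_that("Mann-Whitney bias test behaves across null, separated and tiny inputs", {
  expect_gt(bias_test(rep(1:20, 2), rep(1:20, 2)), 0.9)
  expect_lt(bias_test(21:40, 1:20), 1e-6)
  p <- bias_test(1, 2)
  expect_true(p > 0 && p <= 1)
  expect_error(bias_test(numeric(0), 1), "non-empty")
})

test_that("edge R-squared matches a closed-form OLS oracle", {
  sim <- small_sim(n_taxa = 10, n_samples = 20, seed = 81)
  truth <- sim$truth
  expect_equal(edge_r2(truth, truth), 1)
  expect_equal(edge_r2(truth, 2 * truth + 3), 1)

  set.seed(5)
  est <- truth
  flip <- sample(which(upper.tri(est)), 20)
  est[flip] <- -est[flip]
  est <- (est + t(est)) / 2
  tv <- truth[upper.tri(truth)]
  ev <- est[upper.tri(est)]
  beta <- sum((ev - mean(ev)) * (tv - mean(tv))) / sum((ev - mean(ev))^2)
  resid <- tv - (mean(tv) + beta * (ev - mean(ev)))
  r2_oracle <- 1 - sum(resid^2) / sum((tv - mean(tv))^2)
  expect_equal(edge_r2(truth, est), r2_oracle, tolerance = 1e-10)
  expect_equal(edge_r2(truth, matrix(1, 10, 10)), 0)
})

test_that("edge AUC equals the brute-force pairwise oracle", {
  # 6-pair toy: scores .9 .8 .4 .3 .2 .1, positives ranks 1 and 3
  m <- matrix(0, 4, 4)
  scores <- c(0.9, 0.8, 0.4, 0.3, 0.2, 0.1)
  m[upper.tri(m)] <- scores
  m <- m + t(m)
  truth <- matrix(0, 4, 4)
  truth[upper.tri(truth)] <- c(1, 0, 1, 0, 0, 0) * scores
  truth <- truth + t(truth)
  expect_equal(edge_auc(truth, m), 0.875)

  sim <- small_sim(n_taxa = 8, n_samples = 15, seed = 91)
  expect_equal(edge_auc(sim$truth, sim$truth), 1)
  expect_equal(edge_auc(sim$truth, matrix(1, 8, 8) - diag(8)), 0.5)

  # randomized instances, all with <= 50 pairs, against the brute-force oracle
  for (s in 1:20) {
    set.seed(s)
    n <- sample(5:10, 1)
    tr <- matrix(0, n, n)
    tr[upper.tri(tr)] <- ifelse(runif(n * (n - 1) / 2) < 0.3,
                                rnorm(n * (n - 1) / 2), 0)
    tr <- tr + t(tr)
    if (all(tr[upper.tri(tr)] == 0) || all(tr[upper.tri(tr)] != 0)) next
    es <- matrix(rnorm(n * n), n)
    es <- es + t(es)
    expect_equal(
      edge_auc(tr, es),
      auc_brute(abs(es[upper.tri(es)]), tr[upper.tri(tr)] != 0)
    )
  }
})

test_that("top-N accuracy counts sign-matched true edges", {
  sim <- small_sim(n_taxa = 10, n_samples = 20, seed = 101)
  n_true <- sum(sim$truth[upper.tri(sim$truth)] != 0)
  acc <- top_n_accuracy(sim$truth, sim$truth, n_values = c(5, n_true))
  expect_equal(unname(acc), c(1, 1))
  acc_flip <- top_n_accuracy(sim$truth, -sim$truth, n_values = 5)
  expect_equal(unname(acc_flip), 0)

  truth <- matrix(0, 4, 4)
  truth[1, 2] <- 1; truth[1, 3] <- 1; truth[1, 4] <- 1
  truth <- truth + t(truth)
  est <- truth
  est[1, 3] <- est[3, 1] <- -1 # one wrong sign among the top 3
  expect_equal(unname(top_n_accuracy(truth, est, 3)), 2 / 3)
  expect_error(top_n_accuracy(truth, est, 0), "at least 1")
})

test_that("network thresholding keeps the strongest fraction deterministically", {
  m <- matrix(0, 5, 5)
  m[upper.tri(m)] <- c(0.9, -0.8, 0.7, 0.1, 0.2, 0.3, 0.05, 0, 0.5, 0.4)
  m <- m + t(m)
  colnames(m) <- rownames(m) <- paste0("T", 1:5)
  g1 <- threshold_network(m, 0.1) # 10 pairs -> exactly 1 edge
  expect_equal(igraph::ecount(g1), 1)
  expect_equal(igraph::E(g1)$weight, 0.9)
  g_all <- threshold_network(m, 1)
  expect_equal(igraph::ecount(g_all), sum(m[upper.tri(m)] != 0))

  tie <- matrix(0, 4, 4)
  tie[1, 2] <- tie[3, 4] <- 0.5 # tie at the cutoff
  tie <- tie + t(tie)
  colnames(tie) <- rownames(tie) <- paste0("T", 1:4)
  e1 <- igraph::as_data_frame(threshold_network(tie, 1 / 6))
  e2 <- igraph::as_data_frame(threshold_network(tie, 1 / 6))
  expect_identical(e1, e2)
  expect_equal(nrow(e1), 1)
  expect_equal(e1$from, "T1") # index-ordered tie break
})

test_that("centralities match closed-form values on canonical graphs", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("T", 1:5)
  bet <- hub_scores(star, "betweenness")
  expect_equal(unname(bet), c(1, 0, 0, 0, 0))
  deg <- hub_scores(star, "degree")
  expect_equal(unname(deg), c(1, 0.25, 0.25, 0.25, 0.25))

  ring <- igraph::make_ring(4)
  igraph::V(ring)$name <- paste0("T", 1:4)
  eig <- hub_scores(ring, "eigenvector")
  expect_equal(unname(eig), rep(1, 4))

  iso <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(iso)$name <- paste0("T", 1:3)
  expect_equal(unname(hub_scores(iso, "eigenvector")), rep(0, 3))
})

test_that("gLV keystoneness matches analytic equilibria and block structure", {
  # no interactions: knockouts cannot propagate
  d <- diag(c(2, 1, 3, 1.5))
  colnames(d) <- rownames(d) <- paste0("T", 1:4)
  ks <- lv_keystoneness(d)
  expect_true(all(ks < 1e-6))

  # two disconnected 2-taxon blocks: knocking out in one block leaves the
  # other block's steady state unchanged, matching the analytic equilibrium
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 0.8
  m[3, 4] <- m[4, 3] <- -0.6
  diag(m) <- 1
  colnames(m) <- rownames(m) <- paste0("T", 1:4)
  a <- m
  diag(a) <- 0
  a <- a * (0.5 / max(abs(a)))
  diag(a) <- -1
  base <- glv_equilibrium(a, rep(1, 4))
  ko1 <- glv_equilibrium(a[-1, -1], rep(1, 3))
  # block (3,4) unaffected by removing taxon 1
  expect_equal(ko1[2:3], base[3:4], tolerance = 1e-8)
  bray <- function(u, v) sum(abs(u - v)) / (sum(u) + sum(v))
  expected_ks1 <- bray(base[-1], ko1)
  ks2 <- lv_keystoneness(m)
  expect_equal(unname(ks2[1]), expected_ks1, tolerance = 1e-4)

  # 3-taxon chain: the central strong interactor scores highest
  chain <- matrix(0, 3, 3)
  chain[1, 2] <- chain[2, 1] <- 0.9
  chain[2, 3] <- chain[3, 2] <- 0.7
  diag(chain) <- 1
  colnames(chain) <- rownames(chain) <- paste0("T", 1:3)
  ks3 <- lv_keystoneness(chain)
  expect_equal(names(which.max(ks3)), "T2")
  # and the scores match the analytic-equilibrium oracle
  ac <- chain
  diag(ac) <- 0
  ac <- ac * (0.5 / max(abs(ac)))
  diag(ac) <- -1
  b3 <- glv_equilibrium(ac, rep(1, 3))
  oracle <- vapply(1:3, function(i) {
    bray(b3[-i], glv_equilibrium(ac[-i, -i], rep(1, 2)))
  }, numeric(1))
  expect_equal(unname(ks3), oracle, tolerance = 1e-4)
})

test_that("Louvain recovers planted structure and scores partitions correctly", {
  # two disjoint cliques
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_full_graph(4))
  igraph::V(g)$name <- paste0("T", 1:9)
  igraph::E(g)$weight <- 1
  memb <- detect_communities(g, seed = 1)
  expect_length(unique(memb[1:5]), 1)
  expect_length(unique(memb[6:9]), 1)
  expect_false(memb[1] == memb[9])

  lone <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(lone)$name <- paste0("T", 1:4)
  expect_length(unique(detect_communities(lone, seed = 1)), 4)

  # planted 2-block graph, 30 nodes
  recovered <- 0L
  for (s in 1:10) {
    set.seed(s)
    sbm <- igraph::sample_sbm(30, matrix(c(0.8, 0.02, 0.02, 0.8), 2),
                              block.sizes = c(15, 15))
    igraph::V(sbm)$name <- paste0("T", 1:30)
    igraph::E(sbm)$weight <- 1
    part <- detect_communities(sbm, seed = s)
    tab <- table(part, rep(1:2, each = 15))
    pure <- all(apply(tab, 1, function(r) sum(r > 0)) == 1)
    recovered <- recovered + (length(unique(part)) == 2 && pure)
  }
  expect_equal(recovered, 10L)
})

test_that("community overlap and inclusion follow set arithmetic", {
  nodes <- paste0("T", 1:8)
  same <- setNames(rep(1:2, each = 4), nodes)
  cs <- community_scores(same, same)
  expect_equal(cs$overlap_scores, c(1, 1))
  expect_equal(cs$inclusion_scores, c(1, 1))

  recon <- setNames(c(1, 1, 2, 2, 2, 2, 2, 2), nodes)
  truth <- setNames(rep(1, 8), nodes)
  cs2 <- community_scores(recon, truth)
  expect_equal(sort(cs2$inclusion_scores), c(1, 1))
  expect_equal(sort(cs2$overlap_scores), c(2 / 8, 6 / 8))

  # reconstructed community split evenly across two truth communities
  recon3 <- setNames(c(1, 1, 1, 1, 2, 2, 2, 2), nodes)
  truth3 <- setNames(c(1, 1, 2, 2, 1, 1, 2, 2), nodes)
  cs3 <- community_scores(recon3, truth3)
  expect_equal(cs3$inclusion_scores, c(0.5, 0.5))
  expect_error(community_scores(same, setNames(rep(1, 3), paste0("X", 1:3))),
               "node set")
})

test_that("hub-score R-squared mirrors the edge-level convention", {
  x <- c(0.1, 0.4, 0.9, 0.2, 0.7)
  expect_equal(hub_r2(x, x), 1)
  expect_equal(hub_r2(x, 3 * x - 1), 1)
  expect_equal(hub_r2(x, rep(0.5, 5)), 0)
  y <- c(0.2, 0.1, 0.8, 0.4, 0.6)
  expect_equal(hub_r2(x, y), cor(x, y)^2, tolerance = 1e-12)
})

test_that("oracle log-covariance dominates compositional methods on average", {
  r2 <- list()
  for (t in 1:10) {
    sim <- small_sim(n_taxa = 30, n_samples = 100, seed = 80 + t)
    ests <- run_all_methods(sim$paired, seed = 380 + t,
                            abundances = sim$abund,
                            kingdom = sim$model$kingdom)
    r2[[t]] <- vapply(ests, function(e) {
      if (inherits(e, "method_failure")) NA_real_ else edge_r2(sim$truth, e)
    }, numeric(1))
  }
  mean_r2 <- colMeans(do.call(rbind, r2), na.rm = TRUE)
  compositional <- setdiff(names(mean_r2), "oracle_log_covariance")
  expect_true(all(mean_r2["oracle_log_covariance"] >= mean_r2[compositional]))
})
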