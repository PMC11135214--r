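#' Split off-diagonal entries into intra- and cross-kingdom edges
#'
#' Strict upper-triangle entries of a symmetric matrix, partitioned by
#' whether the two endpoint taxa share a kingdom (diagonal blocks) or not
#' (off-diagonal blocks). The two groups together cover all n(n-1)/2 pairs.
#'
#' @param matrix square symmetric matrix.
#' @param kingdom kingdom labels over `{"A", "B"}`, one per row/column.
#' @return list with numeric vectors `intra` and `cross`.
#' @export
edge_partition <- function(matrix, kingdom) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stop("matrix must be square")
  if (length(kingdom) != nrow(matrix)) stop("one kingdom label per taxon")
  ut <- upper.tri(matrix)
  same <- outer(kingdom, kingdom, "==")
  list(intra = matrix[ut & same], cross = matrix[ut & !same])
}

# strict upper-triangle pair indices, optionally restricted to cross pairs
pair_index <- function(kingdom, subset = c("all", "cross")) {
  subset <- match.arg(subset)
  n <- length(kingdom)
  ut <- upper.tri(diag(n))
  if (subset == "cross") ut <- ut & !outer(kingdom, kingdom, "==")
  which(ut)
}

#' Mean relative edge strength by kingdom block
#'
#' The mean signed edge value within the intra- and cross-kingdom groups,
#' each divided by the largest |off-diagonal| entry of the whole estimate.
#' This is the bias diagnostic: uncorrected methods on paired data show a
#' positive intra-kingdom and negative cross-kingdom mean.
#'
#' @param estimate a [covariance_estimate()] or symmetric matrix.
#' @param kingdom kingdom labels.
#' @return list with `mean_rel_intra` and `mean_rel_cross`.
#' @export
mean_relative_edge_strength <- function(estimate, kingdom) {
  m <- if (inherits(estimate, "covariance_estimate")) estimate$matrix else estimate
  parts <- edge_partition(m, kingdom)
  strongest <- max(abs(c(parts$intra, parts$cross)))
  if (strongest == 0) stop("all off-diagonal entries are zero")
  list(mean_rel_intra = mean(parts$intra) / strongest,
       mean_rel_cross = mean(parts$cross) / strongest)
}

#' Mann-Whitney test between edge groups
#'
#' Two-sided Mann-Whitney U test (tie-corrected normal approximation)
#' comparing the distributions of intra- and cross-kingdom edge values.
#'
#' @param intra,cross numeric vectors of edge values, both non-empty.
#' @return the two-sided p-value.
#' @export
bias_test <- function(intra, cross) {
  if (length(intra) == 0L || length(cross) == 0L) {
    stop("both edge groups must be non-empty")
  }
  if (max(c(intra, cross)) == min(c(intra, cross))) {
    return(1) # all ties: no evidence of a shift
  }
  stats::wilcox.test(intra, cross, exact = FALSE, correct = FALSE)$p.value
}

#' Edge-recovery R-squared
#'
#' Coefficient of determination from ordinary least squares of the true edge
#' values on the estimated edge values, over all strict-upper-triangle pairs
#' (true zeros included) or cross-kingdom pairs only. A constant estimate is
#' scored 0.
#'
#' @param truth true covariance matrix.
#' @param estimate estimated matrix or [covariance_estimate()].
#' @param kingdom kingdom labels (needed for `subset = "cross"`).
#' @param subset `"all"` or `"cross"`.
#' @return R-squared in \[0, 1\].
#' @export
edge_r2 <- function(truth, estimate, kingdom = NULL,
                    subset = c("all", "cross")) {
  subset <- match.arg(subset)
  est <- if (inherits(estimate, "covariance_estimate")) estimate$matrix else estimate
  truth <- as.matrix(truth)
  if (!all(dim(truth) == dim(est))) stop("dimension mismatch")
  if (subset == "cross" && is.null(kingdom)) {
    stop("kingdom labels required for the cross subset")
  }
  idx <- if (subset == "all") which(upper.tri(truth)) else pair_index(kingdom, "cross")
  hub_r2(truth[idx], est[idx])
}

#' R-squared between true and reconstructed node scores
#'
#' OLS (with intercept) of the truth scores on the estimate scores; constant
#' estimate scores give 0. Shared by the edge- and hub-level comparisons.
#'
#' @param truth_scores,estimate_scores equal-length numeric vectors.
#' @return R-squared in \[0, 1\].
#' @export
hub_r2 <- function(truth_scores, estimate_scores) {
  if (length(truth_scores) != length(estimate_scores)) {
    stop("score vectors must have equal length")
  }
  if (stats::sd(estimate_scores) == 0 || stats::sd(truth_scores) == 0) {
    return(0)
  }
  max(stats::cor(truth_scores, estimate_scores)^2, 0)
}

#' Edge-detection AUC
#'
#' Treats |estimated edge| as a classifier score for edge presence. Positives
#' are the edges of the ground-truth support; with `strong_fraction` given,
#' only the top fraction of true edges by |true value| count as positives and
#' the remaining true edges are excluded from the negatives (they are neither
#' clean positives nor clean negatives). The AUC is the Mann-Whitney rank
#' statistic with midranks for ties, so a constant score gives 0.5.
#'
#' @param truth true covariance matrix (support defines true edges).
#' @param estimate estimated matrix or [covariance_estimate()].
#' @param kingdom kingdom labels (needed for `subset = "cross"`).
#' @param subset `"all"` or `"cross"`.
#' @param strong_fraction optional fraction in (0, 1\] of strongest true
#'   edges to treat as positives.
#' @return AUC in \[0, 1\].
#' @export
edge_auc <- function(truth, estimate, kingdom = NULL,
                     subset = c("all", "cross"), strong_fraction = NULL) {
  subset <- match.arg(subset)
  est <- if (inherits(estimate, "covariance_estimate")) estimate$matrix else estimate
  truth <- as.matrix(truth)
  if (!all(dim(truth) == dim(est))) stop("dimension mismatch")
  idx <- if (subset == "all") which(upper.tri(truth)) else pair_index(kingdom, "cross")
  tv <- truth[idx]
  scores <- abs(est[idx])
  positive <- tv != 0
  if (!is.null(strong_fraction)) {
    stopifnot(strong_fraction > 0, strong_fraction <= 1)
    n_true <- sum(positive)
    n_strong <- max(1L, floor(strong_fraction * n_true))
    true_idx <- which(positive)
    strong <- true_idx[order(-abs(tv[true_idx]))[seq_len(n_strong)]]
    keep <- c(strong, which(!positive))
    scores <- scores[keep]
    positive <- c(rep(TRUE, length(strong)), rep(FALSE, sum(!positive)))
  }
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC needs at least one positive and one negative pair")
  }
  r <- rank(scores) # midranks
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Sign-matched accuracy of the top-N strongest inferred edges
#'
#' Takes the N largest |estimated| edges; an edge is correct iff the true
#' value is nonzero and has the same sign as the estimate.
#'
#' @param truth true covariance matrix.
#' @param estimate estimated matrix or [covariance_estimate()].
#' @param n_values integer vector of N values.
#' @param kingdom kingdom labels (needed for `subset = "cross"`).
#' @param subset `"all"` or `"cross"`.
#' @return named numeric vector, one accuracy per N.
#' @export
top_n_accuracy <- function(truth, estimate, n_values = c(10L, 25L, 50L, 100L),
                           kingdom = NULL, subset = c("all", "cross")) {
  subset <- match.arg(subset)
  est <- if (inherits(estimate, "covariance_estimate")) estimate$matrix else estimate
  truth <- as.matrix(truth)
  idx <- if (subset == "all") which(upper.tri(truth)) else pair_index(kingdom, "cross")
  if (any(n_values < 1)) stop("N must be at least 1")
  if (any(n_values > length(idx))) stop("N exceeds the number of pairs")
  tv <- truth[idx]
  ev <- est[idx]
  ord <- order(-abs(ev), seq_along(ev)) # deterministic tie-break
  out <- vapply(n_values, function(n) {
    top <- ord[seq_len(n)]
    mean(tv[top] != 0 & sign(tv[top]) == sign(ev[top]))
  }, numeric(1))
  stats::setNames(out, as.character(n_values))
}

#' Threshold an estimate into a weighted graph
#'
#' Keeps the top fraction of strict-upper-triangle entries by |value| as
#' edges, with their signed weights. The number kept is
#' `ceiling(top_fraction * n_pairs)`; ties at the cutoff are broken by taxon
#' index order, so the edge set is deterministic.
#'
#' @param estimate estimated matrix or [covariance_estimate()].
#' @param top_fraction fraction of pairs to keep, in (0, 1\].
#' @return an [igraph::graph_from_data_frame()] undirected graph whose `weight`
#'   attribute holds the signed edge values; all taxa appear as vertices.
#' @export
threshold_network <- function(estimate, top_fraction = 0.10) {
  if (!(top_fraction > 0 && top_fraction <= 1)) {
    stop("top_fraction must lie in (0, 1]")
  }
  m <- if (inherits(estimate, "covariance_estimate")) estimate$matrix else as.matrix(estimate)
  n <- nrow(m)
  ids <- colnames(m)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ut <- which(upper.tri(m), arr.ind = TRUE)
  vals <- m[upper.tri(m)]
  keep_n <- ceiling(top_fraction * length(vals))
  ord <- order(-abs(vals), ut[, 1L], ut[, 2L])
  keep <- ord[seq_len(keep_n)]
  keep <- keep[vals[keep] != 0] # exact zeros carry no edge
  edges <- data.frame(from = ids[ut[keep, 1L]], to = ids[ut[keep, 2L]],
                      weight = vals[keep])
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = ids))
}

#' Node centralities on a thresholded network
#'
#' Standard normalized centralities on the unweighted topology: betweenness
#' (normalized by (n-1)(n-2)/2), degree (divided by n-1), and eigenvector
#' centrality computed per connected component with a dense eigensolver
#' (principal eigenvector of the component adjacency, scaled to maximum 1
#' within the component; isolated nodes score 0).
#'
#' @param graph an igraph graph, e.g. from [threshold_network()].
#' @param metric one of `"betweenness"`, `"degree"`, `"eigenvector"`.
#' @return named numeric vector over all vertices.
#' @export
hub_scores <- function(graph, metric = c("betweenness", "degree",
                                         "eigenvector")) {
  metric <- match.arg(metric)
  n <- igraph::vcount(graph)
  if (n == 0L) stop("empty graph")
  if (metric == "betweenness") {
    sc <- igraph::betweenness(graph, weights = NA, normalized = TRUE)
  } else if (metric == "degree") {
    sc <- igraph::degree(graph) / max(n - 1L, 1L)
  } else {
    sc <- stats::setNames(numeric(n), igraph::V(graph)$name)
    comp <- igraph::components(graph)
    for (ci in seq_len(comp$no)) {
      members <- which(comp$membership == ci)
      if (length(members) < 2L) next # isolated nodes score 0
      sub <- igraph::induced_subgraph(graph, members)
      a <- igraph::as_adjacency_matrix(sub, sparse = FALSE)
      ev <- eigen(a, symmetric = TRUE)
      v <- abs(ev$vectors[, 1L])
      sc[members] <- v / max(v)
    }
  }
  sc
}

#' Lotka-Volterra knockout keystoneness
#'
#' Interprets the estimate as interaction strengths of a generalized
#' Lotka-Volterra system `dx_i/dt = x_i (r_i + sum_j A_ij x_j)` with
#' `A_ij = c * estimate_ij` off the diagonal (`c = interaction_scale /
#' max|off-diagonal|`), self-limitation `A_ii = -1`, growth `r_i = 1`, and
#' all-ones initial state. The system is integrated to a baseline steady
#' state; each taxon is then removed in turn and the system re-integrated.
#' Keystoneness of a taxon is the Bray-Curtis dissimilarity between the
#' remaining taxa's baseline and knockout steady states, in \[0, 1\].
#' Dynamics that fail to settle (relative derivative above `steady_tol` at
#' the final time) are flagged and scored 1 with a warning.
#'
#' @param estimate estimated matrix or [covariance_estimate()].
#' @param interaction_scale off-diagonal scaling target (default 0.5).
#' @param t_max integration horizon (default 500).
#' @param steady_tol relative-derivative threshold for steadiness.
#' @param seed unused placeholder for interface symmetry (the dynamics are
#'   deterministic); kept so trial-level code can pass one seed everywhere.
#' @return named numeric vector of keystoneness scores in \[0, 1\].
#' @export
lv_keystoneness <- function(estimate, interaction_scale = 0.5, t_max = 500,
                            steady_tol = 1e-6, seed = NULL) {
  m <- if (inherits(estimate, "covariance_estimate")) estimate$matrix else as.matrix(estimate)
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    stop("estimate must be symmetric")
  }
  n <- nrow(m)
  ids <- colnames(m)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  a <- m
  diag(a) <- 0
  max_off <- max(abs(a))
  if (max_off > 0) a <- a * (interaction_scale / max_off)
  diag(a) <- -1
  r <- rep(1, n)

  steady_state <- function(amat, growth) {
    k <- nrow(amat)
    deriv <- function(t, x, parms) {
      x <- pmax(x, 0)
      list(x * (growth + as.vector(amat %*% x)))
    }
    out <- deSolve::lsoda(y = rep(1, k), times = c(0, t_max / 2, t_max),
                          func = deriv, parms = NULL,
                          rtol = 1e-8, atol = 1e-10)
    x_end <- pmax(out[nrow(out), -1L], 0)
    dx <- x_end * (growth + as.vector(amat %*% x_end))
    steady <- max(abs(dx)) <= steady_tol * max(max(abs(x_end)), 1)
    list(x = x_end, steady = steady)
  }
  bray_curtis <- function(u, v) {
    tot <- sum(u) + sum(v)
    if (tot == 0) return(0)
    sum(abs(u - v)) / tot
  }

  base <- steady_state(a, r)
  if (!base$steady) {
    warning("baseline dynamics did not settle; all keystoneness set to 1")
    return(stats::setNames(rep(1, n), ids))
  }
  scores <- numeric(n)
  for (i in seq_len(n)) {
    ko <- steady_state(a[-i, -i, drop = FALSE], r[-i])
    if (!ko$steady) {
      warning(sprintf("knockout of taxon %s did not settle; scored 1", ids[i]))
      scores[i] <- 1
    } else {
      scores[i] <- bray_curtis(base$x[-i], ko$x)
    }
  }
  stats::setNames(scores, ids)
}

#' Louvain community detection
#'
#' Louvain modularity maximization on |edge weight|; deterministic given the
#' seed. Every node is assigned exactly one community; isolated nodes form
#' singletons.
#'
#' @param graph an igraph graph with a `weight` edge attribute (signed
#'   weights are used through their absolute values).
#' @param seed integer seed.
#' @return named integer vector of community ids over all vertices.
#' @export
detect_communities <- function(graph, seed = 0L) {
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  w <- igraph::E(graph)$weight
  w <- if (is.null(w)) NULL else abs(w)
  cl <- with_seed(seed, igraph::cluster_louvain(graph, weights = w))
  stats::setNames(as.integer(igraph::membership(cl)),
                  igraph::V(graph)$name)
}

#' Score reconstructed communities against ground-truth communities
#'
#' For each community of the reconstructed partition: `overlap` is the best
#' Jaccard agreement with any truth community (|intersection| / |union|), and
#' `inclusion` is the largest fraction of the reconstructed community
#' contained in a single truth community (|intersection| / |reconstructed
#' community|).
#'
#' @param recon_partition,truth_partition named membership vectors over the
#'   same node set.
#' @return list of class `community_evaluation` with `overlap_scores` and
#'   `inclusion_scores`, one entry per reconstructed community.
#' @export
community_scores <- function(recon_partition, truth_partition) {
  if (!setequal(names(recon_partition), names(truth_partition))) {
    stop("partitions must cover the same node set")
  }
  truth_partition <- truth_partition[names(recon_partition)]
  rec_comms <- split(names(recon_partition), recon_partition)
  tru_comms <- split(names(truth_partition), truth_partition)
  overlap <- vapply(rec_comms, function(rc) {
    max(vapply(tru_comms, function(tc) {
      length(intersect(rc, tc)) / length(union(rc, tc))
    }, numeric(1)))
  }, numeric(1))
  inclusion <- vapply(rec_comms, function(rc) {
    max(vapply(tru_comms, function(tc) {
      length(intersect(rc, tc)) / length(rc)
    }, numeric(1)))
  }, numeric(1))
  structure(
    list(overlap_scores = unname(overlap),
         inclusion_scores = unname(inclusion)),
    class = "community_evaluation"
  )
}
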