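#' Interaction graph constructor
#'
#' A signed, undirected interaction graph over `n_taxa` nodes. Edges are stored
#' as a two-column integer matrix of node index pairs (1-based, `i < j`, no
#' self loops) with one sign per edge.
#'
#' @param n_taxa number of nodes.
#' @param edges two-column integer matrix of node pairs.
#' @param signs integer vector of +1/-1, one per edge row.
#' @return an object of class `interaction_graph`.
#' @export
interaction_graph <- function(n_taxa, edges, signs) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  signs <- as.integer(signs)
  if (nrow(edges) > 0L) {
    swap <- edges[, 1L] > edges[, 2L]
    edges[swap, ] <- edges[swap, c(2L, 1L)]
  }
  g <- structure(
    list(n_taxa = as.integer(n_taxa), edges = edges, signs = signs),
    class = "interaction_graph"
  )
  validate_interaction_graph(g)
  g
}

#' @rdname interaction_graph
#' @param g an `interaction_graph`.
#' @export
validate_interaction_graph <- function(g) {
  stopifnot(inherits(g, "interaction_graph"))
  if (g$n_taxa < 1L) stop("graph must have at least one node")
  e <- g$edges
  if (nrow(e) != length(g$signs)) stop("one sign required per edge")
  if (nrow(e) > 0L) {
    if (any(e[, 1L] == e[, 2L])) stop("self loops are not allowed")
    if (any(e < 1L) || any(e > g$n_taxa)) stop("edge index out of range")
    key <- paste(e[, 1L], e[, 2L])
    if (anyDuplicated(key)) stop("duplicate edges")
    if (!all(g$signs %in% c(-1L, 1L))) stop("signs must be +1 or -1")
  }
  invisible(g)
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf(
    "<interaction_graph> %d taxa, %d edges (%d negative)\n",
    x$n_taxa, nrow(x$edges), sum(x$signs < 0L)
  ))
  invisible(x)
}

#' Generate a random power-law interaction graph
#'
#' Grows a graph by preferential attachment with triad closure (a power-law
#' cluster construction): after a seed clique on `density_param + 1` nodes,
#' each new node attaches `density_param` edges, the first to an existing node
#' chosen with probability proportional to degree, and each subsequent edge
#' closing a triangle through the previous target with probability
#' `closure_prob` (otherwise again by preferential attachment). The result is
#' a sparse small-world graph with a heavy-tailed degree distribution. Each
#' edge receives a sign, negative with probability `negative_prob`.
#'
#' @param n_taxa number of nodes, at least 4.
#' @param density_param edges added per new node (>= 1); default 2.
#' @param seed integer seed; the construction is deterministic given the seed.
#' @param closure_prob probability of triad closure per secondary edge.
#' @param negative_prob probability that an edge sign is negative.
#' @return an [interaction_graph()].
#' @export
#' @examples
#' g <- generate_powerlaw_graph(50, density_param = 2, seed = 1)
#' table(g$signs)
generate_powerlaw_graph <- function(n_taxa, density_param = 2L, seed,
                                    closure_prob = 0.1, negative_prob = 0.5) {
  if (!is_count(n_taxa) || n_taxa < 4) {
    stop("n_taxa must be an integer >= 4: networks below 4 taxa are degenerate")
  }
  if (!is_count(density_param)) stop("density_param must be a positive integer")
  n_taxa <- as.integer(n_taxa)
  m <- as.integer(density_param)
  if (m + 1L >= n_taxa) stop("density_param too large for n_taxa")

  with_seed(seed, {
    deg <- integer(n_taxa)
    adj <- vector("list", n_taxa) # neighbor lists during growth
    ei <- integer(0)
    ej <- integer(0)
    add_edge <- function(a, b) {
      ei[[length(ei) + 1L]] <<- a
      ej[[length(ej) + 1L]] <<- b
      deg[a] <<- deg[a] + 1L
      deg[b] <<- deg[b] + 1L
      adj[[a]] <<- c(adj[[a]], b)
      adj[[b]] <<- c(adj[[b]], a)
    }
    # seed clique on m + 1 nodes
    for (a in seq_len(m)) {
      for (b in seq.int(a + 1L, m + 1L)) add_edge(a, b)
    }
    for (v in seq.int(m + 2L, n_taxa)) {
      targets <- integer(0)
      prev <- 0L
      while (length(targets) < m) {
        cand <- 0L
        if (length(targets) > 0L && runif(1) < closure_prob && prev > 0L) {
          # close a triangle: neighbor of the previous target not yet linked
          nb <- setdiff(adj[[prev]], c(v, targets))
          if (length(nb) > 0L) cand <- nb[sample.int(length(nb), 1L)]
        }
        if (cand == 0L) {
          # preferential attachment over nodes not already chosen
          avail <- setdiff(seq_len(v - 1L), targets)
          w <- deg[avail]
          cand <- avail[sample.int(length(avail), 1L, prob = w)]
        }
        targets <- c(targets, cand)
        prev <- cand
      }
      for (t in targets) add_edge(v, t)
    }
    signs <- ifelse(runif(length(ei)) < negative_prob, -1L, 1L)
    interaction_graph(n_taxa, cbind(ei, ej), signs)
  })
}

#' Randomly assign taxa to two kingdoms
#'
#' Splits taxa into kingdoms "A" and "B" (e.g. bacteria and fungi), with
#' `round(fraction_a * n_taxa)` taxa in A at uniformly random positions.
#'
#' @param n_taxa number of taxa.
#' @param fraction_a fraction assigned to kingdom A, strictly in (0, 1).
#' @param seed integer seed.
#' @return character vector over `{"A", "B"}` of length `n_taxa`.
#' @export
assign_kingdoms <- function(n_taxa, fraction_a = 0.5, seed) {
  if (!is_count(n_taxa)) stop("n_taxa must be a positive integer")
  if (!(fraction_a > 0 && fraction_a < 1)) stop("fraction_a must lie in (0, 1)")
  n_a <- round(fraction_a * n_taxa)
  if (n_a < 1 || n_a > n_taxa - 1) {
    stop("fraction_a would leave one kingdom empty")
  }
  with_seed(seed, {
    kingdom <- rep("B", n_taxa)
    kingdom[sample.int(n_taxa, n_a)] <- "A"
    kingdom
  })
}

#' Build a positive-definite covariance matrix on a graph's support
#'
#' Off-diagonal entries are placed exactly on the graph's edges, with
#' magnitudes drawn uniformly from `magnitude_range` and signs taken from the
#' graph's edge signs; the diagonal starts at 1. Positive definiteness is then
#' enforced by uniform diagonal loading: if the smallest eigenvalue falls at or
#' below `eps`, `eps - lambda_min` is added to every diagonal entry. Loading
#' only the diagonal preserves the off-diagonal support and signs exactly.
#'
#' @param graph an [interaction_graph()].
#' @param magnitude_range length-2 numeric, uniform range for |off-diagonal|.
#' @param seed integer seed.
#' @param eps eigenvalue floor (> 0); default 0.01.
#' @return symmetric positive-definite matrix of size `n_taxa`.
#' @export
graph_to_covariance <- function(graph, magnitude_range = c(0.2, 1.0), seed,
                                eps = 0.01) {
  validate_interaction_graph(graph)
  stopifnot(length(magnitude_range) == 2L, magnitude_range[1] > 0,
            magnitude_range[1] < magnitude_range[2], eps > 0)
  n <- graph$n_taxa
  with_seed(seed, {
    sigma <- diag(n)
    if (nrow(graph$edges) > 0L) {
      mags <- runif(nrow(graph$edges), magnitude_range[1], magnitude_range[2])
      vals <- mags * graph$signs
      sigma[graph$edges] <- vals
      sigma[graph$edges[, c(2L, 1L), drop = FALSE]] <- vals
    }
    lam_min <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
    if (lam_min <= eps) {
      diag(sigma) <- diag(sigma) + (eps - lam_min)
    }
    sigma
  })
}

#' Structure variant for the cross-kingdom block
#'
#' Controls the density and sign balance of cross-kingdom edges relative to
#' the unbiased default. `structure_variant(1, 0.5)` is the neutral setting:
#' cross-kingdom edges occur at the graph's own density and are negative half
#' the time.
#'
#' @param cross_density_factor positive multiplier on cross-kingdom edge count.
#' @param cross_negative_prob probability in \[0, 1\] that a cross-kingdom edge
#'   is negative.
#' @return an object of class `structure_variant`.
#' @export
structure_variant <- function(cross_density_factor = 1,
                              cross_negative_prob = 0.5) {
  if (!(cross_density_factor > 0)) stop("cross_density_factor must be > 0")
  if (cross_negative_prob < 0 || cross_negative_prob > 1) {
    stop("cross_negative_prob must lie in [0, 1]")
  }
  structure(
    list(cross_density_factor = cross_density_factor,
         cross_negative_prob = cross_negative_prob),
    class = "structure_variant"
  )
}

#' Apply a cross-kingdom structure variant to a graph
#'
#' Rescales the number of cross-kingdom edges by `cross_density_factor`
#' (added edges are drawn uniformly from absent cross-kingdom pairs, removed
#' edges uniformly from present ones) and resamples every cross-kingdom edge
#' sign, negative with probability `cross_negative_prob`. Intra-kingdom edges
#' and their signs are untouched. With a density factor of exactly 1 the edge
#' set is left unchanged and only cross signs are resampled.
#'
#' @param graph an [interaction_graph()].
#' @param kingdom kingdom labels over `{"A", "B"}`, length `n_taxa`.
#' @param variant a [structure_variant()].
#' @param seed integer seed.
#' @return an [interaction_graph()] with the adjusted cross-kingdom block.
#' @export
apply_structure_variant <- function(graph, kingdom, variant, seed) {
  validate_interaction_graph(graph)
  stopifnot(inherits(variant, "structure_variant"),
            length(kingdom) == graph$n_taxa)
  cross <- kingdom[graph$edges[, 1L]] != kingdom[graph$edges[, 2L]]
  n_cross <- sum(cross)
  n_a <- sum(kingdom == "A")
  n_pairs_cross <- n_a * (graph$n_taxa - n_a)
  target <- round(variant$cross_density_factor * n_cross)
  if (target > n_pairs_cross) {
    stop(sprintf(
      "cross_density_factor demands %d cross edges but only %d cross pairs exist",
      target, n_pairs_cross
    ))
  }
  with_seed(seed, {
    e_intra <- graph$edges[!cross, , drop = FALSE]
    s_intra <- graph$signs[!cross]
    e_cross <- graph$edges[cross, , drop = FALSE]
    if (variant$cross_density_factor != 1) {
      if (target < n_cross) {
        keep <- sample.int(n_cross, target)
        e_cross <- e_cross[keep, , drop = FALSE]
      } else if (target > n_cross) {
        ia <- which(kingdom == "A")
        ib <- which(kingdom == "B")
        all_cross <- cbind(
          rep(ia, each = length(ib)),
          rep(ib, times = length(ia))
        )
        swap <- all_cross[, 1L] > all_cross[, 2L]
        all_cross[swap, ] <- all_cross[swap, c(2L, 1L)]
        have <- paste(e_cross[, 1L], e_cross[, 2L])
        absent <- all_cross[!(paste(all_cross[, 1L], all_cross[, 2L]) %in% have),
                            , drop = FALSE]
        add <- absent[sample.int(nrow(absent), target - n_cross), ,
                      drop = FALSE]
        e_cross <- rbind(e_cross, add)
      }
    }
    s_cross <- ifelse(runif(nrow(e_cross)) < variant$cross_negative_prob,
                      -1L, 1L)
    interaction_graph(graph$n_taxa, rbind(e_intra, e_cross),
                      c(s_intra, s_cross))
  })
}

#' Draw mean log-abundances
#'
#' Mean log-abundance of each taxon is uniform on the open interval
#' `(low, high)`; the default range is (-4, 4).
#'
#' @param n_taxa number of taxa.
#' @param low,high interval bounds, `low < high`.
#' @param seed integer seed.
#' @return numeric vector of length `n_taxa`, all entries strictly inside
#'   `(low, high)`.
#' @export
draw_mean_log <- function(n_taxa, low = -4, high = 4, seed) {
  if (!is_count(n_taxa)) stop("n_taxa must be a positive integer")
  if (!(low < high)) stop("low must be strictly below high")
  with_seed(seed, runif(n_taxa, low, high))
}

#' Generate a complete ground-truth model
#'
#' Chains the generator stages — power-law graph, kingdom split, structure
#' variant, positive-definite covariance, mean log-abundances — using child
#' seeds derived from one master seed (see [child_seed()]), and returns the
#' object every simulated data set is drawn from.
#'
#' @param n_taxa number of taxa (default 500).
#' @param density_param edges per new node in the power-law growth.
#' @param closure_prob triad-closure probability.
#' @param fraction_a fraction of taxa in kingdom A.
#' @param variant a [structure_variant()].
#' @param magnitude_range uniform range of |off-diagonal| covariance entries.
#' @param mean_log_range interval for mean log-abundances.
#' @param eps smallest-eigenvalue floor for the covariance.
#' @param seed master integer seed.
#' @return an object of class `ground_truth_model` with fields `graph`,
#'   `covariance`, `mean_log`, `kingdom`, `taxon_ids`.
#' @export
#' @examples
#' m <- ground_truth_model(n_taxa = 30, seed = 1)
#' min(eigen(m$covariance, symmetric = TRUE, only.values = TRUE)$values)
ground_truth_model <- function(n_taxa = 500, density_param = 2L,
                               closure_prob = 0.1, fraction_a = 0.5,
                               variant = structure_variant(),
                               magnitude_range = c(0.2, 1.0),
                               mean_log_range = c(-4, 4),
                               eps = 0.01, seed) {
  graph <- generate_powerlaw_graph(n_taxa, density_param,
                                   seed = child_seed(seed, 0L),
                                   closure_prob = closure_prob)
  kingdom <- assign_kingdoms(n_taxa, fraction_a, seed = child_seed(seed, 1L))
  graph <- apply_structure_variant(graph, kingdom, variant,
                                   seed = child_seed(seed, 2L))
  covariance <- graph_to_covariance(graph, magnitude_range,
                                    seed = child_seed(seed, 3L), eps = eps)
  mean_log <- draw_mean_log(n_taxa, mean_log_range[1], mean_log_range[2],
                            seed = child_seed(seed, 4L))
  taxon_ids <- sprintf("T%04d", seq_len(n_taxa))
  dimnames(covariance) <- list(taxon_ids, taxon_ids)
  names(mean_log) <- taxon_ids
  names(kingdom) <- taxon_ids
  model <- structure(
    list(graph = graph, covariance = covariance, mean_log = mean_log,
         kingdom = kingdom, taxon_ids = taxon_ids),
    class = "ground_truth_model"
  )
  validate_ground_truth_model(model)
  model
}

#' Validate a ground-truth model
#'
#' Asserts the generating-model invariants: the covariance is symmetric and
#' positive definite, its off-diagonal support equals the graph's edge set,
#' every nonzero off-diagonal sign matches the edge sign, and both kingdoms
#' are non-empty.
#'
#' @param model a `ground_truth_model`.
#' @return the model, invisibly; errors if any invariant fails.
#' @export
validate_ground_truth_model <- function(model) {
  stopifnot(inherits(model, "ground_truth_model"))
  sigma <- model$covariance
  n <- model$graph$n_taxa
  if (!isTRUE(all.equal(sigma, t(sigma), tolerance = 1e-12))) {
    stop("covariance is not symmetric")
  }
  lam <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(lam) <= 0) stop("covariance is not positive definite")
  off <- which(upper.tri(sigma) & sigma != 0, arr.ind = TRUE)
  want <- model$graph$edges
  if (nrow(off) != nrow(want) ||
      !setequal(paste(off[, 1L], off[, 2L]), paste(want[, 1L], want[, 2L]))) {
    stop("covariance support does not match graph edges")
  }
  sgn <- sign(sigma[want])
  if (!all(sgn == model$graph$signs)) stop("covariance signs do not match edges")
  if (length(unique(model$kingdom)) < 2L) stop("a kingdom is empty")
  invisible(model)
}

#' @export
print.ground_truth_model <- function(x, ...) {
  cat(sprintf(
    "<ground_truth_model> %d taxa (%d A / %d B), %d edges, lambda_min = %.4f\n",
    x$graph$n_taxa, sum(x$kingdom == "A"), sum(x$kingdom == "B"),
    nrow(x$graph$edges),
    min(eigen(x$covariance, symmetric = TRUE, only.values = TRUE)$values)
  ))
  invisible(x)
}

#' Write / read a ground-truth model as plain-text tables
#'
#' The covariance and mean vector are written as tab-separated matrices with
#' taxon identifiers, kingdom labels as a two-column TSV, and the graph as an
#' edge-list TSV (taxon_i, taxon_j, sign).
#'
#' @param model a `ground_truth_model`.
#' @param dir output directory (created if missing).
#' @return `write_ground_truth` returns `dir` invisibly; `read_ground_truth`
#'   returns a `ground_truth_model`.
#' @export
write_ground_truth <- function(model, dir) {
  validate_ground_truth_model(model)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cov_df <- data.frame(taxon_id = model$taxon_ids, model$covariance,
                       check.names = FALSE)
  utils::write.table(cov_df, file.path(dir, "covariance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(taxon_id = model$taxon_ids, mean_log = model$mean_log),
    file.path(dir, "mean_log.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    data.frame(taxon_id = model$taxon_ids, kingdom = model$kingdom),
    file.path(dir, "kingdom.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  e <- model$graph$edges
  utils::write.table(
    data.frame(taxon_i = model$taxon_ids[e[, 1L]],
               taxon_j = model$taxon_ids[e[, 2L]],
               sign = model$graph$signs),
    file.path(dir, "edges.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(dir) {
  cov_df <- utils::read.delim(file.path(dir, "covariance.tsv"),
                              check.names = FALSE)
  taxon_ids <- cov_df$taxon_id
  sigma <- as.matrix(cov_df[, -1L, drop = FALSE])
  dimnames(sigma) <- list(taxon_ids, taxon_ids)
  mean_df <- utils::read.delim(file.path(dir, "mean_log.tsv"))
  king_df <- utils::read.delim(file.path(dir, "kingdom.tsv"))
  edge_df <- utils::read.delim(file.path(dir, "edges.tsv"))
  idx <- stats::setNames(seq_along(taxon_ids), taxon_ids)
  graph <- interaction_graph(
    length(taxon_ids),
    cbind(idx[edge_df$taxon_i], idx[edge_df$taxon_j]),
    as.integer(edge_df$sign)
  )
  mean_log <- stats::setNames(mean_df$mean_log, mean_df$taxon_id)[taxon_ids]
  kingdom <- stats::setNames(king_df$kingdom, king_df$taxon_id)[taxon_ids]
  model <- structure(
    list(graph = graph, covariance = sigma, mean_log = mean_log,
         kingdom = kingdom, taxon_ids = taxon_ids),
    class = "ground_truth_model"
  )
  validate_ground_truth_model(model)
  model
}
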