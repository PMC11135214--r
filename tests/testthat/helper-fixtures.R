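# Shared fixtures and independent oracles, all built in code at test time.

# small seeded simulation: model + exact abundances + paired reads
small_sim <- function(n_taxa = 20, n_samples = 40, seed = 1,
                      variant = structure_variant(), depth_mean = 1e5,
                      depth_sd = 1e4) {
  model <- ground_truth_model(n_taxa = n_taxa, variant = variant, seed = seed)
  abund <- sample_absolute_abundances(model, n_samples,
                                      seed = child_seed(seed, 51L))
  paired <- simulate_reads(abund, model$kingdom, depth_mean = depth_mean,
                           depth_sd = depth_sd, seed = child_seed(seed, 52L))
  ord <- c(which(model$kingdom == "A"), which(model$kingdom == "B"))
  list(model = model, abund = abund, paired = paired,
       truth = model$covariance[ord, ord], kingdom = model$kingdom[ord])
}

# hand-built abundance table (bypasses the generator on purpose)
manual_abundances <- function(values) {
  values <- as.matrix(values)
  sample_ids <- sprintf("S%04d", seq_len(nrow(values)))
  taxon_ids <- sprintf("T%04d", seq_len(ncol(values)))
  dimnames(values) <- list(sample_ids, taxon_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 taxon_ids = taxon_ids),
            class = "abundance_table")
}

# diagonal-covariance ground truth with given variances (no edges)
diagonal_model <- function(variances, mean_log = NULL, fraction_a = 0.5) {
  n <- length(variances)
  if (is.null(mean_log)) mean_log <- rep(0, n)
  taxon_ids <- sprintf("T%04d", seq_len(n))
  sigma <- diag(variances)
  dimnames(sigma) <- list(taxon_ids, taxon_ids)
  kingdom <- rep(c("A", "B"), length.out = n)
  names(kingdom) <- taxon_ids
  names(mean_log) <- taxon_ids
  structure(
    list(graph = interaction_graph(n, matrix(integer(0), ncol = 2), integer(0)),
         covariance = sigma, mean_log = mean_log, kingdom = kingdom,
         taxon_ids = taxon_ids),
    class = "ground_truth_model"
  )
}

# brute-force AUC: fraction of positive-negative score pairs won (ties = 1/2)
auc_brute <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  wins <- 0
  for (p in pos) wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  wins / (length(pos) * length(neg))
}

# Independent graphical-lasso solver (ADMM), used only as a test oracle.
# Solves min -log det(Theta) + tr(S Theta) + lam * ||Theta||_{1,off}
admm_glasso <- function(s, lam, rho = 1, maxit = 20000, tol = 1e-11) {
  p <- ncol(s)
  theta <- diag(1 / diag(s))
  z <- theta
  u <- matrix(0, p, p)
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  for (it in seq_len(maxit)) {
    ed <- eigen((rho * (z - u) - s) / rho, symmetric = TRUE)
    th_eig <- (ed$values + sqrt(ed$values^2 + 4 / rho)) / 2
    theta <- ed$vectors %*% diag(th_eig) %*% t(ed$vectors)
    z_old <- z
    z <- soft(theta + u, lam / rho)
    diag(z) <- diag(theta + u) # diagonal unpenalized
    u <- u + theta - z
    if (max(abs(theta - z)) < tol && max(abs(z - z_old)) < tol) break
  }
  (z + t(z)) / 2
}

# analytic interior gLV equilibrium: solve r + A x = 0
glv_equilibrium <- function(a, r) {
  solve(-a, r)
}

# write a count_table-shaped TSV from a plain matrix
write_otu_tsv <- function(mat, path) {
  write_count_table(count_table(mat), path)
  path
}
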