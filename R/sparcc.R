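#' Basis variances and correlations from a variation matrix
#'
#' Core of the SparCC procedure. Given the variation matrix
#' `T[a, b] = Var[log(x_a / x_b)]`, solves the linear system for the basis
#' (log-abundance) variances `omega` under the sparsity assumption that most
#' basis correlations are negligible, then forms
#' `rho[a, b] = (omega_a + omega_b - T[a, b]) / (2 sqrt(omega_a omega_b))`.
#' The most strongly correlated pair with `|rho|` above
#' `exclusion_threshold` is then removed from the system and the solve is
#' repeated, up to `max_exclusion_rounds` times, so that a few strong true
#' correlations do not distort the basis variances.
#'
#' @param variation symmetric matrix of log-ratio variances, zero diagonal,
#'   at least 4 taxa (the linear system needs more than 3 components).
#' @param exclusion_threshold |rho| above which the strongest pair is excluded
#'   each round (default 0.1).
#' @param max_exclusion_rounds maximum exclusion iterations (default 10).
#' @return list with `omega` (basis variances), `rho` (correlations, clipped
#'   to \[-1, 1\]), `excluded` (two-column matrix of excluded pairs).
#' @export
#' @examples
#' v <- 0.5
#' tmat <- matrix(v, 4, 4) - diag(rep(v, 4))
#' sparcc_basis(tmat)$omega # v/2 for every taxon
sparcc_basis <- function(variation, exclusion_threshold = 0.1,
                         max_exclusion_rounds = 10L) {
  variation <- as.matrix(variation)
  d <- ncol(variation)
  if (d < 4L) stop("SparCC basis system requires at least 4 taxa")
  if (!isTRUE(all.equal(variation, t(variation), tolerance = 1e-8))) {
    stop("variation matrix must be symmetric")
  }
  diag(variation) <- 0

  m <- matrix(1, d, d)
  diag(m) <- d - 1
  t_vec <- rowSums(variation)
  excluded <- matrix(integer(0), ncol = 2L)
  solve_omega <- function() {
    omega <- solve(m, t_vec)
    if (any(omega <= 0)) {
      warning("non-positive basis variance; falling back to absolute values")
      omega <- abs(omega)
      omega[omega == 0] <- .Machine$double.eps
    }
    omega
  }
  rho_from <- function(omega) {
    denom <- 2 * sqrt(outer(omega, omega))
    rho <- (outer(omega, omega, "+") - variation) / denom
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    rho
  }
  omega <- solve_omega()
  rho <- rho_from(omega)
  for (round in seq_len(max_exclusion_rounds)) {
    cand <- abs(rho)
    diag(cand) <- 0
    if (nrow(excluded) > 0L) {
      cand[excluded] <- 0
      cand[excluded[, c(2L, 1L), drop = FALSE]] <- 0
    }
    top <- which(cand == max(cand), arr.ind = TRUE)[1L, , drop = FALSE]
    if (cand[top] <= exclusion_threshold) break
    i <- top[1L]
    j <- top[2L]
    m[i, j] <- m[j, i] <- 0
    m[i, i] <- m[i, i] - 1
    m[j, j] <- m[j, j] - 1
    t_vec[i] <- t_vec[i] - variation[i, j]
    t_vec[j] <- t_vec[j] - variation[i, j]
    excluded <- rbind(excluded, cbind(i, j))
    if (any(diag(m) < 1)) break # a taxon fully excluded; stop refining
    omega <- solve_omega()
    rho <- rho_from(omega)
  }
  list(omega = omega, rho = rho, excluded = excluded)
}

#' Variation matrix of log-ratio variances
#'
#' `T[a, b] = Var[log(f_a / f_b)]` over samples, computed from the covariance
#' of the log fractions: `T = v 1' + 1 v' - 2 S` with `v = diag(S)`.
#'
#' @param log_fractions samples x taxa matrix of log relative abundances.
#' @return symmetric matrix with zero diagonal.
#' @export
variation_matrix <- function(log_fractions) {
  s <- stats::cov(log_fractions)
  v <- diag(s)
  tm <- outer(v, v, "+") - 2 * s
  diag(tm) <- 0
  tm
}

#' SparCC covariance estimate
#'
#' Runs the SparCC basis-correlation procedure on the concatenated pair of
#' count tables. Each of `n_resamples` rounds draws per-sample taxon
#' fractions from the Dirichlet posterior of the counts under a uniform prior
#' (replacing an additive pseudocount), computes the variation matrix of the
#' log fractions, and solves the basis system with iterative strong-pair
#' exclusion; `omega` and `rho` are aggregated across rounds by the median.
#' The returned matrix is the covariance `rho * sqrt(omega_a * omega_b)` with
#' `omega` on the diagonal, so SparCC lives on the same scale as the other
#' estimators; the median correlation matrix is kept in `meta$rho`.
#'
#' @param paired a [paired_counts()] object; concatenated width must be >= 4.
#' @param exclusion_threshold see [sparcc_basis()].
#' @param max_exclusion_rounds see [sparcc_basis()].
#' @param n_resamples Dirichlet resampling rounds (default 20).
#' @param seed integer seed.
#' @return a [covariance_estimate()] with method `"sparcc"`.
#' @export
sparcc_method <- function(paired, exclusion_threshold = 0.1,
                          max_exclusion_rounds = 10L, n_resamples = 20L,
                          seed) {
  check_samples(paired)
  counts <- cbind(paired$counts_a, paired$counts_b)
  d <- ncol(counts)
  if (d < 4L) stop("SparCC requires at least 4 taxa in total")
  n <- nrow(counts)
  with_seed(seed, {
    rhos <- array(NA_real_, c(d, d, n_resamples))
    omegas <- matrix(NA_real_, n_resamples, d)
    n_fallbacks <- 0L
    for (k in seq_len(n_resamples)) {
      # Dirichlet(counts + 1) fractions via normalized gamma draws
      g <- matrix(stats::rgamma(n * d, shape = as.numeric(counts) + 1), n, d)
      logf <- log(g / rowSums(g))
      fit <- withCallingHandlers(
        sparcc_basis(variation_matrix(logf), exclusion_threshold,
                     max_exclusion_rounds),
        warning = function(w) {
          if (grepl("basis variance", conditionMessage(w))) {
            n_fallbacks <<- n_fallbacks + 1L
            invokeRestart("muffleWarning")
          }
        }
      )
      rhos[, , k] <- fit$rho
      omegas[k, ] <- fit$omega
    }
    if (n_fallbacks > 0L) {
      warning(sprintf(
        "non-positive basis variances in %d of %d resamples; absolute values used there",
        n_fallbacks, n_resamples
      ))
    }
    rho <- apply(rhos, c(1, 2), stats::median)
    rho <- (rho + t(rho)) / 2
    omega <- apply(omegas, 2, stats::median)
    sigma <- rho * sqrt(outer(omega, omega))
    diag(sigma) <- omega
    covariance_estimate("sparcc", sigma, taxon_ids = colnames(counts),
                        meta = list(rho = rho, omega = omega,
                                    n_resamples = n_resamples))
  })
}
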