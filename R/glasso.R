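#' Graphical lasso fit
#'
#' Maximizes the l1-penalized Gaussian log-likelihood
#' `log det(Theta) - trace(S Theta) - lam * ||Theta||_1,off`
#' by block coordinate descent over the working covariance, the classic
#' graphical-lasso algorithm. The penalty applies to off-diagonal entries
#' only, so for `lam >= max |off-diagonal of S|` the solution is exactly
#' `diag(1 / diag(S))`.
#'
#' @param empirical_cov symmetric empirical covariance `S`.
#' @param lam positive regularization parameter.
#' @param maxit_outer maximum outer sweeps (default 500).
#' @param maxit_inner maximum inner lasso passes per column (default 200).
#' @param tol convergence tolerance on the working covariance, relative to
#'   the mean |off-diagonal| of `S` (default 1e-4).
#' @param warm optional warm start, a list with `W` and `B` from a previous
#'   fit at a nearby `lam`.
#' @return the precision matrix `Theta` (symmetric positive definite) with
#'   attributes `W`, `B`, `iterations`, `converged`.
#' @export
glasso_fit <- function(empirical_cov, lam, maxit_outer = 500L,
                       maxit_inner = 200L, tol = 1e-4, warm = NULL) {
  s <- as.matrix(empirical_cov)
  if (!isTRUE(all.equal(s, t(s), tolerance = 1e-8))) {
    stop("empirical covariance must be symmetric")
  }
  if (!(length(lam) == 1L && lam > 0)) stop("lam must be a positive scalar")
  s <- (s + t(s)) / 2
  fit <- glasso_cd(s, lam, as.integer(maxit_outer), as.integer(maxit_inner),
                   tol,
                   if (is.null(warm)) NULL else warm$W,
                   if (is.null(warm)) NULL else warm$B)
  if (!fit$converged) {
    stop(sprintf(
      "graphical lasso did not converge in %d sweeps at lam = %.4g (p = %d)",
      maxit_outer, lam, ncol(s)
    ))
  }
  theta <- fit$Theta
  dimnames(theta) <- dimnames(s)
  attr(theta, "W") <- fit$W
  attr(theta, "B") <- fit$B
  attr(theta, "iterations") <- fit$iterations
  attr(theta, "converged") <- fit$converged
  theta
}

default_lam_grid <- function(s, n_lambda) {
  max_off <- max(abs(s[upper.tri(s)]))
  if (max_off == 0) max_off <- max(diag(s)) * 1e-3 + 1e-12
  exp(seq(log(max_off), log(1e-3 * max_off), length.out = n_lambda))
}

#' Select the graphical-lasso penalty by extended BIC
#'
#' Fits a warm-started solution path over a log-spaced `lam` grid spanning
#' `[1e-3, 1] * max|off-diagonal of S|` and scores each fit with the extended
#' Bayesian information criterion
#' `EBIC = -n (log det Theta - tr(S Theta)) + k log(n) + 4 k gamma log(p)`,
#' where `k` counts nonzero upper-off-diagonal precision entries. If the
#' solver stops converging at the dense end of the path, the path is
#' truncated there with a warning. EBIC is conservative on weakly partially
#' correlated data and can select very sparse (even empty) networks; the
#' stability-based [glasso_select_stars()] is the default in the method
#' wrappers.
#'
#' @param empirical_cov symmetric empirical covariance.
#' @param n_samples number of samples behind the covariance.
#' @param lam_grid optional explicit penalty grid; overrides `n_lambda`.
#' @param n_lambda grid size (default 20).
#' @param gamma EBIC inflation parameter (default 0.5).
#' @param ... passed to [glasso_fit()].
#' @return list with `Theta` (best fit), `lambda`, `path` (data frame),
#'   `sparsity` (fraction of nonzero off-diagonal precision entries).
#' @export
glasso_select_ebic <- function(empirical_cov, n_samples, lam_grid = NULL,
                               n_lambda = 20L, gamma = 0.5, ...) {
  s <- (as.matrix(empirical_cov) + t(as.matrix(empirical_cov))) / 2
  p <- ncol(s)
  if (is.null(lam_grid)) {
    lam_grid <- default_lam_grid(s, n_lambda)
  } else {
    lam_grid <- sort(lam_grid, decreasing = TRUE)
  }
  best <- NULL
  warm <- NULL
  path <- data.frame(lambda = lam_grid, ebic = NA_real_, k = NA_integer_)
  for (i in seq_along(lam_grid)) {
    theta <- tryCatch(glasso_fit(s, lam_grid[i], warm = warm, ...),
                      error = function(e) e)
    if (inherits(theta, "error")) {
      warning(sprintf(
        "penalty path truncated at lam = %.4g: %s",
        lam_grid[i], conditionMessage(theta)
      ))
      break
    }
    warm <- list(W = attr(theta, "W"), B = attr(theta, "B"))
    k <- sum(theta[upper.tri(theta)] != 0)
    ld <- determinant(theta, logarithm = TRUE)
    loglik_term <- as.numeric(ld$modulus) - sum(s * theta)
    ebic <- -n_samples * loglik_term + k * log(n_samples) +
      4 * gamma * k * log(p)
    path$ebic[i] <- ebic
    path$k[i] <- k
    if (is.null(best) || ebic < best$ebic) {
      best <- list(Theta = theta, lambda = lam_grid[i], ebic = ebic, k = k)
    }
  }
  if (is.null(best)) stop("no penalty in the grid produced a converged fit")
  list(Theta = best$Theta, lambda = best$lambda, path = path,
       sparsity = best$k / (p * (p - 1) / 2))
}

#' Select the graphical-lasso penalty by StARS
#'
#' Stability approach to regularization selection: draws `n_subsamples`
#' subsamples without replacement of size `floor(10 * sqrt(n))` (capped at
#' `0.8 n`), fits a warm-started path over the descending `lam` grid in each,
#' and measures, per penalty, the total edge instability
#' `D(lam) = mean over pairs of 2 f (1 - f)` with `f` the across-subsample
#' selection frequency of the pair. `D` is monotonized along the path and the
#' densest penalty with monotonized instability at most `beta` is chosen; the
#' path stops descending once instability exceeds `beta`, so the expensive
#' dense fits are never computed. The returned fit is on the full data at the
#' chosen penalty.
#'
#' @param x data matrix (samples x taxa) whose covariance is being modelled;
#'   subsampling requires the data, not just the covariance.
#' @param lam_grid optional explicit penalty grid.
#' @param n_lambda grid size (default 20).
#' @param n_subsamples number of subsamples (default 20).
#' @param beta instability threshold (default 0.05).
#' @param seed integer seed for the subsample draws.
#' @param ... passed to [glasso_fit()].
#' @return list with `Theta`, `lambda`, `path` (lambda, instability, k on
#'   the full data), `sparsity`.
#' @export
glasso_select_stars <- function(x, lam_grid = NULL, n_lambda = 20L,
                                n_subsamples = 20L, beta = 0.05, seed = 0L,
                                ...) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  s_full <- stats::cov(x)
  if (is.null(lam_grid)) {
    lam_grid <- default_lam_grid(s_full, n_lambda)
  } else {
    lam_grid <- sort(lam_grid, decreasing = TRUE)
  }
  b <- min(floor(10 * sqrt(n)), floor(0.8 * n))
  b <- max(b, 2L)
  subs <- with_seed(seed, {
    lapply(seq_len(n_subsamples), function(i) sample.int(n, b))
  })
  s_subs <- lapply(subs, function(idx) stats::cov(x[idx, , drop = FALSE]))
  warms <- vector("list", n_subsamples)
  ut <- upper.tri(s_full)
  n_pairs <- sum(ut)
  d_bar <- 0
  chosen <- lam_grid[1L]
  path <- data.frame(lambda = lam_grid, instability = NA_real_)
  for (i in seq_along(lam_grid)) {
    freq <- numeric(n_pairs)
    ok <- TRUE
    for (k in seq_len(n_subsamples)) {
      theta <- tryCatch(
        glasso_fit(s_subs[[k]], lam_grid[i], warm = warms[[k]], ...),
        error = function(e) e
      )
      if (inherits(theta, "error")) {
        ok <- FALSE
        break
      }
      warms[[k]] <- list(W = attr(theta, "W"), B = attr(theta, "B"))
      freq <- freq + (theta[ut] != 0)
    }
    if (!ok) break # treat non-convergent penalties as past the stable range
    f <- freq / n_subsamples
    d <- mean(2 * f * (1 - f))
    d_bar <- max(d_bar, d) # monotonized instability
    path$instability[i] <- d_bar
    if (d_bar > beta) break
    chosen <- lam_grid[i]
  }
  theta <- glasso_fit(s_full, chosen, ...)
  k_full <- sum(theta[ut] != 0)
  list(Theta = theta, lambda = chosen, path = path,
       sparsity = k_full / n_pairs)
}

glasso_estimate <- function(x, method, selection, lam_grid, n_lambda, gamma,
                            n_subsamples, beta, seed, ...) {
  sel <- if (selection == "stars") {
    glasso_select_stars(x, lam_grid = lam_grid, n_lambda = n_lambda,
                        n_subsamples = n_subsamples, beta = beta,
                        seed = seed, ...)
  } else {
    glasso_select_ebic(stats::cov(x), nrow(x), lam_grid = lam_grid,
                       n_lambda = n_lambda, gamma = gamma, ...)
  }
  theta <- sel$Theta
  taxon_ids <- colnames(x)
  attributes(theta) <- attributes(theta)["dim"]
  est <- solve(theta)
  est <- (est + t(est)) / 2
  covariance_estimate(
    method, est, taxon_ids = taxon_ids,
    meta = list(lambda = sel$lambda, sparsity = sel$sparsity,
                selection = selection, precision = theta, path = sel$path)
  )
}

#' GLASSO-Mixed method
#'
#' Graphical lasso fitted to the empirical covariance of the mixed-CLR data
#' (CLR taken after concatenating the two tables), with the penalty chosen
#' by StARS stability selection (default) or extended BIC; the returned
#' estimate is the matrix inverse of the fitted precision, so all methods
#' are compared on the covariance scale. The fitted precision, chosen
#' penalty and selection path are kept in `meta`.
#'
#' @inheritParams log_covariance_method
#' @param selection `"stars"` (default) or `"ebic"`.
#' @param lam_grid optional explicit penalty grid.
#' @param n_lambda penalty-grid size (default 20).
#' @param gamma EBIC parameter (default 0.5; EBIC selection only).
#' @param n_subsamples,beta StARS parameters (StARS selection only).
#' @param seed integer seed for StARS subsampling.
#' @param ... passed to [glasso_fit()].
#' @return a [covariance_estimate()].
#' @export
glasso_mixed_method <- function(paired, pseudocount_value = 1,
                                selection = c("stars", "ebic"),
                                lam_grid = NULL, n_lambda = 20L,
                                gamma = 0.5, n_subsamples = 20L,
                                beta = 0.05, seed = 0L, ...) {
  selection <- match.arg(selection)
  check_samples(paired)
  bl <- prepare_blocks(paired, pseudocount_value)
  x <- clr(cbind(bl$a, bl$b))
  glasso_estimate(x, "glasso_mixed", selection, lam_grid, n_lambda, gamma,
                  n_subsamples, beta, seed, ...)
}

#' GLASSO-Split method
#'
#' As [glasso_mixed_method()], but the CLR transform is applied to each
#' kingdom's table separately before concatenation — the paired-data
#' correction — so the estimate inherits the split-CLR invariance to
#' per-sample, per-kingdom scale factors.
#'
#' @inheritParams glasso_mixed_method
#' @return a [covariance_estimate()].
#' @export
glasso_split_method <- function(paired, pseudocount_value = 1,
                                selection = c("stars", "ebic"),
                                lam_grid = NULL, n_lambda = 20L,
                                gamma = 0.5, n_subsamples = 20L,
                                beta = 0.05, seed = 0L, ...) {
  selection <- match.arg(selection)
  check_samples(paired)
  bl <- prepare_blocks(paired, pseudocount_value)
  x <- cbind(clr(bl$a), clr(bl$b))
  glasso_estimate(x, "glasso_split", selection, lam_grid, n_lambda, gamma,
                  n_subsamples, beta, seed, ...)
}
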