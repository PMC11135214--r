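#' Covariance estimate constructor
#'
#' The common output type of all reconstruction methods: a method-labelled
#' symmetric matrix over the concatenated taxon set, kingdom-A block first.
#'
#' @param method method label.
#' @param matrix symmetric numeric matrix.
#' @param taxon_ids taxon identifiers in A-then-B order.
#' @param meta free-form list of fit diagnostics.
#' @return object of class `covariance_estimate`.
#' @export
covariance_estimate <- function(method, matrix, taxon_ids = colnames(matrix),
                                meta = list()) {
  if (!isTRUE(all.equal(matrix, t(matrix), tolerance = 1e-8))) {
    stop("estimate must be symmetric within 1e-8")
  }
  matrix <- (matrix + t(matrix)) / 2
  if (!is.null(taxon_ids)) dimnames(matrix) <- list(taxon_ids, taxon_ids)
  structure(
    list(method = method, matrix = matrix, taxon_ids = taxon_ids, meta = meta),
    class = "covariance_estimate"
  )
}

#' @export
print.covariance_estimate <- function(x, ...) {
  cat(sprintf("<covariance_estimate> method = %s, %d x %d\n",
              x$method, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Add a pseudocount
#'
#' @param counts non-negative numeric matrix.
#' @param value positive pseudocount.
#' @return `counts + value`, entrywise.
#' @export
pseudocount <- function(counts, value = 1) {
  if (!(length(value) == 1L && is.finite(value) && value > 0)) {
    stop("pseudocount value must be a positive number")
  }
  counts + value
}

#' Centered log-ratio transform
#'
#' Row-wise CLR: `log(x) - mean(log(x))` within each row (samples in rows).
#' Invariant to multiplying a row by any positive constant, which is why it
#' removes a single compositional scale factor.
#'
#' @param rows strictly positive numeric matrix, samples x taxa.
#' @return matrix of the same shape; every row sums to zero.
#' @export
clr <- function(rows) {
  rows <- as.matrix(rows)
  if (any(rows <= 0)) stop("clr requires strictly positive entries")
  lg <- log(rows)
  lg - rowMeans(lg)
}

# shared plumbing: pseudocount (skipped when value = 0 and the data are
# already positive), returning the two blocks as positive matrices
prepare_blocks <- function(paired, pseudocount_value) {
  stopifnot(inherits(paired, "paired_counts"))
  a <- paired$counts_a
  b <- paired$counts_b
  if (pseudocount_value > 0) {
    a <- pseudocount(a, pseudocount_value)
    b <- pseudocount(b, pseudocount_value)
  } else if (any(a <= 0) || any(b <= 0)) {
    stop("pseudocount 0 requires strictly positive data")
  }
  list(a = a, b = b)
}

check_samples <- function(paired) {
  if (length(paired$sample_ids) < 2L) {
    stop("at least 2 samples are required to estimate a covariance")
  }
}

#' Log-covariance method
#'
#' Empirical covariance (divisor n - 1) of the log of the pseudocounted,
#' concatenated counts. The naive baseline: no compositional treatment at all.
#'
#' @param paired a [paired_counts()] object.
#' @param pseudocount_value pseudocount added before the log (default 1); 0
#'   skips the pseudocount for already-positive data.
#' @return a [covariance_estimate()].
#' @export
log_covariance_method <- function(paired, pseudocount_value = 1) {
  check_samples(paired)
  bl <- prepare_blocks(paired, pseudocount_value)
  x <- log(cbind(bl$a, bl$b))
  covariance_estimate("log_covariance", stats::cov(x))
}

#' CLR-Mixed method
#'
#' CLR transform applied to the concatenated pair of tables as if they were
#' one composition, then empirical covariance. Correct for a single
#' compositional data set; biased for paired data because the two kingdoms
#' carry unrelated scale factors.
#'
#' @inheritParams log_covariance_method
#' @return a [covariance_estimate()].
#' @export
clr_mixed_method <- function(paired, pseudocount_value = 1) {
  check_samples(paired)
  bl <- prepare_blocks(paired, pseudocount_value)
  covariance_estimate("clr_mixed", stats::cov(clr(cbind(bl$a, bl$b))))
}

#' CLR-Split method
#'
#' CLR transform applied to each kingdom's table separately, transformed rows
#' concatenated, then empirical covariance. The per-kingdom CLR cancels each
#' kingdom's own scale factor, which is the correction paired compositional
#' data require.
#'
#' @inheritParams log_covariance_method
#' @return a [covariance_estimate()].
#' @export
clr_split_method <- function(paired, pseudocount_value = 1) {
  check_samples(paired)
  bl <- prepare_blocks(paired, pseudocount_value)
  covariance_estimate("clr_split", stats::cov(cbind(clr(bl$a), clr(bl$b))))
}

#' Oracle log-covariance of absolute abundances
#'
#' Empirical covariance of the true log-abundances. Computable only in
#' simulation; serves as the upper-bound reference for all compositional
#' methods.
#'
#' @param abundances an `abundance_table`.
#' @param kingdom kingdom labels, used to order columns A-then-B.
#' @return a [covariance_estimate()] with method `oracle_log_covariance`.
#' @export
oracle_log_covariance <- function(abundances, kingdom) {
  stopifnot(inherits(abundances, "abundance_table"))
  ord <- c(which(kingdom == "A"), which(kingdom == "B"))
  covariance_estimate("oracle_log_covariance",
                      stats::cov(log(abundances$values[, ord, drop = FALSE])))
}

#' Cross-kingdom error decomposition
#'
#' For a kingdom-A taxon `a` and kingdom-B taxon `b`, decomposes the variance
#' of the absolute log-ratio into the relative-abundance term, the scale-ratio
#' term, and the cross-covariance term:
#' `Var[log(X_a/Y_b)] = Var[log(x_a/y_b)] + Var[log(q/r)] +
#'  2 Cov[log(q/r), log(x_a/y_b)]`.
#' The identity is algebraic and holds exactly on exact abundances; the
#' `Var[log(q/r)]` term is the error source specific to combining paired
#' compositional data sets.
#'
#' @param abundances an `abundance_table` (exact abundances; simulation only).
#' @param kingdom kingdom labels over `{"A", "B"}`.
#' @param taxon_a column index (into the full taxon set) of a kingdom-A taxon.
#' @param taxon_b column index of a kingdom-B taxon.
#' @return list of class `error_decomposition` with `var_lhs`,
#'   `var_ratio_term`, `var_scale_term`, `covar_cross_term`.
#' @export
error_decomposition <- function(abundances, kingdom, taxon_a, taxon_b) {
  stopifnot(inherits(abundances, "abundance_table"))
  if (kingdom[taxon_a] != "A") stop("taxon_a must belong to kingdom A")
  if (kingdom[taxon_b] != "B") stop("taxon_b must belong to kingdom B")
  sf <- true_scale_factors(abundances, kingdom)
  X <- abundances$values[, taxon_a]
  Y <- abundances$values[, taxon_b]
  x <- X / sf$q # within-kingdom relative abundances
  y <- Y / sf$r
  log_rel <- log(x / y)
  log_scale <- log(sf$q / sf$r)
  structure(
    list(
      var_lhs = stats::var(log(X / Y)),
      var_ratio_term = stats::var(log_rel),
      var_scale_term = stats::var(log_scale),
      covar_cross_term = 2 * stats::cov(log_scale, log_rel)
    ),
    class = "error_decomposition"
  )
}

#' Run all reconstruction methods on one paired data set
#'
#' Runs the six estimators (log-covariance, CLR-Mixed, CLR-Split, SparCC,
#' GLASSO-Mixed, GLASSO-Split) with a shared pseudocount, plus the oracle
#' log-covariance when exact abundances are supplied. A method failure is
#' recorded in the result (entry of class `method_failure`) rather than
#' aborting the batch.
#'
#' @param paired a [paired_counts()] object.
#' @param seed integer seed; each stochastic method gets a child seed.
#' @param pseudocount_value shared pseudocount (default 1).
#' @param sparcc_args list of overrides for [sparcc_method()].
#' @param glasso_args list of overrides for [glasso_mixed_method()] /
#'   [glasso_split_method()].
#' @param abundances optional `abundance_table` of exact abundances; adds the
#'   oracle estimate.
#' @param kingdom kingdom labels, required with `abundances`.
#' @return named list of [covariance_estimate()] objects in fixed order:
#'   log_covariance, clr_mixed, clr_split, sparcc, glasso_mixed, glasso_split
#'   (+ oracle_log_covariance).
#' @export
run_all_methods <- function(paired, seed, pseudocount_value = 1,
                            sparcc_args = list(), glasso_args = list(),
                            abundances = NULL, kingdom = NULL) {
  runs <- list(
    log_covariance = function() {
      log_covariance_method(paired, pseudocount_value)
    },
    clr_mixed = function() clr_mixed_method(paired, pseudocount_value),
    clr_split = function() clr_split_method(paired, pseudocount_value),
    sparcc = function() {
      do.call(sparcc_method,
              c(list(paired = paired, seed = child_seed(seed, 10L)),
                sparcc_args))
    },
    glasso_mixed = function() {
      do.call(glasso_mixed_method,
              c(list(paired = paired, pseudocount_value = pseudocount_value,
                     seed = child_seed(seed, 11L)),
                glasso_args))
    },
    glasso_split = function() {
      do.call(glasso_split_method,
              c(list(paired = paired, pseudocount_value = pseudocount_value,
                     seed = child_seed(seed, 12L)),
                glasso_args))
    }
  )
  out <- lapply(names(runs), function(nm) {
    tryCatch(runs[[nm]](), error = function(e) {
      structure(list(method = nm, message = conditionMessage(e)),
                class = "method_failure")
    })
  })
  names(out) <- names(runs)
  if (!is.null(abundances)) {
    if (is.null(kingdom)) stop("kingdom labels required with abundances")
    out$oracle_log_covariance <- oracle_log_covariance(abundances, kingdom)
  }
  out
}
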