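#' Draw exact absolute abundances from the ground truth
#'
#' Abundances are log-normal: log-abundance vectors are multivariate normal
#' with the model's mean vector and covariance. These are the hidden "true"
#' biomasses that a sequencing experiment never observes directly.
#'
#' @param model a [ground_truth_model()].
#' @param n_samples number of samples (>= 2).
#' @param seed integer seed.
#' @return an object of class `abundance_table`: list with `values`
#'   (n_samples x n_taxa positive matrix), `sample_ids`, `taxon_ids`.
#' @export
sample_absolute_abundances <- function(model, n_samples, seed) {
  validate_ground_truth_model(model)
  if (!is_count(n_samples) || n_samples < 2) {
    stop("n_samples must be an integer >= 2 (covariance needs two samples)")
  }
  n_samples <- as.integer(n_samples)
  logs <- with_seed(seed, {
    MASS::mvrnorm(n_samples, mu = model$mean_log, Sigma = model$covariance)
  })
  if (n_samples == 1L) logs <- matrix(logs, nrow = 1L)
  values <- exp(logs)
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  dimnames(values) <- list(sample_ids, model$taxon_ids)
  structure(
    list(values = values, sample_ids = sample_ids,
         taxon_ids = model$taxon_ids),
    class = "abundance_table"
  )
}

#' Paired count tables constructor
#'
#' The object real paired amplicon experiments observe: one count matrix per
#' kingdom (samples x taxa) over shared samples, with per-sample,
#' per-kingdom read depths. Row sums of each count matrix equal the
#' corresponding depths exactly.
#'
#' @param counts_a,counts_b non-negative integer matrices, samples x taxa.
#' @param sample_ids shared sample identifiers.
#' @return an object of class `paired_counts` with fields `counts_a`,
#'   `counts_b`, `depths_a`, `depths_b`, `sample_ids`, `taxon_ids_a`,
#'   `taxon_ids_b`.
#' @export
paired_counts <- function(counts_a, counts_b, sample_ids = NULL) {
  counts_a <- as.matrix(counts_a)
  counts_b <- as.matrix(counts_b)
  if (nrow(counts_a) != nrow(counts_b)) {
    stop("the two kingdoms must cover the same samples")
  }
  if (any(counts_a < 0) || any(counts_b < 0)) stop("negative counts")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(counts_a)
    if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(nrow(counts_a)))
  }
  rownames(counts_a) <- rownames(counts_b) <- sample_ids
  structure(
    list(counts_a = counts_a, counts_b = counts_b,
         depths_a = rowSums(counts_a), depths_b = rowSums(counts_b),
         sample_ids = sample_ids,
         taxon_ids_a = colnames(counts_a), taxon_ids_b = colnames(counts_b)),
    class = "paired_counts"
  )
}

#' @export
print.paired_counts <- function(x, ...) {
  cat(sprintf(
    "<paired_counts> %d samples; kingdom A: %d taxa (median depth %d); kingdom B: %d taxa (median depth %d)\n",
    length(x$sample_ids), ncol(x$counts_a), as.integer(stats::median(x$depths_a)),
    ncol(x$counts_b), as.integer(stats::median(x$depths_b))
  ))
  invisible(x)
}

#' Simulate paired sequencing reads
#'
#' For each sample and each kingdom independently, a read depth is drawn from
#' Normal(`depth_mean`, `depth_sd`), rounded to the nearest integer and
#' floored at `min_depth`; the sample's counts for that kingdom are then a
#' single multinomial draw of that size with probabilities proportional to
#' the within-kingdom absolute abundances. A single multinomial draw of size
#' R is distributionally identical to R independent categorical reads. The
#' two kingdoms of the same sample get independent depths, as in real
#' 16S/ITS libraries prepared separately.
#'
#' @param abundances an `abundance_table` from [sample_absolute_abundances()].
#' @param kingdom kingdom labels over `{"A", "B"}`, one per taxon column.
#' @param depth_mean mean read depth (default 100000).
#' @param depth_sd depth standard deviation (default 10000).
#' @param seed integer seed.
#' @param depth_multiplier optional multiplier on drawn depths (default 1) for
#'   studying low-depth, zero-heavy regimes.
#' @param min_depth floor applied to drawn depths (default 1000); roughly ten
#'   standard deviations below the default mean, so it essentially never binds
#'   but keeps the generator total.
#' @return a [paired_counts()] object.
#' @export
simulate_reads <- function(abundances, kingdom, depth_mean = 1e5,
                           depth_sd = 1e4, seed, depth_multiplier = 1,
                           min_depth = 1000L) {
  stopifnot(inherits(abundances, "abundance_table"))
  if (!(depth_mean > 0)) stop("depth_mean must be positive")
  vals <- abundances$values
  if (length(kingdom) != ncol(vals)) stop("one kingdom label per taxon")
  ia <- which(kingdom == "A")
  ib <- which(kingdom == "B")
  if (length(ia) == 0L || length(ib) == 0L) stop("both kingdoms must be non-empty")
  n <- nrow(vals)
  with_seed(seed, {
    draw_block <- function(cols) {
      depths <- pmax(round(stats::rnorm(n, depth_mean, depth_sd) *
                             depth_multiplier), min_depth)
      counts <- matrix(0L, n, length(cols),
                       dimnames = list(rownames(vals), colnames(vals)[cols]))
      for (i in seq_len(n)) {
        counts[i, ] <- stats::rmultinom(1L, depths[i], prob = vals[i, cols])
      }
      counts
    }
    counts_a <- draw_block(ia)
    counts_b <- draw_block(ib)
    paired_counts(counts_a, counts_b, sample_ids = rownames(vals))
  })
}

#' True per-sample scale factors
#'
#' The total within-kingdom biomass of each sample: `q` for kingdom A and `r`
#' for kingdom B. These are exactly the unknown factors that convert relative
#' abundances back to absolute ones; the variance of `log(q/r)` is what
#' drives the paired-data error. Available only in simulation — used by
#' diagnostics and tests, never by the inference methods.
#'
#' @param abundances an `abundance_table`.
#' @param kingdom kingdom labels over `{"A", "B"}`, one per taxon column.
#' @return list with numeric vectors `q` and `r`, one entry per sample.
#' @export
true_scale_factors <- function(abundances, kingdom) {
  stopifnot(inherits(abundances, "abundance_table"))
  ia <- kingdom == "A"
  ib <- kingdom == "B"
  if (!any(ia) || !any(ib)) stop("both kingdoms must be non-empty")
  list(
    q = rowSums(abundances$values[, ia, drop = FALSE]),
    r = rowSums(abundances$values[, ib, drop = FALSE])
  )
}
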