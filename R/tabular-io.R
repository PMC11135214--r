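#' Count table constructor
#'
#' A taxa x samples matrix of non-negative integer counts with unique taxon
#' and sample identifiers and a kingdom label for the whole table.
#'
#' @param counts taxa x samples integer matrix.
#' @param taxon_ids,sample_ids identifiers (default: dimnames).
#' @param kingdom kingdom label for the table (default `"A"`).
#' @return object of class `count_table`.
#' @export
count_table <- function(counts, taxon_ids = rownames(counts),
                        sample_ids = colnames(counts), kingdom = "A") {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (is.null(taxon_ids) || anyDuplicated(taxon_ids)) {
    stop("unique taxon identifiers are required")
  }
  if (is.null(sample_ids) || anyDuplicated(sample_ids)) {
    stop("unique sample identifiers are required")
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(taxon_ids, sample_ids)
  structure(
    list(counts = counts, taxon_ids = taxon_ids, sample_ids = sample_ids,
         kingdom = kingdom),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> kingdom %s: %d taxa x %d samples\n",
              x$kingdom, length(x$taxon_ids), length(x$sample_ids)))
  invisible(x)
}

#' Read a taxon-count table
#'
#' Supports the common OTU-table TSV dialect (taxa in rows, first header cell
#' `#OTU ID`, samples in columns) and dense BIOM-JSON (via the biomformat
#' package). Counts are validated as non-negative integers and identifiers as
#' unique; the result round-trips losslessly with [write_count_table()].
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"biom-json"`.
#' @param kingdom kingdom label to attach to the table.
#' @return a [count_table()].
#' @export
read_count_table <- function(path, dialect = c("tsv", "biom-json"),
                             kingdom = "A") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (dialect == "tsv") {
    header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    if (length(header) < 2L || header[1L] != "#OTU ID") {
      stop("TSV count tables must start with a '#OTU ID' header column")
    }
    df <- utils::read.delim(path, check.names = FALSE, comment.char = "",
                            colClasses = c("character"))
    sample_ids <- colnames(df)[-1L]
    taxon_ids <- df[[1L]]
    mat <- suppressWarnings(
      vapply(df[-1L], as.numeric, numeric(nrow(df)))
    )
    mat <- matrix(mat, nrow = nrow(df))
    bad <- which(is.na(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop(sprintf(
        "non-integer or negative count at taxon '%s', sample '%s'",
        taxon_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]
      ))
    }
    if (anyDuplicated(taxon_ids)) {
      stop(sprintf("duplicate taxon id '%s'",
                   taxon_ids[duplicated(taxon_ids)][1L]))
    }
    if (anyDuplicated(sample_ids)) {
      stop(sprintf("duplicate sample id '%s'",
                   sample_ids[duplicated(sample_ids)][1L]))
    }
    dimnames(mat) <- list(taxon_ids, sample_ids)
    count_table(mat, kingdom = kingdom)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("the biomformat package is required for the biom-json dialect")
    }
    b <- biomformat::read_biom(path)
    mat <- as.matrix(biomformat::biom_data(b))
    count_table(mat, kingdom = kingdom)
  }
}

#' Write a taxon-count table
#'
#' @param table a [count_table()].
#' @param path output path.
#' @param dialect `"tsv"` or `"biom-json"`.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path, dialect = c("tsv", "biom-json")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "count_table"))
  if (dialect == "tsv") {
    df <- data.frame(table$counts, check.names = FALSE)
    df <- cbind(stats::setNames(data.frame(table$taxon_ids), "#OTU ID"), df)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("the biomformat package is required for the biom-json dialect")
    }
    b <- biomformat::make_biom(table$counts)
    biomformat::write_biom(b, path)
  }
  invisible(path)
}

#' Pair two count tables over their shared samples
#'
#' Restricts both tables to the intersection of their sample identifiers (in
#' the order of table A) and returns the samples x taxa paired object the
#' inference methods consume. Unmatched samples are reported via a message
#' and recorded in the result.
#'
#' @param table_a,table_b [count_table()] objects for kingdoms A and B.
#' @return a [paired_counts()] object with an extra `dropped` field listing
#'   unmatched sample ids per table.
#' @export
match_samples <- function(table_a, table_b) {
  stopifnot(inherits(table_a, "count_table"), inherits(table_b, "count_table"))
  shared <- intersect(table_a$sample_ids, table_b$sample_ids)
  if (length(shared) < 2L) {
    stop("fewer than 2 shared samples between the two tables")
  }
  dropped <- list(a = setdiff(table_a$sample_ids, shared),
                  b = setdiff(table_b$sample_ids, shared))
  if (length(dropped$a) + length(dropped$b) > 0L) {
    message(sprintf("dropping %d unmatched samples from A, %d from B",
                    length(dropped$a), length(dropped$b)))
  }
  pc <- paired_counts(t(table_a$counts[, shared, drop = FALSE]),
                      t(table_b$counts[, shared, drop = FALSE]),
                      sample_ids = shared)
  pc$dropped <- dropped
  pc
}

#' Keep the most abundant taxa of a table
#'
#' Ranks taxa by mean within-sample relative abundance (each sample's counts
#' divided by its total first, so deep libraries do not dominate) and keeps
#' the top `ceiling(top_fraction * n_taxa)`, with ties broken by taxon id.
#' Idempotent at the same fraction.
#'
#' @param table a [count_table()].
#' @param top_fraction fraction of taxa to keep, in (0, 1\].
#' @return a [count_table()] restricted to the kept taxa (original row order).
#' @export
filter_top_taxa <- function(table, top_fraction) {
  stopifnot(inherits(table, "count_table"))
  if (!(top_fraction > 0 && top_fraction <= 1)) {
    stop("top_fraction must lie in (0, 1]")
  }
  n_keep <- ceiling(top_fraction * length(table$taxon_ids))
  if (n_keep < 1L) stop("top_fraction keeps zero taxa")
  totals <- colSums(table$counts)
  totals[totals == 0] <- 1 # empty samples contribute zero everywhere
  rel <- sweep(table$counts, 2L, totals, "/")
  score <- rowMeans(rel)
  ord <- order(-score, table$taxon_ids)
  keep <- sort(ord[seq_len(n_keep)])
  count_table(table$counts[keep, , drop = FALSE], kingdom = table$kingdom)
}

#' Write / read a covariance estimate as TSV + JSON sidecar
#'
#' The matrix is written as a square TSV with taxon identifiers; scalar meta
#' entries (chosen penalty, sparsity, resample counts) go to a JSON sidecar
#' `<path>.meta.json`.
#'
#' @param estimate a [covariance_estimate()].
#' @param path output TSV path.
#' @return `path` invisibly; `read_estimate` returns a
#'   [covariance_estimate()].
#' @export
write_estimate <- function(estimate, path) {
  stopifnot(inherits(estimate, "covariance_estimate"))
  ids <- estimate$taxon_ids
  if (is.null(ids)) ids <- sprintf("T%04d", seq_len(ncol(estimate$matrix)))
  df <- data.frame(taxon_id = ids, estimate$matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- Filter(function(x) is.atomic(x) && length(x) == 1L, estimate$meta)
  jsonlite::write_json(c(list(method = estimate$method), meta),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_estimate
#' @param path input TSV path (the `.meta.json` sidecar is read if present).
#' @export
read_estimate <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  ids <- df$taxon_id
  m <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(m) <- list(ids, ids)
  meta_path <- paste0(path, ".meta.json")
  meta <- list()
  method <- "unknown"
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    method <- meta$method
    meta$method <- NULL
  }
  covariance_estimate(method, m, taxon_ids = ids, meta = meta)
}

#' Write / read paired count tables
#'
#' One OTU-table TSV per kingdom plus a per-sample depth TSV, mirroring how
#' real paired 16S/ITS data arrive. Reading back and re-pairing reproduces
#' the original object exactly.
#'
#' @param paired a [paired_counts()] object.
#' @param dir output directory.
#' @return `dir` invisibly; `read_paired_counts` returns a
#'   [paired_counts()].
#' @export
write_paired_counts <- function(paired, dir) {
  stopifnot(inherits(paired, "paired_counts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ta <- count_table(t(paired$counts_a), kingdom = "A")
  tb <- count_table(t(paired$counts_b), kingdom = "B")
  write_count_table(ta, file.path(dir, "counts_A.tsv"))
  write_count_table(tb, file.path(dir, "counts_B.tsv"))
  utils::write.table(
    data.frame(sample_id = paired$sample_ids, depth_a = paired$depths_a,
               depth_b = paired$depths_b),
    file.path(dir, "depths.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}

#' @rdname write_paired_counts
#' @export
read_paired_counts <- function(dir) {
  ta <- read_count_table(file.path(dir, "counts_A.tsv"), kingdom = "A")
  tb <- read_count_table(file.path(dir, "counts_B.tsv"), kingdom = "B")
  match_samples(ta, tb)
}
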