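#' Experiment configuration
#'
#' Collects every knob of the simulation benchmark. The defaults reproduce
#' the reference experimental setup: 500 taxa, 75/150/300 samples, 15 trials
#' for edge metrics and 20 for hub metrics, read depth Normal(100000, 10000),
#' mean log-abundances uniform on (-4, 4), and the neutral structure variant.
#'
#' @param n_taxa total taxa (default 500).
#' @param sample_sizes sample counts to benchmark (default c(75, 150, 300)).
#' @param n_trials_edges independent data sets per sample size for edge
#'   metrics (default 15).
#' @param n_trials_hubs trials for hub metrics (default 20); used when
#'   `eval_hubs` is TRUE.
#' @param depth_mean,depth_sd read-depth distribution (default 1e5, 1e4).
#' @param mean_log_range mean log-abundance interval (default c(-4, 4)).
#' @param variant a [structure_variant()].
#' @param density_param,closure_prob,fraction_a,magnitude_range,eps ground
#'   truth generator settings, see [ground_truth_model()].
#' @param pseudocount_value shared pseudocount for log-based methods.
#' @param sparcc_args,glasso_args method parameter overrides.
#' @param methods which estimators to run, a subset of
#'   `c("log_covariance", "clr_mixed", "clr_split", "sparcc",
#'   "glasso_mixed", "glasso_split")`.
#' @param top_edge_fraction edge fraction for thresholded networks (default
#'   0.10).
#' @param topn_values N grid for top-N accuracy.
#' @param strong_fraction strongest-true-edge fraction for the restricted
#'   AUC (default 0.25).
#' @param eval_hubs,eval_communities evaluate hub and community metrics
#'   (default FALSE; edge metrics are always computed).
#' @param master_seed master integer seed.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(n_taxa = 500L,
                              sample_sizes = c(75L, 150L, 300L),
                              n_trials_edges = 15L,
                              n_trials_hubs = 20L,
                              depth_mean = 1e5, depth_sd = 1e4,
                              mean_log_range = c(-4, 4),
                              variant = structure_variant(),
                              density_param = 2L, closure_prob = 0.1,
                              fraction_a = 0.5,
                              magnitude_range = c(0.2, 1.0), eps = 0.01,
                              pseudocount_value = 1,
                              sparcc_args = list(), glasso_args = list(),
                              methods = c("log_covariance", "clr_mixed",
                                          "clr_split", "sparcc",
                                          "glasso_mixed", "glasso_split"),
                              top_edge_fraction = 0.10,
                              topn_values = c(10L, 25L, 50L, 100L),
                              strong_fraction = 0.25,
                              eval_hubs = FALSE, eval_communities = FALSE,
                              master_seed = 1L) {
  stopifnot(n_taxa >= 4, all(sample_sizes >= 2), n_trials_edges >= 1,
            depth_mean > 0, top_edge_fraction > 0, top_edge_fraction <= 1)
  structure(
    list(n_taxa = as.integer(n_taxa),
         sample_sizes = as.integer(sample_sizes),
         n_trials_edges = as.integer(n_trials_edges),
         n_trials_hubs = as.integer(n_trials_hubs),
         depth_mean = depth_mean, depth_sd = depth_sd,
         mean_log_range = mean_log_range, variant = variant,
         density_param = density_param, closure_prob = closure_prob,
         fraction_a = fraction_a, magnitude_range = magnitude_range,
         eps = eps, pseudocount_value = pseudocount_value,
         sparcc_args = sparcc_args, glasso_args = glasso_args,
         methods = methods, top_edge_fraction = top_edge_fraction,
         topn_values = as.integer(topn_values),
         strong_fraction = strong_fraction,
         eval_hubs = eval_hubs, eval_communities = eval_communities,
         master_seed = as.integer(master_seed)),
    class = "experiment_config"
  )
}

# one edge-evaluation record (a single-row data frame)
edge_record <- function(method, est_matrix, truth, kingdom, config) {
  parts <- edge_partition(est_matrix, kingdom)
  mr <- mean_relative_edge_strength(est_matrix, kingdom)
  topn_ok <- config$topn_values[config$topn_values <=
                                  length(pair_index(kingdom, "cross"))]
  topn <- top_n_accuracy(truth, est_matrix, topn_ok)
  row <- data.frame(
    method = method,
    mean_rel_intra = mr$mean_rel_intra,
    mean_rel_cross = mr$mean_rel_cross,
    bias_p_value = bias_test(parts$intra, parts$cross),
    r2_all = edge_r2(truth, est_matrix),
    r2_cross = edge_r2(truth, est_matrix, kingdom, "cross"),
    auc_all = edge_auc(truth, est_matrix),
    auc_cross = edge_auc(truth, est_matrix, kingdom, "cross"),
    auc_strong = edge_auc(truth, est_matrix,
                          strong_fraction = config$strong_fraction)
  )
  for (nm in names(topn)) row[[paste0("topn_", nm)]] <- topn[[nm]]
  row
}

node_record <- function(method, est_matrix, truth_scores, config, seed) {
  g <- threshold_network(est_matrix, config$top_edge_fraction)
  out <- data.frame(method = method)
  for (metric in c("betweenness", "degree", "eigenvector")) {
    out[[paste0("r2_", metric)]] <-
      hub_r2(truth_scores[[metric]], hub_scores(g, metric))
  }
  ks <- lv_keystoneness(est_matrix)
  out$r2_lv_keystoneness <- hub_r2(truth_scores$lv_keystoneness, ks)
  out
}

community_record <- function(method, est_matrix, truth_partition, config,
                             seed) {
  g <- threshold_network(est_matrix, config$top_edge_fraction)
  cs <- community_scores(detect_communities(g, seed), truth_partition)
  data.frame(method = method,
             mean_overlap = mean(cs$overlap_scores),
             mean_inclusion = mean(cs$inclusion_scores))
}

#' Run the full simulation benchmark
#'
#' For every (sample size, trial) cell: generates a fresh ground truth,
#' draws exact abundances and paired reads, runs the configured estimators
#' plus the absolute-abundance oracle and the ground truth itself, and scores
#' every estimate on the edge metrics (bias signature, R-squared, AUC, top-N
#' accuracy). Hub and community metrics are added when enabled in the
#' config. Method failures are recorded per (trial, method) and excluded
#' from aggregates. Fully deterministic given the config's master seed.
#'
#' @param config an [experiment_config()].
#' @param progress print per-trial progress (default FALSE).
#' @return list of class `benchmark_report` with `edge_records`,
#'   `node_records`, `community_records`, `failures`, `aggregates`,
#'   `comparisons`, `config`.
#' @export
run_benchmark <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  edge_records <- list()
  node_records <- list()
  community_records <- list()
  failures <- list()
  cell <- 0L
  for (s in config$sample_sizes) {
    for (trial in seq_len(config$n_trials_edges)) {
      cell <- cell + 1L
      seed <- child_seed(config$master_seed, cell)
      if (progress) {
        message(sprintf("sample size %d, trial %d", s, trial))
      }
      model <- ground_truth_model(
        n_taxa = config$n_taxa, density_param = config$density_param,
        closure_prob = config$closure_prob, fraction_a = config$fraction_a,
        variant = config$variant, magnitude_range = config$magnitude_range,
        mean_log_range = config$mean_log_range, eps = config$eps,
        seed = child_seed(seed, 100L)
      )
      abund <- sample_absolute_abundances(model, s,
                                          seed = child_seed(seed, 101L))
      paired <- simulate_reads(abund, model$kingdom,
                               depth_mean = config$depth_mean,
                               depth_sd = config$depth_sd,
                               seed = child_seed(seed, 102L))
      ests <- run_all_methods(paired, seed = child_seed(seed, 103L),
                              pseudocount_value = config$pseudocount_value,
                              sparcc_args = config$sparcc_args,
                              glasso_args = config$glasso_args,
                              abundances = abund, kingdom = model$kingdom)
      ests <- ests[c(intersect(names(ests), config$methods),
                     "oracle_log_covariance")]
      # kingdom order of estimates is A-then-B; reorder truth to match
      ord <- c(which(model$kingdom == "A"), which(model$kingdom == "B"))
      truth <- model$covariance[ord, ord]
      kingdom_ord <- model$kingdom[ord]
      matrices <- c(list(truth = truth),
                    lapply(ests, function(e) {
                      if (inherits(e, "covariance_estimate")) e$matrix else e
                    }))
      truth_scores <- NULL
      truth_partition <- NULL
      if (config$eval_hubs) {
        gt <- threshold_network(truth, config$top_edge_fraction)
        truth_scores <- list(
          betweenness = hub_scores(gt, "betweenness"),
          degree = hub_scores(gt, "degree"),
          eigenvector = hub_scores(gt, "eigenvector"),
          lv_keystoneness = lv_keystoneness(truth)
        )
      }
      if (config$eval_communities) {
        gt <- threshold_network(truth, config$top_edge_fraction)
        truth_partition <- detect_communities(gt, child_seed(seed, 104L))
      }
      for (nm in names(matrices)) {
        m <- matrices[[nm]]
        if (inherits(ests[[nm]], "method_failure")) {
          failures[[length(failures) + 1L]] <- data.frame(
            sample_size = s, trial = trial, method = nm,
            message = ests[[nm]]$message
          )
          next
        }
        rec <- tryCatch(
          edge_record(nm, m, truth, kingdom_ord, config),
          error = function(e) e
        )
        if (inherits(rec, "error")) {
          failures[[length(failures) + 1L]] <- data.frame(
            sample_size = s, trial = trial, method = nm,
            message = conditionMessage(rec)
          )
          next
        }
        rec <- cbind(data.frame(sample_size = s, trial = trial), rec)
        edge_records[[length(edge_records) + 1L]] <- rec
        if (config$eval_hubs && nm != "truth") {
          nr <- node_record(nm, m, truth_scores, config,
                            child_seed(seed, 105L))
          node_records[[length(node_records) + 1L]] <-
            cbind(data.frame(sample_size = s, trial = trial), nr)
        }
        if (config$eval_communities && nm != "truth") {
          cr <- community_record(nm, m, truth_partition, config,
                                 child_seed(seed, 106L))
          community_records[[length(community_records) + 1L]] <-
            cbind(data.frame(sample_size = s, trial = trial), cr)
        }
      }
    }
  }
  edge_records <- do.call(rbind, edge_records)
  report <- structure(
    list(
      edge_records = edge_records,
      node_records = if (length(node_records)) do.call(rbind, node_records),
      community_records = if (length(community_records)) {
        do.call(rbind, community_records)
      },
      failures = if (length(failures)) do.call(rbind, failures),
      aggregates = aggregate_records(edge_records),
      comparisons = NULL,
      config = config
    ),
    class = "benchmark_report"
  )
  if ("clr_split" %in% edge_records$method) {
    report$comparisons <- tryCatch(
      compare_methods(edge_records, "clr_split", "r2_all"),
      error = function(e) NULL
    )
  }
  report
}

# mean and sd of every metric per (method, sample size)
aggregate_records <- function(records) {
  metrics <- setdiff(names(records),
                     c("sample_size", "trial", "method", "message"))
  agg <- stats::aggregate(
    records[metrics],
    by = list(method = records$method, sample_size = records$sample_size),
    FUN = function(x) c(mean = mean(x), sd = stats::sd(x))
  )
  out <- agg[c("method", "sample_size")]
  for (m in metrics) {
    out[[paste0(m, "_mean")]] <- agg[[m]][, "mean"]
    out[[paste0(m, "_sd")]] <- agg[[m]][, "sd"]
  }
  out
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf(
    "<benchmark_report> %d edge records (%d methods x %d sample sizes), %d failures\n",
    nrow(x$edge_records), length(unique(x$edge_records$method)),
    length(unique(x$edge_records$sample_size)),
    if (is.null(x$failures)) 0L else nrow(x$failures)
  ))
  invisible(x)
}

#' Compare methods against a reference method
#'
#' Two-sided Mann-Whitney U test between the reference method's metric
#' values and each other method's, across trials.
#'
#' @param records edge-record data frame from [run_benchmark()].
#' @param reference_method the reference (typically `"clr_split"`).
#' @param metric metric column name (e.g. `"r2_all"`).
#' @return data frame of methods and p-values.
#' @export
compare_methods <- function(records, reference_method = "clr_split",
                            metric = "r2_all") {
  if (!metric %in% names(records)) stop(sprintf("unknown metric '%s'", metric))
  counts <- table(records$method)
  if (any(counts < 3L)) {
    stop("at least 3 records per method are required")
  }
  ref <- records[[metric]][records$method == reference_method]
  if (length(ref) == 0L) stop("reference method has no records")
  others <- setdiff(unique(records$method), reference_method)
  data.frame(
    method = others,
    p_value = vapply(others, function(m) {
      stats::wilcox.test(ref, records[[metric]][records$method == m],
                         exact = FALSE)$p.value
    }, numeric(1))
  )
}

#' Serialize a benchmark report
#'
#' Per-trial records as JSON-lines, aggregates and comparisons as TSV, and a
#' reproducibility manifest (config, seed, package version) as JSON.
#'
#' @param report a `benchmark_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_benchmark_report <- function(report, dir) {
  stopifnot(inherits(report, "benchmark_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_jsonl <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(df))) {
      writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE,
                                  digits = NA), con)
    }
  }
  write_jsonl(report$edge_records, file.path(dir, "edge_records.jsonl"))
  if (!is.null(report$node_records)) {
    write_jsonl(report$node_records, file.path(dir, "node_records.jsonl"))
  }
  if (!is.null(report$community_records)) {
    write_jsonl(report$community_records,
                file.path(dir, "community_records.jsonl"))
  }
  utils::write.table(report$aggregates, file.path(dir, "aggregates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$comparisons)) {
    utils::write.table(report$comparisons, file.path(dir, "comparisons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- report$config
  cfg$variant <- unclass(cfg$variant)
  manifest <- list(config = unclass(cfg),
                   package_version =
                     as.character(utils::packageVersion("tknet")),
                   r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the six methods and the bias diagnostic on real paired tables
#'
#' Reads two taxon-count tables (one per kingdom), keeps the most abundant
#' taxa of each, pairs the shared samples, runs the six estimators, and
#' computes the bias signature: mean relative intra- and cross-kingdom edge
#' strength and Mann-Whitney p-values comparing edge-strength distributions
#' (intra-A vs cross, intra-B vs cross, and pooled intra vs cross) for each
#' method, plus the thresholded networks.
#'
#' @param table_a_path,table_b_path count-table paths (kingdoms A and B,
#'   e.g. 16S and ITS).
#' @param top_fraction_a,top_fraction_b abundance-filter fractions per
#'   kingdom (default 1 = keep everything).
#' @param dialect table dialect, see [read_count_table()].
#' @param seed integer seed (SparCC resampling).
#' @param config an [experiment_config()] supplying method parameters.
#' @return list of class `real_data_report` with `paired`, `estimates`,
#'   `bias` (per-method data frame), `networks`.
#' @export
run_real_data <- function(table_a_path, table_b_path,
                          top_fraction_a = 1, top_fraction_b = 1,
                          dialect = "tsv", seed = 1L,
                          config = experiment_config()) {
  ta <- read_count_table(table_a_path, dialect, kingdom = "A")
  tb <- read_count_table(table_b_path, dialect, kingdom = "B")
  if (top_fraction_a < 1) ta <- filter_top_taxa(ta, top_fraction_a)
  if (top_fraction_b < 1) tb <- filter_top_taxa(tb, top_fraction_b)
  paired <- match_samples(ta, tb)
  ests <- run_all_methods(paired, seed = seed,
                          pseudocount_value = config$pseudocount_value,
                          sparcc_args = config$sparcc_args,
                          glasso_args = config$glasso_args)
  kingdom <- c(rep("A", ncol(paired$counts_a)),
               rep("B", ncol(paired$counts_b)))
  n_a <- ncol(paired$counts_a)
  bias <- list()
  networks <- list()
  for (nm in names(ests)) {
    e <- ests[[nm]]
    if (inherits(e, "method_failure")) next
    m <- e$matrix
    parts <- edge_partition(m, kingdom)
    # per-block intra values for the per-group tests
    ia <- edge_partition(m[seq_len(n_a), seq_len(n_a)],
                         rep("A", n_a))$intra
    ib <- edge_partition(m[-seq_len(n_a), -seq_len(n_a)],
                         rep("B", ncol(m) - n_a))$intra
    # a fully sparsified estimate has no edge strengths to compare
    mr <- tryCatch(mean_relative_edge_strength(m, kingdom),
                   error = function(e) list(mean_rel_intra = NA_real_,
                                            mean_rel_cross = NA_real_))
    bias[[nm]] <- data.frame(
      method = nm,
      mean_rel_intra = mr$mean_rel_intra,
      mean_rel_cross = mr$mean_rel_cross,
      p_intra_a_vs_cross = bias_test(ia, parts$cross),
      p_intra_b_vs_cross = bias_test(ib, parts$cross),
      p_pooled = bias_test(parts$intra, parts$cross)
    )
    networks[[nm]] <- threshold_network(m, config$top_edge_fraction)
  }
  structure(
    list(paired = paired, estimates = ests,
         bias = do.call(rbind, bias), networks = networks,
         kingdom = kingdom),
    class = "real_data_report"
  )
}
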