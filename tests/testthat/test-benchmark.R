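small_config <- function(...) {
  experiment_config(n_taxa = 24, sample_sizes = 20, n_trials_edges = 1,
                    methods = c("clr_mixed", "clr_split"),
                    topn_values = c(5L, 10L), master_seed = 7, ...)
}

test_that("benchmark bookkeeping: one record per method per trial plus references", {
  rep <- run_benchmark(small_config())
  # 2 methods + ground truth + absolute-abundance oracle
  expect_equal(nrow(rep$edge_records), 4)
  expect_setequal(rep$edge_records$method,
                  c("truth", "oracle_log_covariance", "clr_mixed",
                    "clr_split"))
  expect_true(all(rep$edge_records$auc_all >= 0 &
                    rep$edge_records$auc_all <= 1))
  expect_true(all(rep$edge_records$topn_5 >= 0 &
                    rep$edge_records$topn_5 <= 1))
  expect_null(rep$failures)
})

test_that("benchmark reports are bit-reproducible from the master seed", {
  r1 <- run_benchmark(small_config())
  r2 <- run_benchmark(small_config())
  expect_identical(r1$edge_records, r2$edge_records)
  expect_identical(r1$aggregates, r2$aggregates)
})

test_that("aggregates are recomputable from the per-trial records", {
  cfg <- small_config()
  cfg$n_trials_edges <- 3L
  rep <- run_benchmark(cfg)
  agg <- rep$aggregates
  for (m in unique(rep$edge_records$method)) {
    rows <- rep$edge_records[rep$edge_records$method == m, ]
    expect_equal(agg$r2_all_mean[agg$method == m], mean(rows$r2_all))
    expect_equal(agg$r2_all_sd[agg$method == m], sd(rows$r2_all))
  }
})

test_that("hub and community evaluation attach when enabled", {
  cfg <- small_config(eval_hubs = TRUE, eval_communities = TRUE)
  rep <- run_benchmark(cfg)
  expect_equal(nrow(rep$node_records), 3) # oracle + 2 methods
  expect_true(all(c("r2_betweenness", "r2_degree", "r2_eigenvector",
                    "r2_lv_keystoneness") %in% names(rep$node_records)))
  expect_equal(nrow(rep$community_records), 3)
  expect_true(all(rep$community_records$mean_overlap >= 0 &
                    rep$community_records$mean_overlap <= 1))
})

test_that("method comparison uses Mann-Whitney across trials", {
  rec <- data.frame(
    method = rep(c("clr_split", "clr_mixed", "sparcc"), each = 10),
    r2_all = c(rnorm(10, 0.5, 0.01), rnorm(10, 0.5, 0.01), runif(10, 0.9, 1))
  )
  cmp <- compare_methods(rec, "clr_split", "r2_all")
  expect_lt(cmp$p_value[cmp$method == "sparcc"], 1e-3)
  same <- data.frame(method = rep(c("clr_split", "clr_mixed"), each = 10),
                     r2_all = rep(1:10, 2))
  expect_gt(compare_methods(same, "clr_split", "r2_all")$p_value, 0.9)
  tiny <- data.frame(method = rep(c("clr_split", "clr_mixed"), each = 2),
                     r2_all = rep(1:2, 2))
  expect_error(compare_methods(tiny, "clr_split", "r2_all"), "3 records")
})

test_that("benchmark reports serialize to JSON-lines and TSV", {
  rep <- run_benchmark(small_config())
  dir <- withr::local_tempdir()
  write_benchmark_report(rep, dir)
  lines <- readLines(file.path(dir, "edge_records.jsonl"))
  expect_length(lines, nrow(rep$edge_records))
  first <- jsonlite::fromJSON(lines[1])
  expect_equal(first$r2_all, rep$edge_records$r2_all[1], tolerance = 1e-12)
  agg <- read.delim(file.path(dir, "aggregates.tsv"))
  expect_equal(nrow(agg), nrow(rep$aggregates))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$config$n_taxa, 24)
})

test_that("the real-data runner reproduces the in-memory metrics exactly", {
  sim <- small_sim(n_taxa = 12, n_samples = 15, seed = 131)
  dir <- withr::local_tempdir()
  write_paired_counts(sim$paired, dir)
  cfg <- experiment_config(n_taxa = 12, master_seed = 1)
  res <- run_real_data(file.path(dir, "counts_A.tsv"),
                       file.path(dir, "counts_B.tsv"),
                       seed = 17, config = cfg)
  ests <- run_all_methods(sim$paired, seed = 17,
                          pseudocount_value = cfg$pseudocount_value)
  for (nm in rownames(res$bias)) {
    expect_equal(res$estimates[[nm]]$matrix, ests[[nm]]$matrix,
                 tolerance = 1e-12)
  }
  kingdom <- c(rep("A", 6), rep("B", 6))
  mr <- mean_relative_edge_strength(ests$clr_mixed, kingdom)
  expect_equal(res$bias$mean_rel_intra[res$bias$method == "clr_mixed"],
               mr$mean_rel_intra)
  expect_error(run_real_data(file.path(dir, "missing.tsv"),
                             file.path(dir, "counts_B.tsv")),
               "not found")
})

test_that("strong biomass-ratio variation flags only uncorrected methods", {
  # signature flag: significant intra-vs-cross shift in the positive-intra,
  # negative-cross direction
  flagged <- function(est, kingdom) {
    parts <- edge_partition(est$matrix, kingdom)
    mr <- mean_relative_edge_strength(est$matrix, kingdom)
    bias_test(parts$intra, parts$cross) < 0.05 &&
      mr$mean_rel_intra > mr$mean_rel_cross
  }
  unc_hits <- 0L
  split_hits <- 0L
  n_seeds <- 5L
  for (s in seq_len(n_seeds)) {
    sim <- small_sim(n_taxa = 30, n_samples = 60, seed = 140 + s)
    # amplify the biomass-ratio error: per-sample kingdom scale factors with
    # SD 1 in log space
    set.seed(s)
    vals <- sim$abund$values
    ia <- which(sim$model$kingdom == "A")
    vals[, ia] <- vals[, ia] * exp(rnorm(nrow(vals), 0, 1))
    pc <- simulate_reads(manual_abundances(vals), sim$model$kingdom,
                         seed = 150 + s)
    kingdom <- c(rep("A", length(ia)), rep("B", 30 - length(ia)))
    unc_hits <- unc_hits + flagged(clr_mixed_method(pc), kingdom)
    split_hits <- split_hits + flagged(clr_split_method(pc), kingdom)
  }
  expect_equal(unc_hits, n_seeds)
  expect_lt(split_hits, n_seeds)
})

test_that("corrected methods' bias magnitude stays below the uncorrected intra shift", {
  rec <- bias_run_default()$edge_records
  intra_shift <- mean(vapply(uncorrected_methods, function(m) {
    mean(rec$mean_rel_intra[rec$method == m])
  }, numeric(1)))
  expect_gt(intra_shift, 0)
  for (m in c(corrected_methods, "truth")) {
    rows <- rec[rec$method == m, ]
    expect_lt(mean(abs(rows$mean_rel_intra)), intra_shift)
    expect_lt(mean(abs(rows$mean_rel_cross)), intra_shift)
  }
})

test_that("a negatively biased cross-kingdom truth favours the uncorrected methods", {
  # when most cross-kingdom edges are truly negative, the concatenation
  # artifact happens to point the right way and uncorrected methods gain
  rec_d <- bias_run_default()$edge_records
  rec_n <- bias_run_negative_cross()$edge_records
  mean_r2 <- function(rec, m) mean(rec$r2_all[rec$method == m])
  for (m in uncorrected_methods) {
    expect_gt(mean_r2(rec_n, m), mean_r2(rec_d, m))
  }
})
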