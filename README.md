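# tknet

Covariance-network inference from **paired compositional data**, and a
simulation benchmark for it.

## The problem

Transkingdom microbiome studies sequence the same samples twice: 16S rRNA
amplicons for bacteria, ITS amplicons for fungi. Each assay yields relative
abundances within its own kingdom, so sample *i* provides
`x^i` (bacteria) and `y^i` (fungi) whose true abundances are `q^i x^i` and
`r^i y^i` with unknown, sample-varying totals `q^i`, `r^i`. For two taxa in
the *same* kingdom, log-ratio methods are safe:

```
Var[log(X_a/X_b)] = Var[log(x_a/x_b)]
```

Across kingdoms the scale factors do not cancel:

```
Var[log(X_a/Y_b)] = Var[log(x_a/y_b)] + Var[log(q/r)]
                    + 2 Cov[log(q/r), log(x_a/y_b)]
```

so naively concatenating the two tables injects an error governed by
`Var[log(q/r)]`, the variance of the bacteria-to-fungi biomass ratio. In
inferred networks it appears as a characteristic *bias signature*:
intra-kingdom edges shifted positive and (for shared-centering methods)
cross-kingdom edges shifted negative. The fix is to apply the centered
log-ratio (CLR) transform to each kingdom **separately** before
concatenating.

`tknet` is for researchers who build co-occurrence networks from paired
OTU tables and want to know how much this error matters for their use case.
It provides:

* a synthetic-community generator with a known ground-truth network
  (power-law graph, signed sparse positive-definite covariance, log-normal
  abundances, per-kingdom multinomial read simulation);
* six estimators over the concatenated taxon set: log covariance,
  CLR-mixed, CLR-split, SparCC basis correlations, and graphical-lasso
  fits to mixed- or split-CLR data (StARS penalty selection), all returned
  as covariance matrices;
* the error decomposition above as a diagnostic, plus edge-recovery R²,
  ROC/AUC edge detection, top-N sign-matched accuracy, hub/keystone
  scores (betweenness, degree, eigenvector, Lotka–Volterra knockouts) and
  Louvain community agreement against the ground truth;
* a benchmark driver over replicates × sample sizes × structure variants,
  and a runner that applies the same methods and bias diagnostics to real
  paired OTU tables (TSV or dense BIOM-JSON).

## A worked example

```r
library(tknet)

model  <- ground_truth_model(n_taxa = 60, seed = 42)
abund  <- sample_absolute_abundances(model, 100, seed = 43)
paired <- simulate_reads(abund, model$kingdom, seed = 44)

ests <- run_all_methods(paired, seed = 45,
                        abundances = abund, kingdom = model$kingdom)

ord     <- c(which(model$kingdom == "A"), which(model$kingdom == "B"))
truth   <- model$covariance[ord, ord]
kingdom <- model$kingdom[ord]
do.call(rbind, lapply(ests, function(e) {
  mr <- mean_relative_edge_strength(e, kingdom)
  data.frame(method = e$method,
             r2_all = round(edge_r2(truth, e), 3),
             auc_all = round(edge_auc(truth, e), 3),
             intra = round(mr$mean_rel_intra, 4),
             cross = round(mr$mean_rel_cross, 4))
}))
```

```
                method r2_all auc_all   intra   cross
        log_covariance  0.133   0.710  0.1627  0.0175
             clr_mixed  0.149   0.761  0.0537 -0.1286
             clr_split  0.162   0.773 -0.0731  0.0000
                sparcc  0.154   0.761  0.0932 -0.0875
          glasso_mixed  0.110   0.578  0.0016 -0.0039
          glasso_split  0.071   0.546 -0.0041 -0.0001
 oracle_log_covariance  0.212   0.808  0.0004 -0.0022
```

Reading the table: `r2_all` is the edge-recovery R² against the true
covariance and `auc_all` the edge-detection AUC; `intra`/`cross` are mean
edge strengths relative to the strongest edge in each kingdom block. The
uncorrected methods show the signature (`log_covariance` +0.16 intra;
`clr_mixed` and `sparcc` additionally ≈ −0.1 cross), the split-CLR
correction removes the cross-kingdom shift, and the oracle covariance of
the true (unobservable) abundances bounds what any compositional method
can achieve. The error decomposition itself is one call:

```r
dec <- error_decomposition(abund, model$kingdom,
                           which(model$kingdom == "A")[1],
                           which(model$kingdom == "B")[1])
# Var[log(X_a/Y_b)] = 6.3100; ratio 7.7474 + scale 0.8837 + cross -2.3210
```

The full grid (`run_benchmark(experiment_config(...))`) aggregates these
metrics over trials and sample sizes with Mann–Whitney comparisons against
the CLR-split reference; `run_real_data()` applies the estimators and the
bias diagnostic to a pair of real OTU tables after top-abundance taxon
filtering. A thin command-line wrapper with `simulate`, `infer`,
`evaluate`, `benchmark` and `real` subcommands lives in
`inst/scripts/tknet`.

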