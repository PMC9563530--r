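# gcnprio

Disease-gene prioritization with a semi-supervised graph convolutional
network over protein–protein interaction (PPI) networks and binary Gene
Ontology (GO) features.

## What it does, and for whom

Given a disease with a small set of known genes, the package ranks
candidate genes by their estimated likelihood of involvement. It is aimed
at computational biologists who have (i) gene → GO-term annotations, (ii)
an undirected PPI edge list, (iii) disease gene sets (GMT) and (iv) gene
coordinates, and want a reproducible prioritization pipeline plus the
evaluation and statistics machinery to compare it against other methods.

The core model:

* **Features.** Each gene is encoded as three equal-length binary vectors —
  one per GO namespace (MF, CC, BP) — indicating membership of every term
  in the namespace catalog, zero-padded to the shared width *m* of the
  largest catalog.
* **Propagation.** With self-loop-augmented adjacency *Ã = A + I*, the
  first layer propagates the binary features with a boolean OR product
  (entry (i, j) is 1 iff any neighbour of *i*, or *i* itself, carries
  feature *j*; equivalently sign(*ÃX*)); deeper layers use the ordinary
  sparse product. Each layer is ReLU(prop(*Ã*, *H*) *W* + *b*).
* **Objective.** A semi-supervised loss *L = L_s + λ·L_u*: the mean
  negative log-likelihood of labeled nodes plus a graph-context loss
  *−E log σ(γ · w_c′ e_i)* over sampled (node, context, sign) triples from
  random walks and shared labels, trained by alternating plain SGD steps
  with early stopping on a held-out validation split.
* **Ranking.** For each left-out disease gene, a 100-gene artificial
  linkage interval (the target plus its 99 genomically nearest non-seed
  genes) is scored by three models — one per namespace — and candidates are
  ranked by the mean of the three positive-class probabilities.
* **Evaluation.** Threshold-rank ROC/AUC over the leave-one-out trials,
  precision/recall/F1, and cross-method comparison via within-disease mean
  ranks and the tie-corrected Friedman chi-square test.

A seeded synthetic benchmark (planted disease module + enriched
annotations) exercises the entire pipeline without downloads.

## Worked example

```r
library(gcnprio)

# 1. a synthetic benchmark: 300 genes, 20-gene planted disease module
fx <- cmd_simulate(file.path(tempdir(), "benchmark"), fixture_config())
#> fixture written to /tmp/.../benchmark (20 disease genes)

network  <- load_ppi(fx$paths[["edges"]])
#> ppi_network: 292 genes, 544 undirected edges
ann      <- read_annotations(fx$paths[["annotations"]])
features <- build_feature_matrices(ann, network$gene_order)
features$MF
#> feature_matrix [MF]: 292 genes x 60 columns (60 terms, 0 zero-padding)
coords   <- read_gene_coords(fx$paths[["coordinates"]])
disease  <- intersect(read_gmt(fx$paths[["gmt"]])$disease1,
                      network$gene_order)

# 2. leave-one-out prioritization (3 models per left-out gene)
rls   <- loocv_evaluate(disease, features, network, coords,
                        model_config(seed = 42))
ranks <- target_ranks(rls)
ranks
#>  [1]  1  1 16  1  1  6  1  1  1  1  1  1  3  2  1  1  1  3  7  1
threshold_auc(ranks, 10)   # truncated top-of-list AUC
#> [1] 85.9
threshold_auc(ranks)       # full sweep: calibrated so random ~ 50
#> [1] 98.4
```

17 of the 20 held-out disease genes land in the top 3 of their 100-gene
interval; the truncated threshold-10 AUC of 85.9 is well above both chance
(~5 on the truncated scale) and a degree-only baseline (~71 on the same
fixture).

Method comparison on a published AUC table shipped with the package:

```r
r5 <- cmd_stats(system.file("extdata", "auc_thr5_all_methods.csv",
                            package = "gcnprio"))
round(unlist(r5$mean_ranks), 2)
#>    GCNGP   C-PUGP     DADA    HSSVM     GPEC    Arete WCR_STAR     TLGP   GPrior
#>     1.00     3.25     6.38     7.38     9.00     7.19     3.88     2.25     4.69
sprintf("chi-square = %.2f on df = %d, p = %.3g",
        r5$chi_square, r5$df, r5$p_value)
#> [1] "chi-square = 120.12 on df = 8, p = 3.14e-22"
```

The GCN-based prioritizer holds mean rank 1.00 across the 16 diseases and
the Friedman test rejects rank equality of the nine methods decisively.

## Layout

```
R/                      feature encoding, graph ops, GCN + training,
                        prioritization, evaluation/statistics, synthetic
                        benchmark, pipeline commands
inst/extdata/           published comparison tables (CSV)
inst/cli/gcnprio.R      command-line dispatcher
scripts/acceptance.R    end-to-end reproduction script
tests/testthat/         unit, property and acceptance tests
vignettes/              methods vignette
```
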