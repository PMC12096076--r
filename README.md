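# ppirescore

Network-based re-scoring of shotgun-proteomics protein identifications.

Mass-spectrometry pipelines assign each identified protein a score or a
posterior probability of presence, then cut the list to control the
false discovery rate — at the cost of discarding weakly supported but
truly present proteins, disproportionately the low-abundance ones.
`ppirescore` is for proteomics researchers who want to recover those
proteins: it treats the identified proteome as a graph (proteins as
nodes, known protein–protein interactions as unweighted, undirected
edges) and trains a semi-supervised graph neural network that re-scores
every protein from its own evidence together with its interactors'.

## The model in brief

Each protein *v* carries features *x_v* (by default the raw probability
from the search pipeline). A stack of per-node MLPs around one
message-passing layer produces a logit per protein, whose sigmoid is the
re-scored presence probability. Two interchangeable message-passing
layers are provided:

- **GCN-style** (spectral): `H' = D̂^{-1/2} (A + I) D̂^{-1/2} H W`;
- **SAGE-style** (spatial): `h'_v = W_self h_v + W_neigh mean{h_u : u ∈ N(v)}`,
  with train-time neighbor subsampling as a regularizer.

Training minimizes class-weighted binary cross-entropy on *labeled*
nodes only (labels come from replicate experiments or reference
datasets; most proteins stay unlabeled and are re-scored anyway), with
Adam, weight decay, and model selection by smoothed validation-set ROC
AUC. Everything — including backpropagation through batch normalization
and the sparse propagation operators — is implemented in plain R matrix
algebra and runs on one CPU.

The package also provides: readers for STRING-style edge lists and
evidence tables; a two-component EM mixture (`fit_score_mixture()`)
turning raw scores into probabilities for pipelines that emit no
posterior; ROC AUC with DeLong confidence intervals; top-N promotion
and mRNA-coverage analysis of unconfident proteins; subnetwork
extraction for model interpretation; and a fully seeded synthetic-data
generator (`simulate_ppi_data()`) with planted, network-assortative
protein presence.

## Worked example

A complete run on synthetic data (2000 proteins, planted presence,
30% detection false negatives):

```r
library(ppirescore)

sim <- simulate_ppi_data(synthetic_spec(seed = 7))
labels <- assign_labels_from_replicates(sim$replicates)
graph <- build_protein_graph(sim$proteins, filter_edges(sim$edges, 400), labels)
graph <- split_nodes(graph, seed = 7)
graph
#> <protein_graph> 2000 proteins, 6843 interactions (2 isolated)
#>   features: raw_probability
#>   labels:    positive=138 negative=922 unlabeled=940
#>   splits:    train=636 val=213 test=211 none=940

fit <- train_gnn(graph, model_config(conv_type = "gcn", seed = 7),
                 train_config(seed = 7))
report <- evaluate_predictions(graph, fit, mrna_detected = sim$mrna,
                               top_n = c(50, 100, 200))
report
#> <evaluation_report>
#>   test-mask ROC AUC (DeLong 95% CI):
#>     predicted 0.8088 (0.7234-0.8941)
#>     raw       0.7583 (0.6563-0.8602)
#>   mRNA coverage of top-N unconfident proteins:
#> # A tibble: 3 × 4
#>       n coverage_predicted coverage_raw overlap
#>   <int>              <dbl>        <dbl>   <int>
#> 1    50               0.9          0.92       9
#> 2   100               0.91         0.93      34
#> 3   200               0.91         0.93      77
#>   734 unconfident proteins ranked for promotion (raw < 0.9)
```

The AUC block is the headline: on held-out labeled proteins the
re-scored probability separates present from absent proteins better
than the raw probability (0.81 vs 0.76 here; the intervals are DeLong
95% CIs). The promotion table shows *which* unconfident proteins the
network rescued — proteins with near-zero raw evidence whose
interactors are confidently present:

```r
head(report$promoted, 3)
#> # A tibble: 3 × 6
#>   accession raw_probability predicted_probability rank_raw rank_predicted delta
#>   <chr>               <dbl>                 <dbl>    <int>          <int> <int>
#> 1 P00390            0.00349                 0.538      707             21   686
#> 2 P00940            0.00338                 0.533      708             49   659
#> 3 P00565            0.00649                 0.536      687             31   656
```

`autoplot(fit)` shows the training trace, `autoplot(report)` the mRNA
coverage curves, and
`plot(extract_subnetwork(graph, "P00390", predictions = predict(fit, graph)))`
the one-hop neighborhood explaining a promotion. `tidy()`/`glance()`
methods return tibbles for all fitted objects.

Real data enter through `read_protein_table()` (delimited evidence
tables, configurable columns) and `read_string_edges()` (STRING
`protein.links` downloads); `fit_score_mixture()` fills in raw
probabilities when the pipeline only emits scores. A YAML-driven
command-line interface (`exec/ppirescore`, subcommands `simulate`,
`prepare`, `em`, `train`, `grid`, `predict`, `evaluate`, `subnet`) wires
the same functions into a shell workflow; see `?workflow`.

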