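# repromine

Systems-toxicology profiling of chemicals for **male reproductive
developmental toxicity (MRDT)**.

Regulatory animal-study databases record, per chemical and study, which
male reproductive endpoints were affected and at what dose; parallel
high-throughput screening databases record concentration-response series
against hundreds of molecular targets. `repromine` is for computational
toxicologists who want to mine both: it turns endpoint tables into potency
profiles and MRDT calls, turns screening series into
cytotoxicity-adjusted target scores, and joins the two in a weighted
bipartite chemical-target network. A seeded synthetic-data generator with
planted ground truth makes the whole pipeline testable offline.

## The statistics at the core

**Effect score (in vivo potency).** Per chemical and effect category
(malformation, sperm, histology, organ weight), the category LEL (cLEL) is
the minimum lowest-effect-level (mg/kg/day) over all records; missing
categories are imputed at 10x the chemical's highest observed cLEL; then

```
score = 100 * (v - v_min) / (v_max - v_min),   v = -log10(cLEL)
```

min-maxed over the whole matrix, so 100 is the most potent
chemical-category pair and 0 the least.

**MRDT rule.** A chemical is MRDT if it produces any male reproductive
malformation, or a sperm/histological/weight effect seen *exclusively* in
developmental study contexts (prenatal or generational study, or an
F-generation evaluation). Tumors never count. Database flags can be
unioned with literature-curated flags.

**Cytotoxicity-adjusted Z and gene score (in vitro selectivity).** Hits
are series best fitted by a Hill or gain-loss model whose modeled maximum
exceeds a response threshold. For chemical X with >= 2 hits on the
cytotoxicity panel, m(X) is the median log10 AC50 of those hits (else
m(X) = 3) and M_global is the population median of the per-chemical MADs.
Each hit is standardized as

```
Z(X, A) = (m(X) - log10 AC50(X, A)) / M_global
```

and the gene score `G(X, g)` is the maximum Z over the hit assays mapped
to gene g (mean aggregation available). Large G means activity well below
cytotoxicity -- selective bioactivity. `G' = 10^(-G)` re-expresses it in
micromolar equivalents. Edges of the bipartite network are the pairs with
`G >= z_threshold` (default 0), weighted by G.

## Worked example

```r
library(repromine)

## --- in vivo stream -----------------------------------------------------
sv    <- simulate_invivo(syndrome_sim_config(n_chemicals = 120, seed = 11))
clel  <- impute_missing_clel(aggregate_clel(sv$records))
score <- compute_effect_scores(clel)
flags <- flag_mrdt(sv$records)
sum(flags$is_mrdt)
#> [1] 42

cooccurrence_summary(sv$records, universe = sv$truth$chemical_id)
#> <cooccurrence_summary> 95 of 120 chemicals positive (79%)
#>   category     n_positive pct_of_positive
#> 1 malformation          4             4.2
#> 2 tumor                 6             6.3
#> 3 sperm                21            22
#> 4 histology            48            51
#> 5 weight               94            99

round(score[1:3, ], 1)
#>           malformation sperm histology weight
#> chem_0001          9.6  56.6      42.2   39.2
#> chem_0002         13.8  13.8      75.3   43.4
#> chem_0004         14.2  43.9      46.1   51.2
```

The co-occurrence ladder shows the planted phenotypic hierarchy (weight
change broadest, malformations rarest); the effect-score rows are each
chemical's relative potency per category, 100 being the most potent pair
in the matrix.

```r
## --- in vitro stream ----------------------------------------------------
sa   <- simulate_assays(assay_sim_config(n_chemicals = 10, n_genes = 5, seed = 11))
hits <- call_hits_table(sa$series)
summ <- cytotox_summaries(hits, sa$assay_map)
gs   <- gene_scores(hits, summ, global_mad(summ), sa$assay_map)
head(dplyr::arrange(gs$scores, dplyr::desc(G)), 3)
#>   chemical_id gene_symbol     G n_hit_assays n_assay
#> 1 chem_0008   GENE02       34.3            2       2
#> 2 chem_0004   GENE03       18.5            2       2
#> 3 chem_0002   GENE05       15.8            2       2

net <- build_network(gs$scores, z_threshold = 0)
igraph::ecount(net)
#> [1] 10

evaluate_recovery(sa$truth, scores = gs$scores)
#> <recovery_report>
#>   selectivity AUROC: 1.000
```

The top gene scores are tens of MAD units below cytotoxicity -- the
planted selective pairs -- and the recovery report confirms they rank
perfectly above the cytotoxicity-driven foils.

`run_invivo()` / `run_invitro()` / `run_network()` / `run_all()` run the
same stages over flat files and write every artifact (CSV matrices, JSON
summaries, Newick trees, GraphML/GEXF networks) plus a reproducibility
manifest; `exec/repromine` wraps them as a subcommand CLI.

## Package layout

| Area | Functions |
| --- | --- |
| Vocabulary & records | `default_endpoint_vocabulary`, `read_endpoint_records`, `classify_endpoint` |
| In vivo profiling | `aggregate_clel`, `impute_missing_clel`, `compute_effect_scores`, `flag_mrdt`, `merge_literature_flags`, `cooccurrence_summary`, `concordance_correlation`, `hierarchical_cluster` |
| In vitro scoring | `fit_hill`, `fit_gain_loss`, `select_model`, `call_hit(s_table)`, `cytotox_summary`, `global_mad`, `z_score`, `gene_scores`, `modified_gene_score` |
| Network | `build_network`, `annotate_nodes`, `degree_stats`, `force_layout`, `export_graph`/`import_graph` |
| Simulation & recovery | `syndrome_sim_config`, `simulate_invivo`, `assay_sim_config`, `simulate_assays`, `evaluate_recovery`, `auroc` |
| Orchestration | `run_invivo`, `run_invitro`, `run_network`, `run_all`, `write_simulated_universe` |

The methods vignette (`vignettes/repromine-methods.Rmd`) documents the
model assumptions, parameter defaults, numerical conventions and known
limitations.
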