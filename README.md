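# lincnet

Functional annotation of long intergenic non-coding RNAs (lincRNAs)
through competing endogenous RNA (ceRNA) networks.

Most lincRNAs have no known function. The ceRNA hypothesis provides a
route to annotate them by association: RNAs sharing many miRNA binding
sites compete for the same limited miRNA pool, so their abundances are
positively coupled, and a lincRNA can inherit the function of the coding
genes it competes with. `lincnet` implements that programme for stress
time-course designs (the motivating system is rice under phosphate
starvation: 9 time points × 3 replicates × 2 conditions, root and shoot):

1. **lincRNA candidate filtering** — length ≥ 200 nt, intergenic class
   code, RPKM ≥ 0.5 in at least one sample, no protein similarity
   (coverage > 50% ∧ e-value < 1e−5 rejects), no coding potential;
   plus exon/GC feature summaries from GTF + FASTA.
2. **ceRNA network inference** — for each RNA pair with regulator sets of
   sizes *M*, *N* sharing *n* miRNAs in a universe of *U*, the
   hypergeometric upper tail
   *P(X ≥ n) = Σᵢ C(M,i)·C(U−M,N−i)/C(U,N)* nominates candidate pairs
   (*P* < 0.05), confirmed by positive Spearman correlation (*p* < 0.05)
   over the stress samples; topology reporting (average degree, log–log
   power-law fit).
3. **MCODE community detection** — a from-scratch implementation of
   molecular-complex detection (k-core-based vertex weighting, seeded
   greedy expansion, haircut/fluff post-processing) with the Cytoscape
   plugin defaults.
4. **GO annotation** — community enrichment (same hypergeometric test)
   and a three-tier lincRNA rule: inherit the community's top term; else
   enrich the direct gene neighbors; else take the neighbors' majority
   term.
5. **Key lincRNAs** — hubs (top 20% of node degrees, ties included) that
   are differentially expressed (FDR < 0.05) at any time point; plus
   Eisen-style hierarchical clustering of stress samples on the key
   lincRNAs.

A synthetic-data generator (`sim_config()`, `simulate_*()`,
`run_pipeline()`) plants known ceRNA modules — shared regulator blocks,
correlated expression, module GO labels, late-stress up-regulation — so
the whole pipeline is testable against ground truth without downloads.

## Worked example

```r
library(lincnet)

# Plant 6 ceRNA modules and simulate the full study design
cfg <- sim_config(seed = 101)
res <- run_pipeline(cfg)

topology_report(res$network)[c("nodes", "edges", "lincrnas", "average_degree")]
#> $nodes
#> [1] 48
#> $edges
#> [1] 167
#> $lincrnas
#> [1] 12
#> $average_degree
#> [1] 6.958333

length(res$communities)
#> [1] 6

head(res$linc_annotations, 3)
#>    lincrna      go_id           go_name      tier            p community
#> 1 linc0001 GO:1000001 planted process 1 community 2.649378e-09         1
#> 2 linc0002 GO:1000001 planted process 1 community 2.649378e-09         1
#> 3 linc0003 GO:1000002 planted process 2 community 2.649378e-09         2

head(res$key_report$lincrnas, 3)
#>    lincrna degree      go_id           go_name
#> 1 linc0001      7 GO:1000001 planted process 1
#> 2 linc0002      7 GO:1000001 planted process 1
#> 3 linc0003      7 GO:1000002 planted process 2

unlist(res$metrics)
#>           edge_recall        edge_precision               edge_f1
#>             0.9940476             1.0000000             0.9970149
#>        linc_go_recall      tier1_decoy_rate community_go_accuracy
#>             1.0000000             0.0000000             1.0000000
#>       key_linc_recall   early_late_accuracy
#>             0.8333333             1.0000000
```

The 6 planted modules come back as 6 MCODE communities; every planted
lincRNA is annotated with its own module's GO term through the community
tier; the recovered network misses 0.6% of the planted within-module
edges and adds none; and the 2-group clustering of the 27 stress samples
on the key lincRNAs separates the early (< 7 d) from the late time points
exactly.

The `annotate_lincrnas()` tiers, thresholds and sample filters are all
exposed — see the methods vignette (`vignettes/lincnet-methods.Rmd`) for
the models, parameter meanings and design decisions.

A thin command-line wrapper with subcommands (`simulate`, `filter`,
`features`, `network`, `communities`, `annotate`, `keylincs`, `run-all`)
is installed at `inst/scripts/lincnet-cli.R`.

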