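---
title: "Annotating lincRNAs through ceRNA networks: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating lincRNAs through ceRNA networks: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lincnet)
```

## The problem

Long intergenic non-coding RNAs (lincRNAs) are transcribed from regions
between protein-coding genes, are at least 200 nt long, and have no coding
capacity. Most have no functional annotation. The competing endogenous RNA
(ceRNA) hypothesis offers a route to annotate them by association: RNAs
that share many miRNA binding sites compete for the same limited miRNA
pool, so their abundances are coupled, and a lincRNA can be assigned the
function of the coding genes it competes with. `lincnet` implements this
programme end to end for a stress time-course design — the motivating
system is rice roots and shoots under inorganic-phosphate (Pi) starvation,
sampled at nine time points (1 h to 21 d + 24 h) with three replicates in
each of two conditions — but every stage is generic.

## The ceRNA network model

For an RNA pair $(A, B)$ with miRNA regulator sets $C$ and $D$ inside a
universe of $U$ distinct miRNAs, the evidence that they compete is the
hypergeometric upper tail on the overlap $n = |C \cap D|$:

$$P = \sum_{i=n}^{\min(M,N)} \frac{\binom{M}{i}\binom{U-M}{N-i}}{\binom{U}{N}},
\qquad M = |C|,\; N = |D|.$$

Pairs with $P < 0.05$ are *candidate* ceRNA pairs (`candidate_pairs()`).
Because competition couples abundances positively, candidates are then
confirmed on expression: the Spearman correlation over the stress-condition
samples must be positive with a two-sided $p < 0.05$ (t approximation on
$\rho\sqrt{(m-2)/(1-\rho^2)}$; `build_network()`). Edges retain the overlap
count, both p-values and $\rho$. Design choices worth knowing:

* **Tail direction is $P(X \ge n)$**, the standard over-representation
  convention.
* **All pair types are tested** — gene–gene, gene–lincRNA,
  lincRNA–lincRNA. Published node counts for this analysis imply gene–gene
  edges dominate.
* **The universe $U$ is the distinct miRNAs of the supplied target map**,
  not an external catalogue, so runs are self-contained and reproducible.
* **No multiple-testing correction** on either filter: the method applies
  raw 0.05 thresholds at both steps; a Benjamini–Hochberg variant can be
  had by correcting the returned p-value columns, but it is deliberately
  not the default.
* RNAs with no predicted regulator are excluded before testing (with a
  logged count); candidate pairs with zero expression variance in the
  selected samples are dropped the same way.

`average_degree()` and `degree_powerlaw_fit()` (ordinary least squares of
log10 frequency on log10 degree, zero-frequency degrees omitted) provide
the topology report used to judge whether an inferred network is dense and
scale-free-like.

## Community detection: MCODE

Dense sub-networks are mined with a from-scratch implementation of the
MCODE molecular-complex detection algorithm (`vertex_weights()`,
`find_complexes()`), with the Cytoscape plugin defaults pinned in
`mcode_params()`: degree cutoff 2, node score cutoff 0.2, k-core 2, max
depth 100, haircut on, fluff off.

The weight of a vertex summarizes how dense its immediate surroundings
are: take the subgraph induced by the vertex and its neighbors, find the
highest $k$-core level that subgraph reaches, and multiply that core
number by the subgraph's edge density. Two refinements matter and were
chosen deliberately:

* **The density factor is the density of the whole closed neighborhood.**
  Scoring only the extracted core subgraph would give a vertex that hangs
  off a clique by a single edge the same weight as the clique's own
  members, and seeded expansion would then walk across single-edge bridges
  and merge structurally separate complexes. With neighborhood density,
  bridge endpoints weigh less than clique interiors and complexes stay
  apart.
* **Neighborhoods that reach no 2-core score zero**, and zero-weight
  vertices neither seed complexes nor join them. Otherwise chains and
  rings — where every closed neighborhood is just a path — would
  accumulate into spurious "complexes"; a 30-cycle correctly yields no
  complex at all.

Complex prediction seeds from the highest-weight unassigned vertex and
breadth-first-adds neighbors whose weight is at least
`seed weight × (1 − node_score_cutoff)`; each node joins at most one
complex. Haircut iterates to a fixpoint so every surviving member keeps at
least two intra-complex connections; fluff (off by default) adds boundary
nodes with neighborhood density above 0.1 and may create overlaps.
All ties — seed order, equal scores — break lexicographically by node id,
so results are invariant to node insertion order. A complex's score is its
induced density times its size; complexes of fewer than two members are
discarded.

## Annotation: enrichment and the three-tier rule

GO over-representation (`go_enrichment()`) reuses the same hypergeometric
upper tail with $n$ the query–term intersection, $M$ the annotated query
genes, $N$ the term size and $U$ the universe. The universe defaults to
every gene with at least one GO annotation in the supplied table — the
middle ground among the defensible choices (all genes, annotated genes,
network genes), and configurable. Only genes carry annotations; lincRNAs
are always excluded from $M$. GO terms are flat labels here: no `is_a`
propagation is applied, because the annotation sources this pipeline
consumes are already term-per-gene tables.

Each community is annotated with its minimum-p enriched term
(`annotate_communities()`; ties go to the lexicographically smaller GO id).
LincRNAs then receive at most one term through a three-tier fallback
(`annotate_lincrnas()`):

1. **community** — the lincRNA sits in an annotated community and inherits
   its term (in the rare fluff-induced multi-membership case, the
   highest-scoring community wins);
2. **neighbor_enrichment** — otherwise its direct gene neighbors are
   tested, and the top enriched term is assigned;
3. **neighbor_majority** — otherwise the term carried by the largest
   number of distinct neighbor genes is assigned, ties again by GO id, and
   no p-value is attached.

Tier-3 counts distinct neighbor *genes* per term (not annotations), so a
gene with two terms votes once per term but multi-annotated genes do not
dominate.

## Hubs, key lincRNAs, sample clustering

Hubs are the top 20% of nodes by degree over *all* nodes, lincRNAs and
genes alike (`hub_threshold()`); after sorting degrees the first
`floor(0.2 n)` nodes are taken and boundary ties are included, which makes
the realized threshold a strict lower bound on hub degree — matching the
"degrees higher than …" phrasing such analyses report. Key lincRNAs are
hub lincRNAs whose differential-expression FDR drops below 0.05 at one or
more time points (`select_key_lincrnas()`). DE calls are an input table;
`simple_de()` (two-sided Welch test on log2(RPKM+1), BH-corrected within
time point) exists so the synthetic pipeline is closed, and is explicitly
not a substitute for count-based DE models on real read counts.

`cluster_samples()` clusters stress samples on the key lincRNAs with
average linkage on a correlation distance, Eisen-style: feature rows are
log2(RPKM+1)-transformed and mean-centered, and similarity is the
*uncentered* correlation (the offset fixed at zero). The uncentered form
is deliberate: centered Pearson between sample profiles is invariant to a
constant shift of one sample, so a stress response shared across the
feature lincRNAs — precisely the signature that separates early from late
stress stages — would be invisible to it. The reported 2-group partition
is the tree's top cut.

## The synthetic-data generator

`sim_config()`/`simulate_*()` plant known structure so every stage can be
validated against ground truth. The default configuration is the package's
*recovery configuration*: 60 miRNAs, 90 genes, 30 lincRNAs, 6 modules of
8 RNAs (2 lincRNAs + 6 genes, so all three annotation tiers are
reachable), 4 shared miRNAs per module, background targeting probability
0.02, the 9-time-point × 3-replicate × 2-condition design (27 stress
samples), noise sd 0.3, module activity sd 0.5, `de_effect` 2, late phase
starting at the 7-day position (index 5). Problem sizes were chosen so the
full pipeline runs in seconds; the fixed seed list {101, 102, 103} is used
by the end-to-end recovery tests.

The expression model is additive in log2 space and exponentiated to an
RPKM-like scale:

* a per-RNA baseline ~ N(3, 1);
* a per-module latent activity following an AR(1) trajectory over time
  points (autocorrelation 0.7, stationary sd `module_activity_sd`),
  shared by replicates *and by both conditions*. Sharing across replicates
  makes within-module pairs positively rank-correlated — the property the
  Spearman filter requires; the AR structure reflects that time-course
  expression is autocorrelated, and iid per-time-point draws would
  manufacture single-time-point outliers that average-linkage clustering
  splits off. Sharing across conditions keeps the differential-expression
  null clean: with `de_effect = 0` the two arms are exchangeable;
* a module-level stress response: from `late_start_index` onwards, every
  member of a responsive module is up-shifted in stressed samples by
  `de_effect × Uniform(0.5, 1.5)` (so `de_effect` on average, bounded away
  from zero — a "responsive" module that does not respond would contradict
  its own label). The whole module shifts together because that is what
  the ceRNA premise predicts — competing partners co-respond; an earlier
  design that shifted only the lincRNAs systematically destroyed the very
  lincRNA–gene co-expression the edge filter requires. The heterogeneity
  of the shift across modules is what gives the sample clustering its
  early/late signal;
* independent Gaussian noise (sd `noise_sd`).

`simulate_target_map()` gives every module member all of its module's
miRNAs and draws off-module edges independently with
`background_target_prob`; with zero background the shared-regulator counts
are exactly block-structured. `simulate_go_annotations()` labels module
genes with their module's planted term and background genes with decoy
terms; lincRNAs carry none. `simulate_candidate_transcripts()` emits a
labeled panel spanning every rejection reason of the candidate filter,
including the boundary cases (length exactly 200 kept; RPKM exactly 0.5 in
one sample kept; similarity coverage 0.6 with e-value 1e-4 kept because
the rejection is a strict conjunction).

What the generator does **not** emulate: read-level artifacts, sequence
composition, miRNA binding-site energetics, count noise (values are
continuous RPKM-like quantities), tissue pairs (one tissue per
configuration), and realistic GO ontology structure. Tests passing on this
generator therefore validate the pipeline's logic and statistics — block
recovery, tier assignment, threshold semantics — not performance on real
RNA-seq data.

## lincRNA candidate filtering and feature summaries

`filter_candidates()` applies the published rules with their boundary
semantics made explicit: "smaller than 200 nt removed" keeps length 200;
"RPKM < 0.5 in all samples removed" keeps a transcript reaching 0.5 in any
sample; protein similarity rejects only when coverage > 0.5 **and**
e-value < 1e-5; either coding-potential flag rejects; the assembly class
code must be intergenic ("u"). Rejection reasons report the first failed
rule in that order, but keep/reject outcomes are order-independent.
Intergenic status and coding flags are consumed as precomputed inputs —
the upstream assembly and coding-potential tools are out of scope.
`exon_summaries()` and `gc_content()` compute the per-biotype feature
summaries (exon lengths, exon-count proportions, GC fraction over exonic
A/C/G/T with ambiguous bases excluded) from standard GTF/FASTA via
`rtracklayer` and `Biostrings`; GTF coordinates are 1-based closed, and GC
is strand-symmetric so no reverse complementing is done.

## Numerical and degenerate-input behavior

* `hypergeom_upper_tail()` uses the survival form of the hypergeometric
  CDF and is stable for universes beyond 1e5; it matches exhaustive subset
  enumeration to 1e-12 on all universes up to 12 in the test suite.
* Spearman $\rho = \pm 1$ maps to $p = 0$; zero-variance series yield an
  "undefined" signal and the pair is skipped at pipeline level rather than
  raising.
* Welch tests on constant data return $p = 1$ when group means agree
  (and 0 otherwise) instead of erroring.
* Empty networks, empty candidate lists and empty record sets flow through
  as empty results; empty miRNA universes and sample filters selecting
  fewer than 3 samples are errors.
* All RNG in the generator derives per-table sub-streams from one master
  seed, so adding a table to a fixture never perturbs the others.

## Known limitations

* MCODE parameter defaults are pinned to the Cytoscape plugin's; other
  plugin versions may differ, so communities on real data can deviate
  from published runs.
* The Spearman p-value uses the t approximation, not an exact permutation
  law; at 27 samples the difference is negligible, but at very small m it
  is not.
* Raw (uncorrected) 0.05 thresholds at both edge filters follow the
  method faithfully but admit false edges at scale; the BH option exists
  for users who want control.
* `simple_de()` is not edgeR: it ignores count noise and library-size
  normalization and exists for synthetic closure only.
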