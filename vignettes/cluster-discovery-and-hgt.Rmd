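---
title: "Discovering gene clusters and testing their horizontal transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering gene clusters and testing their horizontal transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clusterhgt)
library(dplyr)
```

## The problem

Fungal secondary-metabolite pathways — psilocybin biosynthesis being the
motivating case — are often encoded by physically clustered genes.  Two
comparative-genomic signatures identify such clusters without any
biochemical prior: (i) a *phenotype-matched taxon distribution* (the genes
occur in all producing genomes and almost no non-producing ones), and
(ii) *co-localization* (the genes sit within a few positions of one
another on a scaffold, conserved across genomes).  Once a cluster is
found, the phylogenies of its genes can be tested for *horizontal gene
transfer* (HGT): a transferred cluster places the recipient's sequences
inside the donor lineage's clade, contradicting the species tree.

`clusterhgt` implements this entire inference chain — homolog grouping,
phenotype filtering, co-localization, boundary refinement, microsynteny,
gene-tree screening with constrained-topology tests, event-parsimony
reconciliation, and genome-content ordination — together with a
synthetic-genome simulator that plants clusters and transfer events as
ground truth, so every stage can be validated end to end without
downloading a single genome.

## The generative model behind the simulator

`simulate_genomes(sim_config())` draws:

* a rooted binary **species tree** with branch lengths uniform on
  `branch_length_range` (default 0.05–0.25 substitutions/site — within
  the range over which protein distances stay comfortably estimable);
* **phenotypes**: a donor clade of `producer_clade_size` taxa plus the
  most distant leaf (the recipient) are producers (`PS_plus`), the rest
  `PS_minus`; this mirrors a donor genus plus one distant recipient
  lineage;
* **ecologies**: each taxon gets `dung`, `wood` or `mycorrhizal` labels
  (some dung/wood taxa carry both, as some litter fungi do);
* **background families** whose presence evolves by a two-state
  gain/loss Markov process (defaults: root presence 0.95, gain 0.02,
  loss 0.05 per unit branch length).  These rates are deliberately low:
  in closely related proteomes most families are near-universal, and a
  sparse loss process keeps phenotype-mimicking absence patterns — the
  false-positive fuel of the taxon filter — realistically rare without
  making them impossible;
* optionally, **ecology-linked families** confined to a drawn number of
  genomes of one niche;
* **protein sequences** evolved site-independently under the WAG model
  (indel-free, so families are natively aligned; the pipeline's claims
  are topological and do not depend on indel realism);
* the **five-gene cluster** (decarboxylase, P450 monooxygenase,
  phosphotransferase, methyltransferase, MFS transporter analogs)
  inserted as a contiguous block, order shuffled per genome, only in
  producers; with `hgt_cluster = TRUE` (the default study condition) the
  recipient's copies evolve on a tree in which the recipient lineage
  branches from the donor's terminal edge;
* optionally (`cluster_relatives = TRUE`) one **deep out-paralog** of
  each cluster family in every genome.  Real cluster genes are
  subfamilies of widespread families, and these relatives supply what a
  large proteome database supplies in practice: outgroup leaves that let
  a gene tree be rooted away from the query and make "nested within the
  donor clade" distinguishable from "sister to the donor clade".
  Without outgroups those two placements are topologically symmetric and
  no screen can separate transfer from ancestral vertical presence.

Every stochastic draw flows from a named substream of one master seed,
so all outputs are reproducible bit for bit.  A `truth` log records the
true presence matrix, family assignments, cluster members, the
transfer event, and both trees.

What the simulator does *not* emulate: indels and alignment ambiguity,
rate heterogeneity across sites, gene fission/fusion, tandem
duplication, or assembly artifacts.  Passing tests therefore demonstrate
the correctness of the inference machinery under its own model
assumptions, not robustness to the full messiness of real annotations.

## Homolog groups

`pairwise_similarity()` performs Smith–Waterman local alignment
(BLOSUM62; affine gaps 11/1, the classic protein-search defaults) on
candidate pairs passing an exact k-mer prefilter (4-mers, at least 2
shared).  E-values follow Karlin–Altschul statistics with the standard
gapped-BLOSUM62 constants (λ = 0.267, K = 0.041) and a database-size
correction.  "Amino-acid similarity" is operationalized as the fraction
of aligned columns with a positive substitution score — the search tools
this stage replaces do not publish their exact definition, so borderline
edges may differ from theirs; both protocol thresholds (0.45 for cluster
detection, 0.40 for synteny screening) act on this quantity.

`mcl_cluster()` runs Markov clustering per connected component with
inflation 2.0, self-loops at each node's maximum incident weight (the
standard regularization; without it near-bipartite components oscillate
with period two), entry pruning at 1e-5, and convergence when the
largest column change falls below 1e-6 (at most 200 iterations).  Edge
weights are `-log10(E)` capped at 200, reciprocal hits averaged.  The
within/between-species weight rescaling of the original orthology
clustering protocol is intentionally omitted: downstream stages depend
on group membership, not on score parity with any specific tool.

## Cluster discovery

* `taxon_filter_groups()` keeps groups present in **all** producer
  genomes and at most `max_negative` non-producers (0–3; the candidate
  set carries 0–1 forward, i.e. three to four genomes total with three
  producers).
* `find_colocalized()` chains candidate genes on a scaffold when no
  more than six genes intervene, merging transitively
  (single-linkage).  A reportable locus needs at least two genes from
  two distinct groups — tandem copies of one family are not a cluster.
* `refine_boundaries()` re-examines up to ten genes on either flank.  A
  flank joins the locus only if its group passes the same phenotype
  filter **and** lies near the locus in every other producer genome.
  The published protocol describes this step as finding "convergence of
  synteny and gene phylogeny" by expert judgment; the package
  operationalizes the checkable core (phenotype distribution plus
  cross-genome adjacency).  The phenotype rule alone proved too
  permissive in simulation — a phenotype-mimicking family adjacent to
  the cluster in a single genome would occasionally be absorbed — and
  the adjacency requirement is precisely what "convergent synteny"
  means.
* `run_discovery()` finally keeps loci whose group set co-localizes in
  *every* producer genome and prunes each locus to that conserved core,
  the programmatic counterpart of evaluating clustering "simultaneously
  in each genome".  One-genome coincidences are thereby excluded.
* `detect_synteny()` scans any genome set for homologs of a locus
  (e-value 1e-5, similarity 0.40) co-localized under the same
  six-intervening-genes rule.

## Trees and likelihoods

Gene trees are built by neighbor joining on Poisson-corrected distances
(`d = -ln(1-p)`, saturation capped at p = 0.95) with bootstrap supports
from column resampling.  This stands in for full ML tree search: the
claims downstream are purely topological, and on the simulator's data NJ
recovers additive topologies exactly.  Likelihoods, however, are
computed exactly: `site_loglik()` implements Felsenstein pruning under
the scaled WAG model (per-column rescaling against underflow; the total
is root-invariant by reversibility), and is cross-checked in the test
suite against an independent likelihood engine.

`rell_test()` compares an optimal and a constrained topology by
resampling estimated per-site log-likelihoods: the one-sided p-value is
the fraction of bootstrap resamples in which the constrained total is at
least as good.  This replaces the multiscale-bootstrap AU test; the
decision rule (reject vertical inheritance when p < 0.05) is preserved,
and the substitution is conservative at the scale used here — its
simulated type-I error is checked to stay at or below 0.07 at nominal
0.05.  When both topologies coincide the p-value is 1 by the ≥
convention, so the null is never rejected on identical trees.

The consensus species tree (`build_species_tree()`) samples single-copy
groups, keeps bootstrap NJ trees whose mean internal support exceeds
70%, and combines them by extended majority-rule consensus (majority
bipartitions, then greedy addition of compatible ones in frequency
order).  "Average bootstrap support" averages internal edges only.  The
quota default is 100 gene trees, as in the published protocol; the test
suite scales it to 15, which already reproduces the true topology in
simulation.

## The transfer screen

`screen_genome()` applies three filters and one test to every gene of a
recipient genome:

1. **Best hit** (`best_hit_filter()`): the top-scoring hit, excluding
   same-genome hits (paralogs would otherwise mask the signal — the
   original description leaves this unstated), must come from a donor
   taxon.
2. **Topology prefilter** (`topology_prefilter()`): on an NJ tree rooted
   at the sequence most distant from the query, the query's sister
   subtree must contain a donor sequence, and at least two internal
   nodes must lie on the query's rootward path before any background
   taxon joins.  An alternative node-distance reading of "separated by
   two or more ancestral nodes" is available as `method =
   "node_distance"`.
3. **Supported nesting** (`supported_nesting_filter()`): on a bootstrap
   tree, the query must again sit next to a donor and be nested inside a
   clade of surrounding-group sequences with more than two containment
   nodes supported above 70%.  "Nested *within* a larger clade" is taken
   literally: the surrounding clade must be a proper subtree — a gene
   tree consisting entirely of query-plus-surrounding sequences offers no
   outside frame, and under most-distant rooting a basal (vertical) query
   is then indistinguishable from a nested one, so such trees are never
   retained.  Practically this means the screen needs gene trees that
   include homologs beyond the donor group, which real proteome databases
   provide and the simulator's `cluster_relatives` option emulates.
4. **Constraint test** (`vertical_constraint_test()`): the
   vertical-inheritance topology — query grafted outside the donor clade
   (next to its own-lineage relatives when present) — is rebuilt by NJ
   on the non-query leaves, branch lengths for both topologies are
   refitted by non-negative least squares on the same distance matrix
   (so identical topologies give identical likelihoods and the test is
   exactly null-centred), and the RELL test decides.

Trees larger than 250 leaves are first reduced to the largest supported
clade containing the query (`reduce_to_supported_clade()`).

On simulations with the planted transfer the screen flags exactly the
five transferred cluster genes and rejects vertical inheritance for
them; on vertical-only simulations no gene reaches stage 3 — matching
the published observation that the genome-wide scan found no transfers
beyond the cluster itself.

## Reconciliation

`lca_reconcile_dl()` is the classical least-common-ancestor mapping
(duplications where a node maps with a child, losses from mapping-depth
differences), the unique minimum under duplication-loss costs.
`dtl_reconcile()` is a dynamic program over (gene node × species node)
allowing speciation, duplication, loss, and transfer to any
non-ancestral species edge, with costs 1.5 / 3.0 / 1.0.  Transfers are
not checked for global time consistency — the standard parsimony
relaxation, which keeps the program polynomial and matches common
practice.  Equal-cost scenarios resolve deterministically (speciation
over duplication over transfer, then a fixed species-node order).
Gene-tree edges with support below the edge-weight threshold (default
1.0, so only zero-support edges) are collapsed first; the resulting
polytomies are re-resolved arbitrarily rather than cost-greedily — at
the default threshold this affects only edges with no support at all.
`compare_models()` prefers the cheaper model, with ties to DL: a
transfer claim must beat vertical explanations outright.

## Genome content

`build_and_filter_matrix()` drops groups present in one genome or in
all genomes; `pca_content()` centers and scales columns (constant
columns are dropped — unit variance is undefined for them) and fixes
each component's sign so its largest-magnitude loading is positive.
`select_loading_groups()` takes the 95th percentile of positive (and of
negative-magnitude) loadings per component, with linear interpolation
between order statistics.  `category_enrichment()` runs one-tailed
Fisher tests with Bonferroni correction over the four default
selections (±PC1, ±PC2).  `niche_specific_groups()` applies the
minimum-carrier cutoffs dung 3 / wood 4 / ectomycorrhizal 2 with strict
absence outside the niche; genomes with two labels count toward both
niches and never disqualify a group for either of them.  Each selected
group is flagged when its presence set is not a clade of the species
tree — the polyphyly pattern the cutoffs were chosen to guarantee.

## Numerical and design choices

* Gene position is 0-based integer rank along a scaffold; "n intervening
  genes" counts genes strictly between two positions.  Strand is
  ignored throughout.
* Tie-breaks are lexicographic everywhere (rooting targets, MCL
  attractor assignment, reconciliation backtracks), making every output
  order-independent and reproducible.
* The problem sizes used by the validation suite — 6 genomes × 300
  families for discovery over 20 seeds, 10 genomes × 12 families for
  the 200 vertical and 50 transfer screens, 16 genomes × 120 families
  for niche recovery, a systematic reconciliation sweep of all gene-tree
  shapes up to 4 leaves (with a sampled 5-leaf layer) — were chosen as
  the smallest instances that still exercise every code path and
  phenotype pattern; the planted signal is not tuned to them.
* The package's parameter registry (`ch_params()`) carries the published
  protocol's operating point as defaults; any override is reported via a
  message so deviations are visible in logs.

## Known limitations

* NJ replaces ML search; with very short alignments or near-saturated
  distances, bootstrap supports will differ from an ML analysis.
* The RELL test is a single-scale approximation of the AU test and can
  be slightly conservative.
* DTL parsimony without time consistency can output transfer scenarios
  that no dated history realizes.
* The similarity fraction is alignment-traceback-defined and will not
  numerically match heuristic search tools on borderline pairs.

## A complete worked run

```{r, eval = FALSE}
sim <- simulate_genomes(sim_config(seed = 1))
disc <- run_discovery(sim)
disc$report
plot_cluster_loci(disc$loci)

scr_sim <- simulate_genomes(sim_config(seed = 1, n_taxa = 10,
                                       producer_clade_size = 6,
                                       cluster_relatives = TRUE,
                                       n_background_families = 20))
run <- run_hgt(scr_sim, recipient = scr_sim$truth$recipient,
               donor_taxa = scr_sim$truth$donor_clade,
               species_tree = scr_sim$truth$species_tree, seed = 1)
glance(run$screen)
```
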