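# clusterhgt

Comparative-genomics machinery for discovering secondary-metabolite gene
clusters in fungal genomes and for testing whether such clusters moved
between lineages by horizontal gene transfer (HGT).

## Who this is for

Evolutionary genomicists who have a set of annotated proteomes, a binary
phenotype (e.g. psilocybin producer / non-producer), and optional ecology
labels, and who want to run the full targeted-discovery + HGT-screening
protocol — or validate it on simulated genomes with known ground truth
before trusting it on real data.

## The method in brief

1. **Homolog groups.** All-vs-all Smith–Waterman (BLOSUM62, affine gaps
   11/1) on k-mer-prefiltered pairs; Karlin–Altschul e-values
   (λ = 0.267, K = 0.041) at cutoff 10⁻⁴; Markov clustering (inflation
   2.0) of the `-log₁₀E` graph.
2. **Taxon filter.** Keep groups present in *all* PS⁺ genomes and ≤ 1
   PS⁻ genome ("three to four genomes total").
3. **Co-localization.** Chain candidate genes separated by ≤ 6
   intervening genes (single linkage); a locus needs ≥ 2 genes from ≥ 2
   groups; refine boundaries over a 10-gene window; require the group
   set to co-localize in every PS⁺ genome.
4. **Microsynteny.** Scan other genomes for locus homologs (e-value
   10⁻⁵, similarity ≥ 0.40) co-localized under the same rule.
5. **HGT screen.** Per recipient gene: best hit must be from a donor
   taxon → NJ tree rooted at the most distant sequence must place the
   query next to a donor, ≥ 2 nodes from background taxa → bootstrap
   tree must nest the query inside the donor group with > 2 nodes at
   > 70% support → a vertical-inheritance constrained topology must be
   rejected by a one-sided RELL test (p < 0.05).
6. **Reconciliation.** Gene tree vs species tree under DL (LCA mapping)
   and DTL event parsimony (duplication 1.5, transfer 3.0, loss 1.0);
   a transfer claim must be strictly more parsimonious.
7. **Genome content.** Genome × group count matrix (singleton and
   universal groups dropped), zero-centred unit-variance PCA, 95th
   percentile loading selection, one-tailed Fisher enrichment with
   Bonferroni correction; niche-specific groups at cutoffs dung 3 /
   wood 4 / ectomycorrhizal 2 with polyphyly flags.

A synthetic-genome simulator (`simulate_genomes()`) generates species
trees, gain/loss gene content, WAG protein sequences, a planted 5-gene
cluster confined to producer taxa, and a cluster transfer from a donor
clade to a distant recipient — with a complete truth log.

## Worked example

```r
library(clusterhgt)

sim  <- simulate_genomes(sim_config(seed = 7))   # 6 genomes, 3 producers
disc <- run_discovery(sim)
disc
#> <ch_discovery>
#>   genes              1665
#>   similarity_edges   3946
#>   homolog_groups     288
#>   candidate_groups   5
#>   raw_loci           3
#>   refined_loci       3
#>   consistent_loci    3
#>   synteny_blocks     3
```

1,665 simulated proteins produce 288 homolog groups; exactly 5 groups
survive the phenotype filter (the planted cluster families), they chain
into one locus per producer genome (3 loci), and each locus shows
conserved synteny in the other producers. `disc$loci` lists the member
genes — here exactly the 15 planted cluster genes, nothing else.

```r
scr_sim <- simulate_genomes(sim_config(seed = 101, n_taxa = 10,
                                       producer_clade_size = 6,
                                       cluster_relatives = TRUE,
                                       n_background_families = 20))
scr <- screen_genome(scr_sim$truth$recipient, scr_sim$genes,
                     donor_taxa = scr_sim$truth$donor_clade, seed = 2)
scr
#> <ch_hgt_screen>
#>   queries                        29
#>   best_hit                       5
#>   prefilter                      5
#>   supported                      5
#>   constraint_rejected_vertical   5
```

Of the recipient's 29 genes, exactly its 5 transferred cluster genes
pass every stage, and the constrained (vertical) topology is rejected
for each (p = 0 at 1000 RELL resamples): the screen recovers the planted
transfer and nothing else.

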