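# Phenotype filtering, co-localization, boundary refinement, synteny.

mk_groups <- function(...) {
  # list of group_id = c("genome:gene", ...)
  specs <- list(...)
  dplyr::bind_rows(lapply(names(specs), function(g) {
    parts <- strsplit(specs[[g]], ":")
    tibble::tibble(group_id = g,
                   genome_id = vapply(parts, `[`, "", 1),
                   gene_id = vapply(parts, `[`, "", 2))
  }))
}

meta6 <- tibble::tibble(
  genome_id = paste0("g", 1:6),
  phenotype = c("PS_plus", "PS_plus", "PS_plus",
                "PS_minus", "PS_minus", "PS_minus"),
  ecology = rep(list("wood"), 6)
)

test_that("taxon filter keeps groups in all producers and bounded negatives", {
  groups <- mk_groups(
    G1 = c("g1:a", "g2:b", "g3:c"),                 # 3/3 PS+, 0 PS-
    G2 = c("g1:d", "g2:e"),                         # 2/3 PS+
    G3 = c("g1:f", "g2:g", "g3:h", "g4:i", "g5:j")  # 3/3 PS+, 2 PS-
  )
  for (lvl in 0:3) {
    got <- taxon_filter_groups(groups, meta6, lvl)
    expect_true("G1" %in% got$group_id)             # retained at every level
    expect_false("G2" %in% got$group_id)            # never retained
  }
  expect_false("G3" %in% taxon_filter_groups(groups, meta6, 1)$group_id)
  expect_true("G3" %in% taxon_filter_groups(groups, meta6, 2)$group_id)
  bad_meta <- meta6
  bad_meta$phenotype <- "PS_minus"
  expect_error(taxon_filter_groups(groups, bad_meta, 1), "no PS\\+")
})

test_that("staged filter counts form a consistent audit trail", {
  groups <- mk_groups(
    G1 = paste0("g", 1:6, ":x"),                    # universal
    G2 = c("g1:a", "g2:b", "g3:c"),                 # all PS+, not universal
    G3 = c("g4:z")                                  # singleton in a PS-
  )
  rep_ <- filter_counts_report(groups, meta6)
  expect_equal(rep_$total, 3L)
  expect_equal(rep_$in_all_ps_plus, 2L)
  expect_equal(rep_$in_all_genomes, 1L)
  expect_equal(rep_$remaining, 1L)
  # all groups universal -> remaining 0
  uni <- mk_groups(G1 = paste0("g", 1:6, ":x"), G2 = paste0("g", 1:6, ":y"))
  expect_equal(filter_counts_report(uni, meta6)$remaining, 0L)
  # disjoint singletons -> in_all_ps_plus 0
  sing <- mk_groups(G1 = "g1:a", G2 = "g2:b")
  expect_equal(filter_counts_report(sing, meta6)$in_all_ps_plus, 0L)
  # bookkeeping identity on simulated data: groups from the truth log
  sim <- small_sim(13, n_background_families = 60)
  tg <- tibble::tibble(group_id = sim$truth$gene_map$family_id,
                       genome_id = sim$truth$gene_map$genome_id,
                       gene_id = sim$truth$gene_map$gene_id)
  rep2 <- filter_counts_report(tg, sim$meta)
  producers <- sim$truth$producers
  truth_all_plus <- sum(apply(sim$truth$presence[producers, , drop = FALSE],
                              2, all))
  expect_equal(rep2$in_all_ps_plus, truth_all_plus)
})

genes_line <- function(idx, genome = "g1", scaffold = "s1") {
  tibble::tibble(genome_id = genome, scaffold_id = scaffold,
                 order_index = idx, gene_id = paste0(genome, ".", idx),
                 function_label = NA_character_)
}

test_that("co-localization respects the six-intervening-gene boundary exactly", {
  genes <- genes_line(0:30)
  p <- ch_params()
  cand <- function(idx, grp) tibble::tibble(
    group_id = grp, genome_id = "g1", gene_id = paste0("g1.", idx))
  # 10 and 17: six intervening -> one locus
  loci <- find_colocalized(dplyr::bind_rows(cand(10, "GA"), cand(17, "GB")),
                           genes, p)
  expect_equal(dplyr::n_distinct(loci$locus_id), 1L)
  # 10 and 18: seven intervening -> none
  loci2 <- find_colocalized(dplyr::bind_rows(cand(10, "GA"), cand(18, "GB")),
                            genes, p)
  expect_equal(nrow(loci2), 0L)
  # 3, 8, 14 chain into one merged three-gene locus
  loci3 <- find_colocalized(dplyr::bind_rows(cand(3, "GA"), cand(8, "GB"),
                                             cand(14, "GC")), genes, p)
  expect_equal(dplyr::n_distinct(loci3$locus_id), 1L)
  expect_setequal(loci3$order_index, c(3L, 8L, 14L))
  # tandem copies of a single family never form a locus
  loci4 <- find_colocalized(dplyr::bind_rows(cand(3, "GA"), cand(5, "GA")),
                            genes, p)
  expect_equal(nrow(loci4), 0L)
})

test_that("chaining equals the brute-force oracle on random scaffolds", {
  set.seed(20)
  for (rep in 1:30) {
    n <- sample(30:120, 1)
    genes <- genes_line(0:(n - 1))
    k <- sample(3:10, 1)
    pick <- sort(sample(0:(n - 1), k))
    cand <- tibble::tibble(
      group_id = paste0("G", sample(1:4, k, TRUE)),
      genome_id = "g1", gene_id = paste0("g1.", pick)
    )
    for (mi in c(0L, 3L, 6L, 10L)) {
      p <- suppressMessages(ch_params(max_intervening = mi))
      got <- find_colocalized(cand, genes, p)
      ora <- coloc_oracle(dplyr::inner_join(
        cand, genes, by = c("genome_id", "gene_id")), mi)
      got_sets <- sort(vapply(split(got$order_index, got$locus_id),
                              function(x) paste(sort(x), collapse = ","), ""))
      ora_sets <- sort(vapply(ora,
                              function(m) paste(sort(m$order_index),
                                                collapse = ","), ""))
      expect_identical(unname(got_sets), unname(ora_sets))
    }
  }
})

test_that("loci are invariant under reversal of scaffold gene order", {
  set.seed(21)
  n <- 60
  genes <- genes_line(0:(n - 1))
  pick <- sort(sample(0:(n - 1), 6))
  cand <- tibble::tibble(group_id = paste0("G", 1:6), genome_id = "g1",
                         gene_id = paste0("g1.", pick))
  p <- ch_params()
  fwd <- find_colocalized(cand, genes, p)
  rev_genes <- genes
  rev_genes$order_index <- (n - 1L) - rev_genes$order_index
  bwd <- find_colocalized(cand, rev_genes, p)
  fwd_sets <- sort(vapply(split(fwd$gene_id, fwd$locus_id),
                          function(x) paste(sort(x), collapse = ","), ""))
  bwd_sets <- sort(vapply(split(bwd$gene_id, bwd$locus_id),
                          function(x) paste(sort(x), collapse = ","), ""))
  expect_identical(unname(fwd_sets), unname(bwd_sets))
})

test_that("boundary refinement admits phenotype-consistent syntenic flanks only", {
  p <- ch_params()
  # three producer genomes with a two-gene seed locus at 10/11, a
  # PS+-restricted flank at 19 in all three (outside the chain, inside the window), and a universal flank at 13
  mk_genome <- function(g) genes_line(0:25, genome = g, scaffold = "s1")
  genes <- dplyr::bind_rows(lapply(paste0("g", 1:6), mk_genome))
  groups <- dplyr::bind_rows(
    mk_groups(SEED1 = paste0("g", 1:3, ":g", 1:3, ".10"),
              SEED2 = paste0("g", 1:3, ":g", 1:3, ".11"),
              FLANK = paste0("g", 1:3, ":g", 1:3, ".19"),
              UNIV = paste0("g", 1:6, ":g", 1:6, ".13"))
  )
  cand <- taxon_filter_groups(groups, meta6, 1)
  loci <- find_colocalized(cand, genes, p)
  ref <- refine_boundaries(loci, genes, groups, meta6, p)
  for (lid in unique(ref$locus_id)) {
    sub <- ref[ref$locus_id == lid, ]
    expect_true("FLANK" %in% sub$group_id)     # PS+-only flank admitted
    expect_false("UNIV" %in% sub$group_id)     # universal flank rejected
  }
  # no candidate flanks: output equals input
  groups2 <- mk_groups(SEED1 = paste0("g", 1:3, ":g", 1:3, ".10"),
                       SEED2 = paste0("g", 1:3, ":g", 1:3, ".11"))
  cand2 <- taxon_filter_groups(groups2, meta6, 1)
  loci2 <- find_colocalized(cand2, genes, p)
  ref2 <- refine_boundaries(loci2, genes, groups2, meta6, p)
  expect_equal(dplyr::arrange(ref2, locus_id, order_index)[, -1],
               dplyr::arrange(loci2, locus_id, order_index)[, -1])
})

test_that("synteny blocks obey the intervening rule and recover planted clusters", {
  sim <- small_sim(13, n_background_families = 60)
  p <- ch_params()
  edges <- pairwise_similarity(sim$genes, p)
  truth_groups <- tibble::tibble(group_id = sim$truth$gene_map$family_id,
                                 genome_id = sim$truth$gene_map$genome_id,
                                 gene_id = sim$truth$gene_map$gene_id)
  cand <- taxon_filter_groups(truth_groups, sim$meta, 1)
  cand <- cand[grepl("^CL", cand$group_id), ]
  loci <- find_colocalized(cand, sim$genes, p)
  producers <- sim$truth$producers
  lid <- unique(loci$locus_id[loci$genome_id == producers[1]])[1]
  locus <- loci[loci$locus_id == lid, ]
  blocks <- detect_synteny(locus, sim$genes, edges, p)
  # self-synteny: the locus genome carries a block equal to the locus
  self_block <- blocks[blocks$target_genome == locus$genome_id[1], ]
  expect_setequal(self_block$target_gene, locus$gene_id)
  # every producer genome carries a recovered copy
  expect_setequal(intersect(unique(blocks$target_genome), producers),
                  producers)
  cl_genes <- sim$truth$cluster_genes
  for (g in producers) {
    got <- sort(blocks$target_gene[blocks$target_genome == g])
    expect_setequal(got, cl_genes$gene_id[cl_genes$genome_id == g])
  }
})

test_that("homologs further than six intervening genes apart form no block", {
  p <- ch_params()
  # locus of two genes in gA; gB has homologs 8 apart
  genes <- dplyr::bind_rows(genes_line(0:20, "gA"), genes_line(0:20, "gB"))
  locus <- tibble::tibble(locus_id = "L1", genome_id = "gA",
                          scaffold_id = "s1", start_index = 0L,
                          end_index = 1L, gene_id = c("gA.0", "gA.1"),
                          group_id = c("G1", "G2"), order_index = 0:1)
  edge1 <- tibble::tibble(query_genome = "gA", query_gene = c("gA.0", "gA.1"),
                          hit_genome = "gB", hit_gene = c("gB.0", "gB.8"),
                          raw_score = 500, evalue = 1e-30, similarity = 0.9)
  blocks <- detect_synteny(locus, genes, edge1, p)
  expect_false("gB" %in% blocks$target_genome)
  # 6 apart: block forms
  edge2 <- edge1
  edge2$hit_gene <- c("gB.0", "gB.7")
  blocks2 <- detect_synteny(locus, genes, edge2, p)
  expect_true("gB" %in% blocks2$target_genome)
})
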