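# Transfer screening: best-hit filter, topology filters, constraint test.

test_that("best-hit filter ranks hits without same-genome paralogs", {
  queries <- tibble::tibble(genome_id = "R", gene_id = c("q1", "q2", "q3", "q4"))
  mk_edge <- function(q, hg, h, s) tibble::tibble(
    query_genome = "R", query_gene = q, hit_genome = hg, hit_gene = h,
    raw_score = s, evalue = 1e-30, similarity = 0.8)
  edges <- dplyr::bind_rows(
    mk_edge("q1", "D", "d1", 500),  mk_edge("q1", "B", "b1", 400),
    # q2: top hit is a same-genome paralog; donor is next
    mk_edge("q2", "R", "par", 900), mk_edge("q2", "D", "d2", 300),
    mk_edge("q2", "B", "b2", 200),
    # q3: best hit from a non-donor genome
    mk_edge("q3", "B", "b3", 600),  mk_edge("q3", "D", "d3", 100)
  )
  kept <- best_hit_filter(queries, edges, donor_taxa = "D")
  expect_setequal(kept$gene_id, c("q1", "q2"))
  expect_equal(kept$hit_gene[kept$gene_id == "q2"], "d2")
  expect_equal(attr(kept, "n_no_hits"), 1L)     # q4 has no hits
  # donor-set monotonicity: enlarging donors never shrinks the retained set
  kept2 <- best_hit_filter(queries, edges, donor_taxa = c("D", "B"))
  expect_true(all(kept$gene_id %in% kept2$gene_id))
})

# hand-built gene trees; leaf labels genome|gene
read_g <- function(txt) ape::read.tree(text = txt)

test_that("topology prefilter needs a donor sister and two separating nodes", {
  p <- ch_params()
  # cherry (q, donor); two more donor-only joins before background
  tr <- read_g("((((R|q:1,D|d1:1):1,D|d2:1):1,D|d3:1):1,B|b1:3);")
  expect_true(topology_prefilter(tr, "R|q", "D", "B", p))
  # query sister to a background leaf
  tr2 <- read_g("(((R|q:1,B|b1:1):1,D|d1:1):1,D|d2:2);")
  expect_false(topology_prefilter(tr2, "R|q", "D", "B", p))
  # background joins at the very next node: only one separating node
  tr3 <- read_g("(((R|q:1,D|d1:1):1,B|b1:1):1,D|d2:2);")
  expect_false(topology_prefilter(tr3, "R|q", "D", "B", p))
  expect_error(topology_prefilter(tr3, "R|zz", "D", "B", p), "not in tree")
})

test_that("supported nesting filter needs three supported containment nodes", {
  p <- ch_params()
  mk <- function(s1, s2, s3) read_g(sprintf(
    "((((((R|q:1,D|d1:1)%d:1,D|d2:1)%d:1,D|d3:1)%d:1,D|d4:1):1,D|d5:3):1,B|out:4);",
    s1, s2, s3))
  expect_true(supported_nesting_filter(mk(95, 88, 80), "R|q", "D", "D", p))
  expect_false(supported_nesting_filter(mk(95, 60, 80), "R|q", "D", "D", p))
  # a tree made wholly of surrounding-group leaves offers no frame for
  # nesting: never retained
  allin <- read_g(
    "(((((R|q:1,D|d1:1)95:1,D|d2:1)88:1,D|d3:1)80:1,D|d4:1):1,D|d5:3);")
  expect_false(supported_nesting_filter(allin, "R|q", "D", "D", p))
  # query and donor not adjacent
  tr <- read_g("((((D|d1:1,D|d2:1)95:1,R|q:1)88:1,D|d3:1)80:1,D|d4:3);")
  expect_false(supported_nesting_filter(tr, "R|q", "X", "D", p))
  # supports absent -> error
  tr_nosup <- read_g("((R|q:1,D|d1:1):1,D|d2:2);")
  expect_error(supported_nesting_filter(tr_nosup, "R|q", "D", "D", p),
               "support")
})

test_that("vertical constraint test rejects under transfer, accepts under vertical", {
  p <- ch_params()
  # transfer scenario: recipient sequence really sits inside the donors;
  # the deep out-paralogs provide the outgroup that anchors the rooting
  sim <- simulate_genomes(sim_config(seed = 41, n_taxa = 10,
                                     producer_clade_size = 6,
                                     cluster_relatives = TRUE,
                                     n_background_families = 5))
  fam <- sim$genes[sim$genes$family_id %in% c("CL1", "CL1R"), ]
  aln <- stats::setNames(fam$protein_seq,
                         clusterhgt:::gene_key(fam$genome_id, fam$gene_id))
  cl <- sim$truth$cluster_genes
  fam <- cl[cl$family_id == "CL1", ]
  qkey <- clusterhgt:::gene_key(sim$truth$recipient,
                                fam$gene_id[fam$genome_id == sim$truth$recipient])
  opt <- nj_tree(poisson_distance(aln))
  res <- vertical_constraint_test(aln, opt, qkey, sim$truth$donor_clade,
                                  params = p, seed = 3)
  expect_true(res$reject)
  # vertical scenario: constraining the query outside the "donor" clade is
  # the truth, so the test must not reject
  sim0 <- simulate_genomes(sim_config(seed = 42, n_taxa = 10,
                                      producer_clade_size = 6,
                                      hgt_cluster = FALSE,
                                      cluster_relatives = TRUE,
                                      n_background_families = 5))
  famg0 <- sim0$genes[sim0$genes$family_id %in% c("CL1", "CL1R"), ]
  aln0 <- stats::setNames(famg0$protein_seq,
                          clusterhgt:::gene_key(famg0$genome_id,
                                                famg0$gene_id))
  cl0 <- sim0$truth$cluster_genes
  fam0 <- cl0[cl0$family_id == "CL1", ]
  qkey0 <- clusterhgt:::gene_key(
    sim0$truth$recipient, fam0$gene_id[fam0$genome_id == sim0$truth$recipient])
  opt0 <- nj_tree(poisson_distance(aln0))
  res0 <- vertical_constraint_test(aln0, opt0, qkey0, sim0$truth$donor_clade,
                                   params = p, seed = 3)
  expect_false(res0$reject)
  # constraint unbuildable without donors or relatives
  expect_error(vertical_constraint_test(aln, opt, qkey, character(),
                                        params = p), "unbuildable")
})

test_that("screen stages are monotone and an empty recipient yields an empty report", {
  sim <- simulate_genomes(sim_config(seed = 43, n_taxa = 10,
                                     producer_clade_size = 6,
                                     cluster_relatives = TRUE,
                                     n_background_families = 20))
  p <- ch_params()
  scr <- screen_genome(sim$truth$recipient, sim$genes,
                       donor_taxa = sim$truth$donor_clade, params = p,
                       seed = 1)
  counts <- stats::setNames(scr$report$n, scr$report$stage)
  expect_lte(counts[["best_hit"]], counts[["queries"]])
  expect_lte(counts[["prefilter"]], counts[["best_hit"]])
  expect_lte(counts[["supported"]], counts[["prefilter"]])
  expect_lte(counts[["constraint_rejected_vertical"]], counts[["supported"]])
  # the five transferred cluster genes are flagged
  cl <- sim$truth$cluster_genes
  rec_genes <- cl$gene_id[cl$genome_id == sim$truth$recipient]
  flagged <- scr$candidates$gene_id[
    scr$candidates$stage_passed == "constraint_rejected_vertical"]
  expect_setequal(intersect(flagged, rec_genes), rec_genes)
  # empty recipient
  scr0 <- screen_genome("nosuch", sim$genes, sim$truth$donor_clade, p)
  expect_equal(nrow(scr0$candidates), 0L)
  expect_equal(sum(scr0$report$n), 0L)
  # tidiers
  expect_s3_class(tidy(scr), "tbl_df")
  expect_equal(glance(scr)$queries, counts[["queries"]])
})
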