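# Distances, neighbor joining, bootstrap, rooting, clade reduction,
# consensus species tree.

test_that("trim_columns drops gap-rich columns and nothing else", {
  aln <- c(A = "MK-V", B = "MC-V", C = "M--V")
  expect_equal(trim_columns(aln, 0.5), c(A = "MKV", B = "MCV", C = "M-V"))
  gapless <- c(A = "MKV", B = "MCV")
  expect_equal(trim_columns(gapless, 0.5), gapless)
  # hand-enumerated mixed case: col2 gap fraction 2/3 > 0.5, col4 1/3 kept
  aln2 <- c(A = "A-CD", B = "A-C-", C = "AACD")
  expect_equal(trim_columns(aln2, 0.5), c(A = "ACD", B = "AC-", C = "ACD"))
  expect_error(trim_columns(c(A = "MK", B = "MKV")), "ragged")
})

test_that("poisson distance matches its closed form and is symmetric", {
  expect_equal(unname(poisson_distance(c(a = "MKVL", b = "MKVL"))[1, 2]), 0)
  # p = 0.5 -> -ln(0.5)
  aln <- c(a = "AAAA", b = "AACC")
  expect_equal(unname(poisson_distance(aln)[1, 2]), -log(0.5),
               tolerance = 1e-12)
  set.seed(2)
  aa <- rownames(clusterhgt:::blosum62_matrix())
  r <- vapply(1:5, function(i) paste(sample(aa, 40, TRUE), collapse = ""), "")
  names(r) <- letters[1:5]
  D <- poisson_distance(r)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  # saturation cap
  expect_lte(max(D), -log(1 - 0.95) + 1e-12)
  expect_error(poisson_distance(c(a = "M-", b = "-K")), "no shared")
})

test_that("NJ recovers additive 4-taxon trees exactly, and 3-taxon lengths are closed form", {
  # additive matrix from a known tree ((A:2,B:3):1,(C:4,D:5));
  tr <- ape::read.tree(text = "((A:2,B:3):1,(C:4,D:5):0);")
  D <- ape::cophenetic.phylo(tr)
  out <- nj_tree(D)
  expect_equal(as.numeric(ape::dist.topo(out, ape::unroot(tr))), 0)
  expect_equal(ape::cophenetic.phylo(out)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)
  # three labels: d(a,x) = (dab + dac - dbc)/2
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(D3)
  el <- stats::setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(unname(el["a"]), (3 + 4 - 5) / 2)
  expect_equal(unname(el["b"]), (3 + 5 - 4) / 2)
  expect_equal(unname(el["c"]), (4 + 5 - 3) / 2)
  expect_error(nj_tree(D3[1:2, 1:2]), "at least 3")
})

test_that("NJ topology recovery on additive distances, 100 random 8-leaf trees", {
  set.seed(4)
  for (k in 1:100) {
    tr <- ape::rtree(8, br = function(n) stats::runif(n, 0.1, 1))
    D <- ape::cophenetic.phylo(tr)
    out <- nj_tree(D)
    expect_equal(as.numeric(ape::dist.topo(out, ape::unroot(tr))), 0)
    expect_equal(max(abs(ape::cophenetic.phylo(out)[rownames(D),
                                                    colnames(D)] - D)), 0,
                 tolerance = 1e-9)
  }
})

test_that("bootstrap supports are deterministic given the seed and high under strong signal", {
  sim_tree <- ape::read.tree(text = "((A:0.3,B:0.3):0.25,(C:0.3,D:0.3):0.25,(E:0.3,F:0.3):0.2);")
  set.seed(10)
  aln <- evolve_family_sequences(sim_tree, LETTERS[1:6], 800L)
  b1 <- bootstrap_tree(aln, n = 100, seed = 42)
  b2 <- bootstrap_tree(aln, n = 100, seed = 42)
  expect_identical(ape::write.tree(b1), ape::write.tree(b2))
  sup <- tree_supports(b1)
  sup <- sup[-1]
  expect_true(all(sup >= 95))
  expect_error(bootstrap_tree(aln, n = 0), "positive")
})

test_that("near-star data yields weak internal support", {
  star <- ape::read.tree(text = "((A:0.5,B:0.5):0.0001,(C:0.5,D:0.5):0.0001,(E:0.5,F:0.5):0.0001);")
  set.seed(11)
  aln <- evolve_family_sequences(star, LETTERS[1:6], 200L)
  sup <- tree_supports(bootstrap_tree(aln, n = 100, seed = 1))
  # the three cherries are solid; the backbone splits are not.  With six
  # leaves the point tree has at most one backbone split beyond the
  # cherries; require that some internal support is weak
  expect_lt(min(sup[-1], na.rm = TRUE), 80)
})

test_that("rooting picks the leaf most distant from the query, ties lexicographic", {
  tr <- ape::read.tree(text = "(q:1,(a:0.5,b:4.5):0.5);")
  r <- root_at_most_distant(tr, "q")
  # b at distance 6 is the outgroup: root's children separate b from the rest
  kids <- r$edge[r$edge[, 1] == ape::Ntip(r) + 1, 2]
  tipsets <- lapply(kids, function(k) clusterhgt:::clade_tips(r, k))
  expect_true(any(vapply(tipsets, identical, TRUE, y = "b")))
  tie <- ape::read.tree(text = "(q:1,(b:2,a:2):1);")
  r2 <- root_at_most_distant(tie, "q")
  kids2 <- r2$edge[r2$edge[, 1] == ape::Ntip(r2) + 1, 2]
  tipsets2 <- lapply(kids2, function(k) clusterhgt:::clade_tips(r2, k))
  expect_true(any(vapply(tipsets2, identical, TRUE, y = "a")))
  # property: the chosen root leaf attains the maximal path length (oracle:
  # all-pairs distances)
  set.seed(12)
  for (k in 1:20) {
    tr <- ape::rtree(7)
    q <- sample(tr$tip.label, 1)
    r <- root_at_most_distant(tr, q)
    kids <- r$edge[r$edge[, 1] == ape::Ntip(r) + 1, 2]
    og <- unlist(lapply(kids, function(kk) clusterhgt:::clade_tips(r, kk)))
    og <- setdiff(og, q)
    dm <- ape::cophenetic.phylo(tr)
    picked <- og[which.max(dm[q, og])]
    expect_equal(max(dm[q, setdiff(tr$tip.label, q)]), max(dm[q, og]))
  }
  expect_error(root_at_most_distant(ape::rtree(4, br = NULL), "t1"),
               "branch lengths")
})

test_that("reduce_to_supported_clade honours size and support bounds", {
  p <- ch_params()
  # 50-leaf tree, all supports 100: whole leaf set (size bound slack)
  tr <- ape::rtree(50)
  tr$node.label <- as.character(rep(100, tr$Nnode))
  out <- reduce_to_supported_clade(tr, tr$tip.label[1], p)
  expect_setequal(out, tr$tip.label)
  # 300-leaf backbone with a supported 40-leaf island around the query
  big <- ape::rtree(300)
  big$node.label <- as.character(rep(10, big$Nnode))
  # find a clade of moderate size and mark it supported
  sizes <- vapply((ape::Ntip(big) + 1):(ape::Ntip(big) + big$Nnode),
                  function(n) length(clusterhgt:::clade_tips(big, n)), 1L)
  node <- which(sizes >= 30 & sizes <= 60)[1] + ape::Ntip(big)
  tips <- clusterhgt:::clade_tips(big, node)
  big$node.label[node - ape::Ntip(big)] <- "95"
  q <- tips[1]
  got <- reduce_to_supported_clade(big, q, p)
  expect_setequal(got, tips)
  # exhaustive oracle: largest qualifying clade containing the query
  sup <- tree_supports(big)
  best <- character()
  for (nd in seq_len(big$Nnode)) {
    tt <- clusterhgt:::clade_tips(big, nd + ape::Ntip(big))
    if (q %in% tt && length(tt) <= p$max_clade_leaves &&
        !is.na(sup[nd]) && sup[nd] >= p$support_threshold &&
        length(tt) > length(best)) best <- tt
  }
  expect_setequal(got, best)
  # no qualifying clade: fall back to the smallest containing clade
  big$node.label[node - ape::Ntip(big)] <- "10"
  expect_warning(out2 <- reduce_to_supported_clade(big, q, p),
                 "no supported clade")
  expect_false(attr(out2, "qualified"))
})

test_that("extended majority-rule consensus keeps majority splits and adds compatible ones", {
  t1 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  t2 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  t3 <- ape::read.tree(text = "((A,C),(B,(D,E)));")
  cons <- extended_majority_consensus(list(t1, t2, t3))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(cons), ape::unroot(t1))), 0)
  # all trees identical -> consensus is that topology
  cons2 <- extended_majority_consensus(list(t1, t1, t1))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(cons2), ape::unroot(t1))), 0)
})

test_that("the consensus species tree recovers the generating topology", {
  sim <- small_sim(31, n_background_families = 60, seq_length = 250L)
  p <- ch_params()
  groups <- tibble::tibble(group_id = sim$truth$gene_map$family_id,
                           genome_id = sim$truth$gene_map$genome_id,
                           gene_id = sim$truth$gene_map$gene_id)
  st <- suppressWarnings(build_species_tree(sim$genes, groups, p,
                                            quota = 15L, seed = 2))
  expect_equal(as.numeric(ape::dist.topo(
    ape::unroot(st), ape::unroot(sim$truth$species_tree))), 0)
})
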