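# Genome-content matrix, ordination, loading selection, enrichment, niches.

test_that("count-matrix filtering drops singleton and universal groups", {
  groups <- dplyr::bind_rows(
    tibble::tibble(group_id = "Gsolo", genome_id = "g1", gene_id = "a"),
    tibble::tibble(group_id = "Gall", genome_id = paste0("g", 1:4),
                   gene_id = paste0("b", 1:4)),
    tibble::tibble(group_id = "Gpair", genome_id = c("g1", "g2"),
                   gene_id = c("c1", "c2"))
  )
  m <- build_and_filter_matrix(groups, paste0("g", 1:4))
  expect_equal(colnames(m), "Gpair")
  expect_equal(unname(m[, "Gpair"]), c(1L, 1L, 0L, 0L))
  solo_only <- groups[groups$group_id == "Gsolo", ]
  expect_error(build_and_filter_matrix(solo_only, paste0("g", 1:4)),
               "no informative")
})

test_that("PCA matches an eigendecomposition oracle and fixes signs", {
  set.seed(30)
  for (k in 1:10) {
    m <- matrix(rpois(6 * 20, 4), 6, 20,
                dimnames = list(paste0("g", 1:6), paste0("G", 1:20)))
    m <- m[, apply(m, 2, stats::var) > 0, drop = FALSE]
    ord <- pca_content(m)
    expect_equal(sum(ord$variance_fraction), 1, tolerance = 1e-9)
    # the eigendecomposition oracle carries p eigenvalues; prcomp returns
    # min(n-1, p) components, the rest are numerically zero
    ev <- eigen(stats::cor(m), symmetric = TRUE)$values
    k <- length(ord$variance_fraction)
    expect_equal(ord$variance_fraction[1:(k - 1)],
                 (ev / sum(ev))[1:(k - 1)], tolerance = 1e-9)
    expect_lt(max(abs(ev[k:length(ev)] / sum(ev))), 1e-12)
    # loadings orthonormal
    L <- as.matrix(ord$loadings[, -1])
    expect_equal(crossprod(L), diag(ncol(L)), ignore_attr = TRUE,
                 tolerance = 1e-9)
    # sign convention
    for (j in seq_len(ncol(L))) {
      expect_gt(L[which.max(abs(L[, j])), j], 0)
    }
    # reconstruction of the scaled matrix from all PCs
    S <- scale(m)
    expect_equal(as.matrix(ord$scores[, -1]) %*% t(L), unclass(S),
                 ignore_attr = TRUE, tolerance = 1e-9)
  }
})

test_that("two distinct duplicated genomes put all variance on PC1", {
  m <- rbind(a = c(5, 1, 3, 2), b = c(1, 4, 2, 6),
             a2 = c(5, 1, 3, 2), b2 = c(1, 4, 2, 6))
  colnames(m) <- paste0("G", 1:4)
  ord <- suppressWarnings(pca_content(m))
  expect_equal(ord$variance_fraction[1], 1, tolerance = 1e-9)
})

test_that("permuting genome rows permutes scores identically", {
  set.seed(31)
  m <- matrix(rpois(8 * 12, 3), 8, 12,
              dimnames = list(paste0("g", 1:8), paste0("G", 1:12)))
  m <- m[, apply(m, 2, stats::var) > 0, drop = FALSE]
  ord1 <- pca_content(m)
  perm <- sample(nrow(m))
  ord2 <- pca_content(m[perm, ])
  j1 <- dplyr::arrange(ord1$scores, genome_id)
  j2 <- dplyr::arrange(ord2$scores, genome_id)
  expect_equal(j1, j2, tolerance = 1e-9)
})

test_that("loading selection matches a percentile oracle", {
  set.seed(32)
  ld <- tibble::tibble(group_id = paste0("G", 1:150),
                       PC1 = c(stats::runif(100, 0.001, 1),
                               -stats::runif(50, 0.001, 1)))
  ord <- structure(list(loadings = ld), class = "ch_ordination")
  sel <- select_loading_groups(ord, 1, 95)
  pos <- ld$PC1[ld$PC1 > 0]
  cutoff <- stats::quantile(pos, 0.95, type = 7)
  expect_setequal(sel$positive, ld$group_id[ld$PC1 >= cutoff & ld$PC1 > 0])
  expect_equal(length(sel$positive), sum(pos >= cutoff))
  # all loadings negative -> positive set empty
  ld2 <- tibble::tibble(group_id = paste0("G", 1:10), PC1 = -runif(10))
  ord2 <- structure(list(loadings = ld2), class = "ch_ordination")
  expect_length(select_loading_groups(ord2, 1, 95)$positive, 0L)
  # a single positive loading selects itself
  ld3 <- tibble::tibble(group_id = c("Ga", "Gb"), PC1 = c(0.8, -0.2))
  ord3 <- structure(list(loadings = ld3), class = "ch_ordination")
  expect_equal(select_loading_groups(ord3, 1, 95)$positive, "Ga")
})

test_that("Fisher enrichment matches the closed-form hypergeometric", {
  ann <- tibble::tibble(group_id = paste0("G", 1:20),
                        category = rep(c("K1", "K2"), each = 10))
  res <- category_enrichment(paste0("G", 1:10), ann, paste0("G", 1:20),
                             alpha = 0.05, n_tests = 4)
  # [[10,0],[0,10]]: p = 1/choose(20,10)
  expect_equal(res$p[res$category == "K1"], 1 / choose(20, 10),
               tolerance = 1e-12)
  # no overlap: one-tailed enrichment p = 1
  expect_equal(res$p[res$category == "K2"], 1, tolerance = 1e-12)
  expect_true(res$significant[res$category == "K1"])
})

test_that("niche-specific selection follows the cutoffs and dual-label rule", {
  meta <- tibble::tibble(
    genome_id = paste0("g", 1:9),
    phenotype = "unknown",
    ecology = list("dung", "dung", "dung", "wood", "wood", "wood", "wood",
                   c("dung", "wood"), "mycorrhizal")
  )
  mk <- function(g, gid) tibble::tibble(group_id = gid, genome_id = g,
                                        gene_id = paste0(g, ".", gid))
  groups <- dplyr::bind_rows(
    mk(c("g1", "g2", "g3"), "D3"),          # 3 dung only -> dung-specific
    mk(c("g1", "g2", "g4"), "DMIX"),        # dung + a wood genome -> excluded
    mk(c("g1", "g2"), "D2"),                # below dung cutoff
    mk(c("g4", "g5", "g6", "g7"), "W4"),    # 4 wood -> wood-specific
    mk(c("g1", "g2", "g8"), "DDUAL"),       # dual genome counts as dung
    mk("g9", "E1")                          # 1 ecm < cutoff 2
  )
  tr <- ape::rtree(9)
  tr$tip.label <- paste0("g", 1:9)
  res <- niche_specific_groups(groups, meta, species_tree = tr)
  dung <- res$group_id[res$niche == "dung"]
  expect_setequal(dung, c("D3", "DDUAL"))
  expect_setequal(res$group_id[res$niche == "wood"], "W4")
  expect_false("E1" %in% res$group_id)
  # missing ecology metadata errors
  expect_error(niche_specific_groups(mk("gX", "Z"), meta), "gX")
})

test_that("polyphyly flag marks non-clade presence sets", {
  tr <- ape::read.tree(text = "((g1,g2),(g3,g4));")
  meta <- tibble::tibble(genome_id = paste0("g", 1:4), phenotype = "unknown",
                         ecology = rep(list("dung"), 4))
  mk <- function(g, gid) tibble::tibble(group_id = gid, genome_id = g,
                                        gene_id = paste0(g, ".", gid))
  groups <- dplyr::bind_rows(
    mk(c("g1", "g2", "g3"), "POLY"),   # not a clade
    mk(c("g1", "g2"), "CLADE")         # a cherry
  )
  res <- niche_specific_groups(groups, meta, species_tree = tr,
                               cutoffs = c(dung = 2L, wood = 4L, ecm = 2L))
  expect_true(res$polyphyletic[res$group_id == "POLY"])
  expect_false(res$polyphyletic[res$group_id == "CLADE"])
})

test_that("ecology-linked families are recovered exactly from simulated data", {
  sim <- simulate_genomes(sim_config(seed = 51, n_taxa = 16,
                                     n_background_families = 150,
                                     ecology_linked_fraction = 0.2,
                                     hgt_cluster = TRUE))
  tg <- tibble::tibble(group_id = sim$truth$gene_map$family_id,
                       genome_id = sim$truth$gene_map$genome_id,
                       gene_id = sim$truth$gene_map$gene_id)
  got <- niche_specific_groups(tg, sim$meta,
                               species_tree = sim$truth$species_tree)
  # oracle: apply the niche rule directly to the true presence matrix
  label_of <- c(dung = "dung", wood = "wood", ecm = "mycorrhizal")
  cutoffs <- c(dung = 3L, wood = 4L, ecm = 2L)
  eco <- stats::setNames(sim$meta$ecology, sim$meta$genome_id)
  for (niche in names(cutoffs)) {
    members <- names(eco)[vapply(eco, function(e) label_of[[niche]] %in% e,
                                 TRUE)]
    pres <- sim$truth$presence
    expected <- colnames(pres)[apply(pres, 2, function(col) {
      carriers <- rownames(pres)[col]
      sum(carriers %in% members) >= cutoffs[[niche]] &&
        all(carriers %in% members)
    })]
    expect_setequal(got$group_id[got$niche == niche], expected)
  }
})
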