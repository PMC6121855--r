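# Genome-wide horizontal-transfer screening: best-hit filtering, preliminary
# tree topology filtering, supported-tree nesting filtering, and the
# constrained-topology likelihood test.

#' Stage 1: best-hit filter
#'
#' Retains queries whose best-scoring hit (same-genome hits are excluded
#' from the ranking, so paralogs cannot mask a donor signal) comes from a
#' donor taxon.  Ties are broken by higher raw score, then lexicographic
#' hit id.  Queries without any hit are dropped silently but counted.
#'
#' @param queries tibble with `genome_id`, `gene_id` (the recipient genes).
#' @param edges similarity edges from [pairwise_similarity()].
#' @param donor_taxa character vector of donor genome ids.
#' @return Tibble of retained queries with their best hit (`genome_id`,
#'   `gene_id`, `hit_genome`, `hit_gene`, `raw_score`); attribute
#'   `n_no_hits` counts queries without hits.
#' @export
best_hit_filter <- function(queries, edges, donor_taxa) {
  qkey <- gene_key(queries$genome_id, queries$gene_id)
  e <- edges[gene_key(edges$query_genome, edges$query_gene) %in% qkey &
               edges$hit_genome != edges$query_genome, ]
  if (nrow(e) == 0L) {
    out <- queries[0, ]
    out$hit_genome <- character(); out$hit_gene <- character()
    out$raw_score <- numeric()
    attr(out, "n_no_hits") <- nrow(queries)
    return(out)
  }
  best <- e |>
    dplyr::group_by(.data$query_genome, .data$query_gene) |>
    dplyr::arrange(dplyr::desc(.data$raw_score),
                   .data$hit_genome, .data$hit_gene, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  n_no_hits <- nrow(queries) -
    dplyr::n_distinct(gene_key(best$query_genome, best$query_gene))
  keep <- best[best$hit_genome %in% donor_taxa, ]
  out <- tibble::tibble(genome_id = keep$query_genome,
                        gene_id = keep$query_gene,
                        hit_genome = keep$hit_genome,
                        hit_gene = keep$hit_gene,
                        raw_score = keep$raw_score)
  attr(out, "n_no_hits") <- n_no_hits
  out
}

leaf_genome <- function(labels) sub("\\|.*$", "", labels)

# Rootward walk bookkeeping: for each step above the query's parent, the
# set of leaves newly added by that node.
rootward_additions <- function(tree, query_leaf) {
  ntip <- length(tree$tip.label)
  qi <- which(tree$tip.label == query_leaf)
  if (!length(qi)) stop("query leaf '", query_leaf, "' not in tree",
                        call. = FALSE)
  parent_of <- rep(NA_integer_, ntip + tree$Nnode)
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  path <- integer()
  u <- parent_of[qi]
  while (!is.na(u)) { path <- c(path, u); u <- parent_of[u] }
  prev <- query_leaf
  lapply(path, function(nd) {
    tips <- clade_tips(tree, nd)
    added <- setdiff(tips, prev)
    prev <<- tips
    list(node = nd, added = added, tips = tips)
  })
}

#' Stage 2: topology prefilter on a preliminary rooted tree
#'
#' True when (a) the query's sister subtree contains a donor-taxon leaf and
#' (b) at least `params$min_separating_nodes` internal nodes lie on the
#' query's rootward path before the first node that brings in any
#' background-taxon leaf.  `method = "node_distance"` instead counts the
#' internal nodes between the query and its nearest background leaf.
#'
#' @param tree rooted gene tree (leaf labels `genome|gene`), e.g. from
#'   [root_at_most_distant()].
#' @param query_leaf the recipient query's leaf label.
#' @param donor_taxa,background_taxa genome-id sets.
#' @param params a [ch_params()].
#' @param method separation-counting convention (see above).
#' @return Logical.
#' @export
topology_prefilter <- function(tree, query_leaf, donor_taxa, background_taxa,
                               params = NULL,
                               method = c("path_nodes", "node_distance")) {
  params <- as_ch_params(params)
  method <- match.arg(method)
  steps <- rootward_additions(tree, query_leaf)
  if (!length(steps)) return(FALSE)
  sister <- steps[[1L]]$added
  if (!any(leaf_genome(sister) %in% donor_taxa)) return(FALSE)
  adds_bg <- vapply(steps, function(s) {
    any(leaf_genome(s$added) %in% background_taxa)
  }, TRUE)
  first_bg <- if (any(adds_bg)) which(adds_bg)[1L] else length(steps) + 1L
  if (method == "path_nodes") {
    (first_bg - 1L) >= params$min_separating_nodes
  } else {
    # nodes strictly between the query and its nearest background leaf:
    # the background leaf hangs off node `first_bg`, so the separation is
    # the number of nodes up to and including that node, minus one
    if (first_bg > length(steps)) return(TRUE)
    first_bg >= params$min_separating_nodes
  }
}

#' Stage 3: supported-nesting filter on a bootstrap tree
#'
#' True when the query shares an immediate ancestor with a donor sequence
#' and sits nested inside a larger clade whose other leaves all belong to
#' the surrounding taxon group, with more than two nodes of the containment
#' chain supported above `params$support_threshold`.
#'
#' @param tree rooted gene tree with bootstrap supports in `node.label`.
#' @param query_leaf leaf label of the query.
#' @param donor_taxa donor genome ids (immediate-ancestor condition).
#' @param surrounding_taxa genome ids of the wider group the query must be
#'   nested within (defaults to the donors).
#' @param params a [ch_params()].
#' @return Logical.
#' @export
supported_nesting_filter <- function(tree, query_leaf, donor_taxa,
                                     surrounding_taxa = donor_taxa,
                                     params = NULL) {
  params <- as_ch_params(params)
  supports <- tree_supports(tree)
  if (is.null(supports)) stop("tree carries no bootstrap supports",
                              call. = FALSE)
  steps <- rootward_additions(tree, query_leaf)
  if (!length(steps)) return(FALSE)
  sister <- steps[[1L]]$added
  if (!any(leaf_genome(sister) %in% donor_taxa)) return(FALSE)
  ntip <- length(tree$tip.label)
  inside <- vapply(steps, function(s) {
    all(leaf_genome(s$added) %in% surrounding_taxa)
  }, TRUE)
  # "nested within a larger clade" requires a proper clade: if every leaf
  # of the tree belongs to the surrounding group, there is no outside frame
  # against which nesting (as opposed to a basal attachment under an
  # arbitrary rooting) can be established
  if (all(inside)) return(FALSE)
  last_inside <- if (!inside[1L]) 0L else which(!inside)[1L] - 1L
  if (last_inside < 1L) return(FALSE)
  chain_nodes <- vapply(steps[seq_len(last_inside)], function(s) s$node, 1L)
  sup <- supports[chain_nodes - ntip]
  sum(!is.na(sup) & sup > params$support_threshold) > 2L
}

#' Constrained-topology test of vertical inheritance
#'
#' Builds the vertical-inheritance alternative to an optimal gene tree —
#' the query forced sister to its own-lineage relatives when any are in the
#' tree, otherwise forced outside (sister to) the donor clade — fits branch
#' lengths for both topologies by least squares on the Poisson distance
#' matrix, and compares them with [rell_test()].  Rejection of the
#' constraint at `params$alpha` is evidence for transfer.
#'
#' @param aln named character vector of aligned sequences (leaf labels).
#' @param optimal_tree the unconstrained tree (e.g. bootstrap NJ tree).
#' @param query_leaf the recipient query's leaf label.
#' @param donor_taxa donor genome ids.
#' @param recipient_clade_taxa genome ids of the query's own lineage; leaves
#'   of these genomes anchor the constraint.
#' @param params a [ch_params()].
#' @param seed integer seed for the RELL resampling.
#' @return List: `p_value`, `delta_ll`, `reject`, `constrained_tree`,
#'   `optimal_tree` (both with refitted branch lengths).
#' @export
vertical_constraint_test <- function(aln, optimal_tree, query_leaf,
                                     donor_taxa,
                                     recipient_clade_taxa = character(),
                                     params = NULL, seed = 1L) {
  params <- as_ch_params(params)
  leaves <- optimal_tree$tip.label
  stopifnot(query_leaf %in% leaves)
  dm <- poisson_distance(aln[leaves])
  others <- setdiff(leaves, query_leaf)
  own <- others[leaf_genome(others) %in% recipient_clade_taxa]
  donors <- others[leaf_genome(others) %in% donor_taxa]
  if (!length(own) && !length(donors)) {
    stop("constraint unbuildable: no own-lineage relatives and no donor ",
         "leaves in the tree", call. = FALSE)
  }
  if (length(others) < 3L) {
    stop("too few non-query leaves to build a constrained topology",
         call. = FALSE)
  }
  backbone <- nj_tree(dm[others, others])
  # the putative donor clade the constraint must exclude the query from:
  # the donor leaves of the query's maximal donor-only enclosing clade in
  # the optimal tree (not every leaf of a donor genome — a genome's distant
  # paralogs elsewhere in the tree are not part of the donor copy)
  donor_adjacent <- character()
  if (length(donors)) {
    rooted_opt <- root_at_most_distant(optimal_tree, query_leaf)
    for (s in rootward_additions(rooted_opt, query_leaf)) {
      if (length(s$added) && all(leaf_genome(s$added) %in% donor_taxa)) {
        donor_adjacent <- c(donor_adjacent, s$added)
      } else {
        break
      }
    }
  }
  anchor <- if (length(own)) {
    own
  } else if (length(donor_adjacent)) {
    donor_adjacent
  } else {
    donors
  }
  where <- if (length(anchor) == 1L) {
    which(backbone$tip.label == anchor)
  } else {
    ape::getMRCA(backbone, anchor)
  }
  ntip_b <- length(backbone$tip.label)
  root_b <- ntip_b + 1L
  if (!is.null(where) && where == root_b) {
    # anchor spans the backbone root: graft onto the root child holding the
    # larger share of anchor leaves
    kids <- backbone$edge[backbone$edge[, 1L] == root_b, 2L]
    share <- vapply(kids, function(k) {
      sum(clade_tips(backbone, k) %in% anchor)
    }, 1L)
    where <- kids[order(-share, kids)][1L]
  }
  pos_edge <- backbone$edge.length[backbone$edge[, 2L] == where]
  constrained <- phytools::bind.tip(
    backbone, query_leaf, edge.length = max(mean(dm[query_leaf, others]), 1e-8),
    where = where, position = max(pos_edge / 2, 1e-8)
  )
  topo_opt <- ape::unroot(optimal_tree)
  topo_con <- ape::unroot(constrained)
  fit_opt <- phangorn::nnls.tree(dm, topo_opt, method = "unrooted")
  fit_con <- phangorn::nnls.tree(dm, topo_con, method = "unrooted")
  fit_opt$edge.length[fit_opt$edge.length < 0] <- 0
  fit_con$edge.length[fit_con$edge.length < 0] <- 0
  res <- rell_test(aln, fit_opt, fit_con, n_resamples = 1000L, seed = seed,
                   alpha = params$alpha)
  c(res, list(constrained_tree = fit_con, optimal_tree = fit_opt))
}

#' Genome-wide transfer screen of one recipient genome
#'
#' Runs the three filtering stages and the constraint test for every gene
#' of the recipient genome: (1) best donor hit, (2) preliminary
#' neighbor-joining tree rooted at the most distant sequence and passed
#' through the topology prefilter, (3) bootstrap tree passed through the
#' supported-nesting filter, then (4) the vertical-inheritance constraint
#' test.  `donor_taxa` is free, so the same operation serves both a
#' lineage-specific screen and, say, a dung-ecology screen.
#'
#' @param recipient recipient genome id.
#' @param genes gene tibble for the whole genome database (with
#'   `protein_seq`).
#' @param donor_taxa candidate donor genome ids.
#' @param params a [ch_params()].
#' @param seed integer seed (bootstraps, RELL).
#' @param edges optional precomputed similarity edges.
#' @param background_taxa genomes whose proximity disqualifies a candidate
#'   at stage 2 (default: everything except the recipient and the donors).
#' @param surrounding_taxa wider group for the stage-3 nesting condition
#'   (default: the donors).
#' @param recipient_clade_taxa own-lineage genomes for the constraint test.
#' @return A `ch_hgt_screen` list: `candidates` (tibble `gene_id`,
#'   `stage_passed`, `best_hit_genome`, `p_value`) and `report` (tibble of
#'   per-stage retention counts).
#' @export
screen_genome <- function(recipient, genes, donor_taxa, params = NULL,
                          seed = 1L, edges = NULL,
                          background_taxa = NULL,
                          surrounding_taxa = donor_taxa,
                          recipient_clade_taxa = character()) {
  params <- as_ch_params(params)
  background_taxa <- background_taxa %||%
    setdiff(unique(genes$genome_id), c(recipient, donor_taxa))
  queries <- genes[genes$genome_id == recipient, c("genome_id", "gene_id")]
  if (nrow(queries) == 0L) {
    return(new_hgt_screen(empty_candidates(),
                          stage_report(nrow(queries), 0L, 0L, 0L, 0L)))
  }
  if (is.null(edges)) edges <- pairwise_similarity(genes, params)
  stage1 <- best_hit_filter(queries, edges, donor_taxa)
  seq_by_key <- stats::setNames(genes$protein_seq,
                                gene_key(genes$genome_id, genes$gene_id))
  candidates <- list()
  n2 <- 0L; n3 <- 0L; n4 <- 0L
  for (i in seq_len(nrow(stage1))) {
    qg <- stage1$gene_id[i]
    qkey <- gene_key(recipient, qg)
    fam_keys <- family_of_query(recipient, qg, edges, params)
    aln <- seq_by_key[fam_keys]
    aln <- aln[nchar(aln) == nchar(aln[qkey])]   # indel-free family members
    rec <- list(gene_id = qg, stage_passed = "best_hit",
                best_hit_genome = stage1$hit_genome[i], p_value = NA_real_)
    if (length(aln) >= 4L) {
      prelim <- nj_tree(poisson_distance(aln))
      rooted <- root_at_most_distant(prelim, qkey)
      if (topology_prefilter(rooted, qkey, donor_taxa, background_taxa,
                             params)) {
        rec$stage_passed <- "prefilter"
        n2 <- n2 + 1L
        boot <- bootstrap_tree(aln, n = params$n_bootstraps,
                               seed = substream(seed, qkey))
        if (length(boot$tip.label) > params$max_clade_leaves) {
          keep <- reduce_to_supported_clade(
            root_at_most_distant(boot, qkey), qkey, params)
          aln <- aln[keep]
          boot <- bootstrap_tree(aln, n = params$n_bootstraps,
                                 seed = substream(seed, qkey))
        }
        rooted_boot <- root_at_most_distant(boot, qkey)
        if (supported_nesting_filter(rooted_boot, qkey, donor_taxa,
                                     surrounding_taxa, params)) {
          rec$stage_passed <- "supported"
          n3 <- n3 + 1L
          test <- try(vertical_constraint_test(
            aln, boot, qkey, donor_taxa, recipient_clade_taxa, params,
            seed = substream(seed, paste0("rell_", qkey))), silent = TRUE)
          if (!inherits(test, "try-error")) {
            rec$p_value <- test$p_value
            if (test$reject) {
              rec$stage_passed <- "constraint_rejected_vertical"
              n4 <- n4 + 1L
            }
          }
        }
      }
    }
    candidates[[length(candidates) + 1L]] <- tibble::as_tibble(rec)
  }
  cand <- if (length(candidates)) dplyr::bind_rows(candidates) else
    empty_candidates()
  new_hgt_screen(cand, stage_report(nrow(queries), nrow(stage1), n2, n3, n4))
}

# Leaves of a query's gene tree: the query, its hits, and the hits' hits
# (one expansion round, so a family's full homolog set is represented even
# when some members fall just under the query's own e-value horizon).
family_of_query <- function(genome, gene, edges, params) {
  qkey <- gene_key(genome, gene)
  keep <- edges$evalue <= params$evalue_homology
  e <- edges[keep, ]
  qidx <- gene_key(e$query_genome, e$query_gene)
  hits1 <- unique(gene_key(e$hit_genome, e$hit_gene)[qidx == qkey])
  hits2 <- unique(gene_key(e$hit_genome, e$hit_gene)[qidx %in% hits1])
  unique(c(qkey, hits1, hits2))
}

empty_candidates <- function() {
  tibble::tibble(gene_id = character(), stage_passed = character(),
                 best_hit_genome = character(), p_value = numeric())
}

stage_report <- function(n_query, n1, n2, n3, n4) {
  tibble::tibble(
    stage = c("queries", "best_hit", "prefilter", "supported",
              "constraint_rejected_vertical"),
    n = c(n_query, n1, n2, n3, n4)
  )
}

new_hgt_screen <- function(candidates, report) {
  structure(list(candidates = candidates, report = report),
            class = "ch_hgt_screen")
}

#' @export
print.ch_hgt_screen <- function(x, ...) {
  cat("<ch_hgt_screen>\n")
  for (k in seq_len(nrow(x$report))) {
    cat(sprintf("  %-30s %d\n", x$report$stage[k], x$report$n[k]))
  }
  invisible(x)
}
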