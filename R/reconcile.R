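# Gene-tree / species-tree reconciliation under event parsimony: the
# classical LCA duplication-loss mapping and a duplication-transfer-loss
# dynamic program with the protocol's costs (duplication 1.5, transfer 3.0,
# loss 1.0).  Transfers may land on any non-comparable species edge; global
# time-consistency of transfers is deliberately not enforced (the standard
# parsimony relaxation).

# -- species-tree scaffolding -------------------------------------------------

species_index <- function(stree) {
  ntip <- length(stree$tip.label)
  n_nodes <- ntip + stree$Nnode
  parent <- rep(NA_integer_, n_nodes)
  children <- vector("list", n_nodes)
  for (k in seq_len(nrow(stree$edge))) {
    p <- stree$edge[k, 1L]; c <- stree$edge[k, 2L]
    parent[c] <- p
    children[[p]] <- c(children[[p]], c)
  }
  root <- ntip + 1L
  depth <- rep(NA_integer_, n_nodes)
  depth[root] <- 0L
  ord <- stats::reorder(stree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    depth[ord$edge[k, 2L]] <- depth[ord$edge[k, 1L]] + 1L
  }
  # ancestor indicator: anc[x, y] TRUE iff x is an ancestor of (or equals) y
  anc <- matrix(FALSE, n_nodes, n_nodes)
  for (v in seq_len(n_nodes)) {
    u <- v
    while (!is.na(u)) { anc[u, v] <- TRUE; u <- parent[u] }
  }
  # deterministic node ordering for tie-breaks: by smallest descendant tip
  min_tip <- vapply(seq_len(n_nodes), function(v) {
    min(stree$tip.label[which(anc[v, seq_len(ntip)])])
  }, "")
  node_order <- order(min_tip, depth, seq_len(n_nodes))
  list(ntip = ntip, n_nodes = n_nodes, parent = parent, children = children,
       root = root, depth = depth, anc = anc, node_order = node_order,
       tip_of = stats::setNames(seq_len(ntip), stree$tip.label))
}

gene_index <- function(gtree) {
  ntip <- length(gtree$tip.label)
  n_nodes <- ntip + gtree$Nnode
  children <- vector("list", n_nodes)
  for (k in seq_len(nrow(gtree$edge))) {
    p <- gtree$edge[k, 1L]
    children[[p]] <- c(children[[p]], gtree$edge[k, 2L])
  }
  po <- stats::reorder(gtree, "postorder")
  post_nodes <- unique(c(po$edge[, 2L], po$edge[, 1L]))
  post_nodes <- post_nodes[post_nodes > ntip]
  list(ntip = ntip, n_nodes = n_nodes, children = children,
       root = ntip + 1L, postorder = post_nodes)
}

# Default leaf -> species assignment: leaf labels "genome|gene".
default_species_map <- function(gtree) {
  stats::setNames(sub("\\|.*$", "", gtree$tip.label), gtree$tip.label)
}

check_binary_rooted <- function(tree, what) {
  if (!ape::is.rooted(tree) || !ape::is.binary(tree)) {
    stop(what, " must be rooted and binary", call. = FALSE)
  }
}

#' Collapse weakly supported gene-tree edges
#'
#' Internal edges whose support is below `threshold` (on the tree's own
#' support scale) are contracted; the resulting polytomies are then resolved
#' arbitrarily (zero-length edges) so the reconciliation input is binary.
#' With the protocol default threshold of 1.0 on a 0-100 scale this only
#' removes zero-support edges.
#'
#' @param gtree `ape::phylo` with supports in `node.label`.
#' @param threshold support threshold.
#' @return Binary `ape::phylo`.
#' @export
collapse_weak_edges <- function(gtree, threshold = 1.0) {
  sup <- tree_supports(gtree)
  if (is.null(sup)) return(gtree)
  ntip <- length(gtree$tip.label)
  weak_nodes <- which(!is.na(sup) & sup < threshold) + ntip
  weak_nodes <- setdiff(weak_nodes, ntip + 1L)    # never contract the root
  if (!length(weak_nodes)) return(gtree)
  keep <- !(gtree$edge[, 2L] %in% weak_nodes)
  tr <- gtree
  tr$edge.length[!keep] <- 0
  tr <- ape::di2multi(tr, tol = 1e-12)
  ape::multi2di(tr, random = FALSE)
}

# -- duplication-loss (LCA) ---------------------------------------------------

#' Duplication-loss reconciliation by LCA mapping
#'
#' Maps every gene-tree node to the last common ancestor of its descendant
#' species (the unique minimal DL reconciliation), counts duplications
#' (nodes mapping to the same species node as a child) and losses (mapping
#' path-depth differences), and prices them.
#'
#' @param gene_tree rooted binary `ape::phylo`; leaf labels `genome|gene`
#'   unless `species_map` says otherwise.
#' @param species_tree rooted binary `ape::phylo`.
#' @param costs a [ch_params()] (uses `dup_cost`, `loss_cost`).
#' @param species_map named character vector mapping gene leaves to species
#'   tip labels.
#' @return A `ch_reconciliation` list: `model`, `n_dup`, `n_transfer`,
#'   `n_loss`, `total_cost`, `mapping` (tibble gene node -> species node).
#' @export
lca_reconcile_dl <- function(gene_tree, species_tree, costs = NULL,
                             species_map = NULL) {
  costs <- as_ch_params(costs)
  check_binary_rooted(gene_tree, "gene tree")
  check_binary_rooted(species_tree, "species tree")
  species_map <- species_map %||% default_species_map(gene_tree)
  si <- species_index(species_tree)
  gi <- gene_index(gene_tree)
  bad <- setdiff(unname(species_map[gene_tree$tip.label]),
                 species_tree$tip.label)
  if (length(bad)) {
    stop("gene leaf mapped to unknown species: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  lca <- function(a, b) {
    while (a != b) {
      if (si$depth[a] > si$depth[b]) a <- si$parent[a]
      else if (si$depth[b] > si$depth[a]) b <- si$parent[b]
      else { a <- si$parent[a]; b <- si$parent[b] }
    }
    a
  }
  M <- integer(gi$n_nodes)
  for (i in seq_len(gi$ntip)) {
    M[i] <- si$tip_of[[species_map[[gene_tree$tip.label[i]]]]]
  }
  n_dup <- 0L; n_loss <- 0L
  for (u in gi$postorder) {
    ch <- gi$children[[u]]
    M[u] <- lca(M[ch[1L]], M[ch[2L]])
    is_dup <- M[u] == M[ch[1L]] || M[u] == M[ch[2L]]
    if (is_dup) n_dup <- n_dup + 1L
    for (v in ch) {
      d <- si$depth[M[v]] - si$depth[M[u]]
      n_loss <- n_loss + if (is_dup) d else max(d - 1L, 0L)
    }
  }
  new_reconciliation("DL", n_dup, 0L, n_loss,
                     costs$dup_cost * n_dup + costs$loss_cost * n_loss,
                     mapping_tibble(gene_tree, species_tree, M, gi, si))
}

mapping_tibble <- function(gene_tree, species_tree, M, gi, si) {
  glab <- c(gene_tree$tip.label,
            sprintf("node%d", seq_len(gi$n_nodes - gi$ntip)))
  slab <- c(species_tree$tip.label,
            sprintf("node%d", seq_len(si$n_nodes - si$ntip)))
  tibble::tibble(gene_node = glab, species_node = slab[M])
}

new_reconciliation <- function(model, n_dup, n_transfer, n_loss, total_cost,
                               mapping) {
  structure(list(model = model, n_dup = as.integer(n_dup),
                 n_transfer = as.integer(n_transfer),
                 n_loss = as.integer(n_loss),
                 total_cost = total_cost, mapping = mapping),
            class = "ch_reconciliation")
}

#' @export
print.ch_reconciliation <- function(x, ...) {
  cat(sprintf("<%s reconciliation>  D = %d, T = %d, L = %d, cost = %.2f\n",
              x$model, x$n_dup, x$n_transfer, x$n_loss, x$total_cost))
  invisible(x)
}

# -- duplication-transfer-loss ------------------------------------------------

#' Duplication-transfer-loss reconciliation (event parsimony)
#'
#' Dynamic program over (gene node, species node) pairs.  Each internal
#' gene node is priced as a speciation, a duplication, or a transfer in
#' which one child lineage jumps to any species edge incomparable with the
#' current one; losses are charged per skipped species edge.  Among
#' equal-cost scenarios the backtrack prefers speciation over loss-bearing
#' descents over duplication over transfer, then the species node earliest
#' in a deterministic node ordering, so results are reproducible.
#'
#' @inheritParams lca_reconcile_dl
#' @param costs a [ch_params()] (uses `dup_cost`, `transfer_cost`,
#'   `loss_cost`).
#' @return A `ch_reconciliation` (see [lca_reconcile_dl()]); `model` is
#'   `"DTL"`.
#' @export
dtl_reconcile <- function(gene_tree, species_tree, costs = NULL,
                          species_map = NULL) {
  costs <- as_ch_params(costs)
  check_binary_rooted(gene_tree, "gene tree")
  check_binary_rooted(species_tree, "species tree")
  species_map <- species_map %||% default_species_map(gene_tree)
  si <- species_index(species_tree)
  gi <- gene_index(gene_tree)
  bad <- setdiff(unname(species_map[gene_tree$tip.label]),
                 species_tree$tip.label)
  if (length(bad)) {
    stop("gene leaf mapped to unknown species: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  D <- costs$dup_cost; Tc <- costs$transfer_cost; Lc <- costs$loss_cost
  ns <- si$n_nodes
  INF <- Inf
  # species nodes, children before parents (deepest first)
  sp_post <- order(si$depth, decreasing = TRUE)
  incomparable <- !(si$anc | t(si$anc))
  Cmat <- matrix(INF, gi$n_nodes, ns)      # c(u, x)
  INmat <- matrix(INF, gi$n_nodes, ns)     # in(u, x)
  OUTmat <- matrix(INF, gi$n_nodes, ns)    # out(u, x)
  fill_in_out <- function(u) {
    for (x in sp_post) {
      ch <- si$children[[x]]
      v <- Cmat[u, x]
      if (length(ch)) {
        v <- min(v, Lc + min(INmat[u, ch[1L]], INmat[u, ch[2L]]))
      }
      INmat[u, x] <<- v
    }
    for (x in seq_len(ns)) {
      inc <- which(incomparable[x, ])
      OUTmat[u, x] <<- if (length(inc)) min(Cmat[u, inc]) else INF
    }
  }
  for (i in seq_len(gi$ntip)) {
    sx <- si$tip_of[[species_map[[gene_tree$tip.label[i]]]]]
    Cmat[i, sx] <- 0
    fill_in_out(i)
  }
  for (u in gi$postorder) {
    ch <- gi$children[[u]]
    v <- ch[1L]; w <- ch[2L]
    for (x in seq_len(ns)) {
      sc <- si$children[[x]]
      best <- INF
      if (length(sc)) {
        best <- min(best,
                    INmat[v, sc[1L]] + INmat[w, sc[2L]],
                    INmat[v, sc[2L]] + INmat[w, sc[1L]])
      }
      best <- min(best, D + INmat[v, x] + INmat[w, x])
      best <- min(best,
                  Tc + INmat[v, x] + OUTmat[w, x],
                  Tc + INmat[w, x] + OUTmat[v, x])
      Cmat[u, x] <- best
    }
    fill_in_out(u)
  }
  root_costs <- Cmat[gi$root, ]
  total <- min(root_costs)
  # deterministic backtrack to count events
  counts <- dtl_backtrack(gi, si, Cmat, INmat, OUTmat, D, Tc, Lc,
                          incomparable)
  M <- counts$mapping
  new_reconciliation("DTL", counts$n_dup, counts$n_transfer, counts$n_loss,
                     total, mapping_tibble(gene_tree, species_tree, M, gi, si))
}

dtl_backtrack <- function(gi, si, Cmat, INmat, OUTmat, D, Tc, Lc,
                          incomparable) {
  n_dup <- 0L; n_transfer <- 0L; n_loss <- 0L
  M <- integer(gi$n_nodes)
  eq <- function(a, b) is.finite(a) && is.finite(b) && abs(a - b) <= 1e-9
  pick_ordered <- function(cands) cands[order(match(cands, si$node_order))][1L]
  # descend a loss chain: find the species node where in(u, x) is realized
  resolve_in <- function(u, x) {
    path_losses <- 0L
    repeat {
      if (eq(INmat[u, x], Cmat[u, x])) return(list(node = x,
                                                   losses = path_losses))
      sc <- si$children[[x]]
      opts <- sc[vapply(sc, function(y) eq(INmat[u, x], Lc + INmat[u, y]),
                        TRUE)]
      x <- pick_ordered(opts)
      path_losses <- path_losses + 1L
    }
  }
  resolve_out <- function(u, x) {
    inc <- which(incomparable[x, ])
    opts <- inc[vapply(inc, function(y) eq(OUTmat[u, x], Cmat[u, y]), TRUE)]
    pick_ordered(opts)
  }
  assign_node <- function(u, x) {
    M[u] <<- x
    if (u <= gi$ntip) return(invisible())
    ch <- gi$children[[u]]
    v <- ch[1L]; w <- ch[2L]
    cost <- Cmat[u, x]
    sc <- si$children[[x]]
    # preference: speciation > duplication > transfer
    if (length(sc)) {
      for (perm in list(c(1L, 2L), c(2L, 1L))) {
        a <- sc[perm[1L]]; b <- sc[perm[2L]]
        if (eq(cost, INmat[v, a] + INmat[w, b])) {
          rv <- resolve_in(v, a); rw <- resolve_in(w, b)
          n_loss <<- n_loss + rv$losses + rw$losses
          assign_node(v, rv$node); assign_node(w, rw$node)
          return(invisible())
        }
      }
    }
    if (eq(cost, D + INmat[v, x] + INmat[w, x])) {
      n_dup <<- n_dup + 1L
      rv <- resolve_in(v, x); rw <- resolve_in(w, x)
      n_loss <<- n_loss + rv$losses + rw$losses
      assign_node(v, rv$node); assign_node(w, rw$node)
      return(invisible())
    }
    for (pair in list(c(v, w), c(w, v))) {
      stay <- pair[1L]; move <- pair[2L]
      if (eq(cost, Tc + INmat[stay, x] + OUTmat[move, x])) {
        n_transfer <<- n_transfer + 1L
        rs <- resolve_in(stay, x)
        n_loss <<- n_loss + rs$losses
        y <- resolve_out(move, x)
        assign_node(stay, rs$node); assign_node(move, y)
        return(invisible())
      }
    }
    stop("internal error: DTL backtrack found no consistent event",
         call. = FALSE)
  }
  root_costs <- Cmat[gi$root, ]
  best <- min(root_costs)
  cands <- which(vapply(seq_len(si$n_nodes),
                        function(x) eq(root_costs[x], best), TRUE))
  assign_node(gi$root, pick_ordered(cands))
  list(n_dup = n_dup, n_transfer = n_transfer, n_loss = n_loss, mapping = M)
}

#' Compare DL and DTL reconciliations of one gene tree
#'
#' Runs both models with the protocol costs and reports which is more
#' parsimonious (ties prefer the more conservative DL model).
#'
#' @inheritParams dtl_reconcile
#' @return List with `dl`, `dtl` (both `ch_reconciliation`) and `preferred`
#'   (`"DL"` or `"DTL"`).
#' @export
compare_models <- function(gene_tree, species_tree, costs = NULL,
                           species_map = NULL) {
  dl <- lca_reconcile_dl(gene_tree, species_tree, costs, species_map)
  dtl <- dtl_reconcile(gene_tree, species_tree, costs, species_map)
  preferred <- if (dtl$total_cost < dl$total_cost) "DTL" else "DL"
  list(dl = dl, dtl = dtl, preferred = preferred)
}
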