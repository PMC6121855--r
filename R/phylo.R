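# Tree building and tree statistics: distances, neighbor joining, bootstrap
# supports, rooting, clade reduction and the consensus species tree.

# Alignment helpers: an alignment is a named character vector of equal-length
# protein strings ("-" for gaps).
aln_matrix <- function(aln) {
  lens <- nchar(aln)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: sequence lengths ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  }
  m <- do.call(rbind, strsplit(aln, ""))
  rownames(m) <- names(aln)
  m
}

#' Remove gap-rich alignment columns
#'
#' @param aln named character vector of equal-length sequences.
#' @param max_gap_fraction columns whose gap fraction exceeds this are
#'   dropped (order of the remaining columns is preserved).
#' @return The trimmed alignment (same names).
#' @export
trim_columns <- function(aln, max_gap_fraction = 0.5) {
  m <- aln_matrix(aln)
  gap_frac <- colMeans(m == "-")
  keep <- gap_frac <= max_gap_fraction
  out <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  stats::setNames(out, names(aln))
}

#' Poisson-corrected protein distances
#'
#' `d = -ln(1 - p)` with `p` the proportion of differing columns among the
#' positions where both sequences are ungapped; `p` is capped at 0.95 so
#' saturated pairs stay finite.
#'
#' @param aln named character vector of equal-length sequences (>= 2).
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
poisson_distance <- function(aln) {
  if (length(aln) < 2L) stop("need at least two sequences", call. = FALSE)
  m <- aln_matrix(aln)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) {
        stop("no shared ungapped columns for pair ", rownames(m)[i], " / ",
             rownames(m)[j], call. = FALSE)
      }
      p <- mean(m[i, ok] != m[j, ok])
      p <- min(p, 0.95)
      d[i, j] <- d[j, i] <- -log(1 - p)
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a distance matrix; rows/columns are
#' ordered lexicographically first so the output is independent of input
#' order, and negative branch lengths are clamped to zero.
#'
#' @param dm symmetric distance matrix with labels.
#' @return Unrooted `ape::phylo`.
#' @export
nj_tree <- function(dm) {
  if (nrow(dm) < 3L) stop("neighbor joining needs at least 3 labels",
                          call. = FALSE)
  ord <- order(rownames(dm))
  tr <- ape::nj(dm[ord, ord])
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the point tree from the full alignment, then `n` column-resampled
#' replicates; each internal edge's support is the percentage of replicates
#' whose tree contains the same bipartition.
#'
#' @param aln named character vector of aligned sequences.
#' @param n number of bootstrap replicates (> 0).
#' @param seed integer seed for the resampling.
#' @return Unrooted `ape::phylo` whose `node.label` carries integer percent
#'   supports ("" on the root node).
#' @export
bootstrap_tree <- function(aln, n = 100L, seed = 1L) {
  if (n <= 0L) stop("n must be positive", call. = FALSE)
  point <- nj_tree(poisson_distance(aln))
  m <- aln_matrix(aln)
  set.seed(seed)
  boots <- vector("list", n)
  for (b in seq_len(n)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_aln <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
    boots[[b]] <- nj_tree(poisson_distance(stats::setNames(rep_aln,
                                                           names(aln))))
  }
  counts <- ape::prop.clades(point, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / n)
  lab <- as.character(support)
  lab[1L] <- ""                          # root of the unrooted representation
  point$node.label <- lab
  point
}

#' Root a tree at the leaf most distant from a query
#'
#' The root is placed on the terminal edge of the leaf with maximal
#' path-length distance from `query_leaf` (ties broken by lexicographically
#' smaller label), the convention used when orienting single-gene trees for
#' transfer screening.
#'
#' @param tree unrooted `ape::phylo` with branch lengths.
#' @param query_leaf leaf label.
#' @return Rooted `ape::phylo`; node labels (supports) follow their edges.
#' @export
root_at_most_distant <- function(tree, query_leaf) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths",
                                      call. = FALSE)
  if (!query_leaf %in% tree$tip.label) {
    stop("query leaf '", query_leaf, "' not in tree", call. = FALSE)
  }
  dm <- ape::cophenetic.phylo(tree)
  others <- setdiff(tree$tip.label, query_leaf)
  d <- dm[query_leaf, others]
  target <- others[order(-d, others)][1L]
  rooted <- ape::root(tree, outgroup = target, resolve.root = TRUE,
                      edgelabel = TRUE)
  rooted
}

#' Largest well-supported clade around a set of query leaves
#'
#' Returns the leaf set of the largest clade that contains every query
#' leaf, has support at least `params$support_threshold`, and spans at most
#' `params$max_clade_leaves` leaves.  If the whole tree fits the size bound
#' it is returned outright.  When no internal clade qualifies, the smallest
#' clade containing the queries is returned with a warning.
#'
#' @param tree rooted `ape::phylo` with supports in `node.label`.
#' @param query_leaves leaf labels that must be inside the clade.
#' @param params a [ch_params()].
#' @return Character vector of leaf labels; attribute `qualified` records
#'   whether a supported clade was found.
#' @export
reduce_to_supported_clade <- function(tree, query_leaves, params = NULL) {
  params <- as_ch_params(params)
  ntip <- length(tree$tip.label)
  stopifnot(all(query_leaves %in% tree$tip.label))
  if (ntip <= params$max_clade_leaves) {
    return(structure(tree$tip.label, qualified = TRUE))
  }
  supports <- tree_supports(tree)
  if (is.null(supports)) stop("tree carries no support values", call. = FALSE)
  best <- NULL
  for (node in seq_len(tree$Nnode)) {
    tips <- clade_tips(tree, ntip + node)
    if (!all(query_leaves %in% tips)) next
    if (length(tips) > params$max_clade_leaves) next
    sup <- supports[node]
    if (!is.na(sup) && sup >= params$support_threshold) {
      if (is.null(best) || length(tips) > length(best)) best <- tips
    }
  }
  if (is.null(best)) {
    mrca <- ape::getMRCA(tree, query_leaves)
    best <- if (is.null(mrca)) query_leaves else clade_tips(tree, mrca)
    warning("no supported clade of admissible size contains the queries; ",
            "returning their smallest containing clade", call. = FALSE)
    return(structure(best, qualified = FALSE))
  }
  structure(best, qualified = TRUE)
}

# Tip labels under a node (the node itself if it is a tip).
clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  tree$tip.label[unlist(phangorn::Descendants(tree, node, "tips"))]
}

#' Consensus species tree from single-copy homolog groups
#'
#' Samples homolog groups with exactly one member in every genome, builds a
#' bootstrap neighbor-joining tree for each, keeps trees whose mean internal
#' support exceeds `params$support_threshold`, and stops once `quota` trees
#' qualify (or the groups are exhausted, in which case the result is flagged).
#' The returned species tree is the extended majority-rule consensus of the
#' qualifying gene trees.
#'
#' @param genes gene tibble with `protein_seq`.
#' @param groups homolog-group tibble.
#' @param params a [ch_params()].
#' @param quota number of qualifying gene trees to accumulate (the published
#'   protocol used 100; tests scale this down).
#' @param seed integer seed (group sampling order and bootstraps).
#' @return Unrooted `ape::phylo` consensus; attributes `n_trees` (number of
#'   qualifying gene trees) and `quota_met`.
#' @export
build_species_tree <- function(genes, groups, params = NULL, quota = 100L,
                               seed = 1L) {
  params <- as_ch_params(params)
  genomes <- sort(unique(genes$genome_id))
  per <- dplyr::count(dplyr::distinct(groups, .data$group_id, .data$genome_id,
                                      .data$gene_id),
                      .data$group_id, .data$genome_id)
  counts <- per |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(n_genomes = dplyr::n(), single = all(.data$n == 1L),
                     .groups = "drop")
  single_copy <- counts$group_id[counts$single &
                                   counts$n_genomes == length(genomes)]
  if (!length(single_copy)) stop("no single-copy groups available",
                                 call. = FALSE)
  set.seed(seed)
  single_copy <- sample(single_copy)
  kept <- list()
  seq_by_key <- stats::setNames(genes$protein_seq,
                                gene_key(genes$genome_id, genes$gene_id))
  for (gid in single_copy) {
    mem <- groups[groups$group_id == gid, ]
    aln <- stats::setNames(seq_by_key[gene_key(mem$genome_id, mem$gene_id)],
                           mem$genome_id)
    if (length(unique(nchar(aln))) != 1L) next   # not natively aligned
    tr <- bootstrap_tree(aln, n = params$n_bootstraps,
                         seed = substream(seed, gid))
    sup <- tree_supports(tr)
    sup <- sup[-1L]                       # internal edges only, not the root
    if (length(sup) && mean(sup, na.rm = TRUE) > params$support_threshold) {
      kept[[length(kept) + 1L]] <- tr
    }
    if (length(kept) >= quota) break
  }
  if (!length(kept)) stop("no gene tree reached the support threshold",
                          call. = FALSE)
  quota_met <- length(kept) >= quota
  if (!quota_met) {
    warning("support-threshold quota not met: consensus of ", length(kept),
            " gene trees", call. = FALSE)
  }
  cons <- extended_majority_consensus(kept)
  attr(cons, "n_trees") <- length(kept)
  attr(cons, "quota_met") <- quota_met
  cons
}

#' Extended majority-rule consensus of trees
#'
#' Keeps every bipartition occurring in more than half the input trees,
#' then greedily adds the remaining bipartitions in order of decreasing
#' frequency whenever they are compatible with the tree built so far.
#'
#' @param trees list of `ape::phylo` on the same leaf set.
#' @return Consensus `ape::phylo` (unrooted, no branch lengths).
#' @export
extended_majority_consensus <- function(trees) {
  class(trees) <- "multiPhylo"
  sp <- phangorn::as.splits(trees)
  w <- attr(sp, "weights")
  labels <- attr(sp, "labels")
  ntree <- length(trees)
  ntip <- length(labels)
  sizes <- lengths(sp)
  nontrivial <- sizes > 1L & sizes < (ntip - 1L)
  ord <- order(-w)
  chosen <- list()
  for (k in ord) {
    if (!nontrivial[k]) next
    cand <- sort(sp[[k]])
    # normalize to the side not containing leaf 1
    if (1L %in% cand) cand <- sort(setdiff(seq_len(ntip), cand))
    if (length(cand) < 2L || length(cand) > ntip - 2L) next
    compat <- all(vapply(chosen, function(cl) {
      splits_compatible(cl, cand, ntip)
    }, TRUE))
    dup <- any(vapply(chosen, identical, TRUE, y = cand))
    # majority splits come first in the frequency ordering and are mutually
    # compatible; greedy addition of lower-frequency compatible splits then
    # realizes the extended rule
    if (compat && !dup) chosen[[length(chosen) + 1L]] <- cand
  }
  tree_from_clades(chosen, labels)
}

# Two clades (sides not containing leaf 1) are compatible iff nested or
# disjoint.
splits_compatible <- function(a, b, ntip) {
  inter <- length(intersect(a, b))
  inter == 0L || inter == length(a) || inter == length(b)
}

# Build a phylo from a set of pairwise-compatible clades (indices into
# `labels`, none containing leaf 1).
tree_from_clades <- function(clades, labels) {
  ntip <- length(labels)
  if (!length(clades)) {
    txt <- paste0("(", paste(labels, collapse = ","), ");")
    return(ape::read.tree(text = txt))
  }
  ord <- order(lengths(clades))
  newick_of <- function(members, available_clades) {
    # members: leaf indices at this level; nest the maximal proper subclades
    inner <- available_clades[vapply(available_clades, function(cl) {
      all(cl %in% members) && length(cl) < length(members)
    }, TRUE)]
    used <- integer()
    parts <- character()
    if (length(inner)) {
      inner <- inner[order(-lengths(inner))]
      for (cl in inner) {
        if (!length(intersect(cl, used))) {
          parts <- c(parts, newick_of(cl, inner))
          used <- c(used, cl)
        }
      }
    }
    singles <- setdiff(members, used)
    parts <- c(parts, labels[singles])
    if (length(parts) == 1L) parts else paste0("(", paste(parts, collapse = ","), ")")
  }
  txt <- paste0(newick_of(seq_len(ntip), clades[ord]), ";")
  ape::read.tree(text = txt)
}
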