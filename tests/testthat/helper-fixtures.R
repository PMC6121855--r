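# Shared fixtures and independent oracles used across test files.

# Small simulation reused by several tests (memoised per session).
small_sim <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 1L, ...) {
    key <- paste0("s", seed, "_", paste(c(...), collapse = "_"))
    if (is.null(cache[[key]])) {
      cache[[key]] <- simulate_genomes(sim_config(seed = seed, ...))
    }
    cache[[key]]
  }
})

# Independent quadratic-DP Smith-Waterman oracle (linear gap extension runs
# handled by affine states), written directly from the recurrences.
sw_oracle <- function(a, b, sub, gap_open = 11, gap_extend = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  m <- length(a); n <- length(b)
  M <- matrix(0, m + 1, n + 1)
  X <- matrix(-Inf, m + 1, n + 1)
  Y <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      X[i, j] <- max(M[i - 1, j] - gap_open, X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open, Y[i, j - 1] - gap_extend)
      s <- sub[a[i - 1], b[j - 1]]
      M[i, j] <- max(0, s + max(M[i - 1, j - 1], X[i - 1, j - 1],
                                Y[i - 1, j - 1]))
      best <- max(best, M[i, j])
    }
  }
  best
}

# Brute-force co-localization oracle: all-pairs adjacency within the
# intervening-gene bound, then transitive closure, then the two-gene /
# two-group locus rule.
coloc_oracle <- function(cand, max_intervening) {
  out <- list()
  for (key in unique(paste(cand$genome_id, cand$scaffold_id))) {
    sub <- cand[paste(cand$genome_id, cand$scaffold_id) == key, ]
    n <- nrow(sub)
    if (n == 0) next
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        adj[i, j] <- i != j &&
          abs(sub$order_index[i] - sub$order_index[j]) - 1L <= max_intervening
      }
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    for (cc in unique(comp)) {
      members <- sub[comp == cc, ]
      if (nrow(members) >= 2 && length(unique(members$group_id)) >= 2) {
        members <- members[order(members$order_index), ]
        out[[length(out) + 1L]] <- members
      }
    }
  }
  out
}

# Reference dense MCL, written independently of the package implementation
# (explicit loops, no pruning shortcuts beyond the published thresholds).
mcl_reference <- function(A, inflation) {
  n <- nrow(A)
  for (i in seq_len(n)) A[i, i] <- max(A[, i], 1)
  M <- sweep(A, 2, colSums(A), "/")
  for (iter in 1:200) {
    E <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) E[i, j] <- sum(M[i, ] * M[, j])
    E <- E^inflation
    E[E < 1e-5] <- 0
    for (j in seq_len(n)) if (sum(E[, j]) > 0) E[, j] <- E[, j] / sum(E[, j])
    if (max(abs(E - M)) < 1e-6) { M <- E; break }
    M <- E
  }
  # clusters: connected components of the limit support
  S <- (M > 1e-6) | t(M > 1e-6)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(S, mode = "undirected"))$membership
  unname(split(seq_len(n), comp))
}

# Exhaustive DTL oracle: minimum over all maps of gene internal nodes to
# species nodes, with per-node event costs read from the map.
dtl_oracle <- function(gene_tree, species_tree, dup = 1.5, trans = 3.0,
                       loss = 1.0, species_map = NULL) {
  if (is.null(species_map)) {
    species_map <- stats::setNames(sub("\\|.*$", "", gene_tree$tip.label),
                                   gene_tree$tip.label)
  }
  si_ntip <- length(species_tree$tip.label)
  ns <- si_ntip + species_tree$Nnode
  parent <- rep(NA_integer_, ns)
  for (k in seq_len(nrow(species_tree$edge))) {
    parent[species_tree$edge[k, 2]] <- species_tree$edge[k, 1]
  }
  depth <- rep(0L, ns)
  for (v in seq_len(ns)) {
    u <- parent[v]
    while (!is.na(u)) { depth[v] <- depth[v] + 1L; u <- parent[u] }
  }
  anc <- matrix(FALSE, ns, ns)
  for (v in seq_len(ns)) {
    u <- v
    while (!is.na(u)) { anc[u, v] <- TRUE; u <- parent[u] }
  }
  children <- vector("list", ns)
  for (k in seq_len(nrow(species_tree$edge))) {
    p <- species_tree$edge[k, 1]
    children[[p]] <- c(children[[p]], species_tree$edge[k, 2])
  }
  dist_to <- function(x, y) depth[y] - depth[x]   # y below x
  # per-node cost of (s, s1, s2): node at s, children at s1, s2
  node_cost <- function(s, s1, s2) {
    best <- Inf
    in1 <- anc[s, s1]; in2 <- anc[s, s2]
    ch <- children[[s]]
    if (in1 && in2 && length(ch)) {
      # speciation: children descend through distinct child subtrees
      for (pr in list(c(1, 2), c(2, 1))) {
        if (anc[ch[pr[1]], s1] && anc[ch[pr[2]], s2]) {
          best <- min(best, loss * (dist_to(s, s1) - 1 + dist_to(s, s2) - 1))
        }
      }
    }
    if (in1 && in2) {
      best <- min(best, dup + loss * (dist_to(s, s1) + dist_to(s, s2)))
    }
    if (in1 && !in2 && !anc[s2, s]) {
      best <- min(best, trans + loss * dist_to(s, s1))
    }
    if (in2 && !in1 && !anc[s1, s]) {
      best <- min(best, trans + loss * dist_to(s, s2))
    }
    best
  }
  g_ntip <- length(gene_tree$tip.label)
  gn <- g_ntip + gene_tree$Nnode
  gchild <- vector("list", gn)
  for (k in seq_len(nrow(gene_tree$edge))) {
    p <- gene_tree$edge[k, 1]
    gchild[[p]] <- c(gchild[[p]], gene_tree$edge[k, 2])
  }
  fixed <- integer(gn)
  stip <- stats::setNames(seq_len(si_ntip), species_tree$tip.label)
  for (i in seq_len(g_ntip)) {
    fixed[i] <- stip[[species_map[[gene_tree$tip.label[i]]]]]
  }
  internals <- (g_ntip + 1L):gn
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), length(internals))))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    mp <- fixed
    mp[internals] <- grid[r, ]
    tot <- 0
    for (u in internals) {
      ch <- gchild[[u]]
      tot <- tot + node_cost(mp[u], mp[ch[1]], mp[ch[2]])
      if (!is.finite(tot)) break
    }
    if (tot < best) best <- tot
  }
  best
}

# Random rooted binary tree over given labels (uniform shapes via random
# sequential joins), with branch lengths.
random_rooted_tree <- function(labels, min_bl = 0.05, max_bl = 0.3) {
  tr <- ape::rtree(length(labels), rooted = TRUE,
                   br = function(n) stats::runif(n, min_bl, max_bl))
  tr$tip.label <- sample(labels)
  tr
}
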