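# Protein similarity graph construction and Markov clustering into homolog
# groups: the all-vs-all search + OrthoMCL stage of the pipeline.

gene_key <- function(genome_id, gene_id) paste(genome_id, gene_id, sep = "|")

split_gene_key <- function(key) {
  parts <- stringr::str_split_fixed(key, stringr::fixed("|"), 2L)
  tibble::tibble(genome_id = parts[, 1L], gene_id = parts[, 2L])
}

#' All-vs-all protein similarity edges
#'
#' Candidate pairs are found with an exact k-mer prefilter (pairs sharing at
#' least `params$kmer_min_shared` distinct k-mers of size `params$kmer_size`)
#' and then aligned by Smith-Waterman local alignment with BLOSUM62 scores
#' and affine gap penalties (`gap_open`/`gap_extend`).  E-values follow the
#' Karlin-Altschul formula `E = K m N exp(-lambda S)` with the standard
#' gapped BLOSUM62 constants (lambda = 0.267, K = 0.041), `m` the query
#' length and `N` the total residue count of the database.  Similarity is
#' the fraction of aligned columns whose substitution score is positive.
#' Edges are emitted in both directions.
#'
#' @param genes tibble with `genome_id`, `gene_id`, `protein_seq` (one row
#'   per gene; sequences over the 20-letter amino-acid alphabet).
#' @param params a [ch_params()]; `evalue_homology` is the retention cutoff.
#' @param evalue_cutoff override for the cutoff (used by the synteny screen,
#'   which runs at `evalue_screen`).
#' @return Tibble of similarity edges: `query_genome`, `query_gene`,
#'   `hit_genome`, `hit_gene`, `raw_score`, `evalue`, `similarity`.
#' @export
pairwise_similarity <- function(genes, params = NULL, evalue_cutoff = NULL) {
  params <- as_ch_params(params)
  cutoff <- evalue_cutoff %||% params$evalue_homology
  if (nrow(genes) == 0L) stop("empty protein set", call. = FALSE)
  if (any(grepl("[^ARNDCQEGHILKMFPSTWYV]", genes$protein_seq))) {
    bad <- genes$gene_id[grepl("[^ARNDCQEGHILKMFPSTWYV]", genes$protein_seq)]
    stop("non-amino-acid characters in sequence(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  cand <- kmer_candidate_pairs(genes$protein_seq, params$kmer_size,
                               params$kmer_min_shared)
  if (nrow(cand) == 0L) {
    return(empty_edges())
  }
  # fast score-only pass, then full alignment (for the similarity fraction)
  # on the pairs that survive the e-value cutoff
  score <- sw_score_batch(genes$protein_seq[cand$i], genes$protein_seq[cand$j],
                          params$gap_open, params$gap_extend)
  n_db <- sum(nchar(genes$protein_seq))
  m_len <- nchar(genes$protein_seq[cand$i])
  evalue <- params$ka_k * m_len * n_db * exp(-params$ka_lambda * score)
  keep <- evalue <= cutoff
  if (!any(keep)) return(empty_edges())
  cand <- cand[keep, ]
  aln <- sw_align_batch(genes$protein_seq[cand$i], genes$protein_seq[cand$j],
                        params$gap_open, params$gap_extend)
  stopifnot(all(abs(aln$raw_score - score[keep]) < 1e-9))
  fwd <- tibble::tibble(
    query_genome = genes$genome_id[cand$i],
    query_gene = genes$gene_id[cand$i],
    hit_genome = genes$genome_id[cand$j],
    hit_gene = genes$gene_id[cand$j],
    raw_score = aln$raw_score,
    evalue = evalue[keep],
    similarity = aln$similarity
  )
  rev <- fwd
  names(rev)[1:4] <- c("hit_genome", "hit_gene", "query_genome", "query_gene")
  # the reverse search sees the hit's length as query length
  rev$evalue <- params$ka_k * nchar(genes$protein_seq[cand$j]) * n_db *
    exp(-params$ka_lambda * rev$raw_score)
  dplyr::bind_rows(fwd, rev[, names(fwd)])
}

empty_edges <- function() {
  tibble::tibble(query_genome = character(), query_gene = character(),
                 hit_genome = character(), hit_gene = character(),
                 raw_score = numeric(), evalue = numeric(),
                 similarity = numeric())
}

# Index sequences by their distinct k-mers and return index pairs (i < j)
# sharing at least `min_shared` of them.
kmer_candidate_pairs <- function(seqs, k, min_shared) {
  n <- length(seqs)
  if (n < 2L) return(tibble::tibble(i = integer(), j = integer()))
  km <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character())
    unique(substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L))
  })
  gene <- rep.int(seq_len(n), lengths(km))
  kall <- unlist(km, use.names = FALSE)
  code <- match(kall, unique(kall))
  out <- count_shared_kmer_pairs(gene, code, as.integer(min_shared))
  out <- out[order(out$i, out$j), ]
  tibble::as_tibble(out)
}

#' Build the weighted similarity graph
#'
#' Edge weight is `-log10(evalue)`, capped at 200 for underflowing e-values;
#' the weights of the two directed hits of a reciprocal pair are averaged.
#' Every gene becomes a node, including genes without any hit.
#'
#' @param edges edge tibble from [pairwise_similarity()].
#' @param genes optional gene tibble whose rows define the full node set
#'   (isolated genes are kept as singleton nodes).
#' @return An `igraph` undirected weighted graph; vertex names are
#'   `genome|gene`.
#' @export
build_graph <- function(edges, genes = NULL) {
  w_of <- function(ev) pmin(-log10(pmax(ev, 1e-200)), 200)
  if (nrow(edges)) {
    e <- tibble::tibble(
      a = gene_key(edges$query_genome, edges$query_gene),
      b = gene_key(edges$hit_genome, edges$hit_gene),
      w = w_of(edges$evalue)
    )
    e <- e[e$a != e$b, ]
    key <- ifelse(e$a < e$b, paste(e$a, e$b, sep = "\r"),
                  paste(e$b, e$a, sep = "\r"))
    agg <- tapply(e$w, key, mean)
    ab <- stringr::str_split_fixed(names(agg), "\r", 2L)
    el <- cbind(ab[, 1L], ab[, 2L])
  } else {
    el <- matrix(character(), 0L, 2L)
    agg <- numeric()
  }
  nodes <- unique(c(el))
  if (!is.null(genes)) {
    nodes <- unique(c(nodes, gene_key(genes$genome_id, genes$gene_id)))
  }
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(nodes, igraph::V(g)$name)),
                            name = setdiff(nodes, igraph::V(g)$name))
  igraph::E(g)$weight <- as.numeric(agg)
  g
}

#' Markov clustering of the similarity graph into homolog groups
#'
#' Runs MCL (van Dongen) independently on every connected component: the
#' column-stochastic transition matrix (with unit self-loops, the standard
#' regularization against period-two oscillation) is alternately squared
#' (expansion) and raised entrywise to `inflation` with renormalization,
#' pruning entries below 1e-5, until the maximum column change falls below
#' 1e-6 or 200 iterations are reached.  Clusters are read off the attractor
#' structure; each gene lands in exactly one group.  Group ids are assigned
#' in order of each group's lexicographically smallest member, which makes
#' the output invariant under node relabeling.
#'
#' @param graph weighted graph from [build_graph()].
#' @param inflation inflation exponent (the published protocol uses 2.0).
#' @return Tibble of homolog groups: `group_id`, `genome_id`, `gene_id`.
#'   A `converged` attribute flags whether all components converged.
#' @export
mcl_cluster <- function(graph, inflation = 2.0) {
  comps <- igraph::components(graph)
  clusters <- list()
  all_converged <- TRUE
  for (ci in seq_len(comps$no)) {
    members <- names(comps$membership)[comps$membership == ci]
    if (length(members) == 1L) {
      clusters[[length(clusters) + 1L]] <- members
      next
    }
    sub <- igraph::induced_subgraph(graph, members)
    A <- igraph::as_adjacency_matrix(sub, attr = "weight", sparse = FALSE)
    res <- mcl_dense(A, inflation)
    if (!res$converged) all_converged <- FALSE
    for (cl in res$clusters) {
      clusters[[length(clusters) + 1L]] <- rownames(A)[cl]
    }
  }
  if (!all_converged) {
    warning("MCL did not converge within 200 iterations on every component;",
            " returning the current clustering", call. = FALSE)
  }
  firsts <- vapply(clusters, function(x) min(x), "")
  clusters <- clusters[order(firsts)]
  out <- tibble::tibble(
    group_id = rep(sprintf("G%05d", seq_along(clusters)), lengths(clusters)),
    key = unlist(clusters, use.names = FALSE)
  )
  out <- dplyr::bind_cols(out["group_id"], split_gene_key(out$key))
  attr(out, "converged") <- all_converged
  out
}

# Dense MCL on one symmetric nonnegative adjacency matrix.
mcl_dense <- function(A, inflation, prune = 1e-5, tol = 1e-6, max_iter = 200L) {
  n <- nrow(A)
  # self-loops at each node's maximum incident weight: the standard MCL
  # regularization (prevents period-two oscillation, keeps attractors local)
  diag(A) <- 0
  diag(A) <- pmax(apply(A, 2L, max), 1)
  M <- A / rep(colSums(A), each = n)     # column-stochastic
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                        # expansion
    M2 <- M2^inflation                   # inflation
    M2[M2 < prune] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- M2 / rep(cs, each = n)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  # attractors: nodes retaining mass on their own diagonal
  attractors <- which(diag(M) > 1e-6)
  if (!length(attractors)) attractors <- seq_len(n)
  # attractor classes: components of the attractor-attractor support graph
  S <- (M[attractors, attractors, drop = FALSE] > 1e-6) |
    t(M[attractors, attractors, drop = FALSE] > 1e-6)
  ag <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                            diag = FALSE)
  cls <- igraph::components(ag)$membership
  # each node joins the class of its highest-weight attractor (ties: lowest)
  assign_cls <- vapply(seq_len(n), function(j) {
    col <- M[attractors, j]
    if (all(col <= 0)) {
      return(NA_integer_)
    }
    best <- which(col == max(col))
    as.integer(min(cls[best]))
  }, 1L)
  # unattracted nodes (numerically dead columns) become singletons
  out <- split(seq_len(n), assign_cls)
  if (anyNA(assign_cls)) {
    out <- c(out, as.list(which(is.na(assign_cls))))
  }
  list(clusters = unname(out), converged = converged)
}

#' Per-genome presence counts of homolog groups
#'
#' @param groups tibble from [mcl_cluster()].
#' @return Tibble `group_id`, `genome_id`, `n` (member count).
#' @export
group_presence <- function(groups) {
  dplyr::count(groups, .data$group_id, .data$genome_id)
}
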