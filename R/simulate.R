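#' Configuration for the synthetic-genome simulator
#'
#' The simulator emulates the study design the pipeline was built for:
#' several related mushroom genomes, a five-gene secondary-metabolite
#' cluster (decarboxylase / P450 monooxygenase / phosphotransferase /
#' methyltransferase / MFS-transporter analogs) present only in "producer"
#' taxa, one horizontal transfer of the whole cluster from a producer clade
#' to one distant producer lineage, plus background gene families whose
#' presence/absence evolves by a two-state gain/loss process and, optionally,
#' families whose presence is forced to track an ecological niche.
#'
#' @param n_taxa number of genomes (>= 4).
#' @param seed master seed; every stochastic draw flows from a named
#'   substream of it, so the whole simulation is reproducible bit-for-bit.
#' @param n_background_families number of vertically evolving families.
#' @param root_present_prob probability a background family is present at the
#'   species-tree root.
#' @param gain_rate,loss_rate gain/loss rates of the presence process, per
#'   unit branch length.
#' @param ecology_linked_fraction fraction of background families whose
#'   presence is forced to be confined to genomes of one ecological niche
#'   (the niche and the number of carriers are drawn per family and logged).
#' @param branch_length_range species-tree branch lengths are drawn uniformly
#'   from this range (substitutions per site).
#' @param seq_length,cluster_seq_length protein lengths (aa) for background
#'   and cluster families.
#' @param cluster_functions function labels of the five planted cluster
#'   families.
#' @param producer_clade_size target size of the donor (vertically inheriting)
#'   producer clade; the recipient producer is the leaf most distant from it.
#' @param hgt_cluster if `TRUE` (default, the study condition) the recipient's
#'   cluster copy descends from the donor lineage, not from the recipient's
#'   own species-tree path.
#' @param hgt_recipient_branch branch length of the grafted recipient lineage
#'   (time since the transfer, substitutions per site).
#' @param cluster_relatives when `TRUE`, every genome also carries one
#'   distant paralog of each cluster family (a deep out-paralog subfamily,
#'   vertically inherited, scattered at random positions).  This mirrors the
#'   fact that secondary-metabolite genes are subfamilies of widespread
#'   families, and gives gene trees the outgroup leaves that the transfer
#'   screen's rooting and nesting judgments rely on.
#' @param cluster_relative_depth extra path length (substitutions per site)
#'   separating the cluster subfamily from its paralog subfamily.
#' @param ecology_probs named probabilities for the `dung`, `wood`,
#'   `mycorrhizal` niches.
#' @param dual_ecology_prob probability that a dung or wood genome carries
#'   both labels (some taxa decay both substrates).
#' @param genes_per_scaffold scaffold size used when laying out gene order.
#' @param n_categories number of coarse functional categories assigned to
#'   families (enrichment-test input).
#'
#' @return A classed list of settings.
#' @export
sim_config <- function(n_taxa = 6L,
                       seed = 1L,
                       n_background_families = 300L,
                       root_present_prob = 0.95,
                       gain_rate = 0.02,
                       loss_rate = 0.05,
                       ecology_linked_fraction = 0,
                       branch_length_range = c(0.05, 0.25),
                       seq_length = 180L,
                       cluster_seq_length = 300L,
                       cluster_functions = c("decarboxylase", "P450",
                                             "phosphotransferase",
                                             "methyltransferase",
                                             "MFS_transporter"),
                       producer_clade_size = 2L,
                       hgt_cluster = TRUE,
                       hgt_recipient_branch = 0.10,
                       cluster_relatives = FALSE,
                       cluster_relative_depth = 0.5,
                       ecology_probs = c(dung = 0.35, wood = 0.45,
                                         mycorrhizal = 0.20),
                       dual_ecology_prob = 0.10,
                       genes_per_scaffold = 50L,
                       n_categories = 8L) {
  if (n_taxa < 4L) stop("n_taxa must be at least 4", call. = FALSE)
  if (gain_rate < 0 || loss_rate < 0) {
    stop("gain/loss rates must be nonnegative", call. = FALSE)
  }
  if (length(cluster_functions) != 5L) {
    stop("the planted cluster has exactly five families", call. = FALSE)
  }
  stopifnot(length(branch_length_range) == 2L,
            all(branch_length_range > 0),
            producer_clade_size >= 1L,
            all(ecology_probs >= 0), sum(ecology_probs) > 0)
  structure(list(
    n_taxa = as.integer(n_taxa), seed = as.integer(seed),
    n_background_families = as.integer(n_background_families),
    root_present_prob = root_present_prob,
    gain_rate = gain_rate, loss_rate = loss_rate,
    ecology_linked_fraction = ecology_linked_fraction,
    branch_length_range = branch_length_range,
    seq_length = as.integer(seq_length),
    cluster_seq_length = as.integer(cluster_seq_length),
    cluster_functions = cluster_functions,
    producer_clade_size = as.integer(producer_clade_size),
    hgt_cluster = isTRUE(hgt_cluster),
    hgt_recipient_branch = hgt_recipient_branch,
    cluster_relatives = isTRUE(cluster_relatives),
    cluster_relative_depth = cluster_relative_depth,
    ecology_probs = ecology_probs / sum(ecology_probs),
    dual_ecology_prob = dual_ecology_prob,
    genes_per_scaffold = as.integer(genes_per_scaffold),
    n_categories = as.integer(n_categories)
  ), class = "sim_config")
}

# Deterministic substream seed derived from the master seed and a stream name.
substream <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) * 7919L + h * 104729L) %% 2147483647L
}

# -- amino-acid model machinery ----------------------------------------------

# Reversible WAG rate matrix scaled to one expected substitution per site,
# with its symmetric eigendecomposition cached for fast P(t).
wag_model <- function() {
  cache <- get0("wag", envir = CH_CACHE)
  if (!is.null(cache)) return(cache)
  n <- 20L
  S <- matrix(0, n, n)
  S[lower.tri(S)] <- WAG_EXCHANGE
  S <- S + t(S)
  pi <- WAG_FREQ
  Q <- S * rep(pi, each = n)        # Q[i,j] = S[i,j] * pi[j]
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  rt <- sqrt(pi)
  B <- Q * (rt %o% (1 / rt))        # symmetric similarity transform
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  m <- list(Q = Q, pi = pi,
            left = e$vectors * (1 / rt), right = t(e$vectors * rt),
            values = e$values)
  assign("wag", m, envir = CH_CACHE)
  m
}

# Transition probability matrix P(t) = exp(Qt) for the WAG model.
aa_transition_matrix <- function(t) {
  m <- wag_model()
  P <- m$left %*% (exp(m$values * t) * m$right)
  P[P < 0] <- 0
  P / rowSums(P)
}

# -- species tree -------------------------------------------------------------

#' Simulate a species tree with phenotypes and ecologies
#'
#' Draws a random binary topology with branch lengths uniform in
#' `config$branch_length_range`, assigns each taxon an ecological niche, and
#' designates the producer taxa: a donor clade of roughly
#' `producer_clade_size` taxa plus the recipient leaf most distant from it.
#'
#' @param config a [sim_config()].
#' @return A list: `tree` (`ape::phylo`, leaf labels `g01`, `g02`, ...),
#'   `meta` (tibble `genome_id`, `phenotype`, `ecology` list-column),
#'   `producers`, `donor_clade`, `recipient`, `donor` (the donor-clade leaf
#'   the transferred lineage grafts onto).
#' @export
simulate_species_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream(config$seed, "species_tree"))
  n <- config$n_taxa
  tree <- ape::rtree(n, rooted = TRUE,
                     br = function(k) stats::runif(k,
                                                   config$branch_length_range[1],
                                                   config$branch_length_range[2]))
  tree$tip.label <- sprintf("g%02d", seq_len(n))
  # ecologies
  niches <- names(config$ecology_probs)
  eco_primary <- sample(niches, n, replace = TRUE, prob = config$ecology_probs)
  ecology <- lapply(seq_len(n), function(i) {
    e <- eco_primary[i]
    other <- setdiff(c("dung", "wood"), e)
    if (e %in% c("dung", "wood") &&
        config$ecology_probs[other] > 0 &&
        stats::runif(1) < config$dual_ecology_prob) {
      sort(c(e, other))
    } else e
  })
  # donor clade: internal node whose tip count is closest to the target
  # (ties: fewer tips, then lexicographically smallest tip set)
  subs <- ape::prop.part(tree)
  tipsets <- lapply(subs, function(ix) sort(tree$tip.label[ix]))
  sizes <- lengths(tipsets)
  keep <- sizes < n                      # exclude the root clade
  cand <- which(keep)
  ord <- order(abs(sizes[cand] - config$producer_clade_size), sizes[cand],
               vapply(tipsets[cand], paste, "", collapse = ","))
  donor_clade <- tipsets[[cand[ord[1L]]]]
  # recipient: leaf with maximal path distance from the donor clade
  dmat <- ape::cophenetic.phylo(tree)
  outside <- setdiff(tree$tip.label, donor_clade)
  score <- vapply(outside, function(tp) min(dmat[tp, donor_clade]), 0)
  recipient <- outside[order(-score, outside)][1L]
  producers <- c(donor_clade, recipient)
  # donor lineage for the cluster transfer: the deepest leaf within the
  # donor clade (the recipient acquires the cluster from a lineage nested
  # well inside the donor genus, not from its base); ties lexicographic
  clade_sub <- ape::keep.tip(tree, donor_clade)
  par <- rep(NA_integer_, ape::Ntip(clade_sub) + clade_sub$Nnode)
  par[clade_sub$edge[, 2L]] <- clade_sub$edge[, 1L]
  node_depth <- vapply(seq_len(ape::Ntip(clade_sub)), function(i) {
    d <- 0L; u <- par[i]
    while (!is.na(u)) { d <- d + 1L; u <- par[u] }
    d
  }, 1L)
  ord_d <- order(-node_depth, clade_sub$tip.label)
  donor <- clade_sub$tip.label[ord_d[1L]]
  meta <- tibble::tibble(
    genome_id = tree$tip.label,
    phenotype = ifelse(tree$tip.label %in% producers, "PS_plus", "PS_minus"),
    ecology = ecology
  )
  list(tree = tree, meta = meta, producers = producers,
       donor_clade = donor_clade, recipient = recipient, donor = donor)
}

# -- gene content -------------------------------------------------------------

#' Simulate background gene-family presence/absence along a tree
#'
#' Presence evolves as a two-state Markov process (gain rate `g`, loss rate
#' `l` per unit branch length): along a branch of length `t` the transition
#' probabilities are `P(absent -> present) = g/(g+l) * (1 - exp(-(g+l) t))`
#' and symmetrically for loss.  A configurable fraction of families is
#' instead "ecology-linked": confined to a drawn number of genomes of one
#' niche and absent everywhere else.
#'
#' @param tree species tree (`ape::phylo`).
#' @param config a [sim_config()].
#' @param meta metadata tibble (needed to draw ecology-linked families);
#'   when `NULL`, `ecology_linked_fraction` must be 0.
#' @return A list: `presence` (logical matrix, taxa x families), `families`
#'   (tibble: `family_id`, `linked`, `niche`, `n_linked`, `category`).
#' @export
simulate_gene_content <- function(tree, config, meta = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$gain_rate < 0 || config$loss_rate < 0) {
    stop("gain/loss rates must be nonnegative", call. = FALSE)
  }
  set.seed(substream(config$seed, "gene_content"))
  nfam <- config$n_background_families
  fam_ids <- sprintf("F%04d", seq_len(nfam))
  n_linked <- round(config$ecology_linked_fraction * nfam)
  if (n_linked > 0 && is.null(meta)) {
    stop("ecology-linked families require taxon metadata", call. = FALSE)
  }
  linked <- rep(FALSE, nfam)
  if (n_linked > 0) linked[sample.int(nfam, n_linked)] <- TRUE

  ntip <- length(tree$tip.label)
  nvert <- sum(!linked)
  presence <- matrix(FALSE, ntip, nfam,
                     dimnames = list(tree$tip.label, fam_ids))

  if (nvert > 0) {
    g <- config$gain_rate; l <- config$loss_rate
    tot <- g + l
    n_nodes <- ntip + tree$Nnode
    states <- matrix(NA, n_nodes, nvert)
    root <- ntip + 1L
    states[root, ] <- stats::runif(nvert) < config$root_present_prob
    # preorder: parents before children
    ord <- stats::reorder(tree, "cladewise")
    for (k in seq_len(nrow(ord$edge))) {
      par <- ord$edge[k, 1L]; child <- ord$edge[k, 2L]
      t_br <- ord$edge.length[k]
      if (tot > 0) {
        pchange <- (1 - exp(-tot * t_br))
        p01 <- g / tot * pchange   # absent -> present
        p10 <- l / tot * pchange   # present -> absent
      } else {
        p01 <- p10 <- 0
      }
      u <- stats::runif(nvert)
      par_state <- states[par, ]
      states[child, ] <- ifelse(par_state, u >= p10, u < p01)
    }
    presence[, !linked] <- states[seq_len(ntip), , drop = FALSE]
  }

  niche <- rep(NA_character_, nfam)
  n_link_carriers <- rep(NA_integer_, nfam)
  if (n_linked > 0) {
    eco_flat <- meta$ecology
    names(eco_flat) <- meta$genome_id
    niche_members <- list(
      dung = meta$genome_id[vapply(eco_flat, function(e) "dung" %in% e, TRUE)],
      wood = meta$genome_id[vapply(eco_flat, function(e) "wood" %in% e, TRUE)],
      ecm  = meta$genome_id[vapply(eco_flat, function(e) "mycorrhizal" %in% e, TRUE)]
    )
    usable <- names(niche_members)[lengths(niche_members) >= 2L]
    if (!length(usable)) stop("no niche has two or more member genomes",
                              call. = FALSE)
    for (j in which(linked)) {
      nch <- sample(usable, 1L)
      members <- niche_members[[nch]]
      k <- sample(2L:length(members), 1L)
      carriers <- sample(members, k)
      presence[carriers, j] <- TRUE
      niche[j] <- nch
      n_link_carriers[j] <- k
    }
  }

  families <- tibble::tibble(
    family_id = fam_ids,
    linked = linked,
    niche = niche,
    n_linked = n_link_carriers,
    category = sprintf("C%02d", sample.int(config$n_categories, nfam,
                                           replace = TRUE))
  )
  list(presence = presence, families = families)
}

# -- sequence evolution -------------------------------------------------------

#' Evolve an indel-free protein family along a tree
#'
#' The root sequence is drawn from the WAG stationary frequencies and
#' propagated down the tree by per-site substitution with transition
#' matrices `exp(Qt)` under the scaled WAG model (one expected substitution
#' per site per unit branch length).  Families are natively aligned because
#' no indels are generated.
#'
#' @param tree family tree (`ape::phylo`, branch lengths in substitutions
#'   per site); leaves are the taxa carrying the family.
#' @param present_taxa taxa to evolve; the tree is pruned to these.  A single
#'   present taxon receives an equilibrium draw (the stationary process makes
#'   this the exact marginal).
#' @param seq_length protein length in amino acids (> 0).
#' @return Named character vector of equal-length protein sequences.
#' @export
evolve_family_sequences <- function(tree, present_taxa, seq_length) {
  if (seq_length < 1L) stop("zero-length root sequence", call. = FALSE)
  if (!length(present_taxa)) stop("family must be present in at least one taxon",
                                  call. = FALSE)
  pi <- wag_model()$pi
  if (length(present_taxa) == 1L) {
    s <- sample.int(20L, seq_length, replace = TRUE, prob = pi)
    out <- paste(AA_ALPHABET[s], collapse = "")
    names(out) <- present_taxa
    return(out)
  }
  sub <- ape::keep.tip(tree, present_taxa)
  ntip <- length(sub$tip.label)
  n_nodes <- ntip + sub$Nnode
  states <- vector("list", n_nodes)
  root <- ntip + 1L
  states[[root]] <- sample.int(20L, seq_length, replace = TRUE, prob = pi)
  ord <- stats::reorder(sub, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1L]; child <- ord$edge[k, 2L]
    P <- aa_transition_matrix(ord$edge.length[k])
    ps <- states[[par]]
    cs <- integer(seq_length)
    for (a in unique(ps)) {
      idx <- which(ps == a)
      cs[idx] <- sample.int(20L, length(idx), replace = TRUE, prob = P[a, ])
    }
    states[[child]] <- cs
  }
  out <- vapply(seq_len(ntip),
                function(i) paste(AA_ALPHABET[states[[i]]], collapse = ""),
                "")
  names(out) <- sub$tip.label
  out
}

# -- cluster planting ---------------------------------------------------------

# Insert rows at independent random positions along a genome's scaffolds,
# then re-rank order indices so they stay consecutive per scaffold.
insert_scattered <- function(sub, rows, genome_id) {
  if (nrow(sub) == 0L) {
    rows$scaffold_id <- paste0(genome_id, "_s01")
    rows$order_index <- sample(seq_len(nrow(rows))) - 1L
    return(dplyr::arrange(rows, .data$order_index))
  }
  scafs <- unique(sub$scaffold_id)
  sub$sort_key <- as.numeric(sub$order_index)
  rows$scaffold_id <- sample(scafs, nrow(rows), replace = TRUE)
  rows$sort_key <- stats::runif(nrow(rows), -0.5,
                                max(sub$order_index) + 0.5)
  merged <- dplyr::bind_rows(sub, rows)
  merged <- merged |>
    dplyr::arrange(.data$scaffold_id, .data$sort_key) |>
    dplyr::group_by(.data$scaffold_id) |>
    dplyr::mutate(order_index = dplyr::row_number() - 1L) |>
    dplyr::ungroup()
  merged$sort_key <- NULL
  merged
}

# Tree along which the transferred cluster families evolve: the recipient
# leaf is detached from its own species-tree position and grafted onto the
# donor leaf's terminal edge (midpoint), with a short post-transfer branch.
graft_recipient_tree <- function(tree, donor, recipient, recipient_branch) {
  pruned <- ape::drop.tip(tree, recipient)
  where <- which(pruned$tip.label == donor)
  pos <- pruned$edge.length[pruned$edge[, 2L] == where] / 2
  phytools::bind.tip(pruned, recipient, edge.length = recipient_branch,
                     where = where, position = pos)
}

#' Plant the five-gene cluster (and its horizontal transfer) into genomes
#'
#' Inserts the five cluster families as a contiguous block (order shuffled
#' per genome within the locus) into each producer genome.  When the
#' configuration requests a cluster transfer, the recipient's cluster
#' sequences are evolved on a tree in which the recipient lineage branches
#' from within the donor clade, so its cluster genes carry the donor's
#' phylogenetic signal while its background genes keep the species-tree
#' signal.
#'
#' @param genes background gene tibble (as assembled by [simulate_genomes()]).
#' @param st species-tree bundle from [simulate_species_tree()].
#' @param config a [sim_config()].
#' @return A list: `genes` (with cluster genes inserted and order indices
#'   rebuilt), `cluster_genes` (tibble genome/gene/family/function),
#'   `cluster_tree` (the tree cluster sequences evolved on), `hgt_events`
#'   (tibble, zero or one row).
#' @export
plant_cluster_and_hgt <- function(genes, st, config) {
  stopifnot(inherits(config, "sim_config"))
  producers <- st$producers
  if (!length(producers)) stop("no producer taxa in the species tree",
                               call. = FALSE)
  if (config$hgt_cluster && !(st$recipient %in% producers)) {
    stop("the recipient of a cluster transfer must be a producer",
         call. = FALSE)
  }
  set.seed(substream(config$seed, "cluster"))
  fam_ids <- sprintf("CL%d", seq_len(5L))
  cluster_tree <- if (config$hgt_cluster) {
    graft_recipient_tree(st$tree, st$donor, st$recipient,
                         config$hgt_recipient_branch)
  } else {
    st$tree
  }
  if (config$cluster_relatives) {
    # joint family tree: the producer cluster subfamily plus a deep
    # out-paralog subfamily carried vertically by every genome
    A <- ape::keep.tip(cluster_tree, producers)
    B <- st$tree
    B$tip.label <- paste0(B$tip.label, "#rel")
    half <- config$cluster_relative_depth / 2
    joint <- ape::read.tree(text = sprintf(
      "(%s:%f,%s:%f);",
      sub(";$", "", ape::write.tree(A)), half,
      sub(";$", "", ape::write.tree(B)), half))
    seqs <- lapply(fam_ids, function(f) {
      evolve_family_sequences(joint, joint$tip.label,
                              config$cluster_seq_length)
    })
  } else {
    seqs <- lapply(fam_ids, function(f) {
      evolve_family_sequences(cluster_tree, producers,
                              config$cluster_seq_length)
    })
  }
  names(seqs) <- fam_ids

  cluster_rows <- list()
  relative_rows <- list()
  out_genes <- list()
  all_genomes <- union(unique(genes$genome_id), producers)
  if (config$cluster_relatives) {
    all_genomes <- union(all_genomes, st$tree$tip.label)
  }
  for (g in all_genomes) {
    sub <- genes[genes$genome_id == g, ]
    if (config$cluster_relatives) {
      rel <- tibble::tibble(
        genome_id = g,
        scaffold_id = NA_character_,
        order_index = NA_integer_,
        gene_id = paste0(g, ".", fam_ids, "r"),
        function_label = NA_character_,
        family_id = paste0(fam_ids, "R"),
        protein_seq = unname(vapply(fam_ids,
                             function(f) unname(seqs[[f]][paste0(g, "#rel")]),
                             ""))
      )
      sub <- insert_scattered(sub, rel, g)
      relative_rows[[g]] <- rel[, c("genome_id", "gene_id", "family_id")]
    }
    if (g %in% producers && nrow(sub) == 0L) {
      # degenerate: a producer with no background genes gets a lone scaffold
      sub <- tibble::tibble(genome_id = character(), scaffold_id = character(),
                            order_index = integer(), gene_id = character(),
                            function_label = character(),
                            family_id = character(), protein_seq = character())
      ord_fams <- sample(fam_ids)
      block <- tibble::tibble(
        genome_id = g, scaffold_id = paste0(g, "_s01"),
        order_index = seq_len(5L) - 1L,
        gene_id = paste0(g, ".", ord_fams),
        function_label = config$cluster_functions[match(ord_fams, fam_ids)],
        family_id = ord_fams,
        protein_seq = unname(vapply(ord_fams, function(f) unname(seqs[[f]][g]), ""))
      )
      cluster_rows[[g]] <- block[, c("genome_id", "gene_id", "family_id",
                                     "function_label")]
      out_genes[[g]] <- block
      next
    }
    if (g %in% producers) {
      ord_fams <- sample(fam_ids)         # gene order varies between clusters
      block <- tibble::tibble(
        genome_id = g,
        scaffold_id = NA_character_,
        order_index = NA_integer_,
        gene_id = paste0(g, ".", ord_fams),
        function_label = config$cluster_functions[match(ord_fams, fam_ids)],
        family_id = ord_fams,
        protein_seq = unname(vapply(ord_fams, function(f) unname(seqs[[f]][g]), ""))
      )
      # insert contiguously within one scaffold
      scafs <- unique(sub$scaffold_id)
      sc <- sample(scafs, 1L)
      sc_rows <- which(sub$scaffold_id == sc)
      at <- sample.int(length(sc_rows) + 1L, 1L) - 1L  # 0..n genes before block
      block$scaffold_id <- sc
      before <- sub[sub$scaffold_id != sc & seq_len(nrow(sub)) < min(sc_rows), ]
      scaffold_genes <- sub[sc_rows, ]
      after <- sub[sub$scaffold_id != sc & seq_len(nrow(sub)) > max(sc_rows), ]
      merged <- dplyr::bind_rows(
        scaffold_genes[seq_len(at), ],
        block,
        if (at < nrow(scaffold_genes)) {
          scaffold_genes[(at + 1L):nrow(scaffold_genes), ]
        }
      )
      merged$order_index <- seq_len(nrow(merged)) - 1L
      sub <- dplyr::bind_rows(before, merged, after)
      cluster_rows[[g]] <- block[, c("genome_id", "gene_id", "family_id",
                                     "function_label")]
    }
    out_genes[[g]] <- sub
  }
  hgt_events <- if (config$hgt_cluster) {
    tibble::tibble(donor = st$donor, recipient = st$recipient,
                   what = "cluster", family_id = list(fam_ids))
  } else {
    tibble::tibble(donor = character(), recipient = character(),
                   what = character(), family_id = list())
  }
  list(genes = dplyr::bind_rows(out_genes),
       cluster_genes = dplyr::bind_rows(cluster_rows),
       relative_genes = if (length(relative_rows)) {
         dplyr::bind_rows(relative_rows)
       } else {
         tibble::tibble(genome_id = character(), gene_id = character(),
                        family_id = character())
       },
       cluster_tree = cluster_tree,
       hgt_events = hgt_events)
}

# -- full simulation ----------------------------------------------------------

#' Simulate a genome bundle with ground truth
#'
#' Runs the full generative model: species tree with phenotypes and
#' ecologies, background family presence/absence, indel-free sequence
#' evolution, gene-order layout on scaffolds, and the planted cluster with
#' its horizontal transfer.  Everything downstream of the master seed is
#' deterministic.
#'
#' @param config a [sim_config()].
#' @return A list with `genes` (gene tibble incl. `protein_seq` and true
#'   `family_id`), `meta` (taxon metadata), `tree` (species tree) and
#'   `truth`, a ground-truth log holding the family table, the true
#'   presence matrix (including cluster families), per-gene family
#'   assignments, cluster member genes, realized transfer events, the
#'   cluster-evolution tree and the species tree.
#' @examples
#' sim <- simulate_genomes(sim_config(n_taxa = 6, n_background_families = 40))
#' dplyr::count(sim$genes, genome_id)
#' @export
simulate_genomes <- function(config = sim_config()) {
  st <- simulate_species_tree(config)
  content <- simulate_gene_content(st$tree, config, st$meta)
  presence <- content$presence

  set.seed(substream(config$seed, "sequences"))
  fam_ids <- colnames(presence)
  seqs <- vector("list", length(fam_ids))
  names(seqs) <- fam_ids
  for (f in fam_ids) {
    carriers <- rownames(presence)[presence[, f]]
    if (!length(carriers)) next
    seqs[[f]] <- evolve_family_sequences(st$tree, carriers, config$seq_length)
  }

  # lay genes out on scaffolds: random order per genome, fixed scaffold size
  set.seed(substream(config$seed, "layout"))
  rows <- list()
  for (g in st$tree$tip.label) {
    fams <- fam_ids[presence[g, ]]
    fams <- sample(fams)
    if (!length(fams)) {
      rows[[g]] <- tibble::tibble(genome_id = character(),
                                  scaffold_id = character(),
                                  order_index = integer(),
                                  gene_id = character(),
                                  function_label = character(),
                                  family_id = character(),
                                  protein_seq = character())
      next
    }
    scaf <- ceiling(seq_along(fams) / config$genes_per_scaffold)
    rows[[g]] <- tibble::tibble(
      genome_id = g,
      scaffold_id = sprintf("%s_s%02d", g, scaf),
      order_index = stats::ave(seq_along(fams), scaf,
                               FUN = seq_along) - 1L,
      gene_id = paste0(g, ".", fams),
      function_label = NA_character_,
      family_id = fams,
      protein_seq = unname(vapply(fams, function(f) unname(seqs[[f]][g]), ""))
    )
  }
  genes <- dplyr::bind_rows(rows)

  planted <- plant_cluster_and_hgt(genes, st, config)
  genes <- dplyr::arrange(planted$genes, .data$genome_id, .data$scaffold_id,
                          .data$order_index)

  cl_pres <- matrix(FALSE, nrow(presence), 5L,
                    dimnames = list(rownames(presence),
                                    sprintf("CL%d", 1:5)))
  cl_pres[st$producers, ] <- TRUE
  families <- dplyr::bind_rows(
    content$families,
    tibble::tibble(family_id = sprintf("CL%d", 1:5), linked = FALSE,
                   niche = NA_character_, n_linked = NA_integer_,
                   category = "cluster")
  )
  if (config$cluster_relatives) {
    rel_pres <- matrix(TRUE, nrow(presence), 5L,
                       dimnames = list(rownames(presence),
                                       sprintf("CL%dR", 1:5)))
    cl_pres <- cbind(cl_pres, rel_pres)
    families <- dplyr::bind_rows(
      families,
      tibble::tibble(family_id = sprintf("CL%dR", 1:5), linked = FALSE,
                     niche = NA_character_, n_linked = NA_integer_,
                     category = "cluster_relative")
    )
  }
  truth <- list(
    families = families,
    presence = cbind(presence, cl_pres),
    gene_map = genes[, c("gene_id", "genome_id", "family_id")],
    cluster_genes = planted$cluster_genes,
    hgt_events = planted$hgt_events,
    cluster_tree = planted$cluster_tree,
    species_tree = st$tree,
    producers = st$producers,
    donor_clade = st$donor_clade,
    recipient = st$recipient,
    donor = st$donor
  )
  list(genes = genes, meta = st$meta, tree = st$tree, truth = truth)
}

#' Write a simulation's ground-truth log as structured text
#'
#' @param truth the `truth` element of a [simulate_genomes()] result.
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_truth_log <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(truth$families, file.path(dir, "families.tsv"))
  pres <- tibble::as_tibble(truth$presence, rownames = "genome_id")
  readr::write_tsv(pres, file.path(dir, "presence.tsv"))
  readr::write_tsv(truth$gene_map, file.path(dir, "gene_map.tsv"))
  readr::write_tsv(truth$cluster_genes, file.path(dir, "cluster_genes.tsv"))
  ev <- truth$hgt_events
  ev$family_id <- vapply(ev$family_id, paste, "", collapse = ",")
  readr::write_tsv(ev, file.path(dir, "hgt_events.tsv"))
  ape::write.tree(truth$species_tree, file.path(dir, "species_tree.nwk"))
  ape::write.tree(truth$cluster_tree, file.path(dir, "cluster_tree.nwk"))
  invisible(dir)
}
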