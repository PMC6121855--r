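# End-to-end orchestration of the discovery and transfer pipelines.

#' Run the targeted cluster-discovery pipeline
#'
#' Executes homology search, Markov clustering, phenotype filtering,
#' co-localization, boundary refinement and the cross-genome consistency
#' check, then scans every surviving locus for conserved synteny.  A locus
#' is reported only when its homolog groups co-localize in every producer
#' genome — the "simultaneous evaluation in each genome" of the published
#' protocol, which suppresses one-genome coincidences.
#'
#' @param bundle either a list with `genes` and `meta` tibbles (e.g. from
#'   [simulate_genomes()] or [read_genome_bundle()]) or the path to a YAML
#'   config file with keys `bundle_dir` (genome bundle directory),
#'   optional `out_dir`, `max_negative` and a `params` block of
#'   [ch_params()] overrides.
#' @param params a [ch_params()].
#' @param max_negative phenotype-filter level for candidate groups.
#' @param out_dir when given, artifact TSVs are written there.
#' @return A `ch_discovery` list: `groups`, `counts` (staged filter
#'   report), `candidates` (candidate group rows), `loci_raw`, `loci`
#'   (refined, cross-genome consistent), `synteny`, `report` (stage/count
#'   tibble), `params`.
#' @export
run_discovery <- function(bundle, params = NULL, max_negative = 1L,
                          out_dir = NULL) {
  if (is.character(bundle)) {
    cfg <- yaml::read_yaml(bundle)
    params <- do.call(ch_params, cfg$params %||% list())
    bundle <- read_genome_bundle(cfg$bundle_dir,
                                 file.path(cfg$bundle_dir, "genes.tsv"),
                                 file.path(cfg$bundle_dir, "metadata.tsv"))
    max_negative <- cfg$max_negative %||% max_negative
    out_dir <- cfg$out_dir %||% out_dir
  }
  params <- as_ch_params(params)
  genes <- bundle$genes
  meta <- bundle$meta
  edges <- pairwise_similarity(genes, params)
  # cluster-detection stage keeps edges meeting the similarity floor
  edges_cluster <- edges[edges$similarity >= params$min_sim_cluster, ]
  graph <- build_graph(edges_cluster, genes)
  groups <- mcl_cluster(graph, params$mcl_inflation)
  counts <- filter_counts_report(groups, meta)
  candidates <- taxon_filter_groups(groups, meta, max_negative)
  loci_raw <- find_colocalized(candidates, genes, params)
  loci_ref <- refine_boundaries(loci_raw, genes, groups, meta, params,
                                max_negative)
  loci <- consistent_loci(loci_ref, meta)
  synteny <- list()
  for (lid in unique(loci$locus_id)) {
    synteny[[lid]] <- detect_synteny(loci[loci$locus_id == lid, ], genes,
                                     edges, params)
  }
  synteny <- if (length(synteny)) {
    dplyr::bind_rows(synteny, .id = "locus_id")
  } else {
    dplyr::bind_cols(tibble::tibble(locus_id = character()), empty_synteny())
  }
  report <- tibble::tibble(
    stage = c("genes", "similarity_edges", "homolog_groups",
              "candidate_groups", "raw_loci", "refined_loci",
              "consistent_loci", "synteny_blocks"),
    n = c(nrow(genes), nrow(edges) / 2L, dplyr::n_distinct(groups$group_id),
          dplyr::n_distinct(candidates$group_id),
          dplyr::n_distinct(loci_raw$locus_id),
          dplyr::n_distinct(loci_ref$locus_id),
          dplyr::n_distinct(loci$locus_id),
          dplyr::n_distinct(synteny$block_id))
  )
  out <- structure(list(groups = groups, counts = counts,
                        candidates = candidates, loci_raw = loci_raw,
                        loci = loci, synteny = synteny, report = report,
                        params = params),
                   class = "ch_discovery")
  if (!is.null(out_dir)) write_discovery(out, out_dir)
  out
}

# Cross-genome consistency: keep loci whose group set co-localizes (>= 2
# shared groups) in every producer genome, then prune each surviving locus
# to the conserved core — the groups found in a locus of every producer.
# One-genome coincidences (a chance candidate adjacent to the cluster in a
# single genome) are thereby excluded from the reported cluster.
consistent_loci <- function(loci, meta) {
  if (nrow(loci) == 0L) return(loci)
  ps_plus <- meta$genome_id[meta$phenotype == "PS_plus"]
  group_sets <- split(loci$group_id, loci$locus_id)
  genome_of <- vapply(split(loci$genome_id, loci$locus_id),
                      function(x) x[[1L]], "")
  keep <- vapply(names(group_sets), function(lid) {
    gs <- unique(group_sets[[lid]])
    all(vapply(setdiff(ps_plus, genome_of[[lid]]), function(h) {
      any(vapply(names(group_sets)[genome_of == h], function(l2) {
        length(intersect(gs, unique(group_sets[[l2]]))) >= 2L
      }, TRUE))
    }, TRUE))
  }, TRUE)
  out <- loci[loci$locus_id %in% names(group_sets)[keep], ]
  if (nrow(out) == 0L) return(out)
  # conserved core: groups present in surviving loci of every producer
  per_genome <- split(out$group_id, out$genome_id)
  core <- Reduce(intersect, lapply(per_genome[intersect(names(per_genome),
                                                        ps_plus)], unique))
  out <- out[out$group_id %in% core, ]
  if (nrow(out) == 0L) return(out)
  out <- out |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::filter(dplyr::n() >= 2L,
                  dplyr::n_distinct(.data$group_id) >= 2L) |>
    dplyr::mutate(start_index = min(.data$order_index),
                  end_index = max(.data$order_index)) |>
    dplyr::ungroup()
  out
}

write_discovery <- function(x, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_tsv(x$groups, file.path(out_dir, "groups.tsv"))
  readr::write_tsv(x$loci, file.path(out_dir, "loci.tsv"))
  readr::write_tsv(x$synteny, file.path(out_dir, "synteny.tsv"))
  readr::write_tsv(x$report, file.path(out_dir, "report.tsv"))
  invisible(out_dir)
}

#' @export
print.ch_discovery <- function(x, ...) {
  cat("<ch_discovery>\n")
  for (k in seq_len(nrow(x$report))) {
    cat(sprintf("  %-18s %d\n", x$report$stage[k], x$report$n[k]))
  }
  invisible(x)
}

#' Run the transfer-detection pipeline
#'
#' Screens a recipient genome against the database with [screen_genome()],
#' then, for every candidate that survived the supported-nesting stage,
#' reconciles its bootstrap gene tree against the species tree under both
#' the DL and DTL models.
#'
#' @param bundle list with `genes` and `meta`, or a YAML config path (keys
#'   `bundle_dir`, `recipient`, `donor_taxa`, optional `species_tree`
#'   Newick path, `params`).
#' @param recipient recipient genome id.
#' @param donor_taxa donor genome ids.
#' @param species_tree `ape::phylo` over the genomes (for reconciliation;
#'   `NULL` skips that step).
#' @param params a [ch_params()].
#' @param seed integer seed.
#' @param ... passed to [screen_genome()] (e.g. `surrounding_taxa`).
#' @return A `ch_hgt_run` list: `screen` (the `ch_hgt_screen`),
#'   `reconciliations` (named list of [compare_models()] results).
#' @export
run_hgt <- function(bundle, recipient, donor_taxa, species_tree = NULL,
                    params = NULL, seed = 1L, ...) {
  if (is.character(bundle)) {
    cfg <- yaml::read_yaml(bundle)
    params <- do.call(ch_params, cfg$params %||% list())
    bundle <- read_genome_bundle(cfg$bundle_dir,
                                 file.path(cfg$bundle_dir, "genes.tsv"),
                                 file.path(cfg$bundle_dir, "metadata.tsv"))
    recipient <- cfg$recipient
    donor_taxa <- cfg$donor_taxa
    if (!is.null(cfg$species_tree)) {
      species_tree <- read_newick(cfg$species_tree)
    }
  }
  params <- as_ch_params(params)
  genes <- bundle$genes
  edges <- pairwise_similarity(genes, params)
  screen <- screen_genome(recipient, genes, donor_taxa, params, seed = seed,
                          edges = edges, ...)
  recs <- list()
  if (!is.null(species_tree)) {
    flagged <- screen$candidates$gene_id[
      screen$candidates$stage_passed %in%
        c("supported", "constraint_rejected_vertical")]
    seq_by_key <- stats::setNames(genes$protein_seq,
                                  gene_key(genes$genome_id, genes$gene_id))
    for (qg in flagged) {
      qkey <- gene_key(recipient, qg)
      fam <- family_of_query(recipient, qg, edges, params)
      aln <- seq_by_key[fam]
      aln <- aln[nchar(aln) == nchar(aln[qkey])]
      if (length(aln) < 3L) next
      gt <- root_at_most_distant(
        bootstrap_tree(aln, params$n_bootstraps,
                       seed = substream(seed, paste0("rec_", qg))), qkey)
      gt <- collapse_weak_edges(gt, params$edge_weight_threshold)
      st <- ape::keep.tip(species_tree,
                          intersect(species_tree$tip.label,
                                    unique(leaf_genome(gt$tip.label))))
      st <- ape::multi2di(st, random = FALSE)
      recs[[qg]] <- try(compare_models(gt, st, params), silent = TRUE)
    }
  }
  structure(list(screen = screen, reconciliations = recs),
            class = "ch_hgt_run")
}

#' @export
print.ch_hgt_run <- function(x, ...) {
  print(x$screen)
  if (length(x$reconciliations)) {
    cat("reconciliations:\n")
    for (nm in names(x$reconciliations)) {
      r <- x$reconciliations[[nm]]
      if (!inherits(r, "try-error")) {
        cat(sprintf("  %s: preferred %s (DL %.1f vs DTL %.1f)\n", nm,
                    r$preferred, r$dl$total_cost, r$dtl$total_cost))
      }
    }
  }
  invisible(x)
}
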