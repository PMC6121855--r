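# The targeted cluster-discovery pipeline: phenotype-distribution filtering
# of homolog groups, co-localization chaining, boundary refinement and
# microsynteny scanning.

#' Filter homolog groups by phenotype distribution
#'
#' Retains groups present in every producer (PS+) genome and in at most
#' `max_negative` non-producer (PS-) genomes — with three producers and
#' `max_negative = 1` this is the "three to four genomes total" candidate
#' rule.
#'
#' @param groups homolog-group tibble (`group_id`, `genome_id`, `gene_id`).
#' @param meta metadata tibble with `genome_id` and `phenotype`
#'   (`PS_plus` / `PS_minus` / `unknown`; unknowns count on neither side).
#' @param max_negative maximum number of PS- genomes a retained group may
#'   occur in (the published protocol sweeps 0-3 and carries 0-1 forward).
#' @return The subset of `groups` rows belonging to retained groups.
#' @export
taxon_filter_groups <- function(groups, meta, max_negative = 1L) {
  ps_plus <- meta$genome_id[meta$phenotype == "PS_plus"]
  ps_minus <- meta$genome_id[meta$phenotype == "PS_minus"]
  if (!length(ps_plus)) stop("no PS+ genomes declared", call. = FALSE)
  tab <- dplyr::distinct(groups, .data$group_id, .data$genome_id)
  stats_tbl <- tab |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(
      n_plus = sum(.data$genome_id %in% ps_plus),
      n_minus = sum(.data$genome_id %in% ps_minus),
      .groups = "drop"
    )
  keep <- stats_tbl$group_id[stats_tbl$n_plus == length(ps_plus) &
                               stats_tbl$n_minus <= max_negative]
  groups[groups$group_id %in% keep, ]
}

#' Staged counts of the phenotype filter (audit trail)
#'
#' Mirrors the protocol's habit of reporting how many groups survive each
#' stage: all groups, groups found in every PS+ genome, groups universal to
#' all genomes, and the remainder after removing the universal ones.
#'
#' @inheritParams taxon_filter_groups
#' @return One-row tibble: `total`, `in_all_ps_plus`, `in_all_genomes`,
#'   `remaining`.
#' @export
filter_counts_report <- function(groups, meta) {
  ps_plus <- meta$genome_id[meta$phenotype == "PS_plus"]
  if (!length(ps_plus)) stop("no PS+ genomes declared", call. = FALSE)
  all_genomes <- meta$genome_id
  tab <- dplyr::distinct(groups, .data$group_id, .data$genome_id)
  per <- tab |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(
      n_plus = sum(.data$genome_id %in% ps_plus),
      n_all = dplyr::n_distinct(.data$genome_id),
      .groups = "drop"
    )
  in_all_plus <- per$n_plus == length(ps_plus)
  universal <- per$n_all == length(all_genomes)
  tibble::tibble(
    total = nrow(per),
    in_all_ps_plus = sum(in_all_plus),
    in_all_genomes = sum(universal),
    remaining = sum(in_all_plus & !universal)
  )
}

#' Chain co-localized candidate genes into cluster loci
#'
#' Single-linkage chaining along each scaffold: two candidate genes belong
#' to the same locus when no more than `params$max_intervening` genes lie
#' strictly between them, and chains merge transitively.  A reportable locus
#' needs at least two member genes from at least two distinct homolog groups
#' (a run of tandem duplicates of one family is not a cluster).
#'
#' @param candidate_groups tibble of candidate groups (`group_id`,
#'   `genome_id`, `gene_id`), e.g. the output of [taxon_filter_groups()].
#' @param genes gene tibble with positions (`genome_id`, `scaffold_id`,
#'   `order_index`, `gene_id`).
#' @param params a [ch_params()].
#' @return Tibble with one row per locus member gene: `locus_id`,
#'   `genome_id`, `scaffold_id`, `start_index`, `end_index`, `gene_id`,
#'   `group_id`, `order_index`.
#' @export
find_colocalized <- function(candidate_groups, genes, params = NULL) {
  params <- as_ch_params(params)
  cand <- dplyr::inner_join(
    genes[, c("genome_id", "scaffold_id", "order_index", "gene_id")],
    candidate_groups[, c("genome_id", "gene_id", "group_id")],
    by = c("genome_id", "gene_id")
  )
  if (nrow(cand) == 0L) return(empty_loci())
  cand <- dplyr::arrange(cand, .data$genome_id, .data$scaffold_id,
                         .data$order_index)
  cand <- cand |>
    dplyr::group_by(.data$genome_id, .data$scaffold_id) |>
    dplyr::mutate(
      gap_break = c(0L, as.integer(diff(.data$order_index) - 1L >
                                     params$max_intervening)),
      chain = cumsum(.data$gap_break)
    ) |>
    dplyr::ungroup()
  loci <- cand |>
    dplyr::group_by(.data$genome_id, .data$scaffold_id, .data$chain) |>
    dplyr::mutate(n_members = dplyr::n(),
                  n_groups = dplyr::n_distinct(.data$group_id),
                  start_index = min(.data$order_index),
                  end_index = max(.data$order_index)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$n_members >= 2L, .data$n_groups >= 2L)
  if (nrow(loci) == 0L) return(empty_loci())
  ids <- loci |>
    dplyr::distinct(.data$genome_id, .data$scaffold_id, .data$start_index) |>
    dplyr::arrange(.data$genome_id, .data$scaffold_id, .data$start_index) |>
    dplyr::mutate(locus_id = sprintf("L%03d", dplyr::row_number()))
  loci <- dplyr::inner_join(loci, ids,
                            by = c("genome_id", "scaffold_id", "start_index"))
  dplyr::select(loci, "locus_id", "genome_id", "scaffold_id", "start_index",
                "end_index", "gene_id", "group_id", "order_index")
}

empty_loci <- function() {
  tibble::tibble(locus_id = character(), genome_id = character(),
                 scaffold_id = character(), start_index = integer(),
                 end_index = integer(), gene_id = character(),
                 group_id = character(), order_index = integer())
}

#' Refine cluster-locus boundaries
#'
#' Repeats the cluster search in a window of up to `params$boundary_window`
#' genes on either side of each locus: a flanking gene is admitted when its
#' homolog group (a) passes the same phenotype filter as the seed
#' candidates and (b) shows convergent synteny — in every other PS+ genome
#' the group has a member within the window of that genome's copy of the
#' locus.  Iterates until a pass admits nothing; boundaries only widen.
#'
#' @param loci locus tibble from [find_colocalized()].
#' @param genes gene tibble with positions.
#' @param groups full homolog-group tibble.
#' @param meta metadata tibble with phenotypes.
#' @param params a [ch_params()].
#' @param max_negative phenotype-filter level used for admission.
#' @return Locus tibble in the same shape, possibly with extra member rows
#'   and widened `start_index`/`end_index`.
#' @export
refine_boundaries <- function(loci, genes, groups, meta, params = NULL,
                              max_negative = 1L) {
  params <- as_ch_params(params)
  if (nrow(loci) == 0L) return(loci)
  passing <- unique(taxon_filter_groups(groups, meta, max_negative)$group_id)
  ps_plus <- meta$genome_id[meta$phenotype == "PS_plus"]
  pos <- dplyr::inner_join(
    genes[, c("genome_id", "scaffold_id", "order_index", "gene_id")],
    groups[, c("genome_id", "gene_id", "group_id")],
    by = c("genome_id", "gene_id")
  )
  out <- list()
  for (lid in unique(loci$locus_id)) {
    cur <- loci[loci$locus_id == lid, ]
    g <- cur$genome_id[1L]; sc <- cur$scaffold_id[1L]
    scaffold <- pos[pos$genome_id == g & pos$scaffold_id == sc, ]
    scaffold <- dplyr::arrange(scaffold, .data$order_index)
    member_idx <- cur$order_index
    repeat {
      lo <- min(member_idx); hi <- max(member_idx)
      flanks <- scaffold[(scaffold$order_index >= lo - params$boundary_window &
                            scaffold$order_index < lo) |
                           (scaffold$order_index > hi &
                              scaffold$order_index <= hi + params$boundary_window), ]
      flanks <- flanks[!is.na(flanks$group_id) &
                         flanks$group_id %in% passing, ]
      if (nrow(flanks) == 0L) break
      locus_groups <- unique(cur$group_id)
      admit <- vapply(seq_len(nrow(flanks)), function(i) {
        flank_syntenic(flanks$group_id[i], locus_groups, pos,
                       setdiff(ps_plus, g), params$boundary_window)
      }, TRUE)
      flanks <- flanks[admit, ]
      if (nrow(flanks) == 0L) break
      add <- dplyr::anti_join(flanks, cur, by = "gene_id")
      if (nrow(add) == 0L) break
      cur <- dplyr::bind_rows(
        cur,
        tibble::tibble(locus_id = lid, genome_id = g, scaffold_id = sc,
                       start_index = NA_integer_, end_index = NA_integer_,
                       gene_id = add$gene_id, group_id = add$group_id,
                       order_index = add$order_index)
      )
      member_idx <- cur$order_index
    }
    cur$start_index <- min(cur$order_index)
    cur$end_index <- max(cur$order_index)
    out[[lid]] <- dplyr::arrange(cur, .data$order_index)
  }
  dplyr::bind_rows(out)
}

# Synteny-convergence check for boundary refinement: in every listed genome
# the flank group must sit within `window` genes of some locus-group member.
flank_syntenic <- function(flank_group, locus_groups, pos, genomes, window) {
  if (!length(genomes)) return(TRUE)
  for (h in genomes) {
    ph <- pos[pos$genome_id == h, ]
    fg <- ph[ph$group_id %in% flank_group, ]
    lg <- ph[ph$group_id %in% locus_groups, ]
    ok <- FALSE
    if (nrow(fg) && nrow(lg)) {
      for (i in seq_len(nrow(fg))) {
        same <- lg$scaffold_id == fg$scaffold_id[i] &
          abs(lg$order_index - fg$order_index[i]) <= window
        if (any(same)) { ok <- TRUE; break }
      }
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Scan genomes for conserved microsynteny of a locus
#'
#' Finds homologs of the locus proteins in the database genomes (e-value at
#' most `params$evalue_screen`, similarity at least
#' `params$min_sim_synteny`), then chains co-localized hits with the same
#' intervening-gene rule used for discovery.  A reported block contains
#' homologs of at least two distinct locus genes.  A locus gene always
#' counts as a homolog of itself, so a locus is in perfect synteny with
#' itself.
#'
#' @param locus one locus (rows of the locus tibble sharing a `locus_id`).
#' @param genes gene tibble for the database genomes.
#' @param edges similarity edges from [pairwise_similarity()] covering the
#'   locus genes versus the database.
#' @param params a [ch_params()].
#' @return Tibble with one row per anchor: `block_id`, `target_genome`,
#'   `target_scaffold`, `target_gene`, `target_order`, `query_gene`,
#'   `block_start`, `block_end`.
#' @export
detect_synteny <- function(locus, genes, edges, params = NULL) {
  params <- as_ch_params(params)
  stopifnot(length(unique(locus$locus_id)) == 1L)
  lg <- locus$gene_id
  hits <- edges[edges$query_gene %in% lg &
                  edges$query_genome %in% locus$genome_id &
                  edges$evalue <= params$evalue_screen &
                  edges$similarity >= params$min_sim_synteny,
                c("query_gene", "hit_genome", "hit_gene")]
  self_hits <- tibble::tibble(query_gene = lg,
                              hit_genome = locus$genome_id,
                              hit_gene = lg)
  hits <- dplyr::distinct(dplyr::bind_rows(hits, self_hits))
  placed <- dplyr::inner_join(
    hits, genes[, c("genome_id", "gene_id", "scaffold_id", "order_index")],
    by = c("hit_genome" = "genome_id", "hit_gene" = "gene_id")
  )
  if (nrow(placed) == 0L) return(empty_synteny())
  placed <- dplyr::arrange(placed, .data$hit_genome, .data$scaffold_id,
                           .data$order_index)
  one_per_pos <- placed |>
    dplyr::group_by(.data$hit_genome, .data$scaffold_id, .data$order_index) |>
    dplyr::summarise(hit_gene = .data$hit_gene[1L],
                     query_genes = list(unique(.data$query_gene)),
                     .groups = "drop")
  chained <- one_per_pos |>
    dplyr::group_by(.data$hit_genome, .data$scaffold_id) |>
    dplyr::mutate(gap_break = c(0L, as.integer(diff(.data$order_index) - 1L >
                                                 params$max_intervening)),
                  chain = cumsum(.data$gap_break)) |>
    dplyr::ungroup()
  blocks <- chained |>
    dplyr::group_by(.data$hit_genome, .data$scaffold_id, .data$chain) |>
    dplyr::mutate(n_queries = dplyr::n_distinct(unlist(.data$query_genes)),
                  n_anchors = dplyr::n(),
                  block_start = min(.data$order_index),
                  block_end = max(.data$order_index)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$n_queries >= 2L, .data$n_anchors >= 2L)
  if (nrow(blocks) == 0L) return(empty_synteny())
  ids <- blocks |>
    dplyr::distinct(.data$hit_genome, .data$scaffold_id, .data$block_start) |>
    dplyr::arrange(.data$hit_genome, .data$scaffold_id, .data$block_start) |>
    dplyr::mutate(block_id = sprintf("B%03d", dplyr::row_number()))
  blocks <- dplyr::inner_join(blocks, ids,
                              by = c("hit_genome", "scaffold_id", "block_start"))
  tibble::tibble(
    block_id = blocks$block_id,
    target_genome = blocks$hit_genome,
    target_scaffold = blocks$scaffold_id,
    target_gene = blocks$hit_gene,
    target_order = blocks$order_index,
    query_gene = vapply(blocks$query_genes, function(q) q[[1L]], ""),
    block_start = blocks$block_start,
    block_end = blocks$block_end
  )
}

empty_synteny <- function() {
  tibble::tibble(block_id = character(), target_genome = character(),
                 target_scaffold = character(), target_gene = character(),
                 target_order = integer(), query_gene = character(),
                 block_start = integer(), block_end = integer())
}
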