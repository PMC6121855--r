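# Genome-content ordination and niche-specific gene detection.

#' Assemble and filter the genome x group count matrix
#'
#' Counts proteins per homolog group per genome and removes the
#' uninformative columns: groups present in exactly one genome and groups
#' present in every genome.
#'
#' @param groups homolog-group tibble (`group_id`, `genome_id`, `gene_id`).
#' @param genomes character vector of all genome ids (rows; genomes without
#'   any group member get zero rows).
#' @return Integer matrix, genomes x groups.
#' @export
build_and_filter_matrix <- function(groups, genomes) {
  counts <- dplyr::count(groups, .data$genome_id, .data$group_id)
  gids <- sort(unique(counts$group_id))
  m <- matrix(0L, length(genomes), length(gids),
              dimnames = list(sort(genomes), gids))
  m[cbind(match(counts$genome_id, rownames(m)),
          match(counts$group_id, colnames(m)))] <- counts$n
  present_in <- colSums(m > 0L)
  keep <- present_in > 1L & present_in < nrow(m)
  m <- m[, keep, drop = FALSE]
  if (ncol(m) == 0L) {
    stop("no informative groups remain after filtering", call. = FALSE)
  }
  m
}

#' Principal component analysis of genome content
#'
#' Columns are centered and scaled to unit variance (constant columns are
#' dropped first with a warning, since unit variance is undefined for
#' them), then decomposed by SVD via [stats::prcomp()].  The sign of each
#' component is fixed so that its largest-magnitude loading is positive,
#' making outputs reproducible.
#'
#' @param m count matrix from [build_and_filter_matrix()].
#' @return A `ch_ordination` list: `scores` (tibble, genomes x PCs),
#'   `loadings` (tibble, groups x PCs), `variance_fraction` (numeric).
#' @export
pca_content <- function(m) {
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need at least two genomes and two groups", call. = FALSE)
  }
  const <- apply(m, 2L, function(x) stats::var(x) == 0)
  if (any(const)) {
    warning(sum(const), " constant column(s) dropped before scaling",
            call. = FALSE)
    m <- m[, !const, drop = FALSE]
  }
  if (ncol(m) < 2L) stop("fewer than two non-constant columns", call. = FALSE)
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  # sign convention: largest-|loading| entry of each PC is positive
  for (k in seq_len(ncol(pc$rotation))) {
    peak <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[peak, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    scores = tibble::as_tibble(pc$x, rownames = "genome_id"),
    loadings = tibble::as_tibble(pc$rotation, rownames = "group_id"),
    variance_fraction = vf
  ), class = "ch_ordination")
}

#' @export
print.ch_ordination <- function(x, ...) {
  cat("<ch_ordination> ", nrow(x$scores), " genomes, ",
      nrow(x$loadings), " groups\n", sep = "")
  vf <- round(100 * x$variance_fraction[1:min(3, length(x$variance_fraction))])
  cat("  variance explained: ", paste0("PC", seq_along(vf), " ", vf, "%",
                                       collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Select high-loading groups on one principal component
#'
#' The positive set holds groups whose loading reaches the
#' `percentile`-th percentile of all positive loadings on that component;
#' the negative set is the analogue on the magnitudes of the negative
#' loadings.  Percentiles interpolate linearly between order statistics.
#'
#' @param ordination a `ch_ordination` from [pca_content()].
#' @param pc_index which component (1-based).
#' @param percentile cutoff percentile (protocol default 95).
#' @return List of character vectors `positive` and `negative`.
#' @export
select_loading_groups <- function(ordination, pc_index = 1L,
                                  percentile = 95) {
  ld <- ordination$loadings
  col <- paste0("PC", pc_index)
  if (!col %in% names(ld)) stop("no component ", col, call. = FALSE)
  v <- stats::setNames(ld[[col]], ld$group_id)
  pos <- v[v > 0]
  neg <- -v[v < 0]
  positive <- if (length(pos)) {
    names(pos)[pos >= stats::quantile(pos, percentile / 100, type = 7)]
  } else character()
  negative <- if (length(neg)) {
    names(neg)[neg >= stats::quantile(neg, percentile / 100, type = 7)]
  } else character()
  list(positive = positive, negative = negative)
}

#' Functional-category enrichment of a group selection
#'
#' One-tailed Fisher's exact test (enrichment direction) of each category
#' among the selected groups against the background, Bonferroni-corrected
#' for the number of selections tested (by default 4: the positive and
#' negative tails of the first two components).
#'
#' @param selected_groups character vector of selected group ids.
#' @param annotations tibble `group_id`, `category`.
#' @param background_groups character vector of all tested group ids.
#' @param alpha significance level after correction.
#' @param n_tests Bonferroni multiplier.
#' @return Tibble: `category`, `n_selected`, `n_background`, `p`,
#'   `p_bonferroni`, `significant`.
#' @export
category_enrichment <- function(selected_groups, annotations,
                                background_groups, alpha = 0.05,
                                n_tests = 4L) {
  ann <- annotations[annotations$group_id %in% background_groups, ]
  sel <- intersect(selected_groups, background_groups)
  out <- list()
  for (cat_ in sort(unique(ann$category))) {
    in_cat <- unique(ann$group_id[ann$category == cat_])
    if (!length(in_cat)) next
    a <- length(intersect(sel, in_cat))
    b <- length(setdiff(sel, in_cat))
    c_ <- length(setdiff(in_cat, sel))
    d <- length(setdiff(background_groups, union(sel, in_cat)))
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE),
                            alternative = "greater")$p.value
    out[[cat_]] <- tibble::tibble(
      category = cat_, n_selected = a, n_background = length(in_cat), p = p
    )
  }
  res <- dplyr::bind_rows(out)
  res$p_bonferroni <- pmin(1, res$p * n_tests)
  res$significant <- res$p_bonferroni < alpha
  res
}

#' Niche-specific homolog groups
#'
#' For each ecological niche, selects groups present in at least the
#' niche's cutoff number of member genomes and absent from every genome
#' not carrying that niche label (genomes with two labels count toward both
#' of their niches and never disqualify a group for either).  Each selected
#' group is additionally flagged as polyphyletic when its presence set is
#' not a clade of the species tree — the pattern that distinguishes
#' ecology-driven retention from simple shared ancestry.
#'
#' @param groups homolog-group tibble.
#' @param meta metadata tibble with `genome_id` and `ecology` (list-column;
#'   labels `dung`, `wood`, `mycorrhizal`).
#' @param species_tree `ape::phylo` over the genomes (for the polyphyly
#'   flag); `NULL` skips the flag.
#' @param cutoffs named integer vector (defaults: dung 3, wood 4, ecm 2).
#' @return Tibble: `niche`, `group_id`, `n_in_niche`, `polyphyletic`.
#' @export
niche_specific_groups <- function(groups, meta, species_tree = NULL,
                                  cutoffs = c(dung = 3L, wood = 4L,
                                              ecm = 2L)) {
  used <- unique(groups$genome_id)
  missing_meta <- setdiff(used, meta$genome_id)
  if (length(missing_meta)) {
    stop("no ecology metadata for genome(s): ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  label_of <- c(dung = "dung", wood = "wood", ecm = "mycorrhizal")
  members <- lapply(label_of, function(lb) {
    meta$genome_id[vapply(meta$ecology, function(e) lb %in% e, TRUE)]
  })
  pres <- dplyr::distinct(groups, .data$group_id, .data$genome_id)
  pres_sets <- split(pres$genome_id, pres$group_id)
  out <- list()
  for (niche in names(cutoffs)) {
    in_niche <- members[[niche]]
    qualifying <- vapply(pres_sets, function(g) {
      sum(g %in% in_niche) >= cutoffs[[niche]] && all(g %in% in_niche)
    }, TRUE)
    ids <- names(pres_sets)[qualifying]
    if (!length(ids)) next
    poly <- vapply(ids, function(gid) {
      g <- pres_sets[[gid]]
      if (is.null(species_tree) || length(g) < 2L) return(NA)
      !ape::is.monophyletic(species_tree, g)
    }, TRUE)
    out[[niche]] <- tibble::tibble(
      niche = niche, group_id = ids,
      n_in_niche = vapply(pres_sets[ids],
                          function(g) sum(g %in% in_niche), 1L),
      polyphyletic = poly
    )
  }
  if (!length(out)) {
    return(tibble::tibble(niche = character(), group_id = character(),
                          n_in_niche = integer(), polyphyletic = logical()))
  }
  dplyr::bind_rows(out)
}
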