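#' Read a genome bundle (protein FASTA + gene table + metadata)
#'
#' A genome bundle is the package's on-disk exchange format: one protein
#' FASTA per genome, a single ordered gene table (TSV with columns
#' `genome_id`, `scaffold_id`, `order_index`, `gene_id`, `function_label`,
#' or GFF3 restricted to `gene` features), and a metadata TSV with columns
#' `genome_id`, `phenotype` (`PS_plus`, `PS_minus` or `unknown`) and
#' `ecology` (comma-separated subset of `dung`, `wood`, `mycorrhizal`).
#'
#' @param fasta_paths character vector of protein FASTA files (one or more
#'   genomes; headers must be gene ids) or a directory containing `*.faa`.
#' @param gene_table_path path to the gene table (TSV or GFF3; GFF3 needs
#'   one file per genome named `<genome_id>.gff3`, or a `genome_id` column
#'   carried in the `##genome` pragma is not supported — use TSV for
#'   multi-genome tables).
#' @param metadata_path path to the metadata TSV.
#'
#' @return A list with tibbles `genes` (one row per gene, ordered by
#'   genome, scaffold and `order_index`, with `protein_seq` attached) and
#'   `meta` (one row per genome; `ecology` is a list-column of character
#'   vectors).
#' @seealso [write_genome_bundle()]
#' @export
read_genome_bundle <- function(fasta_paths, gene_table_path, metadata_path) {
  if (length(fasta_paths) == 1L && dir.exists(fasta_paths)) {
    fasta_paths <- list.files(fasta_paths, pattern = "\\.(faa|fasta|fa)$",
                              full.names = TRUE)
  }
  seqs <- unlist(lapply(fasta_paths, read_protein_fasta))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate gene ids across FASTA files: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  }
  tab <- read_gene_table(gene_table_path)
  missing <- setdiff(tab$gene_id, names(seqs))
  if (length(missing)) {
    stop("gene(s) listed in the gene table but absent from FASTA: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab$protein_seq <- unname(seqs[tab$gene_id])
  meta <- read_metadata(metadata_path)
  validate_genes(tab)
  list(genes = tab, meta = meta)
}

read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  # headers may carry descriptions after the id
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Read an ordered gene table (TSV or GFF3)
#'
#' @param path file path.  A `.gff`/`.gff3` file is parsed with rtracklayer
#'   (only `gene` features are used; `order_index` is the rank of the gene
#'   start along its scaffold, 0-based; the genome id is the file name stem
#'   unless an explicit `genome_id` is given).  Anything else is read as TSV.
#' @param genome_id genome id to assign to GFF3 rows (default: file stem).
#' @return tibble with columns `genome_id`, `scaffold_id`, `order_index`,
#'   `gene_id`, `function_label`.
#' @export
read_gene_table <- function(path, genome_id = NULL) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer_import_genes(path)
    gid <- genome_id %||% sub("\\.gff3?$", "", basename(path), ignore.case = TRUE)
    tab <- tibble::tibble(
      genome_id = gid,
      scaffold_id = as.character(gr$scaffold),
      start = gr$start,
      gene_id = gr$gene_id,
      function_label = gr$function_label
    )
    tab <- dplyr::arrange(tab, .data$scaffold_id, .data$start)
    tab <- dplyr::mutate(
      dplyr::group_by(tab, .data$scaffold_id),
      order_index = seq_along(.data$start) - 1L
    )
    tab <- dplyr::ungroup(tab)
    tab <- dplyr::select(tab, "genome_id", "scaffold_id", "order_index",
                         "gene_id", "function_label")
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             genome_id = readr::col_character(),
                             scaffold_id = readr::col_character(),
                             order_index = readr::col_integer(),
                             gene_id = readr::col_character(),
                             function_label = readr::col_character()
                           ))
  }
  dplyr::arrange(tab, .data$genome_id, .data$scaffold_id, .data$order_index)
}

# rtracklayer-backed GFF3 gene-feature extraction.
rtracklayer_import_genes <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "gene"]
  lab <- if ("function_label" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$function_label)
  } else {
    rep(NA_character_, length(gr))
  }
  list(scaffold = GenomicRanges::seqnames(gr),
       start = GenomicRanges::start(gr),
       gene_id = as.character(gr$ID),
       function_label = lab)
}

read_metadata <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  meta$ecology <- lapply(meta$ecology, function(e) {
    if (is.na(e) || !nzchar(e)) character() else strsplit(e, ",")[[1]]
  })
  tibble::as_tibble(meta)
}

validate_genes <- function(genes) {
  stopifnot(all(c("genome_id", "scaffold_id", "order_index", "gene_id",
                  "protein_seq") %in% names(genes)))
  dup <- dplyr::count(genes, .data$genome_id, .data$scaffold_id,
                      .data$order_index)
  if (any(dup$n > 1L)) {
    bad <- dup[dup$n > 1L, ]
    stop("duplicate order_index within scaffold: ",
         paste(bad$genome_id, bad$scaffold_id, bad$order_index,
               sep = ":", collapse = ", "), call. = FALSE)
  }
  consec <- genes |>
    dplyr::group_by(.data$genome_id, .data$scaffold_id) |>
    dplyr::summarise(ok = all(sort(.data$order_index) ==
                                seq_len(dplyr::n()) - 1L),
                     .groups = "drop")
  if (!all(consec$ok)) {
    stop("order_index values must be consecutive from 0 within each scaffold",
         call. = FALSE)
  }
  if (any(!nzchar(genes$protein_seq))) {
    stop("empty protein sequence for gene(s): ",
         paste(genes$gene_id[!nzchar(genes$protein_seq)], collapse = ", "),
         call. = FALSE)
  }
  invisible(genes)
}

#' Write a genome bundle to a directory
#'
#' Emits one `<genome_id>.faa` protein FASTA per genome, `genes.tsv` (the
#' canonical 5-column gene table) and `metadata.tsv`.  The output of
#' [read_genome_bundle()] on the written files reproduces the input
#' field-for-field.
#'
#' @param genes gene tibble as returned by [read_genome_bundle()] or
#'   [simulate_genomes()].
#' @param meta metadata tibble (`genome_id`, `phenotype`, `ecology`).
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the paths written (named list).
#' @export
write_genome_bundle <- function(genes, meta, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir, call. = FALSE)
  }
  genes <- dplyr::arrange(genes, .data$genome_id, .data$scaffold_id,
                          .data$order_index)
  fasta_paths <- character()
  for (g in unique(genes$genome_id)) {
    sub <- genes[genes$genome_id == g, ]
    p <- file.path(out_dir, paste0(g, ".faa"))
    aa <- Biostrings::AAStringSet(sub$protein_seq)
    names(aa) <- sub$gene_id
    Biostrings::writeXStringSet(aa, p, width = 70L)
    fasta_paths <- c(fasta_paths, p)
  }
  tab_path <- file.path(out_dir, "genes.tsv")
  readr::write_tsv(
    dplyr::select(genes, "genome_id", "scaffold_id", "order_index",
                  "gene_id", "function_label"),
    tab_path
  )
  meta_path <- file.path(out_dir, "metadata.tsv")
  meta_out <- meta
  meta_out$ecology <- vapply(meta$ecology, paste, "", collapse = ",")
  readr::write_tsv(meta_out, meta_path)
  invisible(list(fasta = fasta_paths, gene_table = tab_path,
                 metadata = meta_path))
}

#' Read / write Newick trees with integer support labels
#'
#' Thin wrappers around ape's Newick parser that (a) check parenthesis
#' balance up front and report the offending position, and (b) preserve the
#' distinction between "no support recorded" (no internal node labels) and
#' a support of zero.
#'
#' @param path file path.
#' @return `read_newick()`: an `ape::phylo`; internal-node support values,
#'   when present, live in `node.label` (character, `""` for unlabelled
#'   nodes) and can be extracted with [tree_supports()].
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- cumsum(ifelse(strsplit(txt, "")[[1]] == "(", 1L,
                         ifelse(strsplit(txt, "")[[1]] == ")", -1L, 0L)))
  if (any(depth < 0L)) {
    stop("unbalanced ')' at character ", which(depth < 0L)[1L],
         " of Newick input", call. = FALSE)
  }
  if (depth[length(depth)] != 0L) {
    stop("unbalanced '(' in Newick input (", depth[length(depth)],
         " unclosed at end)", call. = FALSE)
  }
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("failed to parse Newick in ", path, call. = FALSE)
  tr
}

#' @rdname read_newick
#' @param tree an `ape::phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Extract integer supports from a tree's internal-node labels
#'
#' @param tree an `ape::phylo`.
#' @return Numeric vector of length `tree$Nnode` (NA where no support was
#'   recorded), or `NULL` if the tree carries no node labels at all.
#' @export
tree_supports <- function(tree) {
  if (is.null(tree$node.label)) return(NULL)
  suppressWarnings(as.numeric(tree$node.label))
}
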