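#' Pipeline parameter registry
#'
#' Collects every tunable threshold of the discovery / HGT pipeline in one
#' validated list.  The defaults are the operating point of the published
#' protocol the package implements: BLAST-style e-value cutoffs for homolog
#' retrieval (`1e-4`) and synteny screening (`1e-5`), minimum amino-acid
#' similarity for cluster detection (0.45) and synteny (0.40), the
#' six-intervening-gene co-localization rule, a ten-gene boundary-refinement
#' window, Markov-clustering inflation 2.0, 100 bootstrap replicates with a
#' 70 percent support threshold, a 250-leaf cap when reducing large gene
#' trees, a two-node separation rule for the transfer prefilter,
#' duplication/transfer/loss costs of 1.5/3.0/1.0, a 1.0 edge-weight collapse
#' threshold for reconciliation input trees, the 95th loading percentile and
#' niche cutoffs dung 3 / wood 4 / ectomycorrhizal 2 for genome-content
#' analysis, alpha 0.05, and a four-genome cap on candidate groups.
#'
#' @param ... name-value pairs overriding any default, e.g.
#'   `ch_params(max_intervening = 3)`.  Unknown names are an error; non-default
#'   values are reported via a message so that deviations from the standard
#'   protocol are visible in logs.
#'
#' @return A named list with class `"ch_params"`.
#' @examples
#' p <- ch_params()
#' p$max_intervening
#' @export
ch_params <- function(...) {
  defaults <- list(
    evalue_homology      = 1e-4,
    evalue_screen        = 1e-5,
    min_sim_cluster      = 0.45,
    min_sim_synteny      = 0.40,
    max_intervening      = 6L,
    boundary_window      = 10L,
    mcl_inflation        = 2.0,
    n_bootstraps         = 100L,
    support_threshold    = 70L,
    max_clade_leaves     = 250L,
    min_separating_nodes = 2L,
    dup_cost             = 1.5,
    transfer_cost        = 3.0,
    loss_cost            = 1.0,
    edge_weight_threshold = 1.0,
    loading_percentile   = 95,
    niche_cutoffs        = c(dung = 3L, wood = 4L, ecm = 2L),
    alpha                = 0.05,
    candidate_max_genomes = 4L,
    gap_open             = 11,
    gap_extend           = 1,
    ka_lambda            = 0.267,
    ka_k                 = 0.041,
    kmer_size            = 4L,
    kmer_min_shared      = 2L
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(defaults))
    if (length(bad) || is.null(names(over)) || any(names(over) == "")) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    defaults[names(over)] <- over
    message("ch_params: non-default values for ",
            paste(names(over), collapse = ", "))
  }
  p <- defaults
  scalars <- c("evalue_homology", "evalue_screen", "min_sim_cluster",
               "min_sim_synteny", "mcl_inflation", "dup_cost", "transfer_cost",
               "loss_cost", "alpha")
  for (nm in scalars) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0) {
      stop("parameter '", nm, "' must be a single nonnegative number",
           call. = FALSE)
    }
  }
  for (nm in c("max_intervening", "boundary_window", "n_bootstraps",
               "support_threshold", "max_clade_leaves", "min_separating_nodes",
               "candidate_max_genomes")) {
    p[[nm]] <- as.integer(p[[nm]])
    if (is.na(p[[nm]]) || p[[nm]] < 0L) {
      stop("parameter '", nm, "' must be a nonnegative integer", call. = FALSE)
    }
  }
  if (p$loading_percentile <= 0 || p$loading_percentile >= 100) {
    stop("loading_percentile must lie in (0, 100)", call. = FALSE)
  }
  stopifnot(all(p$niche_cutoffs > 0))
  structure(p, class = "ch_params")
}

#' @export
print.ch_params <- function(x, ...) {
  cat("<ch_params> pipeline parameters\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm,
                paste(format(val, digits = 6), collapse = " ")))
  }
  invisible(x)
}

# Coerce NULL to default parameters; validate class otherwise.
as_ch_params <- function(params) {
  if (is.null(params)) return(ch_params())
  if (!inherits(params, "ch_params")) {
    stop("`params` must be built with ch_params()", call. = FALSE)
  }
  params
}
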