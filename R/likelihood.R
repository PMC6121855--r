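# Site log-likelihoods under the fixed WAG model (Felsenstein pruning) and
# the RELL resampling test for comparing two candidate topologies.

#' Per-site log-likelihoods of an alignment on a tree
#'
#' Felsenstein's pruning algorithm under the scaled WAG model with its
#' stationary frequencies (no rate heterogeneity).  Gap characters are
#' treated as missing data.  Likelihoods are rescaled per node to stay in
#' range, so arbitrarily small site probabilities are handled.  For a
#' reversible model the result is independent of root placement.
#'
#' @param tree `ape::phylo` with branch lengths; every leaf needs a sequence.
#' @param aln named character vector of equal-length sequences covering the
#'   tree's leaves.
#' @return Numeric vector of per-site log-likelihoods (all finite, <= 0).
#' @export
site_loglik <- function(tree, aln) {
  missing <- setdiff(tree$tip.label, names(aln))
  if (length(missing)) {
    stop("leaf without sequence: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- aln_matrix(aln[tree$tip.label])
  nsites <- ncol(m)
  ntip <- length(tree$tip.label)
  model <- wag_model()
  # leaf conditional likelihoods: indicator vectors (ones for gaps/missing)
  code <- match(m, AA_ALPHABET)          # ntip x nsites, NA for gaps
  dim(code) <- dim(m)
  n_nodes <- ntip + tree$Nnode
  L <- vector("list", n_nodes)
  logscale <- rep(0, nsites)
  for (i in seq_len(ntip)) {
    li <- matrix(0, 20L, nsites)
    known <- !is.na(code[i, ])
    li[cbind(code[i, known], which(known))] <- 1
    li[, !known] <- 1
    L[[i]] <- li
  }
  # postorder: children before parents
  po <- stats::reorder(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    child <- po$edge[k, 2L]
    par <- po$edge[k, 1L]
    P <- aa_transition_matrix(po$edge.length[k])
    contrib <- P %*% L[[child]]
    L[[par]] <- if (is.null(L[[par]])) contrib else L[[par]] * contrib
    # rescale columns drifting toward underflow
    mx <- apply(L[[par]], 2L, max)
    scale_cols <- mx < 1e-6 & mx > 0
    if (any(scale_cols)) {
      L[[par]][, scale_cols] <- sweep(L[[par]][, scale_cols, drop = FALSE],
                                      2L, mx[scale_cols], "/")
      logscale[scale_cols] <- logscale[scale_cols] + log(mx[scale_cols])
    }
  }
  root <- ntip + 1L
  site_lik <- colSums(model$pi * L[[root]])
  log(site_lik) + logscale
}

#' RELL test of a constrained versus an optimal topology
#'
#' Compares the total log-likelihood of the optimal tree and a constrained
#' alternative by resampling estimated per-site log-likelihoods (RELL): site
#' indices are drawn with replacement `n_resamples` times and the one-sided
#' p-value is the fraction of resamples in which the constrained total is at
#' least as good as the optimal one.  The constraint is rejected when
#' `p < alpha`.
#'
#' @param aln named character vector of aligned sequences.
#' @param tree_optimal,tree_constrained trees on the same leaf set, with
#'   branch lengths.
#' @param n_resamples bootstrap resamples (values below 100 trigger a
#'   warning — the p-value granularity becomes too coarse).
#' @param seed integer seed.
#' @param alpha rejection level (protocol default 0.05).
#' @return List: `p_value`, `delta_ll` (constrained minus optimal total
#'   log-likelihood), `reject` (logical).
#' @export
rell_test <- function(aln, tree_optimal, tree_constrained,
                      n_resamples = 1000L, seed = 1L, alpha = 0.05) {
  if (!setequal(tree_optimal$tip.label, tree_constrained$tip.label)) {
    stop("the two trees must share one leaf set", call. = FALSE)
  }
  if (n_resamples < 100L) {
    warning("fewer than 100 RELL resamples: p-value resolution is coarse",
            call. = FALSE)
  }
  ll_opt <- site_loglik(tree_optimal, aln)
  ll_con <- site_loglik(tree_constrained, aln)
  diff_ll <- ll_con - ll_opt
  delta <- sum(diff_ll)
  nsites <- length(diff_ll)
  set.seed(seed)
  counts <- stats::rmultinom(n_resamples, nsites, rep(1 / nsites, nsites))
  resampled <- as.numeric(crossprod(counts, diff_ll))
  p <- mean(resampled >= 0)
  list(p_value = p, delta_ll = delta, reject = p < alpha)
}
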