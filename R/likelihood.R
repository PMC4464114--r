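# Per-leaf conditional likelihood matrices (20 x n_sites); any character
# outside the 20 standard residues (gap, ambiguity, U/O) is missing data,
# i.e. partial likelihood 1 over all states.
.leaf_partials <- function(aln, labels) {
  ns <- ncol(aln)
  lapply(labels, function(lb) {
    idx <- match(aln[lb, ], .aa_order)
    M <- matrix(1, 20, ns)
    kn <- !is.na(idx)
    M[, kn] <- 0
    M[cbind(idx[kn], which(kn))] <- 1
    M
  })
}

#' Per-site log-likelihoods by Felsenstein pruning
#'
#' Computes the log-likelihood of every alignment column on a tree with
#' branch lengths under a reversible amino-acid model with optional discrete
#' gamma rates and invariant sites. Gaps and ambiguity codes are missing
#' data. With `p_inv > 0`, gamma category rates are divided by
#' `1 - p_inv` so the mean rate stays 1, and the invariant class contributes
#' the stationary probability of the site's shared state. The total
#' log-likelihood (`sum` of the vector) is invariant under re-rooting.
#'
#' @param alignment An [as_alignment()] matrix.
#' @param tree `ape::phylo` with branch lengths; rooted or unrooted.
#' @param model An [substitution_model()] object.
#' @return Numeric vector of per-site log-likelihoods (length = columns).
#' @export
site_log_likelihoods <- function(alignment, tree, model) {
  if (ncol(alignment) == 0L) stop("zero-length alignment")
  if (!setequal(rownames(alignment), tree$tip.label) ||
      length(tree$tip.label) != nrow(alignment)) {
    stop("alignment ids and tree leaves do not match")
  }
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  ns <- ncol(alignment)
  leafL <- .leaf_partials(alignment, tree$tip.label)
  p_inv <- model$p_inv
  rates <- model$rates / (1 - p_inv)
  lik <- numeric(ns)
  root <- tree$edge[nrow(tree$edge), 1]
  for (r in rates) {
    part <- vector("list", nnode)
    part[seq_len(ntip)] <- leafL
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      P <- .pmat(model, tree$edge.length[e] * r)
      contrib <- P %*% part[[ch]]
      part[[p]] <- if (is.null(part[[p]])) contrib else part[[p]] * contrib
    }
    lik <- lik + colSums(part[[root]] * model$freq) / length(rates)
  }
  if (p_inv > 0) {
    # invariant class: product of leaf partials is nonzero only for states
    # compatible with every (non-missing) observation in the column
    prod_leaf <- Reduce(`*`, leafL)
    lik <- (1 - p_inv) * lik + p_inv * colSums(prod_leaf * model$freq)
  }
  log(lik)
}

#' Total log-likelihood of an alignment on a tree
#'
#' @inheritParams site_log_likelihoods
#' @return Numeric scalar, `sum(site_log_likelihoods(...))`.
#' @export
tree_log_likelihood <- function(alignment, tree, model) {
  sum(site_log_likelihoods(alignment, tree, model))
}

#' Maximum-likelihood branch lengths for a fixed topology
#'
#' Optimizes branch lengths (only) for the given topology under the model,
#' leaving the shape parameter and invariant proportion fixed (or estimating
#' the shape when `model$alpha` is `NULL` and `estimate_alpha = TRUE`).
#' Optimization is delegated to the likelihood machinery of
#' \pkg{phangorn}; branch lengths are bounded below by `1e-8` and iterated
#' to a log-likelihood convergence tolerance of `1e-6`.
#'
#' @inheritParams site_log_likelihoods
#' @param estimate_alpha Estimate the gamma shape on this topology when the
#'   model does not fix one.
#' @param control List with elements `epsilon` and `maxit` overriding the
#'   convergence tolerance and iteration cap.
#' @return List with elements `tree` (branch lengths optimized), `logL`,
#'   and `alpha` (the shape actually used).
#' @export
optimize_branch_lengths <- function(alignment, tree, model,
                                    estimate_alpha = FALSE,
                                    control = list()) {
  eps <- control$epsilon %||% 1e-6
  maxit <- control$maxit %||% 10L
  if (length(tree$tip.label) == 2L) {
    # a two-taxon tree has a single free parameter: the path length
    obj <- function(t) {
      tr <- tree
      tr$edge.length <- rep(t / nrow(tree$edge), nrow(tree$edge))
      tree_log_likelihood(alignment, tr, model)
    }
    opt <- optimize(obj, c(1e-8, 10), maximum = TRUE, tol = 1e-8)
    tr <- tree
    tr$edge.length <- rep(opt$maximum / nrow(tree$edge), nrow(tree$edge))
    return(list(tree = tr, logL = opt$objective, alpha = model$alpha))
  }
  pd <- control$phydat %||% .aln_phydat(alignment)
  tree <- ape::unroot(tree)
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  }
  tree$edge.length[tree$edge.length < 1e-8] <- 1e-8
  opt_g <- is.null(model$alpha) && estimate_alpha
  fit <- phangorn::pml(tree, pd, model = "JTT",
                       bf = if (model$frequencies == "empirical")
                         model$freq else NULL,
                       k = if (opt_g) 4L else model$k,
                       shape = if (opt_g) 1 else (model$alpha %||% 1),
                       inv = model$p_inv)
  fit <- phangorn::optim.pml(
    fit, optEdge = TRUE, optGamma = opt_g,
    control = phangorn::pml.control(trace = 0, epsilon = eps, maxit = maxit))
  tr <- fit$tree
  tr$edge.length[tr$edge.length < 1e-8] <- 1e-8
  list(tree = tr, logL = fit$logLik, alpha = fit$shape)
}

# Brute-force likelihood by exhaustive enumeration over internal-node
# states; used only as an independent oracle on tiny trees in the test
# suite, exported so the acceptance machinery can call it.

#' Per-site log-likelihood by exhaustive state enumeration
#'
#' Sums the joint probability over every assignment of states to internal
#' nodes; feasible only for very small trees. Serves as an independent check
#' of the pruning implementation.
#'
#' @inheritParams site_log_likelihoods
#' @return Numeric vector of per-site log-likelihoods.
#' @export
site_log_likelihoods_bruteforce <- function(alignment, tree, model) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  internal <- (ntip + 1):nnode
  root <- tree$edge[nrow(tree$edge), 1]
  ns <- ncol(alignment)
  rates <- model$rates / (1 - model$p_inv)
  leaf_idx <- lapply(tree$tip.label,
                     function(lb) match(alignment[lb, ], .aa_order))
  grid <- as.matrix(expand.grid(rep(list(1:20), length(internal))))
  lik <- matrix(0, nrow(grid), ns)
  total <- numeric(ns)
  for (r in rates) {
    P <- lapply(seq_len(nrow(tree$edge)),
                function(e) .pmat(model, tree$edge.length[e] * r))
    lik[] <- model$freq[grid[, match(root, internal)]]
    for (e in seq_len(nrow(tree$edge))) {
      pa <- grid[, match(tree$edge[e, 1], internal)]
      chn <- tree$edge[e, 2]
      if (chn <= ntip) {
        obs <- leaf_idx[[chn]]
        pr <- matrix(1, nrow(grid), ns)
        kn <- which(!is.na(obs))
        for (s in kn) pr[, s] <- P[[e]][cbind(pa, obs[s])]
        lik <- lik * pr
      } else {
        ch <- grid[, match(chn, internal)]
        lik <- lik * P[[e]][cbind(pa, ch)]
      }
    }
    total <- total + colSums(lik) / length(rates)
  }
  if (model$p_inv > 0) {
    cst <- vapply(seq_len(ns), function(s) {
      obs <- vapply(leaf_idx, `[`, 0L, s)
      obs <- obs[!is.na(obs)]
      if (length(obs) == 0L) 1 else if (length(unique(obs)) == 1L)
        model$freq[obs[1]] else 0
    }, 0)
    total <- (1 - model$p_inv) * total + model$p_inv * cst
  }
  log(total)
}
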