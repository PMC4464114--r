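#' Species assignment for gene-tree leaves
#'
#' @param labels Leaf labels.
#' @param groups Character vector (same length) over
#'   `"cyclostome"`, `"gnathostome"`, `"outgroup"`.
#' @return Named character vector (label -> group).
#' @export
species_assignment <- function(labels, groups) {
  groups <- match.arg(groups, c("cyclostome", "gnathostome", "outgroup"),
                      several.ok = TRUE)
  stopifnot(length(labels) == length(groups))
  if (!"outgroup" %in% groups) stop("at least one outgroup label is required")
  setNames(groups, labels)
}

#' Root a gene-tree topology on its outgroup
#'
#' Places the root on the edge separating all outgroup leaves from the rest,
#' when that bipartition exists in the unrooted topology, and returns the
#' rooted ingroup tree (outgroup leaves removed). When the outgroup is not
#' separable (nested inside the ingroup) the tree is non-rootable in this
#' mode and `NULL` is returned.
#'
#' @param tree `ape::phylo`, rooted or unrooted.
#' @param assignment Named group vector from [species_assignment()] covering
#'   every leaf.
#' @return Rooted ingroup `phylo`, or `NULL` if non-rootable.
#' @export
root_on_outgroup <- function(tree, assignment) {
  out_tips <- names(assignment)[assignment == "outgroup"]
  out_tips <- intersect(tree$tip.label, out_tips)
  if (length(out_tips) == 0L) stop("no outgroup leaf present in tree")
  utree <- ape::unroot(tree)
  rooted <- tryCatch(
    ape::root(utree, outgroup = out_tips, resolve.root = TRUE),
    error = function(e) NULL)
  if (is.null(rooted)) return(NULL)
  # verify the outgroup really forms one side of the root
  root_node <- length(rooted$tip.label) + 1L
  kids <- rooted$edge[rooted$edge[, 1] == root_node, 2]
  sides <- lapply(kids, function(k) {
    if (k <= length(rooted$tip.label)) rooted$tip.label[k]
    else ape::extract.clade(rooted, k)$tip.label
  })
  out_side <- vapply(sides, function(s) all(s %in% out_tips), TRUE)
  if (!any(vapply(sides, function(s) setequal(s, out_tips), TRUE))) {
    return(NULL)
  }
  in_side <- kids[!out_side]
  if (length(in_side) != 1L) return(NULL)
  if (in_side <= length(rooted$tip.label)) {
    stop("ingroup must contain at least 2 leaves")
  }
  ape::extract.clade(rooted, in_side)
}

# Group bitmask below each node: 1 = cyclostome, 2 = gnathostome,
# 4 = outgroup; LCA species-tree mapping is the union of the children's.
.node_masks <- function(tree, assignment) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  mask <- integer(max(tree$edge))
  mask[seq_len(ntip)] <-
    c(cyclostome = 1L, gnathostome = 2L,
      outgroup = 4L)[assignment[tree$tip.label]]
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    mask[p] <- bitwOr(mask[p], mask[ch])
  }
  list(tree = tree, mask = mask, ntip = ntip)
}

#' Count gene duplications by LCA reconciliation
#'
#' Maps every internal node of a rooted binary ingroup gene tree onto the
#' species tree `(outgroup, (cyclostome, gnathostome))` by the
#' last-common-ancestor rule; a node is a duplication when it maps to the
#' same species-tree node as at least one of its children. Duplications are
#' timed by the species-tree node they map to: the
#' cyclostome-gnathostome ancestor (`n_bef`), the gnathostome lineage
#' (`n_aft`), or the cyclostome lineage (`n_cyc`). In this outgroup-rooted
#' mode `n_unk` is 0.
#'
#' @param tree Rooted binary ingroup `phylo` (no outgroup leaves).
#' @param assignment Named group vector covering every leaf.
#' @return Named numeric vector `c(n_bef, n_aft, n_cyc, n_unk)`.
#' @export
reconcile_count <- function(tree, assignment) {
  if (!ape::is.binary.phylo(tree)) stop("gene tree must be binary")
  nm <- .node_masks(tree, assignment)
  if (any(bitwAnd(nm$mask[seq_len(nm$ntip)], 4L) > 0)) {
    stop("outgroup leaves must be removed before reconciliation")
  }
  counts <- c(n_bef = 0, n_aft = 0, n_cyc = 0, n_unk = 0)
  internal <- unique(nm$tree$edge[, 1])
  for (v in internal) {
    kids <- nm$tree$edge[nm$tree$edge[, 1] == v, 2]
    if (any(nm$mask[kids] == nm$mask[v])) {
      cls <- c(`1` = "n_cyc", `2` = "n_aft", `3` = "n_bef")[
        as.character(nm$mask[v])]
      counts[cls] <- counts[cls] + 1
    }
  }
  counts
}

# Reconciliation of a full rooted gene tree that may retain outgroup leaves
# (species tree (outgroup,(C,G))); duplications mapping to the overall root
# are timing-unknown.
.reconcile_full <- function(tree, assignment) {
  nm <- .node_masks(tree, assignment)
  counts <- c(n_bef = 0, n_aft = 0, n_cyc = 0, n_unk = 0)
  internal <- unique(nm$tree$edge[, 1])
  for (v in internal) {
    kids <- nm$tree$edge[nm$tree$edge[, 1] == v, 2]
    if (any(nm$mask[kids] == nm$mask[v])) {
      cls <- switch(as.character(nm$mask[v]),
                    "1" = "n_cyc", "2" = "n_aft", "3" = "n_bef", "n_unk")
      counts[cls] <- counts[cls] + 1
    }
  }
  counts
}

#' Per-topology duplication counts for a set of unrooted topologies
#'
#' In `"outgroup"` mode every topology is rooted on the outgroup edge (the
#' outgroup is dropped and [reconcile_count()] applied), so every
#' duplication has a determinate timing and `n_unk = 0`; topologies whose
#' outgroup is not separable get `NA` counts. In `"agnostic"` mode every
#' branch rooting is considered: admissible rootings are those attaining the
#' minimum total duplication count, each timing class is credited its
#' minimum over admissible rootings, and the remainder — duplications whose
#' timing varies with the rooting — is reported as `n_unk`.
#'
#' @param topologies `multiPhylo` or list of `phylo` over one leaf set.
#' @param assignment Named group vector covering every leaf.
#' @param mode `"outgroup"` (default) or `"agnostic"`.
#' @return `data.frame` with one row per topology and columns `n_bef`,
#'   `n_aft`, `n_cyc`, `n_unk`.
#' @export
count_duplications <- function(topologies, assignment,
                               mode = c("outgroup", "agnostic")) {
  mode <- match.arg(mode)
  rows <- lapply(topologies, function(tr) {
    if (mode == "outgroup") {
      ing <- root_on_outgroup(tr, assignment)
      if (is.null(ing)) return(rep(NA_real_, 4))
      reconcile_count(ing, assignment)
    } else {
      .agnostic_counts(tr, assignment)
    }
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("n_bef", "n_aft", "n_cyc", "n_unk")
  out
}

.agnostic_counts <- function(tree, assignment) {
  utree <- ape::unroot(tree)
  per_root <- lapply(seq_len(nrow(utree$edge)), function(e) {
    rooted <- .root_on_edge(utree, e)
    .reconcile_full(rooted, assignment)
  })
  m <- do.call(rbind, per_root)
  tot <- rowSums(m)
  adm <- m[tot == min(tot), , drop = FALSE]
  stable <- apply(adm[, 1:3, drop = FALSE], 2, min)
  c(stable, n_unk = min(tot) - sum(stable))
}

.root_on_edge <- function(utree, e) {
  child <- utree$edge[e, 2]
  if (child <= length(utree$tip.label)) {
    ape::root(utree, outgroup = utree$tip.label[child],
              resolve.root = TRUE)
  } else {
    tips <- ape::extract.clade(utree, child)$tip.label
    tr <- tryCatch(ape::root(utree, outgroup = tips, resolve.root = TRUE),
                   error = function(err) NULL)
    if (is.null(tr)) ape::root(utree, outgroup = tips[1],
                               resolve.root = TRUE) else tr
  }
}

#' Bootstrap-weighted (probabilistic) duplication counts
#'
#' Weights each topology's integer duplication counts by its RELL bootstrap
#' probability and sums:
#' `N_x = sum_T BP(T) * n_x(T)` for `x` in before / after / cyclostome /
#' unknown. Topologies with undefined counts (non-rootable in outgroup
#' mode) contribute their BP to `n_unk`.
#'
#' @inheritParams count_duplications
#' @param bp Normalized bootstrap-probability vector matching `topologies`.
#' @return List with `per_topology` (integer counts `data.frame`) and
#'   `weighted` (named numeric vector `N_bef`, `N_aft`, `N_cyc`, `N_unk`).
#' @export
probabilistic_counts <- function(topologies, bp, assignment,
                                 mode = c("outgroup", "agnostic")) {
  if (abs(sum(bp) - 1) > 1e-6) stop("bp must be normalized")
  if (length(bp) != length(topologies)) stop("bp length mismatch")
  per <- count_duplications(topologies, assignment, mode)
  w <- c(N_bef = 0, N_aft = 0, N_cyc = 0, N_unk = 0)
  for (i in seq_along(bp)) {
    if (anyNA(per[i, ])) {
      w["N_unk"] <- w["N_unk"] + bp[i]
    } else {
      w <- w + bp[i] * as.numeric(per[i, ])
    }
  }
  list(per_topology = per, weighted = w)
}
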