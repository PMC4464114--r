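#' Enumerate all unrooted binary topologies over a set of OTUs
#'
#' Emits every distinct unrooted binary topology over the (collapsed) OTU
#' labels; the count is the double factorial (2n-5)!!. Constraint groups —
#' OTUs that stand for a fixed subtree of several sequences — are
#' re-expanded verbatim in the returned trees, so enumeration happens over
#' the collapsed label set while the output trees carry the full leaf set.
#'
#' @param otus Character vector of OTU labels (>= 3).
#' @param constraints Named list mapping an OTU label to the Newick string
#'   of its fixed internal subtree, e.g.
#'   `list(g1 = "(hs_Emx1,dr_Emx1)")`. Unlisted labels are single leaves.
#' @param force Allow more than 9 OTUs (combinatorial guard).
#' @return An `ape::multiPhylo` list of topologies (no branch lengths).
#' @export
enumerate_topologies <- function(otus, constraints = NULL, force = FALSE) {
  n <- length(otus)
  if (n < 3) stop("need at least 3 OTUs")
  if (n > 9 && !force) {
    stop("more than 9 OTUs gives ", .double_factorial(2 * n - 5),
         " topologies; use force = TRUE if you mean it")
  }
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = otus)
  if (!is.null(constraints)) {
    bad <- setdiff(names(constraints), otus)
    if (length(bad)) stop("constraint group(s) not among OTUs: ",
                          paste(bad, collapse = ", "))
    trees <- lapply(trees, function(tr) {
      nwk <- ape::write.tree(tr)
      for (lb in names(constraints)) {
        sub <- sub(";$", "", constraints[[lb]])
        nwk <- gsub(paste0("(?<=[(,])", lb, "(?=[,):])"), sub, nwk,
                    perl = TRUE)
      }
      ape::read.tree(text = nwk)
    })
    class(trees) <- "multiPhylo"
  }
  trees
}

.double_factorial <- function(k) prod(seq(k, 1, by = -2))

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration (via \pkg{ape}); the input must be a
#' symmetric non-negative matrix with zero diagonal.
#'
#' @param d Distance matrix (or `dist`).
#' @return Unrooted `ape::phylo` with branch lengths.
#' @export
nj_tree <- function(d) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(m < 0) || any(abs(diag(m)) > 1e-12)) {
    stop("distances must be non-negative with zero diagonal")
  }
  ape::nj(stats::as.dist(m))
}

#' Kimura-corrected protein distance between two aligned sequences
#'
#' The fraction of differing residues `p` over columns where both sequences
#' carry a standard residue, corrected as `-log(1 - p - p^2/5)`. Beyond the
#' domain of the correction (`p` close to 0.85) the distance is saturated
#' and `NA` is returned with a warning.
#'
#' @param seq1,seq2 Aligned sequence strings of equal length.
#' @return Numeric distance (>= 0) or `NA` on saturation.
#' @export
protein_distance <- function(seq1, seq2) {
  a <- strsplit(toupper(seq1), "")[[1]]
  b <- strsplit(toupper(seq2), "")[[1]]
  if (length(a) != length(b)) stop("sequences must have equal length")
  ok <- a %in% .aa_order & b %in% .aa_order
  if (!any(ok)) stop("no shared ungapped columns")
  p <- mean(a[ok] != b[ok])
  arg <- 1 - p - p^2 / 5
  if (arg <= 0) {
    warning("distance saturated (p = ", signif(p, 3), ")")
    return(NA_real_)
  }
  -log(arg)
}

#' Pairwise Kimura protein distance matrix for an alignment
#'
#' @param alignment An [as_alignment()] matrix.
#' @return Symmetric distance matrix with sequence ids as dimnames.
#' @export
protein_dist_matrix <- function(alignment) {
  s <- alignment_strings(alignment)
  n <- length(s)
  m <- matrix(0, n, n, dimnames = list(names(s), names(s)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- protein_distance(s[i], s[j])
    }
  }
  m
}

# Canonical keys for the non-trivial bipartitions (splits) of an unrooted
# tree: each internal edge is keyed by the sorted labels of the side not
# containing the alphabetically first label.
.split_keys <- function(tree) {
  tree <- ape::unroot(tree)
  labs <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    side <- sort(attr(parts, "labels")[p])
    if (length(side) <= 1L || length(side) >= length(labs) - 1L) next
    if (labs[1] %in% side) side <- sort(setdiff(labs, side))
    keys <- c(keys, paste(side, collapse = "|"))
  }
  unique(keys)
}

#' Does a tree contain a clade as an unrooted bipartition?
#'
#' @param tree `ape::phylo`.
#' @param clade Character vector of leaf labels, `2 <= |clade| < n - 1`.
#' @return Logical scalar.
#' @export
has_clade <- function(tree, clade) {
  labs <- sort(tree$tip.label)
  if (!all(clade %in% labs)) stop("clade contains unknown labels")
  if (length(clade) < 2 || length(clade) >= length(labs) - 1) {
    stop("clade size must be between 2 and n - 2")
  }
  side <- sort(unique(clade))
  if (labs[1] %in% side) side <- sort(setdiff(labs, side))
  paste(side, collapse = "|") %in% .split_keys(tree)
}

#' Nonparametric bootstrap support for the splits of a point-estimate tree
#'
#' Resamples alignment columns with replacement, re-infers a tree with
#' `method` on each replicate, and reports for every internal split of the
#' point-estimate tree the fraction of replicate trees containing it.
#'
#' @param alignment An [as_alignment()] matrix (>= 4 sequences).
#' @param method Function `alignment -> phylo`; default: neighbor joining
#'   on Kimura protein distances.
#' @param n_replicates Number of bootstrap replicates (default 100).
#' @param seed Integer seed (required, for reproducibility).
#' @return `data.frame` with columns `split` (label key) and `support`
#'   (percentage), plus attribute `tree` (the point estimate).
#' @export
bootstrap_support <- function(alignment, method = NULL,
                              n_replicates = 100, seed) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (missing(seed)) stop("a seed is required")
  if (nrow(alignment) < 4) stop("need at least 4 sequences")
  if (is.null(method)) {
    method <- function(a) nj_tree(protein_dist_matrix(a))
  }
  set.seed(seed)
  point <- method(alignment)
  keys <- .split_keys(point)
  hit <- setNames(numeric(length(keys)), keys)
  for (b in seq_len(n_replicates)) {
    idx <- sample.int(ncol(alignment), replace = TRUE)
    rep_aln <- as_alignment(unclass(alignment)[, idx, drop = FALSE])
    rk <- .split_keys(method(rep_aln))
    hit[keys %in% rk] <- hit[keys %in% rk] + 1
  }
  structure(data.frame(split = keys, support = 100 * hit / n_replicates,
                       row.names = NULL, stringsAsFactors = FALSE),
            tree = point)
}
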