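# Shared fixtures and independent oracles for the test suite.

aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_peptide <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(aa20, n, replace = TRUE), collapse = "")
}

peptide_table <- function(seqs, species = "sp") {
  data.frame(id = sprintf("p%03d", seq_along(seqs)), species = species,
             gene_id = NA_character_, sequence = seqs,
             stringsAsFactors = FALSE)
}

write_temp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}

random_aa_alignment <- function(ntaxa, nsites, seed) {
  set.seed(seed)
  m <- matrix(sample(aa20, ntaxa * nsites, replace = TRUE), ntaxa, nsites,
              dimnames = list(paste0("t", seq_len(ntaxa)), NULL))
  as_alignment(m)
}

# --- exact RELL oracle: full enumeration of multinomial site-weight
# vectors (feasible for a handful of sites) -------------------------------

compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1, 1))
  out <- NULL
  for (i in 0:n) {
    rest <- compositions(n - i, k - 1L)
    out <- rbind(out, cbind(i, rest))
  }
  unname(out)
}

exact_rell <- function(mat) {
  ns <- ncol(mat); k <- nrow(mat)
  W <- compositions(ns, ns)
  probs <- apply(W, 1, function(w) dmultinom(w, prob = rep(1 / ns, ns)))
  totals <- mat %*% t(W)                      # k x n_compositions
  obs <- rowSums(mat)
  best <- which.max(obs)
  delta <- obs[best] - obs
  bp <- numeric(k)
  kh <- numeric(k)
  shp <- numeric(k)
  cent <- totals - obs                        # exact centering: E[total] = obs
  mxc <- apply(cent, 2, max)
  for (j in seq_along(probs)) {
    mx <- max(totals[, j])
    tied <- which(totals[, j] >= mx - 1e-9)
    bp[tied] <- bp[tied] + probs[j] / length(tied)
  }
  for (i in seq_len(k)) {
    if (delta[i] <= 1e-12) { kh[i] <- 1; shp[i] <- 1; next }
    d_star <- totals[best, ] - totals[i, ]
    kh[i] <- sum(probs[d_star - delta[i] >= delta[i]])
    shp[i] <- sum(probs[mxc - cent[i, ] >= delta[i]])
  }
  list(bp = bp, kh = kh, sh = shp)
}

# --- brute-force minimum-duplication oracle ------------------------------
# Enumerates every valid map of internal gene-tree nodes onto the species
# tree (C, G, V = their ancestor) and minimizes the number of duplication
# nodes; a node is a speciation only when it maps to V and its children map
# into the two distinct descendant lineages.

min_dup_oracle <- function(tree, assignment) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  internal <- sort(unique(tree$edge[, 1]))
  leafmap <- c(cyclostome = 1L, gnathostome = 2L)[assignment[tree$tip.label]]
  kids <- lapply(internal, function(v) tree$edge[tree$edge[, 1] == v, 2])
  grid <- as.matrix(expand.grid(rep(list(c(1L, 2L, 3L)), length(internal))))
  getmap <- function(assign_row, node) {
    if (node <= ntip) leafmap[node] else assign_row[match(node, internal)]
  }
  below <- function(child, parent) {
    parent == 3L || child == parent
  }
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    f <- grid[r, ]
    ok <- TRUE; dups <- 0L
    for (vi in seq_along(internal)) {
      fv <- f[vi]
      ch <- vapply(kids[[vi]], function(x) getmap(f, x), 0L)
      if (!all(vapply(ch, below, TRUE, parent = fv))) { ok <- FALSE; break }
      spec <- fv == 3L && setequal(ch, c(1L, 2L))
      if (!spec) dups <- dups + 1L
    }
    if (ok && dups < best) best <- dups
  }
  best
}

# Six-OTU leaf set and species assignment used across reconciliation tests.
emx_assignment <- function() {
  species_assignment(
    c("g1", "g2", "g3", "cA", "cB", "out"),
    c("gnathostome", "gnathostome", "gnathostome",
      "cyclostome", "cyclostome", "outgroup"))
}
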