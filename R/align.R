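#' Excise HPAA tract spans from a sequence
#'
#' Removes the given (non-overlapping) spans right-to-left; residues outside
#' the spans are unchanged and keep their order, so
#' `nchar(out) == nchar(in) - sum(length)`.
#'
#' @param sequence Sequence string.
#' @param tracts `data.frame` with columns `start` (1-based) and `length`,
#'   e.g. from [find_hpaa_tracts()]. Empty input returns the sequence.
#' @return Modified sequence string.
#' @export
delete_hpaa <- function(sequence, tracts) {
  if (is.null(tracts) || nrow(tracts) == 0L) return(sequence)
  o <- order(tracts$start)
  st <- tracts$start[o]; en <- st + tracts$length[o] - 1L
  if (any(st < 1) || any(en > nchar(sequence))) {
    stop("tract span outside the sequence")
  }
  if (any(st[-1] <= en[-length(en)])) stop("overlapping tract spans")
  for (i in rev(seq_along(st))) {
    sequence <- paste0(substr(sequence, 1, st[i] - 1L),
                       substring(sequence, en[i] + 1L))
  }
  sequence
}

# 20 x ncol residue-frequency profile of an alignment block (gaps and
# non-standard characters carry no mass).
.profile <- function(m) {
  nr <- nrow(m)
  apply(m, 2, function(col) {
    tabulate(match(col, .aa_order), nbins = 20) / nr
  })
}

.blosum_block <- function() {
  .blosum62_ext()[.aa_order, .aa_order]
}

# shared 3-mer distance between two sequence strings
.kmer_dist <- function(a, b, k = 3) {
  ka <- unique(substring(a, 1:(max(nchar(a) - k + 1, 1)),
                         k:max(nchar(a), k)))
  kb <- unique(substring(b, 1:(max(nchar(b) - k + 1, 1)),
                         k:max(nchar(b), k)))
  1 - length(intersect(ka, kb)) / max(min(length(ka), length(kb)), 1)
}

# merge two aligned blocks (character matrices) by profile-profile
# Needleman-Wunsch with affine gaps
.merge_blocks <- function(A, B, gap_open, gap_ext) {
  pa <- .profile(A); pb <- .profile(B)
  S <- t(pa) %*% .blosum_block() %*% pb
  ops <- .profile_align_cpp(S, gap_open, gap_ext)
  la <- ncol(A); lb <- ncol(B)
  outA <- matrix("-", nrow(A), length(ops),
                 dimnames = list(rownames(A), NULL))
  outB <- matrix("-", nrow(B), length(ops),
                 dimnames = list(rownames(B), NULL))
  ia <- 0L; ib <- 0L
  for (k in seq_along(ops)) {
    if (ops[k] != 3L) { ia <- ia + 1L; outA[, k] <- A[, ia] }
    if (ops[k] != 2L) { ib <- ib + 1L; outB[, k] <- B[, ib] }
  }
  rbind(outA, outB)
}

.builtin_align <- function(seqs, gap_open = 10, gap_ext = 0.5) {
  n <- length(seqs)
  blocks <- lapply(seq_len(n), function(i) {
    matrix(strsplit(toupper(seqs[i]), "")[[1]], nrow = 1,
           dimnames = list(names(seqs)[i]))
  })
  if (n == 1L) return(as_alignment(blocks[[1]]))
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- .kmer_dist(seqs[i], seqs[j])
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  grp <- vector("list", n - 1)
  for (r in seq_len(n - 1)) {
    pick <- function(x) if (x < 0) blocks[[-x]] else grp[[x]]
    grp[[r]] <- .merge_blocks(pick(hc$merge[r, 1]), pick(hc$merge[r, 2]),
                              gap_open, gap_ext)
  }
  m <- grp[[n - 1]]
  as_alignment(m[names(seqs), , drop = FALSE])
}

.external_align <- function(seqs, aligner) {
  bin <- switch(aligner,
                mafft = Sys.which("mafft"),
                clustalw = {
                  w <- Sys.which(c("clustalw2", "clustalw"))
                  w[w != ""][1] %||% ""
                },
                tcoffee = Sys.which("t_coffee"))
  if (is.na(bin) || bin == "") {
    warning("aligner '", aligner,
            "' not found on PATH; falling back to the builtin aligner")
    return(.builtin_align(seqs))
  }
  inf <- tempfile(fileext = ".fa"); outf <- tempfile(fileext = ".fa")
  on.exit(unlink(c(inf, outf)), add = TRUE)
  write_fasta(seqs, inf)
  if (aligner == "mafft") {
    res <- system2(bin, c("--quiet", "--auto", inf), stdout = outf)
  } else if (aligner == "clustalw") {
    res <- system2(bin, c(paste0("-infile=", inf), "-output=fasta",
                          paste0("-outfile=", outf)), stdout = NULL)
  } else {
    res <- system2(bin, c(inf, "-output", "fasta_aln", "-outfile", outf,
                          "-quiet"), stdout = NULL)
  }
  if (!file.exists(outf) || file.size(outf) == 0) {
    stop("external aligner '", aligner, "' failed")
  }
  aln <- read_alignment(outf, "fasta")
  as_alignment(unclass(aln)[names(seqs), , drop = FALSE])
}

#' Multiple sequence alignment
#'
#' The builtin aligner is a self-contained progressive aligner: a guide tree
#' from shared-3-mer distances (average linkage) and profile-profile
#' Needleman-Wunsch merges under BLOSUM62 with affine gaps (open 10,
#' extend 0.5). `"mafft"`, `"clustalw"` and `"tcoffee"` shell out to the
#' corresponding external program at default settings, falling back to the
#' builtin aligner with a warning when the binary is absent. Every input
#' sequence is recoverable from its aligned row by removing gaps.
#'
#' @param seqs Named character vector of (unaligned) protein sequences.
#' @param aligner One of `"builtin"`, `"mafft"`, `"clustalw"`, `"tcoffee"`.
#' @return An [as_alignment()] matrix with rows in input order.
#' @export
align_sequences <- function(seqs,
                            aligner = c("builtin", "mafft", "clustalw",
                                        "tcoffee")) {
  aligner <- match.arg(aligner)
  if (length(seqs) < 2 && aligner != "builtin") {
    stop("need at least 2 sequences")
  }
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must carry unique names")
  }
  if (aligner == "builtin") .builtin_align(seqs)
  else .external_align(seqs, aligner)
}

#' Sum-of-pairs score of an alignment
#'
#' BLOSUM62 sum over all aligned residue pairs, with affine gap penalties
#' (open 10, extend 0.5) charged per pairwise gap run; columns where both
#' sequences are gapped are ignored for that pair. Used as the common
#' objective when comparing alternative alignments of the same sequences.
#'
#' @param aln An [as_alignment()] matrix.
#' @param gap_open,gap_ext Affine gap penalties.
#' @return Numeric scalar score.
#' @export
alignment_sp_score <- function(aln, gap_open = 10, gap_ext = 0.5) {
  B <- .blosum62_ext()
  n <- nrow(aln)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- aln[i, ]; b <- aln[j, ]
      both <- a != "-" | b != "-"
      a <- a[both]; b <- b[both]
      res <- a != "-" & b != "-"
      ok <- res & a %in% rownames(B) & b %in% rownames(B)
      total <- total + sum(B[cbind(a[ok], b[ok])])
      gp <- rle(!res)
      runs <- gp$lengths[gp$values]
      total <- total - sum(gap_open + (runs - 1) * gap_ext)
    }
  }
  total
}

#' Trim alignment columns (gap removal plus similarity threshold)
#'
#' First removes every column containing a gap; then, when `st > 0`,
#' removes columns whose similarity score — the mean pairwise residue
#' similarity under BLOSUM62 rescaled to `[0, 1]` — falls below `st`.
#' Raising `st` can only shrink the kept set. This column score mirrors the
#' semantics of similarity-threshold trimming (low-similarity columns drop
#' out as `st` rises) without reproducing any particular program's scale.
#'
#' @param aln An [as_alignment()] matrix.
#' @param st Similarity threshold (0 disables the similarity filter).
#' @return List with `alignment` (trimmed, or `NULL` when every column was
#'   removed) and `kept` (1-based indices of retained columns in the
#'   input).
#' @export
trim_columns <- function(aln, st = 0) {
  stopifnot(st >= 0)
  m <- unclass(aln)
  no_gap <- colSums(m == "-") == 0
  kept <- which(no_gap)
  if (st > 0 && length(kept)) {
    B <- .blosum_block()
    Bn <- (B - min(B)) / (max(B) - min(B))
    sim <- vapply(kept, function(j) {
      col <- m[, j]
      pr <- utils::combn(col, 2)
      ok <- pr[1, ] %in% .aa_order & pr[2, ] %in% .aa_order
      if (!any(ok)) return(0)
      mean(ifelse(ok, Bn[cbind(
        match(pr[1, ], .aa_order), match(pr[2, ], .aa_order))], 0))
    }, 0)
    kept <- kept[sim >= st]
  }
  if (length(kept) == 0L) {
    warning("all columns removed")
    return(list(alignment = NULL, kept = integer(0)))
  }
  list(alignment = as_alignment(m[, kept, drop = FALSE]), kept = kept)
}
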