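#' Synonymous substitution rate by the Nei-Gojobori (1986) method
#'
#' Counts synonymous sites and differences over a codon-aligned, gap-free,
#' in-frame pair of coding sequences, averaging differences equally over all
#' minimal mutational paths between differing codons (paths through stop
#' codons are excluded unless every path hits one), and applies the
#' Jukes-Cantor correction. Changes that create a stop codon count as
#' nonsynonymous. When the proportion of synonymous differences reaches 3/4
#' the correction is undefined and `Ks` is `NA` (saturated).
#'
#' @param cds1,cds2 Equal-length coding sequence strings over A/C/G/T, in
#'   frame 1, without gaps; length must be a multiple of 3 and the pair must
#'   not contain internal stop codons.
#' @return List of class `pairwise_ks` with `Ks`, `S` (synonymous sites),
#'   `Sd` (synonymous differences), `ps`, `saturated`, and `method`.
#' @export
ks_ng86 <- function(cds1, cds2) {
  c1 <- .codons(cds1); c2 <- .codons(cds2)
  if (length(c1) != length(c2)) stop("sequences must have equal length")
  code <- .gcode()
  if (any(code[c1] == "*") || any(code[c2] == "*")) {
    stop("internal stop codon in input")
  }
  S <- (sum(vapply(c1, .syn_sites, 0)) + sum(vapply(c2, .syn_sites, 0))) / 2
  diffs <- vapply(seq_along(c1), function(i) .path_counts(c1[i], c2[i]),
                  numeric(2))
  Sd <- sum(diffs[1, ]); Nd <- sum(diffs[2, ])
  ps <- if (S > 0) Sd / S else 0
  sat <- ps >= 3 / 4
  if (sat) warning("ps >= 3/4: Jukes-Cantor correction undefined (saturated)")
  structure(list(Ks = if (sat) NA_real_ else -3 / 4 * log(1 - 4 / 3 * ps),
                 S = S, Sd = Sd, N = 3 * length(c1) - S, Nd = Nd,
                 ps = ps, saturated = sat, method = "NG86"),
            class = "pairwise_ks")
}

#' @export
print.pairwise_ks <- function(x, ...) {
  cat(sprintf("NG86: S = %.2f, Sd = %.2f, ps = %.4f, Ks = %s\n",
              x$S, x$Sd, x$ps,
              if (x$saturated) "saturated" else sprintf("%.4f", x$Ks)))
  invisible(x)
}

.gcode <- function() {
  code <- Biostrings::GENETIC_CODE
  setNames(as.character(code), names(code))
}

.codons <- function(x) {
  x <- toupper(gsub("\\s", "", x))
  if (grepl("[^ACGTN]", x)) stop("coding sequence must be over A/C/G/T/N")
  n <- nchar(x)
  if (n %% 3 != 0) stop("length not divisible by 3")
  substring(x, seq(1, n, 3), seq(3, n, 3))
}

.nts <- c("A", "C", "G", "T")

# Number of synonymous sites in one codon: at each position the fraction of
# the three possible changes that preserve the amino acid (stop-creating
# changes count as nonsynonymous).
.syn_sites <- function(codon) {
  code <- .gcode()
  aa <- code[codon]
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(.nts, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (!is.na(code[mut]) && code[mut] != "*" && code[mut] == aa) {
        s <- s + 1 / 3
      }
    }
  }
  unname(s)
}

# (synonymous, nonsynonymous) differences between two codons, averaged over
# all minimal substitution paths; paths through stop codons are dropped
# unless every path is.
.path_counts <- function(ca, cb) {
  if (ca == cb) return(c(0, 0))
  code <- .gcode()
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  perms <- .permutations(pos)
  res <- matrix(NA_real_, nrow(perms), 2)
  through_stop <- logical(nrow(perms))
  for (k in seq_len(nrow(perms))) {
    cur <- ca; sd <- 0; nd <- 0
    for (p in perms[k, ]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (code[nxt] == "*") through_stop[k] <- TRUE
      if (code[nxt] == code[cur]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    res[k, ] <- c(sd, nd)
  }
  use <- if (all(through_stop)) rep(TRUE, nrow(perms)) else !through_stop
  colMeans(res[use, , drop = FALSE])
}

.permutations <- function(x) {
  if (length(x) == 1L) return(matrix(x, 1, 1))
  out <- NULL
  for (i in seq_along(x)) {
    rest <- .permutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}
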