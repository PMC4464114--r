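#' Build a protein alignment object
#'
#' Alignments are stored as character matrices (rows = sequences, columns =
#' aligned sites, entries = single uppercase residues or `-`), with unique
#' row names.
#'
#' @param x Named character vector of equal-length aligned strings, or a
#'   character matrix with row names.
#' @return A character matrix of class `aa_alignment`.
#' @export
as_alignment <- function(x) {
  if (is.matrix(x)) {
    m <- toupper(x)
  } else {
    if (is.null(names(x))) stop("sequences must be named")
    L <- unique(nchar(x))
    if (length(L) != 1L) stop("aligned sequences must have equal length")
    m <- matrix(toupper(unlist(strsplit(x, ""))), nrow = length(x),
                byrow = TRUE, dimnames = list(names(x), NULL))
  }
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    stop("alignment rows must carry unique names")
  }
  class(m) <- c("aa_alignment", class(m))
  m
}

#' Collapse an alignment back to strings
#'
#' @param aln An `aa_alignment`.
#' @return Named character vector of aligned strings.
#' @export
alignment_strings <- function(aln) {
  setNames(apply(unclass(aln), 1, paste, collapse = ""), rownames(aln))
}

#' Read a protein alignment
#'
#' @param path Input path.
#' @param format `"fasta"` or (relaxed sequential/interleaved) `"phylip"`.
#' @return An `aa_alignment`.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "fasta") {
    x <- read_fasta(path, alphabet = "protein")
    as_alignment(setNames(x$sequence, x$id))
  } else {
    pd <- phangorn::read.phyDat(path, format = "phylip", type = "AA")
    as_alignment(toupper(as.character(pd)))
  }
}

#' Write a protein alignment
#'
#' @param aln An `aa_alignment`.
#' @param path Output path.
#' @param format `"fasta"` or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  s <- alignment_strings(aln)
  if (format == "fasta") {
    write_fasta(s, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%d %d", length(s), nchar(s[1])), con)
    writeLines(sprintf("%-12s%s", names(s), s), con)
  }
  invisible(path)
}

# phangorn phyDat view of an alignment (gaps/ambiguities handled by phangorn).
.aln_phydat <- function(aln) {
  phangorn::phyDat(unclass(aln), type = "AA")
}
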