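#' Read sequences from a FASTA file
#'
#' Reads protein or nucleotide FASTA and returns a normalized sequence table.
#' Headers are truncated at the first whitespace token; sequences are
#' uppercased. For protein input a single trailing `*` (stop) is stripped
#' with a note, while records with an internal `*` are rejected with a
#' warning and the run continues.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param species Optional species tag stored with every record.
#' @return A `data.frame` with columns `id`, `species`, `gene_id`,
#'   `sequence`, one row per record, in file order.
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide"),
                       species = NA_character_) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file does not exist: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  keep <- rep(TRUE, length(seqs))
  if (alphabet == "protein") {
    trailing <- grepl("\\*$", seqs)
    if (any(trailing)) {
      seqs[trailing] <- sub("\\*$", "", seqs[trailing])
      message(sum(trailing), " record(s) had a trailing stop symbol stripped")
    }
    internal <- grepl("\\*", seqs)
    if (any(internal)) {
      warning("rejected ", sum(internal),
              " record(s) with internal stop symbol: ",
              paste(ids[internal], collapse = ", "))
      keep <- !internal
    }
  }
  if (any(nchar(seqs[keep]) == 0L)) {
    stop("empty sequence for id(s): ",
         paste(ids[keep][nchar(seqs[keep]) == 0L], collapse = ", "))
  }
  data.frame(id = ids[keep], species = species, gene_id = NA_character_,
             sequence = seqs[keep], stringsAsFactors = FALSE)
}

#' Write a sequence table to FASTA
#'
#' @param x A `data.frame` with columns `id` and `sequence`, or a named
#'   character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.data.frame(x)) x <- setNames(x$sequence, x$id)
  ss <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Select one representative peptide per gene
#'
#' Among alternative isoforms of a gene, keeps the single longest peptide;
#' equal lengths are broken by the lexicographically smaller id, so the
#' result is invariant to input order. Peptides absent from `gene_map` are
#' treated as their own gene.
#'
#' @param peptides Sequence table as returned by [read_fasta()].
#' @param gene_map Named character vector (`peptide id -> gene id`) or a
#'   `data.frame` with columns `peptide_id` and `gene_id`. `NULL` keeps all.
#' @return The filtered sequence table, one row per gene, ordered by gene id.
#' @export
select_representatives <- function(peptides, gene_map = NULL) {
  if (is.data.frame(gene_map)) {
    gene_map <- setNames(gene_map$gene_id, gene_map$peptide_id)
  }
  gid <- gene_map[peptides$id]
  gid[is.na(gid)] <- peptides$id[is.na(gid)]
  peptides$gene_id <- unname(gid)
  o <- order(peptides$gene_id, -nchar(peptides$sequence), peptides$id)
  out <- peptides[o, , drop = FALSE]
  out <- out[!duplicated(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Homology-filter settings
#'
#' Parameters for the cross-species reciprocal homolog filter. The builtin
#' backend scores peptide pairs by Smith-Waterman local alignment with
#' BLOSUM62 and affine gaps (open 11, extend 1) and converts the raw score
#' `S` to bits as `(lambda_ka * S - log(k_ka)) / log(2)` with gapped
#' Karlin-Altschul constants. The external backend shells out to `blastp`.
#'
#' @param min_bits Bit-score threshold a cross-species pair must reach
#'   (default 200).
#' @param backend `"builtin"` or `"external"`.
#' @param lambda_ka,k_ka Karlin-Altschul parameters for the bit conversion.
#' @return A list of class `homology_filter_settings`.
#' @export
homology_filter_settings <- function(min_bits = 200,
                                     backend = c("builtin", "external"),
                                     lambda_ka = 0.267, k_ka = 0.041) {
  stopifnot(min_bits > 0, lambda_ka > 0, k_ka > 0)
  structure(list(min_bits = min_bits, backend = match.arg(backend),
                 lambda_ka = lambda_ka, k_ka = k_ka),
            class = "homology_filter_settings")
}

# BLOSUM62 extended so that ambiguity letters (incl. U, O, J) score at the
# matrix minimum, i.e. mismatch-neutral.
.blosum62_ext <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b62 <- NULL
      utils::data("BLOSUM62", package = "Biostrings", envir = environment())
      m <- get("BLOSUM62", envir = environment())
      extra <- setdiff(c("U", "O", "J"), rownames(m))
      lo <- min(m)
      for (ch in extra) {
        m <- rbind(m, lo)
        m <- cbind(m, lo)
        rownames(m)[nrow(m)] <- ch
        colnames(m)[ncol(m)] <- ch
      }
      cache <<- m
    }
    cache
  }
})

#' Local-alignment bit score between two peptides
#'
#' Smith-Waterman score (BLOSUM62, gap open 11 / extend 1) converted to bits
#' via the Karlin-Altschul formula with the constants in `settings`.
#'
#' @param seq1,seq2 Peptide sequence strings.
#' @param settings A [homology_filter_settings()] object.
#' @return Bit score (numeric scalar).
#' @export
pairwise_bit_score <- function(seq1, seq2,
                               settings = homology_filter_settings()) {
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq1), Biostrings::AAString(seq2),
    type = "local", substitutionMatrix = .blosum62_ext(),
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
  (settings$lambda_ka * s - log(settings$k_ka)) / log(2)
}

.best_bits_vs_set <- function(seq, other, settings) {
  best <- -Inf
  for (s2 in other$sequence) {
    best <- max(best, pairwise_bit_score(seq, s2, settings))
    if (best >= settings$min_bits) break
  }
  best
}

.blastp_hits <- function(qry, sbj, settings) {
  if (Sys.which("blastp") == "") {
    stop("external backend requested but 'blastp' is not on the PATH; ",
         "re-run with backend = \"builtin\"")
  }
  qf <- tempfile(fileext = ".fa"); sf <- tempfile(fileext = ".fa")
  on.exit(unlink(c(qf, sf)), add = TRUE)
  write_fasta(qry, qf); write_fasta(sbj, sf)
  out <- system2("blastp",
                 c("-query", qf, "-subject", sf, "-seg", "yes",
                   "-soft_masking", "true",
                   "-outfmt", shQuote("6 qseqid sseqid bitscore")),
                 stdout = TRUE)
  if (length(out) == 0L) {
    return(data.frame(q = character(), s = character(), bits = numeric()))
  }
  parts <- do.call(rbind, strsplit(out, "\t"))
  data.frame(q = parts[, 1], s = parts[, 2],
             bits = as.numeric(parts[, 3]), stringsAsFactors = FALSE)
}

.hit_ids <- function(qry, sbj, settings) {
  # ids of qry with some hit >= min_bits against sbj (reciprocal by symmetry
  # of the builtin scorer; for blastp both directions are required)
  if (settings$backend == "builtin") {
    ok <- vapply(qry$sequence, function(s) {
      .best_bits_vs_set(s, sbj, settings) >= settings$min_bits
    }, TRUE)
    qry$id[ok]
  } else {
    fwd <- .blastp_hits(qry, sbj, settings)
    rev <- .blastp_hits(sbj, qry, settings)
    fwd <- fwd[fwd$bits >= settings$min_bits, ]
    rev <- rev[rev$bits >= settings$min_bits, ]
    pairs <- merge(fwd[c("q", "s")],
                   data.frame(q = rev$s, s = rev$q, stringsAsFactors = FALSE))
    unique(pairs$q)
  }
}

#' Cross-species reciprocal homolog filter
#'
#' Retains a peptide only if, for each of the two other species sets, some
#' cross-species pair involving it reaches `min_bits` bits in both search
#' directions. With the builtin (symmetric) scorer the two directions
#' coincide and are computed once. The result is invariant to the order of
#' the three sets.
#'
#' @param set_a,set_b,set_c Sequence tables from three distinct species.
#' @param settings A [homology_filter_settings()] object.
#' @return A list with filtered elements `a`, `b`, `c`.
#' @export
reciprocal_homolog_filter <- function(set_a, set_b, set_c,
                                      settings = homology_filter_settings()) {
  stopifnot(nrow(set_a) > 0, nrow(set_b) > 0, nrow(set_c) > 0)
  keep <- function(x, y, z) {
    intersect(.hit_ids(x, y, settings), .hit_ids(x, z, settings))
  }
  out <- list(a = set_a[set_a$id %in% keep(set_a, set_b, set_c), ],
              b = set_b[set_b$id %in% keep(set_b, set_a, set_c), ],
              c = set_c[set_c$id %in% keep(set_c, set_a, set_b), ])
  if (any(vapply(out, nrow, 0L) == 0L)) {
    warning("reciprocal homolog filter produced an empty set")
  }
  lapply(out, function(d) { rownames(d) <- NULL; d })
}
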