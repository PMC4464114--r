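#' Find homopolymeric amino-acid (HPAA) tracts in one sequence
#'
#' An HPAA tract is a maximal run of identical standard residues of length
#' at least `min_len`. Ambiguity characters (B, Z, X, J), the rare residues
#' U and O, gaps and any other non-standard symbol terminate runs and never
#' form tracts. A run of length 8 is reported as one tract of length 8,
#' never as overlapping shorter tracts. Coordinates are 1-based inclusive.
#'
#' @param sequence Uppercase protein sequence string.
#' @param min_len Minimum run length (default 6).
#' @return `data.frame` with columns `amino_acid`, `start`, `length`,
#'   ordered left to right. Empty for an empty sequence.
#' @export
find_hpaa_tracts <- function(sequence, min_len = 6) {
  stopifnot(min_len >= 2)
  empty <- data.frame(amino_acid = character(), start = integer(),
                      length = integer(), stringsAsFactors = FALSE)
  if (is.na(sequence) || nchar(sequence) == 0L) return(empty)
  ch <- strsplit(sequence, "")[[1]]
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_len & r$values %in% .aa_order
  if (!any(keep)) return(empty)
  data.frame(amino_acid = r$values[keep], start = starts[keep],
             length = r$lengths[keep], stringsAsFactors = FALSE)
}

#' Tabulate HPAA tracts over a peptide set
#'
#' @param peptides Sequence table (columns `id`, `sequence`).
#' @param min_len Minimum run length.
#' @return `data.frame` with columns `peptide_id`, `amino_acid`, `start`,
#'   `length`.
#' @export
hpaa_tract_table <- function(peptides, min_len = 6) {
  res <- lapply(seq_len(nrow(peptides)), function(i) {
    tr <- find_hpaa_tracts(peptides$sequence[i], min_len)
    if (nrow(tr) == 0L) return(NULL)
    cbind(peptide_id = peptides$id[i], tr, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    res <- data.frame(peptide_id = character(), amino_acid = character(),
                      start = integer(), length = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Frequency of tract-containing peptides per amino acid
#'
#' For each of the 20 amino acids, the fraction of peptides containing at
#' least one HPAA tract of that amino acid, plus an `any` row counting a
#' peptide once however many distinct tract types it carries.
#'
#' @inheritParams hpaa_tract_table
#' @return `data.frame` with columns `amino_acid` (20 letters plus
#'   `"any"`), `n_with_tract`, `n_total`, `frequency`.
#' @export
peptide_frequency_table <- function(peptides, min_len = 6) {
  if (nrow(peptides) == 0L) stop("empty peptide set")
  tr <- hpaa_tract_table(peptides, min_len)
  n <- nrow(peptides)
  per_aa <- vapply(.aa_order, function(a) {
    length(unique(tr$peptide_id[tr$amino_acid == a]))
  }, 0L)
  any_n <- length(unique(tr$peptide_id))
  data.frame(amino_acid = c(.aa_order, "any"),
             n_with_tract = c(per_aa, any_n),
             n_total = n,
             frequency = c(per_aa, any_n) / n,
             stringsAsFactors = FALSE)
}

#' Proportion of residues contained in HPAA tracts
#'
#' Residues inside tracts divided by all residues, overall and restricted to
#' each amino acid's tracts (all denominators are the total residue count).
#'
#' @inheritParams hpaa_tract_table
#' @return `data.frame` with columns `amino_acid` (20 letters plus
#'   `"total"`), `n_in_tracts`, `n_residues`, `proportion`.
#' @export
residue_proportion <- function(peptides, min_len = 6) {
  if (nrow(peptides) == 0L) stop("empty peptide set")
  tr <- hpaa_tract_table(peptides, min_len)
  total_res <- sum(nchar(peptides$sequence))
  per_aa <- vapply(.aa_order, function(a) {
    sum(tr$length[tr$amino_acid == a])
  }, 0L)
  data.frame(amino_acid = c(.aa_order, "total"),
             n_in_tracts = c(per_aa, sum(per_aa)),
             n_residues = total_res,
             proportion = c(per_aa, sum(per_aa)) / total_res,
             stringsAsFactors = FALSE)
}

#' Fraction of long tracts among detected tracts
#'
#' The number of tracts of length at least `long_cut` divided by the number
#' of tracts of length at least `min_len`, optionally restricted to one
#' amino acid. When no tract reaches `min_len` the fraction is undefined and
#' `NA` is returned with a warning (never 0).
#'
#' @inheritParams hpaa_tract_table
#' @param long_cut Long-tract length threshold (default 12).
#' @param amino_acid Optional single letter restricting the count.
#' @return Numeric scalar in `[0, 1]`, or `NA` if undefined.
#' @export
long_tract_fraction <- function(peptides, min_len = 6, long_cut = 12,
                                amino_acid = NULL) {
  tr <- hpaa_tract_table(peptides, min_len)
  if (!is.null(amino_acid)) tr <- tr[tr$amino_acid == amino_acid, ]
  if (nrow(tr) == 0L) {
    warning("no tract of length >= ", min_len, "; fraction undefined")
    return(NA_real_)
  }
  sum(tr$length >= long_cut) / nrow(tr)
}

#' Per-species HPAA summary
#'
#' Combines peptide frequencies, residue proportions and long-tract counts
#' into one per-amino-acid summary table for a species.
#'
#' @inheritParams hpaa_tract_table
#' @param species Species tag recorded in the output.
#' @param long_cut Long-tract threshold (default 12).
#' @return `data.frame`, one row per amino acid plus summary rows `any`
#'   (peptide counts) and `total` (residue counts).
#' @export
hpaa_summary <- function(peptides, species = peptides$species[1],
                         min_len = 6, long_cut = 12) {
  pf <- peptide_frequency_table(peptides, min_len)
  rp <- residue_proportion(peptides, min_len)
  tr <- hpaa_tract_table(peptides, min_len)
  n_ge_L <- vapply(.aa_order, function(a) sum(tr$amino_acid == a), 0L)
  n_ge_12 <- vapply(.aa_order, function(a) {
    sum(tr$amino_acid == a & tr$length >= long_cut)
  }, 0L)
  aa <- .aa_order
  data.frame(species = species, amino_acid = aa,
             n_peptides_with_tract = pf$n_with_tract[match(aa, pf$amino_acid)],
             n_peptides_total = pf$n_total[match(aa, pf$amino_acid)],
             peptide_frequency = pf$frequency[match(aa, pf$amino_acid)],
             n_residues_in_tracts = rp$n_in_tracts[match(aa, rp$amino_acid)],
             n_residues_total = rp$n_residues[match(aa, rp$amino_acid)],
             residue_proportion = rp$proportion[match(aa, rp$amino_acid)],
             n_tracts_ge_L = n_ge_L,
             n_tracts_ge_long = n_ge_12,
             long_tract_fraction = ifelse(n_ge_L > 0, n_ge_12 / n_ge_L, NA),
             stringsAsFactors = FALSE)
}

#' Two-sided test of equality of two proportions
#'
#' Pooled-variance normal-approximation z statistic without continuity
#' correction, with a two-tailed p-value. When both counts are zero (or both
#' equal their totals) the statistic is 0 and p = 1.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return List with elements `z` and `p`.
#' @export
two_proportion_test <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Chi-square test of homogeneity for a k x 2 count table
#'
#' Pearson chi-square without continuity correction, df = k - 1.
#'
#' @param counts Integer matrix with k rows (groups) and 2 columns.
#' @return List with elements `chi2`, `df`, `p`.
#' @export
chi_square_homogeneity <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 2, all(rowSums(counts) > 0))
  if (any(colSums(counts) == 0)) stop("zero column total")
  ct <- stats::chisq.test(counts, correct = FALSE)
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}
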