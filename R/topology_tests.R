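# Resampled total log-likelihoods: topologies x replicates matrix from
# multinomial site resampling (RELL -- no re-optimization).
.rell_totals <- function(mat, n_replicates, seed) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(seed)
  ns <- ncol(mat)
  W <- rmultinom(n_replicates, ns, rep(1 / ns, ns))
  mat %*% W
}

#' RELL bootstrap probabilities for a topology set
#'
#' Resamples alignment sites with replacement by drawing multinomial column
#' weights for the per-site log-likelihood matrix and records, for each
#' replicate, which topology attains the maximal resampled total
#' log-likelihood. Ties are split equally among the tied topologies. The
#' returned bootstrap probabilities (BP) sum to 1.
#'
#' @param mat Numeric matrix, topologies x sites, of per-site
#'   log-likelihoods.
#' @param n_replicates Number of RELL replicates (default 10000).
#' @param seed Integer seed (required).
#' @return Numeric vector of BPs, one per topology (row).
#' @export
rell_bootstrap <- function(mat, n_replicates = 10000, seed) {
  mat <- rbind(mat)
  if (nrow(mat) == 1L) return(1)
  tot <- .rell_totals(mat, n_replicates, seed)
  .argmax_shares(tot) / n_replicates
}

# Row-wise share of replicates in which each row is maximal, ties split.
.argmax_shares <- function(tot, tol = 1e-9) {
  mx <- apply(tot, 2, max)
  is_max <- sweep(tot, 2, mx, function(x, m) x >= m - tol)
  shares <- sweep(is_max, 2, colSums(is_max), "/")
  rowSums(shares)
}

#' One-sided Kishino-Hasegawa test (RELL-based)
#'
#' Tests a topology against the maximum-likelihood topology. The observed
#' statistic is the log-likelihood difference to the best topology; its null
#' distribution is the centered RELL-resampled difference. The best topology
#' reports p = 1 by construction. A normal-approximation variant
#' (`normal = TRUE`) uses the per-site difference variance instead of the
#' resampled distribution.
#'
#' @inheritParams rell_bootstrap
#' @param topology_index Row index of the topology under test.
#' @param normal Use the normal approximation instead of the RELL-centered
#'   distribution.
#' @return One-sided p-value.
#' @export
kh_test <- function(mat, topology_index, n_replicates = 10000, seed,
                    normal = FALSE) {
  mat <- rbind(mat)
  if (nrow(mat) < 2) stop("need at least 2 topologies")
  tot_obs <- rowSums(mat)
  best <- which.max(tot_obs)
  d_obs <- tot_obs[best] - tot_obs[topology_index]
  if (topology_index == best || d_obs <= 1e-12) return(1)
  if (normal) {
    dd <- mat[best, ] - mat[topology_index, ]
    se <- sd(dd) * sqrt(ncol(mat))
    if (se == 0) return(1)
    return(unname(pnorm(d_obs / se, lower.tail = FALSE)))
  }
  tot <- .rell_totals(mat[c(best, topology_index), , drop = FALSE],
                      n_replicates, seed)
  d_star <- tot[1, ] - tot[2, ]
  # center at the exact expectation of the resampled difference (the
  # observed difference), not at the empirical replicate mean
  mean(d_star - d_obs >= d_obs)
}

#' Shimodaira-Hasegawa test over a topology set
#'
#' Simultaneous test of every topology against the maximum-likelihood one,
#' with per-topology centering over a shared set of RELL resamples. For each
#' topology the p-value is the fraction of resamples in which the maximal
#' centered resampled total exceeds that topology's centered total by at
#' least the observed log-likelihood difference. The best topology reports
#' p = 1; SH p-values dominate the corresponding KH p-values.
#'
#' @inheritParams rell_bootstrap
#' @return Numeric vector of p-values, one per topology.
#' @export
sh_test <- function(mat, n_replicates = 10000, seed) {
  mat <- rbind(mat)
  if (nrow(mat) < 2) stop("need at least 2 topologies")
  tot_obs <- rowSums(mat)
  d_obs <- max(tot_obs) - tot_obs
  tot <- .rell_totals(mat, n_replicates, seed)
  cent <- tot - tot_obs   # exact expectation centering per topology
  mx <- apply(cent, 2, max)
  vapply(seq_len(nrow(mat)), function(i) {
    if (d_obs[i] <= 1e-12) 1 else mean(mx - cent[i, ] >= d_obs[i])
  }, 0)
}

#' Full topology-test table (Table-1 style)
#'
#' Ranks topologies by total log-likelihood and reports, for each, the
#' difference to the best topology with its standard error (from the
#' per-site difference variance), the one-sided KH p, the SH p, and the
#' RELL bootstrap probability — the standard summary of an exhaustive ML
#' analysis.
#'
#' @inheritParams rell_bootstrap
#' @param topology_ids Optional labels for the rows of `mat`.
#' @return `data.frame` sorted by rank with columns `rank`, `topology`,
#'   `logL`, `delta`, `se`, `kh_p`, `sh_p`, `bp`.
#' @export
topology_test_table <- function(mat, topology_ids = NULL,
                                n_replicates = 10000, seed) {
  mat <- rbind(mat)
  k <- nrow(mat)
  if (is.null(topology_ids)) topology_ids <- seq_len(k)
  tot <- rowSums(mat)
  best <- which.max(tot)
  delta <- tot[best] - tot
  se <- vapply(seq_len(k), function(i) {
    if (i == best) 0 else sd(mat[best, ] - mat[i, ]) * sqrt(ncol(mat))
  }, 0)
  # one shared set of RELL resamples serves BP, KH and SH
  rtot <- .rell_totals(mat, n_replicates, seed)
  bp <- .argmax_shares(rtot) / n_replicates
  kh <- vapply(seq_len(k), function(i) {
    if (delta[i] <= 1e-12) return(1)
    d_star <- rtot[best, ] - rtot[i, ]
    mean(d_star - delta[i] >= delta[i])
  }, 0)
  cent <- rtot - tot      # exact expectation centering per topology
  mx <- apply(cent, 2, max)
  sh <- vapply(seq_len(k), function(i) {
    if (delta[i] <= 1e-12) 1 else mean(mx - cent[i, ] >= delta[i])
  }, 0)
  out <- data.frame(topology = as.character(topology_ids), logL = tot,
                    delta = delta, se = se, kh_p = kh, sh_p = sh, bp = bp,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$logL), ]
  out <- cbind(rank = seq_len(k), out)
  rownames(out) <- NULL
  out
}

#' Summed bootstrap support for a clade over a topology set
#'
#' The sum of per-topology RELL bootstrap probabilities over topologies in
#' which the clade appears as a bipartition of the unrooted tree — the
#' statistic used to quantify support for a grouping across an exhaustive
#' topology scan.
#'
#' @param bp Numeric vector of bootstrap probabilities (normalized).
#' @param topologies `multiPhylo` (or list of `phylo`) matching `bp`.
#' @param clade Character vector of leaf labels.
#' @return Numeric scalar in `[0, 1]`.
#' @export
clade_support <- function(bp, topologies, clade) {
  if (length(bp) != length(topologies)) {
    stop("bp and topologies lengths differ")
  }
  if (abs(sum(bp) - 1) > 1e-6) stop("bp must be normalized")
  inx <- vapply(topologies, has_clade, TRUE, clade = clade)
  sum(bp[inx])
}
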