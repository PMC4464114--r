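#' Discretize a gamma rate distribution into equal-probability categories
#'
#' Each category is represented by its conditional mean (the mean of the
#' gamma(alpha, alpha) distribution over the category's quantile bin), and
#' the returned rates are rescaled to average exactly 1.
#'
#' @param alpha Gamma shape parameter (> 0).
#' @param ncat Number of categories (>= 1).
#' @return Numeric vector of `ncat` increasing rates with mean 1.
#' @export
discretize_gamma <- function(alpha, ncat = 4) {
  if (alpha <= 0) stop("alpha must be > 0")
  stopifnot(ncat >= 1)
  if (ncat == 1L) return(1)
  qb <- qgamma(seq(0, 1, length.out = ncat + 1), shape = alpha, rate = alpha)
  r <- diff(pgamma(qb, shape = alpha + 1, rate = alpha)) * ncat
  r / mean(r)
}

# Scaled instantaneous rate matrix from exchangeabilities and frequencies;
# mean substitution rate is 1 at stationarity.
.rate_matrix <- function(exch, freq) {
  S <- matrix(0, 20, 20, dimnames = list(.aa_order, .aa_order))
  S[lower.tri(S)] <- exch
  S <- S + t(S)
  Q <- S %*% diag(freq)
  diag(Q) <- -rowSums(Q)
  Q / -sum(freq * diag(Q))
}

# Eigen-decomposition of a reversible Q via similarity to a symmetric matrix.
.eigen_Q <- function(Q, freq) {
  sq <- sqrt(freq)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(values = e$values,
       V = diag(1 / sq) %*% e$vectors,
       Vi = t(e$vectors) %*% diag(sq))
}

#' Amino-acid substitution model
#'
#' A JTT-family model with optional discrete-gamma rate heterogeneity and a
#' proportion of invariant sites. Frequencies are either the model's own
#' (JTT) stationary frequencies or empirical frequencies from supplied
#' sequences (the "+F" variant, with a small pseudocount).
#'
#' @param name Exchangeability matrix; only `"JTT"` is embedded.
#' @param frequencies `"model"` or `"empirical"` (+F).
#' @param alpha Gamma shape parameter; `NULL` means no rate heterogeneity
#'   unless estimated downstream.
#' @param k Number of discrete gamma categories (default 4).
#' @param p_inv Proportion of invariant sites in `[0, 1)` (default 0).
#' @param sequences Character vector of sequences supplying empirical
#'   frequencies when `frequencies = "empirical"`.
#' @return Object of class `aa_model` with the scaled rate matrix, its
#'   eigen-decomposition, frequencies, category rates and weights.
#' @export
substitution_model <- function(name = "JTT",
                               frequencies = c("model", "empirical"),
                               alpha = NULL, k = 4, p_inv = 0,
                               sequences = NULL) {
  name <- match.arg(name)
  frequencies <- match.arg(frequencies)
  stopifnot(p_inv >= 0, p_inv < 1)
  freq <- .jtt_freq
  if (frequencies == "empirical") {
    if (is.null(sequences)) stop("empirical frequencies need sequences")
    ch <- unlist(strsplit(toupper(paste(sequences, collapse = "")), ""))
    cnt <- table(factor(ch, levels = .aa_order)) + 1e-6
    freq <- as.numeric(cnt / sum(cnt))
  }
  names(freq) <- .aa_order
  Q <- .rate_matrix(.jtt_exch, freq)
  rates <- if (is.null(alpha)) 1 else discretize_gamma(alpha, k)
  structure(list(name = name, frequencies = frequencies, freq = freq,
                 Q = Q, eig = .eigen_Q(Q, freq),
                 alpha = alpha, k = if (is.null(alpha)) 1L else k,
                 p_inv = p_inv, rates = rates),
            class = "aa_model")
}

#' @export
print.aa_model <- function(x, ...) {
  cat(x$name,
      if (!is.null(x$alpha)) sprintf("+G%d (alpha = %.4g)", x$k, x$alpha),
      if (x$p_inv > 0) sprintf("+I (p_inv = %.4g)", x$p_inv),
      if (x$frequencies == "empirical") "+F", "\n")
  invisible(x)
}

# Transition probability matrix P(t) for an aa_model.
.pmat <- function(model, t) {
  P <- model$eig$V %*% (exp(model$eig$values * t) * model$eig$Vi)
  P[P < 0] <- 0
  P
}
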