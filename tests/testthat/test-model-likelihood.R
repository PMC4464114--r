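test_that("discrete gamma categories mean to one and match quadrature", {
  expect_equal(discretize_gamma(0.7, 1), 1)
  for (alpha in c(0.2, 0.5, 1.17)) {
    r <- discretize_gamma(alpha, 4)
    expect_equal(mean(r), 1, tolerance = 1e-12)
    expect_true(all(diff(r) > 0))
  }
  # oracle: conditional means by adaptive quadrature over equal-probability
  # bins of the gamma(alpha, alpha) density
  alpha <- 0.5
  qb <- qgamma(seq(0, 1, by = 0.25), alpha, alpha)
  oracle <- vapply(1:4, function(i) {
    4 * integrate(function(x) x * dgamma(x, alpha, alpha),
                  qb[i], qb[i + 1], rel.tol = 1e-12)$value
  }, 0)
  expect_equal(discretize_gamma(alpha, 4), oracle / mean(oracle),
               tolerance = 1e-8)
  expect_error(discretize_gamma(0, 4), "alpha")
})

test_that("embedded JTT matrix is a valid scaled reversible rate matrix", {
  m <- substitution_model("JTT", alpha = NULL)
  expect_equal(rowSums(m$Q), rep(0, 20), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(-sum(m$freq * diag(m$Q)), 1, tolerance = 1e-12)
  # detailed balance
  db <- diag(m$freq) %*% m$Q
  expect_equal(db, t(db), tolerance = 1e-12)
  expect_equal(sum(m$freq), 1, tolerance = 1e-9)
})

test_that("identical sequences at zero branch lengths give log frequencies", {
  s <- random_peptide(30, 5)
  aln <- as_alignment(c(a = s, b = s))
  tree <- ape::read.tree(text = "(a:0,b:0);")
  m <- substitution_model("JTT")
  ll <- site_log_likelihoods(aln, tree, m)
  idx <- match(strsplit(s, "")[[1]], hpaaphylo:::.aa_order)
  expect_equal(ll, log(m$freq[idx]), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("pruning equals exhaustive state enumeration on small trees", {
  for (seed in 1:5) {
    aln <- random_aa_alignment(4, 8, seed)
    set.seed(seed + 100)
    tree <- ape::rtree(4, rooted = FALSE, tip.label = rownames(aln))
    tree$edge.length <- runif(nrow(tree$edge), 0.05, 0.6)
    m <- substitution_model("JTT", alpha = 0.5, k = 4)
    expect_equal(site_log_likelihoods(aln, tree, m),
                 site_log_likelihoods_bruteforce(aln, tree, m),
                 tolerance = 1e-10)
  }
  # +I mixture agrees too
  aln <- random_aa_alignment(4, 8, 11)
  set.seed(42)
  tree <- ape::rtree(4, rooted = FALSE, tip.label = rownames(aln))
  tree$edge.length <- runif(nrow(tree$edge), 0.05, 0.6)
  mi <- substitution_model("JTT", alpha = 0.8, k = 4, p_inv = 0.2)
  expect_equal(site_log_likelihoods(aln, tree, mi),
               site_log_likelihoods_bruteforce(aln, tree, mi),
               tolerance = 1e-10)
})

test_that("log-likelihood is invariant to re-rooting and leaf order", {
  aln <- random_aa_alignment(5, 20, 2)
  set.seed(2)
  tree <- ape::rtree(5, rooted = FALSE, tip.label = rownames(aln))
  tree$edge.length <- runif(nrow(tree$edge), 0.05, 0.5)
  m <- substitution_model("JTT", alpha = 0.37, k = 4)
  base <- tree_log_likelihood(aln, tree, m)
  for (tip in tree$tip.label[1:3]) {
    rr <- ape::root(tree, tip, resolve.root = TRUE)
    expect_equal(tree_log_likelihood(aln, rr, m), base, tolerance = 1e-8)
  }
  perm <- aln[sample(rownames(aln)), , drop = FALSE]
  expect_equal(tree_log_likelihood(as_alignment(perm), tree, m), base,
               tolerance = 1e-10)
})

test_that("gaps and ambiguity codes act as missing data", {
  s <- random_peptide(20, 8)
  aln <- as_alignment(c(a = s, b = s, c = s,
                        d = paste(rep("X", 20), collapse = "")))
  set.seed(8)
  tree <- ape::rtree(4, rooted = FALSE, tip.label = c("a", "b", "c", "d"))
  tree$edge.length <- runif(5, 0.1, 0.3)
  m <- substitution_model("JTT", alpha = 0.5, k = 4)
  ll_full <- site_log_likelihoods(aln, tree, m)
  # an all-missing leaf must not change the likelihood of the others
  aln3 <- as_alignment(unclass(aln)[c("a", "b", "c"), ])
  tree3 <- ape::drop.tip(tree, "d")
  expect_equal(ll_full, site_log_likelihoods(aln3, tree3, m),
               tolerance = 1e-10)
})

test_that("branch-length optimization improves and matches a 1-D oracle", {
  # two-taxon alignment: total length equals the 1-D ML distance
  set.seed(21)
  tr2 <- ape::read.tree(text = "(a:0.2,b:0.2);")
  m <- substitution_model("JTT", alpha = 0.5, k = 4)
  sim <- simulate_protein_evolution(tr2, m, 400, seed = 33)
  fit <- optimize_branch_lengths(sim, tr2, m)
  obj <- function(t) {
    tree_log_likelihood(sim, ape::read.tree(
      text = sprintf("(a:%.10f,b:%.10f);", t / 2, t / 2)), m)
  }
  grid <- seq(0.05, 1.5, by = 5e-4)
  t_hat <- grid[which.max(vapply(grid, obj, 0))]
  expect_equal(sum(fit$tree$edge.length), t_hat, tolerance = 2e-3)
  expect_gte(fit$logL, obj(0.4) - 1e-6)

  # identical sequences drive branch lengths to the lower bound
  s <- random_peptide(60, 3)
  aln <- as_alignment(c(a = s, b = s, c = s, d = s))
  set.seed(3)
  tr4 <- ape::rtree(4, rooted = FALSE, tip.label = c("a", "b", "c", "d"))
  tr4$edge.length <- rep(0.2, 5)
  fit4 <- optimize_branch_lengths(aln, tr4, m)
  expect_true(all(fit4$tree$edge.length <= 1e-6))
  expect_gte(fit4$logL, tree_log_likelihood(aln, tr4, m))
})
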