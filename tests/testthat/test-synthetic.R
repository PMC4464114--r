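test_that("proteome generation is seed-deterministic and honest about
           its truth table", {
  spec <- proteome_spec(n_peptides = 50, len_range = c(80, 200),
                       tract_prob = c(Q = 0.3, A = 0.2))
  g1 <- generate_proteome(spec, seed = 42)
  g2 <- generate_proteome(spec, seed = 42)
  expect_identical(g1, g2)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(g1$peptides, f1); write_fasta(g2$peptides, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  # every truth tract is recovered by the scanner at its insertion point
  tracts <- hpaa_tract_table(g1$peptides, 6)
  for (i in seq_len(nrow(g1$truth))) {
    tt <- g1$truth[i, ]
    hit <- tracts[tracts$peptide_id == tt$peptide_id &
                  tracts$amino_acid == tt$amino_acid, ]
    expect_gte(nrow(hit), 1L)
    expect_true(any(hit$length >= tt$length))
  }
})

test_that("tract-free proteomes show only chance runs at the analytic
           rate", {
  # one residue at high frequency so chance runs are observable
  freqs <- setNames(rep(0.75 / 19, 20), aa20)
  freqs["A"] <- 0.25
  spec <- proteome_spec(n_peptides = 40, len_range = c(400, 400),
                       residue_freq = freqs)
  nrep <- 60
  counts <- vapply(seq_len(nrep), function(r) {
    g <- generate_proteome(spec, seed = 1000 + r)
    sum(hpaa_tract_table(g$peptides, 6)$amino_acid == "A")
  }, 0)
  expected <- 40 * expected_chance_runs(400, 0.25, 6)
  se <- sd(counts) / sqrt(nrep)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("simulated evolution matches stationarity and expected
           divergence", {
  m <- substitution_model("JTT", alpha = 0.5, k = 4)
  # zero branch lengths: all leaves identical
  tr0 <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  s0 <- simulate_protein_evolution(tr0, m, 200, seed = 7)
  expect_equal(unname(alignment_strings(s0)["a"]),
               unname(alignment_strings(s0)["b"]))

  # two-taxon divergence: observed p-distance within 3 binomial SDs of the
  # matrix-exponential expectation, averaged over rate categories
  t_tot <- 0.6
  p_exp <- 1 - mean(vapply(m$rates, function(r) {
    sum(m$freq * diag(hpaaphylo:::.pmat(m, t_tot * r)))
  }, 0))
  tr <- ape::read.tree(text = "(a:0.3,b:0.3);")
  n <- 10000
  sim <- simulate_protein_evolution(tr, m, n, seed = 99)
  p_obs <- mean(sim["a", ] != sim["b", ])
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))

  # leaf residue frequencies near the stationary distribution
  tabs <- table(factor(sim, levels = aa20)) / length(sim)
  expect_lt(max(abs(as.numeric(tabs) - m$freq)),
            3 * sqrt(max(m$freq) * (1 - max(m$freq)) / (2 * n)) + 0.01)
  expect_error(simulate_protein_evolution(
    ape::read.tree(text = "(a:-0.1,b:0.1);"), m, 10, seed = 1),
    "negative")
})

test_that("scenario construction yields the advertised ground truth", {
  sc_b <- make_scenario(scenario_spec("before_split"), seed = 5)
  expect_equal(unname(sc_b$truth), c(2, 0, 0, 0))
  sc_i <- make_scenario(scenario_spec("independent"), seed = 5)
  expect_equal(unname(sc_i$truth), c(0, 2, 1, 0))
  expect_equal(sort(names(sc_b$sequences)),
               sort(c("g1", "g2", "g3", "cA", "cB", "out")))
  expect_true(all(nchar(sc_b$sequences) == 300))

  # convergent injection lands in exactly the designated leaves
  inj <- rbind(hpaa_injection("cA", "Q", 15, 50),
               hpaa_injection("cB", "Q", 15, 50))
  sc_q <- make_scenario(scenario_spec("before_split", injections = inj),
                        seed = 6)
  pep <- peptide_table(unname(sc_q$sequences))
  pep$id <- names(sc_q$sequences)
  tr <- hpaa_tract_table(pep, 15)
  hits <- tr[tr$amino_acid == "Q" & tr$length >= 15, ]
  expect_equal(sort(unique(hits$peptide_id)), c("cA", "cB"))
})

test_that("shared tracts inflate support for the cyclostome pairing when
           the alignment is used untrimmed", {
  model <- substitution_model("JTT", alpha = 0.5, k = 4)
  inj <- rbind(hpaa_injection("cA", "A", 20, 40),
               hpaa_injection("cA", "Q", 20, 62),
               hpaa_injection("cB", "A", 20, 40),
               hpaa_injection("cB", "Q", 20, 62))
  sup <- sapply(1:4, function(r) {
    sc <- make_scenario(scenario_spec("before_split", n_sites = 200,
                                      injections = inj),
                        seed = 70000 + r)
    delta <- sc$sequences
    for (lf in c("cA", "cB")) {
      delta[lf] <- delete_hpaa(delta[[lf]], find_hpaa_tracts(delta[[lf]], 10))
    }
    one <- function(seqs) {
      aln <- align_sequences(seqs, "builtin")   # no trimming
      ex <- exhaustive_ml(aln, otus = names(seqs), model = model,
                          n_replicates = 5000, seed = 80000 + r)
      clade_support(ex$bp, ex$topologies, c("cA", "cB"))
    }
    c(intact = one(sc$sequences), delta = one(delta))
  })
  # the injected tracts act in one direction: never less support intact
  expect_true(all(sup["intact", ] >= sup["delta", ]))
  expect_gt(sum(sup["intact", ]), sum(sup["delta", ]))
})
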