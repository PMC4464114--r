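test_that("tract detection reports maximal runs at the length threshold", {
  tr <- find_hpaa_tracts("MAAAAAAKQQQQQQQQ", 6)
  expect_equal(tr$amino_acid, c("A", "Q"))
  expect_equal(tr$start, c(2L, 9L))
  expect_equal(tr$length, c(6L, 8L))

  expect_equal(nrow(find_hpaa_tracts("AAAAA", 6)), 0L)
  expect_equal(nrow(find_hpaa_tracts("", 6)), 0L)

  # ambiguity characters break runs and never form tracts
  expect_equal(nrow(find_hpaa_tracts("AAAXAAA", 6)), 0L)
  expect_equal(nrow(find_hpaa_tracts("XXXXXXXX", 6)), 0L)
})

test_that("scanning at a higher threshold yields a subset of tracts", {
  set.seed(3)
  for (i in 1:20) {
    s <- paste(sample(c("A", "Q", "G", "K"), 200, replace = TRUE,
                      prob = c(0.55, 0.2, 0.15, 0.1)), collapse = "")
    t6 <- find_hpaa_tracts(s, 6)
    t10 <- find_hpaa_tracts(s, 10)
    expect_true(all(t10$start %in% t6$start))
    expect_true(nrow(t10) <= nrow(t6))
  }
})

test_that("peptide frequencies and residue proportions are exact counts", {
  pep <- peptide_table(c(paste0(strrep("MK", 25), strrep("A", 6),
                                strrep("VR", 22)),
                         random_peptide(150, 1),
                         random_peptide(100, 2)))
  pf <- peptide_frequency_table(pep, 6)
  expect_equal(pf$frequency[pf$amino_acid == "A"], 1 / 3)
  expect_equal(sum(pf$frequency[!pf$amino_acid %in% c("A", "any")]), 0)
  expect_equal(pf$frequency[pf$amino_acid == "any"], 1 / 3)

  # two peptides 50 + 150 with tracts 6 (A) and 12 (Q): total 18/200
  pep2 <- peptide_table(c(paste0(strrep("A", 6), strrep("MK", 22)),
                          paste0(strrep("Q", 12), strrep("KV", 69))))
  rp <- residue_proportion(pep2, 6)
  expect_equal(rp$proportion[rp$amino_acid == "total"], 18 / 200)
  expect_equal(rp$proportion[rp$amino_acid == "A"], 6 / 200)
  # total equals the sum of per-amino-acid numerators over total residues
  expect_equal(rp$n_in_tracts[rp$amino_acid == "total"],
               sum(rp$n_in_tracts[rp$amino_acid != "total"]))

  # tract-free set scores zero everywhere
  pep3 <- peptide_table("MKVRDESTW")
  expect_true(all(peptide_frequency_table(pep3, 6)$frequency == 0))
  expect_equal(
    residue_proportion(pep3, 6)$proportion[21], 0)
  expect_error(peptide_frequency_table(pep3[0, ], 6), "empty")
})

test_that("adding a tract-free peptide never raises a peptide frequency", {
  set.seed(9)
  base <- peptide_table(c(paste0(strrep("Q", 8), random_peptide(90)),
                          random_peptide(120), random_peptide(80)))
  before <- peptide_frequency_table(base, 6)$frequency
  extra <- rbind(base,
                 data.frame(id = "extra", species = "sp",
                            gene_id = NA_character_,
                            sequence = "MKVRDESTWMKVRDESTW",
                            stringsAsFactors = FALSE))
  after <- peptide_frequency_table(extra, 6)$frequency
  expect_true(all(after <= before + 1e-12))
})

test_that("long-tract fractions count boundary lengths correctly", {
  mk <- function(lens) {
    peptide_table(vapply(lens, function(l) {
      paste0(strrep("M", 5), strrep("Q", l), strrep("K", 5))
    }, ""))
  }
  expect_equal(long_tract_fraction(mk(c(6, 12, 13))), 2 / 3)
  expect_equal(long_tract_fraction(mk(c(6, 7))), 0)
  expect_equal(long_tract_fraction(mk(12)), 1)
  expect_warning(res <- long_tract_fraction(mk(5)), "undefined")
  expect_true(is.na(res))
})

test_that("two-proportion z test matches the pooled-variance oracle", {
  r <- two_proportion_test(30, 100, 30, 100)
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)

  r2 <- two_proportion_test(50, 100, 30, 100)
  z_oracle <- 0.20 / sqrt(0.4 * 0.6 * (1 / 100 + 1 / 100))
  expect_equal(r2$z, z_oracle, tolerance = 1e-12)
  expect_equal(r2$p, 2 * pnorm(-z_oracle), tolerance = 1e-12)
  expect_lt(abs(r2$p - 0.0039), 1e-4)

  r3 <- two_proportion_test(0, 10, 0, 20)
  expect_equal(r3$z, 0)
  expect_equal(r3$p, 1)
})

test_that("chi-square homogeneity matches the 2x2 closed form", {
  r <- chi_square_homogeneity(rbind(c(10, 90), c(10, 90)))
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  expect_equal(r$df, 1)

  tab <- rbind(c(20, 80), c(10, 90))
  oracle <- 200 * (20 * 90 - 80 * 10)^2 / (100 * 100 * 30 * 170)
  r2 <- chi_square_homogeneity(tab)
  expect_equal(r2$chi2, oracle, tolerance = 1e-9)
  expect_equal(oracle, 3.9216, tolerance = 1e-4)

  r3 <- chi_square_homogeneity(rbind(c(10, 90), c(10, 90), c(10, 90)))
  expect_equal(r3$chi2, 0)
  expect_equal(r3$df, 2)

  expect_error(chi_square_homogeneity(rbind(c(0, 90), c(0, 80))), "zero")
})
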