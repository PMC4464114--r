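test_that("FASTA parsing normalizes records and enforces id uniqueness", {
  f <- write_temp_fasta(c(">a extra tokens", "mkv", ">b", "MAA"))
  x <- read_fasta(f, "protein")
  expect_equal(x$id, c("a", "b"))
  expect_equal(x$sequence, c("MKV", "MAA"))

  f2 <- write_temp_fasta(c(">a", "mkv*"))
  expect_message(y <- read_fasta(f2, "protein"), "trailing stop")
  expect_equal(y$sequence, "MKV")

  f3 <- write_temp_fasta(c(">a", "MK*V", ">b", "MAA"))
  expect_warning(z <- read_fasta(f3, "protein"), "internal stop")
  expect_equal(z$id, "b")

  f4 <- write_temp_fasta(c(">a", "MKV", ">a", "MAA"))
  expect_error(read_fasta(f4, "protein"), "duplicate.*a")

  f5 <- write_temp_fasta(character(0))
  expect_error(read_fasta(f5, "protein"))
})

test_that("read/write round-trips normalized records", {
  seqs <- c(p1 = random_peptide(40, 1), p2 = random_peptide(60, 2))
  f <- tempfile(fileext = ".fa")
  write_fasta(seqs, f)
  back <- read_fasta(f, "protein")
  expect_equal(setNames(back$sequence, back$id), seqs)
})

test_that("representative selection keeps the longest isoform per gene", {
  pep <- peptide_table(c(random_peptide(100, 1), random_peptide(120, 2),
                         random_peptide(80, 3)))
  gm <- c(p001 = "g", p002 = "g", p003 = "h")
  out <- select_representatives(pep, gm)
  expect_equal(nrow(out), 2L)
  expect_equal(out$id[out$gene_id == "g"], "p002")   # longest isoform
  expect_equal(out$id[out$gene_id == "h"], "p003")   # single isoform

  # equal lengths: lexicographically smaller id wins, order-invariant
  pep2 <- peptide_table(c(random_peptide(50, 4), random_peptide(50, 5)))
  gm2 <- c(p001 = "g", p002 = "g")
  out_fwd <- select_representatives(pep2, gm2)
  out_rev <- select_representatives(pep2[2:1, ], gm2)
  expect_equal(out_fwd$id, "p001")
  expect_equal(out_fwd, out_rev)

  # output size equals the number of distinct genes (ids not in map are
  # their own gene)
  pep3 <- peptide_table(vapply(1:6, function(i) random_peptide(30 + i, i),
                               ""))
  gm3 <- c(p001 = "g1", p002 = "g1", p003 = "g2")
  expect_equal(nrow(select_representatives(pep3, gm3)), 5L)
})

test_that("bit conversion matches a direct ungapped self-alignment oracle", {
  set.seed(42)
  s <- random_peptide(300)
  st <- homology_filter_settings()
  # oracle: for an identical ungapped pair, the optimal local alignment
  # score is the sum of BLOSUM62 diagonal scores
  b62 <- hpaaphylo:::.blosum62_ext()
  raw <- sum(b62[cbind(strsplit(s, "")[[1]], strsplit(s, "")[[1]])])
  expected_bits <- (st$lambda_ka * raw - log(st$k_ka)) / log(2)
  expect_equal(pairwise_bit_score(s, s, st), expected_bits, tolerance = 1e-9)
})

test_that("reciprocal filter keeps conserved peptides and drops short or
           unrelated ones", {
  set.seed(7)
  shared <- random_peptide(300)
  short <- random_peptide(30)
  a <- peptide_table(c(shared, short), species = "sp1")
  b <- peptide_table(c(shared, random_peptide(250)), species = "sp2")
  cc <- peptide_table(c(shared, random_peptide(250)), species = "sp3")
  st <- homology_filter_settings(min_bits = 200)

  # oracle: even a perfect self-match of a 30-mer cannot reach 200 bits
  max_raw <- 30 * max(hpaaphylo:::.blosum62_ext())
  expect_lt((st$lambda_ka * max_raw - log(st$k_ka)) / log(2), 200)

  out <- expect_silent(reciprocal_homolog_filter(a, b, cc, st))
  expect_equal(out$a$id, "p001")
  expect_equal(out$b$id, "p001")
  expect_equal(out$c$id, "p001")

  # symmetric in set order
  out2 <- reciprocal_homolog_filter(b, cc, a, st)
  expect_equal(out2$c$sequence, out$a$sequence)
})
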