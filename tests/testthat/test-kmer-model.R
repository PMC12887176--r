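test_that("revcomp matches definition and is an involution", {
  expect_identical(revcomp("GAAA"), "TTTC")
  expect_identical(revcomp(""), "")
  expect_identical(revcomp("acgtn"), "NACGT")
  # the printed consensus duplex is its own reverse complement
  expect_identical(revcomp(CONSENSUS_OLIGO), CONSENSUS_OLIGO)
  expect_error(revcomp("ACGU"), "invalid alphabet")

  set.seed(11)
  seqs <- random_dna(200, sample(1:40, 200, replace = TRUE))
  expect_identical(revcomp(revcomp(seqs)), seqs)
  expect_identical(revcomp(seqs), vapply(seqs, oracle_revcomp, "", USE.NAMES = FALSE))
})

test_that("canonical form is the lexicographic minimum over strands", {
  expect_identical(canonical_kmer("TTTC"), "GAAA")
  expect_identical(canonical_kmer("AAAA"), "AAAA")
  expect_identical(canonical_kmer("GAAAGTA"), "GAAAGTA")  # revcomp TACTTTC sorts after
  expect_error(canonical_kmer("GANA"), "invalid alphabet")

  set.seed(12)
  km <- random_dna(500, 7)
  cn <- canonical_kmer(km)
  expect_identical(canonical_kmer(cn), cn)               # idempotent
  expect_true(all(cn == km | cn == revcomp(km)))
  expect_true(all(cn <= revcomp(cn)))
  expect_identical(cn, oracle_canonical(km))
})

test_that("complete 7-mer space has 4^7 / 2 canonical members", {
  ck <- canonical_kmers(7)
  expect_length(ck, 8192)
  expect_identical(ck, canonical_kmer(ck))
  expect_false(anyDuplicated(ck) > 0)
})

test_that("k-mer tables parse, collapse strands and reject conflicts", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "GAAAGTA\t3.0", "AAAAAAA\t0.1"), p)
  tb <- read_kmer_table(p)
  expect_s3_class(tb, "kmer_table")
  expect_identical(tb$k, 7L)
  expect_length(tb$z, 2L)
  expect_false(tb$complete)

  writeLines(c("GAAAGTA\t3.0", "TACTTTC\t3.0"), p)
  expect_length(read_kmer_table(p)$z, 1L)                # revcomp collapse

  writeLines(c("GAAAGTA\t3.0", "TACTTTC\t2.0"), p)
  expect_error(read_kmer_table(p), "conflict")

  writeLines(c("GAAAGTA\t3.0", "GAAAGT\t1.0"), p)
  expect_error(read_kmer_table(p), "inconsistent")

  # three columns: escore + zscore, with a header line
  writeLines(c("kmer\tescore\tzscore", "GAAAGTA\t0.49\t3.0"), p)
  tb3 <- read_kmer_table(p)
  expect_equal(unname(tb3$escore["GAAAGTA"]), 0.49)
  expect_equal(unname(tb3$z["GAAAGTA"]), 3.0)

  # writer round trip
  write_kmer_table(tb3, p)
  rt <- read_kmer_table(p)
  expect_equal(rt$z, tb3$z)
  expect_equal(rt$escore, tb3$escore)
})

test_that("affinity lookup is strand symmetric with a predictable default", {
  tb <- kmer_table(c(GAAAGTA = 3))
  expect_equal(kmer_affinity(tb, "TACTTTC"), 3)
  expect_equal(kmer_affinity(tb, "AAAAAAA"), 0)          # incomplete -> default
  expect_equal(kmer_affinity(tb, "AAAAAAA", default = -1), -1)
  expect_error(kmer_affinity(tb, "GAAAGT"), "length")

  set.seed(13)
  full <- kmer_table(stats::setNames(rnorm(8192), canonical_kmers(7)))
  expect_true(full$complete)
  km <- random_dna(2000, 7)
  expect_identical(kmer_affinity(full, km), kmer_affinity(full, revcomp(km)))

  partial <- kmer_table(c(GAAAGTA = 3), complete = TRUE)
  expect_error(kmer_affinity(partial, "AAAAAAA"), "missing k-mer")
})

test_that("linear transform is 2^z, monotone, and inverts log2", {
  expect_equal(z_to_linear(0), 1)
  expect_equal(z_to_linear(3), 8)
  expect_equal(z_to_linear(-1), 0.5)
  expect_error(z_to_linear(NA_real_), "finite")
  expect_error(z_to_linear(Inf), "finite")
  g <- seq(-6, 6, by = 0.25)
  expect_true(all(diff(z_to_linear(g)) > 0))
  expect_equal(z_to_linear(log2(exp(g))), exp(g))
})

test_that("energy logo is a per-column Boltzmann softmax with IC heights", {
  W <- matrix(0, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  lg <- energy_logo(W)
  expect_equal(lg$probs, matrix(0.25, 4, 3, dimnames = list(c("A","C","G","T"), NULL)))
  expect_equal(lg$heights, rep(0, 3))

  W2 <- matrix(c(10, 0, 0, 0), 4, 1)
  lg2 <- energy_logo(W2)
  expect_equal(unname(lg2$probs[1, 1]), exp(10) / (exp(10) + 3), tolerance = 1e-12)
  expect_gt(lg2$probs[1, 1], 0.9998)

  W7 <- matrix(rnorm(28), 4, 7)
  lg7 <- energy_logo(W7)
  expect_identical(lg7$width, 7L)
  expect_equal(colSums(lg7$probs), rep(1, 7), tolerance = 1e-9)
  expect_true(all(lg7$heights >= 0))
  expect_error(energy_logo(matrix(numeric(0), 4, 0)), "width")
  expect_error(energy_logo(matrix(c(1, NA, 0, 0), 4, 1)), "finite")

  p <- withr::local_tempfile(fileext = ".tsv")
  write_logo_matrix(lg7, p)
  m <- read.delim(p, check.names = FALSE)
  expect_identical(m$base, c("A", "C", "G", "T", "height"))
  expect_equal(as.numeric(m[1, -1]), lg7$probs[1, ], tolerance = 1e-6)
})
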