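test_that("probe sets validate their invariants", {
  expect_error(probe_set(c("a", "a"), c("ACGT", "ACGT"), c(1, 2), 1:2, c(1, 1)),
               "unique")
  expect_error(probe_set(c("a", "b"), c("ACGT", "ACG"), c(1, 2), 1:2, 1:2),
               "same length")
  expect_error(probe_set(c("a", "b"), c("ACGT", "ACGT"), c(1, -2), 1:2, 1:2),
               "finite")
  expect_error(probe_set(c("a", "b"), c("ACGT", "ACGT"), c(1, 2), c(1, 1), c(2, 2)),
               "coordinates")

  ps <- toy_probeset(c("ACGTACGT", "TTTTACGT"), c(5, 9))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_probeset(ps, p)
  rt <- read_probeset(p)
  expect_equal(as.data.frame(rt), as.data.frame(ps))
  expect_identical(attr(rt, "variable_end"), attr(ps, "variable_end"))
})

test_that("spatial detrending flattens gradients and preserves the global median", {
  flat <- toy_probeset(random_dna(100, 20), rep(250, 100))
  out <- spatial_detrend(flat, radius = 3)
  expect_equal(out$intensity, flat$intensity)
  expect_error(spatial_detrend(flat, radius = 0), "radius")

  # smooth array gradient times a flat signal: detrending must flatten it
  set.seed(20)
  grid <- expand.grid(row = 1:20, col = 1:20)
  gradient <- toy_probeset(random_dna(400, 20))
  gradient$row <- grid$row; gradient$col <- grid$col
  gradient$intensity <- 200 * exp(0.05 * (grid$row + grid$col))
  det <- spatial_detrend(gradient, radius = 5)
  cv <- function(v) sd(v) / mean(v)
  expect_lt(cv(det$intensity), 0.3 * cv(gradient$intensity))
  expect_lt(cv(det$intensity), 0.1)
  expect_equal(median(det$intensity), median(gradient$intensity),
               tolerance = 1e-9)

  # gradient removal also holds on a full simulated probe set with signal
  sim <- gen_probeset(example_pwm(), n_probes = 1000, noise_sd = 0.05,
                      spatial_gradient = 2, rng_seed = 5)
  det2 <- spatial_detrend(sim$probes, radius = 7)
  expect_equal(median(det2$intensity), median(sim$probes$intensity),
               tolerance = 1e-9)
})

test_that("k-mer z-scores match a brute-force oracle on a toy probe set", {
  set.seed(21)
  seqs <- random_dna(50, 35)
  ints <- exp(rnorm(50, 5, 0.5))
  ps <- toy_probeset(seqs, ints)
  k <- 3
  tb <- kmer_stats(ps, k = k)
  expect_true(tb$complete)
  expect_length(tb$z, 4^k / 2)

  # independent oracle: regex containment on either strand, then median/z
  all3 <- apply(expand.grid(B1 = c("A","C","G","T"), B2 = c("A","C","G","T"),
                            B3 = c("A","C","G","T")), 1, paste, collapse = "")
  canon3 <- sort(unique(oracle_canonical(all3)))
  med <- vapply(canon3, function(m) {
    hit <- grepl(m, seqs, fixed = TRUE) |
      grepl(oracle_revcomp(m), seqs, fixed = TRUE)
    median(log(ints[hit]))
  }, numeric(1))
  z_oracle <- (med - mean(med)) / sd(med)
  expect_equal(unname(tb$z[canon3]), unname(z_oracle), tolerance = 1e-12)

  # z-scores are standardized over table entries
  expect_equal(mean(tb$z), 0, tolerance = 1e-9)
  expect_equal(sd(tb$z), 1, tolerance = 1e-9)
})

test_that("degenerate intensities give all-zero z-scores and energies", {
  set.seed(22)
  ps <- toy_probeset(random_dna(60, 35), rep(100, 60))
  expect_message(tb <- kmer_stats(ps, k = 3), "medians equal")
  expect_true(all(tb$z == 0))
  pw <- seed_and_wobble(ps, k = 3)
  expect_true(all(pw$weights == 0))
})

test_that("uncovered k-mers raise a coverage error naming them", {
  # probes made only of A/C exclude any G/T-containing 3-mer
  ps <- toy_probeset(c("ACAACCAACA", "CCCACACACC"), c(5, 9))
  expect_error(kmer_stats(ps, k = 3), "coverage error")
})

test_that("E-score spans [-0.5, 0.5] and is invariant to monotone transforms", {
  # perfect separation: all probes containing the k-mer outrank the rest
  fg <- rep(paste0("GGGTTT", strrep("A", 10)), 10)
  bg <- rep(strrep("CA", 8), 10)
  ps <- toy_probeset(c(fg, bg), c(100 + 1:10, 1 + 0.1 * (1:10)))
  expect_equal(escore(ps, "GGGTTT"), 0.5)
  expect_equal(escore(ps, "CACACA"), -0.5)  # only in low-intensity probes

  # identical intensities: midranks give exactly 0
  ps0 <- toy_probeset(c(fg, bg), rep(7, 20))
  expect_equal(escore(ps0, "GGGTTT"), 0)

  expect_error(escore(ps, "GGGGGG"), "foreground")

  set.seed(23)
  for (rep in 1:5) {
    psr <- toy_probeset(random_dna(40, 20), exp(rnorm(40, 3, 1)))
    km <- substr(psr$sequence[1], 1, 4)
    e1 <- escore(psr, km)
    psr2 <- psr
    psr2$intensity <- log1p(psr$intensity)
    expect_equal(escore(psr2, km), e1)
    expect_gte(e1, -0.5); expect_lte(e1, 0.5)
  }
})

test_that("seed-and-wobble recovers planted motifs", {
  set.seed(24)
  recs <- numeric(10)
  for (rep in 1:10) {
    cons <- paste(sample(c("A", "C", "G", "T"), 7, replace = TRUE), collapse = "")
    pwm <- example_pwm(cons, p_consensus = 0.85)
    sim <- gen_probeset(pwm, n_probes = 2000, noise_sd = 0.1,
                        rng_seed = 240 + rep)
    pw <- seed_and_wobble(sim$probes, k = 7)
    rec <- cor(as.vector(energy_logo(pw$weights)$probs), as.vector(pwm))
    if (pw$seed != cons)   # seed may come out in the opposite orientation
      rec <- max(rec,
        cor(as.vector(energy_logo(pw$weights)$probs[4:1, 7:1]), as.vector(pwm)))
    recs[rep] <- rec
    # seed bases sit at the zero reference energy
    seed_idx <- cbind(match(strsplit(pw$seed, "")[[1]], c("A","C","G","T")), 1:7)
    expect_true(all(pw$weights[seed_idx] == 0))
  }
  expect_gte(median(recs), 0.9)
})

test_that("the fitted model exposes table, PWM, logo and predictions", {
  sim <- gen_probeset(example_pwm(), n_probes = 700, noise_sd = 0.1, rng_seed = 31)
  fit <- pbm_fit(sim$probes, detrend = FALSE)
  expect_s3_class(fit, "pbm_fit")
  expect_true(fit$table$complete)
  expect_equal(dim(coef(fit)), c(4L, 7L))
  expect_output(print(fit), "PBM binding affinity model")
  expect_output(print(summary(fit)), "Top k-mers")
  # at this probe count the seed is the consensus or a 1-offset neighbor
  # sharing its core (full-scale identity is exercised elsewhere)
  expect_true(grepl("GAAAGT|AAAGTA|TACTTT|ACTTTC", fit$seed))

  tr <- predict(fit, CONSENSUS_OLIGO)
  expect_s3_class(tr, "affinity_track")
  expect_length(tr$z, nchar(CONSENSUS_OLIGO) - 6)
  # the consensus occurrences at offsets 7 and 12 attain the track maximum
  expect_true(all(c(7L, 12L) %in% tr$offsets[tr$z >= max(tr$z) - 1e-9]))
})
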