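test_that("simulated probe sets cover every canonical 7-mer and are seeded", {
  sim <- gen_probeset(example_pwm(), n_probes = 600, rng_seed = 71)
  vs <- attr(sim$probes, "variable_start"); ve <- attr(sim$probes, "variable_end")
  var <- substr(sim$probes$sequence, vs + 1, ve)
  seen <- unique(unlist(lapply(var, function(s) {
    n <- nchar(s) - 6
    oracle_canonical(substring(s, 1:n, 7:(n + 6)))
  })))
  expect_length(seen, 8192)

  sim2 <- gen_probeset(example_pwm(), n_probes = 600, rng_seed = 71)
  expect_identical(sim2$probes, sim$probes)     # byte-identical under one seed
  sim3 <- gen_probeset(example_pwm(), n_probes = 600, rng_seed = 72)
  expect_false(identical(sim3$probes$sequence, sim$probes$sequence))

  expect_error(gen_probeset(example_pwm(), n_probes = 100), "pool")
  expect_error(gen_probeset(example_pwm(), variable_len = 5, n_probes = 600),
               ">= motif width")
})

test_that("without noise the consensus-bearing probes top the intensity range", {
  sim <- gen_probeset(example_pwm(), n_probes = 600, noise_sd = 0, rng_seed = 73)
  vs <- attr(sim$probes, "variable_start"); ve <- attr(sim$probes, "variable_end")
  var <- substr(sim$probes$sequence, vs + 1, ve)
  best <- which(sim$probes$intensity == max(sim$probes$intensity))
  expect_true(all(grepl("GAAAGTA", var[best]) | grepl("TACTTTC", var[best])))
})

test_that("planted promoter sites are recovered regardless of strand", {
  pwm <- example_pwm()
  tab <- pwm_affinity_table(pwm)
  n <- 60
  sim <- gen_promoters(n, pwm = pwm, sites_per_promoter = 1, rng_seed = 74,
                       site_sequences = rep(list("GAAAGTA"), n))
  wins <- extract_promoters(sim$genome, sim$tss)
  hits <- vapply(seq_len(n), function(i) {
    sites <- call_sites(scan_promoter(wins[[i]], tab))
    # the planted site must be called at maximal affinity (the background
    # occasionally holds another consensus copy, a genuine tied site)
    any(abs(sites$peak_pos - sim$truth[[i]]$genomic_starts) <= 3 &
          sites$peak_z >= max(sites$peak_z) - 1e-9)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # both planting strands are represented and recovered
  strands <- vapply(sim$truth, function(t) t$site_strands, character(1))
  expect_setequal(unique(strands), c("+", "-"))
  expect_gte(mean(hits[strands == "-"]), 0.9)
})

test_that("windows without planted sites stay below planted-site affinity", {
  pwm <- example_pwm()
  tab <- pwm_affinity_table(pwm)
  cons_z <- kmer_affinity(tab, "GAAAGTA")
  sim <- gen_promoters(40, pwm = pwm, sites_per_promoter = 0, rng_seed = 75)
  wins <- extract_promoters(sim$genome, sim$tss)
  frac_below <- mean(vapply(wins, function(w)
    max(scan_promoter(w, tab)$z) < cons_z - 1e-9, logical(1)))
  expect_gte(frac_below, 0.75)   # chance consensus occurrence ~17% per window
})

test_that("simulated coverage peaks at the planted site centers", {
  sim <- gen_promoters(3, pwm = example_pwm(), sites_per_promoter = 1,
                       rng_seed = 76)
  cov <- gen_chip_coverage(sim$truth, frag_len = 200, depth = 50,
                           noise_sd = 0.5, rng_seed = 77)
  for (i in 1:3) {
    tr <- sim$truth[[i]]
    y <- pbmscan:::.expand_coverage(cov, tr$chrom, 0, tr$contig_length)
    expect_lte(abs(which.max(y) - 1 - tr$genomic_centers), 2)
    expect_gt(max(y), 45)
  }

  # no sites: flat noise floor only
  sim0 <- gen_promoters(2, pwm = example_pwm(), sites_per_promoter = 0,
                        rng_seed = 78)
  cov0 <- gen_chip_coverage(sim0$truth, depth = 50, noise_sd = 0.5, rng_seed = 79)
  expect_lt(max(cov0$records$value), 5)

  expect_error(gen_chip_coverage(sim$truth, frag_len = 0), "frag_len")

  p <- withr::local_tempfile(fileext = ".bedGraph")
  gen_chip_coverage(sim$truth, rng_seed = 80, path = p)
  rt <- read_bedgraph(p)     # emitted bedGraph is valid and parseable
  expect_gt(nrow(rt$records), 0)
})

test_that("simulated DE tables support cluster recovery and null filtering", {
  sim <- gen_deg_table(600, rng_seed = 81)
  f <- filter_degs(sim$deg)
  cl <- ward_cluster(f, n_clusters = 4)
  truth <- sim$truth_labels[f$genes]
  expect_gte(ari(cl$labels[truth > 0], truth[truth > 0]), 0.9)

  sim2 <- gen_deg_table(600, rng_seed = 81)
  expect_identical(sim2$deg$log2fc, sim$deg$log2fc)

  null_only <- gen_deg_table(400, frac_null = 1, rng_seed = 82)
  expect_lte(length(filter_degs(null_only$deg)$genes), 2L)
  expect_true(all(null_only$truth_labels == 0))
})

test_that("promoter generators emit the on-disk formats the scanners read", {
  d <- withr::local_tempdir()
  sim <- gen_promoters(3, pwm = example_pwm(), rng_seed = 83, dir = d)
  expect_true(file.exists(file.path(d, "genome.fa")))
  wins <- extract_promoters(file.path(d, "genome.fa"), file.path(d, "tss.tsv"))
  expect_length(wins, 3L)
  expect_identical(wins[[1]]$sequence,
                   extract_promoters(sim$genome, sim$tss)[[1]]$sequence)
})
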