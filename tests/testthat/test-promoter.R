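test_that("coordinate converters relate 1-based inclusive and 0-based half-open", {
  z <- to_zero_based(89300997, 89302495)
  expect_equal(z$start, 89300996)
  expect_equal(interval_width(z$start, z$end), 1499)
  expect_equal(interval_width(89300997, 89302495, style = "one_based"), 1499)
  o <- to_one_based(z$start, z$end)
  expect_equal(o$start, 89300997)
  set.seed(31)
  s1 <- sample.int(1e6, 20); e1 <- s1 + sample.int(500, 20)
  rt <- do.call(to_one_based, to_zero_based(s1, e1))
  expect_equal(rt$start, s1); expect_equal(rt$end, e1)
})

test_that("TSS tables read from BED and header TSV", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t5000\t5001\tgeneA\t0\t+", "chr1\t7000\t7001\tgeneB\t0\t-"), p)
  bed <- read_tss_table(p)
  expect_equal(bed$tss, c(5001, 7001))
  expect_equal(bed$strand, c("+", "-"))

  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\ttss\tstrand", "geneA\tchr1\t5001\t+"), p2)
  tsv <- read_tss_table(p2)
  expect_equal(tsv$gene_id, "geneA")
  expect_equal(tsv$tss, 5001)

  writeLines(c("gene_id\tchrom\ttss\tstrand", "geneA\tchr1\t5001\t*"), p2)
  expect_error(read_tss_table(p2), "strand")
})

test_that("promoter extraction follows the strand-aware window arithmetic", {
  set.seed(32)
  contig <- random_dna(1, 10000)
  genome <- c(chrT = contig)
  tss <- data.frame(gene_id = c("gp", "gm"), chrom = "chrT",
                    tss = c(5001, 5000), strand = c("+", "-"))
  wins <- extract_promoters(genome, tss)
  expect_equal(wins$gp$start, 4000)
  expect_equal(wins$gp$end, 5500)
  expect_equal(nchar(wins$gp$sequence), 1500)
  expect_identical(wins$gp$sequence, substr(contig, 4001, 5500))

  expect_equal(wins$gm$start, 4500)
  expect_equal(wins$gm$end, 6000)
  expect_identical(wins$gm$sequence, oracle_revcomp(substr(contig, 4501, 6000)))

  # the TSS base sits at offset `upstream` in gene orientation on both strands
  expect_identical(substr(wins$gp$sequence, 1001, 1001), substr(contig, 5001, 5001))
  expect_identical(substr(wins$gm$sequence, 1001, 1001),
                   oracle_revcomp(substr(contig, 5000, 5000)))

  tss_edge <- data.frame(gene_id = "ge", chrom = "chrT", tss = 100, strand = "+")
  expect_warning(we <- extract_promoters(genome, tss_edge), "truncated")
  expect_true(we$ge$truncated)
  expect_equal(we$ge$start, 0)

  expect_error(extract_promoters(genome,
    data.frame(gene_id = "gx", chrom = "chrX", tss = 500, strand = "+")),
    "unknown chrom")
})

test_that("sequence scoring anchors canonical k-mer scores at start offsets", {
  tb <- kmer_table(c(GAAAGTA = 3))
  tr <- score_sequence(CONSENSUS_OLIGO, tb)
  expect_length(tr$z, nchar(CONSENSUS_OLIGO) - 6)
  expect_equal(tr$offsets[tr$z != 0], c(7L, 12L))  # GAAAGTA fwd, TACTTTC revcomp
  expect_true(all(tr$z[tr$z != 0] == 3))
  expect_equal(tr$linear, 2^tr$z)

  # the oligo is its own revcomp, so its track equals its own mirror image
  expect_equal(tr$z, rev(tr$z))

  expect_message(empty <- score_sequence("GAAAGT", tb), "shorter")
  expect_length(empty$z, 0L)

  # N windows take the configured default
  trn <- score_sequence("GAAAGTANGAAAGTA", tb, default = -1)
  expect_equal(sum(trn$z == -1), 7)

  set.seed(33)
  full <- kmer_table(stats::setNames(rnorm(8192), canonical_kmers(7)))
  for (i in 1:20) {
    s <- random_dna(1, sample(50:150, 1))
    t1 <- score_sequence(s, full)
    t2 <- score_sequence(revcomp(s), full)
    expect_length(t1$z, nchar(s) - 6)
    expect_equal(t1$z, rev(t2$z))                 # strand-collapse mirror
    expect_equal(t1$z, oracle_scan(s, full$z, 7)) # brute-force oracle
  }
})

test_that("bedGraph writing merges equal runs and round trips exactly", {
  tr <- affinity_track("chr1", 100:102, c(0, 0, 0), 7)
  p <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, p, scale = "linear")      # 2^0 = 1 everywhere
  expect_identical(readLines(p), "chr1\t100\t103\t1")

  tr2 <- affinity_track("chr1", c(10, 11), c(0, 3), 7)
  write_bedgraph(tr2, p, scale = "linear")
  expect_identical(readLines(p), c("chr1\t10\t11\t1", "chr1\t11\t12\t8"))

  set.seed(34)
  tr3 <- affinity_track("chr2", 0:199, rnorm(200), 7)
  write_bedgraph(tr3, p, scale = "z", name = "pred")
  expect_match(readLines(p, n = 1), "^track type=bedGraph")
  rt <- read_bedgraph(p)
  expanded <- pbmscan:::.expand_coverage(rt, "chr2", 0, 200)
  expect_identical(expanded, tr3$z)            # value- and coordinate-exact

  bad <- affinity_track("chr1", c(5, 3), c(1, 2), 7)
  expect_error(write_bedgraph(bad, p), "increasing")
})

test_that("site calling merges nearby runs and reports peaks", {
  zeros <- affinity_track("c", 0:99, rep(0, 100), 7)
  expect_equal(nrow(call_sites(zeros)), 0L)

  one <- affinity_track("c", 0:99, replace(rep(0, 100), 51, 3), 7)
  s1 <- call_sites(one)
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$end - s1$start, 7)           # site extent = one k-mer
  expect_equal(s1$peak_pos, 50)
  expect_equal(s1$peak_z, 3)

  # two qualifying positions 3 bp apart merge under merge_gap = 5
  two <- affinity_track("c", 0:99, replace(rep(0, 100), c(41, 44), c(2.5, 3)), 7)
  s2 <- call_sites(two, merge_gap = 5)
  expect_equal(nrow(s2), 1L)
  expect_equal(s2$start, 40); expect_equal(s2$end, 50)
  expect_equal(s2$peak_pos, 43)

  # separation beyond both merge_gap and the window width keeps them apart
  s3 <- call_sites(affinity_track("c", 0:99,
                                  replace(rep(0, 100), c(41, 50), 3), 7),
                   merge_gap = 5)
  expect_equal(nrow(s3), 2L)

  set.seed(35)
  for (i in 1:10) {
    trr <- affinity_track("c", 0:299, rnorm(300, 0, 1.5), 7)
    ss <- call_sites(trr)
    if (nrow(ss) > 1)                          # sites are base-disjoint
      expect_true(all(ss$start[-1] >= ss$end[-nrow(ss)]))
    if (nrow(ss) > 0) {
      expect_true(all(ss$peak_pos >= ss$start & ss$peak_pos < ss$end))
      expect_true(all(ss$peak_z >= 2))
    }
  }
})

test_that("promoter scanning recovers planted sites in genomic coordinates", {
  pwm <- example_pwm()
  tab <- pwm_affinity_table(pwm)
  sim <- gen_promoters(6, pwm = pwm, sites_per_promoter = 1, rng_seed = 36,
                       site_sequences = rep(list("GAAAGTA"), 6))
  wins <- extract_promoters(sim$genome, sim$tss)
  for (i in seq_along(wins)) {
    tr <- scan_promoter(wins[[i]], tab)
    expect_false(is.unsorted(tr$offsets))
    # the planted consensus attains the track maximum (ties possible when
    # the background contains another consensus copy by chance)
    top <- tr$offsets[tr$z >= max(tr$z) - 1e-9]
    expect_true(sim$truth[[i]]$genomic_starts %in% top)
  }
})
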