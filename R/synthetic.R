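#' De Bruijn sequence over the DNA alphabet
#'
#' Order-`k` de Bruijn sequence (FKM / Lyndon-word construction) with the
#' first `k - 1` bases appended so that every one of the `4^k` k-mers
#' occurs in the linear string. Tiling this string with overlaps of
#' `k - 1` guarantees full k-mer coverage of a probe library.
#'
#' @param k Order (word length).
#' @return A single string of length `4^k + k - 1`.
#' @export
de_bruijn_sequence <- function(k) {
  stopifnot(k >= 1)
  n_alpha <- 4L
  a <- integer(n_alpha * k)
  out <- integer(4^k)
  pos <- 0L
  db <- function(t, p) {
    if (t > k) {
      if (k %% p == 0L) {
        seg <- a[2:(p + 1L)]
        out[(pos + 1L):(pos + p)] <<- seg
        pos <<- pos + p
      }
    } else {
      a[t + 1L] <<- a[t - p + 1L]
      db(t + 1L, p)
      j <- a[t - p + 1L] + 1L
      while (j <= n_alpha - 1L) {
        a[t + 1L] <<- j
        db(t + 1L, t)
        j <- j + 1L
      }
    }
  }
  db(1L, 1L)
  s <- paste(.DNA_BASES[out + 1L], collapse = "")
  paste0(s, substr(s, 1L, k - 1L))
}

#' A simple planted binding motif
#'
#' Column-stochastic position probability matrix concentrated on a
#' consensus: the consensus base gets `p_consensus`, the others share the
#' remainder equally. The default consensus is the GAAA-core half-site of
#' the interferon-stimulated response element family.
#'
#' @param consensus Consensus sequence (default `"GAAAGTA"`).
#' @param p_consensus Probability mass on the consensus base per column.
#' @return A 4 x width probability matrix, rows A/C/G/T.
#' @export
example_pwm <- function(consensus = "GAAAGTA", p_consensus = 0.8) {
  stopifnot(p_consensus > 0.25, p_consensus < 1)
  chars <- strsplit(toupper(consensus), "")[[1L]]
  w <- length(chars)
  probs <- matrix((1 - p_consensus) / 3, 4L, w, dimnames = list(.DNA_BASES, NULL))
  probs[cbind(match(chars, .DNA_BASES), seq_len(w))] <- p_consensus
  probs
}

#' Binding energies of a probability PWM
#'
#' Per-position log probability ratios against the preferred base:
#' `e(b, i) = log p(b, i) - log max_b p(b, i)`, so the consensus path has
#' energy 0 and every substitution a negative energy (natural log units).
#' Probabilities are floored at 1e-6 to keep energies finite.
#'
#' @param probs 4 x width column-stochastic matrix.
#' @return 4 x width energy matrix.
#' @export
pwm_energies <- function(probs) {
  probs <- pmax(as.matrix(probs), 1e-6)
  lg <- log(probs)
  sweep(lg, 2L, apply(lg, 2L, max))
}

# Best (max over both strands) PWM energy for every k-mer index 0..4^k-1.
.pwm_energy_by_index <- function(energies) {
  k <- ncol(energies)
  idx <- 0:(4^k - 1L)
  E <- numeric(length(idx))
  r <- idx
  for (j in k:1) {
    E <- E + energies[cbind((r %% 4) + 1L, j)]
    r <- r %/% 4
  }
  pmax(E, E[.rc_index(idx, k) + 1L])
}

#' K-mer affinity table implied by a PWM
#'
#' Scores every canonical k-mer by its best-strand PWM energy and
#' standardizes across the canonical k-mer set, yielding a complete
#' [kmer_table()] whose z-scores mirror what a PBM-derived table for the
#' same motif looks like. Used to bridge a known (or fitted) PWM into the
#' scanning machinery.
#'
#' @param probs 4 x width column-stochastic matrix (or a `pwm_estimate`,
#'   whose softmaxed weights are used).
#' @return A complete [kmer_table()].
#' @export
pwm_affinity_table <- function(probs) {
  if (inherits(probs, "pwm_estimate")) probs <- energy_logo(probs$weights)$probs
  energies <- pwm_energies(probs)
  k <- ncol(energies)
  Emax <- .pwm_energy_by_index(energies)
  ci <- .canonical_indices(k)
  v <- Emax[ci + 1L]
  z <- (v - mean(v)) / stats::sd(v)
  names(z) <- .index_to_kmer(ci, k)
  kmer_table(z, k = k, complete = TRUE)
}

#' Simulate a PBM probe set with a planted motif
#'
#' Emulates the array design: ~15,000 probes of `probe_len` bases whose
#' variable regions come first from tiles of a de Bruijn sequence
#' (guaranteeing every canonical k-mer appears in at least one probe) and
#' then from uniform random sequence, each followed by a constant 3'
#' primer region. Log-intensity is additive:
#' `baseline + best PWM energy over all windows (both strands) +
#' Normal(0, noise_sd)`, plus an optional linear row/column gradient
#' (`spatial_gradient` log-units corner to corner) emulating the spatial
#' artifacts that detrending removes. The best-window (max, not sum)
#' energy matches the scanner-saturation-free regime and the scoring
#' model's max semantics. Fully reproducible from `rng_seed`.
#'
#' @param pwm 4 x width probability matrix (e.g. [example_pwm()]).
#' @param n_probes Number of probes (default 15000, the array scale; must
#'   be at least the de Bruijn pool size, ~566 for k = 7).
#' @param probe_len Probe length in bases (default 60).
#' @param variable_len Variable-region length (default 35; must be >= k).
#' @param noise_sd Normal noise SD in log-intensity units (default 0.1).
#' @param spatial_gradient Corner-to-corner gradient amplitude in
#'   log-intensity units (default 0 = no artifact).
#' @param rng_seed Seed.
#' @param baseline Baseline log-intensity (default `log(1000)`).
#' @return A list: `probes` (a [probe_set()]) and `truth` (planted PWM,
#'   energies, consensus, seed).
#' @export
gen_probeset <- function(pwm, n_probes = 15000L, probe_len = 60L,
                         variable_len = 35L, noise_sd = 0.1,
                         spatial_gradient = 0, rng_seed = 1L,
                         baseline = log(1000)) {
  k <- ncol(pwm)
  if (variable_len < k) stop("variable_len must be >= motif width", call. = FALSE)
  stopifnot(probe_len >= variable_len)
  db <- de_bruijn_sequence(k)
  stride <- variable_len - k + 1L
  starts <- seq(1L, nchar(db) - variable_len + 1L, by = stride)
  if (starts[length(starts)] + variable_len - 1L < nchar(db))
    starts <- c(starts, nchar(db) - variable_len + 1L)
  n_pool <- length(starts)
  if (n_probes < n_pool)
    stop("n_probes must be >= de Bruijn pool size (", n_pool,
         ") to guarantee k-mer coverage", call. = FALSE)
  .with_seed(rng_seed, {
    var_seq <- substring(db, starts, starts + variable_len - 1L)
    n_rand <- n_probes - n_pool
    if (n_rand > 0L) {
      rand <- vapply(seq_len(n_rand), function(i)
        paste(sample(.DNA_BASES, variable_len, replace = TRUE), collapse = ""),
        character(1))
      var_seq <- c(var_seq, rand)
    }
    const_len <- probe_len - variable_len
    const_seq <- if (const_len > 0L) {
      base_const <- "GTCTGTGTTCCGTTGTCCGTGCTGT"  # fixed primer-site sequence
      substr(paste(rep(base_const, ceiling(const_len / nchar(base_const))),
                   collapse = ""), 1L, const_len)
    } else ""
    seqs <- paste0(var_seq, const_seq)

    energies <- pwm_energies(pwm)
    Emax <- .pwm_energy_by_index(energies)
    best <- vapply(var_seq, function(s) {
      idx <- .kmer_indices(.seq_codes(s), k)$fwd
      max(Emax[idx + 1L])
    }, numeric(1), USE.NAMES = FALSE)

    side <- ceiling(sqrt(n_probes))
    rows <- ((seq_len(n_probes) - 1L) %/% side) + 1L
    cols <- ((seq_len(n_probes) - 1L) %% side) + 1L
    grad <- if (side > 1L)
      spatial_gradient * (rows - 1L + cols - 1L) / (2L * (side - 1L))
    else 0
    logI <- baseline + best + grad + stats::rnorm(n_probes, 0, noise_sd)
    probes <- probe_set(sprintf("probe_%05d", seq_len(n_probes)), seqs,
                        exp(logI), rows, cols,
                        variable_start = 0L, variable_end = variable_len)
    cons <- paste(.DNA_BASES[apply(pwm, 2L, which.max)], collapse = "")
    list(probes = probes,
         truth = list(pwm = pwm, energies = energies, consensus = cons,
                      rng_seed = rng_seed))
  })
}

#' Simulate promoters with planted binding sites
#'
#' Generates `n` promoters of `length` bases (uniform ACGT background) with
#' `sites_per_promoter` non-overlapping motif instances sampled from the
#' PWM (or given verbatim via `site_sequences`), planted on random strands
#' at recorded offsets. Each promoter sits on its own contig with `pad`
#' random flanking bases and alternating gene strands, and the emitted TSS
#' table reproduces the promoter window under the default extraction
#' geometry (`upstream` / `length - upstream`).
#'
#' @param n Number of promoters.
#' @param length Window length in bases (default 1500).
#' @param pwm 4 x width probability matrix.
#' @param sites_per_promoter Planted sites per promoter (default 2,
#'   emulating a two-site promoter; 0 gives pure background).
#' @param rng_seed Seed.
#' @param upstream Bases upstream of the TSS within the window (default
#'   1000; downstream is `length - upstream`).
#' @param site_sequences Optional list (length `n`) of character vectors
#'   giving the exact site sequences to plant, overriding PWM sampling.
#' @param pad Flanking contig padding in bases.
#' @param dir Optional directory: writes `genome.fa`, `tss.tsv` and
#'   `truth.json` (requires jsonlite).
#' @return A list: `genome` (`DNAStringSet`), `tss` (data frame), `truth`
#'   (per-promoter planted site offsets in window coordinates, strands,
#'   genomic starts/centers, contig length), `k`.
#' @export
gen_promoters <- function(n, length = 1500L, pwm, sites_per_promoter = 2L,
                          rng_seed = 1L, upstream = 1000L,
                          site_sequences = NULL, pad = 100L, dir = NULL) {
  k <- ncol(pwm)
  downstream <- length - upstream
  stopifnot(n >= 1, downstream > 0, sites_per_promoter * k <= length)
  .with_seed(rng_seed, {
    contigs <- character(n)
    tss <- data.frame(gene_id = sprintf("gene%03d", seq_len(n)),
                      chrom = sprintf("chr%03d", seq_len(n)),
                      tss = NA_integer_, strand = rep_len(c("+", "-"), n),
                      stringsAsFactors = FALSE)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      win <- sample(.DNA_BASES, length, replace = TRUE)
      n_sites <- if (!is.null(site_sequences)) length(site_sequences[[i]]) else sites_per_promoter
      offs <- integer(0)
      redraws <- 0L
      while (length(offs) < n_sites) {
        cand <- sample.int(length - k + 1L, 1L) - 1L
        if (all(abs(cand - offs) >= k)) offs <- c(offs, cand)
        else redraws <- redraws + 1L
        if (redraws > 1000L) stop("cannot place non-overlapping sites", call. = FALSE)
      }
      offs <- sort(offs)
      strands <- sample(c("+", "-"), n_sites, replace = TRUE)
      site_seq <- character(n_sites)
      for (s in seq_len(n_sites)) {
        inst <- if (!is.null(site_sequences)) toupper(site_sequences[[i]][s])
        else paste(apply(pwm, 2L, function(p) sample(.DNA_BASES, 1L, prob = p)),
                   collapse = "")
        site_seq[s] <- inst
        planted <- if (strands[s] == "-") revcomp(inst) else inst
        win[(offs[s] + 1L):(offs[s] + k)] <- strsplit(planted, "")[[1L]]
      }
      win <- paste(win, collapse = "")
      pad_l <- paste(sample(.DNA_BASES, pad, replace = TRUE), collapse = "")
      pad_r <- paste(sample(.DNA_BASES, pad, replace = TRUE), collapse = "")
      gstrand <- tss$strand[i]
      if (gstrand == "+") {
        contigs[i] <- paste0(pad_l, win, pad_r)
        tss$tss[i] <- pad + upstream + 1L
        gstart <- pad + offs
      } else {
        contigs[i] <- paste0(pad_l, revcomp(win), pad_r)
        tss$tss[i] <- pad + downstream
        gstart <- pad + length - offs - k
      }
      truth[[i]] <- list(gene_id = tss$gene_id[i], chrom = tss$chrom[i],
                         gene_strand = gstrand,
                         window_offsets = offs, site_strands = strands,
                         site_sequences = site_seq,
                         genomic_starts = gstart,
                         genomic_centers = gstart + (k - 1L) %/% 2L,
                         contig_length = nchar(contigs[i]))
    }
    genome <- Biostrings::DNAStringSet(contigs)
    names(genome) <- tss$chrom
    out <- list(genome = genome, tss = tss, truth = truth, k = k)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"))
      utils::write.table(tss, file.path(dir, "tss.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      if (requireNamespace("jsonlite", quietly = TRUE))
        jsonlite::write_json(truth, file.path(dir, "truth.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    out
  })
}

#' Simulate ChIP-seq coverage from planted sites
#'
#' Coverage per contig is the sum of triangular kernels of width `frag_len`
#' centered on the true planted site centers (peak height `depth`), plus
#' non-negative half-normal noise — a stand-in for fragment-pileup coverage
#' around true occupancy, not a read-level simulation.
#'
#' @param truth The `truth` element from [gen_promoters()] (or a subset).
#' @param frag_len Fragment/kernel width in bases (>= 1; default 200).
#' @param depth Peak height in coverage units (default 50).
#' @param noise_sd SD of the half-normal noise floor (default 2).
#' @param rng_seed Seed.
#' @param path Optional bedGraph output path.
#' @return A [coverage_track()] (all contigs concatenated record-wise).
#' @export
gen_chip_coverage <- function(truth, frag_len = 200L, depth = 50,
                              noise_sd = 2, rng_seed = 1L, path = NULL) {
  if (frag_len < 1L) stop("frag_len must be >= 1", call. = FALSE)
  half <- frag_len / 2
  .with_seed(rng_seed, {
    recs <- lapply(truth, function(tr) {
      L <- tr$contig_length
      cov <- numeric(L)
      for (cc in tr$genomic_centers) {
        pos <- max(0L, floor(cc - half)):min(L - 1L, ceiling(cc + half))
        cov[pos + 1L] <- cov[pos + 1L] + depth * pmax(0, 1 - abs(pos - cc) / half)
      }
      cov <- cov + abs(stats::rnorm(L, 0, noise_sd))
      cov <- round(cov, 3)  # merge-friendly plateaus
      r <- rle(cov)
      ends <- cumsum(r$lengths)
      data.frame(chrom = tr$chrom, start = ends - r$lengths, end = ends,
                 value = r$values, stringsAsFactors = FALSE)
    })
    track <- coverage_track(do.call(rbind, recs), source = "simulated")
    if (!is.null(path)) write_coverage(track, path)
    track
  })
}

#' Simulate a differential expression table with known clusters
#'
#' Gene log2 fold changes are Normal around per-cluster per-condition
#' means; null genes get near-zero fold changes and Uniform(0,1) adjusted
#' p-values while non-null genes get small ones; base means are
#' log-normal. Ground-truth labels (0 = null) are returned for recovery
#' tests.
#'
#' @param n_genes Total genes.
#' @param cluster_spec List of clusters, each `list(size =, means =
#'   (per-condition), sd =)`. The default emulates four regulatory classes
#'   over five conditions (up-everywhere, down-everywhere, up under
#'   overexpression only, up under interferon only), sized at 20/20/18/17
#'   percent of `n_genes` with the remainder null.
#' @param frac_null Optional fraction of null genes; when given, cluster
#'   sizes are rescaled proportionally to `(1 - frac_null) * n_genes`.
#'   Otherwise nulls fill `n_genes - sum(sizes)`.
#' @param conditions Condition labels (default from the spec's means).
#' @param rng_seed Seed.
#' @return A list: `deg` (a [deg_table()]) and `truth_labels` (integer
#'   vector, 0 for null genes).
#' @export
gen_deg_table <- function(n_genes = 1000L, cluster_spec = NULL,
                          frac_null = NULL, conditions = NULL, rng_seed = 1L) {
  if (is.null(cluster_spec)) {
    frac <- c(0.20, 0.20, 0.18, 0.17)
    sz <- as.integer(round(frac * n_genes))
    cluster_spec <- list(
      list(size = sz[1L], means = c(4, 4, 4, 4, 0), sd = 0.7),
      list(size = sz[2L], means = c(-4, -4, -4, -4, 0), sd = 0.7),
      list(size = sz[3L], means = c(4, 4, 4, 0, 0), sd = 0.7),
      list(size = sz[4L], means = c(0, 4, 0, 4, 0), sd = 0.7))
    if (is.null(conditions))
      conditions <- c("IRF1_OE", "IFNB", "JAK1KO_OE", "IFNARKO_OE", "GFP_OE")
  }
  n_cond <- length(cluster_spec[[1L]]$means)
  if (is.null(conditions)) conditions <- paste0("cond", seq_len(n_cond))
  stopifnot(length(conditions) == n_cond)
  sizes <- vapply(cluster_spec, `[[`, integer(1), "size")
  if (!is.null(frac_null)) {
    stopifnot(frac_null >= 0, frac_null <= 1)
    target <- round((1 - frac_null) * n_genes)
    sizes <- if (target == 0L) rep(0L, length(sizes))
    else as.integer(round(sizes * target / sum(sizes)))
  }
  if (sum(sizes) > n_genes)
    stop("cluster sizes exceed n_genes", call. = FALSE)
  n_null <- n_genes - sum(sizes)
  .with_seed(rng_seed, {
    labels <- c(rep(seq_along(sizes), times = sizes), rep(0L, n_null))
    lfc <- matrix(NA_real_, n_genes, n_cond)
    padj <- matrix(NA_real_, n_genes, n_cond)
    for (g in seq_len(n_genes)) {
      if (labels[g] == 0L) {
        lfc[g, ] <- stats::rnorm(n_cond, 0, 0.3)
        padj[g, ] <- stats::runif(n_cond)
      } else {
        spec <- cluster_spec[[labels[g]]]
        lfc[g, ] <- stats::rnorm(n_cond, spec$means, spec$sd)
        padj[g, ] <- stats::runif(n_cond, 0, 0.02)
      }
    }
    base_mean <- stats::rlnorm(n_genes, log(100), 1)
    genes <- sprintf("gene%05d", seq_len(n_genes))
    colnames(lfc) <- colnames(padj) <- conditions
    list(deg = deg_table(genes, lfc, padj, base_mean, conditions = conditions),
         truth_labels = stats::setNames(labels, genes))
  })
}
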