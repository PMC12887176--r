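# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own encoding pipeline: string
# slicing plus Biostrings for reverse complements, naive loops for the rest.

oracle_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

oracle_canonical <- function(kmers) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  ifelse(kmers <= rc, kmers, rc)
}

# Brute-force per-position k-mer lookup of a named z vector.
oracle_scan <- function(seq, z, k, default = 0) {
  n <- nchar(seq) - k + 1
  if (n < 1) return(numeric(0))
  kmers <- substring(seq, 1:n, k:(n + k - 1))
  canon <- oracle_canonical(kmers)
  out <- unname(z[canon])
  out[is.na(out)] <- default
  out
}

random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE), collapse = ""),
    character(1))
}

# Small probe set with grid coordinates; intensities supplied or uniform.
toy_probeset <- function(seqs, intensity = NULL, variable_end = nchar(seqs[1])) {
  n <- length(seqs)
  side <- ceiling(sqrt(n))
  if (is.null(intensity)) intensity <- rep(100, n)
  probe_set(sprintf("p%03d", seq_len(n)), seqs, intensity,
            row = ((seq_len(n) - 1) %/% side) + 1,
            col = ((seq_len(n) - 1) %% side) + 1,
            variable_start = 0, variable_end = variable_end)
}

# Naive O(n^3) Ward agglomeration via the Lance-Williams update on squared
# Euclidean distances; heights on the ward.D2 scale (sqrt of the merge cost).
oracle_ward <- function(x, n_clusters) {
  n <- nrow(x)
  D2 <- as.matrix(stats::dist(x))^2
  active <- seq_len(n)
  members <- as.list(seq_len(n))
  sizes <- rep(1, n)
  heights <- numeric(n - 1)
  merges <- vector("list", n - 1)
  cost <- D2 / 2  # Ward merge cost for singletons: d^2 / 2
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); best_c <- Inf
    for (ai in seq_along(active)) for (bi in seq_along(active)) {
      if (bi <= ai) next
      i <- active[ai]; j <- active[bi]
      if (cost[i, j] < best_c - 1e-12) { best_c <- cost[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- sqrt(2 * best_c)
    merges[[step]] <- c(i, j)
    # Lance-Williams (Ward) update of merge costs against remaining clusters
    for (k in setdiff(active, c(i, j))) {
      ni <- sizes[i]; nj <- sizes[j]; nk <- sizes[k]
      new_c <- ((ni + nk) * cost[i, k] + (nj + nk) * cost[j, k] -
                  nk * cost[i, j]) / (ni + nj + nk)
      cost[i, k] <- cost[k, i] <- new_c
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
    if (length(active) == n_clusters && !exists("cut_members", inherits = FALSE))
      cut_members <- members[active]
  }
  labels <- integer(n)
  for (ci in seq_along(cut_members)) labels[cut_members[[ci]]] <- ci
  list(heights = heights, labels = labels)
}

# Adjusted Rand index, computed from the contingency table.
ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- ch2(as.vector(tab))
  sum_a <- ch2(rowSums(tab)); sum_b <- ch2(colSums(tab))
  n2 <- ch2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

CONSENSUS_OLIGO <- "GAGAAGTGAAAGTACTTTCACTTCTC"
SCRAMBLE_OLIGO <- "ATATTACGTCGCACTAGGATAGATCT"
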