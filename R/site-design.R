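#' Composition-preserving scramble of a sequence interval
#'
#' Permutes the bases inside a 0-based half-open interval of the sequence
#' (uniformly, seeded) and rejects any candidate for which some k-mer window
#' overlapping the interval still scores `z >= z_ceiling` — a naive single
#' permutation can recreate a high-affinity site by chance, so rejection
#' sampling is required for a scramble that truly eliminates predicted
#' binding. Bases outside the interval are untouched and the base multiset
#' inside the interval is preserved exactly.
#'
#' @param seq A single DNA sequence.
#' @param interval Length-2 vector `c(start, end)`, 0-based half-open,
#'   within `seq`.
#' @param table A [kmer_table()] used for the residual-affinity check.
#' @param z_ceiling Reject candidates with any overlapping window at
#'   `z >= z_ceiling` (default 2.0, the site-calling threshold).
#' @param rng_seed Seed making the draw reproducible.
#' @param max_tries Maximum permutations drawn before an exhaustion error
#'   (which reports the best residual z reached).
#' @param label Variant label.
#' @return An object of class `scramble_variant`: `label`, `sequence`,
#'   `scrambled_intervals`, `rng_seed`, `max_z_region` (residual max z over
#'   windows overlapping the scrambled interval) and `tries`.
#' @export
scramble_interval <- function(seq, interval, table, z_ceiling = 2.0,
                              rng_seed = NULL, max_tries = 1000L,
                              label = "scramble") {
  .scramble_multi(seq, list(interval), table, z_ceiling, rng_seed,
                  max_tries, label)
}

# Jointly scramble several intervals with one accept/reject loop.
.scramble_multi <- function(seq, intervals, table, z_ceiling, rng_seed,
                            max_tries, label) {
  stopifnot(length(seq) == 1L, max_tries >= 1L)
  L <- nchar(seq)
  for (iv in intervals) {
    if (length(iv) != 2L || iv[1L] < 0 || iv[2L] > L || iv[2L] <= iv[1L])
      stop("interval must be 0-based half-open within the sequence", call. = FALSE)
  }
  k <- table$k
  chars0 <- strsplit(toupper(seq), "")[[1L]]
  # window start range whose k-mers overlap any scrambled interval
  win_of <- function(iv) {
    lo <- max(0L, iv[1L] - k + 1L); hi <- min(L - k, iv[2L] - 1L)
    if (hi < lo) integer(0) else lo:hi
  }
  wins <- sort(unique(unlist(lapply(intervals, win_of))))
  region_max_z <- function(chars) {
    if (length(wins) == 0L) return(NA_real_)
    tr <- score_sequence(paste(chars, collapse = ""), table)
    max(tr$z[wins + 1L])
  }
  do_draw <- function() {
    chars <- chars0
    for (iv in intervals) {
      pos <- (iv[1L] + 1L):iv[2L]
      chars[pos] <- chars[pos][sample.int(length(pos))]
    }
    chars
  }
  .with_seed(rng_seed, {
    best_z <- Inf; best <- NULL; tries <- 0L
    repeat {
      tries <- tries + 1L
      cand <- do_draw()
      mz <- region_max_z(cand)
      if (is.na(mz) || mz < z_ceiling) { best <- cand; best_z <- mz; break }
      if (mz < best_z) { best_z <- mz; best <- cand }
      if (tries >= max_tries)
        stop("scramble exhausted after ", max_tries,
             " tries; best residual max z = ", signif(best_z, 4), call. = FALSE)
    }
    structure(list(label = label, sequence = paste(best, collapse = ""),
                   scrambled_intervals = intervals, rng_seed = rng_seed,
                   max_z_region = best_z, tries = tries),
              class = "scramble_variant")
  })
}

#' @export
print.scramble_variant <- function(x, ...) {
  ivs <- vapply(x$scrambled_intervals, function(iv) paste0("[", iv[1L], ",", iv[2L], ")"),
                character(1))
  cat("Scramble variant ", x$label, ": intervals ", paste(ivs, collapse = " "),
      ", residual max z = ", signif(x$max_z_region, 4),
      " (", x$tries, " tries)\n", sep = "")
  invisible(x)
}

#' Design a scrambled-site knockout panel for a promoter
#'
#' Given a promoter sequence with (at least) two predicted binding sites,
#' produces the four-variant panel: wild type (WT), first (strongest) site
#' scrambled (Ps1), second site scrambled (Ps2), and both scrambled (Ps1+2).
#' Sites are ranked by peak z (ties broken by leftmost start); each variant
#' is re-scored in full and summarised by the maximum linear affinity
#' (`2^z`) over the union of the site intervals. With fewer than two sites
#' the panel is restricted to WT plus the single-site variant (with a
#' message).
#'
#' @param x A `promoter_window` or a single DNA sequence.
#' @param table A [kmer_table()].
#' @param sites Optional precomputed `binding_sites` in sequence-relative
#'   coordinates; called from the sequence with `z_min`/`merge_gap` when
#'   omitted.
#' @param z_min,merge_gap Site-calling parameters (see [call_sites()]).
#' @param z_ceiling Residual-affinity ceiling for scrambles (defaults to
#'   `z_min`).
#' @param rng_seed Base seed; each variant derives its own offset seed.
#' @param max_tries Per-variant rejection budget.
#' @return An object of class `knockout_panel`: `variants` (named list of
#'   `scramble_variant`, WT included), `tracks` (re-scored
#'   `affinity_track`s), `sites`, and `summary` (data frame of per-variant
#'   max linear affinity and max z over the site region).
#' @export
design_knockout_panel <- function(x, table, sites = NULL, z_min = 2.0,
                                  merge_gap = 5L, z_ceiling = z_min,
                                  rng_seed = 1L, max_tries = 1000L) {
  seq <- if (inherits(x, "promoter_window")) x$sequence else x
  stopifnot(is.character(seq), length(seq) == 1L)
  track <- score_sequence(seq, table)
  if (is.null(sites)) sites <- call_sites(track, z_min = z_min, merge_gap = merge_gap)
  if (nrow(sites) == 0L)
    stop("no binding sites at z_min = ", z_min, "; nothing to scramble", call. = FALSE)
  ord <- order(-sites$peak_z, sites$start)
  sites <- sites[ord, , drop = FALSE]
  iv <- function(i) c(sites$start[i], sites$end[i])
  k <- table$k

  wt <- structure(list(label = "WT", sequence = toupper(seq),
                       scrambled_intervals = list(), rng_seed = rng_seed,
                       max_z_region = max(sites$peak_z), tries = 0L),
                  class = "scramble_variant")
  variants <- list(WT = wt)
  if (nrow(sites) >= 2L) {
    variants$Ps1 <- .scramble_multi(seq, list(iv(1L)), table, z_ceiling,
                                    rng_seed + 1L, max_tries, "Ps1")
    variants$Ps2 <- .scramble_multi(seq, list(iv(2L)), table, z_ceiling,
                                    rng_seed + 2L, max_tries, "Ps2")
    variants$`Ps1+2` <- .scramble_multi(seq, list(iv(1L), iv(2L)), table,
                                        z_ceiling, rng_seed + 3L, max_tries, "Ps1+2")
    region <- list(iv(1L), iv(2L))
  } else {
    message("design_knockout_panel: < 2 sites called; panel restricted to WT + Ps1")
    variants$Ps1 <- .scramble_multi(seq, list(iv(1L)), table, z_ceiling,
                                    rng_seed + 1L, max_tries, "Ps1")
    region <- list(iv(1L))
  }

  tracks <- lapply(variants, function(v) score_sequence(v$sequence, table))
  region_wins <- sort(unique(unlist(lapply(region, function(r) {
    lo <- max(0L, r[1L] - k + 1L); hi <- min(nchar(seq) - k, r[2L] - 1L)
    if (hi < lo) integer(0) else lo:hi
  }))))
  summ <- do.call(rbind, lapply(names(variants), function(nm) {
    z <- tracks[[nm]]$z[region_wins + 1L]
    data.frame(label = nm, max_z = max(z), max_linear = max(2^z))
  }))
  rownames(summ) <- NULL
  structure(list(variants = variants, tracks = tracks, sites = sites,
                 summary = summ),
            class = "knockout_panel")
}

#' @export
print.knockout_panel <- function(x, ...) {
  cat("Scrambled-site knockout panel (", nrow(x$sites), " sites)\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a knockout panel
#'
#' Emits the variants as multi-FASTA (labels in headers) and, optionally, a
#' TSV of per-variant max affinity scores.
#'
#' @param panel A `knockout_panel`.
#' @param fasta Output FASTA path.
#' @param scores Optional TSV path for the summary table.
#' @return `fasta`, invisibly.
#' @export
write_panel <- function(panel, fasta, scores = NULL) {
  stopifnot(inherits(panel, "knockout_panel"))
  seqs <- Biostrings::DNAStringSet(vapply(panel$variants, `[[`, "", "sequence"))
  names(seqs) <- names(panel$variants)
  Biostrings::writeXStringSet(seqs, fasta)
  if (!is.null(scores))
    utils::write.table(panel$summary, scores, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(fasta)
}

#' Base composition of a sequence
#'
#' @param seq A single DNA sequence.
#' @return Named integer vector of A/C/G/T counts.
#' @export
base_composition <- function(seq) {
  .check_alphabet(seq)
  chars <- strsplit(toupper(seq), "")[[1L]]
  vapply(.DNA_BASES, function(b) sum(chars == b), integer(1))
}

#' Molecular weight of a synthetic DNA oligonucleotide
#'
#' Average-mass molecular weight from per-base monophosphate residue masses
#' (A 313.21, C 289.18, G 329.21, T 304.2 Da) minus 61.96 Da per strand for
#' the missing terminal phosphate (5'-OH synthetic oligo convention). For a
#' duplex, the complementary strand is added.
#'
#' @param seq A single DNA sequence (one strand).
#' @param double_stranded Include the complementary strand (default `TRUE`).
#' @return Molecular weight in Daltons.
#' @examples
#' oligo_mw("GAGAAGTGAAAGTACTTTCACTTCTC") / 1000  # ~15.9 kDa duplex
#' @export
oligo_mw <- function(seq, double_stranded = TRUE) {
  mw1 <- function(s) {
    n <- base_composition(s)
    313.21 * n[["A"]] + 289.18 * n[["C"]] + 329.21 * n[["G"]] + 304.2 * n[["T"]] - 61.96
  }
  mw <- mw1(seq)
  if (double_stranded) mw <- mw + mw1(revcomp(seq))
  mw
}
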