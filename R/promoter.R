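#' Coordinate conversion helpers
#'
#' Internally every interval is 0-based half-open (the native bedGraph/BED
#' convention); genome browsers and the literature print 1-based inclusive
#' coordinates. These converters make the two conventions explicit.
#' `interval_width()` returns the number of covered bases under either
#' convention.
#'
#' @param start1,end1 1-based inclusive interval.
#' @param start0,end0 0-based half-open interval.
#' @param style Which convention `start`/`end` are in.
#' @return A list with `start` and `end` in the other convention, or an
#'   integer width.
#' @examples
#' interval_width(89301927, 89301996, style = "one_based")  # 70 bp
#' to_zero_based(89300997, 89302495)
#' @name coordinates
NULL

#' @rdname coordinates
#' @export
to_zero_based <- function(start1, end1) {
  stopifnot(all(end1 >= start1), all(start1 >= 1))
  list(start = start1 - 1, end = end1)
}

#' @rdname coordinates
#' @export
to_one_based <- function(start0, end0) {
  stopifnot(all(end0 > start0), all(start0 >= 0))
  list(start = start0 + 1, end = end0)
}

#' @rdname coordinates
#' @param start,end Interval in the convention named by `style`.
#' @export
interval_width <- function(start, end, style = c("zero_based", "one_based")) {
  style <- match.arg(style)
  if (style == "one_based") end - start + 1 else end - start
}

#' Read a TSS table
#'
#' Accepts either BED (>= 4 columns, no header: `chrom start end name
#' [score strand]`; the TSS is `start + 1` in 1-based coordinates) or a
#' header TSV with columns `gene_id chrom tss strand` (`tss` 1-based).
#'
#' @param path File path.
#' @return A data frame with columns `gene_id`, `chrom`, `tss` (1-based),
#'   `strand`.
#' @export
read_tss_table <- function(path) {
  first <- readLines(path, n = 1L)
  f <- strsplit(first, "\t", fixed = TRUE)[[1L]]
  is_bed <- length(f) >= 4L && !anyNA(suppressWarnings(as.numeric(f[2:3])))
  if (is_bed) {
    df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    strand <- if (ncol(df) >= 6L) df[[6L]] else "+"
    out <- data.frame(gene_id = df[[4L]], chrom = df[[1L]],
                      tss = df[[2L]] + 1L, strand = strand,
                      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "tss", "strand")
    if (!all(need %in% names(df)))
      stop("TSS table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
    out <- df[need]
  }
  if (!all(out$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  out
}

#' Extract strand-aware promoter windows
#'
#' For each TSS, returns the window spanning `upstream` bases upstream and
#' `downstream` bases downstream of the transcription start site, adjusted
#' for gene orientation. With a 1-based TSS `t`, the 0-based half-open
#' genomic interval is `[t - 1 - upstream, t - 1 + downstream)` on the
#' `+` strand and `[t - downstream, t + upstream)` on the `-` strand; the
#' returned sequence is read in gene orientation (reverse complemented for
#' `-`), so the TSS sits at offset `upstream` within it in both cases.
#' Windows running off a contig are truncated and flagged with a warning.
#'
#' @param genome A `Biostrings::DNAStringSet`, a named character vector of
#'   contig sequences, or a FASTA path.
#' @param tss A data frame as returned by [read_tss_table()] (columns
#'   `gene_id`, `chrom`, `tss`, `strand`), or a path to one.
#' @param upstream,downstream Window extent in bases (defaults 1000 and 500).
#' @return A list of `promoter_window` objects: `gene_id`, `chrom`,
#'   `strand`, `tss` (1-based), `start`/`end` (0-based half-open genomic),
#'   `sequence`, `truncated`.
#' @export
extract_promoters <- function(genome, tss, upstream = 1000L, downstream = 500L) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (inherits(genome, "DNAStringSet")) {
    contigs <- as.character(genome)
    names(contigs) <- sub("\\s.*$", "", names(genome))
  } else contigs <- genome
  if (is.character(tss) && length(tss) == 1L) tss <- read_tss_table(tss)
  stopifnot(upstream >= 0, downstream >= 0, upstream + downstream > 0)

  out <- lapply(seq_len(nrow(tss)), function(i) {
    chrom <- tss$chrom[i]; t1 <- tss$tss[i]; strand <- tss$strand[i]
    if (!chrom %in% names(contigs))
      stop("unknown chrom: ", chrom, call. = FALSE)
    L <- nchar(contigs[[chrom]])
    if (strand == "+") {
      start0 <- t1 - 1L - upstream; end0 <- t1 - 1L + downstream
    } else if (strand == "-") {
      start0 <- t1 - downstream; end0 <- t1 + upstream
    } else stop("strand must be '+' or '-'", call. = FALSE)
    truncated <- FALSE
    if (start0 < 0L || end0 > L) {
      warning("promoter window for ", tss$gene_id[i],
              " exceeds contig bounds; truncated", call. = FALSE)
      start0 <- max(start0, 0L); end0 <- min(end0, L)
      truncated <- TRUE
    }
    seq <- substr(contigs[[chrom]], start0 + 1L, end0)
    if (strand == "-") seq <- revcomp(seq)
    structure(list(gene_id = tss$gene_id[i], chrom = chrom, strand = strand,
                   tss = t1, start = start0, end = end0,
                   sequence = toupper(seq), truncated = truncated),
              class = "promoter_window")
  })
  names(out) <- tss$gene_id
  out
}

#' @export
print.promoter_window <- function(x, ...) {
  cat("Promoter window ", x$gene_id, " (", x$chrom, ":", x$start, "-", x$end,
      " 0-based, strand ", x$strand, ")",
      if (x$truncated) " [truncated]", "\n", sep = "")
  cat("  ", nchar(x$sequence), " nt, TSS at 1-based ", x$tss, "\n", sep = "")
  invisible(x)
}

#' Per-position predicted affinity track of a sequence
#'
#' Slides a window of the table's word length along the sequence and assigns
#' each k-mer's z-score to the k-mer's start offset, giving
#' `length(seq) - k + 1` values. Windows containing `N` (and, for partial
#' tables, missing k-mers) score the missing-k-mer default. Because the
#' table is canonical the scores are inherently strand-collapsed: scoring
#' the reverse complement gives the mirror-image track.
#'
#' @param seq A single DNA sequence (`ACGTN`).
#' @param table A [kmer_table()].
#' @param default Score for N-containing windows / missing k-mers.
#' @param chrom,offset0 Optional genomic anchoring: contig name and the
#'   0-based genomic position of `seq`'s first base.
#' @return An object of class `affinity_track`: `chrom`, `offsets` (0-based
#'   start positions), `z`, `linear` (`2^z`), `k`. A sequence shorter than
#'   `k` yields an empty track (with a message, not an error).
#' @export
score_sequence <- function(seq, table, default = table$default,
                           chrom = NA_character_, offset0 = 0L) {
  stopifnot(inherits(table, "kmer_table"), length(seq) == 1L)
  .check_alphabet(seq)
  k <- table$k
  L <- nchar(seq)
  if (L < k) {
    message("score_sequence: sequence shorter than k; empty track")
    return(affinity_track(chrom, integer(0), numeric(0), k))
  }
  idx <- .kmer_indices(.seq_codes(toupper(seq)), k)$canonical
  z <- .z_lookup(table)[idx + 1L]
  z[is.na(idx)] <- default            # windows containing N
  if (anyNA(z)) {
    if (table$complete)
      stop("missing k-mer in complete table while scoring", call. = FALSE)
    z[is.na(z)] <- default
  }
  affinity_track(chrom, offset0 + 0:(L - k), z, k)
}

#' Affinity track container
#'
#' @param chrom Contig name (may be `NA` for sequence-relative tracks).
#' @param offsets 0-based start positions of each scored k-mer window.
#' @param z Per-position z-scores.
#' @param k Word length of the underlying table.
#' @return An object of class `affinity_track` with `linear = 2^z`.
#' @export
affinity_track <- function(chrom, offsets, z, k) {
  stopifnot(length(offsets) == length(z))
  structure(list(chrom = chrom, offsets = as.integer(offsets),
                 z = as.numeric(z), linear = 2^as.numeric(z),
                 k = as.integer(k)),
            class = "affinity_track")
}

#' @export
print.affinity_track <- function(x, ...) {
  cat("Affinity track", if (!is.na(x$chrom)) paste0(" (", x$chrom, ")"),
      ": ", length(x$z), " positions (k = ", x$k, ")\n", sep = "")
  if (length(x$z)) {
    i <- which.max(x$z)
    cat("  z in [", signif(min(x$z), 3), ", ", signif(max(x$z), 3),
        "], peak at offset ", x$offsets[i], "\n", sep = "")
  }
  invisible(x)
}

#' @export
plot.affinity_track <- function(x, scale = c("linear", "z"), ...) {
  scale <- match.arg(scale)
  y <- if (scale == "linear") x$linear else x$z
  graphics::plot(x$offsets, y, type = "h", xlab = "Offset (0-based)",
                 ylab = if (scale == "linear") "Affinity (2^z)" else "z-score",
                 ...)
  invisible(x)
}

#' Scan a promoter window
#'
#' Scores the window's sequence (gene orientation) and anchors the track to
#' genomic coordinates: on the `-` strand the sequence-relative track is
#' mirrored back so offsets ascend along the genome. Strand symmetry of the
#' canonical table makes the values themselves orientation-free.
#'
#' @param window A `promoter_window` from [extract_promoters()].
#' @param table A [kmer_table()].
#' @param coords `"genomic"` (default) or `"window"` (sequence-relative).
#' @param default Missing-k-mer default.
#' @return An `affinity_track`.
#' @export
scan_promoter <- function(window, table, coords = c("genomic", "window"),
                          default = table$default) {
  stopifnot(inherits(window, "promoter_window"))
  coords <- match.arg(coords)
  tr <- score_sequence(window$sequence, table, default = default)
  if (coords == "window") return(tr)
  k <- table$k
  if (window$strand == "+") {
    offs <- window$start + tr$offsets
    z <- tr$z
  } else {
    offs <- window$end - tr$offsets - k
    ord <- order(offs)
    offs <- offs[ord]; z <- tr$z[ord]
  }
  affinity_track(window$chrom, offs, z, k)
}

#' Write an affinity track as bedGraph
#'
#' UCSC bedGraph: 0-based half-open records `chrom start end value`, one
#' scored position covering one base, with runs of adjacent equal values
#' merged into single records. Values are written in full precision so a
#' read back with [read_bedgraph()] is exact.
#'
#' @param track An `affinity_track` with genomic anchoring (non-`NA` chrom)
#'   and monotone increasing offsets.
#' @param path Output path.
#' @param scale `"linear"` (`2^z`, the visualization scale) or `"z"`.
#' @param name Optional track name; when given, a `track type=bedGraph`
#'   header line is emitted.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, scale = c("linear", "z"), name = NULL) {
  stopifnot(inherits(track, "affinity_track"))
  scale <- match.arg(scale)
  if (is.unsorted(track$offsets, strictly = TRUE))
    stop("track offsets must be strictly increasing", call. = FALSE)
  if (is.na(track$chrom)) stop("track has no genomic anchoring (chrom is NA)", call. = FALSE)
  v <- if (scale == "linear") track$linear else track$z
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(name))
    writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  if (length(v)) {
    # merge runs of adjacent (offset step 1) equal values
    new_rec <- c(TRUE, diff(track$offsets) != 1L | diff(v) != 0)
    grp <- cumsum(new_rec)
    start <- tapply(track$offsets, grp, function(o) o[1L])
    end <- tapply(track$offsets, grp, function(o) o[length(o)] + 1L)
    val <- v[new_rec]
    writeLines(sprintf("%s\t%d\t%d\t%.17g", track$chrom, start, end, val), con)
  }
  invisible(path)
}

#' Call high-affinity binding sites from a track
#'
#' Maximal runs of positions with `z >= z_min`; runs whose start offsets are
#' separated by less than `merge_gap` bases are merged. A site's interval
#' covers every base of its qualifying k-mer windows (`end = last offset +
#' k`); since a window covers `k` bases, runs whose covered intervals still
#' overlap are merged in a second pass, so returned sites are always
#' base-disjoint. Each site reports its peak z-score and peak position
#' (leftmost on ties). An empty result is not an error.
#'
#' @param track An `affinity_track`.
#' @param z_min Calling threshold (default 2.0: about the top 2.3% of
#'   k-mers under normality of the z distribution).
#' @param merge_gap Merge distance in bases (default 5).
#' @return A data frame of class `binding_sites`: `chrom`, `start`, `end`
#'   (0-based half-open), `peak_z`, `peak_pos`, sorted by `start`.
#' @export
call_sites <- function(track, z_min = 2.0, merge_gap = 5L) {
  stopifnot(inherits(track, "affinity_track"))
  if (length(track$z) == 0L) stop("track is empty", call. = FALSE)
  q <- which(track$z >= z_min)
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      peak_z = numeric(0), peak_pos = integer(0))
  class(empty) <- c("binding_sites", "data.frame")
  if (length(q) == 0L) return(empty)
  offs <- track$offsets[q]
  # first pass: gap rule on start offsets; second: merge overlapping extents
  grp <- cumsum(c(TRUE, diff(offs) >= merge_gap & diff(offs) >= track$k))
  sites <- do.call(rbind, lapply(split(seq_along(q), grp), function(ii) {
    o <- offs[ii]; z <- track$z[q[ii]]
    pk <- which.max(z)
    data.frame(chrom = track$chrom, start = min(o), end = max(o) + track$k,
               peak_z = z[pk], peak_pos = o[pk])
  }))
  sites <- sites[order(sites$start), , drop = FALSE]
  rownames(sites) <- NULL
  class(sites) <- c("binding_sites", "data.frame")
  sites
}
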