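#' Coverage track
#'
#' Sorted, non-overlapping 0-based half-open records of per-base signal
#' (e.g. ChIP-seq fragment coverage).
#'
#' @param records Data frame with columns `chrom`, `start`, `end`, `value`.
#' @param source Free-text label for provenance.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(records, source = "") {
  need <- c("chrom", "start", "end", "value")
  stopifnot(all(need %in% names(records)))
  records <- records[need]
  if (nrow(records)) {
    if (any(records$start < 0)) stop("negative coordinates", call. = FALSE)
    if (any(records$end <= records$start)) stop("records must have end > start", call. = FALSE)
    if (any(!is.finite(records$value))) stop("values must be finite", call. = FALSE)
    records <- records[order(records$chrom, records$start), , drop = FALSE]
    by_chrom <- split(seq_len(nrow(records)), records$chrom)
    for (ii in by_chrom) {
      if (length(ii) > 1L && any(records$start[ii][-1L] < records$end[ii][-length(ii)]))
        stop("overlapping records on ", records$chrom[ii[1L]], call. = FALSE)
    }
    rownames(records) <- NULL
  }
  structure(list(records = records, source = source), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("Coverage track (", nrow(x$records), " records",
      if (nzchar(x$source)) paste0(", source: ", x$source), ")\n", sep = "")
  if (nrow(x$records)) print(utils::head(x$records, 4L))
  invisible(x)
}

#' Read a bedGraph file
#'
#' UCSC bedGraph dialect: whitespace-separated `chrom start end value`
#' records, 0-based half-open; `track`, `browser` and `#` lines are
#' ignored. Records are validated (sorted on read; overlapping records and
#' negative coordinates are errors). An empty file yields an empty track.
#'
#' @param path File path.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(track|browser|#|$)", lines)]
  if (length(lines) == 0L)
    return(coverage_track(data.frame(chrom = character(0), start = integer(0),
                                     end = integer(0), value = numeric(0)),
                          source = path))
  f <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(f) < 4L)) stop("bedGraph records need 4 fields", call. = FALSE)
  m <- do.call(rbind, lapply(f, `[`, 1:4))
  rec <- data.frame(chrom = m[, 1L],
                    start = as.numeric(m[, 2L]), end = as.numeric(m[, 3L]),
                    value = as.numeric(m[, 4L]), stringsAsFactors = FALSE)
  if (anyNA(rec$start) || anyNA(rec$end) || anyNA(rec$value))
    stop("non-numeric bedGraph fields", call. = FALSE)
  coverage_track(rec, source = path)
}

#' Write a coverage track as bedGraph
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @param name Optional track name (emits a `track type=bedGraph` header).
#' @return `path`, invisibly.
#' @export
write_coverage <- function(track, path, name = NULL) {
  stopifnot(inherits(track, "coverage_track"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(name))
    writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  r <- track$records
  if (nrow(r))
    writeLines(sprintf("%s\t%d\t%d\t%.17g", r$chrom, as.integer(r$start),
                       as.integer(r$end), r$value), con)
  invisible(path)
}

# Per-base expansion of a coverage track over [from, to) on one chrom.
.expand_coverage <- function(track, chrom, from, to) {
  out <- numeric(to - from)
  r <- track$records
  r <- r[r$chrom == chrom & r$end > from & r$start < to, , drop = FALSE]
  for (i in seq_len(nrow(r))) {
    a <- max(r$start[i], from) - from + 1L
    b <- min(r$end[i], to) - from
    out[a:b] <- r$value[i]
  }
  out
}

#' Correlation between predicted affinity and ChIP-seq coverage
#'
#' Spearman correlation between the per-base predicted linear affinities
#' and the per-base coverage within a promoter window, with a permutation
#' p-value from circular shifts of the predicted track. Circular shifting
#' preserves the autocorrelation structure of the affinity profile (the
#' conservative null for windowed correlation, unlike base-level
#' shuffling); the p-value is `(1 + #\{shifted rho >= observed\}) / (1 +
#' n_perm)`, bounded in (0, 1].
#'
#' @param predicted A genomically anchored `affinity_track`.
#' @param coverage A [coverage_track()].
#' @param window A `promoter_window` (defines the genomic interval; its
#'   chrom must match the tracks).
#' @param n_perm Number of circular shifts (>= 100).
#' @param rng_seed Seed for the shift draws.
#' @return A list with `rho`, `p_perm`, `n` (positions used) and `n_perm`.
#' @export
window_correlation <- function(predicted, coverage, window, n_perm = 1000L,
                               rng_seed = NULL) {
  stopifnot(inherits(predicted, "affinity_track"),
            inherits(coverage, "coverage_track"),
            inherits(window, "promoter_window"))
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  in_win <- predicted$offsets >= window$start & predicted$offsets < window$end
  x <- predicted$linear[in_win]
  offs <- predicted$offsets[in_win]
  if (length(x) < 3L) stop("predicted track does not cover the window", call. = FALSE)
  ycov <- .expand_coverage(coverage, window$chrom, window$start, window$end)
  y <- ycov[offs - window$start + 1L]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant track: Spearman rho undefined", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  n <- length(rx)
  .with_seed(rng_seed, {
    shifts <- sample.int(n - 1L, n_perm, replace = TRUE)
    perm <- vapply(shifts, function(s) {
      stats::cor(rx[c((s + 1L):n, 1:s)], ry)
    }, numeric(1))
    list(rho = rho, p_perm = (1 + sum(perm >= rho)) / (1 + n_perm),
         n = n, n_perm = n_perm)
  })
}

#' Fraction of predicted sites overlapping observed peaks
#'
#' A predicted site counts as overlapped when its peak position falls
#' inside any peak interval (0-based half-open containment).
#'
#' @param sites A `binding_sites` data frame ([call_sites()]).
#' @param peaks Data frame (or 2-column matrix) of peak intervals with
#'   columns `start`, `end`, 0-based half-open, same chrom as the sites.
#' @return Fraction in \[0, 1\].
#' @export
site_overlap <- function(sites, peaks) {
  if (nrow(sites) == 0L)
    stop("undefined fraction: empty site list", call. = FALSE)
  peaks <- as.data.frame(peaks)
  if (!all(c("start", "end") %in% names(peaks)))
    names(peaks)[1:2] <- c("start", "end")
  hit <- vapply(sites$peak_pos, function(p)
    any(p >= peaks$start & p < peaks$end), logical(1))
  mean(hit)
}
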