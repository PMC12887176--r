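#' K-mer affinity table
#'
#' The core predictive model: a lookup from canonical k-mer to a standardized
#' binding affinity z-score (optionally with a rank-based enrichment E-score
#' per entry). Keys are reverse-complement-canonical (see [canonical_kmer()]),
#' which collapses double-stranded measurements and makes every lookup
#' strand symmetric.
#'
#' @param z Named numeric vector of z-scores; names are k-mers (need not be
#'   canonical — they are canonicalized, and a k-mer listed together with its
#'   reverse complement at the same score collapses to one entry; conflicting
#'   scores raise an error).
#' @param k Word length; inferred from the names if missing.
#' @param escore Optional named numeric vector of E-scores in \[-0.5, 0.5\],
#'   same keys as `z`.
#' @param complete Logical: does the table cover every canonical k-mer? If
#'   `NA` (default) it is set by comparing the entry count against `4^k / 2`.
#'   Complete tables raise an error on a missing key; incomplete tables fall
#'   back to `default`.
#' @param default Affinity returned for k-mers absent from an incomplete
#'   table (and for windows containing N when scanning).
#' @return An object of class `kmer_table`.
#' @seealso [read_kmer_table()], [kmer_affinity()], [score_sequence()]
#' @export
kmer_table <- function(z, k = NULL, escore = NULL, complete = NA, default = 0) {
  if (is.null(names(z)) || any(!nzchar(names(z))))
    stop("z must be a named numeric vector keyed by k-mer", call. = FALSE)
  keys <- toupper(names(z))
  lens <- nchar(keys)
  if (length(unique(lens)) != 1L)
    stop("format error: inconsistent k-mer lengths (", paste(unique(lens), collapse = ", "),
         ")", call. = FALSE)
  if (is.null(k)) k <- lens[1L] else if (k != lens[1L])
    stop("format error: k-mers have length ", lens[1L], ", expected k = ", k, call. = FALSE)
  .check_alphabet(keys, allow_n = FALSE, what = "table key")

  canon <- canonical_kmer(keys)
  es <- if (!is.null(escore)) unname(escore[names(z)]) else NULL
  dup <- duplicated(canon)
  if (any(dup)) {
    first <- match(canon, canon)
    conflict <- abs(z - z[first]) > 1e-9
    if (!is.null(es)) conflict <- conflict | (abs(es - es[first]) > 1e-9)
    if (any(conflict))
      stop("conflict error: canonical key(s) ",
           paste(unique(canon[conflict]), collapse = ", "),
           " listed with differing scores", call. = FALSE)
    z <- z[!dup]; canon <- canon[!dup]
    if (!is.null(es)) es <- es[!dup]
  }
  zv <- as.numeric(z)
  names(zv) <- canon
  ord <- order(canon)
  zv <- zv[ord]
  if (!is.null(es)) { es <- as.numeric(es)[ord]; names(es) <- names(zv) }
  n_full <- 4^k / 2
  if (is.na(complete)) complete <- length(zv) == n_full
  structure(
    list(k = as.integer(k), z = zv, escore = es,
         complete = complete, default = default,
         index = .kmer_to_index(names(zv))),
    class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat("K-mer affinity table (k = ", x$k, ")\n", sep = "")
  cat("  entries : ", length(x$z),
      if (x$complete) " (complete)" else " (partial)", "\n", sep = "")
  cat("  z range : [", signif(min(x$z), 4), ", ", signif(max(x$z), 4), "]\n", sep = "")
  top <- utils::head(sort(x$z, decreasing = TRUE), 5L)
  cat("  top     : ", paste0(names(top), " (", signif(top, 3), ")", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Read a UniProbe-style k-mer score table
#'
#' Tab-separated text with a k-mer column and one or two numeric score
#' columns: `kmer<TAB>zscore` or `kmer<TAB>escore<TAB>zscore` (auto-detected
#' from the column count). Lines starting with `#` are comments; a header
#' line is optional and detected by a non-ACGT first field. A k-mer and its
#' reverse complement listed with equal scores collapse to one entry;
#' conflicting scores are an error, never silently resolved.
#'
#' @param path Path to the table.
#' @param k Expected word length (checked against the file if given).
#' @param default Passed to [kmer_table()].
#' @return A [kmer_table()].
#' @export
read_kmer_table <- function(path, k = NULL, default = 0) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("format error: no data rows in ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (grepl("[^ACGTacgt]", fields[[1L]][1L])) {  # header line
    fields <- fields[-1L]; nf <- nf[-1L]
    if (length(fields) == 0L) stop("format error: header only in ", path, call. = FALSE)
  }
  if (length(unique(nf)) != 1L || !nf[1L] %in% c(2L, 3L))
    stop("format error: expected 2 or 3 tab-separated columns, got ",
         paste(unique(nf), collapse = "/"), call. = FALSE)
  m <- do.call(rbind, fields)
  kmers <- m[, 1L]
  if (nf[1L] == 2L) {
    z <- as.numeric(m[, 2L]); es <- NULL
  } else {
    es <- as.numeric(m[, 2L]); z <- as.numeric(m[, 3L])
  }
  if (anyNA(z) || (!is.null(es) && anyNA(es)))
    stop("format error: non-numeric score values in ", path, call. = FALSE)
  names(z) <- kmers
  if (!is.null(es)) names(es) <- kmers
  kmer_table(z, k = k, escore = es, default = default)
}

#' Write a k-mer affinity table
#'
#' Emits the UniProbe-style dialect read by [read_kmer_table()]:
#' `kmer<TAB>zscore`, or `kmer<TAB>escore<TAB>zscore` when E-scores are
#' present.
#'
#' @param table A [kmer_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kmer_table <- function(table, path) {
  stopifnot(inherits(table, "kmer_table"))
  if (is.null(table$escore)) {
    lines <- paste(names(table$z), sprintf("%.17g", table$z), sep = "\t")
  } else {
    lines <- paste(names(table$z), sprintf("%.17g", table$escore),
                   sprintf("%.17g", table$z), sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Look up binding affinity z-scores
#'
#' Strand-symmetric lookup: `kmer_affinity(t, x) == kmer_affinity(t, revcomp(x))`
#' by construction, since the query is canonicalized first.
#'
#' @param table A [kmer_table()].
#' @param kmer Character vector of query k-mers of length `table$k`.
#' @param default Value for keys absent from an incomplete table; defaults to
#'   the table's own `default`. A missing key in a complete table is an error.
#' @return Numeric vector of z-scores.
#' @export
kmer_affinity <- function(table, kmer, default = table$default) {
  stopifnot(inherits(table, "kmer_table"))
  if (length(kmer) == 0L) return(numeric(0))
  if (any(nchar(kmer) != table$k))
    stop("query k-mer length must equal table k = ", table$k, call. = FALSE)
  canon <- canonical_kmer(kmer)
  out <- unname(table$z[canon])
  miss <- is.na(out) & !(canon %in% names(table$z))
  if (any(miss)) {
    if (table$complete)
      stop("missing k-mer in complete table: ", paste(unique(canon[miss]), collapse = ", "),
           call. = FALSE)
    out[miss] <- default
  }
  out
}

#' Linear affinity scale
#'
#' Maps z-scores to a linear relative-affinity scale via the inverse-log2
#' transform `2^z`, the scale used for track visualization. Strictly
#' increasing, with `z = 0` mapping to 1.
#'
#' @param z Numeric vector of finite z-scores.
#' @return `2^z`.
#' @export
z_to_linear <- function(z) {
  if (length(z) && any(!is.finite(z)))
    stop("z must be finite", call. = FALSE)
  2^z
}

#' Energy-normalized logo matrix
#'
#' Converts a per-position, per-base energy matrix (log relative intensity
#' units, reference base at 0) into column-stochastic base probabilities by a
#' per-column Boltzmann softmax, with letter heights given by the information
#' content of each column in bits. This is the matrix behind an
#' energy-normalized sequence logo; rendering is out of scope, but the matrix
#' can be exported with [write_logo_matrix()].
#'
#' @param weights 4 x width finite numeric matrix of energies; rows in order
#'   A, C, G, T (row names, if present, must match).
#' @return An object of class `energy_logo` with elements `width`,
#'   `probs` (4 x width, columns sum to 1) and `heights` (bits, >= 0).
#' @export
energy_logo <- function(weights) {
  weights <- as.matrix(weights)
  if (ncol(weights) == 0L) stop("logo width must be >= 1", call. = FALSE)
  if (nrow(weights) != 4L) stop("weights must have 4 rows (A, C, G, T)", call. = FALSE)
  if (any(!is.finite(weights))) stop("weights must be finite", call. = FALSE)
  if (!is.null(rownames(weights)) && !identical(rownames(weights), .DNA_BASES))
    weights <- weights[.DNA_BASES, , drop = FALSE]
  probs <- apply(weights, 2L, function(w) {
    e <- exp(w - max(w))  # shift for numerical stability; softmax unchanged
    e / sum(e)
  })
  plogp <- ifelse(probs > 0, probs * log2(probs), 0)
  heights <- pmax(2 + colSums(plogp), 0)
  rownames(probs) <- .DNA_BASES
  structure(list(width = ncol(weights), probs = probs, heights = heights),
            class = "energy_logo")
}

#' @export
print.energy_logo <- function(x, ...) {
  cat("Energy-normalized logo matrix, width ", x$width, "\n", sep = "")
  cons <- paste(.DNA_BASES[apply(x$probs, 2L, which.max)], collapse = "")
  cat("  consensus: ", cons, "\n", sep = "")
  cat("  IC (bits): ", paste(sprintf("%.2f", x$heights), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
plot.energy_logo <- function(x, main = "Energy-normalized logo", ...) {
  h <- x$probs * rep(x$heights, each = 4L)
  graphics::barplot(h, names.arg = seq_len(x$width),
                    col = c("#109648", "#255C99", "#F7B32B", "#D62839"),
                    border = NA, xlab = "Position", ylab = "Information (bits)",
                    main = main, ylim = c(0, 2), ...)
  graphics::legend("topright", legend = .DNA_BASES, bty = "n",
                   fill = c("#109648", "#255C99", "#F7B32B", "#D62839"), border = NA)
  invisible(x)
}

#' Export a logo matrix as TSV
#'
#' Rows A/C/G/T, columns 1..width, probabilities; a final row `height` holds
#' the per-column information content in bits.
#'
#' @param logo An [energy_logo()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_logo_matrix <- function(logo, path) {
  stopifnot(inherits(logo, "energy_logo"))
  m <- rbind(logo$probs, height = logo$heights)
  df <- data.frame(base = rownames(m), m, check.names = FALSE)
  colnames(df) <- c("base", seq_len(logo$width))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Dense z lookup by k-mer index (length 4^k, canonical slots filled).
.z_lookup <- function(table) {
  v <- rep(NA_real_, 4^table$k)
  v[table$index + 1L] <- unname(table$z)
  v
}
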