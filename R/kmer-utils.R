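# Internal DNA encoding. A=0 < C=1 < G=2 < T=3 so that the numeric k-mer
# index order equals lexicographic order on the strings; N maps to NA and
# poisons any window that contains it.
.DNA_BASES <- c("A", "C", "G", "T")

.BASE_CODE <- local({
  v <- rep(NA_integer_, 256L)
  v[utf8ToInt("A")] <- 0L; v[utf8ToInt("a")] <- 0L
  v[utf8ToInt("C")] <- 1L; v[utf8ToInt("c")] <- 1L
  v[utf8ToInt("G")] <- 2L; v[utf8ToInt("g")] <- 2L
  v[utf8ToInt("T")] <- 3L; v[utf8ToInt("t")] <- 3L
  v
})

.check_alphabet <- function(seq, allow_n = TRUE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTNacgtn]*$" else "^[ACGTacgt]*$"
  bad <- !grepl(pat, seq)
  if (any(bad)) {
    stop("invalid alphabet in ", what, ": ", sQuote(substr(seq[bad][1L], 1L, 30L)),
         " (allowed: ACGT", if (allow_n) "N", ", case-insensitive)", call. = FALSE)
  }
  invisible(seq)
}

.seq_codes <- function(seq) .BASE_CODE[utf8ToInt(seq)]

#' Reverse complement of DNA sequences
#'
#' Vectorised over its input; always returns uppercase. `N` is its own
#' complement. The operation is an involution: `revcomp(revcomp(x)) == x`.
#'
#' @param seq Character vector of DNA sequences (alphabet `ACGTN`,
#'   case-insensitive). Empty strings are allowed and map to themselves.
#' @return Character vector of reverse complements, uppercase.
#' @examples
#' revcomp("GAAA")
#' revcomp("GAGAAGTGAAAGTACTTTCACTTCTC")  # a palindromic duplex: its own revcomp
#' @export
revcomp <- function(seq) {
  if (length(seq) == 0L) return(character(0))
  .check_alphabet(seq)
  comp <- chartr("ACGTNacgtn", "TGCANTGCAN", seq)
  vapply(comp, function(s) {
    if (!nzchar(s)) return(s)
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Canonical form of a k-mer
#'
#' The canonical form is the lexicographically smaller of a k-mer and its
#' reverse complement. Because PBM probes are double stranded, every
#' measurement is attributed to the canonical k-mer; lookups through
#' [kmer_affinity()] are therefore strand symmetric.
#'
#' @param kmer Character vector of k-mers (alphabet `ACGT` only).
#' @return Character vector of canonical k-mers, uppercase.
#' @examples
#' canonical_kmer("TTTC")     # "GAAA"
#' canonical_kmer("GAAAGTA")  # already canonical
#' @export
canonical_kmer <- function(kmer) {
  if (length(kmer) == 0L) return(character(0))
  .check_alphabet(kmer, allow_n = FALSE, what = "k-mer")
  if (any(!nzchar(kmer))) stop("k-mer must have length >= 1", call. = FALSE)
  up <- toupper(kmer)
  rc <- revcomp(up)
  ifelse(up <= rc, up, rc)
}

# Rolling k-mer indices over an integer-coded sequence. Returns forward,
# reverse-complement and canonical indices for every window start; windows
# containing NA codes (i.e. N) are NA.
.kmer_indices <- function(codes, k) {
  L <- length(codes)
  n <- L - k + 1L
  if (n < 1L) {
    z <- numeric(0)
    return(list(fwd = z, rc = z, canonical = z))
  }
  pw <- 4^(0:(k - 1L))
  fwd <- as.numeric(stats::filter(codes, pw, method = "convolution", sides = 1))[k:L]
  rc <- as.numeric(stats::filter(3 - codes, rev(pw), method = "convolution", sides = 1))[k:L]
  list(fwd = fwd, rc = rc, canonical = pmin(fwd, rc))
}

# Decode numeric k-mer indices back to strings.
.index_to_kmer <- function(idx, k) {
  if (length(idx) == 0L) return(character(0))
  m <- matrix("", nrow = length(idx), ncol = k)
  r <- idx
  for (j in k:1) {
    m[, j] <- .DNA_BASES[(r %% 4) + 1L]
    r <- r %/% 4
  }
  do.call(paste0, split(m, col(m)))
}

.kmer_to_index <- function(kmer) {
  k <- nchar(kmer[1L])
  pw <- 4^((k - 1L):0)
  vapply(kmer, function(s) sum(.BASE_CODE[utf8ToInt(toupper(s))] * pw),
         numeric(1), USE.NAMES = FALSE)
}

# Reverse-complement index for every index 0..4^k-1 (vectorised).
.rc_index <- function(idx, k) {
  out <- numeric(length(idx))
  r <- idx
  for (j in 0:(k - 1L)) {
    out <- out + (3 - (r %% 4)) * 4^(k - 1L - j)
    r <- r %/% 4
  }
  out
}

# Indices (0-based) of all canonical k-mers, in increasing order.
.canonical_indices <- function(k) {
  idx <- 0:(4^k - 1L)
  idx[idx <= .rc_index(idx, k)]
}

#' All canonical k-mers
#'
#' For odd `k` there are exactly `4^k / 2` canonical k-mers (no odd-length
#' DNA palindromes exist).
#'
#' @param k Word length in bases.
#' @return Character vector of canonical k-mers in lexicographic order.
#' @export
canonical_kmers <- function(k) {
  stopifnot(length(k) == 1L, k >= 1)
  .index_to_kmer(.canonical_indices(k), k)
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
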