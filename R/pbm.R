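#' Protein binding microarray probe set
#'
#' Container for PBM probes: sequence, fluorescence intensity and array
#' coordinates. The variable (de Bruijn) region is shared across probes and
#' recorded as a 0-based half-open interval within each sequence; the
#' remainder is the constant 3' primer region used for double-stranding and
#' is excluded from all k-mer statistics.
#'
#' @param probe_id Character vector of unique probe identifiers.
#' @param sequence Character vector of probe sequences (equal lengths).
#' @param intensity Numeric vector of fluorescence intensities (finite, >= 0).
#' @param row,col Integer array coordinates; the (row, col) pair must be
#'   unique per probe.
#' @param variable_start,variable_end 0-based half-open interval of the
#'   variable region within each sequence.
#' @return An object of class `probe_set` (a data frame with attributes).
#' @export
probe_set <- function(probe_id, sequence, intensity, row, col,
                      variable_start = 0L, variable_end = nchar(sequence[1L])) {
  n <- length(probe_id)
  stopifnot(length(sequence) == n, length(intensity) == n,
            length(row) == n, length(col) == n)
  if (anyDuplicated(probe_id)) stop("probe ids must be unique", call. = FALSE)
  if (length(unique(nchar(sequence))) != 1L)
    stop("all probe sequences must have the same length", call. = FALSE)
  .check_alphabet(sequence, what = "probe sequence")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be finite and >= 0", call. = FALSE)
  if (anyDuplicated(paste(row, col)))
    stop("array coordinates must be unique per probe", call. = FALSE)
  L <- nchar(sequence[1L])
  if (variable_start < 0 || variable_end > L || variable_end <= variable_start)
    stop("variable region must be a non-empty interval within the sequence", call. = FALSE)
  structure(
    data.frame(probe_id = as.character(probe_id), sequence = toupper(sequence),
               intensity = as.numeric(intensity),
               row = as.integer(row), col = as.integer(col),
               stringsAsFactors = FALSE),
    variable_start = as.integer(variable_start),
    variable_end = as.integer(variable_end),
    class = c("probe_set", "data.frame"))
}

.variable_region <- function(probes) {
  vs <- attr(probes, "variable_start")
  ve <- attr(probes, "variable_end")
  substr(probes$sequence, vs + 1L, ve)
}

#' @export
print.probe_set <- function(x, ...) {
  cat("PBM probe set: ", nrow(x), " probes, ", nchar(x$sequence[1L]), " nt",
      " (variable region [", attr(x, "variable_start"), ",",
      attr(x, "variable_end"), "))\n", sep = "")
  print(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("  ... ", nrow(x) - 4L, " more\n", sep = "")
  invisible(x)
}

#' Read / write probe sets
#'
#' TSV with columns `probe_id sequence intensity row col`; the variable
#' region interval is carried in `#variable_region_start=` /
#' `#variable_region_end=` comment lines.
#'
#' @param path File path.
#' @return A [probe_set()] (reader) or `path` invisibly (writer).
#' @export
read_probeset <- function(path) {
  lines <- readLines(path)
  cfg <- lines[grepl("^#\\w+=", lines)]
  get_cfg <- function(key, default) {
    hit <- grep(paste0("^#", key, "="), cfg, value = TRUE)
    if (length(hit)) as.integer(sub(".*=", "", hit[1L])) else default
  }
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  probe_set(df$probe_id, df$sequence, df$intensity, df$row, df$col,
            variable_start = get_cfg("variable_region_start", 0L),
            variable_end = get_cfg("variable_region_end", nchar(df$sequence[1L])))
}

#' @rdname read_probeset
#' @param probes A [probe_set()].
#' @export
write_probeset <- function(probes, path) {
  stopifnot(inherits(probes, "probe_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#variable_region_start=", attr(probes, "variable_start")),
               paste0("#variable_region_end=", attr(probes, "variable_end"))), con)
  utils::write.table(as.data.frame(probes), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Spatial detrending of array intensities
#'
#' Removes smooth spatial artifacts (washing gradients, scanner shading) by
#' dividing each probe's intensity by the median intensity of the probes in
#' the `(2 * radius + 1)^2` block centered on its array position, then
#' rescaling so the global median intensity is exactly preserved. The median
#' block statistic resists bright-spot artifacts. A probe whose block holds
#' no other probe falls back to the global median (with a message).
#'
#' @param probes A [probe_set()] with populated array coordinates.
#' @param radius Block radius in array units (>= 1; default 7, a 15 x 15 block).
#' @return A detrended [probe_set()].
#' @export
spatial_detrend <- function(probes, radius = 7L) {
  stopifnot(inherits(probes, "probe_set"))
  if (length(radius) != 1L || !is.finite(radius) || radius < 1)
    stop("radius must be >= 1", call. = FALSE)
  radius <- as.integer(radius)
  nr <- max(probes$row); nc <- max(probes$col)
  M <- matrix(NA_real_, nr, nc)
  M[cbind(probes$row, probes$col)] <- probes$intensity
  gmed <- stats::median(probes$intensity)
  n_fallback <- 0L
  local_med <- vapply(seq_len(nrow(probes)), function(i) {
    r <- probes$row[i]; cl <- probes$col[i]
    blk <- M[max(1L, r - radius):min(nr, r + radius),
             max(1L, cl - radius):min(nc, cl + radius)]
    blk <- blk[!is.na(blk)]
    if (length(blk) < 2L) { n_fallback <<- n_fallback + 1L; return(gmed) }
    stats::median(blk)
  }, numeric(1))
  if (n_fallback > 0L)
    message("spatial_detrend: ", n_fallback,
            " probe(s) had no block neighbors; used global median")
  new_int <- probes$intensity / local_med * gmed
  # explicit rescale: divide-by-local-median only preserves the global
  # median for flat fields, so pin it exactly
  new_int <- new_int * gmed / stats::median(new_int)
  out <- probes
  out$intensity <- new_int
  out
}

# Per-probe canonical k-mer occurrences over the variable regions, computed
# in one pass: all variable regions are concatenated with an NA spacer so a
# single rolling-index call covers every window, and windows spanning probe
# boundaries are poisoned by the spacer.
.kmer_occurrences <- function(probes, k) {
  var <- .variable_region(probes)
  vlen <- nchar(var[1L])
  if (vlen < k) stop("variable region shorter than k", call. = FALSE)
  codes <- .BASE_CODE[utf8ToInt(paste(var, collapse = "N"))]
  idx <- .kmer_indices(codes, k)$canonical
  win_probe <- ((seq_along(idx) - 1L) %/% (vlen + 1L)) + 1L
  keep <- !is.na(idx)
  idx <- idx[keep]; win_probe <- win_probe[keep]
  key <- win_probe * 4^k + idx      # exact in doubles for n_probes * 4^k < 2^53
  first <- !duplicated(key)
  list(probe = win_probe[first], idx = idx[first])
}

#' K-mer z-score table from probe intensities
#'
#' For each canonical k-mer, takes the median of log-intensities over the
#' probes whose variable region contains the k-mer on either strand, then
#' standardizes the medians across all canonical k-mers:
#' `z(m) = (s(m) - mean(s)) / sd(s)`. The resulting table is the per-7-mer
#' "binding affinity score" model. Every canonical k-mer must be covered by
#' at least `min_coverage` probes; otherwise a coverage error lists the
#' missing k-mers. If all medians are equal (zero spread) every z is set to
#' 0 with a message.
#'
#' @param probes A [probe_set()]; intensities must be strictly positive
#'   (they are log-transformed).
#' @param k Word length (default 7).
#' @param min_coverage Minimum number of probes containing each k-mer.
#' @return A complete [kmer_table()].
#' @export
kmer_stats <- function(probes, k = 7L, min_coverage = 1L) {
  med <- .kmer_medians(probes, k, min_coverage)$median
  mu <- mean(med); s <- stats::sd(med)
  if (s == 0) {
    message("kmer_stats: all k-mer medians equal; z-scores set to 0")
    z <- rep(0, length(med))
  } else z <- (med - mu) / s
  names(z) <- names(med)
  kmer_table(z, k = k, complete = TRUE)
}

# Median log-intensity per canonical k-mer, plus the occurrence structure
# (shared by kmer_stats, escore and seed_and_wobble).
.kmer_medians <- function(probes, k, min_coverage = 1L) {
  stopifnot(inherits(probes, "probe_set"))
  if (any(probes$intensity <= 0))
    stop("intensities must be > 0 for log transformation", call. = FALSE)
  occ <- .kmer_occurrences(probes, k)
  all_idx <- .canonical_indices(k)
  counts <- tabulate(match(occ$idx, all_idx), nbins = length(all_idx))
  if (any(counts < min_coverage)) {
    missing <- .index_to_kmer(all_idx[counts < min_coverage], k)
    stop("coverage error: ", length(missing), " canonical ", k,
         "-mer(s) covered by < ", min_coverage, " probes (e.g. ",
         paste(utils::head(missing, 5L), collapse = ", "), ")", call. = FALSE)
  }
  logI <- log(probes$intensity)
  med <- vapply(split(logI[occ$probe], factor(occ$idx, levels = all_idx)),
                stats::median, numeric(1))
  names(med) <- .index_to_kmer(all_idx, k)
  list(median = med, occ = occ, all_idx = all_idx, counts = counts)
}

#' Rank-based enrichment score (E-score) of a k-mer
#'
#' The Mann-Whitney statistic of the probes containing the k-mer
#' (foreground) against all other probes (background), rescaled to
#' `U / (n_fg * n_bg) - 0.5`, bounded in \[-0.5, +0.5\]. Being rank based, it
#' is invariant under any strictly monotone transform of the intensities.
#' `+0.5` is reached only when every foreground probe outranks every
#' background probe.
#'
#' @param probes A [probe_set()].
#' @param kmer A single k-mer (either strand).
#' @return E-score in \[-0.5, 0.5\].
#' @export
escore <- function(probes, kmer) {
  stopifnot(inherits(probes, "probe_set"), length(kmer) == 1L)
  k <- nchar(kmer)
  target <- .kmer_to_index(canonical_kmer(kmer))
  occ <- .kmer_occurrences(probes, k)
  fg <- occ$probe[occ$idx == target]
  n_fg <- length(fg); n_bg <- nrow(probes) - n_fg
  if (n_fg == 0L || n_bg == 0L)
    stop("undefined E-score: empty ", if (n_fg == 0L) "foreground" else "background",
         " for ", kmer, call. = FALSE)
  r <- rank(probes$intensity)  # midranks
  U <- sum(r[fg]) - n_fg * (n_fg + 1) / 2
  U / (n_fg * n_bg) - 0.5
}

# E-scores for every covered canonical k-mer at once (one ranking pass).
.escore_all <- function(probes, k, med_info = NULL) {
  if (is.null(med_info)) med_info <- .kmer_medians(probes, k)
  occ <- med_info$occ
  r <- rank(probes$intensity)
  N <- nrow(probes)
  f <- factor(occ$idx, levels = med_info$all_idx)
  S <- vapply(split(r[occ$probe], f), sum, numeric(1))
  n_fg <- med_info$counts
  U <- S - n_fg * (n_fg + 1) / 2
  e <- U / (n_fg * (N - n_fg)) - 0.5
  names(e) <- names(med_info$median)
  e
}

#' Seed-and-wobble PWM estimation
#'
#' Picks the canonical k-mer with the highest E-score as the seed, then for
#' every position and base estimates the energy cost of the single
#' substitution as the difference in median log-intensity between probes
#' containing the substituted k-mer and probes containing the seed. Seed
#' bases sit at energy 0 (the reference state). A single wobble pass is
#' performed (no iterative seed extension). A substitution with no covering
#' probes gets the configured `floor` energy (with a message).
#'
#' @param probes A [probe_set()].
#' @param k Word length (default 7).
#' @param floor Energy assigned to uncovered substitutions (log units).
#' @return An object of class `pwm_estimate`: `seed` (canonical k-mer),
#'   `weights` (4 x k energy matrix, rows A/C/G/T) and `width`.
#' @export
seed_and_wobble <- function(probes, k = 7L, floor = -5) {
  med_info <- .kmer_medians(probes, k, min_coverage = 0L)
  e <- .escore_all(probes, k, med_info)
  e[med_info$counts == 0] <- -Inf
  seed <- names(which.max(e))
  med <- med_info$median
  seed_med <- med[[seed]]
  seed_chars <- strsplit(seed, "")[[1L]]
  W <- matrix(0, 4L, k, dimnames = list(.DNA_BASES, NULL))
  n_floor <- 0L
  for (i in seq_len(k)) {
    for (b in .DNA_BASES) {
      if (b == seed_chars[i]) next
      var <- seed_chars; var[i] <- b
      vk <- canonical_kmer(paste(var, collapse = ""))
      vmed <- med[vk]
      if (is.na(vmed) || med_info$counts[match(.kmer_to_index(vk), med_info$all_idx)] == 0) {
        W[b, i] <- floor; n_floor <- n_floor + 1L
      } else W[b, i] <- unname(vmed) - seed_med
    }
  }
  if (n_floor > 0L)
    message("seed_and_wobble: ", n_floor,
            " substitution(s) had no covering probes; energy set to floor = ", floor)
  structure(list(seed = seed, weights = W, width = as.integer(k)),
            class = "pwm_estimate")
}

#' @export
print.pwm_estimate <- function(x, ...) {
  cat("Seed-and-wobble PWM estimate\n  seed: ", x$seed,
      " (width ", x$width, ")\n", sep = "")
  cat("  energies (log relative intensity):\n")
  print(round(x$weights, 3))
  invisible(x)
}

#' Fit a PBM binding affinity model
#'
#' The full estimation pipeline over a probe set: optional spatial
#' detrending, the per-k-mer z-score table ([kmer_stats()]) with E-scores,
#' and a seed-and-wobble PWM ([seed_and_wobble()]) with its
#' energy-normalized logo matrix.
#'
#' @param probes A [probe_set()].
#' @param k Word length for the affinity table and the PWM (default 7).
#' @param detrend Apply [spatial_detrend()] first?
#' @param detrend_radius Block radius for detrending.
#' @param min_coverage Per-k-mer probe coverage required by [kmer_stats()].
#' @param wobble_floor Energy floor for uncovered substitutions.
#' @return An object of class `pbm_fit` with components `table`
#'   (a complete [kmer_table()] with E-scores), `pwm` (a `pwm_estimate`),
#'   `logo` (an [energy_logo()]), `seed`, `k` and `n_probes`. Methods:
#'   `print`, `summary`, `coef` (the energy matrix), `predict` (score new
#'   sequences) and `plot` (the logo).
#' @examples
#' sim <- gen_probeset(example_pwm(), n_probes = 700, rng_seed = 1)
#' fit <- pbm_fit(sim$probes, detrend = FALSE)
#' fit$seed
#' @export
pbm_fit <- function(probes, k = 7L, detrend = TRUE, detrend_radius = 7L,
                    min_coverage = 1L, wobble_floor = -5) {
  stopifnot(inherits(probes, "probe_set"))
  cl <- match.call()
  if (detrend) probes <- spatial_detrend(probes, detrend_radius)
  med_info <- .kmer_medians(probes, k, min_coverage)
  mu <- mean(med_info$median); s <- stats::sd(med_info$median)
  z <- if (s == 0) {
    message("pbm_fit: all k-mer medians equal; z-scores set to 0")
    rep(0, length(med_info$median))
  } else (med_info$median - mu) / s
  names(z) <- names(med_info$median)
  es <- .escore_all(probes, k, med_info)
  table <- kmer_table(z, k = k, escore = es, complete = TRUE)
  pwm <- seed_and_wobble(probes, k, floor = wobble_floor)
  structure(
    list(table = table, pwm = pwm, logo = energy_logo(pwm$weights),
         seed = pwm$seed, k = as.integer(k), n_probes = nrow(probes),
         detrended = detrend, call = cl),
    class = "pbm_fit")
}

#' @export
print.pbm_fit <- function(x, ...) {
  cat("PBM binding affinity model (k = ", x$k, ")\n", sep = "")
  cat("  probes    : ", x$n_probes,
      if (x$detrended) " (spatially detrended)" else "", "\n", sep = "")
  cat("  seed      : ", x$seed, "\n", sep = "")
  cat("  table     : ", length(x$table$z), " canonical k-mers, z in [",
      signif(min(x$table$z), 3), ", ", signif(max(x$table$z), 3), "]\n", sep = "")
  invisible(x)
}

#' @export
summary.pbm_fit <- function(object, n_top = 10L, ...) {
  top <- sort(object$table$z, decreasing = TRUE)[seq_len(n_top)]
  out <- list(fit = object,
              top_kmers = data.frame(kmer = names(top), z = unname(top),
                                     escore = unname(object$table$escore[names(top)]),
                                     linear = z_to_linear(unname(top))),
              ic_bits = object$logo$heights)
  class(out) <- "summary.pbm_fit"
  out
}

#' @export
print.summary.pbm_fit <- function(x, ...) {
  print(x$fit)
  cat("\nTop k-mers by z-score:\n")
  print(x$top_kmers, row.names = FALSE, digits = 4)
  cat("\nPer-position information content (bits):\n  ",
      paste(sprintf("%.2f", x$ic_bits), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
coef.pbm_fit <- function(object, ...) object$pwm$weights

#' Predict binding affinity along new sequences
#'
#' @param object A [pbm_fit()].
#' @param newdata Character vector of DNA sequences.
#' @param ... Passed to [score_sequence()].
#' @return A single `affinity_track` if `newdata` has length one, otherwise
#'   a named list of tracks.
#' @export
predict.pbm_fit <- function(object, newdata, ...) {
  tracks <- lapply(newdata, score_sequence, table = object$table, ...)
  if (length(tracks) == 1L) tracks[[1L]] else
    stats::setNames(tracks, names(newdata) %||% paste0("seq", seq_along(tracks)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
plot.pbm_fit <- function(x, ...) plot(x$logo, ...)
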