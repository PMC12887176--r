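#' Differential expression table
#'
#' Holds per-gene log2 fold changes and adjusted p-values across conditions
#' plus the per-gene base mean (mean normalized count), i.e. the output of
#' a differential expression engine such as DESeq2 — fitting that model is
#' out of scope here, this container only consumes its results.
#'
#' @param genes Character vector of gene identifiers.
#' @param log2fc Gene x condition numeric matrix of log2 fold changes.
#' @param padj Gene x condition matrix of adjusted p-values (a vector is
#'   treated as a single-contrast column); values in \[0, 1\] or `NA`.
#' @param base_mean Per-gene mean normalized count.
#' @param conditions Condition labels; default from `colnames(log2fc)`.
#' @return An object of class `deg_table`.
#' @export
deg_table <- function(genes, log2fc, padj, base_mean,
                      conditions = colnames(log2fc)) {
  log2fc <- as.matrix(log2fc)
  if (is.null(dim(padj))) padj <- matrix(padj, ncol = 1L)
  padj <- as.matrix(padj)
  n <- length(genes)
  stopifnot(nrow(log2fc) == n, nrow(padj) == n, length(base_mean) == n)
  if (any(padj < 0 | padj > 1, na.rm = TRUE))
    stop("padj values must lie in [0, 1]", call. = FALSE)
  if (is.null(conditions)) conditions <- paste0("cond", seq_len(ncol(log2fc)))
  colnames(log2fc) <- conditions
  rownames(log2fc) <- rownames(padj) <- genes
  structure(list(genes = as.character(genes), conditions = conditions,
                 log2fc = log2fc, padj = padj,
                 base_mean = as.numeric(base_mean)),
            class = "deg_table")
}

#' @export
print.deg_table <- function(x, ...) {
  cat("DE results table: ", length(x$genes), " genes x ",
      length(x$conditions), " conditions (",
      paste(utils::head(x$conditions, 4L), collapse = ", "),
      if (length(x$conditions) > 4L) ", ...", ")\n", sep = "")
  invisible(x)
}

#' Read / write DE tables
#'
#' TSV with columns `gene`, `<cond>_log2FC` (one per condition),
#' `<cond>_padj` and `baseMean`.
#'
#' @param path File path.
#' @return A [deg_table()] (reader) or `path` invisibly (writer).
#' @export
read_deg_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  lfc_cols <- grep("_log2FC$", names(df), value = TRUE)
  padj_cols <- grep("_padj$", names(df), value = TRUE)
  if (!length(lfc_cols) || !"gene" %in% names(df) || !"baseMean" %in% names(df))
    stop("DE table needs columns gene, <cond>_log2FC..., baseMean", call. = FALSE)
  conds <- sub("_log2FC$", "", lfc_cols)
  lfc <- as.matrix(df[lfc_cols]); colnames(lfc) <- conds
  padj <- if (length(padj_cols)) {
    p <- as.matrix(df[padj_cols]); colnames(p) <- sub("_padj$", "", padj_cols); p
  } else matrix(NA_real_, nrow(df), 1L)
  deg_table(df$gene, lfc, padj, df$baseMean, conditions = conds)
}

#' @rdname read_deg_table
#' @param table A [deg_table()].
#' @export
write_deg_table <- function(table, path) {
  stopifnot(inherits(table, "deg_table"))
  lfc <- table$log2fc; colnames(lfc) <- paste0(table$conditions, "_log2FC")
  padj <- table$padj
  colnames(padj) <- paste0(colnames(table$padj) %||% table$conditions[seq_len(ncol(padj))],
                           "_padj")
  df <- data.frame(gene = table$genes, lfc, padj, baseMean = table$base_mean,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Threshold filtering of differentially expressed genes
#'
#' Keeps a gene iff all three hold: adjusted p-value `<= padj_max` in at
#' least one contrast (missing p-values fail), `|log2FC| >= lfc_min` in at
#' least one condition (inclusive bounds, so log2FC of exactly -2 passes
#' the default), and base mean strictly above `basemean_min`. Filtering is
#' idempotent and monotone in the thresholds.
#'
#' @param table A [deg_table()].
#' @param padj_max Adjusted p-value ceiling (default 0.05).
#' @param lfc_min Minimum absolute log2 fold change (default 2).
#' @param basemean_min Base mean floor, exclusive (default 5).
#' @return The filtered [deg_table()].
#' @export
filter_degs <- function(table, padj_max = 0.05, lfc_min = 2, basemean_min = 5) {
  stopifnot(inherits(table, "deg_table"),
            padj_max > 0, lfc_min > 0, basemean_min > 0)
  if (length(table$genes) == 0L) return(table)
  p_ok <- apply(table$padj, 1L, function(p) any(p <= padj_max, na.rm = TRUE))
  fc_ok <- apply(abs(table$log2fc), 1L, function(v) any(v >= lfc_min, na.rm = TRUE))
  bm_ok <- table$base_mean > basemean_min
  keep <- p_ok & fc_ok & bm_ok
  deg_table(table$genes[keep],
            table$log2fc[keep, , drop = FALSE],
            table$padj[keep, , drop = FALSE],
            table$base_mean[keep],
            conditions = table$conditions)
}

#' Ward hierarchical clustering with a flat cut
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on
#' Euclidean distances of the log2 fold-change profiles (no row
#' standardization by default; the clustering operates in fold-change
#' space), cut into exactly `n_clusters` flat clusters. Cluster ids are
#' contiguous `1..n_clusters` in order of first appearance, and the
#' agglomeration is deterministic given the input order (ties merge the
#' lowest pair index first, the `stats::hclust` convention).
#'
#' @param x Numeric matrix (genes x conditions) or a [deg_table()] (its
#'   `log2fc` matrix is used).
#' @param n_clusters Number of flat clusters (default 4).
#' @return An object of class `cluster_result`: `labels` (named by gene),
#'   `stats` (per-cluster per-condition summary, see [cluster_stats()]),
#'   `hclust` (the linkage record) and `n_clusters`.
#' @export
ward_cluster <- function(x, n_clusters = 4L) {
  if (inherits(x, "deg_table")) x <- x$log2fc
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("values must be finite", call. = FALSE)
  if (nrow(x) < n_clusters)
    stop("need at least n_clusters = ", n_clusters, " rows, got ", nrow(x),
         call. = FALSE)
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  raw <- stats::cutree(hc, k = n_clusters)
  labels <- match(raw, unique(raw))  # contiguous ids in order of appearance
  names(labels) <- rownames(x)
  structure(list(labels = labels, stats = cluster_stats(x, labels),
                 hclust = hc, n_clusters = as.integer(n_clusters)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Ward clustering: ", length(x$labels), " genes in ", x$n_clusters,
      " clusters (sizes ", paste(tabulate(x$labels), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Per-cluster summary statistics
#'
#' For every cluster and condition: the median (50th percentile with linear
#' interpolation), the interquartile range (Q3 - Q1) and the sample
#' standard deviation (n - 1 denominator). Singleton clusters report IQR 0
#' and SD 0 with `singleton = TRUE`, keeping annotations total.
#'
#' @param x Numeric matrix (genes x conditions).
#' @param labels Integer cluster label per row.
#' @return Data frame with columns `cluster`, `condition`, `n_genes`,
#'   `median`, `iqr`, `sd`, `singleton`.
#' @export
cluster_stats <- function(x, labels) {
  x <- as.matrix(x)
  stopifnot(length(labels) == nrow(x))
  conds <- colnames(x) %||% paste0("cond", seq_len(ncol(x)))
  out <- do.call(rbind, lapply(sort(unique(labels)), function(cl) {
    xi <- x[labels == cl, , drop = FALSE]
    single <- nrow(xi) == 1L
    do.call(rbind, lapply(seq_len(ncol(x)), function(j) {
      v <- xi[, j]
      data.frame(cluster = cl, condition = conds[j], n_genes = nrow(xi),
                 median = stats::median(v),
                 iqr = if (single) 0 else
                   unname(diff(stats::quantile(v, c(0.25, 0.75)))),
                 sd = if (single) 0 else stats::sd(v),
                 singleton = single)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Three-way Venn region cardinalities
#'
#' Cardinalities of the seven exclusive regions of three gene sets; the
#' regions always sum to `|A U B U C|` (attached as attribute
#' `union_size`).
#'
#' @param a,b,c Character vectors (duplicates ignored).
#' @return Named integer vector with elements `A_only`, `B_only`, `C_only`,
#'   `AB`, `AC`, `BC`, `ABC`.
#' @export
venn_sets <- function(a, b, c = character(0)) {
  a <- unique(a); b <- unique(b); c <- unique(c)
  u <- union(union(a, b), c)
  in_a <- u %in% a; in_b <- u %in% b; in_c <- u %in% c
  out <- c(A_only = sum(in_a & !in_b & !in_c),
           B_only = sum(!in_a & in_b & !in_c),
           C_only = sum(!in_a & !in_b & in_c),
           AB = sum(in_a & in_b & !in_c),
           AC = sum(in_a & !in_b & in_c),
           BC = sum(!in_a & in_b & in_c),
           ABC = sum(in_a & in_b & in_c))
  attr(out, "union_size") <- length(u)
  out
}
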