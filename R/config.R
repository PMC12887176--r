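#' Run configuration
#'
#' Validated bundle of the pipeline defaults: the 7-mer word length, the
#' 1000/500 promoter window, the site-calling threshold and merge gap, the
#' track scale, and the DEG filtering/clustering thresholds. Every default
#' lives in this one auditable place; the command-line wrapper reads a
#' config file into it and applies flag overrides.
#'
#' @param k Word length (default 7).
#' @param upstream,downstream Promoter window extent in bases.
#' @param z_min Site-calling z threshold.
#' @param merge_gap Site merge distance in bases.
#' @param scale Track scale, `"linear"` (2^z) or `"z"`.
#' @param n_clusters Flat clusters for [ward_cluster()].
#' @param padj_max,lfc_min,basemean_min DEG filter thresholds.
#' @param rng_seed Optional seed threaded through seeded steps.
#' @return An object of class `run_config` (a validated named list).
#' @export
run_config <- function(k = 7L, upstream = 1000L, downstream = 500L,
                       z_min = 2.0, merge_gap = 5L,
                       scale = c("linear", "z"), n_clusters = 4L,
                       padj_max = 0.05, lfc_min = 2, basemean_min = 5,
                       rng_seed = NULL) {
  scale <- match.arg(scale)
  cfg <- list(k = k, upstream = upstream, downstream = downstream,
              z_min = z_min, merge_gap = merge_gap, scale = scale,
              n_clusters = n_clusters, padj_max = padj_max,
              lfc_min = lfc_min, basemean_min = basemean_min,
              rng_seed = rng_seed)
  num <- setdiff(names(cfg), c("scale", "rng_seed"))
  for (nm in num) {
    v <- cfg[[nm]]
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      stop("config field ", sQuote(nm), " must be a single positive number",
           call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  for (nm in names(x))
    cat(sprintf("  %-13s %s\n", nm,
                if (is.null(x[[nm]])) "NULL" else as.character(x[[nm]])))
  invisible(x)
}
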