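#' Read gene sets from a GMT file
#'
#' @param path GMT file (tab-delimited: set id, description, member genes).
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  fgsea::gmtPathways(path)
}

#' Hypergeometric over-representation test for one gene set
#'
#' Upper-tail hypergeometric probability `P(X >= k)` of drawing `k` set
#' members in a query of size `n` from a background of size `N` containing
#' `K` set members, with fold enrichment `(k/n) / (K/N)`. The set is first
#' restricted to the background. With `ease = TRUE` the observed overlap is
#' penalised by one (the EASE-score variant used by some annotation tools).
#'
#' @param query character vector of query gene ids (must be within
#'   `background`).
#' @param set character vector of set member ids.
#' @param background character vector: the gene universe.
#' @param ease logical; apply the EASE penalty.
#' @return list: `k`, `K`, `n`, `N`, `overlap` (gene ids),
#'   `fold_enrichment`, `p_raw`.
#' @export
test_set <- function(query, set, background, ease = FALSE) {
  background <- unique(background)
  query <- unique(query)
  if (!length(background)) stop("empty background", call. = FALSE)
  if (!length(query)) stop("empty query", call. = FALSE)
  if (!all(query %in% background))
    stop("query contains genes outside the background", call. = FALSE)
  set <- unique(intersect(set, background))
  overlap <- intersect(query, set)
  k <- length(overlap)
  K <- length(set)
  n <- length(query)
  N <- length(background)
  k_obs <- if (ease) max(k - 1L, 0L) else k
  p <- phyper(k_obs - 1L, K, N - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, N = N, overlap = overlap,
       fold_enrichment = if (k == 0) 0 else (k / n) / (K / N),
       p_raw = min(p, 1))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH false-discovery-rate adjustment (monotone, order-preserving).
#'
#' @param pvalues numeric vector of raw p-values in `(0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues) | pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  p.adjust(pvalues, method = "BH")
}

#' Over-representation analysis of a gene list against a collection
#'
#' Tests every set with [test_set()], adds BH-adjusted p-values, and flags
#' significance under the dual scheme: a set needs at least `min_genes`
#' query hits, and then, for a `pathway` collection, BH FDR < 0.05 with fold
#' enrichment >= 1.50, or, for an `ontology` collection, raw P < 0.01 with
#' fold enrichment >= 1.10. The FDR column is reported for both kinds even
#' though the ontology rule thresholds the raw P. Sets with no members in
#' the background are dropped.
#'
#' @param genes query gene ids (e.g. differentially methylated genes).
#' @param sets named list of gene sets (see [read_gene_sets()]).
#' @param background gene universe; defaults to the union of all genes on
#'   the array should be supplied explicitly by the caller.
#' @param kind `"pathway"` or `"ontology"`.
#' @param min_genes minimum query hits for significance (default 2).
#' @param ease logical; EASE-penalised p-values.
#' @param fdr_max,p_max,fold_min optional threshold overrides; defaults
#'   follow `kind` as above.
#' @return data.frame sorted by raw p: `set_id`, `gene_count`,
#'   `set_size`, `fold_enrichment`, `p_raw`, `p_fdr`, `significant`,
#'   `genes` (comma-separated overlap).
#' @export
run_enrichment <- function(genes, sets, background,
                           kind = c("pathway", "ontology"),
                           min_genes = 2, ease = FALSE,
                           fdr_max = NULL, p_max = NULL, fold_min = NULL) {
  kind <- match.arg(kind)
  background <- unique(background)
  genes <- unique(genes)
  sets <- lapply(sets, function(s) unique(intersect(s, background)))
  sets <- sets[lengths(sets) > 0]
  if (!length(sets)) stop("no gene sets left after background restriction",
                          call. = FALSE)
  res <- lapply(names(sets), function(nm) {
    r <- test_set(genes, sets[[nm]], background, ease = ease)
    data.frame(set_id = nm, gene_count = r$k, set_size = r$K,
               fold_enrichment = r$fold_enrichment, p_raw = r$p_raw,
               genes = paste(r$overlap, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_fdr <- bh_fdr(out$p_raw)
  if (kind == "pathway") {
    fdr_max <- fdr_max %||% 0.05
    fold_min <- fold_min %||% 1.50
    out$significant <- out$gene_count >= min_genes &
      out$p_fdr < fdr_max & out$fold_enrichment >= fold_min
  } else {
    p_max <- p_max %||% 0.01
    fold_min <- fold_min %||% 1.10
    out$significant <- out$gene_count >= min_genes &
      out$p_raw < p_max & out$fold_enrichment >= fold_min
  }
  out <- out[order(out$p_raw, out$set_id),
             c("set_id", "gene_count", "set_size", "fold_enrichment",
               "p_raw", "p_fdr", "significant", "genes")]
  rownames(out) <- NULL
  out
}
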