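#' Upper-tail hypergeometric over-representation p-value
#'
#' `P(X >= k)` for `X ~ Hypergeom(N, n, K)`: drawing `K` genes (the
#' extreme) from a universe of `N` containing `n` set members.
#'
#' @param k observed set members in the draw.
#' @param K draw (extreme) size.
#' @param n set size in the universe.
#' @param N universe size.
#' @return the upper-tail probability.
#' @export
hypergeom_overrep <- function(k, K, n, N) {
  if (k > min(K, n) || K > N || n > N || k < 0)
    stop("inconsistent counts for hypergeometric test")
  stats::phyper(k - 1, n, N - n, K, lower.tail = FALSE)
}

#' Over-representation of gene sets among fold-change extremes
#'
#' Ranks the universe by shrunken LFC, takes the top and bottom
#' `ceiling(pct * N)` genes, and tests each gene set for
#' over-representation in each extreme with the upper-tail
#' hypergeometric, BH-correcting over all set x direction tests in the
#' run. Mean shrunken LFC of the set members inside the extreme is
#' reported. Ties at the percentile boundary are broken by Wald p-value,
#' then lexicographic id.
#'
#' @param de an `nb_de` object or `de_result`-style data.frame with
#'   `feature_id`, `lfc_shrunk` (and optionally `wald_p`) columns.
#' @param sets named list of gene-id character vectors; each set is
#'   intersected with the universe.
#' @param pct extreme fraction in (0, 0.5) (default 0.01: top/bottom 1%).
#' @return data.frame with `set`, `direction`, `k`, `K`, `n`, `N`, `p`,
#'   `fdr`, `mean_lfc`.
#' @export
percentile_enrichment <- function(de, sets, pct = 0.01) {
  stopifnot(pct > 0, pct < 0.5)
  r <- if (inherits(de, "nb_de")) de$results else as.data.frame(de)
  r <- r[!is.na(r$lfc_shrunk), , drop = FALSE]
  N <- nrow(r)
  m <- ceiling(pct * N)
  p_tie <- if ("wald_p" %in% names(r)) r$wald_p else rep(0, N)
  ord_top <- order(-r$lfc_shrunk, p_tie, r$feature_id)
  ord_bot <- order(r$lfc_shrunk, p_tie, r$feature_id)
  extremes <- list(top = r$feature_id[ord_top[seq_len(m)]],
                   bottom = r$feature_id[ord_bot[seq_len(m)]])
  lfc <- stats::setNames(r$lfc_shrunk, r$feature_id)
  universe <- r$feature_id
  rows <- list()
  for (set_name in names(sets)) {
    members <- intersect(sets[[set_name]], universe)
    for (dir in c("top", "bottom")) {
      hits <- intersect(members, extremes[[dir]])
      rows[[length(rows) + 1]] <- data.frame(
        set = set_name, direction = dir,
        k = length(hits), K = m, n = length(members), N = N,
        p = hypergeom_overrep(length(hits), m, length(members), N),
        mean_lfc = if (length(hits)) mean(lfc[hits]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out[, c("set", "direction", "k", "K", "n", "N", "p", "fdr",
          "mean_lfc")]
}

#' Overlap statistics for two gene sets
#'
#' @param a,b character vectors of gene ids.
#' @return list with `overlap`, `frac_a` (`|a n b| / |a|`), `frac_b`,
#'   `jaccard`.
#' @export
set_overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  inter <- length(intersect(a, b))
  uni <- length(union(a, b))
  list(overlap = inter,
       frac_a = if (length(a)) inter / length(a) else NA_real_,
       frac_b = if (length(b)) inter / length(b) else NA_real_,
       jaccard = if (uni) inter / uni else NA_real_)
}

#' Positional summary of a co-located gene cluster
#'
#' Summarizes DE behaviour of an ordered gene cluster: per-gene and mean
#' shrunken LFC, counts of upregulated and (optionally) ectopic members,
#' and inter-gene distances computed as the left-most coordinate of the
#' next gene body minus the right-most coordinate of the current one,
#' regardless of gene orientation.
#'
#' @param de an `nb_de` or `de_result`-style data.frame.
#' @param cluster data.frame with `gene_id`, `start`, `end` (gene-body
#'   span), ordered or orderable by `start`. Genes absent from `de` are
#'   reported and excluded.
#' @param ectopic optional `ectopic_calls` data.frame for the ectopic
#'   count.
#' @param alpha FDR threshold for the upregulated count (default 0.01).
#' @return list with `table` (per-gene LFC and distance to the next
#'   gene), `mean_lfc`, `n_upregulated`, `n_ectopic`, `missing`.
#' @export
cluster_lfc_summary <- function(de, cluster, ectopic = NULL,
                                alpha = 0.01) {
  if (!nrow(cluster)) stop("empty cluster")
  r <- if (inherits(de, "nb_de")) de$results else as.data.frame(de)
  cluster <- cluster[order(cluster$start), , drop = FALSE]
  present <- cluster$gene_id %in% r$feature_id
  missing <- cluster$gene_id[!present]
  cl <- cluster[present, , drop = FALSE]
  if (!nrow(cl)) {
    # every cluster gene fell below the testable universe (common for
    # silent clusters removed by the low-count filter)
    return(list(table = data.frame(gene_id = character(),
                                   lfc_shrunk = numeric(),
                                   fdr = numeric(),
                                   dist_to_next = numeric()),
                mean_lfc = NA_real_, n_upregulated = 0L,
                n_ectopic = NA_integer_, missing = missing))
  }
  idx <- match(cl$gene_id, r$feature_id)
  lfc <- r$lfc_shrunk[idx]
  fdr <- r$fdr[idx]
  dist_next <- c(cl$start[-1] - cl$end[-nrow(cl)], NA_real_)
  n_ect <- NA_integer_
  if (!is.null(ectopic))
    n_ect <- sum(ectopic$is_ectopic[match(cl$gene_id,
                                          ectopic$gene_id)],
                 na.rm = TRUE)
  list(table = data.frame(gene_id = cl$gene_id, lfc_shrunk = lfc,
                          fdr = fdr, dist_to_next = dist_next,
                          stringsAsFactors = FALSE),
       mean_lfc = mean(lfc, na.rm = TRUE),
       n_upregulated = sum(!is.na(fdr) & fdr < alpha & lfc > 0),
       n_ectopic = n_ect,
       missing = missing)
}
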