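#' Configuration for ectopic-expression calling
#'
#' @param silent_rpkm_max genes with mean wild-type RPKM below this are
#'   candidates for transcriptional inertness (default 2.0).
#' @param silent_p_max p-value threshold for the inertness rank test
#'   (default 0.1).
#' @param fold_min minimum mutant/wild-type fold-change (default 2.0).
#' @param ectopic_q_max BH-adjusted one-sided Mann-Whitney threshold
#'   among fold-passing inert genes (default 0.25).
#' @param silent_test `"signed_rank"` (default): exact one-sided Wilcoxon
#'   signed-rank of wild-type replicate RPKM against the constant
#'   `silent_rpkm_max`; `"mann_whitney"`: one-sided two-sample
#'   Mann-Whitney of wild-type below mutant replicates (the alternative
#'   reading of the inertness criterion).
#' @param pseudocount stabilizer in the fold-change (default 0.01).
#' @return a list of class `ectopic_config`.
#' @export
ectopic_config <- function(silent_rpkm_max = 2.0, silent_p_max = 0.1,
                           fold_min = 2.0, ectopic_q_max = 0.25,
                           silent_test = c("signed_rank", "mann_whitney"),
                           pseudocount = 0.01) {
  stopifnot(silent_rpkm_max > 0, fold_min > 0,
            silent_p_max > 0, silent_p_max < 1,
            ectopic_q_max > 0, ectopic_q_max < 1)
  structure(list(silent_rpkm_max = silent_rpkm_max,
                 silent_p_max = silent_p_max, fold_min = fold_min,
                 ectopic_q_max = ectopic_q_max,
                 silent_test = match.arg(silent_test),
                 pseudocount = pseudocount),
            class = "ectopic_config")
}

#' Flag genes transcriptionally silent in wild type
#'
#' A gene is silent (inert) when its mean wild-type RPKM falls below
#' `silent_rpkm_max` and the configured one-sided location test supports
#' wild-type expression below that threshold at `p < silent_p_max`. The
#' default test is the exact one-sided Wilcoxon signed-rank of replicate
#' RPKM minus the threshold; with few replicates the test cannot reject
#' and the gene stays non-silent even when its mean is low.
#'
#' @param wt_rpkm genes x replicates matrix of wild-type RPKM (>= 2
#'   replicates).
#' @param config an [ectopic_config].
#' @param mut_rpkm mutant RPKM matrix, required when
#'   `silent_test = "mann_whitney"`.
#' @return logical vector of silent flags; attribute `p` carries the test
#'   p-values.
#' @export
call_silent_wt <- function(wt_rpkm, config = ectopic_config(),
                           mut_rpkm = NULL) {
  wt_rpkm <- as.matrix(wt_rpkm)
  if (ncol(wt_rpkm) < 2) stop("silent calling requires >= 2 replicates")
  means <- rowMeans(wt_rpkm)
  p <- vapply(seq_len(nrow(wt_rpkm)), function(i) {
    x <- wt_rpkm[i, ]
    if (config$silent_test == "signed_rank") {
      d <- x - config$silent_rpkm_max
      if (all(d == 0)) return(1)
      suppressWarnings(stats::wilcox.test(
        d[d != 0], mu = 0, alternative = "less",
        exact = TRUE)$p.value)
    } else {
      if (is.null(mut_rpkm))
        stop("mann_whitney inertness test requires mut_rpkm")
      suppressWarnings(stats::wilcox.test(
        x, as.matrix(mut_rpkm)[i, ], alternative = "less",
        exact = TRUE)$p.value)
    }
  }, 0)
  silent <- means < config$silent_rpkm_max & p < config$silent_p_max
  attr(silent, "p") <- p
  silent
}

#' Call ectopically expressed genes
#'
#' Two-step decision on matched wild-type and mutant RPKM matrices:
#' (1) genes silent in wild type per [call_silent_wt()]; (2) among silent
#' genes, those with `(mut_mean + eps) / (wt_mean + eps) > fold_min`
#' enter a one-sided Mann-Whitney U test (mutant above wild type) with
#' BH correction over exactly that entering set; a gene is ectopic when
#' its adjusted p falls below `ectopic_q_max`. Genes failing the fold
#' filter have undefined `q` and are excluded from the BH family, so
#' calls are invariant to adding non-silent genes to the input.
#'
#' @param wt_rpkm,mut_rpkm genes x replicates RPKM matrices with
#'   identical rownames (>= 2 replicates each).
#' @param config an [ectopic_config].
#' @return data.frame of class `ectopic_calls`: `gene_id`,
#'   `wt_mean_rpkm`, `mut_mean_rpkm`, `silent_in_wt`, `fold_change`,
#'   `mw_p`, `q`, `is_ectopic`; attribute `bh_family_size` records the
#'   BH universe size.
#' @export
call_ectopic <- function(wt_rpkm, mut_rpkm, config = ectopic_config()) {
  wt_rpkm <- as.matrix(wt_rpkm); mut_rpkm <- as.matrix(mut_rpkm)
  if (!identical(rownames(wt_rpkm), rownames(mut_rpkm)))
    stop("wild-type and mutant gene universes differ")
  if (ncol(mut_rpkm) < 2) stop("need >= 2 mutant replicates")
  silent <- call_silent_wt(wt_rpkm, config, mut_rpkm)
  wt_mean <- rowMeans(wt_rpkm)
  mut_mean <- rowMeans(mut_rpkm)
  eps <- config$pseudocount
  fold <- (mut_mean + eps) / (wt_mean + eps)
  entering <- silent & fold > config$fold_min
  mw_p <- rep(NA_real_, nrow(wt_rpkm))
  mw_p[entering] <- vapply(which(entering), function(i)
    suppressWarnings(stats::wilcox.test(
      mut_rpkm[i, ], wt_rpkm[i, ], alternative = "greater",
      exact = TRUE)$p.value), 0)
  q <- rep(NA_real_, nrow(wt_rpkm))
  q[entering] <- stats::p.adjust(mw_p[entering], method = "BH")
  is_ectopic <- entering & !is.na(q) & q < config$ectopic_q_max
  out <- data.frame(gene_id = rownames(wt_rpkm),
                    wt_mean_rpkm = wt_mean, mut_mean_rpkm = mut_mean,
                    silent_in_wt = as.logical(silent),
                    fold_change = fold, mw_p = mw_p, q = q,
                    is_ectopic = is_ectopic,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("ectopic_calls", "data.frame")
  attr(out, "bh_family_size") <- sum(entering)
  out
}
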