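#' Configuration for tissue-specificity classification
#'
#' @param tau_threshold genes with tau at or above this value are
#'   candidates for tissue enrichment (default 0.70).
#' @param expression_floor_log2 log2(RPKM) at or below which a gene counts
#'   as not expressed in a tissue (default 1, i.e. RPKM <= 2).
#' @param enrichment_k number of sample standard deviations above the mean
#'   log2(RPKM) a tissue must exceed to be called enriched (default 1.5).
#' @param not_expressed_rule `"all"` (default): a gene is NotExpressed only
#'   when it fails the floor in every tissue; `"any"`: in at least one
#'   tissue (an alternative, stricter reading).
#' @return a list of class `tau_config`.
#' @export
tau_config <- function(tau_threshold = 0.70, expression_floor_log2 = 1.0,
                       enrichment_k = 1.5,
                       not_expressed_rule = c("all", "any")) {
  stopifnot(tau_threshold > 0, tau_threshold <= 1, enrichment_k > 0)
  structure(list(tau_threshold = tau_threshold,
                 expression_floor_log2 = expression_floor_log2,
                 enrichment_k = enrichment_k,
                 not_expressed_rule = match.arg(not_expressed_rule)),
            class = "tau_config")
}

#' Compute the tau tissue-specificity index
#'
#' For a vector of per-tissue log2 expression values x,
#' tau = sum(1 - x_i / max(x)) / (n - 1). Tau is 0 for perfectly uniform
#' expression and 1 for expression confined to a single tissue. Negative
#' values (log2 RPKM of genes below 1 RPKM) are clipped to 0 before the
#' ratio so that x_hat stays in [0, 1]; missing cells (zero RPKM,
#' excluded from the log transform) enter the formula as 0.
#'
#' @param log_expr numeric vector of per-tissue log2 expression, length
#'   >= 2. `NA` cells are treated as 0.
#' @return tau in [0, 1], or `NA` when no entry is strictly positive
#'   (tau undefined).
#' @export
compute_tau <- function(log_expr) {
  x <- as.numeric(log_expr)
  if (length(x) < 2) stop("tau requires at least two tissues")
  x[is.na(x)] <- 0
  x <- pmax(x, 0)
  mx <- max(x)
  if (mx <= 0) return(NA_real_)
  sum(1 - x / mx) / (length(x) - 1)
}

#' Tissues enriched for a gene
#'
#' Returns the tissues whose log2 expression exceeds the across-tissue
#' mean by more than `k` sample standard deviations (n - 1 denominator).
#' A constant vector (zero SD) yields the empty set.
#'
#' @param log_expr named numeric vector of per-tissue log2 expression.
#' @param k standard-deviation multiplier (default 1.5).
#' @return character vector of enriched tissue names (possibly several;
#'   integer indices if `log_expr` is unnamed).
#' @export
assign_enriched_tissues <- function(log_expr, k = 1.5) {
  x <- as.numeric(log_expr)
  if (length(x) < 2) stop("need at least two tissues")
  x[is.na(x)] <- 0
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(character(0))
  hit <- which(x > mean(x) + k * s)
  if (!is.null(names(log_expr))) names(log_expr)[hit] else hit
}

#' Classify genes by tissue specificity
#'
#' Applies the tau index with the study thresholds to an expression atlas
#' (genes x tissue groups, RPKM scale). Each gene is labelled:
#' \describe{
#'   \item{NotExpressed}{log2(RPKM) at or below the floor (default RPKM
#'     <= 2) in every tissue; tau undefined.}
#'   \item{NotEnriched}{expressed but tau below the threshold, or no
#'     tissue clears the mean + k SD enrichment cutoff.}
#'   \item{Enriched}{tau >= threshold with a non-empty enriched-tissue
#'     set.}
#' }
#'
#' @param atlas numeric matrix of RPKM values (genes x tissues, dimnames
#'   required) or an object with an `rpkm` element.
#' @param config a [tau_config].
#' @return a list of class `tissue_classification`: `table` (data.frame
#'   `gene_id`, `tau`, `status`, `enriched_tissues` semicolon-joined) and
#'   `summary` (per-tissue enriched counts, status counts, fraction
#'   tissue-specific).
#' @export
classify_genes <- function(atlas, config = tau_config()) {
  rpkm <- if (is.list(atlas) && !is.null(atlas$rpkm)) atlas$rpkm else atlas
  rpkm <- as.matrix(rpkm)
  if (nrow(rpkm) == 0) stop("empty atlas")
  if (any(rpkm < 0)) stop("RPKM values must be non-negative")
  # zero-RPKM cells are excluded from the log transform (flagged missing)
  logx <- log2(rpkm)
  logx[rpkm == 0] <- NA

  floorv <- config$expression_floor_log2
  below <- is.na(logx) | logx <= floorv
  not_expr <- if (config$not_expressed_rule == "all")
    rowSums(below) == ncol(rpkm) else rowSums(below) > 0

  tau <- apply(logx, 1, compute_tau)
  status <- character(nrow(rpkm))
  enriched <- vector("list", nrow(rpkm))
  for (i in seq_len(nrow(rpkm))) {
    if (not_expr[i]) {
      status[i] <- "NotExpressed"
      tau[i] <- NA_real_
      enriched[[i]] <- character(0)
    } else {
      hits <- assign_enriched_tissues(
        ifelse(is.na(logx[i, ]), 0, logx[i, ]), config$enrichment_k)
      if (!is.na(tau[i]) && tau[i] >= config$tau_threshold &&
          length(hits)) {
        status[i] <- "Enriched"
        enriched[[i]] <- hits
      } else {
        status[i] <- "NotEnriched"
        enriched[[i]] <- character(0)
      }
    }
  }
  tab <- data.frame(
    gene_id = rownames(rpkm), tau = tau,
    status = status,
    enriched_tissues = vapply(enriched, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  per_tissue <- table(factor(unlist(enriched),
                             levels = colnames(rpkm)))
  structure(list(
    table = tab,
    summary = list(
      status_counts = table(factor(status, levels = c(
        "NotExpressed", "NotEnriched", "Enriched"))),
      per_tissue_enriched = per_tissue,
      frac_tissue_specific = mean(status == "Enriched"))),
    class = "tissue_classification")
}

#' @export
print.tissue_classification <- function(x, ...) {
  cat("tissue classification of", nrow(x$table), "genes\n")
  print(x$summary$status_counts)
  cat(sprintf("fraction tissue-specific (Enriched): %.1f%%\n",
              100 * x$summary$frac_tissue_specific))
  invisible(x)
}

#' Write a tissue classification table to TSV
#' @param x a `tissue_classification`.
#' @param path output TSV path.
#' @export
write_classification <- function(x, path) {
  utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
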