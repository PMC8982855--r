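#' Drop features with low mean counts
#'
#' Removes features whose mean raw count across all samples is less than
#' or equal to `min_mean` (default 10), the filter applied before
#' GC-content normalization. Feature order is preserved.
#'
#' @param x a [count_matrix].
#' @param min_mean inclusive removal threshold on the across-sample mean.
#' @return the filtered [count_matrix]; a warning (not an error) is given
#'   when no feature survives.
#' @export
filter_low_count <- function(x, min_mean = 10) {
  stopifnot(inherits(x, "count_matrix"))
  keep <- rowMeans(x$counts) > min_mean
  if (!any(keep)) warning("no feature passes the low-count filter")
  x[keep, ]
}

.as_counts <- function(x) {
  if (inherits(x, "count_matrix")) x$counts
  else if (inherits(x, "normalization_result")) x$normalized_counts
  else as.matrix(x)
}

# map values of one stratum onto quantiles of a pooled reference vector
.quantile_map <- function(v, sorted_ref) {
  m <- length(v)
  N <- length(sorted_ref)
  r <- rank(v, ties.method = "average")
  pos <- if (m == 1) (N + 1) / 2 else 1 + (r - 1) / (m - 1) * (N - 1)
  stats::approx(seq_len(N), sorted_ref, xout = pos, rule = 2)$y
}

#' Within-lane GC-content full-quantile normalization
#'
#' For each sample independently, features are binned into `n_strata`
#' equal-occupancy strata of GC fraction, and the counts within each
#' stratum are replaced by the values at matching quantiles of the
#' sample's pooled (all-strata) count distribution. This removes smooth
#' sample-specific GC bias while preserving the within-stratum rank
#' order. With a single stratum the transform is the identity.
#'
#' @param x a [count_matrix] whose feature metadata carries `gc_fraction`.
#' @param n_strata number of GC strata (default 10).
#' @return an object of class `normalization_result`: list with
#'   `normalized_counts`, `strata_bounds` (GC cut points partitioning
#'   [0,1]), `strata` (per-feature stratum index), `kept_features`.
#' @export
within_lane_gc_fqn <- function(x, n_strata = 10) {
  stopifnot(inherits(x, "count_matrix"), n_strata >= 1)
  gc <- x$feature_meta$gc_fraction
  if (is.null(gc) || any(is.na(gc))) {
    missing <- if (is.null(gc)) rownames(x$counts)
               else rownames(x$counts)[is.na(gc)]
    stop("missing gc_fraction for features: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  n <- nrow(x$counts)
  # equal-occupancy strata over the GC rank
  strata <- if (n_strata == 1) rep(1L, n)
  else as.integer(cut(rank(gc, ties.method = "first"),
                      breaks = n_strata, labels = FALSE,
                      include.lowest = TRUE))
  bounds <- if (n_strata == 1) c(0, 1)
  else c(0, vapply(seq_len(n_strata - 1), function(k)
    mean(c(max(gc[strata == k]), min(gc[strata == k + 1]))), 0), 1)
  norm <- x$counts
  for (j in seq_len(ncol(norm))) {
    pooled <- sort(x$counts[, j])
    for (k in seq_len(n_strata)) {
      sel <- strata == k
      norm[sel, j] <- .quantile_map(x$counts[sel, j], pooled)
    }
  }
  structure(list(normalized_counts = norm, strata_bounds = bounds,
                 strata = strata, kept_features = rownames(norm)),
            class = "normalization_result")
}

#' Between-lane full-quantile normalization
#'
#' Maps each sample's sorted counts onto the mean of all samples' sorted
#' count vectors, equalizing the per-sample count distributions to
#' account for sequencing-depth differences. Rank order within each
#' sample is preserved; tied values share the mean of their positions'
#' reference values. Depth normalization is conventionally unstratified
#' (the default); setting `gc` and `n_strata` instead applies the map
#' within GC strata, for pipelines that keep the feature strata through
#' the depth step.
#'
#' @param x a features x samples matrix, [count_matrix] or
#'   `normalization_result`.
#' @param gc optional per-feature GC fractions enabling the stratified
#'   variant.
#' @param n_strata number of GC strata when `gc` is supplied.
#' @return a `normalization_result` (see [within_lane_gc_fqn()]).
#' @export
between_lane_fqn <- function(x, gc = NULL, n_strata = 1) {
  m <- .as_counts(x)
  if (ncol(m) < 2) stop("between-lane normalization needs >= 2 samples")
  strata <- if (is.null(gc) || n_strata == 1) rep(1L, nrow(m))
  else as.integer(cut(rank(gc, ties.method = "first"),
                      breaks = n_strata, labels = FALSE,
                      include.lowest = TRUE))
  out <- m
  for (k in unique(strata)) {
    sel <- strata == k
    sub <- m[sel, , drop = FALSE]
    ref <- rowMeans(apply(sub, 2, sort))
    for (j in seq_len(ncol(sub))) {
      r <- rank(sub[, j], ties.method = "average")
      out[sel, j] <- stats::approx(seq_along(ref), ref, xout = r,
                                   rule = 2)$y
    }
  }
  structure(list(normalized_counts = out, strata_bounds = c(0, 1),
                 strata = strata,
                 kept_features = rownames(out)),
            class = "normalization_result")
}

#' GLM offsets linking raw to normalized counts
#'
#' Computes per-cell offsets `log((raw + 0.1) / (normalized + 0.1))` so
#' that raw counts can be modelled with expectation
#' `exp(offset) * mu`: feeding raw counts plus these offsets to the NB
#' GLM reproduces inference on the normalized counts.
#'
#' @param raw a [count_matrix] or matrix of raw counts.
#' @param normalized a `normalization_result` or matrix aligned with
#'   `raw` on the kept features.
#' @param pseudocount stabilizer avoiding log(0) (default 0.1).
#' @return matrix of offsets (natural log scale).
#' @export
compute_offsets <- function(raw, normalized, pseudocount = 0.1) {
  r <- .as_counts(raw)
  n <- .as_counts(normalized)
  if (!identical(dim(r), dim(n)))
    stop("raw and normalized matrices have different shapes")
  log((r + pseudocount) / (n + pseudocount))
}

#' Full count normalization: filter, GC, depth, offsets
#'
#' Convenience composition in the fixed order low-count filter ->
#' within-lane GC full-quantile -> between-lane full-quantile -> offsets.
#'
#' @param x a [count_matrix].
#' @param min_mean low-count filter threshold (default 10).
#' @param n_strata GC strata (default 10).
#' @return list with `counts` (filtered [count_matrix]),
#'   `normalized` (matrix), `offsets` (matrix), `strata_bounds`.
#' @export
normalize_counts <- function(x, min_mean = 10, n_strata = 10) {
  filtered <- filter_low_count(x, min_mean)
  wl <- within_lane_gc_fqn(filtered, n_strata)
  bl <- between_lane_fqn(wl)
  offs <- compute_offsets(filtered, bl)
  list(counts = filtered, normalized = bl$normalized_counts,
       offsets = offs, strata_bounds = wl$strata_bounds)
}
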