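# Independent brute-force oracles used across the suite. These are kept
# deliberately naive: enumeration and per-base set arithmetic, never the
# package's own code paths.

# BH step-up from the definition: adj_i = min over j >= rank(i) of
# min(1, m * p_(j) / j)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- pmin(1, m * p[o] / seq_len(m))
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# upper-tail hypergeometric by exhaustive enumeration of all C(N, K)
# draws of a K-subset from 1..N with the set being 1..n
hyper_oracle <- function(k, K, n, N) {
  if (K == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, K)
  hits <- colSums(draws <= n)
  mean(hits >= k)
}

# per-base cover set of an interval collection, as "chrom:pos" strings
base_set <- function(chrom, start, end) {
  if (!length(chrom)) return(character(0))
  unique(unlist(lapply(seq_along(chrom), function(i)
    if (start[i] < end[i])
      paste0(chrom[i], ":", seq(start[i], end[i] - 1)) else character())))
}

# random small interval set on 1-2 chromosomes, spans <= span_max
random_intervals <- function(n, span_max = 2000, chroms = c("cA", "cB")) {
  ch <- sample(chroms, n, replace = TRUE)
  st <- sample.int(span_max, n, replace = TRUE) - 1
  width <- sample.int(200, n, replace = TRUE)
  genomic_intervals(ch, st, st + width,
                    score = round(stats::runif(n, 0, 10), 2))
}

# tiny count_matrix builder for engine tests
make_cm <- function(counts, group = NULL, feature_meta = NULL) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("f%04d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  sm <- if (is.null(group)) NULL
  else data.frame(group = group, row.names = colnames(counts))
  count_matrix(counts, sm, feature_meta)
}
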