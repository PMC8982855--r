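#' Define a genome workspace (chromosome sizes and exclusions)
#'
#' The workspace is the mappable space used by [bin_coverage()] and as the
#' sampling space of [randomized_overlap_enrichment()].
#'
#' @param sizes named numeric vector of chromosome lengths in bp (> 0).
#' @param excluded optional [genomic_intervals] of regions to avoid when
#'   placing randomized intervals; must lie on workspace chromosomes.
#' @return an object of class `genome_workspace`.
#' @export
genome_workspace <- function(sizes, excluded = NULL) {
  if (is.null(names(sizes)) || any(!nzchar(names(sizes))))
    stop("chromosome sizes must be named")
  if (any(sizes <= 0)) stop("chromosome lengths must be > 0")
  if (!is.null(excluded)) {
    bad <- setdiff(unique(excluded$chrom), names(sizes))
    if (length(bad))
      stop("excluded regions on unknown chromosomes: ",
           paste(bad, collapse = ", "))
  }
  structure(list(sizes = sizes, excluded = excluded),
            class = "genome_workspace")
}

#' @export
print.genome_workspace <- function(x, ...) {
  cat("genome_workspace:", length(x$sizes), "chromosomes,",
      format(sum(x$sizes), big.mark = ","), "bp\n")
  invisible(x)
}

# merged (disjoint, sorted) starts/ends per chromosome
.merged_by_chrom <- function(x) {
  if (!nrow(x)) return(list())
  m <- merge_intervals(x)
  split(m[c("start", "end")], m$chrom)
}

#' Merge overlapping and book-ended intervals
#'
#' Returns the minimal set of disjoint intervals covering exactly the
#' union of the input. Book-ended intervals (`[a,b)`, `[b,c)`) are merged,
#' matching `bedtools merge` with distance 0. Scores of merged
#' constituents are max-aggregated; strand is dropped to `"."`.
#'
#' @param x a [genomic_intervals] data.frame.
#' @return a merged [genomic_intervals] data.frame sorted by chromosome
#'   and start.
#' @export
merge_intervals <- function(x) {
  if (!nrow(x))
    return(genomic_intervals(character(), numeric(), numeric()))
  ord <- order(x$chrom, x$start, x$end)
  x <- x[ord, , drop = FALSE]
  out <- lapply(split(x, x$chrom), function(ch) {
    n <- nrow(ch)
    hi <- cummax(ch$end)
    # a new run begins where start exceeds the running max end
    new_run <- c(TRUE, ch$start[-1] > hi[-n])
    grp <- cumsum(new_run)
    data.frame(chrom = ch$chrom[1],
               start = tapply(ch$start, grp, min),
               end = tapply(ch$end, grp, max),
               score = tapply(ch$score, grp, max),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  genomic_intervals(out$chrom, out$start, out$end,
                    name = paste0("merged", seq_len(nrow(out))),
                    score = out$score)
}

#' Remove peaks overlapping a blacklist
#'
#' Default (`mode = "whole"`) removes entire peaks that have at least 1 bp
#' of overlap with any blacklist interval (`bedtools subtract -A`
#' semantics), the rule used to drop peaks sharing space with mock-IP
#' peaks. `mode = "portion"` instead trims away only the overlapped bases,
#' possibly splitting a peak.
#'
#' @param peaks,blacklist [genomic_intervals] data.frames.
#' @param mode `"whole"` or `"portion"`.
#' @return the filtered [genomic_intervals].
#' @export
subtract_whole <- function(peaks, blacklist, mode = c("whole", "portion")) {
  mode <- match.arg(mode)
  if (!nrow(peaks) || !nrow(blacklist))
    return(peaks)
  bl <- .merged_by_chrom(blacklist)
  if (mode == "whole") {
    keep <- vapply(seq_len(nrow(peaks)), function(i) {
      b <- bl[[peaks$chrom[i]]]
      if (is.null(b)) return(TRUE)
      !.any_overlap(peaks$start[i], peaks$end[i], b$start, b$end)
    }, logical(1))
    return(peaks[keep, , drop = FALSE])
  }
  pieces <- lapply(seq_len(nrow(peaks)), function(i) {
    a <- peaks$start[i]; b <- peaks$end[i]
    bb <- bl[[peaks$chrom[i]]]
    if (is.null(bb)) {
      seg <- cbind(a, b)
    } else {
      hit <- bb[bb$start < b & bb$end > a, , drop = FALSE]
      if (!nrow(hit)) {
        seg <- cbind(a, b)
      } else {
        starts <- c(a, pmin(pmax(hit$end, a), b))
        ends <- c(pmin(pmax(hit$start, a), b), b)
        seg <- cbind(starts, ends)[starts < ends, , drop = FALSE]
      }
    }
    if (!nrow(seg)) return(NULL)
    data.frame(chrom = peaks$chrom[i], start = seg[, 1], end = seg[, 2],
               name = peaks$name[i], score = peaks$score[i],
               strand = peaks$strand[i], stringsAsFactors = FALSE)
  })
  pieces <- do.call(rbind, pieces)
  if (is.null(pieces))
    return(genomic_intervals(character(), numeric(), numeric()))
  genomic_intervals(pieces$chrom, pieces$start, pieces$end,
                    name = make.unique(pieces$name), score = pieces$score,
                    strand = pieces$strand)
}

.any_overlap <- function(a, b, starts, ends) {
  any(starts < b & ends > a)
}

#' Annotate genes bound by peaks near their TSS
#'
#' A gene is called bound when a peak interval intersects the window
#' `[tss - window, tss + window + 1)` (i.e. the peak has a base within
#' `window` bp of the TSS in either direction). The reported distance is
#' the signed bp from the TSS to the nearest peak edge (last covered base
#' for peaks upstream of the TSS), 0 when the TSS lies inside a peak, and
#' negative when the peak lies 5' of the gene (strand-aware).
#'
#' @param peaks a [genomic_intervals] data.frame.
#' @param genes a `gene_models` data.frame (see [read_gene_models()]).
#' @param window half-window in bp (default 1000, the 1 kb rule).
#' @return a list with `bound_genes` (character vector) and `table`
#'   (data.frame `gene_id`, `distance`, `bound`; `distance` is `NA` when
#'   the gene's chromosome carries no peak).
#' @export
annotate_tss <- function(peaks, genes, window = 1000) {
  by_chrom <- split(peaks[c("start", "end")], peaks$chrom)
  dist <- rep(NA_real_, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    p <- by_chrom[[genes$chrom[i]]]
    if (is.null(p) || !nrow(p)) next
    tss <- genes$tss[i]
    d_gen <- ifelse(tss >= p$start & tss < p$end, 0,
                    ifelse(p$start > tss, p$start - tss,
                           (p$end - 1) - tss))
    d <- d_gen[which.min(abs(d_gen))]
    if (genes$strand[i] == "-") d <- -d
    dist[i] <- d
  }
  bound <- !is.na(dist) & abs(dist) <= window
  list(bound_genes = genes$gene_id[bound],
       table = data.frame(gene_id = genes$gene_id, distance = dist,
                          bound = bound, stringsAsFactors = FALSE))
}

#' Peak density profile around transcription start sites
#'
#' Accumulates peak anchor points (summits or midpoints) falling within
#' `flank` bp of each TSS into strand-oriented bins: negative positions
#' are upstream of the gene, positive downstream. Frequencies are
#' normalized to sum to 1 over the profile (weighting by the number of
#' peaks in the displayed space); raw counts are retained.
#'
#' @param peaks a [genomic_intervals] data.frame; `anchor = "summit"`
#'   requires `summit_offset` on every peak.
#' @param genes a `gene_models` data.frame.
#' @param flank half-width of the profiled window in bp (default 2000).
#' @param bin bin width in bp (default 50); must divide `flank`.
#' @param anchor `"summit"` or `"midpoint"`.
#' @return a list with `mids` (bin centers, bp relative to TSS), `counts`
#'   (anchor pairs per bin) and `freq` (`counts / sum(counts)`).
#' @export
density_profile <- function(peaks, genes, flank = 2000, bin = 50,
                            anchor = c("summit", "midpoint")) {
  anchor <- match.arg(anchor)
  if (flank %% bin != 0) stop("flank must be divisible by bin")
  if (anchor == "summit") {
    if (any(is.na(peaks$summit_offset)))
      stop("anchor = 'summit' requires summit_offset on every peak")
    pos <- peaks$start + peaks$summit_offset
  } else {
    pos <- floor((peaks$start + peaks$end) / 2)
  }
  n_bins <- 2 * flank / bin
  counts <- numeric(n_bins)
  anchors_by_chrom <- split(pos, peaks$chrom)
  for (i in seq_len(nrow(genes))) {
    a <- anchors_by_chrom[[genes$chrom[i]]]
    if (is.null(a)) next
    rel <- a - genes$tss[i]
    if (genes$strand[i] == "-") rel <- -rel
    rel <- rel[rel >= -flank & rel < flank]
    if (!length(rel)) next
    idx <- floor((rel + flank) / bin) + 1
    tab <- tabulate(idx, nbins = n_bins)
    counts <- counts + tab
  }
  mids <- seq(-flank + bin / 2, flank - bin / 2, by = bin)
  total <- sum(counts)
  list(mids = mids, counts = counts,
       freq = if (total > 0) counts / total else counts)
}

#' Percent peak coverage per genomic bin
#'
#' Peaks are merged first so overlapping peaks count covered bases once;
#' each bin reports `100 * covered bp / bin width`, with the final partial
#' bin of each chromosome normalized by its true width.
#'
#' @param peaks a [genomic_intervals] data.frame.
#' @param workspace a [genome_workspace].
#' @param bin bin width in bp (default 1e5, i.e. 100-kb bins).
#' @return data.frame with `chrom`, `start`, `end`, `pct_coverage`.
#' @export
bin_coverage <- function(peaks, workspace, bin = 1e5) {
  stopifnot(inherits(workspace, "genome_workspace"))
  merged <- merge_intervals(peaks)
  out <- lapply(names(workspace$sizes), function(chrom) {
    len <- workspace$sizes[[chrom]]
    starts <- seq(0, len - 1, by = bin)
    ends <- pmin(starts + bin, len)
    cov <- numeric(length(starts))
    p <- merged[merged$chrom == chrom, , drop = FALSE]
    if (nrow(p)) {
      if (any(p$end > len)) {
        warning("peak beyond end of ", chrom, "; clipped")
        p$end <- pmin(p$end, len)
        p <- p[p$start < p$end, , drop = FALSE]
      }
      for (j in seq_len(nrow(p))) {
        i0 <- floor(p$start[j] / bin) + 1
        i1 <- floor((p$end[j] - 1) / bin) + 1
        for (k in i0:i1) {
          cov[k] <- cov[k] +
            max(0, min(p$end[j], ends[k]) - max(p$start[j], starts[k]))
        }
      }
    }
    data.frame(chrom = chrom, start = starts, end = ends,
               pct_coverage = 100 * cov / (ends - starts),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# coverage function helpers over a merged reference ------------------------

.ref_index <- function(reference) {
  m <- merge_intervals(reference)
  lapply(split(m[c("start", "end")], m$chrom), function(ch) {
    o <- order(ch$start)
    s <- ch$start[o]; e <- ch$end[o]
    list(s = s, e = e, prefix = cumsum(e - s))
  })
}

# covered bp of reference in [0, x)
.cov_at <- function(idx, x) {
  i <- findInterval(x, idx$s)
  out <- numeric(length(x))
  pos <- i > 0
  prev <- ifelse(i > 1, idx$prefix[pmax(i - 1, 1)], 0)
  out[pos] <- prev[pos] +
    pmax(0, pmin(x[pos], idx$e[i[pos]]) - idx$s[i[pos]])
  out
}

# total overlap of query intervals with a .ref_index, by mode
.overlap_with_ref <- function(chrom, start, end, ref, mode) {
  total <- 0
  for (ch in unique(chrom)) {
    idx <- ref[[ch]]
    if (is.null(idx)) next
    sel <- chrom == ch
    a <- start[sel]; b <- end[sel]
    if (mode == "bp") {
      total <- total + sum(.cov_at(idx, b) - .cov_at(idx, a))
    } else {
      i <- findInterval(b - 0.5, idx$s)
      hit <- i >= 1 & ifelse(i >= 1, idx$e[pmax(i, 1)] > a, FALSE)
      total <- total + sum(hit)
    }
  }
  total
}

#' Randomization-based overlap enrichment of two interval sets
#'
#' Tests whether a query peak set overlaps a reference set more than
#' expected by chance, in the style of the Genomic Association Tester:
#' each simulation re-places every query interval (lengths preserved)
#' uniformly at random within the workspace, avoiding excluded regions;
#' overlaps among placed intervals are permitted. Observed and expected
#' overlap are compared as total bp of overlap summed over query
#' intervals against the merged reference (`mode = "bp"`) or as the
#' number of query intervals with at least 1 bp of overlap
#' (`mode = "count"`).
#'
#' @param query,reference [genomic_intervals] data.frames within the
#'   workspace.
#' @param workspace a [genome_workspace].
#' @param n_sims number of randomizations (a warning is given below 100).
#' @param seed integer seed making the simulation reproducible.
#' @param mode `"bp"` or `"count"`.
#' @return an object of class `overlap_enrichment`: list with
#'   `observed_overlap`, `expected_overlap`, `fold_enrichment`,
#'   `empirical_p` (add-one estimator, always > 0), `n_sims`, `seed`,
#'   `mode`, `sim_overlaps`.
#' @export
randomized_overlap_enrichment <- function(query, reference, workspace,
                                          n_sims = 1000, seed = 1,
                                          mode = c("bp", "count")) {
  mode <- match.arg(mode)
  stopifnot(inherits(workspace, "genome_workspace"))
  if (n_sims < 100) warning("n_sims < 100: empirical p is coarse")
  sizes <- workspace$sizes
  lens <- query$end - query$start
  if (any(lens > max(sizes)))
    stop("query interval longer than every chromosome")
  ref <- .ref_index(reference)
  excl <- if (!is.null(workspace$excluded))
    .merged_by_chrom(workspace$excluded) else list()

  observed <- .overlap_with_ref(query$chrom, query$start, query$end,
                                ref, mode)

  set.seed(seed)
  nq <- length(lens)
  chrom_names <- names(sizes)
  sims <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    sim_chrom <- character(nq)
    sim_start <- numeric(nq)
    for (q in seq_len(nq)) {
      L <- lens[q]
      room <- pmax(sizes - L + 1, 0)
      repeat {
        ch <- sample(chrom_names, 1, prob = room)
        st <- floor(stats::runif(1, 0, room[[ch]]))
        ex <- excl[[ch]]
        if (is.null(ex) ||
            !.any_overlap(st, st + L, ex$start, ex$end)) break
      }
      sim_chrom[q] <- ch
      sim_start[q] <- st
    }
    sims[s] <- .overlap_with_ref(sim_chrom, sim_start,
                                 sim_start + lens, ref, mode)
  }
  expected <- mean(sims)
  structure(list(
    observed_overlap = observed,
    expected_overlap = expected,
    fold_enrichment = if (expected > 0) observed / expected else NA_real_,
    empirical_p = (1 + sum(sims >= observed)) / (1 + n_sims),
    n_sims = n_sims, seed = seed, mode = mode, sim_overlaps = sims),
    class = "overlap_enrichment")
}

#' @export
print.overlap_enrichment <- function(x, ...) {
  cat("overlap enrichment (", x$mode, " mode, ", x$n_sims, " sims)\n",
      "  observed: ", x$observed_overlap,
      "  expected: ", signif(x$expected_overlap, 4),
      "  fold: ", signif(x$fold_enrichment, 4),
      "  p: ", signif(x$empirical_p, 4), "\n", sep = "")
  invisible(x)
}
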