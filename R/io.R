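#' Construct a validated count matrix
#'
#' Bundles a features x samples matrix of non-negative integer counts with
#' per-sample metadata (genotype, age, condition, antibody, replicate, ...)
#' and per-feature metadata (length, GC fraction, coordinates, feature
#' class). All downstream normalization and differential-expression
#' functions consume this container.
#'
#' @param counts numeric matrix of non-negative integers, features in rows,
#'   samples in columns; dimnames required.
#' @param sample_meta data.frame with one row per sample (rownames = sample
#'   ids, or a `sample_id` column).
#' @param feature_meta data.frame with one row per feature (rownames =
#'   feature ids, or a `feature_id` column). Recognised columns:
#'   `length` (bp, > 0), `gc_fraction` (in [0,1]), `chrom`, `start`, `end`,
#'   `strand`, `class` (one of gene / repeat / genomic_bin).
#' @return an object of class `count_matrix`: a list with elements
#'   `counts`, `sample_meta`, `feature_meta`.
#' @export
count_matrix <- function(counts, sample_meta = NULL, feature_meta = NULL) {
  counts <- as.matrix(counts)
  if ((is.null(rownames(counts)) && nrow(counts) > 0) ||
      (is.null(colnames(counts)) && ncol(counts) > 0))
    stop("counts must have feature rownames and sample colnames")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (any(!is.finite(counts)))
    stop("counts contain non-finite values")
  if (any(counts < 0))
    stop("counts contain negative values")
  if (any(counts != round(counts)))
    stop("counts contain non-integer values")
  storage.mode(counts) <- "double"

  sample_meta <- .meta_frame(sample_meta, colnames(counts), "sample")
  feature_meta <- .meta_frame(feature_meta, rownames(counts), "feature")

  if (!is.null(feature_meta$gc_fraction)) {
    gc <- feature_meta$gc_fraction
    if (any(!is.na(gc) & (gc < 0 | gc > 1)))
      stop("gc_fraction must lie in [0, 1]")
  }
  if (!is.null(feature_meta$length) &&
      any(!is.na(feature_meta$length) & feature_meta$length <= 0))
    stop("feature length must be > 0")
  if (!is.null(feature_meta$class)) {
    bad <- setdiff(unique(as.character(feature_meta$class)),
                   c("gene", "repeat", "genomic_bin"))
    if (length(bad))
      stop("unknown feature class: ", paste(bad, collapse = ", "))
  }

  structure(list(counts = counts, sample_meta = sample_meta,
                 feature_meta = feature_meta),
            class = "count_matrix")
}

.meta_frame <- function(meta, ids, what) {
  id_col <- paste0(what, "_id")
  if (is.null(meta)) {
    meta <- data.frame(row.names = ids)
  } else {
    meta <- as.data.frame(meta)
    if (id_col %in% names(meta)) {
      rownames(meta) <- meta[[id_col]]
      meta[[id_col]] <- NULL
    }
    missing <- setdiff(ids, rownames(meta))
    if (length(missing))
      stop(what, " present in counts but absent from metadata: ",
           paste(utils::head(missing, 5), collapse = ", "))
    meta <- meta[ids, , drop = FALSE]
  }
  meta
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples\n")
  if (ncol(x$sample_meta))
    cat("sample metadata:", paste(names(x$sample_meta), collapse = ", "),
        "\n")
  if (ncol(x$feature_meta))
    cat("feature metadata:", paste(names(x$feature_meta), collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by features and/or samples
#'
#' @param x a `count_matrix`.
#' @param i feature index/names, `j` sample index/names.
#' @param ... unused.
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  count_matrix(x$counts[i, j, drop = FALSE],
               x$sample_meta[j, , drop = FALSE],
               x$feature_meta[i, , drop = FALSE])
}

#' Read a count table with sample and feature metadata
#'
#' The count file is a TSV with a header row of sample ids and feature ids
#' in the first column. Metadata files are TSVs keyed by `sample_id` /
#' `feature_id` columns.
#'
#' @param path count TSV path.
#' @param sample_meta_path sample metadata TSV path (keyed by `sample_id`).
#' @param feature_meta_path optional feature metadata TSV path (keyed by
#'   `feature_id`).
#' @return a validated [count_matrix].
#' @export
read_count_table <- function(path, sample_meta_path,
                             feature_meta_path = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate feature id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  bad <- which(!is.finite(mat) | mat < 0 | mat != round(mat),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf(
      "non-integer or negative count at feature '%s', sample '%s'",
      ids[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  rownames(mat) <- ids
  smeta <- utils::read.delim(sample_meta_path, check.names = FALSE,
                             stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(smeta))
    stop("sample metadata must have a sample_id column")
  fmeta <- NULL
  if (!is.null(feature_meta_path)) {
    fmeta <- utils::read.delim(feature_meta_path, check.names = FALSE,
                               stringsAsFactors = FALSE)
    if (!"feature_id" %in% names(fmeta))
      stop("feature metadata must have a feature_id column")
  }
  count_matrix(mat, smeta, fmeta)
}

#' Write a count matrix and its metadata to TSV files
#'
#' @param x a `count_matrix`.
#' @param path counts TSV path.
#' @param sample_meta_path,feature_meta_path optional metadata TSV paths.
#' @export
write_count_table <- function(x, path, sample_meta_path = NULL,
                              feature_meta_path = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  tab <- data.frame(feature_id = rownames(x$counts), x$counts,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(sample_meta_path)) {
    sm <- data.frame(sample_id = rownames(x$sample_meta), x$sample_meta,
                     check.names = FALSE)
    utils::write.table(sm, sample_meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(feature_meta_path)) {
    fm <- data.frame(feature_id = rownames(x$feature_meta),
                     x$feature_meta, check.names = FALSE)
    utils::write.table(fm, feature_meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Construct a set of genomic intervals
#'
#' Intervals are 0-based half-open `[start, end)` regardless of the source
#' dialect. `summit_offset` (narrowPeak column 10) is the offset of the
#' point-source summit from `start`; `NA` means absent.
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open coordinates, `0 <= start < end`.
#' @param name interval names.
#' @param score non-negative score (fold enrichment over input).
#' @param strand one of `+`, `-`, `.`.
#' @param summit_offset optional integer offset in `[0, end - start)`.
#' @return a data.frame of class `genomic_intervals`.
#' @export
genomic_intervals <- function(chrom, start, end,
                              name = NULL, score = 0, strand = ".",
                              summit_offset = NA_integer_) {
  n <- length(chrom)
  if (is.null(name)) name <- if (n) paste0("iv", seq_len(n)) else character()
  out <- data.frame(chrom = as.character(chrom),
                    start = as.numeric(start), end = as.numeric(end),
                    name = as.character(name),
                    score = rep_len(as.numeric(score), n),
                    strand = rep_len(as.character(strand), n),
                    summit_offset = rep_len(as.numeric(summit_offset), n),
                    stringsAsFactors = FALSE)
  bad <- which(!(out$start >= 0 & out$start < out$end))
  if (length(bad))
    stop("invalid interval (need 0 <= start < end) at record ", bad[1])
  so <- out$summit_offset
  badso <- which(!is.na(so) & (so < 0 | so >= out$end - out$start))
  if (length(badso))
    stop("summit_offset outside interval at record ", badso[1])
  bad_strand <- setdiff(unique(out$strand), c("+", "-", "."))
  if (length(bad_strand))
    stop("invalid strand: ", paste(bad_strand, collapse = ", "))
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

.dialect_cols <- c(bed3 = 3L, bed6 = 6L, narrowPeak = 10L, broadPeak = 9L)

#' Read a peak/interval file in a BED-family dialect
#'
#' Supports BED3, BED6 and the ENCODE narrowPeak (10 column) and broadPeak
#' (9 column) dialects. Coordinates on disk are already 0-based half-open;
#' they are validated, not shifted. The narrowPeak point-source column is
#' mapped to `summit_offset`, with `-1` mapped to absent.
#'
#' @param path file path.
#' @param dialect one of `"bed3"`, `"bed6"`, `"narrowPeak"`, `"broadPeak"`.
#' @return a [genomic_intervals] data.frame, in file order.
#' @export
read_peaks <- function(path,
                       dialect = c("broadPeak", "narrowPeak", "bed6",
                                   "bed3")) {
  dialect <- match.arg(dialect)
  want <- .dialect_cols[[dialect]]
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines))
    return(genomic_intervals(character(), numeric(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != want)
  if (length(bad))
    stop(sprintf("line %d has %d columns; dialect %s requires %d",
                 bad[1], nf[bad[1]], dialect, want))
  m <- matrix(unlist(fields), ncol = want, byrow = TRUE)
  start <- as.numeric(m[, 2]); end <- as.numeric(m[, 3])
  badc <- which(!(start >= 0 & start < end))
  if (length(badc))
    stop(sprintf("invalid coordinates (start >= end) at line %d", badc[1]))
  name <- if (want >= 4) m[, 4] else paste0("peak", seq_len(nrow(m)))
  strand <- if (want >= 6) m[, 6] else "."
  # signalValue (fold enrichment) is the score for ENCODE dialects,
  # BED column 5 otherwise
  score <- if (want >= 7) as.numeric(m[, 7])
           else if (want >= 5) as.numeric(m[, 5]) else 0
  summit <- if (dialect == "narrowPeak") {
    s <- as.numeric(m[, 10])
    s[s < 0] <- NA
    s
  } else NA_real_
  genomic_intervals(m[, 1], start, end, name = name, score = score,
                    strand = strand, summit_offset = summit)
}

#' Write intervals in a BED-family dialect
#'
#' Inverse of [read_peaks()]: writing then reading is the identity up to
#' numeric formatting.
#'
#' @param x a [genomic_intervals] data.frame.
#' @param path output path.
#' @param dialect output dialect (see [read_peaks()]).
#' @export
write_peaks <- function(x, path,
                        dialect = c("broadPeak", "narrowPeak", "bed6",
                                    "bed3")) {
  dialect <- match.arg(dialect)
  n <- nrow(x)
  cols <- switch(dialect,
    bed3 = data.frame(x$chrom, x$start, x$end),
    bed6 = data.frame(x$chrom, x$start, x$end, x$name, x$score, x$strand),
    broadPeak = data.frame(x$chrom, x$start, x$end, x$name,
                           rep(0L, n), x$strand, x$score,
                           rep(-1, n), rep(-1, n)),
    narrowPeak = data.frame(x$chrom, x$start, x$end, x$name,
                            rep(0L, n), x$strand, x$score,
                            rep(-1, n), rep(-1, n),
                            ifelse(is.na(x$summit_offset), -1,
                                   x$summit_offset)))
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a minimal GTF or a TSV
#'
#' Accepts either a minimal GTF (gene features; 1-based inclusive
#' coordinates, converted to 0-based half-open on read) or a TSV with
#' columns `gene_id`, `chrom`, `start`, `end`, `strand` already in 0-based
#' half-open coordinates. The TSS is `body_start` for `+` genes and
#' `body_end - 1` for `-` genes.
#'
#' @param path file path; format auto-detected (GTF if 9 tab-separated
#'   columns with no `gene_id` header).
#' @return a data.frame of class `gene_models` with columns `gene_id`,
#'   `chrom`, `tss`, `strand`, `body_start`, `body_end`.
#' @export
read_gene_models <- function(path) {
  first <- readLines(path, n = 1L)
  header <- strsplit(first, "\t", fixed = TRUE)[[1]]
  if ("gene_id" %in% header) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    gene_models(tab$gene_id, tab$chrom, tab$start, tab$end, tab$strand)
  } else {
    tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 9) stop("GTF requires 9 columns")
    tab <- tab[tab[[3]] == "gene", , drop = FALSE]
    ids <- sub('.*gene_id[ =]*"?([^";]+)"?.*', "\\1", tab[[9]])
    # GTF is 1-based inclusive: convert to 0-based half-open
    gene_models(ids, tab[[1]], as.numeric(tab[[4]]) - 1,
                as.numeric(tab[[5]]), tab[[7]])
  }
}

#' Construct gene models from 0-based half-open gene spans
#'
#' @param gene_id gene identifiers (unique).
#' @param chrom chromosome names.
#' @param start,end 0-based half-open gene body span.
#' @param strand `+` or `-` (required; the TSS is undefined otherwise).
#' @return a `gene_models` data.frame (see [read_gene_models()]).
#' @export
gene_models <- function(gene_id, chrom, start, end, strand) {
  n <- length(gene_id)
  chrom <- rep_len(as.character(chrom), n)
  strand <- rep_len(as.character(strand), n)
  bad <- setdiff(unique(strand), c("+", "-"))
  if (length(bad))
    stop("strand must be '+' or '-' (TSS undefined for: ",
         paste(bad, collapse = ", "), ")")
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(end <= start)) stop("gene span requires start < end")
  if (anyDuplicated(gene_id)) stop("duplicate gene_id")
  out <- data.frame(gene_id = as.character(gene_id),
                    chrom = as.character(chrom),
                    tss = ifelse(strand == "+", start, end - 1),
                    strand = strand,
                    body_start = start, body_end = end,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Write gene models as a TSV readable by [read_gene_models()]
#' @param x a `gene_models` data.frame.
#' @param path output path.
#' @export
write_gene_models <- function(x, path) {
  tab <- data.frame(gene_id = x$gene_id, chrom = x$chrom,
                    start = x$body_start, end = x$body_end,
                    strand = x$strand)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a two-column chrom.sizes TSV into a genome workspace
#' @param path TSV with chromosome name and length columns (no header).
#' @return a [genome_workspace].
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.delim(path, header = FALSE,
                           stringsAsFactors = FALSE)
  genome_workspace(stats::setNames(as.numeric(tab[[2]]),
                                   as.character(tab[[1]])))
}
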