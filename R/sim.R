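#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the planted-truth simulators. Defaults emulate
#' the study conditions: a 2 genotype x 2 age ovary design with 3
#' replicates per group, a tissue atlas with planted tissue-specific
#' genes at 16-fold contrast, a co-located testis-like ectopic gene
#' cluster (the responsive core of the reporter cluster), NB counts with
#' smooth per-sample GC bias, and an IP/mock ChIP design of 2 antibodies
#' x 2 replicates with promoter-proximal peaks 150 bp upstream of TSSs
#' and sub-2-fold repeat enrichment.
#'
#' @param seed integer; fixes every draw.
#' @param n_genes number of genes.
#' @param n_tissues number of atlas tissue groups (>= 2).
#' @param n_samples_per_group replicates per genotype x age group.
#' @param frac_tissue_specific fraction of atlas genes planted
#'   tissue-specific.
#' @param frac_silent fraction of atlas genes planted not expressed
#'   (RPKM < 2 everywhere).
#' @param ts_fold contrast of the specific tissue over background.
#' @param frac_de fraction of genes with a planted genotype effect.
#' @param frac_age fraction of genes with a planted age main effect
#'   (disjoint from the DE set).
#' @param frac_ectopic fraction of genes planted ectopic (silent in wild
#'   type, expressed in mutant), in addition to the cluster.
#' @param cluster_size number of adjacent planted testis-like cluster
#'   genes, all ectopic.
#' @param lfc_effect mean |log2 fold-change| of planted DE genes.
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2) for
#'   RNA counts.
#' @param chip_dispersion NB dispersion for ChIP repeat/bin counts.
#' @param gc_bias_amplitude per-sample GC-bias amplitude in log2 units
#'   (0 disables the bias).
#' @param depth_variation half-range of per-sample depth factors around 1
#'   (0 gives equal depths).
#' @param genome_length bp per synthetic chromosome in the ChIP genome.
#' @param n_chip_genes gene models in the ChIP genome.
#' @param n_peaks planted binding sites per IP.
#' @param peak_frac_promoter fraction of planted peaks promoter-proximal.
#' @param n_repeats repeat consensus features.
#' @param frac_repeat_enriched fraction of repeats with planted IP
#'   enrichment.
#' @param repeat_ip_fold planted IP/mock fold on enriched repeats
#'   (kept below 2).
#' @param n_bins genomic 1-kb bin features anchoring ChIP normalization.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_genes = 5000, n_tissues = 10,
                       n_samples_per_group = 3,
                       frac_tissue_specific = 0.10, frac_silent = 0.10,
                       ts_fold = 16, frac_de = 0.05, frac_age = 0.05,
                       frac_ectopic = 0.02, cluster_size = 12,
                       lfc_effect = 2, dispersion = 0.1,
                       chip_dispersion = 0.02,
                       gc_bias_amplitude = 0.5, depth_variation = 0.3,
                       genome_length = 2e6, n_chip_genes = 300,
                       n_peaks = 200, peak_frac_promoter = 0.8,
                       n_repeats = 40, frac_repeat_enriched = 0.5,
                       repeat_ip_fold = 1.5, n_bins = 2000) {
  cfg <- as.list(environment())
  if (n_genes < 1) stop("n_genes must be positive")
  fracs <- c(frac_tissue_specific, frac_silent, frac_de, frac_age,
             frac_ectopic, peak_frac_promoter, frac_repeat_enriched)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (n_tissues < 2) stop("need at least 2 tissues")
  if (dispersion < 0 || chip_dispersion < 0)
    stop("dispersion must be >= 0")
  structure(cfg, class = "sim_config")
}

.rnb <- function(n, mu, alpha) {
  if (alpha <= 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / alpha)
}

# deterministic planted-role assignment shared by the atlas and ovary
# generators, so the testis-like identity of misregulated genes is
# coherent across simulated assays
.sim_roles <- function(config) {
  n <- config$n_genes
  chrom <- rep(c("chrA", "chrB"), length.out = n)
  k_cluster <- min(config$cluster_size, sum(chrom == "chrA"))
  cluster_idx <- which(chrom == "chrA")[seq_len(k_cluster)]
  pool <- setdiff(seq_len(n), cluster_idx)
  n_ect_extra <- max(0, round(config$frac_ectopic * n) - k_cluster)
  ect_extra <- pool[seq_len(n_ect_extra)]
  pool <- setdiff(pool, ect_extra)
  n_de <- round(config$frac_de * n)
  de_idx <- pool[seq_len(n_de)]
  pool <- setdiff(pool, de_idx)
  n_age <- round(config$frac_age * n)
  age_idx <- pool[seq_len(n_age)]
  de_up <- de_idx[seq_len(ceiling(n_de / 2))]
  de_dn <- setdiff(de_idx, de_up)
  list(chrom = chrom, cluster = cluster_idx, ect_extra = ect_extra,
       ectopic = c(cluster_idx, ect_extra), de_up = de_up,
       de_dn = de_dn, de = de_idx, age = age_idx,
       # testis-like genes: the derepressed cluster, the other ectopic
       # genes, and the upregulated DE genes
       testis_like = sort(c(cluster_idx, ect_extra, de_up)))
}

#' Generate a synthetic tissue expression atlas with planted truth
#'
#' Background genes get log-normal RPKM roughly even across tissues;
#' planted tissue-specific genes sit on a low baseline with one tissue
#' elevated `ts_fold`-fold; a planted silent fraction stays below 2 RPKM
#' in every tissue.
#'
#' The first tissue group (`tissue01`) plays the testis-like role: the
#' planted ectopic cluster, the other planted ectopic genes and the
#' upregulated planted DE genes of [generate_ovary_counts()] are
#' specific to it, mirroring the derepression signature the analysis is
#' designed to detect; the remaining tissue-specific genes are assigned
#' tissues at random.
#'
#' @param config a [sim_config].
#' @return list with `atlas` (class `expression_atlas`: `rpkm` genes x
#'   tissues matrix) and `truth` (data.frame `gene_id`,
#'   `is_tissue_specific`, `specific_tissue`, `is_silent`).
#' @export
generate_atlas <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  nt <- config$n_tissues
  gene_ids <- sprintf("g%05d", seq_len(n))
  tissues <- sprintf("tissue%02d", seq_len(nt))
  roles <- .sim_roles(config)
  n_ts <- round(config$frac_tissue_specific * n)
  n_sil <- round(config$frac_silent * n)
  specific_idx <- roles$testis_like
  if (length(specific_idx) > n_ts)
    specific_idx <- specific_idx[seq_len(n_ts)]
  extra <- setdiff(seq_len(n), specific_idx)[
    seq_len(max(0, n_ts - length(specific_idx)))]
  role <- rep("background", n)
  role[c(specific_idx, extra)] <- "specific"
  silent_pool <- setdiff(seq_len(n), c(specific_idx, extra))
  role[silent_pool[seq_len(min(n_sil, length(silent_pool)))]] <- "silent"
  rpkm <- matrix(0, n, nt, dimnames = list(gene_ids, tissues))
  specific_tissue <- rep(NA_character_, n)
  specific_tissue[specific_idx] <- tissues[1]
  for (i in seq_len(n)) {
    if (role[i] == "background") {
      base <- stats::rlnorm(1, log(30), 0.7)
      rpkm[i, ] <- base * stats::rlnorm(nt, 0, 0.25)
    } else if (role[i] == "silent") {
      rpkm[i, ] <- stats::runif(nt, 0, 1.5)
    } else {
      base <- stats::rlnorm(1, log(1.2), 0.4)
      vals <- base * stats::rlnorm(nt, 0, 0.25)
      if (is.na(specific_tissue[i]))
        specific_tissue[i] <- tissues[sample.int(nt, 1)]
      t <- match(specific_tissue[i], tissues)
      vals[t] <- vals[t] * config$ts_fold
      rpkm[i, ] <- vals
    }
  }
  atlas <- structure(list(rpkm = rpkm, tissues = tissues),
                     class = "expression_atlas")
  truth <- data.frame(gene_id = gene_ids,
                      is_tissue_specific = role == "specific",
                      specific_tissue = specific_tissue,
                      is_silent = role == "silent",
                      stringsAsFactors = FALSE)
  list(atlas = atlas, truth = truth)
}

#' Generate a synthetic ovary count matrix with planted truth
#'
#' Emulates the 2 genotype x 2 age ovary design: NB counts with mean
#' `mu * depth * g(GC)` where `g` is a smooth per-sample quadratic
#' GC-bias curve on the log scale. Planted DE genes carry a genotype
#' log2 fold-change of `+-lfc_effect` at both ages; a disjoint subset
#' carries an age main effect; planted ectopic genes (including an
#' adjacent co-located cluster on one chromosome) have wild-type RPKM in
#' 0.1-0.5 and mutant RPKM in 5-10.
#'
#' @param config a [sim_config] (`n_samples_per_group >= 2`).
#' @return list with `counts` (a [count_matrix]) and `truth` (data.frame
#'   `gene_id`, `is_de`, `true_lfc`, `is_age`, `is_ectopic`,
#'   `in_cluster`).
#' @export
generate_ovary_counts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_samples_per_group < 2)
    stop("need at least 2 replicates per group")
  set.seed(config$seed + 1L)
  n <- config$n_genes
  reps <- config$n_samples_per_group
  gene_ids <- sprintf("g%05d", seq_len(n))

  sample_meta <- expand.grid(replicate = paste0("r", seq_len(reps)),
                             age = c("d0", "d2"),
                             genotype = c("wt", "mut"),
                             stringsAsFactors = FALSE)
  # wild type and newly-eclosed are the reference levels
  sample_meta$genotype <- factor(sample_meta$genotype,
                                 levels = c("wt", "mut"))
  sample_meta$age <- factor(sample_meta$age, levels = c("d0", "d2"))
  sample_ids <- with(sample_meta, paste(genotype, age, replicate,
                                        sep = "_"))
  rownames(sample_meta) <- sample_ids
  ns <- nrow(sample_meta)

  roles <- .sim_roles(config)
  chrom <- roles$chrom
  cluster_idx <- roles$cluster
  ectopic_idx <- roles$ectopic
  de_idx <- roles$de
  age_idx <- roles$age

  # gene bodies laid head-to-tail per chromosome; the planted cluster
  # occupies the first adjacent slots of chrA
  len <- pmax(200, round(stats::rlnorm(n, log(1500), 0.5)))
  gc <- 0.25 + 0.5 * stats::rbeta(n, 5, 5)
  start <- numeric(n); end <- numeric(n)
  for (ch in c("chrA", "chrB")) {
    idx <- which(chrom == ch)
    gaps <- round(stats::runif(length(idx), 200, 2000))
    st <- cumsum(c(0, (len[idx] + gaps)[-length(idx)]))
    start[idx] <- st
    end[idx] <- st + len[idx]
  }

  mu0 <- stats::rlnorm(n, log(100), 1.0)
  true_lfc <- rep(0, n)
  true_lfc[roles$de_up] <- config$lfc_effect
  true_lfc[roles$de_dn] <- -config$lfc_effect
  age_lfc <- rep(0, n)
  age_lfc[age_idx] <- sample(c(-1, 1), length(age_idx),
                             replace = TRUE) * config$lfc_effect

  # ectopic genes: silent in WT, expressed in mutant, on the RPKM
  # scale; the derepressed cluster reaches high mutant expression
  # (its genes rank among the most upregulated, like the reporter
  # cluster it emulates) while other ectopic genes stay moderate
  nominal_lib <- sum(mu0)
  in_cluster <- ectopic_idx %in% cluster_idx
  wt_rpkm <- stats::runif(length(ectopic_idx), 0.1, 0.5)
  mut_rpkm <- ifelse(in_cluster,
                     stats::runif(length(ectopic_idx), 20, 60),
                     stats::runif(length(ectopic_idx), 5, 10))
  mu_wt_ect <- wt_rpkm * nominal_lib * len[ectopic_idx] / 1e9
  mu_mut_ect <- mut_rpkm * nominal_lib * len[ectopic_idx] / 1e9

  depth <- if (config$depth_variation > 0)
    stats::runif(ns, 1 - config$depth_variation,
                 1 + config$depth_variation) else rep(1, ns)
  gcc <- gc - 0.5
  gbias <- matrix(1, n, ns)
  if (config$gc_bias_amplitude > 0) {
    for (j in seq_len(ns)) {
      q1 <- stats::runif(1, -1, 1) * config$gc_bias_amplitude
      q2 <- stats::runif(1, -1, 1) * config$gc_bias_amplitude
      b <- q1 * 2 * gcc + q2 * (8 * gcc^2 - 1)
      g <- 2^b
      gbias[, j] <- g / exp(mean(log(g)))
    }
  }

  counts <- matrix(0L, n, ns, dimnames = list(gene_ids, sample_ids))
  is_mut <- sample_meta$genotype == "mut"
  is_d2 <- sample_meta$age == "d2"
  for (j in seq_len(ns)) {
    mu <- mu0 * 2^(age_lfc * is_d2[j])
    if (is_mut[j]) mu <- mu * 2^true_lfc
    mu[ectopic_idx] <- if (is_mut[j]) mu_mut_ect else mu_wt_ect
    mu <- mu * depth[j] * gbias[, j]
    counts[, j] <- .rnb(n, mu, config$dispersion)
  }
  sample_meta$library_size <- colSums(counts)

  feature_meta <- data.frame(length = len, gc_fraction = gc,
                             chrom = chrom, start = start, end = end,
                             strand = "+", class = "gene",
                             row.names = gene_ids,
                             stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = gene_ids,
                      is_de = seq_len(n) %in% de_idx,
                      true_lfc = true_lfc,
                      is_age = seq_len(n) %in% age_idx,
                      is_ectopic = seq_len(n) %in% ectopic_idx,
                      in_cluster = seq_len(n) %in% cluster_idx,
                      is_testis_like = seq_len(n) %in% roles$testis_like,
                      stringsAsFactors = FALSE)
  list(counts = count_matrix(counts, sample_meta, feature_meta),
       truth = truth)
}

# place one set of peak intervals around planted summit positions
.peaks_from_summits <- function(chrom, summit, width, score,
                                genome_length) {
  start <- pmax(0, round(summit - width / 2))
  end <- pmin(genome_length, start + width)
  keep <- start < end & summit >= start & summit < end
  genomic_intervals(chrom[keep], start[keep], end[keep],
                    score = score[keep],
                    summit_offset = summit[keep] - start[keep])
}

#' Generate a synthetic ChIP experiment with planted truth
#'
#' Produces IP peak sets for 2 antibodies x 2 replicates plus a mock
#' peak set over a small synthetic genome, gene models, and a repeat /
#' genomic-bin count matrix for IP-vs-mock enrichment. Planted
#' promoter-proximal peaks have summits 150 bp upstream of a TSS
#' (strand-aware) with Gaussian jitter (sd 50 bp); the remainder are
#' uniform. Mock peaks are a small random subset of true sites plus
#' noise. Enriched repeats carry a sub-2-fold planted IP/mock ratio;
#' genomic bins carry none.
#'
#' @param config a [sim_config].
#' @return list with `ip_peaks` (named list of 4 [genomic_intervals]),
#'   `mock_peaks`, `gene_models`, `repeat_counts` (a [count_matrix]),
#'   `workspace` (a [genome_workspace]) and `truth` (list `peaks`,
#'   `repeats`).
#' @export
generate_chip_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  G <- config$genome_length
  chroms <- c(chrA = G, chrB = G)
  ws <- genome_workspace(chroms)

  ng <- config$n_chip_genes
  gchrom <- sample(names(chroms), ng, replace = TRUE)
  tss <- round(stats::runif(ng, 5000, G - 5000))
  strand <- sample(c("+", "-"), ng, replace = TRUE)
  body_len <- round(stats::runif(ng, 1000, 4000))
  gm <- gene_models(sprintf("cg%04d", seq_len(ng)), gchrom,
                    ifelse(strand == "+", tss, tss - body_len + 1),
                    ifelse(strand == "+", tss + body_len, tss + 1),
                    strand)

  np <- config$n_peaks
  n_prom <- round(config$peak_frac_promoter * np)
  target <- sample.int(ng, n_prom, replace = (n_prom > ng))
  jitter <- stats::rnorm(n_prom, 0, 50)
  summit_prom <- ifelse(strand[target] == "+",
                        tss[target] - 150 + jitter,
                        tss[target] + 150 - jitter)
  chrom_prom <- gchrom[target]
  n_bg <- np - n_prom
  chrom_bg <- sample(names(chroms), n_bg, replace = TRUE)
  summit_bg <- round(stats::runif(n_bg, 1000, G - 1000))
  true_chrom <- c(chrom_prom, chrom_bg)
  true_summit <- round(c(summit_prom, summit_bg))
  true_width <- round(stats::runif(np, 300, 700))
  is_promoter <- c(rep(TRUE, n_prom), rep(FALSE, n_bg))

  ip_peaks <- list()
  for (ab in c("ab76", "ab77")) {
    for (r in c("r1", "r2")) {
      shift <- round(stats::rnorm(np, 0, 20))
      score <- stats::runif(np, 2, 6)
      pk <- .peaks_from_summits(true_chrom, true_summit + shift,
                                true_width, score, G)
      n_noise <- round(0.1 * np)
      noise <- .peaks_from_summits(
        sample(names(chroms), n_noise, replace = TRUE),
        round(stats::runif(n_noise, 1000, G - 1000)),
        round(stats::runif(n_noise, 300, 700)),
        stats::runif(n_noise, 1, 2), G)
      ip_peaks[[paste(ab, r, sep = "_")]] <-
        genomic_intervals(c(pk$chrom, noise$chrom),
                          c(pk$start, noise$start),
                          c(pk$end, noise$end),
                          score = c(pk$score, noise$score),
                          summit_offset = c(pk$summit_offset,
                                            noise$summit_offset))
    }
  }
  n_mock_true <- max(1, round(0.03 * np))
  pick <- sample.int(np, n_mock_true)
  n_mock_noise <- max(1, round(0.05 * np))
  mock <- .peaks_from_summits(
    c(true_chrom[pick],
      sample(names(chroms), n_mock_noise, replace = TRUE)),
    c(true_summit[pick],
      round(stats::runif(n_mock_noise, 1000, G - 1000))),
    round(stats::runif(n_mock_true + n_mock_noise, 300, 700)),
    stats::runif(n_mock_true + n_mock_noise, 1, 2), G)

  # repeat + genomic-bin counts over 2 antibodies x 2 reps x IP/mock
  nr <- config$n_repeats
  nb <- config$n_bins
  n_enriched <- round(config$frac_repeat_enriched * nr)
  rep_ids <- sprintf("repeat%03d", seq_len(nr))
  bin_ids <- sprintf("bin%05d", seq_len(nb))
  sm <- expand.grid(condition = c("mock", "IP"),
                    replicate = c("r1", "r2"),
                    antibody = c("ab76", "ab77"),
                    stringsAsFactors = FALSE)
  sm$condition <- factor(sm$condition, levels = c("mock", "IP"))
  rownames(sm) <- with(sm, paste(antibody, replicate, condition,
                                 sep = "_"))
  mu_rep <- stats::rlnorm(nr, log(500), 0.8)
  mu_bin <- stats::rlnorm(nb, log(100), 0.3)
  fold <- rep(1, nr)
  fold[seq_len(n_enriched)] <- config$repeat_ip_fold
  depth <- stats::runif(nrow(sm), 0.8, 1.2)
  cnt <- matrix(0L, nr + nb, nrow(sm),
                dimnames = list(c(rep_ids, bin_ids), rownames(sm)))
  for (j in seq_len(nrow(sm))) {
    f <- if (sm$condition[j] == "IP") fold else rep(1, nr)
    mu <- c(mu_rep * f, mu_bin) * depth[j]
    cnt[, j] <- .rnb(nr + nb, mu, config$chip_dispersion)
  }
  bin_start <- ((seq_len(nb) - 1) %% (G %/% 1000)) * 1000
  fm <- data.frame(
    length = c(rep(1000, nr), rep(1000, nb)),
    gc_fraction = stats::runif(nr + nb, 0.3, 0.7),
    chrom = c(rep(NA_character_, nr),
              rep(names(chroms), length.out = nb)),
    start = c(rep(NA_real_, nr), bin_start),
    end = c(rep(NA_real_, nr), bin_start + 1000),
    strand = ".", class = c(rep("repeat", nr), rep("genomic_bin", nb)),
    row.names = c(rep_ids, bin_ids), stringsAsFactors = FALSE)

  list(ip_peaks = ip_peaks, mock_peaks = mock, gene_models = gm,
       repeat_counts = count_matrix(cnt, sm, fm), workspace = ws,
       truth = list(
         peaks = data.frame(chrom = true_chrom, summit = true_summit,
                            is_promoter_proximal = is_promoter,
                            stringsAsFactors = FALSE),
         repeats = data.frame(feature_id = rep_ids, true_fold = fold,
                              stringsAsFactors = FALSE)))
}
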