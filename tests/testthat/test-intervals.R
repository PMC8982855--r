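test_that("merge unifies overlapping and book-ended intervals", {
  m <- merge_intervals(genomic_intervals(c("c", "c"), c(0, 5),
                                         c(10, 15)))
  expect_equal(m$start, 0); expect_equal(m$end, 15)
  m2 <- merge_intervals(genomic_intervals(c("c", "c"), c(0, 10),
                                          c(10, 20)))
  expect_equal(nrow(m2), 1); expect_equal(m2$end, 20)
  # scores max-aggregate; idempotence
  x <- genomic_intervals(c("c", "c", "d"), c(0, 5, 0), c(10, 15, 5),
                         score = c(1, 7, 2))
  m3 <- merge_intervals(x)
  expect_equal(m3$score[m3$chrom == "c"], 7)
  expect_equal(merge_intervals(m3)[c("chrom", "start", "end")],
               m3[c("chrom", "start", "end")], ignore_attr = TRUE)
})

test_that("merge preserves the covered base set on random instances", {
  set.seed(71)
  for (i in 1:100) {
    x <- random_intervals(sample(1:15, 1))
    m <- merge_intervals(x)
    expect_setequal(base_set(m$chrom, m$start, m$end),
                    base_set(x$chrom, x$start, x$end))
    # merged output is disjoint and sorted with gaps
    for (ch in unique(m$chrom)) {
      s <- m[m$chrom == ch, ]
      if (nrow(s) > 1)
        expect_true(all(s$start[-1] > s$end[-nrow(s)]))
    }
  }
})

test_that("merge and subtract agree with GenomicRanges", {
  set.seed(72)
  for (i in 1:25) {
    x <- random_intervals(sample(2:12, 1))
    m <- merge_intervals(x)
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      factor(x$chrom, levels = sort(unique(x$chrom))),
      IRanges::IRanges(x$start + 1, x$end)))
    expect_equal(m$start, GenomicRanges::start(gr) - 1)
    expect_equal(m$end, GenomicRanges::end(gr))
    y <- random_intervals(sample(1:6, 1))
    sub <- subtract_whole(x, y, mode = "portion")
    grs <- GenomicRanges::setdiff(
      GenomicRanges::GRanges(x$chrom,
                             IRanges::IRanges(x$start + 1, x$end)),
      GenomicRanges::GRanges(y$chrom,
                             IRanges::IRanges(y$start + 1, y$end)))
    expect_setequal(base_set(sub$chrom, sub$start, sub$end),
                    base_set(as.character(GenomicRanges::seqnames(grs)),
                             GenomicRanges::start(grs) - 1,
                             GenomicRanges::end(grs)))
  }
})

test_that("whole-peak subtraction drops any peak touching the blacklist", {
  pk <- genomic_intervals(c("c", "c"), c(100, 300), c(200, 400))
  bl <- genomic_intervals("c", 150, 160)
  out <- subtract_whole(pk, bl)
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 300)
  # portion mode splits instead
  parts <- subtract_whole(pk, bl, mode = "portion")
  expect_equal(parts$start, c(100, 160, 300))
  expect_equal(parts$end, c(150, 200, 400))
  # empty blacklist is the identity
  expect_equal(subtract_whole(pk, genomic_intervals(character(),
                                                    numeric(),
                                                    numeric())),
               pk)
})

test_that("TSS annotation computes signed strand-aware distances", {
  gm <- gene_models(c("plus", "minus"), c("c", "c"), c(2000, 2000),
                    c(6000, 6000), c("+", "-"))
  pk <- genomic_intervals("c", 900, 1200)
  ann <- annotate_tss(pk, gm, window = 1000)
  # + gene TSS 2000: peak upstream, last base 1199 -> -801, bound
  t <- ann$table
  expect_equal(t$distance[t$gene_id == "plus"], -801)
  expect_true(t$bound[t$gene_id == "plus"])
  # - gene TSS 5999: peak 4800 bp away, not bound, sign flipped
  expect_equal(t$distance[t$gene_id == "minus"], 4800)
  expect_false(t$bound[t$gene_id == "minus"])
  # TSS inside a peak: distance 0
  inside <- annotate_tss(genomic_intervals("c", 1990, 2100), gm)
  expect_equal(inside$table$distance[1], 0)
  none <- annotate_tss(genomic_intervals(character(), numeric(),
                                         numeric()), gm)
  expect_equal(length(none$bound_genes), 0)
})

test_that("TSS annotation agrees with an all-pairs oracle and nests", {
  set.seed(73)
  for (i in 1:40) {
    pk <- random_intervals(sample(1:10, 1), span_max = 5000,
                           chroms = "c")
    tsspos <- sample.int(5000, 5) - 1
    gm <- gene_models(paste0("g", 1:5), "c", tsspos, tsspos + 500, "+")
    ann <- annotate_tss(pk, gm, window = 300)
    for (g in 1:5) {
      d_all <- vapply(seq_len(nrow(pk)), function(j) {
        if (tsspos[g] >= pk$start[j] && tsspos[g] < pk$end[j]) 0
        else if (pk$start[j] > tsspos[g]) pk$start[j] - tsspos[g]
        else (pk$end[j] - 1) - tsspos[g]
      }, 0)
      expect_equal(ann$table$distance[g], d_all[which.min(abs(d_all))])
    }
    # nestedness in the window
    prev <- character(0)
    for (w in c(100, 300, 1000, 3000)) {
      cur <- annotate_tss(pk, gm, window = w)$bound_genes
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("density profiles bin anchors strand-aware around the TSS", {
  gm <- gene_models(c("p", "m"), c("c", "c"), c(10000, 20000),
                    c(12000, 22000), c("+", "-"))
  # one peak 150 bp upstream of each TSS in genome coordinates
  pk <- genomic_intervals(c("c", "c"), c(9650, 21950), c(10050, 22350),
                          summit_offset = c(200, 199))
  # + gene: summit 9850 = TSS - 150; - gene TSS 21999, summit 22149
  prof <- density_profile(pk, gm, flank = 2000, bin = 50)
  hit_bins <- prof$mids[prof$counts > 0]
  expect_true(all(hit_bins == -125))
  expect_equal(sum(prof$counts), 2)
  expect_equal(sum(prof$freq), 1)
  expect_error(density_profile(pk, gm, flank = 2000, bin = 33),
               "divisible")
  # summit anchor demands summit offsets
  pk2 <- genomic_intervals("c", 9650, 10050)
  expect_error(density_profile(pk2, gm, anchor = "summit"), "summit")
  # conservation: every in-range (peak, gene) pair is counted once
  set.seed(74)
  pk3 <- random_intervals(30, span_max = 30000, chroms = "c")
  pk3$summit_offset <- floor((pk3$end - pk3$start) / 2)
  prof3 <- density_profile(pk3, gm, flank = 2000, bin = 50)
  anchors <- pk3$start + pk3$summit_offset
  pairs <- 0
  for (g in 1:2) {
    rel <- anchors - gm$tss[g]
    if (gm$strand[g] == "-") rel <- -rel
    pairs <- pairs + sum(rel >= -2000 & rel < 2000)
  }
  expect_equal(sum(prof3$counts), pairs)
})

test_that("bin coverage reports percent covered with merge-first", {
  ws <- genome_workspace(c(c1 = 250000))
  pk <- genomic_intervals(c("c1", "c1"), c(0, 10000), c(50000, 50000))
  cov <- bin_coverage(pk, ws, bin = 1e5)
  expect_equal(cov$pct_coverage, c(50, 0, 0))
  full <- bin_coverage(genomic_intervals("c1", 0, 250000), ws,
                       bin = 1e5)
  expect_equal(full$pct_coverage, c(100, 100, 100))
  # final partial bin normalized by its true width
  half <- bin_coverage(genomic_intervals("c1", 200000, 225000), ws,
                       bin = 1e5)
  expect_equal(half$pct_coverage[3], 50)
  expect_true(all(cov$pct_coverage >= 0 & cov$pct_coverage <= 100))
  expect_warning(bin_coverage(genomic_intervals("c1", 240000, 260000),
                              ws, bin = 1e5), "clipped")
})

test_that("bin coverage equals the per-base oracle on random peaks", {
  set.seed(75)
  ws <- genome_workspace(c(cA = 3000, cB = 2500))
  for (i in 1:30) {
    pk <- random_intervals(sample(1:12, 1), span_max = 2200)
    cov <- bin_coverage(pk, ws, bin = 1000)
    covered <- base_set(pk$chrom, pk$start, pmin(pk$end,
      ws$sizes[pk$chrom]))
    for (r in seq_len(nrow(cov))) {
      inbin <- base_set(cov$chrom[r], cov$start[r], cov$end[r])
      expect_equal(cov$pct_coverage[r],
                   100 * sum(inbin %in% covered) /
                     (cov$end[r] - cov$start[r]))
    }
  }
})

test_that("randomized overlap enrichment is seeded and sane", {
  ws <- genome_workspace(c(c1 = 50000))
  q <- genomic_intervals(rep("c1", 3), c(100, 5000, 9000),
                         c(400, 5400, 9400))
  ref <- genomic_intervals("c1", c(200), c(6000))
  e1 <- randomized_overlap_enrichment(q, ref, ws, n_sims = 200,
                                      seed = 5)
  e2 <- randomized_overlap_enrichment(q, ref, ws, n_sims = 200,
                                      seed = 5)
  expect_identical(e1$sim_overlaps, e2$sim_overlaps)
  expect_gt(e1$empirical_p, 0)
  # reference covering the whole workspace saturates
  sat <- randomized_overlap_enrichment(
    q, genomic_intervals("c1", 0, 50000), ws, n_sims = 100, seed = 1)
  expect_equal(sat$fold_enrichment, 1)
  expect_equal(sat$empirical_p, 1)
  expect_warning(randomized_overlap_enrichment(q, ref, ws, n_sims = 50,
                                               seed = 1), "coarse")
  expect_error(randomized_overlap_enrichment(
    genomic_intervals("c1", 0, 60000), ref, ws, n_sims = 100,
    seed = 1), "longer")
})

test_that("excluded workspace regions are never sampled", {
  excl <- genomic_intervals("c1", 0, 40000)
  ws <- genome_workspace(c(c1 = 50000), excluded = excl)
  q <- genomic_intervals("c1", 45000, 45500)
  ref <- genomic_intervals("c1", 0, 40000)
  e <- randomized_overlap_enrichment(q, ref, ws, n_sims = 100, seed = 2)
  expect_equal(max(e$sim_overlaps), 0)
})
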