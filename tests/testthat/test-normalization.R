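test_that("the low-count filter removes means at or below threshold", {
  cnt <- rbind(exactly10 = c(10L, 10L, 10L),
               just_over = c(11L, 10L, 10L),
               high = c(100L, 90L, 110L))
  colnames(cnt) <- paste0("s", 1:3)
  kept <- filter_low_count(make_cm(cnt))
  expect_setequal(rownames(kept$counts), c("just_over", "high"))
  zero <- make_cm(matrix(0L, 3, 3))
  expect_warning(out <- filter_low_count(zero), "no feature")
  expect_equal(nrow(out$counts), 0)
})

test_that("a single GC stratum makes within-lane normalization a no-op", {
  set.seed(21)
  cnt <- matrix(rpois(50 * 3, 40), 50, 3)
  fm <- data.frame(gc_fraction = runif(50),
                   row.names = sprintf("f%04d", 1:50))
  cm <- make_cm(cnt, feature_meta = fm)
  out <- within_lane_gc_fqn(cm, n_strata = 1)
  expect_equal(out$normalized_counts, cm$counts, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("GC strata with shifted distributions are equalized", {
  set.seed(22)
  base <- stats::rlnorm(300, log(50), 0.5)
  # low-GC features carry a 3x multiplicative bias
  cnt <- matrix(round(c(3 * base[1:150], base[151:300])), ncol = 1)
  fm <- data.frame(gc_fraction = c(runif(150, 0.2, 0.45),
                                   runif(150, 0.55, 0.8)),
                   row.names = sprintf("f%04d", 1:300))
  cm <- make_cm(cbind(cnt, cnt), feature_meta = fm)
  out <- within_lane_gc_fqn(cm, n_strata = 2)
  norm <- out$normalized_counts[, 1]
  med_low <- median(norm[out$strata == 1])
  med_high <- median(norm[out$strata == 2])
  expect_lt(abs(med_low - med_high) / med_high, 0.1)
  # the within-stratum map is monotone: sorting by input sorts the
  # output (new ties may appear where the reference repeats values)
  for (k in 1:2) {
    sel <- out$strata == k
    o <- order(cm$counts[sel, 1])
    expect_true(all(diff(norm[sel][o]) >= -1e-9))
  }
})

test_that("within-lane normalization is idempotent up to interpolation", {
  set.seed(23)
  cnt <- matrix(rnbinom(400 * 2, mu = 60, size = 2), 400, 2)
  fm <- data.frame(gc_fraction = runif(400),
                   row.names = sprintf("f%04d", 1:400))
  cm <- make_cm(cnt, feature_meta = fm)
  once <- within_lane_gc_fqn(cm, 5)
  cm2 <- count_matrix(round(once$normalized_counts), cm$sample_meta,
                      cm$feature_meta)
  twice <- within_lane_gc_fqn(cm2, 5)
  rel <- abs(twice$normalized_counts - round(once$normalized_counts)) /
    (round(once$normalized_counts) + 1)
  expect_lt(median(rel), 0.05)
})

test_that("between-lane normalization equalizes sorted count vectors", {
  a <- c(2, 9, 30, 100)
  m <- cbind(s1 = a, s2 = 2 * a)
  rownames(m) <- paste0("f", 1:4)
  out <- between_lane_fqn(m)$normalized_counts
  expect_equal(out[, 1], 1.5 * a, ignore_attr = TRUE)
  expect_equal(out[, 2], 1.5 * a, ignore_attr = TRUE)
  # identical samples are a fixed point
  same <- cbind(s1 = a, s2 = a)
  rownames(same) <- paste0("f", 1:4)
  expect_equal(between_lane_fqn(same)$normalized_counts, same,
               tolerance = 1e-12)
  # general: sorted columns identical (tie-free input), ranks preserved
  set.seed(24)
  r <- matrix(rlnorm(200 * 4, log(30), 1) *
                rep(c(1, 2, 5, 1), each = 200),
              200, 4, dimnames = list(paste0("f", 1:200), paste0("s", 1:4)))
  n <- between_lane_fqn(r)$normalized_counts
  sorted <- apply(n, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-8)
  for (j in 1:4)
    expect_equal(rank(n[, j], ties.method = "average"),
                 rank(r[, j], ties.method = "average"))
})

test_that("stratified between-lane normalization equalizes per stratum", {
  set.seed(26)
  m <- matrix(rlnorm(200 * 3, log(40), 0.8), 200, 3,
              dimnames = list(paste0("f", 1:200), paste0("s", 1:3)))
  gc <- runif(200)
  out <- between_lane_fqn(m, gc = gc, n_strata = 4)
  for (k in 1:4) {
    sel <- out$strata == k
    sorted <- apply(out$normalized_counts[sel, ], 2, sort)
    expect_lt(max(abs(sorted - sorted[, 1])), 1e-8)
  }
})

test_that("offsets encode the raw / normalized ratio", {
  raw <- matrix(c(100, 10), 1)
  norm <- matrix(c(50, 10), 1)
  off <- compute_offsets(raw, norm)
  expect_equal(off[1, 1], log(100.1 / 50.1))
  expect_equal(off[1, 2], 0)
  expect_equal(compute_offsets(raw, raw), matrix(0, 1, 2))
  # monotone in the ratio
  expect_gt(compute_offsets(matrix(200), matrix(50))[1, 1],
            compute_offsets(matrix(100), matrix(50))[1, 1])
  expect_error(compute_offsets(matrix(1:4, 2), matrix(1:2, 1)),
               "shapes")
})

test_that("raw counts plus offsets reproduce inference on normalized counts", {
  set.seed(25)
  norm <- matrix(rpois(100 * 6, rep(c(50, 200), each = 300)), 100, 6,
                 dimnames = list(paste0("f", 1:100), paste0("s", 1:6)))
  bias <- matrix(runif(600, 0.5, 2), 100, 6)
  raw <- round(norm * bias)
  off <- compute_offsets(raw, norm)
  X <- cbind(1, rep(c(0, 1), each = 3))
  fit_raw <- fit_nb_glm(raw, X, offsets = off,
                        dispersions = rep(0, 100))
  fit_norm <- fit_nb_glm(round(norm), X,
                         dispersions = rep(0, 100))
  expect_equal(fit_raw$coef_log2[, 2], fit_norm$coef_log2[, 2],
               tolerance = 0.05)
})

test_that("GC full-quantile normalization removes a planted GC bias", {
  cfg <- sim_config(seed = 31, n_genes = 2000, gc_bias_amplitude = 1,
                    depth_variation = 0, frac_de = 0, frac_ectopic = 0,
                    frac_age = 0, cluster_size = 0)
  g <- generate_ovary_counts(cfg)
  cm <- filter_low_count(g$counts)
  gc <- cm$feature_meta$gc_fraction
  cor_raw <- apply(cm$counts, 2, function(x) cor(log1p(x), gc))
  wl <- within_lane_gc_fqn(cm, 10)
  cor_norm <- apply(wl$normalized_counts, 2,
                    function(x) cor(log1p(x), gc))
  worst <- which.max(abs(cor_raw))
  expect_gte(1 - abs(cor_norm[worst]) / abs(cor_raw[worst]), 0.8)
})
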