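test_that("size factors recover planted depth ratios", {
  set.seed(41)
  mu <- rlnorm(500, log(100), 1)
  depth <- c(1, 2, 0.5, 1.5)
  cnt <- sapply(depth, function(d) rpois(500, mu * d))
  rownames(cnt) <- paste0("f", 1:500); colnames(cnt) <- paste0("s", 1:4)
  sf <- estimate_size_factors(cnt)
  expect_equal(sf / sf[1], depth / depth[1], tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("dispersion estimates track the generating regime", {
  set.seed(42)
  n <- 1000
  mu <- rlnorm(n, log(150), 0.8)
  X <- stats::model.matrix(~ rep(c("a", "b"), each = 3))
  pois <- matrix(rpois(n * 6, rep(mu, 6)), n, 6,
                 dimnames = list(paste0("f", 1:n), paste0("s", 1:6)))
  expect_lte(median(estimate_dispersion(pois, X)), 0.05)
  nb <- matrix(rnbinom(n * 6, mu = rep(mu, 6), size = 5), n, 6,
               dimnames = dimnames(pois))
  med <- median(estimate_dispersion(nb, X))
  expect_gte(med, 0.1); expect_lte(med, 0.3)
  const <- matrix(7, 3, 6, dimnames = list(paste0("c", 1:3),
                                           paste0("s", 1:6)))
  expect_equal(unname(estimate_dispersion(const, X)), rep(0, 3))
  # replicates are mandatory
  X1 <- stats::model.matrix(~ factor(1:6))
  expect_error(estimate_dispersion(nb, X1), "replicates")
})

test_that("the NB GLM reduces to log mean ratios in the small-dispersion limit", {
  set.seed(43)
  cnt <- cbind(matrix(rpois(50 * 3, 100), 50, 3),
               matrix(rpois(50 * 3, 400), 50, 3))
  dimnames(cnt) <- list(paste0("f", 1:50), paste0("s", 1:6))
  X <- stats::model.matrix(~ rep(c("a", "b"), each = 3))
  fit <- fit_nb_glm(cnt, X, dispersions = rep(1e-8, 50))
  ratio <- log2(rowMeans(cnt[, 4:6]) / rowMeans(cnt[, 1:3]))
  expect_equal(unname(fit$coef_log2[, 2]), unname(ratio),
               tolerance = 1e-6)
  expect_true(all(fit$converged))
  # identical groups: LFC 0, p near 1
  same <- cbind(cnt[, 1:3], cnt[, 1:3])
  colnames(same) <- paste0("s", 1:6)
  fit0 <- fit_nb_glm(same, X, dispersions = rep(1e-8, 50))
  expect_equal(unname(fit0$coef_log2[, 2]), rep(0, 50),
               tolerance = 1e-6)
  expect_gt(min(wald_test(fit0, 2)$wald_p), 0.99)
  # all-zero features are flagged and excluded
  withzero <- rbind(cnt, zero = rep(0L, 6))
  fz <- fit_nb_glm(withzero, X, dispersions = rep(0.01, 51))
  expect_true(fz$flagged[51])
  expect_true(is.na(wald_test(fz, 2)$wald_p[51]))
})

test_that("Wald ordering agrees with a profile-likelihood-ratio oracle", {
  set.seed(44)
  n <- 20
  mu1 <- rlnorm(n, log(80), 0.7)
  fold <- 2^runif(n, -1.5, 1.5)
  alpha <- 0.1
  cnt <- cbind(matrix(rnbinom(n * 3, mu = rep(mu1, 3), size = 1 / alpha),
                      n, 3),
               matrix(rnbinom(n * 3, mu = rep(mu1 * fold, 3),
                              size = 1 / alpha), n, 3))
  dimnames(cnt) <- list(paste0("f", 1:n), paste0("s", 1:6))
  X <- stats::model.matrix(~ rep(c("a", "b"), each = 3))
  fit <- fit_nb_glm(cnt, X, dispersions = rep(alpha, n))
  w <- wald_test(fit, 2)
  z2 <- (w$lfc_mle / w$se)^2
  # oracle: numeric profile likelihood ratio at the same dispersion
  ll <- function(y, mu) sum(dnbinom(y, mu = mu, size = 1 / alpha,
                                    log = TRUE))
  lrt <- vapply(seq_len(n), function(i) {
    y1 <- cnt[i, 1:3]; y2 <- cnt[i, 4:6]
    l_alt <- ll(y1, mean(y1)) + ll(y2, mean(y2))
    l_null <- ll(c(y1, y2), mean(cnt[i, ]))
    2 * (l_alt - l_null)
  }, 0)
  expect_gte(cor(z2, lrt, method = "spearman"), 0.95)
})

test_that("BH adjustment matches the hand and brute-force step-up", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  fit <- structure(list(
    coef_log2 = matrix(1, 1, 1, dimnames = list("f1", "b")),
    se_log2 = matrix(0.5, 1, 1), flagged = FALSE,
    base_mean = 10), class = "nb_fit")
  w <- wald_test(fit, 1)
  expect_equal(w$fdr, w$wald_p)
  set.seed(45)
  for (i in 1:50) {
    pv <- runif(sample(2:40, 1))
    expect_equal(p.adjust(pv, "BH"), bh_oracle(pv))
  }
})

test_that("LFC shrinkage contracts toward zero without changing sign", {
  b <- c(3, 3, 0.5, -2, 1.5)
  se <- c(0.01, 2, 0.3, 0.4, 100)
  fit <- structure(list(
    coef_log2 = matrix(b, 5, 1,
                       dimnames = list(paste0("f", 1:5), "x")),
    se_log2 = matrix(se, 5, 1), flagged = rep(FALSE, 5),
    base_mean = rep(10, 5)), class = "nb_fit")
  sh <- shrink_lfc(fit, 1, prior_scale = 0.7)
  expect_true(all(abs(sh) <= abs(b) + 1e-8))
  expect_true(all(sign(sh) %in% c(0, sign(b))))
  # data dominates the prior at tiny SE; prior dominates at huge SE
  expect_equal(sh[1], 3, tolerance = 0.01)
  expect_lt(abs(sh[5]), 0.05)
  # equal SE: shrinkage preserves magnitude order (distinct magnitudes)
  b2 <- c(-2.9, -2.2, -1.4, -0.6, 0.2, 0.9, 1.7, 2.5, 3.3)
  fit2 <- structure(list(
    coef_log2 = matrix(b2, 9, 1,
                       dimnames = list(paste0("g", 1:9), "x")),
    se_log2 = matrix(0.5, 9, 1), flagged = rep(FALSE, 9),
    base_mean = rep(10, 9)), class = "nb_fit")
  sh2 <- shrink_lfc(fit2, 1, prior_scale = 0.7)
  expect_equal(order(abs(sh2)), order(abs(b2)))
})

test_that("consistent calls demand same-sign per-age effects", {
  set.seed(46)
  n <- 60
  reps <- 3
  sm <- expand.grid(replicate = 1:reps, age = c("d0", "d2"),
                    genotype = c("wt", "mut"))
  sm$genotype <- factor(sm$genotype, levels = c("wt", "mut"))
  sm$age <- factor(sm$age)
  rownames(sm) <- paste0("s", seq_len(nrow(sm)))
  mu <- rlnorm(n, log(200), 0.3)
  # gene 1: up at both ages; gene 2: opposite signs by age
  cnt <- sapply(seq_len(nrow(sm)), function(j) {
    m <- mu
    if (sm$genotype[j] == "mut") {
      m[1] <- m[1] * 4
      m[2] <- m[2] * ifelse(sm$age[j] == "d0", 6, 1 / 6)
    }
    rnbinom(n, mu = m, size = 20)
  })
  dimnames(cnt) <- list(paste0("f", 1:n), rownames(sm))
  cm <- count_matrix(cnt, sm)
  res <- consistent_de_call(cm, alpha = 0.01)
  expect_true("f1" %in% res$called)
  expect_false("f2" %in% res$called)
  # strict mode also drops the interaction gene
  res_strict <- consistent_de_call(cm, alpha = 0.01, strict = TRUE)
  expect_false("f2" %in% res_strict$called)
  # all four groups are mandatory
  cm3 <- cm[, sm$genotype == "wt" | sm$age == "d0"]
  expect_error(consistent_de_call(cm3), "group")
})

test_that("repeat enrichment needs its genomic-bin anchor", {
  set.seed(47)
  cnt <- matrix(rpois(20 * 4, 50), 20, 4,
                dimnames = list(paste0("r", 1:20), paste0("s", 1:4)))
  sm <- data.frame(condition = c("mock", "IP", "mock", "IP"),
                   antibody = c("a", "a", "b", "b"),
                   replicate = c("r1", "r1", "r2", "r2"),
                   row.names = colnames(cnt))
  fm <- data.frame(class = rep("repeat", 20),
                   row.names = rownames(cnt))
  expect_error(repeat_enrichment(count_matrix(cnt, sm, fm)),
               "genomic_bin")
  # no repeats: empty result, not an error
  fm2 <- data.frame(class = rep("genomic_bin", 20),
                    row.names = rownames(cnt))
  out <- repeat_enrichment(count_matrix(cnt, sm, fm2))
  expect_equal(nrow(out), 0)
})

test_that("RPKM follows its unit definition and scaling laws", {
  cnt <- matrix(c(1000, 0), 2, 1,
                dimnames = list(c("a", "b"), "s1"))
  # library 1e6, length 1 kb, size factor 1 -> RPKM 1000
  cnt[2, 1] <- 1e6 - 1000
  r <- rpkm(cnt, lengths = c(1000, 2000), size_factors = 1)
  expect_equal(r["a", 1], 1000)
  r2 <- rpkm(cnt, lengths = c(2000, 2000), size_factors = 1)
  expect_equal(r2["a", 1], 500)
  expect_equal(unname(rpkm(matrix(c(0, 10), 2,
                                  dimnames = list(c("z", "y"), NULL)),
                           lengths = c(1000, 1000),
                           size_factors = 1)["z", 1]),
               0)
  expect_error(rpkm(matrix(0, 2, 1), lengths = c(1, 1),
                    size_factors = 1), "library")
  expect_error(rpkm(matrix(1:2, 2, 1), lengths = c(0, 1)), "lengths")
})
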