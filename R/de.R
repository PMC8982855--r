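#' Median-of-ratios size factors
#'
#' Library-size factors computed against the geometric-mean
#' pseudo-reference over features, the standard count-based estimator.
#'
#' @param counts features x samples matrix (or [count_matrix]).
#' @param features optional subset of feature ids/indices to anchor the
#'   estimate on (e.g. genomic bins for ChIP enrichment).
#' @return numeric vector of per-sample size factors.
#' @export
estimate_size_factors <- function(counts, features = NULL) {
  m <- .as_counts(counts)
  if (!is.null(features)) m <- m[features, , drop = FALSE]
  logm <- log(m)
  loggeo <- rowMeans(logm)
  use <- is.finite(loggeo)
  if (!any(use)) stop("no feature with all-positive counts")
  sf <- apply(logm[use, , drop = FALSE], 2, function(lc)
    exp(stats::median(lc - loggeo[use])))
  sf
}

.design_matrix <- function(sample_meta, design) {
  X <- stats::model.matrix(design, data = sample_meta)
  if (qr(X)$rank < ncol(X)) stop("design matrix is not full rank")
  X
}

# index of the (single) coefficient for a two-level test factor
.test_coef <- function(X, design, test_factor) {
  assign <- attr(X, "assign")
  labels <- attr(stats::terms(design), "term.labels")
  hit <- which(labels == test_factor)
  if (!length(hit)) stop("test factor '", test_factor, "' not in design")
  cols <- which(assign == hit)
  if (length(cols) != 1)
    stop("test factor must have exactly 2 levels")
  cols
}

#' Per-feature NB dispersion by moments with trend shrinkage
#'
#' For each feature a method-of-moments estimate
#' `alpha = max(0, (s2 - mu) / mu^2)` is computed from the design-group
#' residuals of offset-corrected counts (`s2` pooled within-group
#' variance, `mu` overall mean), then shrunk 50/50 on the log scale
#' toward a parametric mean-dispersion trend `a0 + a1 / mu` fitted
#' across features. Because the per-feature estimate carries very few
#' degrees of freedom, estimates falling below the trend are floored at
#' it before the shrink (downward excursions at this sample size are
#' indistinguishable from sampling noise, and propagating them
#' deflates Wald standard errors). Features with exactly zero residual
#' variance keep `alpha = 0`.
#'
#' @param counts features x samples matrix or [count_matrix].
#' @param design model formula over the sample metadata, or a model
#'   matrix; groups are the distinct design rows.
#' @param offsets natural-log offset matrix (default 0).
#' @param sample_meta data.frame needed when `design` is a formula and
#'   `counts` is a bare matrix.
#' @return numeric vector of per-feature dispersions (>= 0).
#' @export
estimate_dispersion <- function(counts, design, offsets = NULL,
                                sample_meta = NULL) {
  m <- .as_counts(counts)
  if (inherits(counts, "count_matrix") && is.null(sample_meta))
    sample_meta <- counts$sample_meta
  X <- if (inherits(design, "formula"))
    .design_matrix(sample_meta, design) else as.matrix(design)
  if (is.null(offsets)) offsets <- matrix(0, nrow(m), ncol(m))
  q <- m / exp(offsets)
  grp <- interaction(as.data.frame(X), drop = TRUE)
  sizes <- table(grp)
  if (sum(sizes - 1) < 1)
    stop("dispersion estimation requires replicates in at least one group")
  gidx <- split(seq_len(ncol(m)), grp)
  mu <- rowMeans(q)
  s2 <- rep(0, nrow(m)); df <- 0
  for (g in gidx) {
    if (length(g) < 2) next
    qg <- q[, g, drop = FALSE]
    vg <- apply(qg, 1, stats::var)
    s2 <- s2 + (length(g) - 1) * vg
    df <- df + length(g) - 1
  }
  s2 <- s2 / df
  alpha_mom <- pmax(0, (s2 - mu) / mu^2)
  alpha_mom[!is.finite(alpha_mom)] <- 0
  usable <- mu > 0 & is.finite(s2)
  if (sum(usable) >= 10) {
    tr <- stats::lm(alpha_mom[usable] ~ I(1 / mu[usable]))
    trend <- pmax(stats::coef(tr)[1] + stats::coef(tr)[2] /
                    pmax(mu, .Machine$double.eps), 1e-6)
    out <- sqrt(pmax(alpha_mom, trend) * trend)
  } else {
    out <- alpha_mom
  }
  # degenerate features with no residual variance at all
  out[s2 == 0] <- 0
  names(out) <- rownames(m)
  out
}

.nb_deviance <- function(y, mu, alpha) {
  mu <- pmax(mu, 1e-10)
  if (alpha <= 0) {
    2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  } else {
    t1 <- ifelse(y > 0, y * log(y / mu), 0)
    t2 <- (y + 1 / alpha) * log((1 + alpha * y) / (1 + alpha * mu))
    2 * sum(t1 - t2)
  }
}

#' Fit per-feature negative-binomial log-link GLMs
#'
#' Iteratively reweighted least squares with fixed per-feature dispersion
#' (variance `mu + alpha * mu^2`), natural-log link plus offsets.
#' Convergence is declared at a deviance tolerance of 1e-8 within 100
#' iterations; non-converged and all-zero features are flagged (all-zero
#' features have undefined coefficients and are excluded from testing).
#'
#' @param counts features x samples matrix or [count_matrix].
#' @param design model formula (with `sample_meta`) or model matrix.
#' @param offsets natural-log offset matrix (default 0).
#' @param dispersions per-feature dispersion vector (default estimated).
#' @param sample_meta data.frame of per-sample factors for formula
#'   designs.
#' @return an object of class `nb_fit`: list with `coef_log2`, `se_log2`
#'   (features x coefficients), `converged`, `flagged`, `dispersions`,
#'   `base_mean` (mean offset-corrected count), `design_matrix`.
#' @export
fit_nb_glm <- function(counts, design, offsets = NULL, dispersions = NULL,
                       sample_meta = NULL) {
  m <- .as_counts(counts)
  if (inherits(counts, "count_matrix") && is.null(sample_meta))
    sample_meta <- counts$sample_meta
  X <- if (inherits(design, "formula"))
    .design_matrix(sample_meta, design) else as.matrix(design)
  if (qr(X)$rank < ncol(X)) stop("design matrix is not full rank")
  if (is.null(offsets)) offsets <- matrix(0, nrow(m), ncol(m))
  if (is.null(dispersions))
    dispersions <- estimate_dispersion(m, X, offsets, sample_meta)
  p <- ncol(X)
  nfeat <- nrow(m)
  beta_out <- matrix(NA_real_, nfeat, p,
                     dimnames = list(rownames(m), colnames(X)))
  se_out <- beta_out
  converged <- logical(nfeat)
  flagged <- logical(nfeat)
  for (i in seq_len(nfeat)) {
    y <- m[i, ]
    o <- offsets[i, ]
    if (all(y == 0)) { flagged[i] <- TRUE; next }
    alpha <- dispersions[i]
    mu <- pmax(y, 0.5)
    eta <- log(mu)
    dev_old <- Inf
    ok <- FALSE
    beta <- NULL
    for (it in seq_len(100)) {
      w <- mu / (1 + alpha * mu)
      z <- (eta - o) + (y - mu) / mu
      xtw <- crossprod(X, w * X)
      beta <- tryCatch(solve(xtw, crossprod(X, w * z)),
                       error = function(e) NULL)
      if (is.null(beta)) break
      eta <- pmin(pmax(drop(X %*% beta) + o, -30), 30)
      mu <- exp(eta)
      dev <- .nb_deviance(y, mu, alpha)
      if (is.finite(dev) && abs(dev - dev_old) <
            1e-8 * (abs(dev) + 0.1)) { ok <- TRUE; break }
      dev_old <- dev
    }
    if (is.null(beta)) { flagged[i] <- TRUE; next }
    converged[i] <- ok
    w <- mu / (1 + alpha * mu)
    cov <- tryCatch(solve(crossprod(X, w * X)), error = function(e) NULL)
    if (is.null(cov)) { flagged[i] <- TRUE; next }
    beta_out[i, ] <- drop(beta) / log(2)
    se_out[i, ] <- sqrt(pmax(diag(cov), 0)) / log(2)
  }
  structure(list(coef_log2 = beta_out, se_log2 = se_out,
                 converged = converged, flagged = flagged,
                 dispersions = dispersions,
                 base_mean = rowMeans(m / exp(offsets)),
                 design_matrix = X),
            class = "nb_fit")
}

#' Wald tests with Benjamini-Hochberg correction
#'
#' Two-sided normal test of a fitted coefficient (`z = lfc / se`), with
#' BH adjustment over all testable features. Features with zero or
#' undefined standard error are flagged and excluded from the adjustment
#' family.
#'
#' @param fit an `nb_fit` from [fit_nb_glm()].
#' @param coef coefficient name or column index to test.
#' @return a data.frame of class `de_result` with columns `feature_id`,
#'   `base_mean`, `lfc_mle`, `se`, `wald_p`, `fdr`.
#' @export
wald_test <- function(fit, coef = ncol(fit$coef_log2)) {
  b <- fit$coef_log2[, coef]
  se <- fit$se_log2[, coef]
  testable <- !fit$flagged & is.finite(b) & is.finite(se) & se > 0
  p <- rep(NA_real_, length(b))
  p[testable] <- 2 * stats::pnorm(-abs(b[testable] / se[testable]))
  fdr <- rep(NA_real_, length(b))
  fdr[testable] <- stats::p.adjust(p[testable], method = "BH")
  out <- data.frame(feature_id = rownames(fit$coef_log2),
                    base_mean = fit$base_mean,
                    lfc_mle = b, se = se, wald_p = p, fdr = fdr,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("de_result", "data.frame")
  out
}

# penalized objective for Cauchy-prior MAP shrinkage (natural-log scale)
.map_shrink_one <- function(bhat, se, scale) {
  if (!is.finite(bhat) || !is.finite(se)) return(NA_real_)
  if (se <= 0) return(bhat)
  f <- function(b) (b - bhat)^2 / (2 * se^2) + log1p((b / scale)^2)
  if (bhat == 0) return(0)
  stats::optimize(f, interval = sort(c(0, bhat)))$minimum
}

#' Shrink log fold-changes under a heavy-tailed prior
#'
#' Maximum-a-posteriori estimate of each feature's LFC under a
#' zero-centered Cauchy prior on the tested coefficient, reducing the
#' variability of LFC estimates for low-count features. The shrunken
#' estimate never exceeds the MLE in magnitude and never flips sign;
#' shrinkage vanishes as the standard error tends to zero. The prior
#' scale is chosen by maximizing the approximate marginal likelihood over
#' the feature panel (normal likelihood integrated against the prior),
#' unless supplied.
#'
#' @param fit an `nb_fit`.
#' @param coef coefficient to shrink (default last).
#' @param prior_scale optional fixed Cauchy scale (natural-log units).
#' @return numeric vector of shrunken log2 fold-changes.
#' @export
shrink_lfc <- function(fit, coef = ncol(fit$coef_log2),
                       prior_scale = NULL) {
  b_ln <- fit$coef_log2[, coef] * log(2)
  se_ln <- fit$se_log2[, coef] * log(2)
  usable <- is.finite(b_ln) & is.finite(se_ln) & se_ln > 0
  if (is.null(prior_scale)) {
    prior_scale <- .marginal_scale(b_ln[usable], se_ln[usable])
  }
  out <- rep(NA_real_, length(b_ln))
  out[usable] <- vapply(which(usable), function(i)
    .map_shrink_one(b_ln[i], se_ln[i], prior_scale), 0)
  # features fit without error (se = 0, data fully informative)
  exact <- is.finite(b_ln) & is.finite(se_ln) & se_ln == 0
  out[exact] <- b_ln[exact]
  out / log(2)
}

# approximate marginal likelihood of the Cauchy scale on the panel
.marginal_scale <- function(b, se, grid = exp(seq(log(0.05), log(4),
                                                  length.out = 12))) {
  if (!length(b)) return(1)
  n <- length(b)
  if (n > 2000) {
    keep <- seq(1, n, length.out = 2000)
    b <- b[keep]; se <- se[keep]
  }
  ll <- vapply(grid, function(s) {
    sum(vapply(seq_along(b), function(i) {
      width <- 6 * max(se[i], s / 4)
      bb <- seq(b[i] - width, b[i] + width, length.out = 41)
      dens <- stats::dnorm(b[i], bb, se[i]) * stats::dcauchy(bb, 0, s)
      log(max(sum(dens) * (bb[2] - bb[1]), 1e-300))
    }, 0))
  }, 0)
  grid[which.max(ll)]
}

#' Negative-binomial differential expression
#'
#' One-stop wrapper around the engine: dispersion estimation, NB GLM fit
#' with offsets, Wald test with BH correction and heavy-tailed-prior LFC
#' shrinkage for a two-level test factor.
#'
#' @param counts a [count_matrix] (or matrix plus `sample_meta`).
#' @param design model formula over the sample factors, e.g.
#'   `~ age + genotype`.
#' @param test_factor name of the tested two-level factor (default the
#'   last term of `design`).
#' @param offsets natural-log offset matrix from [compute_offsets()]
#'   (default 0: size factors should then be folded into offsets by the
#'   caller, or counts assumed comparable).
#' @param alpha FDR threshold recorded for calling (default 0.01).
#' @param shrink logical; compute shrunken LFCs (default TRUE).
#' @param sample_meta data.frame of per-sample factors when `counts` is a
#'   bare matrix.
#' @param dispersions optional per-feature dispersions.
#' @return an object of class `nb_de`: list with `results` (data.frame
#'   `feature_id`, `base_mean`, `lfc_mle`, `lfc_shrunk`, `se`, `wald_p`,
#'   `fdr`, `called`), `fit`, `test_coef`, `alpha`.
#' @export
nb_de <- function(counts, design, test_factor = NULL, offsets = NULL,
                  alpha = 0.01, shrink = TRUE, sample_meta = NULL,
                  dispersions = NULL) {
  if (inherits(counts, "count_matrix") && is.null(sample_meta))
    sample_meta <- counts$sample_meta
  X <- .design_matrix(sample_meta, design)
  if (is.null(test_factor))
    test_factor <- utils::tail(attr(stats::terms(design),
                                    "term.labels"), 1)
  coef_idx <- .test_coef(X, design, test_factor)
  fit <- fit_nb_glm(counts, X, offsets, dispersions, sample_meta)
  res <- wald_test(fit, coef_idx)
  res$lfc_shrunk <- if (shrink) shrink_lfc(fit, coef_idx) else res$lfc_mle
  res$called <- !is.na(res$fdr) & res$fdr < alpha
  res <- res[, c("feature_id", "base_mean", "lfc_mle", "lfc_shrunk",
                 "se", "wald_p", "fdr", "called")]
  structure(list(results = res, fit = fit, test_coef = coef_idx,
                 test_factor = test_factor, alpha = alpha),
            class = "nb_de")
}

#' @export
print.nb_de <- function(x, ...) {
  cat("NB differential expression on", nrow(x$results), "features",
      "(test:", x$test_factor, ")\n")
  cat("called at FDR <", x$alpha, ":", sum(x$results$called), "\n")
  invisible(x)
}

#' @export
summary.nb_de <- function(object, ...) {
  r <- object$results
  cat("features tested:", sum(!is.na(r$fdr)), "of", nrow(r), "\n")
  cat("called at FDR <", object$alpha, ":", sum(r$called),
      "( up:", sum(r$called & r$lfc_shrunk > 0),
      ", down:", sum(r$called & r$lfc_shrunk < 0), ")\n")
  invisible(r)
}

#' @export
coef.nb_de <- function(object, ...) {
  stats::setNames(object$results$lfc_shrunk, object$results$feature_id)
}

#' MA plot of an `nb_de` result
#' @param x an `nb_de` object.
#' @param y unused.
#' @param ... passed to [plot()].
#' @export
plot.nb_de <- function(x, y, ...) {
  r <- x$results
  plot(log10(r$base_mean + 1), r$lfc_shrunk,
       col = ifelse(r$called, "red", "grey40"), pch = 20,
       xlab = "log10 mean normalized count", ylab = "shrunken LFC (log2)",
       ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Differential-expression calls consistent across ages
#'
#' Implements the two-factor ovary calling rule: a gene is called only
#' when (a) the genotype main effect in the additive model
#' `~ age + genotype` passes the FDR threshold, and (b) the per-age
#' genotype contrasts agree in sign, so the change replicates in both
#' newly-eclosed and aged samples. In `strict` mode genes with a
#' significant genotype x age interaction are additionally dropped (the
#' alternative reading of excluding genes whose response differs between
#' ages).
#'
#' @param counts a [count_matrix] whose sample metadata has `age` and
#'   `genotype` factors (2 x 2 design with replicates).
#' @param offsets natural-log offset matrix.
#' @param alpha FDR threshold (default 0.01).
#' @param strict logical; apply the interaction exclusion (default
#'   FALSE).
#' @param genotype_factor,age_factor metadata column names.
#' @return list with `called` (feature ids), `main` (the additive-model
#'   [nb_de]), `per_age_sign` (matrix of per-age LFC signs),
#'   `interaction_fdr` (when `strict`).
#' @export
consistent_de_call <- function(counts, offsets = NULL, alpha = 0.01,
                               strict = FALSE,
                               genotype_factor = "genotype",
                               age_factor = "age") {
  stopifnot(inherits(counts, "count_matrix"))
  sm <- counts$sample_meta
  if (!all(c(genotype_factor, age_factor) %in% names(sm)))
    stop("sample metadata must contain '", genotype_factor, "' and '",
         age_factor, "'")
  geno <- factor(sm[[genotype_factor]])
  age <- factor(sm[[age_factor]])
  if (nlevels(geno) != 2) stop("genotype must have exactly 2 levels")
  if (any(table(geno, age) == 0))
    stop("missing genotype x age group: all four groups are required")
  design <- stats::as.formula(paste("~", age_factor, "+",
                                    genotype_factor))
  main <- nb_de(counts, design, test_factor = genotype_factor,
                offsets = offsets, alpha = alpha)
  ages <- levels(age)
  signs <- sapply(ages, function(a) {
    sel <- which(age == a)
    sub <- counts[, sel]
    off <- if (is.null(offsets)) NULL else offsets[, sel, drop = FALSE]
    d <- stats::as.formula(paste("~", genotype_factor))
    f <- nb_de(sub, d, test_factor = genotype_factor, offsets = off,
               alpha = alpha, shrink = FALSE)
    sign(f$results$lfc_mle)
  })
  rownames(signs) <- main$results$feature_id
  agree <- signs[, 1] != 0 & signs[, 1] == signs[, 2]
  agree[is.na(agree)] <- FALSE
  called <- main$results$called & agree
  interaction_fdr <- NULL
  if (strict) {
    dint <- stats::as.formula(paste("~", age_factor, "*",
                                    genotype_factor))
    Xint <- .design_matrix(sm, dint)
    fiti <- fit_nb_glm(counts, Xint, offsets,
                       sample_meta = sm)
    wi <- wald_test(fiti, ncol(Xint))
    interaction_fdr <- stats::setNames(wi$fdr, wi$feature_id)
    called <- called & !(!is.na(interaction_fdr) &
                           interaction_fdr < alpha)
  }
  list(called = main$results$feature_id[called], main = main,
       per_age_sign = signs, interaction_fdr = interaction_fdr)
}

#' Differential IP-vs-mock enrichment of repeats anchored on genomic bins
#'
#' Tests repeat features for enrichment in IP over mock samples while
#' normalizing against genomic reads: size factors are computed by
#' median-of-ratios on the genomic-bin features only and applied to all
#' features. The condition coefficient is tested in the model
#' `~ antibody + replicate + condition`; a repeat is reported enriched
#' only when it passes the FDR threshold with IP > mock and the per-
#' antibody contrasts agree in (positive) sign, excluding effects driven
#' by a single antibody or cell population.
#'
#' @param counts a [count_matrix] containing both `repeat` and
#'   `genomic_bin` feature classes, with `condition` (levels mock, IP —
#'   mock as reference), `antibody`, `replicate` sample factors.
#' @param alpha FDR threshold (default 0.05).
#' @return a `de_result` data.frame restricted to repeat features with an
#'   extra `enriched` column; attribute `size_factors` carries the
#'   bin-anchored factors.
#' @export
repeat_enrichment <- function(counts, alpha = 0.05) {
  stopifnot(inherits(counts, "count_matrix"))
  cls <- counts$feature_meta$class
  if (is.null(cls) || !any(cls == "genomic_bin"))
    stop("no genomic_bin features: normalization anchor missing")
  reps <- which(cls == "repeat")
  if (!length(reps)) {
    out <- data.frame(feature_id = character(), base_mean = numeric(),
                      lfc_mle = numeric(), lfc_shrunk = numeric(),
                      se = numeric(), wald_p = numeric(),
                      fdr = numeric(), enriched = logical())
    class(out) <- c("de_result", "data.frame")
    return(out)
  }
  sm <- counts$sample_meta
  stopifnot(all(c("condition", "antibody", "replicate") %in% names(sm)))
  cond <- factor(sm$condition)
  if (!all(c("IP", "mock") %in% levels(cond)))
    stop("condition must contain IP and mock samples")
  sm$condition <- stats::relevel(cond, ref = "mock")
  sf <- estimate_size_factors(counts, features = which(cls ==
                                                         "genomic_bin"))
  offsets <- matrix(log(sf), nrow(counts$counts), ncol(counts$counts),
                    byrow = TRUE)
  cm2 <- count_matrix(counts$counts, sm, counts$feature_meta)
  # the full design is saturated per sample; dispersion comes from the
  # condition groups (antibody/replicate carry no planted signal)
  disp <- estimate_dispersion(cm2$counts, ~ condition, offsets,
                              sample_meta = sm)
  de <- nb_de(cm2, ~ antibody + replicate + condition,
              test_factor = "condition", offsets = offsets,
              alpha = alpha, dispersions = disp)
  res <- de$results
  # the genomic bins only anchor normalization: the BH family is the
  # repeats, the features actually under test
  res$fdr <- NA_real_
  testable <- reps[!is.na(res$wald_p[reps])]
  res$fdr[testable] <- stats::p.adjust(res$wald_p[testable],
                                       method = "BH")
  # per-antibody sign consistency
  ab <- factor(sm$antibody)
  signs <- sapply(levels(ab), function(a) {
    sel <- which(ab == a)
    sub <- count_matrix(counts$counts[, sel, drop = FALSE],
                        sm[sel, , drop = FALSE], counts$feature_meta)
    f <- nb_de(sub, ~ condition, test_factor = "condition",
               offsets = offsets[, sel, drop = FALSE], alpha = alpha,
               shrink = FALSE)
    sign(f$results$lfc_mle)
  })
  consistent <- rowSums(signs > 0, na.rm = TRUE) == ncol(signs)
  res$enriched <- !is.na(res$fdr) & res$fdr < alpha &
    res$lfc_mle > 0 & consistent
  out <- res[reps, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  attr(out, "size_factors") <- sf
  out
}

#' Library-size-corrected RPKM
#'
#' `RPKM = normalized count / (corrected library size in millions x
#' feature length in kb)`, where counts are divided by their sample's
#' size factor and the corrected library size is the common (geometric
#' mean) size-factor-corrected total. Low-count features are retained.
#'
#' @param counts features x samples matrix or [count_matrix].
#' @param lengths per-feature lengths in bp (> 0); taken from feature
#'   metadata when `counts` is a [count_matrix] and `lengths` is NULL.
#' @param size_factors per-sample factors (default median-of-ratios;
#'   supply `1` to skip correction).
#' @return matrix of RPKM values.
#' @export
rpkm <- function(counts, lengths = NULL, size_factors = NULL) {
  m <- .as_counts(counts)
  if (is.null(lengths) && inherits(counts, "count_matrix"))
    lengths <- counts$feature_meta$length
  if (is.null(lengths)) stop("feature lengths required")
  if (any(lengths <= 0)) stop("feature lengths must be > 0")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(m)
  size_factors <- rep_len(size_factors, ncol(m))
  libs <- colSums(m) / size_factors
  if (any(libs == 0)) stop("zero library size")
  lib <- exp(mean(log(libs)))
  norm <- sweep(m, 2, size_factors, "/")
  norm / (lib / 1e6) / (lengths / 1e3)
}
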