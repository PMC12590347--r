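#' Median-of-ratios size factors
#'
#' The per-sample size factor is the median, over genes whose geometric mean
#' across samples is positive, of the ratio of the sample's count to that
#' per-gene geometric-mean reference. Genes with a zero anywhere drop out of
#' the reference; the estimate is invariant to gene order and equivariant
#' under scaling of a column.
#'
#' @param x A [count_matrix] or a numeric count matrix (genes x samples).
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
median_of_ratios <- function(x) {
  counts <- if (inherits(x, "count_matrix")) {
    validate_count_matrix(x)
    x$counts
  } else {
    as.matrix(x)
  }
  if (ncol(counts) < 2) stop("need at least 2 samples")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("no gene has positive counts in all samples; ",
         "median-of-ratios needs an all-positive reference ",
         "(consider a pseudo-reference on a filtered matrix)")
  }
  logref <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2,
              function(col) exp(stats::median(log(col) - logref)))
  stats::setNames(sf, colnames(counts))
}

# Fit one NB GLM with log link and known dispersion by IRLS.
# alpha = 0 gives the Poisson fit used for method-of-moments dispersion.
fit_nb_glm <- function(y, X, offset, alpha, max_iter = 50, tol = 1e-8) {
  eta <- log(pmax(y, 0.5)) - offset
  beta <- tryCatch(qr.coef(qr(X), eta), error = function(e) rep(0, ncol(X)))
  beta[is.na(beta)] <- 0
  converged <- FALSE
  XtWX <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    XtWX <- crossprod(X, w * X)
    beta_new <- tryCatch(solve(XtWX, crossprod(X, w * z)),
                         error = function(e) NULL)
    if (is.null(beta_new)) break
    beta_new <- drop(beta_new)
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  se <- rep(NA_real_, ncol(X))
  cov <- tryCatch(solve(crossprod(X, (mu / (1 + alpha * mu)) * X)),
                  error = function(e) NULL)
  if (!is.null(cov)) se <- sqrt(pmax(diag(cov), 0))
  list(beta = beta, se = se, mu = mu, converged = converged)
}

#' Estimate, trend and shrink NB dispersions
#'
#' A simplified empirical-Bayes dispersion workflow. Per gene, the raw
#' dispersion solves the Pearson moment equation
#' `sum((y - mu)^2 / (mu + alpha * mu^2)) = n - p` with `mu` from a
#' dispersion-updated NB fit (a roughly mean-unbiased estimator even at few
#' residual degrees of freedom; genes underdispersed by chance get 0). A
#' mean-dispersion trend `exp(a0 + a1 * log(baseMean))` is then fitted across
#' genes by a Gamma GLM (mean-scale fit, robust to the estimator's skew), and
#' each gene's dispersion is shrunk linearly toward the trend with
#' `prior_df` pseudo-degrees of freedom:
#' `shrunk = (df * raw + prior_df * trend) / (df + prior_df)`.
#' The shrunken value always lies between the raw estimate and the trend.
#'
#' @param counts Count matrix (genes x samples).
#' @param X Design matrix.
#' @param sf Size factors.
#' @param prior_df Weight of the trend in the shrinkage (default 10).
#' @return A list with `raw`, `trend`, `shrunk` dispersion vectors, the trend
#'   coefficients `a0`/`a1` (intercept and slope of the log-mean trend) and
#'   the per-gene `base_mean` of normalized counts.
#' @export
estimate_dispersions <- function(counts, X, sf, prior_df = 10) {
  n <- ncol(counts)
  p <- ncol(X)
  if (n <= p) stop("no residual degrees of freedom for dispersion estimation")
  offset <- log(sf)
  base_mean <- rowMeans(sweep(counts, 2, sf, "/"))
  raw <- rep(NA_real_, nrow(counts))
  pearson_alpha <- function(y, mu, df) {
    f <- function(a) sum((y - mu)^2 / (mu + a * mu^2)) - df
    if (f(0) <= 0) return(0)
    hi <- 1
    while (f(hi) > 0 && hi < 1e4) hi <- hi * 10
    if (f(hi) > 0) return(hi)
    stats::uniroot(f, c(0, hi), tol = 1e-10)$root
  }
  for (g in seq_len(nrow(counts))) {
    y <- counts[g, ]
    if (all(y == 0)) next
    fit <- fit_nb_glm(y, X, offset, alpha = 0)
    a <- pearson_alpha(y, fit$mu, n - p)
    # one dispersion-updated refit so high-count samples stop dominating
    if (a > 0) {
      fit <- fit_nb_glm(y, X, offset, alpha = a)
      a <- pearson_alpha(y, fit$mu, n - p)
    }
    raw[g] <- a
  }
  ok <- !is.na(raw)
  use <- ok & base_mean > 1
  a0 <- log(max(mean(raw[ok], na.rm = TRUE), 1e-4)); a1 <- 0
  if (sum(use) >= 20) {
    # trend fitted to binned means: quantile bins on the base mean, per-bin
    # mean raw dispersion (zero estimates included, keeping the bin mean an
    # unbiased estimate of the local mean dispersion), then a weighted
    # log-linear fit across bins. Robust to the estimator's per-gene skew.
    lx <- log(base_mean[use])
    nb <- min(20L, max(5L, floor(sum(use) / 20)))
    br <- unique(stats::quantile(lx, seq(0, 1, length.out = nb + 1)))
    bins <- cut(lx, br, include.lowest = TRUE)
    m_b <- tapply(raw[use], bins, mean)
    x_b <- tapply(lx, bins, mean)
    w_b <- as.vector(table(bins))
    keep_b <- !is.na(m_b) & m_b > 1e-8 & w_b >= 5
    if (sum(keep_b) >= 3) {
      tf <- stats::lm(log(m_b[keep_b]) ~ x_b[keep_b], weights = w_b[keep_b])
      a0 <- unname(stats::coef(tf)[1]); a1 <- unname(stats::coef(tf)[2])
    }
  }
  trend <- exp(a0 + a1 * log(pmax(base_mean, 1e-8)))
  trend <- pmin(pmax(trend, 1e-8), 100)
  df <- n - p
  shrunk <- (df * raw + prior_df * trend) / (df + prior_df)
  shrunk[!ok] <- trend[!ok]
  shrunk <- pmin(pmax(shrunk, 1e-8), 100)
  list(raw = raw, trend = trend, shrunk = shrunk, a0 = a0, a1 = a1,
       base_mean = base_mean)
}

#' Negative-binomial Wald test for one condition vs the reference
#'
#' Per gene, a negative-binomial generalized linear model with log link and
#' `log(size factor)` offsets is fitted by iteratively reweighted least
#' squares using the shrunken dispersion from [estimate_dispersions]. The
#' design is `~ donor + condition` when `paired` (the default for the
#' paired-donor priming design) and `~ condition` otherwise. The Wald
#' statistic of the condition coefficient is referred to a t distribution
#' with moderated degrees of freedom (residual df plus the dispersion prior
#' df), acknowledging that the shrunken dispersions are estimated, and
#' p-values are Benjamini-Hochberg adjusted; genes that fail to converge
#' or have all-zero counts get `NA` p-values and are excluded from the
#' adjustment denominator.
#'
#' @param x A [count_matrix] whose metadata has a `condition` column (and a
#'   `donor` column when `paired`).
#' @param contrast Condition level to test against the reference.
#' @param reference Reference condition level (default `"unstim"`).
#' @param paired Include donor as a fixed-effect covariate (default `TRUE`).
#' @param size_factors Optional precomputed size factors for the tested
#'   samples; computed by [median_of_ratios] on the subset otherwise.
#' @param prior_df Dispersion-shrinkage prior degrees of freedom.
#' @return A `data.frame` of class `de_result` with per-gene `baseMean`,
#'   `log2FC`, `lfcSE`, `stat`, `pvalue`, `padj` and `converged`, plus
#'   `contrast`/`reference` attributes.
#' @export
nb_wald_test <- function(x, contrast, reference = "unstim", paired = TRUE,
                         size_factors = NULL, prior_df = 10) {
  validate_count_matrix(x)
  if (!"condition" %in% colnames(x$meta)) stop("meta needs a 'condition' column")
  keep <- x$meta$condition %in% c(contrast, reference)
  if (sum(x$meta$condition == contrast) < 2 ||
      sum(x$meta$condition == reference) < 2) {
    stop("need at least 2 samples in each of '", contrast, "' and '",
         reference, "'")
  }
  counts <- x$counts[, keep, drop = FALSE]
  meta <- x$meta[keep, , drop = FALSE]
  cond <- factor(meta$condition, levels = c(reference, contrast))
  if (paired) {
    if (!"donor" %in% colnames(meta)) stop("paired design needs a 'donor' column")
    X <- stats::model.matrix(~ factor(meta$donor) + cond)
  } else {
    X <- stats::model.matrix(~ cond)
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is not full rank")
  if (is.null(size_factors)) size_factors <- median_of_ratios(counts)
  sf <- size_factors[colnames(counts)]
  offset <- log(sf)

  disp <- estimate_dispersions(counts, X, sf, prior_df = prior_df)
  ngene <- nrow(counts)
  log2fc <- se <- stat <- pval <- rep(NA_real_, ngene)
  convg <- rep(FALSE, ngene)
  ci <- ncol(X)  # condition coefficient is last
  for (g in seq_len(ngene)) {
    y <- counts[g, ]
    if (all(y == 0)) next
    fit <- fit_nb_glm(y, X, offset, alpha = disp$shrunk[g])
    if (!fit$converged || is.na(fit$se[ci]) || fit$se[ci] <= 0) next
    convg[g] <- TRUE
    log2fc[g] <- fit$beta[ci] / log(2)
    se[g] <- fit$se[ci] / log(2)
    stat[g] <- fit$beta[ci] / fit$se[ci]
    pval[g] <- 2 * stats::pt(-abs(stat[g]), df = ncol(counts) - ncol(X) + prior_df)
  }
  res <- data.frame(gene = rownames(counts),
                    baseMean = disp$base_mean,
                    log2FC = log2fc, lfcSE = se, stat = stat,
                    pvalue = pval,
                    padj = bh_adjust(pval),
                    converged = convg,
                    row.names = rownames(counts))
  attr(res, "contrast") <- contrast
  attr(res, "reference") <- reference
  attr(res, "dispersion_fit") <- disp[c("a0", "a1")]
  class(res) <- c("de_result", "data.frame")
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment; `NA` entries are
#' propagated and excluded from the denominator.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Vector of q-values, order-preserving on the input indices.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Partition DEGs into condition-unique and shared sets
#'
#' Classifies the union of differentially expressed genes across conditions
#' into genes significant in exactly one condition (unique), in at least two
#' (shared) and in all (core), and reports the shared fraction, mirroring a
#' Venn-diagram reading of a multi-condition DE experiment.
#'
#' @param de Either a named list of `de_result` data.frames (thresholded at
#'   `alpha` on `padj`) or a named list of character vectors of significant
#'   genes per condition.
#' @param alpha FDR threshold used when `de` holds `de_result` objects.
#' @return A list of class `deg_partition` with `unique` (named list per
#'   condition), `shared`, `core`, `multiplicity` (per shared gene, how many
#'   conditions), `shared_fraction` and `all` (the union).
#' @export
partition_degs <- function(de, alpha = 0.05) {
  if (length(de) < 2) stop("need DE gene lists for at least 2 conditions")
  if (is.null(names(de)) || any(names(de) == "")) stop("de must be fully named")
  lists <- lapply(de, function(d) {
    if (inherits(d, "de_result") || is.data.frame(d)) {
      d$gene[!is.na(d$padj) & d$padj < alpha]
    } else {
      as.character(d)
    }
  })
  all_genes <- unique(unlist(lists))
  if (length(all_genes) == 0) {
    warning("no significant genes in any condition; empty partition")
    return(structure(list(
      unique = stats::setNames(rep(list(character(0)), length(lists)),
                               names(lists)),
      shared = character(0), core = character(0),
      multiplicity = stats::setNames(integer(0), character(0)),
      shared_fraction = 0, all = character(0)), class = "deg_partition"))
  }
  hits <- vapply(lists, function(l) all_genes %in% l,
                 logical(length(all_genes)))
  hits <- matrix(hits, nrow = length(all_genes),
                 dimnames = list(all_genes, names(lists)))
  k <- rowSums(hits)
  unique_sets <- lapply(names(lists), function(nm) {
    all_genes[hits[, nm] & k == 1]
  })
  names(unique_sets) <- names(lists)
  shared <- all_genes[k >= 2]
  structure(list(
    unique = unique_sets,
    shared = shared,
    core = all_genes[k == length(lists)],
    multiplicity = stats::setNames(k[k >= 2], shared),
    shared_fraction = if (length(all_genes) > 0)
      length(shared) / length(all_genes) else 0,
    all = all_genes
  ), class = "deg_partition")
}

#' @export
print.deg_partition <- function(x, ...) {
  cat("deg_partition: ", length(x$all), " DEGs; ",
      length(x$shared), " shared (",
      sprintf("%.1f%%", 100 * x$shared_fraction), "), core ",
      length(x$core), "\n", sep = "")
  for (nm in names(x$unique)) {
    cat("  unique to ", nm, ": ", length(x$unique[[nm]]), "\n", sep = "")
  }
  invisible(x)
}
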