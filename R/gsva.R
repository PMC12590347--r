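#' GSVA engine parameters
#'
#' @param kernel Cumulative-density smoothing kernel for the per-gene
#'   expression statistic: `"gaussian"` (log-scale input; bandwidth `sd/4`),
#'   `"poisson"` (raw counts), or `"ecdf_none"` (plain empirical CDF, a pure
#'   rank pipeline).
#' @param tau Weight on the symmetric rank statistic in the random walk
#'   (> 0, default 1).
#' @param score_mode `"max_diff"` (default: largest positive walk deviation
#'   plus largest negative deviation, bounded in `[-1, 1]`) or
#'   `"two_sided_max"` (walk value of largest magnitude).
#' @param min_set_size Minimum mapped genes per set (default 2).
#' @return A list of class `gsva_params`.
#' @export
gsva_params <- function(kernel = c("gaussian", "poisson", "ecdf_none"),
                        tau = 1,
                        score_mode = c("max_diff", "two_sided_max"),
                        min_set_size = 2) {
  kernel <- match.arg(kernel)
  score_mode <- match.arg(score_mode)
  stopifnot(tau > 0, min_set_size >= 1)
  structure(list(kernel = kernel, tau = tau, score_mode = score_mode,
                 min_set_size = min_set_size), class = "gsva_params")
}

#' Sum single-cell counts into pseudobulk profiles
#'
#' @param x A [count_matrix] of cells.
#' @param group Either the name of a metadata column or a vector with one
#'   group label per cell.
#' @param flag_below Groups with fewer cells are flagged (not dropped) in the
#'   output metadata column `small_group`; their scores downstream are
#'   unstable. Default 10.
#' @return A [count_matrix] of per-group summed counts. Metadata keeps
#'   `n_cells`, `small_group` and any cell-level field that is constant
#'   within every group (e.g. `disease`).
#' @export
pseudobulk_aggregate <- function(x, group, flag_below = 10) {
  validate_count_matrix(x)
  if (length(group) == 1 && is.character(group)) {
    if (!group %in% colnames(x$meta)) stop("no metadata column '", group, "'")
    group <- x$meta[[group]]
  }
  if (length(group) != ncol(x$counts)) stop("group must cover every cell")
  g <- if (is.factor(group)) group else factor(group)
  empty <- setdiff(levels(g), unique(as.character(g)))
  if (length(empty) > 0) {
    warning("omitting empty groups: ", paste(empty, collapse = ", "))
    g <- droplevels(g)
  }
  agg <- t(rowsum(t(x$counts), g))
  meta <- data.frame(n_cells = as.integer(table(g)[colnames(agg)]),
                     row.names = colnames(agg))
  meta$small_group <- meta$n_cells < flag_below
  for (col in colnames(x$meta)) {
    per_group <- tapply(x$meta[[col]], g, function(v) {
      u <- unique(v)
      if (length(u) == 1) u else NA
    })
    if (!anyNA(per_group)) {
      meta[[col]] <- as.vector(unlist(per_group)[colnames(agg)])
    }
  }
  count_matrix(agg, meta)
}

#' Counts-per-million with log2 transform
#'
#' `log2(count / library_size * 1e6 + prior)`.
#'
#' @param x A [count_matrix] or numeric count matrix.
#' @param prior Pseudocount added before the log (default 1).
#' @return Numeric matrix of log2 CPM values.
#' @export
cpm_log2 <- function(x, prior = 1) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    stop("zero library size in samples: ",
         paste(colnames(counts)[lib <= 0], collapse = ", "))
  }
  log2(sweep(counts, 2, lib, "/") * 1e6 + prior)
}

# Kernel-smoothed cumulative statistic per gene across samples.
gsva_kcdf <- function(expr, kernel) {
  n <- ncol(expr)
  z <- matrix(0, nrow(expr), n, dimnames = dimnames(expr))
  for (i in seq_len(nrow(expr))) {
    x <- expr[i, ]
    if (kernel == "gaussian") {
      h <- stats::sd(x) / 4
      z[i, ] <- if (h > 0) {
        # M[k, j] = pnorm((x_j - x_k) / h); column means give the smoothed CDF
        colMeans(stats::pnorm(-outer(x, x, "-") / h))
      } else {
        rep(0.5, n)
      }
    } else if (kernel == "poisson") {
      z[i, ] <- colMeans(matrix(stats::ppois(rep(x, each = n), x + 0.5), n, n))
    } else {
      z[i, ] <- rank(x, ties.method = "average") / n
    }
  }
  z
}

#' GSVA enrichment scores
#'
#' The gene set variation analysis statistic: per gene, a kernel-smoothed
#' cumulative density across samples converts expression to a
#' sample-comparable statistic; per sample, genes are ranked by it
#' (decreasing; ties broken by gene order) and the rank is folded into the
#' symmetric statistic `|N/2 - rank|`; a weighted Kolmogorov-Smirnov random
#' walk down the ranking then accumulates `|stat|^tau` (normalized over the
#' set) inside the set and `1/(N - |S|)` outside it. The score is the maximum
#' positive deviation plus the maximum negative deviation of the walk
#' (`max_diff`) or the deviation of largest magnitude (`two_sided_max`).
#'
#' @param expr Genes x samples matrix of expression values (log2 CPM for the
#'   Gaussian kernel, raw counts for the Poisson kernel), or a
#'   [count_matrix].
#' @param sets A [gene_set_collection].
#' @param params A [gsva_params] object.
#' @return Signatures x samples score matrix with a `params` attribute. Sets
#'   with fewer than `min_set_size` mapped genes yield an `NA` row with a
#'   warning naming the missing genes.
#' @export
gsva_score <- function(expr, sets, params = gsva_params()) {
  stopifnot(inherits(sets, "gene_set_collection"),
            inherits(params, "gsva_params"))
  expr <- if (inherits(expr, "count_matrix")) expr$counts else as.matrix(expr)
  if (ncol(expr) < 3) stop("GSVA needs at least 3 samples")
  N <- nrow(expr)
  n <- ncol(expr)
  z <- gsva_kcdf(expr, params$kernel)
  # per-sample decreasing ranking of genes and symmetric rank statistic
  ord <- apply(z, 2, order, decreasing = TRUE)          # N x n gene indices
  rk <- apply(-z, 2, rank, ties.method = "first")       # position of each gene
  srs <- abs(N / 2 - rk)                                # N x n

  out <- matrix(NA_real_, length(sets$sets), n,
                dimnames = list(names(sets$sets), colnames(expr)))
  for (s in seq_along(sets$sets)) {
    genes <- sets$sets[[s]]
    mapped <- intersect(genes, rownames(expr))
    if (length(mapped) < params$min_set_size) {
      warning("set '", names(sets$sets)[s], "' has ", length(mapped),
              " mapped genes (< ", params$min_set_size, "); missing: ",
              paste(utils::head(setdiff(genes, rownames(expr)), 10),
                    collapse = ", "))
      next
    }
    if (length(mapped) >= N) {
      warning("set '", names(sets$sets)[s],
              "' covers every gene; score undefined")
      next
    }
    in_set <- rownames(expr) %in% mapped
    dec_out <- 1 / (N - length(mapped))
    for (j in seq_len(n)) {
      path_in <- in_set[ord[, j]]
      w <- srs[ord[, j], j]^params$tau
      inc <- ifelse(path_in, w / sum(w[path_in]), -dec_out)
      walk <- cumsum(inc)
      out[s, j] <- if (params$score_mode == "max_diff") {
        max(0, max(walk)) + min(0, min(walk))
      } else {
        walk[which.max(abs(walk))]
      }
    }
  }
  attr(out, "params") <- params
  out
}

#' Moderated group comparison of enrichment scores
#'
#' Fits an ordinary linear model per signature to its scores and moderates
#' the residual variances by empirical Bayes (limma engine): variances are
#' shrunk toward a prior estimated across signatures, and the moderated
#' t-statistic of the group coefficient gains the prior degrees of freedom.
#' With only a handful of signatures the prior is weakly estimated, so a
#' warning is emitted below 10 features.
#'
#' @param scores Signatures x samples score matrix (e.g. from [gsva_score]).
#' @param group Factor (or vector) per sample; the first level is the
#'   reference (e.g. healthy).
#' @param covariates Optional data.frame of additional per-sample covariates.
#' @return A list of class `ebayes_fit`: `table` (per signature: `logFC` of
#'   scores, moderated `t`, `p`, BH `q` for each non-reference level),
#'   `df_prior`, `s2_prior`, `s2_post`, `s2_resid`, `df_residual`.
#' @export
fit_linear_model_ebayes <- function(scores, group, covariates = NULL) {
  scores <- as.matrix(scores)
  group <- factor(group)
  if (any(table(group) < 2)) stop("need at least 2 samples per group level")
  if (nrow(scores) < 10) {
    warning("only ", nrow(scores),
            " features; empirical-Bayes prior is weakly estimated below 10")
  }
  dat <- data.frame(group = group)
  form <- ~group
  if (!is.null(covariates)) {
    dat <- cbind(dat, covariates)
    form <- stats::reformulate(c("group", colnames(covariates)))
  }
  design <- stats::model.matrix(form, dat)
  if (ncol(scores) - ncol(design) <= 0) stop("saturated design: no residual df")
  fit <- limma::lmFit(scores, design)
  fit <- limma::eBayes(fit)
  coefs <- grep("^group", colnames(design), value = TRUE)
  tabs <- lapply(coefs, function(cc) {
    data.frame(signature = rownames(scores),
               level = sub("^group", "", cc),
               logFC = fit$coefficients[, cc],
               t = fit$t[, cc],
               p = fit$p.value[, cc],
               row.names = NULL)
  })
  table <- do.call(rbind, tabs)
  table$q <- bh_adjust(table$p)
  structure(list(table = table,
                 df_prior = fit$df.prior,
                 s2_prior = fit$s2.prior,
                 s2_post = fit$s2.post,
                 s2_resid = fit$sigma^2,
                 df_residual = unique(fit$df.residual)),
            class = "ebayes_fit")
}

#' @export
print.ebayes_fit <- function(x, ...) {
  cat("Moderated comparison (prior df ", signif(x$df_prior, 4),
      ", prior variance ", signif(x$s2_prior, 4), ")\n", sep = "")
  print(x$table, digits = 4)
  invisible(x)
}
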