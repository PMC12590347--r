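#' Per-gene z-scores across subjects
#'
#' Standardizes each gene's normalized log expression across subjects:
#' `z = (x - mean) / sd` with the sample (n - 1) standard deviation.
#' Constant genes get `z = 0` with a warning. Input should be normalized
#' log-scale expression (e.g. log2 CPM), typically restricted to the
#' signature genes of interest.
#'
#' @param expr Genes x subjects numeric matrix.
#' @return Matrix of z-scores; each row has mean 0 and sample sd 1 (up to
#'   floating tolerance), except constant genes which are all 0.
#' @export
gene_zscores <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3) stop("need at least 3 subjects")
  mu <- rowMeans(expr)
  sd_ <- apply(expr, 1, stats::sd)
  flat <- sd_ == 0
  if (any(flat)) {
    warning(sum(flat), " constant genes set to z = 0: ",
            paste(utils::head(rownames(expr)[flat], 5), collapse = ", "))
    sd_[flat] <- 1
  }
  (expr - mu) / sd_
}

#' Subject-level signature scores from gene z-scores
#'
#' The manual gene-expression score: per subject, the mean z-score over the
#' genes of each signature.
#'
#' @param z Genes x subjects z-score matrix (from [gene_zscores]).
#' @param signatures A [gene_set_collection].
#' @return Subjects x signatures score matrix; signatures with no mapped
#'   gene give an `NA` column with a warning.
#' @export
subject_signature_scores <- function(z, signatures) {
  stopifnot(inherits(signatures, "gene_set_collection"))
  z <- as.matrix(z)
  out <- matrix(NA_real_, ncol(z), length(signatures$sets),
                dimnames = list(colnames(z), names(signatures$sets)))
  for (sig in names(signatures$sets)) {
    mapped <- intersect(signatures$sets[[sig]], rownames(z))
    if (length(mapped) == 0) {
      warning("signature '", sig, "' has no genes in the matrix")
      next
    }
    out[, sig] <- colMeans(z[mapped, , drop = FALSE])
  }
  out
}

#' Unpaired group comparison of subject signature scores
#'
#' Two-sided Welch t-test per signature between the two groups; `t` is
#' oriented as first group level minus second, so swapping the labels flips
#' its sign.
#'
#' @param scores Subjects x signatures score matrix.
#' @param groups Two-level factor (or vector) per subject.
#' @return data.frame per signature: group means, `t`, `p`. Signatures with
#'   a degenerate group (fewer than 2 finite scores) give `NA`.
#' @export
group_compare <- function(scores, groups) {
  scores <- as.matrix(scores)
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly 2 levels")
  if (length(groups) != nrow(scores)) stop("groups must cover every subject")
  lv <- levels(groups)
  rows <- lapply(colnames(scores), function(sig) {
    x <- scores[groups == lv[1], sig]; x <- x[is.finite(x)]
    y <- scores[groups == lv[2], sig]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) {
      return(data.frame(signature = sig, mean_1 = NA_real_, mean_2 = NA_real_,
                        t = NA_real_, p = NA_real_))
    }
    tt <- stats::t.test(x, y)
    data.frame(signature = sig, mean_1 = mean(x), mean_2 = mean(y),
               t = unname(tt$statistic), p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- paste0("mean_", lv)
  out
}

#' Correlation and regression between two signature scores
#'
#' Spearman rank correlation (with tie correction via average ranks) and an
#' ordinary least-squares regression of `sigB` on `sigA`.
#'
#' @param scores Subjects x signatures score matrix.
#' @param sigA,sigB Signature names (columns of `scores`).
#' @return A list with `rho`, `slope`, `intercept`, `r_squared`, `n`.
#'   Constant score vectors give `rho = NA`.
#' @export
signature_correlation <- function(scores, sigA, sigB) {
  scores <- as.matrix(scores)
  stopifnot(all(c(sigA, sigB) %in% colnames(scores)))
  ok <- is.finite(scores[, sigA]) & is.finite(scores[, sigB])
  if (sum(ok) < 3) stop("need at least 3 subjects with both scores")
  a <- scores[ok, sigA]; b <- scores[ok, sigB]
  rho <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else
    suppressWarnings(stats::cor(a, b, method = "spearman"))
  fit <- stats::lm(b ~ a)
  list(rho = rho,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       n = sum(ok))
}
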