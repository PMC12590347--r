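#' Log-normalize single-cell counts
#'
#' `log(1 + count / cell_total * scale)` with natural log, the standard
#' single-cell normalization (scale 1e4). Cells with zero totals are dropped
#' with a warning. Note the base: per-cell scores use natural log, while the
#' bulk/pseudobulk pipeline uses log2 CPM.
#'
#' @param x A [count_matrix] of cells or a numeric matrix.
#' @param scale Scale factor (default `1e4`).
#' @return Genes x cells matrix of log-normalized values.
#' @export
lognormalize_cells <- function(x, scale = 1e4) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  totals <- colSums(counts)
  drop <- totals <= 0
  if (any(drop)) {
    warning("dropping ", sum(drop), " zero-total cells: ",
            paste(utils::head(colnames(counts)[drop], 5), collapse = ", "))
    counts <- counts[, !drop, drop = FALSE]
    totals <- totals[!drop]
  }
  log1p(sweep(counts, 2, totals, "/") * scale)
}

#' Per-cell signature scores
#'
#' The score of a cell for a signature is the mean log-normalized expression
#' of the signature's genes present in the matrix.
#'
#' @param norm Genes x cells matrix of log-normalized expression.
#' @param signatures A [gene_set_collection].
#' @return Cells x signatures numeric matrix. Signatures with no mapped gene
#'   give an `NA` column with a warning.
#' @export
score_cells <- function(norm, signatures) {
  stopifnot(inherits(signatures, "gene_set_collection"))
  norm <- as.matrix(norm)
  out <- matrix(NA_real_, ncol(norm), length(signatures$sets),
                dimnames = list(colnames(norm), names(signatures$sets)))
  for (sig in names(signatures$sets)) {
    mapped <- intersect(signatures$sets[[sig]], rownames(norm))
    if (length(mapped) == 0) {
      warning("signature '", sig, "' has no genes in the matrix")
      next
    }
    out[, sig] <- colMeans(norm[mapped, , drop = FALSE])
  }
  out
}

#' Cluster-by-signature mean score matrix
#'
#' @param cells Cell annotation data.frame with a `cluster` column, rows
#'   aligned with `scores`.
#' @param scores Cells x signatures score matrix (from [score_cells]).
#' @param z_scale Z-scale each signature across clusters (default `FALSE`);
#'   undefined (NA, with a warning) when there is a single cluster.
#' @return Clusters x signatures matrix of mean scores.
#' @export
cluster_signature_matrix <- function(cells, scores, z_scale = FALSE) {
  stopifnot(nrow(cells) == nrow(scores), "cluster" %in% colnames(cells))
  cl <- factor(cells$cluster)
  m <- rowsum(scores, cl) / as.vector(table(cl))
  if (z_scale) {
    if (nrow(m) < 2) {
      warning("z-scaling undefined with a single cluster")
      m[] <- NA_real_
    } else {
      m <- scale(m)
      attr(m, "scaled:center") <- attr(m, "scaled:scale") <- NULL
    }
  }
  m
}

#' Wilcoxon rank-sum cluster markers
#'
#' Two-sided rank-sum test of one cluster against all other cells, per gene
#' (exact for small tie-free samples, tie-corrected normal approximation
#' otherwise), with BH-adjusted q-values and a log2 fold-change of mean
#' de-logged normalized expression with a pseudocount of 1.
#'
#' @param norm Genes x cells log-normalized matrix.
#' @param clusters Cluster label per cell.
#' @param cluster The cluster to test.
#' @return data.frame with `gene`, `statistic` (rank-sum W), `log2FC`, `p`,
#'   `q`, ordered as the input genes. Constant genes get `p = 1`.
#' @export
wilcoxon_markers <- function(norm, clusters, cluster) {
  norm <- as.matrix(norm)
  clusters <- as.character(clusters)
  if (length(clusters) != ncol(norm)) stop("clusters must cover every cell")
  in_c <- clusters == cluster
  if (sum(in_c) < 3 || sum(!in_c) < 3) {
    stop("cluster and complement each need at least 3 cells")
  }
  res <- apply(norm, 1, function(x) {
    if (max(x) == min(x)) return(c(NA_real_, 1))
    wt <- suppressWarnings(stats::wilcox.test(x[in_c], x[!in_c]))
    c(unname(wt$statistic), wt$p.value)
  })
  mean_in <- rowMeans(expm1(norm[, in_c, drop = FALSE]))
  mean_out <- rowMeans(expm1(norm[, !in_c, drop = FALSE]))
  data.frame(gene = rownames(norm),
             statistic = res[1, ],
             log2FC = log2((mean_in + 1) / (mean_out + 1)),
             p = res[2, ],
             q = bh_adjust(res[2, ]),
             row.names = rownames(norm))
}

#' Disease-vs-healthy contrasts of per-cell signature scores
#'
#' Welch t-tests of per-cell signature scores for each disease against the
#' reference, optionally restricted to one trajectory and/or phase. The
#' reported `logFC` is the difference of group mean scores (scores are means
#' of logged expression, so a difference is the log-scale fold change);
#' `logFC_mode = "ratio"` gives `log2` of the ratio of means instead.
#' BH adjustment runs over the whole signature x disease grid in one batch.
#'
#' @param cells Cell annotation data.frame (`disease`, optionally
#'   `trajectory_id` and `phase`), rows aligned with `scores`.
#' @param scores Cells x signatures score matrix.
#' @param diseases Diseases to test (default: all non-reference labels).
#' @param reference Reference label (default `"healthy"`).
#' @param trajectory,phase Optional filters applied before testing.
#' @param logFC_mode `"difference"` (default) or `"ratio"`.
#' @param min_cells Minimum cells per group (default 3); smaller groups give
#'   `NA` with the reason recorded.
#' @return data.frame with one row per signature x disease: `logFC`, `t`,
#'   `p`, `q`, group sizes and a `reason` column for skipped tests.
#' @export
disease_contrast <- function(cells, scores, diseases = NULL,
                             reference = "healthy", trajectory = NULL,
                             phase = NULL,
                             logFC_mode = c("difference", "ratio"),
                             min_cells = 3) {
  logFC_mode <- match.arg(logFC_mode)
  stopifnot(nrow(cells) == nrow(scores), "disease" %in% colnames(cells))
  keep <- rep(TRUE, nrow(cells))
  if (!is.null(trajectory)) keep <- keep & cells$trajectory_id %in% trajectory
  if (!is.null(phase)) keep <- keep & cells$phase %in% phase
  cells <- cells[keep, , drop = FALSE]
  scores <- scores[keep, , drop = FALSE]
  if (is.null(diseases)) diseases <- setdiff(unique(cells$disease), reference)
  grid <- expand.grid(signature = colnames(scores), disease = diseases,
                      stringsAsFactors = FALSE)
  ref_idx <- cells$disease == reference
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sig <- grid$signature[i]; d <- grid$disease[i]
    x <- scores[cells$disease == d, sig]
    y <- scores[ref_idx, sig]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < min_cells || length(y) < min_cells) {
      return(data.frame(signature = sig, disease = d, logFC = NA_real_,
                        t = NA_real_, p = NA_real_, n_disease = length(x),
                        n_reference = length(y),
                        reason = "fewer cells than min_cells"))
    }
    tt <- stats::t.test(x, y)
    lfc <- if (logFC_mode == "difference") mean(x) - mean(y)
           else log2(mean(x) / mean(y))
    data.frame(signature = sig, disease = d, logFC = lfc,
               t = unname(tt$statistic), p = tt$p.value,
               n_disease = length(x), n_reference = length(y),
               reason = NA_character_)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out
}
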