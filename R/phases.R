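# 1-D Fisher/Jenks natural breaks by dynamic programming over sorted unique
# values (weighted by multiplicity), minimizing total within-bin sum of
# squared deviations. Returns the k-1 interior break values (upper edges of
# the first k-1 bins).
jenks_breaks <- function(x, k) {
  ux <- sort(unique(x))
  cnt <- as.vector(table(factor(x, ux)))
  m <- length(ux)
  if (m <= k) return(ux[-m])
  cw <- cumsum(cnt)
  cs <- cumsum(cnt * ux)
  cs2 <- cumsum(cnt * ux^2)
  sse <- function(i, j) {
    # within-SSE of values i..j (vectorized over i)
    w <- cw[j] - ifelse(i > 1, cw[i - 1], 0)
    s <- cs[j] - ifelse(i > 1, cs[i - 1], 0)
    s2 <- cs2[j] - ifelse(i > 1, cs2[i - 1], 0)
    s2 - s^2 / w
  }
  dp <- matrix(Inf, k, m)
  back <- matrix(0L, k, m)
  dp[1, ] <- vapply(seq_len(m), function(j) sse(1, j), 0)
  for (b in 2:k) {
    for (j in b:m) {
      i <- b:j  # first index of the last bin
      cost <- dp[b - 1, i - 1] + sse(i, j)
      best <- which.min(cost)
      dp[b, j] <- cost[best]
      back[b, j] <- i[best]
    }
  }
  cuts <- integer(k - 1)
  j <- m
  for (b in k:2) {
    i <- back[b, j]
    cuts[b - 1] <- i - 1L  # last unique-value index of bin b-1
    j <- i - 1L
  }
  ux[cuts]
}

#' Bin pseudotime into ordered bins per trajectory
#'
#' `natural_breaks` uses 1-D Jenks/Fisher optimal breaks (minimum within-bin
#' variance, deterministic); `equal_width` splits the pseudotime range into
#' `k` equal intervals; `equal_count` uses quantiles. Trajectories with fewer
#' distinct pseudotime values than `k` fall back to fewer bins with a
#' warning.
#'
#' @param cells Cell annotation data.frame with `trajectory_id` and
#'   `pseudotime` columns.
#' @param method `"natural_breaks"`, `"equal_width"` or `"equal_count"`.
#' @param k Number of bins (>= 2).
#' @return A list of class `phase_assignment`: `cells` (the input plus a
#'   `bin` integer column), `breaks` (interior break values per trajectory)
#'   and `method`.
#' @export
bin_pseudotime <- function(cells, method = c("natural_breaks", "equal_width",
                                             "equal_count"), k = 3) {
  method <- match.arg(method)
  stopifnot(k >= 2, all(c("trajectory_id", "pseudotime") %in% colnames(cells)))
  if (anyNA(cells$pseudotime)) stop("pseudotime missing for some cells")
  cells$bin <- NA_integer_
  breaks <- list()
  for (tr in unique(cells$trajectory_id)) {
    i <- which(cells$trajectory_id == tr)
    pt <- cells$pseudotime[i]
    n_distinct <- length(unique(pt))
    kk <- k
    if (n_distinct < k) {
      warning("trajectory ", tr, " has ", n_distinct,
              " distinct pseudotime values; using ", n_distinct, " bins")
      kk <- n_distinct
    }
    if (kk == 1) {
      cells$bin[i] <- 1L
      breaks[[tr]] <- numeric(0)
      next
    }
    br <- switch(method,
      natural_breaks = jenks_breaks(pt, kk),
      equal_width = min(pt) + diff(range(pt)) * seq_len(kk - 1) / kk,
      equal_count = unname(stats::quantile(pt, seq_len(kk - 1) / kk)))
    br <- unique(br)
    cells$bin[i] <- as.integer(cut(pt, c(-Inf, br, Inf), labels = FALSE))
    breaks[[tr]] <- br
  }
  structure(list(cells = cells, breaks = breaks, method = method, k = k),
            class = "phase_assignment")
}

#' Assign tertile phases (early, mid, late) along each trajectory
#'
#' Cells of each trajectory are split at the 1/3 and 2/3 pseudotime
#' quantiles; cells exactly on a boundary go to the earlier phase. Phase
#' assignment is monotone in pseudotime within a trajectory. Trajectories
#' with fewer than 3 cells are placed entirely in `early` with a warning.
#'
#' @param cells Cell annotation data.frame with `trajectory_id` and
#'   `pseudotime`.
#' @return The input data.frame with an ordered factor column `phase`
#'   (levels early < mid < late) and a `tertile_breaks` attribute per
#'   trajectory.
#' @export
assign_phases <- function(cells) {
  stopifnot(all(c("trajectory_id", "pseudotime") %in% colnames(cells)))
  if (anyNA(cells$pseudotime)) stop("pseudotime missing for some cells")
  phase <- rep(NA_character_, nrow(cells))
  brk <- list()
  for (tr in unique(cells$trajectory_id)) {
    i <- which(cells$trajectory_id == tr)
    pt <- cells$pseudotime[i]
    if (length(i) < 3) {
      warning("trajectory ", tr, " has fewer than 3 cells; all set to early")
      phase[i] <- "early"
      brk[[tr]] <- c(NA_real_, NA_real_)
      next
    }
    q <- stats::quantile(pt, c(1, 2) / 3, names = FALSE)
    if (q[1] == q[2]) {
      if (length(unique(pt)) == 1) {
        warning("trajectory ", tr, " has constant pseudotime; all set to early")
      }
    }
    phase[i] <- ifelse(pt <= q[1], "early", ifelse(pt <= q[2], "mid", "late"))
    brk[[tr]] <- q
  }
  cells$phase <- factor(phase, levels = c("early", "mid", "late"),
                        ordered = TRUE)
  attr(cells, "tertile_breaks") <- brk
  cells
}

#' Fisher exact tests of trajectory utilization per disease
#'
#' For each trajectory T and disease D, tests the 2x2 table
#' `[[D on T, D off T], [healthy on T, healthy off T]]` with a two-sided
#' Fisher exact test (p = sum of all hypergeometric table probabilities not
#' exceeding the observed one), then BH-adjusts across all (T, D) pairs.
#'
#' @param cells Cell annotation data.frame with `trajectory_id` and
#'   `disease`.
#' @param diseases Diseases to test (default all non-reference); diseases
#'   with zero cells are skipped with a warning.
#' @param reference Reference label (default `"healthy"`).
#' @return data.frame with per (trajectory, disease) row: the 2x2 counts,
#'   odds ratio (conditional MLE), `p` and `q`.
#' @export
utilization_fisher <- function(cells, diseases = NULL, reference = "healthy") {
  stopifnot(all(c("trajectory_id", "disease") %in% colnames(cells)))
  if (!any(cells$disease == reference)) {
    stop("no cells with reference label '", reference, "'")
  }
  if (is.null(diseases)) diseases <- setdiff(unique(cells$disease), reference)
  absent <- diseases[!diseases %in% cells$disease]
  if (length(absent) > 0) {
    warning("skipping diseases with no cells: ", paste(absent, collapse = ", "))
    diseases <- setdiff(diseases, absent)
  }
  trajectories <- sort(unique(cells$trajectory_id))
  ref_on <- table(factor(cells$trajectory_id[cells$disease == reference],
                         trajectories))
  n_ref <- sum(cells$disease == reference)
  rows <- list()
  for (d in diseases) {
    d_on <- table(factor(cells$trajectory_id[cells$disease == d], trajectories))
    n_d <- sum(cells$disease == d)
    for (tr in trajectories) {
      tab <- matrix(c(d_on[[tr]], n_d - d_on[[tr]],
                      ref_on[[tr]], n_ref - ref_on[[tr]]),
                    2, byrow = TRUE)
      ft <- stats::fisher.test(tab)
      rows[[length(rows) + 1]] <- data.frame(
        trajectory_id = tr, disease = d,
        disease_on = tab[1, 1], disease_off = tab[1, 2],
        reference_on = tab[2, 1], reference_off = tab[2, 2],
        odds_ratio = unname(ft$estimate), p = ft$p.value)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out
}

#' Mean signature scores per trajectory phase with small-group masking
#'
#' Mean per-cell score for every (trajectory, phase, disease, signature)
#' stratum; strata with fewer than `min_cells` cells are masked (`NA` mean,
#' `masked = TRUE`) while their cell counts stay reported. Masking never
#' alters unmasked values.
#'
#' @param cells Cell annotation data.frame with `trajectory_id`, `phase` and
#'   `disease` (see [assign_phases]).
#' @param scores Cells x signatures score matrix aligned with `cells`.
#' @param min_cells Masking threshold (default 5: strata with fewer cells are
#'   masked; exactly 5 is reported).
#' @return data.frame with `trajectory_id`, `phase`, `disease`, `signature`,
#'   `n`, `mean_score`, `masked`.
#' @export
phase_score_summary <- function(cells, scores, min_cells = 5) {
  stopifnot(nrow(cells) == nrow(scores),
            all(c("trajectory_id", "phase", "disease") %in% colnames(cells)))
  key <- interaction(cells$trajectory_id, cells$phase, cells$disease,
                     drop = TRUE, sep = "\r")
  n <- as.vector(table(key))
  means <- rowsum(scores, key) / n
  parts <- do.call(rbind, strsplit(rownames(means), "\r", fixed = TRUE))
  out <- do.call(rbind, lapply(colnames(scores), function(sig) {
    data.frame(trajectory_id = parts[, 1],
               phase = factor(parts[, 2], c("early", "mid", "late"),
                              ordered = TRUE),
               disease = parts[, 3], signature = sig, n = n,
               mean_score = means[, sig], row.names = NULL)
  }))
  out$masked <- out$n < min_cells
  out$mean_score[out$masked] <- NA_real_
  out[order(out$trajectory_id, out$phase, out$disease, out$signature), ]
}

#' Cell-flow contingency table for alluvial export
#'
#' Complete counts of cells per (disease, trajectory, phase, cluster),
#' including zero-count strata, for plotting cell flow along
#' pseudotime-defined phases.
#'
#' @param cells Cell annotation data.frame with `disease`, `trajectory_id`,
#'   `phase` and `cluster`.
#' @return data.frame with the four stratifiers and `n`.
#' @export
phase_flow_table <- function(cells) {
  stopifnot(all(c("disease", "trajectory_id", "phase", "cluster") %in%
                  colnames(cells)))
  out <- as.data.frame(table(disease = cells$disease,
                             trajectory_id = cells$trajectory_id,
                             phase = cells$phase,
                             cluster = cells$cluster))
  names(out)[names(out) == "Freq"] <- "n"
  out
}

#' Centroid-MST pseudotime (simplified trajectory convenience)
#'
#' A deliberately simple stand-in for principal-curve trajectory inference:
#' a minimum spanning tree over cluster centroids in a 2-D embedding, one
#' trajectory per root-to-leaf path, and per-cell pseudotime equal to the
#' normalized arc position of the cell's projection onto its cluster's path
#' segment. Cells whose cluster lies on a shared segment of branching paths
#' are assigned to every trajectory containing it.
#'
#' @param embedding Cells x 2 numeric matrix (e.g. a UMAP).
#' @param clusters Cluster label per cell.
#' @param root Root cluster name.
#' @return data.frame with `cell_id`, `trajectory_id`, `pseudotime`
#'   (in `[0, 1]` per trajectory).
#' @export
centroid_mst_pseudotime <- function(embedding, clusters, root) {
  embedding <- as.matrix(embedding)
  stopifnot(ncol(embedding) == 2, nrow(embedding) == length(clusters))
  clusters <- as.character(clusters)
  cl_names <- sort(unique(clusters))
  if (length(cl_names) < 2) stop("need at least 2 clusters")
  if (!root %in% cl_names) stop("root cluster '", root, "' not found")
  cent <- rowsum(embedding, clusters) / as.vector(table(factor(clusters)))
  cent <- cent[cl_names, , drop = FALSE]
  adj <- unclass(ape::mst(stats::dist(cent)))
  deg <- rowSums(adj > 0)
  leaves <- setdiff(cl_names[deg == 1], root)
  # paths root -> leaf by parent pointers from a BFS
  parent <- stats::setNames(rep(NA_character_, length(cl_names)), cl_names)
  visited <- root
  queue <- root
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    nb <- cl_names[adj[v, ] > 0]
    for (w in setdiff(nb, visited)) {
      parent[w] <- v
      visited <- c(visited, w)
      queue <- c(queue, w)
    }
  }
  if (is.null(rownames(embedding))) {
    rownames(embedding) <- paste0("cell", seq_len(nrow(embedding)))
  }
  out <- list()
  for (lf in leaves) {
    path <- lf
    while (!is.na(parent[path[1]])) path <- c(parent[path[1]], path)
    seg_len <- sqrt(rowSums((cent[path[-1], , drop = FALSE] -
                               cent[path[-length(path)], , drop = FALSE])^2))
    cum <- c(0, cumsum(seg_len))
    total <- cum[length(cum)]
    for (ci in seq_along(path)) {
      cells_i <- which(clusters == path[ci])
      if (length(cells_i) == 0) next
      # project each cell onto the adjacent path segment
      a_i <- max(ci - 1, 1); b_i <- min(ci + (ci == 1), length(path))
      if (ci > 1) { a_i <- ci - 1; b_i <- ci } else { a_i <- 1; b_i <- 2 }
      a <- cent[path[a_i], ]; b <- cent[path[b_i], ]
      ab <- b - a
      len2 <- sum(ab^2)
      t <- if (len2 > 0) {
        pmin(pmax(((embedding[cells_i, , drop = FALSE] -
                      matrix(a, length(cells_i), 2, byrow = TRUE)) %*% ab) /
                    len2, 0), 1)
      } else {
        rep(0, length(cells_i))
      }
      pos <- cum[a_i] + drop(t) * sqrt(len2)
      out[[length(out) + 1]] <- data.frame(
        cell_id = rownames(embedding)[cells_i],
        trajectory_id = paste0("T", match(lf, leaves)),
        pseudotime = if (total > 0) pos / total else 0)
    }
  }
  do.call(rbind, out)
}
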