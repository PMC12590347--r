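test_that("natural breaks find the obvious gap and match 1-split enumeration", {
  cells <- data.frame(trajectory_id = "T1",
                      pseudotime = c(0, 0.1, 0.2, 5, 5.1, 5.2))
  pa <- bin_pseudotime(cells, "natural_breaks", k = 2)
  expect_equal(pa$cells$bin, c(1, 1, 1, 2, 2, 2))
  # enumeration of all single splits: break must sit between 0.2 and 5
  pts <- cells$pseudotime
  sse <- function(v) if (length(v) < 2) 0 else sum((v - mean(v))^2)
  costs <- sapply(1:5, function(i) sse(pts[1:i]) + sse(pts[(i + 1):6]))
  expect_equal(which.min(costs), 3)
  expect_true(pa$breaks$T1 >= 0.2 && pa$breaks$T1 < 5)
})

test_that("equal-width and equal-count binning behave as documented", {
  cells <- data.frame(trajectory_id = "T1", pseudotime = seq(0, 1, by = 0.125))
  ew <- bin_pseudotime(cells, "equal_width", k = 4)
  expect_equal(ew$breaks$T1, c(0.25, 0.5, 0.75))
  ec <- bin_pseudotime(cells, "equal_count", k = 3)
  expect_equal(as.vector(table(ec$cells$bin)), c(3, 3, 3))
  # degenerate: all identical values fall back to a single bin
  flat <- data.frame(trajectory_id = "T1", pseudotime = rep(0.4, 6))
  expect_warning(pf <- bin_pseudotime(flat, "natural_breaks", k = 3),
                 "distinct pseudotime")
  expect_true(all(pf$cells$bin == 1))
})

test_that("natural breaks minimize within-bin variance on random data", {
  set.seed(26)
  for (rep in 1:5) {
    x <- round(runif(12), 3)
    cells <- data.frame(trajectory_id = "T", pseudotime = x)
    pa <- bin_pseudotime(cells, "natural_breaks", k = 3)
    sse <- function(bins) {
      sum(tapply(x, bins, function(v) sum((v - mean(v))^2)))
    }
    got <- sse(pa$cells$bin)
    # enumerate every ordered 3-partition of the sorted values
    xs <- sort(x)
    best <- Inf
    for (i in 1:10) for (j in (i + 1):11) {
      bins <- cut(x, c(-Inf, xs[i], xs[j], Inf), labels = FALSE)
      if (length(unique(bins)) == 3) best <- min(best, sse(bins))
    }
    expect_equal(got, best, tolerance = 1e-12)
  }
})

test_that("tertile phases split 9 cells 3/3/3 and 10 cells 4/3/3", {
  c9 <- data.frame(trajectory_id = "T1", pseudotime = 0:8)
  p9 <- assign_phases(c9)
  expect_equal(as.vector(table(p9$phase)), c(3, 3, 3))
  expect_equal(as.character(p9$phase[c(1, 5, 9)]), c("early", "mid", "late"))

  c10 <- data.frame(trajectory_id = "T1", pseudotime = seq(0, 1, length.out = 10))
  p10 <- assign_phases(c10)
  expect_equal(as.vector(table(p10$phase)), c(4, 3, 3))

  tiny <- data.frame(trajectory_id = "T1", pseudotime = c(0.1, 0.9))
  expect_warning(pt <- assign_phases(tiny), "fewer than 3")
  expect_true(all(pt$phase == "early"))

  flat <- data.frame(trajectory_id = "T1", pseudotime = rep(0.5, 5))
  expect_warning(pfl <- assign_phases(flat), "constant pseudotime")
  expect_true(all(pfl$phase == "early"))
})

test_that("phase assignment is monotone in pseudotime within a trajectory", {
  set.seed(27)
  cells <- data.frame(trajectory_id = rep(c("T1", "T2"), each = 30),
                      pseudotime = runif(60))
  ph <- assign_phases(cells)
  for (tr in c("T1", "T2")) {
    sub <- ph[ph$trajectory_id == tr, ]
    o <- order(sub$pseudotime)
    expect_true(all(diff(as.integer(sub$phase[o])) >= 0))
  }
})

test_that("Fisher utilization tests match hypergeometric enumeration", {
  # proportional table: OR 1, p 1
  cells <- data.frame(
    trajectory_id = c(rep("T1", 10), rep("T2", 30), rep("T1", 20), rep("T2", 60)),
    disease = rep(c("copd", "healthy"), c(40, 80)))
  res <- utilization_fisher(cells)
  expect_equal(res$p, c(1, 1))
  expect_equal(res$disease_on, c(10, 30))
  expect_equal(res$reference_on, c(20, 60))

  # complete separation 5 vs 5
  sep <- data.frame(trajectory_id = rep(c("T1", "T2"), c(5, 5)),
                    disease = rep(c("copd", "healthy"), c(5, 5)))
  res_sep <- utilization_fisher(sep)
  p_t1 <- res_sep$p[res_sep$trajectory_id == "T1"]
  expect_equal(p_t1, fisher_oracle(matrix(c(5, 0, 0, 5), 2, byrow = TRUE)))
  expect_equal(round(p_t1, 5), 0.00794)

  # random tables with N <= 200 match the enumeration oracle
  set.seed(28)
  for (rep in 1:10) {
    n_d <- sample(5:100, 1); n_h <- sample(5:100, 1)
    cells <- data.frame(
      trajectory_id = c(sample(c("T1", "T2"), n_d, TRUE),
                        sample(c("T1", "T2"), n_h, TRUE)),
      disease = rep(c("copd", "healthy"), c(n_d, n_h)))
    res <- utilization_fisher(cells)
    for (i in seq_len(nrow(res))) {
      tab <- matrix(c(res$disease_on[i], res$disease_off[i],
                      res$reference_on[i], res$reference_off[i]), 2,
                    byrow = TRUE)
      expect_equal(res$p[i], fisher_oracle(tab), tolerance = 1e-9)
    }
  }
})

test_that("utilization q-values reduce to p for a single test", {
  cells <- data.frame(trajectory_id = rep("T1", 30),
                      disease = rep(c("copd", "healthy"), c(10, 20)))
  res <- suppressWarnings(utilization_fisher(cells))
  expect_equal(res$q, res$p)
  expect_error(utilization_fisher(data.frame(trajectory_id = "T1",
                                             disease = "copd")),
               "reference")
  expect_warning(utilization_fisher(cells, diseases = c("copd", "ipf")),
                 "no cells: ipf")
})

test_that("phase score masking activates strictly below the cell threshold", {
  cells <- data.frame(
    trajectory_id = "T1",
    phase = factor(rep(c("early", "mid", "late"), c(4, 5, 6)),
                   c("early", "mid", "late"), ordered = TRUE),
    disease = "copd")
  scores <- cbind(S = seq_len(15))
  out <- phase_score_summary(cells, scores, min_cells = 5)
  early <- out[out$phase == "early", ]
  mid <- out[out$phase == "mid", ]
  late <- out[out$phase == "late", ]
  expect_true(early$masked)             # 4 cells -> masked
  expect_true(is.na(early$mean_score))
  expect_equal(early$n, 4L)             # count still reported
  expect_false(mid$masked)              # 5 cells -> boundary reported
  expect_equal(mid$mean_score, mean(5:9))
  expect_equal(late$mean_score, mean(10:15))
  # masking never alters unmasked values
  loose <- phase_score_summary(cells, scores, min_cells = 1)
  expect_equal(loose$mean_score[match(c("mid", "late"), loose$phase)],
               c(mid$mean_score, late$mean_score))
})

test_that("phase flow table is a complete contingency with right totals", {
  set.seed(29)
  cells <- data.frame(
    disease = sample(c("healthy", "copd"), 50, TRUE),
    trajectory_id = sample(c("T1", "T2"), 50, TRUE),
    phase = factor(sample(c("early", "mid", "late"), 50, TRUE),
                   c("early", "mid", "late"), ordered = TRUE),
    cluster = sample(c("k1", "k2", "k3"), 50, TRUE))
  tab <- phase_flow_table(cells)
  expect_equal(sum(tab$n), 50)
  expect_equal(nrow(tab), 2 * 2 * 3 * 3)  # zero strata included
  perm <- sample(50)
  tab2 <- phase_flow_table(cells[perm, ])
  expect_equal(tab2, tab)
})

test_that("centroid MST pseudotime handles lines, branches and root choice", {
  set.seed(30)
  mk <- function(center, n, cl) {
    cbind(rnorm(n, center[1], 0.05), rnorm(n, center[2], 0.05))
  }
  # three collinear clusters
  emb <- rbind(mk(c(0, 0), 20), mk(c(1, 0), 20), mk(c(2, 0), 20))
  rownames(emb) <- paste0("cell", 1:60)
  cl <- rep(c("a", "b", "c"), each = 20)
  pt <- centroid_mst_pseudotime(emb, cl, root = "a")
  expect_equal(unique(pt$trajectory_id), "T1")
  means <- tapply(pt$pseudotime, cl[match(pt$cell_id, rownames(emb))], mean)
  expect_true(means["a"] < means["b"] && means["b"] < means["c"])
  expect_true(all(pt$pseudotime >= 0 & pt$pseudotime <= 1))
  # reversing the root reverses the ordering
  ptr <- centroid_mst_pseudotime(emb, cl, root = "c")
  meansr <- tapply(ptr$pseudotime, cl[match(ptr$cell_id, rownames(emb))], mean)
  expect_true(meansr["c"] < meansr["b"] && meansr["b"] < meansr["a"])
  # Y shape: two trajectories share the root segment
  embY <- rbind(mk(c(0, 0), 15), mk(c(1, 0), 15),
                mk(c(2, 1), 15), mk(c(2, -1), 15))
  rownames(embY) <- paste0("c", 1:60)
  clY <- rep(c("root", "stem", "up", "down"), each = 15)
  ptY <- centroid_mst_pseudotime(embY, clY, root = "root")
  expect_setequal(unique(ptY$trajectory_id), c("T1", "T2"))
  # stem cells belong to both trajectories
  stem_ids <- rownames(embY)[clY == "stem"]
  expect_true(all(table(ptY$cell_id[ptY$cell_id %in% stem_ids]) == 2))
})
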