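test_that("stratified_split allocates ceiling(fraction * n_c) per class", {
  labels <- rep(c("unstim", "IFNG", "IL33", "IL4IL13", "TGFB"), each = 4)
  sp <- stratified_split(labels, 0.7, seed = 1)
  expect_length(sp$train, 15)  # ceil(0.7 * 4) = 3 per class
  expect_length(sp$test, 5)
  expect_true(all(table(labels[sp$train]) == 3))
  expect_true(all(table(labels[sp$test]) == 1))

  sp50 <- stratified_split(labels, 0.5, seed = 1)
  expect_true(all(table(labels[sp50$train]) == 2))
  expect_true(all(table(labels[sp50$test]) == 2))

  expect_identical(stratified_split(labels, 0.7, seed = 3),
                   stratified_split(labels, 0.7, seed = 3))
  expect_error(stratified_split(labels, 1.0), "between 0 and 1")
  expect_error(stratified_split(c("a", "a", "b"), 0.5), "at least 2")
})

test_that("Clopper-Pearson interval matches beta quantiles and brackets k/n", {
  ci <- clopper_pearson(5, 5, 0.95)
  expect_equal(unname(round(ci["lo"], 4)), 0.4782)
  expect_equal(unname(ci["hi"]), 1)

  expect_equal(unname(clopper_pearson(0, 7, 0.95)["lo"]), 0)
  ci9 <- clopper_pearson(9, 10, 0.95)
  expect_equal(unname(ci9["lo"]), qbeta(0.025, 9, 2))
  expect_equal(unname(ci9["hi"]), qbeta(0.975, 10, 1))

  # interval always contains k/n; width shrinks as n grows at fixed k/n
  widths <- sapply(c(10, 20, 40, 80), function(n) {
    ci <- clopper_pearson(0.8 * n, n, 0.95)
    expect_true(ci["lo"] <= 0.8 && 0.8 <= ci["hi"])
    unname(diff(ci))
  })
  expect_true(all(diff(widths) < 0))
  expect_error(clopper_pearson(1, 0), "positive")
})

test_that("exact binomial tail probabilities match direct pmf summation", {
  expect_equal(exact_binomial_ge(5, 5, 0.2), 0.2^5)
  expect_equal(signif(exact_binomial_ge(9, 10, 0.2), 4), 4.198e-06)
  expect_equal(exact_binomial_ge(0, 12, 0.3), 1)
  # oracle: direct summation over the upper tail for n <= 30
  set.seed(4)
  for (rep in 1:20) {
    n <- sample(1:30, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.05, 0.95)
    direct <- sum(dbinom(k:n, n, p0))
    expect_equal(exact_binomial_ge(k, n, p0), direct, tolerance = 1e-12)
  }
})

test_that("Cohen's kappa matches hand computation and its invariances", {
  # 5 classes, 10 samples, uniform margins, 9 correct
  cm <- diag(2, 5)
  cm[1, 2] <- 1
  cm[1, 1] <- 1
  expect_equal(cohen_kappa(cm), 0.875)
  expect_equal(cohen_kappa(diag(3, 4)), 1)
  # all predictions one class on balanced truth: po = pe
  one_class <- matrix(0, 5, 5)
  one_class[, 1] <- 2
  expect_equal(cohen_kappa(one_class), 0)
  # invariant under simultaneous permutation of classes
  set.seed(8)
  m <- matrix(rpois(16, 3), 4)
  perm <- sample(4)
  expect_equal(cohen_kappa(m), cohen_kappa(m[perm, perm]))
  # kappa = 1 iff diagonal
  expect_true(cohen_kappa(m) < 1)
})

test_that("evaluate_classification reproduces the exact evaluation statistics", {
  classes <- c("unstim", "IFNG", "IL33", "IL4IL13", "TGFB")
  truth5 <- classes
  ev5 <- evaluate_classification(truth5, truth5)
  expect_equal(ev5$accuracy, 1)
  expect_equal(unname(round(ev5$ci["lo"], 4)), 0.4782)
  expect_equal(ev5$nir, 0.2)
  expect_equal(ev5$p_acc_gt_nir, 0.00032)
  expect_equal(ev5$kappa, 1)

  truth10 <- rep(classes, 2)
  pred10 <- truth10
  pred10[1] <- "IFNG"  # 9/10 correct
  ev10 <- evaluate_classification(pred10, truth10)
  expect_equal(ev10$accuracy, 0.9)
  expect_equal(ev10$kappa, 0.875)
  expect_equal(signif(ev10$p_acc_gt_nir, 4), 4.198e-06)
  expect_equal(unname(ev10$sensitivity["unstim"]), 0.5)
  expect_equal(unname(ev10$specificity["IFNG"]), 7 / 8)

  all_wrong <- evaluate_classification(rev(classes)[c(2, 1, 4, 5, 3)], classes)
  expect_equal(all_wrong$accuracy, 0)
  expect_true(all(all_wrong$sensitivity == 0))
})

test_that("multiclass AUC matches enumeration and its boundary conventions", {
  # perfectly ordered scores
  truth <- rep(c("a", "b", "c"), each = 4)
  perfect <- matrix(0.01, 12, 3, dimnames = list(NULL, c("a", "b", "c")))
  perfect[cbind(seq_len(12), match(truth, colnames(perfect)))] <- 0.98
  res <- multiclass_auc(perfect, truth)
  expect_equal(res$M, 1)
  expect_equal(unname(res$one_vs_all), rep(1, 3))

  # all-tied scores give 0.5 everywhere
  flat <- matrix(1 / 3, 12, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(multiclass_auc(flat, truth)$M, 0.5)

  # random instance vs brute-force pairwise rank enumeration
  set.seed(11)
  sc <- matrix(runif(36), 12, 3, dimnames = list(NULL, c("a", "b", "c")))
  res <- multiclass_auc(sc, truth)
  pair_auc <- function(pos, neg) {
    s <- 0
    for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
    s / (length(pos) * length(neg))
  }
  for (i in 1:2) for (j in (i + 1):3) {
    ci <- colnames(sc)[i]; cj <- colnames(sc)[j]
    a_ij <- pair_auc(sc[truth == ci, ci], sc[truth == cj, ci])
    a_ji <- pair_auc(sc[truth == cj, cj], sc[truth == ci, cj])
    expect_equal(res$pairwise[ci, cj], (a_ij + a_ji) / 2)
  }
  expect_equal(res$M, mean(res$pairwise[upper.tri(res$pairwise)]))

  # two classes: Hand-Till M equals the standard two-class AUC
  t2 <- rep(c("a", "b"), each = 6)
  s2 <- cbind(a = runif(12), b = runif(12))
  m2 <- multiclass_auc(s2, t2)
  expect_equal(m2$M,
               (pair_auc(s2[1:6, "a"], s2[7:12, "a"]) +
                  pair_auc(s2[7:12, "b"], s2[1:6, "b"])) / 2)
})

test_that("elastic net shuts off at huge lambda and is deterministic", {
  set.seed(5)
  X <- matrix(rnorm(20 * 30), 20, dimnames = list(NULL, paste0("g", 1:30)))
  labels <- rep(c("a", "b", "c", "d"), each = 5)
  X[labels == "a", 1:3] <- X[labels == "a", 1:3] + 3
  big <- suppressWarnings(fit_multinomial_elastic_net(
    X, labels, selection_params(lambda = 1e6)))
  expect_true(all(abs(big) < 1e-8))
  p <- selection_params(lambda = 0.05)
  b1 <- suppressWarnings(fit_multinomial_elastic_net(X, labels, p))
  b2 <- suppressWarnings(fit_multinomial_elastic_net(X, labels, p))
  expect_identical(b1, b2)
  expect_true(any(abs(b1[, 1:3]) > 1e-8))
})

test_that("zero-variance genes are dropped with a warning and zero coefficients", {
  set.seed(6)
  X <- cbind(matrix(rnorm(40), 10), flat = rep(2, 10))
  colnames(X) <- c(paste0("g", 1:4), "flat")
  labels <- rep(c("a", "b"), each = 5)
  expect_warning(b <- fit_multinomial_elastic_net(X, labels,
    selection_params(lambda = 0.01)), "zero-variance")
  expect_true(all(b[, "flat"] == 0))
})

test_that("extract_signatures follows DEG exclusivity and drop_classes", {
  part <- structure(list(unique = list(A = c("g1", "g2"), B = c("g3"))),
                    class = "deg_partition")
  beta <- matrix(0, 2, 3, dimnames = list(c("A", "B"), c("g1", "g2", "g3")))
  # all zero -> empty collection
  empty <- extract_signatures(beta, part)
  expect_length(empty$sets, 0)
  beta["B", "g1"] <- 0.4   # class comes from exclusivity, not coefficient row
  beta["A", "g3"] <- -0.2
  sigs <- extract_signatures(beta, part)
  expect_equal(sigs$sets, list(A = "g1", B = "g3"))
  dropped <- extract_signatures(beta, part, drop_classes = "A")
  expect_equal(names(dropped$sets), "B")
  # ambiguous gene membership violates the exclusivity precondition
  bad <- structure(list(unique = list(A = "g1", B = c("g1", "g3"))),
                   class = "deg_partition")
  expect_error(extract_signatures(beta, bad, threshold = 1e-8), "exclusivity")
})

test_that("validation network separates a linearly separable toy exactly", {
  set.seed(2)
  X <- rbind(matrix(rnorm(10, 0, 0.2), 5, 2), matrix(rnorm(10, 4, 0.2), 5, 2))
  colnames(X) <- c("f1", "f2")
  labels <- rep(c("lo", "hi"), each = 5)
  Xt <- rbind(matrix(rnorm(8, 0, 0.2), 4, 2), matrix(rnorm(8, 4, 0.2), 4, 2))
  colnames(Xt) <- c("f1", "f2")
  prob <- fit_validation_network(X, labels, Xt, seed = 7)
  pred <- colnames(prob)[apply(prob, 1, which.max)]
  expect_equal(pred, rep(c("lo", "hi"), each = 4))
  # deterministic under seed
  prob2 <- fit_validation_network(X, labels, Xt, seed = 7)
  expect_equal(unclass(prob)[, ], unclass(prob2)[, ])
})

test_that("network on shuffled labels performs near the no-information rate", {
  set.seed(13)
  accs <- replicate(8, {
    X <- matrix(rnorm(40 * 6), 40)
    colnames(X) <- paste0("g", 1:6)
    labels <- sample(rep(c("a", "b"), each = 20))
    prob <- fit_validation_network(X[1:30, ], labels[1:30], X[31:40, ],
                                   seed = sample.int(1e6, 1))
    mean(colnames(prob)[apply(prob, 1, which.max)] == labels[31:40])
  })
  expect_gt(mean(accs), 0.25)
  expect_lt(mean(accs), 0.75)  # near NIR 0.5, far from systematic skill
})
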