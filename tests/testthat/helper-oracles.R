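# Independent brute-force oracles, coded separately from the package engines.

# Benjamini-Hochberg step-up, literal definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (r in m:1) {
    i <- o[r]
    prev <- min(prev, p[i] * m / r)
    q[i] <- prev
  }
  q
}

# Two-sided Fisher exact p for a 2x2 table by full hypergeometric enumeration
# with binomial coefficients: sum of all table probabilities <= observed.
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m1 <- a + b; m2 <- c_ + d; k <- a + c_
  n <- m1 + m2
  xs <- max(0, k - m2):min(k, m1)
  pr <- choose(m1, xs) * choose(m2, k - xs) / choose(n, k)
  obs <- pr[xs == a]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Two-sided exact Wilcoxon rank-sum p by enumeration of all group
# assignments (no ties assumed); p = min(1, 2 * min(lower, upper tail)).
wilcox_oracle <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x)
  r_obs <- sum(rank(vals)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(vals), n1)
  ws <- apply(combs, 2, function(i) sum(rank(vals)[i]) - n1 * (n1 + 1) / 2)
  lo <- mean(ws <= r_obs)
  hi <- mean(ws >= r_obs)
  min(1, 2 * min(lo, hi))
}

# Literal GSVA definition, written independently of the package engine:
# explicit per-gene kernel CDF sums, per-sample decreasing ordering (ties by
# gene order), symmetric rank statistic, and an explicit random walk.
gsva_oracle <- function(expr, sets, tau = 1,
                        kernel = c("gaussian", "poisson", "ecdf_none"),
                        mode = c("max_diff", "two_sided_max")) {
  kernel <- match.arg(kernel)
  mode <- match.arg(mode)
  N <- nrow(expr); n <- ncol(expr)
  z <- matrix(0, N, n)
  for (i in 1:N) {
    for (j in 1:n) {
      if (kernel == "gaussian") {
        h <- sd(expr[i, ]) / 4
        z[i, j] <- if (h > 0) mean(pnorm((expr[i, j] - expr[i, ]) / h)) else 0.5
      } else if (kernel == "poisson") {
        z[i, j] <- mean(ppois(expr[i, j], expr[i, ] + 0.5))
      } else {
        z[i, j] <- mean(expr[i, ] <= expr[i, j])
      }
    }
  }
  out <- matrix(NA_real_, length(sets), n,
                dimnames = list(names(sets), colnames(expr)))
  for (s in seq_along(sets)) {
    mem <- rownames(expr) %in% sets[[s]]
    if (sum(mem) >= N) next
    for (j in 1:n) {
      ord <- order(-z[, j])  # stable: ties keep gene order
      stat <- abs(N / 2 - match(seq_len(N), ord))  # position of each gene
      w <- stat[ord]^tau
      inset <- mem[ord]
      walk <- numeric(N)
      level <- 0
      for (l in 1:N) {
        if (inset[l]) {
          level <- level + w[l] / sum(w[inset])
        } else {
          level <- level - 1 / (N - sum(mem))
        }
        walk[l] <- level
      }
      out[s, j] <- if (mode == "max_diff") {
        max(0, max(walk)) + min(0, min(walk))
      } else {
        walk[which.max(abs(walk))]
      }
    }
  }
  out
}

# Small toy count_matrix used across IO and DE tests.
toy_counts <- function(n_genes = 6, n_samples = 4, seed = 42) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, 20), n_genes,
              dimnames = list(sprintf("g%d", 1:n_genes),
                              sprintf("s%d", 1:n_samples)))
  count_matrix(m)
}

# Toy signature collection on a small gene universe.
toy_signatures <- function() {
  gene_set_collection(list(
    IFNG = sprintf("ifng_g%d", 1:8),
    IL33 = sprintf("il33_g%d", 1:8),
    IL4IL13 = sprintf("il4_g%d", 1:8),
    TGFB = sprintf("tgfb_g%d", 1:8)))
}
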