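#' Parameters for the bulk priming simulation
#'
#' Defaults emulate the design of the priming experiment the package targets:
#' primary mast cells from 4 donors exposed to IFN-gamma, IL-33, IL-4 + IL-13
#' or TGF-beta for 24 h alongside an unstimulated control, sequenced in bulk
#' (20 paired samples). Condition effects are planted on known gene lists so
#' that downstream differential expression and feature selection can be scored
#' against ground truth.
#'
#' @param n_genes Total number of simulated genes.
#' @param n_donors Number of donors; each donor contributes one sample per
#'   condition (paired design).
#' @param conditions Condition labels; the first is the unstimulated reference.
#' @param n_unique_deg_per_condition Number of genes perturbed by exactly one
#'   non-reference condition.
#' @param n_shared_deg Number of genes perturbed by two or more conditions.
#' @param lfc_range Range (log2) from which planted absolute fold changes are
#'   drawn; sign is random. `c(0, 0)` yields a global null.
#' @param dispersion_range Range for gene-wise NB dispersions, drawn
#'   log-uniformly; variance is `mu + alpha * mu^2`.
#' @param donor_sd Standard deviation (natural-log scale) of gene-by-donor
#'   random effects, shared across conditions within a donor.
#' @param lib_size_range Range of per-sample relative library-size factors.
#' @param seed Integer seed; the generator is bit-reproducible given a seed.
#' @return A list of class `bulk_sim_params`.
#' @export
bulk_sim_params <- function(n_genes = 2000,
                            n_donors = 4,
                            conditions = c("unstim", "IFNG", "IL33", "IL4IL13", "TGFB"),
                            n_unique_deg_per_condition = 10,
                            n_shared_deg = 30,
                            lfc_range = c(2, 4),
                            dispersion_range = c(0.01, 0.5),
                            donor_sd = 0.25,
                            lib_size_range = c(0.7, 1.4),
                            seed = 1L) {
  stopifnot(length(conditions) >= 2, n_donors >= 2,
            length(lfc_range) == 2, all(lfc_range >= 0),
            diff(lfc_range) >= 0, all(dispersion_range > 0),
            donor_sd >= 0, all(lib_size_range > 0))
  p <- list(n_genes = n_genes, n_donors = n_donors, conditions = conditions,
            n_unique_deg_per_condition = n_unique_deg_per_condition,
            n_shared_deg = n_shared_deg, lfc_range = lfc_range,
            dispersion_range = dispersion_range, donor_sd = donor_sd,
            lib_size_range = lib_size_range, seed = as.integer(seed))
  class(p) <- "bulk_sim_params"
  p
}

#' Simulate a paired multi-condition bulk priming experiment
#'
#' Counts are negative-binomial with gene-wise mean
#' `exp(baseline + donor effect + condition log-effect) * size factor` and
#' variance `mu + alpha * mu^2`. Condition effects are nonzero exactly on the
#' ground-truth DEG lists: each non-reference condition gets a disjoint block
#' of unique DEGs, and a further block of shared DEGs is perturbed by a random
#' subset of two or more conditions (including a core touched by all).
#'
#' @param params A [bulk_sim_params] object.
#' @return A list with elements `counts` (a [count_matrix] whose metadata
#'   carries `condition` and `donor`) and `truth` (unique DEG list per
#'   condition, shared DEG list, per-gene true log2 fold-change matrix).
#' @export
simulate_bulk_priming <- function(params = bulk_sim_params()) {
  stopifnot(inherits(params, "bulk_sim_params"))
  p <- params
  n_cyt <- length(p$conditions) - 1L
  n_deg <- p$n_unique_deg_per_condition * n_cyt + p$n_shared_deg
  if (n_deg > p$n_genes) {
    stop("requested ", n_deg, " DEGs but only ", p$n_genes, " genes")
  }
  set.seed(p$seed)
  genes <- sprintf("gene%05d", seq_len(p$n_genes))
  ref <- p$conditions[1]
  cyts <- p$conditions[-1]

  # ground truth: disjoint unique blocks, then a shared block
  idx <- seq_len(n_deg)
  unique_idx <- split(idx[seq_len(p$n_unique_deg_per_condition * n_cyt)],
                      rep(seq_len(n_cyt), each = p$n_unique_deg_per_condition))
  names(unique_idx) <- cyts
  shared_idx <- idx[idx > p$n_unique_deg_per_condition * n_cyt]

  lfc <- matrix(0, p$n_genes, n_cyt, dimnames = list(genes, cyts))
  draw_lfc <- function(n) {
    stats::runif(n, p$lfc_range[1], p$lfc_range[2]) * sample(c(-1, 1), n, TRUE)
  }
  for (cc in cyts) lfc[unique_idx[[cc]], cc] <- draw_lfc(length(unique_idx[[cc]]))
  for (g in shared_idx) {
    k <- if (n_cyt == 1) 1 else sample(2:n_cyt, 1)
    hit <- sample(cyts, k)
    lfc[g, hit] <- draw_lfc(k)
  }

  base_log <- stats::runif(p$n_genes, log(5), log(500))
  alpha <- exp(stats::runif(p$n_genes, log(p$dispersion_range[1]),
                            log(p$dispersion_range[2])))
  donor_eff <- matrix(stats::rnorm(p$n_genes * p$n_donors, 0, p$donor_sd),
                      p$n_genes, p$n_donors)
  donors <- sprintf("d%d", seq_len(p$n_donors))
  design <- expand.grid(donor = donors, condition = p$conditions,
                        stringsAsFactors = FALSE)
  sf <- stats::runif(nrow(design), p$lib_size_range[1], p$lib_size_range[2])

  counts <- matrix(0, p$n_genes, nrow(design))
  for (j in seq_len(nrow(design))) {
    cond <- design$condition[j]
    d <- match(design$donor[j], donors)
    log_mu <- base_log + donor_eff[, d]
    if (cond != ref) log_mu <- log_mu + log(2) * lfc[, cond]
    mu <- exp(log_mu) * sf[j]
    counts[, j] <- stats::rnbinom(p$n_genes, mu = mu, size = 1 / alpha)
  }
  dimnames(counts) <- list(genes, paste(design$condition, design$donor, sep = "_"))
  meta <- data.frame(condition = design$condition, donor = design$donor,
                     row.names = colnames(counts))

  no_effect <- all(lfc == 0)
  truth <- list(
    unique_degs = if (no_effect) stats::setNames(rep(list(character(0)), n_cyt), cyts)
                  else lapply(unique_idx, function(i) genes[i]),
    shared_degs = if (no_effect) character(0) else genes[shared_idx],
    log2fc = lfc,
    dispersion = stats::setNames(alpha, genes)
  )
  list(counts = count_matrix(counts, meta), truth = truth)
}

#' Parameters for the tissue single-cell simulation
#'
#' Emulates the structure assumed by the trajectory/phase analytics: tissue
#' mast cells annotated with cluster, disease, pseudotime trajectory and a
#' pseudotime in `[0, 1]`. Disease cells oversample designated trajectories
#' according to per-disease utilization probabilities, and signature genes are
#' shifted per disease on the log scale. By default clusters are the tertile
#' of pseudotime crossed with the trajectory, which makes phase analytics
#' exactly checkable.
#'
#' @param n_cells Total number of cells across all diseases.
#' @param n_genes Number of background genes added to the signature genes.
#' @param n_trajectories Number of pseudotime trajectories.
#' @param utilization Named list, one entry per disease (the reference
#'   `"healthy"` must be present), each a probability vector over
#'   trajectories summing to 1.
#' @param signature_shift Named list disease -> named numeric vector of
#'   per-signature mean shifts on the natural-log scale (default none).
#' @param dropout Bernoulli zero-inflation probability in `[0, 1)` applied on
#'   top of the NB counts.
#' @param dispersion NB dispersion for cell counts.
#' @param base_mean_range Range of per-gene baseline mean counts per cell.
#' @param seed Integer seed.
#' @return A list of class `cell_sim_params`.
#' @export
cell_sim_params <- function(n_cells = 1500,
                            n_genes = 300,
                            n_trajectories = 2,
                            utilization = list(healthy = c(0.5, 0.5),
                                               disease = c(0.5, 0.5)),
                            signature_shift = list(),
                            dropout = 0.2,
                            dispersion = 1,
                            base_mean_range = c(0.1, 2),
                            seed = 1L) {
  if (length(utilization) == 0) stop("empty disease list")
  if (!"healthy" %in% names(utilization)) {
    stop("utilization must include the reference disease label 'healthy'")
  }
  for (d in names(utilization)) {
    u <- utilization[[d]]
    if (length(u) != n_trajectories || abs(sum(u) - 1) > 1e-8 || any(u < 0)) {
      stop("utilization probabilities for '", d,
           "' must be length ", n_trajectories, ", non-negative, summing to 1")
    }
  }
  stopifnot(dropout >= 0, dropout < 1, dispersion > 0)
  p <- list(n_cells = n_cells, n_genes = n_genes,
            n_trajectories = n_trajectories, utilization = utilization,
            signature_shift = signature_shift, dropout = dropout,
            dispersion = dispersion, base_mean_range = base_mean_range,
            seed = as.integer(seed))
  class(p) <- "cell_sim_params"
  p
}

#' Simulate tissue single cells with trajectories, pseudotime and disease labels
#'
#' @param params A [cell_sim_params] object.
#' @param signatures A [gene_set_collection] of signatures; its genes are
#'   included in the simulated gene universe.
#' @return A list with `counts` (a [count_matrix] of cells), `cells` (the
#'   per-cell annotation table: `cell_id`, `sample`, `cluster`, `disease`,
#'   `trajectory_id`, `pseudotime`) and `truth` (utilization probabilities and
#'   planted shifts).
#' @export
simulate_tissue_cells <- function(params, signatures) {
  stopifnot(inherits(params, "cell_sim_params"),
            inherits(signatures, "gene_set_collection"))
  p <- params
  set.seed(p$seed)
  sig_genes <- unique(unlist(signatures$sets))
  genes <- c(sig_genes, sprintf("bg%05d", seq_len(p$n_genes)))
  diseases <- names(p$utilization)

  disease <- rep(diseases, length.out = p$n_cells)
  trajectory <- integer(p$n_cells)
  for (d in diseases) {
    i <- which(disease == d)
    trajectory[i] <- sample.int(p$n_trajectories, length(i), replace = TRUE,
                                prob = p$utilization[[d]])
  }
  pseudotime <- stats::runif(p$n_cells)
  tert <- cut(pseudotime, breaks = c(-Inf, 1 / 3, 2 / 3, Inf),
              labels = c("a", "b", "c"))
  cluster <- paste0("T", trajectory, tert)

  base_mean <- stats::runif(length(genes), p$base_mean_range[1],
                            p$base_mean_range[2])
  shift <- matrix(0, length(genes), length(diseases),
                  dimnames = list(genes, diseases))
  for (d in intersect(names(p$signature_shift), diseases)) {
    s <- p$signature_shift[[d]]
    for (sig in intersect(names(s), names(signatures$sets))) {
      shift[signatures$sets[[sig]], d] <- shift[signatures$sets[[sig]], d] + s[[sig]]
    }
  }
  counts <- matrix(0, length(genes), p$n_cells)
  for (d in diseases) {
    i <- which(disease == d)
    mu <- base_mean * exp(shift[, d])
    counts[, i] <- stats::rnbinom(length(genes) * length(i), mu = mu,
                                  size = 1 / p$dispersion)
  }
  if (p$dropout > 0) {
    keep <- stats::rbinom(length(counts), 1, 1 - p$dropout)
    counts <- counts * keep
  }
  cell_ids <- sprintf("cell%05d", seq_len(p$n_cells))
  dimnames(counts) <- list(genes, cell_ids)
  cells <- data.frame(cell_id = cell_ids,
                      sample = paste0(disease, "_s1"),
                      cluster = cluster,
                      disease = disease,
                      trajectory_id = paste0("T", trajectory),
                      pseudotime = pseudotime,
                      row.names = cell_ids)
  truth <- list(utilization = p$utilization,
                signature_shift = p$signature_shift,
                trajectory = stats::setNames(paste0("T", trajectory), cell_ids),
                pseudotime = stats::setNames(pseudotime, cell_ids))
  list(counts = count_matrix(counts, cells), cells = cells, truth = truth)
}

#' Parameters for the two-group bulk cohort simulation
#'
#' Emulates a bulk cohort split into a "high" and a "low" group (by default
#' 20 vs 17 subjects, the size of an eosinophil-high vs eosinophil-low COPD
#' bronchial-brushing cohort) in which the genes of designated signatures are
#' elevated in the high group by a common log2 effect.
#'
#' @param n_high,n_low Subjects per group (each at least 2).
#' @param shifted_signatures Names of the signatures elevated in `high`.
#' @param effect_size Log2 elevation of every shifted-signature gene (>= 0).
#' @param n_genes Background genes added to the signature genes.
#' @param dispersion_range NB dispersion range (log-uniform).
#' @param seed Integer seed.
#' @return A list of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_high = 20, n_low = 17,
                              shifted_signatures = c("IL33", "TGFB"),
                              effect_size = 1,
                              n_genes = 300,
                              dispersion_range = c(0.05, 0.3),
                              seed = 1L) {
  if (n_high < 2 || n_low < 2) stop("each cohort group needs at least 2 subjects")
  if (effect_size < 0) stop("effect_size must be non-negative")
  p <- list(n_high = n_high, n_low = n_low,
            shifted_signatures = shifted_signatures,
            effect_size = effect_size, n_genes = n_genes,
            dispersion_range = dispersion_range, seed = as.integer(seed))
  class(p) <- "cohort_sim_params"
  p
}

#' Simulate a two-group bulk cohort with planted signature elevation
#'
#' @param params A [cohort_sim_params] object.
#' @param signatures A [gene_set_collection]; genes of
#'   `params$shifted_signatures` are elevated in the `high` group.
#' @return A list with `counts` (a [count_matrix] whose metadata has a
#'   `group` column with levels `high`/`low`) and `truth` (per-signature
#'   planted log2 effects).
#' @export
simulate_cohort <- function(params, signatures) {
  stopifnot(inherits(params, "cohort_sim_params"),
            inherits(signatures, "gene_set_collection"))
  p <- params
  missing_sigs <- setdiff(p$shifted_signatures, names(signatures$sets))
  if (length(missing_sigs) > 0) {
    stop("unknown shifted signatures: ", paste(missing_sigs, collapse = ", "))
  }
  set.seed(p$seed)
  sig_genes <- unique(unlist(signatures$sets))
  genes <- c(sig_genes, sprintf("bg%05d", seq_len(p$n_genes)))
  n <- p$n_high + p$n_low
  group <- rep(c("high", "low"), c(p$n_high, p$n_low))

  base_log <- stats::runif(length(genes), log(5), log(500))
  alpha <- exp(stats::runif(length(genes), log(p$dispersion_range[1]),
                            log(p$dispersion_range[2])))
  shifted_genes <- unique(unlist(signatures$sets[p$shifted_signatures]))
  lfc <- stats::setNames(rep(0, length(genes)), genes)
  lfc[shifted_genes] <- p$effect_size

  counts <- matrix(0, length(genes), n)
  for (j in seq_len(n)) {
    log_mu <- base_log + if (group[j] == "high") log(2) * lfc else 0
    counts[, j] <- stats::rnbinom(length(genes), mu = exp(log_mu), size = 1 / alpha)
  }
  ids <- sprintf("subj%02d", seq_len(n))
  dimnames(counts) <- list(genes, ids)
  meta <- data.frame(group = group, row.names = ids)
  truth <- list(effects = stats::setNames(
    ifelse(names(signatures$sets) %in% p$shifted_signatures, p$effect_size, 0),
    names(signatures$sets)))
  list(counts = count_matrix(counts, meta), truth = truth)
}
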