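# Deterministic negative-binomial synthetic scRNA-seq generator: class-specific
# gene programs (EP/ES/DS with ES intermediate), mitochondrial block for QC,
# and an age-structured donor cohort.

#' Simulation configuration
#'
#' Defaults describe the conditions the rest of the package is exercised
#' under: 1000 genes of which 100 are differentially expressed between the
#' early-proliferative (EP) and deeply-senescent (DS) programs at |log2 FC| =
#' 2 (half up, half down in DS), negative-binomial counts with dispersion 0.1,
#' log-normal library sizes centered at 10,000 UMIs (sd 0.3 on the log scale),
#' and a 10-gene mitochondrial block carrying 5% of counts in expectation.
#' The early-senescent (ES) program sits at `es_interpolation` of the way
#' from EP to DS in log-mean space, with per-cell jitter (`es_jitter_sd`)
#' making ES the heterogeneous bridge population.
#'
#' The cohort block emulates a donor series whose true DS fraction rises with
#' age: ages uniform on `age_range`, per-donor DS fraction
#' `clamp(intercept + slope * age + N(0, noise_sd), 0, 1)`. The defaults
#' (intercept 0.05, slope 0.004/yr, noise sd 0.08 over ages 20-90) plant a
#' population age-burden correlation of roughly 0.65-0.7; see the methods
#' vignette for the power reasoning behind that choice.
#'
#' @param n_genes Total genes (mitochondrial block included).
#' @param n_de_genes Genes differential between EP and DS.
#' @param classes Named integer vector of cells per class; names from
#'   EP/ES/DS.
#' @param es_interpolation ES position between EP (0) and DS (1).
#' @param es_jitter_sd Per-cell sd of the ES interpolation coefficient.
#' @param log2_fc DS-vs-EP effect on DE genes (log2).
#' @param nb_dispersion NB dispersion phi (variance = mu + phi mu^2).
#' @param library_size_log_mean,library_size_log_sd Log-normal library sizes.
#' @param gene_mean_log_sd Spread of gene base means (log-normal).
#' @param mito_fraction Expected fraction of counts in the mitochondrial
#'   block, in `[0, 1)`.
#' @param n_mito_genes Genes in the mitochondrial block (prefix `MT-`).
#' @param cohort List: `n_donors`, `age_range`, `burden_intercept`,
#'   `burden_slope`, `burden_noise_sd`, `cells_per_donor` (min/max).
#' @param seed Seed for the cell-level draws (labels, library sizes, counts,
#'   cohort ages); every draw is reproducible given it.
#' @param program_seed Separate seed fixing the gene-level parameters (base
#'   means, DE gene identities, mitochondrial scaling). Kept apart from
#'   `seed` so datasets sampled under different seeds share the same gene
#'   programs and a classifier trained on one transfers to the others.
#' @return List of class `"senpred_sim_config"`.
#' @export
simulation_config <- function(n_genes = 1000, n_de_genes = 100,
                              classes = c(EP = 1000, DS = 1000),
                              es_interpolation = 0.5, es_jitter_sd = 0.15,
                              log2_fc = 2, nb_dispersion = 0.1,
                              library_size_log_mean = log(1e4),
                              library_size_log_sd = 0.3,
                              gene_mean_log_sd = 1,
                              mito_fraction = 0.05, n_mito_genes = 10,
                              cohort = list(n_donors = 23,
                                            age_range = c(20, 90),
                                            burden_intercept = 0.05,
                                            burden_slope = 0.004,
                                            burden_noise_sd = 0.08,
                                            cells_per_donor = c(120, 400)),
                              seed = 1, program_seed = 101) {
  if (n_de_genes > n_genes) stop("n_de_genes cannot exceed n_genes", call. = FALSE)
  stopifnot(all(classes > 0), es_interpolation >= 0, es_interpolation <= 1,
            nb_dispersion > 0, mito_fraction >= 0, mito_fraction < 1,
            n_mito_genes >= 0, n_mito_genes + n_de_genes <= n_genes,
            all(names(classes) %in% c("EP", "ES", "DS")))
  cfg <- list(n_genes = n_genes, n_de_genes = n_de_genes, classes = classes,
              es_interpolation = es_interpolation, es_jitter_sd = es_jitter_sd,
              log2_fc = log2_fc, nb_dispersion = nb_dispersion,
              library_size_log_mean = library_size_log_mean,
              library_size_log_sd = library_size_log_sd,
              gene_mean_log_sd = gene_mean_log_sd,
              mito_fraction = mito_fraction, n_mito_genes = n_mito_genes,
              cohort = cohort, seed = seed, program_seed = program_seed)
  class(cfg) <- "senpred_sim_config"
  cfg
}

# Gene-level parameters for a config: base relative means, DE
# effects, mitochondrial scaling. Seeded by program_seed, not by the sampling
# seed, so datasets drawn under different seeds share the same gene programs
# and classifiers transfer between them.
.sim_genes <- function(cfg) {
  set.seed(cfg$program_seed)
  n_mito <- cfg$n_mito_genes
  gene_ids <- c(if (n_mito) paste0("MT-SIM", seq_len(n_mito)),
                sprintf("G%04d", seq_len(cfg$n_genes - n_mito)))
  base <- exp(stats::rnorm(cfg$n_genes, 0, cfg$gene_mean_log_sd))
  # expected mitochondrial share = mito_fraction: rescale the block
  if (n_mito > 0) {
    mito <- seq_len(n_mito)
    s_m <- sum(base[mito]); s_o <- sum(base[-mito])
    base[mito] <- if (cfg$mito_fraction == 0) 0 else
      base[mito] * cfg$mito_fraction * s_o / ((1 - cfg$mito_fraction) * s_m)
  }
  de <- numeric(cfg$n_genes)
  de_pool <- setdiff(seq_len(cfg$n_genes), seq_len(n_mito))
  de_idx <- sample(de_pool, cfg$n_de_genes)
  half <- cfg$n_de_genes %/% 2
  de[de_idx] <- cfg$log2_fc * rep(c(1, -1), c(cfg$n_de_genes - half, half))
  list(gene_ids = gene_ids, base = base, de = de, de_idx = de_idx)
}

# Draw counts for cells at interpolation coefficients tvec (EP=0, DS=1).
.sim_cells <- function(cfg, genes, tvec, cell_ids) {
  n <- length(tvec)
  lib <- exp(stats::rnorm(n, cfg$library_size_log_mean, cfg$library_size_log_sd))
  mult <- 2^(outer(genes$de, tvec))                 # genes x cells
  mu <- genes$base * mult
  mu <- sweep(mu, 2L, colSums(mu), "/")             # per-cell proportions
  mu <- sweep(mu, 2L, lib, "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                  size = 1 / cfg$nb_dispersion),
                   nrow = cfg$n_genes,
                   dimnames = list(genes$gene_ids, cell_ids))
  methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
}

#' Simulate class-labeled single-cell counts
#'
#' Draws a labeled EP/ES/DS dataset under the configuration: gene base means
#' log-normal, DE genes shifted by `log2_fc` in DS, ES cells placed at a
#' per-cell jittered interpolation between the EP and DS programs, library
#' sizes log-normal, counts negative-binomial. Fully deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @return List of class `"senpred_sim"`: `counts` (sparse genes x cells),
#'   `labels` (named per-cell), `metadata` (data.frame: `cell_id`, `sample`,
#'   `donor_id`, `donor_age`, `cell_type`), `de_genes` (data.frame `gene`,
#'   `log2_fc`), `config`.
#' @export
simulate_counts <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "senpred_sim_config"))
  genes <- .sim_genes(cfg)
  set.seed(cfg$seed)
  labels <- rep(names(cfg$classes), cfg$classes)
  n <- length(labels)
  tvec <- numeric(n)
  tvec[labels == "DS"] <- 1
  es <- labels == "ES"
  if (any(es)) {
    tvec[es] <- pmin(pmax(stats::rnorm(sum(es), cfg$es_interpolation,
                                       cfg$es_jitter_sd), 0), 1)
  }
  cell_ids <- sprintf("cell_%05d", seq_len(n))
  counts <- .sim_cells(cfg, genes, tvec, cell_ids)
  names(labels) <- cell_ids
  meta <- data.frame(cell_id = cell_ids, sample = labels, donor_id = "",
                     donor_age = NA_real_, cell_type = "fibroblast",
                     row.names = NULL, stringsAsFactors = FALSE)
  structure(list(counts = counts, labels = labels, metadata = meta,
                 de_genes = data.frame(gene = genes$gene_ids[genes$de_idx],
                                       log2_fc = genes$de[genes$de_idx]),
                 config = cfg),
            class = "senpred_sim")
}

#' Simulate an age-structured donor cohort
#'
#' Draws a cohort of donors with ages uniform on the configured range and a
#' true per-donor DS fraction `clamp(intercept + slope * age + noise, 0, 1)`;
#' each donor contributes a uniform random number of fibroblasts (within
#' `cells_per_donor`) whose EP/DS labels are Bernoulli draws at the donor's
#' fraction. Counts come from the same EP/DS gene programs as
#' [simulate_counts()], so a classifier trained on separated EP/DS data can
#' recover the planted age trend end-to-end.
#'
#' @param cfg A [simulation_config()] with the `cohort` block set.
#' @return List of class `"senpred_sim"` with the fields of
#'   [simulate_counts()] plus `truth`: data.frame `donor_id`, `age`,
#'   `true_ds_fraction` (expected, post-clamp), `realized_ds_fraction`,
#'   `n_cells`.
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "senpred_sim_config"))
  co <- cfg$cohort
  stopifnot(co$n_donors >= 1, length(co$age_range) == 2,
            length(co$cells_per_donor) == 2)
  genes <- .sim_genes(cfg)
  set.seed(cfg$seed)
  ages <- stats::runif(co$n_donors, co$age_range[1], co$age_range[2])
  frac <- pmin(pmax(co$burden_intercept + co$burden_slope * ages +
                      stats::rnorm(co$n_donors, 0, co$burden_noise_sd), 0), 1)
  if (all(frac == 0) || all(frac == 1))
    warning("planted DS fractions are all 0 or all 1; age trend unrecoverable",
            call. = FALSE)
  n_cells <- floor(stats::runif(co$n_donors, co$cells_per_donor[1],
                                co$cells_per_donor[2] + 1))
  donor_ids <- sprintf("D%02d", seq_len(co$n_donors))
  labels <- character(0); donor_of <- character(0)
  for (i in seq_len(co$n_donors)) {
    ds <- stats::rbinom(n_cells[i], 1, frac[i]) == 1
    labels <- c(labels, ifelse(ds, "DS", "EP"))
    donor_of <- c(donor_of, rep(donor_ids[i], n_cells[i]))
  }
  n <- length(labels)
  cell_ids <- sprintf("cell_%05d", seq_len(n))
  counts <- .sim_cells(cfg, genes, as.numeric(labels == "DS"), cell_ids)
  names(labels) <- cell_ids
  meta <- data.frame(cell_id = cell_ids, sample = labels, donor_id = donor_of,
                     donor_age = ages[match(donor_of, donor_ids)],
                     cell_type = "fibroblast", row.names = NULL,
                     stringsAsFactors = FALSE)
  realized <- vapply(donor_ids, function(d)
    mean(labels[donor_of == d] == "DS"), numeric(1))
  structure(list(counts = counts, labels = labels, metadata = meta,
                 de_genes = data.frame(gene = genes$gene_ids[genes$de_idx],
                                       log2_fc = genes$de[genes$de_idx]),
                 truth = data.frame(donor_id = donor_ids, age = ages,
                                    true_ds_fraction = frac,
                                    realized_ds_fraction = unname(realized),
                                    n_cells = n_cells,
                                    row.names = NULL, stringsAsFactors = FALSE),
                 config = cfg),
            class = "senpred_sim")
}

#' @export
print.senpred_sim <- function(x, ...) {
  cat("senpred synthetic dataset:", nrow(x$counts), "genes x", ncol(x$counts),
      "cells;", paste(names(table(x$labels)), table(x$labels),
                      sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic dataset as 10x-style files
#'
#' Writes the triplet files via [write_counts()] plus `metadata.tsv`, so
#' downstream tooling can consume the simulation from disk.
#'
#' @param sim A `"senpred_sim"` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "senpred_sim"))
  write_counts(sim$counts, dir)
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
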