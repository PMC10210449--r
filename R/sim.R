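#' Simulation configuration for a two-sex, multi-cell-type tissue
#'
#' Builds a validated configuration object describing a synthetic
#' single-cell experiment: two sexes with replicate samples, a fixed set of
#' cell types whose proportions may differ between the sexes, per-gene
#' negative-binomial expression within each cell type, lognormal per-cell
#' library-size scaling, optional dropout, and an optional within-cell-type
#' regulatory sex effect for a flagged subset of genes.
#'
#' Baseline means and regulatory gene flags are drawn once, deterministically
#' from `seed`, at configuration time, so the analytic ground truth
#' ([expected_bulk_lfc()]) is a pure function of the configuration.
#'
#' @param n_genes Number of genes.
#' @param n_cell_types Number of cell types.
#' @param n_replicates_per_sex Replicate samples per sex (default 3).
#' @param cells_per_sample Cells per sample (default 8000, the typical
#'   droplet loading of one 10x lane).
#' @param type_proportions_female,type_proportions_male Probability vectors
#'   over cell types; must each sum to 1 within 1e-12. A zero entry in one
#'   sex makes that cell type sex-limited.
#' @param baseline_means Optional `n_genes x n_cell_types` nonnegative matrix
#'   of within-type mean expression per cell (before library-size scaling).
#'   If `NULL`, drawn i.i.d. gamma(`baseline_shape`, scale =
#'   `baseline_scale`).
#' @param baseline_shape,baseline_scale Gamma parameters for drawn baselines.
#' @param nb_dispersion Per-gene NB dispersion phi (scalar recycled), with
#'   variance = mu + phi * mu^2.
#' @param libsize_logmean,libsize_logsd Lognormal parameters of the per-cell
#'   library-size scaling factor.
#' @param dropout_rate Independent zero-inflation probability in [0,1]
#'   applied after the count draw (default 0).
#' @param regulatory_fraction Fraction of genes flagged with a within-type
#'   sex effect.
#' @param regulatory_lfc Magnitude (log2 units) of the within-type effect;
#'   applied symmetrically, +lfc/2 to one sex and -lfc/2 to the other, so the
#'   within-type log2 fold change equals `regulatory_lfc` exactly.
#' @param regulatory_cell_types Integer indices of cell types in which the
#'   effect applies (default: all types).
#' @param lfc_threshold Threshold on |expected bulk log2 FC| used to define
#'   the truth set of abundance-driven genes (default 1, the downstream DE
#'   calling threshold).
#' @param omega_by_group Named numeric vector mapping divergence-group labels
#'   to the dN/dS ratio omega used by [simulate_divergence()].
#' @param p_s Per-synonymous-site substitution probability for
#'   [simulate_divergence()].
#' @param seed Integer seed; identical configurations give bit-identical
#'   simulated data.
#' @return An object of class `sim_config`.
#' @seealso [simulate_counts()], [expected_bulk_lfc()],
#'   [simulate_divergence()]
#' @export
sim_config <- function(n_genes, n_cell_types,
                       n_replicates_per_sex = 3L,
                       cells_per_sample = 8000L,
                       type_proportions_female = rep(1 / n_cell_types, n_cell_types),
                       type_proportions_male = type_proportions_female,
                       baseline_means = NULL,
                       baseline_shape = 2, baseline_scale = 4,
                       nb_dispersion = 0.1,
                       libsize_logmean = 0, libsize_logsd = 0.3,
                       dropout_rate = 0,
                       regulatory_fraction = 0, regulatory_lfc = 2,
                       regulatory_cell_types = NULL,
                       lfc_threshold = 1,
                       omega_by_group = c(background = 0.2),
                       p_s = 0.1,
                       seed = 1L) {
  stopifnot(n_genes >= 1, n_cell_types >= 1, n_replicates_per_sex >= 1,
            cells_per_sample >= 1)
  check_props <- function(p, nm) {
    if (length(p) != n_cell_types || any(p < 0) || abs(sum(p) - 1) > 1e-12)
      stop("`", nm, "` must be a length-", n_cell_types,
           " nonnegative vector summing to 1 within 1e-12", call. = FALSE)
  }
  check_props(type_proportions_female, "type_proportions_female")
  check_props(type_proportions_male, "type_proportions_male")
  if (dropout_rate < 0 || dropout_rate > 1)
    stop("`dropout_rate` must be in [0, 1]", call. = FALSE)
  if (regulatory_fraction < 0 || regulatory_fraction > 1)
    stop("`regulatory_fraction` must be in [0, 1]", call. = FALSE)
  nb_dispersion <- rep_len(nb_dispersion, n_genes)
  if (any(nb_dispersion < 0)) stop("dispersions must be >= 0", call. = FALSE)
  if (p_s < 0 || p_s > 1) stop("`p_s` must be in [0, 1]", call. = FALSE)
  if (is.null(names(omega_by_group)) || any(omega_by_group < 0))
    stop("`omega_by_group` must be a named nonnegative vector", call. = FALSE)
  seed <- as.integer(seed)

  gene_ids <- sprintf("gene%0*d", nchar(n_genes), seq_len(n_genes))
  type_ids <- paste0("type", seq_len(n_cell_types))

  set.seed(seed)
  if (is.null(baseline_means)) {
    baseline_means <- matrix(
      stats::rgamma(n_genes * n_cell_types, shape = baseline_shape,
                    scale = baseline_scale),
      n_genes, n_cell_types)
  } else {
    baseline_means <- as.matrix(baseline_means)
    if (!all(dim(baseline_means) == c(n_genes, n_cell_types)))
      stop("`baseline_means` must be ", n_genes, " x ", n_cell_types,
           call. = FALSE)
    if (any(baseline_means < 0) || any(!is.finite(baseline_means)))
      stop("`baseline_means` must be finite and nonnegative", call. = FALSE)
  }
  dimnames(baseline_means) <- list(gene_ids, type_ids)

  if (is.null(regulatory_cell_types)) regulatory_cell_types <- seq_len(n_cell_types)
  regulatory_cell_types <- as.integer(regulatory_cell_types)
  stopifnot(all(regulatory_cell_types %in% seq_len(n_cell_types)))
  n_reg <- round(regulatory_fraction * n_genes)
  reg_genes <- if (n_reg > 0) sort(sample.int(n_genes, n_reg)) else integer(0)
  reg_dir <- if (n_reg > 0) sample(c(1, -1), n_reg, replace = TRUE) else numeric(0)

  structure(list(
    n_genes = as.integer(n_genes), n_cell_types = as.integer(n_cell_types),
    n_replicates_per_sex = as.integer(n_replicates_per_sex),
    cells_per_sample = as.integer(cells_per_sample),
    type_proportions_female = type_proportions_female,
    type_proportions_male = type_proportions_male,
    baseline_means = baseline_means,
    nb_dispersion = nb_dispersion,
    libsize_logmean = libsize_logmean, libsize_logsd = libsize_logsd,
    dropout_rate = dropout_rate,
    regulatory_lfc = regulatory_lfc,
    regulatory_genes = reg_genes,
    regulatory_direction = reg_dir,
    regulatory_cell_types = regulatory_cell_types,
    lfc_threshold = lfc_threshold,
    omega_by_group = omega_by_group,
    p_s = p_s,
    gene_ids = gene_ids, type_ids = type_ids,
    seed = seed), class = "sim_config")
}

#' @exportS3Method base::print
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes,", x$n_cell_types, "cell types,",
      x$n_replicates_per_sex, "replicates/sex,", x$cells_per_sample,
      "cells/sample\n")
  cat("  regulatory genes:", length(x$regulatory_genes),
      "(lfc =", x$regulatory_lfc, "in types",
      paste(x$regulatory_cell_types, collapse = ","), ")\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# per-sex multiplicative effect matrix (genes x types): 2^(+/- dir*lfc/2) at
# flagged (gene, type) pairs, 1 elsewhere
.sim_effects <- function(config) {
  ef <- em <- matrix(1, config$n_genes, config$n_cell_types)
  if (length(config$regulatory_genes)) {
    half <- config$regulatory_direction * config$regulatory_lfc / 2
    for (k in config$regulatory_cell_types) {
      ef[config$regulatory_genes, k] <- 2^half
      em[config$regulatory_genes, k] <- 2^(-half)
    }
  }
  list(female = ef, male = em)
}

#' Analytic expected bulk log2 fold change per gene
#'
#' Closed-form ground truth for the whole-tissue pseudobulk estimator: for
#' each gene, the log2 ratio of the sex-specific mixture means
#' sum_k pi_k * mu_gk * effect_gk (female over male), including any
#' regulatory effects. A gene expressed only in cell types absent from one
#' sex gets a signed infinity and is flagged sex-limited.
#'
#' @param config A [sim_config()] object.
#' @return A data frame with columns `gene_id`, `mean_female`, `mean_male`,
#'   `expected_lfc`, `sex_limited`.
#' @export
expected_bulk_lfc <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  eff <- .sim_effects(config)
  mf <- as.vector((config$baseline_means * eff$female) %*%
                    config$type_proportions_female)
  mm <- as.vector((config$baseline_means * eff$male) %*%
                    config$type_proportions_male)
  lfc <- log2(mf / mm)
  sex_limited <- (mf == 0) != (mm == 0)
  lfc[mf == 0 & mm == 0] <- NA_real_
  data.frame(gene_id = config$gene_ids, mean_female = mf, mean_male = mm,
             expected_lfc = lfc, sex_limited = sex_limited,
             stringsAsFactors = FALSE)
}

#' Simulate a gene-by-cell count matrix with known ground truth
#'
#' Draws, for every sample, cell types from the sex-specific proportion
#' vector, per-cell lognormal library-size factors, and per-gene NB counts
#' with mean `libsize * baseline(gene, type) * 2^(+/- regulatory_lfc/2)` for
#' flagged genes (sign by sex), variance `mu + phi * mu^2`. Optional
#' independent dropout zeroes entries with probability `dropout_rate`.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `counts` (sparse dgCMatrix, genes x cells),
#'   `metadata` (data frame: cell_id, sample_id, sex, replicate, cell_type)
#'   and `truth` (see Details).
#' @details `truth` is a list with `regulatory_genes` (data frame of gene,
#'   cell_type, direction triples), `expected_bulk_lfc` (the
#'   [expected_bulk_lfc()] table), `expected_abundance_driven` (gene ids not
#'   in the regulatory set whose |expected bulk lfc| meets
#'   `config$lfc_threshold`), and `group_label` (per-gene divergence group,
#'   round-robin over `names(config$omega_by_group)`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  eff <- .sim_effects(config)
  G <- config$n_genes
  sizes <- 1 / pmax(config$nb_dispersion, 1e-12)

  blocks <- list(); meta <- list(); bi <- 0L
  for (sex in c("female", "male")) {
    pi_sex <- if (sex == "female") config$type_proportions_female else
      config$type_proportions_male
    base_eff <- config$baseline_means *
      (if (sex == "female") eff$female else eff$male)
    for (r in seq_len(config$n_replicates_per_sex)) {
      sample_id <- paste0(substr(sex, 1, 1), r)
      C <- config$cells_per_sample
      types <- sample.int(config$n_cell_types, C, replace = TRUE, prob = pi_sex)
      lib <- stats::rlnorm(C, config$libsize_logmean, config$libsize_logsd)
      mu <- base_eff[, types, drop = FALSE] *
        matrix(lib, G, C, byrow = TRUE)
      k <- stats::rnbinom(G * C, size = sizes, mu = as.vector(mu))
      if (config$dropout_rate > 0)
        k <- k * stats::rbinom(G * C, 1L, 1 - config$dropout_rate)
      m <- matrix(k, G, C)
      bi <- bi + 1L
      blocks[[bi]] <- Matrix::Matrix(m, sparse = TRUE)
      meta[[bi]] <- data.frame(
        cell_id = paste0(sample_id, "_cell", seq_len(C)),
        sample_id = sample_id, sex = sex, replicate = paste0("rep", r),
        cell_type = config$type_ids[types], stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, blocks)
  metadata <- do.call(rbind, meta)
  rownames(counts) <- config$gene_ids
  colnames(counts) <- metadata$cell_id
  rownames(metadata) <- NULL

  lfc_tab <- expected_bulk_lfc(config)
  reg <- if (length(config$regulatory_genes)) {
    expand <- expand.grid(i = seq_along(config$regulatory_genes),
                          k = config$regulatory_cell_types)
    data.frame(gene_id = config$gene_ids[config$regulatory_genes[expand$i]],
               cell_type = config$type_ids[expand$k],
               direction = ifelse(config$regulatory_direction[expand$i] > 0,
                                  "female", "male"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(0), cell_type = character(0),
               direction = character(0), stringsAsFactors = FALSE)
  }
  abn <- setdiff(
    lfc_tab$gene_id[!is.na(lfc_tab$expected_lfc) &
                      is.finite(lfc_tab$expected_lfc) &
                      abs(lfc_tab$expected_lfc) >= config$lfc_threshold],
    unique(reg$gene_id))
  groups <- names(config$omega_by_group)
  truth <- list(
    regulatory_genes = reg,
    expected_bulk_lfc = lfc_tab,
    expected_abundance_driven = abn,
    group_label = stats::setNames(
      groups[(seq_len(G) - 1L) %% length(groups) + 1L], config$gene_ids))
  list(counts = counts, metadata = metadata, truth = truth)
}

#' Simulate per-gene substitution counts under group-specific omega
#'
#' For each gene, draws synonymous substitutions D_S ~ Binomial(S, p_s) and
#' nonsynonymous substitutions D_N ~ Binomial(N, omega * p_s), where omega is
#' the dN/dS ratio of the gene's group. Per-gene rates dN = D_N/N and
#' dS = D_S/S are recorded.
#'
#' @param config A [sim_config()] object supplying `omega_by_group`, `p_s`
#'   and the seed.
#' @param n_by_gene,s_by_gene Positive per-gene counts of nonsynonymous and
#'   synonymous sites (recycled).
#' @param groups Optional per-gene group labels (must be names of
#'   `config$omega_by_group`); default round-robin assignment.
#' @param n_genes Number of genes (default `config$n_genes`).
#' @return A data frame with columns gene, group, DN, DS, N, S, dN, dS.
#' @export
simulate_divergence <- function(config, n_by_gene, s_by_gene,
                                groups = NULL, n_genes = config$n_genes) {
  stopifnot(inherits(config, "sim_config"))
  N <- rep_len(n_by_gene, n_genes); S <- rep_len(s_by_gene, n_genes)
  if (any(N <= 0) || any(S <= 0))
    stop("site counts N and S must be > 0", call. = FALSE)
  omega <- config$omega_by_group
  if (is.null(groups)) {
    groups <- names(omega)[(seq_len(n_genes) - 1L) %% length(omega) + 1L]
  }
  groups <- rep_len(groups, n_genes)
  if (!all(groups %in% names(omega)))
    stop("`groups` contains labels absent from `omega_by_group`", call. = FALSE)
  pn <- omega[groups] * config$p_s
  if (any(pn > 1))
    stop("omega * p_s exceeds 1: invalid binomial probability", call. = FALSE)
  set.seed(config$seed + 2L)
  DS <- stats::rbinom(n_genes, S, config$p_s)
  DN <- stats::rbinom(n_genes, N, pn)
  data.frame(gene = sprintf("gene%0*d", nchar(n_genes), seq_len(n_genes)),
             group = groups, DN = DN, DS = DS, N = N, S = S,
             dN = DN / N, dS = DS / S, stringsAsFactors = FALSE)
}

#' Write a simulated dataset to disk
#'
#' Writes the count matrix as a 10x-style triplet directory (matrix.mtx +
#' features.tsv + barcodes.tsv), the cell metadata and truth tables as TSV,
#' and the configuration as a flat key=value file.
#'
#' @param sim Result of [simulate_counts()].
#' @param dir Output directory (created if needed).
#' @param config The [sim_config()] used (for the key=value echo); optional.
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$counts, file.path(dir, "counts"))
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$expected_bulk_lfc,
                     file.path(dir, "truth_bulk_lfc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$regulatory_genes,
                     file.path(dir, "truth_regulatory.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(config)) {
    scalars <- Filter(function(x) is.atomic(x) && length(x) == 1,
                      unclass(config))
    writeLines(paste0(names(scalars), "=", unlist(scalars)),
               file.path(dir, "config.txt"))
  }
  invisible(dir)
}
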