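# Shared fixture builders and independent oracles. Everything is generated
# in code; no binary fixtures.

# small dense count matrix wrapped as a sparse dgCMatrix with ids
make_counts <- function(m, genes = NULL, cells = NULL) {
  m <- as.matrix(m)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(m)))
  if (is.null(cells)) cells <- paste0("c", seq_len(ncol(m)))
  dimnames(m) <- list(genes, cells)
  Matrix::Matrix(m, sparse = TRUE)
}

# metadata for a matrix whose cells are split across samples round-robin
make_meta <- function(cells, sample_id, sex, cell_type) {
  data.frame(cell_id = cells, sample_id = sample_id, sex = sex,
             replicate = sample_id, cell_type = cell_type,
             stringsAsFactors = FALSE)
}

# quick two-type simulation used by several tests
quick_sim <- function(seed = 1, n_genes = 60, cells = 80, ...) {
  cfg <- sim_config(n_genes = n_genes, n_cell_types = 2,
                    n_replicates_per_sex = 3, cells_per_sample = cells,
                    seed = seed, ...)
  simulate_counts(cfg)
}

# pseudobulk object built directly from a genes x samples matrix
make_pb <- function(m, sex, stratum = "whole_tissue") {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  structure(list(values = m, sample_ids = colnames(m), sample_sex = sex,
                 stratum = stratum, dropped_samples = character(0)),
            class = "pseudobulk")
}

# minimal de_result for classification tests: calls given directly
make_de <- function(gene_ids, calls) {
  data.frame(gene_id = gene_ids, base_mean = 1, log2fc = 0,
             se_log2fc = 1, p_value = 0.5, fdr = 0.5, call = calls,
             sex_limited = FALSE, stringsAsFactors = FALSE)
}

# divergence table builder
make_div <- function(DN, DS, N, S, gene = NULL, ...) {
  n <- max(length(DN), length(DS), length(N), length(S))
  if (is.null(gene)) gene <- paste0("g", seq_len(n))
  data.frame(gene = gene, DN = rep_len(DN, n), DS = rep_len(DS, n),
             N = rep_len(N, n), S = rep_len(S, n), ...,
             stringsAsFactors = FALSE)
}

# ---- independent oracles -------------------------------------------------

# brute-force BH step-up from the definition: sort ascending, adjusted
# order statistic i is min over j >= i of m p_(j) / j, clipped at 1
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * ps[j] / j)
    adj[i] <- min(best, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# hand-coded 2x2 chi-square with capped Yates continuity correction
# (the textbook contingency computation, coded independently of prop.test)
chisq2x2_oracle <- function(n1, t1, n2, t2, correct = TRUE) {
  x <- rbind(c(n1, t1 - n1), c(n2, t2 - n2))
  E <- outer(rowSums(x), colSums(x)) / sum(x)
  Y <- if (correct) min(0.5, abs(x[1, 1] - E[1, 1])) else 0
  stat <- sum((abs(x - E) - Y)^2 / E)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# textbook Pearson correlation from raw sums
pearson_oracle <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# literal re-application of the filtering definition by double loop
filter_oracle <- function(m, min_cells, min_genes) {
  m <- as.matrix(m)
  gk <- rep(FALSE, nrow(m))
  for (g in seq_len(nrow(m))) gk[g] <- sum(m[g, ] > 0) >= min_cells
  m2 <- m[gk, , drop = FALSE]
  ck <- rep(FALSE, ncol(m2))
  for (ce in seq_len(ncol(m2))) ck[ce] <- sum(m2[, ce] > 0) >= min_genes
  m2[, ck, drop = FALSE]
}
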