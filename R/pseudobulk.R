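# Pseudobulk aggregation, median-of-ratios normalization, and a
# self-contained per-gene negative-binomial Wald test with BH correction.

#' Aggregate single-cell counts to sample-level pseudobulk
#'
#' Sums raw counts over all cells of each sample, either across the whole
#' tissue (`stratum = "whole_tissue"`) or restricted to one cell type.
#' Sums are exact integer arithmetic; a sample contributing zero cells to
#' the stratum is dropped and recorded in the `dropped_samples` attribute.
#'
#' @param counts Genes x cells count matrix.
#' @param meta Cell metadata (see [validate_metadata()]).
#' @param stratum `"whole_tissue"` or a cell-type label present in `meta`.
#' @return A `pseudobulk` object: list with `values` (genes x samples dense
#'   matrix), `sample_ids`, `sample_sex`, `stratum`, `dropped_samples`.
#' @export
aggregate_pseudobulk <- function(counts, meta, stratum = "whole_tissue") {
  .validate_counts(counts)
  validate_metadata(meta, counts)
  idx <- match(colnames(counts), meta$cell_id)
  keep <- rep(TRUE, ncol(counts))
  if (!identical(stratum, "whole_tissue")) {
    if (!stratum %in% meta$cell_type)
      stop("stratum '", stratum, "' not present in metadata", call. = FALSE)
    keep <- meta$cell_type[idx] == stratum
  }
  samples <- unique(meta[c("sample_id", "sex")])
  cell_sample <- meta$sample_id[idx]
  vals <- vapply(samples$sample_id, function(s) {
    cols <- which(keep & cell_sample == s)
    if (length(cols) == 0) rep(NA_real_, nrow(counts))
    else Matrix::rowSums(counts[, cols, drop = FALSE])
  }, numeric(nrow(counts)))
  vals <- matrix(vals, nrow = nrow(counts),
                 dimnames = list(rownames(counts), samples$sample_id))
  dropped <- samples$sample_id[colSums(is.na(vals)) > 0]
  ok <- !samples$sample_id %in% dropped
  structure(list(values = vals[, ok, drop = FALSE],
                 sample_ids = samples$sample_id[ok],
                 sample_sex = samples$sex[ok],
                 stratum = stratum,
                 dropped_samples = dropped),
            class = "pseudobulk")
}

#' @exportS3Method base::print
print.pseudobulk <- function(x, ...) {
  cat("pseudobulk [", x$stratum, "]: ", nrow(x$values), " genes x ",
      length(x$sample_ids), " samples (",
      sum(x$sample_sex == "female"), "F/", sum(x$sample_sex == "male"), "M)",
      if (length(x$dropped_samples))
        paste0("; dropped: ", paste(x$dropped_samples, collapse = ",")),
      "\n", sep = "")
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over reference genes of the ratio of its
#' count to the gene's geometric mean across samples. Reference genes are
#' those with positive counts in every sample; if none exist, falls back to
#' total-count ratios (each sample's total over the geometric mean of
#' totals) with a warning.
#'
#' @param pb A `pseudobulk` object or a genes x samples matrix.
#' @return Positive numeric vector, one factor per sample.
#' @export
size_factors <- function(pb) {
  m <- if (inherits(pb, "pseudobulk")) pb$values else as.matrix(pb)
  if (ncol(m) < 2) stop("need at least 2 samples", call. = FALSE)
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref)) {
    warning("no gene positive in all samples; falling back to total-count ratios")
    tot <- colSums(m)
    return(tot / exp(mean(log(tot))))
  }
  logg <- rowMeans(log(m[ref, , drop = FALSE]))
  sf <- apply(m[ref, , drop = FALSE], 2, function(col)
    stats::median(exp(log(col) - logg)))
  stats::setNames(sf, colnames(m))
}

# Vectorized NB group-mean MLE across genes: Newton iterations on
# eta_g = log q_g for a genes x samples count block with offsets sf.
# Genes with an all-zero row drift to the clamp and are zeroed by the
# caller. Returns the eta vector.
.nb_newton_eta <- function(k, sf, phi, eta, iters = 12L) {
  for (i in seq_len(iters)) {
    mu <- exp(eta) %o% sf
    w <- 1 + phi * mu
    score <- rowSums((k - mu) / w)
    info <- rowSums(mu / w)
    step <- score / pmax(info, 1e-300)
    eta <- pmin(pmax(eta + pmin(pmax(step, -2), 2), -35), 35)
  }
  eta
}

# Per-gene dispersion by maximizing the Cox-Reid adjusted profile
# log-likelihood (APL) over a fixed log-spaced grid, vectorized across
# genes. With prior_df > 0 the objective is the edgeR-style weighted
# likelihood APL_g(phi) + (prior_df / residual_df) * mean_g' APL_g'(phi),
# which moderates the noisy per-gene estimates toward the common optimum;
# prior_df = 0 gives the unmoderated per-gene fit. Returns per-gene
# phi_hat, group means (exact 0 for all-zero groups), and the Fisher
# information of each group's log-mean at the optimum.
.nb_fit_grid <- function(kf, sff, km, sfm, prior_df = 10,
                         phi_grid = exp(seq(log(1e-8), log(100),
                                            length.out = 50L))) {
  G <- nrow(kf)
  P <- length(phi_grid)
  zf <- rowSums(kf) == 0; zm <- rowSums(km) == 0
  eta0f <- log(pmax(rowSums(kf), 0.5) / sum(sff))
  eta0m <- log(pmax(rowSums(km), 0.5) / sum(sfm))
  LL <- QF <- QM <- IF <- IM <- matrix(NA_real_, G, P)
  for (j in seq_len(P)) {
    phi <- phi_grid[j]
    etaf <- .nb_newton_eta(kf, sff, phi, eta0f)
    etam <- .nb_newton_eta(km, sfm, phi, eta0m)
    muf <- exp(etaf) %o% sff; mum <- exp(etam) %o% sfm
    muf[zf, ] <- 0; mum[zm, ] <- 0
    If <- rowSums(muf / (1 + phi * muf))
    Im <- rowSums(mum / (1 + phi * mum))
    LL[, j] <- rowSums(matrix(stats::dnbinom(kf, size = 1 / phi, mu = muf,
                                             log = TRUE), G)) +
      rowSums(matrix(stats::dnbinom(km, size = 1 / phi, mu = mum,
                                    log = TRUE), G)) -
      0.5 * (ifelse(zf, 0, log(pmax(If, 1e-300))) +
               ifelse(zm, 0, log(pmax(Im, 1e-300))))
    QF[, j] <- exp(etaf); QM[, j] <- exp(etam)
    IF[, j] <- If; IM[, j] <- Im
  }
  residual_df <- max(length(sff) + length(sfm) - 2L, 1L)
  w <- prior_df / residual_df
  obj <- if (w > 0) LL + rep(w * colMeans(LL), each = G) else LL
  jstar <- max.col(obj, ties.method = "first")
  ix <- cbind(seq_len(G), jstar)
  out <- list(phi = phi_grid[jstar], qf = QF[ix], qm = QM[ix],
              If = IF[ix], Im = IM[ix])
  out$qf[zf] <- 0; out$qm[zm] <- 0
  out
}

#' Negative-binomial Wald test for sex-biased expression
#'
#' Per gene, fits sex-specific NB means with log(size factor) offsets and a
#' gene-wise dispersion maximizing the Cox-Reid adjusted profile likelihood
#' over a fixed log-spaced grid (moderated toward the genes' common optimum
#' by `prior_df`), then tests the log mean ratio (female over male) with a
#' Wald z statistic. Genes with zero counts in
#' every sample are excluded from testing and returned with call
#' `"untested"`. Benjamini-Hochberg adjustment is applied over tested genes
#' only; a gene is called sex-biased when |log2 FC| >= `lfc_threshold` and
#' FDR < `fdr_threshold`.
#'
#' Genes whose fitted mean is exactly zero in one sex are flagged
#' `sex_limited`; their log2 FC is the sentinel +/-30 and the Wald p is
#' computed after replacing the zero mean by the half-count continuity value
#' `0.5 / sum(size factors)` of that sex.
#'
#' @param pb A `pseudobulk` object.
#' @param lfc_threshold Minimum |log2 FC| for a sex-biased call (default 1).
#' @param fdr_threshold FDR ceiling for a sex-biased call (default 0.05).
#' @param sf Optional precomputed size factors; default [size_factors()].
#' @param prior_df Weight (in prior degrees of freedom) of the shared
#'   dispersion likelihood in the per-gene dispersion fit; 10 by default
#'   (the classic moderation strength for small designs), 0 for a purely
#'   per-gene fit. With 3 samples per sex the per-gene dispersion is too
#'   noisy for a calibrated Wald test without some moderation.
#' @return A `de_result` data frame: gene_id, base_mean, log2fc, se_log2fc,
#'   p_value, fdr, call, sex_limited; attributes `stratum`, `n_female`,
#'   `n_male`.
#' @export
nb_de_test <- function(pb, lfc_threshold = 1, fdr_threshold = 0.05,
                       sf = NULL, prior_df = 10) {
  stopifnot(inherits(pb, "pseudobulk"))
  is_f <- pb$sample_sex == "female"
  sexes <- unique(pb$sample_sex)
  if (length(sexes) < 2)
    stop_stratum("stratum '", pb$stratum, "' is sex-limited (", sexes,
                 " only)")
  if (sum(is_f) < 2 || sum(!is_f) < 2)
    stop_stratum("stratum '", pb$stratum,
                 "' has fewer than 2 samples in one sex")
  m <- pb$values
  if (is.null(sf)) sf <- size_factors(pb)
  sff <- sf[is_f]; sfm <- sf[!is_f]
  G <- nrow(m)
  log2fc <- se <- p <- rep(NA_real_, G)
  base_mean <- rowMeans(sweep(m, 2, sf, "/"))
  sex_limited <- rep(FALSE, G)
  tested <- rowSums(m) > 0
  ln2 <- log(2)

  if (any(tested)) {
    fit <- .nb_fit_grid(m[tested, is_f, drop = FALSE], sff,
                        m[tested, !is_f, drop = FALSE], sfm,
                        prior_df = prior_df)
    qf <- fit$qf; qm <- fit$qm; phi <- fit$phi
    zero_f <- qf == 0; zero_m <- qm == 0
    sl <- xor(zero_f, zero_m)
    lfc <- log2(qf / qm)
    lfc[sl & zero_f] <- -30; lfc[sl & zero_m] <- 30
    # half-count continuity mean for the Wald statistic of sex-limited genes
    qf2 <- ifelse(zero_f, 0.5 / sum(sff), qf)
    qm2 <- ifelse(zero_m, 0.5 / sum(sfm), qm)
    If <- fit$If; Im <- fit$Im
    If[zero_f] <- vapply(which(zero_f), function(i)
      sum(sff * qf2[i] / (1 + phi[i] * sff * qf2[i])), numeric(1))
    Im[zero_m] <- vapply(which(zero_m), function(i)
      sum(sfm * qm2[i] / (1 + phi[i] * sfm * qm2[i])), numeric(1))
    se_beta <- sqrt(1 / If + 1 / Im)
    zstat <- log(qf2 / qm2) / se_beta
    log2fc[tested] <- lfc
    se[tested] <- se_beta / ln2
    p[tested] <- 2 * stats::pnorm(-abs(zstat))
    sex_limited[tested] <- sl
  }
  fdr <- rep(NA_real_, G)
  fdr[tested] <- bh_adjust(p[tested])
  call <- rep("untested", G)
  biased <- tested & abs(log2fc) >= lfc_threshold & fdr < fdr_threshold
  call[tested] <- "unbiased"
  call[biased & log2fc > 0] <- "female_biased"
  call[biased & log2fc < 0] <- "male_biased"
  res <- data.frame(gene_id = rownames(m), base_mean = base_mean,
                    log2fc = log2fc, se_log2fc = se, p_value = p, fdr = fdr,
                    call = call, sex_limited = sex_limited,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "stratum") <- pb$stratum
  attr(res, "n_female") <- sum(is_f)
  attr(res, "n_male") <- sum(!is_f)
  class(res) <- c("de_result", "data.frame")
  res
}

# stratum-level condition: reported by the pipeline, not fatal to it
stop_stratum <- function(...) {
  stop(structure(class = c("stratum_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns, in input order, `adj_(i) = min_(j >= i) m * p_(j) / j` over the
#' ascending order statistics, clipped at 1.
#'
#' @param p Numeric vector of p-values in [0, 1] (NA allowed, passed
#'   through).
#' @return Adjusted values in [0, 1].
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m) {
    o <- order(pv)
    adj <- pmin(1, cummin((m / m:1) * pv[o][m:1])[m:1])
    tmp <- numeric(m); tmp[o] <- adj
    out[ok] <- tmp
  }
  out
}
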