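# Group-aggregated coding-sequence divergence: dN, dS, omega with
# percentile-bootstrap CIs and permutation contrasts between gene groups.

#' Read a per-gene divergence table
#'
#' Expects a TSV with header containing at least the columns gene, DN, DS,
#' N, S (dN and dS are recomputed if absent and cross-checked if present).
#' This is the tabular export of a codon-model fit (one row per gene); the
#' codon model itself is upstream of this package.
#'
#' @param path TSV path.
#' @return Validated data frame with columns gene, DN, DS, N, S, dN, dS
#'   (plus any extra columns, e.g. group).
#' @export
read_divergence <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  validate_divergence(d)
}

#' Validate a divergence table
#'
#' @param d Data frame with columns gene, DN, DS, N, S and optionally
#'   dN, dS.
#' @return The table with dN, dS filled in.
#' @export
validate_divergence <- function(d) {
  need <- c("gene", "DN", "DS", "N", "S")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("divergence table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(d$N <= 0) || any(d$S <= 0))
    stop("site counts N and S must be > 0", call. = FALSE)
  if (any(d$DN < 0) || any(d$DS < 0) ||
      any(!is.finite(d$DN)) || any(!is.finite(d$DS)))
    stop("substitution counts must be finite and >= 0", call. = FALSE)
  if (!is.null(d$dN) && any(abs(d$dN - d$DN / d$N) > 1e-9))
    stop("column dN inconsistent with DN/N", call. = FALSE)
  if (!is.null(d$dS) && any(abs(d$dS - d$DS / d$S) > 1e-9))
    stop("column dS inconsistent with DS/S", call. = FALSE)
  d$dN <- d$DN / d$N
  d$dS <- d$DS / d$S
  d
}

#' Drop mutation-saturated genes
#'
#' Removes genes whose per-gene synonymous rate dS exceeds `ds_max`
#' (default 2; genes at exactly the threshold are retained). Saturated
#' synonymous sites make divergence estimates unreliable.
#'
#' @param records Divergence table (see [validate_divergence()]).
#' @param ds_max Retention ceiling on per-gene dS.
#' @return Filtered table; the number removed is reported via `message()`.
#' @export
filter_saturated <- function(records, ds_max = 2) {
  records <- validate_divergence(records)
  keep <- records$dS <= ds_max
  if (any(!keep))
    message(sum(!keep), " gene(s) removed with dS > ", ds_max)
  records[keep, , drop = FALSE]
}

.group_point <- function(DN, DS, N, S) {
  dn <- sum(DN) / sum(N)
  ds <- sum(DS) / sum(S)
  list(d_N = dn, d_S = ds,
       omega = if (sum(DS) == 0) NA_real_ else dn / ds)
}

#' Group-aggregated divergence rates
#'
#' Aggregates a gene group as total substitutions over total sites:
#' d_N = sum(D_N)/sum(N), d_S = sum(D_S)/sum(S), omega = d_N/d_S. Omega is
#' `NA` (flagged) when the group has no synonymous substitutions.
#'
#' @param records Divergence table for one group (>= 1 gene).
#' @return A `group_divergence` list: n_genes, d_N, d_S, omega,
#'   omega_defined.
#' @export
group_rates <- function(records) {
  records <- validate_divergence(records)
  if (nrow(records) < 1) stop("need at least 1 gene", call. = FALSE)
  pt <- .group_point(records$DN, records$DS, records$N, records$S)
  structure(c(list(n_genes = nrow(records)), pt,
              list(omega_defined = !is.na(pt$omega))),
            class = "group_divergence")
}

#' @exportS3Method base::print
print.group_divergence <- function(x, ...) {
  cat(sprintf("group_divergence: %d genes  d_N=%.4g  d_S=%.4g  omega=%s\n",
              x$n_genes, x$d_N, x$d_S,
              if (x$omega_defined) sprintf("%.4g", x$omega) else "undefined"))
  if (!is.null(x$ci_omega))
    cat(sprintf("  95%% CI omega: [%.4g, %.4g]  (B = %d)\n",
                x$ci_omega[1], x$ci_omega[2], x$bootstrap_B))
  invisible(x)
}

#' Percentile bootstrap confidence intervals for group rates
#'
#' Resamples genes with replacement `B` times, recomputes the aggregated
#' d_N, d_S and omega on each replicate, and returns equal-tailed percentile
#' intervals. Replicates with zero synonymous substitutions are excluded
#' from the omega interval (counted, with a warning).
#'
#' @param records Divergence table for one group (>= 2 genes for a
#'   nondegenerate interval).
#' @param B Number of bootstrap replicates (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @return A `group_divergence` list extending [group_rates()] with ci_dn,
#'   ci_ds, ci_omega, bootstrap_B, n_omega_undefined.
#' @export
bootstrap_ci <- function(records, B = 1000L, level = 0.95, seed = NULL) {
  records <- validate_divergence(records)
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(records)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
  sDN <- colSums(matrix(records$DN[idx], n, B))
  sDS <- colSums(matrix(records$DS[idx], n, B))
  sN <- colSums(matrix(records$N[idx], n, B))
  sS <- colSums(matrix(records$S[idx], n, B))
  dn <- sDN / sN; ds <- sDS / sS
  om <- ifelse(sDS == 0, NA_real_, dn / ds)
  n_undef <- sum(is.na(om))
  if (n_undef > 0)
    warning(n_undef, " bootstrap replicate(s) had no synonymous ",
            "substitutions and were excluded from the omega interval")
  a <- (1 - level) / 2
  qi <- function(x) unname(stats::quantile(x, c(a, 1 - a), na.rm = TRUE))
  out <- group_rates(records)
  out$ci_dn <- qi(dn); out$ci_ds <- qi(ds); out$ci_omega <- qi(om)
  out$bootstrap_B <- as.integer(B)
  out$n_omega_undefined <- n_undef
  out
}

#' Permutation test of a group difference in aggregated rates
#'
#' Pools the two groups' genes, reshuffles the group labels `B` times
#' preserving group sizes, and compares the observed difference of
#' aggregated statistics to the permutation distribution. Two-sided p is
#' `(1 + #{|perm| >= |obs|}) / (B + 1)`.
#'
#' @param records_a,records_b Divergence tables for the two groups.
#' @param B Number of permutations (default 1000).
#' @param statistic `"omega"` (default), `"dn"` or `"ds"`.
#' @param seed Optional integer seed.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (direction of group a minus group b).
#' @return List: statistic, observed_a, observed_b, observed_diff, p_value,
#'   B, n_excluded (replicates with undefined omega).
#' @export
permutation_test <- function(records_a, records_b, B = 1000L,
                             statistic = c("omega", "dn", "ds"),
                             seed = NULL,
                             alternative = c("two.sided", "greater", "less")) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  records_a <- validate_divergence(records_a)
  records_b <- validate_divergence(records_b)
  if (nrow(records_a) == 0 || nrow(records_b) == 0)
    stop("both groups must be nonempty", call. = FALSE)
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  stat_fun <- function(DN, DS, N, S) {
    pt <- .group_point(DN, DS, N, S)
    switch(statistic, omega = pt$omega, dn = pt$d_N, ds = pt$d_S)
  }
  oa <- stat_fun(records_a$DN, records_a$DS, records_a$N, records_a$S)
  ob <- stat_fun(records_b$DN, records_b$DS, records_b$N, records_b$S)
  if (is.na(oa) || is.na(ob))
    stop("observed omega undefined in a group (no synonymous substitutions)",
         call. = FALSE)
  obs <- oa - ob

  pool <- rbind(records_a[c("DN", "DS", "N", "S")],
                records_b[c("DN", "DS", "N", "S")])
  n <- nrow(pool); na <- nrow(records_a)
  totDN <- sum(pool$DN); totDS <- sum(pool$DS)
  totN <- sum(pool$N); totS <- sum(pool$S)
  sel <- matrix(FALSE, n, B)
  for (b in seq_len(B)) sel[sample.int(n, na), b] <- TRUE
  aDN <- crossprod(sel, pool$DN)[, 1]; aDS <- crossprod(sel, pool$DS)[, 1]
  aN <- crossprod(sel, pool$N)[, 1]; aS <- crossprod(sel, pool$S)[, 1]
  stat_a <- switch(statistic,
                   omega = ifelse(aDS == 0, NA, (aDN / aN) / (aDS / aS)),
                   dn = aDN / aN, ds = aDS / aS)
  bDS <- totDS - aDS
  stat_b <- switch(statistic,
                   omega = ifelse(bDS == 0, NA,
                                  ((totDN - aDN) / (totN - aN)) /
                                    (bDS / (totS - aS))),
                   dn = (totDN - aDN) / (totN - aN),
                   ds = bDS / (totS - aS))
  diffs <- stat_a - stat_b
  excluded <- is.na(diffs)
  if (any(excluded))
    warning(sum(excluded), " permutation replicate(s) had undefined omega ",
            "and were excluded")
  diffs <- diffs[!excluded]
  Beff <- length(diffs)
  p <- switch(alternative,
              two.sided = (1 + sum(abs(diffs) >= abs(obs))) / (Beff + 1),
              greater = (1 + sum(diffs >= obs)) / (Beff + 1),
              less = (1 + sum(diffs <= obs)) / (Beff + 1))
  list(statistic = statistic, observed_a = oa, observed_b = ob,
       observed_diff = obs, p_value = p, B = Beff,
       n_excluded = sum(excluded))
}

# compact letter display by insert-and-absorb: groups sharing a letter are
# not significantly different; significant pairs never share a letter
.compact_letters <- function(pmat, alpha = 0.05) {
  g <- nrow(pmat)
  letters_sets <- list(seq_len(g))
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    if (is.na(pmat[i, j]) || pmat[i, j] >= alpha) next
    repeat {
      hit <- which(vapply(letters_sets,
                          function(s) i %in% s && j %in% s, logical(1)))
      if (!length(hit)) break
      s <- letters_sets[[hit[1]]]
      letters_sets[[hit[1]]] <- NULL
      cand <- list(setdiff(s, i), setdiff(s, j))
      for (cs in cand) {
        absorbed <- any(vapply(letters_sets,
                               function(t) all(cs %in% t), logical(1)))
        if (!absorbed && length(cs)) letters_sets <- c(letters_sets, list(cs))
      }
    }
  }
  lab <- rep("", g)
  for (k in seq_along(letters_sets))
    for (m in letters_sets[[k]])
      lab[m] <- paste0(lab[m], letters[k])
  vapply(lab, function(x)
    paste(sort(strsplit(x, "")[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE)
}

#' Divergence rates per gene category with pairwise permutation letters
#'
#' Joins a gene classification to a divergence table and reports, per group
#' (unbiased; bulk-level female/male = all bulk-biased genes; bulk-only
#' female/male; bulk-and-cell female/male; cell-only female/male), the
#' aggregated rates with bootstrap CIs, plus a compact letter display of
#' pairwise permutation tests at `alpha` (groups sharing a letter are not
#' significantly different).
#'
#' @param categories Output of [classify_genes()] (needs gene_id, category,
#'   direction).
#' @param records Divergence table; joined on `gene` == `gene_id`. Apply
#'   [filter_saturated()] beforehand if desired.
#' @param B Bootstrap and permutation replicates (default 1000).
#' @param alpha Pairwise significance level for the letters (default 0.05).
#' @param statistic Statistic for the pairwise tests (default `"omega"`).
#' @param seed Optional integer seed.
#' @param min_genes Groups smaller than this are skipped with a notice
#'   (default 2).
#' @return Data frame: group, n_genes, d_N, d_S, omega, CI bounds, letters.
#' @export
compare_categories <- function(categories, records, B = 1000L, alpha = 0.05,
                               statistic = "omega", seed = NULL,
                               min_genes = 2L) {
  records <- validate_divergence(records)
  idx <- match(records$gene, categories$gene_id)
  if (all(is.na(idx)))
    stop("no gene ids shared between categories and divergence table",
         call. = FALSE)
  records <- records[!is.na(idx), , drop = FALSE]
  cat_r <- categories[idx[!is.na(idx)], ]

  members <- list(unbiased = cat_r$category == "unbiased")
  for (dir in c("female", "male")) {
    members[[paste0("bulk_level_", dir)]] <-
      cat_r$category %in% c("bulk_only", "bulk_and_cell") &
      cat_r$direction == dir
    members[[paste0("bulk_only_", dir)]] <-
      cat_r$category == "bulk_only" & cat_r$direction == dir
    members[[paste0("bulk_and_cell_", dir)]] <-
      cat_r$category == "bulk_and_cell" & cat_r$direction == dir
    members[[paste0("cell_only_", dir)]] <-
      cat_r$category == "cell_only" & cat_r$direction == dir
  }
  sizes <- vapply(members, sum, integer(1))
  skipped <- names(members)[sizes < min_genes]
  if (length(skipped))
    message("skipping group(s) with < ", min_genes, " genes: ",
            paste(skipped, collapse = ", "))
  members <- members[sizes >= min_genes]
  if (!length(members)) stop("no group large enough to compare", call. = FALSE)

  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(names(members), function(gname) {
    gd <- bootstrap_ci(records[members[[gname]], , drop = FALSE], B = B)
    data.frame(group = gname, n_genes = gd$n_genes, d_N = gd$d_N,
               d_S = gd$d_S, omega = gd$omega,
               omega_lo = gd$ci_omega[1], omega_hi = gd$ci_omega[2],
               dn_lo = gd$ci_dn[1], dn_hi = gd$ci_dn[2],
               ds_lo = gd$ci_ds[1], ds_hi = gd$ci_ds[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ng <- length(members)
  pmat <- matrix(NA_real_, ng, ng)
  if (ng > 1) {
    for (i in seq_len(ng - 1)) for (j in (i + 1):ng) {
      pt <- permutation_test(records[members[[i]], , drop = FALSE],
                             records[members[[j]], , drop = FALSE],
                             B = B, statistic = statistic)
      pmat[i, j] <- pmat[j, i] <- pt$p_value
    }
    out$letters <- .compact_letters(pmat, alpha)
  } else out$letters <- "a"
  attr(out, "pairwise_p") <- pmat
  out
}
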