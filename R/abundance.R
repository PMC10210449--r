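# Differential cell-type abundance between sexes: pooled proportions,
# pseudocounted log2 fold change, two-proportion z-test.

#' Pseudocounted log2 fold change between two proportions
#'
#' `log2((prop_female + pseudocount) / (prop_male + pseudocount))`. The
#' pseudocount (default 1e-10) keeps the ratio finite when a cell type is
#' absent from one sex.
#'
#' @param prop_female,prop_male Proportions in [0, 1].
#' @param pseudocount Small positive constant added to both proportions.
#' @return Finite log2 fold change (female over male).
#' @export
abundance_log2fc <- function(prop_female, prop_male, pseudocount = 1e-10) {
  if (any(prop_female < 0) || any(prop_male < 0) ||
      any(prop_female > 1) || any(prop_male > 1))
    stop("proportions must be in [0, 1]", call. = FALSE)
  log2((prop_female + pseudocount) / (prop_male + pseudocount))
}

#' Two-proportion z-test
#'
#' Two-sided test of equality of two binomial proportions, computed as the
#' pooled 2x2 chi-square with Yates continuity correction (the default
#' behaviour of `stats::prop.test`, which this wraps). Identical proportions
#' return p = 1 exactly.
#'
#' @param n1,total1 Successes and trials in group 1.
#' @param n2,total2 Successes and trials in group 2.
#' @param correct Apply the continuity correction (default TRUE).
#' @return Two-sided p-value in [0, 1].
#' @export
two_proportion_test <- function(n1, total1, n2, total2, correct = TRUE) {
  if (any(c(n1, n2) < 0) || n1 > total1 || n2 > total2 ||
      total1 <= 0 || total2 <= 0)
    stop("need 0 <= n <= total and totals > 0", call. = FALSE)
  if (n1 / total1 == n2 / total2) return(1)
  res <- suppressWarnings(
    stats::prop.test(c(n1, n2), c(total1, total2), correct = correct))
  unname(res$p.value)
}

#' Test every cell type for differential abundance between sexes
#'
#' Cells are pooled across replicates within each sex; for each observed
#' cell type the proportion of that sex's cells it accounts for is computed,
#' the pseudocounted log2 fold change (female over male) formed, and a
#' two-proportion z-test run on the pooled counts. A cell type is called
#' female_biased when p < alpha and the fold change is positive, male_biased
#' when p < alpha and negative, otherwise unbiased. Raw p-values are
#' reported without multiple-testing correction.
#'
#' @param meta Cell metadata (see [validate_metadata()]).
#' @param alpha Significance threshold on the raw p-value (default 0.01).
#' @param pseudocount Passed to [abundance_log2fc()].
#' @param correct Continuity correction flag for the z-test.
#' @return Data frame with one row per cell type: cell_type, n_female,
#'   n_male, total_female, total_male, prop_female, prop_male, log2fc,
#'   p_value, call.
#' @export
test_abundance <- function(meta, alpha = 0.01, pseudocount = 1e-10,
                           correct = TRUE) {
  validate_metadata(meta)
  tf <- sum(meta$sex == "female"); tm <- sum(meta$sex == "male")
  if (tf == 0 || tm == 0)
    stop("both sexes must be present in the metadata", call. = FALSE)
  types <- sort(unique(meta$cell_type))
  res <- lapply(types, function(ct) {
    nf <- sum(meta$cell_type == ct & meta$sex == "female")
    nm <- sum(meta$cell_type == ct & meta$sex == "male")
    pf <- nf / tf; pm <- nm / tm
    lfc <- abundance_log2fc(pf, pm, pseudocount)
    p <- two_proportion_test(nf, tf, nm, tm, correct = correct)
    call <- if (p < alpha && lfc > 0) "female_biased"
            else if (p < alpha && lfc < 0) "male_biased" else "unbiased"
    data.frame(cell_type = ct, n_female = nf, n_male = nm,
               total_female = tf, total_male = tm,
               prop_female = pf, prop_male = pm, log2fc = lfc,
               p_value = p, call = call, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-replicate cell-type proportion diagnostics
#'
#' Wilson score 95% intervals for each cell type's proportion within every
#' replicate sample. Diagnostic only: abundance calls pool replicates within
#' sex.
#'
#' @param meta Cell metadata.
#' @return Data frame: sample_id, sex, cell_type, n, total, prop, lower,
#'   upper.
#' @export
abundance_replicate_diagnostics <- function(meta) {
  validate_metadata(meta)
  samples <- unique(meta[c("sample_id", "sex")])
  types <- sort(unique(meta$cell_type))
  out <- list()
  for (i in seq_len(nrow(samples))) {
    s <- samples$sample_id[i]
    tot <- sum(meta$sample_id == s)
    for (ct in types) {
      n <- sum(meta$sample_id == s & meta$cell_type == ct)
      ci <- suppressWarnings(
        stats::prop.test(n, tot, correct = FALSE)$conf.int)
      out[[length(out) + 1L]] <- data.frame(
        sample_id = s, sex = samples$sex[i], cell_type = ct,
        n = n, total = tot, prop = n / tot,
        lower = ci[1], upper = ci[2], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
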