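# Four-way gene classification from whole-tissue and per-cell-type DE calls,
# and the associated summary tables.

.biased <- function(x) x %in% c("female_biased", "male_biased")
.dir_of <- function(x) ifelse(x == "female_biased", "female",
                              ifelse(x == "male_biased", "male", NA))

#' Classify genes by the stratum at which sex bias appears
#'
#' Combines the whole-tissue ("bulk") DE calls with the per-cell-type calls
#' into four mutually exclusive categories:
#' \describe{
#'   \item{bulk_only}{biased at bulk, unbiased in every tested cell type --
#'     the signature of a difference driven by cell-type abundance rather
#'     than regulation;}
#'   \item{bulk_and_cell}{biased at bulk and in at least one cell type;}
#'   \item{cell_only}{biased in at least one cell type but unbiased (or
#'     untested) at bulk -- bias diluted away by aggregation;}
#'   \item{unbiased}{everything else.}
#' }
#' Direction is the bulk direction for bulk-involving categories (with a
#' `direction_conflict` flag when a biased cell type disagrees); for
#' cell_only it is the common direction across biased cell types, else
#' `"mixed"`.
#'
#' @param bulk A `de_result` for the whole tissue (one row per gene,
#'   untested genes included).
#' @param per_cell_type Named list of `de_result` objects, one per tested
#'   cell type.
#' @return Data frame: gene_id, bulk_call, n_cell_tested, n_cell_biased,
#'   category, direction, direction_conflict.
#' @export
classify_genes <- function(bulk, per_cell_type) {
  stopifnot(is.data.frame(bulk), is.list(per_cell_type))
  universe <- bulk$gene_id
  for (ct in names(per_cell_type)) {
    extra <- setdiff(per_cell_type[[ct]]$gene_id, universe)
    if (length(extra))
      stop("cell type '", ct, "' tests gene(s) absent from the bulk universe: ",
           paste(utils::head(extra, 3), collapse = ", "), call. = FALSE)
  }
  ncts <- length(per_cell_type)
  cell_calls <- matrix("untested", length(universe), max(ncts, 1),
                       dimnames = list(universe, names(per_cell_type)))
  for (ct in names(per_cell_type)) {
    d <- per_cell_type[[ct]]
    cell_calls[d$gene_id, ct] <- d$call
  }
  bulk_call <- stats::setNames(bulk$call, bulk$gene_id)

  res <- lapply(universe, function(g) {
    cc <- if (ncts) cell_calls[g, ] else character(0)
    tested <- cc != "untested"
    biased_cc <- cc[.biased(cc)]
    bb <- bulk_call[[g]]
    bulk_biased <- .biased(bb)
    category <-
      if (bulk_biased && length(biased_cc) > 0) "bulk_and_cell"
      else if (bulk_biased) "bulk_only"
      else if (length(biased_cc) > 0) "cell_only"
      else "unbiased"
    conflict <- FALSE
    if (category %in% c("bulk_only", "bulk_and_cell")) {
      direction <- .dir_of(bb)
      conflict <- any(.dir_of(biased_cc) != direction)
    } else if (category == "cell_only") {
      dirs <- unique(.dir_of(biased_cc))
      direction <- if (length(dirs) == 1) dirs else "mixed"
    } else direction <- "n/a"
    data.frame(gene_id = g, bulk_call = bb,
               n_cell_tested = sum(tested),
               n_cell_biased = length(biased_cc),
               category = category, direction = direction,
               direction_conflict = conflict, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarize gene categories at bulk and cell level
#'
#' Produces the per-category, per-direction counts plus the two derived
#' totals: the cell-level count (union of genes biased in at least one cell
#' type, i.e. bulk_and_cell + cell_only) and the bulk-level count
#' (bulk_only + bulk_and_cell), each split by direction, and the fraction of
#' cell-level sex-biased genes that are unbiased at bulk (the false-negative
#' proxy for bulk experiments).
#'
#' @param categories Output of [classify_genes()].
#' @return List with `by_category` (data frame category x direction counts),
#'   `cell_level`, `bulk_level` (named count vectors by direction including
#'   `total`), and `frac_cell_level_bulk_unbiased`.
#' @export
summarize_categories <- function(categories) {
  stopifnot(all(c("category", "direction") %in% names(categories)))
  by_cat <- as.data.frame(table(category = categories$category,
                                direction = categories$direction),
                          stringsAsFactors = FALSE)
  names(by_cat)[3] <- "n_genes"
  by_cat <- by_cat[by_cat$n_genes > 0 | by_cat$category == "unbiased", ]
  count_dir <- function(sub) {
    c(female = sum(sub$direction == "female"),
      male = sum(sub$direction == "male"),
      mixed = sum(sub$direction == "mixed"),
      total = nrow(sub))
  }
  cell_level <- count_dir(categories[categories$category %in%
                                       c("bulk_and_cell", "cell_only"), ])
  bulk_level <- count_dir(categories[categories$category %in%
                                       c("bulk_only", "bulk_and_cell"), ])
  n_cell <- cell_level[["total"]]
  frac <- if (n_cell > 0)
    sum(categories$category == "cell_only") / n_cell else NA_real_
  list(by_category = by_cat, cell_level = cell_level,
       bulk_level = bulk_level, frac_cell_level_bulk_unbiased = frac)
}

#' Expression of bulk-only genes across abundance-biased vs unbiased types
#'
#' Descriptive companion table: for each bulk_only gene, its mean
#' size-factor-normalized pseudobulk expression averaged over cell types
#' with a significant sex difference in abundance versus over unbiased cell
#' types. No test is attached.
#'
#' @param categories Output of [classify_genes()].
#' @param pb_by_type Named list of per-cell-type `pseudobulk` objects.
#' @param abundance Output of [test_abundance()].
#' @return Data frame: gene_id, direction, mean_expr_abundance_biased,
#'   mean_expr_abundance_unbiased.
#' @export
bulk_only_expression_profile <- function(categories, pb_by_type, abundance) {
  genes <- categories$gene_id[categories$category == "bulk_only"]
  biased_types <- abundance$cell_type[abundance$call != "unbiased"]
  norm_mean <- function(pb) {
    sf <- tryCatch(size_factors(pb), error = function(e) colSums(pb$values))
    rowMeans(sweep(pb$values, 2, sf, "/"))
  }
  means <- vapply(pb_by_type, norm_mean, numeric(nrow(pb_by_type[[1]]$values)))
  in_biased <- colnames(means) %in% biased_types
  data.frame(
    gene_id = genes,
    direction = categories$direction[match(genes, categories$gene_id)],
    mean_expr_abundance_biased =
      if (any(in_biased)) rowMeans(means[genes, in_biased, drop = FALSE])
      else NA_real_,
    mean_expr_abundance_unbiased =
      if (any(!in_biased)) rowMeans(means[genes, !in_biased, drop = FALSE])
      else NA_real_,
    stringsAsFactors = FALSE)
}
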