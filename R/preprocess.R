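#' Log-normalize a raw count matrix
#'
#' Scales each cell by its total count, multiplies by `scale_factor` and
#' applies `log1p`: entry (g, c) becomes
#' `ln(1 + count(g, c) / total(c) * scale_factor)`. This is the standard
#' per-cell library-size normalization used throughout single-cell analysis.
#'
#' @param m an [expression_matrix()] with `state = "raw_counts"`.
#' @param scale_factor positive scale, default 10000.
#' @return An [expression_matrix()] with `state = "log_normalized"`.
#' @export
log_normalize <- function(m, scale_factor = 10000) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$state != "raw_counts")
    stop("log_normalize expects raw counts, got state '", m$state, "'")
  if (!is.numeric(scale_factor) || scale_factor <= 0)
    stop("scale_factor must be positive")
  totals <- colSums(m$values)
  zero <- which(totals == 0)
  if (length(zero))
    stop("cells with zero total count: ",
         paste(utils::head(m$cell_ids[zero], 10), collapse = ", "))
  norm <- log1p(sweep(m$values, 2L, totals / scale_factor, "/"))
  expression_matrix(norm, m$gene_ids, m$cell_ids, state = "log_normalized")
}

#' Select variably expressed genes
#'
#' A gene is kept when its mean log-normalized expression across all cells
#' exceeds `mean_cutoff` and its variance-to-mean ratio (VMR, population
#' variance divided by the mean) exceeds `vmr_cutoff`. Both inequalities are
#' strict. Genes with zero mean have no defined VMR and are excluded.
#'
#' @param m an [expression_matrix()] with `state = "log_normalized"`.
#' @param mean_cutoff minimum mean log expression, default 0.1.
#' @param vmr_cutoff minimum variance-to-mean ratio, default 1.
#' @return An object of class `gene_selection`: list with `genes` (kept gene
#'   ids, in source matrix order), per-gene `mean_log_expr` and `vmr` (all
#'   genes), `kept` logical vector, and the `cutoffs`.
#' @export
select_variable_genes <- function(m, mean_cutoff = 0.1, vmr_cutoff = 1.0) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$state != "log_normalized")
    stop("select_variable_genes expects log-normalized input")
  mu <- rowMeans(m$values)
  v <- rowMeans(m$values^2) - mu^2          # population variance
  v <- pmax(v, 0)                           # guard tiny negatives
  vmr <- ifelse(mu > 0, v / mu, 0)
  kept <- mu > mean_cutoff & vmr > vmr_cutoff
  structure(list(genes = m$gene_ids[kept],
                 mean_log_expr = stats::setNames(mu, m$gene_ids),
                 vmr = stats::setNames(vmr, m$gene_ids),
                 kept = stats::setNames(kept, m$gene_ids),
                 cutoffs = c(mean_cutoff = mean_cutoff,
                             vmr_cutoff = vmr_cutoff)),
            class = "gene_selection")
}

#' @export
print.gene_selection <- function(x, ...) {
  cat(sprintf("<gene_selection> %d / %d genes kept (mean > %g, VMR > %g)\n",
              length(x$genes), length(x$kept),
              x$cutoffs[["mean_cutoff"]], x$cutoffs[["vmr_cutoff"]]))
  invisible(x)
}

#' Select transcription factors eligible for modeling
#'
#' A TF is retained when (a) its encoding gene is among the selected variable
#' genes, or it is explicitly listed in `user_include`, and (b) at least
#' `min_targets` of its ChIP-seq prior target genes are among the selected
#' variable genes. The intersection with the variable genes becomes the TF's
#' effective target set. TFs named in `user_include` must still have ChIP-seq
#' prior targets: the availability requirement is unconditional.
#'
#' @param selection a [select_variable_genes()] result.
#' @param prior_targets named list mapping TF name to character vector of
#'   prior target gene ids (from [assign_targets()]).
#' @param tf_gene_ids optional named character vector mapping TF name to the
#'   gene id encoding it; defaults to the TF name itself.
#' @param min_targets minimum effective target-set size, default 10.
#' @param user_include TFs to retain even if not variably expressed.
#' @return Character vector of retained TF names, in `prior_targets` order,
#'   with the effective target sets attached as attribute
#'   `"effective_targets"` (a named list).
#' @export
select_tfs <- function(selection, prior_targets, tf_gene_ids = NULL,
                       min_targets = 10, user_include = character()) {
  stopifnot(inherits(selection, "gene_selection"))
  tfs <- names(prior_targets)
  if (is.null(tfs) || !length(tfs)) stop("prior_targets must be a named list")
  missing_chip <- setdiff(user_include, tfs)
  if (length(missing_chip))
    stop("user_include TFs without ChIP-seq prior targets: ",
         paste(missing_chip, collapse = ", "))
  if (is.null(tf_gene_ids)) tf_gene_ids <- stats::setNames(tfs, tfs)
  genes <- selection$genes
  eff <- lapply(prior_targets, function(t) intersect(t, genes))
  expressed <- unname(tf_gene_ids[tfs]) %in% genes
  keep <- (expressed | tfs %in% user_include) &
    lengths(eff) >= min_targets
  out <- tfs[keep]
  attr(out, "effective_targets") <- eff[keep]
  out
}
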