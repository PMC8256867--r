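#' Expression matrix container
#'
#' A gene x cell numeric matrix together with gene and cell identifiers and a
#' state flag distinguishing raw counts from log-normalized expression. All
#' pipeline stages consume and produce this container so that identifier
#' bookkeeping can be validated once, at construction.
#'
#' @param values numeric matrix, genes in rows, cells in columns.
#' @param gene_ids character vector of unique gene identifiers, one per row.
#' @param cell_ids character vector of unique cell identifiers, one per column.
#' @param state `"raw_counts"` (nonnegative integers) or `"log_normalized"`
#'   (nonnegative finite reals).
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `gene_ids`, `cell_ids`, `state`.
#' @examples
#' m <- expression_matrix(matrix(0:3, 2), c("g1", "g2"), c("c1", "c2"),
#'                        state = "raw_counts")
#' @export
expression_matrix <- function(values, gene_ids, cell_ids,
                              state = c("raw_counts", "log_normalized")) {
  state <- match.arg(state)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- trimws(as.character(gene_ids))
  cell_ids <- trimws(as.character(cell_ids))
  if (nrow(values) != length(gene_ids))
    stop("row count (", nrow(values), ") != number of gene ids (",
         length(gene_ids), ")")
  if (ncol(values) != length(cell_ids))
    stop("column count (", ncol(values), ") != number of cell ids (",
         length(cell_ids), ")")
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene ids: ", paste(utils::head(dup, 5), collapse = ", "))
  dup <- unique(cell_ids[duplicated(cell_ids)])
  if (length(dup))
    stop("duplicate cell ids: ", paste(utils::head(dup, 5), collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  if (any(values < 0))
    stop("expression values must be nonnegative")
  if (state == "raw_counts" && any(values != round(values)))
    stop("raw counts must be integers")
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 state = state),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d cells, state = %s\n",
              length(x$gene_ids), length(x$cell_ids), x$state))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Genomic interval set
#'
#' Named genomic intervals in 0-based half-open coordinates, used for ChIP-seq
#' peaks (label = TF name), promoter windows (label = gene id) and accessible
#' regions.
#'
#' @param chrom character chromosome names.
#' @param start,end integer interval bounds, 0-based half-open, `end > start`.
#' @param label nonempty character labels.
#' @return A data frame of class `interval_set` with columns
#'   `chrom`, `start`, `end`, `label`.
#' @export
interval_set <- function(chrom, start, end, label) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  label <- trimws(as.character(label))
  n <- length(chrom)
  if (length(start) != n || length(end) != n || length(label) != n)
    stop("chrom, start, end, label must have equal length")
  if (any(is.na(start)) || any(is.na(end)))
    stop("interval bounds must be integers")
  if (any(start < 0))
    stop("interval start must be >= 0")
  bad <- which(end <= start)
  if (length(bad))
    stop("interval end must exceed start (record ", bad[1], ")")
  if (any(!nzchar(label)))
    stop("interval labels must be nonempty")
  structure(data.frame(chrom = chrom, start = start, end = end, label = label,
                       stringsAsFactors = FALSE),
            class = c("interval_set", "data.frame"))
}

# GRanges view of an interval_set (1-based closed, as GenomicRanges expects).
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    label = x$label)
}
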