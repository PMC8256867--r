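#' Promoter window presets
#'
#' The window configurations commonly swept when assessing the sensitivity of
#' target assignment to promoter definition. Each entry is
#' `c(upstream, downstream)` in base pairs around the TSS.
#'
#' @return Named list of `c(upstream, downstream)` integer pairs.
#' @export
promoter_window_presets <- function() {
  list(narrow     = c(500L, 50L),
       proximal   = c(1000L, 100L),
       default    = c(2000L, 200L),
       extended   = c(5000L, 5000L),
       distal     = c(10000L, 10000L))
}

#' Build promoter windows around transcription start sites
#'
#' For a gene on the `+` strand the promoter is
#' `[tss - upstream, tss + downstream)`; on the `-` strand the window is
#' reflected to `[tss - downstream, tss + upstream)` so that "upstream" is
#' always 5' of the gene. Windows are clipped at position 0. Every TSS record
#' yields its own window, so genes with several transcripts contribute the
#' union of their windows downstream.
#'
#' @param tss a TSS table as returned by [read_tss()] (0-based positions).
#' @param upstream,downstream nonnegative window extents in bp; defaults
#'   2000 and 200.
#' @param stranded if `FALSE`, every record is treated as `+` strand.
#' @return An [interval_set()] labeled by gene id.
#' @export
promoter_regions <- function(tss, upstream = 2000, downstream = 200,
                             stranded = TRUE) {
  if (!all(c("gene", "chrom", "strand", "tss") %in% names(tss)))
    stop("tss must have columns gene, chrom, strand, tss")
  if (upstream < 0 || downstream < 0)
    stop("upstream and downstream must be nonnegative")
  if (upstream + downstream <= 0)
    stop("promoter window must have positive width")
  strand <- if (stranded) tss$strand else rep("+", nrow(tss))
  if (!all(strand %in% c("+", "-"))) stop("unknown strand symbol")
  plus <- strand == "+"
  start <- ifelse(plus, tss$tss - upstream, tss$tss - downstream)
  end <- ifelse(plus, tss$tss + downstream, tss$tss + upstream)
  start <- pmax(start, 0L)
  interval_set(tss$chrom, start, end, tss$gene)
}

#' Assign target genes to transcription factors by peak-promoter overlap
#'
#' A gene is a target of a TF when at least one of the TF's peaks overlaps at
#' least one of the gene's promoter windows by one or more bases (half-open
#' semantics: abutting intervals do not overlap). Overlap is computed with
#' `GenomicRanges::findOverlaps`.
#'
#' @param peaks an [interval_set()] labeled by TF name.
#' @param promoters an [interval_set()] labeled by gene id.
#' @return Named list mapping TF name to a sorted character vector of target
#'   gene ids. TFs whose peaks hit no promoter map to `character(0)`.
#' @export
assign_targets <- function(peaks, promoters) {
  stopifnot(inherits(peaks, "interval_set"), inherits(promoters, "interval_set"))
  tfs <- sort(unique(peaks$label))
  out <- stats::setNames(rep(list(character(0)), length(tfs)), tfs)
  if (!nrow(peaks) || !nrow(promoters)) return(out)
  # suppressWarnings: disjoint chromosome sets are a valid no-overlap case
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(peaks), as_granges(promoters),
                                minoverlap = 1L))
  if (length(hits)) {
    tf_hit <- peaks$label[S4Vectors::queryHits(hits)]
    gene_hit <- promoters$label[S4Vectors::subjectHits(hits)]
    pairs <- unique(data.frame(tf = tf_hit, gene = gene_hit,
                               stringsAsFactors = FALSE))
    found <- split(pairs$gene, pairs$tf)
    out[names(found)] <- lapply(found, function(g) sort(unique(g)))
  }
  out
}

#' Filter target genes by chromatin accessibility
#'
#' Keeps a gene in a TF's target set only if at least one of the gene's
#' promoter windows overlaps an accessible (open-chromatin) region by at
#' least one base. Useful when ATAC-seq or similar accessibility data are
#' available for the profiled system.
#'
#' @param targets named list TF -> target gene ids.
#' @param promoters promoter [interval_set()] labeled by gene id.
#' @param open_regions accessible-region [interval_set()]; must be nonempty.
#' @return The filtered named list; always a per-TF subset of the input.
#' @export
filter_targets_by_accessibility <- function(targets, promoters, open_regions) {
  stopifnot(inherits(promoters, "interval_set"),
            inherits(open_regions, "interval_set"))
  if (!nrow(open_regions)) stop("open_regions must be nonempty")
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(promoters),
                                as_granges(open_regions),
                                minoverlap = 1L))
  accessible <- unique(promoters$label[S4Vectors::queryHits(hits)])
  lapply(targets, function(g) intersect(g, accessible))
}

#' Build the binary target-prior matrix
#'
#' Encodes the effective target sets as a genes x TFs 0/1 mask: entry (g, k)
#' is 1 when gene g is a prior target of TF k and among the selected variable
#' genes. Rows follow the gene order of `selection`; genes targeted by no
#' retained TF keep an all-zero row and stay in the model under the near-zero
#' loading prior.
#'
#' @param targets named list TF -> target gene ids (from [assign_targets()],
#'   possibly accessibility-filtered).
#' @param selection a [select_variable_genes()] result.
#' @param tfs ordered TF names as returned by [select_tfs()].
#' @param min_targets minimum ones per TF column, default 10; columns below
#'   this violate the selection precondition and raise an error.
#' @param window optional `c(upstream, downstream)` echo of the promoter
#'   window used, stored for provenance.
#' @return An object of class `target_prior`: list with `mask` (0/1 matrix),
#'   `gene_ids`, `tf_names`, `window`.
#' @export
build_prior_matrix <- function(targets, selection, tfs, min_targets = 10,
                               window = c(2000L, 200L)) {
  stopifnot(inherits(selection, "gene_selection"))
  tfs <- as.character(tfs)
  missing <- setdiff(tfs, names(targets))
  if (length(missing))
    stop("TFs without target sets: ", paste(missing, collapse = ", "))
  genes <- selection$genes
  if (!length(genes)) stop("selection contains no genes")
  mask <- matrix(0, nrow = length(genes), ncol = length(tfs),
                 dimnames = list(genes, tfs))
  for (tf in tfs) {
    hit <- intersect(targets[[tf]], genes)
    mask[hit, tf] <- 1
  }
  low <- colSums(mask) < min_targets
  if (any(low))
    stop("TF columns with fewer than ", min_targets, " targets: ",
         paste(tfs[low], collapse = ", "),
         " (run select_tfs before build_prior_matrix)")
  structure(list(mask = mask, gene_ids = genes, tf_names = tfs,
                 window = window),
            class = "target_prior")
}

#' @export
print.target_prior <- function(x, ...) {
  cat(sprintf("<target_prior> %d genes x %d TFs, %d prior links\n",
              length(x$gene_ids), length(x$tf_names), sum(x$mask)))
  invisible(x)
}
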