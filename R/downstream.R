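#' Rank marker TFs for a cell type by random-forest importance
#'
#' Trains a random forest classifying cells of `cell_type` (response 1)
#' against all other cells (response 0) from the inferred activity matrix
#' `Z_mean` (one feature per TF) and ranks TFs by impurity-based feature
#' importance, normalized to sum to 1. Cells are put into a canonical order
#' (sorted by cell id) before training, so the result does not depend on the
#' input cell order.
#'
#' @param fit a [fit_tfa()] result.
#' @param labels named character vector mapping cell id to cell type; must
#'   cover all cells of the fit.
#' @param cell_type the type to profile.
#' @param seed RNG seed for the forest.
#' @param n_trees number of trees, default 500.
#' @return data frame with columns `tf`, `importance`, most important first
#'   (ties broken by TF name).
#' @export
marker_tfs <- function(fit, labels, cell_type, seed, n_trees = 500) {
  stopifnot(inherits(fit, "tfa_fit"))
  cells <- colnames(fit$Z_mean)
  if (!all(cells %in% names(labels)))
    stop("labels must cover every cell of the fit")
  lab <- labels[cells]
  if (!cell_type %in% lab) stop("cell type not present in labels: ", cell_type)
  y <- factor(ifelse(lab == cell_type, 1L, 0L), levels = c(0L, 1L))
  if (length(unique(y)) < 2L || min(table(y)) < 2L)
    stop("need at least 2 cells inside and outside the target type")
  ord <- order(cells)
  x <- t(fit$Z_mean)[ord, , drop = FALSE]
  y <- y[ord]
  set.seed(seed)
  rf <- randomForest::randomForest(x, y, ntree = n_trees)
  imp <- randomForest::importance(rf, type = 2)[, 1L]
  if (sum(imp) > 0) imp <- imp / sum(imp)
  tfs <- rownames(fit$Z_mean)
  imp <- imp[tfs]
  ord2 <- order(-imp, tfs)
  data.frame(tf = tfs[ord2], importance = unname(imp[ord2]),
             stringsAsFactors = FALSE)
}

#' Diffusion distances between cells
#'
#' Builds a Gaussian kernel on cells from Euclidean distances in activity
#' space (bandwidth = median pairwise distance), applies density
#' normalization (alpha = 1), row-normalizes to a Markov transition matrix,
#' and returns diffusion distances at diffusion time 1 computed from the top
#' `n_components` non-trivial eigencomponents:
#' `D(i, j) = sqrt(sum_l lambda_l^2 (psi_l(i) - psi_l(j))^2)`.
#'
#' @param z TF x cell numeric matrix (cells are columns).
#' @param n_components number of non-trivial components, default 20.
#' @return Symmetric cell x cell distance matrix with zero diagonal.
#' @export
diffusion_distances <- function(z, n_components = 20) {
  z <- as.matrix(z)
  m <- ncol(z)
  if (m < n_components + 2)
    stop("need at least n_components + 2 cells (", n_components + 2,
         "), got ", m)
  d <- as.matrix(stats::dist(t(z)))
  sigma <- stats::median(d[upper.tri(d)])
  if (sigma <= 0) sigma <- 1          # all cells identical: any kernel works
  kern <- exp(-d^2 / (2 * sigma^2))
  q <- rowSums(kern)
  kern <- kern / outer(q, q)          # alpha = 1 density normalization
  deg <- rowSums(kern)
  s <- sqrt(deg)
  sym <- kern / outer(s, s)           # symmetric conjugate of the Markov matrix
  es <- eigen(sym, symmetric = TRUE)
  idx <- seq(2L, n_components + 1L)   # drop the trivial stationary component
  lambda <- es$values[idx]
  psi <- es$vectors[, idx, drop = FALSE] / s
  emb <- sweep(psi, 2L, lambda, "*")  # diffusion map at t = 1
  dd <- as.matrix(stats::dist(emb))
  dimnames(dd) <- dimnames(d)
  dd
}

#' Cluster cells by Louvain community detection on a nearest-edge graph
#'
#' Ranks all undirected cell pairs by distance, keeps the
#' `floor(keep_fraction * M(M-1)/2)` smallest (ties at the cutoff broken by
#' lexicographic node-pair order), builds an unweighted graph on those edges
#' and runs Louvain modularity optimization. Cells left without any edge
#' become singleton clusters.
#'
#' @param dist symmetric cell x cell distance matrix.
#' @param keep_fraction fraction of edges kept, default 0.2.
#' @param seed RNG seed for the Louvain pass.
#' @return Integer cluster labels named by cell id, with the realized graph
#'   edge count attached as attribute `"n_edges"`.
#' @export
louvain_cluster <- function(dist, keep_fraction = 0.2, seed = 1L) {
  dist <- as.matrix(dist)
  m <- nrow(dist)
  if (m < 3) stop("need at least 3 cells")
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must be in (0, 1]")
  ids <- rownames(dist)
  if (is.null(ids)) ids <- as.character(seq_len(m))
  ut <- which(upper.tri(dist), arr.ind = TRUE)
  vals <- dist[upper.tri(dist)]
  n_keep <- floor(keep_fraction * m * (m - 1) / 2)
  ord <- order(vals, ut[, 1L], ut[, 2L])
  keep <- utils::head(ord, n_keep)
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  igraph::V(g)$name <- ids
  if (length(keep))
    g <- igraph::add_edges(g, rbind(ut[keep, 1L], ut[keep, 2L]))
  set.seed(seed)
  comm <- igraph::cluster_louvain(g)
  out <- stats::setNames(as.integer(igraph::membership(comm)), ids)
  attr(out, "n_edges") <- igraph::ecount(g)
  out
}

#' Compare two partitions of the same cells
#'
#' Cross-tabulates the two label vectors and derives pair-counting and
#' information-theoretic agreement indices: the Rand index
#' `RI = (a + b) / C(n, 2)` where `a` counts pairs placed together in both
#' partitions and `b` pairs separated in both; the adjusted Rand index (RI
#' corrected for chance agreement); and the normalized mutual information
#' `NMI = 2 I(X;Y) / (H(X) + H(Y))` with natural-log entropies. Two
#' single-cluster partitions have `NMI = 1` by the 0/0 convention.
#'
#' @param x,y label vectors of equal length (>= 2).
#' @return An object of class `partition_metrics`: list with `RI`, `ARI`,
#'   `NMI`, `H_x`, `H_y`, `MI`, pair counts `a` and `b`, and the contingency
#'   `table`.
#' @export
partition_metrics <- function(x, y) {
  if (length(x) != length(y)) stop("label vectors must have equal length")
  n <- length(x)
  if (n < 2) stop("need at least 2 elements")
  tab <- table(x, y)
  a_i <- rowSums(tab)
  b_j <- colSums(tab)
  choose2 <- function(v) sum(v * (v - 1) / 2)
  sum_nij <- choose2(as.vector(tab))
  sum_ai <- choose2(a_i)
  sum_bj <- choose2(b_j)
  total <- n * (n - 1) / 2
  a <- sum_nij
  b <- total - sum_ai - sum_bj + sum_nij
  ri <- (a + b) / total
  expected <- sum_ai * sum_bj / total
  max_index <- (sum_ai + sum_bj) / 2
  ari <- if (max_index == expected) 1 else
    (sum_nij - expected) / (max_index - expected)
  ent <- function(sizes) {
    p <- sizes[sizes > 0] / n
    -sum(p * log(p))
  }
  h_x <- ent(a_i)
  h_y <- ent(b_j)
  h_xy <- ent(as.vector(tab))
  mi <- h_x + h_y - h_xy
  nmi <- if (h_x + h_y == 0) 1 else 2 * mi / (h_x + h_y)
  structure(list(RI = ri, ARI = ari, NMI = nmi,
                 H_x = h_x, H_y = h_y, MI = mi,
                 a = a, b = b, table = tab),
            class = "partition_metrics")
}

#' @export
print.partition_metrics <- function(x, ...) {
  cat(sprintf("<partition_metrics> RI = %.4f  ARI = %.4f  NMI = %.4f\n",
              x$RI, x$ARI, x$NMI))
  invisible(x)
}

#' Jaccard index of two sets
#'
#' `|A intersect B| / |A union B|`; two empty sets are defined to have
#' similarity 1.
#'
#' @param a,b vectors treated as sets.
#' @return A number in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Per-cell activity log fold change against the control mean
#'
#' `log2((Z_mean[tf, cell] + pseudocount) / (control mean + pseudocount))`,
#' where the control mean is the average inferred activity of `tf` over
#' control cells. Lower values are more knockdown-like.
#'
#' @param fit a [fit_tfa()] result.
#' @param perturb perturbation table (columns `cell`, `target`) covering all
#'   cells of the fit.
#' @param tf TF whose activity to score.
#' @param pseudocount added to numerator and denominator, default 1e-6.
#' @return Named numeric vector of per-cell logFC.
#' @export
activity_logfc <- function(fit, perturb, tf, pseudocount = 1e-6) {
  stopifnot(inherits(fit, "tfa_fit"))
  if (!tf %in% rownames(fit$Z_mean)) stop("unknown TF: ", tf)
  cells <- colnames(fit$Z_mean)
  if (!all(cells %in% perturb$cell))
    stop("perturbation table must cover every cell of the fit")
  target <- stats::setNames(perturb$target, perturb$cell)[cells]
  ctrl <- cells[target == "control"]
  if (!length(ctrl)) stop("no control cells")
  z <- fit$Z_mean[tf, ]
  ref <- mean(z[ctrl])
  log2((z + pseudocount) / (ref + pseudocount))
}

#' Pooled AUROC of the perturbation benchmark
#'
#' For each perturbed TF, cells targeted for that TF form the positive class
#' and control cells the negative class; each cell is scored by the negated
#' activity logFC of the TF (so knockdown-like cells score high). The
#' (score, label) pairs of all TFs are pooled into one ranking, and the
#' AUROC is computed as the Mann-Whitney U statistic divided by
#' `n_pos * n_neg`, with ties contributing 1/2.
#'
#' @param fit a [fit_tfa()] result.
#' @param perturb perturbation table (columns `cell`, `target`).
#' @param pseudocount passed to [activity_logfc()], default 1e-6.
#' @return The pooled AUROC in `[0, 1]`, with a per-TF AUROC data frame
#'   attached as attribute `"per_tf"`.
#' @export
perturbation_auroc <- function(fit, perturb, pseudocount = 1e-6) {
  stopifnot(inherits(fit, "tfa_fit"))
  cells <- colnames(fit$Z_mean)
  target <- stats::setNames(perturb$target, perturb$cell)[cells]
  tfs <- setdiff(unique(target), "control")
  tfs <- tfs[!is.na(tfs)]
  if (!length(tfs)) stop("no perturbed cells in the table")
  ctrl <- cells[target == "control"]
  if (!length(ctrl)) stop("no control cells")
  scores <- numeric(0)
  labels <- integer(0)
  per_tf <- list()
  for (tf in tfs) {
    if (!tf %in% rownames(fit$Z_mean)) {
      warning("perturbed TF absent from fit, skipped: ", tf)
      next
    }
    lfc <- activity_logfc(fit, perturb, tf, pseudocount)
    pos_cells <- cells[target == tf]
    s <- c(-lfc[pos_cells], -lfc[ctrl])
    l <- c(rep(1L, length(pos_cells)), rep(0L, length(ctrl)))
    per_tf[[tf]] <- auroc_mann_whitney(s, l)
    scores <- c(scores, s)
    labels <- c(labels, l)
  }
  if (!sum(labels)) stop("no positive cells for any TF present in the fit")
  out <- auroc_mann_whitney(scores, labels)
  attr(out, "per_tf") <- data.frame(tf = names(per_tf),
                                    auroc = unlist(per_tf),
                                    row.names = NULL,
                                    stringsAsFactors = FALSE)
  out
}

# AUROC as U / (n1 n0) from midranks; ties contribute 1/2.
auroc_mann_whitney <- function(scores, labels) {
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("need both classes to compute AUROC")
  r <- rank(scores, ties.method = "average")
  u <- sum(r[labels == 1L]) - n1 * (n1 + 1) / 2
  u / (n1 * n0)
}
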