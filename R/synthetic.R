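#' Describe a synthetic ground-truth scenario
#'
#' Defines the generative setting used to validate the pipeline end-to-end:
#' K TFs with disjoint target programs of `targets_per_tf` genes each, cells
#' split evenly over `n_cell_types` types, each type running its own subset
#' of TF programs. Activities are drawn from `active_beta` for TFs active in
#' a cell's type and `inactive_beta` otherwise (bimodal but inside the
#' model's Beta support), loadings from `|N(loading_scale, loading_scale/3)|`
#' (optionally mixed-sign), and expression is `Y = W Z + N(0, noise_sd)`
#' clipped at zero.
#'
#' @param n_genes,n_tfs,n_cells problem dimensions; defaults 200, 5, 300.
#' @param n_cell_types number of cell types, default `n_tfs` (one program
#'   per type).
#' @param targets_per_tf genes per TF program, default 10 (at least 10 so
#'   downstream TF selection keeps every TF).
#' @param active_tfs_per_type optional named list mapping type name to the
#'   character vector of TFs active in it; the default assigns TF k to type
#'   `(k - 1) %% n_cell_types + 1`.
#' @param loading_scale typical loading magnitude, default 1.
#' @param noise_sd additive Gaussian noise sd on expression, default 0.1.
#' @param active_beta,inactive_beta Beta(shape1, shape2) parameters for
#'   activities in active and inactive cells; defaults (5, 2) and (2, 5).
#' @param loading_sign `"positive"` (default) or `"mixed"`.
#' @param seed RNG seed.
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_genes = 200L, n_tfs = 5L, n_cells = 300L,
                               n_cell_types = n_tfs, targets_per_tf = 10L,
                               active_tfs_per_type = NULL,
                               loading_scale = 1, noise_sd = 0.1,
                               active_beta = c(5, 2), inactive_beta = c(2, 5),
                               loading_sign = c("positive", "mixed"),
                               seed = 1L) {
  loading_sign <- match.arg(loading_sign)
  stopifnot(n_genes >= 1, n_tfs >= 1, n_cells >= 2, n_cell_types >= 1,
            targets_per_tf >= 10, loading_scale > 0, noise_sd >= 0,
            all(active_beta > 0), all(inactive_beta > 0))
  if (n_tfs * targets_per_tf > n_genes)
    stop("disjoint programs need n_tfs * targets_per_tf <= n_genes")
  tf_names <- paste0("TF", seq_len(n_tfs))
  type_names <- paste0("type", seq_len(n_cell_types))
  if (is.null(active_tfs_per_type)) {
    active_tfs_per_type <- stats::setNames(
      lapply(seq_len(n_cell_types), function(j)
        tf_names[((seq_len(n_tfs) - 1L) %% n_cell_types + 1L) == j]),
      type_names)
  }
  stopifnot(all(unlist(active_tfs_per_type) %in% tf_names))
  structure(list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
                 n_cells = as.integer(n_cells),
                 n_cell_types = as.integer(n_cell_types),
                 targets_per_tf = as.integer(targets_per_tf),
                 active_tfs_per_type = active_tfs_per_type,
                 loading_scale = loading_scale, noise_sd = noise_sd,
                 active_beta = active_beta, inactive_beta = inactive_beta,
                 loading_sign = loading_sign, seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Simulate a ground-truth dataset
#'
#' Draws the target mask, true loadings, true activities, cell-type labels
#' and noisy expression for a [synthetic_scenario()]. TF programs are
#' disjoint, so mask columns are pairwise distinct and factors need no
#' permutation alignment when comparing a fit against the truth.
#'
#' @param scenario a [synthetic_scenario()].
#' @return An object of class `synthetic_truth`: list with `Y`
#'   (log-normalized [expression_matrix()]), `mask` (a `target_prior`),
#'   `W_true`, `Z_true`, `labels` (named character), `noise` (the realized
#'   noise matrix, kept so perturbed copies of cells can reuse it), and
#'   `scenario`.
#' @export
simulate_ground_truth <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$seed)
  n <- scenario$n_genes; k <- scenario$n_tfs; m <- scenario$n_cells
  genes <- sprintf("gene%04d", seq_len(n))
  cells <- sprintf("cell%04d", seq_len(m))
  tfs <- paste0("TF", seq_len(k))

  pool <- sample(genes)
  mask <- matrix(0, n, k, dimnames = list(genes, tfs))
  for (j in seq_len(k)) {
    prog <- pool[((j - 1L) * scenario$targets_per_tf + 1L):
                   (j * scenario$targets_per_tf)]
    mask[prog, j] <- 1
  }
  stopifnot(!any(duplicated(t(mask))))     # pairwise-distinct columns

  w <- matrix(0, n, k, dimnames = list(genes, tfs))
  nz <- which(mask == 1)
  amp <- abs(stats::rnorm(length(nz), mean = scenario$loading_scale,
                          sd = scenario$loading_scale / 3))
  if (scenario$loading_sign == "mixed")
    amp <- amp * sample(c(-1, 1), length(nz), replace = TRUE)
  w[nz] <- amp

  types <- paste0("type", seq_len(scenario$n_cell_types))
  labels <- stats::setNames(
    types[(seq_len(m) - 1L) %% scenario$n_cell_types + 1L], cells)
  z <- matrix(0, k, m, dimnames = list(tfs, cells))
  for (j in seq_len(k)) {
    active <- vapply(labels, function(ty)
      tfs[j] %in% scenario$active_tfs_per_type[[ty]], logical(1))
    z[j, active] <- stats::rbeta(sum(active), scenario$active_beta[1],
                                 scenario$active_beta[2])
    z[j, !active] <- stats::rbeta(sum(!active), scenario$inactive_beta[1],
                                  scenario$inactive_beta[2])
  }

  noise <- matrix(stats::rnorm(n * m, sd = scenario$noise_sd), n, m,
                  dimnames = list(genes, cells))
  if (scenario$noise_sd == 0) noise[] <- 0
  y <- pmax(w %*% z + noise, 0)

  structure(list(
    Y = expression_matrix(y, genes, cells, state = "log_normalized"),
    counts = NULL,
    mask = structure(list(mask = mask, gene_ids = genes, tf_names = tfs,
                          window = NULL),
                     class = "target_prior"),
    W_true = w, Z_true = z, labels = labels, noise = noise,
    scenario = scenario),
    class = "synthetic_truth")
}

#' Simulate sequencing counts from a ground truth
#'
#' Draws integer counts for each cell from a multinomial with probabilities
#' proportional to `expm1(Y[, cell])` and total `depth`, emulating
#' library-size sampling so the normalization path can be exercised against
#' a known log-scale truth.
#'
#' @param truth a [simulate_ground_truth()] result.
#' @param depth total counts per cell.
#' @param seed RNG seed, default the scenario seed.
#' @return An [expression_matrix()] with `state = "raw_counts"`.
#' @export
simulate_counts <- function(truth, depth, seed = truth$scenario$seed) {
  stopifnot(inherits(truth, "synthetic_truth"), depth >= 1)
  set.seed(seed)
  expr <- expm1(truth$Y$values)
  tot <- colSums(expr)
  if (any(tot == 0))
    stop("cells with all-zero expression: ",
         paste(utils::head(truth$Y$cell_ids[tot == 0], 5), collapse = ", "))
  counts <- vapply(seq_along(tot), function(j)
    stats::rmultinom(1, size = depth, prob = expr[, j])[, 1],
    numeric(nrow(expr)))
  expression_matrix(counts, truth$Y$gene_ids, truth$Y$cell_ids,
                    state = "raw_counts")
}

#' Simulate a CRISPRi-style perturbation
#'
#' Appends `n_perturbed` cells, each a copy of a randomly chosen existing
#' cell whose activity for `tf` is multiplied by `1 - efficiency`; the
#' copy's expression is regenerated from the perturbed activities reusing
#' the source cell's noise realization (so `efficiency = 0` reproduces the
#' source column exactly). Original cells are labeled `"control"`.
#'
#' @param truth a [simulate_ground_truth()] result.
#' @param tf TF to knock down.
#' @param n_perturbed number of perturbed cells to append; must be smaller
#'   than the number of existing cells.
#' @param efficiency knockdown efficiency in `[0, 1]`.
#' @param seed RNG seed for choosing source cells.
#' @return List with `truth` (the augmented `synthetic_truth`) and `table`
#'   (a perturbation data frame with columns `cell`, `target`).
#' @export
simulate_perturbation <- function(truth, tf, n_perturbed, efficiency, seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (efficiency < 0 || efficiency > 1)
    stop("efficiency must be in [0, 1]")
  if (!tf %in% rownames(truth$Z_true)) stop("unknown TF: ", tf)
  m <- ncol(truth$Z_true)
  if (n_perturbed >= m)
    stop("n_perturbed must be smaller than the number of cells")
  set.seed(seed)
  src <- sample.int(m, n_perturbed, replace = TRUE)
  z_new <- truth$Z_true[, src, drop = FALSE]
  z_new[tf, ] <- z_new[tf, ] * (1 - efficiency)
  y_new <- pmax(truth$W_true %*% z_new + truth$noise[, src, drop = FALSE], 0)
  new_ids <- sprintf("%s_kd%03d", colnames(truth$Z_true)[src],
                     seq_len(n_perturbed))
  colnames(z_new) <- new_ids
  colnames(y_new) <- new_ids
  old_ids <- truth$Y$cell_ids

  aug <- truth
  aug$Y <- expression_matrix(cbind(truth$Y$values, y_new),
                             truth$Y$gene_ids, c(old_ids, new_ids),
                             state = "log_normalized")
  aug$Z_true <- cbind(truth$Z_true, z_new)
  aug$noise <- cbind(truth$noise, truth$noise[, src, drop = FALSE])
  aug$labels <- c(truth$labels,
                  stats::setNames(truth$labels[src], new_ids))
  table <- data.frame(cell = c(old_ids, new_ids),
                      target = c(rep("control", length(old_ids)),
                                 rep(tf, n_perturbed)),
                      stringsAsFactors = FALSE)
  list(truth = aug, table = table)
}
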