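# Programmatic fixtures; everything is generated at test time.

write_mtx_fixture <- function(dir, header_dims, entries, genes, cells) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(dir, "matrix.mtx")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               paste(header_dims, collapse = " "),
               vapply(entries, function(e) paste(e, collapse = " "),
                      character(1))),
             mtx)
  writeLines(genes, file.path(dir, "genes.tsv"))
  writeLines(cells, file.path(dir, "barcodes.tsv"))
  mtx
}

write_bed_fixture <- function(path, lines) {
  writeLines(lines, path)
  path
}

small_norm_matrix <- function(values, genes, cells) {
  expression_matrix(values, genes, cells, state = "log_normalized")
}

# A tiny fitted object wrapping given matrices, for downstream functions that
# only consume posterior means.
stub_fit <- function(W, Z) {
  structure(list(W_mean = W, Z_mean = Z,
                 delta_mean = rep(1, ncol(W)),
                 noise_mean = rep(1, nrow(W)),
                 elbo_trace = data.frame(iteration = integer(0),
                                         elbo = numeric(0)),
                 converged = TRUE,
                 config = model_config(),
                 mask = NULL),
            class = "tfa_fit")
}

# Three well-separated activity blobs for clustering checks.
make_blob_z <- function(m = 300, sd = 0.05, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0.8, 0.2, 0.2, 0.5, 0.3),
                   c(0.2, 0.8, 0.2, 0.3, 0.5),
                   c(0.2, 0.2, 0.8, 0.5, 0.5))
  lab <- rep(1:3, length.out = m)
  z <- t(centers[lab, ]) + matrix(stats::rnorm(5 * m, sd = sd), 5, m)
  z <- pmin(pmax(z, 1e-3), 1 - 1e-3)
  rownames(z) <- paste0("TF", 1:5)
  colnames(z) <- sprintf("c%04d", seq_len(m))
  list(z = z, labels = stats::setNames(lab, colnames(z)))
}
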