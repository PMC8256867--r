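test_that("partition metrics match the worked pair-counting example", {
  pm <- partition_metrics(c(1, 1, 2, 2), c(1, 2, 1, 2))
  expect_equal(pm$a, 0)
  expect_equal(pm$b, 2)
  expect_equal(pm$RI, 1 / 3)
  expect_equal(pm$ARI, -0.5)
  same <- partition_metrics(c(1, 1, 2, 2), c(5, 5, 9, 9))
  expect_equal(same$RI, 1)
  expect_equal(same$ARI, 1)
  expect_equal(same$NMI, 1)
  # two one-cluster partitions: NMI defined as 1 by the 0/0 convention
  expect_equal(partition_metrics(c(1, 1, 1), c(2, 2, 2))$NMI, 1)
})

test_that("partition metrics agree with brute-force pair enumeration", {
  set.seed(17)
  for (i in 1:40) {
    p <- random_partition_pair()
    got <- partition_metrics(p$x, p$y)
    want <- oracle_partition_metrics(p$x, p$y)
    expect_equal(got$RI, want$RI, tolerance = 1e-12)
    expect_equal(got$ARI, want$ARI, tolerance = 1e-12)
    expect_equal(got$NMI, want$NMI, tolerance = 1e-12)
    # symmetry and relabeling invariance
    sym <- partition_metrics(p$y, p$x)
    expect_equal(sym$RI, got$RI)
    expect_equal(sym$ARI, got$ARI)
    expect_equal(sym$NMI, got$NMI)
    relab <- partition_metrics(p$x, 10 - p$y)
    expect_equal(relab$ARI, got$ARI)
    expect_true(got$MI <= min(got$H_x, got$H_y) + 1e-12)
  }
})

test_that("jaccard index handles overlap, identity, disjoint, empty", {
  expect_equal(jaccard_index(c(1, 2), c(2, 3)), 1 / 3)
  expect_equal(jaccard_index(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_index(1:2, 3:4), 0)
  expect_equal(jaccard_index(character(0), character(0)), 1)
})

test_that("diffusion distances form a symmetric zero-diagonal matrix", {
  set.seed(33)
  z <- matrix(runif(4 * 30), 4, 30,
              dimnames = list(NULL, sprintf("c%02d", 1:30)))
  z[, 2] <- z[, 1]                       # duplicate cells
  d <- diffusion_distances(z, 5)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0))
  expect_lt(d[1, 2], 1e-10)              # identical cells at distance 0
  expect_error(diffusion_distances(z[, 1:5], 5), "n_components")
})

test_that("far-separated blobs separate in diffusion space", {
  set.seed(44)
  z <- cbind(matrix(rnorm(4 * 20, 0, 0.1), 4),
             matrix(rnorm(4 * 20, 10, 0.1), 4))
  lab <- rep(1:2, each = 20)
  d <- diffusion_distances(z, 5)
  within <- max(d[lab == 1, lab == 1], d[lab == 2, lab == 2])
  between <- min(d[lab == 1, lab == 2])
  expect_gt(between, within)
})

test_that("louvain clustering keeps the right edge count and finds blobs", {
  set.seed(55)
  pts <- cbind(matrix(rnorm(2 * 12, 0, 0.1), 2),
               matrix(rnorm(2 * 12, 5, 0.1), 2),
               matrix(rnorm(2 * 12, c(0, 10), 0.1), 2))
  colnames(pts) <- sprintf("c%02d", 1:36)
  truth <- rep(1:3, each = 12)
  d <- as.matrix(stats::dist(t(pts)))
  cl <- louvain_cluster(d, 0.2, seed = 1)
  expect_equal(attr(cl, "n_edges"), floor(0.2 * 36 * 35 / 2))
  expect_equal(partition_metrics(truth, cl)$ARI, 1)
  # keep_fraction = 1 on one tight blob collapses to a single community
  one <- matrix(rnorm(2 * 10, 0, 0.05), 2,
                dimnames = list(NULL, sprintf("c%02d", 1:10)))
  d1 <- as.matrix(stats::dist(t(one)))
  cl1 <- louvain_cluster(d1, 1, seed = 1)
  expect_equal(length(unique(cl1)), 1L)
  expect_equal(attr(cl1, "n_edges"), 45L)
  expect_error(louvain_cluster(d1[1:2, 1:2], 0.2, 1), "at least 3")
})

test_that("activity logFC is computed against the control mean", {
  Z <- matrix(c(0.4, 0.2, 0.4, 0.1), 1, 4,
              dimnames = list("TF1", paste0("c", 1:4)))
  fit <- stub_fit(matrix(1, 2, 1, dimnames = list(c("g1", "g2"), "TF1")), Z)
  perturb <- data.frame(cell = paste0("c", 1:4),
                        target = c("control", "TF1", "control", "TF1"))
  lfc <- activity_logfc(fit, perturb, "TF1", pseudocount = 0)
  expect_equal(unname(lfc["c1"]), 0)          # equals the control mean (0.4)
  expect_equal(unname(lfc["c2"]), -1)         # half the control mean
  expect_lt(lfc[["c4"]], lfc[["c2"]])         # monotone in activity
  expect_error(activity_logfc(fit, transform(perturb, target = "TF1"),
                              "TF1"), "control")
})

test_that("pooled AUROC equals the brute-force U-statistic oracle", {
  set.seed(66)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    cells <- sprintf("c%03d", 1:n)
    Z <- matrix(runif(2 * n), 2, n, dimnames = list(c("TF1", "TF2"), cells))
    Z[] <- round(Z, 1)                       # force ties
    fit <- stub_fit(matrix(1, 3, 2,
                           dimnames = list(paste0("g", 1:3),
                                           c("TF1", "TF2"))), Z)
    perturb <- data.frame(cell = cells,
                          target = sample(c("control", "TF1", "TF2"), n,
                                          replace = TRUE,
                                          prob = c(0.5, 0.25, 0.25)))
    if (!"control" %in% perturb$target || all(perturb$target == "control"))
      next
    got <- perturbation_auroc(fit, perturb)
    # oracle: rebuild the pooled (score, label) pairs independently
    ctrl <- perturb$cell[perturb$target == "control"]
    scores <- numeric(0); labels <- integer(0)
    for (tf in setdiff(unique(perturb$target), "control")) {
      ref <- mean(Z[tf, ctrl])
      s <- -log2((Z[tf, ] + 1e-6) / (ref + 1e-6))
      pos <- perturb$cell[perturb$target == tf]
      scores <- c(scores, s[pos], s[ctrl])
      labels <- c(labels, rep(1L, length(pos)), rep(0L, length(ctrl)))
    }
    expect_equal(as.numeric(got), oracle_auroc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUROC reaches 1 on perfect separation and 0.5 on ties", {
  cells <- paste0("c", 1:8)
  Z <- matrix(c(0.9, 0.9, 0.9, 0.9, 0.1, 0.1, 0.1, 0.1), 1, 8,
              dimnames = list("TF1", cells))
  fit <- stub_fit(matrix(1, 2, 1, dimnames = list(c("g1", "g2"), "TF1")), Z)
  perturb <- data.frame(cell = cells, target = rep(c("control", "TF1"),
                                                   each = 4))
  expect_equal(as.numeric(perturbation_auroc(fit, perturb)), 1)
  Zt <- matrix(0.5, 1, 8, dimnames = list("TF1", cells))
  expect_equal(as.numeric(perturbation_auroc(stub_fit(fit$W_mean, Zt),
                                             perturb)), 0.5)
  # invariance under strictly increasing transforms of the activity scores
  Zm <- matrix(runif(8), 1, 8, dimnames = list("TF1", cells))
  a1 <- as.numeric(perturbation_auroc(stub_fit(fit$W_mean, Zm), perturb))
  a2 <- as.numeric(perturbation_auroc(stub_fit(fit$W_mean, Zm^3), perturb))
  expect_equal(a1, a2)
})

test_that("random forest marker ranking finds a planted type-specific TF", {
  b <- make_blob_z(120, seed = 9)
  fit <- stub_fit(matrix(1, 3, 5,
                         dimnames = list(paste0("g", 1:3), rownames(b$z))),
                  b$z)
  labels <- stats::setNames(paste0("type", b$labels), colnames(b$z))
  mk <- marker_tfs(fit, labels, "type1", seed = 1)
  expect_equal(mk$tf[1], "TF1")           # TF1 is high only in type1 blobs
  expect_equal(sum(mk$importance), 1, tolerance = 1e-12)
  # permuting cell order does not change the ranking for a fixed seed
  perm <- sample(ncol(b$z))
  fit2 <- stub_fit(fit$W_mean, b$z[, perm])
  mk2 <- marker_tfs(fit2, labels, "type1", seed = 1)
  expect_equal(mk2$tf, mk$tf)
  expect_equal(mk2$importance, mk$importance)
  expect_error(marker_tfs(fit, labels, "missing-type", seed = 1), "not present")
})
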