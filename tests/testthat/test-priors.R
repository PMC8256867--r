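test_that("promoter windows are strand-aware and clipped at zero", {
  tss <- data.frame(gene = c("a", "b", "c"), chrom = "chr1",
                    strand = c("+", "-", "+"), tss = c(10000L, 10000L, 500L))
  prom <- promoter_regions(tss)
  expect_equal(prom$start, c(8000L, 9800L, 0L))
  expect_equal(prom$end, c(10200L, 12000L, 700L))
  expect_equal(prom$end[1] - prom$start[1], 2200L)
  # stranded = FALSE treats everything as plus strand
  flat <- promoter_regions(tss, stranded = FALSE)
  expect_equal(flat$start[2], 8000L)
  expect_error(promoter_regions(data.frame(gene = "a", chrom = "c",
                                           strand = "*", tss = 1L)),
               "strand")
})

test_that("target assignment uses >=1 base overlap, half-open", {
  prom <- interval_set("chr1", 8000, 10200, "geneA")
  hit <- interval_set("chr1", 8100, 8200, "TF1")
  expect_equal(assign_targets(hit, prom)$TF1, "geneA")
  # abutting half-open intervals do not overlap
  abut <- interval_set("chr1", 10200, 10300, "TF1")
  expect_equal(assign_targets(abut, prom)$TF1, character(0))
  # different chromosomes never count
  other <- interval_set("chr2", 8100, 8200, "TF1")
  expect_equal(assign_targets(other, prom)$TF1, character(0))
})

test_that("target assignment equals the per-base brute-force oracle", {
  set.seed(202)
  for (rep in 1:5) {
    peaks <- random_interval_set(50, labels = c("TF1", "TF2", "TF3"))
    proms <- random_interval_set(50, labels = paste0("g", 1:20))
    got <- assign_targets(peaks, proms)
    want <- oracle_assign_targets(peaks, proms)
    expect_equal(got[names(want)], want)
  }
})

test_that("adding peaks never removes target pairs; wider windows never shrink sets", {
  set.seed(77)
  tss <- data.frame(gene = paste0("g", 1:15), chrom = "chr1", strand = "+",
                    tss = sample(2000:50000, 15))
  peaks <- random_interval_set(30, chroms = "chr1", max_pos = 50000,
                               labels = c("TF1", "TF2"))
  prom <- promoter_regions(tss)
  base <- assign_targets(peaks, prom)
  extra <- interval_set(c(peaks$chrom, "chr1"), c(peaks$start, 100),
                        c(peaks$end, 49000), c(peaks$label, "TF1"))
  more <- assign_targets(extra, prom)
  expect_true(all(base$TF1 %in% more$TF1))
  expect_true(all(base$TF2 %in% more$TF2))
  # window sweep: each preset contains the narrower one's targets
  presets <- promoter_window_presets()
  prev <- NULL
  for (w in presets[c("narrow", "proximal", "default", "distal")]) {
    cur <- assign_targets(peaks, promoter_regions(tss, w[1], w[2]))
    if (!is.null(prev))
      for (tf in names(prev)) expect_true(all(prev[[tf]] %in% cur[[tf]]))
    prev <- cur
  }
})

test_that("accessibility filtering keeps only genes with open promoters", {
  prom <- interval_set(c("chr1", "chr2"), c(100, 100), c(300, 300),
                       c("gA", "gB"))
  targets <- list(TF1 = c("gA", "gB"))
  open_all <- interval_set("chr1", 0, 1000, "open")
  kept <- filter_targets_by_accessibility(targets, prom, open_all)
  expect_equal(kept$TF1, "gA")          # chr2 has no open region
  expect_true(all(kept$TF1 %in% targets$TF1))
  expect_error(filter_targets_by_accessibility(targets, prom,
                                               prom[0, ]), "nonempty")
})

test_that("prior matrix encodes effective target sets with correct column sums", {
  genes <- paste0("g", 1:15)
  vals <- matrix(rep(c(0, 0, 3, 3), each = 15), nrow = 15)
  m <- small_norm_matrix(vals, genes, paste0("c", 1:4))
  sel <- select_variable_genes(m)
  targets <- list(g1 = paste0("g", c(1, 3:13)),      # 12 in selection
                  g2 = c(paste0("g", 4:13), "gX"))   # 10 in selection
  tfs <- select_tfs(sel, targets)
  prior <- build_prior_matrix(targets, sel, tfs)
  expect_true(all(prior$mask %in% c(0, 1)))
  # column sums equal independently computed effective set sizes
  for (tf in prior$tf_names)
    expect_equal(unname(colSums(prior$mask)[tf]),
                 length(intersect(targets[[tf]], sel$genes)))
  expect_equal(rownames(prior$mask), sel$genes)
  # a gene outside the selection contributes no row
  expect_false("gX" %in% rownames(prior$mask))
  # under-populated columns violate the precondition
  expect_error(build_prior_matrix(list(g2 = paste0("g", 1:3)), sel, "g2"),
               "fewer than")
})

test_that("toy prior example: 3 genes, 1 TF targeting g1 and g3", {
  m <- small_norm_matrix(matrix(c(0, 0, 0, 3, 3, 3, 3, 3, 3, 0, 0, 0), 3),
                         paste0("g", 1:3), paste0("c", 1:4))
  sel <- select_variable_genes(m)
  prior <- build_prior_matrix(list(TF1 = c("g1", "g3")), sel, "TF1",
                              min_targets = 2)
  expect_equal(unname(prior$mask[, "TF1"]), c(1, 0, 1))
})
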