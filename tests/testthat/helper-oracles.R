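# Independent oracles, deliberately implemented by brute force so they share
# no code path with the package functions they check.

# Pair-enumeration partition metrics. ARI comes from the 2x2 pair-confusion
# table, a different route than the contingency-table formula.
oracle_partition_metrics <- function(x, y) {
  n <- length(x)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      sx <- x[i] == x[j]
      sy <- y[i] == y[j]
      if (sx && sy) n11 <- n11 + 1
      else if (!sx && !sy) n00 <- n00 + 1
      else if (sx && !sy) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  total <- n * (n - 1) / 2
  ri <- (n11 + n00) / total
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  ari <- if (den == 0) 1 else 2 * (n11 * n00 - n10 * n01) / den
  # direct entropy computation for NMI
  px <- table(x) / n
  py <- table(y) / n
  pxy <- table(x, y) / n
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  mi <- ent(px) + ent(py) - ent(pxy)
  hsum <- ent(px) + ent(py)
  nmi <- if (hsum == 0) 1 else 2 * mi / hsum
  list(RI = ri, ARI = ari, NMI = nmi, a = n11, b = n00)
}

# Quadratic per-base overlap oracle: a gene is a target iff some peak of the
# TF shares at least one genomic base with some promoter of the gene.
oracle_assign_targets <- function(peaks, promoters) {
  tfs <- sort(unique(peaks$label))
  out <- stats::setNames(rep(list(character(0)), length(tfs)), tfs)
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(promoters))) {
      if (peaks$chrom[i] != promoters$chrom[j]) next
      bases_i <- seq(peaks$start[i], peaks$end[i] - 1L)
      bases_j <- seq(promoters$start[j], promoters$end[j] - 1L)
      if (length(intersect(bases_i, bases_j)) > 0) {
        tf <- peaks$label[i]
        out[[tf]] <- union(out[[tf]], promoters$label[j])
      }
    }
  }
  lapply(out, sort)
}

# All-pairs Mann-Whitney AUROC oracle with half credit for ties.
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  acc <- 0
  for (p in pos) for (q in neg)
    acc <- acc + (p > q) + 0.5 * (p == q)
  acc / (length(pos) * length(neg))
}

random_partition_pair <- function(n_max = 12) {
  n <- sample(2:n_max, 1)
  list(x = sample(1:sample(1:4, 1), n, replace = TRUE),
       y = sample(1:sample(1:4, 1), n, replace = TRUE))
}

random_interval_set <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000,
                                labels = letters[1:5]) {
  start <- sample(0:(max_pos - 2), n, replace = TRUE)
  len <- sample(1:50, n, replace = TRUE)
  interval_set(sample(chroms, n, replace = TRUE), start, start + len,
               sample(labels, n, replace = TRUE))
}
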