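#' Read a count matrix from MTX or dense TSV/CSV
#'
#' For `format = "mtx"` the Matrix Market triplet file must be the
#' "coordinate integer general" dialect (the format written by common
#' single-cell exporters for raw counts) and is accompanied by sidecar gene
#' and barcode lists (one identifier per line, extra tab-separated columns
#' ignored). For dense formats the first column holds gene ids and the header
#' row holds cell ids.
#'
#' @param path path to the matrix file.
#' @param format one of `"mtx"`, `"tsv"`, `"csv"`.
#' @param genes_path,barcodes_path sidecar paths for MTX input; default to
#'   `genes.tsv` and `barcodes.tsv` next to `path`.
#' @return An [expression_matrix()] with `state = "raw_counts"`.
#' @export
read_count_matrix <- function(path, format = c("mtx", "tsv", "csv"),
                              genes_path = NULL, barcodes_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    header <- readLines(path, n = 1L)
    want <- "%%matrixmarket matrix coordinate integer general"
    if (!identical(tolower(trimws(header)), want))
      stop("unsupported Matrix Market dialect; expected header '",
           "%%MatrixMarket matrix coordinate integer general'")
    if (is.null(genes_path)) genes_path <- file.path(dirname(path), "genes.tsv")
    if (is.null(barcodes_path))
      barcodes_path <- file.path(dirname(path), "barcodes.tsv")
    for (p in c(genes_path, barcodes_path))
      if (!file.exists(p)) stop("sidecar file not found: ", p)
    m <- as.matrix(Matrix::readMM(path))
    genes <- read_id_column(genes_path)
    cells <- read_id_column(barcodes_path)
    if (length(genes) != nrow(m))
      stop("gene sidecar lists ", length(genes), " ids but matrix has ",
           nrow(m), " rows")
    if (length(cells) != ncol(m))
      stop("barcode sidecar lists ", length(cells), " ids but matrix has ",
           ncol(m), " columns")
    return(expression_matrix(m, genes, cells, state = "raw_counts"))
  }
  sep <- if (format == "tsv") "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  genes <- trimws(as.character(tab[[1L]]))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric entries in ", path)
  expression_matrix(vals, genes, colnames(tab)[-1L], state = "raw_counts")
}

read_id_column <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Read BED intervals
#'
#' Reads BED3+ records into an [interval_set()], keeping the native 0-based
#' half-open coordinates. Labels come either from the BED name column or from
#' the file name (without extension), in which case `path` may be a vector of
#' files whose records are concatenated.
#'
#' @param path one or more BED file paths.
#' @param label_from `"name_column"` (BED column 4) or `"filename"`.
#' @return An [interval_set()].
#' @export
read_bed <- function(path, label_from = c("name_column", "filename")) {
  label_from <- match.arg(label_from)
  if (label_from == "name_column" && length(path) != 1L)
    stop("a single BED file is expected when labels come from the name column")
  parts <- lapply(path, function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    lines <- readLines(p)
    keep <- nzchar(trimws(lines)) & !startsWith(lines, "#") &
      !startsWith(lines, "track") & !startsWith(lines, "browser")
    recs <- lapply(which(keep), function(i) {
      f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
      if (length(f) < 3L)
        stop("malformed BED line ", i, " in ", p, ": fewer than 3 fields")
      start <- suppressWarnings(as.integer(f[2]))
      end <- suppressWarnings(as.integer(f[3]))
      if (is.na(start) || is.na(end))
        stop("malformed BED line ", i, " in ", p, ": non-integer coordinates")
      if (end <= start)
        stop("malformed BED line ", i, " in ", p, ": end <= start")
      label <- if (label_from == "name_column") {
        if (length(f) < 4L)
          stop("missing name column at line ", i, " in ", p)
        f[4]
      } else {
        sub("\\.[^.]*$", "", basename(p))
      }
      list(chrom = f[1], start = start, end = end, label = label)
    })
    recs
  })
  recs <- do.call(c, parts)
  if (!length(recs)) stop("no BED records found")
  interval_set(vapply(recs, `[[`, character(1), "chrom"),
               vapply(recs, `[[`, integer(1), "start"),
               vapply(recs, `[[`, integer(1), "end"),
               vapply(recs, `[[`, character(1), "label"))
}

#' Read a TSS table
#'
#' Tab-separated table with header `gene chrom strand tss`. Positions declared
#' 1-based are converted to the package's internal 0-based convention on read.
#' A gene may have several TSS records (one per transcript).
#'
#' @param path TSV path.
#' @param coordinate_system `"0-based"` or `"1-based"` positions in the file.
#' @return data frame with columns `gene`, `chrom`, `strand`, `tss` (0-based).
#' @export
read_tss <- function(path, coordinate_system = c("0-based", "1-based")) {
  coordinate_system <- match.arg(coordinate_system)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "strand", "tss")
  if (!all(need %in% names(tab)))
    stop("TSS table must have columns: ", paste(need, collapse = ", "))
  tab <- tab[, need]
  tab$gene <- trimws(as.character(tab$gene))
  tab$strand <- as.character(tab$strand)
  if (!all(tab$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  tab$tss <- as.integer(tab$tss)
  if (coordinate_system == "1-based") tab$tss <- tab$tss - 1L
  if (any(tab$tss < 0)) stop("TSS positions must be >= 0 after conversion")
  tab
}

#' Read a perturbation label table
#'
#' Tab-separated table with header `cell target`; `target` is a TF name for
#' perturbed cells and `"control"` otherwise.
#'
#' @param path TSV path.
#' @return data frame with columns `cell`, `target`; one row per cell.
#' @export
read_perturbation_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("cell", "target") %in% names(tab)))
    stop("perturbation table must have columns: cell, target")
  tab$cell <- trimws(as.character(tab$cell))
  if (anyDuplicated(tab$cell))
    stop("duplicate cell ids in perturbation table")
  tab[, c("cell", "target")]
}

fmt17 <- function(x) sprintf("%.17g", x)

write_matrix_tsv <- function(m, path, corner) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(corner, colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(row) paste(fmt17(row), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- as.character(tab[[1L]])
  m
}

#' Write a fitted model to a directory
#'
#' Serializes the posterior-mean weight matrix `W` (genes x TFs) and activity
#' matrix `Z` (TFs x cells) as TSV, plus a JSON metadata sidecar carrying the
#' seed, draw count, ELBO trace, convergence flag and configuration echo.
#' Floats are written at 17 significant digits so that
#' `read_fit(write_fit(fit))` reproduces all matrices exactly.
#'
#' @param fit a [fit_tfa()] result.
#' @param out_dir output directory (created if absent).
#' @return Invisibly, the character vector of files written.
#' @export
write_fit <- function(fit, out_dir) {
  stopifnot(inherits(fit, "tfa_fit"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  w_path <- file.path(out_dir, "W.tsv")
  z_path <- file.path(out_dir, "Z.tsv")
  meta_path <- file.path(out_dir, "meta.json")
  write_matrix_tsv(fit$W_mean, w_path, "gene")
  write_matrix_tsv(fit$Z_mean, z_path, "tf")
  meta <- list(
    seed = fit$config$seed,
    n_posterior_draws = fit$config$n_posterior_draws,
    converged = fit$converged,
    elbo_trace = list(iteration = fit$elbo_trace$iteration,
                      elbo = fmt17(fit$elbo_trace$elbo)),
    delta_mean = fmt17(fit$delta_mean),
    noise_mean = fmt17(fit$noise_mean),
    config = fit$config)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(w_path, z_path, meta_path))
}

#' Read a fitted model written by [write_fit()]
#'
#' @param dir directory holding `W.tsv`, `Z.tsv`, `meta.json`.
#' @return An object of class `tfa_fit`.
#' @export
read_fit <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  config <- meta$config
  structure(list(
    W_mean = read_matrix_tsv(file.path(dir, "W.tsv")),
    Z_mean = read_matrix_tsv(file.path(dir, "Z.tsv")),
    delta_mean = as.numeric(meta$delta_mean),
    noise_mean = as.numeric(meta$noise_mean),
    elbo_trace = data.frame(iteration = as.integer(meta$elbo_trace$iteration),
                            elbo = as.numeric(meta$elbo_trace$elbo)),
    converged = isTRUE(meta$converged),
    config = config,
    mask = NULL),
    class = "tfa_fit")
}
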