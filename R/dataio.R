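#' Preprocessing configuration
#'
#' @param scale_factor library-size scale factor for log-normalization
#'   (default 10000).
#' @param n_hvg number of highly variable genes to keep (default 2000).
#' @param normalization `"lognorm"` or `"tpm"`.
#' @param hvg_reference data on which HVGs are ranked: `"source"` (the target
#'   never influences feature selection) or `"concatenated"`.
#' @return A `PreprocessConfig` list.
#' @export
preprocess_config <- function(scale_factor = 10000, n_hvg = 2000L,
                              normalization = c("lognorm", "tpm"),
                              hvg_reference = c("source", "concatenated")) {
  if (scale_factor <= 0) stop("scale_factor must be positive", call. = FALSE)
  if (n_hvg < 1) stop("n_hvg must be positive", call. = FALSE)
  structure(list(scale_factor = scale_factor, n_hvg = as.integer(n_hvg),
                 normalization = match.arg(normalization),
                 hvg_reference = match.arg(hvg_reference)),
            class = "PreprocessConfig")
}

#' Read an expression dataset from disk
#'
#' Two on-disk layouts are supported: a directory with a Matrix Market
#' `matrix.mtx` plus `genes.tsv` and `barcodes.tsv` (10x convention, stored
#' genes x cells), or a single dense delimited text file with gene and cell
#' names as dimnames. Orientation of a dense file must be declared.
#'
#' @param path directory (MTX layout) or delimited text file.
#' @param orientation `"genes_by_cells"` or `"cells_by_genes"`; applies to
#'   dense files (MTX is always stored genes x cells).
#' @param labels_path optional two-column TSV (cell id, cell type), no header.
#' @param domain domain tag for the resulting dataset.
#' @param sep field separator for dense files (default tab).
#' @return A counts-layer [expression_dataset()].
#' @export
read_dataset <- function(path,
                         orientation = c("genes_by_cells", "cells_by_genes"),
                         labels_path = NULL,
                         domain = c("source", "target"),
                         sep = "\t") {
  orientation <- match.arg(orientation)
  domain <- match.arg(domain)
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    genes_f <- file.path(path, "genes.tsv")
    cells_f <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, genes_f, cells_f)) {
      if (!file.exists(f)) stop("missing file in MTX directory: ", f, call. = FALSE)
    }
    m <- as.matrix(Matrix::readMM(mtx))      # genes x cells on disk
    genes <- readLines(genes_f)
    cells <- readLines(cells_f)
    mat <- t(m)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE)
    m <- as.matrix(df)
    if (orientation == "genes_by_cells") {
      genes <- rownames(m); cells <- colnames(m); mat <- t(m)
    } else {
      cells <- rownames(m); genes <- colnames(m); mat <- m
    }
  }
  labels <- NULL
  if (!is.null(labels_path)) {
    lab <- utils::read.table(labels_path, header = FALSE, sep = "\t",
                             col.names = c("cell_id", "cell_type"),
                             colClasses = "character")
    missing <- setdiff(cells, lab$cell_id)
    if (length(missing) > 0) {
      stop("label file lacks entries for cells: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    labels <- lab$cell_type[match(cells, lab$cell_id)]
  }
  expression_dataset(mat, gene_names = genes, cell_ids = cells, labels = labels,
                     domain = domain, layer = "counts")
}

#' Write an expression dataset to disk
#'
#' @param ds an [expression_dataset()].
#' @param path output directory (`"mtx"` format) or file (`"tsv"` format).
#' @param format `"mtx"` writes `matrix.mtx` (genes x cells) + `genes.tsv` +
#'   `barcodes.tsv` + `labels.tsv` (when labels exist); `"tsv"` writes a single
#'   dense genes x cells table.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, format = c("mtx", "tsv")) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  format <- match.arg(format)
  if (format == "mtx") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    m <- Matrix::Matrix(t(ds$matrix), sparse = TRUE)  # genes x cells
    Matrix::writeMM(m, file.path(path, "matrix.mtx"))
    writeLines(ds$gene_names, file.path(path, "genes.tsv"))
    writeLines(ds$cell_ids, file.path(path, "barcodes.tsv"))
    if (!is.null(ds$labels)) {
      utils::write.table(data.frame(ds$cell_ids, ds$labels),
                         file.path(path, "labels.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
  } else {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    tab <- t(ds$matrix)
    utils::write.table(data.frame(gene = rownames(tab), tab, check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' TPM normalization
#'
#' Counts are divided by gene length (when lengths are supplied), scaled so
#' each cell sums to one million, yielding transcripts per million. Without
#' lengths this is counts per million (CPM), the appropriate depth correction
#' for simulated or UMI data where no length bias exists.
#'
#' @param ds counts-layer [expression_dataset()].
#' @param gene_lengths optional positive numeric vector, one per gene.
#' @return The dataset with layer `"tpm"`.
#' @export
tpm_normalize <- function(ds, gene_lengths = NULL) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (ds$layer != "counts") stop("tpm_normalize expects a counts layer", call. = FALSE)
  m <- ds$matrix
  if (!is.null(gene_lengths)) {
    if (length(gene_lengths) != ncol(m))
      stop("gene_lengths must have one entry per gene", call. = FALSE)
    if (any(gene_lengths <= 0)) stop("gene lengths must be positive", call. = FALSE)
    m <- sweep(m, 2, gene_lengths, "/")
  }
  tot <- rowSums(m)
  if (any(tot == 0)) {
    bad <- ds$cell_ids[tot == 0][1]
    stop("cell with zero total counts: ", bad, " (filter degenerate cells first)",
         call. = FALSE)
  }
  out <- ds
  out$matrix <- m / tot * 1e6
  dimnames(out$matrix) <- dimnames(ds$matrix)
  out$layer <- "tpm"
  out
}

#' Log-normalization
#'
#' Per cell: `log1p(count / total * scale_factor)`, the standard library-size
#' log-normalization with a fixed scale factor.
#'
#' @param ds counts-layer [expression_dataset()].
#' @param cfg a [preprocess_config()]; only `scale_factor` is used.
#' @return The dataset with layer `"lognorm"`.
#' @export
lognorm <- function(ds, cfg = preprocess_config()) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (ds$layer != "counts") stop("lognorm expects a counts layer", call. = FALSE)
  tot <- rowSums(ds$matrix)
  if (any(tot == 0)) {
    bad <- ds$cell_ids[tot == 0][1]
    stop("cell with zero total counts: ", bad, " (filter degenerate cells first)",
         call. = FALSE)
  }
  out <- ds
  out$matrix <- log1p(ds$matrix / tot * cfg$scale_factor)
  dimnames(out$matrix) <- dimnames(ds$matrix)
  out$layer <- "lognorm"
  out
}

# vst-style standardized variance per gene: fit a loess trend of log10
# variance on log10 mean, standardize each value by the trend sd, clip at
# sqrt(N), and take the variance of the clipped values. Deterministic.
standardized_variance <- function(m) {
  mu <- colMeans(m)
  v <- apply(m, 2, stats::var)
  n <- nrow(m)
  sv <- numeric(ncol(m))
  usable <- v > 0 & mu > 0
  if (sum(usable) >= 5) {
    fit <- stats::loess(log10(v[usable]) ~ log10(mu[usable]), span = 0.3,
                        degree = 2)
    expected_sd <- sqrt(10^stats::predict(fit))
    z <- sweep(m[, usable, drop = FALSE], 2, mu[usable], "-")
    z <- sweep(z, 2, expected_sd, "/")
    z <- pmin(z, sqrt(n))
    z <- pmax(z, -sqrt(n))
    sv[usable] <- apply(z, 2, stats::var)
  } else {
    sv[usable] <- v[usable]   # too few genes for a trend; rank by raw variance
  }
  sv
}

#' Select highly variable genes across a domain pair
#'
#' Ranks genes by vst-style standardized variance (variance of standardized,
#' clipped values after removing the mean-variance trend) computed on the
#' reference data, keeps the top `n_hvg`, and restricts both datasets to the
#' same genes in the same order. Ties are broken lexicographically by gene
#' name, so the selection is fully deterministic.
#'
#' @param source,target log-normalized [expression_dataset()]s restricted to a
#'   shared gene set in the same order.
#' @param cfg a [preprocess_config()] (`n_hvg`, `hvg_reference`).
#' @return A list `source`, `target` (layer `"hvg"`), and `genes` (the kept
#'   gene names in rank order).
#' @export
select_hvg <- function(source, target, cfg = preprocess_config()) {
  stopifnot(inherits(source, "ExpressionDataset"),
            inherits(target, "ExpressionDataset"))
  if (!identical(source$gene_names, target$gene_names)) {
    stop("source and target must share an identical gene set/order; ",
         "intersect genes first", call. = FALSE)
  }
  n_shared <- length(source$gene_names)
  if (cfg$n_hvg > n_shared) {
    stop("n_hvg (", cfg$n_hvg, ") exceeds the number of shared genes (",
         n_shared, ")", call. = FALSE)
  }
  ref <- switch(cfg$hvg_reference,
                source = source$matrix,
                concatenated = rbind(source$matrix, target$matrix))
  sv <- standardized_variance(ref)
  ord <- order(-sv, source$gene_names)
  genes <- source$gene_names[ord[seq_len(cfg$n_hvg)]]
  list(source = subset_genes(source, genes, layer = "hvg"),
       target = subset_genes(target, genes, layer = "hvg"),
       genes = genes)
}

#' Read a two-column homolog table
#'
#' @param path TSV with two columns: gene name in species A, gene name in
#'   species B.
#' @param header whether the file has a header row (default FALSE).
#' @return A `HomologTable`: data.frame with columns `a`, `b`.
#' @export
read_homolog_table <- function(path, header = FALSE) {
  tab <- utils::read.table(path, header = header, sep = "\t",
                           colClasses = "character")
  if (ncol(tab) < 2) stop("homolog table needs two columns", call. = FALSE)
  homolog_table(tab[[1]], tab[[2]])
}

#' Construct a homolog table
#'
#' @param a,b parallel character vectors of gene names in the two species.
#' @return A `HomologTable` data.frame with columns `a`, `b`.
#' @export
homolog_table <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be parallel", call. = FALSE)
  if (length(a) == 0) stop("homolog table is empty", call. = FALSE)
  structure(data.frame(a = as.character(a), b = as.character(b),
                       stringsAsFactors = FALSE),
            class = c("HomologTable", "data.frame"))
}

#' Map two datasets onto a shared homolog gene set
#'
#' Genes of `a` are translated through the table into `b`'s namespace; both
#' matrices are restricted to the translated intersection, column-aligned.
#' One-to-many table rows are resolved by keeping the first pair in file
#' order; later rows reusing either gene are dropped, making the mapping
#' one-to-one.
#'
#' @param a,b [expression_dataset()]s (species A resp. B gene names).
#' @param table a [homolog_table()] mapping A names to B names.
#' @return A list `a`, `b` of datasets with identical (B-namespace) columns.
#' @export
intersect_homologs <- function(a, b, table) {
  stopifnot(inherits(a, "ExpressionDataset"), inherits(b, "ExpressionDataset"),
            inherits(table, "HomologTable"))
  keep <- !duplicated(table$a) & !duplicated(table$b)
  tab <- table[keep, , drop = FALSE]
  tab <- tab[tab$a %in% a$gene_names & tab$b %in% b$gene_names, , drop = FALSE]
  if (nrow(tab) == 0) {
    stop("no genes shared between the two datasets after homolog mapping",
         call. = FALSE)
  }
  a_sub <- subset_genes(a, tab$a)
  a_sub$gene_names <- tab$b
  colnames(a_sub$matrix) <- tab$b
  b_sub <- subset_genes(b, tab$b)
  list(a = a_sub, b = b_sub)
}
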