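#' Expression dataset container
#'
#' A light in-memory container for a single-cell expression matrix plus its
#' annotations. Cells are rows, genes are columns (the 10x on-disk convention
#' of genes x cells is transposed on read/write). The `layer` field records
#' what the values are: raw `counts`, depth-normalized `tpm`, log-normalized
#' `lognorm`, or the HVG-restricted model input `hvg`.
#'
#' @param matrix numeric matrix, cells x genes, non-negative.
#' @param gene_names character vector of unique gene names, one per column.
#' @param cell_ids character vector of unique cell ids, one per row.
#' @param labels optional character vector of per-cell type labels.
#' @param domain `"source"` (labeled reference) or `"target"` (query).
#' @param layer one of `"counts"`, `"tpm"`, `"lognorm"`, `"hvg"`.
#'
#' @return An object of class `ExpressionDataset`: a list with fields
#'   `matrix`, `gene_names`, `cell_ids`, `labels`, `domain`, `layer`.
#' @export
expression_dataset <- function(matrix, gene_names, cell_ids, labels = NULL,
                               domain = c("source", "target"),
                               layer = c("counts", "tpm", "lognorm", "hvg")) {
  domain <- match.arg(domain)
  layer <- match.arg(layer)
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  gene_names <- as.character(gene_names)
  cell_ids <- as.character(cell_ids)
  if (ncol(matrix) != length(gene_names)) {
    stop("matrix has ", ncol(matrix), " columns but ", length(gene_names),
         " gene names were given", call. = FALSE)
  }
  if (nrow(matrix) != length(cell_ids)) {
    stop("matrix has ", nrow(matrix), " rows but ", length(cell_ids),
         " cell ids were given", call. = FALSE)
  }
  if (anyDuplicated(gene_names)) {
    dup <- unique(gene_names[duplicated(gene_names)])
    stop("duplicate gene names: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(cell_ids)) {
    stop("duplicate cell ids", call. = FALSE)
  }
  if (any(matrix < 0)) stop("expression values must be non-negative", call. = FALSE)
  if (layer == "counts" && any(abs(matrix - round(matrix)) > 1e-8)) {
    stop("counts layer must contain integers", call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(cell_ids)) {
      stop("labels length (", length(labels), ") differs from number of cells (",
           length(cell_ids), ")", call. = FALSE)
    }
  }
  dimnames(matrix) <- list(cell_ids, gene_names)
  structure(
    list(matrix = matrix, gene_names = gene_names, cell_ids = cell_ids,
         labels = labels, domain = domain, layer = layer),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset [%s/%s]: %d cells x %d genes%s\n",
              x$domain, x$layer, nrow(x$matrix), ncol(x$matrix),
              if (is.null(x$labels)) "" else
                sprintf(", %d label classes", length(unique(x$labels)))))
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$matrix)

#' Restrict a dataset to a subset of genes
#'
#' Columns are reordered to match `genes` exactly, so two datasets subset with
#' the same vector end up column-aligned.
#'
#' @param ds an [expression_dataset()].
#' @param genes character vector; must all be present in `ds$gene_names`.
#' @param layer optional new layer tag (e.g. `"hvg"` after HVG selection).
#' @return A new `ExpressionDataset` with columns `genes`, in that order.
#' @export
subset_genes <- function(ds, genes, layer = ds$layer) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  missing <- setdiff(genes, ds$gene_names)
  if (length(missing) > 0) {
    stop("genes not present in dataset: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  out <- ds
  out$matrix <- ds$matrix[, genes, drop = FALSE]
  out$gene_names <- genes
  out$layer <- layer
  out
}
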