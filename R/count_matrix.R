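#' Construct a CountMatrix
#'
#' The basic container for raw scRNA-seq data: a cells x genes matrix of
#' nonnegative integer counts, cell and gene identifiers, and optional
#' per-cell type labels.
#'
#' @param counts numeric matrix, cells in rows, genes in columns. Entries must
#'   be nonnegative and integer-valued (stored as double).
#' @param cell_ids character vector of unique cell identifiers (rows).
#' @param gene_ids character vector of unique gene identifiers (columns).
#' @param labels optional per-cell labels (character/factor, one per cell).
#' @return an object of class \code{CountMatrix}: a list with elements
#'   \code{counts}, \code{cell_ids}, \code{gene_ids}, \code{labels}.
#' @export
count_matrix <- function(counts, cell_ids = rownames(counts),
                         gene_ids = colnames(counts), labels = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(counts)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(counts))
    stop("cell_ids length (", length(cell_ids), ") != number of rows (",
         nrow(counts), ")")
  if (length(gene_ids) != ncol(counts))
    stop("gene_ids length (", length(gene_ids), ") != number of columns (",
         ncol(counts), ")")
  if (anyDuplicated(cell_ids))
    stop("duplicate cell_ids: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene_ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyNA(counts)) stop("counts contain NA")
  if (any(counts < 0))
    stop("counts must be nonnegative; found ", sum(counts < 0),
         " negative entries")
  if (any(counts != floor(counts)))
    stop("counts must be integer-valued; found ",
         sum(counts != floor(counts)), " non-integer entries")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(counts))
      stop("labels must have exactly one value per cell")
  }
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts, cell_ids = cell_ids, gene_ids = gene_ids,
                 labels = labels),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix: ", nrow(x$counts), " cells x ", ncol(x$counts),
      " genes\n", sep = "")
  zf <- mean(x$counts == 0)
  cat(sprintf("  zero fraction: %.3f\n", zf))
  if (!is.null(x$labels))
    cat("  labels: ", length(unique(x$labels)), " classes\n", sep = "")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)
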