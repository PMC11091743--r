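#' Read a count matrix from disk
#'
#' Reads a cells x genes count matrix from delimited text, Matrix Market, or
#' AnnData HDF5. The internal orientation is always cells x genes; MTX files
#' written in the common genes x cells dialect are detected via the sidecar
#' name files and transposed.
#'
#' @param path path to the matrix file.
#' @param format one of \code{"csv"}, \code{"mtx"}, \code{"h5ad"}. Default
#'   guesses from the file extension.
#' @param genes_file,cells_file for \code{format = "mtx"}: one-name-per-line
#'   sidecar files. Defaults to \code{<path minus .mtx>.genes.txt} and
#'   \code{.cells.txt}.
#' @param layer for \code{format = "h5ad"}: name of the layer holding raw
#'   counts, or \code{NULL} for the main matrix \code{X}.
#' @details \code{format = "h5ad"} requires a \code{python} interpreter with
#'   the \code{anndata} package on the PATH; the matrix is exported to a
#'   temporary MTX triplet and read from there.
#' @return a \code{\link{count_matrix}}.
#' @export
read_counts <- function(path, format = c("auto", "csv", "mtx", "h5ad"),
                        genes_file = NULL, cells_file = NULL, layer = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     csv = "csv", tsv = "csv", txt = "csv",
                     mtx = "mtx", h5ad = "h5ad",
                     stop("cannot guess format from extension '.", ext,
                          "'; pass format= explicitly"))
  }
  switch(format,
         csv  = read_counts_csv(path),
         mtx  = read_counts_mtx(path, genes_file, cells_file),
         h5ad = read_counts_h5ad(path, layer))
}

read_counts_csv <- function(path) {
  dt <- tryCatch(
    data.table::fread(path, header = TRUE),
    error = function(e) stop("failed to parse '", path, "': ",
                             conditionMessage(e)))
  if (ncol(dt) < 2) stop("parse error in '", path,
                         "': need an id column plus at least one gene column")
  cell_ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, with = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(dt[, -1, with = FALSE], is.numeric, logical(1)))
    stop("parse error in '", path, "': non-numeric column(s) ",
         paste(names(bad), collapse = ", "))
  }
  count_matrix(m, cell_ids = cell_ids, gene_ids = colnames(m))
}

mtx_sidecar <- function(path, suffix, override) {
  if (!is.null(override)) return(override)
  appended <- paste0(path, suffix)        # counts.mtx.genes.txt
  if (file.exists(appended)) return(appended)
  sub("\\.mtx$", suffix, path)            # counts.genes.txt
}

read_counts_mtx <- function(path, genes_file = NULL, cells_file = NULL) {
  genes_file <- mtx_sidecar(path, ".genes.txt", genes_file)
  cells_file <- mtx_sidecar(path, ".cells.txt", cells_file)
  for (f in c(genes_file, cells_file))
    if (!file.exists(f)) stop("MTX sidecar name file not found: ", f)
  m <- tryCatch(as.matrix(Matrix::readMM(path)),
                error = function(e) stop("failed to parse '", path, "': ",
                                         conditionMessage(e)))
  genes <- readLines(genes_file)
  cells <- readLines(cells_file)
  if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
    # already cells x genes
  } else if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
    m <- t(m)  # genes x cells dialect
  } else {
    stop("MTX dimensions ", nrow(m), " x ", ncol(m),
         " match neither orientation of the name files (",
         length(cells), " cells, ", length(genes), " genes)")
  }
  count_matrix(m, cell_ids = cells, gene_ids = genes)
}

read_counts_h5ad <- function(path, layer = NULL) {
  py <- Sys.which("python")
  if (py == "") stop("reading .h5ad requires a 'python' interpreter with ",
                     "the anndata package on the PATH")
  out_prefix <- tempfile("h5ad_export_")
  script <- sprintf('
import sys
import anndata, scipy.sparse, scipy.io, numpy as np
ad = anndata.read_h5ad(sys.argv[1])
layer = sys.argv[3]
X = ad.X if layer == "" else ad.layers[layer]
X = scipy.sparse.csr_matrix(X)
scipy.io.mmwrite(sys.argv[2] + ".mtx", X)
with open(sys.argv[2] + ".mtx.cells.txt", "w") as fh:
    fh.write("\\n".join(map(str, ad.obs_names)) + "\\n")
with open(sys.argv[2] + ".mtx.genes.txt", "w") as fh:
    fh.write("\\n".join(map(str, ad.var_names)) + "\\n")
')
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  res <- system2(py, c(sf, shQuote(path), shQuote(out_prefix),
                       shQuote(if (is.null(layer)) "" else layer)),
                 stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(res, "status")) && attr(res, "status") != 0)
    stop("h5ad export failed: ", paste(res, collapse = "\n"))
  mtx <- paste0(out_prefix, ".mtx")
  # obs are rows in AnnData, so the exported matrix is already cells x genes
  read_counts_mtx(mtx)
}

#' Attach per-cell labels from a two-column file
#'
#' Reads a delimited file of (cell id, label) rows and attaches the labels to
#' a \code{CountMatrix} in its cell order. Every cell must appear exactly
#' once; partial labeling is modeled downstream by the labeled-fraction mask,
#' not by missing rows.
#'
#' @param path two-column delimited file (header optional).
#' @param cm a \code{\link{count_matrix}}.
#' @return \code{cm} with \code{labels} set.
#' @export
read_labels <- function(path, cm) {
  stopifnot(inherits(cm, "CountMatrix"))
  dt <- data.table::fread(path, header = "auto",
                          colClasses = list(character = 1:2))
  if (ncol(dt) < 2) stop("label file must have two columns (cell id, label)")
  ids <- as.character(dt[[1]])
  labs <- as.character(dt[[2]])
  extra <- setdiff(ids, cm$cell_ids)
  if (length(extra) > 0)
    stop("label file contains unknown cell id(s): ",
         paste(utils::head(extra, 10), collapse = ", "))
  missing <- setdiff(cm$cell_ids, ids)
  if (length(missing) > 0)
    stop("label file is missing ", length(missing), " cell(s): ",
         paste(utils::head(missing, 10), collapse = ", "))
  if (anyDuplicated(ids))
    stop("label file lists cell(s) more than once: ",
         paste(utils::head(unique(ids[duplicated(ids)]), 10), collapse = ", "))
  cm$labels <- labs[match(cm$cell_ids, ids)]
  cm
}

#' Prepare model inputs from raw counts
#'
#' Filters weakly expressed genes, computes per-cell size factors, and builds
#' the standardized encoder input while keeping the raw counts as the ZINB
#' reconstruction target.
#'
#' Size factor = library size / median library size, so the median cell has
#' size factor 1 and the decoder mean stays on the raw count scale. The
#' encoder input is the per-gene z-score of \code{log1p(count / size_factor)};
#' genes with zero variance after the transform are mapped to all-zero columns
#' rather than dropped, keeping the gene index stable.
#'
#' @param cm a \code{\link{count_matrix}}.
#' @param min_gene_counts genes with total count below this are removed
#'   (default 1 keeps every gene expressed at least once).
#' @param n_top_genes optional number of most-variable genes to retain
#'   (variance of the log1p-normalized expression); \code{NULL} keeps all.
#' @return a list of class \code{PreprocessedData}: \code{x_input} (cells x
#'   genes, standardized), \code{x_raw} (raw counts, same shape),
#'   \code{size_factors}, \code{kept_gene_index} (positions in the original
#'   gene vector), \code{cell_ids}, \code{gene_ids}, \code{labels}.
#' @export
preprocess <- function(cm, min_gene_counts = 1, n_top_genes = NULL) {
  stopifnot(inherits(cm, "CountMatrix"))
  counts <- cm$counts
  if (nrow(counts) == 0 || ncol(counts) == 0) stop("empty count matrix")
  keep <- which(colSums(counts) >= min_gene_counts)
  if (length(keep) == 0) stop("all genes removed by min_gene_counts = ",
                              min_gene_counts)
  counts <- counts[, keep, drop = FALSE]

  lib <- rowSums(counts)
  med <- stats::median(lib)
  if (med <= 0) stop("median library size is zero; cannot form size factors")
  sf <- lib / med
  sf[sf <= 0] <- 1e-8  # cells with empty libraries; keep positive

  norm <- log1p(counts / sf)
  if (!is.null(n_top_genes) && n_top_genes < ncol(norm)) {
    v <- apply(norm, 2, stats::var)
    top <- order(v, decreasing = TRUE)[seq_len(n_top_genes)]
    top <- sort(top)
    keep <- keep[top]
    counts <- counts[, top, drop = FALSE]
    norm <- norm[, top, drop = FALSE]
  }

  mu <- colMeans(norm)
  sd <- apply(norm, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- Inf  # zero-variance guard -> all-zero column
  x_input <- sweep(sweep(norm, 2, mu, "-"), 2, sd, "/")

  structure(list(x_input = x_input, x_raw = counts, size_factors = sf,
                 kept_gene_index = keep, cell_ids = cm$cell_ids,
                 gene_ids = cm$gene_ids[keep], labels = cm$labels),
            class = "PreprocessedData")
}

#' Write clustering results to disk
#'
#' @param labels per-cell cluster labels (integer or character).
#' @param embedding cells x d numeric matrix (latent coordinates).
#' @param path_prefix output prefix; writes \code{<prefix>.labels.tsv}
#'   (cell id, label) and \code{<prefix>.embedding.tsv} (cell id + d columns).
#' @param cell_ids cell identifiers; default \code{rownames(embedding)} or
#'   \code{cell1..n}.
#' @return invisibly, the two file paths.
#' @export
write_results <- function(labels, embedding, path_prefix, cell_ids = NULL) {
  if (length(labels) == 0) stop("empty label vector")
  embedding <- as.matrix(embedding)
  if (length(labels) != nrow(embedding))
    stop("labels length (", length(labels),
         ") != embedding rows (", nrow(embedding), ")")
  if (is.null(cell_ids)) cell_ids <- rownames(embedding)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_along(labels))
  lab_path <- paste0(path_prefix, ".labels.tsv")
  emb_path <- paste0(path_prefix, ".embedding.tsv")
  data.table::fwrite(data.table::data.table(cell_id = cell_ids,
                                            label = labels),
                     lab_path, sep = "\t")
  emb <- data.table::data.table(cell_id = cell_ids)
  for (j in seq_len(ncol(embedding)))
    emb[[paste0("dim", j)]] <- embedding[, j]
  data.table::fwrite(emb, emb_path, sep = "\t")
  invisible(c(labels = lab_path, embedding = emb_path))
}

#' Write a CountMatrix to disk
#'
#' Companion writer for \code{\link{read_counts}}; used by the CLI simulator.
#'
#' @param cm a \code{\link{count_matrix}}.
#' @param path_prefix output prefix.
#' @param format \code{"csv"} (dense, header = gene ids, first column = cell
#'   ids) or \code{"mtx"} (sparse triplet + \code{.cells.txt}/\code{.genes.txt}
#'   sidecars).
#' @return invisibly, the main file path.
#' @export
write_counts <- function(cm, path_prefix, format = c("csv", "mtx")) {
  stopifnot(inherits(cm, "CountMatrix"))
  format <- match.arg(format)
  if (format == "csv") {
    path <- paste0(path_prefix, ".csv")
    dt <- data.table::data.table(cell_id = cm$cell_ids)
    dtm <- data.table::as.data.table(cm$counts)
    data.table::fwrite(cbind(dt, dtm), path)
  } else {
    path <- paste0(path_prefix, ".mtx")
    Matrix::writeMM(Matrix::Matrix(cm$counts, sparse = TRUE), path)
    writeLines(cm$cell_ids, paste0(path, ".cells.txt"))
    writeLines(cm$gene_ids, paste0(path, ".genes.txt"))
  }
  if (!is.null(cm$labels))
    data.table::fwrite(data.table::data.table(cell_id = cm$cell_ids,
                                              label = cm$labels),
                       paste0(path_prefix, ".labels.tsv"), sep = "\t")
  invisible(path)
}
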