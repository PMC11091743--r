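test_that("CountMatrix validation rejects malformed input", {
  m <- matrix(c(1, 0, 2, 3), 2, 2)
  expect_s3_class(count_matrix(m), "CountMatrix")
  expect_error(count_matrix(matrix(c(1, -1, 0, 2), 2, 2)), "negative")
  expect_error(count_matrix(matrix(c(1, 0.5, 0, 2), 2, 2)), "integer")
  expect_error(count_matrix(m, cell_ids = c("a", "a")), "duplicate cell_ids")
  expect_error(count_matrix(m, gene_ids = c("g", "g")), "duplicate gene_ids")
  expect_error(count_matrix(m, labels = "only-one"), "one value per cell")
})

test_that("CSV round-trip preserves counts, ids, and labels", {
  cm <- tiny_cm()
  pfx <- file.path(withr::local_tempdir(), "counts")
  write_counts(cm, pfx, format = "csv")
  cm2 <- read_counts(paste0(pfx, ".csv"))
  expect_equal(unname(cm2$counts), unname(cm$counts))
  expect_equal(cm2$cell_ids, cm$cell_ids)
  expect_equal(cm2$gene_ids, cm$gene_ids)
  cm2 <- read_labels(paste0(pfx, ".labels.tsv"), cm2)
  expect_equal(cm2$labels, cm$labels)
})

test_that("small CSV parses to the expected shape and negatives error", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "m.csv")
  writeLines(c("id,g1,g2", "c1,1,2", "c2,0,3", "c3,4,0"), f)
  cm <- read_counts(f)
  expect_equal(dim(cm), c(3L, 2L))
  expect_equal(cm$gene_ids, c("g1", "g2"))
  f2 <- file.path(dir, "neg.csv")
  writeLines(c("id,g1,g2", "c1,1,-1"), f2)
  expect_error(read_counts(f2), "negative")
})

test_that("MTX orientation is fixed from the sidecar name files", {
  cm <- tiny_cm()
  dir <- withr::local_tempdir()
  pfx <- file.path(dir, "counts")
  write_counts(cm, pfx, format = "mtx")
  cm2 <- read_counts(paste0(pfx, ".mtx"))
  expect_equal(unname(cm2$counts), unname(cm$counts))

  # write the transposed (genes x cells) dialect with the same sidecars
  pfx_t <- file.path(dir, "counts_t")
  Matrix::writeMM(Matrix::Matrix(t(cm$counts), sparse = TRUE),
                  paste0(pfx_t, ".mtx"))
  writeLines(cm$cell_ids, paste0(pfx_t, ".mtx.cells.txt"))
  writeLines(cm$gene_ids, paste0(pfx_t, ".mtx.genes.txt"))
  cm3 <- read_counts(paste0(pfx_t, ".mtx"))
  expect_equal(unname(cm3$counts), unname(cm$counts))
})

test_that("h5ad files written by anndata are read back correctly", {
  skip_if(Sys.which("python") == "", "no python on PATH")
  cm <- tiny_cm()
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "m.csv")
  write_counts(cm, file.path(dir, "m"), format = "csv")
  h5 <- file.path(dir, "m.h5ad")
  script <- sprintf('
import pandas as pd, anndata, numpy as np
df = pd.read_csv(%s, index_col=0)
ad = anndata.AnnData(X=df.values.astype("float32"))
ad.obs_names = df.index.astype(str); ad.var_names = df.columns.astype(str)
ad.write_h5ad(%s)
', shQuote(csv), shQuote(h5))
  sf <- file.path(dir, "mk.py")
  writeLines(script, sf)
  res <- suppressWarnings(system2("python", sf, stdout = TRUE, stderr = TRUE))
  skip_if(!file.exists(h5), "anndata unavailable")
  cm2 <- read_counts(h5)
  expect_equal(unname(cm2$counts), unname(cm$counts))
  expect_equal(cm2$cell_ids, cm$cell_ids)
})

test_that("read_labels requires exact cell coverage", {
  cm <- tiny_cm()
  dir <- withr::local_tempdir()
  ok <- file.path(dir, "ok.tsv")
  writeLines(c("cell\tlabel", paste(cm$cell_ids, cm$labels, sep = "\t")), ok)
  expect_equal(read_labels(ok, cm)$labels, cm$labels)

  miss <- file.path(dir, "miss.tsv")
  writeLines(paste(cm$cell_ids[-1], cm$labels[-1], sep = "\t"), miss)
  expect_error(read_labels(miss, cm), "missing")

  ghost <- file.path(dir, "ghost.tsv")
  writeLines(c(paste(cm$cell_ids, cm$labels, sep = "\t"), "ghost\tA"), ghost)
  expect_error(read_labels(ghost, cm), "ghost")
})

test_that("preprocess filters genes, sets size factors, guards zero variance", {
  # three cells with library sizes 4, 4, 8 -> median 4
  m <- rbind(c(2, 0, 2, 0), c(1, 0, 3, 0), c(4, 0, 4, 0))
  cm <- count_matrix(m)
  pd <- preprocess(cm, min_gene_counts = 1)
  expect_s3_class(pd, "PreprocessedData")
  expect_equal(unname(pd$kept_gene_index), c(1L, 3L))
  expect_equal(ncol(pd$x_raw), 2)      # all-zero columns dropped
  expect_equal(unname(pd$size_factors), c(1, 1, 2))
  expect_equal(unname(median(pd$size_factors)), 1)
  expect_identical(dim(pd$x_input), dim(pd$x_raw))

  # constant normalized gene (equal library sizes) -> all-zero z-scores
  m2 <- rbind(c(5, 1, 2), c(5, 2, 1), c(5, 0, 3))
  pd2 <- preprocess(count_matrix(m2))
  expect_true(all(pd2$x_input[, 1] == 0))
  expect_error(preprocess(count_matrix(matrix(0, 2, 2))), "all genes")
})

test_that("preprocess is deterministic and stable to all-zero gene removal", {
  cm <- tiny_cm()
  pd1 <- preprocess(cm)
  pd2 <- preprocess(cm)
  expect_identical(pd1, pd2)

  with_zero <- count_matrix(cbind(cm$counts, zz = 0),
                            cell_ids = cm$cell_ids,
                            gene_ids = c(cm$gene_ids, "zz"))
  pd3 <- preprocess(with_zero)
  expect_equal(unname(pd3$x_input), unname(pd1$x_input))
})

test_that("write_results emits matching label and embedding files", {
  dir <- withr::local_tempdir()
  pfx <- file.path(dir, "res")
  emb <- matrix(rnorm(6), 3, 2)
  write_results(c(1, 2, 1), emb, pfx, cell_ids = c("a", "b", "c"))
  lab <- data.table::fread(paste0(pfx, ".labels.tsv"))
  expect_equal(nrow(lab), 3)
  expect_equal(lab$label, c(1, 2, 1))
  e <- data.table::fread(paste0(pfx, ".embedding.tsv"))
  expect_equal(dim(e), c(3L, 3L))
  expect_error(write_results(integer(0), emb[0, , drop = FALSE], pfx),
               "empty")
  expect_error(write_results(1:2, emb, pfx), "rows")
})
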