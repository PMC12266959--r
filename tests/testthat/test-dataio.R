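test_that("MTX and TSV round-trips reproduce the matrix exactly", {
  pair <- small_pair(n_genes = 40L, n_source = 15L, n_target = 10L)
  ds <- pair$source
  dir <- withr::local_tempdir()
  write_dataset(ds, file.path(dir, "mtx"), "mtx")
  back <- read_dataset(file.path(dir, "mtx"),
                       labels_path = file.path(dir, "mtx", "labels.tsv"))
  expect_equal(unname(back$matrix), unname(ds$matrix))
  expect_identical(back$gene_names, ds$gene_names)
  expect_identical(back$cell_ids, ds$cell_ids)
  expect_identical(back$labels, ds$labels)

  write_dataset(ds, file.path(dir, "dense.tsv"), "tsv")
  back2 <- read_dataset(file.path(dir, "dense.tsv"), "genes_by_cells")
  expect_equal(unname(back2$matrix), unname(ds$matrix))
})

test_that("a hand-written MTX file is read with its exact entries", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "4 3 5", "1 1 7", "2 1 1", "4 2 3", "3 3 2", "1 3 9"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("g1", "g2", "g3", "g4"), file.path(dir, "genes.tsv"))
  writeLines(c("c1", "c2", "c3"), file.path(dir, "barcodes.tsv"))
  ds <- read_dataset(dir)
  expect_equal(dim(ds$matrix), c(3, 4))
  expect_equal(ds$matrix["c1", "g1"], 7)
  expect_equal(ds$matrix["c2", "g4"], 3)
  expect_equal(ds$matrix["c3", "g1"], 9)
  expect_equal(sum(ds$matrix), 22)
})

test_that("label files must cover every cell, and the error names the cell", {
  dir <- withr::local_tempdir()
  ds <- small_pair(n_genes = 10L, n_source = 5L, n_target = 5L)$source
  write_dataset(ds, file.path(dir, "d"), "mtx")
  lab <- utils::read.table(file.path(dir, "d", "labels.tsv"), sep = "\t")
  utils::write.table(lab[-3, ], file.path(dir, "d", "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  expect_error(read_dataset(file.path(dir, "d"),
                            labels_path = file.path(dir, "d", "labels.tsv")),
               ds$cell_ids[3], fixed = TRUE)
})

test_that("TPM normalization follows the length-corrected formula", {
  ds <- expression_dataset(matrix(c(2, 8), 1, 2), c("g1", "g2"), "c1")
  # unit lengths: proportions of the depth
  t1 <- tpm_normalize(ds)
  expect_equal(unname(t1$matrix[1, ]), c(200000, 800000))
  # lengths (2, 1): rates (1, 8) -> (1/9, 8/9) of a million
  t2 <- tpm_normalize(ds, gene_lengths = c(2, 1))
  expect_equal(unname(t2$matrix[1, ]), c(1e6 / 9, 8e6 / 9))
  # every cell sums to one million
  pair <- small_pair(n_genes = 30L, n_source = 12L, n_target = 8L)
  tp <- tpm_normalize(pair$source)
  expect_equal(unname(rowSums(tp$matrix)), rep(1e6, 12), tolerance = 1e-6)
  # degenerate cell is an error
  z <- expression_dataset(matrix(c(0, 0, 1, 2), 2, 2, byrow = TRUE),
                          c("g1", "g2"), c("c1", "c2"))
  expect_error(tpm_normalize(z), "zero total")
})

test_that("log-normalization matches its closed form and properties", {
  ds <- expression_dataset(matrix(c(1, 1), 1, 2), c("g1", "g2"), "c1")
  ln <- lognorm(ds, preprocess_config(scale_factor = 10000))
  expect_equal(unname(ln$matrix[1, ]), rep(log(5001), 2))
  pair <- small_pair(n_genes = 30L, n_source = 12L, n_target = 8L)
  ln2 <- lognorm(pair$source)
  expect_true(all(is.finite(ln2$matrix)) && all(ln2$matrix >= 0))
  # all-zero gene stays zero
  m <- pair$source$matrix
  m[, 5] <- 0
  ds3 <- expression_dataset(m, pair$source$gene_names, pair$source$cell_ids)
  expect_true(all(lognorm(ds3)$matrix[, 5] == 0))
})

test_that("HVG selection recovers planted variable genes and aligns domains", {
  set.seed(77)
  n <- 60; g <- 50
  # flat genes span a range of means so the mean-variance trend is anchored
  flat_means <- exp(seq(log(5), log(120), length.out = g))
  base <- vapply(flat_means, function(mu) rpois(n, mu), numeric(n))
  # planted genes sit in the interior of the mean range, so the trend
  # around them is anchored by flat genes
  planted <- c(10L, 13L, 16L, 19L, 22L, 25L, 28L, 31L, 34L, 37L)
  groups <- rep(1:2, each = n / 2)
  # planted genes carry a 3x group shift on top of their baseline
  for (j in planted) {
    base[groups == 2, j] <- rpois(sum(groups == 2), 3 * flat_means[j])
  }
  genes <- sprintf("g%02d", 1:g)
  mk <- function(m, dom) {
    expression_dataset(m, genes, sprintf("%s%02d", dom, 1:n), domain =
      if (dom == "s") "source" else "target")
  }
  cfg <- preprocess_config(n_hvg = 10L)
  src <- lognorm(mk(base, "s"), cfg)
  tgt <- lognorm(mk(base, "t"), cfg)
  sel <- select_hvg(src, tgt, cfg)
  expect_setequal(sel$genes, genes[planted])
  expect_identical(sel$source$gene_names, sel$target$gene_names)
  expect_identical(sel$source$layer, "hvg")
  # a gene with constant (log-normalized) values has zero variance and ranks
  # last: with n_hvg = g - 1 it is the one excluded
  lm2 <- src$matrix
  lm2[, 20] <- 1.5
  src2 <- src; src2$matrix <- lm2
  tgt2 <- tgt; tgt2$matrix[, 20] <- 1.5
  cfg2 <- preprocess_config(n_hvg = g - 1L)
  sel2 <- select_hvg(src2, tgt2, cfg2)
  expect_false("g20" %in% sel2$genes)
  # asking for more genes than exist errors with counts
  expect_error(select_hvg(src, tgt, preprocess_config(n_hvg = 51L)), "50")
})

test_that("HVG selection is deterministic", {
  pair <- small_pair(n_genes = 80L, n_source = 30L, n_target = 20L)
  cfg <- preprocess_config(n_hvg = 25L)
  s <- lognorm(pair$source, cfg); t <- lognorm(pair$target, cfg)
  expect_identical(select_hvg(s, t, cfg)$genes, select_hvg(s, t, cfg)$genes)
})

test_that("homolog mapping intersects, aligns and resolves duplicates", {
  a <- expression_dataset(matrix(1:10, 2, 5), sprintf("a%d", 1:5), c("x1", "x2"))
  b <- expression_dataset(matrix(1:12, 2, 6), sprintf("b%d", 1:6), c("y1", "y2"))
  # identity-style table on identical namespaces leaves data unchanged
  ident <- homolog_table(sprintf("a%d", 1:5), sprintf("a%d", 1:5))
  a2 <- expression_dataset(matrix(1:10, 2, 5), sprintf("a%d", 1:5), c("y1", "y2"))
  same <- intersect_homologs(a, a2, ident)
  expect_equal(unname(same$a$matrix), unname(a$matrix))

  tab <- homolog_table(c("a1", "a3", "a5"), c("b2", "b4", "b6"))
  out <- intersect_homologs(a, b, tab)
  expect_identical(out$a$gene_names, c("b2", "b4", "b6"))
  expect_identical(out$b$gene_names, c("b2", "b4", "b6"))
  expect_equal(unname(out$a$matrix[, 1]), unname(a$matrix[, 1]))   # a1 -> b2
  expect_equal(unname(out$b$matrix[, 1]), unname(b$matrix[, 2]))

  # one-to-many rows: first pair by file order wins; duplicate targets dropped.
  # brute-force oracle: scan rows, keep a pair iff neither gene was seen.
  dup <- homolog_table(c("a1", "a1", "a2", "a3"), c("b1", "b2", "b1", "b3"))
  seen_a <- character(); seen_b <- character(); keep <- logical(4)
  for (i in 1:4) {
    keep[i] <- !(dup$a[i] %in% seen_a) && !(dup$b[i] %in% seen_b)
    if (keep[i]) { seen_a <- c(seen_a, dup$a[i]); seen_b <- c(seen_b, dup$b[i]) }
  }
  out2 <- intersect_homologs(a, b, dup)
  expect_identical(out2$a$gene_names, dup$b[keep])

  expect_error(intersect_homologs(a, b, homolog_table("zz", "qq")), "no genes")
})

test_that("preprocessing is deterministic end to end", {
  pair <- small_pair(n_genes = 60L, n_source = 25L, n_target = 15L)
  cfg <- preprocess_config(n_hvg = 20L)
  run <- function() {
    sel <- select_hvg(lognorm(pair$source, cfg), lognorm(pair$target, cfg), cfg)
    sel$source$matrix
  }
  expect_identical(run(), run())
})
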