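test_that("DE flagging applies inclusive species-specific thresholds", {
  mouse <- published_mouse_de()
  flagged <- flag_de(mouse)
  expect_true(flagged$de[flagged$gene_symbol == "Abcc3"])   # 1.69, 3.28e-9
  expect_true(flagged$de[flagged$gene_symbol == "Abcc4"])
  expect_true(flagged$de[flagged$gene_symbol == "Cyp1a2"])  # down-regulation counts
  expect_false(flagged$de[flagged$gene_symbol == "Cyp3a11"]) # 0.30, 0.46
  # boundary rows are inside with >=, <= ...
  edge <- de_table(data.frame(gene_symbol = c("a", "b", "c"),
                              log2fc = c(1, 0.999, 1.5),
                              fdr = c(0.05, 0.01, 0.0500001)), "mouse")
  fe <- flag_de(edge)
  expect_identical(fe$de, c(TRUE, FALSE, FALSE))
  # ... and would flip under strict comparators
  expect_false(with(fe[1, ], abs(log2fc) > 1 & fdr < 0.05))
  hb <- flag_de(de_table(data.frame(gene_symbol = "H1x", log2fc = log2(1.5),
                                    fdr = 0.2), "human"))
  expect_true(hb$de)
  # idempotent
  expect_identical(flag_de(flagged)$de, flagged$de)
})

test_that("ortholog collapsing averages log2FC and keeps the bookkeeping", {
  human <- de_table(data.frame(
    gene_symbol = c("A1", "A2", "B", "C"),
    log2fc = c(1, 3, -0.5, 2),
    fdr = c(0.01, 0.2, 0.03, 0.5)
  ), "human")
  map <- data.frame(human_symbol = c("A1", "A2", "B"),
                    mouse_symbol = c("a", "a", "b"))
  out <- collapse_orthologs(human, map)
  expect_equal(out$log2fc[out$gene_symbol == "a"], 2)      # arithmetic mean
  expect_equal(out$fdr[out$gene_symbol == "a"], 0.01)      # min-FDR convention
  expect_equal(out$log2fc[out$gene_symbol == "b"], -0.5)   # one-to-one passthrough
  expect_equal(attr(out, "n_dropped"), 1)                  # C unmapped
  expect_equal(nrow(out) + 0, 2)  # |groups| + dropped accounts for every row
  expect_error(collapse_orthologs(human, map[0, ]), "empty ortholog map")
  expect_error(ortholog_map(data.frame(human_symbol = c("A", "A"),
                                       mouse_symbol = c("x", "y"))),
               "two mouse symbols")
})

test_that("log2FC correlation equals the explicit-sums Pearson formula", {
  expect_equal(correlate_logfc(
    de_table(data.frame(gene_symbol = c("g1", "g2", "g3"), log2fc = c(1, 2, 3),
                        fdr = 0.01), "mouse"),
    de_table(data.frame(gene_symbol = c("g1", "g2", "g3"), log2fc = c(2, 4, 6),
                        fdr = 0.01), "human"))$r, 1)
  expect_equal(correlate_logfc(
    de_table(data.frame(gene_symbol = c("g1", "g2", "g3"), log2fc = c(1, 2, 3),
                        fdr = 0.01), "mouse"),
    de_table(data.frame(gene_symbol = c("g1", "g2", "g3"), log2fc = c(-2, -4, -6),
                        fdr = 0.01), "human"))$r, -1)
  # brute-force oracle on random tables
  set.seed(31)
  for (rep in 1:5) {
    n <- 40
    genes <- sprintf("g%03d", 1:n)
    x <- rnorm(n); y <- 0.4 * x + rnorm(n)
    res <- correlate_logfc(
      de_table(data.frame(gene_symbol = genes, log2fc = x, fdr = 0.5), "mouse"),
      de_table(data.frame(gene_symbol = genes, log2fc = y, fdr = 0.5), "human"))
    r_brute <- (sum(x * y) - n * mean(x) * mean(y)) /
      sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
    expect_equal(res$r, r_brute, tolerance = 1e-12)
    expect_equal(res$n, n)
  }
  # independent pairs: null correlation
  set.seed(13)
  n <- 1000
  genes <- sprintf("g%04d", 1:n)
  null <- correlate_logfc(
    de_table(data.frame(gene_symbol = genes, log2fc = rnorm(n), fdr = 0.5), "mouse"),
    de_table(data.frame(gene_symbol = genes, log2fc = rnorm(n), fdr = 0.5), "human"))
  expect_lt(abs(null$r), 0.1)
  # gene-set restriction and the minimum-pairs guard
  expect_error(correlate_logfc(
    de_table(data.frame(gene_symbol = genes, log2fc = rnorm(n), fdr = 0.5), "mouse"),
    de_table(data.frame(gene_symbol = genes, log2fc = rnorm(n), fdr = 0.5), "human"),
    gene_set = genes[1:2]), "at least 3")
})

test_that("scaling maps derive 2^log2FC multipliers gated by DE status", {
  sm <- derive_scaling_map(published_mouse_de(), c("Abcc3", "Abcc4", "Cyp3a11"))
  expect_equal(sm$multipliers[["Abcc4"]], 2^3.95, tolerance = 1e-12)
  expect_equal(sm$multipliers[["Abcc3"]], 2^1.69, tolerance = 1e-12)
  expect_equal(sm$multipliers[["Cyp3a11"]], 1)   # not DE -> no scaling
  expect_match(sm$provenance[["Abcc4"]], "from_log2fc")
  expect_identical(sm$provenance[["Cyp3a11"]], "not_de")
  expect_warning(sm2 <- derive_scaling_map(published_mouse_de(), c("Slco1b2")),
                 "absent")
  expect_equal(sm2$multipliers[["Slco1b2"]], 1)
})

test_that("DE tables and ortholog maps read from delimited text", {
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(published_mouse_de(), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  back <- read_de_table(path, "mouse")
  expect_equal(back$log2fc, published_mouse_de()$log2fc)
  expect_identical(attr(back, "species"), "mouse")
  mpath <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(data.frame(human_symbol = "ABCC3", mouse_symbol = "Abcc3"),
                     mpath, sep = ",", row.names = FALSE, quote = FALSE)
  expect_equal(read_ortholog_map(mpath)$mouse_symbol, "Abcc3")
  # malformed tables are rejected
  expect_error(de_table(data.frame(gene_symbol = "g", log2fc = 1, fdr = 1.2),
                        "mouse"), "fdr")
  expect_error(de_table(data.frame(gene_symbol = c("g", "g"), log2fc = 1,
                                   fdr = 0.5), "mouse"), "unique")
})
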