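test_that("DE gene selection applies the strict threshold", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   logFC = c(1, -1, 2, -2),
                   p = c(0.049, 0.05, 0.01, 0.2))
  sel <- select_de_genes(de, alpha = 0.05, prefer_adjusted = FALSE)
  expect_equal(sel, c("A", "C"))   # p = 0.05 excluded, strict <

  # adjusted p preferred when requested and present
  de$adj_p <- c(0.2, 0.2, 0.03, 0.9)
  expect_equal(select_de_genes(de, prefer_adjusted = TRUE), "C")

  # duplicate genes collapse to the smallest nominal p
  dup <- data.frame(gene = c("a", "a"), logFC = c(1, -1), p = c(0.2, 0.01))
  expect_equal(select_de_genes(dup, prefer_adjusted = FALSE), "A")
})

test_that("directional capping keeps the strongest genes per direction", {
  set.seed(14)
  n <- 2000L
  de <- data.frame(
    gene = sprintf("u%04d", 1:(2 * n)),
    logFC = rep(c(1, -1), each = n),
    p = runif(2 * n, 1e-12, 0.049)
  )
  sel <- select_de_genes(de, alpha = 0.05, prefer_adjusted = FALSE,
                         cap = 3000L, per_direction_cap = 1500L)
  expect_length(sel, 3000L)
  up_kept <- sel[sel %in% toupper(de$gene[de$logFC > 0])]
  expect_length(up_kept, 1500L)
  # kept up-genes are exactly the 1500 smallest-p up-regulated ones
  up <- de[de$logFC > 0, ]
  expect_setequal(up_kept,
                  toupper(up$gene[order(up$p, up$gene)][1:1500]))

  # below the cap nothing is trimmed
  small <- de[1:100, ]
  expect_length(select_de_genes(small, prefer_adjusted = FALSE), 100L)

  # capping without any direction information is an input error
  nodir <- de[, c("gene", "p")]
  expect_error(select_de_genes(nodir, prefer_adjusted = FALSE),
               "direction|logFC")
})

test_that("lowering alpha never grows the selected set", {
  set.seed(15)
  de <- data.frame(gene = sprintf("g%03d", 1:200),
                   logFC = rnorm(200), p = runif(200))
  prev <- NULL
  for (alpha in c(0.2, 0.1, 0.05, 0.01)) {
    cur <- select_de_genes(de, alpha = alpha, prefer_adjusted = FALSE)
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("disease profiles compose the stage outputs deterministically", {
  genes <- sprintf("g%02d", 1:30)
  g2p <- data.frame(gene = genes, term = rep(sprintf("P%d", 1:5), each = 6))
  g2f <- data.frame(gene = genes, term = rep(sprintf("F%d", 1:3), times = 10))
  catalog <- annotation_catalog(gene2pathway = g2p, gene2function = g2f)
  ppi <- ppi_table(data.frame(gene_a = c("G01", "G07"),
                              gene_b = c("G25", "G26"),
                              confidence = c(0.99, 0.97)))
  query <- toupper(genes[1:6])  # exactly pathway P1's member set

  prof <- build_disease_profile(query, catalog, ppi, "toy")
  expect_true("P1" %in% prof$pathways)
  expect_true(all(prof$genes %in% prof$ppi_genes))
  expect_setequal(setdiff(prof$ppi_genes, prof$genes), "G25")

  # independent per-tier oracles: upper-tail hypergeometric via dhyper
  # summation, expansion via adjacency scan
  p_oracle <- function(k, K, n, U) sum(stats::dhyper(k:min(n, K), K, U - K, n))
  enr <- enrich_terms(query, "pathway", catalog, fdr_cutoff = 1.1)
  for (i in seq_len(nrow(enr))) {
    expect_equal(enr$p[i], p_oracle(enr$k[i], enr$K[i], 6, 30),
                 tolerance = 1e-12)
  }
  expect_equal(prof$pathways, sort(enr$term[enr$q < 0.25]))

  # no PPI edges -> expansion adds nothing
  prof2 <- build_disease_profile(query, catalog, ppi[0, ], "toy")
  expect_equal(prof2$ppi_genes, sort(query))

  # purity: identical inputs give identical profiles
  expect_identical(prof, build_disease_profile(query, catalog, ppi, "toy"))

  # empty gene set warns and yields empty tiers
  expect_warning(p0 <- build_disease_profile(character(), catalog, ppi), "empty")
  expect_length(p0$genes, 0L)
})

test_that("drug profiles annotate direct plus PPI-expanded targets", {
  catalog <- tiny_catalog()
  ppi <- ppi_table(data.frame(gene_a = "G1", gene_b = "G3", confidence = 1))
  dt <- data.frame(drug_id = c("dA", "dA", "dB"),
                   gene_symbol = c("G1", "G2", "G4"),
                   source = "predicted", rank_at_target = 1L)
  profs <- suppressWarnings(build_drug_profiles(dt, catalog, ppi))
  expect_named(profs, c("dA", "dB"))
  expect_equal(profs$dA$genes, c("G1", "G2"))
  expect_equal(profs$dA$ppi_genes, c("G1", "G2", "G3"))  # one hop via G1-G3
  expect_equal(profs$dB$ppi_genes, "G4")
})
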