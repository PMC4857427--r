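test_that("structure collapsing deduplicates drug-gene pairs with best rank", {
  map <- data.frame(structure_id = c("S1", "S2", "S3", "S4"),
                    protein_accession = c("P1", "P1", "P2", "P2"),
                    gene_symbol = c("EGFR", "EGFR", "KRAS", "KRAS"))
  hits <- data.frame(target_id = c("S1", "S2"),
                     ligand_id = c("X", "X"), rank = c(3L, 1L))
  dt <- collapse_structures(hits, map)
  expect_equal(nrow(dt), 1L)
  expect_equal(dt$gene_symbol, "EGFR")
  expect_equal(dt$rank_at_target, 1L)

  # empty hit set
  empty <- collapse_structures(hits[0, ], map)
  expect_equal(nrow(empty), 0L)

  # 3 drugs x 4 structures -> 2 genes: distinct pairs counted by hand
  hits3 <- expand.grid(target_id = map$structure_id,
                       ligand_id = c("X", "Y", "W"),
                       stringsAsFactors = FALSE)
  hits3$rank <- seq_len(nrow(hits3))
  dt3 <- collapse_structures(hits3, map)
  pairs_by_hand <- unique(data.frame(
    drug = hits3$ligand_id,
    gene = map$gene_symbol[match(hits3$target_id, map$structure_id)]))
  expect_equal(nrow(dt3), nrow(pairs_by_hand))  # 3 drugs x 2 genes = 6

  # unmapped structures go to the rejects report, not an error
  hits_bad <- data.frame(target_id = c("S1", "S9"),
                         ligand_id = c("X", "X"), rank = c(1L, 1L))
  expect_warning(dt_bad <- collapse_structures(hits_bad, map), "rejected")
  expect_equal(attr(dt_bad, "rejects"), "S9")
  expect_equal(nrow(dt_bad), 1L)
})

test_that("PPI filtering applies inclusive cutoff and endpoint membership", {
  ppi <- data.frame(gene_a = c("A", "A", "A", "B"),
                    gene_b = c("B", "C", "D", "C"),
                    confidence = c(0.96, 0.96, 0.94, 0.95))
  known <- c("A", "B", "D")
  kept <- filter_ppi(ppi, 0.95, known)
  expect_equal(nrow(kept), 1L)             # A-B kept
  expect_equal(kept$gene_a, "A")
  # A-C dropped (C unknown), A-D dropped (0.94 < 0.95), B-C dropped (C unknown)
  kept_all <- filter_ppi(ppi, 0.95)
  expect_equal(nrow(kept_all), 3L)         # boundary 0.95 is inclusive

  # duplicate unordered pairs keep the maximum confidence; self-loops drop
  dup <- ppi_table(data.frame(gene_a = c("A", "B", "C"),
                              gene_b = c("B", "A", "C"),
                              confidence = c(0.7, 0.9, 1)))
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$confidence, 0.9)
})

test_that("gene-list expansion adds exactly one PPI hop", {
  ppi <- ppi_table(data.frame(gene_a = c("A", "B", "B"),
                              gene_b = c("C", "D", "E"),
                              confidence = c(1, 1, 1)))
  expect_equal(expand_gene_list(c("A", "B"), ppi),
               c("A", "B", "C", "D", "E"))
  expect_equal(expand_gene_list("A", ppi[0, ]), "A")

  # brute-force adjacency-scan oracle on a random 20-gene fixture
  set.seed(5)
  genes <- sprintf("g%02d", 1:20)
  edges <- data.frame(gene_a = sample(genes, 30, TRUE),
                      gene_b = sample(genes, 30, TRUE),
                      confidence = 1)
  edges <- edges[edges$gene_a != edges$gene_b, ]
  tab <- ppi_table(edges)
  direct <- sample(genes, 5)
  oracle <- toupper(direct)
  for (i in seq_len(nrow(tab))) {
    if (tab$gene_a[i] %in% toupper(direct)) oracle <- c(oracle, tab$gene_b[i])
    if (tab$gene_b[i] %in% toupper(direct)) oracle <- c(oracle, tab$gene_a[i])
  }
  expect_equal(expand_gene_list(direct, tab), sort(unique(oracle)))

  # monotone in the seed set
  sub <- expand_gene_list(direct[1:2], tab)
  expect_true(all(sub %in% expand_gene_list(direct, tab)))

  # two applications walk two hops, not one: chain A-B-C-D
  chain <- ppi_table(data.frame(gene_a = c("A", "B", "C"),
                                gene_b = c("B", "C", "D"),
                                confidence = 1))
  one <- expand_gene_list("A", chain)
  two <- expand_gene_list(one, chain)
  expect_equal(one, c("A", "B"))
  expect_equal(two, c("A", "B", "C"))
})

test_that("term enrichment matches exhaustive draw enumeration", {
  # universe of 20 genes; term holds 5; query of 5 overlaps all 5
  genes <- sprintf("g%02d", 1:20)
  g2p <- data.frame(gene = genes,
                    term = rep(c("T1", "T2", "T3", "T4"), each = 5))
  catalog <- annotation_catalog(gene2pathway = g2p)
  res <- enrich_terms(toupper(genes[1:5]), "pathway", catalog,
                      fdr_cutoff = 0.25)
  expect_equal(res$term[1L], "T1")
  expect_equal(res$k[1L], 5L)
  # oracle: enumerate every C(20,5) draw, count those overlapping T1 in >= 5
  expect_equal(res$p[1L], enum_upper_tail(20, 5, 5, 5), tolerance = 1e-12)

  # gene set exactly equal to one term's member set tops the list
  res2 <- enrich_terms(toupper(genes[6:10]), "pathway", catalog, 0.25)
  expect_equal(res2$term[1L], "T2")

  # no overlapping term passes the cutoff
  catalog_small <- annotation_catalog(
    gene2pathway = data.frame(gene = c("A", "B", "X", "Y"),
                              term = c("T1", "T1", "T2", "T2")))
  none <- enrich_terms(c("X", "Y"), "pathway", catalog_small, 0.05)
  expect_true(all(none$term != "T1"))

  # query genes outside the namespace universe are dropped with a warning
  expect_warning(enrich_terms(c(toupper(genes[1:3]), "NOPE"), "pathway",
                              catalog), "dropped")
})

test_that("BH q-values are monotone in the p-value ordering", {
  set.seed(9)
  genes <- sprintf("g%02d", 1:30)
  g2p <- data.frame(gene = sample(genes, 60, TRUE),
                    term = sample(sprintf("T%d", 1:8), 60, TRUE))
  catalog <- annotation_catalog(gene2pathway = g2p)
  res <- suppressWarnings(  # some sampled query genes are unmapped
    enrich_terms(sample(toupper(genes), 10), "pathway", catalog,
                 fdr_cutoff = 1.0000001))
  expect_true(nrow(res) > 0L)
  expect_true(all(diff(res$q) >= -1e-12))
  expect_true(all(res$q >= res$p - 1e-12))
})
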