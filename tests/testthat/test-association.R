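test_that("hypergeometric overlap test matches enumeration on small universes", {
  u <- sprintf("i%02d", 1:10)
  res <- hypergeom_overlap_test(u[c(1, 2, 3, 6)], u[1:5], u)
  expect_equal(res$k, 3L)
  expect_equal(res$p, enum_upper_tail(10, 5, 4, 3), tolerance = 1e-12)

  # exhaustive draw: p = 1
  all_drawn <- hypergeom_overlap_test(u, u[1:5], u)
  expect_equal(all_drawn$k, 5L)
  expect_equal(all_drawn$p, 1)

  # zero overlap: P(X >= 0) = 1
  expect_equal(hypergeom_overlap_test(u[6:7], u[1:3], u)$p, 1)

  # empty drug set flags "no evidence" with p = 1
  empty <- hypergeom_overlap_test(character(), u[1:3], u)
  expect_true(empty$no_evidence)
  expect_equal(empty$p, 1)

  # out-of-universe items are dropped (with warning)
  expect_warning(out <- hypergeom_overlap_test(c(u[1], "zz"), u[1:3], u),
                 "dropped")
  expect_equal(out$n_drug, 1L)
})

test_that("overlap p-value is monotone decreasing in k at fixed margins", {
  u <- sprintf("i%02d", 1:20)
  p_at_k <- vapply(0:5, function(k) {
    drug <- c(u[seq_len(k)], u[8 + seq_len(5 - k)])  # size 5, overlap k
    hypergeom_overlap_test(drug, u[1:8], u)$p
  }, numeric(1L))
  expect_true(all(diff(p_at_k) < 0))
})

test_that("tier normalization maps the most significant drug to exactly 1", {
  p <- c(d1 = 1e-8, d2 = 1e-4, d3 = 0.2)
  expect_equal(normalize_tier(p), c(d1 = 1, d2 = 0.5, d3 = 0))
  expect_equal(normalize_tier(c(only = 0.01)), c(only = 1))
  expect_equal(normalize_tier(c(a = 0.05, b = 0.8)), c(a = 0, b = 0))
  expect_warning(clamped <- normalize_tier(c(a = 0, b = 0.2)), "clamped")
  expect_equal(unname(clamped), c(1, 0))

  set.seed(8)
  for (i in 1:10) {
    p <- setNames(10^runif(12, -9, 0), sprintf("d%02d", 1:12))
    v <- normalize_tier(p)
    expect_true(all(v >= 0 & v <= 1))
    sig <- p < 0.05
    if (any(sig)) {
      expect_equal(max(v), 1)
      # monotone decreasing in p among significant drugs
      o <- order(p[sig])
      expect_true(all(diff(v[sig][o]) <= 1e-12))
    } else {
      expect_true(all(v == 0))
    }
    expect_true(all((v == 0) == (p >= 0.05)))
  }
})

test_that("association Z-score respects the tier weights and their bound", {
  ones <- setNames(rep(1, 2), c("x", "y"))
  z_all <- drug_disease_z(list(A = ones, B = ones, C = ones, D = ones))
  expect_equal(z_all$z, c(2 + 1 + 0.5 + 0.25, 3.75))
  zeros <- setNames(rep(0, 1), "x")
  expect_equal(drug_disease_z(list(A = zeros, B = zeros, C = zeros,
                                   D = zeros))$z, 0)
  mix <- drug_disease_z(list(A = c(x = 1), B = c(x = 0), C = c(x = 1),
                             D = c(x = 0)))
  expect_equal(mix$z, 2.5)

  # drugs missing from a tier contribute 0 for it
  partial <- drug_disease_z(list(A = c(x = 1), B = c(y = 1),
                                 C = setNames(numeric(), character()),
                                 D = setNames(numeric(), character())))
  expect_equal(partial$z[partial$drug_id == "x"], 2)
  expect_equal(partial$z[partial$drug_id == "y"], 1)

  # gene-tier-only significance outranks all-indirect significance
  tiers <- list(A = c(gene_only = 1, indirect = 0),
                B = c(gene_only = 0, indirect = 1),
                C = c(gene_only = 0, indirect = 1),
                D = c(gene_only = 0, indirect = 1))
  ranked <- rank_drugs(drug_disease_z(tiers))
  expect_equal(ranked$drug_id, c("gene_only", "indirect"))
  expect_equal(ranked$z, c(2, 1.75))
})

test_that("drug ranking is deterministic with documented tie-breaks", {
  sc <- data.frame(drug_id = c("x", "y", "w"), z = c(3, 1, 2))
  expect_equal(rank_drugs(sc)$drug_id, c("x", "w", "y"))

  ties <- data.frame(drug_id = c("b", "a", "c"), z = c(1, 1, 1),
                     p_gene = c(0.5, 0.5, 0.01))
  expect_equal(rank_drugs(ties)$drug_id, c("c", "a", "b"))

  set.seed(44)
  fifty <- data.frame(drug_id = sprintf("d%02d", 1:50), z = runif(50))
  ranked <- rank_drugs(fifty)
  expect_equal(ranked$drug_id,
               fifty$drug_id[order(-fifty$z, fifty$drug_id)])
  expect_equal(ranked$rank, 1:50)
})

test_that("consensus lists re-rank the union of per-study top drugs by mean Z", {
  r1 <- data.frame(drug_id = c("a", "b", "c"), z = c(3, 2, 1), rank = 1:3)
  expect_equal(consensus_rank(list(r1), top_n = 2)$drug_id, c("a", "b"))

  r2 <- data.frame(drug_id = c("b", "d"), z = c(3, 0.5), rank = 1:2)
  cons <- consensus_rank(list(r1, r2), top_n = 2)
  expect_equal(cons$mean_z[cons$drug_id == "b"], 2.5)
  # 'a' is scored only in study 1: its mean uses that single z
  expect_equal(cons$mean_z[cons$drug_id == "a"], 3)

  # brute-force oracle on two larger rankings
  set.seed(77)
  mk <- function() {
    z <- sort(runif(200), decreasing = TRUE)
    data.frame(drug_id = sample(sprintf("d%03d", 1:300), 200), z = z,
               rank = 1:200)
  }
  ra <- mk(); rb <- mk()
  cons2 <- consensus_rank(list(ra, rb), top_n = 100)
  members <- sort(unique(c(ra$drug_id[ra$rank <= 100],
                           rb$drug_id[rb$rank <= 100])))
  mean_by_hand <- vapply(members, function(d) {
    zs <- c(ra$z[ra$drug_id == d], rb$z[rb$drug_id == d])
    mean(zs)
  }, numeric(1L))
  expect_setequal(cons2$drug_id, members)
  expect_equal(cons2$mean_z,
               unname(sort(mean_by_hand, decreasing = TRUE)),
               tolerance = 1e-12)
  expect_error(consensus_rank(list()), "non-empty")
})

test_that("associating profiles yields per-tier p-values and a full ranking", {
  catalog <- tiny_catalog()
  disease <- make_disease_profile(genes = c("G1", "G2", "G3"),
                                  pathways = "P1", functions = "F2")
  drugs <- list(
    hit = make_drug_profile("hit", genes = c("G1", "G2"), pathways = "P1"),
    miss = make_drug_profile("miss", genes = "G8")
  )
  res <- associate_drugs(drugs, disease, catalog)
  expect_equal(res$drug_id[1L], "hit")
  expect_equal(nrow(res), 2L)
  expect_true(all(c("p_gene", "p_pathway", "p_function", "p_ppi") %in%
                    names(res)))
  # gene tier: universe has 8 genes, disease 3, drug 2, overlap 2
  expect_equal(res$p_gene[res$drug_id == "hit"],
               enum_upper_tail(8, 3, 2, 2), tolerance = 1e-12)
  expect_true(all(res$z >= 0 & res$z <= 3.75))
})
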