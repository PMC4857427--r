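test_that("metric normalization maps the favorable extreme to 1", {
  expect_equal(normalize_metric(c(-10, -5, 0), "lower_better"),
               c(1, 0.5, 0))
  expect_equal(normalize_metric(c(0.2, 0.8, 0.5, 1.4), "higher_better"),
               c(0, 0.5, 0.25, 1))
  # constant column: every value equals the most favorable score present
  expect_equal(normalize_metric(c(3, 3, 3), "higher_better"), c(1, 1, 1))
  expect_equal(normalize_metric(5, "lower_better"), 1)
  expect_error(normalize_metric(numeric(0)), "non-empty")
  expect_error(normalize_metric(c(1, NA)), "finite")

  # idempotence on non-degenerate input
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(10)
    once <- normalize_metric(x, "higher_better")
    expect_equal(normalize_metric(once, "higher_better"), once)
  }
})

test_that("scalar Tanimoto matches the closed form and its identities", {
  expect_equal(scalar_tanimoto(5, 5), 1)
  expect_equal(scalar_tanimoto(2, 4), 8 / 12)
  expect_equal(scalar_tanimoto(0, 0), 1)
  expect_equal(scalar_tanimoto(1, -1), -1 / 3)
  # bounded within [-1/3, 1] over random inputs
  set.seed(3)
  a <- rnorm(200); b <- rnorm(200)
  t <- scalar_tanimoto(a, b)
  expect_true(all(t >= -1 / 3 - 1e-12 & t <= 1 + 1e-12))
  expect_error(scalar_tanimoto(Inf, 1), "finite")
})

test_that("shape dissimilarity is the Euclidean distance", {
  v <- c(0.3, -1, 2)
  expect_equal(shape_similarity(v, v), 0)
  expect_equal(shape_similarity(c(0, 0), c(3, 4)), 5)
  expect_equal(shape_similarity(c(1, 2, 3), c(2, 2, 1)), sqrt(5))
  expect_error(shape_similarity(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("contact similarity is reference-contact recall", {
  expect_equal(contact_similarity(c("A", "B", "C"), c("A", "B", "C")), 1)
  expect_equal(contact_similarity(character(), c("A", "B")), 0)
  expect_equal(contact_similarity(c("A", "B", "D", "E"),
                                  c("A", "B", "C", "F")), 0.5)
  expect_error(contact_similarity(c("A"), character()), "non-empty")
})

test_that("a reference-identical ligand attains the maximal composite score", {
  res <- composite_score(perfect_vs_awful_screen())
  expect_equal(res$z_score[res$ligand_id == "perfect"], 16)  # 4 + 1 + 2 + 8 + 1
  expect_equal(res$z_score[res$ligand_id == "awful"], 0)
  expect_equal(res$rank[res$ligand_id == "perfect"], 1L)

  # literal reading: the contact correction inside the descriptor sum
  res_pd <- composite_score(perfect_vs_awful_screen(),
                            score_weights(cs_mode = "per_descriptor"))
  expect_equal(res_pd$z_score[res_pd$ligand_id == "perfect"],
               4 + 1 + 2 + 8 + 8)
})

test_that("composite score equals a term-by-term oracle on a toy screen", {
  scr <- toy_screen()
  res <- composite_score(scr)
  # oracle: every term evaluated with explicit arithmetic, no package calls
  minmax <- function(x, lower) {
    if (max(x) == min(x)) return(rep(1, length(x)))
    s <- (x - min(x)) / (max(x) - min(x))
    if (lower) 1 - s else s
  }
  tani <- function(a, b) if (a == 0 && b == 0) 1 else a * b / (a^2 + b^2 - a * b)
  dock <- c(-7, -5, -2)
  y <- minmax(dock, lower = TRUE)
  d_pocket <- c(sqrt(1 + 1), sqrt(0 + 4), sqrt(4 + 1))
  d_ref <- c(sqrt(1), sqrt(9), sqrt(8))
  fm <- minmax(d_pocket, lower = TRUE)
  fpm <- minmax(d_ref, lower = TRUE)
  x <- c(max(0, tani(4, 4)) + max(0, tani(2, 1)),
         max(0, tani(2, 4)) + max(0, tani(1, 1)),
         max(0, tani(8, 4)) + max(0, tani(8, 1)))
  cs <- c(2 / 4, 1 / 4, 0)
  z_expected <- 4 * y + 1 * fm + 2 * fpm + x + cs
  got <- res$z_score[match(c("lig1", "lig2", "lig3"), res$ligand_id)]
  expect_equal(got, z_expected, tolerance = 1e-12)
  expect_equal(res$ligand_id[res$rank == 1L],
               c("lig1", "lig2", "lig3")[which.max(z_expected)])
})

test_that("ranking is deterministic under ligand permutation and ties", {
  scr <- toy_screen()
  res1 <- composite_score(scr)
  scr_rev <- target_screen(scr$target_id, scr$reference, scr$pocket_shape,
                           rev(scr$ligands))
  res2 <- composite_score(scr_rev)
  expect_equal(res1[order(res1$ligand_id), ],
               res2[order(res2$ligand_id), ], ignore_attr = TRUE)

  # exact ties break lexicographically by ligand id
  ref <- ligand_record("r", 1, c(0, 0), -5, "R1")
  same <- function(id) ligand_record(id, 1, c(0, 0), -4, "R1")
  res <- composite_score(target_screen("T", ref, c(0, 0),
                                       list(same("b"), same("a"), same("c"))))
  expect_equal(res$ligand_id, c("a", "b", "c"))
})

test_that("improving a component never lowers a ligand's composite score", {
  scr <- toy_screen()
  base <- composite_score(scr)
  # give lig2 one more matching contact (does not touch any normalization)
  ligs <- scr$ligands
  ligs[[2]] <- ligand_record("lig2", c(2, 1), c(0, 3), -5,
                             c("R1", "R2", "R9"))
  improved <- composite_score(target_screen("TOY", scr$reference,
                                            scr$pocket_shape, ligs))
  expect_gte(improved$z_score[improved$ligand_id == "lig2"],
             base$z_score[base$ligand_id == "lig2"])
})

test_that("hit calling takes the top-ranked min(k, n) ligands", {
  res <- data.frame(ligand_id = sprintf("L%d", 1:5),
                    z_score = c(5, 4, 3, 2, 1), rank = 1:5)
  expect_equal(call_hits(res, 2), c("L1", "L2"))
  expect_length(call_hits(res, 40), 5L)
  expect_error(call_hits(res, 0), ">= 1")
  # screens mismatching descriptor counts are rejected up front
  ref <- ligand_record("r", c(1, 2), c(0, 0), -5, "R1")
  bad <- ligand_record("x", c(1, 2, 3), c(0, 0), -4)
  expect_error(target_screen("T", ref, c(0, 0), list(bad)),
               "descriptor count")
})
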