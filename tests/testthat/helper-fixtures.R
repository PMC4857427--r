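# Shared in-code fixtures: tiny screens and catalogs built by hand so
# every expected value can be verified independently.

# a screen whose first ligand is an exact copy of the reference (and has
# the best docking score) and whose second ligand is maximally unlike it
perfect_vs_awful_screen <- function() {
  ref <- ligand_record("ref", descriptors = rep(2, 8), shape = c(1, 2, 3),
                       dock_score = -9, contacts = c("R1", "R2", "R3"))
  perfect <- ligand_record("perfect", descriptors = rep(2, 8),
                           shape = c(1, 2, 3), dock_score = -10,
                           contacts = c("R1", "R2", "R3"))
  # negative descriptors give Tanimoto -1/3 (floored to 0); disjoint
  # contacts; far shape; worst dock score in the screen
  awful <- ligand_record("awful", descriptors = rep(-2, 8),
                         shape = c(9, 9, 9), dock_score = -1,
                         contacts = c("R9"))
  target_screen("T1", ref, pocket_shape = c(1, 2, 3),
                ligands = list(perfect, awful))
}

# three-ligand screen with hand-set components for oracle comparison
toy_screen <- function() {
  ref <- ligand_record("ref", descriptors = c(4, 1), shape = c(0, 0),
                       dock_score = -8, contacts = c("R1", "R2", "R3", "R4"))
  l1 <- ligand_record("lig1", descriptors = c(4, 2), shape = c(1, 0),
                      dock_score = -7, contacts = c("R1", "R2"))
  l2 <- ligand_record("lig2", descriptors = c(2, 1), shape = c(0, 3),
                      dock_score = -5, contacts = c("R1", "R9"))
  l3 <- ligand_record("lig3", descriptors = c(8, 8), shape = c(2, 2),
                      dock_score = -2, contacts = character())
  target_screen("TOY", ref, pocket_shape = c(0, 1),
                ligands = list(l1, l2, l3))
}

tiny_catalog <- function() {
  annotation_catalog(
    gene2disease = data.frame(
      gene = c("G1", "G1", "G2", "G4"),
      term = c("Z1", "Z2", "Z1", "Z3")),
    gene2pathway = data.frame(
      gene = c("G1", "G2", "G3", "G4", "G5"),
      term = c("P1", "P1", "P1", "P2", "P2")),
    gene2function = data.frame(
      gene = c("G1", "G2", "G3", "G4", "G5"),
      term = c("F1", "F2", "F2", "F1", "F2")),
    disease_category = data.frame(
      disease = c("Z1", "Z2", "Z3"),
      category = c("immune", "immune", "neuro")),
    genes = sprintf("G%d", 1:8)
  )
}

# simple deterministic profile builders for association tests
make_drug_profile <- function(id, genes, pathways = character(),
                              functions = character(), ppi_genes = genes) {
  structure(list(drug_id = id, genes = genes, pathways = pathways,
                 functions = functions,
                 ppi_genes = sort(unique(c(genes, ppi_genes)))),
            class = "drug_profile")
}

make_disease_profile <- function(genes, pathways = character(),
                                 functions = character(),
                                 ppi_genes = genes) {
  structure(list(disease_id = "toy", genes = genes, pathways = pathways,
                 functions = functions,
                 ppi_genes = sort(unique(c(genes, ppi_genes)))),
            class = "disease_profile")
}

# independent connected-component oracle (union-find, no igraph)
component_sizes_oracle <- function(nodes, edges_from, edges_to) {
  parent <- seq_along(nodes)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (e in seq_along(edges_from)) {
    ra <- find(match(edges_from[e], nodes))
    rb <- find(match(edges_to[e], nodes))
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_along(nodes), find, integer(1L))
  sort(as.integer(table(roots)), decreasing = TRUE)
}

# exhaustive-enumeration hypergeometric oracle: probability that a
# uniformly drawn size-n subset of 1..U overlaps 1..K in >= k elements
enum_upper_tail <- function(U, K, n, k) {
  if (n == 0L) return(as.numeric(k <= 0))
  m <- combn(U, n)
  ov <- colSums(m <= K)
  mean(ov >= k)
}
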