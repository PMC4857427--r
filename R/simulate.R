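# Seeded synthetic-data generators for every pipeline input: annotation
# catalogs, scored PPI tables, structure maps, per-target screens and
# differential-expression tables, with a plantable ground-truth drug so
# end-to-end recovery is testable offline.

#' Specification of a synthetic study
#'
#' Collects the sizes and signal parameters of a synthetic study. The
#' single integer seed drives independent named streams per artifact
#' (catalog, screens, expression, planting) so each can be regenerated on
#' its own. Defaults describe a desk-scale study: a few hundred genes
#' partitioned into overlapping pathway/function terms, a scored PPI
#' graph, a target panel enriched for the first disease's genes, a shared
#' drug library screened against every target, and case-control
#' differential expression with planted disease genes.
#'
#' @param seed Integer seed.
#' @param n_genes,n_pathways,n_functions,n_diseases,n_drugs,n_targets
#'   Universe sizes (all >= 1).
#' @param n_ligands_per_screen Library size per screen; defaults to
#'   `n_drugs` so ligand ids double as drug ids.
#' @param n_planted_targets Number of targets assigned to the planted
#'   drug.
#' @param ppi_density Fraction of gene pairs carrying a PPI edge, in
#'   \[0, 1\].
#' @param planted_drug_overlap Fraction of the planted drug's targets
#'   drawn from the disease's gene set, in \[0, 1\].
#' @param de_effect Differential-expression signal strength (>= 0):
#'   disease-gene p-values are drawn as `Uniform^(1 + de_effect)`, so 0
#'   makes disease genes indistinguishable from background.
#' @param de_noise Standard deviation of background log fold-changes.
#' @param pathway_overlap Fraction of extra (shared) genes added to each
#'   pathway/function beyond the base partition. Default 0.1.
#' @param n_studies Number of DE studies generated per disease. Default 2.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 300L, n_pathways = 50L,
                         n_functions = 50L, n_diseases = 12L, n_drugs = 60L,
                         n_targets = 40L, n_ligands_per_screen = n_drugs,
                         n_planted_targets = 12L, ppi_density = 0.02,
                         planted_drug_overlap = 0.8, de_effect = 50,
                         de_noise = 1, pathway_overlap = 0.1, n_studies = 2L) {
  counts <- c(n_genes = n_genes, n_pathways = n_pathways,
              n_functions = n_functions, n_diseases = n_diseases,
              n_drugs = n_drugs, n_targets = n_targets,
              n_ligands_per_screen = n_ligands_per_screen,
              n_planted_targets = n_planted_targets, n_studies = n_studies)
  if (any(counts < 1)) stop("all counts must be >= 1")
  stopifnot(ppi_density >= 0, ppi_density <= 1,
            planted_drug_overlap >= 0, planted_drug_overlap <= 1,
            de_effect >= 0, de_noise >= 0,
            pathway_overlap >= 0, pathway_overlap <= 1,
            n_targets <= n_genes)
  spec <- c(list(seed = as.integer(seed)),
            as.list(as.integer(counts)),
            list(ppi_density = ppi_density,
                 planted_drug_overlap = planted_drug_overlap,
                 de_effect = de_effect, de_noise = de_noise,
                 pathway_overlap = pathway_overlap))
  names(spec)[2:10] <- names(counts)
  structure(spec, class = "fixture_spec")
}

# named sub-seed streams derived from the master seed; every generator
# seeds from its own stream so artifacts regenerate independently
stream_seed <- function(seed, stream) {
  streams <- c(catalog = 1L, screen = 2L, expression = 3L, plant = 4L)
  if (!stream %in% names(streams)) stop("unknown stream: ", stream)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  s <- sample.int(2147483646L, max(streams))[streams[[stream]]]
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  s
}

partition_terms <- function(genes, n_terms, prefix, overlap_frac) {
  primary <- sample(rep_len(seq_len(n_terms), length(genes)))
  terms <- sprintf("%s%03d", prefix, primary)
  df <- data.frame(gene = genes, term = terms, stringsAsFactors = FALSE)
  if (overlap_frac > 0 && n_terms > 1L) {
    extra <- lapply(seq_len(n_terms), function(t) {
      tid <- sprintf("%s%03d", prefix, t)
      members <- df$gene[df$term == tid]
      pool <- setdiff(genes, members)
      n_extra <- min(length(pool), ceiling(overlap_frac * length(members)))
      if (n_extra == 0L) return(NULL)
      data.frame(gene = sample(pool, n_extra), term = tid,
                 stringsAsFactors = FALSE)
    })
    df <- rbind(df, do.call(rbind, extra))
  }
  df
}

#' Generate a synthetic annotation catalog, PPI table and structure map
#'
#' Genes are partitioned into pathways and functions with a controlled
#' fraction of shared genes; each disease's gene set is the union of one
#' pathway, one function and a random sprinkle (so disease genes are
#' pathway-coherent, as enrichment assumes); PPI edges are sampled at
#' `ppi_density` with confidence ~ Uniform(0.5, 1); target structures map
#' one-to-one to genes, with a fixed share of targets drawn from the
#' first disease's genes so drug-target planting is possible.
#' Deterministic per seed.
#'
#' @param spec A [fixture_spec()].
#' @return List with `catalog` ([annotation_catalog()]), `ppi`
#'   ([ppi_table()]) and `structure_map` (data.frame `structure_id`,
#'   `protein_accession`, `gene_symbol`).
#' @export
generate_catalog <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(stream_seed(spec$seed, "catalog"))
  genes <- sprintf("G%04d", seq_len(spec$n_genes))

  g2p <- partition_terms(genes, spec$n_pathways, "PW", spec$pathway_overlap)
  g2f <- partition_terms(genes, spec$n_functions, "FN", spec$pathway_overlap)
  pw_sets <- split(g2p$gene, g2p$term)
  fn_sets <- split(g2f$gene, g2f$term)

  dis_ids <- sprintf("DIS%03d", seq_len(spec$n_diseases))
  extra_n <- max(2L, ceiling(0.02 * spec$n_genes))
  g2d <- do.call(rbind, lapply(seq_len(spec$n_diseases), function(i) {
    core <- unique(c(
      pw_sets[[sample.int(length(pw_sets), 1L)]],
      fn_sets[[sample.int(length(fn_sets), 1L)]],
      sample(genes, extra_n)
    ))
    data.frame(gene = core, term = dis_ids[i], stringsAsFactors = FALSE)
  }))
  dis_cat <- data.frame(
    disease = dis_ids,
    category = sprintf("CAT%d", sample.int(5L, spec$n_diseases, replace = TRUE)),
    stringsAsFactors = FALSE
  )

  # scored PPI edges at the requested density
  n_pairs <- round(spec$ppi_density * choose(spec$n_genes, 2L))
  ppi <- if (n_pairs > 0L) {
    i <- sample.int(spec$n_genes, 2L * n_pairs, replace = TRUE)
    j <- sample.int(spec$n_genes, 2L * n_pairs, replace = TRUE)
    keep <- i != j
    df <- unique(data.frame(gene_a = genes[pmin(i, j)[keep]],
                            gene_b = genes[pmax(i, j)[keep]],
                            stringsAsFactors = FALSE))
    df <- head(df, n_pairs)
    df$confidence <- runif(nrow(df), 0.5, 1)
    ppi_table(df)
  } else {
    ppi_table(data.frame(gene_a = character(), gene_b = character(),
                         confidence = numeric()))
  }

  # target panel: a fixed share of targets carries first-disease genes
  d1 <- sort(unique(g2d$gene[g2d$term == dis_ids[1L]]))
  k1 <- min(length(d1),
            max(spec$n_planted_targets, ceiling(0.3 * spec$n_targets)),
            spec$n_targets)
  rest_pool <- setdiff(genes, d1)
  n_rest <- spec$n_targets - k1
  target_genes <- c(sample(d1, k1),
                    if (n_rest > 0L) sample(rest_pool, min(n_rest, length(rest_pool))))
  structure_map <- data.frame(
    structure_id = sprintf("S%04d", seq_along(target_genes)),
    protein_accession = sprintf("P%05d", match(target_genes, genes)),
    gene_symbol = target_genes,
    stringsAsFactors = FALSE
  )

  list(
    catalog = annotation_catalog(gene2disease = g2d, gene2pathway = g2p,
                                 gene2function = g2f,
                                 disease_category = dis_cat, genes = genes),
    ppi = ppi,
    structure_map = structure_map
  )
}

# realistic ranges for the 8-descriptor reference panel
random_reference_descriptors <- function() {
  c(sasa = runif(1, 200, 700), volume = runif(1, 300, 1200),
    dipole = runif(1, 0, 10), hb_acceptors = sample(0:10, 1L),
    hb_donors = sample(0:5, 1L), globularity = runif(1, 0.6, 1),
    ionization_potential = runif(1, 8, 11),
    electron_affinity = runif(1, -1, 2))
}

#' Generate per-target synthetic screens with plantable binders
#'
#' Every target receives a reference ligand, a pocket shape close to the
#' reference shape, and a shared ligand library. Planted binders draw all
#' component scores from the favorable extreme of the screen (docking in
#' the library's top decile, near-zero shape distance, near-reference
#' descriptors, 90% contact recall); background ligands are sampled
#' diffusely. Deterministic per (seed, target).
#'
#' @param spec A [fixture_spec()].
#' @param target_ids Character vector of target (structure) ids.
#' @param planted_binders Named list mapping a target id to the ligand ids
#'   planted as strong binders in its screen.
#' @return Named list of [target_screen()] objects.
#' @export
generate_screens <- function(spec, target_ids, planted_binders = list()) {
  stopifnot(inherits(spec, "fixture_spec"), length(target_ids) >= 1L)
  base <- stream_seed(spec$seed, "screen")
  lig_ids <- sprintf("D%03d", seq_len(spec$n_ligands_per_screen))
  residues <- sprintf("R%02d", 1:30)
  out <- lapply(seq_along(target_ids), function(i) {
    set.seed((base + i) %% 2147483647L)
    tid <- target_ids[i]
    ref_desc <- random_reference_descriptors()
    ref_shape <- rnorm(16L)
    ref_contacts <- sample(residues, 10L)
    planted <- as.character(planted_binders[[tid]])
    ligands <- lapply(lig_ids, function(id) {
      if (id %in% planted) {
        ligand_record(
          id,
          descriptors = unname(ref_desc) * runif(8L, 0.97, 1.03),
          shape = ref_shape + rnorm(16L, 0, 0.08),
          dock_score = runif(1, -10.5, -9),
          contacts = sample(ref_contacts, 9L)
        )
      } else {
        n_shared <- sample(0:8, 1L)
        ligand_record(
          id,
          descriptors = unname(ref_desc) * runif(8L, 0.3, 1.9),
          shape = ref_shape + rnorm(16L, 0, 1.2),
          dock_score = runif(1, -10, -2),
          contacts = c(if (n_shared > 0L) sample(ref_contacts, n_shared),
                       sample(residues, 3L))
        )
      }
    })
    reference <- ligand_record(paste0(tid, "_ref"), unname(ref_desc),
                               ref_shape, -11, ref_contacts)
    target_screen(tid, reference, ref_shape + rnorm(16L, 0, 0.15), ligands)
  })
  names(out) <- target_ids
  out
}

#' Generate a synthetic differential-expression table
#'
#' Disease genes receive p-values from `Uniform(0,1)^(1 + de_effect)`
#' (uniform when `de_effect = 0`, concentrated near zero as the effect
#' grows); background genes are Uniform(0,1). Directions are random;
#' disease genes receive a fold-change boost of `de_effect / 2` on top of
#' background noise. Benjamini-Hochberg adjusted p-values are included.
#' Deterministic per (seed, study).
#'
#' @param spec A [fixture_spec()].
#' @param disease_genes Character vector of true disease genes (subset of
#'   the catalog genes).
#' @param study Study index (distinct studies of the same disease use
#'   independent noise). Default 1.
#' @return Data.frame with columns `gene`, `logFC`, `p`, `adj_p`.
#' @export
generate_de_table <- function(spec, disease_genes, study = 1L) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed((stream_seed(spec$seed, "expression") + as.integer(study)) %%
             2147483647L)
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  is_dis <- genes %in% toupper(as.character(disease_genes))
  p <- runif(spec$n_genes)
  p[is_dis] <- runif(sum(is_dis))^(1 + spec$de_effect)
  p <- pmax(p, .Machine$double.xmin)
  dir <- sample(c(-1, 1), spec$n_genes, replace = TRUE)
  lfc <- dir * (abs(rnorm(spec$n_genes, 0, spec$de_noise)) +
                  ifelse(is_dis, spec$de_effect / 2, 0))
  data.frame(gene = genes, logFC = lfc, p = p,
             adj_p = p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Generate every input of a synthetic study, with ground truth
#'
#' Orchestrates the generators: catalog + PPI + structure map, the planted
#' drug's target assignment (a `planted_drug_overlap` fraction of its
#' targets map to genes of the study disease), per-target screens with the
#' planted drug as a strong binder at its targets, and one DE table per
#' study for the disease's genes.
#'
#' @param spec A [fixture_spec()].
#' @return List: `catalog`, `ppi`, `structure_map`, `screens`, `de`
#'   (list of DE tables), and `truth` (disease id and genes, planted drug
#'   id, planted target ids).
#' @export
simulate_inputs <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  cat_out <- generate_catalog(spec)
  catalog <- cat_out$catalog
  smap <- cat_out$structure_map

  disease_id <- "DIS001"
  disease_genes <- sort(catalog_map(catalog, "disease")$gene[
    catalog_map(catalog, "disease")$term == disease_id])

  set.seed(stream_seed(spec$seed, "plant"))
  planted_drug <- "D001"
  dis_targets <- smap$structure_id[smap$gene_symbol %in% disease_genes]
  other_targets <- setdiff(smap$structure_id, dis_targets)
  n_pt <- min(spec$n_planted_targets, nrow(smap))
  n_dis <- min(length(dis_targets), round(spec$planted_drug_overlap * n_pt))
  planted_targets <- c(sample(dis_targets, n_dis),
                       sample(other_targets, min(n_pt - n_dis,
                                                 length(other_targets))))
  planted_binders <- setNames(rep(list(planted_drug),
                                  length(planted_targets)), planted_targets)

  screens <- generate_screens(spec, smap$structure_id, planted_binders)
  de <- lapply(seq_len(spec$n_studies), function(s)
    generate_de_table(spec, disease_genes, study = s))
  names(de) <- sprintf("study%d", seq_len(spec$n_studies))

  list(catalog = catalog, ppi = cat_out$ppi, structure_map = smap,
       screens = screens, de = de,
       truth = list(disease_id = disease_id, disease_genes = disease_genes,
                    planted_drug = planted_drug,
                    planted_targets = sort(planted_targets)))
}
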