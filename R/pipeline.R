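# Pipeline orchestration: configuration, fixture writing, the staged
# score -> network -> profile -> associate -> consensus workflow, and the
# in-memory planted-signal experiment used for calibration studies.

#' Pipeline run configuration
#'
#' Collects every input path, threshold and weight of the staged workflow.
#' Thresholds default to the platform's standard operating point: PPI
#' confidence cutoff 0.95, enrichment FDR 0.25, DE alpha 0.05 with a
#' 3,000-gene cap (1,500 per direction), per-tier significance 0.05 with
#' tier weights 2/1/0.5/0.25, and top-100 per-study lists for consensus.
#' Unknown keys are rejected.
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Integer seed used by the simulate stage.
#' @param simulate Generate all inputs synthetically (TRUE, default) or
#'   read them from the paths below.
#' @param sim_spec A [fixture_spec()] for the simulate stage; its seed is
#'   overridden by `seed`.
#' @param screen_dir,structure_map,gene2disease,gene2pathway,gene2function
#'   Input paths when `simulate = FALSE` (`gene2pathway`/`gene2function`
#'   accept two-column TSV or GMT).
#' @param disease_category,ppi,de_tables Further input paths
#'   (`de_tables`: character vector, one TSV per study).
#' @param k_hits Hits called per target. Default 5 at desk scale (the
#'   production default of 40 suits libraries of thousands).
#' @param cs_mode Contact-correction mode for [score_weights()].
#' @param top1_only Restrict the disease network to rank-1 drug-target
#'   pairs. Default TRUE.
#' @param ppi_cutoff,enrich_fdr,de_alpha,prefer_adjusted,cap,per_direction_cap
#'   Stage thresholds (see [filter_ppi()], [enrich_terms()],
#'   [select_de_genes()]).
#' @param tier_weights Numeric vector `c(a, b, c, d)` for
#'   [weight_config()].
#' @param alpha Tier significance threshold.
#' @param top_n Per-study list length for [consensus_rank()].
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, simulate = TRUE,
                       sim_spec = NULL, screen_dir = NULL,
                       structure_map = NULL, gene2disease = NULL,
                       gene2pathway = NULL, gene2function = NULL,
                       disease_category = NULL, ppi = NULL,
                       de_tables = NULL, k_hits = 5L,
                       cs_mode = "once", top1_only = TRUE,
                       ppi_cutoff = 0.95, enrich_fdr = 0.25,
                       de_alpha = 0.05, prefer_adjusted = FALSE,
                       cap = 3000L, per_direction_cap = 1500L,
                       tier_weights = c(2, 1, 0.5, 0.25), alpha = 0.05,
                       top_n = 100L, log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  stopifnot(is.character(out_dir), length(out_dir) == 1L,
            ppi_cutoff > 0, ppi_cutoff <= 1,
            enrich_fdr > 0, de_alpha > 0, de_alpha <= 1,
            alpha > 0, alpha < 1,
            cap >= 1, per_direction_cap >= 1, top_n >= 1, k_hits >= 1,
            is.numeric(tier_weights), length(tier_weights) == 4L,
            all(tier_weights >= 0))
  if (is.null(sim_spec)) sim_spec <- fixture_spec(seed = seed)
  sim_spec$seed <- as.integer(seed)
  if (!simulate) {
    needed <- c("screen_dir", "structure_map", "gene2disease",
                "gene2pathway", "gene2function", "ppi", "de_tables")
    vals <- list(screen_dir, structure_map, gene2disease, gene2pathway,
                 gene2function, ppi, de_tables)
    miss <- needed[vapply(vals, is.null, logical(1L))]
    if (length(miss) > 0L) {
      stop("simulate = FALSE requires input paths: ",
           paste(miss, collapse = ", "))
    }
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), simulate = simulate,
         sim_spec = sim_spec, screen_dir = screen_dir,
         structure_map = structure_map, gene2disease = gene2disease,
         gene2pathway = gene2pathway, gene2function = gene2function,
         disease_category = disease_category, ppi = ppi,
         de_tables = de_tables, k_hits = as.integer(k_hits),
         cs_mode = cs_mode, top1_only = top1_only,
         ppi_cutoff = ppi_cutoff, enrich_fdr = enrich_fdr,
         de_alpha = de_alpha, prefer_adjusted = prefer_adjusted,
         cap = as.integer(cap),
         per_direction_cap = as.integer(per_direction_cap),
         tier_weights = tier_weights, alpha = alpha,
         top_n = as.integer(top_n), log_level = log_level),
    class = "run_config"
  )
}

#' Load a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are
#' rejected. A `sim_spec` mapping is passed to [fixture_spec()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  known <- names(formals(run_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(cfg$sim_spec)) {
    spec_known <- names(formals(fixture_spec))
    spec_unknown <- setdiff(names(cfg$sim_spec), spec_known)
    if (length(spec_unknown) > 0L) {
      stop("unknown sim_spec key(s): ", paste(spec_unknown, collapse = ", "))
    }
    cfg$sim_spec <- do.call(fixture_spec, cfg$sim_spec)
  }
  if (!is.null(cfg$tier_weights)) cfg$tier_weights <- as.numeric(cfg$tier_weights)
  do.call(run_config, cfg)
}

#' Write every synthetic input of a study to disk
#'
#' Materializes [simulate_inputs()] as the plain-text files the pipeline
#' consumes: screen TSVs with JSON sidecars, structure map, gene-disease
#' and disease-category TSVs, pathway/function GMTs, the PPI TSV and one
#' DE TSV per study.
#'
#' @param sim Output of [simulate_inputs()].
#' @param dir Fixture directory (created).
#' @return Invisibly, a named list of the written paths.
#' @export
write_fixtures <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  screen_dir <- file.path(dir, "screens")
  for (s in sim$screens) write_screen_tsv(s, screen_dir)
  paths <- list(
    screen_dir = screen_dir,
    structure_map = file.path(dir, "structmap.tsv"),
    gene2disease = file.path(dir, "gene2disease.tsv"),
    gene2pathway = file.path(dir, "pathways.gmt"),
    gene2function = file.path(dir, "functions.gmt"),
    disease_category = file.path(dir, "disease_category.tsv"),
    ppi = file.path(dir, "ppi.tsv"),
    de_tables = file.path(dir, sprintf("de_%s.tsv", names(sim$de)))
  )
  write_tsv(sim$structure_map, paths$structure_map)
  g2d <- catalog_map(sim$catalog, "disease")
  write_tsv(g2d, paths$gene2disease)
  pw <- term_genes(sim$catalog, "pathway")
  fn <- term_genes(sim$catalog, "function")
  write_gmt(pw, paths$gene2pathway)
  write_gmt(fn, paths$gene2function)
  cats <- sim$catalog$disease_category
  write_tsv(data.frame(disease = names(cats), category = unname(cats),
                       stringsAsFactors = FALSE), paths$disease_category)
  write_tsv(as.data.frame(sim$ppi), paths$ppi)
  for (i in seq_along(sim$de)) write_tsv(sim$de[[i]], paths$de_tables[i])
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  invisible(paths)
}

pipeline_log <- function(config, stage, msg) {
  if (identical(config$log_level, "info")) {
    message(sprintf("[%s] %s", stage, msg))
  }
}

run_stage <- function(config, stage, fun) {
  tryCatch(fun(), error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full drug-repurposing workflow
#'
#' Executes the staged workflow — simulate (optional), score screens and
#' call hits, collapse structures and build the drug-disease network,
#' profile each DE study, associate and rank drugs per study, and build
#' the multi-study consensus — writing every artifact plus a JSON
#' provenance report (package version, parameters, input digests, row
#' counts per stage) under `out_dir`. A failing stage aborts with the
#' stage name and cause. Outputs are byte-reproducible given (inputs,
#' config, seed).
#'
#' @param config A [run_config()] or the path to a YAML file for
#'   [run_config_from_yaml()].
#' @return Invisibly, the run report (named list).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- run_config_from_yaml(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package = "dgerank",
                 version = as.character(packageVersion("dgerank")),
                 r_version = paste(R.version$major, R.version$minor, sep = "."),
                 seed = config$seed,
                 parameters = config[c("k_hits", "cs_mode", "top1_only",
                                       "ppi_cutoff", "enrich_fdr", "de_alpha",
                                       "prefer_adjusted", "cap",
                                       "per_direction_cap", "tier_weights",
                                       "alpha", "top_n")],
                 stages = list())

  # -- simulate ------------------------------------------------------------
  if (config$simulate) {
    run_stage(config, "simulate", function() {
      sim <- simulate_inputs(config$sim_spec)
      paths <- write_fixtures(sim, file.path(config$out_dir, "fixtures"))
      config$screen_dir <<- paths$screen_dir
      config$structure_map <<- paths$structure_map
      config$gene2disease <<- paths$gene2disease
      config$gene2pathway <<- paths$gene2pathway
      config$gene2function <<- paths$gene2function
      config$disease_category <<- paths$disease_category
      config$ppi <<- paths$ppi
      config$de_tables <<- paths$de_tables
      pipeline_log(config, "simulate",
                   sprintf("%d screens, %d DE studies written",
                           length(sim$screens), length(sim$de)))
    })
  }
  for (p in c(config$structure_map, config$gene2disease, config$gene2pathway,
              config$gene2function, config$ppi, config$de_tables)) {
    if (!file.exists(p)) stop("stage 'inputs' failed: missing input ", p)
  }
  input_paths <- c(config$structure_map, config$gene2disease,
                   config$gene2pathway, config$gene2function, config$ppi,
                   config$de_tables)
  report$input_md5 <- as.list(setNames(unname(md5sum(input_paths)),
                                       basename(input_paths)))

  # -- score ---------------------------------------------------------------
  hits <- run_stage(config, "score", function() {
    screens <- read_screen_dir(config$screen_dir)
    w <- score_weights(cs_mode = config$cs_mode, k_hits = config$k_hits)
    res <- lapply(screens, function(s) {
      r <- composite_score(s, w)
      r$target_id <- s$target_id
      r
    })
    all <- do.call(rbind, res)
    all <- all[, c("target_id", "ligand_id", "z_score", "rank", "is_hit")]
    rownames(all) <- NULL
    write_tsv(all, file.path(config$out_dir, "hits.tsv"))
    pipeline_log(config, "score",
                 sprintf("%d screens scored, %d hit calls",
                         length(screens), sum(all$is_hit)))
    all
  })
  report$stages$score <- list(rows = nrow(hits), hits = sum(hits$is_hit))

  # -- network -------------------------------------------------------------
  catalog <- run_stage(config, "catalog", function() {
    annotation_catalog(
      gene2disease = read_annotation_any(config$gene2disease),
      gene2pathway = read_annotation_any(config$gene2pathway),
      gene2function = read_annotation_any(config$gene2function),
      disease_category = if (!is.null(config$disease_category) &&
                             file.exists(config$disease_category))
        read_tsv(config$disease_category) else NULL
    )
  })
  smap <- read_structure_map_tsv(config$structure_map)
  net_out <- run_stage(config, "network", function() {
    dt <- collapse_structures(hits[hits$is_hit, , drop = FALSE], smap)
    write_tsv(dt, file.path(config$out_dir, "drug_targets.tsv"))
    net <- build_disease_network(dt, catalog, top1_only = config$top1_only)
    write_network(net, "graphml", file.path(config$out_dir, "network.graphml"))
    write_network(net, "sif", file.path(config$out_dir, "network.sif"))
    stats <- network_stats(net)
    jsonlite::write_json(stats, file.path(config$out_dir, "network_stats.json"),
                         auto_unbox = TRUE, digits = NA)
    pipeline_log(config, "network",
                 sprintf("%d drug-target pairs, %d network edges",
                         nrow(dt), stats$n_edges))
    list(dt = dt, net = net, stats = stats)
  })
  report$stages$network <- list(drug_target_rows = nrow(net_out$dt),
                                edges = net_out$stats$n_edges)

  # -- profile -------------------------------------------------------------
  ppi_f <- run_stage(config, "ppi", function() {
    filter_ppi(read_ppi_tsv(config$ppi), config$ppi_cutoff,
               known_genes = smap$gene_symbol)
  })
  profiles <- run_stage(config, "profile", function() {
    out <- list()
    for (i in seq_along(config$de_tables)) {
      study <- file_path_sans_ext(basename(config$de_tables[i]))
      de <- read_de_tsv(config$de_tables[i])
      genes <- select_de_genes(de, alpha = config$de_alpha,
                               prefer_adjusted = config$prefer_adjusted,
                               cap = config$cap,
                               per_direction_cap = config$per_direction_cap)
      prof <- suppressWarnings(
        build_disease_profile(genes, catalog, ppi_f, disease_id = study,
                              enrich_fdr = config$enrich_fdr))
      write_profile_json(prof,
                         file.path(config$out_dir,
                                   sprintf("profile_%s.json", study)))
      pipeline_log(config, "profile",
                   sprintf("%s: %d DE genes selected", study, length(genes)))
      out[[study]] <- prof
    }
    out
  })
  report$stages$profile <- lapply(profiles, function(p)
    list(genes = length(p$genes), pathways = length(p$pathways),
         functions = length(p$functions), ppi_genes = length(p$ppi_genes)))

  # -- associate -----------------------------------------------------------
  rankings <- run_stage(config, "associate", function() {
    drug_profiles <- suppressWarnings(
      build_drug_profiles(net_out$dt, catalog, ppi_f,
                          enrich_fdr = config$enrich_fdr))
    write_profile_json(drug_profiles,
                       file.path(config$out_dir, "drug_profiles.json"))
    w <- weight_config(config$tier_weights[1L], config$tier_weights[2L],
                       config$tier_weights[3L], config$tier_weights[4L],
                       alpha = config$alpha)
    out <- list()
    for (study in names(profiles)) {
      ranked <- associate_drugs(drug_profiles, profiles[[study]], catalog, w)
      write_tsv(ranked[, c("drug_id", "A", "B", "C", "D", "z", "rank")],
                file.path(config$out_dir, sprintf("ranked_%s.tsv", study)))
      jsonlite::write_json(
        ranked, file.path(config$out_dir,
                          sprintf("association_%s.json", study)),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
      pipeline_log(config, "associate",
                   sprintf("%s: %d drugs ranked; top = %s", study,
                           nrow(ranked), ranked$drug_id[1L]))
      out[[study]] <- ranked
    }
    out
  })
  report$stages$associate <- lapply(rankings, function(r)
    list(drugs = nrow(r), top_drug = r$drug_id[1L], top_z = r$z[1L]))

  # -- consensus -----------------------------------------------------------
  if (length(rankings) > 1L) {
    consensus <- run_stage(config, "consensus", function() {
      cons <- consensus_rank(unname(rankings), top_n = config$top_n)
      write_tsv(cons, file.path(config$out_dir, "consensus.tsv"))
      pipeline_log(config, "consensus",
                   sprintf("%d consensus drugs; top = %s", nrow(cons),
                           cons$drug_id[1L]))
      cons
    })
    report$stages$consensus <- list(drugs = nrow(consensus),
                                    top_drug = consensus$drug_id[1L])
  }

  jsonlite::write_json(report, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' In-memory planted-signal experiment
#'
#' Generates one synthetic study, runs the full workflow in memory
#' (score, collapse, PPI filter, profile of the first DE study,
#' associate) and reports where the planted drug ranked — the primary
#' calibration check of the method's end-to-end recovery.
#'
#' @param spec A [fixture_spec()].
#' @param k_hits Hits called per target. Default 5.
#' @param ppi_cutoff,enrich_fdr,de_alpha Stage thresholds as in
#'   [run_config()].
#' @param weights A [weight_config()].
#' @return List: `planted_rank`, `planted_drug`, `ranked` (the full
#'   ranked table), `n_drugs`.
#' @export
run_planted_experiment <- function(spec, k_hits = 5L, ppi_cutoff = 0.95,
                                   enrich_fdr = 0.25, de_alpha = 0.05,
                                   weights = weight_config()) {
  sim <- simulate_inputs(spec)
  w <- score_weights(k_hits = k_hits)
  hit_rows <- lapply(sim$screens, function(s) {
    r <- composite_score(s, w)
    r <- r[r$is_hit, , drop = FALSE]
    r$target_id <- s$target_id
    r
  })
  hits <- do.call(rbind, hit_rows)
  dt <- collapse_structures(hits, sim$structure_map)
  ppi_f <- filter_ppi(sim$ppi, ppi_cutoff,
                      known_genes = sim$structure_map$gene_symbol)
  genes <- select_de_genes(sim$de[[1L]], alpha = de_alpha,
                           prefer_adjusted = FALSE)
  prof <- suppressWarnings(
    build_disease_profile(genes, sim$catalog, ppi_f,
                          disease_id = sim$truth$disease_id,
                          enrich_fdr = enrich_fdr))
  drug_profiles <- suppressWarnings(
    build_drug_profiles(dt, sim$catalog, ppi_f, enrich_fdr = enrich_fdr))
  ranked <- associate_drugs(drug_profiles, prof, sim$catalog, weights)
  list(planted_rank = ranked$rank[ranked$drug_id == sim$truth$planted_drug],
       planted_drug = sim$truth$planted_drug,
       ranked = ranked, n_drugs = nrow(ranked))
}
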