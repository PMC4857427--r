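# Disease and drug profiles: DE gene selection with directional capping,
# and four-tier profiles (genes, enriched pathways, enriched functions,
# PPI-expanded genes).

#' Select differentially expressed genes with directional capping
#'
#' Keeps genes whose p-value (adjusted when requested and available, else
#' nominal) is strictly below `alpha`. When the significant set exceeds
#' `cap`, the `per_direction_cap` smallest-p genes are kept in each
#' direction (the cap mirrors annotation services that accept at most
#' 3,000 genes: 1,500 up- plus 1,500 down-regulated). Duplicate gene rows
#' collapse to the minimum nominal p, keeping that row's direction; ties
#' at the cap boundary break by gene symbol.
#'
#' @param de Data.frame with columns `gene`, `p`, optionally `adj_p`, and
#'   a direction carried either as a signed `logFC` column or an explicit
#'   `direction` column (`"up"`/`"down"` or a signed number).
#' @param alpha Significance threshold (strict `<`). Default 0.05.
#' @param prefer_adjusted Use `adj_p` when present (falling back to the
#'   nominal p when the column is absent or all-NA). Default TRUE.
#' @param cap Maximum size of the selected set. Default 3000.
#' @param per_direction_cap Genes kept per direction when capping triggers.
#'   Default 1500.
#' @return Sorted character vector of selected gene symbols.
#' @export
select_de_genes <- function(de, alpha = 0.05, prefer_adjusted = TRUE,
                            cap = 3000L, per_direction_cap = 1500L) {
  stopifnot(is.data.frame(de), nrow(de) >= 1L,
            all(c("gene", "p") %in% names(de)),
            is.numeric(alpha), alpha > 0, alpha <= 1,
            cap >= 1L, per_direction_cap >= 1L)
  de$gene <- toupper(as.character(de$gene))
  if (any(!is.finite(de$p) | de$p <= 0 | de$p > 1)) {
    stop("nominal p-values must lie in (0, 1]")
  }
  # collapse duplicate genes to the row with the smallest nominal p
  de <- de[order(de$p, de$gene, method = "radix"), , drop = FALSE]
  de <- de[!duplicated(de$gene), , drop = FALSE]

  pvec <- de$p
  if (prefer_adjusted && "adj_p" %in% names(de) && !all(is.na(de$adj_p))) {
    pvec <- de$adj_p
  }
  sig <- is.finite(pvec) & pvec < alpha
  sel <- de[sig, , drop = FALSE]
  psel <- pvec[sig]
  if (nrow(sel) > cap) {
    dir <- de_direction(sel)
    keep <- logical(nrow(sel))
    for (d in c("up", "down")) {
      idx <- which(dir == d)
      idx <- idx[order(psel[idx], sel$gene[idx], method = "radix")]
      keep[head(idx, per_direction_cap)] <- TRUE
    }
    sel <- sel[keep, , drop = FALSE]
  }
  sort(unique(sel$gene))
}

# direction per row from an explicit 'direction' column or the sign of logFC
de_direction <- function(de) {
  if ("direction" %in% names(de)) {
    d <- de$direction
    if (is.numeric(d)) return(ifelse(d >= 0, "up", "down"))
    d <- tolower(as.character(d))
    if (!all(d %in% c("up", "down"))) {
      stop("'direction' must be 'up'/'down' or a signed number")
    }
    return(d)
  }
  if ("logFC" %in% names(de)) {
    return(ifelse(as.numeric(de$logFC) >= 0, "up", "down"))
  }
  stop("capping requires a 'direction' or 'logFC' column")
}

#' Build a four-tier disease profile
#'
#' Turns a selected disease gene set into the four tiers used for
#' drug-disease association: the genes themselves, the pathway and
#' molecular-function terms over-represented in them, and the one-hop
#' PPI expansion of the gene set.
#'
#' @param genes Character vector of disease (differentially expressed)
#'   genes.
#' @param catalog An [annotation_catalog()].
#' @param ppi A [ppi_table()], already filtered at the confidence cutoff.
#' @param disease_id Identifier stored in the profile. Default "disease".
#' @param enrich_fdr FDR cutoff passed to [enrich_terms()]. Default 0.25.
#' @return An object of class `disease_profile`: list with `disease_id`,
#'   `genes`, `pathways`, `functions`, `ppi_genes` (a superset of
#'   `genes`).
#' @export
build_disease_profile <- function(genes, catalog, ppi,
                                  disease_id = "disease", enrich_fdr = 0.25) {
  genes <- sort(unique(toupper(as.character(genes))))
  if (length(genes) == 0L) {
    warning("empty disease gene set: profile tiers will be empty")
    return(structure(list(disease_id = disease_id, genes = character(),
                          pathways = character(), functions = character(),
                          ppi_genes = character()),
                     class = "disease_profile"))
  }
  structure(
    list(disease_id = disease_id,
         genes = genes,
         pathways = sort(enrich_terms(genes, "pathway", catalog, enrich_fdr)$term),
         functions = sort(enrich_terms(genes, "function", catalog, enrich_fdr)$term),
         ppi_genes = expand_gene_list(genes, ppi)),
    class = "disease_profile"
  )
}

#' Build four-tier drug profiles from a drug-target table
#'
#' For every drug: the direct target genes, their one-hop PPI expansion,
#' and the pathway / molecular-function terms over-represented in the
#' expanded list (direct plus indirect targets are annotated together, so
#' interaction partners contribute to a drug's pathway and function
#' signature).
#'
#' @param dt Drug-target table ([collapse_structures()] output or any
#'   data.frame with `drug_id` and `gene_symbol`).
#' @param catalog An [annotation_catalog()].
#' @param ppi A filtered [ppi_table()].
#' @param enrich_fdr FDR cutoff for [enrich_terms()]. Default 0.25.
#' @return Named list of `drug_profile` objects (fields `drug_id`,
#'   `genes`, `pathways`, `functions`, `ppi_genes`).
#' @export
build_drug_profiles <- function(dt, catalog, ppi, enrich_fdr = 0.25) {
  stopifnot(is.data.frame(dt),
            all(c("drug_id", "gene_symbol") %in% names(dt)))
  sets <- split(toupper(as.character(dt$gene_symbol)),
                as.character(dt$drug_id))
  out <- lapply(names(sets), function(d) {
    genes <- sort(unique(sets[[d]]))
    expanded <- expand_gene_list(genes, ppi)
    structure(
      list(drug_id = d,
           genes = genes,
           pathways = sort(enrich_terms(expanded, "pathway", catalog,
                                        enrich_fdr)$term),
           functions = sort(enrich_terms(expanded, "function", catalog,
                                         enrich_fdr)$term),
           ppi_genes = expanded),
      class = "drug_profile"
    )
  })
  names(out) <- names(sets)
  out[order(names(out), method = "radix")]
}

#' Write a profile (or list of profiles) to JSON
#' @param x A `disease_profile`, `drug_profile`, or named list of them.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_profile_json <- function(x, path) {
  strip <- function(p) lapply(unclass(p), function(v) v)
  obj <- if (inherits(x, c("disease_profile", "drug_profile"))) strip(x)
         else lapply(x, strip)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a disease profile written by [write_profile_json()]
#' @param path JSON path.
#' @return A `disease_profile`.
#' @export
read_disease_profile_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(disease_id = obj$disease_id,
         genes = as.character(obj$genes),
         pathways = as.character(obj$pathways),
         functions = as.character(obj$functions),
         ppi_genes = as.character(obj$ppi_genes)),
    class = "disease_profile"
  )
}

#' Read drug profiles written by [write_profile_json()]
#' @param path JSON path.
#' @return Named list of `drug_profile` objects.
#' @export
read_drug_profiles_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(obj, function(p) {
    structure(
      list(drug_id = p$drug_id,
           genes = as.character(p$genes),
           pathways = as.character(p$pathways),
           functions = as.character(p$functions),
           ppi_genes = as.character(p$ppi_genes)),
      class = "drug_profile"
    )
  })
  names(out) <- vapply(out, `[[`, character(1L), "drug_id")
  out
}
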