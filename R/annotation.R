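# Annotation catalogs, PPI filtering/expansion, local term enrichment, and
# collapsing of structure-level hits to gene-level drug-target tables.

clean_multimap <- function(df, what) {
  if (is.null(df)) {
    return(data.frame(gene = character(), term = character(),
                      stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(df), ncol(df) >= 2L)
  out <- data.frame(gene = toupper(as.character(df[[1L]])),
                    term = as.character(df[[2L]]),
                    stringsAsFactors = FALSE)
  out <- out[nzchar(out$gene) & nzchar(out$term), , drop = FALSE]
  out <- unique(out)
  out <- out[order(out$gene, out$term, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct an annotation catalog
#'
#' The biological universe behind the pipeline: gene-disease, gene-pathway
#' and gene-function multimaps plus an optional disease-category table.
#' Gene symbols are case-folded to uppercase on ingest; exact string match
#' thereafter. Each namespace's enrichment universe is the set of genes
#' mapped in that namespace.
#'
#' @param gene2disease,gene2pathway,gene2function Data.frames whose first
#'   two columns are gene symbol and term id (long multimap form), or NULL.
#' @param disease_category Optional data.frame (disease, category).
#' @param genes Optional character vector of extra universe genes.
#' @return An object of class `annotation_catalog`.
#' @export
annotation_catalog <- function(gene2disease = NULL, gene2pathway = NULL,
                               gene2function = NULL, disease_category = NULL,
                               genes = NULL) {
  maps <- list(
    disease = clean_multimap(gene2disease, "gene2disease"),
    pathway = clean_multimap(gene2pathway, "gene2pathway"),
    `function` = clean_multimap(gene2function, "gene2function")
  )
  cat_map <- NULL
  if (!is.null(disease_category)) {
    stopifnot(is.data.frame(disease_category), ncol(disease_category) >= 2L)
    cat_map <- setNames(as.character(disease_category[[2L]]),
                        as.character(disease_category[[1L]]))
  }
  universe <- sort(unique(c(toupper(as.character(genes)),
                            unlist(lapply(maps, `[[`, "gene"), use.names = FALSE))))
  universe <- universe[nzchar(universe)]
  structure(
    list(maps = maps, disease_category = cat_map, genes = universe),
    class = "annotation_catalog"
  )
}

catalog_map <- function(catalog, namespace = c("disease", "pathway", "function")) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  namespace <- match.arg(namespace)
  catalog$maps[[namespace]]
}

#' Terms of one catalog namespace
#' @param catalog An [annotation_catalog()].
#' @param namespace One of `"disease"`, `"pathway"`, `"function"`.
#' @return Sorted character vector of term ids.
#' @export
catalog_terms <- function(catalog, namespace) {
  sort(unique(catalog_map(catalog, namespace)$term))
}

#' Gene sets of one catalog namespace
#' @inheritParams catalog_terms
#' @return Named list mapping term id to its character gene set.
#' @export
term_genes <- function(catalog, namespace) {
  m <- catalog_map(catalog, namespace)
  split(m$gene, m$term)
}

#' Construct a protein-protein interaction table
#'
#' Cleans a scored undirected PPI edge list: gene symbols are uppercased,
#' self-loops dropped, and duplicate unordered pairs collapsed keeping the
#' maximum confidence.
#'
#' @param edges Data.frame whose first three columns are gene_a, gene_b and
#'   a confidence score in \[0, 1\].
#' @return A cleaned data.frame of class `ppi_table` with columns `gene_a`,
#'   `gene_b` (lexicographically ordered within row) and `confidence`.
#' @export
ppi_table <- function(edges) {
  if (inherits(edges, "ppi_table")) return(edges)
  stopifnot(is.data.frame(edges), ncol(edges) >= 3L)
  a <- toupper(as.character(edges[[1L]]))
  b <- toupper(as.character(edges[[2L]]))
  conf <- as.numeric(edges[[3L]])
  if (any(!is.finite(conf)) || any(conf < 0 | conf > 1)) {
    stop("PPI confidence scores must lie in [0, 1]")
  }
  keep <- a != b & nzchar(a) & nzchar(b)
  a <- a[keep]; b <- b[keep]; conf <- conf[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  df <- data.frame(gene_a = lo, gene_b = hi, confidence = conf,
                   stringsAsFactors = FALSE)
  # keep max confidence per unordered pair
  df <- df[order(df$gene_a, df$gene_b, -df$confidence, method = "radix"), ,
           drop = FALSE]
  df <- df[!duplicated(df[c("gene_a", "gene_b")]), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ppi_table", "data.frame")
  df
}

#' Filter a PPI table by confidence and endpoint membership
#'
#' Keeps edges whose confidence is at least `cutoff` (inclusive) and, when
#' `known_genes` is given, whose endpoints both belong to the known protein
#' set — interactions reaching outside the screened target space are
#' excluded.
#'
#' @param ppi A [ppi_table()] (or coercible data.frame).
#' @param cutoff Confidence threshold in (0, 1\]; default 0.95.
#' @param known_genes Optional character vector of admissible genes.
#' @return Filtered `ppi_table`.
#' @export
filter_ppi <- function(ppi, cutoff = 0.95, known_genes = NULL) {
  ppi <- ppi_table(ppi)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0, cutoff <= 1)
  keep <- ppi$confidence >= cutoff
  if (!is.null(known_genes)) {
    known_genes <- toupper(as.character(known_genes))
    keep <- keep & ppi$gene_a %in% known_genes & ppi$gene_b %in% known_genes
  }
  out <- ppi[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expand a gene set by first-degree interaction partners
#'
#' Adds the one-hop PPI neighbors of every gene in `direct`; the result is
#' always a superset of `direct`, and applying the function twice walks two
#' hops (expansion is intentionally not idempotent).
#'
#' @param direct Character vector of seed genes.
#' @param ppi A pre-filtered [ppi_table()].
#' @return Sorted character vector: `direct` plus its PPI neighbors.
#' @export
expand_gene_list <- function(direct, ppi) {
  ppi <- ppi_table(ppi)
  direct <- unique(toupper(as.character(direct)))
  nb <- c(ppi$gene_b[ppi$gene_a %in% direct],
          ppi$gene_a[ppi$gene_b %in% direct])
  sort(unique(c(direct, nb)))
}

#' Hypergeometric term over-representation within a catalog namespace
#'
#' Tests every term of the namespace for over-representation of the query
#' genes against the namespace's gene universe, using the upper-tail
#' hypergeometric probability `P(X >= k)`, adjusts for multiple testing
#' and reports terms passing the FDR cutoff. Query genes absent from the
#' universe are dropped with a warning stating the count.
#'
#' @param genes Character vector of query genes.
#' @param namespace `"pathway"` or `"function"` (disease terms may also be
#'   enriched).
#' @param catalog An [annotation_catalog()].
#' @param fdr_cutoff Report terms with adjusted p below this value;
#'   default 0.25.
#' @param adjust Multiple-testing adjustment, `"BH"` (default) or
#'   `"bonferroni"`.
#' @return Data.frame with columns `term`, `k` (overlap), `K` (term size),
#'   `p`, `q`, sorted by `p` then term id; zero rows when nothing passes.
#' @export
enrich_terms <- function(genes, namespace = c("pathway", "function", "disease"),
                         catalog, fdr_cutoff = 0.25,
                         adjust = c("BH", "bonferroni")) {
  namespace <- match.arg(namespace)
  adjust <- match.arg(adjust)
  stopifnot(is.numeric(fdr_cutoff), fdr_cutoff > 0)
  empty <- data.frame(term = character(), k = integer(), K = integer(),
                      p = numeric(), q = numeric(), stringsAsFactors = FALSE)
  genes <- unique(toupper(as.character(genes)))
  m <- catalog_map(catalog, namespace)
  universe <- unique(m$gene)
  dropped <- setdiff(genes, universe)
  if (length(dropped) > 0L) {
    warning(sprintf("%d query gene(s) absent from the %s universe were dropped",
                    length(dropped), namespace))
  }
  genes <- intersect(genes, universe)
  if (length(genes) == 0L || nrow(m) == 0L) return(empty)

  sets <- split(m$gene, m$term)
  n_u <- length(universe)
  n_q <- length(genes)
  kk <- vapply(sets, function(g) length(intersect(g, genes)), integer(1L))
  bigk <- lengths(sets)
  p <- phyper(kk - 1L, bigk, n_u - bigk, n_q, lower.tail = FALSE)
  q <- p.adjust(p, method = adjust)
  out <- data.frame(term = names(sets), k = as.integer(kk),
                    K = as.integer(bigk), p = as.numeric(p),
                    q = as.numeric(q), stringsAsFactors = FALSE)
  out <- out[out$q < fdr_cutoff, , drop = FALSE]
  out <- out[order(out$p, out$term, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse structure-level hits to a gene-level drug-target table
#'
#' Different crystal structures of the same protein are merged through a
#' structure-to-gene map, deduplicating drug-gene pairs and keeping the
#' best (minimum) per-target rank across collapsed structures. Hits whose
#' structure is missing from the map are not fatal: they are dropped and
#' reported in the `rejects` attribute.
#'
#' @param hits Data.frame of called hits with columns `target_id`
#'   (structure id), `ligand_id` and optionally `rank`.
#' @param map Structure map data.frame with columns `structure_id`,
#'   `protein_accession`, `gene_symbol` (one accession per structure).
#' @return Data.frame with columns `drug_id`, `gene_symbol`, `source`
#'   (`"predicted"`) and `rank_at_target` (best rank, NA when absent);
#'   attribute `rejects` lists unmapped structure ids.
#' @export
collapse_structures <- function(hits, map) {
  stopifnot(is.data.frame(hits),
            all(c("target_id", "ligand_id") %in% names(hits)),
            is.data.frame(map),
            all(c("structure_id", "gene_symbol") %in% names(map)))
  map <- map[, intersect(c("structure_id", "protein_accession", "gene_symbol"),
                         names(map)), drop = FALSE]
  map$gene_symbol <- toupper(as.character(map$gene_symbol))
  if (anyDuplicated(map$structure_id)) {
    first <- !duplicated(map$structure_id)
    if (nrow(unique(map)) != sum(first)) {
      stop("structure map assigns multiple proteins to one structure id")
    }
    map <- map[first, , drop = FALSE]
  }
  rejects <- sort(unique(as.character(
    hits$target_id[!hits$target_id %in% map$structure_id])))
  if (length(rejects) > 0L) {
    warning(sprintf("%d structure id(s) without a map entry were rejected",
                    length(rejects)))
  }
  idx <- match(hits$target_id, map$structure_id)
  ok <- !is.na(idx)
  rnk <- if ("rank" %in% names(hits)) as.integer(hits$rank) else
    rep(NA_integer_, nrow(hits))
  df <- data.frame(drug_id = as.character(hits$ligand_id[ok]),
                   gene_symbol = map$gene_symbol[idx[ok]],
                   rank_at_target = rnk[ok],
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    out <- data.frame(drug_id = character(), gene_symbol = character(),
                      source = character(), rank_at_target = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "rejects") <- rejects
    return(out)
  }
  key <- paste(df$drug_id, df$gene_symbol, sep = "\r")
  best <- tapply(df$rank_at_target, key, function(r)
    if (all(is.na(r))) NA_integer_ else min(r, na.rm = TRUE))
  first <- !duplicated(key)
  out <- df[first, , drop = FALSE]
  out$rank_at_target <- as.integer(best[key[first]])
  out$source <- "predicted"
  out <- out[order(out$drug_id, out$gene_symbol, method = "radix"),
             c("drug_id", "gene_symbol", "source", "rank_at_target"),
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  out
}
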