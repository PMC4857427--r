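# Drug-disease bipartite networks: construction from gene-level drug-target
# tables, summary statistics, and GraphML/SIF export.

#' Construct a drug-disease bipartite network
#'
#' @param edges Data.frame with columns `drug` and `disease`.
#' @param categories Optional named character vector mapping disease id to
#'   a disease category.
#' @return An object of class `bipartite_network` with unique sorted edges
#'   and the two node sets.
#' @export
bipartite_network <- function(edges, categories = NULL) {
  stopifnot(is.data.frame(edges), all(c("drug", "disease") %in% names(edges)))
  edges <- unique(data.frame(drug = as.character(edges$drug),
                             disease = as.character(edges$disease),
                             stringsAsFactors = FALSE))
  edges <- edges[order(edges$drug, edges$disease, method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(edges = edges,
         drugs = sort(unique(edges$drug)),
         diseases = sort(unique(edges$disease)),
         categories = categories),
    class = "bipartite_network"
  )
}

#' Build the drug-disease network from a drug-target table
#'
#' Connects a drug to a disease whenever one of its (predicted) target
#' genes carries a gene-disease annotation for that disorder: every
#' disorder annotated to a predicted target becomes associated with the
#' drug. With `top1_only = TRUE` only targets at which the drug ranked
#' first (after structure collapsing) are used.
#'
#' @param dt Drug-target table from [collapse_structures()] (columns
#'   `drug_id`, `gene_symbol`, optionally `rank_at_target`).
#' @param catalog An [annotation_catalog()] with gene-disease annotations.
#' @param top1_only Restrict to `rank_at_target == 1` rows. Default FALSE.
#' @return A [bipartite_network()], carrying the catalog's disease
#'   categories when present.
#' @export
build_disease_network <- function(dt, catalog, top1_only = FALSE) {
  stopifnot(is.data.frame(dt),
            all(c("drug_id", "gene_symbol") %in% names(dt)))
  g2d <- catalog_map(catalog, "disease")
  if (nrow(g2d) == 0L) stop("catalog has no gene-disease annotations")
  if (top1_only) {
    if (!"rank_at_target" %in% names(dt)) {
      stop("'top1_only' requires a 'rank_at_target' column")
    }
    dt <- dt[!is.na(dt$rank_at_target) & dt$rank_at_target == 1L, ,
             drop = FALSE]
  }
  mrg <- merge(
    data.frame(drug = as.character(dt$drug_id),
               gene = toupper(as.character(dt$gene_symbol)),
               stringsAsFactors = FALSE),
    g2d, by = "gene"
  )
  bipartite_network(data.frame(drug = mrg$drug, disease = mrg$term,
                               stringsAsFactors = FALSE),
                    categories = catalog$disease_category)
}

# internal: igraph view of the bipartite network; node names are prefixed
# with their class so a drug and a disease may share an identifier
as_bipartite_igraph <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  # paste0() turns zero-length input into "", so prefix only non-empty sets
  pfx <- function(p, x) if (length(x) == 0L) character(0) else paste0(p, x)
  drugs <- pfx("drug:", net$drugs)
  dis <- pfx("disease:", net$diseases)
  cats <- rep(NA_character_, length(net$diseases))
  if (!is.null(net$categories)) {
    hit <- match(net$diseases, names(net$categories))
    cats <- unname(net$categories[hit])
  }
  verts <- data.frame(
    name = c(drugs, dis),
    node_class = c(rep("drug", length(drugs)), rep("disease", length(dis))),
    category = c(rep(NA_character_, length(drugs)), cats),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(from = pfx("drug:", net$edges$drug),
                      to = pfx("disease:", net$edges$disease),
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

#' Summary statistics of a bipartite network
#'
#' @param net A [bipartite_network()].
#' @return List with node counts per class, edge count, per-class degree
#'   summaries, the degree distribution (degree -> node count), connected
#'   component sizes (descending) and the largest component size. All
#'   entries are JSON-serializable.
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  if (nrow(net$edges) == 0L) {
    return(list(n_drugs = length(net$drugs), n_diseases = length(net$diseases),
                n_edges = 0L, mean_drug_degree = 0, mean_disease_degree = 0,
                degree_distribution = list(),
                component_sizes = integer(), largest_component = 0L))
  }
  g <- as_bipartite_igraph(net)
  deg <- igraph::degree(g)
  cls <- igraph::vertex_attr(g, "node_class")
  comp <- igraph::components(g)
  sizes <- sort(as.integer(comp$csize), decreasing = TRUE)
  dd <- table(deg)
  list(
    n_drugs = length(net$drugs),
    n_diseases = length(net$diseases),
    n_edges = nrow(net$edges),
    mean_drug_degree = mean(deg[cls == "drug"]),
    mean_disease_degree = mean(deg[cls == "disease"]),
    degree_distribution = as.list(setNames(as.integer(dd), names(dd))),
    component_sizes = sizes,
    largest_component = sizes[1L]
  )
}

#' Export a bipartite network to GraphML or SIF
#'
#' GraphML carries `node_class` and `category` node attributes (via
#' igraph); SIF uses the relation `targets_disease`, one edge per line.
#' Node and edge ordering is stable for reproducible diffs.
#'
#' @param net A [bipartite_network()].
#' @param format `"graphml"` or `"sif"`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, format = c("graphml", "sif"), path) {
  stopifnot(inherits(net, "bipartite_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    g <- as_bipartite_igraph(net)
    # igraph refuses NA character attributes in GraphML; blank them
    cat_attr <- igraph::vertex_attr(g, "category")
    cat_attr[is.na(cat_attr)] <- ""
    g <- igraph::set_vertex_attr(g, "category", value = cat_attr)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    lines <- sprintf("%s\ttargets_disease\t%s",
                     net$edges$drug, net$edges$disease)
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a SIF edge file back into a bipartite network
#'
#' @param path SIF file written by [write_network()].
#' @return A [bipartite_network()].
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(bipartite_network(data.frame(drug = character(),
                                        disease = character())))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0L) stop(sprintf("malformed SIF line %d", bad[1L]))
  bipartite_network(data.frame(
    drug = vapply(parts, `[[`, character(1L), 1L),
    disease = vapply(parts, `[[`, character(1L), 3L),
    stringsAsFactors = FALSE
  ))
}
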