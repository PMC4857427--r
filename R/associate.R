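# Drug-disease association: per-tier hypergeometric over-representation,
# log-ratio normalization of significant p-values, the weighted association
# Z-score, ranking, and multi-study consensus lists.

#' Tier weights and significance threshold for the association score
#'
#' The association Z-score is `z = a*A + b*B + c*C + d*D` over the
#' normalized gene (A), pathway (B), molecular-function (C) and PPI (D)
#' tier values. Default weights 2, 1, 0.5, 0.25 prioritize direct binding
#' of disease-regulated gene products, with each more indirect tier
#' weighted less.
#'
#' @param a,b,c,d Non-negative tier weights; defaults 2, 1, 0.5, 0.25.
#' @param alpha Per-tier significance threshold (strict `<`); default 0.05.
#' @return An object of class `weight_config`.
#' @export
weight_config <- function(a = 2, b = 1, c = 0.5, d = 0.25, alpha = 0.05) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, alpha > 0, alpha < 1)
  structure(list(a = a, b = b, c = c, d = d, alpha = alpha),
            class = "weight_config")
}

#' Hypergeometric overlap test between a drug set and a disease set
#'
#' Upper-tail probability `P(X >= k)` of drawing at least the observed
#' overlap `k` when `|drug_set|` items are drawn without replacement from
#' a universe containing `|disease_set|` "success" items. Items outside
#' the universe are dropped before testing; an empty drug or disease set
#' yields p = 1 with the `no_evidence` flag set.
#'
#' @param drug_set,disease_set Character vectors of tier items (genes or
#'   term ids).
#' @param universe Character vector: the tier's sampling universe.
#' @param warn Warn when items are dropped for falling outside the
#'   universe. Default TRUE.
#' @return List of class `tier_association`: `k`, `n_drug`, `n_disease`,
#'   `n_universe`, `p`, `no_evidence`.
#' @export
hypergeom_overlap_test <- function(drug_set, disease_set, universe,
                                   warn = TRUE) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("tier universe must be non-empty")
  drug_set <- unique(as.character(drug_set))
  disease_set <- unique(as.character(disease_set))
  n_out <- sum(!drug_set %in% universe) + sum(!disease_set %in% universe)
  if (n_out > 0L && warn) {
    warning(sprintf("%d item(s) outside the tier universe were dropped", n_out))
  }
  dr <- intersect(drug_set, universe)
  di <- intersect(disease_set, universe)
  k <- length(intersect(dr, di))
  no_evidence <- length(dr) == 0L || length(di) == 0L
  p <- if (no_evidence) 1 else
    phyper(k - 1L, length(di), length(universe) - length(di), length(dr),
           lower.tail = FALSE)
  structure(
    list(k = k, n_drug = length(dr), n_disease = length(di),
         n_universe = length(universe), p = as.numeric(p),
         no_evidence = no_evidence),
    class = "tier_association"
  )
}

#' Normalize per-drug tier p-values to the unit interval
#'
#' Drugs significant at `alpha` (strict `<`) get
#' `log10(p) / log10(p_min)` where `p_min` is the smallest significant
#' p-value of the tier, so the most significantly associated drug maps to
#' exactly 1; all non-significant drugs map to 0, and so does everything
#' when no drug is significant. The log ratio is base-invariant; base 10
#' is used. Non-positive p-values are clamped to the smallest positive
#' double with a warning.
#'
#' @param pvals Named numeric vector of per-drug p-values.
#' @param alpha Significance threshold; default 0.05.
#' @return Named numeric vector in \[0, 1\].
#' @export
normalize_tier <- function(pvals, alpha = 0.05) {
  stopifnot(is.numeric(pvals), length(pvals) >= 1L)
  p <- pvals
  if (any(p <= 0, na.rm = TRUE)) {
    warning("non-positive p-value(s) clamped to the smallest positive double")
    p[p <= 0] <- .Machine$double.xmin
  }
  out <- setNames(numeric(length(p)), names(p))
  sig <- is.finite(p) & p < alpha
  if (any(sig)) {
    p_min <- min(p[sig])
    out[sig] <- log10(p[sig]) / log10(p_min)
  }
  out
}

#' Combine normalized tier values into the association Z-score
#'
#' @param tiers List with named numeric vectors `A` (gene), `B` (pathway),
#'   `C` (function), `D` (ppi); drugs missing from a tier contribute 0
#'   for it.
#' @param weights A [weight_config()].
#' @return Data.frame with columns `drug_id`, `A`, `B`, `C`, `D`, `z`.
#' @export
drug_disease_z <- function(tiers, weights = weight_config()) {
  stopifnot(is.list(tiers), all(c("A", "B", "C", "D") %in% names(tiers)))
  drugs <- sort(unique(unlist(lapply(tiers[c("A", "B", "C", "D")], names),
                              use.names = FALSE)))
  if (length(drugs) == 0L) stop("tier maps carry no drug names")
  get <- function(v) {
    out <- setNames(numeric(length(drugs)), drugs)
    if (length(v) > 0L) out[names(v)] <- v
    out
  }
  a <- get(tiers$A); b <- get(tiers$B); c_ <- get(tiers$C); d <- get(tiers$D)
  z <- weights$a * a + weights$b * b + weights$c * c_ + weights$d * d
  data.frame(drug_id = drugs, A = unname(a), B = unname(b), C = unname(c_),
             D = unname(d), z = unname(z), stringsAsFactors = FALSE)
}

#' Rank drugs by descending association Z-score
#'
#' Ties break by ascending gene-tier p-value (column `p_gene`, when
#' present) and then lexicographically by drug id, so rankings are
#' deterministic.
#'
#' @param scores Data.frame with `drug_id` and `z` (optionally `p_gene`).
#' @return The data.frame reordered, with a `rank` column 1..n.
#' @export
rank_drugs <- function(scores) {
  stopifnot(is.data.frame(scores), all(c("drug_id", "z") %in% names(scores)))
  pg <- if ("p_gene" %in% names(scores)) scores$p_gene else
    rep(1, nrow(scores))
  ord <- order(-scores$z, pg, scores$drug_id, method = "radix")
  out <- scores[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Score and rank every drug against a disease profile
#'
#' Runs the hypergeometric overlap test at each of the four tiers (genes,
#' pathways, functions, PPI-expanded genes), normalizes each tier's
#' p-values across drugs, combines them with the tier weights and ranks
#' descending. Tier universes: the catalog gene universe for the gene and
#' PPI tiers, the catalog term universes for pathways and functions.
#'
#' @param drug_profiles Named list of `drug_profile` objects
#'   ([build_drug_profiles()]).
#' @param disease_profile A `disease_profile`
#'   ([build_disease_profile()]).
#' @param catalog An [annotation_catalog()] supplying the universes.
#' @param weights A [weight_config()].
#' @return Ranked data.frame with columns `drug_id`, `A`..`D`, `z`,
#'   `rank`, and the per-tier p-values `p_gene`, `p_pathway`,
#'   `p_function`, `p_ppi`.
#' @export
associate_drugs <- function(drug_profiles, disease_profile, catalog,
                            weights = weight_config()) {
  stopifnot(length(drug_profiles) >= 1L,
            inherits(disease_profile, "disease_profile"),
            inherits(catalog, "annotation_catalog"))
  universes <- list(
    A = catalog$genes,
    B = catalog_terms(catalog, "pathway"),
    C = catalog_terms(catalog, "function"),
    D = catalog$genes
  )
  fields <- c(A = "genes", B = "pathways", C = "functions", D = "ppi_genes")
  dfields <- c(A = "genes", B = "pathways", C = "functions", D = "ppi_genes")
  drugs <- vapply(drug_profiles, `[[`, character(1L), "drug_id")
  pmat <- sapply(names(fields), function(tier) {
    u <- universes[[tier]]
    dset <- disease_profile[[dfields[[tier]]]]
    vapply(drug_profiles, function(dp)
      hypergeom_overlap_test(dp[[fields[[tier]]]], dset, u, warn = FALSE)$p,
      numeric(1L))
  })
  pmat <- matrix(pmat, nrow = length(drugs),
                 dimnames = list(drugs, names(fields)))
  tiers <- lapply(names(fields), function(tier)
    normalize_tier(setNames(pmat[, tier], drugs), weights$alpha))
  names(tiers) <- names(fields)
  scores <- drug_disease_z(tiers, weights)
  scores$p_gene <- pmat[scores$drug_id, "A"]
  scores$p_pathway <- pmat[scores$drug_id, "B"]
  scores$p_function <- pmat[scores$drug_id, "C"]
  scores$p_ppi <- pmat[scores$drug_id, "D"]
  rank_drugs(scores)
}

#' Multi-study consensus drug list
#'
#' Takes the union of each study's top-`top_n` drugs and re-ranks the
#' members by their mean association Z-score across all studies in which
#' they were scored (not only those where they made the cut).
#'
#' @param rankings Non-empty list of ranked data.frames
#'   ([associate_drugs()] output, or any frame with `drug_id`, `z`,
#'   `rank`).
#' @param top_n Per-study list length for membership; default 100.
#' @return Data.frame with `drug_id`, `n_studies` (studies with a score),
#'   `mean_z` and `rank`, ordered by descending mean Z (ties by drug id).
#' @export
consensus_rank <- function(rankings, top_n = 100L) {
  if (!is.list(rankings) || length(rankings) == 0L ||
      !all(vapply(rankings, is.data.frame, logical(1L)))) {
    stop("'rankings' must be a non-empty list of ranked data.frames")
  }
  for (r in rankings) {
    if (!all(c("drug_id", "z", "rank") %in% names(r))) {
      stop("each ranking needs columns 'drug_id', 'z', 'rank'")
    }
  }
  members <- sort(unique(unlist(lapply(rankings, function(r)
    head(r$drug_id[order(r$rank)], top_n)), use.names = FALSE)))
  zs <- sapply(rankings, function(r)
    setNames(r$z, r$drug_id)[members])
  zs <- matrix(zs, nrow = length(members),
               dimnames = list(members, NULL))
  mean_z <- apply(zs, 1L, function(v) mean(v[!is.na(v)]))
  n_st <- apply(zs, 1L, function(v) sum(!is.na(v)))
  out <- data.frame(drug_id = members, n_studies = as.integer(n_st),
                    mean_z = unname(mean_z), stringsAsFactors = FALSE)
  ord <- order(-out$mean_z, out$drug_id, method = "radix")
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
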