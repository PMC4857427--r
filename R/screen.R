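# Composite drug-target scoring: per-target virtual screens are scored by a
# weighted sum of a normalized docking score, normalized ligand-pocket and
# ligand-reference shape similarities, per-descriptor continuous Tanimoto
# similarities to the co-crystallized reference, and a binding-site contact
# correction. Top-k ligands per target are called hits.

#' Scoring weights for the composite drug-target score
#'
#' Holds the weights of the composite score and the hit-calling threshold.
#' Defaults follow the calibrated weighting used for proteochemometric
#' target fishing: docking weight 4, pocket-shape weight 1, reference-shape
#' weight 2, and the top 40 ligands per target called as hits.
#'
#' @param w_k Weight of the normalized docking score. Default 4.
#' @param w_m Weight(s) of the normalized ligand-pocket shape similarity,
#'   one per shape-resolution pair. Default 1.
#' @param w_m_prime Weight(s) of the normalized ligand-reference shape
#'   similarity. Default 2.
#' @param cs_mode How the contact-similarity correction enters the score:
#'   `"once"` adds it a single time (default); `"per_descriptor"` adds it
#'   once per physicochemical descriptor, i.e. the literal reading of the
#'   score with the correction inside the descriptor summation.
#' @param k_hits Number of top-ranked ligands called as hits per target.
#'   Default 40.
#' @return An object of class `score_weights`.
#' @export
score_weights <- function(w_k = 4, w_m = 1, w_m_prime = 2,
                          cs_mode = c("once", "per_descriptor"),
                          k_hits = 40L) {
  cs_mode <- match.arg(cs_mode)
  stopifnot(
    is.numeric(w_k), length(w_k) == 1L, w_k >= 0,
    is.numeric(w_m), all(w_m >= 0),
    is.numeric(w_m_prime), all(w_m_prime >= 0),
    is.numeric(k_hits), length(k_hits) == 1L, k_hits >= 1
  )
  structure(
    list(w_k = w_k, w_m = w_m, w_m_prime = w_m_prime,
         cs_mode = cs_mode, k_hits = as.integer(k_hits)),
    class = "score_weights"
  )
}

#' Min-max normalize a screening metric to the unit interval
#'
#' Linearly rescales a vector of raw component scores so that the most
#' favorable observed value maps to 1 and the least favorable to 0. For a
#' constant column every value equals the most favorable score present, so
#' all values map to 1 (this also covers single-ligand screens).
#'
#' @param values Numeric vector of raw scores; must be finite and non-empty.
#' @param orientation `"higher_better"` if large raw values are favorable
#'   (e.g. similarity), `"lower_better"` if small values are favorable
#'   (e.g. docking energies, shape distances).
#' @return Numeric vector in \[0, 1\], same length as `values`.
#' @export
normalize_metric <- function(values,
                             orientation = c("higher_better", "lower_better")) {
  orientation <- match.arg(orientation)
  if (length(values) == 0L) stop("'values' must be non-empty")
  if (!is.numeric(values) || !all(is.finite(values))) {
    stop("'values' must be finite numbers")
  }
  rng <- range(values)
  if (rng[1L] == rng[2L]) return(rep(1, length(values)))
  out <- (values - rng[1L]) / (rng[2L] - rng[1L])
  if (orientation == "lower_better") out <- 1 - out
  out
}

#' Continuous Tanimoto similarity of two scalar descriptors
#'
#' Continuous (real-valued) Tanimoto coefficient
#' `T = a*b / (a^2 + b^2 - a*b)`, which equals 1 for identical non-zero
#' values and lies in \[-1/3, 1\]. The degenerate pair (0, 0) is defined as
#' 1 (identical descriptor values). Vectorized over `a` and `b`; inside the
#' composite score negative values are floored at 0.
#'
#' @param a,b Finite numeric vectors (recycled).
#' @return Numeric vector of Tanimoto coefficients.
#' @export
scalar_tanimoto <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) ||
      !all(is.finite(a)) || !all(is.finite(b))) {
    stop("'a' and 'b' must be finite numbers")
  }
  denom <- a^2 + b^2 - a * b
  # denom == 0 only when a == b == 0 (positive-definite quadratic form)
  ifelse(denom == 0, 1, (a * b) / denom)
}

#' Euclidean distance between two shape-coefficient vectors
#'
#' Shapes are represented by spherical-harmonic expansion coefficient
#' vectors; dissimilarity is their Euclidean distance. Downstream the
#' distances of a whole screen are min-max normalized with orientation
#' `"lower_better"` so the closest shape scores 1.
#'
#' @param a,b Equal-length finite numeric coefficient vectors.
#' @return Non-negative Euclidean distance.
#' @export
shape_similarity <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) ||
      !all(is.finite(a)) || !all(is.finite(b))) {
    stop("shape coefficients must be finite numbers")
  }
  if (length(a) == 0L || length(a) != length(b)) {
    stop("shape coefficient vectors must be non-empty and of equal length")
  }
  sqrt(sum((a - b)^2))
}

#' Contact similarity between a docked ligand and the reference ligand
#'
#' Correction term rewarding ligands whose binding-site contacts reproduce
#' those of the co-crystallized reference: the fraction of reference contact
#' residues also touched by the ligand, `|L intersect R| / |R|`.
#'
#' @param ligand_contacts Character vector of residue identifiers contacted
#'   by the docked ligand (may be empty).
#' @param reference_contacts Non-empty character vector of residue
#'   identifiers contacted by the reference ligand.
#' @return Contact similarity in \[0, 1\].
#' @export
contact_similarity <- function(ligand_contacts, reference_contacts) {
  reference_contacts <- unique(as.character(reference_contacts))
  if (length(reference_contacts) == 0L) {
    stop("reference contact set must be non-empty")
  }
  ligand_contacts <- unique(as.character(ligand_contacts))
  length(intersect(ligand_contacts, reference_contacts)) /
    length(reference_contacts)
}

# coerce a shape argument (numeric vector or list of vectors) to a list of
# finite numeric vectors; list length is the number M of shape-term pairs
as_shape_list <- function(shape, what = "shape") {
  if (is.numeric(shape)) shape <- list(shape)
  if (!is.list(shape) || length(shape) == 0L) {
    stop(sprintf("'%s' must be a numeric vector or non-empty list of them", what))
  }
  for (v in shape) {
    if (!is.numeric(v) || length(v) == 0L || !all(is.finite(v))) {
      stop(sprintf("'%s' coefficients must be non-empty finite numeric vectors", what))
    }
  }
  shape
}

#' Construct a ligand record
#'
#' One docked ligand in a target screen: identifier, physicochemical
#' descriptor vector, shape-coefficient vector(s), raw docking score
#' (more negative = better binding) and the set of contacted residues.
#'
#' @param ligand_id Non-empty string, unique within a screen.
#' @param descriptors Finite numeric vector of physicochemical descriptors
#'   (the standard panel has 8: solvent-accessible surface area, volume,
#'   dipole, H-bond acceptors, H-bond donors, globularity, ionization
#'   potential, electron affinity).
#' @param shape Numeric shape-coefficient vector, or a list of vectors for
#'   multi-resolution shape sets.
#' @param dock_score Finite raw docking score (lower is better).
#' @param contacts Character vector of contacted residue identifiers.
#' @return An object of class `ligand_record`.
#' @export
ligand_record <- function(ligand_id, descriptors, shape, dock_score,
                          contacts = character()) {
  stopifnot(
    is.character(ligand_id), length(ligand_id) == 1L, nzchar(ligand_id),
    is.numeric(descriptors), length(descriptors) >= 1L,
    all(is.finite(descriptors)),
    is.numeric(dock_score), length(dock_score) == 1L, is.finite(dock_score)
  )
  structure(
    list(ligand_id = ligand_id,
         descriptors = as.numeric(descriptors),
         shape = as_shape_list(shape, "shape"),
         dock_score = as.numeric(dock_score),
         contacts = unique(as.character(contacts))),
    class = "ligand_record"
  )
}

#' Construct a target screen
#'
#' One protein target's virtual screen: the co-crystallized reference
#' ligand, the binding-pocket shape and the docked ligand library. All
#' ligands must share the reference's descriptor count and shape layout.
#'
#' @param target_id Non-empty string (structure identifier).
#' @param reference A [ligand_record()] for the reference ligand; its
#'   contact set must be non-empty.
#' @param pocket_shape Pocket shape-coefficient vector (or list of vectors),
#'   same layout as the ligand shapes.
#' @param ligands Non-empty list of [ligand_record()]s with unique ids.
#' @return An object of class `target_screen`.
#' @export
target_screen <- function(target_id, reference, pocket_shape, ligands) {
  stopifnot(
    is.character(target_id), length(target_id) == 1L, nzchar(target_id),
    inherits(reference, "ligand_record"),
    is.list(ligands), length(ligands) >= 1L
  )
  if (length(reference$contacts) == 0L) {
    stop("reference ligand must have a non-empty contact set")
  }
  pocket_shape <- as_shape_list(pocket_shape, "pocket_shape")
  m <- length(pocket_shape)
  if (length(reference$shape) != m) {
    stop("reference and pocket shape sets must have the same number of resolutions")
  }
  n_desc <- length(reference$descriptors)
  ids <- character(length(ligands))
  for (i in seq_along(ligands)) {
    l <- ligands[[i]]
    if (!inherits(l, "ligand_record")) stop("'ligands' must be ligand_record objects")
    if (length(l$descriptors) != n_desc) {
      stop(sprintf("ligand '%s': descriptor count %d != reference's %d",
                   l$ligand_id, length(l$descriptors), n_desc))
    }
    if (length(l$shape) != m) {
      stop(sprintf("ligand '%s': shape set size differs from pocket's", l$ligand_id))
    }
    ids[i] <- l$ligand_id
  }
  if (anyDuplicated(ids)) stop("ligand ids must be unique within a screen")
  structure(
    list(target_id = target_id, reference = reference,
         pocket_shape = pocket_shape, ligands = ligands),
    class = "target_screen"
  )
}

#' Composite drug-target score for a screen
#'
#' Scores every ligand of a target screen with the weighted composite
#' `Z = w_k * Y + sum_m (w_m * f_m + w'_m * f'_m) + sum_n X_n + w_cs * CS`
#' where `Y` is the screen-normalized docking score, `f_m` / `f'_m` are
#' screen-normalized (0-1, 1 best) ligand-pocket / ligand-reference shape
#' similarities, `X_n` is the continuous Tanimoto similarity to the
#' reference for descriptor `n` floored at 0, and `CS` the contact
#' correction (weighted 1 for `cs_mode = "once"`, or by the descriptor
#' count for `"per_descriptor"`). Ligands are ranked by descending score,
#' ties broken lexicographically by ligand id.
#'
#' @param screen A [target_screen()].
#' @param weights A [score_weights()] configuration.
#' @return A data.frame with one row per ligand, ordered by rank, with
#'   columns `ligand_id`, `z_score`, `rank` and `is_hit`
#'   (`rank <= k_hits`).
#' @export
composite_score <- function(screen, weights = score_weights()) {
  stopifnot(inherits(screen, "target_screen"), inherits(weights, "score_weights"))
  ligs <- screen$ligands
  n <- length(ligs)
  ids <- vapply(ligs, function(l) l$ligand_id, character(1L))

  dock <- vapply(ligs, function(l) l$dock_score, numeric(1L))
  y <- normalize_metric(dock, "lower_better")

  m_pairs <- length(screen$pocket_shape)
  w_m <- rep_len(weights$w_m, m_pairs)
  w_mp <- rep_len(weights$w_m_prime, m_pairs)
  shape_term <- numeric(n)
  for (m in seq_len(m_pairs)) {
    d_pocket <- vapply(ligs, function(l)
      shape_similarity(l$shape[[m]], screen$pocket_shape[[m]]), numeric(1L))
    d_ref <- vapply(ligs, function(l)
      shape_similarity(l$shape[[m]], screen$reference$shape[[m]]), numeric(1L))
    shape_term <- shape_term +
      w_m[m] * normalize_metric(d_pocket, "lower_better") +
      w_mp[m] * normalize_metric(d_ref, "lower_better")
  }

  ref_desc <- screen$reference$descriptors
  x <- vapply(ligs, function(l)
    sum(pmax(0, scalar_tanimoto(l$descriptors, ref_desc))), numeric(1L))

  cs <- vapply(ligs, function(l)
    contact_similarity(l$contacts, screen$reference$contacts), numeric(1L))
  w_cs <- if (weights$cs_mode == "once") 1 else length(ref_desc)

  z <- weights$w_k * y + shape_term + x + w_cs * cs
  ord <- order(-z, ids, method = "radix")
  rnk <- integer(n)
  rnk[ord] <- seq_len(n)
  out <- data.frame(
    ligand_id = ids, z_score = z, rank = rnk,
    is_hit = rnk <= min(weights$k_hits, n),
    stringsAsFactors = FALSE
  )
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call the top-k hits of a scored screen
#'
#' @param results Data.frame from [composite_score()] (needs `ligand_id`
#'   and `rank`).
#' @param k Number of hits to call; `min(k, n)` ligands are returned.
#' @return Character vector of hit ligand ids, in rank order.
#' @export
call_hits <- function(results, k = 40L) {
  stopifnot(is.data.frame(results),
            all(c("ligand_id", "rank") %in% names(results)))
  if (!is.numeric(k) || length(k) != 1L || k < 1) stop("'k' must be >= 1")
  results <- results[order(results$rank), , drop = FALSE]
  head(results$ligand_id, min(as.integer(k), nrow(results)))
}
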