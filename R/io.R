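# Readers and writers for the pipeline's plain-text formats: TSV tables,
# GMT gene sets, per-target screen tables with JSON pocket sidecars.

#' Write a data.frame as UTF-8 TSV
#'
#' Single header row; doubles printed with 6 significant digits for
#' diff-stable output.
#'
#' @param df Data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- trimws(formatC(signif(out[[j]], 6L), format = "g",
                                 digits = 6L))
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Input path.
#' @param required Character vector of column names that must be present.
#' @return Data.frame.
#' @export
read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!is.null(required) && !all(required %in% names(df))) {
    stop(sprintf("'%s' lacks required column(s): %s", path,
                 paste(setdiff(required, names(df)), collapse = ", ")))
  }
  df
}

#' Read a GMT gene-set file
#'
#' Tab-separated: term id, description, then one gene per field. Terms
#' repeated on several lines are merged by gene union; gene symbols are
#' uppercased.
#'
#' @param path GMT file path.
#' @return Named list mapping term id to a sorted character gene set.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  out <- list()
  for (i in seq_along(lines)) {
    if (!nzchar(lines[i])) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop(sprintf("malformed GMT line %d in '%s' (need term, description, genes)",
                   i, path))
    }
    genes <- toupper(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    out[[f[1L]]] <- sort(unique(c(out[[f[1L]]], genes)))
  }
  out
}

#' Write a named list of gene sets as GMT
#' @param sets Named list of character gene sets.
#' @param path Output path.
#' @param descriptions Optional character vector of per-term descriptions
#'   (recycled; defaults to the term id).
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), length(names(sets)) == length(sets))
  terms <- sort(names(sets))
  desc <- if (is.null(descriptions)) terms else rep_len(descriptions, length(terms))
  lines <- vapply(seq_along(terms), function(i)
    paste(c(terms[i], desc[i], sort(unique(toupper(sets[[terms[i]]])))),
          collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}

# convert a GMT-style list (term -> genes) to the long gene/term multimap
gmt_to_multimap <- function(sets) {
  if (length(sets) == 0L) {
    return(data.frame(gene = character(), term = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(gene = unlist(sets, use.names = FALSE),
             term = rep(names(sets), lengths(sets)),
             stringsAsFactors = FALSE)
}

# read a gene->term annotation from either a two-column TSV or a GMT file
read_annotation_any <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    gmt_to_multimap(read_gmt(path))
  } else {
    df <- read_tsv(path)
    names(df)[1:2] <- c("gene", "term")
    df[, 1:2]
  }
}

#' Write one target screen as TSV plus a JSON pocket sidecar
#'
#' The TSV holds one row per ligand (and an `is_reference = 1` row for
#' the reference): `ligand_id`, `is_reference`, `dock_score`, `shape`
#' (semicolon-joined coefficients; multi-resolution sets joined with
#' `|`), the 8 descriptor columns and comma-joined `contacts`. The
#' sidecar `<target_id>.json` stores the target id and pocket shape.
#'
#' @param screen A [target_screen()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the TSV path.
#' @export
write_screen_tsv <- function(screen, dir) {
  stopifnot(inherits(screen, "target_screen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt_shape <- function(sh) paste(vapply(sh, function(v)
    paste(formatC(v, format = "g", digits = 10L), collapse = ";"),
    character(1L)), collapse = "|")
  row_of <- function(l, is_ref) {
    desc <- setNames(as.list(l$descriptors),
                     rep_len(DESCRIPTOR_NAMES, length(l$descriptors)))
    c(list(ligand_id = l$ligand_id, is_reference = as.integer(is_ref),
           dock_score = l$dock_score, shape = fmt_shape(l$shape)),
      desc,
      list(contacts = paste(l$contacts, collapse = ",")))
  }
  rows <- c(list(row_of(screen$reference, TRUE)),
            lapply(screen$ligands, row_of, is_ref = FALSE))
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  tsv <- file.path(dir, paste0(screen$target_id, ".tsv"))
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  jsonlite::write_json(
    list(target_id = screen$target_id,
         pocket_shape = screen$pocket_shape),
    file.path(dir, paste0(screen$target_id, ".json")),
    auto_unbox = TRUE, digits = NA
  )
  invisible(tsv)
}

parse_shape <- function(s) {
  lapply(strsplit(s, "|", fixed = TRUE)[[1L]], function(part)
    as.numeric(strsplit(part, ";", fixed = TRUE)[[1L]]))
}

#' Read a target screen from TSV plus its JSON pocket sidecar
#' @param tsv_path Path to the `<target_id>.tsv` screen table; the sidecar
#'   is looked up as `<target_id>.json` next to it.
#' @return A [target_screen()].
#' @export
read_screen_tsv <- function(tsv_path) {
  df <- read_tsv(tsv_path, required = c("ligand_id", "is_reference",
                                        "dock_score", "shape", "contacts"))
  sidecar <- paste0(file_path_sans_ext(tsv_path), ".json")
  if (!file.exists(sidecar)) stop("missing pocket sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  desc_cols <- setdiff(names(df), c("ligand_id", "is_reference",
                                    "dock_score", "shape", "contacts"))
  mk <- function(i) {
    contacts <- strsplit(as.character(df$contacts[i]), ",", fixed = TRUE)[[1L]]
    ligand_record(as.character(df$ligand_id[i]),
                  as.numeric(df[i, desc_cols]),
                  parse_shape(as.character(df$shape[i])),
                  as.numeric(df$dock_score[i]),
                  contacts[nzchar(contacts)])
  }
  ref_i <- which(df$is_reference == 1L)
  if (length(ref_i) != 1L) stop("screen must have exactly one reference row")
  pocket <- meta$pocket_shape
  if (is.list(pocket)) pocket <- lapply(pocket, as.numeric) else
    pocket <- as.numeric(pocket)
  target_screen(as.character(meta$target_id), mk(ref_i), pocket,
                lapply(setdiff(seq_len(nrow(df)), ref_i), mk))
}

#' Read every screen (`*.tsv` + sidecar) in a directory
#' @param dir Directory of screen tables.
#' @return Named list of [target_screen()] objects.
#' @export
read_screen_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0L) stop("no screen tables (*.tsv) found in ", dir)
  screens <- lapply(files, read_screen_tsv)
  names(screens) <- vapply(screens, `[[`, character(1L), "target_id")
  screens
}

#' Read a PPI edge TSV (gene_a, gene_b, confidence)
#' @param path TSV path.
#' @return A [ppi_table()].
#' @export
read_ppi_tsv <- function(path) {
  ppi_table(read_tsv(path, required = c("gene_a", "gene_b", "confidence")))
}

#' Read a differential-expression TSV (gene, logFC, p, adj_p)
#' @param path TSV path.
#' @return Data.frame.
#' @export
read_de_tsv <- function(path) {
  read_tsv(path, required = c("gene", "p"))
}

#' Read a structure map TSV (structure_id, protein_accession, gene_symbol)
#' @param path TSV path.
#' @return Data.frame.
#' @export
read_structure_map_tsv <- function(path) {
  read_tsv(path, required = c("structure_id", "gene_symbol"))
}
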