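# Exchange-format readers and writers. All tabular formats are TSV with a
# header row, UTF-8; sequences are FASTA; configuration and reports are JSON.

.required_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

.read_tsv <- function(path, what, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    warning(what, ": empty file, returning empty table", call. = FALSE)
    df <- as.data.frame(setNames(rep(list(character()), length(required)),
                                 required))
    return(df)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""), fileEncoding = "UTF-8")
  .required_cols(df, required, what)
  df
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write the typed input tables
#'
#' Each reader validates the column roster and basic invariants; each writer
#' produces a TSV that the matching reader restores losslessly (round-trip
#' identity at printed precision, deterministic column order).
#'
#' Table rosters:
#' \describe{
#'   \item{compounds}{`compound_id`, `smiles`, `ob`, `dl`, and optionally the
#'     five ADMET level columns `admet_as`, `admet_bbb`, `admet_cyp2d6`,
#'     `admet_hepatotox`, `admet_ppb`.}
#'   \item{docking}{`compound_id`, `target_id`, `s_i`, `s_m`, `success`
#'     (logical). Failed dockings carry no score requirement.}
#'   \item{ppi}{`target_a`, `target_b`, `combined_score` in (0, 1].}
#'   \item{pathways}{`pathway_id`, `name`, `p_value`, `q_value`,
#'     `member_targets` and `diseases` as `;`-joined id lists.}
#' }
#'
#' @param path file path.
#' @param df table to write.
#' @return the validated `data.frame` (readers) or `path` invisibly (writers).
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_compound_table <- function(path) {
  df <- .read_tsv(path, "compound table", c("compound_id", "smiles", "ob", "dl"))
  if (anyDuplicated(df$compound_id)) {
    stop("duplicate compound_id: ",
         paste(unique(df$compound_id[duplicated(df$compound_id)]),
               collapse = ", "), call. = FALSE)
  }
  for (col in c("ob", "dl")) df[[col]] <- as.numeric(df[[col]])
  df
}

#' @rdname table_io
#' @export
write_compound_table <- function(df, path) .write_tsv(df, path)

#' @rdname table_io
#' @export
read_docking_table <- function(path) {
  df <- .read_tsv(path, "docking table",
                  c("compound_id", "target_id", "s_i", "s_m", "success"))
  df$s_i <- as.numeric(df$s_i)
  df$s_m <- as.numeric(df$s_m)
  df$success <- as.logical(df$success)
  bad <- which(df$success & !(df$s_m > 0))
  if (length(bad) > 0) {
    stop("docking table: successful records need s_m > 0 at line(s) ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname table_io
#' @export
write_docking_table <- function(df, path) .write_tsv(df, path)

#' @rdname table_io
#' @export
read_ppi_table <- function(path) {
  df <- .read_tsv(path, "PPI table", c("target_a", "target_b", "combined_score"))
  df$combined_score <- as.numeric(df$combined_score)
  bad <- which(df$target_a == df$target_b |
               !(df$combined_score > 0 & df$combined_score <= 1))
  if (length(bad) > 0) {
    stop("PPI table: self-loop or combined_score outside (0,1] at line(s) ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname table_io
#' @export
write_ppi_table <- function(df, path) .write_tsv(df, path)

#' @rdname table_io
#' @export
read_pathway_table <- function(path) {
  df <- .read_tsv(path, "pathway table",
                  c("pathway_id", "name", "p_value", "q_value",
                    "member_targets", "diseases"))
  df$p_value <- as.numeric(df$p_value)
  df$q_value <- as.numeric(df$q_value)
  bad <- which(df$p_value < 0 | df$p_value > 1 | df$q_value < 0 | df$q_value > 1)
  if (length(bad) > 0) {
    stop("pathway table: p/q outside [0,1] at line(s) ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname table_io
#' @export
write_pathway_table <- function(df, path) .write_tsv(df, path)

#' Split / join `;`-separated id lists used in pathway tables
#' @param x character vector of joined lists (or list of character vectors).
#' @return list of character vectors (or character vector).
#' @export
split_ids <- function(x) {
  lapply(strsplit(ifelse(is.na(x) | x == "", "", x), ";", fixed = TRUE),
         function(v) v[nzchar(v)])
}

#' @rdname split_ids
#' @export
join_ids <- function(x) vapply(x, paste, character(1), collapse = ";")

#' Read protein sequences from FASTA
#'
#' Record ids may carry a `|full` or `|motif` suffix distinguishing the
#' full-length sequence from the motif ("functional length") variant of the
#' same target; unsuffixed ids are treated as full-length.
#'
#' @param path FASTA file.
#' @return data.frame with `target_id`, `variant` and `sequence` columns.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    warning("protein FASTA: empty file, returning empty table", call. = FALSE)
    return(data.frame(target_id = character(), variant = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  ids <- names(recs)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  parts <- strsplit(ids, "|", fixed = TRUE)
  data.frame(
    target_id = vapply(parts, `[`, character(1), 1),
    variant = vapply(parts, function(p) {
      if (length(p) > 1) p[2] else "full"
    }, character(1)),
    sequence = toupper(vapply(recs, as.character, character(1))),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' @rdname read_protein_fasta
#' @param df table as returned by `read_protein_fasta`.
#' @param path output path.
#' @export
write_protein_fasta <- function(df, path) {
  ids <- paste(df$target_id, df$variant, sep = "|")
  seqinr::write.fasta(as.list(df$sequence), ids, file.out = path)
  invisible(path)
}

#' Screen compound nodes on oral bioavailability and drug-likeness
#'
#' Keeps compounds with `ob >= ob_min` and `dl >= dl_min` (both bounds
#' inclusive), preserving row order. Idempotent.
#'
#' @param table compound table (see [read_compound_table()]).
#' @param ob_min,dl_min inclusive thresholds; defaults are the standard
#'   screening values OB >= 30\%, DL >= 0.18.
#' @return filtered compound table.
#' @export
filter_compounds <- function(table, ob_min = 30, dl_min = 0.18) {
  .required_cols(table, c("ob", "dl"), "compound table")
  if (!is.numeric(table$ob) || !is.numeric(table$dl)) {
    stop("compound table: ob and dl must be numeric", call. = FALSE)
  }
  table[table$ob >= ob_min & table$dl >= dl_min, , drop = FALSE]
}

#' Screen pathway nodes on enrichment significance
#'
#' Keeps pathways with `p_value < p_max` (strict) that retain at least one
#' member target; pathways without clustered gene targets are deleted.
#'
#' @param table pathway table (see [read_pathway_table()]).
#' @param p_max strict threshold, default 1e-8.
#' @return filtered pathway table (warns when empty).
#' @export
filter_pathways <- function(table, p_max = 1e-8) {
  .required_cols(table, c("p_value", "member_targets"), "pathway table")
  members <- split_ids(table$member_targets)
  keep <- table$p_value < p_max & lengths(members) > 0
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("pathway filter removed every pathway")
  out
}

#' Load a full input bundle
#'
#' @param paths named list/vector with entries `compounds`, `docking`, `ppi`,
#'   `pathways`, and optionally `sequences` (FASTA) and `peaks`.
#' @param config optional [ctpdn_config()]; when given, the compound and
#'   pathway node filters are applied on load.
#' @return named list of typed tables.
#' @export
load_inputs <- function(paths, config = NULL) {
  bundle <- list(
    compounds = read_compound_table(paths[["compounds"]]),
    docking = read_docking_table(paths[["docking"]]),
    ppi = read_ppi_table(paths[["ppi"]]),
    pathways = read_pathway_table(paths[["pathways"]])
  )
  if (!is.null(paths[["sequences"]])) {
    bundle$sequences <- read_protein_fasta(paths[["sequences"]])
  }
  if (!is.null(paths[["peaks"]])) {
    bundle$peaks <- read_peak_table(paths[["peaks"]])
  }
  if (!is.null(config)) {
    bundle$compounds <- filter_compounds(bundle$compounds,
                                         config$ob_min, config$dl_min)
    bundle$pathways <- filter_pathways(bundle$pathways, config$pathway_p_max)
  }
  bundle
}

#' Serialize an analysis report to JSON
#'
#' Data frames become arrays of row objects; +Inf path lengths are written as
#' the literal string `"inf"` so the report survives strict JSON parsers.
#'
#' @param results named list of results (data frames, vectors, scalars).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  enc <- rapply(results, function(x) {
    if (is.numeric(x)) ifelse(is.infinite(x), "inf", x) else x
  }, how = "replace")
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
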