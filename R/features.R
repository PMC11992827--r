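# Assembly of the four compound-target interaction feature datasets.
#
# Each row is a compound-target pair; columns are the compound fingerprint
# block (MACCS 167 or ECFP6 2048 bits), the five ADMET level columns, and
# the 29-entry protein descriptor block, in that fixed order. The four
# dataset kinds combine the two fingerprints with the two sequence variants:
# MF (MACCS x full length), MM (MACCS x motif), EF (ECFP6 x full length),
# EM (ECFP6 x motif). Before duplicate-column removal the column counts are
# 167 + 5 + 29 = 201 (MF/MM) and 2048 + 5 + 29 = 2082 (EF/EM).

.ADMET_COLS <- c("admet_as", "admet_bbb", "admet_cyp2d6", "admet_hepatotox",
                 "admet_ppb")

.FEATURE_KINDS <- c("MF", "MM", "EF", "EM")

#' Assemble a compound-target interaction feature table
#'
#' @param pairs data.frame with `compound_id`, `target_id` and optionally a
#'   binary `label` column (1 = interacting, 0 = not; typically the docking
#'   outcome).
#' @param compounds compound table with `compound_id`, `smiles` and the five
#'   ADMET columns `admet_as`, `admet_bbb`, `admet_cyp2d6`,
#'   `admet_hepatotox`, `admet_ppb`.
#' @param sequences protein sequence table with `target_id`, `variant`
#'   (`"full"`/`"motif"`) and `sequence` (see [read_protein_fasta()]).
#' @param kind one of `"MF"`, `"MM"`, `"EF"`, `"EM"`.
#' @return object of class `cti_feature_table`: a data.frame of descriptor
#'   columns plus a final `label` column (NA when `pairs` had none), with
#'   attributes `kind` and `roster` (descriptor column names).
#' @export
assemble_feature_table <- function(pairs, compounds, sequences,
                                   kind = c("MF", "MM", "EF", "EM")) {
  kind <- match.arg(kind)
  fp_fun <- if (substr(kind, 1, 1) == "M") maccs_fp else ecfp6_fp
  variant <- if (substr(kind, 2, 2) == "F") "full" else "motif"

  .required_cols(pairs, c("compound_id", "target_id"), "pairs table")
  .required_cols(compounds, c("compound_id", "smiles", .ADMET_COLS),
                 "compound table")
  .required_cols(sequences, c("target_id", "variant", "sequence"),
                 "sequence table")

  seqs <- sequences[sequences$variant == variant, , drop = FALSE]
  missing_seq <- setdiff(unique(pairs$target_id), seqs$target_id)
  if (length(missing_seq) > 0) {
    stop(sprintf("missing %s-length sequence for target(s): %s", variant,
                 paste(missing_seq, collapse = ", ")))
  }
  missing_cmp <- setdiff(unique(pairs$compound_id), compounds$compound_id)
  if (length(missing_cmp) > 0) {
    stop("pairs reference unknown compound(s): ",
         paste(missing_cmp, collapse = ", "))
  }

  used_cmp <- unique(as.character(pairs$compound_id))
  if (nrow(pairs) == 0) {
    fp_cols <- if (identical(fp_fun, maccs_fp)) sprintf("MACCS_%03d", 0:166)
               else sprintf("ECFP6_%04d", 1:2048)
    roster <- c(fp_cols, .ADMET_COLS, .PROT_DESC_NAMES)
    out <- as.data.frame(matrix(numeric(0), 0, length(roster) + 1,
                                dimnames = list(NULL, c(roster, "label"))))
    return(structure(out, kind = kind, roster = roster,
                     class = c("cti_feature_table", "data.frame")))
  }

  ci <- match(used_cmp, compounds$compound_id)
  fp <- fp_fun(as.character(compounds$smiles[ci]), used_cmp)
  admet <- as.matrix(compounds[ci, .ADMET_COLS, drop = FALSE])
  rownames(admet) <- used_cmp
  if (any(!is.finite(admet))) {
    stop("non-finite ADMET values for compound(s): ",
         paste(used_cmp[!stats::complete.cases(admet)], collapse = ", "))
  }

  used_tgt <- unique(as.character(pairs$target_id))
  prot <- t(vapply(used_tgt, function(t_id) {
    s <- seqs$sequence[match(t_id, seqs$target_id)]
    protein_descriptor_vector(s)
  }, numeric(length(.PROT_DESC_NAMES))))

  X <- cbind(fp[match(pairs$compound_id, used_cmp), , drop = FALSE],
             admet[match(pairs$compound_id, used_cmp), , drop = FALSE],
             prot[match(pairs$target_id, used_tgt), , drop = FALSE])
  out <- as.data.frame(X, row.names = NULL)
  out$label <- if ("label" %in% names(pairs)) as.integer(pairs$label) else
    NA_integer_
  structure(out, kind = kind, roster = colnames(X),
            class = c("cti_feature_table", "data.frame"))
}

#' Drop duplicated descriptor columns
#'
#' Removes every descriptor column identical (across all rows) to an earlier
#' one, keeping the first occurrence; constant columns participate in the
#' matching like any other. The `label` column is never touched. Idempotent.
#'
#' @param table a `cti_feature_table` (or plain data.frame with a `label`
#'   column last).
#' @return the table without duplicated columns; attribute
#'   `n_features_before` records the pre-removal descriptor count.
#' @export
drop_duplicate_columns <- function(table) {
  lab <- table$label
  desc <- table[, setdiff(names(table), "label"), drop = FALSE]
  keep <- !duplicated(as.list(desc))
  out <- desc[, keep, drop = FALSE]
  out$label <- lab
  structure(out, kind = attr(table, "kind"), roster = names(out)[-ncol(out)],
            n_features_before = ncol(desc),
            class = c("cti_feature_table", "data.frame"))
}

#' @export
print.cti_feature_table <- function(x, ...) {
  cat(sprintf("CTI feature table (%s): %d pair(s) x %d descriptor column(s)\n",
              attr(x, "kind") %||% "?", nrow(x), ncol(x) - 1L))
  if (!all(is.na(x$label))) {
    cat(sprintf("  labels: %d positive / %d negative\n",
                sum(x$label == 1, na.rm = TRUE),
                sum(x$label == 0, na.rm = TRUE)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
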