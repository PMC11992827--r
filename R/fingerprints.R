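# Molecular fingerprints via ChemmineR's OpenBabel backend.
#
# MACCS: OpenBabel evaluates the 166 MACCS SMARTS keys and returns a
# 256-bit padded vector with key k stored at 0-based position k; the first
# 167 positions are kept, so the vector is emitted with position 0 present
# but unused (bit index = MACCS key number).
#
# ECFP6: extended-connectivity (circular, radius 3) fingerprint, hashed by
# OpenBabel into 4096 bits and folded here (bitwise OR of the two halves)
# to the conventional 2048-bit layout. Folding preserves determinism and
# canonicalisation invariance.

.smiles_to_sdf <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- paste0("cmp", seq_along(smiles))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(setNames(smiles, ids))),
    error = function(e) {
      stop("unparseable SMILES among compound(s) ",
           paste(ids, collapse = ", "), ": ", conditionMessage(e),
           call. = FALSE)
    })
  if (anyDuplicated(ids)) {
    ids <- make.unique(ids, sep = "_")
  }
  ChemmineR::cid(sdf) <- ids
  ok <- ChemmineR::validSDF(sdf)
  if (!all(ok)) {
    stop("unparseable SMILES for compound(s): ",
         paste(ids[!ok], collapse = ", "), call. = FALSE)
  }
  sdf
}

#' MACCS substructure-key fingerprints
#'
#' @param smiles character vector of SMILES strings.
#' @param ids optional compound ids used in error messages and rownames.
#' @return binary integer matrix, one row per compound, 167 columns
#'   (`MACCS_000` ... `MACCS_166`; position 0 present but unused, columns
#'   indexed by MACCS key number).
#' @export
maccs_fp <- function(smiles, ids = NULL) {
  sdf <- .smiles_to_sdf(smiles, ids)
  m <- ChemmineR::fingerprintOB(sdf, "MACCS")@fpma
  m <- m[, seq_len(167), drop = FALSE]
  storage.mode(m) <- "integer"
  colnames(m) <- sprintf("MACCS_%03d", 0:166)
  m
}

#' ECFP6 circular fingerprints folded to 2048 bits
#'
#' @inheritParams maccs_fp
#' @return binary integer matrix, one row per compound, 2048 columns
#'   (`ECFP6_0001` ... `ECFP6_2048`).
#' @export
ecfp6_fp <- function(smiles, ids = NULL) {
  sdf <- .smiles_to_sdf(smiles, ids)
  m <- ChemmineR::fingerprintOB(sdf, "ECFP6")@fpma
  while (ncol(m) > 2048) {
    half <- ncol(m) / 2
    m <- (m[, seq_len(half), drop = FALSE] |
            m[, half + seq_len(half), drop = FALSE]) * 1L
  }
  storage.mode(m) <- "integer"
  colnames(m) <- sprintf("ECFP6_%04d", seq_len(ncol(m)))
  m
}
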