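# Sequence-derived protein physicochemical descriptors (ProtParam-style).
# The descriptor vector has exactly 29 entries: 20 amino-acid composition
# counts, theoretical pI, two 280 nm extinction coefficients (cystine-bonded
# and reduced), three estimated N-end-rule half-lives (mammalian, yeast,
# E. coli; hours), instability index, aliphatic index, and GRAVY.

.check_seq <- function(seq, tolerate_ambiguous = FALSE, min_len = 1) {
  if (length(seq) != 1 || is.na(seq)) stop("expected a single sequence string")
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) < min_len) {
    stop(sprintf("sequence must have at least %d residue(s)", min_len))
  }
  bad <- setdiff(unique(chars), .AA)
  if (length(bad) > 0) {
    if (!tolerate_ambiguous) {
      stop("non-standard residue(s): ", paste(bad, collapse = ", "),
           " (set tolerate_ambiguous = TRUE to drop them)")
    }
    warning("dropping non-standard residue(s): ", paste(bad, collapse = ", "))
    chars <- chars[chars %in% .AA]
    if (length(chars) < min_len) stop("no standard residues left")
  }
  chars
}

#' Amino-acid composition counts
#'
#' @param seq protein sequence (single string over the 20-letter alphabet).
#' @param tolerate_ambiguous drop non-standard letters (B, Z, X, U, ...) with
#'   a warning instead of erroring.
#' @return named integer vector of 20 counts (order ACDEFGHIKLMNPQRSTVWY);
#'   counts sum to the (standard-residue) sequence length.
#' @export
aa_composition <- function(seq, tolerate_ambiguous = FALSE) {
  chars <- .check_seq(seq, tolerate_ambiguous)
  counts <- table(factor(chars, levels = .AA))
  setNames(as.integer(counts), .AA)
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues; bounded by the table
#' extremes `[-4.5, 4.5]`.
#'
#' @inheritParams aa_composition
#' @return numeric scalar.
#' @export
gravy <- function(seq, tolerate_ambiguous = FALSE) {
  chars <- .check_seq(seq, tolerate_ambiguous)
  mean(.KD_HYDROPATHY[chars])
}

#' Aliphatic index
#'
#' Ikai's index: `AI = X_Ala + 2.9 X_Val + 3.9 (X_Ile + X_Leu)` with X the
#' mole percent of each residue.
#'
#' @inheritParams aa_composition
#' @return numeric scalar.
#' @export
aliphatic_index <- function(seq, tolerate_ambiguous = FALSE) {
  cnt <- aa_composition(seq, tolerate_ambiguous)
  x <- 100 * cnt / sum(cnt)
  unname(x["A"] + 2.9 * x["V"] + 3.9 * (x["I"] + x["L"]))
}

#' Molar extinction coefficients at 280 nm
#'
#' Edelhoch/Pace increments: 5500 per Trp, 1490 per Tyr, plus 125 per
#' cystine pair (`floor(nCys / 2)`) in the cystine-bonded form.
#'
#' @inheritParams aa_composition
#' @return named numeric vector `c(cystine = , reduced = )` (1/(M cm)).
#' @export
extinction_coefficients <- function(seq, tolerate_ambiguous = FALSE) {
  cnt <- aa_composition(seq, tolerate_ambiguous)
  reduced <- .EXT_TRP * cnt[["W"]] + .EXT_TYR * cnt[["Y"]]
  cystine <- reduced + .EXT_CYSTINE * (cnt[["C"]] %/% 2L)
  c(cystine = cystine, reduced = reduced)
}

#' Estimated half-life (N-end rule)
#'
#' Table lookup on the N-terminal residue against the Expasy N-end-rule
#' table. Open-ended entries (">20 h", ">10 h") are encoded as their numeric
#' bound; minute-scale entries are converted to hours.
#'
#' @inheritParams aa_composition
#' @return named numeric vector `c(mammalian = , yeast = , ecoli = )`, hours.
#' @export
estimated_half_life <- function(seq, tolerate_ambiguous = FALSE) {
  chars <- .check_seq(seq, tolerate_ambiguous)
  first <- chars[1]
  setNames(.HALF_LIFE[first, ], colnames(.HALF_LIFE))
}

#' Instability index
#'
#' Guruprasad's dipeptide statistic:
#' `II = (10 / L) * sum DIWV(x_i, x_{i+1})` over the `L - 1` overlapping
#' dipeptides, with the published dipeptide instability weight table.
#' Values above 40 predict an unstable protein in vitro.
#'
#' @inheritParams aa_composition
#' @return numeric scalar; errors on sequences shorter than 2 residues.
#' @export
instability_index <- function(seq, tolerate_ambiguous = FALSE) {
  chars <- .check_seq(seq, tolerate_ambiguous, min_len = 2)
  L <- length(chars)
  s <- sum(.DIWV[cbind(chars[-L], chars[-1])])
  10 / L * s
}

.net_charge <- function(pH, counts, first) {
  pk_nt <- if (first %in% names(.PKA_NTERM)) .PKA_NTERM[[first]] else
    .PKA_NTERM_DEFAULT
  pos <- 1 / (1 + 10^(pH - pk_nt))
  for (aa in names(.PKA_SIDE_POS)) {
    pos <- pos + counts[[aa]] / (1 + 10^(pH - .PKA_SIDE_POS[[aa]]))
  }
  neg <- 1 / (1 + 10^(.PKA_CTERM - pH))
  for (aa in names(.PKA_SIDE_NEG)) {
    neg <- neg + counts[[aa]] / (1 + 10^(.PKA_SIDE_NEG[[aa]] - pH))
  }
  pos - neg
}

#' Theoretical isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge of the sequence is zero,
#' found by bisection on `[0, 14]` with the Bjellqvist pKa set (including
#' the residue-specific N-terminal values used by the Expasy server).
#'
#' @inheritParams aa_composition
#' @param tol bisection tolerance on pH (default 0.01 as is conventional;
#'   iteration continues until the net charge is below 1e-3 or the bracket
#'   is below 1e-6).
#' @return numeric pI.
#' @export
theoretical_pi <- function(seq, tolerate_ambiguous = FALSE, tol = 0.01) {
  chars <- .check_seq(seq, tolerate_ambiguous)
  counts <- aa_composition(paste(chars, collapse = ""))
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- .net_charge(mid, counts, chars[1])
    if (abs(q) < 1e-3 || (hi - lo) < min(tol, 1e-6)) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

.PROT_DESC_NAMES <- c(paste0("aa_", .AA), "pi", "eps_cystine", "eps_reduced",
                      "hl_mammalian", "hl_yeast", "hl_ecoli",
                      "instability", "aliphatic", "gravy")

#' Full 29-entry protein descriptor vector
#'
#' Fixed order: 20 composition counts (`aa_A` ... `aa_Y`), `pi`,
#' `eps_cystine`, `eps_reduced`, `hl_mammalian`, `hl_yeast`, `hl_ecoli`,
#' `instability`, `aliphatic`, `gravy`.
#'
#' @inheritParams aa_composition
#' @return named numeric vector of length 29.
#' @export
protein_descriptor_vector <- function(seq, tolerate_ambiguous = FALSE) {
  chars <- .check_seq(seq, tolerate_ambiguous, min_len = 2)
  clean <- paste(chars, collapse = "")
  eps <- extinction_coefficients(clean)
  hl <- estimated_half_life(clean)
  v <- c(aa_composition(clean), theoretical_pi(clean),
         eps[["cystine"]], eps[["reduced"]],
         hl[["mammalian"]], hl[["yeast"]], hl[["ecoli"]],
         instability_index(clean), aliphatic_index(clean), gravy(clean))
  setNames(v, .PROT_DESC_NAMES)
}
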