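# Synthetic fixtures with known ground truth. Every generator is a pure
# function of its spec (which carries the seed): the same spec reproduces
# the same tables bit for bit. Ground-truth records are returned alongside
# the data so downstream tests never re-derive the truth from generator
# internals.

#' Simulation specification
#'
#' Collects every knob of the three generators. The defaults mirror the
#' study conditions the package emulates: a formula-scale network (tens of
#' compounds, ~20 hub targets, a handful of enriched pathways, two disease
#' nodes), a docking-labelled pair set of 966 pairs, and a three-group
#' (Con/Mod/BWG) serum peak table with pooled QC injections.
#'
#' @param seed integer master seed.
#' @param n_compounds,n_targets,n_pathways,n_diseases network layer sizes.
#' @param cti_density probability a compound-target docking succeeds
#'   (published whole-formula success rates were roughly 20-35\%).
#' @param tti_density probability a target pair has a PPI edge.
#' @param s_m_range range of reference-ligand docking scores.
#' @param planted_multiplier docking-ratio multiplier of the planted best
#'   compound (its score ratio is this multiple of the per-target maximum of
#'   all other compounds).
#' @param n_pairs labelled compound-target pairs for the classifier set.
#' @param rule_bit_prevalence target prevalence of the planted fingerprint
#'   bit in the labelling rule.
#' @param label_noise probability a label is flipped.
#' @param seq_len_range protein sequence length range.
#' @param residue_freq `"uniform"` or `"background"` (Robinson-Robinson-like
#'   frequencies).
#' @param n_features,n_per_group,n_qc peak-table dimensions (three groups
#'   Con/Mod/BWG of `n_per_group` each plus `n_qc` QC injections).
#' @param n_planted,effect_size planted differential features and their
#'   group-mean shift in units of the feature's log-scale SD.
#' @param missing_rate completely-at-random missingness rate in biological
#'   samples.
#' @param qc_rsd target QC relative standard deviation.
#' @param feature_log_sd log10-scale within-group SD of every feature.
#' @return object of class `ctpdn_simspec`.
#' @export
sim_spec <- function(seed = 1L,
                     n_compounds = 10, n_targets = 8, n_pathways = 4,
                     n_diseases = 2, cti_density = 0.3, tti_density = 0.3,
                     s_m_range = c(20, 60), planted_multiplier = 2,
                     n_pairs = 966, rule_bit_prevalence = 0.7,
                     label_noise = 0, seq_len_range = c(50, 300),
                     residue_freq = c("uniform", "background"),
                     n_features = 200, n_per_group = 6, n_qc = 6,
                     n_planted = 3, effect_size = 4, missing_rate = 0.05,
                     qc_rsd = 0.05, feature_log_sd = 0.15) {
  residue_freq <- match.arg(residue_freq)
  stopifnot(n_compounds >= 1, n_targets >= 1, n_pathways >= 1,
            n_diseases >= 1, cti_density > 0, cti_density <= 1,
            label_noise >= 0, label_noise < 1,
            missing_rate >= 0, missing_rate < 1, planted_multiplier > 0)
  structure(as.list(environment()), class = "ctpdn_simspec")
}

#' Generate a network fixture with a planted best compound
#'
#' Draws docking, PPI, pathway and disease-link tables. One compound (the
#' planted one) docks successfully against every target with a score ratio
#' `planted_multiplier` times the per-target maximum of all other
#' compounds, so for any multiplier > 1 it is guaranteed to attain the
#' minimal mean shortest-path length.
#'
#' @param spec a [sim_spec()].
#' @return list with `compounds`, `docking`, `ppi`, `pathways` tables and
#'   `truth` (`planted_compound`, `multiplier`).
#' @export
gen_network <- function(spec) {
  stopifnot(inherits(spec, "ctpdn_simspec"))
  set.seed(spec$seed)
  comp <- sprintf("C%02d", seq_len(spec$n_compounds))
  tgt <- sprintf("T%02d", seq_len(spec$n_targets))
  pw <- sprintf("P%02d", seq_len(spec$n_pathways))
  dis <- sprintf("D%02d", seq_len(spec$n_diseases))
  planted <- comp[1]

  s_m <- stats::runif(spec$n_targets, spec$s_m_range[1], spec$s_m_range[2])
  ratio <- matrix(stats::runif(spec$n_compounds * spec$n_targets, 0.5, 1.5),
                  spec$n_compounds, spec$n_targets,
                  dimnames = list(comp, tgt))
  others_max <- if (spec$n_compounds > 1) {
    apply(ratio[-1, , drop = FALSE], 2, max)
  } else ratio[1, ]
  ratio[1, ] <- spec$planted_multiplier * others_max
  success <- matrix(stats::runif(spec$n_compounds * spec$n_targets) <
                      spec$cti_density,
                    spec$n_compounds, spec$n_targets)
  success[1, ] <- TRUE                       # planted compound always docks
  docking <- data.frame(
    compound_id = rep(comp, times = spec$n_targets),
    target_id = rep(tgt, each = spec$n_compounds),
    s_i = as.vector(ratio * rep(s_m, each = spec$n_compounds)),
    s_m = rep(s_m, each = spec$n_compounds),
    success = as.vector(success), stringsAsFactors = FALSE)
  docking$s_i[!docking$success] <- NA
  docking$s_m[!docking$success] <- NA

  prs <- which(upper.tri(matrix(0, spec$n_targets, spec$n_targets)),
               arr.ind = TRUE)
  keep <- stats::runif(nrow(prs)) < spec$tti_density
  ppi <- data.frame(target_a = tgt[prs[keep, 1]], target_b = tgt[prs[keep, 2]],
                    combined_score = stats::runif(sum(keep), 0.4, 0.99),
                    stringsAsFactors = FALSE)

  members <- lapply(seq_len(spec$n_pathways), function(i) {
    m <- tgt[stats::runif(spec$n_targets) < 0.5]
    if (length(m) == 0) m <- sample(tgt, 1)
    m
  })
  dlinks <- lapply(seq_len(spec$n_pathways), function(i) {
    d <- dis[stats::runif(spec$n_diseases) < 0.7]
    if (length(d) == 0) d <- sample(dis, 1)
    d
  })
  # every disease must be linked to at least one pathway
  for (d in dis) {
    if (!any(vapply(dlinks, function(x) d %in% x, logical(1)))) {
      j <- sample(spec$n_pathways, 1)
      dlinks[[j]] <- c(dlinks[[j]], d)
    }
  }
  pathways <- data.frame(
    pathway_id = pw, name = paste("pathway", pw),
    p_value = 10^(-stats::runif(spec$n_pathways, 9, 15)),
    q_value = 10^(-stats::runif(spec$n_pathways, 8, 14)),
    member_targets = join_ids(members), diseases = join_ids(dlinks),
    stringsAsFactors = FALSE)

  compounds <- data.frame(compound_id = comp,
                          smiles = NA_character_,
                          ob = stats::runif(spec$n_compounds, 30, 90),
                          dl = stats::runif(spec$n_compounds, 0.18, 0.9),
                          stringsAsFactors = FALSE)

  list(compounds = compounds, docking = docking, ppi = ppi,
       pathways = pathways,
       truth = list(planted_compound = planted,
                    multiplier = spec$planted_multiplier))
}

.SMILES_RINGS <- c("c1ccccc1", "C1CCCCC1", "c1ccncc1", "c1ccoc1",
                   "C1CCNCC1", "c1ccc2ccccc2c1", "C1CCOCC1", "c1cc[nH]c1")
.SMILES_PREFIX <- c("", "C", "CC", "CCO", "CN", "CCN", "CC(C)", "COC",
                    "CC(=O)", "OCC")
.SMILES_SUFFIX <- c("", "O", "N", "C", "CO", "OC", "C(=O)O", "CC", "CN",
                    "C(C)O")

.gen_smiles_pool <- function() {
  g <- expand.grid(p = .SMILES_PREFIX, r = .SMILES_RINGS, s = .SMILES_SUFFIX,
                   stringsAsFactors = FALSE)
  unique(paste0(g$p, g$r, g$s))
}

.RESIDUE_BG <- c(A = .078, C = .019, D = .053, E = .063, F = .039, G = .072,
                 H = .023, I = .053, K = .059, L = .091, M = .022, N = .045,
                 P = .052, Q = .043, R = .051, S = .068, T = .059, V = .066,
                 W = .014, Y = .032)

.gen_sequences <- function(n, len_range, freq_mode) {
  prob <- if (freq_mode == "uniform") rep(1 / 20, 20) else
    .RESIDUE_BG / sum(.RESIDUE_BG)
  vapply(seq_len(n), function(i) {
    L <- sample(seq(len_range[1], len_range[2]), 1)
    paste(sample(.AA, L, replace = TRUE, prob = prob), collapse = "")
  }, character(1))
}

#' Generate a labelled compound-target pair set with a planted rule
#'
#' Compounds get SMILES from a small fragment grammar (rings, chains, O/N
#' substitutions) and fabricated ADMET levels; targets get random sequences
#' (full-length, plus a motif variant cut from the middle). The binary
#' label follows the planted rule *fingerprint bit b set AND target GRAVY
#' above the median*, with the bit chosen (per draw) as the MACCS bit whose
#' prevalence is closest to `rule_bit_prevalence`, XOR label noise.
#'
#' @param spec a [sim_spec()].
#' @return list with `compounds`, `sequences`, `pairs` (with `label`) and
#'   `truth` (`rule_bit`, `gravy_median`, `bayes_label`, class balance).
#' @export
gen_cti_dataset <- function(spec) {
  stopifnot(inherits(spec, "ctpdn_simspec"))
  set.seed(spec$seed + 1L)
  pool <- .gen_smiles_pool()
  n_cmp <- min(60, length(pool))
  smiles <- sample(pool, n_cmp)
  comp <- sprintf("C%03d", seq_len(n_cmp))
  admet <- matrix(sample(0:4, n_cmp * 5, replace = TRUE), n_cmp, 5,
                  dimnames = list(NULL, .ADMET_COLS))
  compounds <- data.frame(compound_id = comp, smiles = smiles,
                          ob = stats::runif(n_cmp, 30, 90),
                          dl = stats::runif(n_cmp, 0.18, 0.9),
                          admet, stringsAsFactors = FALSE)

  n_tgt <- 20
  tgt <- sprintf("T%03d", seq_len(n_tgt))
  full <- .gen_sequences(n_tgt, spec$seq_len_range, spec$residue_freq)
  motif <- vapply(full, function(s) {
    L <- nchar(s); w <- max(10, L %/% 4)
    substr(s, (L - w) %/% 2 + 1, (L - w) %/% 2 + w)
  }, character(1))
  sequences <- data.frame(
    target_id = rep(tgt, 2), variant = rep(c("full", "motif"), each = n_tgt),
    sequence = c(full, unname(motif)), stringsAsFactors = FALSE)

  fp <- maccs_fp(smiles, comp)
  prev <- colMeans(fp)
  usable <- which(prev >= 0.05 & prev <= 0.95)
  rule_bit <- usable[which.min(abs(prev[usable] - spec$rule_bit_prevalence))]
  gr <- vapply(full, gravy, numeric(1))
  gr_med <- stats::median(gr)
  high_gravy <- setNames(gr > gr_med, tgt)

  all_pairs <- expand.grid(compound_id = comp, target_id = tgt,
                           stringsAsFactors = FALSE)
  pairs <- all_pairs[sample(nrow(all_pairs), min(spec$n_pairs,
                                                 nrow(all_pairs))), ]
  rownames(pairs) <- NULL
  bayes <- as.integer(fp[match(pairs$compound_id, comp), rule_bit] == 1 &
                        high_gravy[pairs$target_id])
  flip <- stats::runif(nrow(pairs)) < spec$label_noise
  pairs$label <- as.integer(xor(bayes == 1, flip))

  list(compounds = compounds, sequences = sequences, pairs = pairs,
       truth = list(rule_bit = colnames(fp)[rule_bit],
                    gravy_median = gr_med, bayes_label = bayes,
                    balance = mean(pairs$label)))
}

#' Generate a peak table with planted differential features
#'
#' Intensities are log-normal: feature `f` has log10 baseline
#' `mu_f ~ U(4, 7)` and within-group SD `feature_log_sd`. The first
#' `n_planted` features shift the Mod group's log mean by
#' `effect_size * feature_log_sd` (the BWG group stays at the Con level,
#' emulating treatment reversal). QC injections are drawn around the
#' feature baseline with relative SD `qc_rsd` on the raw scale; missingness
#' is completely at random in biological samples only.
#'
#' @param spec a [sim_spec()].
#' @return list with `peaks` (a [peak_table()]) and `truth`
#'   (`planted_features`, `effect_size`).
#' @export
gen_peak_table <- function(spec) {
  stopifnot(inherits(spec, "ctpdn_simspec"))
  set.seed(spec$seed + 2L)
  Fn <- spec$n_features; npg <- spec$n_per_group; nqc <- spec$n_qc
  groups <- rep(c("Con", "Mod", "BWG"), each = npg)
  ids <- sprintf("F%04d", seq_len(Fn))
  mu <- stats::runif(Fn, 4, 7)
  shift <- rep(0, Fn)
  planted <- integer(0)
  if (spec$n_planted > 0) {
    planted <- seq_len(min(spec$n_planted, Fn))
    shift[planted] <- spec$effect_size * spec$feature_log_sd
  }
  mk <- function(mu_vec) {
    10^(mu_vec + stats::rnorm(Fn, 0, spec$feature_log_sd))
  }
  bio <- sapply(seq_along(groups), function(i) {
    if (groups[i] == "Mod") mk(mu + shift) else mk(mu)
  })
  qc <- sapply(seq_len(nqc), function(i) {
    v <- 10^mu * (1 + stats::rnorm(Fn, 0, spec$qc_rsd))
    pmax(v, 10^mu * 0.01)
  })
  X <- cbind(bio, qc)
  colnames(X) <- c(sprintf("%s%d", groups, sequence(rle(groups)$lengths)),
                   sprintf("QC%d", seq_len(nqc)))
  rownames(X) <- ids
  if (spec$missing_rate > 0) {
    drop <- matrix(stats::runif(Fn * length(groups)) < spec$missing_rate,
                   Fn, length(groups))
    X[, seq_along(groups)][drop] <- NA
  }
  pt <- peak_table(X, c(groups, rep("QC", nqc)),
                   is_qc = c(rep(FALSE, length(groups)), rep(TRUE, nqc)))
  list(peaks = pt,
       truth = list(planted_features = ids[planted],
                    effect_size = spec$effect_size))
}
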