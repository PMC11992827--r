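# Untargeted serum-metabolomics screening chain. A peak table holds a
# features x samples intensity matrix (NA = missing) with per-sample group
# and QC annotations; filters are applied in the fixed order
# missingness -> mean imputation -> QC-RSD -> low-SD -> normalisation
# (sum -> log10 -> mean-centre), with each stage logged in the provenance.

#' Construct a peak table
#'
#' @param intensity numeric matrix, features in rows (rownames = feature
#'   ids), samples in columns; `NA` encodes a missing peak (distinct from
#'   zero intensity).
#' @param group character/factor per sample (e.g. `"Con"`, `"Mod"`,
#'   `"BWG"`); QC injections may carry any label.
#' @param is_qc logical per sample.
#' @param mz,rt optional per-feature mass-to-charge and retention time.
#' @return object of class `ctpdn_peaks`.
#' @export
peak_table <- function(intensity, group, is_qc = rep(FALSE, ncol(intensity)),
                       mz = NULL, rt = NULL) {
  stopifnot(is.matrix(intensity), ncol(intensity) == length(group),
            ncol(intensity) == length(is_qc))
  if (is.null(rownames(intensity))) {
    rownames(intensity) <- sprintf("F%04d", seq_len(nrow(intensity)))
  }
  if (any(intensity < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  structure(list(intensity = intensity, group = as.character(group),
                 is_qc = as.logical(is_qc), mz = mz, rt = rt,
                 prelog = NULL, normalized = NULL,
                 log = character(0)),
            class = "ctpdn_peaks")
}

#' @export
print.ctpdn_peaks <- function(x, ...) {
  cat(sprintf("Peak table: %d feature(s) x %d sample(s) (%d QC)\n",
              nrow(x$intensity), ncol(x$intensity), sum(x$is_qc)))
  gt <- table(x$group[!x$is_qc])
  cat("  groups:", paste(sprintf("%s=%d", names(gt), gt), collapse = ", "), "\n")
  if (length(x$log) > 0) cat("  provenance:\n", paste("   -", x$log, collapse = "\n"), "\n")
  invisible(x)
}

.log_stage <- function(pt, msg) {
  pt$log <- c(pt$log, sprintf("%s (features: %d)", msg, nrow(pt$intensity)))
  pt
}

#' Missingness filter and mean imputation
#'
#' Removes features missing in more than `max_missing` of the samples, then
#' replaces the remaining missing entries by that feature's observed mean.
#'
#' @param pt a [peak_table()].
#' @param max_missing maximum tolerated missing fraction (default 0.8).
#' @return filtered, imputed peak table.
#' @export
filter_missing <- function(pt, max_missing = 0.8) {
  stopifnot(inherits(pt, "ctpdn_peaks"))
  frac <- rowMeans(is.na(pt$intensity))
  pt$intensity <- pt$intensity[frac <= max_missing, , drop = FALSE]
  if (!is.null(pt$mz)) pt$mz <- pt$mz[frac <= max_missing]
  if (!is.null(pt$rt)) pt$rt <- pt$rt[frac <= max_missing]
  na_idx <- which(is.na(pt$intensity), arr.ind = TRUE)
  if (nrow(na_idx) > 0) {
    rmeans <- rowMeans(pt$intensity, na.rm = TRUE)
    pt$intensity[na_idx] <- rmeans[na_idx[, 1]]
  }
  .log_stage(pt, sprintf("missingness filter (> %g) + mean imputation",
                         max_missing))
}

#' QC relative-standard-deviation filter
#'
#' Removes features whose relative standard deviation (sd/mean) across the
#' pooled QC injections exceeds `max_rsd`; features with non-positive QC
#' mean have undefined RSD and are removed with a warning.
#'
#' @param pt a [peak_table()] with at least two QC samples.
#' @param max_rsd maximum RSD (default 0.20 = 20\%).
#' @return filtered peak table.
#' @export
filter_qc_rsd <- function(pt, max_rsd = 0.20) {
  stopifnot(inherits(pt, "ctpdn_peaks"))
  if (sum(pt$is_qc) < 2) stop("need at least two QC samples")
  qc <- pt$intensity[, pt$is_qc, drop = FALSE]
  m <- rowMeans(qc)
  s <- apply(qc, 1, stats::sd)
  undef <- !(m > 0)
  if (any(undef)) {
    warning(sum(undef), " feature(s) with non-positive QC mean removed (undefined RSD)")
  }
  rsd <- ifelse(undef, Inf, s / m)
  keep <- rsd <= max_rsd & !undef
  pt$intensity <- pt$intensity[keep, , drop = FALSE]
  if (!is.null(pt$mz)) pt$mz <- pt$mz[keep]
  if (!is.null(pt$rt)) pt$rt <- pt$rt[keep]
  .log_stage(pt, sprintf("QC RSD filter (> %g%%)", 100 * max_rsd))
}

#' Low-variance filter
#'
#' Drops the `drop_fraction` of features with the lowest standard deviation
#' across the biological (non-QC) samples; exactly
#' `ceiling((1 - drop_fraction) * F)` features survive. Ties are broken by
#' feature id so the result is deterministic.
#'
#' @param pt a [peak_table()].
#' @param drop_fraction fraction to drop (default 0.40).
#' @return filtered peak table.
#' @export
filter_low_sd <- function(pt, drop_fraction = 0.40) {
  stopifnot(inherits(pt, "ctpdn_peaks"), drop_fraction >= 0, drop_fraction < 1)
  if (drop_fraction == 0) return(.log_stage(pt, "SD filter (0%, identity)"))
  Fn <- nrow(pt$intensity)
  n_keep <- ceiling((1 - drop_fraction) * Fn)
  s <- apply(pt$intensity[, !pt$is_qc, drop = FALSE], 1, stats::sd)
  ord <- order(-s, rownames(pt$intensity))   # drop from the low-SD end
  keep_ids <- sort(rownames(pt$intensity)[ord[seq_len(n_keep)]])
  keep <- rownames(pt$intensity) %in% keep_ids
  pt$intensity <- pt$intensity[keep, , drop = FALSE]
  if (!is.null(pt$mz)) pt$mz <- pt$mz[keep]
  if (!is.null(pt$rt)) pt$rt <- pt$rt[keep]
  .log_stage(pt, sprintf("SD variance filter (lowest %g%%)", 100 * drop_fraction))
}

#' Sum normalization, log10 transform and mean centring
#'
#' Each sample is scaled so its total intensity equals the median sample
#' total (per-sample sum normalization), the scaled intensities are
#' log10-transformed with a pseudo-count of half the smallest positive
#' scaled intensity, and every feature is mean-centred. With
#' `autoscale = TRUE` features are additionally divided by their standard
#' deviation. The pre-log (sum-normalized) matrix is retained for
#' fold-change computation.
#'
#' @param pt a [peak_table()] (run the filters first).
#' @param autoscale also scale features to unit variance (default FALSE:
#'   mean-centring only).
#' @return peak table with `prelog` and `normalized` matrices filled in.
#' @export
normalize_table <- function(pt, autoscale = FALSE) {
  stopifnot(inherits(pt, "ctpdn_peaks"))
  X <- pt$intensity
  totals <- colSums(X)
  if (any(totals <= 0)) stop("sample(s) with non-positive total intensity")
  target <- stats::median(totals)
  Xs <- sweep(X, 2, totals / target, `/`)
  pos <- Xs[Xs > 0]
  pc <- if (length(pos) > 0) min(pos) / 2 else 1
  Xl <- log10(Xs + pc)
  ctr <- rowMeans(Xl)
  Xc <- Xl - ctr
  if (autoscale) {
    s <- apply(Xc, 1, stats::sd)
    Xc <- Xc / ifelse(s > 0, s, 1)
  }
  pt$prelog <- Xs
  pt$normalized <- Xc
  .log_stage(pt, sprintf("sum normalization + log10 (pseudo-count %.3g) + %s",
                         pc, if (autoscale) "autoscaling" else "mean centring"))
}

#' PLS-DA variable importance in projection (VIP)
#'
#' Fits a NIPALS PLS regression of the (centred) class indicator on the
#' feature matrix and returns per-feature VIP scores
#' `VIP_j = sqrt(F * sum_a(SS_a w_aj^2) / sum_a SS_a)` with `SS_a` the
#' y-variance explained by component `a` and unit-norm loading weights, so
#' the VIP scores satisfy `mean(VIP^2) = 1` exactly.
#'
#' @param X samples x features numeric matrix (already on the normalized
#'   log scale).
#' @param groups two-level factor/character per sample.
#' @param n_components number of PLS components (default 2, capped at the
#'   available rank).
#' @return named numeric VIP vector (zero-variance features get VIP 0 with
#'   a warning).
#' @export
pls_da_vip <- function(X, groups, n_components = 2) {
  X <- as.matrix(X)
  g <- factor(groups)
  if (nlevels(g) != 2) stop("pls_da_vip: exactly two groups required")
  y <- ifelse(g == levels(g)[1], 0, 1)
  n <- nrow(X); p <- ncol(X)
  if (any(apply(X, 2, stats::sd) == 0)) {
    warning("zero-variance feature(s) present; their VIP is 0")
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  A <- min(n_components, n - 1, p)
  W <- matrix(0, p, A); SS <- numeric(A)
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { A <- a - 1L; break }
    w <- w / nw
    t_ <- drop(Xc %*% w)
    tt <- sum(t_^2)
    if (tt < 1e-12) { A <- a - 1L; break }
    p_ <- drop(crossprod(Xc, t_)) / tt
    q_ <- sum(yc * t_) / tt
    Xc <- Xc - tcrossprod(t_, p_)
    yc <- yc - q_ * t_
    W[, a] <- w
    SS[a] <- q_^2 * tt
  }
  if (A == 0) return(setNames(rep(0, p), colnames(X)))
  W <- W[, seq_len(A), drop = FALSE]; SS <- SS[seq_len(A)]
  vip <- sqrt(p * drop(W^2 %*% SS) / sum(SS))
  setNames(vip, colnames(X))
}

#' Differential-metabolite screen
#'
#' For each feature: VIP from [pls_da_vip()] on the normalized log-scale
#' data of the two groups, a two-sided Welch t-test on the same scale, and
#' the fold change `mean(group_b) / mean(group_a)` on the pre-log
#' sum-normalized scale. A feature passes when `vip > vip_min`,
#' `p < p_max` and `max(FC, 1/FC) > fc_min` (the fold-change criterion is
#' bidirectional).
#'
#' @param pt a normalized [peak_table()] (see [normalize_table()]).
#' @param group_a,group_b the two group labels to compare (defaults
#'   `"Con"` vs `"Mod"`); `fc` is reported as `group_b / group_a`.
#' @param vip_min,p_max,fc_min screen thresholds (defaults 1, 0.05, 1).
#' @param n_components PLS components for the VIP.
#' @return data.frame `feature_id`, `vip`, `p`, `fc`, `passes`.
#' @export
differential_screen <- function(pt, group_a = "Con", group_b = "Mod",
                                vip_min = 1, p_max = 0.05, fc_min = 1,
                                n_components = 2) {
  stopifnot(inherits(pt, "ctpdn_peaks"))
  if (is.null(pt$normalized)) stop("run normalize_table() first")
  sel_a <- pt$group == group_a & !pt$is_qc
  sel_b <- pt$group == group_b & !pt$is_qc
  if (sum(sel_a) < 2 || sum(sel_b) < 2) stop("need >= 2 samples per group")
  Xn <- t(pt$normalized[, sel_a | sel_b, drop = FALSE])
  g <- ifelse(pt$group[sel_a | sel_b] == group_a, group_a, group_b)
  vip <- pls_da_vip(Xn, g, n_components)
  feats <- rownames(pt$normalized)
  p <- vapply(feats, function(f) {
    a <- pt$normalized[f, sel_a]; b <- pt$normalized[f, sel_b]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) return(1)
    stats::t.test(b, a)$p.value
  }, numeric(1))
  fc <- rowMeans(pt$prelog[feats, sel_b, drop = FALSE]) /
    rowMeans(pt$prelog[feats, sel_a, drop = FALSE])
  passes <- vip > vip_min & p < p_max & pmax(fc, 1 / fc) > fc_min
  data.frame(feature_id = feats, vip = as.numeric(vip[feats]),
             p = as.numeric(p), fc = as.numeric(fc),
             passes = as.logical(passes),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Random-forest biomarker panel
#'
#' Ranks features by random-forest importance under repeated stratified
#' cross-validation and reports the top-`k` panel. Performance is estimated
#' without leakage: within every fold the panel is re-selected on the
#' training part only, a forest is refit on that panel, and accuracy / rank
#' AUC are measured on the held-out part; the reported panel comes from the
#' importance aggregated over the training folds.
#'
#' @param pt a normalized [peak_table()].
#' @param group_a,group_b the two groups to separate.
#' @param k panel size (default 10, capped at the feature count).
#' @param seed integer seed; the panel is deterministic given the seed.
#' @param n_folds,n_repeats cross-validation design (default 5 x 2).
#' @param ntree trees per forest (default 500).
#' @return object of class `ctpdn_panel`: list with `panel` (ranked feature
#'   ids), `cv_accuracy`, `cv_auc`, `importance` (aggregated), `seed`.
#' @export
rf_biomarker_panel <- function(pt, group_a = "Con", group_b = "Mod", k = 10,
                               seed = 1L, n_folds = 5, n_repeats = 2,
                               ntree = 500) {
  stopifnot(inherits(pt, "ctpdn_peaks"))
  if (is.null(pt$normalized)) stop("run normalize_table() first")
  sel <- (pt$group %in% c(group_a, group_b)) & !pt$is_qc
  X <- t(pt$normalized[, sel, drop = FALSE])
  y <- factor(pt$group[sel], levels = c(group_a, group_b))
  n <- nrow(X)
  if (n < 10) stop("need at least 10 samples")
  k <- min(k, ncol(X))
  set.seed(seed)
  imp_sum <- setNames(numeric(ncol(X)), colnames(X))
  acc <- c(); scores <- c(); truth <- c()
  for (rep_i in seq_len(n_repeats)) {
    fold <- integer(n)
    for (cls in levels(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      rf_full <- randomForest::randomForest(X[tr, , drop = FALSE], y[tr],
                                            ntree = ntree, importance = FALSE)
      imp <- rf_full$importance[, "MeanDecreaseGini"]
      imp_sum[names(imp)] <- imp_sum[names(imp)] + imp
      panel_f <- names(sort(imp, decreasing = TRUE))[seq_len(k)]
      rf_panel <- randomForest::randomForest(X[tr, panel_f, drop = FALSE],
                                             y[tr], ntree = ntree)
      pr <- predict(rf_panel, X[!tr, panel_f, drop = FALSE], type = "prob")
      pred <- levels(y)[max.col(pr)]
      acc <- c(acc, mean(pred == as.character(y[!tr])))
      scores <- c(scores, pr[, group_b])
      truth <- c(truth, as.integer(y[!tr] == group_b))
    }
  }
  ord <- order(-imp_sum, names(imp_sum))
  panel <- names(imp_sum)[ord][seq_len(k)]
  structure(list(panel = panel, cv_accuracy = mean(acc),
                 cv_auc = rank_auc(scores, truth),
                 importance = imp_sum[ord], seed = as.integer(seed),
                 groups = c(group_a, group_b), k = k),
            class = "ctpdn_panel")
}

#' @export
print.ctpdn_panel <- function(x, ...) {
  cat(sprintf("Random-forest biomarker panel (%s vs %s): top %d feature(s)\n",
              x$groups[1], x$groups[2], x$k))
  cat("  ", paste(x$panel, collapse = ", "), "\n")
  cat(sprintf("  CV accuracy %.3f, CV AUC %.3f\n", x$cv_accuracy, x$cv_auc))
  invisible(x)
}

#' Intersect two biomarker panels
#'
#' @param panel_a,panel_b `ctpdn_panel` objects or character vectors.
#' @return character vector of common feature ids, in `panel_a`'s order.
#' @export
intersect_panels <- function(panel_a, panel_b) {
  a <- if (inherits(panel_a, "ctpdn_panel")) panel_a$panel else panel_a
  b <- if (inherits(panel_b, "ctpdn_panel")) panel_b$panel else panel_b
  a[a %in% b]
}

#' Read / write a peak table
#'
#' TSV layout: first column `feature_id`, remaining columns one per sample;
#' two annotation rows above the data, `#group` (sample group labels) and
#' `#qc` (`TRUE`/`FALSE`), are encoded as the first two data rows with
#' `feature_id` values `#group` and `#qc`.
#'
#' @param path file path.
#' @param pt a [peak_table()].
#' @return the peak table (reader) or `path` invisibly (writer).
#' @export
read_peak_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  .required_cols(df, "feature_id", "peak table")
  gi <- match("#group", df$feature_id)
  qi <- match("#qc", df$feature_id)
  if (is.na(gi) || is.na(qi)) stop("peak table needs #group and #qc rows")
  samples <- setdiff(names(df), "feature_id")
  group <- as.character(df[gi, samples])
  is_qc <- as.logical(df[qi, samples])
  dat <- df[-c(gi, qi), , drop = FALSE]
  X <- as.matrix(dat[, samples, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- dat$feature_id
  peak_table(X, group, is_qc)
}

#' @rdname read_peak_table
#' @export
write_peak_table <- function(pt, path) {
  stopifnot(inherits(pt, "ctpdn_peaks"))
  samples <- colnames(pt$intensity)
  if (is.null(samples)) {
    samples <- sprintf("S%03d", seq_len(ncol(pt$intensity)))
  }
  hdr <- data.frame(feature_id = c("#group", "#qc"), stringsAsFactors = FALSE)
  ann <- rbind(pt$group, as.character(pt$is_qc))
  body <- data.frame(feature_id = rownames(pt$intensity),
                     pt$intensity, check.names = FALSE,
                     stringsAsFactors = FALSE)
  colnames(ann) <- samples
  colnames(body) <- c("feature_id", samples)
  out <- rbind(cbind(hdr, ann, stringsAsFactors = FALSE), body)
  .write_tsv(out, path)
}
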