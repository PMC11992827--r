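# Discrete AdaBoost (SAMME-style) over depth-limited rpart trees for
# compound-target interaction prediction. The ensemble decision is
# sign(sum_k alpha_k G_k(x)) with weak learners G_k in {-1, +1}; each tree
# is grown on the weighted sample and pruned back so that it uses at most
# `max_splits` splits (defaults: max splits 20, 30 learners, learning
# rate 0.1).

#' Min-max feature normalization
#'
#' Rescales every descriptor column to `[0, 1]` using its own min/max
#' (`method = "minmax"`, the default) or to z-scores. Constant columns map
#' to 0. The fitted parameters are attached so the identical transform can
#' be replayed on new data with [apply_normalization()]; replayed values may
#' fall outside `[0, 1]` when a test row lies outside the training range,
#' which is allowed.
#'
#' @param table data.frame or matrix of numeric descriptors (a `label`
#'   column, if present, is passed through untouched).
#' @param method `"minmax"` or `"zscore"`.
#' @return normalized table with attribute `norm_params`.
#' @export
normalize_features <- function(table, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  lab <- if ("label" %in% colnames(table)) table[["label"]] else NULL
  X <- as.matrix(table[, setdiff(colnames(table), "label"), drop = FALSE])
  if (!is.numeric(X)) stop("descriptor columns must be numeric")
  if (method == "minmax") {
    lo <- apply(X, 2, min); hi <- apply(X, 2, max)
    params <- list(method = method, center = lo,
                   scale = ifelse(hi > lo, hi - lo, 1))
  } else {
    mu <- colMeans(X); sd <- apply(X, 2, stats::sd)
    params <- list(method = method, center = mu,
                   scale = ifelse(sd > 0, sd, 1))
  }
  out <- apply_normalization(params, X)
  out <- as.data.frame(out)
  if (!is.null(lab)) out$label <- lab
  attr(out, "norm_params") <- params
  out
}

#' @rdname normalize_features
#' @param params the `norm_params` attribute from a fitted normalization.
#' @param newdata data to transform with the stored parameters.
#' @export
apply_normalization <- function(params, newdata) {
  X <- as.matrix(newdata[, names(params$center), drop = FALSE])
  sweep(sweep(X, 2, params$center, `-`), 2, params$scale, `/`)
}

.grow_weak_learner <- function(X, y01, w, max_splits) {
  df <- data.frame(X, .y = factor(y01, levels = c(0, 1)), check.names = FALSE)
  fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                      control = rpart::rpart.control(
                        cp = 0, minsplit = 2, minbucket = 1, xval = 0,
                        maxdepth = min(30, max(2, ceiling(log2(max_splits + 1)) + 2)),
                        maxcompete = 0, maxsurrogate = 0, usesurrogate = 0))
  cpt <- fit$cptable
  if (!is.null(cpt) && max(cpt[, "nsplit"]) > max_splits) {
    ok <- cpt[cpt[, "nsplit"] <= max_splits, , drop = FALSE]
    fit <- rpart::prune(fit, cp = ok[nrow(ok), "CP"] + 1e-12)
  }
  fit
}

#' Fit a discrete AdaBoost compound-target interaction classifier
#'
#' @param table feature table (data.frame/matrix); a `label` column is used
#'   as the response when `labels` is missing.
#' @param labels binary vector (0/1), one per row.
#' @param max_splits maximum splits per weak-learner tree (default 20).
#' @param n_learners maximum number of weak learners K (default 30; training
#'   stops early when a learner reaches zero or >= 1/2 weighted error).
#' @param learning_rate shrinkage applied to every alpha_k (default 0.1).
#' @param seed integer; fitting is deterministic given the seed.
#' @param normalize apply [normalize_features()] before fitting (default
#'   TRUE); the transform is stored in the model for prediction.
#' @return object of class `ctpdn_adaboost` with elements `learners`,
#'   `alpha`, `train_error` (staged), `norm_params`, `levels`.
#' @export
fit_adaboost <- function(table, labels = NULL, max_splits = 20,
                         n_learners = 30, learning_rate = 0.1, seed = 1L,
                         normalize = TRUE) {
  if (is.null(labels)) {
    if (!("label" %in% colnames(table))) stop("no labels supplied")
    labels <- table[["label"]]
  }
  X <- as.data.frame(table)[, setdiff(colnames(table), "label"), drop = FALSE]
  y01 <- as.integer(labels)
  if (any(is.na(X)) || any(!is.finite(as.matrix(X)))) {
    stop("feature table contains missing or non-finite values")
  }
  if (length(unique(y01)) < 2) stop("labels must contain both classes")
  stopifnot(all(y01 %in% c(0L, 1L)), nrow(X) == length(y01))

  norm_params <- NULL
  if (normalize) {
    nf <- normalize_features(X)
    norm_params <- attr(nf, "norm_params")
    X <- nf[, setdiff(colnames(nf), "label"), drop = FALSE]
  }
  set.seed(seed)
  n <- nrow(X)
  w <- rep(1 / n, n)
  ysgn <- ifelse(y01 == 1, 1, -1)
  learners <- list(); alpha <- numeric(0); staged_err <- numeric(0)
  Fx <- numeric(n)
  for (k in seq_len(n_learners)) {
    fit <- .grow_weak_learner(X, y01, w * n, max_splits)
    pred01 <- as.integer(as.character(predict(fit, X, type = "class")))
    hsgn <- ifelse(pred01 == 1, 1, -1)
    err <- sum(w[hsgn != ysgn])
    if (err >= 0.5) break
    eps <- max(err, 1e-10)
    a <- learning_rate * 0.5 * log((1 - eps) / eps)
    learners[[length(learners) + 1]] <- fit
    alpha <- c(alpha, a)
    Fx <- Fx + a * hsgn
    staged_err <- c(staged_err, mean((Fx > 0) != (y01 == 1)))
    w <- w * exp(-a * ysgn * hsgn)
    w <- w / sum(w)
    if (err < 1e-10) break
  }
  if (length(learners) == 0) stop("no weak learner beat chance on this data")
  structure(list(learners = learners, alpha = alpha,
                 train_error = staged_err, norm_params = norm_params,
                 max_splits = max_splits, learning_rate = learning_rate,
                 seed = as.integer(seed),
                 feature_names = colnames(X)),
            class = "ctpdn_adaboost")
}

#' @export
print.ctpdn_adaboost <- function(x, ...) {
  cat(sprintf("AdaBoost CTI classifier: %d weak learner(s), lr=%g\n",
              length(x$learners), x$learning_rate))
  cat(sprintf("  final training error: %.4f\n",
              x$train_error[length(x$train_error)]))
  invisible(x)
}

#' Predict with an AdaBoost CTI classifier
#'
#' The score is the weighted ensemble sum `sum_k alpha_k G_k(x)`; the label
#' is 1 when the score is strictly positive and 0 otherwise (a tie at
#' exactly 0 predicts negative).
#'
#' @param object a `ctpdn_adaboost` model.
#' @param newdata feature table (a `label` column is ignored).
#' @param ... unused.
#' @return data.frame with `score` and `label`.
#' @export
predict.ctpdn_adaboost <- function(object, newdata, ...) {
  X <- as.data.frame(newdata)[, setdiff(colnames(newdata), "label"),
                              drop = FALSE]
  if (nrow(X) == 0) {
    return(data.frame(score = numeric(0), label = integer(0)))
  }
  if (!is.null(object$norm_params)) {
    X <- as.data.frame(apply_normalization(object$norm_params, X))
  }
  score <- numeric(nrow(X))
  for (k in seq_along(object$learners)) {
    pred01 <- as.integer(as.character(
      predict(object$learners[[k]], X, type = "class")))
    score <- score + object$alpha[k] * ifelse(pred01 == 1, 1, -1)
  }
  data.frame(score = score, label = as.integer(score > 0))
}

.canonical_row_order <- function(X, labels) {
  do.call(order, c(list(labels), as.list(as.data.frame(X))))
}

#' Stratified k-fold cross-validation of the AdaBoost classifier
#'
#' Rows are partitioned into `k` folds, stratified by label; the fold
#' assignment is keyed to the seed and to the row *contents* (rows are put
#' in a canonical order before assignment), so permuting the input rows
#' does not change the aggregate metrics. Normalization is fitted within
#' each training fold only and replayed on the held-out fold.
#'
#' @param table feature table with a `label` column (or supply `labels`).
#' @param labels optional binary vector.
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold assignment and learner fits.
#' @param ... passed to [fit_adaboost()].
#' @return object of class `ctpdn_cv`: list with `folds` (per-fold
#'   [cti_metrics()] reports), `aggregate` (metrics on the pooled held-out
#'   predictions), `fold_sizes`, `seed`.
#' @export
kfold_cv <- function(table, labels = NULL, k = 10, seed = 1L, ...) {
  if (is.null(labels)) labels <- table[["label"]]
  X <- as.data.frame(table)[, setdiff(colnames(table), "label"), drop = FALSE]
  y <- as.integer(labels)
  n <- nrow(X)
  if (n < k) stop("need at least k rows")
  ord <- .canonical_row_order(X, y)
  Xo <- X[ord, , drop = FALSE]; yo <- y[ord]
  set.seed(seed)
  fold <- integer(n)
  for (cls in unique(yo)) {
    idx <- which(yo == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold_reports <- vector("list", k)
  pooled_scores <- numeric(0); pooled_pred <- integer(0)
  pooled_truth <- integer(0)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    model <- fit_adaboost(Xo[tr, , drop = FALSE], yo[tr], seed = seed, ...)
    pr <- predict(model, Xo[te, , drop = FALSE])
    fold_reports[[f]] <- cti_metrics(pr$label, yo[te], scores = pr$score)
    pooled_scores <- c(pooled_scores, pr$score)
    pooled_pred <- c(pooled_pred, pr$label)
    pooled_truth <- c(pooled_truth, yo[te])
  }
  structure(list(folds = fold_reports,
                 aggregate = cti_metrics(pooled_pred, pooled_truth,
                                         scores = pooled_scores),
                 fold_sizes = as.integer(table(fold)), k = k,
                 seed = as.integer(seed)),
            class = "ctpdn_cv")
}

#' @export
print.ctpdn_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$k, x$seed))
  agg <- x$aggregate
  cat(sprintf("  pooled: precision %.3f  recall %.3f  F1 %.3f  AUC %.3f  MCC %.3f\n",
              agg$precision, agg$recall, agg$f1, agg$auc, agg$mcc))
  invisible(x)
}

#' Per-target success-rate screen
#'
#' Featurizes every compound x target pair with the model's dataset kind and
#' reports, per target, the percentage of compounds predicted to interact
#' (label 1) -- the "rate of successful CTI".
#'
#' @param model a fitted `ctpdn_adaboost`.
#' @param compounds compound table (SMILES + ADMET columns).
#' @param sequences sequence table with the variant required by `kind`.
#' @param kind dataset kind the model was trained on.
#' @return data.frame `target_id`, `n_compounds`, `success_rate` (percent).
#' @export
screen_targets <- function(model, compounds, sequences,
                           kind = c("MF", "MM", "EF", "EM")) {
  kind <- match.arg(kind)
  variant <- if (substr(kind, 2, 2) == "F") "full" else "motif"
  tg <- unique(sequences$target_id[sequences$variant == variant])
  pairs <- expand.grid(compound_id = compounds$compound_id, target_id = tg,
                       stringsAsFactors = FALSE)
  feats <- assemble_feature_table(pairs, compounds, sequences, kind)
  pr <- predict(model, feats)
  rate <- 100 * tapply(pr$label, pairs$target_id, mean)
  data.frame(target_id = names(rate),
             n_compounds = as.integer(table(pairs$target_id)[names(rate)]),
             success_rate = as.numeric(rate),
             row.names = NULL, stringsAsFactors = FALSE)
}
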