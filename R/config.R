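#' Run configuration for the screening pipeline
#'
#' Collects every tunable threshold, mode switch and model hyperparameter in
#' one serializable object, so the pipeline generalises beyond the defaults.
#' Defaults are the standard screening conditions: compounds kept at
#' oral bioavailability >= 30\% and drug-likeness >= 0.18, pathways kept at
#' enrichment p < 1e-8, QC features kept at relative standard deviation
#' <= 20\%, the 40\% lowest-variance features dropped, and differential
#' metabolites called at VIP > 1, p < 0.05 and bidirectional fold change > 1.
#'
#' @param ob_min minimum oral bioavailability, percent.
#' @param dl_min minimum drug-likeness score.
#' @param pathway_p_max strict upper bound on pathway enrichment p-value.
#' @param missing_max maximum tolerated missing fraction per feature.
#' @param rsd_max maximum QC relative standard deviation (sd/mean).
#' @param sd_filter_fraction fraction of lowest-SD features to drop.
#' @param vip_min,p_max,fc_min differential-metabolite screen thresholds.
#' @param tti_mode `"score"` uses the PPI combined score directly as the raw
#'   target-target score before the reciprocal length step; `"reciprocal"`
#'   uses its reciprocal.
#' @param tpi_mode `"exist"` scores target-pathway membership as 1;
#'   `"qweight"` uses -log10(q) clipped to `[1e-3, 1e3]`.
#' @param sigmoid_sign `"positive"` is the literal weight 1/(1+exp(-L));
#'   `"negative"` flips the exponent sign.
#' @param max_splits,n_learners,learning_rate AdaBoost hyperparameters.
#' @param seed integer seed recorded with the run.
#' @return object of class `ctpdn_config` (a named list).
#' @export
ctpdn_config <- function(ob_min = 30, dl_min = 0.18, pathway_p_max = 1e-8,
                         missing_max = 0.8, rsd_max = 0.20,
                         sd_filter_fraction = 0.40,
                         vip_min = 1, p_max = 0.05, fc_min = 1,
                         tti_mode = c("score", "reciprocal"),
                         tpi_mode = c("exist", "qweight"),
                         sigmoid_sign = c("positive", "negative"),
                         max_splits = 20, n_learners = 30,
                         learning_rate = 0.1, seed = 1L) {
  tti_mode <- match.arg(tti_mode)
  tpi_mode <- match.arg(tpi_mode)
  sigmoid_sign <- match.arg(sigmoid_sign)
  stopifnot(ob_min >= 0, dl_min >= 0,
            pathway_p_max > 0, pathway_p_max <= 1,
            missing_max >= 0, missing_max < 1,
            rsd_max > 0, sd_filter_fraction >= 0, sd_filter_fraction < 1,
            vip_min >= 0, p_max > 0, p_max <= 1, fc_min >= 1,
            max_splits >= 1, n_learners >= 1, learning_rate > 0)
  structure(list(
    ob_min = ob_min, dl_min = dl_min, pathway_p_max = pathway_p_max,
    missing_max = missing_max, rsd_max = rsd_max,
    sd_filter_fraction = sd_filter_fraction,
    vip_min = vip_min, p_max = p_max, fc_min = fc_min,
    tti_mode = tti_mode, tpi_mode = tpi_mode, sigmoid_sign = sigmoid_sign,
    max_splits = max_splits, n_learners = n_learners,
    learning_rate = learning_rate, seed = as.integer(seed)
  ), class = "ctpdn_config")
}

#' Read / write a run configuration as JSON
#'
#' Round-trips through [ctpdn_config()], so thresholds are re-validated on
#' load and unknown fields are rejected.
#'
#' @param config a `ctpdn_config` object.
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns the
#'   configuration object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ctpdn_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(ctpdn_config))
  bad <- setdiff(names(x), known)
  if (length(bad) > 0) {
    stop("unknown configuration fields: ", paste(bad, collapse = ", "))
  }
  do.call(ctpdn_config, x)
}

#' @export
print.ctpdn_config <- function(x, ...) {
  cat("Screening pipeline configuration\n")
  cat(sprintf("  compound filter : OB >= %g%%, DL >= %g\n", x$ob_min, x$dl_min))
  cat(sprintf("  pathway filter  : p < %g\n", x$pathway_p_max))
  cat(sprintf("  edge modes      : TTI=%s, TPI=%s, sigmoid=%s\n",
              x$tti_mode, x$tpi_mode, x$sigmoid_sign))
  cat(sprintf("  AdaBoost        : %d learners, <=%d splits, lr=%g\n",
              x$n_learners, x$max_splits, x$learning_rate))
  cat(sprintf("  metabo screen   : VIP>%g, p<%g, FC>%g (bidirectional)\n",
              x$vip_min, x$p_max, x$fc_min))
  invisible(x)
}
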