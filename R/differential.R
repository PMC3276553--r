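#' Per-CpG supervised differential methylation
#'
#' Fits, for every probe, an ordinary least squares model of the beta value
#' on disease status plus covariates (the standard EWAS orientation), and
#' reports the t statistic and two-sided p-value of the status coefficient.
#' A positive effect means higher methylation in cases. Chip should be
#' passed as a covariate to adjust batch effects; character covariates are
#' treated as categorical.
#'
#' @param bm A \code{\link{beta_matrix}}.
#' @param status Either the name of a two-level annotation column or a
#'   vector (length = samples) coercible to two levels; the second sorted
#'   level (or \code{case_level}) is the case class.
#' @param covariates Character vector of annotation column names to adjust
#'   for (e.g. \code{c("age", "chip", "bs_intensity")}).
#' @param case_level Optional explicit case label.
#' @return A data.frame of class \code{differential_result} with columns
#'   \code{probe_id}, \code{t_stat}, \code{p_value}, \code{effect}
#'   (adjusted case-control beta difference) and \code{n_used}; probes
#'   whose model is unfittable (collinearity, a class lost to missingness)
#'   get NA rows.
#' @export
fit_cpg_models <- function(bm, status, covariates = character(),
                           case_level = NULL) {
  ann <- bm$samples
  st <- if (is.character(status) && length(status) == 1L) {
    if (is.null(ann[[status]])) stop("no annotation column '", status, "'")
    ann[[status]]
  } else status
  if (length(st) != ncol(bm$values))
    stop("status length must equal the number of samples")
  st <- factor(st)
  if (nlevels(st) != 2L)
    stop("status must have exactly two classes, found ", nlevels(st))
  if (!is.null(case_level)) st <- stats::relevel(st, ref = setdiff(levels(st),
                                                                   case_level))
  if (min(table(st)) < 2L) stop("each status class needs >= 2 samples")
  miss <- setdiff(covariates, names(ann))
  if (length(miss))
    stop("covariate(s) absent from annotations: ", paste(miss, collapse = ", "))

  df <- data.frame(.status = as.numeric(st) - 1)  # 1 = case
  for (cv in covariates) {
    v <- ann[[cv]]
    df[[cv]] <- if (is.character(v) || is.logical(v)) factor(v) else v
  }
  ok_row <- stats::complete.cases(df)

  fit_one <- function(y) {
    use <- ok_row & !is.na(y)
    d <- df[use, , drop = FALSE]
    if (length(unique(d$.status)) < 2L)
      return(c(NA, NA, NA, sum(use)))
    fit <- try(stats::lm(y[use] ~ ., data = d), silent = TRUE)
    if (inherits(fit, "try-error")) return(c(NA, NA, NA, sum(use)))
    if (is.na(stats::coef(fit)[".status"]))  # status collinear with covariates
      return(c(NA, NA, NA, sum(use)))
    cf <- stats::coef(summary(fit))
    if (!".status" %in% rownames(cf))
      return(c(NA, NA, NA, sum(use)))
    c(cf[".status", "t value"], cf[".status", "Pr(>|t|)"],
      cf[".status", "Estimate"], sum(use))
  }

  res <- t(apply(bm$values, 1, fit_one))
  out <- data.frame(probe_id = rownames(bm$values),
                    t_stat = res[, 1], p_value = res[, 2],
                    effect = res[, 3], n_used = as.integer(res[, 4]),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Call hyper- and hypomethylated probes
#'
#' @param results A \code{differential_result} data.frame.
#' @param p_threshold Raw p-value threshold in (0, 1); the analysis uses
#'   stage-specific raw thresholds (e.g. 0.1 for pre-dysplasia cohorts,
#'   0.001 for invasive cancer) rather than FDR control.
#' @param fdr If TRUE, threshold Benjamini-Hochberg adjusted p instead.
#' @return A list with character vectors \code{hyper} (p below threshold,
#'   effect > 0) and \code{hypo} (effect < 0).
#' @export
call_differential <- function(results, p_threshold, fdr = FALSE) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  p <- if (fdr) stats::p.adjust(results$p_value, "BH") else results$p_value
  sig <- !is.na(p) & p < p_threshold
  list(hyper = results$probe_id[sig & results$effect > 0],
       hypo  = results$probe_id[sig & results$effect < 0])
}

#' Exact two-sided binomial test for hyper/hypo skew
#'
#' Tests whether significantly hyper- and hypomethylated calls within a
#' locus category are balanced, against the symmetric null proportion 0.5.
#'
#' @param n_hyper,n_hypo Non-negative counts.
#' @return Two-sided exact binomial p-value.
#' @export
binomial_skew <- function(n_hyper, n_hypo) {
  stopifnot(n_hyper >= 0, n_hypo >= 0)
  if (n_hyper + n_hypo < 1)
    stop("binomial skew undefined: both counts are zero")
  stats::binom.test(n_hyper, n_hyper + n_hypo, p = 0.5)$p.value
}
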