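#' Split samples into tertile groups of an index
#'
#' Empirical tertiles with deterministic tie handling: samples are ranked
#' with ties broken by their original order, then split into three
#' near-equal groups. The middle tertile is retained in the output but is
#' conventionally excluded from two-group survival comparisons.
#'
#' @param x Numeric vector (>= 3 non-missing, non-constant values).
#' @return Factor with levels \code{lower}, \code{middle}, \code{upper}
#'   (NA where \code{x} is NA); tertile cut-points kept in attribute
#'   \code{cutpoints}.
#' @export
tertile_groups <- function(x) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 3) stop("tertiles undefined on fewer than 3 values")
  if (length(unique(x[ok])) == 1L) stop("tertiles undefined: index is constant")
  r <- rank(x[ok], ties.method = "first")  # stable: ties keep input order
  b1 <- floor(n / 3); b2 <- floor(2 * n / 3)
  g <- cut(r, breaks = c(0, b1, b2, n),
           labels = c("lower", "middle", "upper"))
  if (anyDuplicated(x[ok]))
    message(sprintf("tertile_groups: ties present; group sizes %d/%d/%d",
                    b1, b2 - b1, n - b2))
  out <- factor(rep(NA_character_, length(x)),
                levels = c("lower", "middle", "upper"))
  out[ok] <- g
  attr(out, "cutpoints") <- stats::quantile(x[ok], c(1, 2) / 3, names = FALSE)
  out
}

#' Cox proportional-hazards fit for an instability index
#'
#' Univariate or multivariate Cox regression of survival on a continuous
#' index, optionally standardized so the hazard ratio is per standard
#' deviation. For the multivariate model, pass the clinical covariates that
#' screened as associated with survival in univariate analysis (see
#' \code{\link{screen_covariates}}).
#'
#' @param time,event Follow-up time and 0/1 event indicator.
#' @param index Numeric index per sample (e.g. DeMI).
#' @param covariates Optional data.frame of additional covariates.
#' @param standardize Scale the index to unit SD (default TRUE), so HR is
#'   per SD.
#' @param tertile Fit the upper-vs-lower tertile contrast instead of the
#'   continuous index (middle tertile dropped).
#' @return An object of class \code{survival_result}: list with \code{hr},
#'   \code{ci_low}, \code{ci_high}, \code{p_value}, \code{n},
#'   \code{covariates}, \code{scale} ("per SD", "per unit" or
#'   "upper vs lower tertile") and the underlying \code{fit}.
#' @export
cox_fit <- function(time, event, index, covariates = NULL,
                    standardize = TRUE, tertile = FALSE) {
  ok <- !is.na(time) & !is.na(event) & !is.na(index)
  if (!is.null(covariates)) ok <- ok & stats::complete.cases(covariates)
  time <- time[ok]; event <- event[ok]; index <- index[ok]
  if (sum(event) < 1)
    stop(errorCondition("Cox fit impossible: no events",
                        class = c("cox_no_events", "error", "condition")))
  if (length(unique(index)) == 1L)
    stop(errorCondition("Cox fit impossible: index is constant",
                        class = c("cox_constant_index", "error", "condition")))
  if (tertile) {
    g <- tertile_groups(index)
    keep <- g %in% c("lower", "upper")
    d <- data.frame(time = time[keep], event = event[keep],
                    .index = droplevels(g[keep]))
    scale_lab <- "upper vs lower tertile"
  } else {
    z <- if (standardize) as.numeric(scale(index)) else index
    d <- data.frame(time = time, event = event, .index = z)
    scale_lab <- if (standardize) "per SD" else "per unit"
  }
  if (!is.null(covariates))
    d <- cbind(d, covariates[ok, , drop = FALSE][
      if (tertile) g %in% c("lower", "upper") else TRUE, , drop = FALSE])
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ ., data = d),
    error = function(e)
      stop(errorCondition(paste("Cox fit failed:", conditionMessage(e)),
                          class = c("cox_fit_failed", "error", "condition"))))
  sm <- summary(fit)
  row <- grep("^\\.index", rownames(sm$coefficients))[1]
  structure(list(hr = unname(sm$coefficients[row, "exp(coef)"]),
                 ci_low = unname(sm$conf.int[row, "lower .95"]),
                 ci_high = unname(sm$conf.int[row, "upper .95"]),
                 p_value = unname(sm$coefficients[row, "Pr(>|z|)"]),
                 n = sm$n, covariates = setdiff(names(d),
                                                c("time", "event", ".index")),
                 scale = scale_lab, fit = fit),
            class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat(sprintf("Cox model (%s): HR = %.3g (95%% CI %.3g-%.3g), p = %.3g, n = %d\n",
              x$scale, x$hr, x$ci_low, x$ci_high, x$p_value, x$n))
  if (length(x$covariates))
    cat("  adjusted for:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Screen covariates by univariate survival association
#'
#' Helper for multivariate model building: keeps covariates whose
#' univariate Cox p-value is below \code{alpha}, reporting every decision.
#'
#' @param time,event Survival outcome.
#' @param covariates data.frame of candidate covariates.
#' @param alpha Univariate p-value threshold (default 0.05).
#' @return Character vector of retained covariate names.
#' @export
screen_covariates <- function(time, event, covariates, alpha = 0.05) {
  keep <- character(0)
  for (cv in names(covariates)) {
    p <- tryCatch({
      d <- data.frame(time = time, event = event, x = covariates[[cv]])
      d <- d[stats::complete.cases(d), ]
      fit <- survival::coxph(survival::Surv(time, event) ~ x, data = d)
      min(summary(fit)$coefficients[, "Pr(>|z|)"])
    }, error = function(e) NA_real_)
    msg <- if (is.na(p)) "unfittable, dropped"
           else sprintf("univariate p = %.3g, %s", p,
                        if (p < alpha) "kept" else "dropped")
    message(sprintf("screen_covariates: %s -> %s", cv, msg))
    if (!is.na(p) && p < alpha) keep <- c(keep, cv)
  }
  keep
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival estimates per group with a two-sided log-rank
#' test; with a single group only the curves are returned.
#'
#' @param time,event Survival outcome.
#' @param groups Factor of group labels.
#' @return A list of class \code{km_result}: \code{fit} (a
#'   \code{survfit} object) and \code{logrank_p} (NA for a single group).
#' @export
km_curves <- function(time, event, groups) {
  ok <- !is.na(time) & !is.na(event) & !is.na(groups)
  d <- data.frame(time = time[ok], event = event[ok],
                  g = droplevels(factor(groups[ok])))
  if (nrow(d) == 0) stop("no usable observations")
  fit <- survival::survfit(survival::Surv(time, event) ~ g, data = d)
  p <- NA_real_
  if (nlevels(d$g) >= 2 && sum(d$event) > 0) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
    p <- stats::pchisq(sd$chisq, df = nlevels(d$g) - 1, lower.tail = FALSE)
  }
  structure(list(fit = fit, logrank_p = p), class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  print(x$fit)
  cat(sprintf("log-rank p = %.3g\n", x$logrank_p))
  invisible(x)
}

#' @export
plot.km_result <- function(x, ...) {
  graphics::plot(x$fit, xlab = "time", ylab = "survival", ...)
  invisible(x)
}

#' One-tailed Wilcoxon rank-sum test for a stage shift
#'
#' Tests whether the index in group \code{b} (e.g. metastases) is
#' stochastically larger than in group \code{a} (e.g. primary tumours).
#' The exact distribution is used when both groups have at most 25
#' untied values; otherwise the normal approximation with continuity
#' correction.
#'
#' @param a,b Numeric vectors.
#' @return List with \code{p_value}, \code{statistic} (rank-sum W for
#'   \code{a} vs \code{b}), \code{exact} (logical), \code{all_tied}
#'   (logical; p is 1 when every value is identical).
#' @export
stage_shift_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  if (length(unique(c(a, b))) == 1L)
    return(list(p_value = 1, statistic = NA_real_, exact = FALSE,
                all_tied = TRUE))
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) <= 25 && length(b) <= 25
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "less", exact = exact,
                       correct = TRUE))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       exact = exact, all_tied = FALSE)
}

#' ROC curve area for discriminating two sample classes
#'
#' Rank-based AUC (the Mann-Whitney probability that a random positive
#' scores above a random negative, ties counted half) with a DeLong 95\%
#' confidence interval.
#'
#' @param index Numeric score per sample.
#' @param labels Class labels (two levels).
#' @param positive Label of the positive class (e.g. \code{"metastasis"});
#'   defaults to the second sorted level.
#' @return List of class \code{roc_result}: \code{auc}, \code{ci_low},
#'   \code{ci_high}, \code{n_pos}, \code{n_neg},
#'   \code{ci_method = "delong"} and the underlying \code{pROC} object.
#' @export
roc_auc <- function(index, labels, positive = NULL) {
  ok <- !is.na(index) & !is.na(labels)
  index <- index[ok]; labels <- factor(labels[ok])
  if (nlevels(droplevels(labels)) != 2L)
    stop("labels must have exactly two classes present")
  if (is.null(positive)) positive <- levels(labels)[2]
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("one class is empty")
  r <- rank(index)
  n1 <- sum(pos); n0 <- sum(!pos)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  roc <- pROC::roc(response = pos, predictor = index, direction = "<",
                   levels = c(FALSE, TRUE), quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(roc, method = "delong"))
  structure(list(auc = auc, ci_low = ci[1], ci_high = ci[3],
                 n_pos = n1, n_neg = n0, ci_method = "delong", roc = roc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI %.3f-%.3f, %s), %d pos / %d neg\n",
              x$auc, x$ci_low, x$ci_high, x$ci_method, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$roc, ...)
  invisible(x)
}

#' TET expression anti-correlation and MESC enrichment
#'
#' Correlates each hypomethylated CpG's beta values with per-sample TET
#' mRNA expression across tumours (Spearman by default), flags CpGs
#' significantly anti-correlated (rho < 0 and p < \code{alpha}), and tests
#' by Fisher's exact test whether MESC CpGs are enriched among the
#' anti-correlated set relative to the remaining hypomethylated CpGs. Also
#' returns the correlation table ranked from most to least anti-correlated
#' (heatmap-ready ordering).
#'
#' @param bm_tumours A \code{\link{beta_matrix}} of tumour samples.
#' @param hypo_probes Character vector of hypomethylated probe ids.
#' @param tet_expr Named (or sample-ordered) numeric vector of TET
#'   expression, one value per tumour sample.
#' @param mesc A \code{\link{locus_set}} of MESC probes.
#' @param alpha Significance level for "anti-correlated" (default 0.05).
#' @param method \code{"spearman"} (default) or \code{"pearson"}.
#' @return List of class \code{tet_result}: \code{correlations}
#'   (data.frame probe_id, rho, p_value, significant_anti, is_mesc, ranked
#'   by rho), \code{enrichment} (an \code{enrichment_result}),
#'   \code{method}, \code{alpha}.
#' @export
tet_anticorrelation <- function(bm_tumours, hypo_probes, tet_expr, mesc,
                                alpha = 0.05,
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  vals <- bm_tumours$values
  if (!is.null(names(tet_expr)))
    tet_expr <- tet_expr[colnames(vals)]
  ok_s <- !is.na(tet_expr)
  if (sum(ok_s) < 5)
    stop("need at least 5 samples with TET expression")
  if (length(unique(tet_expr[ok_s])) == 1L)
    stop("TET expression is constant")
  probes <- intersect(hypo_probes, rownames(vals))
  if (length(probes) == 0L) stop("no hypomethylated probes found in the matrix")
  res <- t(vapply(probes, function(p) {
    ct <- suppressWarnings(
      stats::cor.test(vals[p, ok_s], tet_expr[ok_s], method = method))
    c(ct$estimate, ct$p.value)
  }, numeric(2)))
  out <- data.frame(probe_id = probes, rho = res[, 1], p_value = res[, 2],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$significant_anti <- !is.na(out$rho) & out$rho < 0 &
    !is.na(out$p_value) & out$p_value < alpha
  out$is_mesc <- out$probe_id %in% mesc$members
  out <- out[order(out$rho, out$probe_id), , drop = FALSE]
  enr <- fisher_enrichment(out$probe_id[out$significant_anti], mesc, probes)
  enr$direction <- "anti-correlated"
  structure(list(correlations = out, enrichment = enr, method = method,
                 alpha = alpha),
            class = "tet_result")
}

#' @export
print.tet_result <- function(x, ...) {
  cat(sprintf("TET anti-correlation (%s, alpha = %g): %d of %d probes significant\n",
              x$method, x$alpha, sum(x$correlations$significant_anti),
              nrow(x$correlations)))
  print(x$enrichment)
  invisible(x)
}
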