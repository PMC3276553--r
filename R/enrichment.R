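#' Fisher enrichment from a 2x2 table of counts
#'
#' Core tabulated form of \code{\link{fisher_enrichment}}: \code{a} selected
#' probes in the target set, \code{b} selected outside it, \code{c}
#' unselected in the set, \code{d} unselected outside it. The odds ratio is
#' the sample cross-product ratio a*d / (b*c); the two-tailed p-value is
#' Fisher's exact test; the 95\% CI comes from the Woolf log-OR normal
#' approximation, with a Haldane-Anscombe 0.5 correction applied to every
#' cell (and flagged) when any cell is zero. Tables with an empty margin
#' are flagged degenerate and get no p-value.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param conf_level Confidence level for the odds-ratio interval.
#' @param name,direction Optional labels carried into the result.
#' @return An object of class \code{enrichment_result}: list with
#'   \code{table} (named vector a,b,c,d), \code{odds_ratio}, \code{ci_low},
#'   \code{ci_high}, \code{p_value}, \code{degenerate},
#'   \code{haldane_corrected}, \code{name}, \code{direction}.
#' @export
fisher_counts <- function(a, b, c, d, conf_level = 0.95,
                          name = "", direction = "") {
  cells <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  degenerate <- (a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0
  or <- if (b * c > 0) (a * d) / (b * c)
        else if (a * d > 0) Inf else NaN
  corrected <- any(cells == 0)
  cc <- if (corrected) cells + 0.5 else cells
  se <- sqrt(sum(1 / cc))
  or_c <- (cc["a"] * cc["d"]) / (cc["b"] * cc["c"])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- unname(exp(log(or_c) + c(-1, 1) * z * se))
  p <- if (degenerate) NA_real_ else
    stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))$p.value
  structure(list(table = cells, odds_ratio = or,
                 ci_low = ci[1], ci_high = ci[2], p_value = p,
                 degenerate = degenerate, haldane_corrected = corrected,
                 name = name, direction = direction),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Enrichment%s%s: OR = %.3g (95%% CI %.3g-%.3g), p = %.3g\n",
              if (nzchar(x$name)) paste0(" of ", x$name) else "",
              if (nzchar(x$direction)) paste0(" [", x$direction, "]") else "",
              x$odds_ratio, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  table: a=%d b=%d c=%d d=%d%s%s\n",
              x$table["a"], x$table["b"], x$table["c"], x$table["d"],
              if (x$degenerate) " (degenerate: empty margin, no p)" else "",
              if (x$haldane_corrected) " (CI Haldane-corrected)" else ""))
  invisible(x)
}

#' Fisher enrichment of a locus set among selected probes
#'
#' Two-tailed Fisher's exact test of whether \code{selected} probes are
#' enriched for members of \code{target}, relative to a reference
#' \code{universe} (by default the full QC-passing array manifest, which
#' avoids array-composition bias). The target is intersected with the
#' universe before tabulation.
#'
#' @param selected Character vector of probe ids; must lie in
#'   \code{universe}.
#' @param target A \code{\link{locus_set}} (or character vector of ids).
#' @param universe Character vector of reference probe ids.
#' @param conf_level Confidence level for the OR interval.
#' @return An \code{enrichment_result}; degenerate (no p-value) when
#'   \code{selected} is empty or the target does not intersect the
#'   universe.
#' @export
fisher_enrichment <- function(selected, target, universe, conf_level = 0.95) {
  tgt <- if (inherits(target, "locus_set")) target$members else
    as.character(target)
  name <- if (inherits(target, "locus_set")) target$name else ""
  selected <- unique(as.character(selected))
  universe <- unique(as.character(universe))
  if (!all(selected %in% universe))
    stop("selected probes must be a subset of the universe")
  tgt <- intersect(tgt, universe)
  a <- length(intersect(selected, tgt))
  b <- length(selected) - a
  c <- length(tgt) - a
  d <- length(universe) - a - b - c
  fisher_counts(a, b, c, d, conf_level = conf_level, name = name)
}

#' Baseline-matched enrichment of methylation change
#'
#' Restricts the enrichment universe to probes with the stated baseline
#' methylation in normal tissue, then tests the target set among probes
#' that move in the stated direction in cases. For \code{direction =
#' "hyper"} the universe is probes with normal mean beta below
#' \code{baseline_cut} (default 0.2) and the selection is probes whose case
#' mean is strictly higher; for \code{"hypo"} the universe is normal mean
#' beta above \code{baseline_cut} (default 0.4) and the selection moves
#' lower. Optionally the selection is intersected with a significance call
#' list from the supervised analysis.
#'
#' @param normal_means,case_means Named numeric vectors of per-probe mean
#'   beta (same probe space); a \code{\link{beta_matrix}} of normals may be
#'   passed for \code{normal_means}.
#' @param target A \code{\link{locus_set}}.
#' @param direction \code{"hyper"} or \code{"hypo"}.
#' @param baseline_cut Baseline mean-beta cut-point; defaults to 0.2 for
#'   hyper and 0.4 for hypo.
#' @param sig_probes Optional character vector: restrict the selection to
#'   these probes (significance-gated mode).
#' @return An \code{enrichment_result}.
#' @export
baseline_matched_enrichment <- function(normal_means, case_means, target,
                                        direction = c("hyper", "hypo"),
                                        baseline_cut = NULL,
                                        sig_probes = NULL) {
  direction <- match.arg(direction)
  if (inherits(normal_means, "beta_matrix"))
    normal_means <- rowMeans(normal_means$values, na.rm = TRUE)
  if (is.null(baseline_cut))
    baseline_cut <- if (direction == "hyper") 0.2 else 0.4
  probes <- intersect(names(normal_means), names(case_means))
  nm <- normal_means[probes]
  cm <- case_means[probes]
  universe <- if (direction == "hyper") probes[!is.na(nm) & nm < baseline_cut]
              else probes[!is.na(nm) & nm > baseline_cut]
  if (length(universe) == 0L) {
    warning("no probes pass the baseline criterion; degenerate enrichment")
    return(fisher_counts(0, 0, 0, 0, name = target$name,
                         direction = direction))
  }
  moved <- if (direction == "hyper")
    universe[cm[universe] > nm[universe]]
  else universe[cm[universe] < nm[universe]]
  if (!is.null(sig_probes)) moved <- intersect(moved, sig_probes)
  res <- fisher_enrichment(moved, target, universe)
  res$direction <- direction
  res$selected <- moved
  res$universe <- universe
  res
}

#' Enrichment against baseline-matched control probes
#'
#' Tests whether target probes change more often than non-target control
#' probes with the same baseline methylation, so that enrichment cannot be
#' an artefact of the starting methylation level in normal tissue. The
#' universe is the union of target probes and non-target probes whose
#' normal mean beta lies in \code{baseline_band} (open interval); the
#' selection is probes moving in the stated direction.
#'
#' @inheritParams baseline_matched_enrichment
#' @param baseline_band Numeric length-2 (low, high): the band of normal
#'   mean beta defining matched controls.
#' @return An \code{enrichment_result}.
#' @export
control_matched_enrichment <- function(normal_means, case_means, target,
                                       direction = c("hyper", "hypo"),
                                       baseline_band, sig_probes = NULL) {
  direction <- match.arg(direction)
  if (inherits(normal_means, "beta_matrix"))
    normal_means <- rowMeans(normal_means$values, na.rm = TRUE)
  stopifnot(length(baseline_band) == 2, baseline_band[1] < baseline_band[2])
  probes <- intersect(names(normal_means), names(case_means))
  nm <- normal_means[probes]
  cm <- case_means[probes]
  in_band <- !is.na(nm) & nm > baseline_band[1] & nm < baseline_band[2]
  is_tgt <- probes %in% target$members
  universe <- probes[in_band]  # targets and controls matched on baseline
  controls <- probes[!is_tgt & in_band]
  if (length(controls) == 0L)
    stop("no control probes fall in the baseline band; widen the band")
  moved <- if (direction == "hyper")
    universe[cm[universe] > nm[universe]]
  else universe[cm[universe] < nm[universe]]
  if (!is.null(sig_probes)) moved <- intersect(moved, sig_probes)
  res <- fisher_enrichment(moved, target, universe)
  res$direction <- direction
  res$selected <- moved
  res$universe <- universe
  res
}
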