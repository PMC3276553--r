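#' Discretize beta values into methylation states
#'
#' Maps beta to three states: unmethylated (0) for beta < \code{lower},
#' hemimethylated (1) for \code{lower} <= beta <= \code{upper} (both
#' boundaries inclusive), methylated (2) for beta > \code{upper}. Missing
#' beta gives a missing state.
#'
#' @param beta Numeric vector in [0, 1].
#' @param lower,upper State thresholds (defaults 0.25 and 0.7).
#' @return Integer vector of states 0/1/2 (NA preserved).
#' @export
discretize <- function(beta, lower = 0.25, upper = 0.7) {
  stopifnot(lower < upper)
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  out <- ifelse(beta < lower, 0L, ifelse(beta <= upper, 1L, 2L))
  as.integer(out)
}

#' Select CpGs with stable methylation state across normal samples
#'
#' A probe is stable when its discretized state is identical in all
#' non-missing normal samples (at least \code{min_normals} of them). The
#' stable state and the mean beta across those normals are stored; the mean
#' is the reference point for the buffered transition calls.
#'
#' @param bm_normals A \code{\link{beta_matrix}} of normal samples only
#'   (>= 2 columns).
#' @param min_normals Minimum non-missing normals per probe (default 2).
#' @param lower,upper State thresholds passed to \code{\link{discretize}}.
#' @return A data.frame of class \code{stable_set} with columns
#'   \code{probe_id}, \code{stable_state}, \code{normal_mean_beta},
#'   \code{n_normals}; thresholds kept as attributes.
#' @export
find_stable <- function(bm_normals, min_normals = 2, lower = 0.25,
                        upper = 0.7) {
  vals <- if (inherits(bm_normals, "beta_matrix")) bm_normals$values
          else as.matrix(bm_normals)
  if (ncol(vals) < 2)
    stop("stability is undefined on fewer than 2 normal samples")
  if (min_normals < 2) stop("min_normals must be >= 2")
  st <- matrix(discretize(vals, lower, upper), nrow = nrow(vals),
               dimnames = dimnames(vals))
  n_ok <- rowSums(!is.na(st))
  rng_min <- suppressWarnings(apply(st, 1, min, na.rm = TRUE))
  rng_max <- suppressWarnings(apply(st, 1, max, na.rm = TRUE))
  stable <- n_ok >= min_normals & rng_min == rng_max
  out <- data.frame(probe_id = rownames(vals)[stable],
                    stable_state = rng_min[stable],
                    normal_mean_beta = rowMeans(vals, na.rm = TRUE)[stable],
                    n_normals = as.integer(n_ok[stable]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "lower") <- lower
  attr(out, "upper") <- upper
  class(out) <- c("stable_set", "data.frame")
  out
}

#' Call buffered state transitions for one tumour sample
#'
#' For each stable probe, a transition is called when (i) the discretized
#' tumour state differs from the stable normal state AND (ii) the absolute
#' change in beta relative to the normal mean is at least \code{buffer}
#' (default 0.10). The buffer makes the call robust to the placement of the
#' discretization thresholds: a small beta shift that merely trespasses a
#' threshold is not counted.
#'
#' @param sample_beta Named numeric vector of tumour beta values.
#' @param stable A \code{\link{find_stable}} result.
#' @param buffer Minimum absolute beta change in [0, 1) (default 0.10).
#' @return Character vector aligned with \code{stable}: one of
#'   \code{"0->1/2"}, \code{"1->2"}, \code{"1->0"}, \code{"2->0/1"},
#'   \code{"none"}, or NA where the tumour beta is missing.
#' @export
transitions <- function(sample_beta, stable, buffer = 0.10) {
  stopifnot(buffer >= 0, buffer < 1)
  lower <- attr(stable, "lower") %||% 0.25
  upper <- attr(stable, "upper") %||% 0.7
  b <- sample_beta[stable$probe_id]
  st <- discretize(b, lower, upper)
  s0 <- stable$stable_state
  changed <- !is.na(st) & st != s0 &
    abs(b - stable$normal_mean_beta) >= buffer
  lab <- rep(NA_character_, nrow(stable))
  lab[!is.na(st)] <- "none"
  lab[changed & s0 == 0L] <- "0->1/2"
  lab[changed & s0 == 1L & st == 2L] <- "1->2"
  lab[changed & s0 == 1L & st == 0L] <- "1->0"
  lab[changed & s0 == 2L] <- "2->0/1"
  lab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-sample index computation on a restricted stable set
.indices_one <- function(sample_beta, stable, buffer) {
  lab <- transitions(sample_beta, stable, buffer)
  ok <- !is.na(lab)
  s0 <- stable$stable_state
  n0 <- sum(ok & s0 == 0L); n1 <- sum(ok & s0 == 1L); n2 <- sum(ok & s0 == 2L)
  frac <- function(k, n) if (n == 0L) NA_real_ else k / n
  c(n0 = n0, n1 = n1, n2 = n2,
    f_0_gain = frac(sum(lab == "0->1/2", na.rm = TRUE), n0),
    f_1_gain = frac(sum(lab == "1->2", na.rm = TRUE), n1),
    f_1_loss = frac(sum(lab == "1->0", na.rm = TRUE), n1),
    f_2_loss = frac(sum(lab == "2->0/1", na.rm = TRUE), n2),
    combined_demi = frac(sum(lab %in% c("1->0", "2->0/1"), na.rm = TRUE),
                         n1 + n2))
}

#' Epigenetic Instability Indices (EpI) per tumour sample
#'
#' For every tumour sample, the fraction of stable CpGs undergoing each of
#' the four buffered state transitions, each divided by the number of
#' stable CpGs with the corresponding baseline state that are non-missing
#' in that sample: \code{f_0_gain} (0 -> 1/2), \code{f_1_gain} (1 -> 2),
#' \code{f_1_loss} (1 -> 0) and \code{f_2_loss} (2 -> 0/1). \code{f_2_loss}
#' is the Demethylation Instability Index (DeMI, also in column
#' \code{demi}); \code{combined_demi} pools the 1 -> 0 and 2 -> 0/1
#' transitions over the pooled state-1/2 denominator. When locus sets are
#' supplied the same indices are additionally computed on the stable CpGs
#' restricted to each set (columns prefixed with the set name), giving the
#' stem-cell indices PCGT (0 -> 1/2), MESC (1 -> 0) and MESC (2 -> 0/1).
#' Zero-denominator indices are reported as NA, never as 0.
#'
#' @param bm A \code{\link{beta_matrix}} of tumour samples, or a named
#'   numeric vector for a single sample.
#' @param stable A \code{\link{find_stable}} result from the matched normal
#'   cohort.
#' @param locus_sets Named list of \code{\link{locus_set}}s (e.g.
#'   \code{list(mesc = ..., pcgt = ...)}).
#' @param buffer Minimum absolute beta change for a transition call.
#' @return A data.frame of class \code{epi_indices}: one row per sample
#'   with denominators (\code{n0}, \code{n1}, \code{n2}), the four indices,
#'   \code{demi}, \code{combined_demi}, and the restricted variants.
#' @export
epi_indices <- function(bm, stable, locus_sets = list(), buffer = 0.10) {
  vals <- if (inherits(bm, "beta_matrix")) bm$values
          else if (is.matrix(bm)) bm
          else matrix(bm, ncol = 1, dimnames = list(names(bm), "sample_1"))
  if (nrow(stable) == 0L) stop("the stable set is empty")
  subsets <- c(list(all = stable),
               lapply(locus_sets, function(s) {
                 sub <- stable[stable$probe_id %in% s$members, , drop = FALSE]
                 attr(sub, "lower") <- attr(stable, "lower")
                 attr(sub, "upper") <- attr(stable, "upper")
                 sub
               }))
  rows <- lapply(seq_len(ncol(vals)), function(j) {
    v <- vals[, j]
    names(v) <- rownames(vals)
    unlist(lapply(names(subsets), function(nm) {
      x <- .indices_one(v, subsets[[nm]], buffer)
      if (nm == "all") x else stats::setNames(x, paste0(nm, "_", names(x)))
    }))
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(data.frame(sample_id = colnames(vals),
                          stringsAsFactors = FALSE), out)
  out$demi <- out$f_2_loss
  for (nm in names(locus_sets))
    out[[paste0(nm, "_demi")]] <- out[[paste0(nm, "_f_2_loss")]]
  grp <- if (inherits(bm, "beta_matrix")) bm$samples$group else NULL
  if (!is.null(grp)) out$group <- grp
  attr(out, "buffer") <- buffer
  class(out) <- c("epi_indices", "data.frame")
  out
}

#' @export
print.epi_indices <- function(x, ...) {
  cat(sprintf("Epigenetic instability indices: %d sample(s), buffer = %g\n",
              nrow(x), attr(x, "buffer")))
  print.data.frame(utils::head(
    x[, intersect(c("sample_id", "group", "f_0_gain", "f_1_gain",
                    "f_1_loss", "demi", "combined_demi"), names(x))], 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more row(s)\n")
  invisible(x)
}

#' @export
summary.epi_indices <- function(object, ...) {
  idx <- intersect(c("f_0_gain", "f_1_gain", "f_1_loss", "demi",
                     "combined_demi", "mesc_demi", "mesc_combined_demi",
                     "pcgt_f_0_gain"), names(object))
  out <- do.call(rbind, lapply(idx, function(cn) {
    v <- object[[cn]]
    data.frame(index = cn, n = sum(!is.na(v)), mean = mean(v, na.rm = TRUE),
               median = stats::median(v, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  out
}

#' @export
plot.epi_indices <- function(x, index = "demi", ...) {
  if (!is.null(x$group) && length(unique(x$group)) > 1)
    graphics::boxplot(x[[index]] ~ x$group, xlab = "group", ylab = index, ...)
  else
    graphics::hist(x[[index]], xlab = index, main = "", ...)
  invisible(x)
}

#' Combined demethylation instability index for one sample
#'
#' Pooled fraction of qualifying demethylation transitions (1 -> 0 and
#' 2 -> 0/1) over the pooled count of stable MESC CpGs in states 1 and 2
#' (micro-average), so the statistic remains a fraction of CpGs.
#'
#' @param sample_beta Named numeric vector of tumour beta values.
#' @param stable A \code{\link{find_stable}} result.
#' @param mesc A \code{\link{locus_set}} of MESC probes.
#' @param buffer Minimum absolute beta change.
#' @return A single fraction, or NA when no stable MESC CpGs have baseline
#'   state 1 or 2.
#' @export
combined_demi <- function(sample_beta, stable, mesc, buffer = 0.10) {
  sub <- stable[stable$probe_id %in% mesc$members &
                  stable$stable_state %in% c(1L, 2L), , drop = FALSE]
  attr(sub, "lower") <- attr(stable, "lower")
  attr(sub, "upper") <- attr(stable, "upper")
  if (nrow(sub) == 0L) {
    warning("no stable MESC CpGs with baseline state 1 or 2")
    return(NA_real_)
  }
  lab <- transitions(sample_beta, sub, buffer)
  ok <- !is.na(lab)
  if (!any(ok)) return(NA_real_)
  sum(lab %in% c("1->0", "2->0/1"), na.rm = TRUE) / sum(ok)
}

#' Per-CpG hypomethylation frequency across a tumour cohort
#'
#' For each stable MESC CpG (baseline state 1 or 2), the fraction of
#' tumours in which it undergoes a qualifying demethylation transition
#' (1 -> 0 or 2 -> 0/1). Rows are sorted by decreasing frequency with ties
#' broken alphabetically by probe id, the ranking used to pick the most
#' recurrently hypomethylated CpGs.
#'
#' @param bm_tumours A \code{\link{beta_matrix}} of tumour samples.
#' @param stable A \code{\link{find_stable}} result.
#' @param mesc A \code{\link{locus_set}} of MESC probes.
#' @param buffer Minimum absolute beta change.
#' @return data.frame with columns \code{probe_id}, \code{stable_state},
#'   \code{n_tumours} (non-missing), \code{frequency}, sorted.
#' @export
hypo_frequency <- function(bm_tumours, stable, mesc, buffer = 0.10) {
  vals <- bm_tumours$values
  sub <- stable[stable$probe_id %in% mesc$members &
                  stable$stable_state %in% c(1L, 2L), , drop = FALSE]
  attr(sub, "lower") <- attr(stable, "lower")
  attr(sub, "upper") <- attr(stable, "upper")
  if (nrow(sub) == 0L) {
    warning("no stable MESC CpGs with baseline state 1 or 2")
    return(data.frame(probe_id = character(0), stable_state = integer(0),
                      n_tumours = integer(0), frequency = numeric(0)))
  }
  hit <- matrix(FALSE, nrow(sub), ncol(vals))
  ok <- matrix(FALSE, nrow(sub), ncol(vals))
  for (j in seq_len(ncol(vals))) {
    v <- vals[, j]
    names(v) <- rownames(vals)
    lab <- transitions(v, sub, buffer)
    ok[, j] <- !is.na(lab)
    hit[, j] <- lab %in% c("1->0", "2->0/1") & ok[, j]
  }
  n_t <- rowSums(ok)
  freq <- ifelse(n_t > 0, rowSums(hit) / n_t, NA_real_)
  out <- data.frame(probe_id = sub$probe_id, stable_state = sub$stable_state,
                    n_tumours = as.integer(n_t), frequency = freq,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$frequency, out$probe_id), , drop = FALSE]
}
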