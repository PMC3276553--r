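#' Compute beta values from background-corrected intensities
#'
#' Evaluates beta = max(M, 0) / (max(M, 0) + max(U, 0) + offset), the
#' methylated-allele fraction estimate for Infinium arrays. Negative
#' background-corrected intensities are clamped at zero; the additive offset
#' (default 100) regularises low-intensity probes, so beta lies in [0, 1).
#'
#' @param M,U Numeric vectors of methylated / unmethylated allele
#'   intensities (recycled to common length).
#' @param offset Regularising constant added to the denominator.
#' @return Numeric vector of beta values in [0, 1).
#' @export
compute_beta <- function(M, U, offset = 100) {
  if (!all(is.finite(M)) || !all(is.finite(U)))
    stop("compute_beta: intensities must be finite")
  m <- pmax(M, 0)
  u <- pmax(U, 0)
  m / (m + u + offset)
}

#' Construct a beta matrix with sample annotations
#'
#' @param values Numeric matrix, probes in rows (rownames are probe ids),
#'   samples in columns; all non-missing entries must be in [0, 1].
#' @param samples data.frame of per-sample annotations with a unique
#'   \code{sample_id} column matching \code{colnames(values)}; typical
#'   columns are \code{group} (stage label), \code{age}, \code{chip},
#'   \code{bs_intensity}, \code{surv_time}, \code{surv_event}.
#' @param detection_p Optional matrix of detection p-values, same
#'   dimensions as \code{values}.
#' @return An object of class \code{beta_matrix}: a list with elements
#'   \code{values}, \code{samples}, \code{detection_p}.
#' @export
beta_matrix <- function(values, samples, detection_p = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have probe ids as rownames")
  if (anyDuplicated(rownames(values))) stop("duplicate probe ids")
  if (!is.data.frame(samples) || is.null(samples$sample_id))
    stop("samples must be a data.frame with a sample_id column")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  if (nrow(samples) != ncol(values))
    stop("nrow(samples) must equal ncol(values)")
  if (is.null(colnames(values))) colnames(values) <- samples$sample_id
  if (!identical(colnames(values), as.character(samples$sample_id)))
    stop("colnames(values) must match samples$sample_id (in order)")
  rng <- range(values, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
    stop("beta values must lie in [0, 1]")
  if (!is.null(samples$surv_event)) {
    st <- samples$surv_time
    if (is.null(st) || any(!is.na(samples$surv_event) & is.na(st)))
      stop("surv_event present without surv_time")
  }
  if (!is.null(detection_p)) {
    detection_p <- as.matrix(detection_p)
    if (!identical(dim(detection_p), dim(values)))
      stop("detection_p dimensions must match values")
  }
  structure(list(values = values, samples = samples,
                 detection_p = detection_p),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$samples$group))
    print(table(group = x$samples$group))
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$values)

#' Subset a beta matrix by probes and/or samples
#'
#' @param x A \code{beta_matrix}.
#' @param i Probe index (ids, logical or integer).
#' @param j Sample index.
#' @param ... Unused.
#' @return The subsetted \code{beta_matrix}.
#' @export
`[.beta_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  beta_matrix(x$values[i, j, drop = FALSE],
              x$samples[match(colnames(x$values[, j, drop = FALSE]),
                              x$samples$sample_id), , drop = FALSE],
              if (!is.null(x$detection_p))
                x$detection_p[i, j, drop = FALSE])
}

#' Read a beta-value matrix from delimited text
#'
#' Probes as rows, samples as columns, first column the probe id.
#' GEO series-matrix-style comment lines beginning with \code{!} are
#' skipped.
#'
#' @param path Path to a TSV file.
#' @param annotations Optional path to a CSV of sample annotations keyed by
#'   \code{sample_id}; if omitted a minimal annotation frame is built from
#'   the column names.
#' @return A \code{\link{beta_matrix}}.
#' @export
read_beta_matrix <- function(path, annotations = NULL) {
  x <- utils::read.delim(path, comment.char = "!", check.names = FALSE,
                         stringsAsFactors = FALSE)
  probes <- as.character(x[[1]])
  vals <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- probes
  ann <- if (is.null(annotations))
    data.frame(sample_id = colnames(vals), stringsAsFactors = FALSE)
  else read_sample_annotations(annotations)
  ann <- ann[match(colnames(vals), ann$sample_id), , drop = FALSE]
  if (anyNA(ann$sample_id))
    stop("annotation file does not cover all samples in the matrix")
  rownames(ann) <- NULL
  beta_matrix(vals, ann)
}

#' Read per-sample annotations
#'
#' @param path CSV keyed by \code{sample_id}.
#' @return data.frame of annotations.
#' @export
read_sample_annotations <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(x$sample_id)) stop("annotations need a sample_id column")
  x
}

# Sarle-style bimodality coefficient of a beta distribution's sample;
# > ~0.55 suggests the two-mode shape typical of a good methylation array.
bimodality_coefficient <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(NA_real_)
  g1 <- mean((x - m)^3) / s2^1.5
  g2 <- mean((x - m)^4) / s2^2 - 3
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Sample-level quality control
#'
#' Excludes samples whose bisulfite-conversion control intensity falls below
#' \code{bs_threshold} (strictly below; a sample exactly at the threshold is
#' retained). Samples whose total-intensity summary (annotation column
#' \code{total_intensity}, e.g. the per-sample median of U+M) lies outside
#' median +/- \code{iqr_mult} x IQR across samples are flagged as outliers,
#' and excluded only when \code{exclude_intensity_outliers = TRUE}. A
#' per-sample bimodality coefficient of the beta distribution is reported
#' for manual review; it never excludes.
#'
#' @param bm A \code{\link{beta_matrix}} whose annotations may carry
#'   \code{bs_intensity} and \code{total_intensity}.
#' @param bs_threshold Bisulfite-control intensity cut-off (default 4000).
#' @param iqr_mult Multiplier for the total-intensity outlier fence.
#' @param exclude_intensity_outliers Exclude (not just flag) intensity
#'   outliers.
#' @return The filtered \code{beta_matrix}, with a \code{qc_report}
#'   attribute: a data.frame of sample_id, excluded, reason, bimodality.
#' @export
qc_filter_samples <- function(bm, bs_threshold = 4000, iqr_mult = 3,
                              exclude_intensity_outliers = FALSE) {
  ann <- bm$samples
  n <- nrow(ann)
  reason <- character(n)
  excl <- logical(n)
  if (is.null(ann$bs_intensity) || all(is.na(ann$bs_intensity))) {
    warning("no bs_intensity annotation; bisulfite-control QC skipped")
  } else {
    low <- !is.na(ann$bs_intensity) & ann$bs_intensity < bs_threshold
    excl[low] <- TRUE
    reason[low] <- "bs_control"
  }
  if (!is.null(ann$total_intensity) && !all(is.na(ann$total_intensity))) {
    ti <- ann$total_intensity
    med <- stats::median(ti, na.rm = TRUE)
    iqr <- stats::IQR(ti, na.rm = TRUE)
    out <- !is.na(ti) & abs(ti - med) > iqr_mult * iqr
    if (exclude_intensity_outliers) {
      reason[out & !excl] <- "total_intensity"
      excl[out] <- TRUE
    } else {
      reason[out & !excl] <- "total_intensity_flag_only"
    }
  }
  bimod <- apply(bm$values, 2, bimodality_coefficient)
  report <- data.frame(sample_id = ann$sample_id, excluded = excl,
                       reason = reason, bimodality = bimod,
                       row.names = NULL, stringsAsFactors = FALSE)
  if (all(excl)) stop("sample QC excluded every sample")
  message(sprintf("qc_filter_samples: %d of %d sample(s) excluded",
                  sum(excl), n))
  out_bm <- if (any(excl)) bm[, !excl] else bm
  attr(out_bm, "qc_report") <- report
  out_bm
}

#' Probe-level quality control by detection p-value
#'
#' Retains probes detected above background (detection p <
#' \code{detection_alpha}) in at least \code{min_fraction_detected} of
#' samples.
#'
#' @param bm A \code{\link{beta_matrix}} carrying a \code{detection_p}
#'   matrix.
#' @param detection_alpha Detection p-value threshold (default 0.05).
#' @param min_fraction_detected Minimum fraction of samples in which a
#'   probe must be detected (default 0.95).
#' @param strict Error when no detection matrix is present (default TRUE);
#'   otherwise pass through with a warning.
#' @return The probe-filtered \code{beta_matrix}.
#' @export
qc_filter_probes <- function(bm, detection_alpha = 0.05,
                             min_fraction_detected = 0.95, strict = TRUE) {
  if (is.null(bm$detection_p)) {
    if (strict) stop("no detection p-value matrix present")
    warning("no detection p-value matrix; probe QC skipped")
    return(bm)
  }
  det <- rowMeans(bm$detection_p < detection_alpha, na.rm = TRUE)
  keep <- det >= min_fraction_detected
  if (!any(keep)) stop("probe QC dropped every probe")
  message(sprintf("qc_filter_probes: %d of %d probe(s) retained",
                  sum(keep), length(keep)))
  bm[keep, ]
}
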