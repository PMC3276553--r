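#' Construct a locus set
#'
#' A locus set is a named collection of unique probe (or CpG site)
#' identifiers together with a free-text provenance string recording how it
#' was derived (source file, derivation parameters).
#'
#' @param name Label for the set (e.g. \code{"MESC"}, \code{"PCGT"}).
#' @param members Character vector of probe identifiers; duplicates are
#'   collapsed.
#' @param provenance Free text describing the origin of the set.
#' @return An object of class \code{locus_set}: a list with elements
#'   \code{name}, \code{members} (unique character vector) and
#'   \code{provenance}.
#' @export
locus_set <- function(name, members, provenance = "") {
  members <- as.character(members)
  members <- members[!is.na(members)]
  dup <- sum(duplicated(members))
  members <- unique(members)
  if (dup > 0L)
    message(sprintf("locus_set '%s': collapsed %d duplicate member id(s)",
                    name, dup))
  if (length(members) == 0L)
    warning(sprintf("locus_set '%s' is empty", name))
  structure(list(name = as.character(name), members = members,
                 provenance = as.character(provenance)),
            class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("Locus set '%s': %d members\n", x$name, length(x$members)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.locus_set <- function(x) length(x$members)

#' Read strand-resolved bisulfite read counts
#'
#' Reads a tab-delimited table of per-CpG whole-genome bisulfite sequencing
#' calls with one row per CpG site and C/T read counts for each strand
#' (Lister-style). A header with columns \code{chrom}, \code{pos},
#' \code{fwd_c}, \code{fwd_t}, \code{rev_c}, \code{rev_t} is required;
#' \code{pos} is 1-based.
#'
#' @param path Path to the tab-delimited file.
#' @return A data.frame with the six columns above plus a \code{site_id}
#'   column (\code{chrom:pos}).
#' @export
read_wgbs_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "pos", "fwd_c", "fwd_t", "rev_c", "rev_t")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("WGBS count table is missing required column(s): ",
         paste(miss, collapse = ", "))
  x <- x[, need]
  cnt <- as.matrix(x[, c("fwd_c", "fwd_t", "rev_c", "rev_t")])
  if (any(cnt < 0, na.rm = TRUE)) stop("negative read counts")
  if (any(x$pos < 1, na.rm = TRUE)) stop("positions must be 1-based (>= 1)")
  x$site_id <- paste0(x$chrom, ":", x$pos)
  x
}

#' Per-site methylation level from strand-resolved read counts
#'
#' The methylation level of a strand is the fraction of cytosine reads,
#' C/(C+T); the overall level is the mean of the two strand levels when both
#' strands are covered, otherwise the level of the covered strand.
#'
#' @param sites A data.frame with columns \code{fwd_c}, \code{fwd_t},
#'   \code{rev_c}, \code{rev_t} (as returned by \code{\link{read_wgbs_counts}}).
#' @return \code{sites} with added columns \code{fwd_level},
#'   \code{rev_level} (NA where a strand has zero coverage) and
#'   \code{overall_level}.
#' @export
site_methylation_level <- function(sites) {
  fwd_n <- sites$fwd_c + sites$fwd_t
  rev_n <- sites$rev_c + sites$rev_t
  if (any(fwd_n == 0 & rev_n == 0))
    stop("methylation level undefined: site(s) with zero coverage on both strands")
  fwd <- ifelse(fwd_n > 0, sites$fwd_c / fwd_n, NA_real_)
  rev <- ifelse(rev_n > 0, sites$rev_c / rev_n, NA_real_)
  overall <- rowMeans(cbind(fwd, rev), na.rm = TRUE)
  sites$fwd_level <- fwd
  sites$rev_level <- rev
  sites$overall_level <- overall
  sites
}

#' Derive the MESC locus set from bisulfite read counts
#'
#' A CpG site is called Methylated in Embryonic Stem Cells (MESC) when it is
#' sufficiently covered and its overall mean methylation level (average of
#' the forward- and reverse-strand C/(C+T) fractions) is strictly greater
#' than \code{level_min}. The default coverage rule requires the total
#' number of C and T reads summed over both strands to be at least
#' \code{coverage_min}; with \code{per_strand = TRUE} each strand must
#' individually reach \code{coverage_min}.
#'
#' @param sites A data.frame of strand-resolved counts (see
#'   \code{\link{read_wgbs_counts}}).
#' @param coverage_min Minimum read coverage (default 5).
#' @param level_min Minimum overall methylation level, exclusive
#'   (default 0.8).
#' @param per_strand If TRUE, apply \code{coverage_min} to each strand
#'   separately rather than to the total across strands.
#' @return A \code{\link{locus_set}} whose members are the \code{site_id}s
#'   of the qualifying sites.
#' @export
derive_mesc <- function(sites, coverage_min = 5, level_min = 0.8,
                        per_strand = FALSE) {
  stopifnot(coverage_min >= 1, level_min > 0, level_min < 1)
  if (nrow(sites) == 0L) {
    warning("no input sites; MESC set is empty")
    return(locus_set("MESC", character(0),
                     provenance = "derived from 0 sites"))
  }
  if (is.null(sites$site_id))
    sites$site_id <- paste0(sites$chrom, ":", sites$pos)
  fwd_n <- sites$fwd_c + sites$fwd_t
  rev_n <- sites$rev_c + sites$rev_t
  covered <- if (per_strand) fwd_n >= coverage_min & rev_n >= coverage_min
             else fwd_n + rev_n >= coverage_min
  sites <- sites[covered & (fwd_n + rev_n) > 0, , drop = FALSE]
  if (nrow(sites) == 0L) {
    warning("no sites pass the coverage rule; MESC set is empty")
    return(locus_set("MESC", character(0),
                     provenance = "derived: none passed coverage"))
  }
  sites <- site_methylation_level(sites)
  keep <- sites$overall_level > level_min
  locus_set("MESC", sites$site_id[keep],
            provenance = sprintf(
              "derived from WGBS counts: coverage >= %d (%s), overall level > %g",
              coverage_min, if (per_strand) "per strand" else "total",
              level_min))
}

#' Load a locus set from a supplementary-style table
#'
#' Reads a delimited text table of array probes belonging to a locus class
#' (the IlluminaID / geneID / symbol / MapInfo / chromosome layout of
#' published supplementary tables) and returns the unique probe identifiers
#' as a locus set. Duplicate rows are collapsed with a message.
#'
#' @param path Path to a CSV or tab-delimited file (delimiter sniffed from
#'   the header line).
#' @param id_column Name of the probe-identifier column
#'   (default \code{"IlluminaID"}).
#' @param name Set name; defaults to the file name without extension.
#' @return A \code{\link{locus_set}}.
#' @export
load_locus_table <- function(path, id_column = "IlluminaID", name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         quote = "\"", comment.char = "")
  if (!id_column %in% names(x))
    stop(sprintf("locus table %s has no column '%s' (found: %s)",
                 path, id_column, paste(names(x), collapse = ", ")))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  locus_set(name, x[[id_column]], provenance = path)
}

#' Read an array probe manifest
#'
#' @param path CSV with columns \code{probe_id}, \code{gene},
#'   \code{chromosome}, \code{position}.
#' @return A data.frame with those columns and logical flag columns
#'   \code{is_pcgt}, \code{is_mesc}, \code{is_pmd} initialised to FALSE.
#' @export
read_manifest <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("probe_id", "gene", "chromosome", "position")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$probe_id)) stop("manifest probe_id values must be unique")
  for (fl in c("is_pcgt", "is_mesc", "is_pmd"))
    if (is.null(x[[fl]])) x[[fl]] <- FALSE
  x
}

#' Read a BED-style PMD annotation
#'
#' Partially methylated domains as 0-based half-open intervals
#' (\code{chrom}, \code{start}, \code{end}); no header expected.
#'
#' @param path Path to a 3+ column BED file.
#' @return A data.frame with columns \code{chrom}, \code{start}, \code{end}.
#' @export
read_pmd_bed <- function(path) {
  x <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (ncol(x) < 3) stop("PMD BED file needs at least 3 columns")
  x <- x[, 1:3]
  names(x) <- c("chrom", "start", "end")
  if (any(x$end <= x$start)) stop("PMD intervals must have end > start")
  x
}

#' Annotate a manifest with locus-class flags
#'
#' Sets \code{is_pcgt} / \code{is_mesc} by probe-id membership and
#' \code{is_pmd} by genomic overlap with PMD intervals (a probe is inside a
#' PMD when its 1-based position lies in the 0-based half-open interval
#' \code{[start, end)}). Flags may combine freely; the operation is
#' idempotent.
#'
#' @param manifest A manifest data.frame (see \code{\link{read_manifest}}).
#' @param pcgt,mesc Optional \code{\link{locus_set}}s of probe ids.
#' @param pmd Optional data.frame of BED intervals
#'   (see \code{\link{read_pmd_bed}}).
#' @return The manifest with flag columns set.
#' @export
annotate_manifest <- function(manifest, pcgt = NULL, mesc = NULL, pmd = NULL) {
  stopifnot(is.data.frame(manifest), "probe_id" %in% names(manifest))
  flag_by_id <- function(set, col) {
    hit <- manifest$probe_id %in% set$members
    if (!any(hit))
      warning(sprintf(
        "locus set '%s' has zero overlap with the manifest (id-space mismatch?)",
        set$name))
    manifest[[col]] <<- hit
    message(sprintf("annotate_manifest: %d probe(s) flagged %s", sum(hit), col))
  }
  if (!is.null(pcgt)) flag_by_id(pcgt, "is_pcgt")
  if (!is.null(mesc)) flag_by_id(mesc, "is_mesc")
  if (!is.null(pmd)) {
    # BED is 0-based half-open; probe position is 1-based, so containment in
    # [start, end) is start + 1 <= pos <= end
    pr <- GenomicRanges::GRanges(manifest$chromosome,
                                 IRanges::IRanges(manifest$position,
                                                  manifest$position))
    iv <- GenomicRanges::GRanges(pmd$chrom,
                                 IRanges::IRanges(pmd$start + 1L, pmd$end))
    hit <- IRanges::overlapsAny(pr, iv)
    if (!any(hit)) warning("PMD intervals overlap no manifest probe")
    manifest$is_pmd <- hit
    message(sprintf("annotate_manifest: %d probe(s) flagged is_pmd", sum(hit)))
  }
  manifest
}
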