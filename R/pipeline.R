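write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

default_run_config <- function() {
  list(seed = 1L,
       outdir = "epistab_run",
       stage = "cancer",
       sim = list(),                      # sim_config overrides
       qc = list(bs_threshold = 4000, detection_alpha = 0.05,
                 min_fraction_detected = 0.95),
       diff = list(p_threshold = 0.001, covariates = c("age", "chip")),
       enrich = list(baseline_hyper = 0.2, baseline_hypo = 0.4),
       instability = list(buffer = 0.10, lower = 0.25, upper = 0.7),
       loci = list(coverage_min = 5, level_min = 0.8),
       survival = list(standardize = TRUE),
       tet = list(alpha = 0.05, method = "spearman"),
       inputs = list())
}

merge_config <- function(base, override, path = "") {
  for (k in names(override)) {
    if (!k %in% names(base))
      stop(sprintf("unknown config key '%s%s'", path, k))
    if (is.list(base[[k]]) && is.list(override[[k]]) &&
        !is.null(names(base[[k]])) && k != "inputs" && k != "sim")
      base[[k]] <- merge_config(base[[k]], override[[k]],
                                paste0(path, k, "."))
    else base[[k]] <- override[[k]]
  }
  base
}

load_run_config <- function(config = NULL) {
  base <- default_run_config()
  if (is.null(config)) return(base)
  if (is.character(config)) config <- yaml::read_yaml(config)
  merge_config(base, config)
}

write_run_manifest <- function(dir, subcommand, cfg, inputs = character(0)) {
  hashes <- if (length(inputs))
    as.list(tools::md5sum(inputs[file.exists(inputs)])) else list()
  manifest <- list(subcommand = subcommand,
                   package_version = as.character(
                     utils::packageVersion("epistab")),
                   parameters = cfg[setdiff(names(cfg), "inputs")],
                   input_md5 = hashes)
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message("parameters: ",
          jsonlite::toJSON(cfg[setdiff(names(cfg), "inputs")],
                           auto_unbox = TRUE, digits = NA))
}

stage_dir <- function(cfg, stage) {
  d <- file.path(cfg$outdir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

need_input <- function(cfg, key) {
  p <- cfg$inputs[[key]]
  if (is.null(p))
    stop(sprintf("missing required input '%s' in config$inputs", key))
  if (!file.exists(p))
    stop(sprintf("input '%s' does not exist: %s", key, p))
  p
}

#' Run one pipeline stage
#'
#' Thin orchestration layer over the package functions. Each subcommand
#' reads its inputs from \code{config$inputs}, writes delimited outputs
#' plus a \code{run_manifest.json} (parameters, package version, input
#' hashes) into a stage subfolder of \code{config$outdir}, and returns its
#' main result invisibly. \code{demo} chains
#' simulate -> qc -> diff -> enrich -> instability -> survival -> tet on
#' simulated defaults.
#'
#' @param subcommand One of \code{"simulate"}, \code{"derive-loci"},
#'   \code{"qc"}, \code{"diff"}, \code{"enrich"}, \code{"instability"},
#'   \code{"survival"}, \code{"tet"}, \code{"demo"}.
#' @param config A named list of overrides, or the path to a YAML file;
#'   unknown keys are rejected. See the pipeline vignette for the layout.
#' @return The stage's main result, invisibly.
#' @export
run_stage <- function(subcommand = c("simulate", "derive-loci", "qc", "diff",
                                     "enrich", "instability", "survival",
                                     "tet", "demo"),
                      config = NULL) {
  subcommand <- match.arg(subcommand)
  cfg <- load_run_config(config)
  switch(subcommand,
         "simulate" = stage_simulate(cfg),
         "derive-loci" = stage_derive_loci(cfg),
         "qc" = stage_qc(cfg),
         "diff" = stage_diff(cfg),
         "enrich" = stage_enrich(cfg),
         "instability" = stage_instability(cfg),
         "survival" = stage_survival(cfg),
         "tet" = stage_tet(cfg),
         "demo" = run_demo(cfg$outdir, cfg$seed, config = cfg))
}

stage_simulate <- function(cfg) {
  d <- stage_dir(cfg, "simulate")
  scfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
  sm <- simulate_manifest(scfg)
  bm <- simulate_cohort(scfg, cfg$stage, sm)
  truth <- attr(bm, "truth")

  write_tsv(sm$manifest, file.path(d, "manifest.csv"))
  write_tsv(data.frame(IlluminaID = sm$mesc$members),
            file.path(d, "mesc_loci.tsv"))
  write_tsv(data.frame(IlluminaID = sm$pcgt$members),
            file.path(d, "pcgt_loci.tsv"))
  write_tsv(sm$pmd, file.path(d, "pmd.bed"))
  beta_out <- data.frame(probe_id = rownames(bm$values), bm$values,
                         check.names = FALSE)
  write_tsv(beta_out, file.path(d, "beta.tsv"))
  utils::write.csv(bm$samples, file.path(d, "annotations.csv"),
                   row.names = FALSE)
  write_tsv(truth, file.path(d, "truth.tsv"))
  wg <- simulate_wgbs_counts(scfg)
  write_tsv(wg$counts[, c("chrom", "pos", "fwd_c", "fwd_t", "rev_c",
                          "rev_t")], file.path(d, "wgbs_counts.tsv"))
  write_run_manifest(d, "simulate", cfg)
  invisible(bm)
}

stage_derive_loci <- function(cfg) {
  d <- stage_dir(cfg, "derive-loci")
  counts <- read_wgbs_counts(need_input(cfg, "wgbs_counts"))
  mesc <- derive_mesc(counts, coverage_min = cfg$loci$coverage_min,
                      level_min = cfg$loci$level_min)
  write_tsv(data.frame(site_id = mesc$members), file.path(d, "mesc_sites.tsv"))
  write_run_manifest(d, "derive-loci", cfg, cfg$inputs$wgbs_counts)
  invisible(mesc)
}

stage_qc <- function(cfg) {
  d <- stage_dir(cfg, "qc")
  bm <- read_beta_matrix(need_input(cfg, "beta"),
                         annotations = need_input(cfg, "annotations"))
  bm <- qc_filter_samples(bm, bs_threshold = cfg$qc$bs_threshold)
  report <- attr(bm, "qc_report")
  if (!is.null(bm$detection_p))
    bm <- qc_filter_probes(bm, cfg$qc$detection_alpha,
                           cfg$qc$min_fraction_detected)
  write_tsv(data.frame(probe_id = rownames(bm$values), bm$values,
                       check.names = FALSE), file.path(d, "beta_qc.tsv"))
  utils::write.csv(bm$samples, file.path(d, "annotations_qc.csv"),
                   row.names = FALSE)
  write_tsv(report, file.path(d, "qc_report.tsv"))
  write_run_manifest(d, "qc", cfg,
                     c(cfg$inputs$beta, cfg$inputs$annotations))
  invisible(bm)
}

.split_cohort <- function(bm) {
  normals <- bm[, bm$samples$group == "normal"]
  cases <- bm[, bm$samples$group != "normal"]
  list(normals = normals, cases = cases)
}

stage_diff <- function(cfg) {
  d <- stage_dir(cfg, "diff")
  bm <- read_beta_matrix(need_input(cfg, "beta"),
                         annotations = need_input(cfg, "annotations"))
  status <- as.integer(bm$samples$group != "normal")
  res <- fit_cpg_models(bm, status, covariates = cfg$diff$covariates)
  calls <- call_differential(res, cfg$diff$p_threshold)
  write_tsv(res, file.path(d, "differential.tsv"))
  write_tsv(data.frame(probe_id = calls$hyper), file.path(d, "hyper.tsv"))
  write_tsv(data.frame(probe_id = calls$hypo), file.path(d, "hypo.tsv"))
  write_run_manifest(d, "diff", cfg,
                     c(cfg$inputs$beta, cfg$inputs$annotations))
  invisible(res)
}

enrichment_row <- function(e) {
  data.frame(set = e$name, direction = e$direction,
             a = e$table["a"], b = e$table["b"], c = e$table["c"],
             d = e$table["d"], odds_ratio = e$odds_ratio,
             ci_low = e$ci_low, ci_high = e$ci_high, p_value = e$p_value,
             degenerate = e$degenerate, row.names = NULL)
}

stage_enrich <- function(cfg) {
  d <- stage_dir(cfg, "enrich")
  bm <- read_beta_matrix(need_input(cfg, "beta"),
                         annotations = need_input(cfg, "annotations"))
  pcgt <- load_locus_table(need_input(cfg, "pcgt"), name = "PCGT")
  mesc <- load_locus_table(need_input(cfg, "mesc"), name = "MESC")
  parts <- .split_cohort(bm)
  nm <- rowMeans(parts$normals$values, na.rm = TRUE)
  cm <- rowMeans(parts$cases$values, na.rm = TRUE)
  hyper <- baseline_matched_enrichment(nm, cm, pcgt, "hyper",
                                       cfg$enrich$baseline_hyper)
  hypo <- baseline_matched_enrichment(nm, cm, mesc, "hypo",
                                      cfg$enrich$baseline_hypo)
  out <- rbind(enrichment_row(hyper), enrichment_row(hypo))
  write_tsv(out, file.path(d, "enrichment.tsv"))
  write_tsv(data.frame(probe_id = hyper$selected),
            file.path(d, "hyper_moved.tsv"))
  write_tsv(data.frame(probe_id = hypo$selected),
            file.path(d, "hypo_moved.tsv"))
  write_run_manifest(d, "enrich", cfg,
                     unlist(cfg$inputs[c("beta", "annotations", "pcgt",
                                         "mesc")]))
  invisible(list(hyper = hyper, hypo = hypo))
}

stage_instability <- function(cfg) {
  d <- stage_dir(cfg, "instability")
  bm <- read_beta_matrix(need_input(cfg, "beta"),
                         annotations = need_input(cfg, "annotations"))
  pcgt <- load_locus_table(need_input(cfg, "pcgt"), name = "PCGT")
  mesc <- load_locus_table(need_input(cfg, "mesc"), name = "MESC")
  parts <- .split_cohort(bm)
  if (ncol(parts$normals$values) < 2)
    stop("instability stage needs >= 2 normal samples in the cohort ",
         "(inputs 'beta'/'annotations' with group == 'normal')")
  stable <- find_stable(parts$normals, lower = cfg$instability$lower,
                        upper = cfg$instability$upper)
  idx <- epi_indices(parts$cases, stable,
                     locus_sets = list(mesc = mesc, pcgt = pcgt),
                     buffer = cfg$instability$buffer)
  write_tsv(as.data.frame(idx), file.path(d, "epi_indices.tsv"))
  write_tsv(as.data.frame(stable), file.path(d, "stable_set.tsv"))
  hf <- hypo_frequency(parts$cases, stable, mesc,
                       buffer = cfg$instability$buffer)
  write_tsv(hf, file.path(d, "hypo_frequency.tsv"))
  write_run_manifest(d, "instability", cfg,
                     unlist(cfg$inputs[c("beta", "annotations", "pcgt",
                                         "mesc")]))
  invisible(idx)
}

stage_survival <- function(cfg) {
  d <- stage_dir(cfg, "survival")
  idx <- utils::read.delim(need_input(cfg, "indices"),
                           stringsAsFactors = FALSE)
  surv <- utils::read.csv(need_input(cfg, "survival"),
                          stringsAsFactors = FALSE)
  m <- merge(idx, surv, by = "sample_id")
  index_col <- cfg$inputs$index_column %||% "mesc_demi"
  fit <- cox_fit(m$time, m$event, m[[index_col]],
                 standardize = cfg$survival$standardize)
  groups <- tertile_groups(m[[index_col]])
  km <- km_curves(m$time[groups != "middle"], m$event[groups != "middle"],
                  droplevels(groups[groups != "middle"]))
  out <- data.frame(index = index_col, hr = fit$hr, ci_low = fit$ci_low,
                    ci_high = fit$ci_high, p_value = fit$p_value,
                    n = fit$n, scale = fit$scale,
                    logrank_p_tertiles = km$logrank_p)
  write_tsv(out, file.path(d, "survival.tsv"))
  write_run_manifest(d, "survival", cfg,
                     c(cfg$inputs$indices, cfg$inputs$survival))
  invisible(list(cox = fit, km = km))
}

stage_tet <- function(cfg) {
  d <- stage_dir(cfg, "tet")
  bm <- read_beta_matrix(need_input(cfg, "beta"),
                         annotations = need_input(cfg, "annotations"))
  hypo <- utils::read.delim(need_input(cfg, "hypo"),
                            stringsAsFactors = FALSE)$probe_id
  mesc <- load_locus_table(need_input(cfg, "mesc"), name = "MESC")
  tet <- utils::read.csv(need_input(cfg, "tet"), stringsAsFactors = FALSE)
  expr <- stats::setNames(tet$expression, tet$sample_id)
  cases <- bm[, bm$samples$group != "normal"]
  res <- tet_anticorrelation(cases, hypo, expr, mesc,
                             alpha = cfg$tet$alpha,
                             method = cfg$tet$method)
  write_tsv(res$correlations, file.path(d, "tet_correlations.tsv"))
  write_tsv(enrichment_row(res$enrichment), file.path(d, "tet_enrichment.tsv"))
  write_run_manifest(d, "tet", cfg,
                     unlist(cfg$inputs[c("beta", "annotations", "hypo",
                                         "mesc", "tet")]))
  invisible(res)
}

#' Run the end-to-end demo pipeline on simulated data
#'
#' Chains simulate -> qc -> diff -> enrich -> instability -> survival ->
#' tet on a simulated invasive-cancer cohort, writing every stage's
#' delimited outputs under \code{outdir}. Fully deterministic given
#' \code{seed}.
#'
#' @param outdir Output directory (stage subfolders are created inside).
#' @param seed Integer seed.
#' @param config Optional pre-merged run config (internal use).
#' @return Invisible list with the main per-stage results.
#' @export
run_demo <- function(outdir = "epistab_demo", seed = 1, config = NULL) {
  cfg <- if (is.null(config)) load_run_config(list(seed = as.integer(seed),
                                                   outdir = outdir))
         else config
  cfg$outdir <- outdir
  sim_d <- file.path(outdir, "simulate")
  stage_simulate(cfg)
  cfg$inputs <- list(beta = file.path(sim_d, "beta.tsv"),
                     annotations = file.path(sim_d, "annotations.csv"),
                     pcgt = file.path(sim_d, "pcgt_loci.tsv"),
                     mesc = file.path(sim_d, "mesc_loci.tsv"),
                     wgbs_counts = file.path(sim_d, "wgbs_counts.tsv"))
  mesc_sites <- stage_derive_loci(cfg)
  bm <- stage_qc(cfg)
  cfg$inputs$beta <- file.path(outdir, "qc", "beta_qc.tsv")
  cfg$inputs$annotations <- file.path(outdir, "qc", "annotations_qc.csv")
  diff_res <- stage_diff(cfg)
  enr <- stage_enrich(cfg)
  idx <- stage_instability(cfg)

  # survival and TET inputs derived from the simulated truth
  scfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
  demi <- idx$mesc_demi
  surv <- simulate_survival(scfg, demi)
  surv$sample_id <- idx$sample_id
  utils::write.csv(surv, file.path(outdir, "simulate", "survival.csv"),
                   row.names = FALSE)
  cfg$inputs$indices <- file.path(outdir, "instability", "epi_indices.tsv")
  cfg$inputs$survival <- file.path(outdir, "simulate", "survival.csv")
  sv <- stage_survival(cfg)

  tet <- simulate_tet(scfg, stats::setNames(demi, idx$sample_id))
  utils::write.csv(data.frame(sample_id = names(tet), expression = tet),
                   file.path(outdir, "simulate", "tet.csv"),
                   row.names = FALSE)
  # the TET analysis runs on the baseline-defined hypomethylated set (normal
  # mean beta above the baseline cut, lower mean in cases)
  cfg$inputs$hypo <- file.path(outdir, "enrich", "hypo_moved.tsv")
  cfg$inputs$tet <- file.path(outdir, "simulate", "tet.csv")
  tt <- stage_tet(cfg)
  invisible(list(mesc_sites = mesc_sites, qc = bm, diff = diff_res,
                 enrich = enr, indices = idx, survival = sv, tet = tt))
}
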