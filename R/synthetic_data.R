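#' Configuration for the synthetic cohort generator
#'
#' Bundles every parameter of the simulator with validation. Defaults
#' emulate a 27k-style cervical/endometrial study design: beta-distributed
#' beta values per locus class, a monotone stage gradient of MESC
#' demethylation (before-dysplasia < dysplasia < invasive cancer <
#' metastasis), chip batch effects on the logit scale, DeMI-linked
#' exponential survival and TET expression anti-correlated with MESC
#' methylation.
#'
#' @param seed Integer seed; mandatory, every simulator output is a
#'   deterministic function of the config.
#' @param n_probes Number of array probes.
#' @param frac_pcgt,frac_mesc Fractions of probes in the PCGT / MESC
#'   classes (disjoint; must sum to <= 1).
#' @param frac_pmd Fraction of probes inside PMDs (independent of class).
#' @param frac_mesc_hemi Fraction of MESC probes hemimethylated (rather
#'   than fully methylated) in normal tissue.
#' @param n_normals Normal samples per cohort.
#' @param n_cases Named integer vector of case counts per stage
#'   (\code{bdy}, \code{dysplasia}, \code{cancer}, \code{metastasis}).
#' @param pcgt_gain_prob Per-stage probability that a susceptible PCGT
#'   probe gains methylation in a case sample.
#' @param mesc_loss_prob Per-stage probability that a susceptible MESC
#'   probe loses methylation; must be non-decreasing across stages.
#' @param stage_dispersion Between-tumour heterogeneity of the alteration
#'   probabilities: each case sample gets its own probability drawn from a
#'   Beta distribution with the stage mean and this precision, taken as
#'   stratified quantiles so the cohort mean sits on the stage value
#'   exactly. \code{Inf} gives every tumour the shared stage probability.
#' @param concentration Beta-distribution precision of per-probe beta
#'   noise (use \code{Inf} for noise-free values).
#' @param n_chips Number of chips (12 samples each, assigned in order).
#' @param chip_shift Total spread of chip batch shifts on the logit scale.
#' @param baseline_hazard,loghr_per_sd,censoring_rate Survival model:
#'   exponential baseline hazard, log hazard ratio per SD of DeMI,
#'   expected censoring fraction.
#' @param tet_slope,tet_noise_sd TET expression model: slope on the
#'   per-sample demethylation burden and Gaussian noise SD.
#' @param n_sites,mean_coverage,high_frac Bisulfite read-count simulator:
#'   number of CpG sites, mean total coverage, fraction of sites drawn
#'   from the highly methylated mixture component.
#' @return Validated list of class \code{sim_config}.
#' @export
sim_config <- function(seed,
                       n_probes = 2000,
                       frac_pcgt = 0.10,
                       frac_mesc = 0.25,
                       frac_pmd = 0.15,
                       frac_mesc_hemi = 0.3,
                       n_normals = 15,
                       n_cases = c(bdy = 75, dysplasia = 18, cancer = 48,
                                   metastasis = 20),
                       pcgt_gain_prob = c(bdy = 0.10, dysplasia = 0.15,
                                          cancer = 0.18, metastasis = 0.18),
                       mesc_loss_prob = c(bdy = 0.05, dysplasia = 0.10,
                                          cancer = 0.20, metastasis = 0.35),
                       stage_dispersion = 6,
                       concentration = 200,
                       n_chips = 2,
                       chip_shift = 0.15,
                       baseline_hazard = 0.1,
                       loghr_per_sd = log(1.8),
                       censoring_rate = 0.3,
                       tet_slope = 1,
                       tet_noise_sd = 0.5,
                       n_sites = 500,
                       mean_coverage = 15,
                       high_frac = 0.5) {
  if (missing(seed)) stop("sim_config: a seed is mandatory")
  seed <- as.integer(seed)
  stages <- c("bdy", "dysplasia", "cancer", "metastasis")
  stopifnot(frac_pcgt >= 0, frac_mesc >= 0, frac_pcgt + frac_mesc <= 1,
            frac_pmd >= 0, frac_pmd <= 1,
            all(pcgt_gain_prob >= 0), all(pcgt_gain_prob <= 1),
            all(mesc_loss_prob >= 0), all(mesc_loss_prob <= 1),
            censoring_rate >= 0, censoring_rate <= 1,
            baseline_hazard > 0, concentration > 0, stage_dispersion > 0,
            n_normals >= 2, all(n_cases >= 1))
  if (is.null(names(n_cases))) names(n_cases) <- stages
  if (is.null(names(pcgt_gain_prob))) names(pcgt_gain_prob) <- stages
  if (is.null(names(mesc_loss_prob))) names(mesc_loss_prob) <- stages
  if (is.unsorted(mesc_loss_prob[stages]))
    stop("mesc_loss_prob must be non-decreasing across stages")
  structure(list(seed = seed, n_probes = n_probes, frac_pcgt = frac_pcgt,
                 frac_mesc = frac_mesc, frac_pmd = frac_pmd,
                 frac_mesc_hemi = frac_mesc_hemi, n_normals = n_normals,
                 n_cases = n_cases, pcgt_gain_prob = pcgt_gain_prob,
                 mesc_loss_prob = mesc_loss_prob,
                 stage_dispersion = stage_dispersion,
                 concentration = concentration, n_chips = n_chips,
                 chip_shift = chip_shift, baseline_hazard = baseline_hazard,
                 loghr_per_sd = loghr_per_sd, censoring_rate = censoring_rate,
                 tet_slope = tet_slope, tet_noise_sd = tet_noise_sd,
                 n_sites = n_sites, mean_coverage = mean_coverage,
                 high_frac = high_frac, stages = stages),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_probes, "probes, seed", x$seed, "\n")
  cat("  mesc_loss_prob:", paste(names(x$mesc_loss_prob),
                                 x$mesc_loss_prob, sep = "=",
                                 collapse = " "), "\n")
  invisible(x)
}

logistic <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

# beta noise around mean m with precision k; k = Inf returns m exactly
rbeta_mean <- function(n, m, k) {
  if (is.infinite(k)) return(rep(m, length.out = n))
  stats::rbeta(n, m * k, (1 - m) * k)
}

#' Simulate an array manifest with locus-class structure
#'
#' Generates probe ids, genomic coordinates, disjoint PCGT/MESC class
#' assignments, a PMD flag realised by genuine BED intervals, and per-probe
#' baseline mean beta: PCGT probes start lowly methylated (~0.08), MESC
#' probes highly (~0.85, with a hemimethylated subset ~0.5, mirroring that
#' most of these loci carry high methylation in normal tissue), remaining
#' probes a low/mid/high mixture.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return List of class \code{sim_manifest}: \code{manifest} (annotated
#'   data.frame), \code{pcgt}, \code{mesc} (\code{locus_set}s), \code{pmd}
#'   (BED data.frame), \code{baseline_mean} (named vector).
#' @export
simulate_manifest <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_probes
  ids <- sprintf("cg%08d", seq_len(n))
  chrom <- sample(paste0("chr", 1:22), n, replace = TRUE)
  pos <- integer(n)
  for (ch in unique(chrom)) {
    k <- sum(chrom == ch)
    pos[chrom == ch] <- sort(sample.int(5e7, k))
  }
  n_pcgt <- round(cfg$frac_pcgt * n)
  n_mesc <- round(cfg$frac_mesc * n)
  cls <- sample(rep(c("pcgt", "mesc", "other"),
                    c(n_pcgt, n_mesc, n - n_pcgt - n_mesc)))
  is_pmd_true <- stats::runif(n) < cfg$frac_pmd

  base <- numeric(n)
  base[cls == "pcgt"] <- 0.03 + 0.1 * stats::rbeta(sum(cls == "pcgt"), 2, 2)
  i_mesc <- which(cls == "mesc")
  hemi <- stats::runif(length(i_mesc)) < cfg$frac_mesc_hemi
  base[i_mesc[!hemi]] <- 0.80 + 0.12 * stats::rbeta(sum(!hemi), 2, 2)
  base[i_mesc[hemi]] <- 0.40 + 0.15 * stats::rbeta(sum(hemi), 2, 2)
  i_other <- which(cls == "other")
  comp <- sample(1:3, length(i_other), replace = TRUE, prob = c(.4, .3, .3))
  base[i_other[comp == 1]] <- 0.03 + 0.1 * stats::rbeta(sum(comp == 1), 2, 2)
  base[i_other[comp == 2]] <- 0.40 + 0.15 * stats::rbeta(sum(comp == 2), 2, 2)
  base[i_other[comp == 3]] <- 0.80 + 0.12 * stats::rbeta(sum(comp == 3), 2, 2)
  names(base) <- ids

  # realise PMD flags as intervals tight around each flagged probe so no
  # unflagged probe is swallowed
  pmd_rows <- lapply(which(is_pmd_true), function(i) {
    same <- which(chrom == chrom[i])
    gaps <- abs(pos[same] - pos[i])
    nn <- min(gaps[gaps > 0], Inf)
    hw <- max(1L, min(500L, as.integer(floor(nn / 2)) - 1L))
    data.frame(chrom = chrom[i], start = pos[i] - hw, end = pos[i] + hw,
               stringsAsFactors = FALSE)
  })
  pmd <- if (length(pmd_rows)) do.call(rbind, pmd_rows)
         else data.frame(chrom = character(0), start = integer(0),
                         end = integer(0))

  manifest <- data.frame(probe_id = ids, gene = paste0("GENE", seq_len(n)),
                         chromosome = chrom, position = pos,
                         stringsAsFactors = FALSE)
  pcgt <- locus_set("PCGT", ids[cls == "pcgt"], "simulated")
  mesc <- locus_set("MESC", ids[cls == "mesc"], "simulated")
  manifest <- suppressMessages(
    annotate_manifest(manifest, pcgt = pcgt, mesc = mesc,
                      pmd = if (nrow(pmd)) pmd else NULL))
  structure(list(manifest = manifest, pcgt = pcgt, mesc = mesc, pmd = pmd,
                 baseline_mean = base),
            class = "sim_manifest")
}

#' Simulate a staged case-control methylation cohort
#'
#' Draws normal and case beta values per probe from Beta distributions
#' centred on the class baselines, plants stage-dependent methylation
#' changes (PCGT gains from the unmethylated state, MESC losses from the
#' hemi- and fully methylated states) that cross a state boundary by more
#' than the transition buffer, and adds chip batch shifts on the logit
#' scale. The planted flips are emitted as a first-class truth table so
#' recovery tests never re-infer ground truth.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param stage One of \code{"bdy"}, \code{"dysplasia"}, \code{"cancer"},
#'   \code{"metastasis"}.
#' @param sim_man Optional pre-computed \code{\link{simulate_manifest}}
#'   result (so several stages share one manifest).
#' @return A \code{\link{beta_matrix}} of normals followed by cases, with
#'   annotations (group, age, chip, bs_intensity) and attributes
#'   \code{truth} (data.frame probe_id, sample_id, transition) and
#'   \code{sim_man}.
#' @export
simulate_cohort <- function(cfg, stage = "cancer", sim_man = NULL) {
  stage <- match.arg(stage, cfg$stages)
  if (is.null(sim_man)) sim_man <- simulate_manifest(cfg)
  set.seed(cfg$seed + 7L * match(stage, cfg$stages))
  base <- sim_man$baseline_mean
  n <- length(base)
  n_cases <- cfg$n_cases[[stage]]
  n_tot <- cfg$n_normals + n_cases
  if (n_tot < 1) stop("zero samples requested")
  ids <- c(sprintf("N%03d", seq_len(cfg$n_normals)),
           sprintf("T%03d", seq_len(n_cases)))
  grp <- c(rep("normal", cfg$n_normals), rep(stage, n_cases))

  is_pcgt <- sim_man$manifest$is_pcgt
  is_mesc <- sim_man$manifest$is_mesc
  # susceptible probes: PCGT starting unmethylated; MESC starting hemi/full
  sus_gain <- is_pcgt & base < 0.25
  sus_loss <- is_mesc & base >= 0.25

  # per-tumour alteration propensities: stratified Beta quantiles around the
  # stage probability, permuted, so the cohort mean equals the stage value
  draw_props <- function(q) {
    if (!is.finite(cfg$stage_dispersion) || q <= 0 || q >= 1)
      return(rep(q, n_cases))
    grid <- stats::qbeta((seq_len(n_cases) - 0.5) / n_cases,
                         q * cfg$stage_dispersion,
                         (1 - q) * cfg$stage_dispersion)
    sample(grid)
  }
  q_gain_s <- draw_props(cfg$pcgt_gain_prob[[stage]])
  q_loss_s <- draw_props(cfg$mesc_loss_prob[[stage]])

  vals <- matrix(NA_real_, n, n_tot, dimnames = list(names(base), ids))
  truth <- list()
  for (j in seq_len(n_tot)) {
    m <- base
    if (grp[j] != "normal") {
      jc <- j - cfg$n_normals
      flip_gain <- sus_gain & stats::runif(n) < q_gain_s[jc]
      flip_loss <- sus_loss & stats::runif(n) < q_loss_s[jc]
      m[flip_gain] <- 0.55          # state 0 -> 1, shift >> buffer
      m[flip_loss] <- 0.08          # state 1/2 -> 0, shift >> buffer
      if (any(flip_gain | flip_loss)) {
        tr <- character(n)
        tr[flip_gain] <- "0->1/2"
        tr[flip_loss & base > 0.7] <- "2->0/1"
        tr[flip_loss & base <= 0.7] <- "1->0"
        k <- which(flip_gain | flip_loss)
        truth[[length(truth) + 1L]] <-
          data.frame(probe_id = names(base)[k], sample_id = ids[j],
                     transition = tr[k], stringsAsFactors = FALSE)
      }
    }
    vals[, j] <- rbeta_mean(n, m, cfg$concentration)
  }

  chip <- paste0("chip", ((seq_len(n_tot) - 1) %/% 12) %% cfg$n_chips + 1)
  if (cfg$chip_shift > 0 && cfg$n_chips > 1) {
    shifts <- seq(-cfg$chip_shift / 2, cfg$chip_shift / 2,
                  length.out = cfg$n_chips)
    names(shifts) <- paste0("chip", seq_len(cfg$n_chips))
    eps <- 1e-6
    for (j in seq_len(n_tot)) {
      v <- pmin(pmax(vals[, j], eps), 1 - eps)
      vals[, j] <- logistic(logit(v) + shifts[[chip[j]]])
    }
  }

  ann <- data.frame(sample_id = ids, group = grp,
                    age = round(stats::runif(n_tot, 35, 70)),
                    chip = chip,
                    bs_intensity = round(stats::runif(n_tot, 4200, 9000)),
                    stringsAsFactors = FALSE)
  bm <- beta_matrix(vals, ann)
  attr(bm, "truth") <- if (length(truth)) do.call(rbind, truth)
    else data.frame(probe_id = character(0), sample_id = character(0),
                    transition = character(0))
  attr(bm, "sim_man") <- sim_man
  bm
}

#' Simulate survival outcomes linked to an instability index
#'
#' Exponential event times with log hazard linear in the standardized
#' index, and independent exponential censoring tuned to the configured
#' censoring fraction. With \code{censoring_rate = 1} every subject is
#' censored.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param demi Numeric instability index per sample (e.g. DeMI).
#' @return data.frame with \code{time} and \code{event} (0/1).
#' @export
simulate_survival <- function(cfg, demi) {
  set.seed(cfg$seed + 101L)
  n <- length(demi)
  z <- if (stats::sd(demi, na.rm = TRUE) > 0) as.numeric(scale(demi))
       else rep(0, n)
  z[is.na(z)] <- 0
  rate <- cfg$baseline_hazard * exp(cfg$loghr_per_sd * z)
  t_ev <- stats::rexp(n, rate)
  if (cfg$censoring_rate >= 1)
    return(data.frame(time = t_ev, event = 0L))
  if (cfg$censoring_rate <= 0)
    return(data.frame(time = t_ev, event = 1L))
  rate_c <- cfg$baseline_hazard * cfg$censoring_rate /
    (1 - cfg$censoring_rate)
  t_c <- stats::rexp(n, rate_c)
  data.frame(time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c))
}

#' Simulate strand-resolved bisulfite read counts
#'
#' Per-site true methylation levels are drawn from a bimodal mixture
#' (a highly methylated component near 0.9 and a diffuse component), strand
#' coverages from a Poisson, and C reads binomially. The true levels are
#' emitted so classifier operating characteristics can be measured.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param coverage Optional fixed total coverage per site (overrides the
#'   Poisson draw; split evenly across strands).
#' @return List: \code{counts} (data.frame chrom, pos, fwd_c, fwd_t,
#'   rev_c, rev_t, site_id), \code{truth} (site_id, true_level,
#'   true_mesc = level > 0.8).
#' @export
simulate_wgbs_counts <- function(cfg, coverage = NULL) {
  set.seed(cfg$seed + 202L)
  n <- cfg$n_sites
  high <- stats::runif(n) < cfg$high_frac
  lvl <- ifelse(high, stats::rbeta(n, 36, 4), stats::rbeta(n, 2, 2))
  if (is.null(coverage)) {
    fwd_n <- stats::rpois(n, cfg$mean_coverage / 2)
    rev_n <- stats::rpois(n, cfg$mean_coverage / 2)
  } else {
    fwd_n <- rep(ceiling(coverage / 2), n)
    rev_n <- rep(floor(coverage / 2), n)
  }
  fwd_c <- stats::rbinom(n, fwd_n, lvl)
  rev_c <- stats::rbinom(n, rev_n, lvl)
  pos <- sort(sample.int(1e7, n))
  counts <- data.frame(chrom = "chr1", pos = pos,
                       fwd_c = fwd_c, fwd_t = fwd_n - fwd_c,
                       rev_c = rev_c, rev_t = rev_n - rev_c,
                       stringsAsFactors = FALSE)
  counts$site_id <- paste0(counts$chrom, ":", counts$pos)
  list(counts = counts,
       truth = data.frame(site_id = counts$site_id, true_level = lvl,
                          true_mesc = lvl > 0.8, stringsAsFactors = FALSE))
}

#' Simulate TET expression anti-correlated with demethylation
#'
#' Expression is a linear function of each sample's demethylation burden
#' plus Gaussian noise, so beta values at demethylated MESC probes
#' anti-correlate with expression.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param burden Numeric per-sample demethylation burden (e.g. the
#'   fraction of planted demethylation flips, or DeMI).
#' @return Named numeric vector of expression values.
#' @export
simulate_tet <- function(cfg, burden) {
  stopifnot(is.finite(cfg$tet_slope))
  set.seed(cfg$seed + 303L)
  b <- if (stats::sd(burden, na.rm = TRUE) > 0) as.numeric(scale(burden))
       else burden
  expr <- cfg$tet_slope * b + stats::rnorm(length(burden), 0, cfg$tet_noise_sd)
  names(expr) <- names(burden)
  expr
}
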