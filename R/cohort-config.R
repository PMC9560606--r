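# Cohort configuration and the packaged generator spectra.

ORGAN_LABELS <- c("brain", "blood", "heart", "liver", "other")
STAGE_LABELS <- c("early", "late", "tumor")

#' Packaged trinucleotide spectra used by the synthetic generator
#'
#' Four 96-channel spectra with clock-like shapes: `cpg_clock` (C>T at CpG
#' sites, SBS1-like), `flat_clock` (broad low-intensity profile dominated by
#' C>T and T>C, SBS5/SBS40-like), `tcn` (T>C-rich) and `oxid` (C>A-rich,
#' used for the tumor mixture). These are generator parameters, not claims
#' about real mutational processes; columns are normalized to sum to 1.
#'
#' @return 96 x 4 numeric matrix, rows named by [sbs_channels()].
#' @export
generator_spectra <- function() {
  ch <- sbs_channels()
  info <- parse_channel(ch)
  sub <- paste0(info$ref, ">", info$alt)

  cpg <- ifelse(sub == "C>T" & info$down == "G", 1, 0.002)
  flat <- ifelse(sub == "C>T", 0.6, ifelse(sub == "T>C", 0.45, 0.12))
  tcn <- ifelse(sub == "T>C", 1, 0.03)
  oxid <- ifelse(sub == "C>A", 1, 0.05)

  m <- cbind(cpg_clock = cpg, flat_clock = flat, tcn = tcn, oxid = oxid)
  rownames(m) <- ch
  sweep(m, 2, colSums(m), "/")
}

# Default per-stage mixture weights over generator_spectra() columns.
default_signature_mix <- function() {
  rbind(
    early = c(cpg_clock = 0.15, flat_clock = 0.45, tcn = 0.40, oxid = 0.00),
    late  = c(cpg_clock = 0.35, flat_clock = 0.50, tcn = 0.13, oxid = 0.02),
    tumor = c(cpg_clock = 0.20, flat_clock = 0.30, tcn = 0.10, oxid = 0.40)
  )
}

#' Configuration for the synthetic multi-tissue cohort generator
#'
#' Defaults restate the cohort the generator emulates: ~500x depth, early
#' clones shared across organs (VAF mean 6.17%, sd 3.32%), organ-restricted
#' late clones (VAF mean 1.50%, sd 3.29%; blood burden rising linearly with
#' age), tumor clones at high VAF, and an oxoG-like artifact load. VAFs are
#' drawn from normals with these parameters truncated to (0, 1]; see the
#' methods vignette for the effect of truncation on the realized means.
#'
#' @param n_individuals number of individuals.
#' @param organs_per_individual organ labels sampled by every individual
#'   (one tissue per organ; a tumor specimen is added separately).
#' @param age_range numeric length-2, years; ages drawn uniformly.
#' @param depth_mean mean sequencing depth (reads) per site.
#' @param seq_error_rate per-base substitution error probability.
#' @param early_rate expected early (pre-gastrulation, multi-organ)
#'   mutations per individual.
#' @param late_rate_by_organ named vector of expected late mutations for
#'   non-blood organs.
#' @param blood_intercept,blood_slope blood late-mutation Poisson mean is
#'   `blood_intercept + blood_slope * age` (slope > 0: clonal
#'   hematopoiesis-like age dependence).
#' @param tumor_fraction fraction of individuals carrying a tumor specimen.
#' @param tumor_rate expected tumor mutations per tumor specimen.
#' @param vaf_params list with per-stage `c(mean, sd)` of the truncated
#'   normal clone-VAF distributions.
#' @param signature_mix 3 x 4 matrix of per-stage weights over
#'   [generator_spectra()] columns; rows early/late/tumor, rows sum to 1.
#' @param oxog_rate fraction of noise sites converted into oxoG-like
#'   orientation-biased artifacts.
#' @param n_noise_sites non-mutant sites with error-only reads, per
#'   individual (gives the caller a null to control FDR against).
#' @param n_blacklist_artifacts artifact sites planted inside blacklist
#'   intervals per individual (true positives for the region filters).
#' @param fraction_blacklisted total fraction of the genome covered by the
#'   six blacklist tracks together.
#' @param genome_size synthetic contig length (bp).
#' @param n_genes number of synthetic single-exon coding genes.
#' @param seed integer RNG seed; every downstream draw derives from it.
#' @return validated list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_individuals = 5, seed = 1)
#' cfg$depth_mean
cohort_config <- function(n_individuals = 50,
                          organs_per_individual = c("brain", "blood", "liver"),
                          age_range = c(0, 90),
                          depth_mean = 500,
                          seq_error_rate = 1e-3,
                          early_rate = 0.54,
                          late_rate_by_organ = c(brain = 0.67, heart = 1.12,
                                                 liver = 1.12, other = 1.12),
                          blood_intercept = 2.0,
                          blood_slope = 0.16,
                          tumor_fraction = 0.1,
                          tumor_rate = 8.12,
                          vaf_params = list(
                            early = c(mean = 0.0617, sd = 0.0332),
                            late = c(mean = 0.0150, sd = 0.0329),
                            tumor = c(mean = 0.15, sd = 0.05)),
                          signature_mix = default_signature_mix(),
                          oxog_rate = 0.05,
                          n_noise_sites = 50,
                          n_blacklist_artifacts = 2,
                          fraction_blacklisted = 0.05,
                          genome_size = 5e5,
                          n_genes = 50,
                          seed = 1L) {
  if (length(organs_per_individual) == 0) {
    stop("configuration error: at least one organ per individual is required")
  }
  if (!all(organs_per_individual %in% ORGAN_LABELS)) {
    stop("unknown organ label(s): ",
         paste(setdiff(organs_per_individual, ORGAN_LABELS), collapse = ", "))
  }
  rates <- c(early_rate, late_rate_by_organ, blood_intercept, blood_slope,
             tumor_rate, oxog_rate, fraction_blacklisted)
  if (any(rates < 0)) stop("all rates must be >= 0")
  if (seq_error_rate <= 0 || seq_error_rate >= 1) {
    stop("seq_error_rate must be in (0, 1)")
  }
  if (tumor_fraction < 0 || tumor_fraction > 1) {
    stop("tumor_fraction must be in [0, 1]")
  }
  stopifnot(is.matrix(signature_mix),
            nrow(signature_mix) == 3,
            all(rownames(signature_mix) == STAGE_LABELS))
  if (any(abs(rowSums(signature_mix) - 1) > 1e-8)) {
    stop("signature_mix rows must each sum to 1")
  }
  for (st in names(vaf_params)) {
    p <- vaf_params[[st]]
    if (p[["mean"]] <= 0 || p[["mean"]] > 1 || p[["sd"]] <= 0) {
      stop("invalid vaf_params for stage ", st)
    }
  }
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    organs_per_individual = organs_per_individual,
    age_range = age_range,
    depth_mean = depth_mean,
    seq_error_rate = seq_error_rate,
    early_rate = early_rate,
    late_rate_by_organ = late_rate_by_organ,
    blood_intercept = blood_intercept,
    blood_slope = blood_slope,
    tumor_fraction = tumor_fraction,
    tumor_rate = tumor_rate,
    vaf_params = vaf_params,
    signature_mix = signature_mix,
    oxog_rate = oxog_rate,
    n_noise_sites = as.integer(n_noise_sites),
    n_blacklist_artifacts = as.integer(n_blacklist_artifacts),
    fraction_blacklisted = fraction_blacklisted,
    genome_size = as.integer(genome_size),
    n_genes = as.integer(n_genes),
    contig = "chr1",
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  cfg
}

#' Mean of a normal truncated to (0, Inf)
#'
#' The generator draws clone VAFs from normals truncated at zero, so the
#' realized mean exceeds the nominal `mean` parameter; this analytic form is
#' what planted-parameter recovery converges to.
#'
#' @param mean,sd untruncated normal parameters.
#' @return the truncated-normal mean.
#' @export
truncnorm_mean <- function(mean, sd) {
  a <- -mean / sd
  mean + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

# Draw n values from Normal(mean, sd) truncated to (lo, hi] by rejection.
rtruncnorm <- function(n, mean, sd, lo = 0, hi = 1) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x > lo & x <= hi])
  }
  out[seq_len(n)]
}
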