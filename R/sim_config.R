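#' Simulation configuration for synthetic multi-region tumor cohorts
#'
#' Bundles all knobs of the synthetic-cohort generator. Defaults emulate a
#' deep-amplicon multi-region study of a single patient: a small clone tree
#' rooted in normal tissue, region-specific clonal mixing, arm-level copy
#' number events carried by the trunk, and binomially sampled read counts.
#'
#' @param n_clones Number of tumor clones (>= 1). The first clone is truncal:
#'   it is the unique tumor child of the normal root and carries the
#'   oncohistone-like driver plus obligate partner when a driver template is
#'   used.
#' @param n_regions Number of spatially distinct samples (>= 1).
#' @param mutations_per_clone Anonymous passenger mutations simulated per
#'   clone, in addition to any template drivers.
#' @param mean_depth Mean sequencing depth for the somatic variant read
#'   counts; 4000 emulates deep amplicon sequencing, 70 a whole exome.
#' @param wes_depth Mean depth used for germline het-site B-allele counts and
#'   arm coverage (the copy-number input is exome-like even when variants are
#'   re-sequenced deeply).
#' @param purity_range Length-2 numeric in \[0,1\], low <= high; per-region
#'   tumor purity is drawn uniformly from this interval.
#' @param n_arms Number of chromosome arms in the synthetic genome; arms are
#'   labelled `"arm01"` ... and mutations are placed on them uniformly.
#' @param cnv_rate Expected (Poisson) number of arm-level CNV events drawn per
#'   clone. Events are assigned to the truncal clone unless
#'   `cnv_truncal_only = FALSE`.
#' @param het_sites_per_arm Germline heterozygous sites simulated per arm.
#' @param dropout_prob Per region, probability that each non-truncal clone is
#'   absent (mixing proportion zeroed), creating spatial heterogeneity.
#' @param dirichlet_alpha Concentration of the symmetric Dirichlet used to
#'   split purity across clones within a region.
#' @param mutant_homolog_duplicated If `TRUE` (default) an arm duplication
#'   copies the mutation-bearing homolog (2 of 3 copies mutant), which is the
#'   configuration the duplication read-count correction inverts exactly.
#'   `FALSE` duplicates the wild-type homolog (1 of 3) for robustness studies.
#' @param mutant_allele_retained If `TRUE` (default) deletions and
#'   copy-neutral LOH retain the mutant haplotype; `FALSE` loses it.
#' @param cnv_truncal_only If `TRUE` (default) all CNV events are carried by
#'   the truncal clone (arm-scale events are modelled as early); `FALSE`
#'   leaves each event on the clone that drew it.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration including this seed.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_clones = 3, n_regions = 4, seed = 7)
#' @export
sim_config <- function(n_clones = 4, n_regions = 6, mutations_per_clone = 50,
                       mean_depth = 4000, wes_depth = 70,
                       purity_range = c(0.7, 0.9), n_arms = 10,
                       cnv_rate = 0.5, het_sites_per_arm = 100,
                       dropout_prob = 0.2, dirichlet_alpha = 1,
                       mutant_homolog_duplicated = TRUE,
                       mutant_allele_retained = TRUE,
                       cnv_truncal_only = TRUE, seed = 1) {
  cfg <- list(n_clones = as.integer(n_clones), n_regions = as.integer(n_regions),
              mutations_per_clone = as.integer(mutations_per_clone),
              mean_depth = mean_depth, wes_depth = wes_depth,
              purity_range = as.numeric(purity_range), n_arms = as.integer(n_arms),
              cnv_rate = cnv_rate, het_sites_per_arm = as.integer(het_sites_per_arm),
              dropout_prob = dropout_prob, dirichlet_alpha = dirichlet_alpha,
              mutant_homolog_duplicated = isTRUE(mutant_homolog_duplicated),
              mutant_allele_retained = isTRUE(mutant_allele_retained),
              cnv_truncal_only = isTRUE(cnv_truncal_only), seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (is.na(cfg$n_clones) || cfg$n_clones < 1L)
    stop("invalid config: n_clones must be >= 1", call. = FALSE)
  if (is.na(cfg$n_regions) || cfg$n_regions < 1L)
    stop("invalid config: n_regions must be >= 1", call. = FALSE)
  if (!is.numeric(cfg$mean_depth) || cfg$mean_depth <= 0)
    stop("invalid config: mean_depth must be > 0", call. = FALSE)
  if (!is.numeric(cfg$wes_depth) || cfg$wes_depth <= 0)
    stop("invalid config: wes_depth must be > 0", call. = FALSE)
  pr <- cfg$purity_range
  if (length(pr) != 2L || any(is.na(pr)) || pr[1] > pr[2] || pr[1] < 0 || pr[2] > 1)
    stop("invalid config: purity_range must be (low, high) within [0,1]", call. = FALSE)
  if (cfg$mutations_per_clone < 0L) stop("invalid config: mutations_per_clone < 0", call. = FALSE)
  if (cfg$n_arms < 1L) stop("invalid config: n_arms must be >= 1", call. = FALSE)
  if (cfg$cnv_rate < 0) stop("invalid config: cnv_rate must be >= 0", call. = FALSE)
  if (cfg$dropout_prob < 0 || cfg$dropout_prob >= 1)
    stop("invalid config: dropout_prob must be in [0,1)", call. = FALSE)
  invisible(cfg)
}
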