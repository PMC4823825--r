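# Arm-level CNV calling from germline-het B-allele imbalance plus tumor/normal
# normalized coverage. The imbalance test is depth-aware: the null
# distribution of the mean folded BAF deviation is obtained by Monte-Carlo
# simulation of balanced binomial sites at the observed depths, so the same
# thresholds work at 70x and at much higher depth.

#' Default thresholds for arm classification
#'
#' @param alpha Significance level for the BAF imbalance p-value (default
#'   0.01).
#' @param dev_min Minimum mean folded deviation |BAF - 0.5| to call imbalance
#'   (default 0.05), a floor against significant-but-tiny shifts at extreme
#'   depth.
#' @param t_cov Half-width of the log2 coverage-ratio band treated as "no
#'   change" (default 0.15).
#' @param min_depth,min_sites Minimum per-site depth and minimum number of
#'   evaluable sites for an arm to be testable.
#' @param n_null Monte-Carlo replicates for the null distribution.
#' @return Named list.
#' @export
cnv_thresholds <- function(alpha = 0.01, dev_min = 0.05, t_cov = 0.15,
                           min_depth = 10L, min_sites = 10L, n_null = 10000L) {
  list(alpha = alpha, dev_min = dev_min, t_cov = t_cov,
       min_depth = as.integer(min_depth), min_sites = as.integer(min_sites),
       n_null = as.integer(n_null))
}

#' Mean folded BAF deviation and its Monte-Carlo p-value
#'
#' Per-site BAF is `b/(a+b)`, folded as `|BAF - 0.5|`; the statistic is the
#' mean folded deviation over evaluable sites. Its null distribution under a
#' balanced diploid arm is simulated by drawing Binomial(depth_i, 0.5) counts
#' at the same depths; the p-value uses the add-one Monte-Carlo estimator.
#'
#' @param a_count,b_count Integer allele counts per het site.
#' @param thresholds See [cnv_thresholds()].
#' @param seed Seed for the null simulation.
#' @return List with `evaluable`, `n_sites`, `mean_folded_baf_dev`,
#'   `baf_p_value`.
#' @export
folded_baf_deviation <- function(a_count, b_count, thresholds = cnv_thresholds(),
                                 seed = NULL) {
  stop_scalar_count(a_count, "a_count")
  stop_scalar_count(b_count, "b_count")
  depth <- a_count + b_count
  keep <- depth >= thresholds$min_depth
  a <- a_count[keep]; b <- b_count[keep]; depth <- depth[keep]
  n <- length(depth)
  if (n < thresholds$min_sites)
    return(list(evaluable = FALSE, n_sites = n,
                mean_folded_baf_dev = NA_real_, baf_p_value = NA_real_))
  dev <- mean(abs(b / depth - 0.5))
  B <- thresholds$n_null
  null_mean <- with_seed(seed, {
    x <- stats::rbinom(n * B, rep(depth, times = B), 0.5)
    .colMeans(abs(x / rep(depth, times = B) - 0.5), n, B)
  })
  p <- (1 + sum(null_mean >= dev)) / (B + 1)
  list(evaluable = TRUE, n_sites = n, mean_folded_baf_dev = dev, baf_p_value = p)
}

#' Median-centered log2 tumor/normal coverage ratio per arm
#'
#' `log2(tumor_mean / normal_mean)` per arm, minus the genome-wide median of
#' that quantity, so that (the majority of) neutral arms sit at 0.
#'
#' @param tumor_means,normal_means Positive per-arm mean coverages, same
#'   length, optionally named by arm.
#' @return Numeric vector of centered log2 ratios.
#' @export
normalized_arm_coverage <- function(tumor_means, normal_means) {
  if (length(tumor_means) != length(normal_means))
    stop("tumor and normal arm vectors differ in length", call. = FALSE)
  if (any(tumor_means <= 0) || any(normal_means <= 0))
    stop("arm mean coverages must be positive", call. = FALSE)
  r <- log2(tumor_means / normal_means)
  r - stats::median(r)
}

#' Classify one arm from its imbalance and coverage statistics
#'
#' Decision table: imbalance is significant when the BAF p-value is below
#' `alpha` and the mean folded deviation is at least `dev_min`. Significant
#' imbalance with increased coverage is a duplication, with decreased
#' coverage a deletion, with unchanged coverage copy-neutral LOH; without
#' significant imbalance the arm is neutral.
#'
#' @param stats List/row with `mean_folded_baf_dev`, `baf_p_value`,
#'   `log2_coverage_ratio` (and optionally `evaluable`).
#' @param thresholds See [cnv_thresholds()].
#' @return Character scalar: `"duplication"`, `"deletion"`, `"cn_loh"`,
#'   `"neutral"`, or `"unevaluable"`.
#' @export
classify_arm <- function(stats, thresholds = cnv_thresholds()) {
  if (isFALSE(stats$evaluable) || is.na(stats$mean_folded_baf_dev)) return("unevaluable")
  significant <- stats$baf_p_value < thresholds$alpha &&
    stats$mean_folded_baf_dev >= thresholds$dev_min
  if (!significant) return("neutral")
  r <- stats$log2_coverage_ratio
  if (is.na(r)) return("cn_loh")  # imbalance without coverage: cannot direct
  if (r > thresholds$t_cov) "duplication"
  else if (r < -thresholds$t_cov) "deletion"
  else "cn_loh"
}

#' Call arm-level CNV events for every sample of a cohort
#'
#' @param het_sites `data.frame` with `sample_id, arm, a_count, b_count`
#'   (e.g. the het-site TSV written by [write_cohort()]).
#' @param arm_coverage `data.frame` with `sample_id, arm, tumor_mean,
#'   normal_mean`.
#' @param thresholds See [cnv_thresholds()].
#' @param seed Seed for the Monte-Carlo nulls.
#' @return `data.frame` with one row per (sample, arm): `sample_id, arm,
#'   event, n_sites, mean_folded_baf_dev, baf_p_value, log2_coverage_ratio`.
#' @export
call_cnv_profile <- function(het_sites, arm_coverage,
                             thresholds = cnv_thresholds(), seed = 1) {
  samples <- unique(het_sites$sample_id)
  out <- list()
  for (s in samples) {
    hs <- het_sites[het_sites$sample_id == s, ]
    cv <- arm_coverage[arm_coverage$sample_id == s, ]
    arms <- unique(hs$arm)
    if (!setequal(arms, unique(cv$arm)))
      stop("arm mismatch between het-site and coverage inputs for sample ", s,
           call. = FALSE)
    cv <- cv[match(arms, cv$arm), ]
    ratios <- normalized_arm_coverage(cv$tumor_mean, cv$normal_mean)
    for (i in seq_along(arms)) {
      a <- arms[i]
      site <- hs[hs$arm == a, ]
      fb <- folded_baf_deviation(site$a_count, site$b_count, thresholds,
                                 seed = seed + i)
      st <- list(evaluable = fb$evaluable,
                 mean_folded_baf_dev = fb$mean_folded_baf_dev,
                 baf_p_value = fb$baf_p_value,
                 log2_coverage_ratio = ratios[i])
      out[[length(out) + 1L]] <- data.frame(
        sample_id = s, arm = a, event = classify_arm(st, thresholds),
        n_sites = fb$n_sites, mean_folded_baf_dev = fb$mean_folded_baf_dev,
        baf_p_value = fb$baf_p_value, log2_coverage_ratio = ratios[i],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write arm calls as a BED-like TSV
#'
#' One row per (sample, arm) with 1-based inclusive arm-span placeholders
#' (arms are configuration labels here, not genome coordinates).
#'
#' @param calls Output of [call_cnv_profile()].
#' @param path Output path.
#' @export
write_cnv_calls <- function(calls, path) {
  bed <- data.frame(chrom = sub("arm", "c", calls$arm), start = 1L,
                    end = 1000000L, calls, stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate one arm's het-site counts and coverage at a given event
#'
#' Power-study helper: an arm carrying `event` at aggregate clonal fraction
#' `clonal_fraction` (0 = null arm), with `n_sites` het sites at Poisson
#' depth around `mean_depth` scaled by the mean copy number. Which homolog
#' carries the event is randomized per site.
#'
#' @param event `"neutral"`, `"duplication"`, `"deletion"`, or `"cn_loh"`.
#' @param clonal_fraction Fraction of cells carrying the event, in \[0,1\].
#' @param n_sites Number of het sites.
#' @param mean_depth Mean exome depth.
#' @param seed Integer seed.
#' @return List with `a_count`, `b_count`, `tumor_mean`, `normal_mean`.
#' @export
simulate_arm_baf <- function(event = c("neutral", "duplication", "deletion", "cn_loh"),
                             clonal_fraction = 0, n_sites = 100, mean_depth = 70,
                             seed = NULL) {
  event <- match.arg(event)
  f <- clonal_fraction
  stopifnot(f >= 0, f <= 1)
  if (event == "neutral" || f == 0) {
    baf_hit <- 0.5; cn <- 2
  } else if (event == "duplication") {
    baf_hit <- (1 + f) / (2 + f); cn <- 2 + f
  } else if (event == "deletion") {
    baf_hit <- (1 - f) / (2 - f); cn <- 2 - f
  } else {
    baf_hit <- (1 + f) / 2; cn <- 2
  }
  with_seed(seed, {
    depth <- stats::rpois(n_sites, mean_depth * cn / 2)
    eb <- ifelse(stats::runif(n_sites) < 0.5, baf_hit, 1 - baf_hit)
    b <- stats::rbinom(n_sites, depth, eb)
    list(a_count = depth - b, b_count = b, tumor_mean = mean(depth),
         normal_mean = mean(stats::rpois(n_sites, mean_depth)))
  })
}
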