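# Droplet digital PCR quantification. A reaction is partitioned into
# thousands of droplets; target concentration follows from the fraction of
# positive droplets by Poisson statistics: with occupancy lambda per droplet,
# P(negative) = exp(-lambda), so lambda = -ln(1 - positive/total).

#' Poisson occupancy from droplet counts
#'
#' @param positive Positive droplet count(s), `0 <= positive < total`.
#' @param total Total droplet count(s), > 0.
#' @return Mean target molecules per droplet, `-ln(1 - positive/total)`.
#' @examples
#' poisson_lambda(0, 15000)              # 0
#' poisson_lambda(7500, 15000)           # ln 2
#' @export
poisson_lambda <- function(positive, total) {
  stop_scalar_count(positive, "positive")
  stop_scalar_count(total, "total")
  if (any(total <= 0)) stop("total droplet count must be positive", call. = FALSE)
  if (any(positive > total)) stop("invalid input: positive > total", call. = FALSE)
  if (any(positive == total))
    stop("saturated assay: every droplet positive, concentration unbounded", call. = FALSE)
  -log(1 - positive / total)
}

#' Target concentration in copies per microliter
#'
#' @inheritParams poisson_lambda
#' @param droplet_volume Droplet volume in microliters. The default 0.00085
#'   (0.85 nl) is a commonly published droplet volume, supplied as an
#'   explicit assumption rather than an instrument constant.
#' @return Copies per microliter, `lambda / droplet_volume`.
#' @export
concentration <- function(positive, total, droplet_volume = 0.00085) {
  if (any(droplet_volume <= 0)) stop("droplet_volume must be positive", call. = FALSE)
  poisson_lambda(positive, total) / droplet_volume
}

#' Mutant fraction of total gene copies, with a delta-method interval
#'
#' The mutant fraction is `100 * lambda_mut / (lambda_mut + lambda_wt)`
#' (droplet volume cancels). The confidence interval propagates the
#' per-channel sampling variance of the Poisson occupancy estimate,
#' `var(lambda_hat) = p / ((1 - p) N)` with `p` the positive fraction, by the
#' delta method.
#'
#' @param positive_mut,total_mut Mutant-channel droplet counts.
#' @param positive_wt,total_wt Wild-type-channel droplet counts.
#' @param conf Confidence level (default 0.95).
#' @return List: `fraction_pct`, `ci_lower_pct`, `ci_upper_pct`,
#'   `lambda_mut`, `lambda_wt`.
#' @export
mutant_fraction <- function(positive_mut, total_mut, positive_wt, total_wt,
                            conf = 0.95) {
  lm <- poisson_lambda(positive_mut, total_mut)
  lw <- poisson_lambda(positive_wt, total_wt)
  if (lm + lw <= 0) stop("undefined fraction: both channels empty", call. = FALSE)
  f <- lm / (lm + lw)
  pm <- positive_mut / total_mut
  pw <- positive_wt / total_wt
  var_lm <- pm / ((1 - pm) * total_mut)
  var_lw <- pw / ((1 - pw) * total_wt)
  s2 <- (lw^2 * var_lm + lm^2 * var_lw) / (lm + lw)^4
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(fraction_pct = 100 * f,
       ci_lower_pct = 100 * max(0, f - z * sqrt(s2)),
       ci_upper_pct = 100 * min(1, f + z * sqrt(s2)),
       lambda_mut = lm, lambda_wt = lw)
}

#' Simulate one droplet assay at known occupancy
#'
#' Positive droplets are Binomial(`n_droplets`, `1 - exp(-lambda)`).
#'
#' @param lambda True molecules per droplet.
#' @param n_droplets Droplets in the partition.
#' @param seed Integer seed (NULL = current stream).
#' @return List with `positive`, `total`.
#' @export
simulate_droplet_assay <- function(lambda, n_droplets = 15000, seed = NULL) {
  stopifnot(lambda >= 0, n_droplets > 0)
  with_seed(seed, list(positive = stats::rbinom(1, n_droplets, 1 - exp(-lambda)),
                       total = as.integer(n_droplets)))
}

#' Quantify a table of droplet assays
#'
#' @param assays `data.frame` with columns `sample`, `channel`
#'   (`mutant`/`wildtype`), `positive`, `total`.
#' @param droplet_volume Droplet volume in microliters.
#' @param conf Confidence level for the mutant-fraction interval.
#' @return `data.frame`: one row per sample with per-channel lambda and
#'   copies/ul plus `mutant_pct` and its interval.
#' @export
ddpcr_quantify <- function(assays, droplet_volume = 0.00085, conf = 0.95) {
  out <- list()
  for (s in unique(assays$sample)) {
    a <- assays[assays$sample == s, ]
    mu <- a[a$channel == "mutant", ][1, ]
    wt <- a[a$channel == "wildtype", ][1, ]
    if (is.na(mu$positive) || is.na(wt$positive))
      stop("sample ", s, " needs one mutant and one wildtype assay", call. = FALSE)
    mf <- mutant_fraction(mu$positive, mu$total, wt$positive, wt$total, conf)
    out[[length(out) + 1L]] <- data.frame(
      sample = s, lambda_mut = mf$lambda_mut, lambda_wt = mf$lambda_wt,
      copies_per_ul_mut = mf$lambda_mut / droplet_volume,
      copies_per_ul_wt = mf$lambda_wt / droplet_volume,
      mutant_pct = mf$fraction_pct, ci_lower_pct = mf$ci_lower_pct,
      ci_upper_pct = mf$ci_upper_pct, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
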