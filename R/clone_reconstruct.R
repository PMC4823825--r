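# Cellular-frequency estimation and mutation clustering.
#
# The cellular frequency (CCF) of a mutation is approximately 2 x corrected
# VAF / purity for a diploid heterozygous site; corrections having mapped all
# CNV states back to the diploid scale. Mutations are clustered across
# samples with a finite binomial-mixture EM (component mean VAFs shared by
# all member mutations, per sample), with the number of components chosen by
# BIC -- a deterministic, desk-scale replacement for Dirichlet-process
# clustering of cellular frequencies.

#' Build a CCF matrix from corrected counts
#'
#' CCF = min(1, 2 x corrected VAF / purity). Corrected counts are rounded to
#' the nearest integer here (the single place an integer-count likelihood is
#' needed); cells with rounded depth below `min_depth` are flagged missing.
#'
#' @param corrected Output of [apply_corrections()].
#' @param purity Optional named per-sample purity vector in (0,1\]; defaults
#'   to 1 (unknown), in which case frequencies are on the purity-scaled
#'   cell-fraction scale, which the tree constraints tolerate unchanged.
#' @param min_depth Minimum (corrected, rounded) depth for a cell to count.
#' @return Object of class `ccf_matrix`: matrices `ccf`, `alt`, `dep`,
#'   `missing` (mutations x samples), plus `purity`, `mutations`, `samples`,
#'   `n_capped`.
#' @export
estimate_ccf <- function(corrected, purity = NULL, min_depth = 10) {
  mutations <- unique(corrected$mutation_id)
  samples <- unique(corrected$sample_id)
  if (!is.null(purity)) {
    if (any(purity <= 0)) stop("purity must be > 0", call. = FALSE)
    if (is.null(names(purity))) {
      if (length(purity) == 1L) purity <- stats::setNames(rep(purity, length(samples)), samples)
      else stop("per-sample purity must be named by sample", call. = FALSE)
    }
    purity <- purity[samples]
    if (anyNA(purity)) stop("purity missing for some samples", call. = FALSE)
  } else purity <- stats::setNames(rep(1, length(samples)), samples)
  shape <- list(mutations, samples)
  alt <- dep <- ccf <- matrix(NA_real_, length(mutations), length(samples), dimnames = shape)
  idx <- cbind(match(corrected$mutation_id, mutations),
               match(corrected$sample_id, samples))
  alt[idx] <- round(corrected$alt_prime)
  dep[idx] <- round(corrected$ref_prime + corrected$alt_prime)
  vaf <- alt / dep
  raw_ccf <- sweep(2 * vaf, 2, purity, "/")
  n_capped <- sum(raw_ccf > 1, na.rm = TRUE)
  ccf <- pmin(raw_ccf, 1)
  missing <- is.na(dep) | dep < min_depth
  ccf[missing] <- NA_real_
  out <- list(ccf = ccf, alt = alt, dep = dep, missing = missing,
              purity = purity, mutations = mutations, samples = samples,
              n_capped = n_capped)
  class(out) <- "ccf_matrix"
  out
}

#' Wrap a plain CCF matrix (no read counts) as a `ccf_matrix`
#'
#' For noiseless/analytic inputs: tree scoring then uses constraint
#' violations only (no binomial likelihood term).
#'
#' @param mat Numeric mutations x samples matrix of cellular frequencies in
#'   \[0,1\].
#' @param purity Per-sample purity (default 1).
#' @return A `ccf_matrix` with NULL count matrices.
#' @export
ccf_from_matrix <- function(mat, purity = 1) {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("M", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("S", seq_len(ncol(mat)))
  samples <- colnames(mat)
  purity <- if (length(purity) == 1L) stats::setNames(rep(purity, length(samples)), samples) else purity
  out <- list(ccf = mat, alt = NULL, dep = NULL,
              missing = is.na(mat), purity = purity,
              mutations = rownames(mat), samples = samples, n_capped = 0L)
  class(out) <- "ccf_matrix"
  out
}

# One EM run of a k-component binomial mixture with shared per-sample
# component means. NA cells contribute nothing to the likelihood.
em_binom_mixture <- function(alt, dep, k, theta0, max_iter = 500, tol = 1e-8) {
  n <- nrow(alt); S <- ncol(alt)
  obs <- !is.na(dep) & dep > 0
  alt0 <- ifelse(obs, alt, 0)
  dep0 <- ifelse(obs, dep, 0)
  lchoose_term <- ifelse(obs, lchoose(dep0, alt0), 0)
  theta <- clamp_prob(theta0, 1e-6)
  log_pi <- rep(-log(k), k)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    comp_ll <- matrix(0, n, k)
    for (j in seq_len(k)) {
      lp <- sweep(alt0, 2, log(theta[j, ]), "*") +
        sweep(dep0 - alt0, 2, log(1 - theta[j, ]), "*") + lchoose_term
      comp_ll[, j] <- rowSums(lp)
    }
    a <- sweep(comp_ll, 2, log_pi, "+")
    mx <- apply(a, 1, max)
    lse <- mx + log(rowSums(exp(a - mx)))
    ll <- sum(lse)
    r <- exp(a - lse)
    # M step
    nk <- colSums(r)
    log_pi <- log(clamp_prob(nk / n, 1e-12))
    for (j in seq_len(k)) {
      num <- colSums(r[, j] * alt0)
      den <- colSums(r[, j] * dep0)
      theta[j, ] <- clamp_prob(ifelse(den > 0, num / den, theta[j, ]), 1e-6)
    }
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(loglik = ll, theta = theta, pi = exp(log_pi), resp = r)
}

#' Cluster mutations by cellular frequency across samples
#'
#' Fits k-component binomial mixtures for k = 1..`k_max` on the corrected
#' (alt, depth) counts, selects k by BIC, and assigns each mutation to its
#' maximum-responsibility component. Components left empty under the hard
#' assignment are dropped. Deterministic given `seed`.
#'
#' @param ccf A `ccf_matrix` with count matrices ([estimate_ccf()]).
#' @param k_max Largest number of clusters tried.
#' @param restarts Seeded EM restarts per k (best likelihood kept).
#' @param seed Integer seed.
#' @return Object of class `mutation_clusters`: `assignment` (named integer),
#'   `k`, `ccf_means` (k x samples, capped to \[0,1\]), `theta` (component
#'   mean VAFs), `sizes`, `bic` (per k), `loglik`.
#' @export
cluster_mutations <- function(ccf, k_max = 6, restarts = 10, seed = 1) {
  if (is.null(ccf$alt)) stop("cluster_mutations needs read counts; use manual_clusters for analytic input", call. = FALSE)
  alt <- ccf$alt; dep <- ccf$dep
  alt[ccf$missing] <- NA; dep[ccf$missing] <- NA
  usable <- rowSums(!is.na(dep)) > 0
  if (any(!usable)) {
    warning(sum(!usable), " all-missing mutation(s) excluded from clustering", call. = FALSE)
    alt <- alt[usable, , drop = FALSE]; dep <- dep[usable, , drop = FALSE]
  }
  n <- nrow(alt); S <- ncol(alt)
  if (n < 1L) stop("no mutations to cluster", call. = FALSE)
  vaf_obs <- alt / dep
  row_mean <- rowMeans(vaf_obs, na.rm = TRUE)
  fill <- function(m) { m[is.na(m)] <- row_mean[row(m)[is.na(m)]]; m[is.na(m)] <- 0.25; m }
  vaf_filled <- fill(vaf_obs)
  k_max <- min(k_max, n)
  fits <- vector("list", k_max)
  bic <- rep(NA_real_, k_max)
  with_seed(seed, {
    for (k in seq_len(k_max)) {
      best <- NULL
      for (r in seq_len(restarts)) {
        pick <- if (k == 1L) matrix(colMeans(vaf_filled), 1) else
          vaf_filled[sample.int(n, k), , drop = FALSE]
        pick <- clamp_prob(pick + stats::rnorm(length(pick), 0, 0.01), 1e-4)
        fit <- em_binom_mixture(alt, dep, k, pick)
        if (is.null(best) || fit$loglik > best$loglik) best <- fit
        if (k == 1L) break  # closed-form optimum; restarts add nothing
      }
      fits[[k]] <- best
      bic[k] <- -2 * best$loglik + (k * S + (k - 1)) * log(n)
    }
  })
  k_sel <- which.min(bic)
  fit <- fits[[k_sel]]
  assign <- max.col(fit$resp, ties.method = "first")
  keep <- sort(unique(assign))
  theta <- fit$theta[keep, , drop = FALSE]
  assign <- match(assign, keep)
  # order clusters by decreasing overall mean CCF (cluster 1 ~ truncal)
  ccf_means <- pmin(sweep(2 * theta, 2, ccf$purity, "/"), 1)
  ord <- order(-rowMeans(ccf_means))
  theta <- theta[ord, , drop = FALSE]
  ccf_means <- ccf_means[ord, , drop = FALSE]
  assign <- match(assign, ord)
  # standard error of each cluster-mean CCF (binomial, depth-aggregated)
  dep_tot <- matrix(0, length(keep), S)
  for (j in seq_along(keep))
    dep_tot[j, ] <- colSums(dep[assign == j, , drop = FALSE], na.rm = TRUE)
  se_means <- sweep(2 * sqrt(theta * (1 - theta) / pmax(dep_tot, 1)), 2,
                    ccf$purity, "/")
  rownames(ccf_means) <- rownames(theta) <- rownames(se_means) <- paste0("C", seq_along(keep))
  colnames(ccf_means) <- colnames(theta) <- colnames(se_means) <- ccf$samples
  out <- list(assignment = stats::setNames(assign, rownames(alt)),
              k = length(keep), ccf_means = ccf_means, theta = theta,
              se_means = se_means,
              sizes = as.integer(table(factor(assign, levels = seq_along(keep)))),
              bic = bic, loglik = fit$loglik)
  class(out) <- "mutation_clusters"
  out
}

#' Build clusters from a known assignment
#'
#' Used for analytic/noiseless input or when the grouping is known. Cluster
#' frequencies are depth-weighted means of member CCFs (plain means when no
#' counts are attached).
#'
#' @param ccf A `ccf_matrix`.
#' @param assignment Integer cluster ids named by mutation id (1..k).
#' @return A `mutation_clusters` object.
#' @export
manual_clusters <- function(ccf, assignment) {
  assignment <- assignment[ccf$mutations]
  if (anyNA(assignment)) stop("assignment must cover every mutation", call. = FALSE)
  ks <- sort(unique(assignment))
  assignment <- match(assignment, ks)
  k <- length(ks)
  S <- length(ccf$samples)
  means <- matrix(NA_real_, k, S, dimnames = list(paste0("C", seq_len(k)), ccf$samples))
  w <- if (is.null(ccf$dep)) matrix(1, nrow(ccf$ccf), S) else ifelse(is.na(ccf$dep), 0, ccf$dep)
  cc <- ccf$ccf
  for (j in seq_len(k)) {
    rows <- which(assignment == j)
    for (s in seq_len(S)) {
      vals <- cc[rows, s]; ws <- w[rows, s]
      ok <- !is.na(vals) & ws > 0
      means[j, s] <- if (any(ok)) sum(vals[ok] * ws[ok]) / sum(ws[ok]) else NA_real_
    }
  }
  means[is.na(means)] <- 0
  se <- matrix(0, k, S, dimnames = dimnames(means))
  if (!is.null(ccf$dep)) {
    for (j in seq_len(k)) {
      dep_tot <- colSums(w[assignment == j, , drop = FALSE])
      th <- clamp_prob(means[j, ] * ccf$purity / 2, 1e-6)
      se[j, ] <- 2 * sqrt(th * (1 - th) / pmax(dep_tot, 1)) / ccf$purity
    }
  }
  out <- list(assignment = stats::setNames(assignment, ccf$mutations), k = k,
              ccf_means = pmin(pmax(means, 0), 1), theta = NULL, se_means = se,
              sizes = as.integer(table(factor(assignment, levels = seq_len(k)))),
              bic = NULL, loglik = NA_real_)
  class(out) <- "mutation_clusters"
  out
}
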