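# Temporal ordering of mutations from multi-region cellular frequencies, and
# spatial/driver classification including obligate-partner detection.
#
# Ordering rests on clade-frequency dominance: an ancestor's cellular
# frequency is at least its descendant's in every sample, and strictly larger
# wherever the ancestral clone contributes cells of its own. The comparison
# tolerance is coupled to binomial standard errors because depth can differ
# ~60-fold between exome and amplicon data.

#' Default driver gene list
#'
#' Histone H3 variants plus the recurrent partner and accessory driver genes
#' of pediatric midline glioma. Supplied as data (a character vector), not
#' hard-wired into the classification logic.
#' @return Character vector of gene symbols.
#' @export
default_driver_genes <- function() {
  c("H3F3A", "HIST1H3B", "HIST2H3C", "TP53", "PPM1D", "ACVR1",
    "PIK3R1", "PIK3CA", "ATRX", "PTEN")
}

ccf_se <- function(ccf, mutation, samples) {
  if (is.null(ccf$alt)) return(stats::setNames(rep(0, length(samples)), samples))
  a <- ccf$alt[mutation, samples]
  d <- ccf$dep[mutation, samples]
  vt <- (a + 0.5) / (d + 1)                  # shrunk VAF keeps SE > 0 at 0/1
  se <- 2 * sqrt(vt * (1 - vt) / d) / ccf$purity[samples]
  se[is.na(se)] <- Inf
  se
}

#' Order a pair of mutations from their cellular frequencies
#'
#' `A_first` when A's CCF is at least B's (within tolerance) in every shared
#' sample and strictly larger in at least one; symmetric for `B_first`;
#' `unresolved` when the two never separate beyond tolerance; `incomparable`
#' when each exceeds the other somewhere (distinct branches);
#' `unevaluable` with fewer than two shared samples.
#'
#' @param ccf A `ccf_matrix`.
#' @param a,b Mutation ids.
#' @param tolerance Numeric per-sample tolerance, or NULL to use twice the
#'   pooled binomial standard error of the CCF difference.
#' @return List with `verdict` and `evidence` (per-sample CCFs, difference,
#'   tolerance).
#' @export
pairwise_order <- function(ccf, a, b, tolerance = NULL) {
  shared <- ccf$samples[!ccf$missing[a, ] & !ccf$missing[b, ]]
  if (length(shared) < 2L)
    return(list(verdict = "unevaluable",
                evidence = data.frame(sample = character(0))))
  fa <- ccf$ccf[a, shared]
  fb <- ccf$ccf[b, shared]
  tol <- if (!is.null(tolerance)) rep_len(tolerance, length(shared))
  else 2 * sqrt(ccf_se(ccf, a, shared)^2 + ccf_se(ccf, b, shared)^2)
  gt_a <- any(fa > fb + tol)
  gt_b <- any(fb > fa + tol)
  verdict <- if (gt_a && gt_b) "incomparable"
  else if (gt_a) "A_first"
  else if (gt_b) "B_first"
  else "unresolved"
  list(verdict = verdict,
       evidence = data.frame(sample = shared, ccf_a = fa, ccf_b = fb,
                             diff = fa - fb, tolerance = tol,
                             stringsAsFactors = FALSE))
}

#' Build the partial temporal order over a set of mutations
#'
#' Runs [pairwise_order()] over all pairs, demotes any cycles to unresolved
#' (with a warning), and reports the transitive reduction of the ordered
#' pairs plus the roots (candidate initial events: mutations never observed
#' to be later than another).
#'
#' @param ccf A `ccf_matrix`.
#' @param mutations Mutation ids to order (default: all in `ccf`).
#' @param tolerance Passed to [pairwise_order()].
#' @return List with `pairs` (`data.frame` earlier/later, transitively
#'   reduced), `unresolved`, `incomparable`, `unevaluable` (pair frames),
#'   `roots`, `evidence` (named list per ordered pair).
#' @export
build_partial_order <- function(ccf, mutations = NULL, tolerance = NULL) {
  muts <- mutations %||% ccf$mutations
  n <- length(muts)
  edge <- matrix(FALSE, n, n, dimnames = list(muts, muts))
  unresolved <- incomparable <- unevaluable <- list()
  evidence <- list()
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    po <- pairwise_order(ccf, muts[i], muts[j], tolerance)
    v <- po$verdict
    if (v == "A_first") {
      edge[i, j] <- TRUE
      evidence[[paste(muts[i], muts[j], sep = "->")]] <- po$evidence
    } else if (v == "B_first") {
      edge[j, i] <- TRUE
      evidence[[paste(muts[j], muts[i], sep = "->")]] <- po$evidence
    } else if (v == "unresolved") {
      unresolved[[length(unresolved) + 1L]] <- c(muts[i], muts[j])
    } else if (v == "incomparable") {
      incomparable[[length(incomparable) + 1L]] <- c(muts[i], muts[j])
    } else {
      unevaluable[[length(unevaluable) + 1L]] <- c(muts[i], muts[j])
    }
  }
  # reachability closure (Warshall); mutual reachability marks a cycle
  reach <- edge
  for (m in seq_len(n)) reach <- reach | (outer(reach[, m], reach[m, ], "&"))
  cyc <- which(reach & t(reach), arr.ind = TRUE)
  if (nrow(cyc) > 0L) {
    warning("cyclic ordering evidence; demoting ", nrow(cyc) / 2,
            " pair(s) to unresolved", call. = FALSE)
    for (r in seq_len(nrow(cyc))) {
      i <- cyc[r, 1]; j <- cyc[r, 2]
      if (edge[i, j]) {
        edge[i, j] <- FALSE
        unresolved[[length(unresolved) + 1L]] <- sort(c(muts[i], muts[j]))
      }
    }
    reach <- edge
    for (m in seq_len(n)) reach <- reach | (outer(reach[, m], reach[m, ], "&"))
  }
  # transitive reduction: drop (i,j) when a longer path i -> m -> j exists
  reduced <- edge
  for (i in seq_len(n)) for (j in seq_len(n)) if (edge[i, j]) {
    via <- any(edge[i, ] & reach[, j] & seq_len(n) != i & seq_len(n) != j)
    if (via) reduced[i, j] <- FALSE
  }
  pair_df <- function(lst) {
    if (length(lst) == 0L) return(data.frame(a = character(0), b = character(0),
                                             stringsAsFactors = FALSE))
    unique(data.frame(a = vapply(lst, `[`, "", 1), b = vapply(lst, `[`, "", 2),
                      stringsAsFactors = FALSE))
  }
  idx <- which(reduced, arr.ind = TRUE)
  pairs <- data.frame(earlier = muts[idx[, 1]], later = muts[idx[, 2]],
                      stringsAsFactors = FALSE)
  roots <- muts[colSums(edge) == 0L]
  list(pairs = pairs[order(pairs$earlier, pairs$later), , drop = FALSE],
       unresolved = pair_df(unresolved), incomparable = pair_df(incomparable),
       unevaluable = pair_df(unevaluable), roots = roots, evidence = evidence)
}

#' Spatial classification of mutations across tumor samples
#'
#' `ubiquitous`: present in every evaluable tumor sample; `shared`: present
#' in at least two but not all; `private`: present in exactly one. Mutations
#' present nowhere are excluded (class NA, noted).
#'
#' @param presence A `presence_matrix`.
#' @param tumor_samples Samples to classify over. Default: samples in which
#'   at least one driver-gene mutation is present (requires `genes`).
#' @param genes Named character vector (mutation id -> gene symbol); only
#'   needed for the default `tumor_samples` rule.
#' @param driver_genes Driver gene list for the default tumor-sample rule.
#' @return `data.frame`: `mutation_id, n_present, n_evaluable, spatial_class,
#'   note`.
#' @export
classify_spatial <- function(presence, tumor_samples = NULL, genes = NULL,
                             driver_genes = default_driver_genes()) {
  pm <- unclass(presence)
  if (is.null(tumor_samples)) {
    if (is.null(genes)) stop("supply tumor_samples or genes for the oncogenic-content rule",
                             call. = FALSE)
    drv <- rownames(pm)[genes[rownames(pm)] %in% driver_genes]
    tumor_samples <- colnames(pm)[colSums(pm[drv, , drop = FALSE] == "present") > 0]
  }
  if (length(tumor_samples) == 0L) stop("no tumor samples identified", call. = FALSE)
  pm <- pm[, tumor_samples, drop = FALSE]
  out <- data.frame(mutation_id = rownames(pm),
                    n_present = rowSums(pm == "present"),
                    n_evaluable = rowSums(pm != "unevaluable"),
                    stringsAsFactors = FALSE)
  cls <- rep(NA_character_, nrow(out))
  note <- rep("", nrow(out))
  ok <- out$n_evaluable > 0
  cls[ok & out$n_present == out$n_evaluable & out$n_present > 0] <- "ubiquitous"
  cls[ok & out$n_present >= 2 & out$n_present < out$n_evaluable] <- "shared"
  cls[ok & out$n_present == 1 & out$n_evaluable > 1] <- "private"
  # a single evaluable sample cannot distinguish private from ubiquitous;
  # present-in-all takes precedence above, so only absent-everywhere remains
  note[ok & out$n_present == 0] <- "absent in all tumor samples; excluded"
  note[!ok] <- "unevaluable everywhere"
  out$spatial_class <- cls
  out$note <- note
  rownames(out) <- NULL
  out
}

#' Driver-category classification
#'
#' `main_driver`: driver-gene mutation mapping to the truncal cluster and
#' spatially ubiquitous; `accessory_driver`: driver-gene mutation that is
#' subclonal (non-truncal cluster) or non-ubiquitous; `passenger`: everything
#' else.
#'
#' @param spatial Output of [classify_spatial()].
#' @param genes Named character vector (mutation id -> gene).
#' @param tree A fitted `clone_tree` (for the truncal test).
#' @param driver_genes Driver gene list.
#' @return `spatial` with a `driver_category` column appended.
#' @export
classify_driver <- function(spatial, genes, tree, driver_genes = default_driver_genes()) {
  truncal_clusters <- which(tree$parent == 0L)
  assign <- tree$clusters$assignment
  out <- spatial
  cat <- rep("passenger", nrow(out))
  g <- genes[out$mutation_id]
  in_list <- !is.na(g) & g %in% driver_genes
  truncal <- assign[out$mutation_id] %in% truncal_clusters
  ubi <- !is.na(out$spatial_class) & out$spatial_class == "ubiquitous"
  cat[in_list & truncal & ubi] <- "main_driver"
  cat[in_list & !(truncal & ubi)] <- "accessory_driver"
  cat[is.na(out$spatial_class)] <- NA_character_
  out$driver_category <- cat
  out
}

#' Detect obligate partnership with the oncohistone-like mutation
#'
#' For each tumor sample, checks whether at least one partner-gene mutation
#' co-occurs with the oncohistone mutation. Partnership is obligate when
#' co-occurrence holds in every evaluable tumor sample; when no single
#' partner gene covers all samples but their union does (complementary
#' sibling subclones), the partnership is flagged `complementary`.
#'
#' @param presence A `presence_matrix`.
#' @param genes Named character vector (mutation id -> gene).
#' @param oncohistone_gene Gene symbol of the oncohistone-like mutation.
#' @param partner_genes Candidate partner gene symbols.
#' @param tumor_samples Samples to assess (default: samples where the
#'   oncohistone mutation is present).
#' @return List: `applicable`, `obligate`, `mode` (`"single"`,
#'   `"complementary"`, `"none"`), `per_sample` (`data.frame`),
#'   `covering_partners`, `failing_samples`.
#' @export
detect_obligate_partners <- function(presence, genes, oncohistone_gene = "H3F3A",
                                     partner_genes = c("TP53", "PPM1D", "ACVR1", "PIK3R1"),
                                     tumor_samples = NULL) {
  pm <- unclass(presence)
  onco_rows <- rownames(pm)[genes[rownames(pm)] %in% oncohistone_gene]
  if (length(onco_rows) == 0L)
    return(list(applicable = FALSE, obligate = NA, mode = "none",
                per_sample = NULL, covering_partners = character(0),
                failing_samples = character(0)))
  onco_present <- colSums(pm[onco_rows, , drop = FALSE] == "present") > 0
  tumor_samples <- tumor_samples %||% colnames(pm)[onco_present]
  partner_rows <- rownames(pm)[genes[rownames(pm)] %in% partner_genes]
  per <- data.frame(sample_id = tumor_samples,
                    oncohistone_present = onco_present[tumor_samples],
                    stringsAsFactors = FALSE)
  per$partners_present <- vapply(tumor_samples, function(s) {
    hit <- partner_rows[pm[partner_rows, s] == "present"]
    paste(sort(unique(genes[hit])), collapse = ",")
  }, character(1))
  per$covered <- nzchar(per$partners_present)
  obligate <- all(per$covered) && nrow(per) > 0
  single <- vapply(partner_genes, function(g) {
    rows <- rownames(pm)[genes[rownames(pm)] %in% g]
    length(rows) > 0 && all(colSums(pm[rows, tumor_samples, drop = FALSE] == "present") > 0)
  }, logical(1))
  mode <- if (!obligate) "none" else if (any(single)) "single" else "complementary"
  list(applicable = TRUE, obligate = obligate, mode = mode, per_sample = per,
       covering_partners = partner_genes[single],
       failing_samples = per$sample_id[!per$covered])
}

#' Write the mutation classification table as TSV
#' @param classification Output of [classify_driver()] (or [classify_spatial()]).
#' @param path Output path.
#' @export
write_classification <- function(classification, path) {
  utils::write.table(classification, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize a partial temporal order as JSON
#'
#' Lossless for the edge structure: ordered pairs (after transitive
#' reduction), unresolved/incomparable/unevaluable pairs, roots, and the
#' per-pair frequency evidence.
#'
#' @param order Output of [build_partial_order()].
#' @param path Output path.
#' @export
write_order_json <- function(order, path) {
  jsonlite::write_json(order, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
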