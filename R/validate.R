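# Ground-truth comparison for simulation studies.

#' Compare a fitted clone tree with the generating truth
#'
#' Maps each fitted cluster to the true clone carrying the majority of its
#' member mutations, then checks that the mapping is a bijection and that the
#' induced parent relation equals the true tree. The mixing-proportion error
#' is the mean absolute difference between fitted and true mixing (including
#' the normal component) under that mapping.
#'
#' @param cohort A `sim_cohort` (the generating truth).
#' @param clusters The `mutation_clusters` fitted on the cohort.
#' @param tree The fitted `clone_tree`.
#' @return List: `topology_exact` (logical), `mixing_mae` (NA unless the
#'   mapping is a bijection), `clone_map` (fitted cluster -> true clone),
#'   `k_fitted`, `k_true`.
#' @export
compare_to_truth <- function(cohort, clusters, tree) {
  truth <- cohort$truth
  k_true <- truth$tree$n_clones
  true_clone <- truth$mutations$clone[match(names(clusters$assignment),
                                            truth$mutations$mutation_id)]
  maj <- vapply(split(true_clone, clusters$assignment), function(x)
    as.integer(names(sort(table(x), decreasing = TRUE))[1]), integer(1))
  bijection <- clusters$k == k_true && length(unique(maj)) == k_true
  if (!bijection)
    return(list(topology_exact = FALSE, mixing_mae = NA_real_, clone_map = maj,
                k_fitted = clusters$k, k_true = k_true))
  induced <- integer(k_true)
  for (c in seq_len(clusters$k)) {
    p <- tree$parent[c]
    induced[maj[c]] <- if (p == 0L) 0L else maj[p]
  }
  est <- tree$mixing
  rownames(est) <- c(paste0("clone", maj), "normal")
  mae <- mean(abs(est[rownames(truth$mixtures), ] - truth$mixtures))
  list(topology_exact = all(induced == truth$tree$parent), mixing_mae = mae,
       clone_map = maj, k_fitted = clusters$k, k_true = k_true)
}
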