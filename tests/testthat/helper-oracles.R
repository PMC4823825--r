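# Independent oracles used across the suite. These deliberately re-derive
# quantities through different code paths than the package.

# correction formulas as a coefficient table: ref' = a*ref + b*alt, alt' = c*alt
oracle_correct_counts <- function(ref, alt, event) {
  coefs <- rbind(duplication     = c(1, 0.0, 0.5),
                 deletion        = c(1, 1.0, 1.0),
                 cn_loh          = c(1, 0.5, 0.5),
                 chrX_hemizygous = c(2, 1.0, 1.0),
                 none            = c(1, 0.0, 1.0))
  k <- coefs[event, , drop = FALSE]
  cbind(ref_prime = k[, 1] * ref + k[, 2] * alt, alt_prime = k[, 3] * alt)
}

# brute-force enumeration of parent vectors over k clusters: each parent in
# {0, 1..k}\{self}, exactly one cluster under the normal root, no cycles
oracle_enumerate_parent_vectors <- function(k) {
  if (k == 1L) return(matrix(0L, 1, 1))
  grid <- as.matrix(expand.grid(rep(list(0:k), k)))
  keep <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- grid[i, ]
    if (any(p == seq_len(k))) next
    if (sum(p == 0L) != 1L) next
    ok <- TRUE
    for (v in seq_len(k)) {
      seen <- integer(0)
      u <- v
      while (u != 0L) {
        if (u %in% seen) { ok <- FALSE; break }
        seen <- c(seen, u)
        u <- p[u]
      }
      if (!ok) break
    }
    keep[i] <- ok
  }
  m <- grid[keep, , drop = FALSE]
  dimnames(m) <- NULL
  m
}

# strict ancestor relation from a parent vector
oracle_ancestor_relation <- function(parent) {
  k <- length(parent)
  anc <- matrix(FALSE, k, k)
  for (v in seq_len(k)) {
    p <- parent[v]
    while (p != 0L) { anc[p, v] <- TRUE; p <- parent[p] }
  }
  anc
}

# expected VAF by explicit per-clone cell bookkeeping (independent of the
# package's tabulated computation)
oracle_expected_vaf <- function(tumor, mutation_id, region) {
  cfg <- tumor$config
  mu <- tumor$mutations[tumor$mutations$mutation_id == mutation_id, ]
  k <- tumor$tree$n_clones
  anc_or_self <- function(c) {
    out <- c
    p <- tumor$tree$parent[c]
    while (p != 0L) { out <- c(out, p); p <- tumor$tree$parent[p] }
    out
  }
  num <- 0; den <- 0
  for (c in seq_len(k)) {
    m <- tumor$mixtures[paste0("clone", c), region]
    lineage <- anc_or_self(c)
    ev <- tumor$cnv[tumor$cnv$arm == mu$arm & tumor$cnv$clone %in% lineage, ]
    copies <- 2; mult <- 1
    if (nrow(ev) == 1) {
      if (ev$event == "duplication") {
        copies <- 3; mult <- if (cfg$mutant_homolog_duplicated) 2 else 1
      } else if (ev$event == "deletion") {
        copies <- 1; mult <- if (cfg$mutant_allele_retained) 1 else 0
      } else {
        copies <- 2; mult <- if (cfg$mutant_allele_retained) 2 else 0
      }
    }
    carries <- mu$clone %in% lineage
    num <- num + m * (if (carries) mult else 0)
    den <- den + m * copies
  }
  den <- den + 2 * tumor$mixtures["normal", region]
  num / den
}

# small cohort settings used by several IO/clustering tests
small_cohort <- function(seed, n_clones = 2, n_regions = 3, muts = 10,
                         depth = 4000, cnv_rate = 0) {
  simulate_cohort(sim_config(n_clones = n_clones, n_regions = n_regions,
                             mutations_per_clone = muts, mean_depth = depth,
                             cnv_rate = cnv_rate, seed = seed))
}
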