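test_that("CCF estimation applies the 2 x VAF / purity rule with a cap", {
  corr <- data.frame(mutation_id = c("m1", "m2", "m3"), sample_id = "S1",
                     ref_prime = c(50, 90, 30), alt_prime = c(50, 10, 70),
                     event_applied = "none",
                     corrected_vaf = c(0.5, 0.1, 0.7), stringsAsFactors = FALSE)
  cc1 <- estimate_ccf(corr)
  expect_equal(unname(cc1$ccf[, "S1"]), c(1.0, 0.2, 1.0))  # m3 capped
  expect_equal(cc1$n_capped, 1L)
  cc2 <- estimate_ccf(corr, purity = c(S1 = 0.8))
  expect_equal(unname(cc2$ccf["m2", "S1"]), 0.25)
  expect_error(estimate_ccf(corr, purity = c(S1 = 0)), "purity")
  # shallow cells are flagged missing
  corr$ref_prime[2] <- 4; corr$alt_prime[2] <- 1
  cc3 <- estimate_ccf(corr)
  expect_true(cc3$missing["m2", "S1"])
})

test_that("mixture clustering finds one component for homogeneous input", {
  alt <- matrix(rbinom(40 * 3, 400, 0.25), 40, 3,
                dimnames = list(paste0("m", 1:40), paste0("S", 1:3)))
  corr <- data.frame(mutation_id = rep(rownames(alt), 3),
                     sample_id = rep(colnames(alt), each = 40),
                     ref_prime = 400 - as.vector(alt), alt_prime = as.vector(alt),
                     event_applied = "none",
                     corrected_vaf = as.vector(alt) / 400, stringsAsFactors = FALSE)
  cl <- cluster_mutations(estimate_ccf(corr), k_max = 4, seed = 1)
  expect_equal(cl$k, 1L)
})

test_that("well-separated groups are recovered exactly and match a nearest-mean oracle", {
  for (seed in 1:5) {
    co <- simulate_cohort(sim_config(n_clones = 2, n_regions = 6,
                                     mutations_per_clone = 50, mean_depth = 4000,
                                     purity_range = c(0.9, 0.9), dropout_prob = 0,
                                     cnv_rate = 0, seed = seed))
    ccf <- estimate_ccf(apply_corrections(co$counts))
    cl <- cluster_mutations(ccf, k_max = 4, seed = seed)
    expect_equal(cl$k, 2L, label = sprintf("seed %d", seed))
    truth <- co$truth$mutations$clone[match(names(cl$assignment),
                                            co$truth$mutations$mutation_id)]
    # brute-force oracle: assign to the nearer of the two true VAF profiles
    ev <- co$expected_vaf[names(cl$assignment), ]
    obs <- ccf$alt / ccf$dep
    prof <- rbind(colMeans(ev[truth == 1, ]), colMeans(ev[truth == 2, ]))
    oracle <- apply(obs, 1, function(v)
      which.min(c(sum((v - prof[1, ])^2), sum((v - prof[2, ])^2))))
    # perfect agreement with truth and with the oracle, up to labels
    expect_equal(sum(table(cl$assignment, truth) != 0), 2L)
    expect_equal(sum(table(cl$assignment, oracle) != 0), 2L)
  }
})

test_that("the branching-partner pattern yields three frequency clusters", {
  co <- branching_partner_cohort(seed = 2, passengers_per_clone = 15)
  ccf <- estimate_ccf(apply_corrections(co$counts))
  cl <- cluster_mutations(ccf, k_max = 6, seed = 2)
  expect_equal(cl$k, 3L)
  cmp <- compare_to_truth(co, cl, fit_tree(ccf, cl))
  expect_true(cmp$topology_exact)
})

test_that("tree enumeration counts k^(k-1) rooted labeled trees", {
  expect_equal(nrow(enumerate_trees(1)), 1L)
  t2 <- enumerate_trees(2)
  expect_equal(nrow(t2), 2L)  # the two chains: trunk 1 -> 2 and trunk 2 -> 1
  expect_setequal(apply(t2, 1, paste, collapse = ","), c("0,1", "2,0"))
  expect_equal(nrow(enumerate_trees(3)), 9L)
  for (k in 2:4) {
    got <- apply(enumerate_trees(k), 1, paste, collapse = ",")
    want <- apply(oracle_enumerate_parent_vectors(k), 1, paste, collapse = ",")
    expect_setequal(got, want)
    expect_equal(length(got), as.integer(k^(k - 1)))
  }
  expect_error(enumerate_trees(9), "ceiling")
})

test_that("scoring projects onto the sum-condition polytope", {
  Fm <- rbind(C1 = c(0.9, 0.8), C2 = c(0.5, 0.2), C3 = c(0.3, 0.5))
  colnames(Fm) <- c("S1", "S2")
  ccf <- ccf_from_matrix(rbind(m1 = Fm[1, ], m2 = Fm[2, ], m3 = Fm[3, ]))
  cl <- manual_clusters(ccf, c(m1 = 1, m2 = 2, m3 = 3))
  ok <- score_tree(c(0L, 1L, 1L), cl, ccf)   # branching: consistent
  expect_equal(ok$violation_total, 0)
  expect_equal(ok$freq, cl$ccf_means)
  bad <- score_tree(c(0L, 1L, 2L), cl, ccf, tol_base = 0)  # C3 under C2: 0.2 < 0.5
  expect_gt(bad$violation_total, 0)
  expect_lt(bad$score, ok$score)
})

test_that("the fitted tree matches hand-worked and degenerate cases", {
  # single clonal cluster: one tumor node, no normal contamination
  one <- ccf_from_matrix(matrix(1, 1, 3, dimnames = list("m1", paste0("S", 1:3))))
  cl1 <- manual_clusters(one, c(m1 = 1))
  tr1 <- fit_tree(one, cl1)
  expect_equal(tr1$parent, 0L)
  expect_equal(unname(tr1$mixing["normal", ]), rep(0, 3))
  expect_error(fit_tree(one, NULL), "empty cluster")

  # A dominates B and C, but B and C cross: only the branching tree fits
  Fm <- rbind(c(0.9, 0.8), c(0.5, 0.2), c(0.3, 0.5))
  dimnames(Fm) <- list(c("mA", "mB", "mC"), c("S1", "S2"))
  ccf <- ccf_from_matrix(Fm)
  cl <- manual_clusters(ccf, c(mA = 1, mB = 2, mC = 3))
  tr <- fit_tree(ccf, cl, tol_base = 0)
  expect_equal(tr$parent, c(0L, 1L, 1L))
  expect_equal(unname(tr$mixing[1, "S1"]), 0.1)  # 0.9 - (0.5 + 0.3)
  expect_equal(tr$violation_total, 0)
})

test_that("exhaustive search equals the argmax over an independent enumeration", {
  for (seed in 1:10) {
    k <- sample(2:4, 1)
    inst <- random_noiseless_instance(k, 6, seed = 500 + seed)
    ccf <- ccf_from_matrix(inst$freq)
    cl <- manual_clusters(ccf, stats::setNames(seq_len(k), rownames(inst$freq)))
    tr <- fit_tree(ccf, cl)
    cand <- oracle_enumerate_parent_vectors(k)
    sc <- apply(cand, 1, function(p) score_tree(as.integer(p), cl, ccf)$score)
    expect_equal(tr$score, max(sc), tolerance = 1e-9)
    expect_equal(tr$parent, as.integer(cand[which.max(sc), ]))
    expect_equal(tr$parent, inst$parent)
  }
})

test_that("fitted trees satisfy the mixing-proportion invariants", {
  for (seed in 1:5) {
    co <- small_cohort(seed, n_clones = 3, n_regions = 4, muts = 20)
    ccf <- estimate_ccf(apply_corrections(co$counts))
    cl <- cluster_mutations(ccf, k_max = 5, seed = seed)
    tr <- fit_tree(ccf, cl)
    expect_true(all(abs(colSums(tr$mixing) - 1) < 1e-9))
    expect_true(all(tr$mixing >= 0))
    tr2 <- fit_tree(ccf, cluster_mutations(ccf, k_max = 5, seed = seed))
    expect_identical(export_tree(tr, "json"), export_tree(tr2, "json"))
  }
})

test_that("display pruning collapses only sub-threshold trajectories", {
  Fm <- rbind(c(0.9, 0.9), c(0.5, 0.4), c(0.012, 0.008))
  dimnames(Fm) <- list(c("mA", "mB", "mC"), c("S1", "S2"))
  ccf <- ccf_from_matrix(Fm)
  tr <- fit_tree(ccf, manual_clusters(ccf, c(mA = 1, mB = 2, mC = 3)), tol_base = 0)
  pr <- prune_tree(tr, 0.05)
  expect_equal(sum(pr$node_map == which(rownames(tr$freq) == "C3")), 0)
  expect_equal(length(pr$display_parent), 2L)
  expect_equal(colSums(pr$display_mixing), colSums(tr$mixing))
  keep <- prune_tree(tr, 0)
  expect_equal(length(keep$display_parent), 3L)
  expect_equal(keep$node_map, 1:3)
  full <- prune_tree(tr, 0.05)
  expect_identical(full$fitted, tr)
})

test_that("serializations round-trip and parse in standard readers", {
  co <- small_cohort(9, n_clones = 3, n_regions = 3, muts = 10)
  ccf <- estimate_ccf(apply_corrections(co$counts))
  cl <- cluster_mutations(ccf, k_max = 4, seed = 9)
  tr <- fit_tree(ccf, cl)
  back <- import_tree_json(export_tree(tr, "json"))
  expect_equal(back$parent, tr$parent)
  expect_equal(back$freq, tr$freq)
  expect_equal(back$mixing, tr$mixing, tolerance = 1e-12)

  dot <- export_tree(tr, "dot")
  expect_equal(length(gregexpr("label=", dot)[[1]]), tr$k + 1L)  # clusters + normal
  expect_equal(length(gregexpr("->", dot)[[1]]), tr$k)

  nwk <- export_tree(tr, "newick")
  skip_if_not_installed("ape")
  tree <- ape::read.tree(text = nwk)
  expect_s3_class(tree, "phylo")
  expect_true(all(sort(c(tree$tip.label, tree$node.label)) ==
                    sort(c("normal", rownames(tr$freq)))))
  expect_error(export_tree(tr, "nexus"))
})
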