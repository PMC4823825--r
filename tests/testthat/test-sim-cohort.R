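test_that("configuration validation rejects impossible studies", {
  expect_error(sim_config(n_clones = 0), "n_clones")
  expect_error(sim_config(n_regions = 0), "n_regions")
  expect_error(sim_config(mean_depth = 0), "mean_depth")
  expect_error(sim_config(purity_range = c(0.9, 0.7)), "purity_range")
  expect_error(sim_config(purity_range = c(-0.1, 0.5)), "purity_range")
})

test_that("clone trees have a normal root, a unique trunk, and are seeded", {
  t1 <- simulate_clone_tree(sim_config(n_clones = 1))
  expect_identical(t1$parent, 0L)
  a <- simulate_clone_tree(sim_config(n_clones = 3, seed = 7))
  b <- simulate_clone_tree(sim_config(n_clones = 3, seed = 7))
  expect_identical(a, b)
  expect_equal(sum(a$parent == 0L), 1L)
  expect_equal(a$parent[1], 0L)
})

test_that("random attachment is uniform over labeled topologies (chi-square)", {
  # 4 clones: clone 3 picks among {1,2}, clone 4 among {1,2,3} -> 6 labeled
  # trees each with probability 1/6 under sequential uniform attachment
  keys <- vapply(1:1500, function(s)
    paste(simulate_clone_tree(sim_config(n_clones = 4, seed = s))$parent,
          collapse = ""), character(1))
  tab <- table(keys)
  expect_equal(length(tab), 6L)
  expect_gt(stats::chisq.test(tab, p = rep(1 / 6, 6))$p.value, 1e-3)
})

test_that("driver templates place mutations on the intended clones", {
  cfg <- sim_config(n_clones = 3, mutations_per_clone = 5, seed = 3)
  tree <- simulate_clone_tree(cfg)
  tmpl <- list(list(gene = "H3F3A", role = "truncal"),
               list(gene = "TP53", role = "truncal"),
               list(gene = "PIK3CA", role = "subclonal"))
  mu <- assign_mutations(tree, cfg, tmpl)
  expect_equal(mu$clone[mu$gene == "H3F3A"], 1L)
  expect_equal(mu$clone[mu$gene == "TP53"], 1L)
  expect_gt(mu$clone[mu$gene == "PIK3CA"], 1L)
  expect_equal(sum(mu$driver_label == "passenger"), 15L)

  plain <- assign_mutations(tree, cfg, NULL)
  expect_true(all(plain$driver_label == "passenger"))
  expect_error(assign_mutations(tree, cfg, list(list(gene = "X", role = 9))),
               "absent clone")
})

test_that("region mixtures are simplex draws with subclone dropout", {
  cfg <- sim_config(n_clones = 4, n_regions = 6, seed = 5)
  tree <- simulate_clone_tree(cfg)
  mix <- simulate_region_mixtures(tree, cfg)
  expect_true(all(abs(colSums(mix) - 1) < 1e-12))
  expect_true(all(mix >= 0))
  # seeded fixture exhibits spatial heterogeneity: some subclone absent somewhere
  expect_true(any(mix[2:4, ] == 0))

  pure <- sim_config(n_clones = 1, n_regions = 2, purity_range = c(1, 1), seed = 1)
  pm <- simulate_region_mixtures(simulate_clone_tree(pure), pure)
  expect_equal(unname(pm["clone1", ]), c(1, 1))
  expect_equal(unname(pm["normal", ]), c(0, 0))
})

test_that("expected VAF follows the copy-number bookkeeping", {
  base <- function(...) {
    cfg <- sim_config(n_clones = 1, n_regions = 1, mutations_per_clone = 1,
                      purity_range = c(1, 1), cnv_rate = 0, seed = 2, ...)
    simulate_cohort(cfg)
  }
  co <- base()
  expect_equal(expected_vaf(co$truth, co$truth$mutations$mutation_id[1], "R1"), 0.5)

  cfg <- sim_config(n_clones = 2, n_regions = 2, mutations_per_clone = 2,
                    purity_range = c(0.6, 0.6), cnv_rate = 0, seed = 4)
  co2 <- simulate_cohort(cfg)
  truncal <- co2$truth$mutations$mutation_id[co2$truth$mutations$clone == 1][1]
  expect_equal(expected_vaf(co2$truth, truncal, "R1"), 0.3)  # purity/2

  # clonal duplication at purity 1: mutant homolog duplicated -> 2/3;
  # wild-type homolog duplicated -> 1/3; confirmed by per-cell enumeration
  for (flag in c(TRUE, FALSE)) {
    cfg3 <- sim_config(n_clones = 1, n_regions = 1, mutations_per_clone = 3,
                       purity_range = c(1, 1), cnv_rate = 0, seed = 6,
                       mutant_homolog_duplicated = flag)
    co3 <- simulate_cohort(cfg3)
    co3$truth$cnv <- data.frame(clone = 1L, arm = co3$truth$mutations$arm[1],
                                event = "duplication", stringsAsFactors = FALSE)
    mid <- co3$truth$mutations$mutation_id[1]
    expect_equal(expected_vaf(co3$truth, mid, "R1"), if (flag) 2 / 3 else 1 / 3)
    expect_equal(expected_vaf(co3$truth, mid, "R1"),
                 oracle_expected_vaf(co3$truth, mid, "R1"))
  }
})

test_that("expected VAF agrees with the per-cell enumeration oracle on random tumors", {
  cfg <- sim_config(n_clones = 4, n_regions = 3, mutations_per_clone = 4,
                    cnv_rate = 1.5, cnv_truncal_only = FALSE, seed = 11)
  co <- simulate_cohort(cfg)
  for (mid in co$truth$mutations$mutation_id)
    for (r in colnames(co$truth$mixtures))
      expect_equal(expected_vaf(co$truth, mid, r),
                   oracle_expected_vaf(co$truth, mid, r), tolerance = 1e-12)
})

test_that("expected VAF is monotone in the mutation clade's mixture", {
  cfg <- sim_config(n_clones = 2, n_regions = 1, mutations_per_clone = 1,
                    cnv_rate = 0, seed = 1)
  co <- simulate_cohort(cfg)
  mid <- co$truth$mutations$mutation_id[co$truth$mutations$clone == 2][1]
  vals <- vapply(seq(0, 0.5, by = 0.1), function(f2) {
    co$truth$mixtures[, 1] <- c(0.3, f2, 0.7 - f2)
    expected_vaf(co$truth, mid, "R1")
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("read-count sampling is binomial around the expected VAF and seeded", {
  expect_equal(simulate_read_counts(rep(0, 50), 100, seed = 1)$alt_count, rep(0L, 50))
  expect_identical(simulate_read_counts(0.3, 70, seed = 9),
                   simulate_read_counts(0.3, 70, seed = 9))
  expect_error(simulate_read_counts(0.5, 0), "mean_depth")
  expect_error(simulate_read_counts(1.2, 10), "VAF")
  rc <- simulate_read_counts(rep(0.5, 1000), 4000, seed = 2)
  frac <- mean(rc$alt_count / (rc$alt_count + rc$ref_count))
  se <- sqrt(0.25 / 4000) / sqrt(1000)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("germline BAF shifts follow the aneuploidy copy model", {
  # no CNV: folded deviation is the balanced-binomial baseline at high depth
  co <- small_cohort(3)
  ab <- simulate_baf_sites(co$truth, "R1", co$truth$config, seed = 1)
  baf <- ab$sites$b_count / (ab$sites$a_count + ab$sites$b_count)
  expect_lt(mean(abs(baf - 0.5)), 0.1)

  # clonal CN-LOH at purity 1: one parental allele fully lost
  cfg <- sim_config(n_clones = 1, n_regions = 1, mutations_per_clone = 1,
                    purity_range = c(1, 1), het_sites_per_arm = 200,
                    wes_depth = 500, seed = 5)
  co2 <- simulate_cohort(cfg)
  co2$truth$cnv <- data.frame(clone = 1L, arm = "arm01", event = "cn_loh",
                              stringsAsFactors = FALSE)
  ab2 <- simulate_baf_sites(co2$truth, "R1", cfg, seed = 2)
  s1 <- ab2$sites[ab2$sites$arm == "arm01", ]
  expect_equal(mean(abs(s1$b_count / (s1$a_count + s1$b_count) - 0.5)), 0.5,
               tolerance = 1e-6)

  # duplication at clonal fraction 0.5: gained-allele frequency 1.5/2.5 = 0.6
  cfg3 <- sim_config(n_clones = 1, n_regions = 1, mutations_per_clone = 1,
                     purity_range = c(0.5, 0.5), het_sites_per_arm = 400,
                     wes_depth = 2000, seed = 8)
  co3 <- simulate_cohort(cfg3)
  co3$truth$cnv <- data.frame(clone = 1L, arm = "arm01", event = "duplication",
                              stringsAsFactors = FALSE)
  ab3 <- simulate_baf_sites(co3$truth, "R1", cfg3, seed = 3)
  s3 <- ab3$sites[ab3$sites$arm == "arm01", ]
  expect_equal(mean(abs(s3$b_count / (s3$a_count + s3$b_count) - 0.5)), 0.1,
               tolerance = 0.01)
  expect_gt(ab3$coverage$tumor_mean[ab3$coverage$arm == "arm01"] /
              ab3$coverage$normal_mean[ab3$coverage$arm == "arm01"], 1.15)
})

test_that("cohorts round-trip through disk losslessly and deterministically", {
  co <- small_cohort(7)
  d1 <- withr::local_tempdir()
  write_cohort(co, d1)
  back <- read_counts_tsv(file.path(d1, "variant_counts.tsv"))
  expect_equal(back, co$counts)
  expect_equal(nrow(back),
               nrow(co$truth$mutations) * co$truth$config$n_regions)
  tr <- read_cohort_truth(file.path(d1, "truth.json"))
  expect_equal(tr$parent, co$truth$tree$parent)
  expect_equal(tr$mixtures, co$truth$mixtures)
  # connectivity: every clone walks up to the normal root
  for (v in seq_along(tr$parent)) {
    p <- v
    for (i in 1:10) { if (p == 0) break; p <- tr$parent[p] }
    expect_equal(p, 0L)
  }
  # byte-identical regeneration under the same config + seed
  d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(co$truth$config), d2)
  for (f in c("variant_counts.tsv", "het_sites.tsv", "arm_coverage.tsv", "truth.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})
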