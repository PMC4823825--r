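mk_ccf <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- paste0("S", seq_len(ncol(m)))
  ccf_from_matrix(m)
}

test_that("pairwise ordering distinguishes dominance, ties, and branches", {
  ccf <- mk_ccf(A = c(1, 1), B = c(0.5, 0.2), C = c(0.3, 0.5), D = c(1, 1))
  expect_equal(pairwise_order(ccf, "A", "B", tolerance = 1e-6)$verdict, "A_first")
  expect_equal(pairwise_order(ccf, "B", "A", tolerance = 1e-6)$verdict, "B_first")
  expect_equal(pairwise_order(ccf, "A", "D", tolerance = 1e-6)$verdict, "unresolved")
  expect_equal(pairwise_order(ccf, "B", "C", tolerance = 1e-6)$verdict, "incomparable")
  one <- ccf_from_matrix(matrix(c(1, 0.5), 2, 1,
                                dimnames = list(c("A", "B"), "S1")))
  expect_equal(pairwise_order(one, "A", "B")$verdict, "unevaluable")
})

test_that("ordering is symmetric under swapping the pair", {
  set.seed(42)
  for (i in 1:25) {
    m <- matrix(runif(6), 2, 3, dimnames = list(c("A", "B"), paste0("S", 1:3)))
    ccf <- ccf_from_matrix(m)
    ab <- pairwise_order(ccf, "A", "B", tolerance = 0.05)$verdict
    ba <- pairwise_order(ccf, "B", "A", tolerance = 0.05)$verdict
    flip <- c(A_first = "B_first", B_first = "A_first",
              unresolved = "unresolved", incomparable = "incomparable")
    expect_equal(ba, unname(flip[ab]))
  }
})

test_that("count-based tolerance scales with depth", {
  deep <- estimate_ccf(data.frame(
    mutation_id = rep(c("A", "B"), each = 2),
    sample_id = rep(c("S1", "S2"), 2),
    ref_prime = c(2000, 2000, 2200, 2200), alt_prime = c(2000, 2000, 1800, 1800),
    event_applied = "none", corrected_vaf = c(0.5, 0.5, 0.45, 0.45)))
  shallow <- estimate_ccf(data.frame(
    mutation_id = rep(c("A", "B"), each = 2),
    sample_id = rep(c("S1", "S2"), 2),
    ref_prime = c(35, 35, 39, 39), alt_prime = c(35, 35, 31, 31),
    event_applied = "none", corrected_vaf = c(0.5, 0.5, 31 / 70, 31 / 70)))
  # a 0.10 CCF gap clears 2x the pooled binomial SE at 4000x (~0.045) but
  # not at 70x (~0.34)
  expect_equal(pairwise_order(deep, "A", "B")$verdict, "A_first")
  expect_equal(pairwise_order(shallow, "A", "B")$verdict, "unresolved")
})

test_that("the partial order recovers the ancestor relation and its roots", {
  for (seed in 1:5) {
    co <- small_cohort(seed, n_clones = 3, n_regions = 5, muts = 3)
    ccf <- estimate_ccf(apply_corrections(co$counts))
    truncal <- co$truth$mutations$mutation_id[co$truth$mutations$clone == 1]
    sub <- co$truth$mutations$mutation_id[co$truth$mutations$clone != 1]
    po <- build_partial_order(ccf, c(truncal[1], sub))
    expect_true(truncal[1] %in% po$roots,
                label = sprintf("seed %d truncal root", seed))
    expect_false(any(po$pairs$later == truncal[1]))
  }
  empty <- build_partial_order(mk_ccf(A = c(1, 1)), character(0))
  expect_equal(nrow(empty$pairs), 0L)
  expect_length(empty$roots, 0L)
})

test_that("the branching-partner fixture orders the trunk first, siblings incomparable", {
  co <- branching_partner_cohort(seed = 3)
  ccf <- estimate_ccf(apply_corrections(co$counts))
  po <- build_partial_order(ccf, c("M0001", "M0002", "M0003"))
  expect_equal(po$roots, "M0001")
  expect_equal(nrow(po$incomparable), 1L)
  expect_setequal(unlist(po$incomparable[1, ]), c("M0002", "M0003"))
  expect_setequal(po$pairs$later, c("M0002", "M0003"))
})

test_that("the demotion rule guarantees an acyclic order", {
  set.seed(7)
  for (i in 1:20) {
    m <- matrix(runif(5 * 4), 5, 4,
                dimnames = list(paste0("m", 1:5), paste0("S", 1:4)))
    po <- build_partial_order(ccf_from_matrix(m), tolerance = 0.02)
    if (nrow(po$pairs) == 0L) next
    g <- matrix(FALSE, 5, 5, dimnames = list(rownames(m), rownames(m)))
    g[cbind(po$pairs$earlier, po$pairs$later)] <- TRUE
    reach <- g
    for (k in 1:5) reach <- reach | (outer(reach[, k], reach[k, ], "&"))
    expect_false(any(diag(reach)))
  }
})

test_that("spatial classes partition evaluable mutations", {
  pm <- matrix("absent", 4, 6, dimnames = list(paste0("m", 1:4), paste0("S", 1:6)))
  pm["m1", ] <- "present"
  pm["m2", c("S1", "S2")] <- "present"
  pm["m3", "S4"] <- "present"
  class(pm) <- c("presence_matrix", class(pm))
  sp <- classify_spatial(pm, tumor_samples = colnames(pm))
  expect_equal(sp$spatial_class, c("ubiquitous", "shared", "private", NA))
  expect_match(sp$note[4], "absent")
  evaluable <- !is.na(sp$spatial_class)
  expect_equal(sum(evaluable), 3L)
  expect_false(any(duplicated(sp$mutation_id)))
})

test_that("driver categories follow gene list, clonality, and spatial class", {
  co <- branching_partner_cohort(seed = 5)
  ccf <- estimate_ccf(apply_corrections(co$counts))
  cl <- cluster_mutations(ccf, k_max = 5, seed = 5)
  tr <- fit_tree(ccf, cl)
  pres <- build_presence_matrix(co$counts, "amplicon")
  genes <- stats::setNames(co$truth$mutations$gene, co$truth$mutations$mutation_id)
  sp <- classify_spatial(pres, genes = genes)
  out <- classify_driver(sp, genes, tr)
  expect_equal(out$driver_category[out$mutation_id == "M0001"], "main_driver")
  expect_equal(out$driver_category[out$mutation_id == "M0002"], "accessory_driver")
  expect_equal(out$driver_category[out$mutation_id == "M0003"], "accessory_driver")
  expect_true(all(out$driver_category[grepl("^PSG", genes[out$mutation_id])] ==
                    "passenger", na.rm = TRUE))
  # an ubiquitous mutation in a non-listed gene stays a passenger
  g2 <- genes
  truncal_psg <- co$truth$mutations$mutation_id[co$truth$mutations$clone == 1 &
                                                  co$truth$mutations$driver_label == "passenger"][1]
  expect_equal(out$driver_category[out$mutation_id == truncal_psg], "passenger")
})

test_that("obligate partnership detection distinguishes single, complementary, none", {
  pm <- matrix("absent", 3, 6,
               dimnames = list(c("h3", "p1", "p2"), paste0("S", 1:6)))
  class(pm) <- c("presence_matrix", class(pm))
  genes <- c(h3 = "H3F3A", p1 = "TP53", p2 = "PPM1D")
  pm["h3", ] <- "present"

  pm1 <- pm; pm1["p1", ] <- "present"
  r1 <- detect_obligate_partners(pm1, genes)
  expect_true(r1$obligate); expect_equal(r1$mode, "single")
  expect_true("TP53" %in% r1$covering_partners)

  pm2 <- pm; pm2["p1", 1:3] <- "present"; pm2["p2", 4:6] <- "present"
  r2 <- detect_obligate_partners(pm2, genes)
  expect_true(r2$obligate); expect_equal(r2$mode, "complementary")
  expect_length(r2$covering_partners, 0L)

  pm3 <- pm; pm3["p1", 1:5] <- "present"
  r3 <- detect_obligate_partners(pm3, genes)
  expect_false(r3$obligate); expect_equal(r3$mode, "none")
  expect_equal(r3$failing_samples, "S6")

  none <- detect_obligate_partners(pm, stats::setNames(rep("PSG", 3), rownames(pm)))
  expect_false(none$applicable)
})
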