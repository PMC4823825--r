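# Synthetic multi-region cohort generator with known ground truth.
#
# A cohort is one patient: a rooted clone tree (normal root, unique truncal
# tumor clone), mutations assigned to clones, per-region clonal mixing
# proportions, arm-level CNV events, and read counts sampled binomially at a
# chosen depth. Germline het-site B-allele counts and arm coverage are
# simulated at exome-like depth so the copy-number caller can be exercised.

# ---- tree helpers (parent vector; 0 = normal root, clones 1..K) -------------

# logical K x K matrix: subtree_mask[e, c] is TRUE when clone c lies in the
# subtree rooted at clone e (e is an ancestor of c, or c itself)
subtree_mask <- function(parent) {
  k <- length(parent)
  m <- diag(k) > 0
  for (c in seq_len(k)) {
    p <- parent[c]
    while (p != 0L) {
      m[p, c] <- TRUE
      p <- parent[p]
    }
  }
  m
}

#' Simulate a random clone-tree skeleton
#'
#' Builds a rooted tree over `n_clones` tumor clones beneath a normal root.
#' Clone 1 is truncal (the unique child of the normal root); each subsequent
#' clone attaches uniformly at random to one of the clones already present.
#'
#' @param config A [sim_config()].
#' @return List with `parent` (integer vector, `parent[i]` is the parent clone
#'   of clone `i`, 0 meaning the normal root) and `n_clones`.
#' @export
simulate_clone_tree <- function(config) {
  validate_sim_config(config)
  k <- config$n_clones
  with_seed(config$seed, {
    parent <- integer(k)
    parent[1] <- 0L
    if (k >= 2L) {
      for (i in 2:k) parent[i] <- sample.int(i - 1L, 1L)
    }
    list(parent = parent, n_clones = k)
  })
}

#' Assign mutations and driver labels to clones
#'
#' Each clone receives `mutations_per_clone` anonymous passenger mutations.
#' A driver template places named driver-gene mutations on specific clones:
#' role `"truncal"` targets clone 1, role `"subclonal"` a random non-truncal
#' clone, and an integer role a specific clone id. The classical template is
#' an oncohistone-like truncal driver plus an obligate truncal partner.
#'
#' @param tree Output of [simulate_clone_tree()].
#' @param config A [sim_config()].
#' @param driver_template List of `list(gene =, role =)` entries (or NULL).
#' @return `data.frame` with columns `mutation_id`, `gene`, `clone`,
#'   `driver_label` (`main_driver`/`accessory_driver`/`passenger`), `arm`,
#'   `chrom`, `pos`.
#' @export
assign_mutations <- function(tree, config, driver_template = NULL) {
  k <- tree$n_clones
  rows <- list()
  with_seed(config$seed + 1L, {
    idx <- 0L
    for (tmpl in driver_template %||% list()) {
      gene <- tmpl$gene
      role <- tmpl$role
      clone <- if (identical(role, "truncal")) 1L
      else if (identical(role, "subclonal")) {
        if (k < 2L) stop("template references a subclone but the tree has none", call. = FALSE)
        sample(2:k, 1L)
      } else {
        cl <- as.integer(role)
        if (is.na(cl) || cl < 1L || cl > k)
          stop(sprintf("template role '%s' references an absent clone", as.character(role)), call. = FALSE)
        cl
      }
      idx <- idx + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        mutation_id = sprintf("M%04d", idx), gene = gene, clone = clone,
        driver_label = if (clone == 1L) "main_driver" else "accessory_driver",
        stringsAsFactors = FALSE)
    }
    for (cl in seq_len(k)) {
      n <- config$mutations_per_clone
      if (n > 0L) {
        ids <- sprintf("M%04d", idx + seq_len(n))
        idx <- idx + n
        rows[[length(rows) + 1L]] <- data.frame(
          mutation_id = ids, gene = sprintf("PSG_%s", ids), clone = cl,
          driver_label = "passenger", stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    if (is.null(df) || nrow(df) == 0L)
      stop("no mutations to assign: empty template and mutations_per_clone = 0", call. = FALSE)
    df$arm <- sprintf("arm%02d", sample.int(config$n_arms, nrow(df), replace = TRUE))
    df$chrom <- sub("arm", "c", df$arm)
    df$pos <- seq_len(nrow(df)) * 1000L
    rownames(df) <- NULL
    df
  })
}

#' Simulate per-region clonal mixing proportions
#'
#' For each region a tumor purity is drawn uniformly from
#' `config$purity_range` and split across tumor clones with a symmetric
#' Dirichlet draw; the remainder is the normal-cell component. Each
#' non-truncal clone is independently zeroed with probability
#' `config$dropout_prob`, producing regions that lack some subclones.
#'
#' @inheritParams assign_mutations
#' @return `(n_clones + 1) x n_regions` matrix of mixing proportions; the last
#'   row is the normal component; columns sum to 1.
#' @export
simulate_region_mixtures <- function(tree, config) {
  k <- tree$n_clones
  with_seed(config$seed + 2L, {
    mix <- matrix(0, nrow = k + 1L, ncol = config$n_regions,
                  dimnames = list(c(paste0("clone", seq_len(k)), "normal"),
                                  paste0("R", seq_len(config$n_regions))))
    for (r in seq_len(config$n_regions)) {
      purity <- stats::runif(1, config$purity_range[1], config$purity_range[2])
      w <- rdirichlet1(k, config$dirichlet_alpha)
      if (k >= 2L && config$dropout_prob > 0) {
        drop <- stats::runif(k - 1L) < config$dropout_prob
        w[-1][drop] <- 0
      }
      w <- w / sum(w)
      mix[seq_len(k), r] <- purity * w
      mix[k + 1L, r] <- 1 - purity
    }
    stopifnot(all(abs(colSums(mix) - 1) < 1e-12), all(mix >= 0))
    mix
  })
}

# Draw arm-level CNV events. Poisson(cnv_rate) events per clone; each event
# claims an arm not already affected (one event per arm genome-wide keeps the
# allele bookkeeping single-event). With cnv_truncal_only all events move to
# the truncal clone.
simulate_cnv_assignment <- function(tree, config) {
  with_seed(config$seed + 3L, {
    events <- data.frame(clone = integer(), arm = character(), event = character(),
                         stringsAsFactors = FALSE)
    free_arms <- sprintf("arm%02d", seq_len(config$n_arms))
    for (cl in seq_len(tree$n_clones)) {
      n <- stats::rpois(1, config$cnv_rate)
      n <- min(n, length(free_arms))
      if (n > 0L) {
        arms <- sample(free_arms, n)
        free_arms <- setdiff(free_arms, arms)
        types <- sample(c("duplication", "deletion", "cn_loh"), n, replace = TRUE)
        target <- if (config$cnv_truncal_only) 1L else cl
        events <- rbind(events, data.frame(clone = target, arm = arms, event = types,
                                           stringsAsFactors = FALSE))
      }
    }
    events
  })
}

# ---- expected VAF -----------------------------------------------------------

# Per-region expected VAF for every (clone, arm) combination.
# Returns a list of K x n_arms matrices, one per region.
expected_vaf_table <- function(tumor) {
  cfg <- tumor$config
  k <- tumor$tree$n_clones
  arms <- sprintf("arm%02d", seq_len(cfg$n_arms))
  sub <- subtree_mask(tumor$tree$parent)
  # copies per cell and mutant multiplicity, per clone x arm
  tot <- matrix(2, nrow = k, ncol = cfg$n_arms, dimnames = list(NULL, arms))
  mult <- matrix(1, nrow = k, ncol = cfg$n_arms, dimnames = list(NULL, arms))
  if (nrow(tumor$cnv) > 0L) {
    for (i in seq_len(nrow(tumor$cnv))) {
      e <- tumor$cnv[i, ]
      hit <- sub[e$clone, ]  # clones carrying the event
      a <- e$arm
      if (e$event == "duplication") {
        tot[hit, a] <- 3
        mult[hit, a] <- if (cfg$mutant_homolog_duplicated) 2 else 1
      } else if (e$event == "deletion") {
        tot[hit, a] <- 1
        mult[hit, a] <- if (cfg$mutant_allele_retained) 1 else 0
      } else if (e$event == "cn_loh") {
        tot[hit, a] <- 2
        mult[hit, a] <- if (cfg$mutant_allele_retained) 2 else 0
      } else stop("unknown CNV event: ", e$event, call. = FALSE)
    }
  }
  regions <- colnames(tumor$mixtures)
  out <- vector("list", length(regions))
  names(out) <- regions
  for (r in seq_along(regions)) {
    m <- tumor$mixtures[seq_len(k), r]
    m_norm <- tumor$mixtures[k + 1L, r]
    denom <- as.numeric(m %*% tot) + 2 * m_norm            # per arm
    vaf <- matrix(NA_real_, nrow = k, ncol = cfg$n_arms, dimnames = list(NULL, arms))
    for (q in seq_len(k)) {
      carried <- sub[q, ]                                   # cells bearing the mutation
      num <- as.numeric((m * carried) %*% mult)             # per arm
      if (any(denom <= 0)) stop("undefined VAF: total copy weight is zero", call. = FALSE)
      vaf[q, ] <- num / denom
    }
    out[[r]] <- vaf
  }
  out
}

#' Expected variant allele fraction of a mutation in a region
#'
#' Closed form: mutant copies carried by the clones at/below the mutation's
#' clone, weighted by the region's mixing proportions, divided by total locus
#' copies (normal cells contribute two wild-type copies). Arm-level CNV events
#' modify copy number and mutant multiplicity for the clones that carry them:
#' duplication gives 3 copies (2 mutant when the mutant homolog is duplicated,
#' the default), deletion 1 copy, copy-neutral LOH 2 copies (both mutant when
#' the mutant haplotype is retained, the default).
#'
#' @param tumor A ground-truth tumor as built by [simulate_cohort()] (element
#'   `truth`).
#' @param mutation_id Mutation identifier present in `tumor$mutations`.
#' @param region Region/sample identifier (column of `tumor$mixtures`).
#' @return Expected VAF in \[0, 1\].
#' @export
expected_vaf <- function(tumor, mutation_id, region) {
  mu <- tumor$mutations[tumor$mutations$mutation_id == mutation_id, ]
  if (nrow(mu) != 1L) stop("unknown mutation_id: ", mutation_id, call. = FALSE)
  if (!region %in% colnames(tumor$mixtures)) stop("unknown region: ", region, call. = FALSE)
  tab <- expected_vaf_table(tumor)
  unname(tab[[region]][mu$clone, mu$arm])
}

#' Sample read counts at a given expected VAF
#'
#' Depth is Poisson around `mean_depth`; the alternate count is binomial at
#' the expected VAF. Vectorized over `vaf`.
#'
#' @param vaf Expected variant allele fraction(s) in \[0,1\].
#' @param mean_depth Mean sequencing depth (> 0).
#' @param seed Integer seed (NULL to use the current RNG stream).
#' @return `data.frame` with `ref_count`, `alt_count`.
#' @export
simulate_read_counts <- function(vaf, mean_depth, seed = NULL) {
  if (any(vaf < 0 | vaf > 1)) stop("expected VAF must lie in [0,1]", call. = FALSE)
  if (mean_depth <= 0) stop("mean_depth must be > 0", call. = FALSE)
  with_seed(seed, {
    depth <- stats::rpois(length(vaf), mean_depth)
    alt <- stats::rbinom(length(vaf), depth, vaf)
    data.frame(ref_count = depth - alt, alt_count = alt)
  })
}

# ---- germline het sites and arm coverage ------------------------------------

#' Simulate germline het-site B-allele counts and arm coverage for one region
#'
#' On a neutral arm the expected B-allele frequency is 0.5. An arm event at
#' aggregate clonal fraction f shifts the allele on the affected homolog:
#' duplication to (1+f)/(2+f) (other homolog 1/(2+f)), deletion to
#' (1-f)/(2-f) (retained 1/(2-f)), copy-neutral LOH to (1±f)/2. Which parental
#' homolog carries the event is randomized per site, so the folded deviation
#' |BAF - 0.5| is the invariant signal. Site depth is Poisson at
#' `wes_depth x mean copy number / 2`; arm coverage means for tumor (from the
#' simulated sites) and a matched normal are also returned.
#'
#' @param tumor Ground-truth tumor (element `truth` of [simulate_cohort()]).
#' @param region Region identifier.
#' @param config The cohort's [sim_config()].
#' @param seed Integer seed.
#' @return List with `sites` (`data.frame`: sample_id, arm, chrom, pos,
#'   a_count, b_count) and `coverage` (`data.frame`: sample_id, arm,
#'   tumor_mean, normal_mean).
#' @export
simulate_baf_sites <- function(tumor, region, config, seed = NULL) {
  k <- tumor$tree$n_clones
  sub <- subtree_mask(tumor$tree$parent)
  m <- tumor$mixtures[seq_len(k), region]
  arms <- sprintf("arm%02d", seq_len(config$n_arms))
  with_seed(seed, {
    site_rows <- vector("list", length(arms))
    cov_rows <- vector("list", length(arms))
    for (ai in seq_along(arms)) {
      a <- arms[ai]
      ev <- tumor$cnv[tumor$cnv$arm == a, , drop = FALSE]
      f <- if (nrow(ev) == 1L) sum(m[sub[ev$clone, ]]) else 0
      if (nrow(ev) == 1L && f > 0) {
        type <- ev$event
        if (type == "duplication") {
          baf_hit <- (1 + f) / (2 + f); cn <- 2 + f
        } else if (type == "deletion") {
          baf_hit <- (1 - f) / (2 - f); cn <- 2 - f
        } else {                       # cn_loh
          baf_hit <- (1 + f) / 2; cn <- 2
        }
      } else {
        baf_hit <- 0.5; cn <- 2
      }
      n <- config$het_sites_per_arm
      depth <- stats::rpois(n, config$wes_depth * cn / 2)
      # randomize which parental allele ("B") sits on the affected homolog
      eb <- ifelse(stats::runif(n) < 0.5, baf_hit, 1 - baf_hit)
      b <- stats::rbinom(n, depth, eb)
      site_rows[[ai]] <- data.frame(
        sample_id = region, arm = a, chrom = sub("arm", "c", a),
        pos = seq_len(n) * 500L, a_count = depth - b, b_count = b,
        stringsAsFactors = FALSE)
      cov_rows[[ai]] <- data.frame(
        sample_id = region, arm = a, tumor_mean = mean(depth),
        normal_mean = mean(stats::rpois(n, config$wes_depth)),
        stringsAsFactors = FALSE)
    }
    list(sites = do.call(rbind, site_rows), coverage = do.call(rbind, cov_rows))
  })
}

# ---- cohort orchestration ---------------------------------------------------

#' Simulate a complete multi-region cohort with ground truth
#'
#' Runs the whole generator: clone tree, mutation assignment (with an optional
#' driver template), region mixtures, CNV assignment, expected VAFs, variant
#' read counts, and germline het-site/coverage data. Fully deterministic given
#' the configuration (which includes the seed).
#'
#' @param config A [sim_config()].
#' @param driver_template Passed to [assign_mutations()].
#' @return Object of class `sim_cohort`: list with `truth` (tree, mutations,
#'   mixtures, cnv, config), `counts` (long `data.frame` of per-sample
#'   ref/alt counts), `het_sites`, `arm_coverage`, and `expected_vaf`
#'   (mutation x region matrix).
#' @examples
#' co <- simulate_cohort(sim_config(n_clones = 2, n_regions = 3,
#'                                  mutations_per_clone = 5, mean_depth = 100))
#' head(co$counts)
#' @export
simulate_cohort <- function(config, driver_template = NULL) {
  validate_sim_config(config)
  tree <- simulate_clone_tree(config)
  mutations <- assign_mutations(tree, config, driver_template)
  mixtures <- simulate_region_mixtures(tree, config)
  cnv <- simulate_cnv_assignment(tree, config)
  truth <- list(tree = tree, mutations = mutations, mixtures = mixtures,
                cnv = cnv, config = config)
  class(truth) <- "true_tumor"
  build_cohort_counts(truth)
}

# Sample counts + het sites for an already-built ground-truth tumor.
build_cohort_counts <- function(truth) {
  config <- truth$config
  vaf_tab <- expected_vaf_table(truth)
  regions <- colnames(truth$mixtures)
  evaf <- sapply(regions, function(r)
    vaf_tab[[r]][cbind(truth$mutations$clone, match(truth$mutations$arm, colnames(vaf_tab[[r]])))])
  evaf <- matrix(evaf, nrow = nrow(truth$mutations),
                 dimnames = list(truth$mutations$mutation_id, regions))
  counts <- with_seed(config$seed + 4L, {
    rows <- vector("list", length(regions))
    for (r in seq_along(regions)) {
      rc <- simulate_read_counts(evaf[, r], config$mean_depth)
      rows[[r]] <- data.frame(
        mutation_id = truth$mutations$mutation_id, gene = truth$mutations$gene,
        chrom = truth$mutations$chrom, pos = truth$mutations$pos,
        arm = truth$mutations$arm, sample_id = regions[r],
        ref_count = rc$ref_count, alt_count = rc$alt_count,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  het <- with_seed(config$seed + 5L, {
    per_region <- lapply(regions, function(r) simulate_baf_sites(truth, r, config))
    list(sites = do.call(rbind, lapply(per_region, `[[`, "sites")),
         coverage = do.call(rbind, lapply(per_region, `[[`, "coverage")))
  })
  rownames(counts) <- NULL
  out <- list(truth = truth, counts = counts, het_sites = het$sites,
              arm_coverage = het$coverage, expected_vaf = evaf)
  class(out) <- "sim_cohort"
  out
}

#' A fixed two-subclone branching fixture (oncohistone trunk, complementary partners)
#'
#' Builds the canonical branching pattern seen in tumors carrying a truncal
#' oncohistone mutation with two complementary partner subclones: the trunk
#' carries an H3 K27M-like mutation; one sibling subclone carries a TP53-like
#' mutation present in the first half of the regions, the other a PPM1D-like
#' mutation present in the second half. Mixing proportions are fixed
#' (truncal 0.3, active subclone 0.5, normal 0.2); only the read sampling is
#' random.
#'
#' @param seed Integer seed for the read sampling.
#' @param n_regions Even number of regions (default 6).
#' @param mean_depth Sequencing depth (default 4000, amplicon-like).
#' @param passengers_per_clone Passenger mutations per clone (default 3).
#' @return A `sim_cohort` object.
#' @export
branching_partner_cohort <- function(seed = 1, n_regions = 6, mean_depth = 4000,
                                     passengers_per_clone = 3) {
  stopifnot(n_regions >= 2, n_regions %% 2 == 0)
  config <- sim_config(n_clones = 3, n_regions = n_regions,
                       mutations_per_clone = passengers_per_clone,
                       mean_depth = mean_depth, cnv_rate = 0, dropout_prob = 0,
                       seed = as.integer(seed))
  tree <- list(parent = c(0L, 1L, 1L), n_clones = 3L)
  drv <- data.frame(
    mutation_id = c("M0001", "M0002", "M0003"),
    gene = c("H3F3A", "TP53", "PPM1D"), clone = 1:3,
    driver_label = c("main_driver", "accessory_driver", "accessory_driver"),
    stringsAsFactors = FALSE)
  psg <- NULL
  if (passengers_per_clone > 0) {
    ids <- sprintf("M%04d", 3L + seq_len(3 * passengers_per_clone))
    psg <- data.frame(mutation_id = ids, gene = paste0("PSG_", ids),
                      clone = rep(1:3, each = passengers_per_clone),
                      driver_label = "passenger", stringsAsFactors = FALSE)
  }
  mutations <- rbind(drv, psg)
  mutations$arm <- sprintf("arm%02d", rep_len(seq_len(config$n_arms), nrow(mutations)))
  mutations$chrom <- sub("arm", "c", mutations$arm)
  mutations$pos <- seq_len(nrow(mutations)) * 1000L
  half <- n_regions / 2
  mix <- matrix(0, nrow = 4, ncol = n_regions,
                dimnames = list(c("clone1", "clone2", "clone3", "normal"),
                                paste0("R", seq_len(n_regions))))
  mix["clone1", ] <- 0.3
  mix["clone2", seq_len(half)] <- 0.5
  mix["clone3", half + seq_len(half)] <- 0.5
  mix["normal", ] <- 1 - colSums(mix[1:3, , drop = FALSE])
  truth <- list(tree = tree, mutations = mutations, mixtures = mix,
                cnv = data.frame(clone = integer(), arm = character(),
                                 event = character(), stringsAsFactors = FALSE),
                config = config)
  class(truth) <- "true_tumor"
  build_cohort_counts(truth)
}

# ---- on-disk round trip -----------------------------------------------------

#' Write a simulated cohort to disk
#'
#' Emits the variant count TSV, het-site TSV, arm coverage TSV, and a ground
#' truth JSON (tree, mixtures, assignments, CNV events) in the formats the IO
#' module reads back.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir, call. = FALSE)
  paths <- c(counts = file.path(dir, "variant_counts.tsv"),
             het = file.path(dir, "het_sites.tsv"),
             coverage = file.path(dir, "arm_coverage.tsv"),
             truth = file.path(dir, "truth.json"))
  utils::write.table(cohort$counts, paths["counts"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$het_sites, paths["het"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$arm_coverage, paths["coverage"], sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- cohort$truth
  truth_json <- list(
    parent = tr$tree$parent,
    mutations = tr$mutations,
    mixtures = list(rows = rownames(tr$mixtures), cols = colnames(tr$mixtures),
                    values = unname(as.data.frame(tr$mixtures))),
    cnv = tr$cnv)
  jsonlite::write_json(truth_json, paths["truth"], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}

#' Read back the ground-truth JSON written by [write_cohort()]
#' @param path Path to `truth.json`.
#' @return List with `parent`, `mutations`, `mixtures` (matrix), `cnv`.
#' @export
read_cohort_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mix <- as.matrix(as.data.frame(x$mixtures$values))
  dimnames(mix) <- list(x$mixtures$rows, x$mixtures$cols)
  cnv <- if (length(x$cnv) == 0) {
    data.frame(clone = integer(), arm = character(), event = character(),
               stringsAsFactors = FALSE)
  } else as.data.frame(x$cnv)
  list(parent = as.integer(x$parent), mutations = as.data.frame(x$mutations),
       mixtures = mix, cnv = cnv)
}

#' Random noiseless clade-frequency instance with a known tree
#'
#' Draws a random clone tree and region mixtures and returns exact (noise
#' free) clade frequencies. With `identifiable = TRUE` (default) mixtures are
#' redrawn until (i) the true tree is the unique candidate feasible within
#' the baseline sum-condition tolerance, (ii) every ancestor pair separates
#' by more than `margin` in at least one region, and (iii) every
#' non-ancestral pair crosses by more than `margin` in both directions.
#' Without these conditions no method can distinguish a chain from siblings
#' whenever the pigeonhole never binds, nor ancestry from chance dominance;
#' rejection makes the instance carry the information the recovery
#' properties assert.
#'
#' @param n_clones Number of clones (1..7).
#' @param n_regions Number of regions.
#' @param seed Integer seed.
#' @param identifiable Rejection-sample for identifiability (default TRUE).
#' @param margin Separation margin used by the rejection rules (default
#'   0.03, comfortably above the 0.02 baseline tolerance).
#' @param purity_range Per-region purity bounds.
#' @param max_tries Redraws before giving up (error).
#' @return List: `parent`, `freq` (clones x regions clade frequencies),
#'   `mixing` ((clones+1) x regions incl. normal).
#' @export
random_noiseless_instance <- function(n_clones, n_regions, seed,
                                      identifiable = TRUE, margin = 0.03,
                                      purity_range = c(0.6, 0.95),
                                      max_tries = 500) {
  k <- as.integer(n_clones)
  stopifnot(k >= 1L, n_regions >= 2L)
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      parent <- integer(k)
      if (k >= 2L) for (i in 2:k) parent[i] <- sample.int(i - 1L, 1L)
      A <- ancestor_matrix(parent)
      m <- matrix(0, k, n_regions)
      for (r in seq_len(n_regions)) {
        purity <- stats::runif(1, purity_range[1], purity_range[2])
        m[, r] <- purity * rdirichlet1(k, 1)
      }
      Fm <- A %*% m
      if (!identifiable) return(build_instance(parent, Fm, m))
      anc <- A > 0; diag(anc) <- FALSE
      ok <- TRUE
      for (a in seq_len(k)) for (b in seq_len(k)) {
        if (a >= b) next
        if (anc[a, b] || anc[b, a]) {
          hi <- if (anc[a, b]) Fm[a, ] - Fm[b, ] else Fm[b, ] - Fm[a, ]
          if (max(hi) <= margin) { ok <- FALSE; break }
        } else {
          if (max(Fm[a, ] - Fm[b, ]) <= margin ||
              max(Fm[b, ] - Fm[a, ]) <= margin) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      # the true tree must be the unique candidate feasible within tolerance
      trees <- enumerate_trees(k)
      n_feas <- 0L
      for (t in seq_len(nrow(trees))) {
        p <- trees[t, ]
        feas <- TRUE
        for (r in seq_len(n_regions)) {
          f <- Fm[, r]
          cs <- rep(0, k)
          for (u in seq_len(k)) if (p[u] != 0L) cs[p[u]] <- cs[p[u]] + f[u]
          if (any(f - cs < -0.02)) { feas <- FALSE; break }
        }
        if (feas) n_feas <- n_feas + 1L
        if (n_feas > 1L) break
      }
      if (n_feas == 1L) return(build_instance(parent, Fm, m))
    }
    stop("no identifiable instance found in ", max_tries, " tries", call. = FALSE)
  })
}

build_instance <- function(parent, Fm, m) {
  k <- length(parent)
  dimnames(Fm) <- list(paste0("clone", seq_len(k)), paste0("R", seq_len(ncol(Fm))))
  mix <- rbind(m, 1 - colSums(m))
  dimnames(mix) <- list(c(rownames(Fm), "normal"), colnames(Fm))
  list(parent = parent, freq = Fm, mixing = mix)
}
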