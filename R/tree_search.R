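# Clone-tree search: exhaustive enumeration of rooted labeled trees over the
# mutation clusters (normal root on top), penalized-likelihood scoring under
# the parent-child sum condition, deterministic model selection, and tree
# serialization. Exhaustive search is feasible because k^(k-1) trees exist
# for k clusters; beyond k = 7 a heuristic would be needed and we stop with
# an informative error instead.

# Decode one Pruefer sequence over n labeled nodes into a parent vector
# rooted at node `root`.
decode_prufer <- function(seq, n, root = n) {
  deg <- tabulate(seq, n) + 1L
  edges <- matrix(0L, nrow = n - 1L, ncol = 2L)
  ptr <- 0L
  leaves <- which(deg == 1L)
  for (s in seq) {
    l <- leaves[1L]
    ptr <- ptr + 1L
    edges[ptr, ] <- c(l, s)
    deg[l] <- 0L
    deg[s] <- deg[s] - 1L
    leaves <- leaves[-1L]
    if (deg[s] == 1L) leaves <- sort(c(leaves, s))
  }
  last <- which(deg == 1L)
  edges[n - 1L, ] <- last
  # orient away from root by BFS
  adj <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  parent <- integer(n)
  parent[root] <- 0L
  queue <- root
  seen <- logical(n); seen[root] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) if (!seen[w]) {
      seen[w] <- TRUE
      parent[w] <- v
      queue <- c(queue, w)
    }
  }
  parent
}

#' Enumerate all rooted labeled clone trees over k clusters
#'
#' Every tumor descends from a single founding clone, so the normal root has
#' exactly one child: candidate trees are the rooted labeled trees over the k
#' clusters (Cayley: k^(k-2) labeled trees, each rootable at any of its k
#' nodes, k^(k-1) in total), with the normal root attached above the chosen
#' truncal cluster. Generated by decoding every Pruefer sequence on k labeled
#' nodes and orienting from each root in turn.
#'
#' @param k Number of clusters (1 <= k <= `k_tree_max`).
#' @param k_tree_max Exhaustive-search ceiling (default 7).
#' @return Integer matrix, one row per tree; entry `[t, i]` is the parent of
#'   cluster i in tree t (0 = normal root; exactly one cluster per tree has
#'   parent 0).
#' @export
enumerate_trees <- function(k, k_tree_max = 7) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > k_tree_max)
    stop("k = ", k, " exceeds the exhaustive-search ceiling (", k_tree_max,
         "); reduce k_max in clustering or use a heuristic search", call. = FALSE)
  if (k == 1L) return(matrix(0L, nrow = 1L, ncol = 1L))
  seqs <- if (k == 2L) matrix(integer(0), nrow = 1L, ncol = 0L)
  else as.matrix(expand.grid(rep(list(seq_len(k)), k - 2L)))
  out <- matrix(0L, nrow = nrow(seqs) * k, ncol = k)
  row <- 0L
  for (t in seq_len(nrow(seqs))) {
    for (r in seq_len(k)) {
      row <- row + 1L
      out[row, ] <- decode_prufer(as.integer(seqs[t, ]), k, root = r)
    }
  }
  out
}

# ancestor-or-self indicator matrix from a parent vector: A[v, u] = 1 when v
# is an ancestor of u or v == u, so clade frequencies are f = A %*% m.
ancestor_matrix <- function(parent) {
  k <- length(parent)
  A <- diag(k)
  for (u in seq_len(k)) {
    p <- parent[u]
    while (p != 0L) { A[p, u] <- 1; p <- parent[p] }
  }
  A
}

# Lawson-Hanson nonnegative least squares: min ||C x - d||, x >= 0.
# Problems here are tiny (<= 8 unknowns) but can be badly scaled by the
# sum-constraint penalty row, so the iteration budget is generous.
nnls_lh <- function(C, d, tol = 1e-10, maxit = 500) {
  n <- ncol(C)
  x <- rep(0, n)
  P <- logical(n)
  w <- as.numeric(crossprod(C, d))
  it <- 0L
  while (any(!P) && it < maxit) {
    free <- which(!P)
    if (max(w[free]) <= tol) break
    P[free[which.max(w[free])]] <- TRUE
    repeat {
      it <- it + 1L
      s <- rep(0, n)
      s[P] <- qr.solve(C[, P, drop = FALSE], d)
      if (all(s[P] > tol)) { x <- s; break }
      q <- which(P & s <= tol)
      alpha <- min(x[q] / (x[q] - s[q] + 1e-300))
      x <- pmax(0, x + alpha * (s - x))
      P <- P & x > tol
      if (it >= maxit) { x <- pmax(s, 0); break }
    }
    w <- as.numeric(crossprod(C, d - C %*% x))
  }
  x
}

# Project observed cluster frequencies (one sample) onto the feasible set
# {f = A m, m >= -tol, sum(m) <= 1} by least squares; `tol` is the per-node
# sum-condition tolerance (sampling noise allowance). Within tolerance the
# projection is the identity; otherwise NNLS over (m, m_normal) with a
# heavily weighted sum-to-one row gives the strict projection.
project_sample <- function(f, parent, A = ancestor_matrix(parent), tol = 0) {
  k <- length(f)
  tol <- rep_len(tol, k)
  child_sum <- rep(0, k)
  for (u in seq_len(k)) if (parent[u] != 0L) child_sum[parent[u]] <- child_sum[parent[u]] + f[u]
  m <- f - child_sum
  root_sum <- sum(f[parent == 0L])
  if (all(m >= -tol - 1e-9) && root_sum <= 1 + 1e-9)
    return(list(freq = f, mixing = pmax(m, 0), dist = 0))
  rho <- 1e6
  C <- rbind(cbind(A, 0), sqrt(rho))
  d <- c(f, sqrt(rho))
  x <- nnls_lh(C, d)
  mm <- x[seq_len(k)]
  proj <- as.numeric(A %*% mm)
  list(freq = proj, mixing = mm, dist = sqrt(sum((proj - f)^2)))
}

#' Score one candidate clone tree
#'
#' Per sample, cluster frequencies are projected onto the feasible set of the
#' candidate (parent frequency at least the sum of its children, everything
#' in \[0,1\], total tumor fraction at most 1) by constrained least squares.
#' The log-likelihood is the binomial likelihood of the member counts at the
#' projected frequencies; the violation total is the summed projection
#' distance; the score is `loglik - lambda * violation_total`.
#'
#' @param parent Integer parent vector over clusters (0 = normal root).
#' @param clusters A `mutation_clusters`.
#' @param ccf The `ccf_matrix` the clusters were built from.
#' @param lambda Constraint penalty weight (default 100).
#' @param tol_base Depth-independent part of the sum-condition tolerance;
#'   the full per-node tolerance is `tol_base + 2 x pooled SE` of the
#'   parent-minus-children frequency difference (default 0.02).
#' @return List: `loglik`, `violation_total`, `score`, `freq` (projected
#'   k x samples), `mixing` ((k+1) x samples incl. normal).
#' @export
score_tree <- function(parent, clusters, ccf, lambda = 100, tol_base = 0.02) {
  Fm <- clusters$ccf_means
  k <- nrow(Fm); S <- ncol(Fm)
  A <- ancestor_matrix(parent)
  se <- clusters$se_means %||% matrix(0, k, S)
  tolm <- sum_condition_tolerance(parent, se, tol_base)
  freq <- matrix(0, k, S, dimnames = dimnames(Fm))
  mixing <- matrix(0, k + 1L, S,
                   dimnames = list(c(rownames(Fm), "normal"), colnames(Fm)))
  viol <- 0
  for (s in seq_len(S)) {
    pr <- project_sample(Fm[, s], parent, A, tol = tolm[, s])
    freq[, s] <- pr$freq
    mixing[seq_len(k), s] <- pr$mixing
    viol <- viol + pr$dist
  }
  mixing[k + 1L, ] <- pmax(0, 1 - colSums(mixing[seq_len(k), , drop = FALSE]))
  ll <- 0
  if (!is.null(ccf$alt)) {
    assign <- clusters$assignment
    rows <- match(names(assign), ccf$mutations)
    for (s in seq_len(S)) {
      p <- clamp_prob(freq[assign, s] * ccf$purity[s] / 2)
      a <- ccf$alt[rows, s]; d <- ccf$dep[rows, s]
      ok <- !is.na(d) & !ccf$missing[rows, s]
      ll <- ll + sum(stats::dbinom(a[ok], d[ok], p[ok], log = TRUE))
    }
  }
  list(loglik = ll, violation_total = viol, score = ll - lambda * viol,
       freq = freq, mixing = mixing)
}

# per-node, per-sample tolerance on the sum condition: tol_base plus twice
# the pooled SE of (parent frequency - sum of children frequencies)
sum_condition_tolerance <- function(parent, se, tol_base) {
  k <- length(parent)
  pooled2 <- se^2
  for (u in seq_len(k)) if (parent[u] != 0L)
    pooled2[parent[u], ] <- pooled2[parent[u], ] + se[u, ]^2
  tol_base + 2 * sqrt(pooled2)
}

# number of (edge, sample) combinations where the observed child sum exceeds
# the parent frequency beyond tolerance (tie-break statistic)
count_violating_edges <- function(parent, Fm, se = NULL, tol_base = 0.02) {
  k <- length(parent)
  se <- se %||% matrix(0, k, ncol(Fm))
  tolm <- sum_condition_tolerance(parent, se, tol_base)
  total <- 0L
  for (s in seq_len(ncol(Fm))) {
    f <- Fm[, s]
    child_sum <- rep(0, k)
    for (u in seq_len(k)) if (parent[u] != 0L) child_sum[parent[u]] <- child_sum[parent[u]] + f[u]
    total <- total + sum(f < child_sum - tolm[, s])
    if (sum(f[parent == 0L]) > 1 + tol_base) total <- total + 1L
  }
  total
}

#' Fit the clone tree by exhaustive penalized-likelihood search
#'
#' Scores every tree from [enumerate_trees()] and returns the best. Exact
#' score ties are broken by fewer violating edges on the observed
#' frequencies, then by preferring the maximally nested tree (most ancestor
#' relations: a spurious nesting must survive the sum condition in every
#' sample, whereas a spurious flat placement is never falsifiable), then by
#' the lexicographically smallest parent vector, so the result is
#' deterministic; the size of the tied set is reported.
#'
#' Mixing proportions per sample are `freq(v) - sum(freq(children))` on the
#' projected frequencies (floored at zero) and the normal component is one
#' minus the total tumor fraction.
#'
#' @inheritParams score_tree
#' @param k_tree_max Exhaustive ceiling passed to [enumerate_trees()].
#' @return Object of class `clone_tree`: `parent`, `freq`, `mixing`,
#'   `loglik`, `violation_total`, `score`, `n_ties`, `clusters`, `samples`.
#' @export
fit_tree <- function(ccf, clusters, lambda = 100, k_tree_max = 7, tol_base = 0.02) {
  if (is.null(clusters) || clusters$k < 1L) stop("empty cluster set", call. = FALSE)
  trees <- enumerate_trees(clusters$k, k_tree_max)
  scores <- vector("list", nrow(trees))
  best_score <- -Inf
  for (t in seq_len(nrow(trees))) {
    sc <- score_tree(trees[t, ], clusters, ccf, lambda, tol_base)
    scores[[t]] <- sc
    if (sc$score > best_score) best_score <- sc$score
  }
  tied <- which(vapply(scores, function(s) s$score >= best_score - 1e-9, logical(1)))
  if (length(tied) > 1L) {
    nv <- vapply(tied, function(t)
      count_violating_edges(trees[t, ], clusters$ccf_means, clusters$se_means, tol_base),
      integer(1))
    tied <- tied[nv == min(nv)]
  }
  if (length(tied) > 1L) {
    nest <- vapply(tied, function(t) sum(ancestor_matrix(trees[t, ])), numeric(1))
    tied <- tied[nest == max(nest)]
  }
  if (length(tied) > 1L) {
    ordmat <- trees[tied, , drop = FALSE]
    tied <- tied[do.call(order, as.data.frame(ordmat))]
  }
  pick <- tied[1L]
  sc <- scores[[pick]]
  out <- list(parent = trees[pick, ], k = clusters$k, freq = sc$freq,
              mixing = sc$mixing, loglik = sc$loglik,
              violation_total = sc$violation_total, score = sc$score,
              n_ties = length(tied), clusters = clusters,
              samples = colnames(clusters$ccf_means))
  class(out) <- "clone_tree"
  out
}

#' Collapse low-contribution nodes for display
#'
#' Nodes whose mixing proportion is below `threshold` in every sample are
#' collapsed into their nearest surviving ancestor (trajectory display rule,
#' default contribution threshold 0.05); the fitted tree itself is unchanged.
#'
#' @param tree A `clone_tree`.
#' @param threshold Minimum mixing proportion a node must reach in at least
#'   one sample to be displayed (default 0.05; 0 keeps everything).
#' @return List: `fitted` (the input), `display_parent` (parent vector over
#'   surviving nodes, named by cluster), `node_map` (cluster -> surviving
#'   node id, 0 = normal), `display_mixing` (aggregated mixing incl. normal).
#' @export
prune_tree <- function(tree, threshold = 0.05) {
  k <- tree$k
  own_max <- apply(tree$mixing[seq_len(k), , drop = FALSE], 1, max)
  survive <- own_max >= threshold
  node_map <- integer(k)
  nearest_survivor <- function(v) {
    p <- v
    while (p != 0L && !survive[p]) p <- tree$parent[p]
    p
  }
  for (v in seq_len(k)) node_map[v] <- if (survive[v]) v else nearest_survivor(tree$parent[v])
  display_parent <- stats::setNames(integer(sum(survive)), rownames(tree$freq)[survive])
  surv_ids <- which(survive)
  for (i in seq_along(surv_ids)) {
    v <- surv_ids[i]
    p <- tree$parent[v]
    while (p != 0L && !survive[p]) p <- tree$parent[p]
    display_parent[i] <- p
  }
  S <- ncol(tree$mixing)
  dm <- matrix(0, length(surv_ids) + 1L, S,
               dimnames = list(c(rownames(tree$freq)[surv_ids], "normal"),
                               colnames(tree$mixing)))
  for (v in seq_len(k)) {
    tgt <- node_map[v]
    if (tgt != 0L) {
      row <- match(tgt, surv_ids)
      dm[row, ] <- dm[row, ] + tree$mixing[v, ]
    } else {
      dm["normal", ] <- dm["normal", ] + tree$mixing[v, ]
    }
  }
  dm["normal", ] <- dm["normal", ] + tree$mixing[k + 1L, ]
  list(fitted = tree, display_parent = display_parent, node_map = node_map,
       display_mixing = dm, threshold = threshold)
}

#' Serialize a clone tree
#'
#' `json` is lossless (round-trips through [import_tree_json()]); `dot` is a
#' Graphviz digraph with one node statement per cluster (labels carry cluster
#' size and per-sample mixing) plus the normal root; `newick` is
#' topology-only with cluster labels.
#'
#' @param tree A `clone_tree`.
#' @param format `"json"`, `"dot"`, or `"newick"`.
#' @return A character scalar.
#' @export
export_tree <- function(tree, format = c("json", "dot", "newick")) {
  format <- match.arg(format)
  k <- tree$k
  labels <- rownames(tree$freq)
  if (format == "json") {
    payload <- list(parent = tree$parent, labels = labels, samples = tree$samples,
                    freq = unname(as.data.frame(tree$freq)),
                    mixing = unname(as.data.frame(tree$mixing)),
                    loglik = tree$loglik, violation_total = tree$violation_total,
                    score = tree$score, n_ties = tree$n_ties,
                    sizes = tree$clusters$sizes,
                    assignment = as.list(tree$clusters$assignment))
    return(as.character(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE)))
  }
  if (format == "dot") {
    lines <- c("digraph clone_tree {", "  node [shape=box];",
               "  N0 [label=\"normal\"];")
    for (v in seq_len(k)) {
      mix <- paste(sprintf("%.2f", tree$mixing[v, ]), collapse = ",")
      lines <- c(lines, sprintf("  N%d [label=\"%s (n=%d)\\nmix: %s\"];",
                                v, labels[v], tree$clusters$sizes[v], mix))
    }
    for (v in seq_len(k))
      lines <- c(lines, sprintf("  N%d -> N%d;", tree$parent[v], v))
    return(paste(c(lines, "}"), collapse = "\n"))
  }
  # newick
  children <- lapply(0:k, function(p) which(tree$parent == p))
  nw <- function(v) {
    kids <- children[[v + 1L]]
    lab <- if (v == 0L) "normal" else labels[v]
    if (length(kids) == 0L) lab
    else paste0("(", paste(vapply(kids, nw, character(1)), collapse = ","), ")", lab)
  }
  paste0(nw(0L), ";")
}

#' Rebuild a clone tree from its JSON serialization
#' @param text JSON string or path produced by [export_tree()].
#' @return A `clone_tree` (cluster membership restored; theta/BIC are not
#'   serialized).
#' @export
import_tree_json <- function(text) {
  x <- jsonlite::fromJSON(text)
  freq <- as.matrix(as.data.frame(x$freq))
  dimnames(freq) <- list(x$labels, x$samples)
  mixing <- as.matrix(as.data.frame(x$mixing))
  dimnames(mixing) <- list(c(x$labels, "normal"), x$samples)
  assignment <- unlist(x$assignment)
  clusters <- list(assignment = assignment, k = length(x$labels),
                   ccf_means = freq, theta = NULL,
                   sizes = as.integer(x$sizes), bic = NULL, loglik = x$loglik)
  class(clusters) <- "mutation_clusters"
  out <- list(parent = as.integer(x$parent), k = length(x$labels), freq = freq,
              mixing = mixing, loglik = x$loglik,
              violation_total = x$violation_total, score = x$score,
              n_ties = x$n_ties, clusters = clusters, samples = x$samples)
  class(out) <- "clone_tree"
  out
}

#' Write the cluster assignment table as TSV
#' @param clusters A `mutation_clusters`.
#' @param path Output path.
#' @export
write_cluster_assignments <- function(clusters, path) {
  df <- data.frame(mutation_id = names(clusters$assignment),
                   cluster = paste0("C", clusters$assignment),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
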