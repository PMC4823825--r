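# Reading/writing variant count tables and VCF allele depths, and per-sample
# presence calling under the support filters used for exome and deep-amplicon
# data.

COUNT_COLS <- c("mutation_id", "gene", "chrom", "pos", "arm", "sample_id",
                "ref_count", "alt_count")

#' Read a variant count TSV
#'
#' Expected columns: `mutation_id, gene, chrom, pos, arm, sample_id,
#' ref_count, alt_count` (1-based positions). Malformed rows are rejected
#' with their row number.
#'
#' @param path Path to the TSV.
#' @return `data.frame` of variant observations.
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(COUNT_COLS, names(df))
  if (length(missing) > 0)
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  df <- df[, COUNT_COLS]
  for (col in c("pos", "ref_count", "alt_count"))
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  bad <- which(is.na(df$ref_count) | is.na(df$alt_count) |
                 df$ref_count < 0 | df$alt_count < 0 | is.na(df$pos) | df$pos < 1)
  if (length(bad) > 0)
    stop("schema error: malformed row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         " (negative counts or invalid position)", call. = FALSE)
  dup <- duplicated(df[, c("mutation_id", "sample_id")])
  if (any(dup))
    stop("schema error: duplicated (mutation_id, sample_id) at row(s) ",
         paste(utils::head(which(dup), 5), collapse = ", "), call. = FALSE)
  df
}

#' Write a variant count TSV
#' @param observations `data.frame` in the [read_counts_tsv()] schema.
#' @param path Output path.
#' @export
write_counts_tsv <- function(observations, path) {
  utils::write.table(observations[, COUNT_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample allele depths from a VCF
#'
#' Extracts the `AD` (allele depth) FORMAT field into one observation per
#' (variant, sample); multi-allelic records are split per alternate allele,
#' sharing the position. The `arm` column is left `NA` (arm membership is a
#' user-supplied configuration table, not inferred from a genome build).
#'
#' @param path Path to a VCF 4.x file with genotype columns carrying `AD`.
#' @return `data.frame` of variant observations.
#' @export
read_vcf_allele_depths <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) < 2L)
    stop("unsupported input: VCF has no genotype columns", call. = FALSE)
  fmt <- v@gt[, 1]
  if (!any(grepl("(^|:)AD(:|$)", fmt)))
    stop("unsupported input: VCF lacks the AD allele-depth field", call. = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7, dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER")))
  samples <- colnames(ad)
  rows <- list()
  for (i in seq_len(nrow(ad))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (s in samples) {
      parts <- suppressWarnings(as.integer(strsplit(ad[i, s] %||% NA_character_, ",", fixed = TRUE)[[1]]))
      if (length(parts) < 1L || all(is.na(parts))) next
      for (j in seq_along(alts)) {
        altc <- if (length(parts) >= j + 1L && !is.na(parts[j + 1L])) parts[j + 1L] else 0L
        rows[[length(rows) + 1L]] <- data.frame(
          mutation_id = paste(fix[i, "CHROM"], fix[i, "POS"], fix[i, "REF"], alts[j], sep = ":"),
          gene = NA_character_, chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
          arm = NA_character_, sample_id = s,
          ref_count = parts[1L], alt_count = altc, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    stop("unsupported input: no parseable AD values in VCF", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default presence-calling parameters
#'
#' WES mode reflects the exome support filter: a variant is present when
#' depth >= `min_depth` and the alternate fraction is at least 10%
#' (boundary inclusive). Amplicon mode is a one-sided binomial test of the
#' alternate count against a sequencing error rate, with a minimum alternate
#' count, suited to ~4,000x data where true subclones sit far below 10%.
#'
#' @param mode `"wes"` or `"amplicon"`.
#' @return Named list of parameters.
#' @export
presence_params <- function(mode = c("wes", "amplicon")) {
  mode <- match.arg(mode)
  if (mode == "wes") list(mode = "wes", min_depth = 10L, min_vaf = 0.10)
  else list(mode = "amplicon", min_depth = 10L, min_alt = 5L, error_rate = 0.002,
            alpha = 1e-3)
}

#' Call per-sample presence of a mutation
#'
#' @param ref_count,alt_count Nonnegative integer counts (vectorized).
#' @param mode `"wes"` or `"amplicon"`.
#' @param params Parameter list, see [presence_params()].
#' @return Character vector in `{"present", "absent", "unevaluable"}`.
#' @examples
#' call_presence(90, 10, "wes")   # exactly 10% -> present
#' call_presence(95, 5, "wes")    # 5% -> absent
#' @export
call_presence <- function(ref_count, alt_count, mode = c("wes", "amplicon"),
                          params = NULL) {
  mode <- match.arg(mode)
  params <- params %||% presence_params(mode)
  stop_scalar_count(ref_count, "ref_count")
  stop_scalar_count(alt_count, "alt_count")
  depth <- ref_count + alt_count
  out <- rep("absent", length(depth))
  out[depth < params$min_depth] <- "unevaluable"
  ok <- depth >= params$min_depth
  if (mode == "wes") {
    out[ok & alt_count / pmax(depth, 1) >= params$min_vaf] <- "present"
  } else {
    # one-sided exact binomial tail: P(X >= alt | depth, error_rate)
    p <- stats::pbinom(alt_count - 1, depth, params$error_rate, lower.tail = FALSE)
    out[ok & alt_count >= params$min_alt & p < params$alpha] <- "present"
  }
  out
}

#' Build the mutation x sample presence matrix
#'
#' Rows and columns follow first appearance in the input; cells without an
#' observation are `unevaluable`. Duplicate (mutation, sample) pairs with
#' conflicting counts are an error.
#'
#' @param observations Variant observations ([read_counts_tsv()] schema).
#' @inheritParams call_presence
#' @return Character matrix (`present`/`absent`/`unevaluable`) of class
#'   `presence_matrix` with mutations as rows, samples as columns.
#' @export
build_presence_matrix <- function(observations, mode = c("wes", "amplicon"),
                                  params = NULL) {
  mode <- match.arg(mode)
  key <- paste(observations$mutation_id, observations$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- duplicated(key) | duplicated(key, fromLast = TRUE)
    grp <- split(observations[d, c("ref_count", "alt_count")], key[d])
    conflict <- vapply(grp, function(g) nrow(unique(g)) > 1L, logical(1))
    if (any(conflict))
      stop("conflicting duplicate observations for ",
           sub("\r", " / ", names(grp)[conflict][1]), call. = FALSE)
    observations <- observations[!duplicated(key), ]
  }
  muts <- unique(observations$mutation_id)
  samples <- unique(observations$sample_id)
  m <- matrix("unevaluable", nrow = length(muts), ncol = length(samples),
              dimnames = list(muts, samples))
  calls <- call_presence(observations$ref_count, observations$alt_count, mode, params)
  m[cbind(match(observations$mutation_id, muts),
          match(observations$sample_id, samples))] <- calls
  class(m) <- c("presence_matrix", class(m))
  m
}

#' Write a presence matrix as TSV (1 = present, 0 = absent, NA = unevaluable)
#' @param presence A `presence_matrix`.
#' @param path Output path.
#' @export
write_presence_matrix <- function(presence, path) {
  num <- matrix(NA_integer_, nrow = nrow(presence), ncol = ncol(presence),
                dimnames = dimnames(presence))
  num[unclass(presence) == "present"] <- 1L
  num[unclass(presence) == "absent"] <- 0L
  df <- data.frame(mutation_id = rownames(num), num, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
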