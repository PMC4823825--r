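# Copy-number-aware correction of somatic allele read counts, so that the
# variant allele fractions fed to tree reconstruction are comparable across
# CNV states. The four corrections map a clonal heterozygous mutation back to
# the diploid VAF scale:
#   duplication:      Ref' = Ref,           Alt' = Alt / 2
#   deletion:         Ref' = Ref + Alt,     Alt' = Alt
#   chrX hemizygous:  Ref' = Ref * 2 + Alt, Alt' = Alt
#   copy-neutral LOH: Ref' = Ref + Alt / 2, Alt' = Alt / 2
# Corrected counts are kept real-valued; integer rounding happens only where
# a count-based likelihood requires it (centralized in estimate_ccf()).

CORRECTION_EVENTS <- c("duplication", "deletion", "cn_loh", "chrX_hemizygous", "none")

#' Correct a ref/alt read-count pair for an arm-level CNV event
#'
#' Vectorized over all arguments. `event = "none"` is the identity.
#'
#' @param ref,alt Nonnegative integer read counts.
#' @param event Character vector over `duplication`, `deletion`, `cn_loh`,
#'   `chrX_hemizygous`, `none`.
#' @return `data.frame` with real-valued `ref_prime`, `alt_prime`.
#' @examples
#' correct_counts(100, 50, "duplication")   # (100, 25)
#' correct_counts(60, 40, "deletion")       # (100, 40)
#' correct_counts(30, 30, "chrX_hemizygous")# (90, 30)
#' correct_counts(50, 40, "cn_loh")         # (70, 20)
#' @export
correct_counts <- function(ref, alt, event) {
  stop_scalar_count(ref, "ref")
  stop_scalar_count(alt, "alt")
  n <- max(length(ref), length(alt), length(event))
  ref <- rep_len(as.numeric(ref), n)
  alt <- rep_len(as.numeric(alt), n)
  event <- rep_len(as.character(event), n)
  bad <- !event %in% CORRECTION_EVENTS
  if (any(bad)) stop("unknown event label: ", event[bad][1], call. = FALSE)
  rp <- ref
  ap <- alt
  i <- event == "duplication"
  ap[i] <- alt[i] / 2
  i <- event == "deletion"
  rp[i] <- ref[i] + alt[i]
  i <- event == "chrX_hemizygous"
  rp[i] <- ref[i] * 2 + alt[i]
  i <- event == "cn_loh"
  rp[i] <- ref[i] + alt[i] / 2
  ap[i] <- alt[i] / 2
  data.frame(ref_prime = rp, alt_prime = ap)
}

#' Apply CNV corrections to a table of variant observations
#'
#' Joins each observation to its sample's arm-level CNV call and applies
#' [correct_counts()]. For XY individuals, observations on chromosome X take
#' the hemizygous correction, which has precedence over any arm event.
#'
#' @param observations Variant observations ([read_counts_tsv()] schema).
#' @param cnv_calls `data.frame` with `sample_id, arm, event` (e.g. from
#'   [call_cnv_profile()]); events other than the four correction labels
#'   (`neutral`, `unevaluable`) mean no correction.
#' @param sex `"XX"` or `"XY"`.
#' @param strict If `TRUE`, an observation on an arm with no call is an
#'   error; otherwise neutral is assumed with a warning.
#' @return `data.frame`: `mutation_id, sample_id, ref_prime, alt_prime,
#'   event_applied, corrected_vaf` (NA when both corrected counts are 0).
#' @export
apply_corrections <- function(observations, cnv_calls = NULL, sex = c("XX", "XY"),
                              strict = FALSE) {
  sex <- match.arg(sex)
  ev <- rep("none", nrow(observations))
  if (!is.null(cnv_calls) && nrow(cnv_calls) > 0) {
    key_obs <- paste(observations$sample_id, observations$arm, sep = "\r")
    key_call <- paste(cnv_calls$sample_id, cnv_calls$arm, sep = "\r")
    idx <- match(key_obs, key_call)
    if (anyNA(idx)) {
      msg <- paste0(sum(is.na(idx)), " observation(s) on arms with no CNV call")
      if (strict) stop(msg, call. = FALSE)
      warning(msg, "; assuming neutral", call. = FALSE)
    }
    called <- cnv_calls$event[idx]
    use <- !is.na(idx) & called %in% c("duplication", "deletion", "cn_loh")
    ev[use] <- called[use]
  }
  if (sex == "XY") {
    on_x <- observations$chrom %in% c("X", "chrX", "x")
    ev[on_x] <- "chrX_hemizygous"
  }
  cc <- correct_counts(observations$ref_count, observations$alt_count, ev)
  denom <- cc$ref_prime + cc$alt_prime
  data.frame(mutation_id = observations$mutation_id,
             sample_id = observations$sample_id,
             arm = observations$arm,
             ref_prime = cc$ref_prime, alt_prime = cc$alt_prime,
             event_applied = ev,
             corrected_vaf = ifelse(denom > 0, cc$alt_prime / denom, NA_real_),
             stringsAsFactors = FALSE)
}
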