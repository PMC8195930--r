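# Repertoire diversity and convergence metrics, and their paired
# pre/post-treatment ratios.

#' Shannon entropy of a clone-frequency vector
#'
#' Returns \eqn{H = -\sum_i p_i \log p_i} in nats. Exact zeros are dropped
#' before evaluation; the remaining frequencies must sum to 1 within 1e-9.
#'
#' @param frequencies Numeric vector of clone frequencies.
#' @return Entropy in nats (0 for a single clone, `ln(R)` for `R` uniform
#'   clones).
#' @export
shannon_entropy <- function(frequencies) {
  p <- frequencies[frequencies != 0]
  if (any(p < 0)) stop("frequencies must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9) {
    stop("frequencies must sum to 1 (got ", format(sum(p), digits = 12), ")",
         call. = FALSE)
  }
  -sum(p * log(p))
}

#' Repertoire clonality
#'
#' Clonality is one minus the normalised Shannon entropy of productive clone
#' frequencies: \eqn{1 - H / \log R}, where `R` is the number of unique
#' productive clones (richness). It ranges from 0, when all clonotypes are
#' equally common, to 1 (in the limit), when the repertoire is dominated by
#' a single clone. The value is independent of the logarithm base.
#'
#' @param x A [repertoire()] object, or a numeric vector of clone
#'   frequencies summing to 1.
#' @return Clonality in `[0, 1]`.
#' @export
#' @examples
#' clonality(rep(1 / 1000, 1000))        # perfectly even: 0
#' clonality(c(0.5, 0.25, 0.25))         # 0.0536
clonality <- function(x) UseMethod("clonality")

#' @export
clonality.numeric <- function(x) {
  p <- x[x != 0]
  r <- length(p)
  if (r <= 1L) {
    stop("clonality is undefined for a repertoire with a single clone ",
         "(log richness is zero)", call. = FALSE)
  }
  1 - shannon_entropy(p) / log(r)
}

#' @export
clonality.tcr_repertoire <- function(x) {
  clonality(productive_frequencies(x))
}

productive_frequencies <- function(rep) {
  rep$records$frequency[rep$records$productive]
}

#' TCR convergence frequency (TCF)
#'
#' The aggregate frequency of productive clones whose amino-acid CDR3 is
#' shared (by exact string equality) with at least one other
#' nucleotide-distinct clone in the same repertoire. Clones lacking an
#' amino-acid sequence are excluded, with a message reporting how many.
#'
#' @param rep A [repertoire()] object.
#' @return TCF in `[0, 1]`.
#' @export
convergence_frequency <- function(rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  rec <- rep$records[rep$records$productive, , drop = FALSE]
  missing_aa <- is.na(rec$aa_cdr3) | !nzchar(rec$aa_cdr3)
  if (any(missing_aa)) {
    message(sum(missing_aa), " productive clone(s) lack an amino-acid CDR3 ",
            "and are excluded from TCF")
    rec <- rec[!missing_aa, , drop = FALSE]
  }
  if (!nrow(rec)) return(0)
  shared <- ave(seq_len(nrow(rec)), rec$aa_cdr3, FUN = length) >= 2
  sum(rec$frequency[shared])
}

#' Ratio of a post-treatment metric to its baseline value
#'
#' Used for relative clonality (RCL) and relative TCF (RTCF): the ratio of
#' the post-treatment (C1D15) value to the baseline (C1D1) value. A ratio
#' of at least 1 marks the metric as "increased" after treatment.
#'
#' @param baseline_value,post_value Metric values at the two timepoints.
#' @return `post_value / baseline_value`.
#' @export
relative_metric <- function(baseline_value, post_value) {
  if (any(baseline_value == 0)) {
    stop("relative metric is undefined when the baseline value is 0",
         call. = FALSE)
  }
  post_value / baseline_value
}

#' Per-sample repertoire metrics
#'
#' @param rep A [repertoire()] object.
#' @return A one-row tibble: `sample_id`, `patient_id`, `timepoint`,
#'   `richness` (unique productive clones), `entropy_nats`, `clonality`,
#'   `tcf`.
#' @export
repertoire_metrics <- function(rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  p <- productive_frequencies(rep)
  tibble::tibble(
    sample_id = rep$sample_id,
    patient_id = rep$patient_id,
    timepoint = rep$timepoint,
    richness = length(p),
    entropy_nats = shannon_entropy(p),
    clonality = clonality(p),
    tcf = convergence_frequency(rep))
}

#' Paired course metrics: RCL, RTCF, and dynamic-group labels
#'
#' For a patient with both timepoints passing QC, computes relative
#' clonality (`rcl`) and relative TCF (`rtcf`) and assigns the dichotomous
#' groups: `increased_clonality` and `increased_tcf` are `TRUE` when the
#' respective ratio is `>= 1` (a ratio of exactly 1 counts as increased),
#' and `dual_group` is `"dual-increase"` when both increased, `"rest"`
#' otherwise. Patients without a complete pair get `NA` metrics and labels.
#'
#' @param course A `patient_course` from [pair_timepoints()].
#' @return A one-row tibble: `patient_id`, `baseline_clonality`,
#'   `post_clonality`, `baseline_tcf`, `post_tcf`, `rcl`, `rtcf`,
#'   `increased_clonality`, `increased_tcf`, `dual_group`.
#' @export
course_metrics <- function(course) {
  stopifnot(inherits(course, "patient_course"))
  out <- tibble::tibble(
    patient_id = course$patient_id,
    baseline_clonality = NA_real_, post_clonality = NA_real_,
    baseline_tcf = NA_real_, post_tcf = NA_real_,
    rcl = NA_real_, rtcf = NA_real_,
    increased_clonality = NA, increased_tcf = NA,
    dual_group = NA_character_)
  if (!is.null(course$baseline)) {
    out$baseline_clonality <- clonality(course$baseline)
    out$baseline_tcf <- convergence_frequency(course$baseline)
  }
  if (!is.null(course$post)) {
    out$post_clonality <- clonality(course$post)
    out$post_tcf <- convergence_frequency(course$post)
  }
  if (!course$has_both) return(out)

  out$rcl <- relative_metric(out$baseline_clonality, out$post_clonality)
  out$rtcf <- if (out$baseline_tcf > 0) {
    relative_metric(out$baseline_tcf, out$post_tcf)
  } else NA_real_
  labels <- assign_dynamic_groups(out$rcl, out$rtcf)
  out$increased_clonality <- labels$increased_clonality
  out$increased_tcf <- labels$increased_tcf
  out$dual_group <- labels$dual_group
  out
}

#' Dichotomous dynamic-group labels from RCL and RTCF
#'
#' @param rcl,rtcf Relative clonality and relative TCF (vectors recycle).
#' @return A tibble with `increased_clonality` (`rcl >= 1`), `increased_tcf`
#'   (`rtcf >= 1`), and `dual_group` (`"dual-increase"` when both are
#'   `TRUE`, `"rest"` otherwise, `NA` when either input ratio is missing).
#' @export
assign_dynamic_groups <- function(rcl, rtcf) {
  inc_cl <- ifelse(is.na(rcl), NA, rcl >= 1)
  inc_tcf <- ifelse(is.na(rtcf), NA, rtcf >= 1)
  dual <- ifelse(is.na(inc_cl) | is.na(inc_tcf), NA_character_,
                 ifelse(inc_cl & inc_tcf, "dual-increase", "rest"))
  tibble::tibble(increased_clonality = inc_cl,
                 increased_tcf = inc_tcf,
                 dual_group = dual)
}

#' Metrics tables for a whole cohort
#'
#' Convenience wrapper running [repertoire_metrics()] over every passing
#' sample and [course_metrics()] over every patient course.
#'
#' @param courses A list of `patient_course` objects from
#'   [pair_timepoints()].
#' @return A list with `samples` (per-sample metrics tibble) and `courses`
#'   (per-patient course tibble).
#' @export
cohort_metrics <- function(courses) {
  reps <- list()
  for (course in courses) {
    if (!is.null(course$baseline)) reps <- c(reps, list(course$baseline))
    if (!is.null(course$post)) reps <- c(reps, list(course$post))
  }
  samples <- if (length(reps)) {
    dplyr::bind_rows(lapply(reps, repertoire_metrics))
  } else {
    tibble::tibble(sample_id = character(), patient_id = character(),
                   timepoint = character(), richness = integer(),
                   entropy_nats = double(), clonality = double(),
                   tcf = double())
  }
  list(samples = samples,
       courses = dplyr::bind_rows(lapply(courses, course_metrics)))
}
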