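# Synthetic cohort generator: skewed clone-size distributions, nucleotide ->
# amino-acid convergence, paired timepoints with controlled clonality shifts,
# and survival whose hazard depends on the realized clonality change.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
NT_ALPHABET <- c("A", "C", "G", "T")

#' Simulation parameters for a synthetic TCR cohort
#'
#' Defaults describe a cohort of the size and composition typical of an
#' early-phase checkpoint-blockade trial arm: 71 patients sampled at
#' baseline (C1D1) and two weeks after the first dose (C1D15), repertoires
#' of 1500 unique clones at about one million reads per library (so every
#' sample passes the default QC by construction), a Zipf-like clone-size
#' distribution, a small fraction of clones emitted as several
#' nucleotide-distinct variants of one amino-acid sequence, and exponential
#' survival whose hazard doubles for patients whose realized clonality
#' increased after treatment.
#'
#' @param n_patients Number of patients (two samples each).
#' @param n_clones_per_sample Unique nucleotide clones per sample.
#' @param clone_size_exponent Power-law tail index of the rank-frequency
#'   distribution (weights proportional to rank^-exponent, perturbed
#'   log-normally).
#' @param clone_size_noise_sd SD of the multiplicative log-normal
#'   perturbation of clone weights.
#' @param convergence_rate Probability that a clone re-uses the amino-acid
#'   sequence of an earlier clone under a distinct nucleotide sequence
#'   (true convergent pairs).
#' @param near_neighbor_rate Probability that a clone is a single
#'   amino-acid edit of an earlier clone (populates network edges).
#' @param clonality_shift_mean,clonality_shift_sd Mean and SD of the
#'   patient-level log-normal multiplier applied to the post-treatment
#'   skew (multiplier > 1 sharpens the clone-size distribution, raising
#'   clonality).
#' @param true_log_hr_rcl Log hazard ratio attached to the realized
#'   increased-clonality indicator (realized RCL >= 1).
#' @param baseline_hazard Exponential hazard per month in the
#'   decreased-clonality group.
#' @param censoring_rate Probability a patient receives a random uniform
#'   censoring time before administrative end of follow-up.
#' @param max_followup_months Administrative censoring horizon.
#' @param total_reads Library read depth per sample.
#' @param unproductive_read_fraction Fraction of reads carried by
#'   unproductive (out-of-frame / stop-containing) rearrangements.
#' @param n_unproductive Number of unproductive records per sample.
#' @param aa_length_range Min/max amino-acid CDR3 length.
#' @param n_qc_fail Number of patients whose post-treatment sample is
#'   emitted with 999 unique clones, i.e. deliberately failing the
#'   unique-clone QC criterion.
#' @param seed RNG seed; the same seed reproduces the cohort exactly.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_patients = 71,
                       n_clones_per_sample = 1500,
                       clone_size_exponent = 1.0,
                       clone_size_noise_sd = 0.5,
                       convergence_rate = 0.05,
                       near_neighbor_rate = 0.05,
                       clonality_shift_mean = 0,
                       clonality_shift_sd = 0.25,
                       true_log_hr_rcl = log(2),
                       baseline_hazard = 0.02,
                       censoring_rate = 0.3,
                       max_followup_months = 36,
                       total_reads = 1e6,
                       unproductive_read_fraction = 0.15,
                       n_unproductive = 30,
                       aa_length_range = c(8, 20),
                       n_qc_fail = 0,
                       seed = 1L) {
  p <- as.list(environment())
  with(p, {
    stopifnot(n_patients >= 1, n_clones_per_sample >= 2,
              clone_size_exponent > 0,
              convergence_rate >= 0, convergence_rate <= 1,
              near_neighbor_rate >= 0, near_neighbor_rate <= 1,
              convergence_rate + near_neighbor_rate <= 1,
              baseline_hazard > 0, censoring_rate >= 0, censoring_rate <= 1,
              max_followup_months > 0, total_reads > 0,
              unproductive_read_fraction >= 0,
              unproductive_read_fraction < 1,
              length(aa_length_range) == 2,
              aa_length_range[1] >= 3,
              aa_length_range[1] <= aa_length_range[2],
              n_qc_fail >= 0, n_qc_fail <= n_patients)
  })
  structure(p, class = "sim_params")
}

#' Draw a skewed clone-frequency vector
#'
#' Unnormalised weights follow a rank power-law `rank^-exponent`, perturbed
#' multiplicatively by a log-normal factor, then raised to `skew_modifier`
#' and normalised to sum to 1. `skew_modifier -> 0` flattens the
#' distribution towards uniform (clonality near 0); larger values sharpen
#' it (higher clonality).
#'
#' @param n_clones Number of clones (>= 2).
#' @param exponent Power-law tail index (> 0).
#' @param skew_modifier Sharpening exponent (>= 0).
#' @param noise_sd SD of the log-normal perturbation.
#' @return Frequency vector summing to 1.
#' @export
sample_clone_frequencies <- function(n_clones, exponent = 1,
                                     skew_modifier = 1, noise_sd = 0.5) {
  stopifnot(n_clones >= 2, exponent > 0, skew_modifier >= 0, noise_sd >= 0)
  w <- (seq_len(n_clones)^(-exponent) *
          exp(stats::rnorm(n_clones, 0, noise_sd)))^skew_modifier
  w / sum(w)
}

random_strings <- function(n, lengths, alphabet) {
  if (!n) return(character())
  lengths <- rep_len(lengths, n)
  codes <- sample.int(length(alphabet), sum(lengths), replace = TRUE)
  cpp_paste_codes(codes, as.integer(lengths), alphabet)
}

# One random amino-acid substitution at a random position.
mutate_one <- function(aa) {
  pos <- sample.int(nchar(aa), 1L)
  old <- substr(aa, pos, pos)
  substr(aa, pos, pos) <- sample(setdiff(AA_ALPHABET, old), 1L)
  aa
}

#' Generate synthetic clonotype sequences
#'
#' Random amino-acid CDR3s over the 20 standard residues, each paired with
#' a distinct random nucleotide sequence of three times the amino-acid
#' length. With probability `convergence_rate` a clone re-uses the
#' amino-acid sequence of a random earlier clone (a true convergent pair:
#' identical `aa_cdr3`, distinct `nt_cdr3`); with probability
#' `near_neighbor_rate` it is instead a single amino-acid edit of an
#' earlier clone, populating distance-1 network edges.
#'
#' @inheritParams sim_params
#' @param n_clones Number of clones to generate.
#' @return A tibble with `nt_cdr3` and `aa_cdr3`.
#' @export
sample_clonotype_sequences <- function(n_clones, convergence_rate = 0.05,
                                       near_neighbor_rate = 0.05,
                                       aa_length_range = c(8, 20)) {
  stopifnot(n_clones >= 1)
  lens <- sample(seq(aa_length_range[1], aa_length_range[2]),
                 n_clones, replace = TRUE)
  aa <- random_strings(n_clones, lens, AA_ALPHABET)
  u <- stats::runif(n_clones)
  for (i in seq_len(n_clones)[-1]) {
    if (u[i] < convergence_rate) {
      aa[i] <- aa[sample.int(i - 1L, 1L)]
    } else if (u[i] < convergence_rate + near_neighbor_rate) {
      aa[i] <- mutate_one(aa[sample.int(i - 1L, 1L)])
    }
  }
  nt <- random_strings(n_clones, 3L * nchar(aa), NT_ALPHABET)
  while (anyDuplicated(nt)) {
    dup <- which(duplicated(nt))
    nt[dup] <- random_strings(length(dup), 3L * nchar(aa[dup]), NT_ALPHABET)
  }
  tibble::new_tibble(list(nt_cdr3 = nt, aa_cdr3 = aa), nrow = n_clones)
}

# Build one synthetic sample as a tcr_repertoire.
simulate_repertoire <- function(params, patient_id, timepoint,
                                skew_modifier, n_clones,
                                n_unproductive = params$n_unproductive) {
  freqs <- sample_clone_frequencies(
    n_clones, exponent = params$clone_size_exponent,
    skew_modifier = skew_modifier, noise_sd = params$clone_size_noise_sd)
  seqs <- sample_clonotype_sequences(
    n_clones, convergence_rate = params$convergence_rate,
    near_neighbor_rate = params$near_neighbor_rate,
    aa_length_range = params$aa_length_range)

  prod_reads <- round(params$total_reads *
                        (1 - params$unproductive_read_fraction))
  counts <- as.vector(stats::rmultinom(1, prod_reads, freqs))
  counts[counts == 0L] <- 1L  # keep richness fixed at n_clones

  nt <- seqs$nt_cdr3
  aa <- seqs$aa_cdr3
  productive <- rep(TRUE, n_clones)

  n_unprod <- n_unproductive
  unprod_reads <- params$total_reads - prod_reads
  if (n_unprod > 0 && unprod_reads > 0) {
    ulens <- sample(seq(params$aa_length_range[1], params$aa_length_range[2]),
                    n_unprod, replace = TRUE)
    uaa <- random_strings(n_unprod, ulens, AA_ALPHABET)
    # stop codon marks the unproductive rearrangement
    substr(uaa, ulens, ulens) <- "*"
    unt <- random_strings(n_unprod, 3L * ulens, NT_ALPHABET)
    ucounts <- as.vector(stats::rmultinom(1, unprod_reads,
                                          rep(1 / n_unprod, n_unprod)))
    nt <- c(nt, unt)
    aa <- c(aa, uaa)
    counts <- c(counts, ucounts)
    productive <- c(productive, rep(FALSE, n_unprod))
  }
  records <- tibble::new_tibble(
    list(nt_cdr3 = nt, aa_cdr3 = aa, read_count = counts,
         productive = productive),
    nrow = length(nt))

  repertoire(records,
             sample_id = paste0(patient_id, "_", timepoint),
             patient_id = patient_id, timepoint = timepoint,
             total_reads = sum(records$read_count))
}

#' Simulate a complete synthetic cohort
#'
#' Per patient: draws a latent log-normal clonality-shift multiplier,
#' builds a baseline (C1D1) and a post-treatment (C1D15) repertoire whose
#' realized relative clonality (RCL) tracks the latent shift, then draws an
#' exponential survival time with hazard
#' `baseline_hazard * exp(true_log_hr_rcl)` when the *realized* RCL is
#' `>= 1` and `baseline_hazard` otherwise, under independent uniform
#' censoring. Clinical covariates are drawn independently of survival at
#' prevalences typical of an advanced NSCLC trial population. The first
#' `n_qc_fail` patients receive a post sample with 999 unique clones so
#' that QC removes exactly those samples.
#'
#' @param params A [sim_params()] object.
#' @return A `synthetic_cohort`: list with `params`, `repertoires` (named
#'   list of [repertoire()] objects), `clinical` (tibble:
#'   `patient_id`, `os_months`, `event`, and eight binary covariates), and
#'   `truth` (tibble: `patient_id`, `latent_shift`, `realized_rcl`,
#'   `true_increase`, `hazard_multiplier`).
#' @export
simulate_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)

  prevalence <- c(male_sex = 0.549, age_ge_65 = 0.507, squamous = 0.521,
                  pdl1_low_neg = 0.290, ecog_1 = 0.634, ever_smoker = 0.930,
                  prior_line = 0.296, liver_mets = 0.275)

  n_pat <- params$n_patients
  ids <- sprintf("P%03d", seq_len(n_pat))
  repertoires <- vector("list", 2L * n_pat)
  rep_ids <- character(2L * n_pat)
  shift <- rcl <- os <- numeric(n_pat)
  event <- integer(n_pat)
  covs <- matrix(0L, n_pat, length(prevalence),
                 dimnames = list(NULL, names(prevalence)))

  for (k in seq_len(n_pat)) {
    pid <- ids[k]
    shift[k] <- exp(stats::rnorm(1, params$clonality_shift_mean,
                                 params$clonality_shift_sd))
    n_post <- if (k <= params$n_qc_fail) 999L else params$n_clones_per_sample
    baseline <- simulate_repertoire(params, pid, "C1D1",
                                    skew_modifier = 1,
                                    n_clones = params$n_clones_per_sample)
    # QC-failing samples carry exactly 999 unique clones in total, so the
    # unproductive records are suppressed for them
    post <- simulate_repertoire(
      params, pid, "C1D15", skew_modifier = shift[k], n_clones = n_post,
      n_unproductive = if (k <= params$n_qc_fail) 0L else
        params$n_unproductive)
    repertoires[[2L * k - 1L]] <- baseline
    repertoires[[2L * k]] <- post
    rep_ids[c(2L * k - 1L, 2L * k)] <- c(baseline$sample_id, post$sample_id)

    rcl[k] <- clonality(post) / clonality(baseline)
    mult <- exp(params$true_log_hr_rcl * (rcl[k] >= 1))
    t_event <- stats::rexp(1, params$baseline_hazard * mult)
    t_cens <- if (stats::runif(1) < params$censoring_rate) {
      stats::runif(1, 0, params$max_followup_months)
    } else {
      params$max_followup_months
    }
    os[k] <- max(min(t_event, t_cens), 0.01)
    event[k] <- as.integer(t_event <= t_cens)
    covs[k, ] <- as.integer(stats::runif(length(prevalence)) < prevalence)
  }
  names(repertoires) <- rep_ids

  clinical <- tibble::as_tibble(cbind(
    tibble::tibble(patient_id = ids, os_months = os, event = event),
    tibble::as_tibble(covs)))
  truth <- tibble::tibble(
    patient_id = ids, latent_shift = shift, realized_rcl = rcl,
    true_increase = rcl >= 1,
    hazard_multiplier = exp(params$true_log_hr_rcl * (rcl >= 1)))

  structure(list(params = params,
                 repertoires = repertoires,
                 clinical = clinical,
                 truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d repertoires (seed %d)\n",
              x$params$n_patients, length(x$repertoires),
              x$params$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits one clonotype table per sample (named `<patient>_<timepoint>` with
#' the dialect's extension), the clinical CSV, and a `truth.json` sidecar
#' with the latent per-patient values for recovery scoring.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @param dialect Clonotype dialect, as in [write_clonotype_table()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, dialect = c("simple_csv", "airr_tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (dialect == "airr_tsv") ".tsv" else ".csv"
  for (rep in cohort$repertoires) {
    write_clonotype_table(rep, file.path(dir, paste0(rep$sample_id, ext)),
                          dialect = dialect)
  }
  readr::write_csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   progress = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}
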