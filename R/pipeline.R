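# End-to-end orchestration: ingest -> QC -> metrics -> networks -> survival,
# with a run log and patient-conservation accounting.

CLINICAL_COVARIATES <- c("male_sex", "age_ge_65", "squamous", "pdl1_low_neg",
                         "ecog_1", "ever_smoker", "prior_line", "liver_mets")

#' Pipeline configuration
#'
#' Exactly one input mode must be active: real-input mode (`clonotype_dir`
#' plus `clinical_path`) or simulate mode (`simulate`, a [sim_params()]
#' object). In real-input mode clonotype files are discovered as
#' `<patient>_<timepoint>.<ext>` within `clonotype_dir`.
#'
#' @param clonotype_dir Directory of clonotype tables.
#' @param clinical_path Clinical CSV path (see [read_clinical_table()]).
#' @param dialect Clonotype dialect (`"simple_csv"` or `"airr_tsv"`).
#' @param simulate A [sim_params()] object for simulate mode.
#' @param thresholds A [qc_thresholds()] object.
#' @param diameter_units `"edges"` or `"vertices"`, see
#'   [network_diameter()].
#' @param ties Cox tie handling, see [cox_fit()].
#' @param p_keep Backward-selection retention threshold.
#' @param output_dir Optional directory for CSV/JSON artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(clonotype_dir = NULL, clinical_path = NULL,
                            dialect = c("simple_csv", "airr_tsv"),
                            simulate = NULL,
                            thresholds = qc_thresholds(),
                            diameter_units = c("edges", "vertices"),
                            ties = c("efron", "breslow"),
                            p_keep = 0.2,
                            output_dir = NULL) {
  dialect <- match.arg(dialect)
  diameter_units <- match.arg(diameter_units)
  ties <- match.arg(ties)
  real_mode <- !is.null(clonotype_dir) || !is.null(clinical_path)
  sim_mode <- !is.null(simulate)
  if (real_mode == sim_mode) {
    stop("exactly one of real-input mode (clonotype_dir + clinical_path) ",
         "or simulate mode (simulate = sim_params(...)) must be active",
         call. = FALSE)
  }
  if (real_mode && (is.null(clonotype_dir) || is.null(clinical_path))) {
    stop("real-input mode needs both clonotype_dir and clinical_path",
         call. = FALSE)
  }
  if (sim_mode) stopifnot(inherits(simulate, "sim_params"))
  stopifnot(inherits(thresholds, "qc_thresholds"),
            p_keep > 0, p_keep <= 1)
  structure(list(clonotype_dir = clonotype_dir,
                 clinical_path = clinical_path, dialect = dialect,
                 simulate = simulate, thresholds = thresholds,
                 diameter_units = diameter_units, ties = ties,
                 p_keep = p_keep, output_dir = output_dir),
            class = "pipeline_config")
}

discover_samples <- function(dir, dialect) {
  ext <- if (dialect == "airr_tsv") "\\.tsv$" else "\\.csv$"
  files <- sort(list.files(dir, pattern = ext, full.names = TRUE))
  files <- files[!grepl("clinical", basename(files))]
  samples <- list()
  for (f in files) {
    stem <- sub("\\.[^.]*$", "", basename(f))
    parts <- regmatches(stem, regexec("^(.*)_(C1D1|C1D15)$", stem))[[1]]
    if (length(parts) != 3L) {
      message("skipping ", basename(f),
              ": name is not <patient>_<timepoint>")
      next
    }
    samples[[stem]] <- read_clonotype_table(
      f, dialect = dialect, sample_id = stem,
      patient_id = parts[2], timepoint = parts[3])
  }
  samples
}

#' Run the full repertoire-to-survival pipeline
#'
#' Stages, in order: ingest clonotype and clinical tables (or simulate a
#' cohort), apply sample QC, pair timepoints into patient courses, compute
#' per-sample and per-course metrics, build per-patient convergence
#' networks with the median-diameter split, and fit the survival layer
#' (Kaplan-Meier summaries with log-rank tests for the four groupings —
#' relative clonality, relative TCF, dual increase, network diameter — plus
#' univariable Cox models per term and a backward-selected multivariable
#' model). Every patient in the input appears exactly once in either the
#' analysis tables or the exclusion log.
#'
#' @param config A [pipeline_config()] object.
#' @return An `analysis_report`: list with `sample_metrics`,
#'   `course_metrics`, `network_summary`, `km_summaries`, `cox_table`,
#'   `multivariable_trace`, `clonality_association`, `qc_log`,
#'   `patient_log`, `run_log`, and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  run_log <- list()
  log_stage <- function(stage, n_in, n_out, note = "") {
    run_log[[length(run_log) + 1L]] <<- tibble::tibble(
      stage = stage, n_in = n_in, n_out = n_out, note = note)
  }

  # -- ingest ---------------------------------------------------------------
  if (!is.null(config$simulate)) {
    cohort <- simulate_cohort(config$simulate)
    samples <- unname(cohort$repertoires)
    clinical <- cohort$clinical
  } else {
    samples <- unname(discover_samples(config$clonotype_dir, config$dialect))
    clinical <- read_clinical_table(config$clinical_path)
  }
  all_patients <- unique(vapply(samples, `[[`, character(1), "patient_id"))
  log_stage("ingest", length(samples), length(samples),
            sprintf("%d patients", length(all_patients)))

  # -- QC -------------------------------------------------------------------
  qc <- lapply(samples, qc_filter, thresholds = config$thresholds)
  qc_pass <- vapply(qc, `[[`, logical(1), "pass")
  qc_log <- dplyr::bind_rows(lapply(seq_along(samples), function(i) {
    tibble::tibble(sample_id = samples[[i]]$sample_id,
                   patient_id = samples[[i]]$patient_id,
                   timepoint = samples[[i]]$timepoint,
                   pass = qc_pass[i],
                   reasons = paste(qc[[i]]$reasons, collapse = "; "))
  }))
  log_stage("qc", length(samples), sum(qc_pass),
            sprintf("%d sample(s) removed", sum(!qc_pass)))

  # -- pairing --------------------------------------------------------------
  courses <- pair_timepoints(samples, qc_pass)
  kept <- Filter(function(cr) !is.null(cr$baseline) || !is.null(cr$post),
                 courses)
  patient_log <- tibble::tibble(
    patient_id = all_patients,
    status = ifelse(all_patients %in% names(kept), "analyzed", "excluded"),
    reason = ifelse(all_patients %in% names(kept), "",
                    "no sample passed QC"))
  log_stage("pairing", length(all_patients), length(kept),
            sprintf("%d with both timepoints",
                    sum(vapply(kept, `[[`, logical(1), "has_both"))))

  # -- metrics --------------------------------------------------------------
  metrics <- cohort_metrics(kept)
  log_stage("metrics", length(kept), nrow(metrics$courses))

  # -- networks -------------------------------------------------------------
  graphs <- lapply(kept, build_network)
  net <- network_summary(graphs, units = config$diameter_units)
  log_stage("networks", length(kept), nrow(net))

  # -- survival layer -------------------------------------------------------
  feats <- dplyr::left_join(metrics$courses,
                            net[, c("patient_id", "diameter",
                                    "diameter_group")],
                            by = "patient_id")
  feats <- dplyr::left_join(feats, clinical, by = "patient_id")
  feats <- feats[!is.na(feats$os_months), , drop = FALSE]
  log_stage("survival", nrow(metrics$courses), nrow(feats),
            "courses with clinical follow-up")

  km <- dplyr::bind_rows(
    km_group_summary(feats, ifelse(is.na(feats$increased_clonality), NA,
                                   ifelse(feats$increased_clonality,
                                          "increased", "decreased")),
                     grouping = "rcl"),
    km_group_summary(feats, ifelse(is.na(feats$increased_tcf), NA,
                                   ifelse(feats$increased_tcf,
                                          "increased", "decreased")),
                     grouping = "rtcf"),
    km_group_summary(feats, feats$dual_group, grouping = "dual"),
    km_group_summary(feats, feats$diameter_group, grouping = "diameter"))

  covs <- intersect(CLINICAL_COVARIATES, names(feats))
  feats$increased_clonality_num <- as.numeric(feats$increased_clonality)
  uni_terms <- c(covs, "baseline_clonality", "rcl",
                 "increased_clonality_num")
  uni <- dplyr::bind_rows(lapply(uni_terms, function(tm) {
    res <- tryCatch(cox_fit(feats, tm, ties = config$ties),
                    error = function(e) NULL)
    if (is.null(res)) {
      return(tibble::tibble(term = tm, hr = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, p = NA_real_))
    }
    res$terms[, c("term", "hr", "ci_low", "ci_high", "p")]
  }))
  names(uni)[-1] <- paste0("uni_", names(uni)[-1])

  full_terms <- c(covs, "increased_clonality_num")
  multi <- tryCatch(
    backward_select(feats, full_terms, p_keep = config$p_keep,
                    ties = config$ties),
    error = function(e) list(final = NULL,
                             trace = tibble::tibble(step = integer(),
                                                    removed = character(),
                                                    p = double())))
  if (!is.null(multi$final)) {
    mt <- multi$final$terms[, c("term", "hr", "ci_low", "ci_high", "p")]
    names(mt)[-1] <- paste0("multi_", names(mt)[-1])
    cox_table <- dplyr::left_join(uni, mt, by = "term")
  } else {
    cox_table <- uni
    cox_table$multi_hr <- NA_real_
    cox_table$multi_ci_low <- NA_real_
    cox_table$multi_ci_high <- NA_real_
    cox_table$multi_p <- NA_real_
  }

  assoc <- tryCatch(
    covariate_association_with_rcl(feats, covs),
    error = function(e) {
      tibble::tibble(term = character(), estimate = double(), or = double(),
                     ci_low = double(), ci_high = double(), p = double())
    })

  run_log <- dplyr::bind_rows(run_log)
  report <- structure(
    list(sample_metrics = metrics$samples,
         course_metrics = metrics$courses,
         network_summary = net,
         km_summaries = km,
         cox_table = cox_table,
         multivariable_trace = multi$trace,
         clonality_association = assoc,
         qc_log = qc_log,
         patient_log = patient_log,
         run_log = run_log,
         config = config),
    class = "analysis_report")

  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  print(x$run_log)
  invisible(x)
}

#' Write report artifacts to a directory
#'
#' @param report An [run_pipeline()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("sample_metrics", "course_metrics", "network_summary",
              "km_summaries", "cox_table", "multivariable_trace",
              "clonality_association", "qc_log", "patient_log", "run_log")
  for (tb in tables) {
    readr::write_csv(report[[tb]], file.path(dir, paste0(tb, ".csv")),
                     progress = FALSE)
  }
  invisible(dir)
}

#' Baseline characteristics table
#'
#' Frequency and percentage for binary covariates, median (range) for
#' continuous columns, in the style of a trial Table 1. Percentages are
#' printed to one decimal place.
#'
#' @param clinical Clinical tibble from [read_clinical_table()].
#' @param covariates Columns to summarise (defaults to the known covariate
#'   set intersected with the table).
#' @return A tibble with `characteristic` and `summary`.
#' @export
summarize_baseline <- function(clinical,
                               covariates = intersect(CLINICAL_COVARIATES,
                                                      names(clinical))) {
  unknown <- setdiff(covariates, names(clinical))
  if (length(unknown)) {
    stop("unknown covariate(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(clinical)
  rows <- lapply(covariates, function(cv) {
    v <- clinical[[cv]]
    v <- v[!is.na(v)]
    if (!length(v)) {
      warning("covariate '", cv, "' is empty; omitted", call. = FALSE)
      return(NULL)
    }
    if (all(v %in% c(0, 1, TRUE, FALSE))) {
      k <- sum(as.logical(v))
      tibble::tibble(characteristic = paste0(cv, " - no. (%)"),
                     summary = sprintf("%d (%.1f)", k, 100 * k / n))
    } else {
      tibble::tibble(characteristic = paste0(cv, " - median (range)"),
                     summary = sprintf("%.1f (%.1f-%.1f)",
                                       stats::median(v), min(v), max(v)))
    }
  })
  dplyr::bind_rows(rows)
}
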