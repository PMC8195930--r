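# Clonotype table ingestion, sample-level QC, and timepoint pairing.

AIRR_COLUMNS <- c("junction", "junction_aa", "duplicate_count",
                  "v_call", "j_call", "productive")
SIMPLE_COLUMNS <- c("nt_cdr3", "aa_cdr3", "read_count")

#' Construct a TCR repertoire from clonotype records
#'
#' A repertoire holds the clonotype table of one sample (one patient at one
#' timepoint). Clone identity is the nucleotide CDR3: rows sharing an
#' `nt_cdr3` are aggregated by summing `read_count`. Clone frequencies are
#' computed over productive records only; unproductive records are retained
#' (they enter `productive_fraction` and QC) but carry `NA` frequency and are
#' excluded from every downstream metric.
#'
#' @param records A data frame with columns `nt_cdr3`, `aa_cdr3`,
#'   `read_count`, and optionally `productive` (default `TRUE`), `v_gene`,
#'   `j_gene`.
#' @param sample_id,patient_id Sample and patient identifiers.
#' @param timepoint `"C1D1"` (baseline, pre-infusion) or `"C1D15"` (before the
#'   second infusion).
#' @param total_reads Library read depth. When `NULL` (the default) it falls
#'   back to the sum of `read_count` over all records, which is a lower bound
#'   on the true depth.
#'
#' @return An object of class `tcr_repertoire`: a list with the aggregated
#'   `records` tibble (columns `nt_cdr3`, `aa_cdr3`, `read_count`,
#'   `frequency`, `v_gene`, `j_gene`, `productive`), `sample_id`,
#'   `patient_id`, `timepoint`, `total_reads`, `productive_fraction`, and
#'   `n_unique_clones`.
#' @export
#' @examples
#' rep <- repertoire(
#'   data.frame(nt_cdr3 = c("TGTGCC", "TGCGCC", "TGTGCA"),
#'              aa_cdr3 = c("CASSL", "CASSL", "CASTL"),
#'              read_count = c(10, 30, 60)),
#'   sample_id = "S1", patient_id = "P1", timepoint = "C1D1")
#' rep$records$frequency
repertoire <- function(records, sample_id = NA_character_,
                       patient_id = NA_character_,
                       timepoint = c("C1D1", "C1D15"),
                       total_reads = NULL) {
  timepoint <- match.arg(timepoint)
  records <- tibble::as_tibble(records)
  for (col in c("nt_cdr3", "aa_cdr3", "read_count")) {
    if (!col %in% names(records)) {
      stop("clonotype records lack mandatory column '", col, "'",
           call. = FALSE)
    }
  }
  if (!"productive" %in% names(records)) records$productive <- TRUE
  if (!"v_gene" %in% names(records)) records$v_gene <- NA_character_
  if (!"j_gene" %in% names(records)) records$j_gene <- NA_character_

  records$nt_cdr3 <- as.character(records$nt_cdr3)
  records$aa_cdr3 <- as.character(records$aa_cdr3)
  records$read_count <- as.numeric(records$read_count)
  records$productive <- as.logical(records$productive)

  if (any(is.na(records$nt_cdr3) | !nzchar(records$nt_cdr3))) {
    stop("nt_cdr3 must be non-empty for every record", call. = FALSE)
  }
  if (any(is.na(records$read_count) | records$read_count < 0)) {
    stop("read_count must be a non-negative number for every record",
         call. = FALSE)
  }
  if (any(is.na(records$productive))) {
    stop("productive flag must be TRUE or FALSE for every record",
         call. = FALSE)
  }

  # Aggregate to nucleotide-level clones; annotation columns take the value
  # of the first (largest-count) row within each clone.
  records <- records[order(-records$read_count), , drop = FALSE]
  if (anyDuplicated(records$nt_cdr3)) {
    sums <- rowsum(records$read_count, records$nt_cdr3)
    records <- records[!duplicated(records$nt_cdr3), , drop = FALSE]
    records$read_count <- unname(sums[records$nt_cdr3, 1L])
  }
  records <- records[order(-records$read_count, records$nt_cdr3), ,
                     drop = FALSE]

  all_reads <- sum(records$read_count)
  productive_reads <- sum(records$read_count[records$productive])
  if (nrow(records) > 0L && productive_reads <= 0) {
    stop("degenerate sample: zero productive reads", call. = FALSE)
  }
  records$frequency <- ifelse(records$productive,
                              records$read_count / productive_reads,
                              NA_real_)

  records <- records[, c("nt_cdr3", "aa_cdr3", "read_count", "frequency",
                         "v_gene", "j_gene", "productive")]

  if (is.null(total_reads)) total_reads <- all_reads
  if (total_reads < all_reads) {
    stop("total_reads (", total_reads, ") is below the sum of read counts (",
         all_reads, ")", call. = FALSE)
  }

  structure(
    list(sample_id = sample_id,
         patient_id = patient_id,
         timepoint = timepoint,
         records = records,
         total_reads = total_reads,
         productive_fraction = if (all_reads > 0) {
           productive_reads / all_reads
         } else 0,
         n_unique_clones = nrow(records)),
    class = "tcr_repertoire")
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat("<tcr_repertoire> sample", x$sample_id,
      sprintf("(patient %s, %s)\n", x$patient_id, x$timepoint))
  cat(sprintf("  %d unique clones, %s reads, %.1f%% productive\n",
              x$n_unique_clones, format(x$total_reads, big.mark = ","),
              100 * x$productive_fraction))
  invisible(x)
}

#' Read a clonotype table into a repertoire
#'
#' Supports two dialects: `"airr_tsv"`, the AIRR Rearrangement TSV with
#' columns `junction` (nucleotide CDR3), `junction_aa`, `duplicate_count`,
#' `v_call`, `j_call`, `productive`; and `"simple_csv"`, a comma-separated
#' table with columns `nt_cdr3`, `aa_cdr3`, `read_count` and optional
#' `productive`, `v_gene`, `j_gene`. Clone frequencies are always recomputed
#' from read counts on ingestion (over productive records), never trusted
#' from the file.
#'
#' @param path Path to the table.
#' @param dialect `"airr_tsv"` or `"simple_csv"`.
#' @inheritParams repertoire
#' @return A [repertoire()] object.
#' @export
read_clonotype_table <- function(path, dialect = c("airr_tsv", "simple_csv"),
                                 sample_id = NULL, patient_id = NA_character_,
                                 timepoint = c("C1D1", "C1D15"),
                                 total_reads = NULL) {
  dialect <- match.arg(dialect)
  timepoint <- match.arg(timepoint)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }

  if (dialect == "airr_tsv") {
    tab <- readr::read_tsv(path, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = "c"))
    missing <- setdiff(AIRR_COLUMNS, names(tab))
    if (length(missing)) {
      stop("AIRR table ", path, " lacks mandatory column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    records <- tibble::tibble(
      nt_cdr3 = tab$junction,
      aa_cdr3 = tab$junction_aa,
      read_count = as.numeric(tab$duplicate_count),
      v_gene = tab$v_call,
      j_gene = tab$j_call,
      productive = parse_airr_logical(tab$productive))
  } else {
    tab <- readr::read_csv(path, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = "c"))
    missing <- setdiff(SIMPLE_COLUMNS, names(tab))
    if (length(missing)) {
      stop("simple_csv table ", path, " lacks mandatory column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    records <- tibble::tibble(
      nt_cdr3 = tab$nt_cdr3,
      aa_cdr3 = tab$aa_cdr3,
      read_count = as.numeric(tab$read_count),
      v_gene = if ("v_gene" %in% names(tab)) tab$v_gene else NA_character_,
      j_gene = if ("j_gene" %in% names(tab)) tab$j_gene else NA_character_,
      productive = if ("productive" %in% names(tab)) {
        parse_airr_logical(tab$productive)
      } else TRUE)
  }

  repertoire(records, sample_id = sample_id, patient_id = patient_id,
             timepoint = timepoint, total_reads = total_reads)
}

# AIRR encodes logicals as T/F; accept the common spellings.
parse_airr_logical <- function(x) {
  out <- rep(NA, length(x))
  out[x %in% c("T", "TRUE", "true", "True", "1")] <- TRUE
  out[x %in% c("F", "FALSE", "false", "False", "0")] <- FALSE
  out
}

#' Write a repertoire back to a clonotype table
#'
#' Writing then re-reading with the same dialect reproduces the repertoire
#' exactly (records, counts, and all derived fields).
#'
#' @param rep A [repertoire()] object.
#' @param path Output path.
#' @param dialect `"airr_tsv"` or `"simple_csv"`.
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(rep, path,
                                  dialect = c("airr_tsv", "simple_csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(rep, "tcr_repertoire"))
  rec <- rep$records
  ok <- tryCatch({
    if (dialect == "airr_tsv") {
      out <- tibble::tibble(
        junction = rec$nt_cdr3,
        junction_aa = rec$aa_cdr3,
        duplicate_count = rec$read_count,
        v_call = rec$v_gene,
        j_call = rec$j_gene,
        productive = ifelse(rec$productive, "T", "F"))
      readr::write_tsv(out, path, progress = FALSE)
    } else {
      out <- tibble::tibble(
        nt_cdr3 = rec$nt_cdr3,
        aa_cdr3 = rec$aa_cdr3,
        read_count = rec$read_count,
        productive = ifelse(rec$productive, "TRUE", "FALSE"),
        v_gene = rec$v_gene,
        j_gene = rec$j_gene)
      readr::write_csv(out, path, progress = FALSE)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("failed to write clonotype table to ", path, ": ",
         conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

#' Sample-level quality-control thresholds
#'
#' Defaults follow the retention rule used for bulk TCR-beta sequencing
#' libraries: at least 1000 unique clones, at least 800,000 reads of library
#' depth, and at least 40% productive reads.
#'
#' @param min_unique_clones Minimum number of unique nucleotide clones.
#' @param min_read_depth Minimum library read depth.
#' @param min_productive_fraction Minimum fraction of productive reads.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_unique_clones = 1000,
                          min_read_depth = 800000,
                          min_productive_fraction = 0.40) {
  stopifnot(min_unique_clones >= 0, min_read_depth >= 0,
            min_productive_fraction >= 0)
  structure(list(min_unique_clones = min_unique_clones,
                 min_read_depth = min_read_depth,
                 min_productive_fraction = min_productive_fraction),
            class = "qc_thresholds")
}

#' Apply sample-level QC to a repertoire
#'
#' A sample passes when all three criteria hold (each boundary inclusive):
#' `n_unique_clones >= min_unique_clones`, `total_reads >= min_read_depth`,
#' and `productive_fraction >= min_productive_fraction`.
#'
#' @param rep A [repertoire()] object.
#' @param thresholds A [qc_thresholds()] object.
#' @return A list with `pass` (logical) and `reasons` (character vector
#'   naming every failed criterion; empty when passing).
#' @export
qc_filter <- function(rep, thresholds = qc_thresholds()) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  reasons <- character()
  if (rep$n_unique_clones < thresholds$min_unique_clones) {
    reasons <- c(reasons, sprintf(
      "unique clones %d < %d", rep$n_unique_clones,
      thresholds$min_unique_clones))
  }
  if (rep$total_reads < thresholds$min_read_depth) {
    reasons <- c(reasons, sprintf(
      "read depth %s < %s", format(rep$total_reads, scientific = FALSE),
      format(thresholds$min_read_depth, scientific = FALSE)))
  }
  if (rep$productive_fraction < thresholds$min_productive_fraction) {
    reasons <- c(reasons, sprintf(
      "productive fraction %.3f < %.3f", rep$productive_fraction,
      thresholds$min_productive_fraction))
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Pair baseline and post-treatment samples into patient courses
#'
#' Groups QC-annotated samples by patient. A course has `has_both = TRUE`
#' only when both the C1D1 (baseline) and C1D15 (post) samples are present
#' *and* both passed QC; patients with a single passing timepoint are
#' retained for baseline-only analyses. Samples failing QC are dropped from
#' the course slots.
#'
#' @param samples A list of [repertoire()] objects.
#' @param qc_pass Logical vector, one flag per sample (e.g. from
#'   [qc_filter()]). Defaults to all passing.
#' @return A named list of `patient_course` objects, each with `patient_id`,
#'   `baseline` (repertoire or `NULL`), `post`, and `has_both`.
#' @export
pair_timepoints <- function(samples, qc_pass = rep(TRUE, length(samples))) {
  stopifnot(length(qc_pass) == length(samples))
  if (!length(samples)) return(structure(list(), names = character()))
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  pats <- vapply(samples, `[[`, character(1), "patient_id")
  tps <- vapply(samples, `[[`, character(1), "timepoint")
  key <- paste(pats, tps)
  if (anyDuplicated(key)) {
    stop("more than one sample for patient/timepoint: ",
         key[duplicated(key)][1L], call. = FALSE)
  }

  patients <- unique(pats)
  by_patient <- split(seq_along(samples), factor(pats, levels = patients))
  courses <- lapply(patients, function(p) {
    baseline <- post <- NULL
    for (i in by_patient[[p]]) {
      if (!qc_pass[i]) next
      if (tps[i] == "C1D1") baseline <- samples[[i]]
      if (tps[i] == "C1D15") post <- samples[[i]]
    }
    structure(list(patient_id = p, baseline = baseline, post = post,
                   has_both = !is.null(baseline) && !is.null(post)),
              class = "patient_course")
  })
  names(courses) <- patients
  courses
}

#' Read a patient-level clinical table
#'
#' Expects a CSV with columns `patient_id`, `os_months` (overall survival in
#' months from treatment start), `event` (1 = death observed, 0 = censored),
#' and any subset of the binary covariates `male_sex`, `age_ge_65`,
#' `squamous`, `pdl1_low_neg`, `ecog_1`, `ever_smoker`, `prior_line`,
#' `liver_mets`.
#'
#' @param path CSV path.
#' @return A tibble, one row per patient.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("patient_id", "os_months", "event")) {
    if (!col %in% names(tab)) {
      stop("clinical table lacks mandatory column '", col, "'",
           call. = FALSE)
    }
  }
  tab$patient_id <- as.character(tab$patient_id)
  if (any(tab$os_months <= 0, na.rm = TRUE)) {
    stop("os_months must be positive", call. = FALSE)
  }
  if (anyDuplicated(tab$patient_id)) {
    stop("duplicate patient_id in clinical table", call. = FALSE)
  }
  tab
}
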