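# Survival association layer: Kaplan-Meier estimation, log-rank tests, Cox
# proportional-hazards models with backward stepwise selection, and the
# covariate association with post-treatment clonality change.

#' Kaplan-Meier estimate of overall survival
#'
#' Product-limit estimator. The median is the smallest time at which the
#' survival curve drops to 0.5 or below; when the curve never reaches 0.5
#' the median is "not reached" and reported as `NA` with
#' `median_reached = FALSE`.
#'
#' @param time Follow-up times (months).
#' @param event Event indicator (1/TRUE = death observed, 0/FALSE =
#'   censored).
#' @return A `km_curve`: list with `curve` (tibble `time`, `n_risk`,
#'   `n_event`, `survival`), `median` (numeric or `NA`), `median_reached`,
#'   `n`, `n_events`.
#' @export
km_estimate <- function(time, event) {
  if (!length(time)) stop("no survival records", call. = FALSE)
  stopifnot(length(time) == length(event))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  med <- unname(summary(fit)$table["median"])
  structure(
    list(curve = tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                                n_event = fit$n.event, survival = fit$surv),
         median = med,
         median_reached = !is.na(med),
         n = fit$n,
         n_events = sum(fit$n.event)),
    class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, events = %d, median = %s\n",
              x$n, x$n_events, format_median(x$median)))
  invisible(x)
}

# "NR" (not reached) is a distinguished token, never a number.
format_median <- function(median) {
  if (is.na(median)) "NR" else format(round(median, 1), nsmall = 1)
}

#' Log-rank test for survival differences between groups
#'
#' @param time,event As in [km_estimate()].
#' @param group Group labels (2 or more non-empty groups).
#' @return A list with `chisq`, `df`, and `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L) {
    stop("log-rank test needs at least two non-empty groups", call. = FALSE)
  }
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(fit$n) - 1L
  list(chisq = unname(fit$chisq), df = df,
       p = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Fit a Cox proportional-hazards model
#'
#' Maximises the Cox partial likelihood over the requested terms and reports
#' per-term hazard ratios with Wald 95% confidence intervals and p-values.
#'
#' @param data Data frame with columns `os_months`, `event`, and every term.
#' @param terms Character vector of covariate names.
#' @param ties Tie handling: `"efron"` (default) or `"breslow"`.
#' @return A `cox_result`: list with `terms` (tibble `term`, `coef`, `hr`,
#'   `ci_low`, `ci_high`, `p`), `loglik`, `n`, `n_events`, `ties`, and the
#'   underlying `fit`.
#' @export
cox_fit <- function(data, terms, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(length(terms) >= 1L)
  missing_cols <- setdiff(c("os_months", "event", terms), names(data))
  if (length(missing_cols)) {
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- data[stats::complete.cases(data[, c("os_months", "event", terms)]), ]
  if (sum(data$event) < 1) {
    stop("Cox model needs at least one observed event", call. = FALSE)
  }
  for (tm in terms) {
    v <- data[[tm]]
    if (length(unique(v[!is.na(v)])) < 2L) {
      stop("degenerate design: covariate '", tm,
           "' is constant across subjects", call. = FALSE)
    }
  }

  fml <- stats::reformulate(terms,
                            response = "survival::Surv(os_months, event)")
  fit <- survival::coxph(fml, data = data, ties = ties)

  co <- summary(fit)$coefficients
  se <- co[, "se(coef)"]
  if (any(!is.finite(se)) || any(se > 50)) {
    bad <- rownames(co)[!is.finite(se) | se > 50][1L]
    stop("Cox model did not converge (monotone likelihood or complete ",
         "separation) for term '", bad, "'", call. = FALSE)
  }
  z <- stats::qnorm(0.975)
  structure(
    list(terms = tibble::tibble(
           term = rownames(co),
           coef = unname(co[, "coef"]),
           hr = unname(exp(co[, "coef"])),
           ci_low = unname(exp(co[, "coef"] - z * se)),
           ci_high = unname(exp(co[, "coef"] + z * se)),
           p = unname(co[, "Pr(>|z|)"])),
         loglik = fit$loglik[length(fit$loglik)],
         n = fit$n, n_events = fit$nevent, ties = ties, fit = fit),
    class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> n = %d, events = %d, ties = %s\n",
              x$n, x$n_events, x$ties))
  print(x$terms)
  invisible(x)
}

#' Backward stepwise selection for a Cox model
#'
#' Pure backward elimination: starting from the full model, repeatedly
#' refits after removing the single term with the largest Wald p-value at
#' or above `p_keep`, until every remaining term has `p < p_keep` (no
#' re-entry of removed terms). An all-noise model may end empty; this is
#' returned without error as `final = NULL`.
#'
#' @inheritParams cox_fit
#' @param full_terms Terms of the full starting model.
#' @param p_keep Retention threshold on the Wald p-value (default 0.2).
#' @return A list with `final` (a `cox_result`, or `NULL` when every term
#'   was removed) and `trace` (tibble `step`, `removed`, `p`).
#' @export
backward_select <- function(data, full_terms, p_keep = 0.2,
                            ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  terms <- full_terms
  trace <- tibble::tibble(step = integer(), removed = character(),
                          p = double())
  step <- 0L
  fit <- cox_fit(data, terms, ties = ties)
  repeat {
    worst <- which.max(fit$terms$p)
    if (fit$terms$p[worst] < p_keep) break
    step <- step + 1L
    # coefficient rows map 1:1 to terms (all covariates binary/continuous)
    removed <- terms[worst]
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      step = step, removed = removed, p = fit$terms$p[worst]))
    terms <- setdiff(terms, removed)
    if (!length(terms)) return(list(final = NULL, trace = trace))
    fit <- cox_fit(data, terms, ties = ties)
  }
  list(final = fit, trace = trace)
}

#' Covariate association with post-treatment clonality increase
#'
#' Multivariable logistic regression of the binary increased-clonality
#' indicator (relative clonality >= 1) on the clinical covariates, with
#' per-covariate Wald p-values. Covariates constant across patients are
#' excluded with a message.
#'
#' @param data Data frame with the logical/0-1 column `increased_clonality`
#'   and the covariate columns.
#' @param covariates Character vector of covariate names.
#' @return A tibble: `term`, `estimate` (log odds ratio), `or`, `ci_low`,
#'   `ci_high`, `p`.
#' @export
covariate_association_with_rcl <- function(data, covariates) {
  stopifnot("increased_clonality" %in% names(data))
  data <- data[!is.na(data$increased_clonality), , drop = FALSE]
  if (nrow(data) < 10L) {
    stop("need at least 10 patients with a defined increased-clonality ",
         "label", call. = FALSE)
  }
  keep <- character()
  for (cv in covariates) {
    v <- data[[cv]]
    if (length(unique(v[!is.na(v)])) < 2L) {
      message("covariate '", cv, "' is constant; excluded from the model")
    } else {
      keep <- c(keep, cv)
    }
  }
  if (!length(keep)) stop("no usable covariates", call. = FALSE)
  fml <- stats::reformulate(keep, response = "increased_clonality")
  fit <- stats::glm(fml, data = data, family = stats::binomial())
  co <- summary(fit)$coefficients
  co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
  if (any(co[, "Std. Error"] > 50)) {
    bad <- rownames(co)[co[, "Std. Error"] > 50][1L]
    stop("complete separation detected for term '", bad, "'", call. = FALSE)
  }
  z <- stats::qnorm(0.975)
  tibble::tibble(
    term = rownames(co),
    estimate = unname(co[, "Estimate"]),
    or = unname(exp(co[, "Estimate"])),
    ci_low = unname(exp(co[, "Estimate"] - z * co[, "Std. Error"])),
    ci_high = unname(exp(co[, "Estimate"] + z * co[, "Std. Error"])),
    p = unname(co[, "Pr(>|z|)"]))
}

#' Kaplan-Meier group summary with log-rank test
#'
#' @param data Data frame with `os_months` and `event`.
#' @param group Group labels aligned with `data` rows; `NA` rows are
#'   dropped.
#' @param grouping Name for the grouping, carried into the output.
#' @return A tibble with one row per group (`grouping`, `group`, `n`,
#'   `events`, `median_os` formatted with `"NR"` for not reached,
#'   `logrank_p`).
#' @export
km_group_summary <- function(data, group, grouping = "group") {
  keep <- !is.na(group)
  data <- data[keep, , drop = FALSE]
  group <- as.character(group[keep])
  if (!nrow(data) || length(unique(group)) < 2L) {
    return(tibble::tibble(grouping = character(), group = character(),
                          n = integer(), events = integer(),
                          median_os = character(), logrank_p = double()))
  }
  lr <- logrank_test(data$os_months, data$event, group)
  dplyr::bind_rows(lapply(sort(unique(group)), function(gr) {
    km <- km_estimate(data$os_months[group == gr], data$event[group == gr])
    tibble::tibble(grouping = grouping, group = gr, n = km$n,
                   events = km$n_events,
                   median_os = format_median(km$median),
                   logrank_p = lr$p)
  }))
}
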