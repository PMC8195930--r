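test_that("Kaplan-Meier matches hand product-limit computations", {
  km <- km_estimate(1:5, rep(1, 5))
  expect_equal(km$curve$survival[km$curve$time == 3], 0.4)
  expect_equal(km$median, 3)
  expect_true(km$median_reached)

  flat <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(flat$curve$survival == 1))
  expect_false(flat$median_reached)

  half <- km_estimate(c(2, 5), c(1, 0))
  expect_equal(half$curve$survival[half$curve$time == 2], 0.5)
  expect_equal(half$median, 2)
  expect_error(km_estimate(numeric(), numeric()), "no survival records")
})

test_that("KM on fully observed data equals the empirical survival function", {
  set.seed(41)
  t <- stats::rexp(40, 0.1)
  km <- km_estimate(t, rep(1, 40))
  ecdf_surv <- vapply(km$curve$time, function(x) mean(t > x), numeric(1))
  expect_equal(km$curve$survival, ecdf_surv)
})

test_that("log-rank test: null, invariances, and power", {
  t <- c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5)
  e <- rep(1, 10)
  g <- rep(c("a", "b"), each = 5)
  null_res <- logrank_test(t, e, g)
  expect_equal(null_res$chisq, 0, tolerance = 1e-10)
  expect_equal(null_res$p, 1, tolerance = 1e-10)

  set.seed(42)
  t2 <- c(stats::rexp(30, 0.1), stats::rexp(30, 0.4))
  g2 <- rep(c("a", "b"), each = 30)
  swap <- logrank_test(t2, rep(1, 60), g2)
  expect_equal(logrank_test(t2, rep(1, 60), rev(g2))$chisq, swap$chisq)

  expect_error(logrank_test(t2, rep(1, 60), rep("a", 60)), "two")

  # power: hazard ratio 3, n = 500 per arm, no censoring
  set.seed(43)
  hits <- vapply(1:200, function(i) {
    tt <- c(stats::rexp(500, 0.05), stats::rexp(500, 0.15))
    logrank_test(tt, rep(1, 1000), rep(c("a", "b"), each = 500))$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("Cox fit recovers null and non-null effects in simulation", {
  # null covariate: mean log-HR within 3 SD-of-the-mean of 0 over 200 seeds
  set.seed(44)
  coefs <- vapply(1:200, function(i) {
    d <- data.frame(os_months = stats::rexp(300, 0.1),
                    event = 1, x = stats::rbinom(300, 1, 0.5))
    cox_fit(d, "x")$terms$coef
  }, numeric(1))
  expect_lt(abs(mean(coefs)), 3 * stats::sd(coefs) / sqrt(200))

  # true HR 2.0, n = 500, ~30% censoring: mean HR within [1.8, 2.2]
  set.seed(45)
  hrs <- vapply(1:200, function(i) {
    x <- stats::rbinom(500, 1, 0.5)
    t_event <- stats::rexp(500, 0.1 * 2^x)
    t_cens <- stats::rexp(500, 0.043)
    d <- data.frame(os_months = pmin(t_event, t_cens),
                    event = as.integer(t_event <= t_cens), x = x)
    cox_fit(d, "x")$terms$hr
  }, numeric(1))
  expect_gte(mean(hrs), 1.8)
  expect_lte(mean(hrs), 2.2)
})

test_that("Cox fit validates its design and reports Wald intervals", {
  d <- data.frame(os_months = c(1, 2, 3, 4), event = c(0, 0, 0, 0),
                  x = c(0, 1, 0, 1))
  expect_error(cox_fit(d, "x"), "at least one observed event")
  d$event <- c(1, 1, 0, 0)
  d$z <- 1
  expect_error(cox_fit(d, "z"), "constant")
  expect_error(cox_fit(d, "missing_col"), "missing_col")

  set.seed(46)
  d2 <- data.frame(os_months = stats::rexp(80, 0.1), event = 1,
                   x = stats::runif(80))
  fit <- cox_fit(d2, "x")
  expect_true(fit$terms$ci_low <= fit$terms$hr)
  expect_true(fit$terms$hr <= fit$terms$ci_high)
  expect_gt(fit$terms$hr, 0)
})

test_that("Efron and Breslow agree when all event times are distinct", {
  set.seed(47)
  d <- data.frame(os_months = sample(seq(1, 400) / 7, 60),
                  event = stats::rbinom(60, 1, 0.8),
                  x = stats::rbinom(60, 1, 0.5))
  fe <- cox_fit(d, "x", ties = "efron")
  fb <- cox_fit(d, "x", ties = "breslow")
  expect_equal(fe$terms$coef, fb$terms$coef, tolerance = 1e-10)
})

test_that("backward selection is a fixed point when all terms are strong", {
  set.seed(48)
  n <- 400
  x1 <- stats::rbinom(n, 1, 0.5)
  x2 <- stats::rbinom(n, 1, 0.5)
  t_event <- stats::rexp(n, 0.05 * exp(log(3) * x1 + log(3) * x2))
  d <- data.frame(os_months = t_event, event = 1, x1 = x1, x2 = x2)
  sel <- backward_select(d, c("x1", "x2"))
  expect_equal(nrow(sel$trace), 0L)
  expect_setequal(sel$final$terms$term, c("x1", "x2"))
  full <- cox_fit(d, c("x1", "x2"))
  expect_equal(sel$final$terms$coef, full$terms$coef)
})

test_that("backward selection retains a true covariate among noise", {
  set.seed(49)
  kept <- vapply(1:100, function(i) {
    n <- 400
    x <- stats::rbinom(n, 1, 0.5)
    noise <- matrix(stats::rbinom(n * 5, 1, 0.5), n, 5)
    colnames(noise) <- paste0("n", 1:5)
    d <- data.frame(os_months = stats::rexp(n, 0.05 * 2^x), event = 1,
                    x = x, noise)
    sel <- backward_select(d, c("x", paste0("n", 1:5)))
    !is.null(sel$final) && "x" %in% sel$final$terms$term
  }, logical(1))
  expect_gte(mean(kept), 0.9)
})

test_that("backward selection terminates, never drops retained terms,
           and tolerates all-noise models", {
  set.seed(50)
  n <- 200
  noise <- matrix(stats::rbinom(n * 4, 1, 0.5), n, 4)
  colnames(noise) <- paste0("n", 1:4)
  d <- data.frame(os_months = stats::rexp(n, 0.1), event = 1, noise)
  sel <- backward_select(d, paste0("n", 1:4), p_keep = 0.2)
  expect_lte(nrow(sel$trace), 4L)
  if (!is.null(sel$final)) {
    expect_true(all(sel$final$terms$p < 0.2))
    expect_false(any(sel$final$terms$term %in% sel$trace$removed))
  }
  # forcing every term out must return an empty model without error
  sel0 <- backward_select(d, paste0("n", 1:4), p_keep = 1e-12)
  expect_null(sel0$final)
  expect_equal(nrow(sel0$trace), 4L)
})

test_that("clonality-change association: power and degenerate covariates", {
  set.seed(51)
  hits <- vapply(1:100, function(i) {
    n <- 200
    male <- stats::rbinom(n, 1, 0.5)
    inc <- stats::rbinom(n, 1, ifelse(male == 1, 0.7, 0.3))
    d <- data.frame(increased_clonality = inc, male_sex = male,
                    age_ge_65 = stats::rbinom(n, 1, 0.5))
    res <- covariate_association_with_rcl(d, c("male_sex", "age_ge_65"))
    res$p[res$term == "male_sex"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  d <- data.frame(increased_clonality = stats::rbinom(50, 1, 0.5),
                  male_sex = stats::rbinom(50, 1, 0.5),
                  all_same = 1)
  expect_message(
    res <- covariate_association_with_rcl(d, c("male_sex", "all_same")),
    "constant")
  expect_false("all_same" %in% res$term)
  expect_error(covariate_association_with_rcl(
    data.frame(increased_clonality = c(1, 0), male_sex = c(1, 0)),
    "male_sex"), "at least 10")
})

test_that("clonality-change association p-values are calibrated under null", {
  set.seed(52)
  pvals <- vapply(1:500, function(i) {
    n <- 60
    d <- data.frame(increased_clonality = stats::rbinom(n, 1, 0.5),
                    male_sex = stats::rbinom(n, 1, 0.5))
    covariate_association_with_rcl(d, "male_sex")$p
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("KM group summaries carry NR medians and log-rank p", {
  set.seed(53)
  d <- data.frame(os_months = c(stats::rexp(30, 0.2), stats::rexp(30, 0.01)),
                  event = rep(1:0, c(30, 30)))
  grp <- rep(c("bad", "good"), each = 30)
  tab <- km_group_summary(d, grp, grouping = "demo")
  expect_equal(tab$grouping, c("demo", "demo"))
  expect_equal(tab$median_os[tab$group == "good"], "NR")
  expect_equal(tab$logrank_p[1], tab$logrank_p[2])
  # degenerate single-group input yields an empty frame, not an error
  expect_equal(nrow(km_group_summary(d, rep("x", 60))), 0L)
})
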