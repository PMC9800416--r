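surv_tbl <- function(time, event, group = NULL) {
  t <- tibble::tibble(time = time, event = event)
  if (!is.null(group)) t$group <- group
  t
}

test_that("KM estimator matches hand-computed product limits", {
  # all censored: flat at 1
  flat <- km_curve(surv_tbl(c(2, 4, 6), c(FALSE, FALSE, FALSE)))
  expect_true(all(flat$survival == 1))

  # events at 1 and 3, censoring at 2
  km <- km_curve(surv_tbl(c(1, 2, 3), c(TRUE, FALSE, TRUE)))
  s_at <- function(t) km$survival[max(which(km$time <= t))]
  expect_equal(s_at(0), 1)
  expect_equal(s_at(1.5), 2 / 3)
  expect_equal(s_at(3), 0)

  # duplicating every sample leaves the curve unchanged
  km2 <- km_curve(surv_tbl(rep(c(1, 2, 3), 2), rep(c(TRUE, FALSE, TRUE), 2)))
  expect_equal(unique(km2$survival), unique(km$survival))
})

test_that("KM equals the brute-force product over event times", {
  withr::with_seed(90, {
    time <- round(rexp(40, 0.1), 2)
    event <- runif(40) < 0.7
  })
  km <- km_curve(surv_tbl(time, event))
  for (t in c(2, 5, 10, 20)) {
    expect_equal(km$survival[max(which(km$time <= t))],
                 km_brute(time, event, t), tolerance = 1e-12)
  }
})

test_that("log-rank is null on identical groups, invariant to time units", {
  time <- c(1, 3, 5, 7); event <- c(TRUE, TRUE, FALSE, TRUE)
  same <- surv_tbl(rep(time, 2), rep(event, 2), rep(c("a", "b"), each = 4))
  res <- log_rank(same)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)

  withr::with_seed(91, {
    s <- surv_tbl(rexp(60, 0.1), runif(60) < 0.7, rep(c("a", "b"), 30))
  })
  r1 <- log_rank(s)
  s2 <- s; s2$time <- s2$time * 30.4  # months -> days
  expect_equal(log_rank(s2)$statistic, r1$statistic, tolerance = 1e-12)

  expect_error(log_rank(surv_tbl(c(1, 2), c(FALSE, FALSE), c("a", "b"))),
               "no events")
})

test_that("log-rank detects a planted hazard ratio with high power", {
  hits <- purrr::map_lgl(1:100, function(s) {
    withr::with_seed(1000 + s, {
      t1 <- rexp(50, 0.1); t2 <- rexp(50, 0.3)   # hazard ratio 3
      cens <- rexp(100, 0.045)                   # ~30% censoring
      time <- pmin(c(t1, t2), cens)
      event <- c(t1, t2) <= cens
    })
    log_rank(surv_tbl(time, event, rep(c("a", "b"), each = 50)))$p_value < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("log-rank type-I error is controlled on the null", {
  rejections <- purrr::map_lgl(1:2000, function(s) {
    withr::with_seed(5000 + s, {
      time <- rexp(60, 0.1)
      event <- runif(60) < 0.7
      group <- rep(c("a", "b"), 30)
    })
    log_rank(surv_tbl(time, event, group))$p_value < 0.05
  })
  expect_lte(mean(rejections), 0.07)
})

test_that("Cox handles symmetry, inversion, and recovers a planted HR", {
  time <- c(1, 3, 5, 7); event <- c(TRUE, TRUE, FALSE, TRUE)
  same <- surv_tbl(rep(time, 2), rep(event, 2), rep(c("a", "b"), each = 4))
  expect_equal(cox_univariate(same)$hr, 1, tolerance = 1e-6)

  withr::with_seed(92, {
    s <- surv_tbl(rexp(80, 0.1), runif(80) < 0.8, rep(c("a", "b"), 40))
  })
  fit <- cox_univariate(s)
  flipped <- s
  flipped$group <- ifelse(s$group == "a", "z", "a")  # invert level order
  expect_equal(cox_univariate(flipped)$hr, 1 / fit$hr, tolerance = 1e-9)

  hrs <- purrr::map_dbl(1:20, function(s) {
    withr::with_seed(2000 + s, {
      t1 <- rexp(100, 0.1); t2 <- rexp(100, 0.2)  # HR 2
      cens <- rexp(200, 0.03)                     # ~20% censoring
      time <- pmin(c(t1, t2), cens)
      event <- c(t1, t2) <= cens
    })
    cox_univariate(surv_tbl(time, event, rep(c("a", "b"), each = 100)))$hr
  })
  expect_gte(median(hrs), 1.6)
  expect_lte(median(hrs), 2.5)

  no_ev <- surv_tbl(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE),
                    rep(c("a", "b"), each = 2))
  expect_error(cox_univariate(no_ev), "monotone likelihood")
})

test_that("tidy and glance expose the Cox fit in broom shape", {
  withr::with_seed(93, {
    s <- surv_tbl(rexp(60, 0.1), runif(60) < 0.8, rep(c("a", "b"), 30))
  })
  fit <- cox_univariate(s)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic",
                     "p.value", "conf.low", "conf.high"))
  expect_equal(exp(td$estimate), fit$hr)
  expect_equal(glance(fit)$n, 60)
})

test_that("the six-month endpoint censors at the boundary inclusively", {
  s <- surv_tbl(c(3, 6, 6.5, 9), c(TRUE, TRUE, TRUE, TRUE),
                c("a", "a", "b", "b"))
  r <- rfs6m(s)
  expect_equal(r$samples$time, c(3, 6, 6, 6))
  expect_equal(r$samples$event, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unname(r$table["yes", "a"]), 2)
  expect_equal(unname(r$table["yes", "b"]), 0)

  late <- surv_tbl(c(8, 9, 10, 11), rep(TRUE, 4), rep(c("a", "b"), 2))
  expect_message(r2 <- rfs6m(late), "degenerate")
  expect_equal(sum(r2$table["yes", ]), 0)
  expect_true(is.na(r2$test$p_value))
})

test_that("early-relapse chi-square p-values are near-uniform on the null", {
  ps <- purrr::map_dbl(1:200, function(s) {
    withr::with_seed(7000 + s, {
      time <- rexp(200, 0.12)
      event <- rep(TRUE, 200)
      group <- rep(c("a", "b"), 100)
    })
    rfs6m(surv_tbl(time, event, group))$test$p_value
  })
  # table counts are discrete, so a few identical p-values are expected
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("administrative censoring respects the stated boundary rule", {
  s <- surv_tbl(c(5, 6, 7), c(TRUE, TRUE, TRUE))
  c6 <- censor_at(s, 6)
  expect_equal(c6$event, c(TRUE, TRUE, FALSE))
  expect_equal(c6$time, c(5, 6, 6))
  expect_error(censor_at(surv_tbl(0, TRUE), 6), "> 0")
})
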