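# simulated cohort with exponential survival and one planted log-hazard
sim_cohort <- function(n, beta = 0, seed = 1, censor = FALSE,
                       binary = TRUE) {
  set.seed(seed)
  x <- if (binary) rbinom(n, 1, 0.5) else rnorm(n)
  t_ev <- rexp(n, rate = 0.01 * exp(beta * x))
  if (censor) {
    t_cs <- rexp(n, rate = 0.004)
    time <- pmin(t_ev, t_cs); event <- as.integer(t_ev <= t_cs)
  } else { time <- t_ev; event <- rep(1L, n) }
  clinical <- data.frame(sample_id = paste0("s", seq_len(n)),
                         time = time, event = event, subtype = "CIN",
                         stringsAsFactors = FALSE)
  expr <- matrix(x, nrow = 1,
                 dimnames = list("gX", clinical$sample_id))
  survival_data(clinical, expr)
}

test_that("univariate Cox flags degenerate inputs and recovers planted beta", {
  cens <- sim_cohort(20, censor = FALSE)
  cens$clinical$event <- 0L
  r <- univariate_cox(cens, "gX")
  expect_false(r$ok)

  flat <- sim_cohort(20)
  flat$expression["gX", ] <- 1
  expect_false(univariate_cox(flat, "gX")$ok)

  sd_ <- sim_cohort(300, beta = 1, seed = 5, censor = TRUE)
  r <- univariate_cox(sd_, "gX")
  expect_true(r$ok)
  expect_lt(abs(r$beta - 1), 0.25)
  expect_error(univariate_cox(sd_, "nope"), "not in expression")
})

test_that("signature screening keeps p < threshold genes in input order", {
  set.seed(11)
  n <- 300
  x <- matrix(rnorm(4 * n), nrow = 4,
              dimnames = list(c("risk1", "risk2", "null1", "null2"),
                              paste0("s", 1:n)))
  lh <- 1.0 * x["risk1", ] + 1.0 * x["risk2", ]
  t_ev <- rexp(n, rate = 0.01 * exp(lh))
  clinical <- data.frame(sample_id = paste0("s", 1:n), time = t_ev,
                         event = 1L, subtype = "CIN")
  sd_ <- survival_data(clinical, x)
  model <- build_signature(sd_, rownames(x))
  expect_true(all(c("risk1", "risk2") %in% model$genes))
  expect_true(all(model$beta[model$genes %in% c("risk1", "risk2")] > 0))

  expect_warning(empty <- build_signature(sd_, rownames(x),
                                          p_threshold = 0),
                 "empty model")
  expect_equal(empty$n, 0L)

  dup <- build_signature(sd_, c("risk1", "risk1"))
  expect_equal(dup$beta[1], dup$beta[2])
})

test_that("risk score is the exact linear combination", {
  model <- structure(list(genes = c("a", "b"), beta = c(0.5, -1), n = 2L),
                     class = "risk_model")
  expect_equal(risk_score(model, c(a = 2, b = 1)), 0)
  expect_equal(risk_score(model, c(a = 3.2, b = 0)), 1.6)
  empty <- structure(list(genes = character(), beta = numeric(), n = 0L),
                     class = "risk_model")
  expect_equal(risk_score(empty, c(a = 1)), 0)
  expect_error(risk_score(model, c(a = 1)), "missing signature gene")
  # linearity in expression
  e <- c(a = 1.3, b = -0.7)
  expect_equal(risk_score(model, 3 * e), 3 * risk_score(model, e))
})

test_that("median dichotomization sends ties to low risk", {
  mk <- function(scores) {
    n <- length(scores)
    clinical <- data.frame(sample_id = paste0("s", 1:n), time = 1:n,
                           event = 1L, subtype = "CIN")
    sd_ <- survival_data(clinical,
                         matrix(scores, 1, dimnames = list(
                           "g", clinical$sample_id)))
    model <- structure(list(genes = "g", beta = 1, n = 1L),
                       class = "risk_model")
    dichotomize(sd_, model)
  }
  d <- mk(c(1, 2, 3, 4))
  expect_equal(d$cutoff, 2.5)
  expect_setequal(d$high_risk, c("s3", "s4"))
  d3 <- mk(c(1, 2, 3))
  expect_equal(d3$cutoff, 2)
  expect_equal(d3$high_risk, "s3")
  expect_error(mk(rep(2, 4)), "non-informative")
})

test_that("Kaplan-Meier steps only at events and matches hand risk sets", {
  km <- km_estimate(data.frame(time = c(1, 2), event = c(1, 1)))
  expect_equal(km$surv, c(0.5, 0))

  km2 <- km_estimate(data.frame(time = c(1, 2), event = c(1, 0)))
  expect_equal(km2$surv[km2$time == 1], 0.5)
  expect_equal(min(km2$surv), 0.5)  # censoring adds no step

  # mixed case against hand-tabulated risk sets:
  # events at 1 (n=6), 3 (n=4), 5 (n=2); censored at 2 and 4
  cl <- data.frame(time = c(1, 2, 3, 3, 4, 5), event = c(1, 0, 1, 1, 0, 1))
  km3 <- km_estimate(cl)
  s_hand <- cumprod(c(1 - 1 / 6, 1 - 2 / 4, 1 - 1 / 1))
  expect_equal(km3$surv[km3$n_event > 0], s_hand)

  # without censoring the curve equals the empirical survival function
  set.seed(2)
  tt <- rexp(40)
  km4 <- km_estimate(data.frame(time = tt, event = 1L))
  for (q in quantile(tt, c(0.2, 0.5, 0.8)))
    expect_equal(km_surv_at(km4, q), oracle_empirical_surv(tt, q))
  # monotone non-increasing from S(0) = 1
  expect_true(all(diff(c(1, km4$surv)) <= 1e-12))
})

test_that("log-rank is null on duplicated groups and label-symmetric", {
  a <- data.frame(time = c(3, 5, 8, 10), event = c(1, 0, 1, 1))
  same <- logrank(a, a)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)

  b <- data.frame(time = c(1, 2, 4, 9), event = c(1, 1, 0, 1))
  expect_equal(logrank(a, b)$statistic, logrank(b, a)$statistic)

  # single event: one term, variance n_a n_b / n^2 ... hand value 1
  single <- logrank(data.frame(time = 1, event = 1),
                    data.frame(time = 2, event = 0))
  expect_equal(single$statistic, 1)
  expect_error(logrank(data.frame(time = 1, event = 0),
                       data.frame(time = 2, event = 0)), "no events")
})

test_that("subtype markers classify protective genes and respect thresholds", {
  sd_ <- sim_cohort(200, beta = -0.8, seed = 7, censor = TRUE,
                    binary = FALSE)
  mk <- suppressWarnings(subtype_markers(sd_, "gX", subtypes = "CIN"))
  expect_equal(nrow(mk), 1L)
  expect_equal(mk$class, "Protective")
  expect_lt(mk$beta, 0)

  # too few events: subtype skipped with a warning
  few <- sim_cohort(10, seed = 3)
  few$clinical$event <- c(1L, rep(0L, 9))
  expect_warning(out <- subtype_markers(few, "gX", subtypes = "CIN"),
                 "fewer than 2 events")
  expect_equal(nrow(out), 0L)
})
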