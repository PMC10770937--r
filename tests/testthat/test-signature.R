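test_that("the 7:3 split reproduces the cohort-scale counts and is seeded", {
  ids <- sprintf("P%03d", 1:274)
  ev <- rep(c(1, 0), length.out = 274)
  s1 <- split_cohort(ids, ev, seed = 5)
  expect_equal(sum(s1$set == "train"), 192L)
  expect_equal(sum(s1$set == "test"), 82L)
  s2 <- split_cohort(ids, ev, seed = 5)
  expect_identical(s1, s2)
  expect_false(identical(s1$set, split_cohort(ids, ev, seed = 6)$set))

  big <- split_cohort(sprintf("Q%04d", 1:1000), rep(1, 1000), seed = 1)
  expect_true(abs(mean(big$set == "train") - 0.7) <= 0.01)

  expect_warning(
    split_cohort(sprintf("R%03d", 1:30), rep(c(1, 0, 0), 10), seed = 1,
                 n_variables = 10),
    "events per variable")
})

test_that("all three rankings put a strongly prognostic feature first", {
  set.seed(20)
  n <- 300; p <- 20
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%02d", 1:p)))
  # f01 perfectly rank-orders the hazard; the rest is noise
  time <- rexp(n, rate = exp(1.5 * x[, 1]))
  event <- rep(1L, n)
  for (m in c("lasso", "boosting", "random_forest")) {
    rk <- rank_importance(x, time, event, method = m, seed = 3, n_boot = 50)
    expect_identical(rk$top10[1L], "f01")
  }
})

test_that("constant features get zero importance and rankings are seeded", {
  set.seed(21)
  n <- 120
  x <- cbind(sig = rnorm(n), flat = rep(1, n), noise = rnorm(n))
  time <- rexp(n, exp(x[, "sig"])); event <- rbinom(n, 1, 0.7)
  expect_message(
    rk <- rank_importance(x, time, event, "lasso", seed = 2),
    "constant")
  expect_equal(unname(rk$scores["flat"]), 0)
  rk2 <- suppressMessages(
    rank_importance(x, time, event, "boosting", seed = 9, n_boot = 20))
  rk3 <- suppressMessages(
    rank_importance(x, time, event, "boosting", seed = 9, n_boot = 20))
  expect_identical(rk2$scores, rk3$scores)
})

test_that("top-10 intersection keeps shared features ordered by mean rank", {
  mk <- function(top) structure(list(method = "lasso",
                                     scores = numeric(0), top10 = top),
                                class = "trm_ranking")
  a <- mk(c("A", "B", "C", "D"))
  b <- mk(c("B", "A", "E", "C"))
  c_ <- mk(c("C", "B", "A", "F"))
  expect_identical(intersect_top10(list(a, b, c_)), c("B", "A", "C"))
  expect_identical(intersect_top10(list(a, a, a)), c("A", "B", "C", "D"))
  expect_error(intersect_top10(list(a, mk(c("X", "Y")), a)), "no feature")
})

test_that("the cut-point search finds a planted separation and matches brute force", {
  # survival perfectly separated at feature = 5
  n <- 60
  values <- c(seq(1, 5, length.out = 30), seq(5.2, 9, length.out = 30))
  time <- c(runif(30, 50, 100), runif(30, 1, 20))
  event <- rep(1L, n)
  cut <- find_cutoff(values, time, event)
  expect_gte(cut, 4.8)
  expect_lt(cut, 5.2)

  expect_error(find_cutoff(rep(2, 40), runif(40), rbinom(40, 1, 0.5)),
               "cut-point")

  # exhaustive scan equals an independent log-rank computation
  set.seed(30)
  v <- rnorm(50); t2 <- rexp(50, exp(0.5 * v)); e2 <- rbinom(50, 1, 0.8)
  cand <- sort(unique(v))
  ok <- vapply(cand, function(th) {
    min(sum(v > th), sum(v <= th)) >= ceiling(0.1 * 50)
  }, logical(1L))
  stats <- vapply(cand[ok], function(th) {
    brute_logrank_chisq(v > th, t2, e2)
  }, numeric(1L))
  best <- cand[ok][which.max(stats)]
  got <- find_cutoff(v, t2, e2)
  expect_equal(as.numeric(got), best, tolerance = 1e-9)
  expect_equal(attr(got, "statistic"), max(stats), tolerance = 1e-9)
})

test_that("signature weights are univariate Cox log hazard ratios", {
  set.seed(40)
  n <- 300
  f1 <- rnorm(n); f2 <- rnorm(n)
  x1 <- as.numeric(f1 > 0); x2 <- as.numeric(f2 > 0)
  b1 <- 0.9; b2 <- -0.8
  time <- rexp(n, rate = 0.02 * exp(b1 * x1 + b2 * x2))
  cens <- runif(n, 0, 150)
  feats <- data.frame(patient_id = sprintf("P%03d", 1:n), f1 = f1, f2 = f2)
  model <- fit_signature(feats, pmin(time, cens),
                         as.integer(time <= cens), c("f1", "f2"))
  # planted log hazard ratios recovered within +/- 25%
  expect_lt(abs(model$weights[["f1"]] - b1), 0.25 * abs(b1))
  expect_lt(abs(model$weights[["f2"]] - b2), 0.25 * abs(b2))
  expect_equal(model$hr, exp(model$weights), tolerance = 1e-12)
})

test_that("scoring is the exact weighted indicator sum with imputation", {
  model <- structure(
    list(features = c("a", "b"),
         medians = c(a = 0, b = 0),
         cutoffs = c(a = 1, b = 2),
         weights = c(a = log(2.04), b = log(0.41)),
         hr = c(a = 2.04, b = 0.41),
         sis_cutoff = 0, min_frac = 0.1),
    class = "trm_sis")
  feats <- data.frame(a = c(2, 0, 2, NA), b = c(3, 0, 0, 3))
  sc <- score_patients(model, feats)
  expect_equal(sc$sis,
               c(log(2.04) + log(0.41), 0, log(2.04), log(0.41)))
  expect_identical(sc$risk_group, c("low", "low", "high", "low"))
  # monotone: raising an indicator with positive weight never lowers SIS
  expect_gte(sc$sis[3L], sc$sis[1L])
})

test_that("model serialization round-trips and scoring uses no test data", {
  set.seed(50)
  n <- 120
  feats <- data.frame(patient_id = sprintf("P%03d", 1:n),
                      u = rnorm(n), v = rnorm(n))
  time <- rexp(n, 0.02 * exp(0.8 * (feats$u > 0)))
  event <- rbinom(n, 1, 0.8)
  model <- fit_signature(feats, time, event, c("u", "v"))
  path <- withr::local_tempfile(fileext = ".json")
  write_signature(model, path, radius = 20)
  model2 <- read_signature(path)
  expect_equal(model2$weights, model$weights)
  expect_equal(model2$cutoffs, model$cutoffs)
  expect_equal(model2$sis_cutoff, model$sis_cutoff)
  expect_equal(model2$radius, 20)

  # mutating the scored (test) data cannot change the model or the
  # scores of untouched patients
  newdata <- feats
  newdata$u[1:10] <- 99
  s_ref <- score_patients(model, feats)
  s_mut <- score_patients(model, newdata)
  expect_equal(s_mut$sis[11:n], s_ref$sis[11:n])
})
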