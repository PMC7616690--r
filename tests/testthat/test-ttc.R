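# Sigmoid-CDF head, losses, risk score, stratification, baselines.

test_that("spatial entropy hits its analytic extremes", {
  M <- array(1, c(1, 12, 12, 16))           # uniform over 2304 positions
  expect_equal(spatial_entropy(M), log(2304), tolerance = 1e-12)
  M1 <- array(0, c(1, 12, 12, 16)); M1[1, 3, 4, 5] <- 7
  expect_equal(spatial_entropy(M1), 0)
  M2 <- array(0, c(1, 4, 4, 2)); M2[1, 1, 1, 1] <- 2; M2[1, 2, 2, 2] <- 2
  expect_equal(spatial_entropy(M2), log(2))
  expect_error(spatial_entropy(array(0, c(1, 2, 2, 2))), "positive sum")
})

test_that("head_predict: b monotone in mean(M), a = 0.5 at zero entropy input", {
  cls <- withr::with_seed(1, ttc_classifier())
  b_of <- function(scale) {
    M <- array(scale, c(1, 6, 6, 4))
    head_predict(M, cls)$b
  }
  bs <- vapply(c(0.1, 0.5, 1, 2, 5), b_of, numeric(1))
  expect_true(all(diff(bs) < 0))            # larger GAP -> smaller b
  # one-hot M has H = 0 -> a = sigmoid(0) = 0.5 regardless of alpha2
  M1 <- array(0, c(1, 6, 6, 4)); M1[1, 2, 3, 1] <- 3
  expect_equal(head_predict(M1, cls)$a, 0.5)
  # alpha2 = 0 -> a = 0.5 for any M
  cls$alpha2$params$log_v <- -Inf
  M <- array(runif(144), c(1, 6, 6, 4))
  expect_equal(head_predict(M, cls)$a, 0.5)
})

test_that("CDF evaluation matches the closed form and is monotone", {
  cdf <- sigmoid_cdf(a = 0.2, b = 0.5)
  expect_equal(cdf_eval(cdf, 0.5), 0.5)     # p at t = b is exactly 1/2
  expect_equal(cdf_eval(cdf, 1.0), 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_lt(cdf_eval(cdf, -50), 1e-8)
  # monotone over random parameter draws
  withr::with_seed(2, for (i in 1:25) {
    cd <- sigmoid_cdf(runif(1, 0.01, 0.99), runif(1, 0, 2))
    ts <- sort(runif(7, -1, 2))
    expect_true(all(diff(cdf_eval(cd, ts)) > 0))
  })
})

test_that("interval-censored loss covers its three cases", {
  # case 3 with p0 = p1 = 0.5: -0.5(log .5) * 2 terms * 2 points = log 2
  cdf5 <- sigmoid_cdf(a = 0.5, b = 0.5)
  # construct a CDF with p ~ 0.5 at both ends: b = 0.5 gives symmetric p
  lab3 <- ttc_label(-Inf, 0)
  p0 <- cdf_eval(cdf5, 0); p1 <- cdf_eval(cdf5, 1)
  expect_equal(ttc_loss(cdf5, lab3),
               -0.5 * log(p0) - 0.5 * log(p1), tolerance = 1e-12)
  # case 1 -> 0 when the CDF separates the bracket perfectly
  sharp <- sigmoid_cdf(a = 0.011, b = 0.5)
  lab1 <- ttc_label(1, 17)  # normalized ~0.056 and ~0.94
  expect_lt(ttc_loss(sharp, lab1), 0.01)
  # case 2 equals case 1 evaluated at t = 0, 1 with labels (0, 0)
  lab2 <- ttc_label(Inf, Inf)
  ce <- function(p, y) -0.5 * (y * log(p) + (1 - y) * log(1 - p))
  cdf <- sigmoid_cdf(0.3, 0.8)
  expect_equal(ttc_loss(cdf, lab2),
               ce(cdf_eval(cdf, 0), 0) + ce(cdf_eval(cdf, 1), 0))
  # invalid partition rejected
  expect_error(ttc_label(10, 25), "none of the three")
  expect_error(ttc_label(12, 5), "none of the three")
})

test_that("total TTC loss adds the two regularizers", {
  M <- array(0.2, c(1, 3, 3, 4))
  roi <- array(1, c(3, 3, 4))
  t0 <- ttc_total_loss(1.5, a = 0, M = M, roi_small = roi)
  expect_equal(t0$loss, 1.5)                 # both penalties vanish
  roi2 <- roi; roi2[, , 1] <- 0              # 9 positions outside
  t1 <- ttc_total_loss(1.5, a = 0.4, M = M, roi_small = roi2)
  expect_equal(t1$breakdown$pen_a, 0.1 * 0.16)
  expect_equal(t1$breakdown$pen_mask, 0.1 * 0.2 * 9, tolerance = 1e-12)
})

test_that("risk score: extremes, closed form, monotonicity, ordering", {
  expect_equal(risk_score(sigmoid_cdf(0.3, 0)), 1)
  expect_lt(risk_score(sigmoid_cdf(0.3, 50)), 1e-8)
  expect_equal(risk_score(sigmoid_cdf(0.2, 0.5)), 2 / (1 + exp(2)),
               tolerance = 1e-12)
  rs <- vapply(c(0, 0.2, 0.5, 1, 2), function(b)
    risk_score(sigmoid_cdf(0.3, b)), numeric(1))
  expect_true(all(diff(rs) < 0))             # strictly decreasing in b
  # ordering equals the ordering of -b at fixed a
  withr::with_seed(3, {
    bs <- runif(20, 0, 3)
    r <- vapply(bs, function(b) risk_score(sigmoid_cdf(0.4, b)), numeric(1))
    expect_equal(order(r), order(-bs))
  })
  expect_error(risk_score(list(a = 0.3, b = -1)), "negative")
})

test_that("risk stratification uses the printed boundaries", {
  expect_equal(as.character(stratify_risk(0.33)), "low")
  expect_equal(as.character(stratify_risk(0.34)), "moderate")
  expect_equal(as.character(stratify_risk(0.67)), "moderate")
  expect_equal(as.character(stratify_risk(0.68)), "high")
  expect_equal(as.character(stratify_risk(1.0)), "high")
  expect_equal(as.character(stratify_risk(0)), "low")
})

test_that("classifier: softplus(0) map, shape, pointwise permutation equivariance", {
  cls <- withr::with_seed(4, ttc_classifier())
  # zero weights -> softplus(0) = log 2 everywhere
  for (l in list(cls$conv1, cls$conv2, cls$conv3))
    l$params <- lapply(l$params, function(p) p * 0)
  f <- random_feature_map(c(12L, 12L, 16L), seed = 8)
  M <- classifier_forward(f, cls)
  expect_equal(dim(M), c(1L, 12L, 12L, 16L))
  expect_true(all(abs(M - log(2)) < 1e-12))
  # pointwise network: permuting spatial positions permutes M identically
  cls2 <- withr::with_seed(5, ttc_classifier())
  f2 <- random_feature_map(c(4L, 3L, 2L), seed = 9)
  M2 <- classifier_forward(f2, cls2)
  perm <- c(3, 1, 4, 2)
  fp <- f2; fp$F <- f2$F[, perm, , , drop = FALSE]
  Mp <- classifier_forward(fp, cls2)
  expect_equal(Mp, M2[, perm, , , drop = FALSE])
})

test_that("regression baseline bins and its loss follow the contract", {
  b5 <- regression_baseline_bins(5)
  expect_false(b5$within_0); expect_true(b5$within_6)
  expect_true(b5$within_12); expect_true(b5$within_18)
  b18.5 <- regression_baseline_bins(18.5)
  expect_false(any(unlist(b18.5[, -1])))
  expect_equal(regression_baseline_loss(6, 6, 12), 9)  # (6 - 9)^2
})

test_that("multi-label baseline emits four probabilities; checker counts", {
  cls <- withr::with_seed(6, multilabel_classifier())
  for (l in list(cls$conv1, cls$conv2, cls$conv3))
    l$params <- lapply(l$params, function(p) p * 0)
  f <- random_feature_map(c(3L, 3L, 4L), seed = 10)
  p <- multilabel_baseline(f, cls)
  expect_length(p, 4)
  expect_true(all(p == 0.5))                 # zero logits -> 0.5 each
  expect_equal(count_monotonicity_violations(c(0.2, 0.4, 0.3, 0.5)), 1)
  expect_equal(count_monotonicity_violations(c(0.1, 0.2, 0.3, 0.4)), 0)
  expect_equal(count_monotonicity_violations(c(0.9, 0.5, 0.4, 0.2)), 3)
})

test_that("direct CDF fit recovers b from bracketing labels", {
  true <- sigmoid_cdf(a = 0.15, b = 0.55)
  labels <- withr::with_seed(7, lapply(1:120, function(i) {
    t_star <- true$b + rnorm(1, 0, 0.08)
    lo <- max(0, t_star - runif(1, 0.05, 0.25))
    hi <- min(1, t_star + runif(1, 0.05, 0.25))
    if (hi <= lo || hi <= 0) return(NULL)
    ttc_label(lo * 18, hi * 18)
  }))
  labels <- Filter(Negate(is.null), labels)
  fit <- fit_ttc_direct(labels)
  expect_lt(abs(fit$b - true$b), 0.05)
  td <- tidy(fit)
  expect_equal(td$term, c("a", "b"))
  expect_equal(td$estimate[2], fit$b)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n, length(labels))
})
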