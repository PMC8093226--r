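test_that("BCR labeling follows the second-test-above-cut rule", {
  # second value > 0.2 at year 3 -> event at 3
  expect_equal(bcr_label(c(1, 2, 3), c(0.1, 0.3, 0.4)),
               list(time = 3, event = 1L))
  # all below cut: censored at last test
  expect_equal(bcr_label(c(1, 3, 5), c(0.1, 0.15, 0.2)),
               list(time = 5, event = 0L))
  # a single elevated value does not qualify
  expect_equal(bcr_label(c(1, 2, 4), c(0.1, 0.5, 0.1)),
               list(time = 4, event = 0L))
  # elevated tests need not be consecutive
  expect_equal(bcr_label(c(1, 2, 3, 4), c(0.3, 0.1, 0.1, 0.25)),
               list(time = 4, event = 1L))
  # exclusion: no test at least 30 days post-surgery
  expect_error(bcr_label(c(0.01), c(0.1)), "no_qualifying_psa_test")
})

test_that("z-normalization fits on training and transfers to validation", {
  set.seed(100)
  x <- matrix(rnorm(200, 5, 3), 50, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  z <- fit_zscore(x)
  xs <- apply_zscore(x, z)
  expect_lt(max(abs(colMeans(xs))), 1e-9)
  expect_lt(max(abs(apply(xs, 2, sd) - 1)), 1e-9)
  xv <- matrix(rnorm(40, 9, 1), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  xvs <- apply_zscore(xv, z)
  expect_equal(xvs[1, 1], (xv[1, 1] - z$mu[["f1"]]) / z$sigma[["f1"]])
  xc <- cbind(x, const = 7)
  expect_equal(fit_zscore(xc)$constant, "const")
})

test_that("elastic-net Cox recovers a planted sparse support", {
  hits <- vapply(1:8, function(s) {
    set.seed(s)
    n <- 300; p <- 20
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%02d", 1:p)))
    eta <- 0.8 * x[, 1] - 0.8 * x[, 2] + 0.8 * x[, 3]
    tt <- rexp(n, exp(eta))
    cc <- runif(n, 0, quantile(tt, 0.9))
    m <- fit_elasticnet_cox(x, pmin(tt, cc), as.integer(tt <= cc), seed = s)
    all(m$beta[c("f01", "f02", "f03")] != 0)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("ridge limit keeps every coefficient nonzero", {
  set.seed(101)
  n <- 150
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  eta <- x[, 1]
  tt <- rexp(n, exp(eta))
  m <- fit_elasticnet_cox(x, tt, rep(1L, n), alpha = 0, seed = 1)
  expect_true(all(m$beta != 0))
})

test_that("risk scoring is centered, monotone, and breaks ties low", {
  set.seed(102)
  x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  z <- fit_zscore(x)
  m <- lumenmorph:::cox_en_model(c("a", "b", "c"), c(0.5, -0.2, 0),
                                 z$mu, z$sigma, 0.5, 0.1, threshold = 0.5)
  at_mean <- risk_score(m, z$mu)
  expect_equal(at_mean$lp, 0, tolerance = 1e-12)
  expect_equal(at_mean$score, 0.5)
  expect_identical(at_mean$category, "low")  # boundary goes to low
  up <- z$mu; up["a"] <- up["a"] + z$sigma["a"]
  expect_gt(risk_score(m, up)$score, 0.5)
  expect_error(risk_score(m, c(a = 1, b = 2)), "missing model feature")
})

test_that("threshold learning splits well-separated score clusters", {
  set.seed(103)
  n <- 60
  scores <- c(runif(n / 2, 0.1, 0.3), runif(n / 2, 0.7, 0.9))
  eta <- ifelse(scores > 0.5, 1.5, -1.5)
  tt <- rexp(n, exp(eta)); ev <- rep(1L, n)
  thr <- learn_threshold(scores, tt, ev)
  # the optimal cut is the largest low-cluster score: "score > thr" then
  # reproduces the true grouping exactly
  expect_equal(thr, max(scores[scores < 0.5]))
  expect_lt(thr, 0.7)
  expect_error(learn_threshold(rep(0.4, 50), rexp(50), rep(1L, 50)),
               "degenerate")
  # mirrored scores give the mirrored threshold
  thr2 <- learn_threshold(1 - scores, tt, ev)
  srt <- sort(scores)
  nxt <- srt[findInterval(thr, srt) + 1L]    # split just below the next score
  expect_equal(thr2, 1 - nxt, tolerance = 1e-9)
})

test_that("the published six-feature model round-trips the printed hazard ratios", {
  m <- published_model()
  expect_length(m$beta, 6)
  hr <- c(1.002, 0.932, 1.100, 0.968, 0.929, 0.977)
  expect_equal(unname(exp(m$beta)), hr, tolerance = 1e-9)
  expect_equal(unname(m$beta["shape:median:distance_ratio"]), log(1.100))
  expect_equal(log(1.100), 0.0953, tolerance = 1e-3)
  x <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, m$feature_names))
  expect_error(risk_score(m, x), "normalization")
  m2 <- set_normalization(m, x)
  expect_silent(risk_score(m2, x))
})

test_that("the combined clinical model uses reference-coded grade and log2 PSA", {
  set.seed(104)
  n <- 160
  cl <- data.frame(patient_id = seq_len(n),
                   grade_group = sample(1:5, n, replace = TRUE),
                   psa_preop = rlnorm(n, log(8), 0.6))
  sc <- plogis(rnorm(n))
  eta <- 2 * qlogis(sc) + 0.5 * log2(cl$psa_preop)
  tt <- rexp(n, 0.1 * exp(eta))
  cl$time <- tt; cl$event <- 1L
  hp <- risk_model_plus(sc, cl, seed = 1)
  expect_setequal(setdiff(colnames(hp$design), c("score", "log2_psa")),
                  paste0("grade_group_", 2:5))
  # log2 coding: doubling PSA shifts the covariate by exactly 1
  cl2 <- cl; cl2$psa_preop <- cl$psa_preop * 2
  hp2 <- risk_model_plus(sc, cl2, seed = 1)
  expect_equal(hp2$design[, "log2_psa"], hp$design[, "log2_psa"] + 1)
  # grade group absent from training drops its dummy with a warning
  cl3 <- cl[cl$grade_group != 5, ]
  expect_warning(hp3 <- risk_model_plus(sc[cl$grade_group != 5], cl3, seed = 1),
                 "absent")
  expect_false("grade_group_5" %in% colnames(hp3$design))
})

test_that("refitting on model-simulated data recovers the coefficients", {
  set.seed(105)
  n <- 1000
  beta <- c(f1 = 0.6, f2 = -0.4, f3 = 0.2)
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, names(beta)))
  tt <- rexp(n, exp(drop(x %*% beta)))
  fit <- survival::coxph(survival::Surv(tt, rep(1, n)) ~ x)
  expect_lt(max(abs(coef(fit) - beta)), 0.15)
})
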