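test_that("logrank statistic matches hand risk-set enumeration", {
  # 6-subject worked example with censoring
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 0, 1, 1, 0, 1)
  grp <- c("a", "a", "a", "b", "b", "b")
  kl <- km_logrank(grp, time, event)
  expect_equal(kl$chisq, logrank_oracle(grp, time, event), tolerance = 1e-9)
  # identical groups (duplicated data): no separation
  kl0 <- km_logrank(rep(c("a", "b"), each = 4), rep(c(1, 2, 3, 4), 2),
                    rep(c(1, 1, 0, 1), 2))
  expect_equal(kl0$chisq, 0, tolerance = 1e-12)
  expect_equal(kl0$logrank_p, 1, tolerance = 1e-9)
  # no events: NA report
  kln <- km_logrank(grp, time, rep(0L, 6))
  expect_true(is.na(kln$logrank_p))
  expect_error(km_logrank(rep("a", 5), 1:5, rep(1, 5)), "2 groups")
})

test_that("KM estimator equals 1 - ECDF without censoring", {
  set.seed(110)
  tt <- rexp(40)
  fit <- survival::survfit(survival::Surv(tt, rep(1, 40)) ~ 1)
  ecdf_surv <- 1 - ecdf(tt)(fit$time)
  expect_equal(fit$surv, ecdf_surv, tolerance = 1e-12)
})

test_that("c-index matches brute-force pair enumeration and conventions", {
  # orientation: higher risk score with shorter time is concordant
  tt <- c(5, 4, 3, 2, 1)
  expect_equal(harrell_cindex(c(1, 2, 3, 4, 5), tt, rep(1, 5)), 1)
  expect_equal(harrell_cindex(c(5, 4, 3, 2, 1), tt, rep(1, 5)), 0)
  expect_equal(harrell_cindex(rep(2, 5), tt, rep(1, 5)), 0.5)
  # worked 5-subject set with one censored subject vs exhaustive pairs
  time <- c(2, 4, 3, 5, 1); event <- c(1, 0, 1, 1, 1)
  sc <- c(0.9, 0.3, 0.5, 0.1, 0.8)
  expect_equal(harrell_cindex(sc, time, event),
               cindex_oracle(sc, time, event), tolerance = 1e-12)
  set.seed(111)
  for (i in 1:10) {
    n <- 12
    tt <- rexp(n); ev <- rbinom(n, 1, 0.7); sc <- rnorm(n)
    expect_equal(harrell_cindex(sc, tt, ev), cindex_oracle(sc, tt, ev),
                 tolerance = 1e-12)
  }
})

test_that("paired bootstrap comparison behaves at the identity and nested cases", {
  set.seed(112)
  n <- 80
  eta <- rnorm(n)
  tt <- rexp(n, exp(eta)); ev <- rbinom(n, 1, 0.8)
  bc <- bootstrap_compare(eta, eta, tt, ev, B = 200, seed = 3)
  expect_equal(bc$win_fraction, 0, tolerance = 1e-12)  # never strictly greater
  expect_equal(bc$p_value, 1)
  expect_gte(bc$cindex_a, bc$ci_a[1]); expect_lte(bc$cindex_a, bc$ci_a[2])
  # nested information: the full predictor beats its noisy component
  noisy <- eta + rnorm(n, 0, 2)
  bc2 <- bootstrap_compare(eta, noisy, tt, ev, B = 200, seed = 3)
  expect_gt(bc2$win_fraction, 0.5)
  expect_warning(bootstrap_compare(eta, noisy, tt, ev, B = 50, seed = 1),
                 "fewer than 100")
})

test_that("multivariable Cox recovers a known hazard ratio and reports references", {
  set.seed(113)
  n <- 500
  xb <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.2 * exp(log(2) * xb))
  d <- data.frame(time = tt, event = 1L, marker = xb,
                  grade = factor(sample(1:3, n, replace = TRUE)))
  tab <- multivariable_cox(d, c("marker", "grade"))
  hr <- tab$hr[tab$covariate == "marker"]
  expect_gt(hr, 1.6); expect_lt(hr, 2.5)
  ref <- tab[tab$covariate == "grade" & tab$note == "ref", ]
  expect_equal(ref$level, "1")
  expect_true(is.na(ref$hr))
  d$dup <- d$marker
  expect_error(multivariable_cox(d, c("marker", "dup")), "aliased")
})

test_that("subgroup analysis applies the Bonferroni threshold", {
  set.seed(114)
  n <- 120
  risk <- rep(c("low", "high"), n / 2)
  eta <- ifelse(risk == "high", 1, -1)
  tt <- rexp(n, exp(eta)); ev <- rep(1L, n)
  subs <- setNames(lapply(1:15, function(i) rep(TRUE, n)), paste0("g", 1:15))
  sa <- subgroup_analysis(risk, tt, ev, subs)
  expect_equal(sa$threshold, 0.0033)
  expect_equal(sa$k, 15)
  expect_true(all(sa$table$significant))
  sa1 <- subgroup_analysis(risk, tt, ev, list(all = rep(TRUE, n)))
  expect_equal(sa1$threshold, 0.05)
  # determinism across duplicated definitions
  sa2 <- subgroup_analysis(risk, tt, ev, subs)
  expect_identical(sa$table$logrank_p, sa2$table$logrank_p)
  # subgroups with < 2 per risk group are skipped with a reason
  tiny <- rep(FALSE, n); tiny[1:3] <- TRUE
  sa3 <- subgroup_analysis(risk, tt, ev, list(tiny = tiny))
  expect_match(sa3$table$note, "skipped")
})

test_that("genomic-classifier categories follow the published cut-points", {
  expect_equal(decipher_categorize(c(0.44, 0.61)), c("low", "high"))
  expect_equal(decipher_categorize(c(0.45, 0.60)),
               c("intermediate", "intermediate"))
  expect_equal(decipher_categorize(0.50, merged = TRUE),
               decipher_categorize(0.30, merged = TRUE))
  expect_error(decipher_categorize(1.2), "0, 1")
})

test_that("the true linear predictor outperforms any single component", {
  set.seed(115)
  wins <- vapply(1:10, function(s) {
    set.seed(s + 200)
    n <- 500
    x <- matrix(rnorm(n * 3), n, 3)
    beta <- c(0.7, 0.5, -0.6)
    eta <- drop(x %*% beta)
    tt <- rexp(n, exp(eta)); ev <- rbinom(n, 1, 0.8)
    c_eta <- harrell_cindex(eta, tt, ev)
    c_each <- vapply(1:3, function(j)
      harrell_cindex(x[, j] * sign(beta[j]), tt, ev), numeric(1))
    c_eta > max(c_each)
  }, logical(1))
  expect_true(all(wins))
})

test_that("logrank p is consistent with a permutation Monte-Carlo null", {
  set.seed(116)
  n <- 40
  tt <- rexp(n); ev <- rbinom(n, 1, 0.8)
  grp <- rep(c("a", "b"), n / 2)
  kl <- km_logrank(grp, tt, ev)
  perm <- replicate(400, {
    g <- sample(grp)
    suppressWarnings(km_logrank(g, tt, ev)$chisq)
  })
  p_mc <- mean(perm >= kl$chisq)
  expect_lt(abs(p_mc - kl$logrank_p), 3 * sqrt(0.25 / 400) + 0.05)
})
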