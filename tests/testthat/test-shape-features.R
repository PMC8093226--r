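test_that("boundary resampling spaces points equally and normalizes orientation", {
  b <- resample_boundary(unit_square(), 8)
  gaps <- sqrt(rowSums((b$points[c(2:8, 1), ] - b$points)^2))
  expect_lt(max(gaps) - min(gaps), 1e-9)
  cw <- unit_square()[4:1, ]
  bcw <- resample_boundary(cw, 16)
  expect_gt(polygon_signed_area <- lumenmorph:::polygon_signed_area(bcw$points), 0)
  bc <- resample_boundary(circle_poly(r = 10, n = 256), 128)
  expect_lt(max(abs(bc$radii - 10)) / 10, 0.005)
  expect_error(resample_boundary(rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))),
               "self-intersecting")
})

test_that("Fourier descriptors match a brute-force DFT and their invariances", {
  # circle: all descriptors vanish
  fd_circ <- fourier_descriptors(resample_boundary(circle_poly(n = 256), 128))
  expect_lt(max(fd_circ), 1e-3)
  # ellipse: FD2 dominates, and every FD matches the direct DFT sum
  ell <- make_lumen_deterministic <- {
    th <- seq(0, 2 * pi, length.out = 129)[-129]
    a <- sqrt(2); bb <- 1 / sqrt(2)
    r <- (a * bb) / sqrt((bb * cos(th))^2 + (a * sin(th))^2)
    cbind(10 * r * cos(th), 10 * r * sin(th))
  }
  b <- resample_boundary(ell, 128)
  fd <- fourier_descriptors(b)
  expect_equal(unname(which.max(fd)), 2)
  dft_oracle <- vapply(1:10, function(k) {
    t <- seq_along(b$radii) - 1
    Mod(sum(b$radii * exp(-2i * pi * k * t / length(b$radii))))
  }, numeric(1)) / sum(b$radii)
  expect_lt(max(abs(fd - dft_oracle)), 1e-12)
  # scale invariance
  b2 <- resample_boundary(ell * 2, 128)
  expect_lt(max(abs(fourier_descriptors(b2) - fd)), 1e-6)
})

test_that("Parseval identity holds for the radius signal", {
  set.seed(4)
  for (i in 1:5) {
    p <- make_lumen(shape_params("crescent", boundary_noise = 0.1))
    r <- resample_boundary(p, 128)$radii
    f <- fft(r) / length(r)
    expect_equal(sum(Mod(f)^2), sum(r^2) / length(r), tolerance = 1e-9)
  }
})

test_that("Hu moments carry their analytic invariances", {
  blob <- blob_poly()
  raw <- invariant_moments(blob, log_compress = FALSE)
  rot <- invariant_moments(rotate_poly(blob, 37 * pi / 180, c(5, -2)),
                           log_compress = FALSE)
  expect_lt(max(abs((raw[1:6] - rot[1:6]) / raw[1:6])), 1e-4)
  # disk: phi1 = 1/(2 pi)
  disk <- circle_poly(r = 12, n = 256)
  expect_equal(unname(invariant_moments(disk, log_compress = FALSE)["hu1"]),
               1 / (2 * pi), tolerance = 0.01)
  # mirroring flips phi7, preserves phi1..phi6
  mir <- blob; mir[, 1] <- -mir[, 1]
  m <- invariant_moments(mir, log_compress = FALSE)
  expect_equal(unname(m["hu7"]), -unname(raw["hu7"]), tolerance = 1e-9)
  expect_lt(max(abs(m[1:6] - raw[1:6])), 1e-12)
  # compressed values round-trip the compression formula
  comp <- invariant_moments(blob)
  expect_equal(unname(comp["hu1"]),
               sign(raw["hu1"]) * log10(1 + abs(raw["hu1"]) * 1e6) / 6,
               ignore_attr = TRUE)
})

test_that("distance ratio matches closed/numeric oracles and orders elongation", {
  bc <- resample_boundary(circle_poly(n = 256), 128)
  expect_equal(distance_ratio(bc), 1, tolerance = 1e-3)
  # unit square oracle: mean center-to-boundary distance over arclength
  t <- seq(0, 0.5, length.out = 20001)[-20001]
  mean_r <- mean(sqrt(0.25 + t^2))  # one half-edge; all eight are congruent
  want <- mean_r / (sqrt(2) / 2)
  bsq <- resample_boundary(unit_square(), 512)
  expect_equal(distance_ratio(bsq), want, tolerance = 0.01)
  expect_equal(want, 0.81, tolerance = 0.01)
  r2 <- distance_ratio(resample_boundary(
    make_ellipse <- local({
      th <- seq(0, 2 * pi, length.out = 129)[-129]
      cbind(2 * cos(th), sin(th))
    }), 128))
  r4 <- distance_ratio(resample_boundary(local({
    th <- seq(0, 2 * pi, length.out = 129)[-129]
    cbind(4 * cos(th), sin(th))
  }), 128))
  expect_lt(r4, r2)
})

test_that("aggregation statistics match their pinned conventions", {
  expect_equal(aggregate_stats(rep(3, 7)),
               c(mean = 3, sd = 0, median = 3, p5_p95_ratio = 1))
  st <- aggregate_stats(1:100)
  # brute-force linear-interpolation percentile oracle
  v <- sort(1:100)
  h <- function(p) { x <- (100 - 1) * p + 1
                     v[floor(x)] + (x - floor(x)) * (v[ceiling(x)] - v[floor(x)]) }
  expect_equal(unname(st["p5_p95_ratio"]), h(0.05) / h(0.95))
  expect_equal(h(0.05) / h(0.95), 5.95 / 95.05)
  expect_equal(unname(aggregate_stats(5)["sd"]), 0)
  expect_true(all(is.na(aggregate_stats(numeric(0)))))
})

test_that("the shape block is 96 long with the published feature names", {
  set.seed(9)
  lum <- lapply(1:8, function(i)
    make_lumen(shape_params("disk", size_um = 20, boundary_noise = 0),
               center = c(30 + (i - 1) %% 4 * 50, 30 + (i - 1) %/% 4 * 50)))
  ls <- lumen_set(unit_square(side = 240), lum, validate = FALSE)
  sb <- shape_block(ls)
  expect_length(sb, 96)
  published <- c("shape:mean:fd3", "shape:sd:hu1",
                 "shape:median:distance_ratio", "shape:p5_p95_ratio:fd6",
                 "shape:p5_p95_ratio:fd9")
  expect_true(all(published %in% names(sb)))
  # identical disks: every SD-statistic feature is (numerically) zero
  sds <- sb[grepl("^shape:sd:", names(sb))]
  expect_lt(max(abs(sds)), 1e-6)
})

test_that("the shape block is invariant to rigid motion and scale", {
  set.seed(10)
  lum <- lapply(1:6, function(i)
    make_lumen(shape_params(c("disk", "ellipse", "crescent")[1 + i %% 3],
                            size_um = 25, boundary_noise = 0.08),
               center = c(40 + (i - 1) %% 3 * 60, 40 + (i - 1) %/% 3 * 60)))
  reg <- unit_square(side = 220)
  base <- shape_block(lumen_set(reg, lum, validate = FALSE))
  ang <- 0.61; shift <- c(31.7, -12.3)
  lum_rt <- lapply(lum, function(p)
    sweep(rotate_poly(p, ang, c(110, 110)), 2, shift, "+"))
  reg_rt <- sweep(rotate_poly(reg, ang, c(110, 110)), 2, shift, "+")
  moved <- shape_block(lumen_set(reg_rt, lum_rt, validate = FALSE))
  denom <- pmax(abs(base), 1e-6)
  expect_lt(max(abs(moved - base) / denom), 1e-3)
  scaled <- shape_block(lumen_set(reg * 2, lapply(lum, function(p) p * 2),
                                  validate = FALSE))
  # scale-free descriptors: everything except the divider-dimension fit is
  # exactly scale invariant; the whole block must agree to 1e-3 relative
  expect_lt(max(abs(scaled - base) / denom), 1e-3)
})

test_that("disk-only and crescent-only regions separate on mean FD3", {
  set.seed(14)
  mk <- function(cls) {
    lum <- lapply(1:10, function(i)
      make_lumen(shape_params(cls, size_um = 24, notch_depth = 0.5,
                              boundary_noise = 0.02),
                 center = c(35 + (i - 1) %% 5 * 45, 40 + (i - 1) %/% 5 * 55)))
    shape_block(lumen_set(unit_square(side = 270), lum,
                          validate = FALSE))["shape:mean:fd3"]
  }
  disks <- mean(replicate(5, mk("disk")))
  cres <- mean(replicate(5, mk("crescent")))
  expect_lt(disks, cres)
})
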