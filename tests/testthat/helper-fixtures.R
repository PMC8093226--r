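# Shared fixtures: small deterministic geometries and cohorts built in code.

# regular n-gon approximating a circle
circle_poly <- function(r = 10, center = c(0, 0), n = 128L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
}

unit_square <- function(side = 1, origin = c(0, 0)) {
  rbind(c(origin[1], origin[2]),
        c(origin[1] + side, origin[2]),
        c(origin[1] + side, origin[2] + side),
        c(origin[1], origin[2] + side))
}

rotate_poly <- function(p, angle, center = c(0, 0)) {
  R <- rbind(c(cos(angle), -sin(angle)), c(sin(angle), cos(angle)))
  sweep(sweep(p, 2, center) %*% t(R), 2, center, "+")
}

# an asymmetric blob with non-degenerate higher-order moments
blob_poly <- function(n = 96L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- 10 + 2.5 * cos(th) + 1.5 * sin(2 * th) + 0.8 * cos(3 * th + 0.7)
  cbind(x = r * cos(th), y = r * sin(th))
}

# small geometry-only cohort shared by model-level tests
small_cohort <- function(n = 60, seed = 42,
                         weights = c(disk_fraction = 1), ...) {
  spec <- cohort_spec(n_patients = n, seed = seed,
                      glands_per_region = c(12L, 22L), canvas_um = 512,
                      risk_weights = weights, ...)
  simulate_cohort(spec)
}

# brute-force ray-casting point-in-polygon (independent of mgcv)
pip_oracle <- function(pt, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > pt[2]) != (yj > pt[2]) &&
        pt[1] < (xj - xi) * (pt[2] - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# brute-force Harrell c-index by pair enumeration
cindex_oracle <- function(scores, time, event) {
  n <- length(scores)
  conc <- 0; comp <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    # comparable iff the smaller observed time is an event
    ti <- time[i]; tj <- time[j]
    if (ti == tj && event[i] == event[j]) next
    first <- if (ti < tj) i else j
    second <- if (ti < tj) j else i
    if (ti == tj) { first <- if (event[i] == 1) i else j
                    second <- if (event[i] == 1) j else i }
    if (event[first] != 1) next
    comp <- comp + 1
    ds <- scores[first] - scores[second]
    if (ds > 0) conc <- conc + 1
    else if (ds == 0) conc <- conc + 0.5
  }
  if (comp == 0) return(NA_real_)
  conc / comp
}

# hand risk-set enumeration of the two-sample logrank statistic
logrank_oracle <- function(group, time, event) {
  g <- as.integer(factor(group)) - 1L  # 0/1
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n_tot <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d_tot <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    e1 <- d_tot * n1 / n_tot
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n_tot > 1)
      v <- v + d_tot * (n1 / n_tot) * (1 - n1 / n_tot) *
        (n_tot - d_tot) / (n_tot - 1)
  }
  (o_minus_e)^2 / v
}
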