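# Synthetic cohort generator: pseudo-H&E region images with ground-truth
# lumen geometry and Cox-linked survival outcomes. The generator is the
# test bed for every downstream stage; its defaults define the study
# conditions used throughout the package's tests and examples.

#' Shape parameters for a single synthetic lumen
#'
#' @param shape_class one of `"disk"`, `"ellipse"`, `"crescent"`.
#' @param size_um equivalent diameter in microns (diameter of the disk with
#'   the same area).
#' @param aspect major/minor axis ratio (>= 1), used by ellipses.
#' @param notch_depth crescent notch depth as a fraction of radius, in [0, 1).
#' @param boundary_noise SD of the radial perturbation as a fraction of the
#'   local radius.
#' @return Validated parameter list of class `shape_params`.
#' @export
shape_params <- function(shape_class = c("disk", "ellipse", "crescent"),
                         size_um = 40, aspect = 1.6, notch_depth = 0.5,
                         boundary_noise = 0.03) {
  shape_class <- match.arg(shape_class)
  if (size_um <= 0) stop("size_um must be positive")
  if (aspect < 1) stop("aspect must be >= 1")
  if (notch_depth < 0 || notch_depth >= 1)
    stop("notch_depth must be in [0, 1)")
  if (boundary_noise < 0) stop("boundary_noise must be nonnegative")
  structure(list(shape_class = shape_class, size_um = size_um,
                 aspect = aspect, notch_depth = notch_depth,
                 boundary_noise = boundary_noise),
            class = "shape_params")
}

#' Generate one lumen polygon
#'
#' Shapes are star-shaped polar forms (disk, ellipse, disk with a Gaussian
#' radial notch for the crescent), optionally perturbed by smooth radial
#' noise, randomly rotated, and rescaled so the equivalent diameter matches
#' `size_um` exactly when `boundary_noise = 0`.
#'
#' Uses the R random number generator; seed upstream for reproducibility.
#'
#' @param params a [shape_params()].
#' @param center xy center in microns.
#' @param n_vertices polygon resolution (>= 32).
#' @return Two-column vertex matrix (counterclockwise, simple).
#' @export
make_lumen <- function(params, center = c(0, 0), n_vertices = 64L) {
  stopifnot(inherits(params, "shape_params"), n_vertices >= 32)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- switch(params$shape_class,
    disk = rep(1, n_vertices),
    ellipse = {
      a <- sqrt(params$aspect); b <- 1 / sqrt(params$aspect)
      (a * b) / sqrt((b * cos(th))^2 + (a * sin(th))^2)
    },
    crescent = {
      # Gaussian radial notch at angle 0, width 0.8 rad, periodic distance
      d <- pmin(abs(th), 2 * pi - abs(th))
      1 - params$notch_depth * exp(-(d / 0.8)^2)
    }
  )
  if (params$boundary_noise > 0) {
    raw <- stats::rnorm(n_vertices)
    k <- 7L
    noise <- stats::filter(c(raw[(n_vertices - k + 1):n_vertices], raw,
                             raw[1:k]),
                           rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)
    noise <- as.numeric(noise[(k + 1):(k + n_vertices)])
    noise <- noise / max(stats::sd(noise), 1e-12)
    r <- r * pmax(1 + params$boundary_noise * noise, 0.1)
  }
  rot <- stats::runif(1, 0, 2 * pi)
  pts <- cbind(r * cos(th + rot), r * sin(th + rot))
  # rescale so polygon area equals that of a disk with diameter size_um
  area <- polygon_area(pts)
  s <- sqrt(pi * (params$size_um / 2)^2 / area)
  pts <- pts * s
  pts[, 1] <- pts[, 1] + center[1]
  pts[, 2] <- pts[, 2] + center[2]
  colnames(pts) <- c("x", "y")
  polygon_ccw(pts)
}

#' Cohort-level generator specification
#'
#' @param n_patients number of patients (>= 2).
#' @param glands_per_region integer range (min >= 10, mirroring the
#'   at-least-10-glands annotation rule).
#' @param disk_fraction cohort-mean proportion of disk-shaped lumens.
#' @param density_heterogeneity SD of the log-Gaussian intensity field that
#'   drives spatially varying gland density.
#' @param risk_weights named weights over the per-patient generator knobs
#'   (any of `disk_fraction`, `aspect`, `density_heterogeneity`, `size_um`).
#' @param baseline Weibull baseline: list(shape, scale) — scale in years.
#' @param censor_rate target fraction censored, in [0, 1).
#' @param n_sites number of pseudo-sites (stain presets).
#' @param boundary_noise lumen boundary roughness.
#' @param canvas_um square region side in microns.
#' @param seed integer seed driving the whole cohort.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 100L,
                        glands_per_region = c(15L, 40L),
                        disk_fraction = 0.5,
                        density_heterogeneity = 0.6,
                        risk_weights = c(disk_fraction = 1),
                        baseline = list(shape = 1.5, scale = 8),
                        censor_rate = 0.5,
                        n_sites = 3L,
                        boundary_noise = 0.05,
                        canvas_um = 1024,
                        seed = 1L) {
  if (n_patients < 2) stop("n_patients must be >= 2")
  if (glands_per_region[1] < 10)
    stop("glands_per_region minimum must be >= 10")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0, 1)")
  structure(as.list(environment()), class = "cohort_spec")
}

# Smooth log-Gaussian intensity field on a coarse grid (approximate GP by
# kernel-smoothed white noise, rescaled to the requested marginal SD).
log_gaussian_field <- function(ngrid = 32L, sd = 0.6, smooth_cells = 3) {
  z <- matrix(stats::rnorm(ngrid^2), ngrid, ngrid)
  ks <- ceiling(3 * smooth_cells)
  kx <- stats::dnorm(seq(-ks, ks), sd = smooth_cells)
  k2 <- outer(kx, kx); k2 <- k2 / sum(k2)
  zp <- matrix(0, ngrid + 2 * ks, ngrid + 2 * ks)
  zp[ks + seq_len(ngrid), ks + seq_len(ngrid)] <- z
  sm <- matrix(0, ngrid, ngrid)
  for (i in seq_len(ngrid)) for (j in seq_len(ngrid)) {
    sm[i, j] <- sum(zp[i:(i + 2 * ks), j:(j + 2 * ks)] * k2)
  }
  sm <- sm / max(stats::sd(as.numeric(sm)), 1e-12) * sd
  sm
}

#' Place gland centers by an inhomogeneous Poisson process
#'
#' Centers are drawn by thinning against a log-Gaussian intensity field and
#' accepted subject to a minimum spacing.
#'
#' @param n target number of glands.
#' @param canvas_um square side length (microns).
#' @param margin_um keep-out border.
#' @param min_spacing minimum centroid spacing (microns).
#' @param density_heterogeneity SD of the log intensity field.
#' @param max_attempts rejection budget per gland.
#' @return n x 2 matrix of centers.
#' @export
place_gland_centers <- function(n, canvas_um, margin_um, min_spacing,
                                density_heterogeneity = 0.6,
                                max_attempts = 200L) {
  fld <- log_gaussian_field(32L, density_heterogeneity)
  lam <- exp(fld); lam <- lam / max(lam)
  pts <- matrix(numeric(0), ncol = 2)
  lo <- margin_um; hi <- canvas_um - margin_um
  for (i in seq_len(n)) {
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      p <- stats::runif(2, lo, hi)
      gi <- pmin(pmax(ceiling(p / canvas_um * 32), 1), 32)
      if (stats::runif(1) > lam[gi[2], gi[1]]) next
      if (nrow(pts) > 0 &&
          min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) < min_spacing)
        next
      pts <- rbind(pts, p)
      placed <- TRUE
      break
    }
    if (!placed) break  # canvas saturated; return what fits
  }
  pts
}

#' Stain preset for a pseudo-site
#'
#' Perturbs stroma hue and brightness to emulate site-specific staining and
#' scanning.
#' @param site integer site index (1-based) or a preset list to pass through.
#' @return List with `stroma`, `lumen` RGB triples, `brightness`, `noise_sd`.
#' @export
stain_preset <- function(site = 1L) {
  if (is.list(site)) return(site)
  presets <- list(
    list(stroma = c(0.91, 0.62, 0.76), brightness = 1.00, noise_sd = 0.025),
    list(stroma = c(0.86, 0.58, 0.83), brightness = 0.94, noise_sd = 0.035),
    list(stroma = c(0.95, 0.70, 0.72), brightness = 1.05, noise_sd = 0.020),
    list(stroma = c(0.82, 0.55, 0.70), brightness = 0.90, noise_sd = 0.045),
    list(stroma = c(0.93, 0.66, 0.80), brightness = 1.02, noise_sd = 0.030)
  )
  p <- presets[[((site - 1L) %% length(presets)) + 1L]]
  p$lumen <- c(0.97, 0.95, 0.97)
  p
}

#' Render a synthetic region as a pseudo-H&E image plus label mask
#'
#' Lumens are drawn near-white on a textured pink stroma; the label mask is
#' the exact rasterization of the generator polygons.
#'
#' @param lumens list of lumen polygons (microns).
#' @param canvas_px square canvas side in pixels.
#' @param mpp microns per pixel.
#' @param stain stain preset (see [stain_preset()]).
#' @return List: `image` (canvas_px x canvas_px x 3 array in \[0,1\]),
#'   `mask` (integer label matrix), `mpp`.
#' @export
render_region <- function(lumens, canvas_px = 1024L, mpp = 1,
                          stain = stain_preset(1L)) {
  n <- canvas_px
  mask <- matrix(0L, n, n)
  for (k in seq_along(lumens)) {
    poly <- lumens[[k]]
    bb <- apply(poly, 2, range) / mpp
    r0 <- max(floor(bb[1, 2]), 0L); r1 <- min(ceiling(bb[2, 2]) + 1L, n)
    c0 <- max(floor(bb[1, 1]), 0L); c1 <- min(ceiling(bb[2, 1]) + 1L, n)
    if (r1 <= r0 || c1 <= c0) next
    sub <- rasterize_polygon(poly, r1 - r0, c1 - c0, mpp,
                             origin = c(c0 * mpp, r0 * mpp))
    rows <- (r0 + 1):r1; cols <- (c0 + 1):c1
    old <- mask[rows, cols]
    if (any(old[sub] != 0L))
      stop("overlapping lumens in render_region (labels ",
           paste(unique(old[sub][old[sub] != 0]), collapse = ","), " vs ", k, ")")
    old[sub] <- k
    mask[rows, cols] <- old
  }
  # textured stroma: coarse smooth noise upsampled
  coarse <- matrix(stats::rnorm(64 * 64, 0, 1), 64, 64)
  tex <- as.matrix(EBImage::resize(EBImage::Image(coarse), w = n, h = n))
  tex <- tex / max(stats::sd(as.numeric(tex)), 1e-12) * stain$noise_sd
  img <- array(0, c(n, n, 3))
  lum <- mask > 0L
  for (ch in 1:3) {
    base <- stain$stroma[ch] * stain$brightness + tex
    base[lum] <- stain$lumen[ch] * stain$brightness +
      tex[lum] * 0.3
    img[, , ch] <- pmin(pmax(base, 0), 1)
  }
  list(image = img, mask = mask, mpp = mpp)
}

#' Simulate proportional-hazards survival outcomes from generator knobs
#'
#' Event times follow a Weibull baseline with linear predictor
#' eta = sum_i w_i z_i over column-standardized knob values; censoring is
#' administrative at a Uniform(0, t_max) draw per patient, with t_max
#' calibrated by Monte-Carlo inversion to achieve approximately
#' `censor_rate`.
#'
#' @param knobs data.frame/matrix of per-patient generator knob values.
#' @param risk_weights named vector over columns of `knobs`.
#' @param baseline list(shape, scale) of the Weibull baseline (years).
#' @param censor_rate target censored fraction in [0, 1).
#' @return data.frame: `time` (years), `event` (1 = observed), `eta`.
#' @export
simulate_survival <- function(knobs, risk_weights,
                              baseline = list(shape = 1.5, scale = 8),
                              censor_rate = 0.5) {
  knobs <- as.data.frame(knobs)
  miss <- setdiff(names(risk_weights), names(knobs))
  if (length(miss) > 0)
    stop("risk_weights name knobs absent from the cohort: ",
         paste(miss, collapse = ", "))
  if (all(risk_weights == 0) && censor_rate >= 1)
    stop("no events possible: all weights zero with censor_rate 1")
  z <- vapply(names(risk_weights), function(nm) {
    v <- knobs[[nm]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }, numeric(nrow(knobs)))
  eta <- drop(z %*% risk_weights)
  n <- length(eta)
  u <- stats::runif(n)
  tt <- baseline$scale * (-log(u) / exp(eta))^(1 / baseline$shape)
  if (censor_rate <= 0) {
    return(data.frame(time = tt, event = 1L, eta = eta))
  }
  # calibrate t_max: censored fraction = E[ min(T, tmax) ] / tmax
  f <- function(tm) mean(pmin(tt, tm)) / tm - censor_rate
  tmax <- tryCatch(stats::uniroot(f, c(1e-3, 1e4))$root,
                   error = function(e) max(tt))
  cc <- stats::runif(n, 0, tmax)
  data.frame(time = pmin(tt, cc), event = as.integer(tt <= cc), eta = eta)
}

#' Simulate a full synthetic cohort
#'
#' Draws per-patient generator knobs, builds ground-truth lumen geometry per
#' region, simulates Cox-linked survival outcomes and correlated synthetic
#' clinical covariates (grade group, PSA, margins, stage, a synthetic
#' genomic-classifier score), and optionally renders pseudo-H&E images.
#' Fixing `spec$seed` reproduces the cohort bit-identically.
#'
#' @param spec a [cohort_spec()].
#' @param render also render images/masks (slower).
#' @return List: `lumen_sets` (list of [lumen_set()]), `clinical`
#'   (data.frame), `truth` (knobs + linear predictor), `renders`
#'   (list or NULL), `spec`.
#' @export
simulate_cohort <- function(spec, render = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  knobs <- data.frame(
    disk_fraction = stats::rbeta(n, spec$disk_fraction * 8,
                                 (1 - spec$disk_fraction) * 8),
    aspect = 1 + stats::rgamma(n, shape = 2, scale = 0.35),
    density_heterogeneity =
      pmax(stats::rnorm(n, spec$density_heterogeneity,
                        0.25 * spec$density_heterogeneity + 1e-9), 0.05),
    size_um = stats::rlnorm(n, log(45), 0.15)
  )
  surv <- simulate_survival(knobs, spec$risk_weights, spec$baseline,
                            spec$censor_rate)
  margin <- 40
  ann <- rbind(c(margin * 0.5, margin * 0.5),
               c(spec$canvas_um - margin * 0.5, margin * 0.5),
               c(spec$canvas_um - margin * 0.5, spec$canvas_um - margin * 0.5),
               c(margin * 0.5, spec$canvas_um - margin * 0.5))
  sites <- paste0("site", ((seq_len(n) - 1L) %% spec$n_sites) + 1L)
  lumen_sets <- vector("list", n)
  renders <- if (render) vector("list", n) else NULL
  for (i in seq_len(n)) {
    ng <- sample(seq(spec$glands_per_region[1], spec$glands_per_region[2]), 1)
    spacing <- 1.2 * knobs$size_um[i]
    ctrs <- place_gland_centers(ng, spec$canvas_um, margin, spacing,
                                knobs$density_heterogeneity[i])
    lum <- vector("list", nrow(ctrs))
    for (g in seq_len(nrow(ctrs))) {
      cls <- if (stats::runif(1) < knobs$disk_fraction[i]) "disk"
             else if (stats::runif(1) < 0.5) "ellipse" else "crescent"
      sp <- shape_params(cls,
                         size_um = stats::rlnorm(1, log(knobs$size_um[i]), 0.2),
                         aspect = knobs$aspect[i],
                         notch_depth = 0.5,
                         boundary_noise = spec$boundary_noise)
      lum[[g]] <- make_lumen(sp, center = ctrs[g, ])
    }
    lumen_sets[[i]] <- lumen_set(ann, lum, source = "synthetic",
                                 region_id = sprintf("pt%03d", i),
                                 validate = FALSE)
    if (render) {
      site_idx <- ((i - 1L) %% spec$n_sites) + 1L
      renders[[i]] <- render_region(lum, canvas_px = round(spec$canvas_um),
                                    mpp = 1, stain = stain_preset(site_idx))
    }
  }
  eta_z <- as.numeric(scale(surv$eta))
  if (any(!is.finite(eta_z))) eta_z <- rep(0, n)
  grade <- pmin(pmax(1L + stats::rpois(n, lambda = exp(0.35 * eta_z)), 1L), 5L)
  clinical <- data.frame(
    patient_id = sprintf("pt%03d", seq_len(n)),
    time = surv$time,
    event = surv$event,
    grade_group = grade,
    margins_positive = stats::runif(n) < stats::plogis(-1 + 0.5 * eta_z),
    psa_preop = stats::rlnorm(n, log(7) + 0.25 * eta_z, 0.5),
    stage_ge_T2b = stats::runif(n) < stats::plogis(-0.5 + 0.4 * eta_z),
    site = sites,
    decipher = pmin(pmax(stats::plogis(0.9 * eta_z +
                                       stats::rnorm(n, 0, 0.8)), 0), 1)
  )
  truth <- cbind(patient_id = clinical$patient_id, knobs, eta = surv$eta)
  list(lumen_sets = lumen_sets, clinical = clinical, truth = truth,
       renders = renders, spec = spec)
}
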