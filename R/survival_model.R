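# Elastic-net Cox risk modeling: BCR labeling from PSA series, training-set
# z-normalization, penalized fitting (alpha = 0.5, 10-fold CV), risk scoring
# on a bounded [0, 1] scale, threshold learning, the published six-feature
# model, and the combined clinical model.

#' Label biochemical recurrence from a post-surgery PSA series
#'
#' A patient is labeled BCR at the date of the second PSA value strictly
#' above the cut (tests need not be consecutive), and censored at the last
#' available test otherwise. Patients without a qualifying test at least
#' `min_followup_days` after surgery are excluded.
#'
#' @param psa_times test times in years after surgery.
#' @param psa_values PSA values in ng/mL.
#' @param psa_cut recurrence cut in ng/mL (default 0.2).
#' @param min_followup_days minimum post-surgery follow-up for inclusion.
#' @return List: `time` (years), `event` (0/1); or an error with a reason
#'   code when the patient does not qualify.
#' @export
bcr_label <- function(psa_times, psa_values, psa_cut = 0.2,
                      min_followup_days = 30) {
  stopifnot(length(psa_times) == length(psa_values))
  ord <- order(psa_times)
  psa_times <- psa_times[ord]; psa_values <- psa_values[ord]
  keep <- psa_times > 0
  psa_times <- psa_times[keep]; psa_values <- psa_values[keep]
  if (length(psa_times) == 0 ||
      max(psa_times) < min_followup_days / 365.25)
    stop("patient excluded: no_qualifying_psa_test")
  above <- which(psa_values > psa_cut)
  if (length(above) >= 2) {
    list(time = psa_times[above[2]], event = 1L)
  } else {
    list(time = psa_times[length(psa_times)], event = 0L)
  }
}

#' Fit z-normalization parameters on a training matrix
#'
#' @param x_train matrix (patients x features), >= 2 rows.
#' @return List: `mu`, `sigma` (named), `constant` (names of zero-variance
#'   columns, to be excluded downstream).
#' @export
fit_zscore <- function(x_train) {
  x_train <- as.matrix(x_train)
  if (nrow(x_train) < 2) stop("need at least 2 rows")
  mu <- colMeans(x_train, na.rm = TRUE)
  sigma <- apply(x_train, 2, stats::sd, na.rm = TRUE)
  constant <- colnames(x_train)[!is.finite(sigma) | sigma == 0]
  list(mu = mu, sigma = sigma, constant = constant)
}

#' Apply training-set z-normalization to a matrix
#' @param x matrix with the training columns.
#' @param z a [fit_zscore()] result.
#' @return Standardized matrix (training columns only, constants excluded).
#' @export
apply_zscore <- function(x, z) {
  cols <- setdiff(names(z$mu), z$constant)
  xs <- as.matrix(x)[, cols, drop = FALSE]
  sweep(sweep(xs, 2, z$mu[cols]), 2, z$sigma[cols], "/")
}

#' Construct a penalized Cox risk model object
#' @keywords internal
cox_en_model <- function(feature_names, beta, mu, sigma, alpha, lambda,
                         threshold = NA_real_) {
  stopifnot(length(beta) == length(feature_names))
  structure(list(feature_names = feature_names,
                 beta = stats::setNames(beta, feature_names),
                 mu = mu, sigma = sigma, alpha = alpha, lambda = lambda,
                 threshold = threshold),
            class = "cox_en_model")
}

#' @export
print.cox_en_model <- function(x, ...) {
  nz <- sum(x$beta != 0)
  cat(sprintf("<cox_en_model> %d features (%d nonzero), alpha = %.2f, lambda = %.4g, threshold = %s\n",
              length(x$beta), nz, x$alpha, x$lambda,
              ifelse(is.na(x$threshold), "unset", sprintf("%.3f", x$threshold))))
  invisible(x)
}

#' Fit an elastic-net penalized Cox model
#'
#' Cox partial likelihood with penalty lambda (alpha L1 + (1 - alpha)/2 L2),
#' lambda chosen by 10-fold cross-validated partial-likelihood deviance
#' with a seeded fold assignment; Breslow handling of ties. Features are
#' z-normalized internally on the training data (so coefficients are per-SD
#' log hazard ratios) and constant columns are excluded.
#'
#' @param x matrix (patients x features), raw scale.
#' @param time,event survival outcome (years, 0/1).
#' @param alpha elastic-net mixing (default 0.5).
#' @param nfolds CV folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param lambda_rule `"min"` (CV minimum) or `"1se"`.
#' @return A `cox_en_model` (threshold unset).
#' @export
fit_elasticnet_cox <- function(x, time, event, alpha = 0.5, nfolds = 10L,
                               seed = 1L, lambda_rule = c("min", "1se")) {
  lambda_rule <- match.arg(lambda_rule)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  if (sum(event) < 1) stop("no events in the training data")
  if (sum(event) < 10)
    warning("fewer than 10 events; penalized fit may be unstable")
  z <- fit_zscore(x)
  xs <- apply_zscore(x, z)
  y <- survival::Surv(time, event)
  set.seed(seed)
  foldid <- sample(rep(seq_len(nfolds), length.out = nrow(xs)))
  cv <- glmnet::cv.glmnet(xs, y, family = "cox", alpha = alpha,
                          foldid = foldid, standardize = FALSE,
                          ties = "breslow")
  lam <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  beta <- as.numeric(stats::coef(cv, s = lam))
  cox_en_model(colnames(xs), beta, z$mu[colnames(xs)], z$sigma[colnames(xs)],
               alpha, lam)
}

#' Score patients with a penalized Cox risk model
#'
#' The linear predictor is the weighted sum of z-normalized features; the
#' bounded score is its logistic transform; the category is high-risk iff
#' the score strictly exceeds the model threshold.
#'
#' @param model a `cox_en_model` with normalization set.
#' @param x matrix or vector of raw features containing every model feature.
#' @return data.frame: `lp`, `score` (in \[0, 1\]), `category`
#'   (`"low"`/`"high"`; NA when the threshold is unset).
#' @export
risk_score <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  miss <- setdiff(model$feature_names, colnames(x))
  if (length(miss) > 0)
    stop("missing model feature(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(model$mu[model$feature_names])))
    stop("model normalization (mu/sigma) is unset; supply a reference ",
         "cohort via set_normalization()")
  xs <- sweep(sweep(x[, model$feature_names, drop = FALSE], 2,
                    model$mu[model$feature_names]), 2,
              model$sigma[model$feature_names], "/")
  lp <- drop(xs %*% model$beta)
  score <- stats::plogis(lp)
  category <- if (is.na(model$threshold)) NA_character_ else
    ifelse(score > model$threshold, "high", "low")
  data.frame(lp = lp, score = score, category = category,
             stringsAsFactors = FALSE)
}

#' Learn the low/high-risk threshold on training scores
#'
#' Scans every observed score between the 10th and 90th percentiles as a
#' candidate cut and keeps the one maximizing the logrank chi-square of the
#' induced two-group split; ties resolve to the lower threshold.
#'
#' @param scores training risk scores.
#' @param time,event training outcome.
#' @param quantile_range candidate window (default 10th-90th percentiles).
#' @return The learned threshold (a score value).
#' @export
learn_threshold <- function(scores, time, event,
                            quantile_range = c(0.1, 0.9)) {
  if (sum(event) < 10) warning("fewer than 10 events for threshold learning")
  if (max(scores) - min(scores) < .Machine$double.eps)
    stop("degenerate scores: all equal")
  qs <- stats::quantile(scores, quantile_range, type = 7)
  cand <- sort(unique(scores[scores >= qs[1] & scores <= qs[2]]))
  cand <- cand[cand < max(scores)]  # "score > cut" must split both ways
  if (length(cand) == 0) cand <- stats::median(scores)
  chis <- vapply(cand, function(ct) {
    grp <- scores > ct
    if (length(unique(grp)) < 2) return(-Inf)
    sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
    sd$chisq
  }, numeric(1))
  cand[which.max(chis)]  # which.max takes the first (lowest) on ties
}

#' Attach a learned threshold to a model
#' @param model a `cox_en_model`.
#' @param threshold score cut from [learn_threshold()].
#' @return Updated model.
#' @export
set_threshold <- function(model, threshold) {
  model$threshold <- threshold
  model
}

#' Set model normalization from a reference cohort
#'
#' The published model carries per-SD weights but no normalization; supply
#' the reference feature matrix whose mean/SD define the z-scale.
#'
#' @param model a `cox_en_model`.
#' @param x_ref reference matrix containing the model features.
#' @return Updated model.
#' @export
set_normalization <- function(model, x_ref) {
  z <- fit_zscore(as.matrix(x_ref)[, model$feature_names, drop = FALSE])
  if (length(z$constant) > 0)
    stop("constant reference feature(s): ", paste(z$constant, collapse = ", "))
  model$mu <- z$mu
  model$sigma <- z$sigma
  model
}

#' The published six-feature lumen morphometry model
#'
#' Per-SD weights are the logs of the published per-feature hazard ratios:
#' five lumen shape features and one sub-graph arrangement feature.
#' Normalization (mu/sigma) must be supplied from a reference cohort via
#' [set_normalization()] before scoring.
#'
#' @return A `cox_en_model` with unset normalization and threshold.
#' @export
published_model <- function() {
  hr <- c("shape:mean:fd3" = 1.002,
          "shape:sd:hu1" = 0.932,
          "shape:median:distance_ratio" = 1.100,
          "shape:p5_p95_ratio:fd6" = 0.968,
          "shape:p5_p95_ratio:fd9" = 0.929,
          "subgraph:kurtosis:edge_length" = 0.977)
  cox_en_model(names(hr), log(hr),
               mu = stats::setNames(rep(NA_real_, 6), names(hr)),
               sigma = stats::setNames(rep(NA_real_, 6), names(hr)),
               alpha = 0.5, lambda = NA_real_)
}

#' Combined image-plus-clinical risk model
#'
#' Elastic-net Cox over the continuous morphometry risk score, log2
#' preoperative PSA, and Gleason grade-group indicators (groups 2-5 against
#' reference group 1), with a threshold learned as for the image-only model.
#' Complete cases only; grade groups absent from training are dropped with
#' a warning.
#'
#' @param scores morphometry risk scores (bounded scale).
#' @param clinical data.frame with `psa_preop`, `grade_group`, `time`,
#'   `event`.
#' @param seed fold seed.
#' @param alpha,nfolds elastic-net hyperparameters.
#' @return List: `model` (`cox_en_model` with threshold), `design`
#'   (the training design matrix), `complete` (logical rows used).
#' @export
risk_model_plus <- function(scores, clinical, seed = 1L, alpha = 0.5,
                            nfolds = 10L) {
  stopifnot(nrow(clinical) == length(scores))
  complete <- is.finite(scores) & is.finite(clinical$psa_preop) &
    !is.na(clinical$grade_group) & is.finite(clinical$time) &
    !is.na(clinical$event)
  cl <- clinical[complete, ]
  sc <- scores[complete]
  gg <- factor(cl$grade_group, levels = 1:5)
  absent <- levels(gg)[-1][!(levels(gg)[-1] %in% unique(as.character(gg)))]
  if (length(absent) > 0)
    warning("grade group(s) absent from training: ",
            paste(absent, collapse = ", "), "; dummy dropped")
  dummies <- stats::model.matrix(~ gg)[, -1, drop = FALSE]
  colnames(dummies) <- sub("^gg", "grade_group_", colnames(dummies))
  present <- colSums(dummies) > 0
  x <- cbind(score = sc, log2_psa = log2(cl$psa_preop),
             dummies[, present, drop = FALSE])
  m <- fit_elasticnet_cox(x, cl$time, cl$event, alpha = alpha,
                          nfolds = nfolds, seed = seed)
  rs <- risk_score(m, x)
  thr <- learn_threshold(rs$score, cl$time, cl$event)
  list(model = set_threshold(m, thr), design = x, complete = complete)
}
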