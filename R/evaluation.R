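# Survival evaluation: Kaplan-Meier curves and logrank tests, hazard ratios,
# Harrell's c-index with paired bootstrap comparison, multivariable Cox
# tables, Bonferroni-corrected subgroup analysis, and genomic-classifier
# risk categories.

#' Kaplan-Meier curves and two-group logrank test
#'
#' @param groups two-level grouping (factor/character/logical).
#' @param time,event survival outcome.
#' @return List of class `km_logrank`: `fit` (survfit), `chisq`,
#'   `logrank_p` (NA when there are no events), `hr`, `hr_ci` (Wald 95% CI
#'   from an unpenalized Cox fit), `median_time` per group.
#' @export
km_logrank <- function(groups, time, event) {
  g <- factor(groups)
  # risk categories order low -> high so the HR reads high-vs-low
  if (setequal(levels(g), c("low", "high"))) g <- factor(g, c("low", "high"))
  if (nlevels(g) != 2) stop("need exactly 2 groups")
  if (min(table(g)) < 1) stop("empty group")
  y <- survival::Surv(time, event)
  fit <- survival::survfit(y ~ g)
  if (sum(event) == 0) {
    chisq <- NA_real_; p <- NA_real_; hr <- NA_real_; ci <- c(NA_real_, NA_real_)
  } else {
    sd <- survival::survdiff(y ~ g)
    chisq <- sd$chisq
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
    cx <- survival::coxph(y ~ g)
    hr <- unname(exp(stats::coef(cx)))
    ci <- unname(exp(stats::confint(cx)))
  }
  med <- summary(fit)$table
  med_time <- if (is.matrix(med)) med[, "median"] else med["median"]
  structure(list(fit = fit, chisq = chisq, logrank_p = p, hr = hr,
                 hr_ci = ci, median_time = med_time, groups = levels(g)),
            class = "km_logrank")
}

#' Harrell's concordance index
#'
#' Fraction of comparable pairs (smaller observed time is an event) whose
#' risk ordering agrees with the survival ordering; score ties count 1/2.
#' Orientation: higher score means higher risk (shorter time), so a perfect
#' risk ranking gives 1 and a perfectly reversed ranking gives 0.
#'
#' @param scores risk scores.
#' @param time,event survival outcome.
#' @return c-index in \[0, 1\]; NA when no comparable pairs exist.
#' @export
harrell_cindex <- function(scores, time, event) {
  ok <- is.finite(scores) & is.finite(time) & !is.na(event)
  if (sum(event[ok]) == 0) return(NA_real_)
  cc <- survival::concordance(survival::Surv(time[ok], event[ok]) ~ scores[ok],
                              reverse = TRUE)
  n_pairs <- sum(cc$count[c("concordant", "discordant", "tied.x")])
  if (n_pairs == 0) return(NA_real_)
  unname(cc$concordance)
}

#' Paired bootstrap comparison of two risk scores
#'
#' Patient-level paired bootstrap of the c-index of two scores on the same
#' subjects: percentile 95% CIs, the fraction of iterations where A beats
#' B, and a two-tailed t-test on the paired differences.
#'
#' @param scores_a,scores_b two risk scores over the same patients.
#' @param time,event survival outcome.
#' @param B bootstrap iterations (default 1000; < 100 warns).
#' @param seed resampling seed.
#' @return List: `cindex_a`, `cindex_b` (point estimates), `ci_a`, `ci_b`,
#'   `win_fraction`, `p_value`.
#' @export
bootstrap_compare <- function(scores_a, scores_b, time, event, B = 1000L,
                              seed = 1L) {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(time))
  if (B < 100) warning("fewer than 100 bootstrap iterations")
  n <- length(time)
  set.seed(seed)
  ca <- numeric(B); cb <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    ca[b] <- harrell_cindex(scores_a[idx], time[idx], event[idx])
    cb[b] <- harrell_cindex(scores_b[idx], time[idx], event[idx])
  }
  ok <- is.finite(ca) & is.finite(cb)
  d <- ca[ok] - cb[ok]
  p <- if (stats::sd(d) < .Machine$double.eps) 1 else
    stats::t.test(d)$p.value
  list(cindex_a = harrell_cindex(scores_a, time, event),
       cindex_b = harrell_cindex(scores_b, time, event),
       ci_a = stats::quantile(ca[ok], c(0.025, 0.975), names = FALSE),
       ci_b = stats::quantile(cb[ok], c(0.025, 0.975), names = FALSE),
       win_fraction = mean(ca[ok] > cb[ok]),
       p_value = p)
}

#' Multivariable (or univariable) Cox proportional-hazards table
#'
#' Unpenalized Cox fit over the supplied covariates; factors are
#' reference-coded and the reference level is reported as `"ref"`.
#'
#' @param data data.frame containing `time`, `event` and the covariates.
#' @param covariates character vector of column names; factor columns give
#'   one row per non-reference level.
#' @return data.frame: `covariate`, `level`, `hr`, `lo95`, `hi95`, `p`
#'   (reference rows carry `"ref"` and NA statistics).
#' @export
multivariable_cox <- function(data, covariates) {
  cc <- stats::complete.cases(data[, c("time", "event", covariates)])
  d <- data[cc, ]
  if (sum(d$event) < 10) warning("fewer than 10 events among complete cases")
  x <- stats::model.matrix(
    stats::reformulate(covariates), data = d)[, -1, drop = FALSE]
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    dep <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(dep, collapse = ", "))
  }
  d$.surv <- survival::Surv(d$time, d$event)
  fit <- survival::coxph(stats::reformulate(covariates, response = ".surv"),
                         data = d)
  est <- stats::coef(fit)
  ci <- stats::confint(fit)
  pv <- summary(fit)$coefficients[, "Pr(>|z|)"]
  if (is.null(names(pv))) pv <- stats::setNames(pv, names(est))
  row1 <- function(cv, lv, nm, note = "") {
    if (note == "ref") {
      data.frame(covariate = cv, level = lv, hr = NA_real_, lo95 = NA_real_,
                 hi95 = NA_real_, p = NA_real_, note = "ref")
    } else {
      data.frame(covariate = cv, level = lv, hr = exp(unname(est[nm])),
                 lo95 = exp(ci[nm, 1]), hi95 = exp(ci[nm, 2]),
                 p = unname(pv[nm]), note = "")
    }
  }
  rows <- list()
  for (cv in covariates) {
    v <- d[[cv]]
    if (is.factor(v) || is.character(v)) {
      v <- factor(v)
      rows[[length(rows) + 1L]] <- row1(cv, levels(v)[1], NA, note = "ref")
      for (lv in levels(v)[-1])
        rows[[length(rows) + 1L]] <- row1(cv, lv, paste0(cv, lv))
    } else {
      rows[[length(rows) + 1L]] <- row1(cv, "", cv)
    }
  }
  do.call(rbind, rows)
}

#' Subgroup analysis with Bonferroni correction
#'
#' Runs the two-group logrank/HR evaluation inside each clinically defined
#' subgroup and flags significance at the Bonferroni-corrected threshold
#' 0.05 / k over the k subgroups tested (reported to 4 decimal places).
#'
#' @param risk_category per-patient `"low"`/`"high"` risk labels.
#' @param time,event survival outcome.
#' @param subgroups named list of logical vectors selecting patients.
#' @return List: `table` (data.frame per subgroup: n, events, logrank p,
#'   HR, significance flag), `threshold` (corrected alpha), `k`.
#' @export
subgroup_analysis <- function(risk_category, time, event, subgroups) {
  k <- length(subgroups)
  thr <- round(0.05 / k, 4)
  rows <- lapply(names(subgroups), function(nm) {
    sel <- subgroups[[nm]] & !is.na(risk_category)
    rc <- risk_category[sel]
    if (length(unique(rc)) < 2 || min(table(rc)) < 2) {
      return(data.frame(subgroup = nm, n = sum(sel),
                        events = sum(event[sel]), logrank_p = NA_real_,
                        hr = NA_real_, significant = NA,
                        note = "skipped: <2 per risk group"))
    }
    kl <- km_logrank(rc, time[sel], event[sel])
    data.frame(subgroup = nm, n = sum(sel), events = sum(event[sel]),
               logrank_p = kl$logrank_p, hr = kl$hr,
               significant = !is.na(kl$logrank_p) && kl$logrank_p < thr,
               note = "")
  })
  list(table = do.call(rbind, rows), threshold = thr, k = k)
}

#' Genomic-classifier risk categories from published cut-points
#'
#' Low risk below 0.45, high risk above 0.60, intermediate in the closed
#' interval between; `merged = TRUE` pools low and intermediate.
#'
#' @param score numeric scores in \[0, 1\].
#' @param merged merge low + intermediate into one group.
#' @return Character vector of categories.
#' @export
decipher_categorize <- function(score, merged = FALSE) {
  if (any(score < 0 | score > 1, na.rm = TRUE))
    stop("scores must lie in [0, 1]")
  cat3 <- ifelse(score < 0.45, "low", ifelse(score > 0.60, "high",
                                             "intermediate"))
  if (!merged) return(cat3)
  ifelse(cat3 == "high", "high", "low_intermediate")
}

#' Full two-group survival evaluation report
#'
#' @param risk_category `"low"`/`"high"` per patient.
#' @param scores continuous risk scores (for the c-index).
#' @param time,event survival outcome.
#' @param B bootstrap iterations for the c-index CI.
#' @param seed bootstrap seed.
#' @return List of class `eval_report`: logrank p, HR + CI, c-index + CI,
#'   per-group KM summary and median years-to-event.
#' @export
evaluate_stratification <- function(risk_category, scores, time, event,
                                    B = 1000L, seed = 1L) {
  kl <- km_logrank(risk_category, time, event)
  ci <- harrell_cindex(scores, time, event)
  set.seed(seed)
  n <- length(time)
  boot <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    harrell_cindex(scores[idx], time[idx], event[idx])
  }, numeric(1))
  boot <- boot[is.finite(boot)]
  structure(list(logrank_p = kl$logrank_p, chisq = kl$chisq, hr = kl$hr,
                 hr_ci = kl$hr_ci, cindex = ci,
                 cindex_ci = stats::quantile(boot, c(0.025, 0.975),
                                             names = FALSE),
                 km = kl$fit, median_time = kl$median_time),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> logrank p = %.3g, HR = %.2f (%.2f-%.2f), c-index = %.3f (%.3f-%.3f)\n",
              x$logrank_p, x$hr, x$hr_ci[1], x$hr_ci[2], x$cindex,
              x$cindex_ci[1], x$cindex_ci[2]))
  invisible(x)
}
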