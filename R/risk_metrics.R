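# Incremental predictive value of a marker over a baseline risk function:
# absolute 10-year risk from a Cox fit, continuous and categorical net
# reclassification improvement (NRI), integrated discrimination improvement
# (IDI), weighted Harrell concordance for case-cohort data, and bootstrap
# percentile confidence intervals. Case-cohort weights make the subcohort
# stand in for the full cohort in all weighted means.

#' Absolute risk at the horizon from a Cox model
#'
#' `risk = 1 - S0(h)^exp(lp - lp_center)` where `S0(h)` is the baseline
#' survival at the horizon for a subject at the centering point of the
#' linear predictor.
#'
#' @param lp numeric linear predictor values.
#' @param s0 baseline survival at the horizon, in (0, 1].
#' @param lp_center centering constant (the mean linear predictor used when
#'   `s0` was estimated); default 0, i.e. `lp` already centered.
#' @return Numeric vector of absolute risks in `[0, 1]`.
#' @export
predicted_risk <- function(lp, s0, lp_center = 0) {
  assert_scalar_number(s0, "s0")
  if (s0 <= 0 || s0 > 1) stop("`s0` must be in (0, 1]", call. = FALSE)
  1 - s0^exp(lp - lp_center)
}

#' Ten-year risk from a fitted weighted Cox model
#'
#' Convenience wrapper: extracts the baseline cumulative hazard at the
#' horizon (centered at the covariate means, the [survival::basehaz]
#' default) and maps each row of `newdata` to an absolute risk.
#'
#' @param fit a `cox_fit` from [fit_weighted_cox].
#' @param newdata data frame holding the model terms.
#' @param horizon prediction horizon in years (default 10).
#' @return Numeric vector of absolute risks.
#' @export
risk_from_fit <- function(fit, newdata, horizon = 10) {
  stopifnot(inherits(fit, "cox_fit"))
  bh <- survival::basehaz(fit$fit, centered = TRUE)
  idx <- findInterval(horizon, bh$time)
  if (idx < 1L) return(rep(0, nrow(newdata)))
  s0 <- exp(-bh$hazard[idx])
  terms <- names(fit$coefficients)
  x <- as.matrix(newdata[, terms, drop = FALSE])
  lp <- drop(x %*% fit$coefficients)
  center <- sum(fit$fit$means * fit$coefficients)
  predicted_risk(lp, s0, lp_center = center)
}

check_pairs <- function(risk_old, risk_new, event, weight) {
  stopifnot(length(risk_old) == length(risk_new),
            length(event) == length(risk_old),
            length(weight) == length(risk_old),
            all(risk_old >= 0 & risk_old <= 1),
            all(risk_new >= 0 & risk_new <= 1),
            all(weight > 0))
  if (sum(event) < 1 || sum(!event) < 1) {
    stop("need at least one event and one non-event", call. = FALSE)
  }
  invisible(NULL)
}

#' Continuous net reclassification improvement
#'
#' `NRI = [P(up|event) - P(down|event)] + [P(down|nonevent) - P(up|nonevent)]`
#' where up/down means the new model's risk is greater/less than the old
#' model's; ties count neither way. Probabilities are weighted proportions
#' so case-cohort weights are honoured. Reported in percent.
#'
#' @param risk_old,risk_new predicted risks under the baseline and extended
#'   model.
#' @param event logical (or 0/1) event indicator.
#' @param weight positive sampling weights (default 1).
#' @return The continuous NRI in percent (range -200..200).
#' @export
continuous_nri <- function(risk_old, risk_new, event,
                           weight = rep(1, length(event))) {
  event <- as.logical(event)
  check_pairs(risk_old, risk_new, event, weight)
  up <- risk_new > risk_old
  down <- risk_new < risk_old
  if (!any(up | down)) {
    warning("all risk pairs tied; NRI is 0", call. = FALSE)
  }
  p_up_e <- weighted.mean(up[event], weight[event])
  p_dn_e <- weighted.mean(down[event], weight[event])
  p_up_n <- weighted.mean(up[!event], weight[!event])
  p_dn_n <- weighted.mean(down[!event], weight[!event])
  100 * ((p_up_e - p_dn_e) + (p_dn_n - p_up_n))
}

#' Categorical net reclassification improvement
#'
#' Same net-movement formula as [continuous_nri], with up/down defined by a
#' change of risk category across the supplied cutoffs (default the single
#' conventional 10\% ten-year-risk boundary).
#'
#' @inheritParams continuous_nri
#' @param cutoffs strictly increasing category boundaries in (0, 1).
#' @return The categorical NRI in percent.
#' @export
categorical_nri <- function(risk_old, risk_new, event, cutoffs = 0.10,
                            weight = rep(1, length(event))) {
  event <- as.logical(event)
  check_pairs(risk_old, risk_new, event, weight)
  if (any(cutoffs <= 0) || any(cutoffs >= 1) ||
      is.unsorted(cutoffs, strictly = TRUE)) {
    stop("`cutoffs` must be strictly increasing within (0, 1)", call. = FALSE)
  }
  cat_old <- findInterval(risk_old, cutoffs)
  cat_new <- findInterval(risk_new, cutoffs)
  up <- cat_new > cat_old
  down <- cat_new < cat_old
  p_up_e <- weighted.mean(up[event], weight[event])
  p_dn_e <- weighted.mean(down[event], weight[event])
  p_up_n <- weighted.mean(up[!event], weight[!event])
  p_dn_n <- weighted.mean(down[!event], weight[!event])
  100 * ((p_up_e - p_dn_e) + (p_dn_n - p_up_n))
}

#' Integrated discrimination improvement
#'
#' `IDI = (mean_new - mean_old | events) - (mean_new - mean_old |
#' non-events)`, with weighted means.
#'
#' @inheritParams continuous_nri
#' @return The IDI on the probability scale (range -1..1).
#' @export
idi <- function(risk_old, risk_new, event, weight = rep(1, length(event))) {
  event <- as.logical(event)
  check_pairs(risk_old, risk_new, event, weight)
  d <- risk_new - risk_old
  weighted.mean(d[event], weight[event]) -
    weighted.mean(d[!event], weight[!event])
}

#' Weighted Harrell concordance for survival risk predictions
#'
#' Fraction of usable subject pairs in which the model assigns the higher
#' risk to the subject who fails earlier. A pair is usable when the earlier
#' time belongs to an event (the later subject is then known to survive
#' longer). Ties in predicted risk count one half. Each pair is weighted by
#' the product of the subjects' case-cohort weights.
#'
#' @param risk predicted risks.
#' @param time follow-up times (years).
#' @param event logical (or 0/1) event indicator.
#' @param weight positive subject weights (default 1).
#' @return Concordance in `[0, 1]`, or `NA` with a warning when no pair is
#'   usable.
#' @export
weighted_cindex <- function(risk, time, event,
                            weight = rep(1, length(event))) {
  event <- as.logical(event)
  stopifnot(length(risk) == length(time), length(time) == length(event),
            all(weight > 0))
  idx_e <- which(event)
  num <- 0; den <- 0
  for (i in idx_e) {
    # comparable: j still at risk when i fails (t_j > t_i), or tied-time
    # non-event (censored at i's failure time counts as surviving past it)
    comp <- which(time > time[i] | (time == time[i] & !event))
    comp <- setdiff(comp, i)
    if (!length(comp)) next
    w <- weight[i] * weight[comp]
    conc <- (risk[i] > risk[comp]) + 0.5 * (risk[i] == risk[comp])
    num <- num + sum(w * conc)
    den <- den + sum(w)
  }
  if (den == 0) {
    warning("no usable pairs; concordance undefined", call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' Bootstrap percentile confidence interval for a reclassification metric
#'
#' Resamples subjects with replacement, recomputes the metric, and reports
#' the percentile 95\% interval plus a two-sided bootstrap p-value for the
#' null that the metric is 0 (twice the smaller tail proportion of the
#' bootstrap distribution around 0). Deterministic given `seed`.
#'
#' @param metric_fn function taking an index vector (the resampled subject
#'   indices) and returning a scalar metric value.
#' @param n number of subjects.
#' @param B number of bootstrap resamples (>= 100).
#' @param seed integer seed.
#' @param max_failures maximum tolerated fraction of resamples where the
#'   metric is undefined (default 0.10).
#' @return A list: `estimate` (full-sample metric), `ci95`, `p`, `n_boot`,
#'   `seed`, `boot` (the bootstrap draws).
#' @export
bootstrap_ci <- function(metric_fn, n, B = 1000L, seed = 1L,
                         max_failures = 0.10) {
  assert_count(B, "B", min = 100L)
  estimate <- tryCatch(suppressWarnings(metric_fn(seq_len(n))),
                       error = function(e) NA_real_)
  boot <- with_stream_seed(seed, "bootstrap", {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(suppressWarnings(metric_fn(idx)),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  fail_frac <- mean(!is.finite(boot))
  if (fail_frac > max_failures) {
    stop(sprintf("metric undefined in %.0f%% of resamples", 100 * fail_frac),
         call. = FALSE)
  }
  boot_ok <- boot[is.finite(boot)]
  ci <- unname(quantile(boot_ok, c(0.025, 0.975)))
  p <- 2 * min(mean(boot_ok <= 0), mean(boot_ok >= 0))
  list(estimate = estimate, ci95 = ci, p = min(p, 1),
       n_boot = length(boot_ok), seed = as.integer(seed), boot = boot)
}

#' Reclassification analysis of an extended risk model
#'
#' Computes the four incremental-value metrics (continuous NRI at the
#' conventional percent scale, categorical NRI at the supplied cutoff,
#' IDI, and the gain in weighted concordance) comparing an extended risk
#' model against a baseline model, with bootstrap percentile intervals.
#'
#' @param risk_old,risk_new baseline and extended predicted risks.
#' @param time,event follow-up time and event indicator.
#' @param weight case-cohort weights (default 1).
#' @param cutoffs categorical NRI cutoffs (default 0.10).
#' @param B bootstrap resamples.
#' @param seed integer seed.
#' @return Data frame with one row per metric: `metric`, `estimate`,
#'   `ci_low`, `ci_high`, `p`, `n_boot`.
#' @export
reclassification <- function(risk_old, risk_new, time, event,
                             weight = rep(1, length(event)),
                             cutoffs = 0.10, B = 1000L, seed = 1L) {
  event <- as.logical(event)
  metrics <- list(
    cNRI = function(i) continuous_nri(risk_old[i], risk_new[i], event[i],
                                      weight[i]),
    catNRI = function(i) categorical_nri(risk_old[i], risk_new[i], event[i],
                                         cutoffs, weight[i]),
    IDI = function(i) idi(risk_old[i], risk_new[i], event[i], weight[i]),
    deltaC = function(i) {
      weighted_cindex(risk_new[i], time[i], event[i], weight[i]) -
        weighted_cindex(risk_old[i], time[i], event[i], weight[i])
    })
  rows <- lapply(names(metrics), function(mname) {
    bc <- bootstrap_ci(metrics[[mname]], length(event), B = B,
                       seed = derive_seed(seed, mname))
    data.frame(metric = mname, estimate = bc$estimate,
               ci_low = bc$ci95[1], ci_high = bc$ci95[2], p = bc$p,
               n_boot = bc$n_boot, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
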