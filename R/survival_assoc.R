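# Case-cohort weighted Cox proportional-hazards association. The analysis
# set of a case-cohort design (all events plus a random subcohort) cannot be
# analysed as a plain cohort: non-case subcohort members stand in for the
# whole censored cohort and must be upweighted. Barlow weighting is the
# default: subcohort person-time is weighted by the inverse sampling
# fraction, while each case contributes its own failure with weight 1 (a
# case outside the subcohort enters the risk set just before its failure).

#' Expand case-cohort records into weighted counting-process form
#'
#' Produces the (start, stop, event, weight) records realizing the chosen
#' case-cohort weighting scheme, suitable for a weighted Cox fit with robust
#' variance.
#'
#' \describe{
#'   \item{Barlow}{subcohort person-time before failure gets weight
#'     `1/sampling_fraction`; every failure itself gets weight 1; cases
#'     outside the subcohort enter just before their failure time.}
#'   \item{Prentice}{subcohort person-time gets weight 1 (no reweighting);
#'     cases outside the subcohort still enter just before failure.}
#' }
#'
#' @param records data frame with columns `time` (years, > 0), `event`
#'   (0/1), `in_subcohort` (logical), plus any covariate columns (carried
#'   through).
#' @param sampling_fraction fraction of the cohort sampled into the
#'   subcohort, in (0, 1]; when `NULL` it must be supplied via
#'   `cohort_size`.
#' @param cohort_size full cohort size, used to estimate the sampling
#'   fraction as `sum(in_subcohort) / cohort_size` when `sampling_fraction`
#'   is `NULL`.
#' @param scheme `"barlow"` (default) or `"prentice"`.
#' @param eps half-width of the pre-failure interval for case entry/failure
#'   splitting, in years.
#' @return The expanded data frame with columns `start`, `stop`, `event`,
#'   `weight` and all covariate columns; attribute `sampling_fraction`
#'   records the value used.
#' @export
assign_casecohort_weights <- function(records, sampling_fraction = NULL,
                                      cohort_size = NULL,
                                      scheme = c("barlow", "prentice"),
                                      eps = 1e-5) {
  scheme <- match.arg(scheme)
  stopifnot(all(c("time", "event", "in_subcohort") %in% names(records)))
  if (any(records$time <= 0)) stop("times must be positive", call. = FALSE)
  if (!all(records$event == 1L | records$in_subcohort)) {
    stop("every record must be an event, a subcohort member, or both",
         call. = FALSE)
  }
  if (is.null(sampling_fraction)) {
    if (is.null(cohort_size)) {
      stop("supply `sampling_fraction` or `cohort_size`", call. = FALSE)
    }
    sampling_fraction <- sum(records$in_subcohort) / cohort_size
  }
  if (sampling_fraction <= 0 || sampling_fraction > 1) {
    stop("`sampling_fraction` must be in (0, 1]", call. = FALSE)
  }
  w_sub <- if (scheme == "barlow") 1 / sampling_fraction else 1
  if (!"id" %in% names(records)) {
    records$id <- sprintf("r%05d", seq_len(nrow(records)))
  }

  covars <- setdiff(names(records), c("start", "stop", "weight"))
  pieces <- list()
  add <- function(rows, start, stop, event, weight) {
    if (nrow(rows) == 0L) return()
    piece <- rows[, covars, drop = FALSE]
    piece$start <- start; piece$stop <- stop
    piece$event <- event; piece$weight <- weight
    pieces[[length(pieces) + 1L]] <<- piece
  }

  sub_nc <- records[records$in_subcohort & records$event == 0L, , drop = FALSE]
  add(sub_nc, 0, sub_nc$time, 0L, w_sub)

  sub_c <- records[records$in_subcohort & records$event == 1L, , drop = FALSE]
  if (nrow(sub_c)) {
    pre <- pmax(sub_c$time - eps, 0)
    add(sub_c[pre > 0, , drop = FALSE], 0, pre[pre > 0], 0L, w_sub)
    add(sub_c, pre, sub_c$time, 1L, 1)
  }

  out_c <- records[!records$in_subcohort & records$event == 1L, , drop = FALSE]
  add(out_c, pmax(out_c$time - eps, 0), out_c$time, 1L, 1)

  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "sampling_fraction") <- sampling_fraction
  attr(out, "scheme") <- scheme
  out
}

#' Weighted Cox proportional-hazards fit with robust variance
#'
#' Maximizes the weighted Cox partial likelihood (Breslow tie handling by
#' default) and reports robust (sandwich) standard errors, hazard ratios and
#' normal-approximation 95\% confidence intervals on the log scale. This is
#' the estimator behind both the plain cohort fit (all weights 1) and the
#' case-cohort fit on records expanded by [assign_casecohort_weights].
#'
#' @param data data frame with either `time`/`event` or
#'   `start`/`stop`/`event` columns, an optional `weight` column, and the
#'   model terms.
#' @param terms character vector of covariate names to include.
#' @param ties tie-handling method, `"breslow"` (default) or `"efron"`.
#' @return A list of class `cox_fit`: `coefficients`, `robust_se`, `hr`,
#'   `ci95` (2-column matrix), `p`, `n_events`, `converged`, and the
#'   underlying [survival::coxph] object as `fit`.
#' @export
fit_weighted_cox <- function(data, terms, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  stopifnot(all(terms %in% names(data)))
  if (!"event" %in% names(data) || sum(data$event) < 1) {
    stop("need at least one event", call. = FALSE)
  }
  zero_var <- vapply(data[terms], function(x) var(as.numeric(x)) == 0,
                     logical(1))
  if (any(zero_var)) {
    stop(sprintf("zero-variance term(s): %s",
                 paste(terms[zero_var], collapse = ", ")), call. = FALSE)
  }
  surv <- if (all(c("start", "stop") %in% names(data))) {
    "survival::Surv(start, stop, event)"
  } else "survival::Surv(time, event)"
  rhs <- paste(sprintf("`%s`", terms), collapse = "+")
  if ("id" %in% names(data)) {
    rhs <- paste(rhs, "+ survival::cluster(id)")   # robust SE over subjects
  }
  fml <- stats::as.formula(paste(surv, "~", rhs))
  weights <- if ("weight" %in% names(data)) data$weight else rep(1, nrow(data))
  fit <- survival::coxph(fml, data = data, weights = weights,
                         ties = ties, robust = TRUE,
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 100))
  beta <- coef(fit)
  se <- sqrt(diag(vcov(fit)))          # robust variance when robust = TRUE
  names(beta) <- names(se) <- terms
  ci <- cbind(low = exp(beta - 1.96 * se), high = exp(beta + 1.96 * se))
  structure(list(coefficients = beta, robust_se = se, hr = exp(beta),
                 ci95 = ci,
                 p = 2 * pnorm(-abs(beta / se)),
                 n_events = fit$nevent,
                 converged = fit$iter < 100L,
                 fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("weighted Cox fit: %d events\n", x$n_events))
  print(data.frame(coef = x$coefficients, HR = x$hr, se = x$robust_se,
                   ci_low = x$ci95[, "low"], ci_high = x$ci95[, "high"],
                   p = x$p))
  invisible(x)
}

#' Per-miRNA case-cohort Cox association scan
#'
#' For each miRNA: restrict to complete cases for that miRNA (non-detects
#' removed from the analysis), expand records with the chosen case-cohort
#' weighting, and fit two adjustment sets -- model A (age + sex + miRNA) and
#' model B (full classical risk-factor adjustment: age, sex, smoking,
#' cholesterol, blood pressure, diabetes, + miRNA). Per-model-set
#' Benjamini-Hochberg adjustment is applied over the scanned miRNAs.
#'
#' @param records case-cohort data frame (`time`, `event`, `in_subcohort`,
#'   covariates, one column per miRNA).
#' @param mirnas character vector of miRNA column names to scan.
#' @param adjustments named list of covariate sets; default the two sets
#'   above.
#' @param sampling_fraction,cohort_size,scheme passed to
#'   [assign_casecohort_weights].
#' @param min_cases minimum complete-case count for a fit (default 10).
#' @return Data frame with one row per miRNA per adjustment set: `mirna`,
#'   `adjustment`, `n`, `n_events`, `hr`, `ci_low`, `ci_high`, `loghr`,
#'   `robust_se`, `p`, `p_adj`, `status`.
#' @export
run_mirna_scan <- function(records, mirnas,
                           adjustments = list(
                             age_sex = c("age", "sex"),
                             full = c("age", "sex", "smoking", "chol",
                                      "sbp", "diabetes")),
                           sampling_fraction = NULL, cohort_size = NULL,
                           scheme = "barlow", min_cases = 10L) {
  stopifnot(all(mirnas %in% names(records)))
  if (is.null(sampling_fraction) && is.null(cohort_size)) {
    stop("supply `sampling_fraction` or `cohort_size`", call. = FALSE)
  }
  out <- list()
  for (adj_name in names(adjustments)) {
    adj <- adjustments[[adj_name]]
    rows <- lapply(mirnas, function(m) {
      res <- data.frame(mirna = m, adjustment = adj_name, n = NA_integer_,
                        n_events = NA_integer_, hr = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        loghr = NA_real_, robust_se = NA_real_, p = NA_real_,
                        p_adj = NA_real_, status = "ok",
                        stringsAsFactors = FALSE)
      cc <- records[!is.na(records[[m]]), , drop = FALSE]
      res$n <- nrow(cc)
      res$n_events <- sum(cc$event)
      if (nrow(cc) < min_cases) {
        res$status <- sprintf("fewer than %d complete cases", min_cases)
        return(res)
      }
      if (var(cc[[m]]) == 0) {
        res$status <- "zero variance"
        return(res)
      }
      tryCatch({
        wrec <- assign_casecohort_weights(cc, sampling_fraction,
                                          cohort_size, scheme)
        fit <- fit_weighted_cox(wrec, c(adj, m))
        res$hr <- fit$hr[m]
        res$ci_low <- fit$ci95[m, "low"]
        res$ci_high <- fit$ci95[m, "high"]
        res$loghr <- fit$coefficients[m]
        res$robust_se <- fit$robust_se[m]
        res$p <- fit$p[m]
        res
      }, error = function(e) {
        res$status <- conditionMessage(e)
        res
      })
    })
    tab <- do.call(rbind, rows)
    tab$p_adj <- bh_adjust(tab$p)
    out[[adj_name]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
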