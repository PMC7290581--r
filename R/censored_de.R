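# Case-control differential expression on deltaCt with non-detects treated
# as right-censored observations. High deltaCt = low expression, so a
# non-detect (expression below the detection limit) is an observation known
# only to exceed every detected deltaCt: censoring at the per-miRNA maximum
# observed value is right censoring on the deltaCt axis, and Kaplan-Meier /
# log-rank machinery applies with deltaCt playing the role of time.

#' Censor non-detects at the per-miRNA maximum observed value
#'
#' @param values numeric vector of \eqn{\Delta}Ct values for one miRNA
#'   (`NA` = non-detect).
#' @param group factor or character vector of group labels, same length.
#' @return A data frame of class `censored_vector` with columns `value`,
#'   `censored`, `group`: missing entries carry the maximum observed value
#'   with `censored = TRUE`.
#' @examples
#' censor_nondetects(c(-1, 0, 2, NA), rep("a", 4))
#' @export
censor_nondetects <- function(values, group) {
  stopifnot(length(values) == length(group))
  if (all(is.na(values))) {
    stop("all values missing for this miRNA; it should have been filtered",
         call. = FALSE)
  }
  cmax <- max(values, na.rm = TRUE)
  out <- data.frame(value = ifelse(is.na(values), cmax, values),
                    censored = is.na(values),
                    group = as.character(group),
                    stringsAsFactors = FALSE)
  class(out) <- c("censored_vector", "data.frame")
  out
}

# survival expects nonnegative "time"; shift deltaCt so the smallest value
# maps to 0 (log-rank is shift-invariant; the restricted mean is shifted back)
shift_to_time <- function(value) value - min(value)

#' Kaplan-Meier restricted mean of a censored \eqn{\Delta}Ct sample
#'
#' Treats \eqn{\Delta}Ct as the ordering axis, computes the product-limit
#' survivor estimate, and returns the restricted mean: the area under the
#' survivor curve from the minimum observation up to the largest observation
#' (censored or not), shifted back to the \eqn{\Delta}Ct origin. With no
#' censoring this equals the arithmetic mean exactly. Censored values tied
#' with an uncensored value rank after it (the standard convention).
#'
#' @param value numeric \eqn{\Delta}Ct values (already censoring-imputed,
#'   see [censor_nondetects]).
#' @param censored logical censoring flags.
#' @return The restricted mean (\eqn{\Delta}Ct units), or `NA` with a
#'   warning when every observation is censored.
#' @export
km_restricted_mean <- function(value, censored = rep(FALSE, length(value))) {
  stopifnot(length(value) == length(censored))
  if (all(censored)) {
    warning("all observations censored; restricted mean undefined",
            call. = FALSE)
    return(NA_real_)
  }
  t0 <- min(value)
  fit <- survival::survfit(
    survival::Surv(shift_to_time(value), !censored) ~ 1)
  # area under S(t) from 0 to the largest observation
  times <- c(0, fit$time)
  surv <- c(1, fit$surv)
  tau <- max(shift_to_time(value))
  keep <- times <= tau
  times <- c(times[keep], tau)
  widths <- diff(times)
  t0 + sum(surv[seq_along(widths)] * widths)
}

#' Two-group log-rank test on the censored \eqn{\Delta}Ct axis
#'
#' @param cv a `censored_vector` (see [censor_nondetects]) with exactly two
#'   groups, each containing at least one uncensored observation.
#' @return A list with `chisq` (1-df statistic) and `p`.
#' @export
logrank_test <- function(cv) {
  stopifnot(inherits(cv, "censored_vector"))
  groups <- unique(cv$group)
  if (length(groups) != 2L) {
    stop("log-rank test requires exactly 2 groups", call. = FALSE)
  }
  for (g in groups) {
    if (!any(!cv$censored[cv$group == g])) {
      stop(sprintf("group '%s' has no uncensored observation", g),
           call. = FALSE)
    }
  }
  sd <- survival::survdiff(
    survival::Surv(shift_to_time(cv$value), !cv$censored) ~ group,
    data = cv)
  list(chisq = unname(sd$chisq),
       p = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Fold change from group mean \eqn{\Delta}Ct
#'
#' `2^-(mean_case - mean_control)`: because lower \eqn{\Delta}Ct means
#' higher expression, a miRNA upregulated in cases yields a fold change
#' above 1.
#'
#' @param mean_case,mean_control group restricted means (\eqn{\Delta}Ct).
#' @return The fold change (positive real).
#' @export
fold_change <- function(mean_case, mean_control) {
  stopifnot(is.finite(mean_case), is.finite(mean_control))
  2^-(mean_case - mean_control)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, delegated to
#' [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone in `p`, never smaller than `p`,
#'   capped at 1).
#' @export
bh_adjust <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  p.adjust(p, method = "BH")
}

#' Case-control differential expression with censored non-detects
#'
#' For each miRNA of a normalized \eqn{\Delta}Ct matrix: impute non-detects
#' at the per-miRNA maximum observed value with a censoring flag, compute
#' Kaplan-Meier restricted means per group, the log-rank p-value, the fold
#' change `2^-(mean_case - mean_control)`, and finally Benjamini-Hochberg
#' adjustment across all tested miRNAs. Per-miRNA failures (e.g. a group
#' with no detected value) are returned as flagged rows, not errors.
#'
#' @param delta a [delta_ct] matrix.
#' @param group vector of `"case"` / `"control"` labels (or any two labels;
#'   `case_label` names the numerator group), one per sample.
#' @param case_label label of the case group, default `"case"`.
#' @return A data frame (one row per miRNA, sorted by adjusted p) with
#'   columns `mirna`, `mean_case`, `mean_control`, `fold_change`,
#'   `logrank_chisq`, `p`, `p_adj`, `n_case`, `n_control`, `n_censored`,
#'   `status` (`"ok"` or the failure reason).
#' @export
run_case_control <- function(delta, group, case_label = "case") {
  stopifnot(inherits(delta, "delta_ct"),
            length(group) == nrow(delta$values))
  group <- as.character(group)
  labs <- unique(group)
  if (length(labs) != 2L || !case_label %in% labs) {
    stop("`group` must contain exactly two labels including `case_label`",
         call. = FALSE)
  }
  control_label <- setdiff(labs, case_label)

  rows <- lapply(colnames(delta$values), function(m) {
    v <- delta$values[, m]
    res <- data.frame(mirna = m, mean_case = NA_real_,
                      mean_control = NA_real_, fold_change = NA_real_,
                      logrank_chisq = NA_real_, p = NA_real_,
                      p_adj = NA_real_,
                      n_case = sum(group == case_label & !is.na(v)),
                      n_control = sum(group == control_label & !is.na(v)),
                      n_censored = sum(is.na(v)),
                      status = "ok", stringsAsFactors = FALSE)
    out <- tryCatch({
      cv <- censor_nondetects(v, group)
      ca <- cv[cv$group == case_label, ]
      co <- cv[cv$group == control_label, ]
      res$mean_case <- km_restricted_mean(ca$value, ca$censored)
      res$mean_control <- km_restricted_mean(co$value, co$censored)
      res$fold_change <- fold_change(res$mean_case, res$mean_control)
      lr <- logrank_test(cv)
      res$logrank_chisq <- lr$chisq
      res$p <- lr$p
      res
    }, error = function(e) {
      res$status <- conditionMessage(e)
      res
    }, warning = function(w) {
      res$status <- conditionMessage(w)
      res
    })
    out
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out[order(out$p_adj, out$p), , drop = FALSE]
}
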