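# In-vitro candidate screening on a summarized log2 expression matrix:
# empirical-Bayes moderated t contrasts (each oxidized condition vs native),
# orthogonal-polynomial trend tests across the three ordered conditions, and
# the conjunction selection rule. The moderated t shrinks per-feature
# variances toward a common prior estimated by method of moments on the
# scaled-F distribution of the sample variances.

# Solve trigamma(y) = x by Newton iteration (monotone decreasing function).
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif) / y < 1e-8) break
    }
    y
  }, numeric(1))
}

# Method-of-moments fit of the scaled-F model for sample variances s2 with
# df residual degrees of freedom; returns prior df d0 and prior value s02.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(prior_df = d0, prior_var = s02)
}

#' Empirical-Bayes moderated t contrast between two conditions
#'
#' Per-feature two-group comparison in which the pooled sample variances are
#' shrunk toward a common prior: the posterior variance is
#' `(d0 * s0^2 + d * s^2) / (d0 + d)` with residual df `d` and prior df
#' `d0`, and the moderated t has `d0 + d` degrees of freedom. The prior
#' `(d0, s0^2)` is estimated across features by method of moments on the
#' log sample variances. `prior_df = 0` recovers the ordinary two-sample
#' pooled t exactly; `prior_df = Inf` gives every feature the common prior
#' variance.
#'
#' @param expr features x samples log2 expression matrix.
#' @param groups sample condition labels.
#' @param contrast length-2 character: `c(numerator, denominator)`
#'   conditions; log2 fold change is numerator minus denominator.
#' @param prior_df `NULL` (estimate from the data), 0, `Inf`, or any
#'   non-negative value to force the prior degrees of freedom.
#' @return Data frame `feature`, `log2fc`, `t`, `df`, `p`, with the fitted
#'   prior in attributes `prior_df` and `prior_var`.
#' @export
moderated_t <- function(expr, groups, contrast, prior_df = NULL) {
  stopifnot(is.matrix(expr), length(groups) == ncol(expr),
            length(contrast) == 2L)
  g1 <- groups == contrast[1]
  g2 <- groups == contrast[2]
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2L || n2 < 2L) {
    stop("need >= 2 replicates in each contrasted condition", call. = FALSE)
  }
  m1 <- rowMeans(expr[, g1, drop = FALSE])
  m2 <- rowMeans(expr[, g2, drop = FALSE])
  ss <- rowSums((expr[, g1, drop = FALSE] - m1)^2) +
    rowSums((expr[, g2, drop = FALSE] - m2)^2)
  d <- n1 + n2 - 2L
  if (d < 1L) stop("zero residual degrees of freedom", call. = FALSE)
  s2 <- ss / d

  if (is.null(prior_df)) {
    prior <- fit_variance_prior(s2, d)
  } else {
    if (!is.numeric(prior_df) || length(prior_df) != 1L || is.na(prior_df) ||
        prior_df < 0) {
      stop("`prior_df` must be a single non-negative number (Inf allowed)",
           call. = FALSE)
    }
    prior <- list(prior_df = prior_df,
                  prior_var = if (prior_df > 0) {
                    fit_variance_prior(s2, d)$prior_var
                  } else 0)
  }
  d0 <- prior$prior_df
  s02 <- prior$prior_var
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else {
    (d0 * s02 + d * s2) / (d0 + d)
  }
  log2fc <- m1 - m2
  tstat <- log2fc / sqrt(s2_post * (1 / n1 + 1 / n2))
  df_total <- d0 + d
  p <- 2 * pt(-abs(tstat), df = df_total)
  out <- data.frame(feature = rownames(expr), log2fc = log2fc, t = tstat,
                    df = df_total, p = p, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s02
  out
}

#' Linear and quadratic trend tests across three ordered conditions
#'
#' Fits, per feature, a Gaussian linear model on orthogonal polynomial
#' contrasts of the ordered condition factor and tests the linear and
#' quadratic coefficients. With three equally spaced conditions the
#' contrasts are proportional to (-1, 0, +1) and (+1, -2, +1) on the
#' condition means, so a symmetric peaked profile loads only on the
#' quadratic term and a monotone linear profile only on the linear term.
#'
#' @param expr features x samples log2 expression matrix.
#' @param condition ordered factor (3 levels) per sample.
#' @return Data frame `feature`, `linear_estimate`, `linear_p`,
#'   `quadratic_estimate`, `quadratic_p`.
#' @export
trend_test <- function(expr, condition) {
  stopifnot(is.matrix(expr), length(condition) == ncol(expr))
  condition <- droplevels(as.factor(condition))
  if (nlevels(condition) != 3L) {
    stop("trend test requires the 3 ordered conditions to be present",
         call. = FALSE)
  }
  cp <- contr.poly(3)
  x <- cbind(intercept = 1,
             linear = cp[as.integer(condition), 1],
             quadratic = cp[as.integer(condition), 2])
  xtx_inv <- solve(crossprod(x))
  betas <- expr %*% x %*% xtx_inv      # features x 3 coefficient matrix
  fitted <- betas %*% t(x)
  rss <- rowSums((expr - fitted)^2)
  df_res <- ncol(expr) - 3L
  if (df_res < 1L) stop("no residual degrees of freedom", call. = FALSE)
  sigma2 <- rss / df_res

  p_for <- function(col) {
    se <- sqrt(sigma2 * xtx_inv[col, col])
    est <- betas[, col]
    p <- 2 * pt(-abs(est / se), df = df_res)
    # noiseless degenerate fits: declare exact zeros null, the rest certain
    zero_sd <- sigma2 < .Machine$double.eps * 100
    p[zero_sd] <- ifelse(abs(est[zero_sd]) < 1e-10, 1, 0)
    p
  }
  data.frame(feature = rownames(expr),
             linear_estimate = betas[, "linear"],
             linear_p = p_for("linear"),
             quadratic_estimate = betas[, "quadratic"],
             quadratic_p = p_for("quadratic"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Screen an in-vitro expression experiment for candidate features
#'
#' Per cell type: moderated t contrasts of each oxidized condition against
#' the native condition, and linear/quadratic trend tests across the three
#' ordered conditions. Returns one row per feature per cell type with the
#' selection flag of [select_candidates] applied.
#'
#' @param expr features x samples log2 matrix.
#' @param samples data frame with `sample_id`, `condition` (ordered factor,
#'   native first), `cell_type`, matching the columns of `expr`.
#' @param fc_min minimum absolute fold change (natural scale), default 1.5.
#' @param alpha significance level for contrast and trend p-values
#'   (unadjusted, as is conventional for this screening step).
#' @param prior_df optional forced prior df for [moderated_t].
#' @return Data frame `feature`, `cell_type`, `log2fc_mox`, `p_mox`,
#'   `log2fc_hox`, `p_hox`, `trend_p_linear`, `trend_p_quadratic`,
#'   `selected` (rule satisfied in that cell type), `selected_any`
#'   (satisfied in at least one cell type).
#' @export
screen_expression <- function(expr, samples, fc_min = 1.5, alpha = 0.05,
                              prior_df = NULL) {
  stopifnot(all(c("sample_id", "condition", "cell_type") %in% names(samples)),
            identical(colnames(expr), samples$sample_id))
  if (!is.factor(samples$condition)) {
    stop("`condition` must be a factor with the native condition as its first level",
         call. = FALSE)
  }
  conds <- levels(samples$condition)
  if (length(conds) != 3L) stop("expect 3 ordered conditions", call. = FALSE)
  native <- conds[1]; mid <- conds[2]; high <- conds[3]

  per_ct <- lapply(unique(samples$cell_type), function(ct) {
    sel <- samples$cell_type == ct
    e <- expr[, sel, drop = FALSE]
    grp <- as.character(samples$condition[sel])
    mox <- moderated_t(e, grp, c(mid, native), prior_df = prior_df)
    hox <- moderated_t(e, grp, c(high, native), prior_df = prior_df)
    tr <- trend_test(e, factor(samples$condition[sel], levels = conds,
                               ordered = TRUE))
    data.frame(feature = mox$feature, cell_type = ct,
               log2fc_mox = mox$log2fc, p_mox = mox$p,
               log2fc_hox = hox$log2fc, p_hox = hox$p,
               trend_p_linear = tr$linear_p,
               trend_p_quadratic = tr$quadratic_p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per_ct)
  select_candidates(tab, fc_min = fc_min, alpha = alpha)
}

#' Apply the candidate selection rule to a screen table
#'
#' A feature is selected in a cell type when it shows `|fold change| >=
#' fc_min` with `p < alpha` in at least one oxidized-vs-native contrast,
#' AND a linear or quadratic trend with `p < alpha`. `selected_any` marks
#' features satisfying the rule in at least one cell type.
#'
#' @param tab screen table as produced by [screen_expression] (columns
#'   `feature`, `cell_type`, `log2fc_mox`, `p_mox`, `log2fc_hox`, `p_hox`,
#'   `trend_p_linear`, `trend_p_quadratic`).
#' @param fc_min,alpha thresholds (natural-scale fold change; unadjusted p).
#' @return `tab` with logical columns `selected` and `selected_any` added.
#' @export
select_candidates <- function(tab, fc_min = 1.5, alpha = 0.05) {
  needed <- c("feature", "cell_type", "log2fc_mox", "p_mox", "log2fc_hox",
              "p_hox", "trend_p_linear", "trend_p_quadratic")
  stopifnot(all(needed %in% names(tab)))
  lfc <- log2(fc_min)
  contrast_hit <- (abs(tab$log2fc_mox) >= lfc & tab$p_mox < alpha) |
    (abs(tab$log2fc_hox) >= lfc & tab$p_hox < alpha)
  trend_hit <- tab$trend_p_linear < alpha | tab$trend_p_quadratic < alpha
  tab$selected <- contrast_hit & trend_hit
  any_by_feature <- tapply(tab$selected, tab$feature, any)
  tab$selected_any <- unname(any_by_feature[tab$feature])
  tab
}

#' Cross-platform validation by Spearman correlation
#'
#' Rank correlation between per-feature summaries from two platforms
#' (e.g. array log2 expression vs qPCR \eqn{\Delta}Ct); since lower
#' \eqn{\Delta}Ct means higher expression, agreement shows as a negative
#' coefficient.
#'
#' @param x,y named numeric vectors of per-feature summaries; matched on
#'   names.
#' @return A list `rho`, `p`, `n` (matched features used).
#' @export
cross_platform_correlation <- function(x, y) {
  common <- intersect(names(x), names(y))
  if (length(common) < 3L) {
    stop("need at least 3 matched features", call. = FALSE)
  }
  xv <- x[common]; yv <- y[common]
  if (sd(xv) == 0 || sd(yv) == 0) {
    stop("constant vector; rank correlation undefined", call. = FALSE)
  }
  ct <- suppressWarnings(cor.test(xv, yv, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(common))
}
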