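# QC filtering, plate-effect correction and global normalization of raw Ct
# tables. Pipeline order is enforced through the provenance log:
# validity -> feature filter -> sample filter -> plate correction -> deltaCt.

#' Drop qPCR observations that failed amplification QC
#'
#' Observations whose validity flag is `FALSE` (amplification-quality score
#' below threshold or no exponential curve) become missing, exactly as
#' reactions with no Ct value.
#'
#' @param ct a [ct_matrix] carrying a validity mask.
#' @return The filtered [ct_matrix]; the number of converted entries is
#'   reported via `message()` and recorded in the provenance log.
#' @export
apply_validity_filter <- function(ct) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (is.null(ct$valid)) {
    return(update_ct(ct, step = "validity(none)"))
  }
  drop <- !ct$valid & !is.na(ct$values)
  values <- ct$values
  values[drop] <- NA_real_
  message(sprintf("validity filter: %d observation(s) set to missing",
                  sum(drop)))
  update_ct(ct, values = values, valid = NULL,
            step = sprintf("validity(%d dropped)", sum(drop)))
}

#' Exclude miRNAs with excessive missingness or infeasible plate correction
#'
#' A miRNA is excluded when its non-detect fraction strictly exceeds
#' `max_missing_frac`, or when it has fewer than two observed values on some
#' plate that has observations at all -- the minimal condition for
#' estimating that plate's location and scale parameters.
#'
#' @param ct a [ct_matrix].
#' @param max_missing_frac exclusion threshold on the per-miRNA missing
#'   fraction (strict inequality), default 0.90.
#' @return A list with `ct` (filtered matrix) and `excluded` (data frame
#'   `mirna`, `reason`). When every miRNA is excluded, `ct` has zero columns
#'   and a warning is raised.
#' @export
filter_features <- function(ct, max_missing_frac = 0.90) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (!is.numeric(max_missing_frac) || max_missing_frac <= 0 ||
      max_missing_frac > 1) {
    stop("`max_missing_frac` must be in (0, 1]", call. = FALSE)
  }
  miss_frac <- colMeans(is.na(ct$values))
  too_missing <- miss_frac > max_missing_frac

  plate_infeasible <- vapply(seq_len(ncol(ct$values)), function(j) {
    obs <- tapply(!is.na(ct$values[, j]), ct$plate, sum)
    any(obs > 0L & obs < 2L)
  }, logical(1))

  reason <- rep(NA_character_, ncol(ct$values))
  reason[plate_infeasible] <- "plate-correction infeasible"
  reason[too_missing] <- sprintf("missing fraction %.2f > %.2f",
                                 miss_frac[too_missing], max_missing_frac)
  drop <- too_missing | plate_infeasible
  excluded <- data.frame(mirna = colnames(ct$values)[drop],
                         reason = reason[drop], stringsAsFactors = FALSE)
  if (all(drop)) {
    warning("all miRNAs excluded by the feature filter", call. = FALSE)
  }
  out <- update_ct(ct, values = ct$values[, !drop, drop = FALSE],
                   valid = if (is.null(ct$valid)) NULL else
                     ct$valid[, !drop, drop = FALSE],
                   step = sprintf("feature_filter(%d dropped)", sum(drop)))
  list(ct = out, excluded = excluded)
}

#' Exclude samples with excessive missingness
#'
#' @param ct a [ct_matrix].
#' @param max_missing_frac exclusion threshold on the per-sample missing
#'   fraction (strict inequality), default 0.95.
#' @return A list with `ct` and `excluded` (character vector of sample ids).
#' @export
filter_samples <- function(ct, max_missing_frac = 0.95) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (!is.numeric(max_missing_frac) || max_missing_frac <= 0 ||
      max_missing_frac > 1) {
    stop("`max_missing_frac` must be in (0, 1]", call. = FALSE)
  }
  miss_frac <- rowMeans(is.na(ct$values))
  drop <- miss_frac > max_missing_frac
  if (all(drop)) {
    warning("all samples excluded by the sample filter", call. = FALSE)
  }
  out <- update_ct(ct, values = ct$values[!drop, , drop = FALSE],
                   plate = ct$plate[!drop],
                   valid = if (is.null(ct$valid)) NULL else
                     ct$valid[!drop, , drop = FALSE],
                   step = sprintf("sample_filter(%d dropped)", sum(drop)))
  list(ct = out, excluded = rownames(ct$values)[drop])
}

#' Correct plate (batch) effects by parametric empirical Bayes
#'
#' Location/scale batch adjustment in the classical empirical-Bayes style:
#' Ct values are standardized per miRNA, per-plate location and scale
#' parameters are estimated and shrunk toward across-plate priors (normal
#' prior for locations, inverse-gamma for scales, hyperparameters by method
#' of moments, posterior found by the standard fixed-point iteration), and
#' the adjusted values are rescaled back. Missing entries remain missing;
#' sums and means use only observed values, so moderate missingness is
#' handled naturally. With a single plate the input is returned unchanged.
#'
#' @param ct a [ct_matrix]; every miRNA should have at least two observed
#'   values on every plate where it is observed (see [filter_features]).
#' @param mean_only if `TRUE`, adjust locations only (scale parameters fixed
#'   at 1). Automatically applied per miRNA/plate cell with zero within-plate
#'   variance, with a warning.
#' @param conv convergence tolerance of the EB fixed-point iteration.
#' @return The corrected [ct_matrix].
#' @export
correct_plate_effects <- function(ct, mean_only = FALSE, conv = 1e-4) {
  stopifnot(inherits(ct, "ct_matrix"))
  plates <- unique(ct$plate)
  if (length(plates) < 2L) {
    return(update_ct(ct, step = "plate_correction(single plate, identity)"))
  }
  # work on miRNAs x samples, the orientation batch models are written in
  x <- t(ct$values)
  batch <- factor(ct$plate, levels = plates)
  n_batch <- nlevels(batch)
  g <- nrow(x)

  obs <- !is.na(x)
  n_gb <- vapply(levels(batch), function(b)
    rowSums(obs[, batch == b, drop = FALSE]), numeric(g))   # g x B
  if (any(n_gb > 0L & n_gb < 2L)) {
    stop("some miRNA has a single observation on a plate; run filter_features first",
         call. = FALSE)
  }
  batch_mean <- vapply(levels(batch), function(b)
    rowMeans(x[, batch == b, drop = FALSE], na.rm = TRUE), numeric(g))
  n_g <- rowSums(n_gb)

  # weighted grand mean and pooled variance, as in design-based standardization
  grand <- rowSums(batch_mean * n_gb, na.rm = TRUE) / n_g
  centered <- x - grand
  fitted_batch <- batch_mean[, as.integer(batch), drop = FALSE]
  var_pooled <- rowSums((x - fitted_batch)^2, na.rm = TRUE) / n_g
  if (any(var_pooled <= 0)) {
    warning("zero pooled variance for some miRNA; location-only adjustment used",
            call. = FALSE)
    var_pooled[var_pooled <= 0] <- 1
  }
  s_data <- centered / sqrt(var_pooled)

  gamma_hat <- vapply(levels(batch), function(b)
    rowMeans(s_data[, batch == b, drop = FALSE], na.rm = TRUE), numeric(g))
  delta_hat <- vapply(levels(batch), function(b)
    apply(s_data[, batch == b, drop = FALSE], 1, var, na.rm = TRUE),
    numeric(g))
  unobserved <- n_gb == 0L                     # miRNA absent from that plate
  gamma_hat[unobserved] <- NA_real_
  zero_var <- !unobserved & (!is.finite(delta_hat) | delta_hat <= 0)
  if (any(zero_var)) {
    warning(sprintf(
      "%d miRNA/plate cell(s) with zero within-plate variance; location-only there",
      sum(zero_var)), call. = FALSE)
  }
  delta_hat[zero_var | unobserved] <- 1

  # empirical-Bayes hyperparameters, method of moments per batch
  gamma_bar <- colMeans(gamma_hat, na.rm = TRUE)
  tau2 <- apply(gamma_hat, 2, var, na.rm = TRUE)
  a_prior <- apply(delta_hat, 2, function(d) {
    m <- mean(d); s2 <- var(d); (2 * s2 + m^2) / s2
  })
  b_prior <- apply(delta_hat, 2, function(d) {
    m <- mean(d); s2 <- var(d); (m * s2 + m^3) / s2
  })

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (b in seq_len(n_batch)) {
    sel <- batch == levels(batch)[b]
    sd_b <- s_data[, sel, drop = FALSE]
    n_b <- n_gb[, b]
    if (mean_only || !is.finite(a_prior[b]) || !is.finite(b_prior[b]) ||
        !is.finite(tau2[b]) || tau2[b] <= 0) {
      gamma_star[, b] <- if (is.finite(tau2[b]) && tau2[b] > 0) {
        (tau2[b] * n_b * gamma_hat[, b] + gamma_bar[b]) /
          (tau2[b] * n_b + 1)
      } else gamma_hat[, b]
      delta_star[, b] <- 1
      next
    }
    g_old <- gamma_hat[, b]
    d_old <- delta_hat[, b]
    change <- Inf
    iter <- 0L
    while (change > conv && iter < 100L) {
      g_new <- (tau2[b] * n_b * gamma_hat[, b] + d_old * gamma_bar[b]) /
        (tau2[b] * n_b + d_old)
      sum2 <- rowSums((sd_b - g_new)^2, na.rm = TRUE)
      d_new <- (0.5 * sum2 + b_prior[b]) / (n_b / 2 + a_prior[b] - 1)
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-8),
                    abs(d_new - d_old) / d_old, na.rm = TRUE)
      g_old <- g_new
      d_old <- d_new
      iter <- iter + 1L
    }
    gamma_star[, b] <- g_old
    delta_star[, b] <- d_old
  }
  delta_star[zero_var] <- 1
  if (mean_only) delta_star[] <- 1

  adj <- s_data
  for (b in seq_len(n_batch)) {
    sel <- batch == levels(batch)[b]
    adj[, sel] <- (s_data[, sel, drop = FALSE] - gamma_star[, b]) /
      sqrt(delta_star[, b])
  }
  adj <- adj * sqrt(var_pooled) + grand

  update_ct(ct, values = t(adj),
            step = sprintf("plate_correction(EB, %d plates)", n_batch))
}

#' Delta-Ct matrix: globally normalized Ct values
#'
#' @param values numeric samples x miRNAs matrix of \eqn{\Delta}Ct values
#'   (`NA` = non-detect).
#' @param reference per-sample reference (mean Ct of that sample's expressed
#'   miRNAs).
#' @param provenance processing log inherited from the [ct_matrix].
#' @return An object of class `delta_ct`.
#' @export
delta_ct <- function(values, reference, provenance = character()) {
  stopifnot(is.matrix(values), length(reference) == nrow(values))
  structure(list(values = values, reference = reference,
                 provenance = provenance),
            class = "delta_ct")
}

#' @export
print.delta_ct <- function(x, ...) {
  cat(sprintf("delta_ct: %d samples x %d miRNAs, %.1f%% non-detect\n",
              nrow(x$values), ncol(x$values), 100 * mean(is.na(x$values))))
  invisible(x)
}

#' Global mean normalization to Delta-Ct
#'
#' Subtracts from each observed Ct the mean Ct of all expressed (observed)
#' miRNAs of the same sample: `dCt[i, j] = Ct[i, j] - mean(Ct[i, observed])`.
#' Lower \eqn{\Delta}Ct therefore means higher relative expression. Samples
#' with no observed miRNA must have been excluded beforehand
#' ([filter_samples]); encountering one signals a pipeline-order violation.
#'
#' @param ct a [ct_matrix] (after filtering and plate correction).
#' @return A [delta_ct] object.
#' @examples
#' ct <- ct_matrix(matrix(c(20, 22, 24), 1, 3,
#'                        dimnames = list("s1", c("a", "b", "c"))), "P1")
#' global_normalize(ct)$values   # -2, 0, +2
#' @export
global_normalize <- function(ct) {
  stopifnot(inherits(ct, "ct_matrix"))
  n_obs <- rowSums(!is.na(ct$values))
  if (any(n_obs == 0L)) {
    stop("sample(s) with zero observed miRNAs reached normalization; ",
         "run filter_samples first", call. = FALSE)
  }
  ref <- rowMeans(ct$values, na.rm = TRUE)
  delta_ct(ct$values - ref, ref,
           provenance = c(ct$provenance, "global_normalize"))
}

#' Run the full Ct processing chain
#'
#' Convenience wrapper applying, in order: validity filter, feature filter,
#' sample filter, plate-effect correction, global normalization.
#'
#' @param ct a raw [ct_matrix].
#' @param feature_missing_max,sample_missing_max missingness thresholds.
#' @param plate_correction set `FALSE` to skip the empirical-Bayes step.
#' @return A list with `delta` (a [delta_ct]), `ct` (the processed
#'   [ct_matrix] before normalization), `excluded_features`,
#'   `excluded_samples`.
#' @export
process_ct <- function(ct, feature_missing_max = 0.90,
                       sample_missing_max = 0.95, plate_correction = TRUE) {
  ct <- apply_validity_filter(ct)
  ff <- filter_features(ct, feature_missing_max)
  fs <- filter_samples(ff$ct, sample_missing_max)
  ct2 <- if (plate_correction) correct_plate_effects(fs$ct) else fs$ct
  list(delta = global_normalize(ct2), ct = ct2,
       excluded_features = ff$excluded, excluded_samples = fs$excluded)
}
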