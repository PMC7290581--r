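# Synthetic-data generators emulating the study design: a qPCR panel measured
# on plates with a limit of detection, an age/sex-matched case-control
# contrast, a followed cohort subsampled as a case-cohort, an in-vitro
# three-condition expression experiment, and toy target/pathway annotation.

#' Configuration for the synthetic case-control qPCR study
#'
#' Defaults reproduce the design of a serum miRNA panel study: 476 myocardial
#' infarction cases and 487 matched controls measured on a ~48-assay custom
#' qPCR panel across 8 plates, with Ct noise, additive and multiplicative
#' plate effects, a Ct limit of detection generating non-detects, and a small
#' rate of amplification-QC failures.
#'
#' @param n_cases,n_controls group sizes.
#' @param n_mirnas panel size (ignored if `baseline_ct` is supplied).
#' @param n_plates number of qPCR plates; samples are assigned round-robin
#'   after shuffling, so plates are balanced in case/control composition.
#' @param true_log2_fc named numeric vector of true log2 fold changes
#'   (cases vs controls) for a subset of miRNAs; unnamed miRNAs get 0.
#'   Positive values mean upregulation in cases (lower Ct).
#' @param baseline_ct named numeric vector of control-group mean Ct per
#'   miRNA; default evenly spans 24-33 cycles so the panel covers abundant
#'   through near-detection-limit species.
#' @param sd_ct within-group Ct standard deviation (cycles).
#' @param plate_shift_sd SD of the additive per-plate Ct offset (cycles).
#' @param plate_scale_sd SD, on the log scale, of the multiplicative
#'   per-plate noise inflation.
#' @param lod_ct limit of detection: latent Ct above this is a non-detect.
#' @param invalid_rate probability that an otherwise-detected reaction fails
#'   amplification QC (flagged invalid, not missing).
#' @param seed integer base seed; all draws derive from named substreams.
#' @return A list of class `cc_config`.
#' @export
cc_config <- function(n_cases = 476L, n_controls = 487L, n_mirnas = 48L,
                      n_plates = 8L, true_log2_fc = NULL, baseline_ct = NULL,
                      sd_ct = 1.5, plate_shift_sd = 0.5, plate_scale_sd = 0.1,
                      lod_ct = 35, invalid_rate = 0.01, seed = 1L) {
  assert_count(n_cases, "n_cases"); assert_count(n_controls, "n_controls")
  assert_count(n_plates, "n_plates")
  assert_scalar_number(sd_ct, "sd_ct", positive = TRUE)
  assert_scalar_number(plate_shift_sd, "plate_shift_sd", nonneg = TRUE)
  assert_scalar_number(plate_scale_sd, "plate_scale_sd", nonneg = TRUE)
  if (!is.finite(lod_ct) && lod_ct > 0) lod_ct <- Inf
  assert_scalar_number(invalid_rate, "invalid_rate", nonneg = TRUE)
  if (is.null(baseline_ct)) {
    assert_count(n_mirnas, "n_mirnas")
    baseline_ct <- setNames(seq(24, 33, length.out = n_mirnas),
                            sprintf("mir%02d", seq_len(n_mirnas)))
  }
  if (is.null(names(baseline_ct))) {
    stop("`baseline_ct` must be a named vector", call. = FALSE)
  }
  fc <- setNames(numeric(length(baseline_ct)), names(baseline_ct))
  if (!is.null(true_log2_fc)) {
    if (is.null(names(true_log2_fc)) ||
        !all(names(true_log2_fc) %in% names(fc))) {
      stop("`true_log2_fc` names must be a subset of the panel miRNAs",
           call. = FALSE)
    }
    fc[names(true_log2_fc)] <- true_log2_fc
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_plates = as.integer(n_plates),
                 true_log2_fc = fc, baseline_ct = baseline_ct,
                 sd_ct = sd_ct, plate_shift_sd = plate_shift_sd,
                 plate_scale_sd = plate_scale_sd, lod_ct = lod_ct,
                 invalid_rate = invalid_rate, seed = as.integer(seed)),
            class = "cc_config")
}

#' Simulate the case-control qPCR study
#'
#' Latent Ct for sample i, miRNA j is
#' `baseline_ct[j] - status_i * true_log2_fc[j] + shift_plate + scale_plate *
#' N(0, sd_ct^2)` with `status_i = 1` for cases; a latent Ct above the limit
#' of detection is emitted as a non-detect (`NA`). Case and control
#' covariates are drawn from the same distribution, emulating an age- and
#' sex-matched design without pair identifiers.
#'
#' @param config a [cc_config].
#' @return A list with elements
#'   \describe{
#'     \item{ct}{a [ct_matrix] with validity flags and plate labels,}
#'     \item{meta}{sample metadata (`sample_id`, `group`, `plate`, `age`,
#'       `sex`),}
#'     \item{truth}{per-miRNA table of the planted log2 fold change, the
#'       fold change realized by the latent (uncensored) draws, and the
#'       realized non-detect fraction.}
#'   }
#' @examples
#' sim <- simulate_case_control(cc_config(n_cases = 30, n_controls = 30,
#'                                        n_mirnas = 5, seed = 7))
#' sim$ct
#' @export
simulate_case_control <- function(config) {
  stopifnot(inherits(config, "cc_config"))
  n <- config$n_cases + config$n_controls
  mirnas <- names(config$baseline_ct)
  p <- length(mirnas)

  status <- c(rep(1L, config$n_cases), rep(0L, config$n_controls))
  ids <- sprintf("s%04d", seq_len(n))

  plate <- with_stream_seed(config$seed, "plates", {
    sample(rep_len(sprintf("P%d", seq_len(config$n_plates)), n))
  })
  shifts <- with_stream_seed(config$seed, "plate_shift",
                             rnorm(config$n_plates, 0, config$plate_shift_sd))
  scales <- with_stream_seed(config$seed, "plate_scale",
                             exp(rnorm(config$n_plates, 0,
                                       config$plate_scale_sd)))
  names(shifts) <- names(scales) <- sprintf("P%d", seq_len(config$n_plates))

  noise <- with_stream_seed(config$seed, "ct_noise",
                            matrix(rnorm(n * p, 0, config$sd_ct), n, p))
  latent <- matrix(config$baseline_ct, n, p, byrow = TRUE) -
    outer(status, config$true_log2_fc) +
    shifts[plate] + scales[plate] * noise
  dimnames(latent) <- list(ids, mirnas)

  values <- latent
  values[latent > config$lod_ct] <- NA_real_

  valid <- with_stream_seed(config$seed, "validity", {
    matrix(runif(n * p) >= config$invalid_rate, n, p)
  })
  valid[is.na(values)] <- TRUE   # validity is a property of detected curves

  meta <- with_stream_seed(config$seed, "covariates", {
    data.frame(sample_id = ids,
               group = ifelse(status == 1L, "case", "control"),
               plate = plate,
               age = round(rnorm(n, 60, 8), 1),
               sex = rbinom(n, 1L, 0.72),
               stringsAsFactors = FALSE)
  })

  case <- status == 1L
  realized_fc <- 2^-(colMeans(latent[case, , drop = FALSE]) -
                       colMeans(latent[!case, , drop = FALSE]))
  truth <- data.frame(mirna = mirnas,
                      true_log2_fc = unname(config$true_log2_fc),
                      realized_fc = unname(realized_fc),
                      nondetect_frac = unname(colMeans(is.na(values))),
                      stringsAsFactors = FALSE)

  list(ct = ct_matrix(values, plate, valid, provenance = "simulated"),
       meta = meta, truth = truth)
}

#' Configuration for the synthetic followed cohort and case-cohort sample
#'
#' Defaults emulate a population cohort followed 10 years for incident
#' coronary events: ~2% cumulative incidence (about 100 events in 5000
#' participants), classical risk factors with hazard-ratio magnitudes typical
#' of coronary risk functions, and a case-cohort sample holding all events
#' plus a random subcohort of four times the event count.
#'
#' @param n_cohort cohort size.
#' @param horizon administrative censoring time, years.
#' @param baseline_hazard events per year for a participant at the covariate
#'   mean (the linear predictor is centered).
#' @param dist event-time distribution: `"exponential"` or `"weibull"`.
#' @param weibull_shape shape parameter when `dist = "weibull"`.
#' @param mirna_log_hr named numeric vector of log hazard ratios per unit of
#'   each miRNA's expression value (normalized \eqn{\Delta}Ct scale,
#'   standard-normal across the cohort); names define the simulated panel.
#' @param covariate_log_hr named log hazard ratios for the classical risk
#'   factors (per year of age, male sex, current smoking, mmol/L total
#'   cholesterol, mmHg systolic pressure, diabetes).
#' @param subcohort_ratio subcohort size as a multiple of the event count.
#' @param seed integer base seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_cohort = 5000L, horizon = 10,
                          baseline_hazard = 0.002,
                          dist = c("exponential", "weibull"),
                          weibull_shape = 1.2,
                          mirna_log_hr = setNames(numeric(14),
                                                  sprintf("mir%02d", 1:14)),
                          covariate_log_hr = c(age = 0.06, sex = 0.45,
                                               smoking = 0.55, chol = 0.20,
                                               sbp = 0.015, diabetes = 0.65),
                          subcohort_ratio = 4L, seed = 1L) {
  assert_count(n_cohort, "n_cohort")
  assert_scalar_number(horizon, "horizon", positive = TRUE)
  assert_scalar_number(baseline_hazard, "baseline_hazard", positive = TRUE)
  assert_count(subcohort_ratio, "subcohort_ratio")
  dist <- match.arg(dist)
  if (is.null(names(mirna_log_hr))) {
    stop("`mirna_log_hr` must be named", call. = FALSE)
  }
  structure(list(n_cohort = as.integer(n_cohort), horizon = horizon,
                 baseline_hazard = baseline_hazard, dist = dist,
                 weibull_shape = weibull_shape,
                 mirna_log_hr = mirna_log_hr,
                 covariate_log_hr = covariate_log_hr,
                 subcohort_ratio = as.integer(subcohort_ratio),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# draw the classical risk-factor table for a cohort
draw_covariates <- function(n) {
  data.frame(age = round(rnorm(n, 55, 10), 1),
             sex = rbinom(n, 1L, 0.50),
             smoking = rbinom(n, 1L, 0.28),
             chol = round(rnorm(n, 5.6, 1.0), 2),
             sbp = round(rnorm(n, 131, 17), 0),
             diabetes = rbinom(n, 1L, 0.12))
}

#' Simulate the followed cohort and its case-cohort sample
#'
#' Event times follow a proportional-hazards model (exponential by default,
#' Weibull optional) on the classical risk factors plus the simulated miRNA
#' values, with administrative censoring at the horizon. The case-cohort
#' analysis table holds all events plus a simple random subcohort of
#' `subcohort_ratio` times the event count.
#'
#' @param config a [cohort_config].
#' @param max_attempts redraw limit when a draw realizes zero events.
#' @return A list with elements `cohort` (full cohort data frame: `id`,
#'   covariates, miRNA values, `time`, `event`), `casecohort` (the analysis
#'   subset with an `in_subcohort` flag), and `truth` (planted log hazard
#'   ratios, realized event count, subcohort sampling fraction).
#' @export
simulate_cohort <- function(config, max_attempts = 10L) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_cohort
  mirnas <- names(config$mirna_log_hr)

  for (attempt in seq_len(max_attempts)) {
    stream <- sprintf("cohort_attempt%d", attempt)
    dat <- with_stream_seed(config$seed, stream, {
      cov <- draw_covariates(n)
      mir <- matrix(rnorm(n * length(mirnas)), n,
                    dimnames = list(NULL, mirnas))
      lp <- as.matrix(cov) %*% config$covariate_log_hr[names(cov)] +
        mir %*% config$mirna_log_hr
      lp <- as.numeric(lp - mean(lp))
      u <- runif(n)
      t_event <- switch(config$dist,
        exponential = -log(u) / (config$baseline_hazard * exp(lp)),
        weibull = {
          # H(t) = h0 * exp(lp) * t^shape  =>  t = (-log U / (h0 e^lp))^(1/shape)
          (-log(u) / (config$baseline_hazard * exp(lp)))^(1 / config$weibull_shape)
        })
      time <- pmin(t_event, config$horizon)
      event <- as.integer(t_event <= config$horizon)
      data.frame(id = sprintf("c%05d", seq_len(n)), cov, mir,
                 time = time, event = event,
                 stringsAsFactors = FALSE, check.names = FALSE)
    })
    n_events <- sum(dat$event)
    if (n_events > 0L) break
    if (attempt == max_attempts) {
      stop(sprintf("no events realized in %d attempts; raise baseline_hazard",
                   max_attempts), call. = FALSE)
    }
  }

  sub_size <- min(n, config$subcohort_ratio * n_events)
  sub_idx <- with_stream_seed(config$seed, "subcohort",
                              sample.int(n, sub_size))
  in_sub <- seq_len(n) %in% sub_idx
  keep <- in_sub | dat$event == 1L
  casecohort <- dat[keep, , drop = FALSE]
  casecohort$in_subcohort <- in_sub[keep]
  rownames(casecohort) <- NULL

  truth <- list(mirna_log_hr = config$mirna_log_hr,
                covariate_log_hr = config$covariate_log_hr,
                n_events = n_events,
                sampling_fraction = sub_size / n)
  list(cohort = dat, casecohort = casecohort, truth = truth)
}

#' Configuration for the synthetic in-vitro expression experiment
#'
#' Emulates a two-cell-type (endothelial, vascular smooth muscle) experiment
#' in which cells are exposed to three ordered lipoprotein conditions
#' (native, moderately oxidized, highly oxidized LDL) and expression is
#' measured on a log2 scale with replicate noise. Each feature's mean
#' profile across the ordered conditions is flat, linear, or quadratic
#' (peaked at the middle condition) with a declared log2 amplitude.
#'
#' @param n_features number of features when `trend_spec` is not supplied;
#'   the default spec makes ~10\% of features trended per cell type.
#' @param n_replicates replicates per condition per cell type.
#' @param conditions ordered condition labels (exactly 3).
#' @param cell_types cell-type labels.
#' @param trend_spec data frame with columns `feature`, `shape`
#'   (`"flat"|"linear"|"quadratic"`), `amplitude` (log2 units); built
#'   randomly when `NULL`.
#' @param noise_sd replicate log2 noise SD.
#' @param seed integer base seed.
#' @return A list of class `array_config`.
#' @export
array_config <- function(n_features = 200L, n_replicates = 3L,
                         conditions = c("nLDL", "moxLDL", "hoxLDL"),
                         cell_types = c("EC", "VSMC"),
                         trend_spec = NULL, noise_sd = 0.3, seed = 1L) {
  assert_count(n_replicates, "n_replicates")
  assert_scalar_number(noise_sd, "noise_sd", positive = TRUE)
  if (length(conditions) != 3L) {
    stop("`conditions` must be exactly 3 ordered levels", call. = FALSE)
  }
  if (n_replicates < 2L) {
    stop("at least 2 replicates per condition are required to estimate variance",
         call. = FALSE)
  }
  if (is.null(trend_spec)) {
    assert_count(n_features, "n_features")
    feats <- sprintf("feat%03d", seq_len(n_features))
    trend_spec <- with_stream_seed(seed, "trend_spec", {
      shape <- rep("flat", n_features)
      n_lin <- max(1L, round(0.06 * n_features))
      n_quad <- max(1L, round(0.04 * n_features))
      pick <- sample.int(n_features, n_lin + n_quad)
      shape[pick[seq_len(n_lin)]] <- "linear"
      shape[pick[-seq_len(n_lin)]] <- "quadratic"
      amp <- numeric(n_features)
      amp[shape != "flat"] <- sample(c(-1, 1), sum(shape != "flat"), TRUE) *
        runif(sum(shape != "flat"), 1, 2)
      data.frame(feature = feats, shape = shape, amplitude = amp,
                 stringsAsFactors = FALSE)
    })
  }
  stopifnot(all(c("feature", "shape", "amplitude") %in% names(trend_spec)),
            all(trend_spec$shape %in% c("flat", "linear", "quadratic")))
  structure(list(n_replicates = as.integer(n_replicates),
                 conditions = conditions, cell_types = cell_types,
                 trend_spec = trend_spec, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "array_config")
}

#' Simulate the in-vitro expression matrix
#'
#' @param config an [array_config].
#' @return A list with `expr` (features x samples log2 matrix) and `samples`
#'   (data frame: `sample_id`, `condition` as an ordered factor, `cell_type`,
#'   `replicate`).
#' @export
simulate_array <- function(config) {
  stopifnot(inherits(config, "array_config"))
  spec <- config$trend_spec
  nf <- nrow(spec)
  conds <- config$conditions

  samples <- expand.grid(replicate = seq_len(config$n_replicates),
                         condition = conds, cell_type = config$cell_types,
                         stringsAsFactors = FALSE)
  samples$condition <- factor(samples$condition, levels = conds,
                              ordered = TRUE)
  samples$sample_id <- sprintf("%s_%s_r%d", samples$cell_type,
                               as.character(samples$condition),
                               samples$replicate)

  # condition profile on a 0..1 dose axis; quadratic peaks mid-condition
  dose <- c(0, 0.5, 1)[as.integer(samples$condition)]
  profile <- function(shape, amp) {
    switch(shape,
           flat = rep(0, nrow(samples)),
           linear = amp * dose,
           quadratic = amp * 4 * dose * (1 - dose))
  }

  expr <- with_stream_seed(config$seed, "array", {
    base <- runif(nf, 4, 10)
    m <- matrix(0, nf, nrow(samples),
                dimnames = list(spec$feature, samples$sample_id))
    for (i in seq_len(nf)) {
      m[i, ] <- base[i] + profile(spec$shape[i], spec$amplitude[i]) +
        rnorm(nrow(samples), 0, config$noise_sd)
    }
    m
  })
  list(expr = expr, samples = samples[, c("sample_id", "condition",
                                          "cell_type", "replicate")])
}

#' Simulate target scores, pathway sets and expressed-gene lists
#'
#' Builds a toy annotation layer for downstream interpretation: a gene
#' universe with per-gene target scores (a context score, more negative =
#' stronger repression, and a non-negative aggregate score) spanning the
#' conventional filtering thresholds; random pathway gene sets; and one
#' expressed-gene list per cell type. Optionally plants an enriched pathway
#' by composing part of it from score-passing target genes.
#'
#' @param n_genes universe size.
#' @param n_sets number of pathway sets.
#' @param target_fraction fraction of the universe given target-like
#'   (threshold-passing) scores, in (0, 1].
#' @param set_size_range inclusive range of pathway sizes.
#' @param expressed_fraction named fractions of the universe expressed per
#'   cell type.
#' @param plant optional list `list(set = <index or name>, frac = <0..1>)`:
#'   that fraction of the planted set is drawn from threshold-passing genes.
#' @param seed integer seed.
#' @return A list with `scores` (data frame `gene`, `context_score`,
#'   `aggregate_score`), `collection` (a [gene_set_collection]), and
#'   `expressed` (named list of gene vectors per cell type).
#' @export
simulate_annotation <- function(n_genes = 500L, n_sets = 10L,
                                target_fraction = 0.25,
                                set_size_range = c(15L, 60L),
                                expressed_fraction = c(EC = 0.75,
                                                       VSMC = 0.85),
                                plant = NULL, seed = 1L) {
  assert_count(n_genes, "n_genes"); assert_count(n_sets, "n_sets")
  if (n_genes < n_sets) stop("need n_genes >= n_sets", call. = FALSE)
  if (!is.numeric(target_fraction) || target_fraction <= 0 ||
      target_fraction > 1) {
    stop("`target_fraction` must be in (0, 1]", call. = FALSE)
  }
  with_stream_seed(seed, "annotation", {
    genes <- sprintf("GENE%04d", seq_len(n_genes))
    is_target <- runif(n_genes) < target_fraction
    context <- ifelse(is_target, runif(n_genes, -0.8, -0.31),
                      runif(n_genes, -0.3, 0.1))
    aggregate <- ifelse(is_target, runif(n_genes, 0.3, 0.8),
                        runif(n_genes, 0, 0.29))
    scores <- data.frame(gene = genes,
                         context_score = round(context, 3),
                         aggregate_score = round(aggregate, 3),
                         stringsAsFactors = FALSE)

    sizes <- sample(seq(set_size_range[1], set_size_range[2]), n_sets,
                    replace = TRUE)
    sets <- lapply(sizes, function(k) sample(genes, k))
    names(sets) <- sprintf("pathway%02d", seq_len(n_sets))
    if (!is.null(plant)) {
      idx <- if (is.character(plant$set)) plant$set else names(sets)[plant$set]
      k <- length(sets[[idx]])
      k_t <- min(round(plant$frac * k), sum(is_target))
      sets[[idx]] <- c(sample(genes[is_target], k_t),
                       sample(genes[!is_target], k - k_t))
    }
    collection <- gene_set_collection(sets, universe = genes)

    expressed <- lapply(expressed_fraction, function(f) {
      sort(sample(genes, round(f * n_genes)))
    })
    list(scores = scores, collection = collection, expressed = expressed)
  })
}
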