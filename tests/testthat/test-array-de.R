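# Moderated t (EB variance shrinkage), orthogonal trend contrasts, the
# candidate selection rule, and cross-platform rank correlation.

sim_expr <- function(nf = 200, n_per = 4, sd = 0.5, seed = 1,
                     groups = c("ctl", "trt")) {
  set.seed(seed)
  g <- rep(groups, each = n_per)
  m <- matrix(rnorm(nf * length(g), 7, sd), nf,
              dimnames = list(sprintf("f%03d", 1:nf), NULL))
  list(expr = m, groups = g)
}

test_that("prior df forced to 0 recovers the ordinary two-sample t exactly", {
  s <- sim_expr(nf = 60, seed = 2)
  mt <- moderated_t(s$expr, s$groups, c("trt", "ctl"), prior_df = 0)
  ordinary <- apply(s$expr, 1, function(row) {
    tt <- t.test(row[s$groups == "trt"], row[s$groups == "ctl"],
                 var.equal = TRUE)
    tt$statistic
  })
  expect_equal(unname(mt$t), unname(ordinary), tolerance = 1e-12)
  expect_equal(mt$df, rep(6, 60))
})

test_that("infinite prior df pools every feature to the common variance", {
  s <- sim_expr(nf = 80, seed = 3)
  mt <- moderated_t(s$expr, s$groups, c("trt", "ctl"), prior_df = Inf)
  s02 <- attr(mt, "prior_var")
  tt <- mt$log2fc / sqrt(s02 * (1 / 4 + 1 / 4))
  expect_equal(mt$t, tt, tolerance = 1e-12)
})

test_that("the variance prior is recovered from simulated data", {
  est <- vapply(1:5, function(s) {
    sim <- sim_expr(nf = 500, sd = 1, seed = 10 + s)
    attr(moderated_t(sim$expr, sim$groups, c("trt", "ctl")), "prior_var")
  }, numeric(1))
  expect_true(all(abs(est - 1) < 0.2))
})

test_that("moderated t matches the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  s <- sim_expr(nf = 300, seed = 6)
  design <- cbind(1, as.integer(s$groups == "trt"))
  lf <- limma::eBayes(limma::lmFit(s$expr, design))
  mt <- moderated_t(s$expr, s$groups, c("trt", "ctl"))
  expect_equal(attr(mt, "prior_df"), lf$df.prior, tolerance = 1e-6)
  expect_equal(attr(mt, "prior_var"), lf$s2.prior, tolerance = 1e-6)
  expect_equal(unname(mt$t), unname(lf$t[, 2]), tolerance = 1e-8)
  expect_equal(unname(mt$p), unname(lf$p.value[, 2]), tolerance = 1e-8)
})

test_that("trend contrasts separate linear from quadratic profiles", {
  cond <- factor(rep(c("nLDL", "moxLDL", "hoxLDL"), each = 3),
                 levels = c("nLDL", "moxLDL", "hoxLDL"), ordered = TRUE)
  lin <- rep(c(0, 1, 2), each = 3)
  quad <- rep(c(0, 1, 0), each = 3)
  expr <- rbind(lin = lin, quad = quad, flat = rep(1, 9))
  tt <- trend_test(expr, cond)
  expect_lt(tt$linear_p[1], 1e-6)                 # pure linear
  expect_equal(tt$quadratic_estimate[1], 0, tolerance = 1e-10)
  expect_equal(tt$quadratic_p[1], 1)
  expect_equal(tt$linear_estimate[2], 0, tolerance = 1e-10)  # pure quadratic
  expect_lt(tt$quadratic_p[2], 1e-6)
  expect_equal(tt$linear_p[3], 1)                 # flat
  expect_error(trend_test(expr[, 1:6], droplevels(cond[1:6])), "3 ordered")
})

test_that("trend estimates agree with lm on polynomial contrasts", {
  set.seed(8)
  cond <- factor(rep(c("a", "b", "c"), each = 4),
                 levels = c("a", "b", "c"), ordered = TRUE)
  expr <- matrix(rnorm(5 * 12), 5, dimnames = list(paste0("g", 1:5), NULL))
  tt <- trend_test(expr, cond)
  for (i in 1:5) {
    fit <- summary(lm(expr[i, ] ~ cond))          # ordered factor -> .L, .Q
    expect_equal(tt$linear_p[i], fit$coefficients["cond.L", 4],
                 tolerance = 1e-9)
    expect_equal(tt$quadratic_p[i], fit$coefficients["cond.Q", 4],
                 tolerance = 1e-9)
  }
})

test_that("flat truth keeps the linear-trend rejection rate near alpha", {
  set.seed(12)
  cond <- factor(rep(c("a", "b", "c"), each = 3),
                 levels = c("a", "b", "c"), ordered = TRUE)
  expr <- matrix(rnorm(2000 * 9), 2000)
  rownames(expr) <- sprintf("g%04d", 1:2000)
  tt <- trend_test(expr, cond)
  rate <- mean(tt$linear_p < 0.05)
  expect_gt(rate, 0.03); expect_lt(rate, 0.07)
})

test_that("selection rule is the exact conjunction and is monotone", {
  tab <- data.frame(feature = sprintf("f%02d", 1:4), cell_type = "EC",
                    log2fc_mox = c(2, 0.3, 2, 0.1),
                    p_mox = c(0.001, 0.001, 0.2, 0.9),
                    log2fc_hox = c(0, 0, 0, 0),
                    p_hox = c(0.9, 0.9, 0.9, 0.9),
                    trend_p_linear = c(0.01, 0.01, 0.01, 0.6),
                    trend_p_quadratic = c(0.5, 0.5, 0.5, 0.6))
  out <- select_candidates(tab)
  expect_equal(out$selected, c(TRUE, FALSE, FALSE, FALSE))
  # significant contrast but no trend -> deselected
  tab2 <- tab[1, ]; tab2$trend_p_linear <- 0.2; tab2$trend_p_quadratic <- 0.2
  expect_false(select_candidates(tab2)$selected)
  # monotonicity: decreasing p or increasing |fc| never deselects
  set.seed(3)
  for (i in 1:50) {
    base <- data.frame(feature = "f", cell_type = "EC",
                       log2fc_mox = rnorm(1), p_mox = runif(1),
                       log2fc_hox = rnorm(1), p_hox = runif(1),
                       trend_p_linear = runif(1),
                       trend_p_quadratic = runif(1))
    better <- transform(base,
                        log2fc_mox = log2fc_mox * 1.5,
                        p_mox = p_mox / 2, p_hox = p_hox / 2,
                        trend_p_linear = trend_p_linear / 2)
    if (select_candidates(base)$selected) {
      expect_true(select_candidates(better)$selected)
    }
  }
})

test_that("screen of a simulated experiment finds the trended features", {
  cfg <- array_config(n_features = 150, noise_sd = 0.2, seed = 14)
  sim <- simulate_array(cfg)
  scr <- screen_expression(sim$expr, sim$samples)
  truth <- cfg$trend_spec
  trended <- truth$feature[truth$shape != "flat" & abs(truth$amplitude) >= 1]
  hit <- unique(scr$feature[scr$selected_any])
  expect_gt(mean(trended %in% hit), 0.8)       # high power at these settings
  flat <- truth$feature[truth$shape == "flat"]
  expect_lt(mean(flat %in% hit), 0.15)         # few false selections
})

test_that("cross-platform correlation behaves and recovers planted rho", {
  x <- setNames(1:10, paste0("m", 1:10))
  expect_equal(cross_platform_correlation(x, -x)$rho, -1)
  expect_error(cross_platform_correlation(x[1:2], -x[1:2]), "3 matched")
  expect_error(cross_platform_correlation(x, setNames(rep(1, 10), names(x))),
               "constant")
  # latent bivariate-normal correlation -0.5 at the validation panel size
  # of 51; the implied Spearman is (6/pi) asin(rho/2) ~ -0.48
  est <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 51
    z1 <- rnorm(n); z2 <- rnorm(n)
    a <- setNames(z1, paste0("m", 1:n))
    b <- setNames(-0.5 * z1 + sqrt(1 - 0.25) * z2, paste0("m", 1:n))
    cross_platform_correlation(a, b)$rho
  }, numeric(1))
  expect_lt(abs(mean(est) - (6 / pi) * asin(-0.25)), 0.15)
})
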