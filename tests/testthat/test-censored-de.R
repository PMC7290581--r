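# Censored differential expression: censoring rule, KM restricted means
# against a hand product-limit oracle, log-rank against risk-set enumeration,
# fold-change arithmetic, BH, and the assembled per-miRNA table.

test_that("non-detects are censored at the per-miRNA maximum observed value", {
  cv <- censor_nondetects(c(-1, 0, 2, NA), rep("a", 4))
  expect_equal(cv$value, c(-1, 0, 2, 2))
  expect_equal(cv$censored, c(FALSE, FALSE, FALSE, TRUE))
  # no missing -> all uncensored, unchanged
  cv2 <- censor_nondetects(c(1, 2), c("a", "b"))
  expect_false(any(cv2$censored))
  # one observed, rest missing -> all pinned to it
  cv3 <- censor_nondetects(c(NA, 5, NA), rep("a", 3))
  expect_equal(cv3$value, c(5, 5, 5))
  expect_error(censor_nondetects(c(NA, NA), c("a", "a")), "filtered")
})

test_that("KM restricted mean equals the arithmetic mean without censoring", {
  expect_equal(km_restricted_mean(c(1, 2, 3)), 2)
  for (s in 1:20) {
    set.seed(s)
    v <- rnorm(sample(3:40, 1))
    expect_equal(km_restricted_mean(v), mean(v), tolerance = 1e-12)
  }
})

test_that("KM restricted mean matches hand product-limit enumeration", {
  # worked toy: events at 1, 2; censored at 3 => S steps 1 -> 2/3 -> 1/3,
  # restricted mean = 1 + 2/3 + 1/3 = 2
  expect_equal(km_restricted_mean(c(1, 2, 3), c(FALSE, FALSE, TRUE)), 2)
  for (s in 1:25) {
    set.seed(100 + s)
    n <- sample(3:12, 1)
    v <- round(rnorm(n), 1)           # induce ties
    cen <- runif(n) < 0.3
    if (all(cen)) cen[1] <- FALSE
    expect_equal(km_restricted_mean(v, cen), oracle_km_rmean(v, cen),
                 tolerance = 1e-10, info = paste("seed", s))
  }
})

test_that("all-equal values give that value regardless of censoring", {
  expect_equal(km_restricted_mean(rep(4, 6), c(TRUE, FALSE, TRUE, FALSE,
                                               TRUE, FALSE)), 4)
  expect_warning(out <- km_restricted_mean(c(1, 2), c(TRUE, TRUE)),
                 "undefined")
  expect_true(is.na(out))
})

test_that("log-rank statistic matches risk-set enumeration", {
  # textbook-style toy: 6 observations, 1 censored
  v <- c(1, 2, 3, 4, 5, 6)
  cen <- c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  grp <- c("a", "b", "a", "b", "a", "b")
  cv <- censor_nondetects(ifelse(cen, NA, v), grp)
  cv$value <- v; cv$censored <- cen          # keep the designed pattern
  lr <- logrank_test(cv)
  expect_equal(lr$chisq, oracle_logrank(v, cen, grp), tolerance = 1e-10)
  # randomized instances with ties and censoring
  for (s in 1:20) {
    set.seed(200 + s)
    n <- sample(8:30, 1)
    v <- round(rnorm(n), 1)
    cen <- runif(n) < 0.25
    grp <- sample(c("x", "y"), n, replace = TRUE)
    if (length(unique(grp)) < 2 || !any(!cen[grp == "x"]) ||
        !any(!cen[grp == "y"])) next
    cv <- structure(data.frame(value = v, censored = cen, group = grp),
                    class = c("censored_vector", "data.frame"))
    expect_equal(logrank_test(cv)$chisq, oracle_logrank(v, cen, grp),
                 tolerance = 1e-8, info = paste("seed", s))
  }
})

test_that("log-rank is symmetric and shift-invariant", {
  v <- c(0.3, -1, 2, 0.3, 1.1, -0.5, 0.9, 2)
  grp <- rep(c("a", "b"), each = 4)
  cv_id <- structure(data.frame(value = rep(v[1:4], 2),
                                censored = rep(FALSE, 8),
                                group = grp),
                     class = c("censored_vector", "data.frame"))
  lr <- logrank_test(cv_id)         # identical multisets
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  cv <- structure(data.frame(value = v, censored = rep(c(FALSE, TRUE), 4),
                             group = grp),
                  class = c("censored_vector", "data.frame"))
  cv_shift <- cv
  cv_shift$value <- cv$value + 11.3
  expect_equal(logrank_test(cv)$chisq, logrank_test(cv_shift)$chisq,
               tolerance = 1e-12)
  expect_error(logrank_test(structure(
    data.frame(value = 1:3, censored = rep(FALSE, 3), group = rep("a", 3)),
    class = c("censored_vector", "data.frame"))), "2 groups")
})

test_that("fold change follows 2^-(difference) and is antisymmetric", {
  expect_equal(fold_change(1, 1), 1)
  expect_equal(fold_change(-1, 0), 2)
  expect_equal(fold_change(-log2(4.85), 0), 4.85)
  for (s in 1:10) {
    set.seed(s)
    a <- rnorm(1); b <- rnorm(1)
    expect_equal(fold_change(a, b), 1 / fold_change(b, a), tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  for (s in 1:10) {
    set.seed(s)
    p <- runif(sample(2:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))   # monotone in raw p
  }
})

test_that("run_case_control returns one row per miRNA and flags failures", {
  sim <- simulate_case_control(cc_config(n_cases = 80, n_controls = 80,
                                         n_mirnas = 14, n_plates = 2,
                                         lod_ct = 33, seed = 15))
  res <- suppressMessages(process_ct(sim$ct))
  de <- run_case_control(res$delta, sim$meta$group)
  expect_equal(nrow(de), ncol(res$delta$values))
  expect_true(all(de$p_adj >= de$p - 1e-12, na.rm = TRUE))
  expect_true(all(de$fold_change > 0, na.rm = TRUE))
  # a miRNA missing in every case is flagged, not fatal
  vals <- res$delta$values
  vals[sim$meta$group[match(rownames(vals), sim$meta$sample_id)] == "case",
       1] <- NA
  de2 <- run_case_control(delta_ct(vals, rep(0, nrow(vals))),
                          sim$meta$group[match(rownames(vals),
                                               sim$meta$sample_id)])
  expect_true(any(de2$status != "ok"))
  expect_equal(nrow(de2), ncol(vals))
})

test_that("null panel yields no BH-significant miRNAs", {
  sim <- simulate_case_control(cc_config(n_cases = 150, n_controls = 150,
                                         n_mirnas = 10, n_plates = 2,
                                         seed = 33))
  res <- suppressMessages(process_ct(sim$ct))
  de <- run_case_control(res$delta, sim$meta$group)
  expect_lte(sum(de$p_adj < 0.05, na.rm = TRUE), 1L)
})
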