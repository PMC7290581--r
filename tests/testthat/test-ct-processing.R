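# QC filters, empirical-Bayes plate correction, global normalization.

mk_ct <- function(values, plate = rep("P1", nrow(values)), valid = NULL) {
  dimnames(values) <- list(sprintf("s%d", seq_len(nrow(values))),
                           sprintf("m%d", seq_len(ncol(values))))
  if (!is.null(valid)) dimnames(valid) <- dimnames(values)
  ct_matrix(values, plate, valid)
}

test_that("validity filter converts flagged observations to missing", {
  v <- matrix(c(20, 21, 22, 23), 2)
  valid <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2)
  ct <- mk_ct(v, valid = valid)
  out <- suppressMessages(apply_validity_filter(ct))
  expect_equal(sum(is.na(out$values)), 1L)
  expect_true(is.na(out$values[2, 1]))
  # all valid -> identity
  ct2 <- mk_ct(v, valid = matrix(TRUE, 2, 2))
  expect_equal(suppressMessages(apply_validity_filter(ct2))$values, ct2$values)
  # all invalid -> fully missing
  ct3 <- mk_ct(v, valid = matrix(FALSE, 2, 2))
  expect_true(all(is.na(suppressMessages(apply_validity_filter(ct3))$values)))
})

test_that("feature filter applies the strict >90% missingness rule", {
  n <- 100
  v <- matrix(rnorm(n * 3, 25), n, 3)
  v[1:91, 1] <- NA    # 91% missing -> excluded
  v[1:90, 2] <- NA    # exactly 90% -> retained
  ct <- mk_ct(v)
  res <- filter_features(ct)
  expect_identical(res$excluded$mirna, "m1")
  expect_match(res$excluded$reason, "missing fraction")
  expect_identical(colnames(res$ct$values), c("m2", "m3"))
})

test_that("feature filter drops miRNAs that defeat plate correction", {
  set.seed(1)
  v <- matrix(rnorm(40 * 2, 25), 40, 2)
  plate <- rep(c("P1", "P2"), each = 20)
  v[21:39, 1] <- NA                 # single observation on plate P2
  ct <- mk_ct(v, plate)
  res <- filter_features(ct)
  expect_identical(res$excluded$mirna, "m1")
  expect_identical(res$excluded$reason, "plate-correction infeasible")
  # and the correction indeed refuses such input
  expect_error(correct_plate_effects(ct), "single observation")
})

test_that("sample filter applies the strict >95% rule", {
  v <- matrix(rnorm(300, 25), 3, 100)
  v[1, 1:96] <- NA    # 96% -> excluded
  v[2, 1:95] <- NA    # 95% boundary -> retained
  ct <- mk_ct(v)
  res <- filter_samples(ct)
  expect_identical(res$excluded, "s1")
  expect_equal(nrow(res$ct$values), 2L)
  # no missing values anywhere -> no exclusions
  ct2 <- mk_ct(matrix(rnorm(40, 25), 4))
  expect_length(filter_samples(ct2)$excluded, 0L)
})

test_that("filters are idempotent", {
  sim <- simulate_case_control(cc_config(n_cases = 60, n_controls = 60,
                                         n_mirnas = 8, n_plates = 2,
                                         lod_ct = 30, seed = 4))
  once <- filter_features(sim$ct)$ct
  twice <- filter_features(once)$ct
  expect_equal(twice$values, once$values)
  s_once <- filter_samples(once)$ct
  s_twice <- filter_samples(s_once)$ct
  expect_equal(s_twice$values, s_once$values)
})

test_that("single plate makes plate correction the identity", {
  ct <- mk_ct(matrix(rnorm(60, 25), 10, 6))
  out <- correct_plate_effects(ct)
  expect_equal(out$values, ct$values)
})

test_that("a pure location offset between two plates is removed", {
  set.seed(7)
  n <- 40
  v <- matrix(rep(c(24, 26, 28), each = n), n, 3) +
    matrix(rnorm(n * 3, 0, 1e-6), n, 3)   # tiny jitter so scales estimable
  plate <- rep(c("A", "B"), each = n / 2)
  v[plate == "B", ] <- v[plate == "B", ] + 2
  ct <- mk_ct(v, plate)
  out <- correct_plate_effects(ct)
  for (j in 1:3) {
    dd <- mean(out$values[plate == "A", j]) - mean(out$values[plate == "B", j])
    expect_lt(abs(dd), 1e-3)
  }
  # overall per-miRNA mean preserved
  expect_equal(unname(colMeans(out$values)), unname(colMeans(v)),
               tolerance = 1e-6)
})

test_that("plate correction matches the reference empirical-Bayes batch
           adjustment on complete data", {
  skip_if_not_installed("sva")
  ct <- make_plate_fixture(n_per_plate = 25, n_plates = 4, n_mir = 8,
                           seed = 11)
  ours <- correct_plate_effects(ct)
  ref <- t(suppressMessages(
    sva::ComBat(dat = t(ct$values), batch = factor(ct$plate))))
  expect_equal(unname(ours$values), unname(ref), tolerance = 1e-6)
})

test_that("planted plate offsets shrink between-plate variance by >90%", {
  set.seed(31)
  offsets <- rnorm(8, 0, 1)
  ct <- make_plate_fixture(n_per_plate = 25, n_plates = 8, n_mir = 10,
                           offsets = offsets, noise = 0.4, seed = 13)
  out <- correct_plate_effects(ct)
  plate_var <- function(m) {
    mean(apply(m, 2, function(col) var(tapply(col, ct$plate, mean))))
  }
  expect_lt(plate_var(out$values), 0.1 * plate_var(ct$values))
})

test_that("plate correction keeps missing entries missing", {
  ct <- make_plate_fixture(seed = 17)
  ct$values[cbind(c(3, 10, 50), c(1, 2, 5))] <- NA
  out <- correct_plate_effects(ct)
  expect_identical(is.na(out$values), is.na(ct$values))
})

test_that("global normalization is the per-sample mean subtraction", {
  ct <- mk_ct(matrix(c(20, 22, 24), 1, 3))
  d <- global_normalize(ct)
  expect_equal(unname(d$values[1, ]), c(-2, 0, 2))
  expect_equal(unname(d$reference), 22)
  # invariance to a per-sample additive shift
  ct2 <- mk_ct(matrix(c(20, 22, 24) + 7, 1, 3))
  expect_equal(global_normalize(ct2)$values, d$values)
  # single observed miRNA -> deltaCt 0
  ct3 <- mk_ct(matrix(c(25, NA, NA), 1, 3))
  expect_equal(unname(global_normalize(ct3)$values[1, 1]), 0)
})

test_that("normalization rejects samples with no observed values", {
  v <- matrix(c(NA, NA, 20, 21), 2, 2, byrow = TRUE)
  expect_error(global_normalize(mk_ct(v)), "filter_samples")
})

test_that("plate correction then normalization commutes with a global shift", {
  ct <- make_plate_fixture(seed = 23)
  a <- global_normalize(correct_plate_effects(ct))$values
  ct_shift <- ct_matrix(ct$values + 3, ct$plate)
  b <- global_normalize(correct_plate_effects(ct_shift))$values
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("process_ct records the enforced pipeline order", {
  sim <- simulate_case_control(cc_config(n_cases = 50, n_controls = 50,
                                         n_mirnas = 6, n_plates = 2,
                                         seed = 6))
  res <- suppressMessages(process_ct(sim$ct))
  prov <- res$delta$provenance
  expect_true(which(grepl("validity", prov)) <
                which(grepl("feature_filter", prov)))
  expect_true(which(grepl("feature_filter", prov)) <
                which(grepl("sample_filter", prov)))
  expect_true(which(grepl("sample_filter", prov)) <
                which(grepl("plate_correction", prov)))
  expect_identical(prov[length(prov)], "global_normalize")
})

test_that("wide Ct table round-trips through TSV", {
  sim <- simulate_case_control(cc_config(n_cases = 15, n_controls = 15,
                                         n_mirnas = 5, n_plates = 2,
                                         lod_ct = 31, seed = 12))
  path <- tempfile(fileext = ".tsv")
  write_ct_table(sim$ct, path)
  back <- read_ct_table(path, sim$meta)
  expect_equal(back$values, sim$ct$values, tolerance = 1e-12)
  expect_identical(back$plate, sim$ct$plate)
})
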