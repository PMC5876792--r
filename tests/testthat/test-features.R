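# The 45-feature registry: hand-computable examples, estimator recovery,
# scaling behavior, registry bookkeeping.

test_that("time-domain statistics match hand arithmetic on {1,2,3,4}", {
  td <- time_domain_stats(c(1, 2, 3, 4))
  expect_equal(td[["M"]], 2.5)
  expect_equal(td[["SD"]], sd(c(1, 2, 3, 4)), tolerance = 1e-12)
  expect_equal(td[["SD"]], 1.2910, tolerance = 1e-4)
  expect_equal(td[["RMS"]], sqrt(30 / 4), tolerance = 1e-12)
  expect_equal(td[["RMS"]], 2.7386, tolerance = 1e-4)
  # type-7 quantiles: q75 = 3.25, q25 = 1.75
  expect_equal(td[["IQR"]], 1.5)
  expect_error(time_domain_stats(rep(2, 10)), "degenerate")
})

test_that("skewness ~ 0 and kurtosis ~ 3 for a large Gaussian sample", {
  set.seed(30)
  x <- rnorm(1e5)
  td <- time_domain_stats(x)
  expect_lt(abs(td[["Skew"]]), 0.05)
  expect_lt(abs(td[["Kurt"]] - 3), 0.1)
})

test_that("entropy of a nearly one-bin distribution is near zero", {
  x <- c(rep(0, 990), rep(1, 10))  # SD > 0, 99% of mass in one bin
  td <- time_domain_stats(x)
  expect_lt(td[["E"]], 0.1)
  # uniform over bins comes out near log2(100)
  u <- seq(0, 1, length.out = 10000)
  expect_gt(time_domain_stats(u)[["E"]], 6.5)
})

test_that("Nakagami moment estimators recover known parameters", {
  expect_equal(nakagami_fit(c(1, 2))[["omega"]], 2.5)
  expect_error(nakagami_fit(c(-1, rep(1, 20))), "domain")
  set.seed(31)
  for (mu in c(0.5, 1, 2, 5)) {
    x <- rnakagami(1e5, mu, omega = 2)
    fit <- nakagami_fit(x)
    expect_lt(abs(fit[["mu"]] - mu) / mu, 0.05)
    expect_lt(abs(fit[["omega"]] - 2) / 2, 0.03)
  }
})

test_that("sorted DCT coefficients are monotone in magnitude", {
  set.seed(32)
  cc <- dct_sorted(abs(rnorm(500)) + 1)
  expect_true(all(diff(abs(cc)) <= 1e-14))
})

test_that("energy percentage follows the vector-norm definition", {
  expect_equal(energy_percentage(c(4, 3), 1), 80)
  expect_equal(energy_percentage(c(4, 3), 2), 100)
  expect_equal(energy_percentage(c(1, 1, 1, 1), 2), 100 * sqrt(2) / 2,
               tolerance = 1e-12)
  set.seed(33)
  cc <- dct_sorted(abs(rnorm(100)))
  p <- vapply(1:100, function(k) energy_percentage(cc, k), numeric(1))
  expect_true(all(diff(p) >= -1e-12))
  expect_equal(p[100], 100)
  expect_error(energy_percentage(c(0, 0), 1), "zero")
})

test_that("N_DCT counts coefficients to the 98% energy threshold", {
  expect_identical(n_dct(c(5, 0, 0)), 1L)
  expect_identical(n_dct(c(4, 3)), 2L)
  # flat (white) spectra need most coefficients: N_DCT > N/2
  set.seed(34)
  for (i in 1:5) {
    cc <- dct_sorted(rnorm(256))
    expect_gt(n_dct(cc), 128)
  }
})

test_that("DCT spectrum summary scales as documented", {
  fs <- 5000
  env <- rep(2, 500)
  s <- dct_spectrum_summary(env, fs)
  expect_equal(s[["Peak_DCT"]], sqrt(500) * 2, tolerance = 1e-12)
  expect_equal(s[["P_DCT"]], 500 * 4, tolerance = 1e-9)
  z <- dct_spectrum_summary(rep(0, 100), fs)
  expect_identical(unname(z), c(0, 0, 0))
  set.seed(35)
  e1 <- abs(rnorm(400)) + 0.5
  s1 <- dct_spectrum_summary(e1, fs)
  s2 <- dct_spectrum_summary(2 * e1, fs)
  expect_equal(s2[["AUC_DCT"]], 2 * s1[["AUC_DCT"]], tolerance = 1e-12)
  expect_equal(s2[["Peak_DCT"]], 2 * s1[["Peak_DCT"]], tolerance = 1e-12)
  expect_equal(s2[["P_DCT"]], 4 * s1[["P_DCT"]], tolerance = 1e-12)
})

test_that("featurize emits the full 45-name registry, deterministically", {
  x <- make_epoch_samples(seed = 40)
  fv <- featurize(x, fs = 5000)
  expect_identical(names(fv), feature_names())
  expect_length(fv, 45)
  expect_true(all(is.finite(fv)))
  # partition: 7 time stats + 2 Nakagami + 24 DCT + 12 wavelet
  expect_length(grep("^E_DCT_l", names(fv)), 20)
  expect_length(grep("^E_(Haar|Db10)", names(fv)), 12)
  expect_identical(fv, featurize(x, fs = 5000))
  wl <- fv[grep("^E_(Haar|Db10)", names(fv))]
  expect_true(all(wl >= 0 & wl <= 1))
  expect_lte(sum(fv[paste0("E_Haar", 1:6)]), 1 + 1e-9)
  expect_lte(sum(fv[paste0("E_Db10_", 1:6)]), 1 + 1e-9)
})

test_that("feature scaling audit: invariant vs homogeneous features", {
  x <- make_epoch_samples(seed = 41)
  f1 <- featurize(x, fs = 5000)
  f2 <- featurize(2 * x, fs = 5000)
  invariant <- c("Skew", "Kurt", "mu_nakagami", "N_DCT",
                 paste0("E_Haar", 1:6), paste0("E_Db10_", 1:6))
  for (nm in invariant)
    expect_equal(f2[[nm]], f1[[nm]], tolerance = 1e-6, label = nm)
  for (nm in c("SD", "RMS", "IQR", "AUC_DCT", "Peak_DCT"))
    expect_equal(f2[[nm]], 2 * f1[[nm]], tolerance = 1e-9, label = nm)
  expect_equal(f2[["P_DCT"]], 4 * f1[["P_DCT"]], tolerance = 1e-9)
  expect_equal(f2[["omega_nakagami"]], 4 * f1[["omega_nakagami"]],
               tolerance = 1e-9)
})

test_that("particle averaging collapses epochs to one row per particle", {
  tb <- data.frame(particle_id = c("a", "a", "b"),
                   class_label = c("x", "x", "y"),
                   epoch_index = c(0, 1, 0),
                   M = c(1, 3, 7), SD = c(2, 2, 5))
  pa <- particle_average(tb)
  expect_identical(nrow(pa), 2L)
  expect_equal(pa$M[pa$particle_id == "a"], 2)
  expect_equal(pa$M[pa$particle_id == "b"], 7)
  expect_identical(pa$n_epochs, c(2L, 1L))
})
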