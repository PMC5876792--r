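# Fisher discriminant: exclusions, standardization, scatter matrices,
# eigen solution against brute-force direction search, projection and
# contribution weights.

test_that("default exclusions leave 43 of 45 features", {
  tb <- as.data.frame(as.list(setNames(rnorm(45), feature_names())))
  colnames(tb) <- feature_names()
  out <- exclude_features(tb)
  expect_identical(ncol(out), 43L)
  expect_false(any(c("RMS", "omega_nakagami") %in% colnames(out)))
  expect_identical(exclude_features(tb, character(0)), tb)
  expect_error(exclude_features(tb, "no_such_feature"), "unknown")
})

test_that("standardization centers, scales, and round-trips", {
  std <- standardize_features(cbind(a = c(1, 3), b = c(0, 10)))
  expect_equal(unname(std$x[, "a"]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  set.seed(50)
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  s1 <- standardize_features(x)
  expect_lt(max(abs(colMeans(s1$x))), 1e-10)
  expect_lt(max(abs(apply(s1$x, 2, sd) - 1)), 1e-10)
  s2 <- standardize_features(s1$x)   # idempotence on standardized input
  expect_equal(s2$x, s1$x, tolerance = 1e-10, ignore_attr = TRUE)
  # applying stored parameters reproduces the standardized table
  z <- sweep(sweep(x, 2, s1$center), 2, s1$scale, "/")
  expect_equal(z, s1$x, tolerance = 1e-12)
  expect_error(standardize_features(cbind(a = rep(1, 5), b = rnorm(5))),
               "zero-variance.*a")
})

test_that("scatter matrices obey the decomposition identity", {
  # 1-D: classes {0,0} and {1,1} -> no within-scatter, positive between
  sm <- scatter_matrices(matrix(c(0, 0, 1, 1)), c("a", "a", "b", "b"))
  expect_equal(sm$S_within[1, 1], 0)
  expect_gt(sm$S_between[1, 1], 0)
  # identical rows everywhere -> both zero
  sm0 <- scatter_matrices(matrix(1, 6, 2), rep(c("a", "b", "c"), 2))
  expect_true(all(sm0$S_within == 0) && all(abs(sm0$S_between) < 1e-15))
  # S_within + count-weighted between == total scatter
  set.seed(51)
  x <- matrix(rnorm(60 * 5), 60, 5)
  labels <- rep(c("a", "b", "c"), each = 20)
  sm <- scatter_matrices(x, labels)
  n <- nrow(x)
  total <- crossprod(sweep(x, 2, colMeans(x)))
  expect_equal(sm$S_within + n * sm$S_between, total, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(scatter_matrices(x[1:21, ], c(rep("a", 20), "b")),
               "singleton")
})

test_that("1-D two-class fit reproduces the direct between/within ratio", {
  set.seed(52)
  x <- matrix(c(rnorm(100, 0), rnorm(100, 1)), ncol = 1,
              dimnames = list(NULL, "f"))
  labels <- rep(c("a", "b"), each = 100)
  m <- lda_fit(x, labels, ridge = 0)
  expect_equal(abs(unname(m$phi)), 1)
  z <- (x - mean(x)) / sd(x)
  sm <- scatter_matrices(z, labels)
  expect_equal(m$lambda, sm$S_between[1, 1] / sm$S_within[1, 1],
               tolerance = 1e-10)
  expect_gt(abs(diff(m$class_means_projected)), 0.5)
})

test_that("symmetric 2-D problem recovers the mean-difference axis", {
  set.seed(53)
  n <- 500
  x <- rbind(cbind(rnorm(n, 0), rnorm(n, 0)),
             cbind(rnorm(n, 1), rnorm(n, 0)))
  colnames(x) <- c("f1", "f2")
  m <- lda_fit(x, rep(c("a", "b"), each = n))
  expect_gt(abs(m$phi[["f1"]]), 0.99)
  expect_lt(abs(m$phi[["f2"]]), 0.1)
})

test_that("fitted direction beats 10,000 random unit directions", {
  set.seed(54)
  n <- 80
  x <- matrix(rnorm(4 * n * 10), 4 * n, 10)
  mus <- matrix(rnorm(40, sd = 0.8), 4, 10)
  labels <- rep(letters[1:4], each = n)
  for (c_i in 1:4) x[labels == letters[c_i], ] <-
    sweep(x[labels == letters[c_i], ], 2, -mus[c_i, ])
  colnames(x) <- paste0("f", 1:10)
  m <- lda_fit(x, labels)
  std <- standardize_features(x)
  sm <- scatter_matrices(std$x, labels)
  rq <- function(v) drop(crossprod(v, sm$S_between %*% v) /
                           crossprod(v, sm$S_within %*% v))
  best_random <- max(vapply(seq_len(10000), function(i) {
    v <- rnorm(10); rq(v / sqrt(sum(v^2)))
  }, numeric(1)))
  expect_gte(rq(m$phi) * (1 + 1e-10), best_random)
})

test_that("lambda is invariant to affine feature rescaling", {
  set.seed(55)
  x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  labels <- rep(c("g1", "g2"), each = 50)
  x[labels == "g2", 1] <- x[labels == "g2", 1] + 1
  m1 <- lda_fit(x, labels)
  x2 <- x
  x2[, 2] <- 100 * x2[, 2] - 7
  x2[, 3] <- -0.01 * x2[, 3]
  m2 <- lda_fit(x2, labels)
  expect_equal(m1$lambda, m2$lambda, tolerance = 1e-8)
})

test_that("rank-deficient S_between (4 classes) is handled", {
  set.seed(56)
  x <- matrix(rnorm(200 * 8), 200, 8, dimnames = list(NULL, paste0("f", 1:8)))
  labels <- rep(letters[1:4], each = 50)
  x[, 1] <- x[, 1] + match(labels, letters)
  m <- lda_fit(x, labels)
  expect_true(is.finite(m$lambda))
  expect_equal(sum(m$phi^2), 1, tolerance = 1e-12)
})

test_that("known single-direction class separation is recovered", {
  set.seed(57)
  d <- 6; n <- 200
  u <- rnorm(d); u <- u / sqrt(sum(u^2))
  x <- rbind(matrix(rnorm(n * d), n, d),
             matrix(rnorm(n * d), n, d) + 2 * matrix(u, n, d, byrow = TRUE))
  colnames(x) <- paste0("f", 1:d)
  m <- lda_fit(x, rep(c("a", "b"), each = n))
  # compare in the original feature space: unstandardize the direction
  phi_raw <- m$phi / m$scale
  phi_raw <- phi_raw / sqrt(sum(phi_raw^2))
  expect_gt(abs(sum(phi_raw * u)), 0.95)
})

test_that("projection is consistent with training class means", {
  run <- small_run()
  m <- run$model
  expect_equal(sum(m$phi^2), 1, tolerance = 1e-12)
  ft <- run$feature_table
  sc <- lda_transform(m, ft)
  cm <- tapply(sc$score, ft$class_label, mean)
  expect_equal(unname(cm[names(m$class_means_projected)]),
               unname(m$class_means_projected), tolerance = 1e-10)
  # a row at the training global mean projects to ~0
  gm <- as.data.frame(as.list(m$center))
  colnames(gm) <- m$features
  expect_lt(abs(lda_transform(m, gm)$score), 1e-10)
  expect_error(lda_transform(m, gm[, 1:10]), "missing")
})

test_that("contribution weights are ranked squared components", {
  run <- small_run()
  cw <- contribution_weights(run$model)
  expect_equal(sum(cw$weight), 1, tolerance = 1e-12)
  expect_true(all(diff(cw$weight) <= 1e-15))
  expect_setequal(cw$feature, run$model$features)
})

test_that("orientation pins the reference class to the lowest mean", {
  run <- small_run()
  m <- orient_discriminant(run$model, "no_particle")
  expect_identical(names(which.min(m$class_means_projected)),
                   "no_particle")
  expect_error(orient_discriminant(m, "nope"), "unknown")
})
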