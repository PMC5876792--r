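# Fisher linear discriminant, written out as the generalized eigenproblem
# S_between phi = lambda S_within phi over standardized features, reduced to a
# single discriminant direction. The eigenvector of the LARGEST generalized
# eigenvalue is taken: that is the maximizer of the between/within Rayleigh
# quotient, the stated objective of the method.

#' Drop features from a feature table
#'
#' Default exclusions: `RMS` (redundant with SD) and `omega_nakagami`
#' (outlier-dominated), leaving 43 of the 45 registry features for the
#' discriminant.
#'
#' @param table Feature table (epoch- or particle-level).
#' @param names Columns to drop.
#' @return The table without those columns.
#' @export
exclude_features <- function(table, names = c("RMS", "omega_nakagami")) {
  if (length(names) == 0) return(table)
  missing <- setdiff(names, colnames(table))
  if (length(missing) > 0)
    stop("unknown feature(s): ", paste(missing, collapse = ", "))
  table[, setdiff(colnames(table), names), drop = FALSE]
}

#' Column standardization
#'
#' Centers each feature to mean 0 and scales to SD 1 (denominator n-1),
#' retaining the training statistics for out-of-sample projection.
#'
#' @param x Numeric matrix or data frame of feature columns.
#' @return List: `x` (standardized matrix), `center`, `scale` (named
#'   vectors).
#' @export
standardize_features <- function(x) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  bad <- !is.finite(scl) | scl == 0
  if (any(bad))
    stop("zero-variance feature(s): ",
         paste(colnames(x)[bad], collapse = ", "))
  list(x = sweep(sweep(x, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

#' Between- and within-class scatter matrices
#'
#' `S_within = sum_c sum_{x in c} (x - xbar_c)(x - xbar_c)^T` (unnormalized
#' per-class scatter, summed over classes) and
#' `S_between = sum_c p_c (xbar_c - xbar)(xbar_c - xbar)^T` with `p_c` the
#' class row-proportion. Both symmetric positive semidefinite; with k
#' classes `S_between` has rank at most k - 1.
#'
#' @param x Numeric matrix, one row per observation.
#' @param labels Class labels (length `nrow(x)`).
#' @return List `S_between`, `S_within`.
#' @export
scatter_matrices <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  cls <- unique(labels)
  if (length(cls) < 2) stop("need at least 2 classes")
  d <- ncol(x)
  n <- nrow(x)
  gm <- colMeans(x)
  Sw <- matrix(0, d, d)
  Sb <- matrix(0, d, d)
  for (cl in cls) {
    xi <- x[labels == cl, , drop = FALSE]
    if (nrow(xi) < 2) stop("singleton class: ", cl)
    mi <- colMeans(xi)
    ci <- sweep(xi, 2, mi)
    Sw <- Sw + crossprod(ci)
    dm <- mi - gm
    Sb <- Sb + (nrow(xi) / n) * tcrossprod(dm)
  }
  dimnames(Sw) <- dimnames(Sb) <- list(colnames(x), colnames(x))
  list(S_between = Sb, S_within = Sw)
}

#' Fit the single-direction linear discriminant
#'
#' Standardizes the features, forms the scatter matrices, and solves
#' `S_between phi = lambda (S_within + ridge * tr(S_within)/d * I) phi` via a
#' Cholesky reduction to an ordinary symmetric eigenproblem. Returns the
#' direction of the largest generalized eigenvalue, unit-normalized, with
#' the sign fixed so that the largest-magnitude component is positive.
#'
#' @param x Matrix or data frame of feature columns only (apply
#'   [exclude_features()] first; metadata columns must not be present).
#' @param labels Class labels, one per row.
#' @param ridge Relative ridge added to `S_within` to keep near-singular
#'   problems determinate (default 1e-6).
#' @return An object of class `"lda_model"`: `phi` (named unit vector),
#'   `lambda` (generalized eigenvalue = Rayleigh quotient w.r.t. the
#'   regularized within-scatter), `class_means_projected`, `center`,
#'   `scale`, `features`, `ridge`.
#' @export
lda_fit <- function(x, labels, ridge = 1e-6) {
  std <- standardize_features(x)
  z <- std$x
  sm <- scatter_matrices(z, labels)
  d <- ncol(z)
  Swr <- sm$S_within + ridge * sum(diag(sm$S_within)) / d * diag(d)
  ch <- tryCatch(chol(Swr), error = function(e)
    stop("numerical error: regularized within-scatter not positive ",
         "definite (condition issue); ", conditionMessage(e)))
  # phi solves Sb phi = lambda Swr phi  <=>  (L^-1 Sb L^-T) u = lambda u,
  # with Swr = L L^T and phi = L^-T u.
  L <- t(ch)
  B <- forwardsolve(L, sm$S_between)
  A <- t(forwardsolve(L, t(B)))
  A <- (A + t(A)) / 2
  eg <- eigen(A, symmetric = TRUE)
  if (!all(is.finite(eg$values)))
    stop("numerical error: non-finite eigen-solution")
  phi <- backsolve(ch, eg$vectors[, 1])
  phi <- phi / sqrt(sum(phi^2))
  if (phi[which.max(abs(phi))] < 0) phi <- -phi
  names(phi) <- colnames(z)
  scores <- drop(z %*% phi)
  lambda <- drop(crossprod(phi, sm$S_between %*% phi) /
                   crossprod(phi, Swr %*% phi))
  structure(
    list(phi = phi, lambda = lambda,
         class_means_projected = tapply(scores, as.character(labels), mean),
         center = std$center, scale = std$scale,
         features = colnames(z), ridge = ridge),
    class = "lda_model")
}

#' Project feature rows onto the discriminant
#'
#' `score = phi . (row - center) / scale` using the training
#' standardization. Metadata columns in `table` are carried through.
#'
#' @param model An `"lda_model"`.
#' @param table Data frame or matrix containing (at least) the model's
#'   feature columns.
#' @return Data frame with any metadata columns of `table` plus a `score`
#'   column.
#' @export
lda_transform <- function(model, table) {
  stopifnot(inherits(model, "lda_model"))
  missing <- setdiff(model$features, colnames(table))
  if (length(missing) > 0)
    stop("column mismatch; missing feature(s): ",
         paste(missing, collapse = ", "))
  x <- as.matrix(table[, model$features, drop = FALSE])
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  meta <- setdiff(colnames(table), model$features)
  out <- if (length(meta) > 0 && is.data.frame(table))
    table[, meta, drop = FALSE] else data.frame(row = seq_len(nrow(x)))
  out$score <- drop(z %*% model$phi)
  out
}

#' Per-feature contribution weights of the discriminant
#'
#' The squared components of the unit direction `phi` sum to 1 and measure
#' each (standardized) feature's contribution to the single discriminant
#' score; both the signed components and the squared weights are returned,
#' ranked by magnitude.
#'
#' @param model An `"lda_model"`.
#' @return Data frame `feature`, `phi`, `weight` (= phi^2), sorted by
#'   descending weight.
#' @export
contribution_weights <- function(model) {
  stopifnot(inherits(model, "lda_model"))
  out <- data.frame(feature = names(model$phi), phi = unname(model$phi),
                    weight = unname(model$phi^2))
  out <- out[order(-out$weight), ]
  rownames(out) <- NULL
  out
}

#' Orient the discriminant against a reference class
#'
#' A discriminant axis has no intrinsic sign. For interpretation the
#' pipeline orients it so the stated reference class (the blank,
#' "no particle") has the lowest projected class mean: the score then reads
#' as back-scattered signal content relative to the blank.
#'
#' @param model An `"lda_model"`.
#' @param reference_class Label whose projected mean should be the minimum.
#' @return The (possibly sign-flipped) model.
#' @export
orient_discriminant <- function(model, reference_class) {
  stopifnot(inherits(model, "lda_model"))
  cm <- model$class_means_projected
  if (!reference_class %in% names(cm))
    stop("unknown reference class: ", reference_class)
  if (cm[reference_class] > min(cm)) {
    model$phi <- -model$phi
    model$class_means_projected <- -cm
  }
  model
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d features, lambda = %.4g\n",
              length(x$phi), x$lambda))
  cat("projected class means:\n")
  print(round(x$class_means_projected, 4))
  invisible(x)
}
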