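# Nonparametric statistical layer over the per-particle table: per-feature
# Kruskal-Wallis screening, post-hoc pairwise Mann-Whitney tests,
# Bhattacharyya class separability, and the Spearman correlation of the
# class-mean discriminant score against dn*d. No multiple-testing correction
# is applied; raw p-values are flagged at 0.05 (*) and 0.001 (**).

#' Kruskal-Wallis test across classes
#'
#' Rank-based H statistic with tie correction; p-value from the chi-square
#' approximation with (groups - 1) degrees of freedom (`stats::kruskal.test`).
#' If all values are identical, H = 0 and p = 1.
#'
#' @param values Per-particle scalars.
#' @param labels Class labels.
#' @return List `H`, `p`.
#' @export
kruskal_4way <- function(values, labels) {
  labels <- factor(labels)
  stopifnot(length(values) == length(labels), nlevels(labels) >= 2)
  if (length(unique(values)) == 1) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(values, labels)
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Pairwise Mann-Whitney tests
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney U) test for every pair of
#' classes, ordered by class label order of appearance (for the 4-class
#' study: 1-2, 1-3, 1-4, 2-3, 2-4, 3-4). The exact distribution is used when
#' both groups have fewer than 8 untied observations; otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @inheritParams kruskal_4way
#' @return Named vector of p-values, one per class pair
#'   (`"classA_vs_classB"`).
#' @export
pairwise_mann_whitney <- function(values, labels) {
  labels <- as.character(labels)
  cls <- unique(labels)
  stopifnot(length(cls) >= 2)
  prs <- utils::combn(cls, 2, simplify = FALSE)
  p <- vapply(prs, function(pr) {
    a <- values[labels == pr[1]]
    b <- values[labels == pr[2]]
    if (length(a) == 0 || length(b) == 0)
      stop("empty group in pair ", paste(pr, collapse = " vs "))
    if (length(unique(c(a, b))) == 1) return(1)  # degenerate: no evidence
    exact <- length(a) < 8 && length(b) < 8 &&
      !any(duplicated(c(a, b)))
    suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  }, numeric(1))
  names(p) <- vapply(prs, function(pr) paste(pr, collapse = "_vs_"),
                     character(1))
  p
}

#' Bhattacharyya distance between two class samples
#'
#' Univariate Gaussian form per feature j:
#' `D_j = (mu_a - mu_b)^2 / (4 (s_a^2 + s_b^2)) +
#' 0.5 * log((s_a^2 + s_b^2) / (2 s_a s_b))`,
#' averaged over the features (default). The multivariate Gaussian closed
#' form (`method = "multivariate"`) is available as an alternative reading:
#' `D = (1/8) dm^T Sbar^-1 dm + 0.5 * log(det Sbar /
#' sqrt(det Sa * det Sb))` with `Sbar = (Sa + Sb)/2`.
#'
#' @param x_a,x_b Matrices/data frames of feature rows for the two classes
#'   (>= 2 rows each; per-feature SDs > 0).
#' @param method `"univariate"` (per-feature average) or `"multivariate"`.
#' @return Non-negative scalar distance; 0 for identical Gaussian summaries.
#' @export
bhattacharyya_pair <- function(x_a, x_b,
                               method = c("univariate", "multivariate")) {
  method <- match.arg(method)
  x_a <- as.matrix(x_a); x_b <- as.matrix(x_b)
  stopifnot(nrow(x_a) >= 2, nrow(x_b) >= 2, ncol(x_a) == ncol(x_b))
  if (method == "univariate") {
    va <- apply(x_a, 2, stats::var)
    vb <- apply(x_b, 2, stats::var)
    if (any(va == 0) || any(vb == 0)) stop("zero variance feature")
    dm <- colMeans(x_a) - colMeans(x_b)
    dj <- dm^2 / (4 * (va + vb)) + 0.5 * log((va + vb) / (2 * sqrt(va * vb)))
    mean(dj)
  } else {
    Sa <- stats::cov(x_a); Sb <- stats::cov(x_b)
    Sm <- (Sa + Sb) / 2
    dm <- colMeans(x_a) - colMeans(x_b)
    ld <- function(S) as.numeric(determinant(S, logarithm = TRUE)$modulus)
    drop(crossprod(dm, solve(Sm, dm)) / 8) +
      0.5 * (ld(Sm) - (ld(Sa) + ld(Sb)) / 2)
  }
}

#' Pairwise class-separability report
#'
#' Bhattacharyya distance for every class pair over a chosen feature subset,
#' plus the grand mean over pairs; used to compare e.g. the top-3 against the
#' bottom-3 discriminant-weighted features.
#'
#' @param table Per-particle feature table (metadata columns allowed).
#' @param labels Class labels (defaults to `table$class_label`).
#' @param features Character vector of feature columns to use.
#' @param method Passed to [bhattacharyya_pair()].
#' @return List: `distances` (named vector per class pair), `mean`.
#' @export
separability_report <- function(table, labels = table$class_label, features,
                                method = c("univariate", "multivariate")) {
  method <- match.arg(method)
  stopifnot(length(features) >= 1, all(features %in% colnames(table)))
  labels <- as.character(labels)
  cls <- unique(labels)
  prs <- utils::combn(cls, 2, simplify = FALSE)
  d <- vapply(prs, function(pr) {
    bhattacharyya_pair(table[labels == pr[1], features, drop = FALSE],
                       table[labels == pr[2], features, drop = FALSE],
                       method = method)
  }, numeric(1))
  names(d) <- vapply(prs, function(pr) paste(pr, collapse = "_vs_"),
                     character(1))
  structure(list(distances = d, mean = mean(d), features = features),
            class = "pairwise_distance_set")
}

#' Spearman correlation of class-mean scores against dn*d
#'
#' Rank correlation between the per-class mean discriminant score and the
#' refractive-index-contrast times diameter product (0 for the blank class),
#' two-sided. With only 4 classes the exact permutation null is used by
#' `stats::cor.test`, whose smallest attainable two-sided p at rho = 1 is
#' 2/24.
#'
#' @param class_mean_scores Named vector of per-class mean scores.
#' @param dnd_values Named vector of dn*d per class (same names), or a list
#'   of [particle_class_spec()] from which they are computed.
#' @return List `rho`, `p`.
#' @export
spearman_vs_dnd <- function(class_mean_scores, dnd_values) {
  if (is.list(dnd_values) &&
      all(vapply(dnd_values, inherits, logical(1), "particle_class_spec"))) {
    dnd_values <- stats::setNames(
      vapply(dnd_values, dnd, numeric(1)),
      vapply(dnd_values, function(s) s$label, character(1)))
  }
  stopifnot(length(class_mean_scores) >= 3,
            all(names(class_mean_scores) %in% names(dnd_values)))
  dv <- dnd_values[names(class_mean_scores)]
  if (any(duplicated(dv)))
    warning("ties in dn*d; tie-corrected rho")
  ct <- suppressWarnings(
    stats::cor.test(class_mean_scores, dv, method = "spearman",
                    alternative = "two.sided"))
  list(rho = unname(ct$estimate), p = unname(ct$p.value))
}

#' Per-feature statistical screen
#'
#' Runs the Kruskal-Wallis test and all pairwise Mann-Whitney tests for
#' every feature column of the per-particle table (and for a `score` column
#' if present), with significance flags at 0.05 and 0.001 (the * / **
#' convention).
#'
#' @param particle_table Per-particle table with `class_label` and feature
#'   columns ([particle_average()] output, optionally with a `score`
#'   column merged in).
#' @return Data frame, one row per variable: `feature`, `H`, `p_kw`,
#'   `sig05`, `sig001`, then one p-value column per class pair.
#' @export
feature_screen <- function(particle_table) {
  labels <- particle_table$class_label
  vars <- setdiff(colnames(particle_table),
                  c("particle_id", "class_label", "n_epochs"))
  rows <- lapply(vars, function(v) {
    x <- particle_table[[v]]
    kw <- kruskal_4way(x, labels)
    mw <- pairwise_mann_whitney(x, labels)
    cbind(data.frame(feature = v, H = kw$H, p_kw = kw$p,
                     sig05 = kw$p < 0.05, sig001 = kw$p < 0.001),
          as.data.frame(t(mw)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
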