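# The 45-feature registry computed per accepted 2 s epoch:
#  1-7   time-domain statistics (M, SD, RMS, Skew, Kurt, IQR, Entropy)
#  8-9   Nakagami shape/scale fitted to the Hilbert envelope
# 10-29  20 largest-magnitude envelope-DCT coefficients (signed, sorted)
# 30-33  N_DCT (coefficients for 98% energy), AUC, Peak, total power of the
#        envelope DCT spectrum
# 34-45  relative detail-band powers, 6 levels, Haar and Db10

#' Feature registry names
#'
#' The 45 feature names in registry order (metadata columns excluded),
#' partitioned 7 time-domain statistics + 2 Nakagami parameters + 24 DCT
#' features + 12 wavelet relative powers.
#'
#' @return Character vector of length 45.
#' @export
feature_names <- function() {
  c("M", "SD", "RMS", "Skew", "Kurt", "IQR", "E",
    "mu_nakagami", "omega_nakagami",
    paste0("E_DCT_l", 1:20),
    "N_DCT", "AUC_DCT", "Peak_DCT", "P_DCT",
    paste0("E_Haar", 1:6), paste0("E_Db10_", 1:6))
}

#' Time-domain statistics of an epoch
#'
#' Standard sample definitions: SD with denominator n-1; skewness and
#' kurtosis as the central-moment ratios `m3 / m2^1.5` and `m4 / m2^2`
#' (kurtosis non-excess, Gaussian -> 3); IQR with type-7 (linear
#' interpolation) quantiles; entropy as the Shannon entropy (bits) of the
#' 100-bin equal-width amplitude histogram spanning `[min, max]`, empty bins
#' contributing 0.
#'
#' @param x Numeric vector (length >= 4, SD > 0).
#' @return Named vector `M, SD, RMS, Skew, Kurt, IQR, E`.
#' @export
time_domain_stats <- function(x) {
  stopifnot(length(x) >= 4)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("degenerate-epoch: zero variance (should have been rejected)")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  c(M = m, SD = s, RMS = sqrt(mean(x^2)),
    Skew = mean((x - m)^3) / m2^1.5,
    Kurt = mean((x - m)^4) / m2^2,
    IQR = unname(stats::IQR(x, type = 7)),
    E = shannon_entropy(x, bins = 100))
}

shannon_entropy <- function(x, bins = 100) {
  br <- seq(min(x), max(x), length.out = bins + 1)
  cnt <- tabulate(findInterval(x, br, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = bins)
  p <- cnt[cnt > 0] / length(x)
  -sum(p * log2(p))
}

#' Moment-based Nakagami fit
#'
#' Inverse-normalized-variance estimators for the Nakagami family:
#' `omega_hat = mean(x^2)` and `mu_hat = omega_hat^2 / Var(x^2)` (sample
#' variance, denominator n-1).
#'
#' @param x Positive magnitudes (length >= 2).
#' @return Named vector `mu, omega`.
#' @export
nakagami_fit <- function(x) {
  if (any(x <= 0)) stop("domain error: non-positive magnitudes")
  stopifnot(length(x) >= 2)
  x2 <- x^2
  omega <- mean(x2)
  v <- stats::var(x2)
  if (!is.finite(v) || v == 0) stop("degenerate-fit: Var(x^2) is zero")
  c(mu = omega^2 / v, omega = omega)
}

#' Magnitude-sorted DCT coefficients
#'
#' Orthonormal DCT-II of the envelope, returned sorted by descending
#' magnitude (signed values retained; ties broken by ascending original
#' index).
#'
#' @param envelope Numeric vector (length >= 20).
#' @return Numeric vector of all N coefficients, sorted.
#' @export
dct_sorted <- function(envelope) {
  stopifnot(length(envelope) >= 20)
  cc <- dct_ii(envelope)
  cc[order(-abs(cc), seq_along(cc))]
}

#' Energy percentage captured by the first k sorted coefficients
#'
#' `P = 100 * ||(c_1..c_k)|| / ||(c_1..c_n)||`; non-decreasing in k with
#' `P(n) = 100`.
#'
#' @param sorted_coeffs Coefficients sorted by descending magnitude.
#' @param k Number of leading coefficients (1 <= k <= n).
#' @return Percentage in (0, 100].
#' @export
energy_percentage <- function(sorted_coeffs, k) {
  n <- length(sorted_coeffs)
  stopifnot(k >= 1, k <= n)
  tot <- sum(sorted_coeffs^2)
  if (tot == 0) stop("undefined: all coefficients are zero")
  100 * sqrt(sum(sorted_coeffs[seq_len(k)]^2) / tot)
}

#' Number of DCT coefficients capturing a target energy percentage
#'
#' Smallest k with `energy_percentage(k) >= threshold_pct` (default 98).
#'
#' @inheritParams energy_percentage
#' @param threshold_pct Target percentage.
#' @return Integer k.
#' @export
n_dct <- function(sorted_coeffs, threshold_pct = 98) {
  tot <- sum(sorted_coeffs^2)
  if (tot == 0) stop("undefined: all coefficients are zero")
  p <- 100 * sqrt(cumsum(sorted_coeffs^2) / tot)
  as.integer(which(p >= threshold_pct)[1])
}

#' Summary statistics of the DCT spectrum
#'
#' Coefficient l (0-based) is mapped to frequency `l * fs / (2N)`, covering
#' 0 to fs/2. AUC is the trapezoidal integral of |coefficient| over
#' frequency; Peak the maximum magnitude; P the total power (sum of squared
#' coefficients).
#'
#' @param envelope Numeric vector.
#' @param fs Sampling rate, Hz.
#' @return Named vector `AUC_DCT, Peak_DCT, P_DCT`.
#' @export
dct_spectrum_summary <- function(envelope, fs) {
  cc <- dct_ii(envelope)
  n <- length(cc)
  a <- abs(cc)
  df <- fs / (2 * n)
  auc <- if (n > 1) sum((a[-1] + a[-n]) / 2) * df else 0
  c(AUC_DCT = auc, Peak_DCT = max(a), P_DCT = sum(cc^2))
}

#' Wavelet relative detail-band powers
#'
#' 6-level periodized orthogonal decomposition ([dwt_periodized()]); the
#' level-j feature is the fraction of total (truncated-window) signal energy
#' carried by the level-j detail band. Because the transform is orthonormal,
#' detail energies plus the final approximation energy sum exactly to the
#' signal energy.
#'
#' @param x Numeric vector (length >= `2^levels * filter length`).
#' @param mother `"haar"` or `"db10"`.
#' @param levels Number of levels (default 6).
#' @return Named vector of `levels` relative powers in `[0, 1]`.
#' @export
wavelet_relative_power <- function(x, mother = c("haar", "db10"),
                                   levels = 6) {
  mother <- match.arg(mother)
  w <- dwt_periodized(x, mother, levels)
  tot <- sum(x[seq_len(w$n_used)]^2)
  if (tot == 0) return(stats::setNames(rep(0, levels),
                                       paste0("L", seq_len(levels))))
  e <- vapply(w$details, function(d) sum(d^2), numeric(1)) / tot
  stats::setNames(e, paste0("L", seq_len(levels)))
}

#' Compute the 45-feature vector of one epoch
#'
#' Time-domain statistics and wavelet relative powers are computed on the
#' (filtered) epoch samples; the Nakagami fit and all DCT features operate on
#' the Hilbert envelope of the epoch. Deterministic.
#'
#' @param epoch An `"epoch"` or a numeric vector of filtered samples.
#' @param fs Sampling rate, Hz (taken from the epoch if omitted).
#' @return Named numeric vector of length 45 ([feature_names()] order).
#' @export
featurize <- function(epoch, fs = NULL) {
  if (inherits(epoch, "epoch")) {
    fs <- epoch$fs
    x <- epoch$samples
  } else x <- epoch
  stopifnot(!is.null(fs))
  td <- time_domain_stats(x)
  env <- hilbert_envelope(x)
  nak <- nakagami_fit(env[env > 0])
  sc <- dct_sorted(env)
  spec <- dct_spectrum_summary(env, fs)
  out <- c(td,
           mu_nakagami = unname(nak["mu"]),
           omega_nakagami = unname(nak["omega"]),
           stats::setNames(sc[1:20], paste0("E_DCT_l", 1:20)),
           N_DCT = n_dct(sc),
           spec,
           stats::setNames(wavelet_relative_power(x, "haar"),
                           paste0("E_Haar", 1:6)),
           stats::setNames(wavelet_relative_power(x, "db10"),
                           paste0("E_Db10_", 1:6)))
  stopifnot(identical(names(out), feature_names()), all(is.finite(out)))
  out
}

#' Feature table over the accepted epochs of one or more epoch sets
#'
#' @param epoch_sets An `"epoch_set"` or list of them.
#' @return Data frame: metadata columns `particle_id`, `class_label`,
#'   `epoch_index`, then the 45 features in registry order. One row per
#'   accepted epoch.
#' @export
featurize_epochs <- function(epoch_sets) {
  if (inherits(epoch_sets, "epoch_set")) epoch_sets <- list(epoch_sets)
  rows <- list()
  for (es in epoch_sets) {
    for (e in es$epochs) {
      if (!isTRUE(e$accepted)) next
      fv <- featurize(e)
      rows[[length(rows) + 1L]] <-
        data.frame(particle_id = e$particle_id, class_label = e$class_label,
                   epoch_index = e$index, t(fv), check.names = FALSE)
    }
  }
  if (length(rows) == 0)
    stop("no accepted epochs to featurize")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-particle feature averaging
#'
#' Collapses the epoch-level table to one row per particle by the arithmetic
#' mean of each feature over that particle's accepted epochs; this is the
#' granularity at which the statistical layer operates.
#'
#' @param table Epoch-level feature table ([featurize_epochs()]).
#' @return Data frame: `particle_id`, `class_label`, `n_epochs`, then the
#'   feature columns.
#' @export
particle_average <- function(table) {
  feat <- setdiff(names(table), c("particle_id", "class_label",
                                  "epoch_index"))
  sp <- split(table, table$particle_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(particle_id = d$particle_id[1],
               class_label = d$class_label[1],
               n_epochs = nrow(d),
               t(colMeans(d[feat])), check.names = FALSE)
  }))
  out <- out[order(match(out$particle_id, unique(table$particle_id))), ]
  rownames(out) <- NULL
  out
}
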