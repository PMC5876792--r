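# Synthetic back-scattered acquisitions: amplitude-modulated 1 kHz carrier with
# slow multiplicative Nakagami envelope fluctuations, broadband noise and
# occasional spike artifacts. Stands in for the study's raw photodetector data.

#' Particle class specification
#'
#' Describes one class of trapped scatterer: its optical/morphological
#' parameters (diameter, refractive indices), the number of particles measured,
#' and the envelope-statistics parameters that encode its heterogeneity.
#'
#' The scattering amplitude of the synthetic signal is proportional to
#' `(n_particle - n_medium) * diameter` (the "dn*d" product), the physical
#' driver of back-scattered intensity for particles of similar size.
#'
#' @param label Class label, one of `"no_particle"`, `"pmma"`, `"ps"`,
#'   `"yeast"` (free-form labels are accepted for custom designs).
#' @param diameter Particle diameter in meters (`NA` for the blank class).
#' @param n_particle Particle refractive index (`NA` for the blank class).
#' @param n_medium Medium refractive index. De-ionized water: 1.327.
#' @param count Number of particles (acquisitions) for this class.
#' @param nakagami_mu Shape parameter of the Nakagami envelope-fluctuation
#'   process (> 0). Low values = heterogeneous, spiky envelope (biological
#'   cells); high values = near-Gaussian fluctuation (homogeneous beads).
#' @param env_depth Relative depth of the multiplicative envelope fluctuation
#'   (>= 0); 0 disables it.
#' @return An object of class `"particle_class_spec"`.
#' @seealso [default_study_design()], [dnd()]
#' @export
particle_class_spec <- function(label, diameter = NA_real_,
                                n_particle = NA_real_, n_medium = 1.327,
                                count = 1L, nakagami_mu = 3, env_depth = 0.1) {
  blank <- is.na(diameter) || is.na(n_particle)
  if (!blank) {
    stopifnot(diameter > 0, n_particle >= n_medium)
  }
  stopifnot(is.finite(n_medium), count >= 1, nakagami_mu > 0, env_depth >= 0)
  structure(
    list(label = as.character(label), diameter = diameter,
         n_particle = n_particle, n_medium = n_medium,
         count = as.integer(count), nakagami_mu = nakagami_mu,
         env_depth = env_depth),
    class = "particle_class_spec")
}

#' Refractive-index-contrast times diameter product
#'
#' `dnd(spec)` returns `(n_particle - n_medium) * diameter` in meters; exactly
#' 0 for a blank (no-particle) class.
#'
#' @param spec A [particle_class_spec()].
#' @return Non-negative scalar, meters.
#' @export
dnd <- function(spec) {
  stopifnot(inherits(spec, "particle_class_spec"))
  if (is.na(spec$diameter) || is.na(spec$n_particle)) return(0)
  (spec$n_particle - spec$n_medium) * spec$diameter
}

#' Default four-class study design
#'
#' The study conditions emulated by the generator: 16 blank acquisitions,
#' 16 PMMA particles (8 um, n = 1.4843), 18 polystyrene particles (8 um,
#' n = 1.5731) and 16 living yeast cells (6-7 um, n = 1.49-1.53; midpoints
#' 6.5 um and 1.51 used as the single representative value), all in
#' de-ionized water (n = 1.327).
#'
#' Envelope-statistics parameters encode particle homogeneity: synthetic
#' beads fluctuate shallowly with near-Gaussian statistics (high Nakagami
#' shape), living yeast fluctuates deeply with a heavy-tailed envelope (low
#' shape); the blank has no multiplicative term (carrier baseline + noise
#' only, the fiber still reflects).
#'
#' @return List of four [particle_class_spec()] objects, in class order
#'   (no particle, PMMA, PS, yeast).
#' @export
default_study_design <- function() {
  list(
    particle_class_spec("no_particle", count = 16L,
                        nakagami_mu = 5, env_depth = 0),
    particle_class_spec("pmma", diameter = 8e-6, n_particle = 1.4843,
                        count = 16L, nakagami_mu = 3.0, env_depth = 0.15),
    particle_class_spec("ps", diameter = 8e-6, n_particle = 1.5731,
                        count = 18L, nakagami_mu = 3.5, env_depth = 0.12),
    particle_class_spec("yeast", diameter = 6.5e-6, n_particle = 1.51,
                        count = 16L, nakagami_mu = 0.9, env_depth = 0.35))
}

#' Acquisition configuration
#'
#' Parameters of the simulated acquisition chain.
#'
#' @param fs Sampling rate, Hz.
#' @param duration Acquisition length, seconds.
#' @param f_mod Laser-modulation carrier frequency, Hz (must satisfy
#'   `fs > 2 * f_mod`).
#' @param gain Photodetector gain, volts per (refractive-index * meter); maps
#'   `dnd` to carrier amplitude.
#' @param baseline Carrier amplitude with no particle trapped, volts (back
#'   reflection of the fiber tip itself).
#' @param noise_sd Additive broadband (white Gaussian) noise SD, volts.
#' @param env_cutoff Low-pass cutoff of the slow envelope-fluctuation
#'   process, Hz.
#' @param artifact_rate Expected number of spike artifacts per acquisition
#'   (Poisson mean; >= 0).
#' @param artifact_scale Spike amplitude as a multiple of the signal SD.
#' @param particle_sd Log-normal SD of the per-particle amplitude effect.
#' @param seed Integer seed; the whole dataset is a deterministic function of
#'   `(design, config, seed)`.
#' @return An object of class `"acquisition_config"`.
#' @export
acquisition_config <- function(fs = 5000, duration = 120, f_mod = 1000,
                               gain = 1e6, baseline = 0.2, noise_sd = 0.05,
                               env_cutoff = 25, artifact_rate = 1.5,
                               artifact_scale = 12, particle_sd = 0.1,
                               seed = 1L) {
  vals <- c(fs, duration, f_mod, gain, baseline, noise_sd, env_cutoff,
            artifact_rate, artifact_scale, particle_sd)
  if (!all(is.finite(vals))) stop("invalid-config: non-finite parameter")
  stopifnot(fs > 2 * f_mod, duration > 0,
            gain >= 0, baseline >= 0, noise_sd >= 0, env_cutoff >= 0,
            artifact_rate >= 0, artifact_scale >= 0, particle_sd >= 0)
  structure(
    list(fs = fs, duration = duration, f_mod = f_mod, gain = gain,
         baseline = baseline, noise_sd = noise_sd, env_cutoff = env_cutoff,
         artifact_rate = artifact_rate, artifact_scale = artifact_scale,
         particle_sd = particle_sd, seed = as.integer(seed)),
    class = "acquisition_config")
}

# Evaluate expr under a given RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Deterministic child seed per (global seed, class label, particle index):
# an LCG-style mix over a string hash of the label, keeping every
# intermediate below 2^53. Hashing the label (not its design position) means
# subsetting the design leaves the retained particles' signals unchanged.
child_seed <- function(seed, class_label, particle_idx) {
  h <- 0
  for (code in utf8ToInt(as.character(class_label)))
    h <- (h * 131 + code) %% 2147483647
  s <- (as.numeric(seed) %% 2147483647) + 1
  s <- (s * 48271) %% 2147483647
  s <- (s + h * 69621 + particle_idx * 16807) %% 2147483647
  as.integer(s)
}

#' Random draws from the Nakagami distribution
#'
#' If `Y ~ Gamma(shape = mu, scale = omega / mu)` then `sqrt(Y)` is
#' Nakagami-m with shape `mu` and scale (second moment) `omega`. `mu = 1`
#' recovers the Rayleigh distribution.
#'
#' @param n Number of draws.
#' @param mu Shape parameter (> 0).
#' @param omega Scale parameter, `E[X^2]` (> 0).
#' @return Numeric vector of positive draws.
#' @export
rnakagami <- function(n, mu, omega = 1) {
  stopifnot(mu > 0, omega > 0)
  sqrt(stats::rgamma(n, shape = mu, scale = omega / mu))
}

# Analytic mean and SD of Nakagami(mu, omega).
nakagami_moments <- function(mu, omega = 1) {
  m <- exp(lgamma(mu + 0.5) - lgamma(mu)) * sqrt(omega / mu)
  v <- omega - m^2
  c(mean = m, sd = sqrt(v))
}

# Band-limited process with an exact Nakagami(mu, 1) marginal: low-pass
# filtered Gaussian noise mapped through the Nakagami quantile function
# (Gaussian copula). Filtering the Nakagami draws directly would gaussianize
# the marginal; mapping after filtering preserves it exactly.
nakagami_process <- function(n, mu, fs, cutoff) {
  g <- stats::rnorm(n)
  if (cutoff > 0 && cutoff < fs / 2 && n > 24) {
    bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
    g <- signal::filtfilt(bf, g)
    g <- (g - mean(g)) / stats::sd(g)
  }
  u <- stats::pnorm(g)
  eps <- 1e-12
  u <- pmin(pmax(u, eps), 1 - eps)
  sqrt(stats::qgamma(u, shape = mu, scale = 1 / mu))
}

#' Synthesize one back-scattered acquisition
#'
#' Signal model:
#' `s[t] = (baseline + A * particle_effect * (1 + env_depth * w[t])) *
#' sin(2 * pi * f_mod * t) + n[t]`, where `A = gain * dnd(spec)`, `w` is a
#' zero-mean unit-variance band-limited process with Nakagami(`nakagami_mu`)
#' marginal (see Details) and `n` is white Gaussian noise with SD `noise_sd`.
#' Deterministic given `seed`.
#'
#' @details The slow multiplicative fluctuation is produced by mapping
#' low-pass-filtered Gaussian noise (cutoff `env_cutoff`) through the
#' Nakagami quantile function, then standardizing with the analytic
#' Nakagami moments; this keeps the marginal exactly Nakagami while
#' band-limiting the temporal structure.
#'
#' @param spec A [particle_class_spec()].
#' @param cfg An [acquisition_config()].
#' @param particle_effect Positive per-particle amplitude multiplier (drawn
#'   upstream, see [generate_dataset()]).
#' @param particle_id Identifier string stored in the result.
#' @param seed Integer seed for this acquisition.
#' @return An object of class `"acquisition"`: list with `samples`, `fs`,
#'   `class_label`, `particle_id`, `provenance`.
#' @export
synthesize_acquisition <- function(spec, cfg, particle_effect = 1,
                                   particle_id = spec$label,
                                   seed = cfg$seed) {
  stopifnot(inherits(spec, "particle_class_spec"),
            inherits(cfg, "acquisition_config"))
  if (!is.finite(particle_effect) || particle_effect <= 0)
    stop("invalid-config: particle_effect must be finite and > 0")
  n <- round(cfg$fs * cfg$duration)
  tt <- (seq_len(n) - 1) / cfg$fs
  amp <- cfg$gain * dnd(spec) * particle_effect
  samples <- with_seed(seed, {
    env <- rep(1, n)
    if (amp > 0 && spec$env_depth > 0) {
      w <- nakagami_process(n, spec$nakagami_mu, cfg$fs, cfg$env_cutoff)
      mom <- nakagami_moments(spec$nakagami_mu)
      w <- (w - mom["mean"]) / mom["sd"]
      env <- 1 + spec$env_depth * w
    }
    carrier <- (cfg$baseline + amp * env) * sinpi(2 * cfg$f_mod * tt)
    if (cfg$noise_sd > 0) carrier + stats::rnorm(n, sd = cfg$noise_sd)
    else carrier
  })
  structure(
    list(samples = as.numeric(samples), fs = cfg$fs,
         class_label = spec$label, particle_id = as.character(particle_id),
         provenance = list(generator = "scatterid", seed = as.integer(seed),
                           particle_effect = particle_effect,
                           duration = cfg$duration,
                           dnd = dnd(spec),
                           nakagami_mu = spec$nakagami_mu,
                           env_depth = spec$env_depth)),
    class = "acquisition")
}

#' Inject spike artifacts into an acquisition
#'
#' Adds `Poisson(artifact_rate)`-many single-sample impulses of amplitude
#' `artifact_scale * SD(samples)` (random sign) at uniform random positions.
#' With `artifact_rate = 0` the input is returned unchanged.
#'
#' @param acq An `"acquisition"`.
#' @param cfg An [acquisition_config()] (uses `artifact_rate`,
#'   `artifact_scale`).
#' @param seed Integer seed.
#' @return Modified copy of `acq`; number of injected spikes recorded in
#'   `provenance$n_artifacts`.
#' @export
inject_artifacts <- function(acq, cfg, seed = cfg$seed) {
  stopifnot(inherits(acq, "acquisition"), cfg$artifact_rate >= 0)
  if (cfg$artifact_rate == 0) return(acq)
  n <- length(acq$samples)
  out <- acq
  with_seed(seed, {
    k <- stats::rpois(1, cfg$artifact_rate)
    if (k > 0) {
      pos <- sample.int(n, k, replace = TRUE)
      sgn <- sample(c(-1, 1), k, replace = TRUE)
      out$samples[pos] <- out$samples[pos] +
        sgn * cfg$artifact_scale * stats::sd(acq$samples)
    }
    out$provenance$n_artifacts <- k
    out$provenance$artifact_positions <- if (k > 0) sort(pos) else integer(0)
  })
  out
}

#' Generate a full synthetic dataset
#'
#' One acquisition per particle per class. Per-particle amplitude effects are
#' drawn log-normally (`sdlog = cfg$particle_sd`); each particle's signal is
#' generated under a deterministic child seed derived from `cfg$seed`, so
#' subsetting the design does not reshuffle other particles' signals.
#'
#' @param specs List of [particle_class_spec()] with distinct labels.
#' @param cfg An [acquisition_config()].
#' @param artifacts Inject spike artifacts per `cfg` (default `TRUE`).
#' @return List of `"acquisition"` objects (length `sum(counts)`).
#' @export
generate_dataset <- function(specs, cfg, artifacts = TRUE) {
  stopifnot(length(specs) >= 1)
  labels <- vapply(specs, function(s) s$label, character(1))
  if (anyDuplicated(labels))
    stop("invalid-design: duplicate class labels")
  out <- vector("list", sum(vapply(specs, function(s) s$count, integer(1))))
  k <- 0L
  for (ci in seq_along(specs)) {
    spec <- specs[[ci]]
    for (pi in seq_len(spec$count)) {
      sd_i <- child_seed(cfg$seed, spec$label, pi)
      pe <- with_seed(sd_i, stats::rlnorm(1, 0, cfg$particle_sd))
      id <- sprintf("%s_%02d", spec$label, pi)
      acq <- synthesize_acquisition(spec, cfg, particle_effect = pe,
                                    particle_id = id, seed = sd_i + 1L)
      if (artifacts && cfg$artifact_rate > 0)
        acq <- inject_artifacts(acq, cfg, seed = sd_i + 2L)
      k <- k + 1L
      out[[k]] <- acq
    }
  }
  out
}
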