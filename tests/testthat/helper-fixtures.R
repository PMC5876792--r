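# Shared fixtures, built in code. small_run() memoizes one reduced-scale
# pipeline run (short acquisitions, full four-class design) reused across
# test files.

.fixture_env <- new.env(parent = emptyenv())

small_config <- function(duration = 10, seed = 101L, counts = NULL) {
  design <- default_study_design()
  if (!is.null(counts))
    design <- Map(function(s, k) { s$count <- as.integer(k); s },
                  design, counts)
  run_config(design = design,
             acquisition = acquisition_config(duration = duration,
                                              seed = seed))
}

small_run <- function() {
  if (is.null(.fixture_env$run))
    .fixture_env$run <- run_pipeline(small_config(duration = 10,
                                                  counts = c(3, 3, 3, 3)))
  .fixture_env$run
}

# One clean filtered epoch of synthetic signal (no artifacts).
make_epoch_samples <- function(seed = 5, spec = default_study_design()[[3]],
                               duration = 2) {
  cfg <- acquisition_config(duration = duration, artifact_rate = 0,
                            seed = seed)
  acq <- synthesize_acquisition(spec, cfg, particle_effect = 1,
                                particle_id = "fix", seed = seed)
  highpass(acq$samples, cfg$fs)
}

# Direct O(N^2) orthonormal DCT-II from its definition: the independent
# oracle for the FFT-based implementation.
dct_direct <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(k) {
    s <- if (k == 0) sqrt(1 / n) else sqrt(2 / n)
    s * sum(x * cos(pi * k * (2 * (0:(n - 1)) + 1) / (2 * n)))
  }, numeric(1))
}

# Kruskal-Wallis H from the textbook rank formula (tie-corrected):
# independent oracle for the packaged wrapper.
kw_brute <- function(values, labels) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, labels, function(ri) length(ri) * mean(ri)^2)) -
    3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}
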