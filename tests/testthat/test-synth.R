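# Synthetic acquisition generator: signal model, determinism, artifact
# plumbing, study-design bookkeeping, envelope statistics.

test_that("blank class with all stochastic terms off is a pure carrier", {
  spec <- particle_class_spec("no_particle", count = 1L, env_depth = 0)
  cfg <- acquisition_config(duration = 1, baseline = 1, noise_sd = 0,
                            artifact_rate = 0, seed = 3)
  acq <- synthesize_acquisition(spec, cfg)
  tt <- (seq_len(5000) - 1) / 5000
  expect_equal(acq$samples, sinpi(2 * 1000 * tt), tolerance = 1e-12)
})

test_that("generator is deterministic given the seed", {
  spec <- default_study_design()[[4]]
  cfg <- acquisition_config(duration = 2, seed = 9)
  a1 <- synthesize_acquisition(spec, cfg, particle_effect = 1.1, seed = 77)
  a2 <- synthesize_acquisition(spec, cfg, particle_effect = 1.1, seed = 77)
  expect_identical(a1$samples, a2$samples)
  a3 <- synthesize_acquisition(spec, cfg, particle_effect = 1.1, seed = 78)
  expect_false(identical(a1$samples, a3$samples))
})

test_that("default study design reproduces the published bookkeeping", {
  design <- default_study_design()
  counts <- vapply(design, function(s) s$count, integer(1))
  expect_identical(counts, c(16L, 16L, 18L, 16L))
  expect_equal(sum(counts) * acquisition_config()$duration, 7920)
  # dn*d ordering drives amplitude ordering: ps > pmma > yeast > blank
  dnds <- vapply(design, dnd, numeric(1))
  names(dnds) <- vapply(design, function(s) s$label, character(1))
  expect_true(dnds["ps"] > dnds["pmma"])
  expect_true(dnds["pmma"] > dnds["yeast"])
  expect_true(dnds["yeast"] > 0)
  expect_identical(unname(dnds["no_particle"]), 0)
})

test_that("generate_dataset honors counts, ids, sample lengths and seed", {
  design <- default_study_design()
  design <- lapply(design, function(s) { s$count <- 1L; s })
  cfg <- acquisition_config(duration = 4, seed = 21)
  ds <- generate_dataset(design, cfg)
  expect_length(ds, 4)
  expect_true(all(vapply(ds, function(a) length(a$samples), numeric(1)) ==
                    20000))
  ids <- vapply(ds, function(a) a$particle_id, character(1))
  expect_false(anyDuplicated(ids) > 0)
  ds2 <- generate_dataset(design, cfg)
  expect_identical(lapply(ds, `[[`, "samples"),
                   lapply(ds2, `[[`, "samples"))
  bad <- design
  bad[[2]]$label <- bad[[1]]$label
  expect_error(generate_dataset(bad, cfg), "duplicate")
})

test_that("artifact injection: identity at rate 0, Poisson mean at rate 2", {
  spec <- default_study_design()[[2]]
  cfg0 <- acquisition_config(duration = 2, artifact_rate = 0, seed = 4)
  acq <- synthesize_acquisition(spec, cfg0)
  expect_identical(inject_artifacts(acq, cfg0), acq)
  cfg2 <- acquisition_config(duration = 2, artifact_rate = 2, seed = 4)
  ks <- vapply(seq_len(1000), function(i) {
    out <- inject_artifacts(acq, cfg2, seed = i)
    out$provenance$n_artifacts
  }, numeric(1))
  # Monte-Carlo mean vs Poisson mean 2: SE = sqrt(2/1000) ~ 0.045
  expect_lt(abs(mean(ks) - 2), 3 * sqrt(2 / 1000))
})

test_that("an injected high-amplitude spike gets its epoch rejected", {
  spec <- particle_class_spec("no_particle", count = 1L, env_depth = 0)
  cfg <- acquisition_config(duration = 10, baseline = 0, noise_sd = 0.05,
                            artifact_rate = 0, seed = 8)
  acq <- synthesize_acquisition(spec, cfg)  # pure Gaussian noise
  # place one 10 SD spike deterministically inside epoch index 2
  acq$samples[23000] <- acq$samples[23000] + 10 * sd(acq$samples)
  es <- preprocess_acquisition(acq)
  expect_identical(es$n_rejected, 1L)
  expect_false(es$epochs[[3]]$accepted)
  expect_true(all(vapply(es$epochs[-3], function(e) e$accepted,
                         logical(1))))
})

test_that("mean epoch power is ordered like gain * dn * d across classes", {
  design <- default_study_design()
  cfg <- acquisition_config(duration = 70, artifact_rate = 0, seed = 31)
  pw <- vapply(design, function(spec) {
    acq <- synthesize_acquisition(spec, cfg, particle_effect = 1,
                                  seed = cfg$seed + spec$count)
    es <- preprocess_acquisition(acq)
    expect_gte(es$n_accepted, 30)
    mean(vapply(es$epochs, function(e) mean(e$samples^2), numeric(1)))
  }, numeric(1))
  names(pw) <- vapply(design, function(s) s$label, character(1))
  expect_true(pw["ps"] > pw["pmma"])
  expect_true(pw["pmma"] > pw["yeast"])
  expect_true(pw["yeast"] > pw["no_particle"])
})

test_that("envelope process retains the configured Nakagami shape", {
  for (mu in c(0.9, 3)) {
    w <- scatterid:::with_seed(61 + mu * 10,
                               scatterid:::nakagami_process(1e5, mu,
                                                            fs = 5000,
                                                            cutoff = 25))
    fit <- nakagami_fit(w)
    expect_lt(abs(fit["mu"] - mu) / mu, 0.10)
  }
})
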