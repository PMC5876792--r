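# One reproducible run: simulate -> preprocess -> featurize -> discriminant
# -> statistics, with plain-text file formats (CSV tables, JSON sidecars /
# model / report). Every artifact is a deterministic function of
# (design, config, seed).

#' Run configuration
#'
#' Bundles the study design and all stage parameters.
#'
#' @param design List of [particle_class_spec()] (default
#'   [default_study_design()]).
#' @param acquisition An [acquisition_config()].
#' @param preprocess A [preprocess_params()].
#' @param exclude Features excluded before the discriminant fit.
#' @param ridge Ridge for [lda_fit()].
#' @param reference_class Class used to orient the score
#'   ([orient_discriminant()]); defaults to the first design label.
#' @param bhattacharyya `"univariate"` or `"multivariate"`.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(design = default_study_design(),
                       acquisition = acquisition_config(),
                       preprocess = preprocess_params(),
                       exclude = c("RMS", "omega_nakagami"),
                       ridge = 1e-6,
                       reference_class = design[[1]]$label,
                       bhattacharyya = "univariate") {
  structure(list(design = design, acquisition = acquisition,
                 preprocess = preprocess, exclude = exclude, ridge = ridge,
                 reference_class = reference_class,
                 bhattacharyya = bhattacharyya),
            class = "run_config")
}

#' Execute the full pipeline
#'
#' Streams one acquisition at a time (synthesize, inject artifacts,
#' preprocess, featurize) so memory stays flat, then fits the discriminant
#' on the epoch-level table, projects, averages scores per particle, orients
#' the score against the reference class, and runs the statistical layer on
#' the per-particle granularity.
#'
#' @param config A [run_config()].
#' @param out_dir Directory for output files, or `NULL` to skip writing.
#' @param verbose Log per-stage tallies.
#' @return List: `manifest`, `feature_table` (epoch level),
#'   `particle_table`, `model`, `scores` (per-particle, with `score`
#'   column), `class_means`, `stats` (screen incl. the score row,
#'   `spearman`, `separability_top`, `separability_bottom`).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config$acquisition
  labels <- vapply(config$design, function(s) s$label, character(1))
  if (anyDuplicated(labels)) stop("invalid-design: duplicate class labels")

  feat_rows <- list()
  n_acq <- 0L; n_epochs <- 0L; n_accepted <- 0L
  for (ci in seq_along(config$design)) {
    spec <- config$design[[ci]]
    for (pi in seq_len(spec$count)) {
      sd_i <- child_seed(cfg$seed, spec$label, pi)
      pe <- with_seed(sd_i, stats::rlnorm(1, 0, cfg$particle_sd))
      id <- sprintf("%s_%02d", spec$label, pi)
      acq <- synthesize_acquisition(spec, cfg, particle_effect = pe,
                                    particle_id = id, seed = sd_i + 1L)
      if (cfg$artifact_rate > 0)
        acq <- inject_artifacts(acq, cfg, seed = sd_i + 2L)
      es <- preprocess_acquisition(acq, config$preprocess,
                                   verbose = verbose)
      n_acq <- n_acq + 1L
      n_epochs <- n_epochs + es$n_total
      n_accepted <- n_accepted + es$n_accepted
      if (es$n_accepted == 0) {
        warning("particle ", id, " has no accepted epochs; excluded")
        next
      }
      feat_rows[[length(feat_rows) + 1L]] <- featurize_epochs(es)
    }
  }
  feature_table <- do.call(rbind, feat_rows)
  rownames(feature_table) <- NULL

  meta <- c("particle_id", "class_label", "epoch_index")
  x_epoch <- exclude_features(feature_table[, setdiff(names(feature_table),
                                                      meta)],
                              config$exclude)
  model <- lda_fit(x_epoch, feature_table$class_label, ridge = config$ridge)
  model <- orient_discriminant(model, config$reference_class)

  particle_table <- particle_average(feature_table)
  p_scores <- lda_transform(model, particle_table)
  class_means <- tapply(p_scores$score, p_scores$class_label, mean)

  screen_tab <- particle_table
  screen_tab$score <- p_scores$score
  screen <- feature_screen(screen_tab)

  sp <- spearman_vs_dnd(
    stats::setNames(as.numeric(class_means), names(class_means)),
    config$design)

  cw <- contribution_weights(model)
  top3 <- utils::head(cw$feature, 3)
  bottom3 <- utils::tail(cw$feature, 3)
  # Bhattacharyya summaries need >= 2 particles per class; skip at smoke scale
  enough <- all(table(particle_table$class_label) >= 2)
  sep_top <- if (enough)
    separability_report(particle_table, features = top3,
                        method = config$bhattacharyya) else NULL
  sep_bottom <- if (enough)
    separability_report(particle_table, features = bottom3,
                        method = config$bhattacharyya) else NULL

  manifest <- list(
    package = "scatterid",
    version = as.character(utils::packageVersion("scatterid")),
    seed = cfg$seed,
    n_acquisitions = n_acq,
    total_signal_seconds = n_acq * cfg$duration,
    n_epochs = n_epochs,
    n_accepted = n_accepted,
    n_rejected = n_epochs - n_accepted,
    n_particles = nrow(particle_table),
    n_features = length(feature_names()),
    n_retained = length(model$features))

  out <- list(manifest = manifest, feature_table = feature_table,
              particle_table = particle_table, model = model,
              scores = p_scores, class_means = class_means,
              stats = list(screen = screen, spearman = sp,
                           separability_top = sep_top,
                           separability_bottom = sep_bottom,
                           weights = cw))
  if (!is.null(out_dir)) write_run(out, out_dir)
  if (verbose)
    message(sprintf(
      "run: %d acquisitions (%g s), %d/%d epochs accepted, rho = %.2f",
      n_acq, manifest$total_signal_seconds, n_accepted, n_epochs, sp$rho))
  invisible(out)
}

# ---- file formats -----------------------------------------------------------

#' Write / read an acquisition (CSV + JSON sidecar)
#'
#' Samples as plain text (one value per line, no header) beside a
#' `<path>.json` sidecar holding `class_label`, `particle_id`, `fs`,
#' `duration` and generator provenance. Round trip is lossless to within
#' 15 significant digits.
#'
#' @param acq An `"acquisition"`.
#' @param path Sample-file path (sidecar written at `<path>.json`).
#' @return `write_acquisition`: `path`, invisibly. `read_acquisition`: the
#'   acquisition.
#' @export
write_acquisition <- function(acq, path) {
  stopifnot(inherits(acq, "acquisition"))
  writeLines(formatC(acq$samples, format = "g", digits = 15), path)
  side <- list(class_label = acq$class_label, particle_id = acq$particle_id,
               fs = acq$fs, duration = length(acq$samples) / acq$fs,
               provenance = acq$provenance)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_acquisition
#' @param path Sample-file path written by [write_acquisition()].
#' @export
read_acquisition <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("format error: missing sidecar ", sidecar)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(side$fs)) stop("format error: sidecar missing fs")
  samples <- as.numeric(readLines(path))
  if (any(!is.finite(samples))) stop("format error: non-finite samples")
  structure(list(samples = samples, fs = as.numeric(side$fs),
                 class_label = side$class_label,
                 particle_id = side$particle_id,
                 provenance = side$provenance),
            class = "acquisition")
}

#' Write / read a feature table (CSV, fixed column order)
#'
#' @param table Feature or score table.
#' @param path CSV path.
#' @return `read_feature_table` returns the data frame; a schema error names
#'   missing columns when `expected` is given.
#' @param expected Optional expected column names to validate on read.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, expected = NULL) {
  out <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(expected)) {
    missing <- setdiff(expected, colnames(out))
    if (length(missing) > 0)
      stop("schema mismatch; missing column(s): ",
           paste(missing, collapse = ", "))
  }
  out
}

#' Serialize / restore a fitted discriminant model (JSON)
#'
#' @param model An `"lda_model"`.
#' @param path JSON path.
#' @export
write_lda_model <- function(model, path) {
  stopifnot(inherits(model, "lda_model"))
  obj <- list(features = model$features, phi = unname(model$phi),
              lambda = model$lambda,
              class_means_projected =
                as.list(model$class_means_projected),
              center = as.list(model$center), scale = as.list(model$scale),
              ridge = model$ridge)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lda_model
#' @export
read_lda_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(phi = stats::setNames(as.numeric(obj$phi), obj$features),
         lambda = obj$lambda,
         class_means_projected = unlist(obj$class_means_projected),
         center = unlist(obj$center), scale = unlist(obj$scale),
         features = obj$features, ridge = obj$ridge),
    class = "lda_model")
}

#' Read a run configuration from YAML or JSON
#'
#' The file may define `classes` (fields of [particle_class_spec()]),
#' `acquisition`, `preprocess`, and top-level `exclude`, `ridge`,
#' `reference_class`, `bhattacharyya`; omitted parts fall back to defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  design <- if (is.null(obj$classes)) default_study_design()
  else lapply(seq_len(NROW(obj$classes)), function(i) {
    cl <- as.list(if (is.data.frame(obj$classes)) obj$classes[i, ]
                  else obj$classes[[i]])
    # absent fields arrive as NULL (YAML) or NA (JSON data frame); drop both
    # so the constructor defaults apply (diameter NA stays meaningful only
    # for the blank class, which is also its default)
    drop_f <- vapply(cl, function(z)
      is.null(z) || (length(z) == 1 && is.na(z)), logical(1))
    do.call(particle_class_spec, cl[!drop_f])
  })
  acq <- do.call(acquisition_config, as.list(obj$acquisition))
  pp <- do.call(preprocess_params, as.list(obj$preprocess))
  args <- list(design = design, acquisition = acq, preprocess = pp)
  for (f in c("exclude", "ridge", "reference_class", "bhattacharyya"))
    if (!is.null(obj[[f]])) args[[f]] <- unlist(obj[[f]])
  do.call(run_config, args)
}

# Write all run artifacts under out_dir.
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(run$feature_table,
                      file.path(out_dir, "features_epoch.csv"))
  write_feature_table(run$particle_table,
                      file.path(out_dir, "features_particle.csv"))
  write_feature_table(run$scores, file.path(out_dir, "scores_particle.csv"))
  write_lda_model(run$model, file.path(out_dir, "lda_model.json"))
  write_feature_table(run$stats$screen, file.path(out_dir, "screen.csv"))
  write_feature_table(run$stats$weights,
                      file.path(out_dir, "lda_weights.csv"))
  sep_json <- function(s) if (is.null(s)) NULL else
    list(features = s$features, distances = as.list(s$distances),
         mean = s$mean)
  report <- list(
    manifest = run$manifest,
    class_means = as.list(run$class_means),
    spearman = run$stats$spearman,
    separability_top = sep_json(run$stats$separability_top),
    separability_bottom = sep_json(run$stats$separability_bottom))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
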