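#' Export a model comparison as CSV artifacts
#'
#' Writes a grid CSV (one row per model x split, with every metric) and one
#' scatter CSV per model (`observed`, `predicted`, `split`, `within_band`)
#' so that every grid number can be recomputed from the scatter files.
#'
#' @param comparison a `lodge_comparison` from [compare_models()].
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
export_comparison <- function(comparison, dir) {
  stopifnot(inherits(comparison, "lodge_comparison"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid_path <- file.path(dir, "comparison_grid.csv")
  utils::write.csv(format_num_df(comparison$grid), grid_path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  scatter_paths <- character()
  for (nm in unique(comparison$scatter$model)) {
    p <- file.path(dir, sprintf("scatter_%s.csv", nm))
    sub <- comparison$scatter[comparison$scatter$model == nm,
                              c("observed", "predicted", "split",
                                "within_band")]
    utils::write.csv(format_num_df(sub), p, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
    scatter_paths[nm] <- p
  }
  invisible(list(grid = grid_path, scatter = scatter_paths))
}

# fixed-precision formatting so CSV output is byte-stable across platforms
format_num_df <- function(df) {
  for (cn in names(df)) {
    if (is.numeric(df[[cn]]) && !is.integer(df[[cn]])) {
      df[[cn]] <- sprintf("%.12g", df[[cn]])
    }
  }
  df
}

#' Default pipeline configuration
#'
#' @param seed master seed.
#' @param n_accessions,n_reps,n_images study-fixture sizes.
#' @param image_noise_sd RGB noise for generated canopy images.
#' @param train_fraction,models comparison settings; `models` is a subset
#'   of `c("mlr", "ann", "svr", "rf")`.
#' @return nested config list, serializable as YAML.
#' @export
pipeline_config <- function(seed = 1, n_accessions = 228, n_reps = 2,
                            n_images = 6, image_noise_sd = 0,
                            train_fraction = 0.75,
                            models = c("mlr", "ann", "svr", "rf")) {
  list(seed = seed,
       simulate = list(n_accessions = n_accessions, n_reps = n_reps,
                       n_images = n_images,
                       image_noise_sd = image_noise_sd),
       compare = list(train_fraction = train_fraction,
                      models = as.list(models)))
}

validate_pipeline_config <- function(config) {
  need <- c("seed", "simulate", "compare")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    stop("config error at ", paste(missing, collapse = ", "),
         ": required section missing", call. = FALSE)
  }
  sim <- config$simulate
  for (f in c("n_accessions", "n_reps", "n_images")) {
    if (is.null(sim[[f]]) || sim[[f]] < 0) {
      stop("config error at simulate.", f, ": non-negative value required",
           call. = FALSE)
    }
  }
  cmp <- config$compare
  if (is.null(cmp$train_fraction) || cmp$train_fraction <= 0 ||
      cmp$train_fraction >= 1) {
    stop("config error at compare.train_fraction: must lie in (0, 1)",
         call. = FALSE)
  }
  bad <- setdiff(unlist(cmp$models), c("mlr", "ann", "svr", "rf"))
  if (length(bad)) {
    stop("config error at compare.models: unknown model(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' Simulate a study fixture, score every plot from its field-protocol
#' measurements, estimate lodged area from the generated canopy images,
#' fit and compare the configured predictors on a shared 75/25 split, and
#' write all artifacts plus a run manifest into `out_dir`. Given a fixed
#' seed, all artifacts except the manifest timestamp are byte-identical
#' across runs.
#'
#' @param config a [pipeline_config()] list, or a path to a YAML file with
#'   the same structure.
#' @param out_dir artifact directory.
#' @return named list of artifact paths (also written to the manifest).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  sim <- config$simulate

  study <- gen_study(n_accessions = sim$n_accessions, n_reps = sim$n_reps,
                     n_images = sim$n_images,
                     noise_sd = sim$image_noise_sd %||% 0,
                     seed = seed, out_dir = out_dir)

  scored <- score_plots(study$plots)
  scores_path <- file.path(out_dir, "scores.csv")
  write_score_csv(format_num_df(scored), scores_path)

  paths <- list(traits = study$paths$traits, plots = study$paths$plots,
                scores = scores_path, images = study$paths$images)

  if (sim$n_images > 0) {
    la <- la_from_images(study$paths$images)
    la_path <- file.path(out_dir, "image_la.csv")
    utils::write.csv(format_num_df(la), la_path, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
    paths$image_la <- la_path
  }

  model_names <- unlist(config$compare$models)
  if (length(model_names)) {
    configs <- lapply(model_names, function(m) {
      switch(m, mlr = mlr_config(),
             ann = ann_config(seed = seed),
             svr = svr_config(),
             rf = rf_config(seed = seed))
    })
    names(configs) <- model_names
    cmp <- compare_models(study$traits, configs,
                          train_fraction = config$compare$train_fraction,
                          split_seed = seed)
    exp_paths <- export_comparison(cmp, out_dir)
    paths$comparison <- exp_paths$grid
    paths$scatter <- exp_paths$scatter
    if ("mlr" %in% model_names) {
      sp <- split_train_test(study$traits,
                             config$compare$train_fraction, seed)
      trace <- stepwise_mlr(sp$train)$trace
      trace_path <- file.path(out_dir, "stepwise_trace.csv")
      utils::write.csv(format_num_df(trace), trace_path,
                       row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8")
      paths$stepwise_trace <- trace_path
    }
    manifest_split <- cmp$split_sizes
  } else {
    manifest_split <- NULL
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("lodgescore")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = seed,
    config = config,
    split_sizes = as.list(manifest_split),
    n_plots = nrow(study$plots),
    n_images = sim$n_images,
    artifacts = lapply(paths, function(p) as.list(basename(unlist(p))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths$manifest <- file.path(out_dir, "manifest.json")
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
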