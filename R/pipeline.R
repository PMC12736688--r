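#' Pipeline configuration
#'
#' End-to-end run configuration tying together the scene, preprocessing,
#' feature, model, training and evaluation stages. Unknown keys are
#' rejected so configuration typos fail loudly.
#'
#' @param scene A [scene_config()].
#' @param preset Feature preset (see [feature_channels()]).
#' @param mask_set Quality codes treated as missing.
#' @param sg_window,sg_order,harmonics,period Reconstruction parameters.
#' @param architecture Architecture preset name (see
#'   [architecture_preset()]).
#' @param test_fraction Polygon-level test fraction.
#' @param training A [train_config()].
#' @param threshold Rice-probability classification threshold.
#' @param seed Global seed (model init and split).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(scene = scene_config(), preset = "complete",
                            mask_set = default_mask_codes(),
                            sg_window = 7, sg_order = 2, harmonics = 2,
                            period = 365, architecture = "full",
                            test_fraction = 0.2,
                            training = train_config(), threshold = 0.5,
                            seed = 1) {
  structure(list(scene = scene, preset = preset, mask_set = mask_set,
                 sg_window = sg_window, sg_order = sg_order,
                 harmonics = harmonics, period = period,
                 architecture = architecture,
                 test_fraction = test_fraction, training = training,
                 threshold = threshold, seed = as.integer(seed)),
            class = "pipeline_config")
}

# stable fingerprint of a configuration, stamped into every artifact
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(rapply(unclass(config), unclass, how = "replace")),
             tmp)
  unname(tools::md5sum(tmp))
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()], [scene_config()] and
#' [train_config()] under `scene:` and `training:` blocks. Unknown keys at
#' any level raise an error.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) stop("unknown configuration key(s) in ", where, ": ",
                          paste(bad, collapse = ", "))
  }
  check_keys(raw, c("scene", "training", "preset", "mask_set", "sg_window",
                    "sg_order", "harmonics", "period", "architecture",
                    "test_fraction", "threshold", "seed"), "top level")
  sc <- raw$scene %||% list()
  check_keys(sc, names(formals(scene_config)), "scene")
  tr <- raw$training %||% list()
  check_keys(tr, names(formals(train_config)), "training")
  args <- raw[setdiff(names(raw), c("scene", "training"))]
  args$scene <- do.call(scene_config, sc)
  args$training <- do.call(train_config, tr)
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline
#'
#' Executes simulate, reconstruct, featurize, split, train, evaluate in
#' order, writing artifacts (evaluation JSON, model checkpoint, training
#' history) stamped with the configuration hash and seed. Re-running the
#' same configuration reproduces the evaluation report bit-identically
#' under single-threaded execution. A stage failure aborts with an error
#' naming the stage; artifacts of completed stages are kept.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param write_dataset Also serialize the simulated scene as CSV.
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with the trained model, the evaluation report
#'   and artifact paths.
#' @export
run_pipeline <- function(config, out_dir = tempfile("ricesits_run_"),
                         write_dataset = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  say <- function(...) if (!quiet) message(...)
  t_all <- Sys.time()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say(sprintf("[%s] done in %.1fs", name,
                as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  scene <- stage("simulate", build_dataset(config$scene))
  paths <- list()
  if (write_dataset) {
    paths$dataset <- file.path(out_dir, "scene.csv")
    write_scene_csv(scene, paths$dataset)
  }
  recon <- stage("preprocess",
                 reconstruct_scene(scene, mask_set = config$mask_set,
                                   sg_window = config$sg_window,
                                   sg_order = config$sg_order,
                                   K = config$harmonics,
                                   period = config$period))
  fs <- stage("featurize", featurize_scene(recon, preset = config$preset))
  sp <- stage("split", group_split(fs$polygon_id, fs$label,
                                   test_fraction = config$test_fraction,
                                   seed = config$seed))
  fs_train <- subset_features(fs, sp$train)
  fs_test <- subset_features(fs, sp$test)

  model <- stage("train", {
    cfg <- architecture_preset(config$architecture,
                               n_channels = dim(fs$X)[3])
    m <- sits_former(cfg, seed = config$seed)
    m$feature_preset <- config$preset
    train_sits_former(m, fs_train, config$training)
  })

  report <- stage("evaluate", {
    prob <- predict(model, fs_test)[, 2]
    eval_report(fs_test$label, prob, threshold = config$threshold)
  })

  paths$checkpoint <- file.path(out_dir, "model.rds")
  save_checkpoint(model, paths$checkpoint)
  paths$evaluation <- file.path(out_dir, "evaluation.json")
  jsonlite::write_json(
    list(config_hash = hash, seed = config$seed,
         n_train = length(sp$train), n_test = length(sp$test),
         confusion = unclass(report$confusion),
         metrics = report$metrics,
         probability_overlap = report$probability$overlap),
    paths$evaluation, auto_unbox = TRUE, digits = NA)
  paths$history <- file.path(out_dir, "history.json")
  jsonlite::write_json(
    list(config_hash = hash,
         loss = model$history$loss, acc = model$history$acc,
         lr = model$history$lr, clip_count = model$history$clip_count),
    paths$history, auto_unbox = TRUE, digits = NA)
  say(sprintf("pipeline complete in %.1fs (config %s)",
              as.numeric(Sys.time() - t_all, units = "secs"), hash))
  invisible(list(model = model, report = report, split = sp, paths = paths,
                 config_hash = hash))
}
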