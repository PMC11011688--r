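#' Run configuration for the end-to-end pipeline
#'
#' A fully serializable description of a run: synthetic-generation block,
#' preprocessing, selector and classifier settings, split parameters, seed
#' and output directory. A run's config + seed reproduces its outputs.
#'
#' @param n_per_class scenes per class for simulation (default 20).
#' @param shape scene size in pixels (default c(64, 64)).
#' @param preprocess preset name for [preprocess_spec()] (default "RAW").
#' @param use_cars logical (default TRUE).
#' @param cars_runs CARS sampling runs (default 50).
#' @param classifiers character subset of c("plsda", "svm", "ann").
#' @param tissue_modes character subset of
#'   c("differentiated", "overall_average").
#' @param train_fraction SPXY training share (default 0.75).
#' @param cv_folds stratified CV folds (default 10).
#' @param seed master seed.
#' @param outdir output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(n_per_class = 20L, shape = c(64L, 64L),
                       preprocess = "RAW", use_cars = TRUE, cars_runs = 50L,
                       classifiers = c("plsda", "svm", "ann"),
                       tissue_modes = c("differentiated", "overall_average"),
                       train_fraction = 0.75, cv_folds = 10L, seed = 1L,
                       outdir = tempfile("beefhsi_run_")) {
  stopifnot(all(classifiers %in% c("plsda", "svm", "ann")),
            all(tissue_modes %in% c("differentiated", "overall_average")))
  if (n_per_class < 1L) {
    stop_beefhsi("n_per_class must be >= 1", class = "beefhsi_value_error")
  }
  structure(list(n_per_class = as.integer(n_per_class),
                 shape = as.integer(shape), preprocess = preprocess,
                 use_cars = use_cars, cars_runs = as.integer(cars_runs),
                 classifiers = classifiers, tissue_modes = tissue_modes,
                 train_fraction = train_fraction,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed),
                 outdir = outdir),
            class = "run_config")
}

#' Read/write a run configuration as YAML
#' @param path YAML file path.
#' @return `read_run_config`: a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop_beefhsi("unknown config key(s): %s", paste(bad, collapse = ", "),
                 class = "beefhsi_config_error")
  }
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Simulate a dataset to disk
#'
#' Generates `4 * n_per_class` synthetic scenes per the config, writes each
#' as a portable container (cube + reference frames + mask) under
#' `outdir/scenes/`, plus `manifest.csv` (scene_id, class, seed,
#' fat_fraction, path).
#'
#' @param config a `run_config`.
#' @return path of the manifest file, invisibly.
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  scene_dir <- file.path(config$outdir, "scenes")
  dir.create(scene_dir, recursive = TRUE, showWarnings = FALSE)
  tmpl <- scene_config(shape = config$shape)
  scenes <- make_dataset(config$n_per_class, tmpl, seed = config$seed)
  manifest <- attr(scenes, "manifest")
  manifest$path <- file.path(scene_dir,
                             sprintf("scene_%03d.bhc", manifest$scene_id))
  for (i in seq_along(scenes)) {
    write_cube(scenes[[i]]$raw, manifest$path[i], format = "container",
               refs = scenes[[i]]$refs, mask = scenes[[i]]$mask)
  }
  manifest_path <- file.path(config$outdir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}

load_scenes <- function(config) {
  manifest_path <- file.path(config$outdir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    stop_beefhsi("no manifest at %s; run cmd_simulate first", manifest_path,
                 class = "beefhsi_config_error")
  }
  manifest <- utils::read.csv(manifest_path)
  scenes <- lapply(seq_len(nrow(manifest)), function(i) {
    obj <- read_cube(manifest$path[i])
    list(raw = obj$cube, refs = obj$refs, mask = obj$mask,
         class_label = manifest$class[i])
  })
  attr(scenes, "manifest") <- manifest
  scenes
}

#' Run the full classification pipeline
#'
#' Executes calibrate, segment, ROI spectrum extraction, preprocessing,
#' SPXY split, CARS selection, classifier fits and evaluation for every
#' requested (tissue mode x classifier) design, then renders deterioration
#' maps for the first scene of each class with the differentiated PLS-DA
#' models. Reports are written under `outdir`: `report.json`, per-design
#' confusion CSVs, deterioration PNGs and index arrays, and `run_log.txt`.
#'
#' @param config a `run_config`.
#' @param scenes optional in-memory scene list (as from [make_dataset()]);
#'   read from disk per the manifest when omitted.
#' @return list of per-design results (invisibly also written to disk).
#' @export
cmd_run <- function(config, scenes = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("beefhsi run, seed %d, started %s", config$seed,
                         format(t0)),
                 sprintf("R %s, beefhsi %s", getRversion(),
                         as.character(utils::packageVersion("beefhsi"))))
  if (is.null(scenes)) scenes <- load_scenes(config)
  extracted <- extract_spectra(scenes, spec = preprocess_spec(config$preprocess))
  log_lines <- c(log_lines, sprintf("extracted %d scenes in %.1f s",
                                    length(scenes),
                                    as.numeric(Sys.time() - t0, "secs")))
  results <- list()
  for (mode in config$tissue_modes) {
    for (clf in config$classifiers) {
      key <- paste(mode, clf, sep = "_")
      t1 <- Sys.time()
      res <- run_experiment(extracted, tissue_mode = mode, classifier = clf,
                            use_cars = config$use_cars,
                            train_fraction = config$train_fraction,
                            cv_folds = config$cv_folds,
                            cars_runs = config$cars_runs,
                            seed = config$seed)
      results[[key]] <- res
      utils::write.csv(res$report$confusion,
                       file.path(config$outdir,
                                 sprintf("confusion_%s.csv", key)))
      log_lines <- c(log_lines,
                     sprintf("%s: ACC %.4f (CV %.4f) in %.1f s", key,
                             res$report$acc, res$cv_report$acc,
                             as.numeric(Sys.time() - t1, "secs")))
    }
  }
  # deterioration maps: differentiated PLS-DA models on CARS subsets
  map_key <- "differentiated_plsda"
  if (!is.null(results[[map_key]]) && config$use_cars) {
    sel <- results[[map_key]]$selection
    models <- results[[map_key]]$models
    classes <- freshness_classes()
    manifest <- attr(scenes, "manifest")
    map_summary <- list()
    for (cl in classes) {
      i <- if (!is.null(manifest)) which(manifest$class == cl)[1] else
        which(vapply(scenes, function(s) s$class_label, "") == cl)[1]
      sc <- scenes[[i]]
      cube <- calibrate_reflectance(sc$raw, sc$refs)
      dmap <- pixel_deterioration(cube, sc$mask, models, sel,
                                  spec = preprocess_spec(config$preprocess))
      saveRDS(dmap$index,
              file.path(config$outdir, sprintf("deterioration_%s.rds", cl)))
      write_map_png(dmap, file.path(config$outdir,
                                    sprintf("deterioration_%s.png", cl)))
      map_summary[[cl]] <- mean(dmap$index, na.rm = TRUE)
    }
    results$map_mean_index <- unlist(map_summary)
  }
  summary <- list(
    seed = config$seed,
    designs = lapply(results[setdiff(names(results), "map_mean_index")],
                     function(r) list(acc = r$report$acc,
                                      cv_acc = r$cv_report$acc,
                                      n_test = r$report$n)),
    map_mean_index = as.list(results$map_mean_index))
  jsonlite::write_json(summary, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(config$outdir, "run_log.txt"))
  invisible(results)
}
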