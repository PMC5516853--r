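#' Configuration for the end-to-end landscape pipeline
#'
#' Validates all numeric parameters up front, so a bad configuration fails
#' before any computation. The configuration round-trips losslessly
#' through YAML via [write_config()] / [read_config()].
#'
#' @param expression path to the expression table (genes x samples).
#' @param annotation path to the sample -> stage table.
#' @param out_dir output directory.
#' @param stage_order optional explicit stage order (default: first
#'   appearance in the annotation file).
#' @param threshold discretisation threshold (> 0, default 0.5).
#' @param sd z-score denominator, `"sample"` or `"population"`.
#' @param feature_method `"none"`, `"elbow"` or `"top_k"`.
#' @param k gene count for `feature_method = "top_k"`.
#' @param grid_size landscape grid resolution (>= 2, default 50).
#' @param margin landscape bounding-box margin (default 0.1).
#' @param perturb run the perturbation analysis (default FALSE).
#' @param fractions,repeats perturbation settings.
#' @param switches detect switched genes (default TRUE).
#' @param pairs stage pairs for switch detection.
#' @param lenient lenient switch rule.
#' @param plots write the two landscape views as PNG files (default TRUE).
#' @param seed master seed for all randomised steps.
#' @return a `hopfield_config` list.
#' @export
hopfield_config <- function(expression, annotation, out_dir,
                            stage_order = NULL,
                            threshold = 0.5, sd = "sample",
                            feature_method = "none", k = NULL,
                            grid_size = 50, margin = 0.1,
                            perturb = FALSE,
                            fractions = c(0.05, 0.1, 0.2, 0.5, 0.9),
                            repeats = 100,
                            switches = TRUE, pairs = "successive",
                            lenient = FALSE, plots = TRUE, seed = 1) {
  if (!is_number(threshold) || threshold <= 0) {
    stop("`threshold` must be positive", call. = FALSE)
  }
  sd <- match.arg(sd, c("sample", "population"))
  feature_method <- match.arg(feature_method, c("none", "elbow", "top_k"))
  if (feature_method == "top_k" && !is_count(k, min = 2)) {
    stop("`k` must be an integer >= 2 when feature_method = \"top_k\"",
         call. = FALSE)
  }
  if (!is_count(grid_size, min = 2)) {
    stop("`grid_size` must be an integer >= 2", call. = FALSE)
  }
  if (!is_number(margin) || margin < 0) {
    stop("`margin` must be non-negative", call. = FALSE)
  }
  if (isTRUE(perturb)) {
    if (!is_count(repeats, min = 2)) {
      stop("`repeats` must be an integer >= 2", call. = FALSE)
    }
    if (length(fractions) == 0 ||
        any(!is.finite(fractions) | fractions <= 0 | fractions > 1)) {
      stop("`fractions` must all lie in (0, 1]", call. = FALSE)
    }
  }
  if (!is_count(seed, min = 0)) stop("`seed` must be an integer >= 0",
                                     call. = FALSE)
  structure(list(expression = expression, annotation = annotation,
                 out_dir = out_dir, stage_order = stage_order,
                 threshold = threshold, sd = sd,
                 feature_method = feature_method, k = k,
                 grid_size = as.integer(grid_size), margin = margin,
                 perturb = isTRUE(perturb), fractions = fractions,
                 repeats = as.integer(repeats),
                 switches = isTRUE(switches), pairs = pairs,
                 lenient = isTRUE(lenient), plots = isTRUE(plots),
                 seed = as.integer(seed)),
            class = "hopfield_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [hopfield_config()].
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pairs <- raw$pairs
  if (is.list(pairs)) pairs <- lapply(pairs, as.character)
  hopfield_config(expression = raw$expression, annotation = raw$annotation,
                  out_dir = raw$out_dir, stage_order = raw$stage_order,
                  threshold = raw$threshold, sd = raw$sd,
                  feature_method = raw$feature_method, k = raw$k,
                  grid_size = raw$grid_size, margin = raw$margin,
                  perturb = raw$perturb,
                  fractions = as.numeric(raw$fractions),
                  repeats = raw$repeats, switches = raw$switches,
                  pairs = pairs, lenient = raw$lenient,
                  plots = raw$plots, seed = raw$seed)
}

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[hopscape:%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full landscape pipeline
#'
#' Executes normalisation, feature selection, weight-matrix construction,
#' energy profiling, landscape rendering, and optionally perturbation
#' analysis and switch detection, writing every result plus a
#' machine-readable run manifest (parameters, seed, package and R
#' versions, input checksums) to the output directory. Any stage error
#' aborts with a diagnostic naming the stage. Reruns with the same
#' configuration and seed produce byte-identical numeric outputs.
#'
#' @param config a [hopfield_config()].
#' @return invisibly, a list with the computed objects and the paths of
#'   all artifacts written.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "hopfield_config")) {
    stop("`config` must be created by hopfield_config() or read_config()",
         call. = FALSE)
  }
  cfg <- config
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  files <- list()
  run_stage <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
    pipeline_log(stage, "done in %.2f s", proc.time()[["elapsed"]] - t0)
    out
  }

  inputs <- run_stage("load", {
    x <- read_expression(cfg$expression)
    ann <- read_stage_annotation(cfg$annotation,
                                 stage_order = cfg$stage_order)
    validate_annotation(ann, x)
    pipeline_log("load", "%d genes x %d samples, %d stages",
                 nrow(x), ncol(x), nlevels(ann$stage))
    list(x = x, ann = ann)
  })
  x <- inputs$x
  ann <- inputs$ann

  z <- run_stage("normalise", zscore_normalize(x, sd = cfg$sd))
  z <- run_stage("feature-select", {
    # variances are ranked on the raw matrix; the z-scored rows of the
    # selected genes are what flows downstream
    out <- switch(cfg$feature_method,
                  none = z,
                  elbow = z[rownames(select_features(x, "elbow")), ,
                            drop = FALSE],
                  top_k = z[rownames(select_features(x, "top_k", cfg$k)), ,
                            drop = FALSE])
    pipeline_log("feature-select", "%d of %d genes retained (%s)",
                 nrow(out), nrow(x), cfg$feature_method)
    out
  })
  states <- run_stage("discretise", discretize(z, cfg$threshold))
  W <- run_stage("weights", build_weight_matrix(z))
  profile <- run_stage("energies", stage_energies(states, W, ann))
  landscape <- run_stage("landscape",
                         render_surface(z, W, threshold = cfg$threshold,
                                        grid_size = cfg$grid_size,
                                        ann = ann, margin = cfg$margin))

  files$energies_tsv <- file.path(cfg$out_dir, "energies.tsv")
  write_energy_profile(profile, files$energies_tsv, "tsv")
  files$energies_json <- file.path(cfg$out_dir, "energy_profile.json")
  write_energy_profile(profile, files$energies_json, "json")
  files$weights <- file.path(cfg$out_dir, "weight_matrix.tsv")
  write_weight_matrix(W, files$weights)
  files$surface <- file.path(cfg$out_dir, "surface.tsv")
  write_surface(landscape, files$surface)
  files$landscape_json <- file.path(cfg$out_dir, "landscape.json")
  write_landscape_json(landscape, files$landscape_json)
  files$trajectory <- file.path(cfg$out_dir, "trajectory.tsv")
  utils::write.table(landscape$trajectory, files$trajectory, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  report <- NULL
  if (cfg$switches) {
    report <- run_stage("switches",
                        detect_switches(states, ann, pairs = cfg$pairs,
                                        lenient = cfg$lenient))
    files$switches <- write_switch_report(report, cfg$out_dir)
  }
  pert <- NULL
  if (cfg$perturb) {
    pert <- run_stage("perturbation",
                      run_perturbation_analysis(z, ann,
                                                threshold = cfg$threshold,
                                                fractions = cfg$fractions,
                                                repeats = cfg$repeats,
                                                seed = cfg$seed))
    files$perturbation <- file.path(cfg$out_dir, "perturbation.tsv")
    files$perturbation_summary <- file.path(cfg$out_dir,
                                            "perturbation_summary.json")
    write_perturbation(pert, files$perturbation, files$perturbation_summary)
  }
  if (cfg$plots) {
    run_stage("plots", {
      files$plot_3d <- file.path(cfg$out_dir, "landscape_3d.png")
      grDevices::png(files$plot_3d, width = 900, height = 700)
      plot(landscape, type = "persp")
      grDevices::dev.off()
      files$plot_top <- file.path(cfg$out_dir, "landscape_top.png")
      grDevices::png(files$plot_top, width = 900, height = 700)
      plot(landscape, type = "top")
      grDevices::dev.off()
      NULL
    })
  }

  manifest <- list(
    package = "hopscape",
    package_version = as.character(utils::packageVersion("hopscape")),
    r_version = R.version.string,
    parameters = unclass(cfg)[setdiff(names(cfg),
                                      c("expression", "annotation",
                                        "out_dir"))],
    inputs = list(
      expression = list(path = cfg$expression,
                        md5 = unname(tools::md5sum(cfg$expression)),
                        genes = nrow(x), samples = ncol(x)),
      annotation = list(path = cfg$annotation,
                        md5 = unname(tools::md5sum(cfg$annotation)),
                        stages = stage_order(ann))),
    dimensions = list(genes_selected = nrow(z),
                      grid = c(cfg$grid_size, cfg$grid_size)))
  files$manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                       digits = NA)
  pipeline_log("done", "artifacts in %s", cfg$out_dir)

  invisible(list(expression = x, normalized = z, states = states,
                 weights = W, profile = profile, landscape = landscape,
                 switches = report, perturbation = pert,
                 files = files, manifest = manifest))
}
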