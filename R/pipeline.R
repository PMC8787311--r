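# End-to-end orchestration: YAML config, seeded simulation, reconstruction ->
# classification -> density (+ morphometry when an SWC is given), and run
# manifests that make every run replayable.

#' Default end-to-end configuration
#'
#' A nested list mirroring the YAML config accepted by [read_config()]:
#' `generator` (spindle and spine parameters), `render` (optics/noise),
#' `pipeline` (reconstruction parameters, see [pipeline_config()]), `rules`
#' (classifier thresholds, see [spine_rules()]), `density_bins`, and `seed`.
#'
#' @return A named list of class `smp_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 20220111L,
    generator = list(
      kind = "segment",              # "segment" or "spindle_neuron"
      target_length = 75,
      density_per_um = 0.8,
      n_spines = 60L,
      grouping = 0,
      class_mix = list(thin = 0.25, stubby = 0.20, wide = 0.15,
                       mushroom = 0.30, ramified = 0.10),
      spinule_fraction = 0.15
    ),
    render = list(
      dx = 0.1, dy = 0.1, dz = 0.1,
      extent = c(12.7, 12.7, 15.0),
      psf_sigma_xy = 0.15, psf_sigma_z = 0.30,
      bg_level = 200, fg_level = 60,
      speckle_density = 0.02, illumination_gradient = 0.1, noise_sd = 14
    ),
    pipeline = unclass(pipeline_config(zfactor = 1)),
    rules = unclass(spine_rules()),
    density_bins = list(sparse = 0.3, moderate = 1.0)
  ), class = "smp_config")
}

#' Read and validate a YAML pipeline configuration
#'
#' Unknown keys are rejected and every provided section is validated through
#' its constructor; omitted keys take the defaults of [default_config()].
#'
#' @param path YAML file.
#' @return A validated `smp_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  raw <- yaml::read_yaml(path)
  base <- default_config()
  unknown <- setdiff(names(raw), names(base))
  if (length(unknown)) stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in names(raw)) {
    if (is.list(base[[sec]]) && is.list(raw[[sec]])) {
      bad <- setdiff(names(raw[[sec]]), names(base[[sec]]))
      if (length(bad)) stop("unknown key(s) in ", sec, ": ", paste(bad, collapse = ", "))
      base[[sec]][names(raw[[sec]])] <- raw[[sec]]
    } else {
      base[[sec]] <- raw[[sec]]
    }
  }
  # validate through the constructors
  do.call(pipeline_config, base$pipeline)
  do.call(spine_rules, base$rules)
  mix <- unlist(base$generator$class_mix)
  if (abs(sum(mix) - 1) > 1e-6) stop("generator class_mix must sum to 1")
  if (!is.numeric(base$seed) || length(base$seed) != 1) stop("seed must be a single integer")
  base
}

#' Write a configuration as YAML
#'
#' @param config an `smp_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

file_hashes <- function(paths) {
  h <- tools::md5sum(paths)
  setNames(as.character(h), basename(paths))
}

write_manifest <- function(outdir, config, seed, stages, outputs, inputs = character()) {
  manifest <- list(
    tool = "spindlemorph",
    version = as.character(utils::packageVersion("spindlemorph")),
    seed = seed,
    config = unclass(config),
    input_hashes = as.list(if (length(inputs)) file_hashes(inputs) else setNames(list(), character())),
    stages = stages,
    outputs = as.list(file_hashes(outputs))
  )
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Simulate a phantom and write its artifacts
#'
#' Generates the phantom morphology, decorates it with ground-truth spines,
#' renders the stack, and writes: `phantom.swc`, `stack.tif` (+ spacing
#' sidecar), `truth_mask.tif`, `truth_spines.csv`, `truth.json` (manifest of
#' the ground truth) and `manifest.json`. Deterministic: the same config and
#' seed give hash-identical outputs.
#'
#' @param config an `smp_config` (see [default_config()]).
#' @param seed overrides `config$seed` if given.
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with `truth`, `mask`, `stack` and `paths`.
#' @export
simulate_phantom <- function(config = default_config(), seed = NULL, outdir) {
  seed <- as.integer(seed %||% config$seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gen <- config$generator
  rnd <- config$render
  spacing <- voxel_spacing(rnd$dx, rnd$dy, rnd$dz)
  morph <- if (identical(gen$kind, "segment")) {
    segment_phantom(target_length = gen$target_length, field = unlist(rnd$extent))
  } else {
    generate_spindle_swc(spindle_params(seed = derive_seed(seed, "morphology")))
  }
  truth <- decorate_with_spines(
    morph, density_per_um = gen$density_per_um,
    class_mix = unlist(gen$class_mix), grouping = gen$grouping,
    seed = seed, spinule_fraction = gen$spinule_fraction,
    n_spines = gen$n_spines
  )
  mask <- voxelize_truth(truth, spacing, extent = unlist(rnd$extent), origin = c(0, 0, 0))
  stack <- render_stack(truth, spacing,
                        psf_sigma_xy = rnd$psf_sigma_xy, psf_sigma_z = rnd$psf_sigma_z,
                        bg_level = rnd$bg_level, fg_level = rnd$fg_level,
                        speckle_density = rnd$speckle_density,
                        illumination_gradient = rnd$illumination_gradient,
                        noise_sd = rnd$noise_sd,
                        seed = derive_seed(seed, "render"), mask = mask)
  paths <- list(
    swc = file.path(outdir, "phantom.swc"),
    stack = file.path(outdir, "stack.tif"),
    truth_mask = file.path(outdir, "truth_mask.tif"),
    truth_csv = file.path(outdir, "truth_spines.csv"),
    truth_json = file.path(outdir, "truth.json")
  )
  write_swc(morph, paths$swc, comment = "spindlemorph phantom morphology")
  write_stack(stack, paths$stack)
  write_mask(mask, paths$truth_mask)
  spines_flat <- truth$spines %>% select(-"geom")
  write.csv(spines_flat, paths$truth_csv, row.names = FALSE)
  jsonlite::write_json(
    list(density_per_um = truth$density_per_um,
         decorated_length = truth$decorated_length,
         n_spines = nrow(truth$spines), seed = seed,
         class_counts = as.list(table(truth$spines$class_label))),
    paths$truth_json, auto_unbox = TRUE, digits = NA
  )
  write_manifest(outdir, config, seed,
                 stages = list(list(stage = "simulate",
                                    params = list(generator = gen, render = rnd))),
                 outputs = unlist(paths, use.names = FALSE))
  invisible(list(truth = truth, mask = mask, stack = stack, paths = paths))
}

#' Run the full analysis pipeline on a stack
#'
#' Reconstruct -> classify -> density, plus morphometry when an SWC is given.
#' Writes `mask.tif`, `spines.csv`, `report.json` and `manifest.json` to
#' `outdir`. Stage failures abort with a stage-tagged message.
#'
#' @param stack an [image_stack()] or path to a TIFF (with spacing sidecar).
#' @param config an `smp_config`.
#' @param outdir output directory.
#' @param swc optional [neuron_morphology()] or SWC path for morphometry.
#' @param vertical_axis pial direction for the spindle qualifier.
#' @return Invisibly, a list: `volume`, `spines`, `density`, `morphometry`
#'   (or NULL), `paths`.
#' @export
run_pipeline <- function(stack, config = default_config(), outdir,
                         swc = NULL, vertical_axis = c(0, 1, 0)) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character()
  if (is.character(stack)) {
    inputs <- c(inputs, stack)
    stack <- read_stack(stack)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  pcfg <- do.call(pipeline_config, config$pipeline)
  rules <- do.call(spine_rules, config$rules)
  volume <- stage("reconstruct", reconstruct_spines(stack, pcfg))
  spines <- stage("classify", classify_spines(volume, rules = rules))
  dens <- if (nrow(spines) == 0 && (attr(spines, "axis_length_um") %||% 0) <= 0) {
    list(density_per_um = 0, band = "sparse", n_spines = 0L, length_um = 0,
         per_class = tibble(class = character(), n = integer(),
                            density_per_um = numeric()))
  } else {
    stage("density", spine_density(spines, bins = unlist(config$density_bins)))
  }
  morpho <- NULL
  if (!is.null(swc)) {
    if (is.character(swc)) {
      inputs <- c(inputs, swc)
      swc <- read_swc(swc)
    }
    # the spindle qualifier needs a soma and primary dendrites; isolated
    # dendritic segments still get the cylinder-model metrics
    qual <- tryCatch(classify_spindle(swc, vertical_axis = vertical_axis),
                     error = function(e) NULL)
    morpho <- stage("morphometry", list(
      report = morphometry_report(swc),
      spindle = qual
    ))
  }
  paths <- list(mask = file.path(outdir, "mask.tif"),
                spines = file.path(outdir, "spines.csv"),
                report = file.path(outdir, "report.json"))
  write_mask(volume, paths$mask)
  write.csv(as.data.frame(spines), paths$spines, row.names = FALSE)
  report <- list(
    stages = volume$provenance,
    summary = attr(volume, "summary"),
    density = dens[c("density_per_um", "band", "n_spines", "length_um")],
    per_class = as.list(setNames(dens$per_class$n, dens$per_class$class))
  )
  if (!is.null(morpho)) {
    report$morphometry <- as.list(as_tibble(unclass(morpho$report))[1, ])
    if (!is.null(morpho$spindle)) {
      report$spindle <- list(is_spindle = morpho$spindle$is_spindle,
                             criteria = morpho$spindle$criteria)
    }
  }
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  write_manifest(outdir, config, config$seed,
                 stages = volume$provenance,
                 outputs = unlist(paths, use.names = FALSE), inputs = inputs)
  invisible(list(volume = volume, spines = spines, density = dens,
                 morphometry = morpho, paths = paths))
}

#' Replay a run from its manifest
#'
#' Re-executes [run_pipeline()] with the config snapshot stored in a
#' manifest. Deterministic stages reproduce byte-identical outputs.
#'
#' @param manifest_path path to a `manifest.json` written by [run_pipeline()].
#' @param stack the input stack (object or path), as in the original run.
#' @param outdir output directory for the replay.
#' @return See [run_pipeline()].
#' @export
replay_manifest <- function(manifest_path, stack, outdir) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- default_config()
  for (sec in intersect(names(man$config), names(cfg))) {
    if (is.list(cfg[[sec]])) {
      cfg[[sec]][names(man$config[[sec]])] <- man$config[[sec]]
    } else {
      cfg[[sec]] <- man$config[[sec]]
    }
  }
  run_pipeline(stack, cfg, outdir)
}

#' Validate an SWC file
#'
#' @param path SWC path.
#' @return A list `valid`/`message`; `valid = TRUE` when the file parses and
#'   the tree invariants hold.
#' @export
validate_swc <- function(path) {
  res <- tryCatch({
    m <- read_swc(path)
    list(valid = TRUE, message = sprintf("%d nodes, root id %d",
                                         nrow(m), m$id[m$parent == -1L]))
  }, error = function(e) list(valid = FALSE, message = conditionMessage(e)))
  res
}
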