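# Chain skull stripping, tissue segmentation, region extraction, cortical
# reconstruction and equivolumetric layering into one reproducible run.

#' Pipeline configuration
#'
#' Collects every stage parameter of [run_cortex_pipeline()] with its
#' default. Any entry can be overridden by name.
#'
#' @param region extraction target (see [region_recipes()]).
#' @param n_layers number of laminae.
#' @param structures active label table (default: the single-hemisphere
#'   phantom set: background, csf, gm_left, wm_left, subcortex_left,
#'   ventricle_left).
#' @param tissue_params intensity parameters used to register the pipeline's
#'   contrast models (see [default_tissue_params()]).
#' @param noise_sd noise multiplier the contrast models should assume.
#' @param prior optional list of per-structure prior probability volumes
#'   (e.g. [hemisphere_priors()] for two-hemisphere data).
#' @param skullstrip,mgdm,cruise,layering named lists of stage parameters
#'   passed through to the stage functions.
#' @param save_data,output_dir,file_name,overwrite saving controls; every
#'   stage's outputs are written via [save_output_set()] when `save_data`.
#' @export
pipeline_config <- function(region = "left_cerebrum", n_layers = 4,
                            structures = NULL,
                            tissue_params = default_tissue_params(),
                            noise_sd = 0.1, prior = NULL,
                            skullstrip = list(), mgdm = list(),
                            cruise = list(), layering = list(),
                            save_data = FALSE, output_dir = NULL,
                            file_name = "phantom", overwrite = FALSE) {
  if (is.null(structures)) {
    lt <- phantom_labels()
    structures <- lt[lt$id <= 5L, ]
  }
  structure(list(
    region = region, n_layers = n_layers, structures = structures,
    tissue_params = tissue_params, noise_sd = noise_sd, prior = prior,
    skullstrip = skullstrip, mgdm = mgdm, cruise = cruise,
    layering = layering, save_data = isTRUE(save_data),
    output_dir = output_dir, file_name = file_name,
    overwrite = isTRUE(overwrite)), class = "cx_pipelineconfig")
}

#' Soft left/right hemisphere priors
#'
#' Builds a per-structure prior stack that disambiguates mirror-symmetric
#' intensity models: structures named `*_left` are favoured on the low-x
#' side of the grid and `*_right` on the high-x side; unlateralized
#' structures get a flat prior.
#'
#' @param proto a `cx_volume` defining the grid.
#' @param structures label table (columns `id`, `name`).
#' @param softness transition width in voxels.
#' @return List of probability `cx_volume`s, one per structure row.
#' @export
hemisphere_priors <- function(proto, structures, softness = 2) {
  d <- dim(proto$data)
  x <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  mid <- (d[1] + 1) / 2
  wl <- 1 / (1 + exp((x - mid) / softness))
  lapply(structures$name, function(nm) {
    w <- if (grepl("_left$", nm)) wl
         else if (grepl("_right$", nm)) 1 - wl
         else array(0.5, d)
    vol_like(w, proto)
  })
}

# register contrast models describing the pipeline's (masked) input images:
# class sds are scaled by the assumed noise level and the background class is
# re-centred at zero because skull stripping zeroes it
pipeline_models <- function(tissue_params, noise_sd) {
  eff <- max(noise_sd, 0.02)
  tp <- tissue_params
  for (cn in names(tp)) {
    tp[[cn]] <- lapply(tp[[cn]], function(p) c(p[1], eff * p[2]))
    tp[[cn]][["background"]] <- c(0, eff * 50)
  }
  register_phantom_models(tp, prefix = "Pipeline")
}

#' Run the full cortical processing pipeline
#'
#' Executes skull stripping, topology-preserving tissue segmentation,
#' region extraction, cortical boundary reconstruction and equivolumetric
#' layering in order, passing each stage's outputs to the next by key. The
#' run is deterministic: identical inputs and configuration give identical
#' outputs. A machine-readable run log recording all parameters is attached
#' (and saved alongside the outputs when saving is enabled); when a stage
#' fails, the error names the stage and carries the partial results in its
#' `partial` field.
#'
#' @param inv2 second-inversion `cx_volume` (drives the brain mask).
#' @param t1w,t1map optional companion `cx_volume`s; segmentation uses the
#'   masked companions when present, otherwise the masked second inversion.
#' @param config a [pipeline_config()].
#' @return Named list of stage output sets: `skullstrip`, `mgdm`,
#'   `extract`, `cruise`, `layering`, plus `log`.
#' @export
run_cortex_pipeline <- function(inv2, t1w = NULL, t1map = NULL,
                                config = pipeline_config()) {
  results <- list()
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop(errorCondition(
        sprintf("pipeline stage '%s' failed: %s", name,
                conditionMessage(e)),
        class = c("cx_pipeline_error", "cortexr_error", "error"),
        partial = results))
    })
  }
  results$skullstrip <- stage("skullstrip", function()
    do.call(mp2rage_skullstripping,
            c(list(second_inversion = inv2, t1_weighted = t1w,
                   t1_map = t1map), config$skullstrip)))
  model_names <- pipeline_models(config$tissue_params, config$noise_sd)
  contrasts <- list(); types <- character(0)
  if (!is.null(results$skullstrip$t1w_masked)) {
    contrasts <- c(contrasts, list(results$skullstrip$t1w_masked))
    types <- c(types, model_names[["t1w"]])
  }
  if (!is.null(results$skullstrip$t1map_masked)) {
    contrasts <- c(contrasts, list(results$skullstrip$t1map_masked))
    types <- c(types, model_names[["t1map"]])
  }
  if (!length(contrasts)) {
    contrasts <- list(results$skullstrip$inv2_masked)
    types <- model_names[["inv2"]]
  }
  results$mgdm <- stage("mgdm", function()
    do.call(mgdm_segmentation,
            c(list(contrasts = contrasts, contrast_types = types,
                   structures = config$structures, prior = config$prior),
              config$mgdm)))
  results$extract <- stage("extract", function()
    extract_brain_region(results$mgdm, config$region))
  results$cruise <- stage("cruise", function()
    do.call(cruise_cortex_extraction,
            c(list(init_image = results$extract$inside_mask,
                   wm_image = results$extract$inside_proba,
                   gm_image = results$extract$region_proba,
                   csf_image = results$extract$background_proba),
              config$cruise)))
  results$layering <- stage("layering", function()
    do.call(volumetric_layering,
            c(list(inner_levelset = results$cruise$gwb,
                   outer_levelset = results$cruise$cgb,
                   n_layers = config$n_layers), config$layering)))
  results$log <- list(
    package = "cortexr",
    version = as.character(utils::packageVersion("cortexr")),
    region = config$region, n_layers = config$n_layers,
    structures = config$structures$name,
    noise_sd = config$noise_sd,
    stage_parameters = list(skullstrip = config$skullstrip,
                            mgdm = config$mgdm, cruise = config$cruise,
                            layering = config$layering),
    contrast_types = types)
  if (config$save_data) {
    if (is.null(config$output_dir))
      cx_stop("output_dir is required when save_data is set",
              "cx_validation_error")
    for (nm in c("skullstrip", "mgdm", "extract", "cruise", "layering"))
      save_output_set(results[[nm]], config$output_dir, config$file_name,
                      overwrite = config$overwrite)
    jsonlite::write_json(
      results$log,
      file.path(config$output_dir,
                paste0(config$file_name, "_pipeline_log.json")),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  results
}
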