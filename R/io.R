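# Configuration files and simple columnar exports.

#' Write a model configuration to YAML
#'
#' Parameter names mirror the model parameter tables (e.g. `C_m`, `g_L`,
#' `tau_Iw`, `cp_PP`, `r_th`).
#'
#' @param config see [default_config()]
#' @param path output file
#' @export
write_config <- function(config, path) {
  ser <- lapply(config, function(x) {
    x <- unclass(x)
    if (is.numeric(x)) as.list(x) else
      lapply(x, function(v) if (length(v) > 1) as.list(v) else v)
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Read a model configuration from YAML
#'
#' Unknown keys are rejected; missing sections fall back to defaults.
#'
#' @param path YAML file written by [write_config()] or hand-edited
#' @return parameter bundle as [default_config()]
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  ctors <- list(neuron = neuron_params, basket = basket_params,
                receptor = receptor_params, stp = stp_params,
                bcpnn = bcpnn_params, stdp = stdp_params,
                layout = layout_params, connectivity = connectivity_params,
                stimulation = stimulation_params, ema = ema_params,
                sim = sim_params)
  for (nm in names(raw)) {
    if (!nm %in% names(ctors)) stop("unknown config section: ", nm)
    args <- lapply(raw[[nm]], function(v) if (is.list(v)) unlist(v) else v)
    cfg[[nm]] <- do.call(ctors[[nm]], args)
  }
  cfg
}

#' Write a spike raster as two-column text
#' @param raster data.frame with `time` (ms) and `neuron`
#' @param path output file
#' @export
write_raster <- function(raster, path) {
  write.table(raster[, c("time", "neuron")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a recall table as CSV
#' @param recall data.frame (e.g. `run_experiment()$recall`)
#' @param path output file
#' @export
write_recall <- function(recall, path) {
  utils::write.csv(recall, path, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run manifest with full parameter provenance
#'
#' @param config experiment configuration
#' @param model_config model parameter bundle
#' @param seed base seed
#' @param path output file
#' @export
write_manifest <- function(config, model_config, seed, path) {
  man <- list(variant = config$variant, rule = config$rule,
              n_trials = config$n_trials, seed = seed,
              parameters = lapply(model_config, unclass),
              package_version = as.character(utils::packageVersion("semnet")))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
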