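# Run configuration: one nested YAML document with blocks for the
# generator, preprocessing chain, model and training protocol.  Unknown
# keys are rejected so silent typos cannot change a run, and a config
# round-trips losslessly through YAML.

#' Default run configuration
#'
#' @return Nested list with blocks `generator`, `preprocess`, `model`,
#'   `training`, plus a global `seed` and `out_dir`.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "runs",
    generator = list(
      image_width = 480L, image_height = 270L,
      noise_sigma = 4, salt_pepper_fraction = 0.002,
      n_per_class = list(unfertilized = 10L, live = 10L, abnormal = 10L)),
    preprocess = list(
      median_kernel = 5L, otsu_offset = 100L, bbox_scale = 1.1,
      input_size = 224L),
    model = list(
      depth = 34L, attention = "cbam", reduction = 16L, ca_reduction = 32L,
      spatial_kernel = 7L, width_factor = 1),
    training = list(
      epochs = 50L, batch_size = 16L, learning_rate = 0.001,
      split = c(0.6, 0.2, 0.2), flip = TRUE, normalize = TRUE)
  )
}

check_known_keys <- function(cfg, ref, path = "") {
  if (!is.list(cfg)) return(invisible(TRUE))
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra))
    stopf("unknown config key%s: %s", if (length(extra) > 1) "s" else "",
          paste0(path, extra, collapse = ", "))
  for (nm in names(cfg))
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])))
      check_known_keys(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
  invisible(TRUE)
}

#' Validate and complete a run configuration
#'
#' Merges a partial configuration over [default_config()], rejecting
#' unknown keys at any nesting level.
#'
#' @param config Partial nested list (or NULL for the defaults).
#' @return The completed configuration.
#' @export
validate_config <- function(config = NULL) {
  ref <- default_config()
  if (is.null(config)) return(ref)
  check_known_keys(config, ref)
  modifyList(ref, config)
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param config Configuration list.
#' @return `load_config()` returns the validated configuration;
#'   `save_config()` returns `path` invisibly.
#' @export
load_config <- function(path) validate_config(yaml::read_yaml(path))

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# short content hash of a config, for run-directory provenance
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config, tf)
  substr(unname(tools::md5sum(tf)), 1L, 8L)
}

# build the module-level parameter objects from the config blocks
config_generator_params <- function(config) {
  g <- config$generator
  generator_params(image_width = g$image_width, image_height = g$image_height,
                   noise_sigma = g$noise_sigma,
                   salt_pepper_fraction = g$salt_pepper_fraction,
                   seed = config$seed)
}

config_preprocess <- function(config) {
  p <- config$preprocess
  preprocess_config(median_kernel = p$median_kernel,
                    otsu_offset = p$otsu_offset,
                    bbox_scale = p$bbox_scale,
                    input_size = p$input_size)
}

config_model_spec <- function(config) {
  m <- config$model
  model_spec(depth = m$depth, attention = m$attention,
             reduction = m$reduction, ca_reduction = m$ca_reduction,
             spatial_kernel = m$spatial_kernel,
             width_factor = m$width_factor,
             input_size = config$preprocess$input_size)
}

config_training <- function(config) {
  t <- config$training
  candle_config(epochs = t$epochs, batch_size = t$batch_size,
                learning_rate = t$learning_rate, split = unlist(t$split),
                flip = t$flip, normalize = t$normalize,
                seed = config$seed)
}
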