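#' Read a pipeline configuration from YAML
#'
#' Builds the configuration objects of the pipeline from one YAML file
#' with optional top-level sections `phantom`, `simulator`, `model` and
#' `training`; unspecified fields keep the package defaults.
#'
#' Example:
#' ```yaml
#' phantom:
#'   lung_radius_range: [0.3, 0.6]
#'   heart_radius_range: [0.1, 0.3]
#' simulator:
#'   mesh_elements: 1024
#' model:
#'   depth: 4
#'   base_channels: 16
#' training:
#'   epochs: 60
#'   wc_grid: [1.0, 1.5, 1.8, 2.0]
#' ```
#'
#' @param path path to the YAML file.
#' @return list with elements `phantom` ([phantom_config()]),
#'   `simulator` (argument list for [eit_simulator()]), `model`
#'   ([model_spec()]) and `training` ([training_config()]).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  mk <- function(fn, args) do.call(fn, args %||% list())
  ph <- raw$phantom %||% list()
  if (!is.null(ph$lung_centers)) ph$lung_centers <- matrix(unlist(ph$lung_centers), 2, 2, byrow = TRUE)
  list(phantom = mk(phantom_config, ph),
       simulator = raw$simulator %||% list(),
       model = mk(model_spec, raw$model),
       training = mk(training_config, raw$training))
}
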