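## YAML run configuration shared by the CLI and the experiment drivers.

#' Default run configuration
#'
#' @return A nested list mirroring the YAML config sections: `cohort`,
#'   `registration`, `model_a`, `model_b`, `transfer`, `rom`.
#' @export
default_config <- function() {
  list(
    cohort = list(n_healthy = 28L, n_inph = 12L, master_seed = 1L,
                  image_shape = c(160L, 160L), voxel_size = 1.0, mesh_h = 1.5),
    registration = list(backend = "analytic", levels = c(4L, 2L, 1L),
                        iterations = 100L, sigma_update = 1.0,
                        sigma_total = 1.5),
    model_a = unclass(model_a_params()),
    model_b = list(B_in = 2.0, Q_prod = 0.33 * ML_MIN_MM3_S,
                   p_DS = 8.4 * MMHG_PA, p_CSF = 10 * MMHG_PA,
                   beta1 = 1e-3, beta2 = 1e-3, beta3 = 1e-7),
    transfer = list(k_neighbors = 8L, sigma_factor = 1.0),
    rom = list(d_values = c(2L, 5L, 10L, 20L, 30L), subsets = "full")
  )
}

#' Read a run configuration
#'
#' Reads a YAML file and merges it over [default_config()]; missing keys
#' take their defaults.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return The merged configuration list with a `hash` attribute.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (sec in names(user)) {
      if (is.list(user[[sec]]) && sec %in% names(cfg)) {
        cfg[[sec]][names(user[[sec]])] <- user[[sec]]
      } else {
        cfg[[sec]] <- user[[sec]]
      }
    }
  }
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

#' Write a configuration to YAML
#' @param cfg configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  attr(cfg, "hash") <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# order-independent content hash for provenance stamping
config_hash <- function(cfg) {
  attr(cfg, "hash") <- NULL
  s <- yaml::as.yaml(cfg[order(names(cfg))])
  sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 997)) %% 4294967291)
}

config_cohort_spec <- function(cfg) {
  co <- cfg$cohort
  cohort_spec(co$n_healthy, co$n_inph, co$master_seed,
              unlist(co$image_shape), co$voxel_size, co$mesh_h)
}

config_params_a <- function(cfg) do.call(model_a_params, cfg$model_a)
config_params_b <- function(cfg) do.call(model_b_params, cfg$model_b)
config_reg_opts <- function(cfg) {
  r <- cfg$registration
  register_opts(unlist(r$levels), r$iterations, r$sigma_update, r$sigma_total)
}
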