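## Run configuration: nested defaults, YAML override.

#' Default pipeline configuration
#'
#' Every numeric default of the pipeline, overridable per section via
#' \code{\link{load_config}}.
#' @export
stip_config <- function() {
  list(
    scale_space = list(n_scales = 8L, step = 0.15, substeps = 4L,
                       conductance_k = NULL,
                       conductance_form = "exponential"),
    detector = list(type = "hessian_temporal", kappa = 0.005, sigma_i = 2,
                    tau_i = 1, min_strength_rel = 1e-3, connectivity = 8L),
    scale_selection = list(rule = "elbow_max_d2"),
    motion = list(alpha = NULL, rho = 2, n_iters = 200, pyramid_levels = 2L),
    segmentation = list(bandwidth_rel = 0.5, min_superpixel_px = 5L,
                        connectivity = 4L, marker_tol = 0.02),
    detection = list(expected_radius = 6, eps_percentile = 0.15, min_pts = 10L,
                     epochs = 200L, lr = 1e-2, batch = 64L, seed = 1L),
    refinement = list(n_iters = 50L, nu = NULL, window = 7L,
                      solidity_threshold = 0.95, hmax = 0.5),
    tracking = list(reject_threshold = 0.1, fallback_sigma_rel = 1,
                    max_daughters = 2L),
    metrics = list(weights = list(ns = 5, fn = 10, fp = 1, ed = 1, ea = 1.5,
                                  ec = 1))
  )
}

#' Load a YAML configuration over the defaults
#' @param path YAML file with any subset of the sections of
#'   \code{\link{stip_config}}; missing keys keep their defaults.
#' @export
load_config <- function(path = NULL) {
  cfg <- stip_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  modifyList(cfg, user)
}
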