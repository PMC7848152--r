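#' Run the phantom-to-comparison perfusion pipeline
#'
#' Convenience driver chaining the full prediction pipeline on the synthetic
#' phantom: generate the labelled slice, calibrate porosity with the
#' phantom's known air/cortical greyscale levels, compute one
#' porosity-weighted geodesic map per inlet (two junctional-epithelium
#' points, one inferior alveolar canal), combine them, flag the
#' slow-diffusion regions, then run the tracer simulation from the same
#' inlets and compare map and simulation by rank correlation. The map and
#' simulation domains are restricted to tissue (non-air pixels): medium
#' enters the model only through the three inlets.
#'
#' @param params [phantom_params()] for the phantom.
#' @param band_width contour band width, mm (default 1).
#' @param config [sim_config()] for the tracer simulation.
#' @param slow_quantile quantile defining the slow-region mask
#'   (default 0.9).
#' @param simulate set `FALSE` to skip the tracer simulation and comparison
#'   (map only).
#' @return List of class `perfusion_pipeline`: `phantom`, `porosity`,
#'   `inlet_maps`, `map` (combined), `slow_mask`, and (when simulated)
#'   `field` and `comparison`.
#' @export
run_perfusion_pipeline <- function(params = phantom_params(),
                                   band_width = 1,
                                   config = sim_config(),
                                   slow_quantile = 0.9,
                                   simulate = TRUE) {
  phantom <- make_phantom(params)
  porosity <- calibrate_porosity(phantom$slice,
                                 air_endpoint = params$levels[["air"]],
                                 cortical_endpoint = params$levels[["cortical"]])
  domain <- !phantom_mask(phantom, "air")
  inlet_maps <- lapply(seq_len(nrow(phantom$inlets)), function(i)
    weighted_geodesic_map(porosity, phantom$inlets[i, ],
                          band_width = band_width, domain = domain))
  map <- combine_inlet_maps(inlet_maps)
  out <- list(phantom = phantom, porosity = porosity,
              inlet_maps = inlet_maps, map = map,
              slow_mask = slow_region_mask(map, slow_quantile))
  if (simulate) {
    out$field <- simulate_tracer(porosity, phantom$inlets, config,
                                 domain = domain)
    out$comparison <- compare_map_to_sim(map, out$field, slow_quantile)
  }
  structure(out, class = "perfusion_pipeline")
}
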