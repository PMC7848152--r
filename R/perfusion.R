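#' Tracer simulation configuration
#'
#' Settings for the in-silico ink test: an explicit finite-difference
#' solution of the heterogeneous diffusion equation
#' `dc/dt = div(D(x) grad c)` with `D(x) = D0 * porosity(x)`.
#'
#' The 18 h default duration matches the window over which ink diffusion was
#' assessed in the culture system (18-21 h). `D0` is a working parameter
#' chosen so that a uniform soft-tissue medium perfuses fully within that
#' window; map-vs-simulation comparisons are rank-based, so its exact value
#' has little influence.
#'
#' @param D0 base diffusivity at porosity 1, mm^2/h.
#' @param duration simulated time, hours (default 18).
#' @param time_step explicit time step, hours; `NULL` picks 90% of the
#'   stability bound `h^2 / (4 * D0 * max(porosity))`.
#' @param arrival_threshold fraction of the source concentration at which a
#'   pixel counts as reached (ink visible), default 0.1.
#' @param source_concentration tracer concentration held at the inlets.
#' @param source_duration hours during which the inlets are held at the
#'   source concentration (Dirichlet); `Inf` (default) holds them for the
#'   whole run. Finite values release the sources afterwards, which makes
#'   total tracer mass exactly conserved from that time on.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(D0 = 2.0, duration = 18, time_step = NULL,
                       arrival_threshold = 0.1, source_concentration = 1,
                       source_duration = Inf) {
  stopifnot(D0 > 0, duration > 0,
            arrival_threshold > 0, arrival_threshold < 1,
            source_concentration > 0, source_duration > 0)
  if (!is.null(time_step)) stopifnot(time_step > 0)
  structure(list(D0 = D0, duration = duration, time_step = time_step,
                 arrival_threshold = arrival_threshold,
                 source_concentration = source_concentration,
                 source_duration = source_duration),
            class = "sim_config")
}

#' Simulate tracer diffusion from the inlets (in-silico ink test)
#'
#' Explicit FTCS integration of `dc/dt = div(D grad c)` on the porosity
#' grid, with `D = D0 * porosity`, harmonic-mean interface diffusivities
#' (correct flux across sharp porosity jumps such as the cortical boundary),
#' zero-flux outer boundaries, and the inlet pixels held at the source
#' concentration. Records each pixel's first-arrival time: the earliest
#' simulated time its concentration reaches `arrival_threshold *
#' source_concentration`.
#'
#' @param porosity a `porosity_map`; pixels below its impermeable threshold
#'   get zero diffusivity.
#' @param inlets data frame with columns `row`, `col` (e.g. the phantom's
#'   inlet table); all must be permeable.
#' @param config a [sim_config()].
#' @param domain optional logical matrix; pixels outside get zero
#'   diffusivity.
#' @return An object of class `arrival_field`: list with matrices `arrival`
#'   (hours; `Inf` where the threshold was never reached) and
#'   `final_concentration`, the per-step total `mass` trace, `times` (the
#'   step grid), and the `config`.
#' @export
simulate_tracer <- function(porosity, inlets, config = sim_config(),
                            domain = NULL) {
  stopifnot(inherits(porosity, "porosity_map"), inherits(config, "sim_config"))
  if (any(!is.finite(porosity$porosity)))
    stop("non-finite porosity values in the map")
  porosity <- apply_domain(porosity, domain)
  inlets <- check_inlets(porosity, inlets)

  por <- porosity$porosity
  por[por < porosity$impermeable_threshold] <- 0
  D <- config$D0 * por
  h <- porosity$pixel_size
  bound <- h^2 / (4 * max(D))
  dt <- config$time_step
  if (is.null(dt)) dt <- 0.9 * bound
  if (dt > bound)
    stop(sprintf(paste0("unstable time step: dt = %g h exceeds the explicit ",
                        "stability bound h^2 / (4 Dmax) = %g h"), dt, bound))
  nsteps <- as.integer(ceiling(config$duration / dt))
  freeze_step <- if (is.finite(config$source_duration))
    as.integer(ceiling(config$source_duration / dt)) else nsteps + 1L

  res <- ftcs_diffuse_cpp(D, inlets$row, inlets$col, h, dt, nsteps,
                          config$source_concentration,
                          config$arrival_threshold, freeze_step)
  structure(list(arrival = res$arrival,
                 final_concentration = res$concentration,
                 mass = as.numeric(res$mass),
                 times = seq(0, by = dt, length.out = nsteps + 1L),
                 config = config, inlets = inlets, pixel_size = h),
            class = "arrival_field")
}

#' @export
print.arrival_field <- function(x, ...) {
  fin <- x$arrival[is.finite(x$arrival)]
  cat(sprintf(paste0("<arrival_field> %d x %d pixels; %.1f h simulated in ",
                     "%d steps\n  %.1f%% of pixels reached; arrival range ",
                     "[%.2f, %.2f] h\n"),
              nrow(x$arrival), ncol(x$arrival), max(x$times),
              length(x$times) - 1L, 100 * mean(is.finite(x$arrival)),
              min(fin), max(fin)))
  invisible(x)
}

#' Compare the weighted diffusion map with the tracer simulation
#'
#' Rank-based concordance between the predicted porosity-weighted cost and
#' the simulated first-arrival time, restricted to pixels reached in both
#' representations. Also reports how many pixels are reached in exactly one
#' of the two, and the Jaccard overlap of the two slow-region masks (upper
#' cost/arrival quantile on the mutually reached set).
#'
#' @param map a `diffusion_map`.
#' @param field an `arrival_field` on the same grid.
#' @param slow_quantile quantile defining both slow-region masks
#'   (default 0.9).
#' @return A list of class `map_sim_comparison`: `spearman`, `n_mutual`,
#'   `only_map`, `only_sim`, `jaccard_slow`, `slow_quantile`.
#' @export
compare_map_to_sim <- function(map, field, slow_quantile = 0.9) {
  stopifnot(inherits(map, "diffusion_map"), inherits(field, "arrival_field"))
  if (!all(dim(map$cost) == dim(field$arrival)))
    stop("map and simulation grids have different shapes")
  sim_reached <- is.finite(field$arrival)
  mutual <- map$reachable & sim_reached
  n <- sum(mutual)
  if (n < 10L)
    stop("fewer than 10 pixels are reached in both the map and the ",
         "simulation; comparison is meaningless")
  cost <- map$cost[mutual]
  arr <- field$arrival[mutual]
  rho <- cor(cost, arr, method = "spearman")
  qc <- stats::quantile(cost, slow_quantile, names = FALSE)
  qa <- stats::quantile(arr, slow_quantile, names = FALSE)
  slow_map <- cost > qc
  slow_sim <- arr > qa
  uni <- sum(slow_map | slow_sim)
  structure(list(spearman = rho, n_mutual = n,
                 only_map = sum(map$reachable & !sim_reached),
                 only_sim = sum(sim_reached & !map$reachable),
                 jaccard_slow = if (uni > 0) sum(slow_map & slow_sim) / uni
                                else NA_real_,
                 slow_quantile = slow_quantile),
            class = "map_sim_comparison")
}

#' @export
print.map_sim_comparison <- function(x, ...) {
  cat(sprintf(paste0("<map_sim_comparison> Spearman rho = %.3f on %d ",
                     "mutually reached pixels\n  reached only in map: %d; ",
                     "only in simulation: %d\n  slow-region Jaccard overlap ",
                     "(q = %.2f): %.3f\n"),
              x$spearman, x$n_mutual, x$only_map, x$only_sim,
              x$slow_quantile, x$jaccard_slow))
  invisible(x)
}
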