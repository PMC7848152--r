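#' Greyscale slice
#'
#' A 2D grid of greyscale intensities with a physical pixel size, the raster
#' substrate for porosity calibration. Intensities are arbitrary scanner
#' units; by convention greyscale is proportional to mineral density.
#'
#' @param intensities numeric matrix of intensities (rows = image rows).
#' @param pixel_size physical size of one pixel in mm; must be positive.
#' @return An object of class `greyscale_slice`: a list with elements
#'   `intensities` and `pixel_size`.
#' @examples
#' s <- greyscale_slice(matrix(0:255, 16, 16), pixel_size = 0.0492)
#' @export
greyscale_slice <- function(intensities, pixel_size) {
  if (!is.matrix(intensities) || !is.numeric(intensities) ||
      length(intensities) == 0L)
    stop("`intensities` must be a non-empty numeric matrix")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (mm/pixel)")
  structure(list(intensities = intensities, pixel_size = pixel_size),
            class = "greyscale_slice")
}

#' @export
print.greyscale_slice <- function(x, ...) {
  cat(sprintf("<greyscale_slice> %d x %d pixels, %.4f mm/pixel, range [%g, %g]\n",
              nrow(x$intensities), ncol(x$intensities), x$pixel_size,
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Calibrate a greyscale slice to a porosity map
#'
#' Linear two-endpoint calibration: a pixel at the air endpoint intensity has
#' porosity 1 (100%), a pixel at the cortical endpoint has porosity 0, and
#' intermediate intensities interpolate linearly,
#' `porosity = (cortical - g) / (cortical - air)`, clamped to \[0, 1\] outside
#' the endpoint range. Porosity is stored as a fraction; multiply by 100 for
#' percent.
#'
#' @param slice a [greyscale_slice].
#' @param air_endpoint intensity mapping to 100% porosity (extracellular
#'   space / air).
#' @param cortical_endpoint intensity mapping to 0% porosity (dense cortical
#'   bone); must exceed `air_endpoint`.
#' @param impermeable_threshold porosity fraction below which a pixel is
#'   treated as blocked by downstream mapping (default 0.01). Prevents
#'   division by near-zero porosity in the weighted-path cost.
#' @return An object of class `porosity_map`: list with `porosity` matrix
#'   (fractions), `pixel_size`, the two endpoints and the threshold.
#' @examples
#' s <- greyscale_slice(matrix(c(0, 50, 100), 1), pixel_size = 0.05)
#' p <- calibrate_porosity(s, air_endpoint = 0, cortical_endpoint = 100)
#' p$porosity  # 1.0, 0.5, 0.0
#' @export
calibrate_porosity <- function(slice, air_endpoint, cortical_endpoint,
                               impermeable_threshold = 0.01) {
  stopifnot(inherits(slice, "greyscale_slice"))
  if (!is.finite(air_endpoint) || !is.finite(cortical_endpoint))
    stop("calibration endpoints must be finite")
  if (air_endpoint >= cortical_endpoint)
    stop("calibration error: air endpoint must be strictly below the ",
         "cortical endpoint (got ", air_endpoint, " >= ", cortical_endpoint, ")")
  g <- slice$intensities
  por <- (cortical_endpoint - g) / (cortical_endpoint - air_endpoint)
  por <- matrix(pmin(1, pmax(0, por)), nrow(g), ncol(g))
  structure(list(porosity = por,
                 pixel_size = slice$pixel_size,
                 air_endpoint = air_endpoint,
                 cortical_endpoint = cortical_endpoint,
                 impermeable_threshold = impermeable_threshold),
            class = "porosity_map")
}

#' @export
print.porosity_map <- function(x, ...) {
  cat(sprintf(paste0("<porosity_map> %d x %d pixels, %.4f mm/pixel\n",
                     "  endpoints: air = %g, cortical = %g; blocked below %.3f\n",
                     "  porosity range [%.3f, %.3f], %.1f%% blocked\n"),
              nrow(x$porosity), ncol(x$porosity), x$pixel_size,
              x$air_endpoint, x$cortical_endpoint, x$impermeable_threshold,
              min(x$porosity), max(x$porosity),
              100 * mean(x$porosity < x$impermeable_threshold)))
  invisible(x)
}

#' Estimate calibration endpoints from the slice itself
#'
#' When explicit air/cortical endpoint intensities are unknown, take them as
#' intensity quantiles of the slice. The defaults (0.01, 0.99) are robust to
#' speckle; quantiles 0 and 1 reproduce the exact image minimum/maximum.
#'
#' @param slice a [greyscale_slice].
#' @param low_quantile,high_quantile quantiles in \[0, 1\] with
#'   `low_quantile < high_quantile`.
#' @return Named numeric vector `c(air_endpoint =, cortical_endpoint =)`.
#' @export
estimate_endpoints <- function(slice, low_quantile = 0.01,
                               high_quantile = 0.99) {
  stopifnot(inherits(slice, "greyscale_slice"))
  if (!(low_quantile >= 0 && low_quantile < high_quantile && high_quantile <= 1))
    stop("quantiles must satisfy 0 <= low < high <= 1")
  q <- quantile(slice$intensities, c(low_quantile, high_quantile),
                names = FALSE, type = 7)
  if (q[1] >= q[2])
    stop("endpoint estimation failed: the intensity quantiles coincide ",
         "(constant or near-constant image)")
  c(air_endpoint = q[1], cortical_endpoint = q[2])
}
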