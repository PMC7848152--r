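#' @keywords internal
new_diffusion_map <- function(cost, band_width, pixel_size, inlets,
                              weighted) {
  reachable <- is.finite(cost)
  band <- matrix(NA_integer_, nrow(cost), ncol(cost))
  # 1-based bands on half-open intervals [k*w, (k+1)*w); a cost exactly on a
  # boundary belongs to the upper band
  band[reachable] <- as.integer(floor(cost[reachable] / band_width)) + 1L
  structure(list(cost = cost, band = band, reachable = reachable,
                 band_width = band_width, pixel_size = pixel_size,
                 inlets = inlets, weighted = weighted),
            class = "diffusion_map")
}

#' @export
print.diffusion_map <- function(x, ...) {
  fin <- x$cost[x$reachable]
  cat(sprintf(paste0("<diffusion_map> (%s) %d x %d pixels, %.4f mm/pixel, ",
                     "band width %g mm\n  %d inlet(s); %.1f%% reachable; ",
                     "cost range [%.2f, %.2f] effective mm; max band %d\n"),
              if (x$weighted) "porosity-weighted" else "tissue depth",
              nrow(x$cost), ncol(x$cost), x$pixel_size, x$band_width,
              nrow(x$inlets), 100 * mean(x$reachable),
              min(fin), max(fin), max(x$band, na.rm = TRUE)))
  invisible(x)
}

check_inlets <- function(porosity, inlets) {
  if (is.numeric(inlets) && length(inlets) == 2L)
    inlets <- data.frame(row = inlets[1], col = inlets[2])
  stopifnot(is.data.frame(inlets), all(c("row", "col") %in% names(inlets)),
            nrow(inlets) >= 1L)
  nr <- nrow(porosity$porosity); nc <- ncol(porosity$porosity)
  if (any(inlets$row < 1 | inlets$row > nr | inlets$col < 1 | inlets$col > nc))
    stop("inlet coordinates fall outside the grid")
  if (anyDuplicated(inlets[c("row", "col")]))
    stop("inlet points must be distinct")
  por <- porosity$porosity[cbind(inlets$row, inlets$col)]
  if (any(por < porosity$impermeable_threshold))
    stop("inlet lies on a blocked pixel (porosity below the impermeable ",
         "threshold)")
  inlets
}

apply_domain <- function(porosity, domain) {
  if (is.null(domain)) return(porosity)
  stopifnot(is.logical(domain),
            all(dim(domain) == dim(porosity$porosity)))
  porosity$porosity[!domain] <- 0
  porosity
}

#' Porosity-weighted geodesic diffusion map from one inlet
#'
#' Computes, for every pixel, the minimum over permeable paths from the inlet
#' of the accumulated step cost `step_length (mm) / porosity`, i.e. the
#' porosity-weighted tissue depth in effective millimetres: the lower the
#' porosity (the denser the bone), the more contour bands accrue per
#' physical millimetre. Paths move on the 8-connected pixel graph (diagonal
#' steps are sqrt(2) times longer); each step is weighted by the porosity of
#' its destination pixel (or the mean of the two endpoint porosities with
#' `weight_rule = "mean"`). Pixels with porosity below the map's impermeable
#' threshold are excluded from the graph, so the cortical shell blocks all
#' paths. The cost field is quantized into 1-based contour bands of
#' `band_width` millimetres.
#'
#' @param porosity a `porosity_map` from [calibrate_porosity()].
#' @param inlet inlet pixel as `c(row, col)` or a one-row data frame with
#'   columns `row`, `col`; must be permeable.
#' @param band_width contour band width in effective mm (default 1, one
#'   contour per millimetre).
#' @param weight_rule `"destination"` (default) or `"mean"`.
#' @param domain optional logical matrix restricting the map to a tissue
#'   region (pixels outside are treated as blocked).
#' @return An object of class `diffusion_map` with matrices `cost`
#'   (effective mm; `Inf` at unreachable pixels), `band` (integer, `NA`
#'   where unreachable) and `reachable`, plus `band_width`, `pixel_size`
#'   and the inlet table.
#' @examples
#' s <- greyscale_slice(matrix(0, 5, 5), pixel_size = 1)
#' p <- calibrate_porosity(s, 0, 100)   # porosity 1 everywhere
#' m <- weighted_geodesic_map(p, c(3, 3))
#' m$cost[3, ]  # 2, 1, 0, 1, 2 mm
#' @export
weighted_geodesic_map <- function(porosity, inlet, band_width = 1,
                                  weight_rule = c("destination", "mean"),
                                  domain = NULL) {
  stopifnot(inherits(porosity, "porosity_map"), band_width > 0)
  weight_rule <- match.arg(weight_rule)
  if (any(!is.finite(porosity$porosity)))
    stop("non-finite porosity values in the map")
  porosity <- apply_domain(porosity, domain)
  inlet <- check_inlets(porosity, inlet)
  cost <- grid_dijkstra_cpp(porosity$porosity, inlet$row, inlet$col,
                            porosity$pixel_size,
                            porosity$impermeable_threshold,
                            weighted = TRUE,
                            weight_mode = if (weight_rule == "mean") 1L else 0L)
  new_diffusion_map(cost, band_width, porosity$pixel_size, inlet,
                    weighted = TRUE)
}

#' Unweighted tissue-depth contour map from one inlet
#'
#' Geodesic distance in millimetres from the inlet through permeable pixels,
#' ignoring porosity except for impermeability: the classical tissue-depth
#' contour map (distance from the gingival epithelium or the mandibular
#' canal), quantized into bands of `band_width` mm (default: one contour per
#' millimetre). Equivalent to [weighted_geodesic_map()] with porosity 1 on
#' every permeable pixel.
#'
#' @inheritParams weighted_geodesic_map
#' @return A `diffusion_map` (see [weighted_geodesic_map()]).
#' @export
depth_contour_map <- function(porosity, inlet, band_width = 1,
                              domain = NULL) {
  stopifnot(inherits(porosity, "porosity_map"), band_width > 0)
  if (any(!is.finite(porosity$porosity)))
    stop("non-finite porosity values in the map")
  porosity <- apply_domain(porosity, domain)
  inlet <- check_inlets(porosity, inlet)
  cost <- grid_dijkstra_cpp(porosity$porosity, inlet$row, inlet$col,
                            porosity$pixel_size,
                            porosity$impermeable_threshold,
                            weighted = FALSE, weight_mode = 0L)
  new_diffusion_map(cost, band_width, porosity$pixel_size, inlet,
                    weighted = FALSE)
}

#' Combine per-inlet diffusion maps into a single map
#'
#' Takes the per-pixel minimum cost across the inlet maps (a molecule
#' arrives by the easiest route); a pixel is reachable if it is reachable
#' from any inlet, and contour bands are recomputed from the combined cost.
#'
#' @param maps a list of `diffusion_map` objects sharing grid shape, pixel
#'   size and band width.
#' @return A combined `diffusion_map`.
#' @export
combine_inlet_maps <- function(maps) {
  if (!is.list(maps) || length(maps) == 0L ||
      !all(vapply(maps, inherits, logical(1), "diffusion_map")))
    stop("`maps` must be a non-empty list of diffusion_map objects")
  ref <- maps[[1]]
  for (m in maps[-1]) {
    if (!all(dim(m$cost) == dim(ref$cost)))
      stop("maps have mismatched grid shapes")
    if (m$pixel_size != ref$pixel_size || m$band_width != ref$band_width)
      stop("maps have mismatched pixel size or band width")
  }
  cost <- Reduce(pmin, lapply(maps, `[[`, "cost"))
  inlets <- unique(do.call(rbind, lapply(maps, `[[`, "inlets")))
  new_diffusion_map(cost, ref$band_width, ref$pixel_size, inlets,
                    weighted = any(vapply(maps, `[[`, logical(1), "weighted")))
}

#' Flag slow-diffusion (hard-to-reach) regions
#'
#' Marks reachable pixels whose cost strictly exceeds the given quantile of
#' the reachable cost distribution. Unreachable pixels are not part of the
#' mask; they are reported via the `unreachable` attribute.
#'
#' @param map a `diffusion_map`.
#' @param quantile fraction in \[0, 1); default 0.9 flags the slowest decile.
#' @return Logical matrix, `TRUE` on slow pixels, with attributes
#'   `threshold` (the cost cutoff) and `unreachable` (logical matrix of
#'   pixels no inlet can reach at all).
#' @export
slow_region_mask <- function(map, quantile = 0.9) {
  stopifnot(inherits(map, "diffusion_map"), quantile >= 0, quantile < 1)
  fin <- map$cost[map$reachable]
  if (length(fin) == 0L) stop("map has no reachable pixels")
  thr <- stats::quantile(fin, quantile, names = FALSE, type = 7)
  mask <- map$reachable & map$cost > thr
  attr(mask, "threshold") <- thr
  attr(mask, "unreachable") <- !map$reachable
  mask
}

#' Render a diffusion map to a PNG image
#'
#' Writes an RGB image in which each contour band gets a distinct colour
#' from a fixed sequential palette, unreachable pixels are drawn in a
#' reserved sentinel grey, and (optionally) the slow-region mask is overlaid
#' in red. Output is deterministic: the same map always produces identical
#' bytes.
#'
#' @param map a `diffusion_map`.
#' @param file output PNG path.
#' @param slow_quantile if non-`NULL`, overlay [slow_region_mask()] at this
#'   quantile.
#' @return Invisibly, a list with the band `palette` (one colour per band),
#'   the sentinel colour and the file path.
#' @export
render_map <- function(map, file, slow_quantile = NULL) {
  stopifnot(inherits(map, "diffusion_map"))
  nb <- max(map$band, na.rm = TRUE)
  palette <- hcl.colors(nb, "YlGnBu", rev = TRUE)
  sentinel <- "#404040"
  rgbmat <- col2rgb(c(sentinel, palette)) / 255
  idx <- ifelse(map$reachable, map$band + 1L, 1L)
  img <- array(0, c(nrow(map$cost), ncol(map$cost), 3))
  for (ch in 1:3) img[, , ch] <- matrix(rgbmat[ch, idx], nrow(map$cost))
  if (!is.null(slow_quantile)) {
    slow <- slow_region_mask(map, slow_quantile)
    img[, , 1][slow] <- 0.85
    img[, , 2][slow] <- 0.10
    img[, , 3][slow] <- 0.10
  }
  png::writePNG(img, file)
  invisible(list(palette = palette, sentinel = sentinel, file = file))
}
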