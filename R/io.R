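#' Read a greyscale slice from PNG or TIFF
#'
#' 8- or 16-bit greyscale images are read into native integer intensity
#' units (PNG values, which the reader normalises to \[0, 1\], are rescaled
#' by the bit depth; TIFFs are read as-is).
#'
#' @param path image path (`.png`, `.tif`/`.tiff`).
#' @param pixel_size mm per pixel.
#' @param bits PNG bit depth used to restore integer units (default 8;
#'   ignored for TIFF, which is read in native units).
#' @return A [greyscale_slice].
#' @export
read_greyscale <- function(path, pixel_size, bits = 8) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path) * (2^bits - 1),
    tif = ,
    tiff = tiff::readTIFF(path, as.is = TRUE),
    stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3L) img <- img[, , 1]  # first channel of RGB input
  greyscale_slice(round(img), pixel_size)
}

#' Write a greyscale slice to disk
#'
#' Intensities are scaled by `max_intensity` into \[0, 1\] and written with
#' 16 bits per sample as TIFF (lossless for integer intensities up to
#' `max_intensity`) or as an 8-bit PNG preview.
#'
#' @param slice a [greyscale_slice].
#' @param path output path (`.tif`/`.tiff` or `.png`).
#' @param max_intensity full-scale intensity (default 65535).
#' @return The path, invisibly.
#' @export
write_greyscale <- function(slice, path, max_intensity = 65535) {
  stopifnot(inherits(slice, "greyscale_slice"))
  img <- matrix(pmin(1, pmax(0, slice$intensities / max_intensity)),
                nrow(slice$intensities), ncol(slice$intensities))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 16L),
    stop("unsupported image format: .", ext))
  invisible(path)
}

#' Write a porosity map as 32-bit float TIFF plus an 8-bit preview PNG
#'
#' @param map a `porosity_map`.
#' @param tiff_path output TIFF (fractions, float).
#' @param preview_path optional PNG preview (porosity as 8-bit greyscale).
#' @return `tiff_path`, invisibly.
#' @export
write_porosity <- function(map, tiff_path, preview_path = NULL) {
  stopifnot(inherits(map, "porosity_map"))
  tiff::writeTIFF(map$porosity, tiff_path, bits.per.sample = 32L)
  if (!is.null(preview_path)) png::writePNG(map$porosity, preview_path)
  invisible(tiff_path)
}

#' Read a porosity map from a float TIFF
#'
#' @param path TIFF written by [write_porosity()].
#' @param pixel_size mm per pixel.
#' @param air_endpoint,cortical_endpoint the calibration endpoints to attach.
#' @param impermeable_threshold blocked-pixel cutoff (default 0.01).
#' @return A `porosity_map`.
#' @export
read_porosity <- function(path, pixel_size, air_endpoint = 0,
                          cortical_endpoint = 1,
                          impermeable_threshold = 0.01) {
  por <- tiff::readTIFF(path)
  structure(list(porosity = por, pixel_size = pixel_size,
                 air_endpoint = air_endpoint,
                 cortical_endpoint = cortical_endpoint,
                 impermeable_threshold = impermeable_threshold),
            class = "porosity_map")
}

#' Write an inlet table as CSV
#'
#' Coordinates are written 0-based with origin top-left (`x` = column,
#' `y` = row), the interchange convention for image tools.
#'
#' @param inlets data frame `row`, `col`, `label` (1-based, R convention).
#' @param file output CSV path.
#' @return The path, invisibly.
#' @export
write_inlets_csv <- function(inlets, file) {
  stopifnot(all(c("row", "col", "label") %in% names(inlets)))
  write.csv(data.frame(x = inlets$col - 1L, y = inlets$row - 1L,
                       label = inlets$label),
            file, row.names = FALSE)
  invisible(file)
}

#' Read an inlet table from CSV
#'
#' @param file CSV with 0-based `x`, `y`, `label` columns (see
#'   [write_inlets_csv()]).
#' @return Data frame `row`, `col`, `label` (1-based).
#' @export
read_inlets_csv <- function(file) {
  d <- read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("x", "y", "label") %in% names(d)))
  data.frame(row = d$y + 1L, col = d$x + 1L, label = d$label,
             stringsAsFactors = FALSE)
}

#' Write a phantom to disk
#'
#' Writes the slice (16-bit TIFF + 8-bit preview PNG), the label grid
#' (8-bit PNG of class codes), the inlet CSV and the generating parameters
#' as YAML.
#'
#' @param phantom a [make_phantom()] result.
#' @param dir output directory (created if missing).
#' @param basename file stem (default `"phantom"`).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_phantom <- function(phantom, dir, basename = "phantom") {
  stopifnot(inherits(phantom, "labeled_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, basename)
  paths <- c(slice = paste0(stem, "_slice.tif"),
             preview = paste0(stem, "_slice.png"),
             labels = paste0(stem, "_labels.png"),
             inlets = paste0(stem, "_inlets.csv"),
             params = paste0(stem, "_params.yaml"))
  write_greyscale(phantom$slice, paths["slice"])
  pv <- phantom$slice$intensities / max(phantom$slice$intensities)
  png::writePNG(matrix(pmin(1, pv), nrow(pv), ncol(pv)), paths["preview"])
  png::writePNG(phantom$labels / 255, paths["labels"])
  write_inlets_csv(phantom$inlets, paths["inlets"])
  p <- unclass(phantom$params)
  p$levels <- as.list(p$levels)
  yaml::write_yaml(p, paths["params"])
  invisible(paths)
}
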