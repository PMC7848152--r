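#' Parameters for the molar-in-mandible phantom
#'
#' Defines the geometry and greyscale levels of a synthetic coronal slice of
#' a molar in its mandibular socket: an impermeable outer cortical shell,
#' graded trabecular bone, a tooth with a two-root bifurcation, a
#' periodontal-ligament (PDL) gap around the roots, a gingival cap, and the
#' inferior alveolar canal. Greyscale is proportional to mineral density, so
#' the class levels must satisfy cortical > trabecular > soft tissue > air.
#'
#' The default pixel size matches a 49.2 um scan resolution; the default
#' tooth-mineral level equals the cortical level so that the slice maximum is
#' the cortical calibration endpoint and the tooth calibrates to zero
#' porosity (impermeable), like the cortical shell.
#'
#' @param grid_height,grid_width grid size in pixels.
#' @param pixel_size mm per pixel.
#' @param levels named numeric vector of greyscale levels (intensity units)
#'   for classes `air`, `gingiva`, `pdl`, `canal`, `trabecular`, `cortical`,
#'   `tooth`.
#' @param trabecular_grade extra greyscale added to trabecular bone towards
#'   the periphery (denser bone near the shell).
#' @param septum_grade extra greyscale added to the interradicular septum
#'   (the furcation region between the roots is densely enclosed bone).
#'   `trabecular + trabecular_grade + septum_grade` must stay below the
#'   cortical level.
#' @param shell_thickness cortical shell thickness, mm.
#' @param pdl_thickness PDL gap width around the roots, mm.
#' @param canal_radius radius of the inferior alveolar canal, mm.
#' @param noise_sd additive Gaussian greyscale noise SD (0 = noise-free).
#' @param seed integer seed for the noise draw.
#' @return A validated list of class `phantom_params`.
#' @export
phantom_params <- function(grid_height = 256, grid_width = 256,
                           pixel_size = 0.0492,
                           levels = c(air = 0, gingiva = 70, pdl = 80,
                                      canal = 70, trabecular = 150,
                                      cortical = 230, tooth = 230),
                           trabecular_grade = 40,
                           septum_grade = 30,
                           shell_thickness = 0.4,
                           pdl_thickness = 0.4,
                           canal_radius = 0.6,
                           noise_sd = 5,
                           seed = 1L) {
  p <- list(grid_height = as.integer(grid_height),
            grid_width = as.integer(grid_width),
            pixel_size = pixel_size, levels = levels,
            trabecular_grade = trabecular_grade,
            septum_grade = septum_grade,
            shell_thickness = shell_thickness,
            pdl_thickness = pdl_thickness,
            canal_radius = canal_radius,
            noise_sd = noise_sd, seed = as.integer(seed))
  need <- c("air", "gingiva", "pdl", "canal", "trabecular", "cortical", "tooth")
  if (!all(need %in% names(levels)))
    stop("`levels` must name all of: ", paste(need, collapse = ", "))
  soft <- max(levels[c("gingiva", "pdl", "canal")])
  if (!(levels["cortical"] > levels["trabecular"] + trabecular_grade +
          septum_grade &&
        levels["trabecular"] > soft && soft > levels["air"]))
    stop("greyscale levels must be ordered cortical > graded trabecular > ",
         "soft tissue > air (greyscale is proportional to density)")
  geom <- c(pixel_size, shell_thickness, pdl_thickness, canal_radius)
  if (any(!is.finite(geom)) || any(geom <= 0))
    stop("pixel_size, shell_thickness, pdl_thickness and canal_radius must ",
         "all be strictly positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (p$grid_height < 64 || p$grid_width < 64)
    stop("configuration error: grid too small to contain shell and tooth ",
         "(need at least 64 x 64 pixels)")
  structure(p, class = "phantom_params")
}

# tissue class codes used in the label grid
phantom_classes <- function() {
  c(air = 1L, gingiva = 2L, pdl = 3L, trabecular = 4L, cortical = 5L,
    tooth = 6L, canal = 7L)
}

#' Generate a labelled molar-in-mandible phantom slice
#'
#' Builds the synthetic coronal slice described by [phantom_params()]: a
#' closed cortical ring around trabecular bone (the only opening is the tooth
#' socket under the gingival cap), a two-rooted tooth whose bifurcation is
#' enclosed between the roots, a permeable PDL gap lining the socket, a
#' gingival cap carrying the two junctional-epithelium inlet points, and the
#' inferior alveolar canal carrying the third inlet. Greyscale is assembled
#' from the class levels (trabecular bone graded denser towards the
#' periphery) plus optional Gaussian noise; the draw is deterministic given
#' the seed.
#'
#' @param params a [phantom_params()] object.
#' @return An object of class `labeled_phantom`: list with
#' \describe{
#'   \item{slice}{a [greyscale_slice] (noise included).}
#'   \item{labels}{integer matrix of tissue classes; see attribute
#'     `classes` for the code/name table.}
#'   \item{inlets}{data frame `row`, `col`, `label` with two
#'     `junctional-epithelium` points and one `inferior-alveolar-canal`.}
#'   \item{zones}{ground-truth masks: `bifurcation` (inter-root region) and
#'     `lateral_rim` (deep trabecular adjacent to the lateral cortical
#'     shell), the regions expected to be slowest to perfuse.}
#'   \item{params}{the generating parameters.}
#' }
#' @examples
#' ph <- make_phantom(phantom_params(noise_sd = 0))
#' table(attr(ph$labels, "classes")[ph$labels])
#' @export
make_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  nr <- params$grid_height; nc <- params$grid_width
  lv <- params$levels
  cls <- phantom_classes()

  # normalized coordinates of pixel centres, origin top-left, y downwards
  y <- matrix((seq_len(nr) - 0.5) / nr, nr, nc)
  x <- matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc)

  shell_px <- max(1L, as.integer(round(params$shell_thickness / params$pixel_size)))
  pdl_px   <- max(1L, as.integer(round(params$pdl_thickness / params$pixel_size)))
  canal_px <- max(1L, as.integer(round(params$canal_radius / params$pixel_size)))

  # mandible body: rectangle with an elliptical lower border
  mand <- (x >= 0.10 & x <= 0.90 & y >= 0.40 & y <= 0.68) |
    (((x - 0.5) / 0.40)^2 + ((y - 0.68) / 0.26)^2 <= 1 & y >= 0.40)
  interior <- EBImage::erode(mand * 1L,
                             EBImage::makeBrush(2L * shell_px + 1L, "disc")) > 0
  if (!any(interior))
    stop("configuration error: cortical shell thickness leaves no ",
         "trabecular interior on this grid")

  labels <- matrix(cls["air"], nr, nc)
  labels[mand] <- cls["cortical"]
  labels[interior] <- cls["trabecular"]

  # gingival cap over the alveolar crest (replaces air only)
  ging <- (((x - 0.5) / 0.36)^2 + ((y - 0.40) / 0.12)^2 <= 1) &
    labels == cls["air"]
  labels[ging] <- cls["gingiva"]

  # tooth: crown, cervical trunk, two tapering roots, furcation dome
  crown <- ((x - 0.5) / 0.17)^2 + ((y - 0.27) / 0.14)^2 <= 1
  trunk <- abs(x - 0.5) <= 0.12 & y >= 0.34 & y <= 0.405
  rw <- 0.035 * (1 - 0.4 * pmax(0, (y - 0.38)) / 0.28)
  roots <- y >= 0.38 & y <= 0.66 &
    (abs(x - (0.5 - 0.085)) <= rw | abs(x - (0.5 + 0.085)) <= rw)
  dome <- abs(x - 0.5) <= 0.048 & y >= 0.38 & y <= 0.425
  tooth <- crown | trunk | roots | dome
  labels[tooth] <- cls["tooth"]

  # interradicular septum: the furcation pocket between the roots is
  # densely enclosed bone, and its thin furcal PDL is below the scan
  # resolution, so no PDL gap is painted there
  septum <- abs(x - 0.5) <= 0.085 & y >= 0.41 & y <= 0.70

  # PDL gap lining the socket: a thin permeable band around the tooth from
  # the cervix down (punches the socket opening through the crest cortex)
  dil <- EBImage::dilate(tooth * 1L,
                         EBImage::makeBrush(2L * pdl_px + 1L, "disc")) > 0
  pdl <- dil & !tooth & y >= 0.34 & labels != cls["air"] & !septum
  labels[pdl] <- cls["pdl"]

  # inferior alveolar canal: a soft-tissue void in the trabecular bone
  canal <- ((x - 0.5) * nc)^2 + ((y - 0.82) * nr)^2 <= canal_px^2
  if (!all(labels[canal] == cls["trabecular"]))
    stop("configuration error: the inferior alveolar canal does not fit ",
         "inside the trabecular bone")
  labels[canal] <- cls["canal"]

  # inlets: two junctional-epithelium points in the PDL at the cervix and
  # one at the canal centre
  r0 <- as.integer(round(0.36 * nr))
  pick_je <- function(side) {
    cols <- which(labels[r0, ] == cls["pdl"])
    cols <- if (side == "left") cols[cols < nc / 2] else cols[cols > nc / 2]
    if (length(cols) == 0L)
      stop("configuration error: no PDL pixels at the cervix to host a ",
           "junctional-epithelium inlet")
    cols[ceiling(length(cols) / 2)]
  }
  inlets <- data.frame(
    row = c(r0, r0, as.integer(round(0.82 * nr))),
    col = c(pick_je("left"), pick_je("right"), as.integer(round(0.5 * nc))),
    label = c("junctional-epithelium", "junctional-epithelium",
              "inferior-alveolar-canal"),
    stringsAsFactors = FALSE)
  ok <- labels[cbind(inlets$row, inlets$col)] %in%
    cls[c("pdl", "gingiva", "canal")]
  if (!all(ok))
    stop("configuration error: an inlet fell on a blocked or air pixel")

  # ground-truth slow-perfusion zones
  bifurcation <- abs(x - 0.5) <= 0.05 & y >= 0.43 & y <= 0.60 &
    (labels == cls["trabecular"] | labels == cls["pdl"])
  rim <- interior &
    !(EBImage::erode(interior * 1L,
                     EBImage::makeBrush(4L * shell_px + 1L, "disc")) > 0)
  lateral_rim <- rim & (x < 0.24 | x > 0.76) & y > 0.45 & y < 0.75 &
    labels == cls["trabecular"]

  # greyscale assembly: class levels, peripheral trabecular densification,
  # then seeded additive noise
  base <- matrix(lv["air"], nr, nc)
  for (nm in names(cls)) base[labels == cls[nm]] <- lv[nm]
  radfrac <- pmin(1, sqrt(((x - 0.5) / 0.40)^2 + ((y - 0.68) / 0.26)^2))
  tb <- labels == cls["trabecular"]
  base[tb] <- base[tb] + params$trabecular_grade * radfrac[tb]
  sep <- tb & septum
  base[sep] <- base[sep] + params$septum_grade
  if (params$noise_sd > 0) {
    noise <- withr::with_seed(params$seed,
                              rnorm(nr * nc, 0, params$noise_sd))
    base <- matrix(pmax(0, base + noise), nr, nc)
  }

  attr(labels, "classes") <- setNames(names(cls), cls)
  structure(list(slice = greyscale_slice(base, params$pixel_size),
                 labels = labels,
                 inlets = inlets,
                 zones = list(bifurcation = bifurcation,
                              lateral_rim = lateral_rim),
                 params = params),
            class = "labeled_phantom")
}

#' @export
print.labeled_phantom <- function(x, ...) {
  cat(sprintf("<labeled_phantom> %d x %d pixels, %.4f mm/pixel\n",
              nrow(x$labels), ncol(x$labels), x$params$pixel_size))
  tab <- table(attr(x$labels, "classes")[as.character(x$labels)])
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  inlets: %d junctional-epithelium, %d inferior-alveolar-canal\n",
              sum(x$inlets$label == "junctional-epithelium"),
              sum(x$inlets$label == "inferior-alveolar-canal")))
  invisible(x)
}

#' Logical mask of one phantom tissue class
#'
#' @param phantom a [make_phantom()] result.
#' @param class class name (`"air"`, `"gingiva"`, `"pdl"`, `"trabecular"`,
#'   `"cortical"`, `"tooth"`, `"canal"`).
#' @return logical matrix.
#' @export
phantom_mask <- function(phantom, class) {
  stopifnot(inherits(phantom, "labeled_phantom"))
  cls <- phantom_classes()
  if (!class %in% names(cls)) stop("unknown tissue class: ", class)
  phantom$labels == cls[class]
}
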