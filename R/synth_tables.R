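#' Default histomorphometry criteria: means and SDs per group
#'
#' The built-in table of per-criterion means and standard deviations for the
#' fresh-control and 4-day organ-culture groups: cell counts per mm^2 of PDL
#' and of bone, blood-vessel counts per mm^2 of PDL and of bone, and PDL
#' thickness at mid-root in micrometres.
#'
#' @return Data frame `criterion`, `group`, `mean`, `sd`.
#' @export
histomorph_reference <- function() {
  crit <- c("cells_per_mm2_pdl", "cells_per_mm2_bone",
            "vessels_per_mm2_pdl", "vessels_per_mm2_bone",
            "pdl_thickness_um")
  data.frame(
    criterion = rep(crit, each = 2L),
    group = rep(c("fresh_control", "organ_culture_4d"), times = 5L),
    mean = c(148.3, 158.7, 24.6, 24.17, 2.5, 1.8, 1.6, 1.5, 1079.6, 1124.6),
    sd   = c(26.23, 26.08, 3.01, 4.6, 1.05, 0.75, 0.5, 0.54, 175.6, 284.4),
    stringsAsFactors = FALSE)
}

#' Parameters for the histomorphometry field generator
#'
#' @param reference data frame `criterion`, `group`, `mean`, `sd`; defaults
#'   to [histomorph_reference()]. SDs must be non-negative.
#' @param samples_per_group number of teeth per group (default 3).
#' @param fields_per_sample fields counted per sample (default 9: three
#'   random fields in each of three sections).
#' @param seed integer seed.
#' @return A list of class `histomorph_params`.
#' @export
histomorph_params <- function(reference = histomorph_reference(),
                              samples_per_group = 3L,
                              fields_per_sample = 9L,
                              seed = 1L) {
  stopifnot(is.data.frame(reference),
            all(c("criterion", "group", "mean", "sd") %in% names(reference)))
  if (any(reference$sd < 0)) stop("SDs must be non-negative")
  if (fields_per_sample < 1L) stop("fields_per_sample must be >= 1")
  if (samples_per_group < 1L) stop("samples_per_group must be >= 1")
  structure(list(reference = reference,
                 samples_per_group = as.integer(samples_per_group),
                 fields_per_sample = as.integer(fields_per_sample),
                 seed = as.integer(seed)),
            class = "histomorph_params")
}

#' Generate a field-level histomorphometry table
#'
#' Draws field observations from a normal model at each criterion x group
#' mean/SD, truncated at zero by resampling (counts and thicknesses are
#' physically non-negative). Deterministic given the seed.
#'
#' @param params a [histomorph_params()].
#' @return Data frame `group`, `sample`, `criterion`, `field`, `value`.
#' @export
make_histomorph_table <- function(params = histomorph_params()) {
  stopifnot(inherits(params, "histomorph_params"))
  ref <- params$reference
  ns <- params$samples_per_group; nf <- params$fields_per_sample
  withr::with_seed(params$seed, {
    rows <- lapply(seq_len(nrow(ref)), function(i) {
      n <- ns * nf
      v <- rnorm(n, ref$mean[i], ref$sd[i])
      while (any(bad <- v < 0))                      # truncate by resampling
        v[bad] <- rnorm(sum(bad), ref$mean[i], ref$sd[i])
      data.frame(group = ref$group[i],
                 sample = paste0(ref$group[i], "_s", rep(seq_len(ns), each = nf)),
                 criterion = ref$criterion[i],
                 field = rep(seq_len(nf), times = ns),
                 value = v, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Configuration for the synthetic assay-table generator
#'
#' Per-tissue baselines for the XTT readings and ground-truth glucose
#' consumption for the whole-sample glucose records, at two culture time
#' points. Baselines are plausible bench values: a fresh high-glucose medium
#' around 450 mg/dL, tissue weights of a dissected panel, triplicate
#' absorbance readings.
#'
#' @param tissues character vector drawn from the dissected panel
#'   `gingiva`, `pdl`, `alveolar_bone`, `cortical_bone`.
#' @param days culture days at which readings are taken (default 1 and 4).
#' @param xtt_baseline named numeric: background-corrected 450 nm signal per
#'   tissue at day 1.
#' @param xtt_decline multiplicative signal retention per extra culture day.
#' @param a690_level constant 690 nm background.
#' @param tissue_weight named numeric, g per tissue piece.
#' @param pooled_volume pooled XTT + DMSO volume, mL.
#' @param replicates absorbance replicates per tissue/day (default 3).
#' @param glucose_fresh fresh-medium glucose, mg/dL.
#' @param glucose_rate ground-truth consumption, mg per g per day.
#' @param medium_volume medium volume, mL.
#' @param sample_weight whole-sample weight, g.
#' @param noise_sd absorbance / concentration noise SD (0 = noise-free;
#'   glucose noise is scaled by 100x, reflecting mg/dL units).
#' @param seed integer seed.
#' @return A list of class `assay_config`.
#' @export
assay_config <- function(tissues = c("gingiva", "pdl", "alveolar_bone",
                                     "cortical_bone"),
                         days = c(1L, 4L),
                         xtt_baseline = c(gingiva = 0.90, pdl = 0.70,
                                          alveolar_bone = 0.45,
                                          cortical_bone = 0.20),
                         xtt_decline = 0.95,
                         a690_level = 0.05,
                         tissue_weight = c(gingiva = 0.8, pdl = 0.15,
                                           alveolar_bone = 1.2,
                                           cortical_bone = 2.0),
                         pooled_volume = 1.5,
                         replicates = 3L,
                         glucose_fresh = 450,
                         glucose_rate = 1.2,
                         medium_volume = 50,
                         sample_weight = 13.04,
                         noise_sd = 0.01,
                         seed = 1L) {
  panel <- c("gingiva", "pdl", "alveolar_bone", "cortical_bone")
  unknown <- setdiff(tissues, panel)
  if (length(unknown))
    stop("unknown tissue class(es): ", paste(unknown, collapse = ", "))
  if (!all(tissues %in% names(xtt_baseline)) ||
      !all(tissues %in% names(tissue_weight)))
    stop("xtt_baseline and tissue_weight must name every tissue")
  if (any(tissue_weight[tissues] <= 0) || sample_weight <= 0)
    stop("tissue weights must be positive")
  stopifnot(pooled_volume > 0, medium_volume > 0, replicates >= 1L,
            glucose_fresh > 0, glucose_rate >= 0, noise_sd >= 0,
            xtt_decline > 0, all(days > 0))
  structure(list(tissues = tissues, days = as.integer(days),
                 xtt_baseline = xtt_baseline, xtt_decline = xtt_decline,
                 a690_level = a690_level, tissue_weight = tissue_weight,
                 pooled_volume = pooled_volume,
                 replicates = as.integer(replicates),
                 glucose_fresh = glucose_fresh, glucose_rate = glucose_rate,
                 medium_volume = medium_volume, sample_weight = sample_weight,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "assay_config")
}

#' Generate synthetic XTT and glucose reading tables
#'
#' Emulates the bench readings the viability analytics consume: triplicate
#' 450/690 nm absorbances per dissected tissue at each culture day, and
#' whole-sample glucose records whose conditioned concentration is derived
#' from the configured ground-truth consumption rate (so with `noise_sd =
#' 0`, [glucose_consumption()] recovers the configured rate exactly).
#' Deterministic given the seed.
#'
#' @param config an [assay_config()].
#' @return List with data frames `xtt` (`tissue`, `day`, `replicate`,
#'   `a450`, `a690`, `tissue_weight`, `pooled_volume`) and `glucose`
#'   (`day`, `fresh_concentration`, `conditioned_concentration`,
#'   `medium_volume`, `tissue_weight`, `days_in_culture`).
#' @export
make_assay_table <- function(config = assay_config()) {
  stopifnot(inherits(config, "assay_config"))
  withr::with_seed(config$seed, {
    xtt <- expand.grid(tissue = config$tissues, day = config$days,
                       replicate = seq_len(config$replicates),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    signal <- config$xtt_baseline[xtt$tissue] *
      config$xtt_decline^(xtt$day - min(config$days))
    xtt$a450 <- pmax(0, config$a690_level + signal +
                       rnorm(nrow(xtt), 0, config$noise_sd))
    xtt$a690 <- pmax(0, config$a690_level +
                       rnorm(nrow(xtt), 0, config$noise_sd))
    xtt$tissue_weight <- unname(config$tissue_weight[xtt$tissue])
    xtt$pooled_volume <- config$pooled_volume

    glc <- data.frame(day = config$days)
    used_mg <- config$glucose_rate * config$sample_weight * glc$day
    glc$fresh_concentration <- config$glucose_fresh
    glc$conditioned_concentration <-
      pmax(0, config$glucose_fresh - used_mg * 100 / config$medium_volume +
             rnorm(nrow(glc), 0, 100 * config$noise_sd))
    glc$medium_volume <- config$medium_volume
    glc$tissue_weight <- config$sample_weight
    glc$days_in_culture <- glc$day
    list(xtt = xtt, glucose = glc)
  })
}
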