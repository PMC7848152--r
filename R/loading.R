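#' Construct a bioreactor loading regime
#'
#' An ordered set of sinusoidal compressive loading phases, each defined by
#' its force range (newtons, compression negative), frequency and cycle
#' count, with an optional amplitude tolerance (the rig's load accuracy, as
#' a percentage).
#'
#' @param phases data frame with columns `name`, `force_min`, `force_max`
#'   (N, `force_min < force_max <= 0` for compressive loading), `frequency`
#'   (Hz, positive), `cycle_count` (integer >= 1), `tolerance` (% of
#'   amplitude; `NA` if unspecified).
#' @return The validated data frame with class `loading_regime`.
#' @seealso [default_regime()]
#' @export
loading_regime <- function(phases) {
  need <- c("name", "force_min", "force_max", "frequency", "cycle_count",
            "tolerance")
  stopifnot(is.data.frame(phases), all(need %in% names(phases)),
            nrow(phases) >= 1L)
  with(phases, {
    if (any(frequency <= 0)) stop("frequencies must be positive")
    if (any(cycle_count < 1)) stop("cycle counts must be >= 1")
    if (any(force_min >= force_max))
      stop("force_min must be below force_max in every phase")
    if (any(force_max > 0))
      stop("compressive phases require force_max <= 0 N")
  })
  phases$cycle_count <- as.integer(phases$cycle_count)
  structure(phases, class = c("loading_regime", "data.frame"))
}

#' The chewing-simulation loading regime
#'
#' Two contiguous phases applied through the occlusal loading cap: a
#' pre-cycling phase from -5 to -45 N at 0.25 Hz for 10 cycles, then the
#' main chewing phase from -5 to -100 N at 1 Hz for 1,400 cycles with a
#' +/- 2.6% load tolerance (the rig's reported accuracy, not injected
#' noise).
#'
#' @return A [loading_regime()] with the two phases.
#' @examples
#' default_regime()
#' @export
default_regime <- function() {
  loading_regime(data.frame(
    name = c("pre_cycle", "main"),
    force_min = c(-45, -100),
    force_max = c(-5, -5),
    frequency = c(0.25, 1),
    cycle_count = c(10L, 1400L),
    tolerance = c(NA_real_, 2.6),
    stringsAsFactors = FALSE))
}

#' Render a loading regime as a sampled force waveform
#'
#' Each phase is a sinusoid `force(t) = midpoint + amplitude * sin(2 pi f t
#' + phi0)` with the starting phase chosen so every phase begins at its
#' least-compressive extreme (`force_max`); phases are concatenated without
#' gaps, each lasting `cycle_count / frequency` seconds. Optionally injects
#' seeded multiplicative amplitude jitter at the phase tolerance, for
#' testing waveform verification against the rig's stated load accuracy.
#'
#' @param regime a [loading_regime()].
#' @param sample_rate Hz; must be at least 20x the highest phase frequency.
#' @param jitter_seed if non-`NULL`, per-cycle amplitude jitter is drawn
#'   uniformly within +/- `tolerance` percent (phases with `NA` tolerance
#'   are left exact).
#' @return Data frame `time_s`, `force_N`, `phase` sampled on a uniform
#'   grid starting at t = 0 (the final instant is not sampled).
#' @examples
#' w <- render_waveform(default_regime(), sample_rate = 100)
#' range(w$force_N)   # -100, -5
#' max(w$time_s)      # just under 1440 s
#' @export
render_waveform <- function(regime, sample_rate = 100, jitter_seed = NULL) {
  stopifnot(inherits(regime, "loading_regime"), sample_rate > 0)
  fmax <- max(regime$frequency)
  if (sample_rate < 20 * fmax)
    stop(sprintf("undersampling: sample_rate must be at least 20 x the %g Hz ",
                 fmax), "maximum phase frequency (>= ", 20 * fmax, " Hz)")
  t_offset <- 0
  segs <- vector("list", nrow(regime))
  for (i in seq_len(nrow(regime))) {
    ph <- regime[i, ]
    duration <- ph$cycle_count / ph$frequency
    n <- round(duration * sample_rate)
    t_local <- seq_len(n) / sample_rate - 1 / sample_rate
    mid <- (ph$force_max + ph$force_min) / 2
    amp <- (ph$force_max - ph$force_min) / 2
    if (!is.null(jitter_seed) && is.finite(ph$tolerance)) {
      jit <- withr::with_seed(jitter_seed + i, {
        percyc <- stats::runif(ph$cycle_count, -ph$tolerance, ph$tolerance) / 100
        percyc[pmin(floor(t_local * ph$frequency) + 1L, ph$cycle_count)]
      })
      amp <- amp * (1 + jit)
    }
    # phi0 = pi/2: each phase starts at force_max (the -5 N extreme)
    force <- mid + amp * sin(2 * pi * ph$frequency * t_local + pi / 2)
    segs[[i]] <- data.frame(time_s = t_offset + t_local, force_N = force,
                            phase = ph$name, stringsAsFactors = FALSE)
    t_offset <- t_offset + duration
  }
  do.call(rbind, segs)
}

#' Count complete loading cycles in a rendered waveform phase
#'
#' Counts full sinusoid periods in one phase segment from the zero
#' crossings of the mean-removed force trace: a complete period contributes
#' one downward and one upward crossing, so the count is
#' `floor(total crossings / 2)`.
#'
#' @param series a [render_waveform()] data frame (or any data frame with
#'   `time_s`, `force_N`, `phase`).
#' @param phase phase name to count; must match a `phase` value.
#' @return Integer cycle count.
#' @export
count_cycles <- function(series, phase) {
  stopifnot(is.data.frame(series),
            all(c("time_s", "force_N", "phase") %in% names(series)))
  seg <- series[series$phase == phase, ]
  if (nrow(seg) == 0L) stop("no samples for phase: ", phase)
  s <- seg$force_N - mean(seg$force_N)
  a <- s[-length(s)]; b <- s[-1]
  crossings <- sum(a > 0 & b <= 0) + sum(a <= 0 & b > 0)
  n <- crossings %/% 2L
  if (n < 1L)
    stop("segment for phase '", phase, "' is shorter than one period")
  as.integer(n)
}

#' Write a waveform to a two-column CSV
#'
#' @param series a [render_waveform()] data frame.
#' @param file output path; columns `time_s`, `force_N`.
#' @return The file path, invisibly.
#' @export
write_waveform_csv <- function(series, file) {
  write.csv(series[c("time_s", "force_N")], file, row.names = FALSE)
  invisible(file)
}
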