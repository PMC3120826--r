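#' Parametric description of one kinetic-occlusion stimulus movie
#'
#' A `stimulus_spec` fully determines one random-dot movie: a central disc of
#' coherently translating dots with an irregular (radial-frequency perturbed)
#' outline, surrounded by a static-outline annulus of dots that survive from
#' frame to frame with a configurable probability (the surround's temporal
#' coherence), on a neutral gray background.  The center and surround outlines
#' never move; all motion is carried by the dot textures.
#'
#' Dot luminances within a region are the two levels
#' `mean_luminance * (1 +/- contrast)`, symmetric about `mean_luminance`, so
#' Michelson contrast equals `contrast` and contrast manipulations never change
#' a region's mean luminance.
#'
#' The per-frame center displacement
#' `center_speed_deg_per_s * pixels_per_degree / frame_rate_hz` must resolve to
#' an integer pixel vector along `motion_direction_deg`; non-integer
#' displacements are rejected rather than silently rounded, so dot motion is
#' exactly on-grid (the defaults give 6 deg/s * 25 px/deg / 75 Hz = 2 px/frame).
#'
#' @param frame_size_px integer vector `c(height, width)` of each frame.
#' @param pixels_per_degree spatial scale, pixels per degree of visual angle.
#' @param stimulus_diameter_deg nominal diameter of the central disc, degrees.
#' @param surround_outer_diameter_deg outer diameter of the surround annulus.
#' @param center_outline_seed integer seed fixing the irregular center outline.
#' @param outline_amplitude amplitude of the radial outline perturbation
#'   (0 gives an exact circle).
#' @param dot_density probability in (0, 1] that a pixel carries a lit dot.
#' @param center_contrast,surround_contrast Michelson contrast of each region's
#'   dots, in `[0, 1]`.
#' @param mean_luminance mean (and background) luminance in (0, 1).
#' @param center_speed_deg_per_s translation speed of the center texture.
#' @param motion_direction_deg direction of center motion; 0 = rightward,
#'   counter-clockwise positive (90 = upward).
#' @param frame_rate_hz frame rate of the movie.
#' @param duration_s movie duration; `round(duration_s * frame_rate_hz)` frames.
#' @param surround_temporal_coherence probability in `[0.5, 1]` that a surround
#'   dot survives one frame unchanged (1 = static dots, 0.5 = random flicker).
#'   Values in `[50, 100]` are interpreted as percent.
#' @param rng_seed master seed for the movie's dot textures.
#'
#' @return an object of class `stimulus_spec` (a validated named list).
#' @seealso [generate_sequence()], [coherence_to_survival()]
#' @examples
#' spec <- stimulus_spec(duration_s = 0.2, frame_size_px = c(64, 64),
#'                       stimulus_diameter_deg = 1.6,
#'                       surround_outer_diameter_deg = 2.4)
#' spec$n_frames
#' @export
stimulus_spec <- function(frame_size_px = c(256L, 256L),
                          pixels_per_degree = 25,
                          stimulus_diameter_deg = 6.2,
                          surround_outer_diameter_deg = 10,
                          center_outline_seed = 1L,
                          outline_amplitude = 0.1,
                          dot_density = 0.5,
                          center_contrast = 1,
                          surround_contrast = 1,
                          mean_luminance = 0.5,
                          center_speed_deg_per_s = 6,
                          motion_direction_deg = 90,
                          frame_rate_hz = 75,
                          duration_s = 4,
                          surround_temporal_coherence = 1,
                          rng_seed = 1L) {
  spec <- structure(
    list(
      frame_size_px = as.integer(frame_size_px),
      pixels_per_degree = pixels_per_degree,
      stimulus_diameter_deg = stimulus_diameter_deg,
      surround_outer_diameter_deg = surround_outer_diameter_deg,
      center_outline_seed = as.integer(center_outline_seed),
      outline_amplitude = outline_amplitude,
      dot_density = dot_density,
      center_contrast = center_contrast,
      surround_contrast = surround_contrast,
      mean_luminance = mean_luminance,
      center_speed_deg_per_s = center_speed_deg_per_s,
      motion_direction_deg = motion_direction_deg,
      frame_rate_hz = frame_rate_hz,
      duration_s = duration_s,
      surround_temporal_coherence =
        coherence_to_survival(surround_temporal_coherence),
      rng_seed = as.integer(rng_seed)
    ),
    class = "stimulus_spec"
  )
  validate_stimulus_spec(spec)
}

#' Default stimulus specification
#'
#' The standard study conditions: 256 x 256 frames at 25 px/deg, a 6.2 deg
#' center disc of 50%-density dots at Michelson contrast 1.0 translating at
#' 6 deg/s, 75 Hz frames for 4 s (300 frames), static surround.
#'
#' @param ... overrides passed to [stimulus_spec()].
#' @return a `stimulus_spec`.
#' @export
default_stimulus_spec <- function(...) {
  stimulus_spec(...)
}

#' Validate a stimulus specification
#'
#' Checks ranges, geometry (the perturbed center disc and the surround annulus
#' must fit inside the frame) and the integer-displacement constraint, and
#' attaches derived quantities (`n_frames`, `displacement_px`,
#' `displacement_vec`).
#'
#' @param spec a `stimulus_spec`.
#' @return the validated spec with derived fields filled in.
#' @export
validate_stimulus_spec <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  s <- spec
  if (length(s$frame_size_px) != 2L || any(s$frame_size_px < 8L)) {
    stop("frame_size_px must be two integers >= 8")
  }
  if (!is.numeric(s$pixels_per_degree) || s$pixels_per_degree <= 0) {
    stop("pixels_per_degree must be positive")
  }
  if (!is_prob(s$dot_density) || s$dot_density == 0) {
    stop("dot_density must lie in (0, 1]")
  }
  if (!is_prob(s$center_contrast) || !is_prob(s$surround_contrast)) {
    stop("contrasts must lie in [0, 1]")
  }
  if (!is_prob(s$mean_luminance) || s$mean_luminance == 0 ||
      s$mean_luminance == 1) {
    stop("mean_luminance must lie in (0, 1)")
  }
  if (s$mean_luminance * (1 + max(s$center_contrast, s$surround_contrast)) > 1) {
    stop("mean_luminance * (1 + contrast) exceeds the display range")
  }
  if (s$center_speed_deg_per_s < 0) stop("center_speed_deg_per_s must be >= 0")
  if (s$frame_rate_hz <= 0 || s$duration_s <= 0) {
    stop("frame_rate_hz and duration_s must be positive")
  }
  if (s$outline_amplitude < 0) stop("outline_amplitude must be >= 0")

  s$n_frames <- as.integer(round(s$duration_s * s$frame_rate_hz))
  if (s$n_frames < 1L) stop("duration_s * frame_rate_hz must give >= 1 frame")

  dv <- displacement_vector(s$center_speed_deg_per_s, s$motion_direction_deg,
                            s$pixels_per_degree, s$frame_rate_hz)
  s$displacement_px <- dv$displacement_px
  s$displacement_vec <- dv$v

  # Geometry: the worst-case perturbed center radius and the surround outer
  # radius must both fit inside the frame.
  r_center_max <- s$stimulus_diameter_deg * s$pixels_per_degree / 2 *
    (1 + s$outline_amplitude * length(outline_frequencies()))
  r_out <- s$surround_outer_diameter_deg * s$pixels_per_degree / 2
  half_extent <- (min(s$frame_size_px) - 1) / 2
  if (r_center_max > half_extent) {
    stop("center disc (including outline perturbation) exceeds the frame")
  }
  if (r_out > half_extent + 0.5) {
    stop("surround outer diameter exceeds the frame")
  }
  if (r_out <= s$stimulus_diameter_deg * s$pixels_per_degree / 2) {
    stop("surround outer diameter must exceed the center diameter")
  }
  s
}

# Radial frequencies of the irregular-outline perturbation.
outline_frequencies <- function() 3:7

#' Map surround temporal coherence to a per-frame survival probability
#'
#' Temporal coherence is defined as the probability that a given surround dot
#' survives one frame unchanged, so the mapping is the identity; 100%
#' coherence means static dots and 50% means random flicker.  Accepts either a
#' fraction in `[0.5, 1]` or a percentage in `[50, 100]`.
#'
#' @param coherence coherence as a fraction or percent.
#' @return survival probability as a fraction in `[0.5, 1]`.
#' @examples
#' coherence_to_survival(100)  # static dots -> 1
#' coherence_to_survival(0.5)  # random flicker -> 0.5
#' @export
coherence_to_survival <- function(coherence) {
  if (!is.numeric(coherence) || length(coherence) != 1L ||
      !is.finite(coherence)) {
    stop("coherence must be a single finite number")
  }
  if (coherence >= 50 && coherence <= 100) coherence <- coherence / 100
  if (coherence < 0.5 || coherence > 1) {
    stop("temporal coherence must lie in [0.5, 1] (or [50, 100] percent)")
  }
  coherence
}

# Per-frame pixel displacement of the center texture.  Returns the scalar
# displacement and the integer (row, col) shift; errors if either is not an
# integer (sub-pixel motion is rejected by design).
displacement_vector <- function(speed_deg_per_s, direction_deg,
                                pixels_per_degree, frame_rate_hz) {
  d <- speed_deg_per_s * pixels_per_degree / frame_rate_hz
  if (speed_deg_per_s == 0) {
    return(list(displacement_px = 0L, v = c(0L, 0L)))
  }
  if (abs(d - round(d)) > 1e-9 || round(d) < 1) {
    stop(sprintf(
      "per-frame displacement %.6f px does not round to a positive integer",
      d
    ))
  }
  d <- round(d)
  th <- direction_deg * pi / 180
  vc <- d * cos(th)   # column shift, rightward positive
  vr <- -d * sin(th)  # row shift, downward positive (origin top-left)
  if (abs(vc - round(vc)) > 1e-9 || abs(vr - round(vr)) > 1e-9) {
    stop("motion direction does not give an integer per-frame pixel shift")
  }
  list(displacement_px = as.integer(d), v = as.integer(round(c(vr, vc))))
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat("Kinetic-occlusion stimulus spec\n")
  cat(sprintf("  frame: %d x %d px (%.1f px/deg), %d frames at %g Hz (%g s)\n",
              x$frame_size_px[1], x$frame_size_px[2], x$pixels_per_degree,
              x$n_frames %||% round(x$duration_s * x$frame_rate_hz),
              x$frame_rate_hz, x$duration_s))
  cat(sprintf("  center: %.1f deg dia, contrast %.2f, %g deg/s at %g deg\n",
              x$stimulus_diameter_deg, x$center_contrast,
              x$center_speed_deg_per_s, x$motion_direction_deg))
  cat(sprintf("  surround: outer %.1f deg, contrast %.2f, coherence %.2f\n",
              x$surround_outer_diameter_deg, x$surround_contrast,
              x$surround_temporal_coherence))
  cat(sprintf("  dot density %.2f, mean luminance %.2f, seed %d\n",
              x$dot_density, x$mean_luminance, x$rng_seed))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
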