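#' Irregular center-disc mask
#'
#' Builds the static, simply-connected center region as a radial-frequency
#' perturbed circle: `r(theta) = R * (1 + A * sum_k sin(k * theta + phi_k))`
#' with low frequencies `k in 3..7` and phases drawn from
#' `center_outline_seed`.  `outline_amplitude = 0` gives an exact circular
#' disc.  The mask is deterministic given the seed.
#'
#' @param frame_size_px `c(height, width)` in pixels.
#' @param stimulus_diameter_deg nominal disc diameter in degrees.
#' @param pixels_per_degree pixels per degree.
#' @param center_outline_seed integer seed for the perturbation phases.
#' @param outline_amplitude perturbation amplitude (default 0.1).
#' @return logical `height x width` matrix, `TRUE` inside the disc.
#' @export
make_center_mask <- function(frame_size_px, stimulus_diameter_deg,
                             pixels_per_degree, center_outline_seed,
                             outline_amplitude = 0.1) {
  H <- as.integer(frame_size_px[1])
  W <- as.integer(frame_size_px[2])
  R <- stimulus_diameter_deg * pixels_per_degree / 2
  freqs <- outline_frequencies()
  if (2 * R > min(H, W) - 1) {
    stop("center disc diameter exceeds the frame")
  }
  phases <- with_seed(as.integer(center_outline_seed),
                      stats::runif(length(freqs), 0, 2 * pi))
  cy <- (H + 1) / 2
  cx <- (W + 1) / 2
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  dx <- xx - cx
  dy <- -(yy - cy)  # y increases upward
  theta <- atan2(dy, dx)
  pert <- 0
  for (i in seq_along(freqs)) {
    pert <- pert + sin(freqs[i] * theta + phases[i])
  }
  rad <- R * (1 + outline_amplitude * pert)
  if (max(rad) > (min(H, W) - 1) / 2) {
    stop("perturbed center outline exceeds the frame")
  }
  sqrt(dx^2 + dy^2) <= rad
}

# Surround annulus: inside the outer circle, outside the center mask.
make_surround_mask <- function(center_mask, surround_outer_diameter_deg,
                               pixels_per_degree) {
  H <- nrow(center_mask)
  W <- ncol(center_mask)
  r_out <- surround_outer_diameter_deg * pixels_per_degree / 2
  cy <- (H + 1) / 2
  cx <- (W + 1) / 2
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  inside <- sqrt((xx - cx)^2 + (yy - cy)^2) <= r_out
  inside & !center_mask
}

# The two dot luminance levels of a region: mean * (1 -/+ contrast).
region_levels <- function(mean_luminance, contrast) {
  c(lo = mean_luminance * (1 - contrast), hi = mean_luminance * (1 + contrast))
}

#' Generate a kinetic-occlusion random-dot movie
#'
#' Renders the movie described by `spec`.  The center shows a hidden binary
#' dot texture translating rigidly at the configured integer per-frame
#' displacement, sampled through the static center mask: dots crossing the
#' leading boundary are deleted and fresh dots accrete at the trailing
#' boundary.  Surround dots survive each frame with probability equal to the
#' temporal coherence and are otherwise resampled at the dot density.
#'
#' The center and surround textures are driven by independent RNG streams
#' derived from `spec$rng_seed`, so two specs differing only in surround
#' settings share a bit-identical center pixel stream.
#'
#' @param spec a [stimulus_spec()].
#' @return a `frame_sequence`: list with `frames` (H x W x T luminance array
#'   in `[0, 1]`), logical `center_mask` and `surround_mask`, the generating
#'   `spec`, and `hidden` (the hidden translating texture, kept as ground
#'   truth for verification probes).
#' @export
generate_sequence <- function(spec) {
  spec <- validate_stimulus_spec(spec)
  H <- spec$frame_size_px[1]
  W <- spec$frame_size_px[2]
  T_ <- spec$n_frames
  v <- spec$displacement_vec  # (row, col) shift of the texture per frame

  center <- make_center_mask(spec$frame_size_px, spec$stimulus_diameter_deg,
                             spec$pixels_per_degree, spec$center_outline_seed,
                             spec$outline_amplitude)
  surround <- make_surround_mask(center, spec$surround_outer_diameter_deg,
                                 spec$pixels_per_degree)

  seeds <- derive_stream_seeds(spec$rng_seed, 2L)

  # Hidden center texture canvas covering every texture coordinate sampled by
  # any frame: frame t (1-based) shows texture cell p - (t - 1) * v at pixel p.
  cidx <- which(center, arr.ind = TRUE)
  r_rng <- range(cidx[, 1])
  c_rng <- range(cidx[, 2])
  row0 <- r_rng[1] - max(0L, (T_ - 1L) * v[1])
  row1 <- r_rng[2] - min(0L, (T_ - 1L) * v[1])
  col0 <- c_rng[1] - max(0L, (T_ - 1L) * v[2])
  col1 <- c_rng[2] - min(0L, (T_ - 1L) * v[2])
  nr <- row1 - row0 + 1L
  nc <- col1 - col0 + 1L
  canvas <- with_seed(seeds[1], matrix(
    stats::rbinom(nr * nc, 1L, spec$dot_density) == 1L, nr, nc
  ))

  lev_c <- region_levels(spec$mean_luminance, spec$center_contrast)
  lev_s <- region_levels(spec$mean_luminance, spec$surround_contrast)

  frames <- array(spec$mean_luminance, dim = c(H, W, T_))
  plane <- as.numeric(H) * W
  # Center: index the canvas per frame, writing through flat indices.
  base_r <- cidx[, 1] - row0 + 1L
  base_c <- cidx[, 2] - col0 + 1L
  nrc <- nrow(canvas)
  cen_flat <- as.numeric(cidx[, 1] + (cidx[, 2] - 1L) * H)
  for (t in seq_len(T_)) {
    x <- canvas[(base_r - (t - 1L) * v[1]) +
                  (base_c - (t - 1L) * v[2] - 1L) * nrc]
    frames[cen_flat + (t - 1) * plane] <-
      lev_c["lo"] + (lev_c["hi"] - lev_c["lo"]) * x
  }

  # Surround: persistent-state dot process under its own stream.
  sidx <- as.numeric(which(surround))
  n_sur <- length(sidx)
  s <- spec$surround_temporal_coherence
  with_seed(seeds[2], {
    state <- stats::rbinom(n_sur, 1L, spec$dot_density)
    for (t in seq_len(T_)) {
      if (t > 1L) {
        keep <- stats::runif(n_sur) < s
        fresh <- stats::rbinom(n_sur, 1L, spec$dot_density)
        state[!keep] <- fresh[!keep]
      }
      frames[sidx + (t - 1) * plane] <-
        lev_s["lo"] + (lev_s["hi"] - lev_s["lo"]) * state
    }
  })

  structure(
    list(
      frames = frames,
      center_mask = center,
      surround_mask = surround,
      spec = spec,
      hidden = list(canvas = canvas, row0 = row0, col0 = col0, v = v)
    ),
    class = "frame_sequence"
  )
}

#' Generate a movie under the explicit near-surface (N) model
#'
#' The alternative generative model used by the ideal observer: the center is
#' a near surface whose dots persist at each retinal location, switching state
#' (on to off or vice versa) with probability `switch_prob` per frame.  Masks,
#' surround process and luminance mapping are identical to
#' [generate_sequence()].  Used as the Monte-Carlo oracle for the N-model
#' transition probabilities.
#'
#' @param spec a [stimulus_spec()]; its speed is ignored (the N model carries
#'   no deletion).
#' @param switch_prob per-pixel, per-frame state-switch probability.
#' @return a `frame_sequence` (with `hidden = NULL`).
#' @export
generate_near_model_sequence <- function(spec, switch_prob = 0.1) {
  spec <- validate_stimulus_spec(spec)
  stopifnot(is_prob(switch_prob))
  H <- spec$frame_size_px[1]
  W <- spec$frame_size_px[2]
  T_ <- spec$n_frames

  center <- make_center_mask(spec$frame_size_px, spec$stimulus_diameter_deg,
                             spec$pixels_per_degree, spec$center_outline_seed,
                             spec$outline_amplitude)
  surround <- make_surround_mask(center, spec$surround_outer_diameter_deg,
                                 spec$pixels_per_degree)
  seeds <- derive_stream_seeds(spec$rng_seed, 2L)
  lev_c <- region_levels(spec$mean_luminance, spec$center_contrast)
  lev_s <- region_levels(spec$mean_luminance, spec$surround_contrast)

  frames <- array(spec$mean_luminance, dim = c(H, W, T_))
  cen <- which(center)
  n_cen <- length(cen)
  with_seed(seeds[1], {
    state <- stats::rbinom(n_cen, 1L, spec$dot_density)
    for (t in seq_len(T_)) {
      if (t > 1L) {
        flip <- stats::runif(n_cen) < switch_prob
        state[flip] <- 1L - state[flip]
      }
      fr <- frames[, , t]
      fr[cen] <- lev_c["lo"] + (lev_c["hi"] - lev_c["lo"]) * state
      frames[, , t] <- fr
    }
  })

  sidx <- which(surround)
  n_sur <- length(sidx)
  s <- spec$surround_temporal_coherence
  with_seed(seeds[2], {
    state <- stats::rbinom(n_sur, 1L, spec$dot_density)
    for (t in seq_len(T_)) {
      if (t > 1L) {
        keep <- stats::runif(n_sur) < s
        fresh <- stats::rbinom(n_sur, 1L, spec$dot_density)
        state[!keep] <- fresh[!keep]
      }
      fr <- frames[, , t]
      fr[sidx] <- lev_s["lo"] + (lev_s["hi"] - lev_s["lo"]) * state
      frames[, , t] <- fr
    }
  })

  structure(
    list(frames = frames, center_mask = center, surround_mask = surround,
         spec = spec, hidden = NULL),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame_sequence: %d frames of %d x %d px\n", d[3], d[1], d[2]))
  cat(sprintf("  center %d px, surround %d px, coherence %.2f, seed %d\n",
              sum(x$center_mask), sum(x$surround_mask),
              x$spec$surround_temporal_coherence, x$spec$rng_seed))
  invisible(x)
}

# Resolve a region argument to a logical pixel mask.
region_mask <- function(sequence, region = c("center", "surround", "stimulus")) {
  region <- match.arg(region)
  m <- switch(region,
              center = sequence$center_mask,
              surround = sequence$surround_mask,
              stimulus = sequence$center_mask | sequence$surround_mask)
  if (!any(m)) stop("region '", region, "' contains no pixels")
  m
}

#' Rescale a region's dot contrast, preserving its mean luminance
#'
#' Compresses the region's dot luminances toward `mean_luminance` so that its
#' Michelson contrast equals `new_contrast`.  The dot on/off pattern and its
#' dynamics (including surround flicker) are untouched, and the region mean is
#' conserved exactly because the levels are symmetric about the mean.
#'
#' @param sequence a `frame_sequence`.
#' @param region `"center"` or `"surround"`.
#' @param new_contrast target Michelson contrast in `[0, 1]`.
#' @return the modified `frame_sequence`.
#' @export
set_region_contrast <- function(sequence, region, new_contrast) {
  stopifnot(inherits(sequence, "frame_sequence"))
  region <- match.arg(region, c("center", "surround"))
  if (!is_prob(new_contrast)) stop("new_contrast must lie in [0, 1]")
  old <- switch(region, center = sequence$spec$center_contrast,
                surround = sequence$spec$surround_contrast)
  if (old == new_contrast) return(sequence)
  if (old == 0) stop("cannot rescale a region whose current contrast is 0")
  m <- sequence$spec$mean_luminance
  mask <- region_mask(sequence, region)
  T_ <- dim(sequence$frames)[3]
  idx <- which(mask)
  scale <- new_contrast / old
  for (t in seq_len(T_)) {
    fr <- sequence$frames[, , t]
    fr[idx] <- m + (fr[idx] - m) * scale
    sequence$frames[, , t] <- fr
  }
  if (region == "center") {
    sequence$spec$center_contrast <- new_contrast
  } else {
    sequence$spec$surround_contrast <- new_contrast
  }
  sequence
}

#' Measure the lit-dot fraction of a region
#'
#' Fraction of region pixels at the high luminance level, pooled over all
#' frames (or one frame).  Requires the region's contrast to be positive so
#' the two levels are distinguishable.
#'
#' @param sequence a `frame_sequence`.
#' @param region `"center"`, `"surround"`, or `"stimulus"` (both pooled).
#' @param frame optional single frame index; default pools all frames.
#' @return estimated dot density as a fraction.
#' @export
measure_density <- function(sequence, region = "stimulus", frame = NULL) {
  mask <- region_mask(sequence, region)
  m <- sequence$spec$mean_luminance
  ts <- if (is.null(frame)) seq_len(dim(sequence$frames)[3]) else frame
  lit <- 0
  tot <- 0
  for (t in ts) {
    fr <- sequence$frames[, , t]
    vals <- fr[mask]
    if (all(abs(vals - m) < 1e-12)) {
      stop("region has zero contrast; dot state is not measurable")
    }
    lit <- lit + sum(vals > m)
    tot <- tot + length(vals)
  }
  lit / tot
}

#' Measure the Michelson contrast of a region
#'
#' `(Lmax - Lmin) / (Lmax + Lmin)` over the region's pixel luminances across
#' all frames.
#'
#' @inheritParams measure_density
#' @return Michelson contrast.
#' @export
measure_michelson <- function(sequence, region = "stimulus") {
  mask <- region_mask(sequence, region)
  vals <- apply(sequence$frames, 3, function(fr) range(fr[mask]))
  lmin <- min(vals[1, ])
  lmax <- max(vals[2, ])
  (lmax - lmin) / (lmax + lmin)
}

#' Estimate the surround dots' per-frame survival probability
#'
#' Computes the raw consecutive-frame pixel agreement `a` over the surround
#' and inverts the chance-corrected relation `a = s + (1 - s) * m`, where
#' `m = d^2 + (1 - d)^2` is the chance-match rate at dot density `d`, giving
#' `s = (a - m) / (1 - m)`.
#'
#' @param sequence a `frame_sequence` with at least 2 frames.
#' @return estimated survival probability.
#' @export
measure_survival <- function(sequence) {
  T_ <- dim(sequence$frames)[3]
  if (T_ < 2L) stop("survival estimation needs at least 2 frames")
  mask <- region_mask(sequence, "surround")
  d <- sequence$spec$dot_density
  m_lum <- sequence$spec$mean_luminance
  agree <- 0
  tot <- 0
  prev <- sequence$frames[, , 1][mask] > m_lum
  for (t in 2:T_) {
    cur <- sequence$frames[, , t][mask] > m_lum
    agree <- agree + sum(cur == prev)
    tot <- tot + length(cur)
    prev <- cur
  }
  a <- agree / tot
  m <- d^2 + (1 - d)^2
  (a - m) / (1 - m)
}

#' Space-time plot of a movie
#'
#' Collapses the movie onto the motion axis: rows are time (frame index),
#' columns are space along the axis of center motion, averaged over a band of
#' pixels perpendicular to that axis.  Translating center dots trace oblique
#' lines; static surround dots trace lines parallel to the time axis.
#' Supports the cardinal motion directions (0, 90, 180, 270 deg).
#'
#' @param sequence a `frame_sequence`.
#' @param column_band integer indices of the perpendicular band to average
#'   over (columns for vertical motion, rows for horizontal motion); defaults
#'   to a 5-pixel band through the frame center.
#' @return a `T x S` matrix of class `st_plot` (rows = time, columns = space).
#' @export
st_plot <- function(sequence, column_band = NULL) {
  spec <- sequence$spec
  dir <- spec$motion_direction_deg %% 360
  vertical <- isTRUE(all.equal(dir %% 180, 90))
  horizontal <- isTRUE(all.equal(dir %% 180, 0))
  if (!vertical && !horizontal) {
    stop("st_plot supports cardinal motion directions only")
  }
  d <- dim(sequence$frames)
  H <- d[1]; W <- d[2]; T_ <- d[3]
  if (is.null(column_band)) {
    mid <- round((if (vertical) W else H) / 2)
    column_band <- (mid - 2):(mid + 2)
  }
  lim <- if (vertical) W else H
  if (any(column_band < 1L) || any(column_band > lim)) {
    stop("column_band outside the frame")
  }
  S <- if (vertical) H else W
  out <- matrix(NA_real_, T_, S)
  for (t in seq_len(T_)) {
    fr <- sequence$frames[, , t]
    out[t, ] <- if (vertical) {
      rowMeans(fr[, column_band, drop = FALSE])
    } else {
      colMeans(fr[column_band, , drop = FALSE])
    }
  }
  structure(out, class = c("st_plot", "matrix"))
}

#' @export
plot.st_plot <- function(x, ...) {
  graphics::image(t(unclass(x))[, rev(seq_len(nrow(x)))],
                  col = grDevices::gray.colors(256, 0, 1),
                  xlab = "space (px along motion axis)", ylab = "time (frames)",
                  ...)
  invisible(x)
}

#' Extract the hidden center texture of one frame
#'
#' Returns the ground-truth translating texture (logical dot states) over the
#' center's bounding box at frame `t`, before masking by the center outline.
#'
#' @param sequence a `frame_sequence` produced by [generate_sequence()].
#' @param t frame index.
#' @return logical matrix of dot states.
#' @export
hidden_texture_frame <- function(sequence, t) {
  h <- sequence$hidden
  if (is.null(h)) stop("sequence carries no hidden texture")
  T_ <- dim(sequence$frames)[3]
  stopifnot(is_count(t), t >= 1, t <= T_)
  cidx <- which(sequence$center_mask, arr.ind = TRUE)
  r_rng <- range(cidx[, 1])
  c_rng <- range(cidx[, 2])
  rows <- (r_rng[1]:r_rng[2]) - (t - 1L) * h$v[1] - h$row0 + 1L
  cols <- (c_rng[1]:c_rng[2]) - (t - 1L) * h$v[2] - h$col0 + 1L
  h$canvas[rows, cols, drop = FALSE]
}

#' Recover the center translation speed from the hidden texture
#'
#' Locates the integer shift maximizing the match between the hidden center
#' textures of successive frames (exhaustive cross-correlation over small
#' offsets) and converts the per-frame displacement to degrees per second
#' using the configured pixel scale and frame rate.
#'
#' @param sequence a `frame_sequence` with a hidden texture and >= 2 frames.
#' @param max_shift largest candidate shift searched in each direction.
#' @return list with `displacement_px`, `shift` (row, col) and
#'   `speed_deg_per_s`.
#' @export
estimate_center_speed <- function(sequence, max_shift = 5L) {
  T_ <- dim(sequence$frames)[3]
  if (T_ < 2L) stop("need at least 2 frames")
  f1 <- hidden_texture_frame(sequence, 1L)
  f2 <- hidden_texture_frame(sequence, 2L)
  best <- c(NA_integer_, NA_integer_)
  best_score <- -Inf
  H <- nrow(f1); W <- ncol(f1)
  for (dr in -max_shift:max_shift) {
    for (dc in -max_shift:max_shift) {
      r1 <- max(1L, 1L + dr):min(H, H + dr)
      c1 <- max(1L, 1L + dc):min(W, W + dc)
      a <- f1[r1 - dr, c1 - dc, drop = FALSE]
      b <- f2[r1, c1, drop = FALSE]
      score <- mean(a == b)
      if (score > best_score) {
        best_score <- score
        best <- c(dr, dc)
      }
    }
  }
  # Frame t+1 shows texture cell p - t*v at pixel p, so the texture window
  # appears shifted by +v on the retina; the matching offset recovers v.
  d_px <- sqrt(sum(best^2))
  list(
    displacement_px = d_px,
    shift = best,
    match = best_score,
    speed_deg_per_s = d_px * sequence$spec$frame_rate_hz /
      sequence$spec$pixels_per_degree
  )
}
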