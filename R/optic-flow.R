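# Dense optic flow via the classic Horn-Schunck algorithm, plus a
# warped-difference detector for the accretion-deletion zone.

#' Horn-Schunck dense optic flow
#'
#' Iteratively minimizes the brightness-constancy plus `alpha^2`-weighted
#' smoothness energy with the classic averaging update:
#' `u <- u_bar - Ex * (Ex u_bar + Ey v_bar + Et) / (alpha^2 + Ex^2 + Ey^2)`
#' (and likewise for `v`), where `u_bar`, `v_bar` are weighted local means
#' (3 x 3 kernel, 1/6 edge and 1/12 corner weights).  Frames are Gaussian
#' pre-smoothed before differentiation; binary dot stimuli are not
#' differentiable, so some pre-smoothing is required for meaningful
#' gradients.  The computation is deterministic: fixed inputs and iteration
#' count give bit-identical output.
#'
#' @param frame_t,frame_t1 equal-sized luminance matrices (no NAs).
#' @param alpha smoothness weight (> 0).
#' @param n_iter number of iterations.
#' @param pre_smooth_sigma Gaussian pre-smoothing sigma in pixels (0 = none).
#' @param deriv_scheme `"hs"` for the original forward 2x2x2 cube estimators;
#'   `"central"` for symmetric central differences (exactly
#'   reflection-equivariant).
#' @return a `flow_field`: list with `u` (column/x velocity, rightward
#'   positive), `v` (row/y velocity, downward positive), both px/frame;
#'   `energy` (per-iteration objective trace), `residual` (final energy) and
#'   `iterations_run`.
#' @references Horn, B.K.P. & Schunck, B.G. (1981). Determining optical flow.
#'   Artificial Intelligence 17, 185-203.
#' @export
horn_schunck <- function(frame_t, frame_t1, alpha = 1, n_iter = 200L,
                         pre_smooth_sigma = 1.5,
                         deriv_scheme = c("hs", "central")) {
  deriv_scheme <- match.arg(deriv_scheme)
  stopifnot(is.matrix(frame_t), identical(dim(frame_t), dim(frame_t1)),
            alpha > 0, is_count(n_iter))
  if (anyNA(frame_t) || anyNA(frame_t1)) stop("NAs in input frames")
  # Luminance is rescaled to the classic 0-255 gray range so that the alpha
  # defaults keep their conventional Horn-Schunck meaning; the returned flow
  # is unaffected by this scaling (alpha trades off against gradient units).
  f1 <- frame_t * 255
  f2 <- frame_t1 * 255
  if (pre_smooth_sigma > 0) {
    f1 <- as.matrix(EBImage::gblur(f1, sigma = pre_smooth_sigma))
    f2 <- as.matrix(EBImage::gblur(f2, sigma = pre_smooth_sigma))
  }
  sh <- function(m, dr, dc) shift_mat(m, dr, dc, pad = "replicate")
  if (deriv_scheme == "hs") {
    # Original 2x2x2 cube estimators (averages of forward differences).
    Ex <- ((sh(f1, 0, 1) - f1) + (sh(f1, 1, 1) - sh(f1, 1, 0)) +
             (sh(f2, 0, 1) - f2) + (sh(f2, 1, 1) - sh(f2, 1, 0))) / 4
    Ey <- ((sh(f1, 1, 0) - f1) + (sh(f1, 1, 1) - sh(f1, 0, 1)) +
             (sh(f2, 1, 0) - f2) + (sh(f2, 1, 1) - sh(f2, 0, 1))) / 4
    Et <- ((f2 - f1) + (sh(f2, 0, 1) - sh(f1, 0, 1)) +
             (sh(f2, 1, 0) - sh(f1, 1, 0)) +
             (sh(f2, 1, 1) - sh(f1, 1, 1))) / 4
  } else {
    fm <- (f1 + f2) / 2
    Ex <- (sh(fm, 0, 1) - sh(fm, 0, -1)) / 2
    Ey <- (sh(fm, 1, 0) - sh(fm, -1, 0)) / 2
    Et <- f2 - f1
  }
  # Sums are grouped into mirror-symmetric pairs so the update is bit-exactly
  # equivariant under left-right reflection (IEEE addition is commutative but
  # not associative).
  avg <- function(m) {
    ((sh(m, -1, 0) + sh(m, 1, 0)) + (sh(m, 0, -1) + sh(m, 0, 1))) / 6 +
      ((sh(m, -1, -1) + sh(m, -1, 1)) + (sh(m, 1, -1) + sh(m, 1, 1))) / 12
  }
  H <- nrow(f1)
  W <- ncol(f1)
  u <- matrix(0, H, W)
  v <- matrix(0, H, W)
  denom <- alpha^2 + Ex^2 + Ey^2
  energy_of <- function(u, v) {
    bc <- Ex * u + Ey * v + Et
    sum(bc^2) + alpha^2 * (sum((u - avg(u))^2) + sum((v - avg(v))^2))
  }
  energy <- numeric(n_iter + 1L)
  energy[1] <- energy_of(u, v)
  for (k in seq_len(n_iter)) {
    ub <- avg(u)
    vb <- avg(v)
    corr <- (Ex * ub + Ey * vb + Et) / denom
    u <- ub - Ex * corr
    v <- vb - Ey * corr
    energy[k + 1L] <- energy_of(u, v)
  }
  structure(
    list(u = u, v = v, energy = energy, residual = energy[n_iter + 1L],
         iterations_run = as.integer(n_iter), alpha = alpha,
         pre_smooth_sigma = pre_smooth_sigma, deriv_scheme = deriv_scheme),
    class = "flow_field"
  )
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(
    "flow_field: %d x %d px, %d iterations (alpha = %g, sigma = %g)\n",
    nrow(x$u), ncol(x$u), x$iterations_run, x$alpha, x$pre_smooth_sigma
  ))
  cat(sprintf("  mean |flow| %.3f px/frame, final energy %.4g\n",
              mean(sqrt(x$u^2 + x$v^2)), x$residual))
  invisible(x)
}

#' Detect the accretion-deletion zone of a frame pair
#'
#' Flags pixels whose frame-t content has no flow-consistent correspondence in
#' frame t+1: the magnitude of the warped difference
#' `|I(t+1)(p + flow(p)) - I(t)(p)|` exceeds `threshold` (default: half the
#' dot luminance step, i.e. half of `2 * mean_luminance * contrast`).
#' Because the stimulus dots live on the pixel grid, the flow is snapped to
#' the nearest integer displacement before warping (`snap_flow = TRUE`);
#' fractional warps of a binary dot texture would register spurious
#' mismatches everywhere.  The binary map is then cleaned morphologically
#' with a 1-px radius: a closing first (at 50% dot density, half of the
#' deleted dots coincide with the occluding texture by chance, punching
#' random holes into the deletion band), then an opening to remove isolated
#' speckle.
#'
#' @param sequence a `frame_sequence`.
#' @param flow a [horn_schunck()] flow field computed on the same pair.
#' @param pair index of the frame pair (frames `pair` and `pair + 1`).
#' @param threshold warped-difference threshold; `NULL` for the default.
#' @param clean_radius radius of the morphological cleaning (0 = none).
#' @param snap_flow round the flow to integer pixel shifts before warping.
#' @return an `ad_zone`: list with logical `mask` and numeric `score`
#'   (per-pixel warped-difference magnitude).
#' @export
detect_ad_zone <- function(sequence, flow, pair = 1L, threshold = NULL,
                           clean_radius = 1L, snap_flow = TRUE) {
  stopifnot(inherits(sequence, "frame_sequence"),
            inherits(flow, "flow_field"))
  T_ <- dim(sequence$frames)[3]
  stopifnot(is_count(pair), pair >= 1L, pair + 1L <= T_)
  f1 <- sequence$frames[, , pair]
  f2 <- sequence$frames[, , pair + 1L]
  if (is.null(threshold)) {
    step <- 2 * sequence$spec$mean_luminance *
      max(sequence$spec$center_contrast, sequence$spec$surround_contrast)
    threshold <- step / 2
  }
  H <- nrow(f1)
  W <- ncol(f1)
  u <- flow$u
  v <- flow$v
  if (snap_flow) {
    u <- round(u)
    v <- round(v)
  }
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  warped <- matrix(bilinear_sample(f2, rr + v, cc + u), H, W)
  score <- abs(warped - f1)
  mask <- score > threshold
  if (clean_radius > 0L) {
    brush <- EBImage::makeBrush(2L * as.integer(clean_radius) + 1L,
                                shape = "diamond")
    m <- EBImage::closing(mask * 1, brush)
    mask <- EBImage::opening(m, brush) > 0.5
  }
  structure(list(mask = mask, score = score, threshold = threshold),
            class = "ad_zone")
}

# Jaccard index of two logical masks.
jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}

#' Compare optic flow between two surround conditions
#'
#' For two movies sharing the same center pixel stream (e.g. static vs
#' flickering surround), computes Horn-Schunck flow on the same frame pair in
#' both and reports the mean endpoint error between conditions, separately
#' for the interior of the center (center mask eroded by `interior_erosion`
#' pixels) and for the surround.
#'
#' @param sequence_static,sequence_flicker two `frame_sequence`s with
#'   identical masks.
#' @param pair frame-pair index.
#' @param interior_erosion erosion radius defining the center interior.
#' @param ... arguments passed to [horn_schunck()].
#' @return a `flow_comparison`: list with `center_epe`, `surround_epe`
#'   (mean endpoint errors, px/frame) and the two flow fields.
#' @export
compare_flow_conditions <- function(sequence_static, sequence_flicker,
                                    pair = 1L, interior_erosion = 3L, ...) {
  stopifnot(inherits(sequence_static, "frame_sequence"),
            inherits(sequence_flicker, "frame_sequence"))
  if (!identical(sequence_static$center_mask, sequence_flicker$center_mask) ||
      !identical(sequence_static$surround_mask,
                 sequence_flicker$surround_mask)) {
    stop("the two sequences have mismatched region masks")
  }
  fa <- horn_schunck(sequence_static$frames[, , pair],
                     sequence_static$frames[, , pair + 1L], ...)
  fb <- horn_schunck(sequence_flicker$frames[, , pair],
                     sequence_flicker$frames[, , pair + 1L], ...)
  epe <- sqrt((fa$u - fb$u)^2 + (fa$v - fb$v)^2)
  interior <- sequence_static$center_mask
  if (interior_erosion > 0L) {
    brush <- EBImage::makeBrush(2L * as.integer(interior_erosion) + 1L,
                                shape = "disc")
    interior <- EBImage::erode(interior * 1, brush) > 0.5
  }
  structure(
    list(center_epe = mean(epe[interior]),
         surround_epe = mean(epe[sequence_static$surround_mask]),
         flow_static = fa, flow_flicker = fb, interior_mask = interior),
    class = "flow_comparison"
  )
}

#' @export
print.flow_comparison <- function(x, ...) {
  cat(sprintf(
    "flow_comparison: center interior EPE %.3f px/frame, surround EPE %.3f px/frame\n",
    x$center_epe, x$surround_epe
  ))
  invisible(x)
}
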