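# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the caller's
#' RNG state afterwards, so seeded generators do not perturb user code.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Derive n independent sub-stream seeds from one master seed.  Keeps, e.g.,
# the center texture stream untouched by how many draws the surround consumes.
derive_stream_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

# Shifted copy of a matrix: out[i, j] = m[i + dr, j + dc].
# pad = "replicate" clamps indices to the border, pad = "zero" fills with 0.
shift_mat <- function(m, dr, dc, pad = c("replicate", "zero")) {
  pad <- match.arg(pad)
  H <- nrow(m)
  W <- ncol(m)
  ri <- seq_len(H) + dr
  ci <- seq_len(W) + dc
  if (pad == "replicate") {
    return(m[pmin(pmax(ri, 1L), H), pmin(pmax(ci, 1L), W), drop = FALSE])
  }
  out <- matrix(vector(typeof(m), 1L), H, W)
  ok_r <- ri >= 1L & ri <= H
  ok_c <- ci >= 1L & ci <= W
  out[ok_r, ok_c] <- m[ri[ok_r], ci[ok_c]]
  out
}

# Bilinearly sample `img` at (possibly fractional) row/col coordinates,
# clamping to the frame border.
bilinear_sample <- function(img, ri, ci) {
  H <- nrow(img)
  W <- ncol(img)
  ri <- pmin(pmax(as.vector(ri), 1), H)
  ci <- pmin(pmax(as.vector(ci), 1), W)
  r0 <- floor(ri)
  c0 <- floor(ci)
  r1 <- pmin(r0 + 1, H)
  c1 <- pmin(c0 + 1, W)
  fr <- ri - r0
  fc <- ci - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c1)] * (1 - fr) * fc +
    img[cbind(r1, c1)] * fr * fc
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}
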