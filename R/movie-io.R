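# Lossless movie serialization: PNG frame stack + JSON sidecar.
#
# Stimulus frames take only a handful of discrete luminance levels, so each
# frame is stored as an 8-bit PNG of palette indices (index / 255) with the
# palette of level values recorded in the sidecar.  This round-trips exactly,
# which a direct 8-bit luminance encoding would not (e.g. 0.5 is not
# representable as n/255).

#' Export a movie as a PNG frame stack with a JSON sidecar
#'
#' Writes `frame_0001.png`, ... (zero-padded), mask images, and
#' `sidecar.json` holding the generating spec, the luminance palette, and the
#' frame count.  The hidden ground-truth texture is not serialized.
#'
#' @param sequence a `frame_sequence`.
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @seealso [import_movie()]
#' @export
export_movie <- function(sequence, path) {
  stopifnot(inherits(sequence, "frame_sequence"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory: ", path)
  T_ <- dim(sequence$frames)[3]
  palette <- sort(unique(as.vector(sequence$frames)))
  if (length(palette) > 256L) stop("more than 256 luminance levels")
  for (t in seq_len(T_)) {
    fr <- sequence$frames[, , t]
    idx <- match(fr, palette) - 1L
    png::writePNG(matrix(idx / 255, nrow(fr), ncol(fr)),
                  file.path(path, sprintf("frame_%04d.png", t)))
  }
  png::writePNG(sequence$center_mask * 1,
                file.path(path, "center_mask.png"))
  png::writePNG(sequence$surround_mask * 1,
                file.path(path, "surround_mask.png"))
  sidecar <- list(
    format = "adcue-movie-1",
    n_frames = T_,
    frame_size_px = dim(sequence$frames)[1:2],
    palette = palette,
    spec = unclass(sequence$spec)
  )
  jsonlite::write_json(sidecar, file.path(path, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import a movie written by [export_movie()]
#'
#' Reconstructs the `frame_sequence` exactly (frames, masks, spec).  With
#' `validate = TRUE` the movie is regenerated from the sidecar's spec and
#' compared against the stored frames; a mismatch (e.g. a sidecar seed that
#' differs from the frames' generator seed) raises a validation warning.
#'
#' @param path directory written by [export_movie()].
#' @param validate logical; regenerate from the sidecar spec and compare.
#' @return a `frame_sequence` (with `hidden = NULL`).
#' @export
import_movie <- function(path, validate = FALSE) {
  sidecar_path <- file.path(path, "sidecar.json")
  if (!file.exists(sidecar_path)) stop("missing sidecar.json in ", path)
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (!identical(sidecar$format, "adcue-movie-1")) {
    stop("unrecognized movie format")
  }
  T_ <- sidecar$n_frames
  hw <- as.integer(sidecar$frame_size_px)
  palette <- as.numeric(sidecar$palette)
  frames <- array(NA_real_, dim = c(hw[1], hw[2], T_))
  for (t in seq_len(T_)) {
    f <- file.path(path, sprintf("frame_%04d.png", t))
    if (!file.exists(f)) stop("missing frame file: ", f)
    idx <- round(png::readPNG(f) * 255) + 1L
    frames[, , t] <- palette[idx]
  }
  center <- png::readPNG(file.path(path, "center_mask.png")) > 0.5
  surround <- png::readPNG(file.path(path, "surround_mask.png")) > 0.5
  spec_fields <- sidecar$spec
  spec <- do.call(stimulus_spec,
                  spec_fields[intersect(names(spec_fields),
                                        names(formals(stimulus_spec)))])
  out <- structure(
    list(frames = frames, center_mask = center, surround_mask = surround,
         spec = spec, hidden = NULL),
    class = "frame_sequence"
  )
  if (validate) {
    regen <- generate_sequence(spec)
    if (!isTRUE(all.equal(regen$frames, frames, tolerance = 0))) {
      warning("stored frames do not match regeneration from the sidecar spec ",
              "(seed or spec mismatch)")
    }
  }
  out
}
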