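#' Time-lapse (or z-) image stack
#'
#' A lightweight container for a single-channel grayscale stack: a list of
#' equally sized nonnegative intensity matrices plus per-frame timestamps in
#' seconds. Matrices are indexed `[y + 1, x + 1]` with 0-based pixel centers
#' at integer coordinates (row-major, image convention). For foci data the
#' third dimension is z: construct one stack whose "frames" are z planes and
#' set `z = TRUE`.
#'
#' @param frames list of numeric matrices, all the same dimension, values
#'   >= 0.
#' @param timestamps numeric vector of acquisition times in seconds, one per
#'   frame, strictly increasing. For z stacks this is the plane index.
#' @param channel free-text channel label (e.g. `"488"` or `"561"`).
#' @param z logical; `TRUE` if the pages are z planes of one acquisition
#'   rather than timepoints.
#' @return An object of class `image_stack`.
#' @examples
#' st <- image_stack(list(matrix(1, 4, 4), matrix(2, 4, 4)), c(0, 30))
#' dim_stack(st)
#' @export
image_stack <- function(frames, timestamps, channel = "488", z = FALSE) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  }
  stopifnot(is.list(frames), length(frames) >= 1L)
  d <- dim(frames[[1]])
  for (f in frames) {
    if (!is.matrix(f) || !identical(dim(f), d))
      stopf("all frames must be matrices of identical dimension")
    if (any(f < 0)) stopf("intensities must be >= 0")
  }
  if (length(timestamps) != length(frames))
    stopf("need one timestamp per frame")
  if (any(diff(timestamps) <= 0))
    stopf("timestamps must be strictly increasing")
  structure(list(frames = frames, timestamps = as.numeric(timestamps),
                 channel = as.character(channel), z = isTRUE(z)),
            class = "image_stack")
}

#' @rdname image_stack
#' @param x an `image_stack`.
#' @return `dim_stack()`: integer `c(height, width, n_frames)`.
#' @export
dim_stack <- function(x) {
  stopifnot(inherits(x, "image_stack"))
  c(dim(x$frames[[1]]), length(x$frames))
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim_stack(x)
  cat(sprintf("<image_stack> %d x %d px, %d %s, channel %s\n",
              d[2], d[1], d[3], if (x$z) "z planes" else "frames", x$channel))
  invisible(x)
}

#' Maximum-intensity projection
#'
#' Collapses a z stack to a single 2D frame by the per-pixel maximum over
#' planes.
#'
#' @param x an `image_stack` (typically with `z = TRUE`) or a list of
#'   matrices.
#' @return a numeric matrix.
#' @export
max_project <- function(x) {
  frames <- if (inherits(x, "image_stack")) x$frames else x
  out <- frames[[1]]
  for (i in seq_along(frames)[-1]) out <- pmax(out, frames[[i]])
  out
}
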