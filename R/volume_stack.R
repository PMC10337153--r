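#' zpeel: surface-guided peeling and projection of 3D microscopy stacks
#'
#' Peel a 3D z-stack along a fitted sphere or a user-guided cubic-spline
#' surface, then collapse the remaining volume to 2D by maximum-intensity
#' projection. See `vignette("peeling-methods", package = "zpeel")` for the
#' underlying model and the synthetic benchmark.
#'
#' @keywords internal
"_PACKAGE"

#' Multi-dimensional image stack
#'
#' Container for a grayscale image volume with axes `(x, y, z)` and optional
#' channel and time axes. Intensities are stored as a 5-D numeric array
#' indexed `[x, y, z, c, t]`; `x` runs along TIFF columns, `y` along rows,
#' and `z = 1` is the first acquired (shallowest) plane. All internal
#' geometry is 0-based and in voxel units; user-facing depths (control-point
#' files, CLI) are 1-based and converted exactly once at the I/O boundary.
#'
#' @param data numeric array with 3 to 5 dimensions, interpreted as
#'   `(x, y, z)`, `(x, y, z, c)` or `(x, y, z, c, t)`. Missing trailing axes
#'   are added with extent 1.
#' @param dtype storage class of the pixel data: `"uint8"`, `"uint16"` or
#'   `"float"`. Defaults to `"float"`; integer dtypes require non-negative
#'   whole values within range.
#' @return An object of class `volume_stack`: a list with elements `data`
#'   (5-D array) and `dtype`.
#' @examples
#' v <- volume_stack(array(0, c(8, 8, 4)), dtype = "uint8")
#' stack_dims(v)
#' @export
volume_stack <- function(data, dtype = c("float", "uint8", "uint16")) {
  dtype <- match.arg(dtype)
  if (!is.array(data) || !is.numeric(data)) {
    stop("`data` must be a numeric array", call. = FALSE)
  }
  nd <- length(dim(data))
  if (nd < 3L || nd > 5L) {
    stop("`data` must have 3 to 5 dimensions (x, y, z[, c[, t]])", call. = FALSE)
  }
  dim(data) <- as.integer(unname(c(dim(data), rep(1L, 5L - nd))))
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("intensities must be finite", call. = FALSE)
  if (dtype != "float") {
    rng <- if (dtype == "uint8") 255 else 65535
    if (any(data < 0) || any(data > rng)) {
      stop(sprintf("values out of range for %s", dtype), call. = FALSE)
    }
    if (any(data != round(data))) {
      stop(sprintf("non-integer values for %s dtype", dtype), call. = FALSE)
    }
  }
  structure(list(data = data, dtype = dtype), class = "volume_stack")
}

#' Dimensions of a volume stack
#'
#' @param volume a [volume_stack()].
#' @return Named integer vector `c(w, h, d, c, t)`.
#' @export
stack_dims <- function(volume) {
  stopifnot(inherits(volume, "volume_stack"))
  d <- dim(volume$data)
  c(w = d[1L], h = d[2L], d = d[3L], c = d[4L], t = d[5L])
}

#' Extract one 3-D channel/frame sub-volume
#'
#' @param volume a [volume_stack()].
#' @param channel,frame 1-based channel and frame indices.
#' @return A plain `w x h x d` numeric array.
#' @export
sub_volume <- function(volume, channel = 1L, frame = 1L) {
  dm <- stack_dims(volume)
  if (channel < 1L || channel > dm["c"]) stop("channel out of range", call. = FALSE)
  if (frame < 1L || frame > dm["t"]) stop("frame out of range", call. = FALSE)
  arr <- volume$data[, , , channel, frame, drop = FALSE]
  dim(arr) <- unname(dm[1:3])
  arr
}

#' Convert a stack to float storage
#'
#' @param volume a [volume_stack()].
#' @return The same stack with `dtype = "float"`.
#' @export
as_float <- function(volume) {
  stopifnot(inherits(volume, "volume_stack"))
  volume$dtype <- "float"
  volume
}

#' @export
print.volume_stack <- function(x, ...) {
  dm <- stack_dims(x)
  cat(sprintf(
    "<volume_stack> %d x %d x %d voxels, %d channel(s), %d frame(s), %s\n",
    dm["w"], dm["h"], dm["d"], dm["c"], dm["t"], x$dtype
  ))
  cat(sprintf("  intensity range: [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

# replace one channel/frame sub-volume in place (internal)
set_sub_volume <- function(volume, arr, channel = 1L, frame = 1L) {
  dm <- stack_dims(volume)
  stopifnot(all(dim(arr) == dm[1:3]))
  volume$data[, , , channel, frame] <- arr
  volume
}
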