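# Peeling and projection: Ip = I * T, then maximum-intensity projection.

#' Binary peel mask
#'
#' A binary volume `T` over `(x, y, z)`; the peeled stack is the voxelwise
#' product `I * T`.
#'
#' @param x logical or 0/1 numeric 3-D array.
#' @return An object of class `peel_mask` (logical 3-D array).
#' @export
peel_mask <- function(x) {
  if (inherits(x, "peel_mask")) return(x)
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop("a peel mask must be a 3-D array", call. = FALSE)
  }
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) stop("peel mask values must be strictly binary", call. = FALSE)
    x <- array(x != 0, dim(x))
  } else if (!is.logical(x)) {
    stop("peel mask must be logical or 0/1 numeric", call. = FALSE)
  }
  if (anyNA(x)) stop("peel mask values must be strictly binary", call. = FALSE)
  structure(x, class = "peel_mask")
}

#' @export
print.peel_mask <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<peel_mask> %d x %d x %d, %d/%d voxels kept\n",
              d[1L], d[2L], d[3L], sum(x), length(x)))
  invisible(x)
}

#' Apply a peel mask to a volume
#'
#' Computes the peeled stack `Ip = I * T` voxelwise. A single mask is shared
#' by all channels and frames; a list of masks (one per frame) applies
#' per-frame geometry, still shared across channels.
#'
#' @param volume a [volume_stack()].
#' @param mask a [peel_mask()] with the volume's xyz dims, or a list of one
#'   per frame.
#' @return The peeled [volume_stack()] (same dtype; masked voxels are 0).
#' @export
apply_mask <- function(volume, mask) {
  stopifnot(inherits(volume, "volume_stack"))
  dm <- stack_dims(volume)
  masks <- if (is.list(mask) && !inherits(mask, "peel_mask")) mask else rep(list(mask), dm[["t"]])
  if (length(masks) != dm[["t"]]) {
    stop(sprintf("need one mask per frame (%d), got %d", dm[["t"]], length(masks)), call. = FALSE)
  }
  masks <- lapply(masks, peel_mask)
  for (m in masks) {
    if (!all(dim(m) == dm[1:3])) stop("mask dims do not match volume xyz dims", call. = FALSE)
  }
  out <- volume
  for (ti in seq_len(dm[["t"]])) {
    m <- as.numeric(masks[[ti]])
    for (ci in seq_len(dm[["c"]])) {
      out$data[, , , ci, ti] <- out$data[, , , ci, ti] * m
    }
  }
  out
}

#' Maximum-intensity projection
#'
#' Collapses the z axis: each output pixel is the maximum intensity along
#' its (x, y) column, per channel and frame. If a mask (or list of
#' per-frame masks) is supplied the volume is peeled first and the
#' projection carries a validity mask marking columns that kept at least
#' one voxel; pixels of fully peeled columns are set to 0, which is
#' ambiguous against true black on its own -- hence the explicit validity
#' plane. Without a mask every column is valid.
#'
#' @param volume a [volume_stack()].
#' @param mask optional [peel_mask()] or list of per-frame masks.
#' @return An object of class `projection2d`: list with `values`
#'   (`w x h x c x t` array), `validity` (`w x h x t` logical array) and
#'   `dtype`.
#' @export
max_projection <- function(volume, mask = NULL) {
  stopifnot(inherits(volume, "volume_stack"))
  dm <- stack_dims(volume)
  masks <- NULL
  if (!is.null(mask)) {
    volume <- apply_mask(volume, mask)
    masks <- if (is.list(mask) && !inherits(mask, "peel_mask")) {
      lapply(mask, peel_mask)
    } else {
      rep(list(peel_mask(mask)), dm[["t"]])
    }
  }
  vals <- array(0, unname(dm[c("w", "h", "c", "t")]))
  valid <- array(TRUE, unname(dm[c("w", "h", "t")]))
  for (ti in seq_len(dm[["t"]])) {
    if (!is.null(masks)) {
      valid[, , ti] <- apply(unclass(masks[[ti]]), c(1L, 2L), any)
    }
    for (ci in seq_len(dm[["c"]])) {
      mx <- volume$data[, , 1L, ci, ti]
      for (zi in seq_len(dm[["d"]])[-1L]) {
        mx <- pmax(mx, volume$data[, , zi, ci, ti])
      }
      if (!is.null(masks)) mx[!valid[, , ti]] <- 0
      vals[, , ci, ti] <- mx
    }
  }
  structure(list(values = vals, validity = valid, dtype = volume$dtype),
            class = "projection2d")
}

#' @export
print.projection2d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<projection2d> %d x %d pixels, %d channel(s), %d frame(s), %s; %.1f%% valid\n",
              d[1L], d[2L], d[3L], d[4L], x$dtype, 100 * mean(x$validity)))
  invisible(x)
}

#' Extract one projection plane as a matrix
#'
#' @param projection a `projection2d`.
#' @param channel,frame 1-based indices.
#' @return A `w x h` numeric matrix.
#' @export
projection_image <- function(projection, channel = 1L, frame = 1L) {
  stopifnot(inherits(projection, "projection2d"))
  m <- projection$values[, , channel, frame]
  dim(m) <- dim(projection$values)[1:2]
  m
}

#' Convert a projection to a volume stack (for writing to TIFF)
#'
#' @param projection a `projection2d`.
#' @param float_out write as float regardless of source dtype.
#' @return A [volume_stack()] with `d = 1`.
#' @export
projection_stack <- function(projection, float_out = FALSE) {
  stopifnot(inherits(projection, "projection2d"))
  d <- dim(projection$values)
  arr <- array(projection$values, c(d[1L], d[2L], 1L, d[3L], d[4L]))
  dtype <- if (float_out) "float" else projection$dtype
  volume_stack(arr, dtype = dtype)
}

#' Full peel-and-project pipeline
#'
#' Composes the stages for every frame of a stack: build the peel geometry
#' (per-frame sphere fits, or a spline surface per frame with temporal
#' interpolation of control points), peel, and project all channels. The
#' pipeline introduces no arithmetic of its own -- its output equals
#' applying [fit_sphere()]/[fit_spline_surface()], the mask constructor,
#' [apply_mask()] and [max_projection()] stage by stage.
#'
#' @param volume a [volume_stack()].
#' @param mode `"sphere"` or `"spline"`.
#' @param alpha,region sphere mode: radius fraction and `"inner"`/`"outer"`
#'   (see [sphere_mask()]).
#' @param grids spline mode: a [control_point_grid()] (single-frame stacks)
#'   or list of grids at two or more annotated frames.
#' @param side spline mode: `"upper"` or `"lower"` (see [spline_mask()]).
#' @param channel channel used for sphere fitting (the mask applies to all
#'   channels).
#' @param threshold,max_fit_voxels,seed passed to [fit_sphere()].
#' @param keep_peeled also return the peeled 3-D stack.
#' @return An object of class `peel_result`: list with `projection` (a
#'   `projection2d`), `models` (per-frame `sphere_model`s) or `surfaces`
#'   (per-frame `spline_surface`s), `masks`, `params`, and optionally
#'   `peeled`.
#' @export
run_pipeline <- function(volume, mode = c("sphere", "spline"),
                         alpha = 1, region = "inner",
                         grids = NULL, side = "upper",
                         channel = 1L, threshold = "otsu",
                         max_fit_voxels = 100000L, seed = 1L,
                         keep_peeled = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(volume, "volume_stack"))
  dm <- stack_dims(volume)
  res <- list(mode = mode)
  if (mode == "sphere") {
    models <- fit_sphere_timeseries(volume, channel = channel, threshold = threshold,
                                    max_fit_voxels = max_fit_voxels, seed = seed)
    masks <- lapply(models, function(m) {
      if (inherits(m, "condition")) stop("sphere fit failed on a frame: ", conditionMessage(m), call. = FALSE)
      sphere_mask(volume, m, alpha = alpha, region = region)
    })
    res$models <- models
    res$params <- list(alpha = alpha, region = region, channel = channel,
                       threshold = threshold, max_fit_voxels = max_fit_voxels, seed = seed)
  } else {
    if (is.null(grids)) stop("spline mode requires control-point grids", call. = FALSE)
    if (inherits(grids, "control_point_grid")) grids <- list(grids)
    surfaces <- if (dm[["t"]] == 1L) {
      if (length(grids) != 1L) stop("single-frame stack: provide exactly one control-point grid", call. = FALSE)
      list(fit_spline_surface(grids[[1L]]))
    } else {
      interpolate_grids_over_time(grids, dm[["t"]])
    }
    masks <- lapply(surfaces, function(s) spline_mask(volume, s, side = side))
    res$surfaces <- surfaces
    res$params <- list(side = side, grid_size = grids[[1L]]$g,
                       annotated_frames = vapply(grids, function(g) g$frame, 0L))
  }
  res$projection <- max_projection(volume, masks)
  res$masks <- masks
  if (keep_peeled) res$peeled <- apply_mask(volume, masks)
  structure(res, class = "peel_result")
}

#' @export
print.peel_result <- function(x, ...) {
  cat(sprintf("<peel_result> mode: %s\n", x$mode))
  print(x$projection)
  if (x$mode == "sphere") {
    for (i in seq_along(x$models)) {
      cat(sprintf(" frame %d: ", i)); print(x$models[[i]])
    }
  } else {
    cat(sprintf(" side: %s, %d surface(s)\n", x$params$side, length(x$surfaces)))
  }
  invisible(x)
}
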