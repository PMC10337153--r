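# User-guided cubic-spline surfaces.
#
# The user annotates depths z(k, n) on a small regular grid of (x, y)
# positions (3x3, 4x4 or 5x5, anchored at the image borders). A smooth
# surface S(x, y) interpolating those depths is built as a tensor-product
# of 1-D natural cubic splines, and the volume is cut into the half-spaces
# above and below S. Depths are 1-based (z = 1 is the shallowest plane, as
# presented to the user in ImageJ); geometry is converted to the 0-based
# internal axis exactly once, inside spline_mask().

#' Control-point grid for a spline surface
#'
#' @param depths numeric `g x g` matrix of 1-based z-depths;
#'   `depths[k, n]` belongs to the k-th grid node along x and the n-th
#'   along y. `g` must be 3, 4 or 5.
#' @param dims target volume dims: a [volume_stack()] or `c(w, h, d)`. Grid
#'   nodes are evenly spaced over `[0, w-1] x [0, h-1]`, borders included,
#'   so the surface interpolates (never extrapolates) over the whole image.
#' @param frame 1-based time frame the grid annotates.
#' @param allow_outside_depths permit depths outside `[1, d]`. Off by
#'   default (interactive annotations are depths of existing planes); the
#'   synthetic benchmark turns it on so a geometric cut may exit the volume
#'   -- columns where the cut lies deeper than the stack are then simply
#'   not peeled from above.
#' @return An object of class `control_point_grid`.
#' @export
control_point_grid <- function(depths, dims, frame = 1L,
                               allow_outside_depths = FALSE) {
  dm <- mask_dims(dims)
  depths <- as.matrix(depths)
  g <- nrow(depths)
  if (!g %in% 3:5 || ncol(depths) != g) {
    stop("depths must be a g x g matrix with g in {3, 4, 5}", call. = FALSE)
  }
  if (!all(is.finite(depths))) stop("control depths must be finite", call. = FALSE)
  if (!allow_outside_depths && (any(depths < 1) || any(depths > dm[3L]))) {
    stop(sprintf("control depths must lie within [1, %d]", dm[3L]), call. = FALSE)
  }
  structure(
    list(depths = unname(depths), g = g,
         xnodes = grid_nodes(g, dm[1L]), ynodes = grid_nodes(g, dm[2L]),
         dims = dm, frame = as.integer(frame),
         allow_outside_depths = isTRUE(allow_outside_depths)),
    class = "control_point_grid"
  )
}

grid_nodes <- function(g, extent) seq(0, extent - 1, length.out = g)

#' @export
print.control_point_grid <- function(x, ...) {
  cat(sprintf("<control_point_grid> %dx%d nodes over %dx%dx%d volume, frame %d\n",
              x$g, x$g, x$dims[1L], x$dims[2L], x$dims[3L], x$frame))
  print(x$depths)
  invisible(x)
}

#' Interpolating spline surface through a control-point grid
#'
#' Builds the tensor-product natural-cubic-spline surface `S(x, y)` that
#' passes through every control depth. Natural boundary conditions (zero
#' second derivative at the grid borders) are used in both axes; the
#' surface is C2 inside the grid domain and reproduces constant and planar
#' depth fields exactly.
#'
#' @param grid a [control_point_grid()].
#' @return An object of class `spline_surface` with an `$at(x, y)`
#'   evaluator (vectorized, 0-based pixel coordinates, 1-based depths).
#' @seealso [surface_field()], [spline_mask()]
#' @export
fit_spline_surface <- function(grid) {
  stopifnot(inherits(grid, "control_point_grid"))
  if (anyDuplicated(grid$xnodes) || anyDuplicated(grid$ynodes)) {
    stop("duplicate grid node coordinates", call. = FALSE)
  }
  # stage 1: one natural spline along x per y-node row
  fx <- lapply(seq_len(grid$g), function(n) {
    stats::splinefun(grid$xnodes, grid$depths[, n], method = "natural")
  })
  ynodes <- grid$ynodes
  at <- function(x, y) {
    stopifnot(length(x) == length(y))
    m <- vapply(fx, function(f) f(x), numeric(length(x)))  # |x| x g
    if (length(x) == 1L) dim(m) <- c(1L, length(fx))
    vapply(seq_along(x), function(i) {
      stats::splinefun(ynodes, m[i, ], method = "natural")(y[i])
    }, numeric(1L))
  }
  structure(
    list(at = at, fx = fx, grid = grid, boundary = "natural"),
    class = "spline_surface"
  )
}

#' Evaluate a spline surface on the full pixel grid
#'
#' @param surface a `spline_surface`.
#' @return A `w x h` matrix of 1-based depths, `[x, y]` indexed.
#' @export
surface_field <- function(surface) {
  stopifnot(inherits(surface, "spline_surface"))
  g <- surface$grid
  w <- g$dims[1L]; h <- g$dims[2L]
  xs <- seq(0, w - 1)
  m <- vapply(surface$fx, function(f) f(xs), numeric(w))  # w x g
  ys <- seq(0, h - 1)
  out <- matrix(0, w, h)
  for (i in seq_len(w)) {
    out[i, ] <- stats::splinefun(g$ynodes, m[i, ], method = "natural")(ys)
  }
  out
}

#' @export
print.spline_surface <- function(x, ...) {
  g <- x$grid
  cat(sprintf("<spline_surface> %dx%d natural tensor spline over %dx%d image (depths in [%g, %g])\n",
              g$g, g$g, g$dims[1L], g$dims[2L], min(g$depths), max(g$depths)))
  invisible(x)
}

#' Half-space peel mask from a spline surface
#'
#' Cuts the volume at the surface: with `side = "lower"` a voxel at 0-based
#' `(X, Y, Z)` is kept iff `S(X, Y) <= Z` (deeper than or on the surface;
#' equality voxels belong to the lower mask); `side = "upper"` is the exact
#' complement. `S` is stored in the user-facing 1-based depth convention
#' and converted here by subtracting 1.
#'
#' @param dims a [volume_stack()] or `c(w, h, d)`; must match the grid the
#'   surface was built on.
#' @param surface a `spline_surface` from [fit_spline_surface()].
#' @param side `"lower"` or `"upper"`.
#' @return A [peel_mask()]; per (x, y) column the lower mask is a
#'   contiguous suffix in z.
#' @export
spline_mask <- function(dims, surface, side = c("lower", "upper")) {
  side <- match.arg(side)
  dm <- mask_dims(dims)
  g <- surface$grid
  if (!all(dm[1:2] == g$dims[1:2])) {
    stop("surface grid dims do not match the volume", call. = FALSE)
  }
  s0 <- surface_field(surface) - 1  # 0-based surface depth
  lower <- outer(s0, 0:(dm[3L] - 1), "<=")
  peel_mask(if (side == "lower") lower else !lower)
}

#' Interpolate control-point grids across a time series
#'
#' Given grids annotated at two or more frames, builds one surface per
#' frame of the series: each control node's depth is interpolated linearly
#' in time between annotated frames (constant extrapolation before the
#' first and after the last), then a spline surface is fitted per frame.
#' At annotated frames the given depths are reproduced exactly.
#'
#' @param grids list of [control_point_grid()]s with identical grid size
#'   and dims, at distinct frames within `[1, t_total]`.
#' @param t_total number of frames in the series.
#' @return A list of `t_total` `spline_surface` objects.
#' @export
interpolate_grids_over_time <- function(grids, t_total) {
  if (length(grids) < 2L) stop("need control-point grids for at least two frames", call. = FALSE)
  stopifnot(all(vapply(grids, inherits, TRUE, "control_point_grid")))
  gs <- vapply(grids, function(g) g$g, 0L)
  if (length(unique(gs)) != 1L) stop("control-point grids have mismatched grid sizes", call. = FALSE)
  frames <- vapply(grids, function(g) g$frame, 0L)
  if (anyDuplicated(frames)) stop("duplicate frame indices in control-point grids", call. = FALSE)
  if (any(frames < 1L) || any(frames > t_total)) {
    stop(sprintf("annotated frames must lie within [1, %d]", t_total), call. = FALSE)
  }
  ord <- order(frames)
  grids <- grids[ord]; frames <- frames[ord]
  g <- gs[1L]
  dims <- grids[[1L]]$dims
  depth_mats <- lapply(seq_len(t_total), function(ti) matrix(0, g, g))
  for (k in seq_len(g)) {
    for (n in seq_len(g)) {
      zs <- vapply(grids, function(gr) gr$depths[k, n], 0)
      zt <- if (length(frames) == 1L) rep(zs, t_total) else {
        stats::approx(frames, zs, xout = seq_len(t_total), rule = 2)$y
      }
      for (ti in seq_len(t_total)) depth_mats[[ti]][k, n] <- zt[ti]
    }
  }
  allow <- any(vapply(grids, function(g) isTRUE(g$allow_outside_depths), TRUE))
  lapply(seq_len(t_total), function(ti) {
    fit_spline_surface(control_point_grid(depth_mats[[ti]], dims, frame = ti,
                                          allow_outside_depths = allow))
  })
}

#' Read control points from JSON or CSV
#'
#' Two schemas are accepted. JSON:
#' `{"grid_size": g, "dims": [w, h, d], "frames": [{"frame": f, "depths": [...]}]}`
#' where `depths` is a row-major `g*g` array of 1-based z-depths (rows are
#' constant-y lines, x varying fastest). CSV: columns
#' `frame, row, col, z` with 1-based node indices (`row` along y, `col`
#' along x) and 1-based depths.
#'
#' @param path path to a `.json` or `.csv` file.
#' @param dims target volume dims (a [volume_stack()] or `c(w, h, d)`);
#'   required for CSV, optional for JSON (overrides the stored dims).
#' @return A list of [control_point_grid()]s, one per annotated frame.
#' @export
read_control_points <- function(path, dims = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    spec <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (is.null(spec$grid_size) || is.null(spec$frames)) {
      stop("control-point JSON must have fields 'grid_size' and 'frames'", call. = FALSE)
    }
    g <- as.integer(spec$grid_size)
    if (is.null(dims)) {
      if (is.null(spec$dims)) stop("control-point JSON lacks 'dims' and no dims were supplied", call. = FALSE)
      dims <- as.integer(spec$dims)
    }
    frames <- spec$frames
    if (is.data.frame(frames)) {
      frames <- lapply(seq_len(nrow(frames)), function(i) {
        list(frame = frames$frame[i], depths = frames$depths[[i]])
      })
    }
    allow <- isTRUE(spec$allow_outside_depths)
    lapply(frames, function(fr) {
      z <- as.numeric(unlist(fr$depths))
      if (length(z) != g * g) {
        stop(sprintf("frame %s: expected %d depths, got %d", fr$frame, g * g, length(z)), call. = FALSE)
      }
      # row-major: rows are constant-y, x fastest -> fills [x, y] by column
      control_point_grid(matrix(z, g, g), dims, frame = as.integer(fr$frame),
                         allow_outside_depths = allow)
    })
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    if (is.null(dims)) stop("reading CSV control points requires `dims`", call. = FALSE)
    tab <- utils::read.csv(path)
    need <- c("frame", "row", "col", "z")
    if (!all(need %in% names(tab))) {
      stop("control-point CSV must have columns frame, row, col, z", call. = FALSE)
    }
    g <- max(tab$row, tab$col)
    lapply(split(tab, tab$frame), function(fr) {
      if (nrow(fr) != g * g) {
        stop(sprintf("frame %d: expected %d rows, got %d", fr$frame[1L], g * g, nrow(fr)), call. = FALSE)
      }
      depths <- matrix(NA_real_, g, g)
      depths[cbind(fr$col, fr$row)] <- fr$z
      if (anyNA(depths)) stop("control-point CSV does not cover the full grid", call. = FALSE)
      control_point_grid(depths, dims, frame = fr$frame[1L])
    })
  } else {
    stop("control-point file must be .json or .csv", call. = FALSE)
  }
}

#' Write control points to JSON
#'
#' Inverse of [read_control_points()] (JSON schema).
#'
#' @param grids a [control_point_grid()] or list of them.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_control_points <- function(grids, path) {
  if (inherits(grids, "control_point_grid")) grids <- list(grids)
  g <- grids[[1L]]$g
  spec <- list(
    grid_size = g,
    dims = grids[[1L]]$dims,
    allow_outside_depths = isTRUE(grids[[1L]]$allow_outside_depths),
    frames = lapply(grids, function(gr) {
      list(frame = gr$frame, depths = as.vector(gr$depths))  # row-major, x fastest
    })
  )
  writeLines(jsonlite::toJSON(spec, auto_unbox = TRUE, digits = NA, pretty = TRUE), path)
  invisible(path)
}
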