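# Robust sphere fitting and radial peel masks.
#
# The surface model for sphere-like specimens (e.g. embryos during epiboly)
# is a single sphere fitted to all foreground voxels. The fit minimizes the
# L1 norm of the algebraic residuals,
#
#     sum_i | (Xi - x0)^2 + (Yi - y0)^2 + (Zi - z0)^2 - r0^2 |
#
# over center (x0, y0, z0) and radius r0, where i runs over voxels whose
# intensity exceeds a threshold (Otsu by default). The L1 loss keeps the fit
# robust against bright outlier voxels that a plain least-squares fit would
# be dragged towards.

#' Fit a sphere to thresholded foreground voxels
#'
#' Thresholds one channel/frame of the stack, then fits center and radius by
#' minimizing the L1 norm of the algebraic sphere residuals over foreground
#' voxel coordinates (0-based voxel units). The optimizer is initialized at
#' the foreground centroid with the RMS distance to it as radius (the
#' closed-form least-squares solution for a centered sphere) and refined
#' with Nelder-Mead on the exact non-smooth objective, which can only
#' improve on the initial objective value.
#'
#' @param volume a [volume_stack()].
#' @param channel,frame sub-volume used for fitting (1-based). The resulting
#'   model/mask is typically applied to all channels.
#' @param threshold `"otsu"` (default) or a numeric threshold `tau`;
#'   foreground is `intensity > tau`.
#' @param max_fit_voxels cap on the number of foreground voxels entering the
#'   objective; larger sets are uniformly subsampled (seeded, reproducible).
#' @param seed RNG seed for the subsampling (does not touch the global RNG
#'   stream).
#' @param tol relative convergence tolerance of the optimizer.
#' @param maxit maximum optimizer iterations.
#' @return An object of class `sphere_model`: list with `x0, y0, z0, r0`
#'   (continuous voxel coordinates), `objective` (L1 objective at the
#'   solution), `n_fit` (voxels used) and `threshold`.
#' @seealso [sphere_mask()], [fit_sphere_timeseries()]
#' @export
fit_sphere <- function(volume, channel = 1L, frame = 1L, threshold = "otsu",
                       max_fit_voxels = 100000L, seed = 1L,
                       tol = 1e-10, maxit = 5000L) {
  if (max_fit_voxels < 4L) stop("max_fit_voxels must be >= 4", call. = FALSE)
  arr <- sub_volume(volume, channel, frame)
  tau <- if (identical(threshold, "otsu")) {
    otsu_threshold(volume, channel, frame)
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    threshold
  }
  fg <- which(arr > tau, arr.ind = TRUE)
  fit_sphere_points(fg - 1, tau, max_fit_voxels, seed, tol, maxit)
}

fit_sphere_points <- function(pts, tau, max_fit_voxels = 100000L, seed = 1L,
                              tol = 1e-10, maxit = 5000L) {
  if (nrow(pts) < 4L) {
    stop(sprintf("insufficient foreground: %d voxels above threshold (need >= 4)", nrow(pts)), call. = FALSE)
  }
  if (nrow(pts) > max_fit_voxels) {
    keep <- with_seed(seed, sample.int(nrow(pts), max_fit_voxels))
    pts <- pts[keep, , drop = FALSE]
  }
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr), nu = 0, nv = 0)$d
  if (sv[3L] < 1e-8 * max(sv[1L], 1)) {
    stop("degenerate geometry: foreground voxels are coplanar", call. = FALSE)
  }
  x <- pts[, 1L]; y <- pts[, 2L]; z <- pts[, 3L]
  obj <- function(p) {
    sum(abs((x - p[1L])^2 + (y - p[2L])^2 + (z - p[3L])^2 - p[4L]^2))
  }
  r_init <- sqrt(mean((x - ctr[1L])^2 + (y - ctr[2L])^2 + (z - ctr[3L])^2))
  p0 <- unname(c(ctr, r_init))
  fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = tol))
  if (fit$convergence != 0L && fit$value > obj(p0)) {
    stop(sprintf(
      "sphere fit did not converge (code %d); last iterate: center (%.3f, %.3f, %.3f), r %.3f",
      fit$convergence, fit$par[1L], fit$par[2L], fit$par[3L], abs(fit$par[4L])
    ), call. = FALSE)
  }
  p <- unname(fit$par)
  structure(
    list(x0 = p[1L], y0 = p[2L], z0 = p[3L], r0 = abs(p[4L]),
         objective = fit$value, n_fit = nrow(pts), threshold = tau),
    class = "sphere_model"
  )
}

#' @export
print.sphere_model <- function(x, ...) {
  cat(sprintf(
    "<sphere_model> center (%.3f, %.3f, %.3f), radius %.3f [voxels]\n  L1 objective %.4g over %d voxels (threshold %.4g)\n",
    x$x0, x$y0, x$z0, x$r0, x$objective, x$n_fit, x$threshold
  ))
  invisible(x)
}

#' Radial peel mask from a fitted sphere
#'
#' Builds the binary peel mask for a sphere model: with `region = "inner"` a
#' voxel at 0-based coordinates `(X, Y, Z)` is kept iff
#' `(X-x0)^2 + (Y-y0)^2 + (Z-z0)^2 <= (alpha * r0)^2` (boundary voxels are
#' included); `region = "outer"` is the exact set complement.
#'
#' @param dims volume dimensions: a [volume_stack()] or an integer vector
#'   `c(w, h, d)`.
#' @param model a `sphere_model` from [fit_sphere()].
#' @param alpha radius scale factor in `[0, 1]`.
#' @param region `"inner"` (inside the scaled sphere) or `"outer"`.
#' @return A [peel_mask()] with the xyz dimensions of the volume.
#' @export
sphere_mask <- function(dims, model, alpha = 1, region = c("inner", "outer")) {
  region <- match.arg(region)
  stopifnot(inherits(model, "sphere_model"), model$r0 > 0)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  dm <- mask_dims(dims)
  dx2 <- (seq_len(dm[1L]) - 1 - model$x0)^2
  dy2 <- (seq_len(dm[2L]) - 1 - model$y0)^2
  dz2 <- (seq_len(dm[3L]) - 1 - model$z0)^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  inner <- d2 <= (alpha * model$r0)^2
  peel_mask(if (region == "inner") inner else !inner)
}

#' Fit independent spheres to each frame of a time series
#'
#' Applies [fit_sphere()] to every frame of a time-lapse stack. The Otsu
#' threshold (when used) is recomputed per frame. A failing frame does not
#' abort the series: its entry carries the error condition, and the indices
#' of failed frames are attached as attribute `"failed_frames"`. If every
#' frame fails, an aggregate error listing the per-frame causes is raised.
#'
#' @inheritParams fit_sphere
#' @return A list of `sphere_model` objects (class `sphere_model_series`),
#'   one per frame; failed frames hold the error condition instead.
#' @export
fit_sphere_timeseries <- function(volume, channel = 1L, threshold = "otsu",
                                  max_fit_voxels = 100000L, seed = 1L,
                                  tol = 1e-10, maxit = 5000L) {
  nt <- stack_dims(volume)[["t"]]
  out <- vector("list", nt)
  failed <- integer(0)
  for (ti in seq_len(nt)) {
    out[[ti]] <- tryCatch(
      fit_sphere(volume, channel = channel, frame = ti, threshold = threshold,
                 max_fit_voxels = max_fit_voxels, seed = seed,
                 tol = tol, maxit = maxit),
      error = function(e) { e }
    )
    if (inherits(out[[ti]], "condition")) failed <- c(failed, ti)
  }
  if (length(failed) == nt) {
    msgs <- vapply(out, conditionMessage, "")
    stop("sphere fit failed on every frame:\n",
         paste(sprintf("  frame %d: %s", seq_len(nt), msgs), collapse = "\n"),
         call. = FALSE)
  }
  structure(out, failed_frames = failed, class = "sphere_model_series")
}

#' Serialize sphere models to JSON
#'
#' @param models a `sphere_model` or `sphere_model_series`.
#' @param path optional file to write; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
sphere_to_json <- function(models, path = NULL) {
  if (inherits(models, "sphere_model")) models <- list(models)
  rec <- lapply(models, function(m) {
    if (inherits(m, "condition")) {
      list(error = conditionMessage(m))
    } else {
      m[c("x0", "y0", "z0", "r0", "objective", "n_fit", "threshold")]
    }
  })
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

# run code with a private RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

mask_dims <- function(dims) {
  if (inherits(dims, "volume_stack")) {
    unname(stack_dims(dims)[1:3])
  } else {
    stopifnot(is.numeric(dims), length(dims) >= 3L)
    as.integer(dims[1:3])
  }
}
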