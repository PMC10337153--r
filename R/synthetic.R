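# Synthetic benchmark volumes with ground truth.
#
# The two-sheet phantom emulates the core difficulty the peeler addresses:
# a bright curved sheet S1 occluding a dimmer parallel sheet S2 underneath.
# Both sheets are parabolic cylinders in depth,
#
#     S1: z = a * x^2          (intensity 255)
#     S2: z = a * x^2 + b      (intensity 128)
#
# with a = d / h^2 and b = d / 2 for a w x h x d volume, so S1 sweeps the
# full depth range across the image and S2 leaves the volume where
# a*x^2 + b exceeds it. Additive Gaussian noise (mean and variance 0.01 on
# the normalized [0, 1] intensity scale) is applied to every voxel and the
# noised volume is saturated back into [0, 1] before rescaling by 255 --
# the behavior of the standard noise-addition routines in scientific image
# processing, and the convention under which the benchmark's published
# projection errors are reproduced (see the methods vignette).

#' Specification of the two-sheet synthetic volume
#'
#' @param w,h,d volume dimensions in voxels (defaults 512 x 512 x 50).
#' @param v1,v2 sheet intensities for S1 (bright, default 255) and S2 (dim,
#'   default 128) on the 0-255 scale.
#' @param a,b sheet geometry coefficients; default `a = d/h^2`, `b = d/2`.
#' @param noise_mean,noise_var mean and variance of the additive Gaussian
#'   noise on the normalized [0, 1] scale (defaults 0.01 and 0.01).
#' @param thickness sheet thickness in voxels (default 1).
#' @param clip saturate noised intensities into [0, 1] before rescaling
#'   (default `TRUE`); set `FALSE` for unbounded additive noise.
#' @param seed RNG seed for the noise realization.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(w = 512L, h = 512L, d = 50L,
                           v1 = 255, v2 = 128,
                           a = d / h^2, b = d / 2,
                           noise_mean = 0.01, noise_var = 0.01,
                           thickness = 1L, clip = TRUE, seed = 1L) {
  if (min(w, h, d) < 1L) stop("volume dimensions must be >= 1", call. = FALSE)
  if (a * (h - 1)^2 > d) stop("S1 must fit the depth range: a * (h-1)^2 <= d", call. = FALSE)
  if (b >= d) stop("sheet offset b must be smaller than the depth d", call. = FALSE)
  if (noise_var < 0 || thickness < 1) stop("invalid noise variance or thickness", call. = FALSE)
  structure(
    list(w = as.integer(w), h = as.integer(h), d = as.integer(d),
         v1 = v1, v2 = v2, a = a, b = b,
         noise_mean = noise_mean, noise_var = noise_var,
         thickness = thickness, clip = clip, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate the two-sheet benchmark volume with ground truth
#'
#' Background is 0; voxels within `thickness/2` of the rounded sheet depth
#' are set to the sheet intensity, the brighter sheet S1 winning where the
#' sheets would collide. Gaussian noise is then added on the normalized
#' scale (see [synthetic_spec()]) and the volume is returned as float on
#' the 0-255 scale. The pre-noise volume is deterministic; the noise is
#' reproducible from `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `volume` (a float [volume_stack()]), `truth` (class
#'   `synthetic_truth`: continuous surfaces `s1(x)`, `s2(x)` in 0-based
#'   voxel depths, and logical `w x h` evaluation domains `domain1`,
#'   `domain2` marking columns where each sheet exists), and `spec`.
#' @export
make_two_sheet_volume <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  w <- spec$w; h <- spec$h; d <- spec$d
  x <- 0:(w - 1)
  z1 <- round(spec$a * x^2)
  z2 <- round(spec$a * x^2 + spec$b)
  half <- spec$thickness / 2
  vol <- array(0, c(w, h, d))
  for (zi in 0:(d - 1)) {
    in2 <- abs(zi - z2) <= half
    if (any(in2)) vol[in2, , zi + 1L] <- spec$v2
  }
  for (zi in 0:(d - 1)) {  # S1 painted after S2: brighter sheet wins collisions
    in1 <- abs(zi - z1) <= half
    if (any(in1)) vol[in1, , zi + 1L] <- spec$v1
  }
  nv <- vol / 255
  if (spec$noise_var > 0) {
    noise <- with_seed(spec$seed,
      array(stats::rnorm(length(nv), spec$noise_mean, sqrt(spec$noise_var)), dim(nv)))
    nv <- nv + noise
  }
  if (spec$clip) nv <- pmin(pmax(nv, 0), 1)
  truth <- structure(
    list(
      s1 = function(x) spec$a * x^2,
      s2 = function(x) spec$a * x^2 + spec$b,
      domain1 = matrix(TRUE, w, h),
      domain2 = matrix(spec$a * x^2 + spec$b <= d - 1, w, h),
      spec = spec
    ),
    class = "synthetic_truth"
  )
  list(volume = volume_stack(nv * 255, dtype = "float"), truth = truth, spec = spec)
}

#' Spherical-shell phantom
#'
#' A thin spherical shell of bright voxels on dark background: voxels whose
#' distance to the center is within `shell_thickness/2` of the radius get
#' the foreground value; optional Gaussian noise (gray levels) on top.
#' Used to exercise and validate the sphere fitting.
#'
#' @param center numeric length-3, 0-based voxel coordinates.
#' @param radius sphere radius in voxels.
#' @param shell_thickness shell thickness in voxels (default 1).
#' @param dims volume dimensions `c(w, h, d)` (default 64^3).
#' @param foreground shell intensity (default 255).
#' @param noise_sd standard deviation of additive Gaussian noise in gray
#'   levels (default 0, none).
#' @param seed RNG seed for the noise.
#' @return A float [volume_stack()].
#' @export
make_sphere_phantom <- function(center, radius, shell_thickness = 1,
                                dims = c(64L, 64L, 64L), foreground = 255,
                                noise_sd = 0, seed = 1L) {
  stopifnot(length(center) == 3L, radius > 0)
  dm <- as.integer(dims[1:3])
  if (any(center - radius - shell_thickness / 2 < 0) ||
      any(center + radius + shell_thickness / 2 > dm - 1)) {
    stop("sphere exceeds volume bounds", call. = FALSE)
  }
  dx2 <- (0:(dm[1L] - 1) - center[1L])^2
  dy2 <- (0:(dm[2L] - 1) - center[2L])^2
  dz2 <- (0:(dm[3L] - 1) - center[3L])^2
  dist <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
  vol <- array(0, dm)
  vol[abs(dist - radius) <= shell_thickness / 2] <- foreground
  if (noise_sd > 0) {
    vol <- vol + with_seed(seed, array(stats::rnorm(length(vol), 0, noise_sd), dm))
  }
  volume_stack(vol, dtype = "float")
}

#' Default control-point grid for the two-sheet benchmark
#'
#' Samples the mid-surface `a*x^2 + b/2` -- the cut halfway between the two
#' sheets -- at the grid nodes (1-based depths, floored at 1). Where the
#' mid-surface runs deeper than the stack the depth is kept as is rather
#' than clamped to `d`: the cut simply exits the volume and those columns
#' are not peeled from above. (Clamping the node depths to `d` would drag
#' the interpolated surface below the bright sheet near the image border
#' and cut it off -- no interpolating surface through clamped nodes can
#' retain it.) Keeping the volume above this cut (`side = "upper"`)
#' retrieves the bright sheet S1; keeping the volume below
#' (`side = "lower"`) retrieves the dim sheet S2. The recommended side is
#' attached as attribute `"side"`.
#'
#' @param spec a [synthetic_spec()].
#' @param target which sheet the peel should retrieve, `"S1"` or `"S2"`.
#' @param grid_size grid size g in 3:5 (default 5).
#' @return A [control_point_grid()] with attribute `"side"`.
#' @export
default_experiment_grid <- function(spec, target = c("S1", "S2"), grid_size = 5L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  target <- match.arg(target)
  xk <- grid_nodes(grid_size, spec$w)
  z <- pmax(spec$a * xk^2 + spec$b / 2 + 1, 1)  # 1-based, may exceed d
  depths <- matrix(rep(z, grid_size), grid_size, grid_size)
  grid <- control_point_grid(depths, c(spec$w, spec$h, spec$d),
                             allow_outside_depths = TRUE)
  attr(grid, "side") <- if (target == "S1") "upper" else "lower"
  grid
}

#' Serialize the synthetic ground truth parameters to JSON
#'
#' @param truth a `synthetic_truth`.
#' @param path optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
truth_to_json <- function(truth, path = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  sp <- truth$spec
  rec <- list(
    w = sp$w, h = sp$h, d = sp$d, a = sp$a, b = sp$b,
    v1 = sp$v1, v2 = sp$v2,
    noise_mean = sp$noise_mean, noise_var = sp$noise_var,
    thickness = sp$thickness, clip = sp$clip, seed = sp$seed,
    s1 = "z = a*x^2 (0-based)", s2 = "z = a*x^2 + b (0-based)"
  )
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
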