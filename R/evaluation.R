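# Evaluation metrics: RMSE against a known sheet intensity, Dice overlap.

#' RMSE of a projection against a constant target intensity
#'
#' Root-mean-squared error `sqrt(sum_i (target - I(x_i, y_i))^2 / N)` over
#' the `N` pixels of an evaluation domain -- the pixels "where the
#' retrieved plane is defined". Pixels outside the domain never contribute.
#' The error is reported on the intensity scale of the projection (0-255
#' for the synthetic benchmark).
#'
#' @param projection a `projection2d` or a plain `w x h` numeric matrix.
#' @param target the reference gray level (e.g. 255 for the bright sheet).
#' @param domain optional logical `w x h` matrix; `NULL` means the full
#'   image. For a `projection2d`, the domain is additionally intersected
#'   with the projection's validity mask.
#' @param channel,frame which plane of a `projection2d` to score.
#' @return The RMSE as a single numeric (gray levels).
#' @export
rmse_vs_constant <- function(projection, target, domain = NULL,
                             channel = 1L, frame = 1L) {
  if (inherits(projection, "projection2d")) {
    img <- projection_image(projection, channel, frame)
    valid <- projection$validity[, , frame]
    dim(valid) <- dim(img)
    domain <- if (is.null(domain)) valid else (domain & valid)
  } else {
    img <- as.matrix(projection)
    if (is.null(domain)) domain <- matrix(TRUE, nrow(img), ncol(img))
  }
  if (!all(dim(domain) == dim(img))) stop("domain dims do not match the projection", call. = FALSE)
  n <- sum(domain)
  if (n < 1L) stop("empty evaluation domain", call. = FALSE)
  sqrt(sum((target - img[domain])^2) / n)
}

#' Dice similarity coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`: 1 for identical non-empty masks, 0
#' for disjoint ones. Symmetric in its arguments.
#'
#' @param a,b logical (or 0/1 numeric) arrays of identical dimensions.
#' @return The coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- as_binary(a); b <- as_binary(b)
  if (!identical(dim(a), dim(b)) || length(a) != length(b)) {
    stop("mask dims do not match", call. = FALSE)
  }
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) stop("Dice coefficient is undefined for two empty masks", call. = FALSE)
  2 * sum(a & b) / (na + nb)
}

as_binary <- function(x) {
  if (is.logical(x)) {
    if (anyNA(x)) stop("masks must not contain NA", call. = FALSE)
    return(x)
  }
  if (is.numeric(x) && all(x %in% c(0, 1))) return(x != 0)
  stop("masks must be logical or 0/1 numeric", call. = FALSE)
}
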