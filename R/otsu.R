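#' Otsu threshold of a 3-D sub-volume
#'
#' Computes the classic Otsu threshold on the full 3-D histogram of one
#' channel/frame of a stack: intensities are min-max scaled into 256 bins
#' and the inter-bin cut maximizing the between-class variance is selected.
#' The min-max scaling makes the threshold dtype-independent (8-bit, 16-bit
#' and float volumes with the same relative histogram give the same relative
#' threshold), and adding a constant offset to all intensities shifts the
#' returned threshold by exactly that offset.
#'
#' The returned value is the upper edge of the last background bin, mapped
#' back to the original intensity scale, so foreground selection is
#' `intensity > tau` and at least one voxel always strictly exceeds `tau`.
#'
#' @param volume a [volume_stack()] (or plain 3-D array).
#' @param channel,frame which sub-volume to threshold (1-based).
#' @param bins number of histogram bins (default 256).
#' @return The threshold `tau` as a single numeric on the intensity scale of
#'   the input.
#' @examples
#' v <- volume_stack(array(rep(c(50, 200), each = 32), c(4, 4, 4)))
#' otsu_threshold(v)
#' @export
otsu_threshold <- function(volume, channel = 1L, frame = 1L, bins = 256L) {
  arr <- if (inherits(volume, "volume_stack")) sub_volume(volume, channel, frame) else volume
  lo <- min(arr); hi <- max(arr)
  if (hi <= lo) stop("degenerate histogram: volume is constant", call. = FALSE)
  idx <- pmin(floor((arr - lo) / (hi - lo) * bins), bins - 1L)
  counts <- tabulate(idx + 1L, nbins = bins)
  k <- otsu_from_counts(counts)
  lo + (k + 1) / bins * (hi - lo)
}

# 0-based index k of the last background bin maximizing between-class
# variance; ties resolved to the smallest k
otsu_from_counts <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  lev <- seq_along(counts) - 1
  w0 <- cumsum(p)
  mu <- cumsum(p * lev)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  sigma_b <- sigma_b[-length(sigma_b)]  # cut must leave both classes non-empty
  which.max(sigma_b) - 1L
}
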