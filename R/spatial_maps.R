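#' Threshold a fluorescence image into a spread profile
#'
#' Assuming peak fluorescence corresponds to the maximum injected
#' concentration and pixel intensity is proportional to concentration, the
#' mask threshold is the pixel value equivalent to an EC20 concentration:
#' `(ec20 / max_concentration) * max(image)`. The profile's extents are the
#' mask bounding box scaled by the pixel pitch.
#'
#' @param image Grayscale matrix (rows = y, columns = x).
#' @param max_concentration Injected concentration (mM).
#' @param ec20 EC20 concentration (mM); must be below `max_concentration`.
#' @param center Injection center `c(x, y)` in pixels.
#' @param pixel_um Pixel pitch in micrometers (default 1).
#' @return List of class `spread_profile`: `mask` (logical matrix),
#'   `center`, `threshold`, `extent_um` (`c(ml, ap)` bounding-box diameters),
#'   `equivalent_radius_px` (radius of a disc with the mask's area).
#' @export
threshold_spread <- function(image, max_concentration, ec20, center,
                             pixel_um = 1) {
  if (max(image) <= 0) stop("image has no positive pixels")
  if (ec20 >= max_concentration) stop("ec20 must be below max_concentration")
  thr <- (ec20 / max_concentration) * max(image)
  mask <- image >= thr
  extent <- c(0, 0)
  if (any(mask)) {
    ij <- which(mask, arr.ind = TRUE)
    extent <- c(diff(range(ij[, 2])) + 1, diff(range(ij[, 1])) + 1) * pixel_um
  }
  structure(list(mask = mask, center = center, threshold = thr,
                 extent_um = extent,
                 equivalent_radius_px = sqrt(sum(mask) / pi)),
            class = "spread_profile")
}

#' Modal spread profile across mice
#'
#' Translates each mask so its injection center sits at a common center
#' (integer-pixel shifts, no rotation or scaling) and intersects them: the
#' modal profile keeps pixels positive across all mice.
#'
#' @param profiles List of `spread_profile`s.
#' @return Logical matrix (dimensions of the first profile), the pixel-wise
#'   AND of the aligned masks.
#' @export
modal_spread <- function(profiles) {
  if (length(profiles) < 1) stop("need at least one profile")
  dims <- dim(profiles[[1]]$mask)
  ref <- floor(c(dims[2], dims[1]) / 2) + 1  # (x, y) central pixel
  out <- matrix(TRUE, dims[1], dims[2])
  for (p in profiles) {
    sh <- shift_mask(p$mask, round(ref[1] - p$center[1]),
                     round(ref[2] - p$center[2]))
    out <- out & sh
  }
  out
}

# Integer translation of a logical matrix by (dx, dy) pixels (x = columns,
# y = rows); pixels shifted in from outside are FALSE.
shift_mask <- function(mask, dx, dy) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- mask[src_r[ok_r], src_c[ok_c]]
  out
}

#' Proportional overlap density of two image channels
#'
#' Elementwise square-root product of the two (non-negative) channel
#' matrices, smoothed with a 2-D Gaussian kernel of SD `smoothing_sd` pixels
#' (default 5). Symmetric in its channels; when a == b the result is the
#' smoothed channel itself.
#'
#' @param channel_a,channel_b Non-negative matrices of equal shape.
#' @param smoothing_sd Gaussian SD in pixels (default 5).
#' @return Matrix of class `overlap_density` values (attribute
#'   `smoothing_sd`).
#' @export
overlap_density <- function(channel_a, channel_b, smoothing_sd = 5) {
  if (!all(dim(channel_a) == dim(channel_b))) stop("channel shapes differ")
  if (min(channel_a) < 0 || min(channel_b) < 0) stop("negative pixels")
  prod <- sqrt(channel_a) * sqrt(channel_b)
  out <- gauss_smooth_2d(prod, smoothing_sd)
  attr(out, "smoothing_sd") <- smoothing_sd
  out
}

# Separable 2-D Gaussian smoothing, kernel truncated at +/-4 SD and
# renormalized at the borders (so a constant image stays constant).
gauss_smooth_2d <- function(img, sd_px) {
  if (sd_px <= 0) return(img)
  half <- ceiling(4 * sd_px)
  k <- stats::dnorm(-half:half, sd = sd_px)
  smooth1 <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    out <- matrix(0, nr, nc)
    for (i in seq_len(nr)) {
      lo <- max(1, i - half); hi <- min(nr, i + half)
      kk <- k[(lo - i + half + 1):(hi - i + half + 1)]
      out[i, ] <- crossprod(kk, m[lo:hi, , drop = FALSE]) / sum(kk)
    }
    out
  }
  t(smooth1(t(smooth1(img))))
}
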