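#' Viewing geometry for acuity control
#'
#' @param acuity_cpd Receiver spatial acuity in cycles per degree.
#' @param distance_mm Viewing distance in millimetres.
#' @param px_per_mra_target Output resolution: pixels per minimum resolvable
#'   angle after rescaling (default 5).
#' @return An object of class `"viewing_geometry"`.
#' @examples
#' viewing_geometry(6, 500)  # blue-tit acuity at half a metre
#' @export
viewing_geometry <- function(acuity_cpd, distance_mm, px_per_mra_target = 5) {
  vals <- c(acuity_cpd, distance_mm, px_per_mra_target)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("viewing geometry parameters must be positive", call. = FALSE)
  }
  structure(list(acuity_cpd = acuity_cpd, distance_mm = distance_mm,
                 px_per_mra_target = px_per_mra_target),
            class = "viewing_geometry")
}

#' @export
print.viewing_geometry <- function(x, ...) {
  cat(sprintf("<viewing_geometry: %.3g cpd at %.4g mm, %g px/MRA target>\n",
              x$acuity_cpd, x$distance_mm, x$px_per_mra_target))
  invisible(x)
}

#' Minimum resolvable angle geometry
#'
#' The minimum resolvable angle (MRA) is 1/acuity degrees. Its physical
#' span at the scene is `2 * distance * tan(MRA/2)` and its span in pixels
#' follows from the scene's pixel scale.
#'
#' @param g A [viewing_geometry()].
#' @param scale_px_per_mm Scene pixel scale (px per mm).
#' @return List with `mra_deg`, `mra_mm`, `mra_px`.
#' @export
mra_geometry <- function(g, scale_px_per_mm) {
  stopifnot(inherits(g, "viewing_geometry"))
  if (!is.finite(scale_px_per_mm) || scale_px_per_mm <= 0) {
    stop("scale_px_per_mm must be positive", call. = FALSE)
  }
  mra_deg <- 1 / g$acuity_cpd
  mra_mm <- 2 * g$distance_mm * tan((mra_deg / 2) * pi / 180)
  list(mra_deg = mra_deg, mra_mm = mra_mm,
       mra_px = mra_mm * scale_px_per_mm)
}

# Reflect-padded separable Gaussian convolution of one matrix.
# sigma in pixels; kernel truncated at 4 sigma and renormalised, so the
# pixel mean is conserved up to numerical noise.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  m <- conv_cols_reflect(m, k)
  t(conv_cols_reflect(t(m), k))
}

# Convolve each column of m with kernel k using reflect padding.
conv_cols_reflect <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  n <- nrow(m)
  idx <- reflect_index(seq(1L - r, n + r), n)
  mp <- m[idx, , drop = FALSE]
  # band matrix: row i of the output takes kernel window i..i+2r of mp
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    out <- out + k[j] * mp[seq_len(n) + (j - 1L), , drop = FALSE]
  }
  out
}

# Reflect out-of-range indices into 1..n, half-sample symmetric
# (x[0] = x[1]): this boundary conserves the total for symmetric kernels.
# Applied iteratively so it also works for kernel radii exceeding n.
reflect_index <- function(i, n) {
  repeat {
    below <- i < 1L
    above <- i > n
    if (!any(below) && !any(above)) return(i)
    i[below] <- 1L - i[below]
    i[above] <- 2L * n + 1L - i[above]
  }
}

# Bilinear resize of a matrix to nrow_out x ncol_out (pixel-centre aligned).
resize_bilinear <- function(m, nrow_out, ncol_out) {
  src_r <- sample_positions(nrow(m), nrow_out)
  src_c <- sample_positions(ncol(m), ncol_out)
  r0 <- pmin(pmax(floor(src_r), 1L), nrow(m)); r1 <- pmin(r0 + 1L, nrow(m))
  c0 <- pmin(pmax(floor(src_c), 1L), ncol(m)); c1 <- pmin(c0 + 1L, ncol(m))
  wr <- matrix(pmin(pmax(src_r - r0, 0), 1), nrow_out, ncol_out)
  wc <- matrix(pmin(pmax(src_c - c0, 0), 1), nrow_out, ncol_out, byrow = TRUE)
  top <- m[r0, c0, drop = FALSE] * (1 - wc) + m[r0, c1, drop = FALSE] * wc
  bot <- m[r1, c0, drop = FALSE] * (1 - wc) + m[r1, c1, drop = FALSE] * wc
  top * (1 - wr) + bot * wr
}

# Nearest-neighbour resize (for integer label masks).
resize_nearest <- function(m, nrow_out, ncol_out) {
  src_r <- pmin(pmax(round(sample_positions(nrow(m), nrow_out)), 1L), nrow(m))
  src_c <- pmin(pmax(round(sample_positions(ncol(m), ncol_out)), 1L), ncol(m))
  m[src_r, src_c, drop = FALSE]
}

# Source-coordinate positions (1-based, pixel centres) for resizing n -> n_out.
sample_positions <- function(n, n_out) {
  (seq_len(n_out) - 0.5) * n / n_out + 0.5
}

#' Gaussian acuity control: blur and rescale for a receiver and distance
#'
#' Models the loss of spatial information at a given acuity and viewing
#' distance: every channel is blurred with a Gaussian whose full width at
#' half maximum equals one minimum resolvable angle (MRA) in pixels
#' (sigma = mra_px / 2.355), then bilinearly rescaled so that one MRA spans
#' `px_per_mra_target` pixels. A mask, if supplied, is rescaled with
#' nearest-neighbour interpolation so labels stay integers.
#'
#' The whole image is processed (not individual ROIs). If the computed MRA
#' is below 2 px the scene is already at or below receiver resolution; a
#' warning is issued and only a minimal blur is applied.
#'
#' @param img A [catch_image()].
#' @param g A [viewing_geometry()].
#' @param mask Optional [roi_mask()] to carry through the rescaling.
#' @return A [catch_image()] (with attribute `"mask"` holding the rescaled
#'   [roi_mask()] when `mask` was given). The output `scale_px_per_mm`
#'   reflects the rescaled pixel size.
#' @export
apply_acuity <- function(img, g, mask = NULL) {
  stopifnot(inherits(img, "catch_image"), inherits(g, "viewing_geometry"))
  d <- dim(img)
  if (any(d == 0)) stop("empty image", call. = FALSE)
  geo <- mra_geometry(g, img$scale_px_per_mm)
  mra_px <- geo$mra_px
  if (mra_px < 2) {
    warning(sprintf(
      "MRA is %.2f px (< 2): image is at/below receiver resolution; applying minimal blur",
      mra_px), call. = FALSE)
    mra_px <- 2
  }
  sigma <- mra_px / 2.355  # FWHM -> sigma
  factor <- g$px_per_mra_target / mra_px
  nrow_out <- max(1L, round(d[1] * factor))
  ncol_out <- max(1L, round(d[2] * factor))
  chans <- lapply(img$channels, function(m) {
    resize_bilinear(gaussian_blur(m, sigma), nrow_out, ncol_out)
  })
  out <- catch_image(chans, img$scale_px_per_mm * nrow_out / d[1],
                     img$receptor_names)
  if (!is.null(mask)) {
    rm2 <- resize_nearest(unclass(mask), nrow_out, ncol_out)
    attr(out, "mask") <- roi_mask(rm2, require_both = FALSE)
  }
  out
}
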