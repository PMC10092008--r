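#' Octave-spaced spatial scales for granularity analysis
#'
#' Geometric sequence of pattern scales (in pixels): `min_px`,
#' `min_px * multiplier`, ... capped at the smaller of `max_px` and the
#' largest image dimension. Defaults follow the convention of a step
#' multiplier of two from 2 px up to 1200 px.
#'
#' @param image_size Integer vector (dimensions of the image to be
#'   analysed); scales never exceed its maximum.
#' @param min_px Smallest scale (>= 2).
#' @param max_px Largest allowed scale.
#' @param multiplier Geometric step (> 1).
#' @return Increasing numeric vector of scales in pixels.
#' @examples
#' band_scales(c(512, 512))  # 2 4 8 ... 512
#' @export
band_scales <- function(image_size, min_px = 2, max_px = 1200,
                        multiplier = 2) {
  if (min_px < 2) stop("min_px must be at least 2", call. = FALSE)
  if (multiplier <= 1) stop("multiplier must exceed 1", call. = FALSE)
  cap <- min(max_px, max(image_size))
  if (cap < min_px) {
    stop("image smaller than the minimum pattern scale", call. = FALSE)
  }
  n <- floor(log(cap / min_px, base = multiplier)) + 1
  min_px * multiplier^(seq_len(n) - 1)
}

# fft frequencies in cycles/px for length n (R convention, DC first)
fft_freq <- function(n) {
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)
  if (n == 1) k <- 0
  k[seq_len(n)] / n
}

# Squared radial frequency grid for an nr x nc image.
freq_sq_grid <- function(nr, nc) {
  outer(fft_freq(nr)^2, fft_freq(nc)^2, "+")
}

# Band transfer functions: power-complementary differences of super-
# Gaussian (order 2) low-passes. The low-pass with cutoff period w has
# power 2^-((f w)^4) — half power at period w, with a steeper shoulder
# than a plain Gaussian, close to the sharp ring filters granularity
# toolboxes use. The band at scale s is the difference of the chained
# low-passes with cutoff periods s/sqrt(m) and s*sqrt(m): peak response
# sits at period s and the band powers telescope across octaves. With
# complete_highpass the finest band absorbs all remaining fine structure,
# so band powers tile the spectrum (minus a small residual beyond the
# coarsest scale).
band_transfer_power <- function(f2, scale, multiplier, finest,
                                complete_highpass) {
  p_hi <- if (finest && complete_highpass) {
    1
  } else {
    2^(-(f2 * (scale / sqrt(multiplier))^2)^2)
  }
  p_lo <- 2^(-(f2 * (scale * sqrt(multiplier))^2)^2)
  pmax(p_hi - p_lo, 0)
}

#' Bandpass decomposition of an image across pattern scales
#'
#' Fourier-domain filtering: the image (mean-subtracted) is multiplied by a
#' bandpass transfer function per scale and transformed back. Bands are
#' zero-mean. The per-scale filters are power-complementary differences of
#' chained super-Gaussian low-passes whose half-power cutoffs are
#' geometrically centred on the scale, so band variances approximately tile
#' the image's total variance and a pure sinusoid loads predominantly on
#' the band matching its period; the finest band is completed to a residual
#' high-pass by default.
#'
#' @param m Numeric matrix (one image channel).
#' @param scales Scales in px, e.g. from [band_scales()].
#' @param multiplier Geometric step used to build `scales`.
#' @param complete_highpass Fold all structure finer than the smallest scale
#'   into the finest band (default `TRUE`).
#' @return Named list of zero-mean matrices, one per scale.
#' @export
bandpass_stack <- function(m, scales, multiplier = 2,
                           complete_highpass = TRUE) {
  if (!is.matrix(m) || !is.numeric(m)) stop("m must be a numeric matrix",
                                            call. = FALSE)
  if (anyNA(m)) stop("image contains NA/NaN pixels", call. = FALSE)
  nr <- nrow(m); nc <- ncol(m)
  f2 <- freq_sq_grid(nr, nc)
  fm <- stats::fft(m - mean(m))
  finest <- which.min(scales)
  out <- lapply(seq_along(scales), function(i) {
    h <- sqrt(band_transfer_power(f2, scales[i], multiplier,
                                  finest = (i == finest),
                                  complete_highpass = complete_highpass))
    Re(stats::fft(fm * h, inverse = TRUE)) / (nr * nc)
  })
  names(out) <- as.character(scales)
  out
}

#' Pattern energy spectrum of one ROI
#'
#' Granularity analysis: the image channel is bandpass-filtered at
#' octave-spaced scales and the pattern "energy" at each scale is the
#' standard deviation of the filtered pixel values within the ROI.
#' Filtering always runs on the full image (masked-out, label-0 pixels are
#' replaced by the mean of the labelled pixels before the FFT to avoid edge
#' artefacts); only the energy measurement is restricted to the ROI.
#'
#' @param img A [catch_image()] (or a bare numeric matrix).
#' @param mask A [roi_mask()], or `NULL` to use every pixel.
#' @param roi_label ROI to measure (1 = animal, 2 = background). Ignored
#'   when `mask` is `NULL`.
#' @param scales Scales in px; default [band_scales()] for this image.
#' @param channel Channel name to analyse; default the last channel
#'   (conventionally the luminance/double-cone channel, which is assumed to
#'   mediate pattern perception in birds).
#' @param normalize Divide energies by their sum (default `TRUE`); skipped
#'   with `normalized = FALSE` in the result when total energy is zero.
#' @param multiplier Geometric step for the filter bank.
#' @return A `"pattern_spectrum"`: list with `scales_px`, `energies`,
#'   `normalized`, `roi_label`, `channel`.
#' @export
pattern_energy_spectrum <- function(img, mask = NULL, roi_label = 1L,
                                    scales = NULL, channel = NULL,
                                    normalize = TRUE, multiplier = 2) {
  if (inherits(img, "catch_image")) {
    if (is.null(channel)) channel <- names(img$channels)[length(img$channels)]
    m <- img$channels[[channel]]
    if (is.null(m)) stop("no channel named ", channel, call. = FALSE)
  } else {
    m <- img
    if (is.null(channel)) channel <- "value"
  }
  if (is.null(scales)) scales <- band_scales(dim(m))
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(m))) stop("mask shape mismatch", call. = FALSE)
    sel <- mask == roi_label
    if (!any(sel)) stop("ROI label ", roi_label, " is empty", call. = FALSE)
    if (sum(sel) < 4) stop("ROI needs at least 4 pixels", call. = FALSE)
    labelled <- mask != 0L
    if (any(!labelled)) m[!labelled] <- mean(m[labelled])
  } else {
    sel <- matrix(TRUE, nrow(m), ncol(m))
    roi_label <- NA_integer_
  }
  bands <- bandpass_stack(m, scales, multiplier = multiplier)
  energies <- vapply(bands, function(b) stats::sd(b[sel]), 0)
  normalized <- FALSE
  if (normalize) {
    tot <- sum(energies)
    if (tot > 0) {
      energies <- energies / tot
      normalized <- TRUE
    } else {
      warning("total pattern energy is zero; normalization skipped",
              call. = FALSE)
    }
  }
  structure(list(scales_px = scales,
                 energies = stats::setNames(unname(energies),
                                            as.character(scales)),
                 normalized = normalized, roi_label = roi_label,
                 channel = channel),
            class = "pattern_spectrum")
}

#' @export
print.pattern_spectrum <- function(x, ...) {
  cat(sprintf("<pattern_spectrum: roi %s, channel %s%s>\n",
              x$roi_label, x$channel,
              if (x$normalized) ", normalized" else ""))
  print(round(x$energies, 4))
  invisible(x)
}

#' Pattern energy difference (PED) between two pattern spectra
#'
#' Aggregate absolute difference between two granularity spectra across all
#' spatial scales; low values indicate similar pattern, i.e. good background
#' pattern matching. The default is the sum of per-scale absolute
#' differences of unit-sum normalized spectra (a total-variation-style
#' metric bounded by 2); `aggregate = "mean"` divides by the number of
#' scales, and raw (unnormalized) spectra are accepted as long as both
#' spectra share the same normalization state.
#'
#' @param a,b `pattern_spectrum`s on identical scales with the same
#'   normalization state.
#' @param aggregate `"sum"` (default) or `"mean"` over scales.
#' @return A `"ped_result"`: list with `ped`, `per_scale`, `scales_px`,
#'   `aggregate`, `normalized`.
#' @export
ped <- function(a, b, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(a, "pattern_spectrum"), inherits(b, "pattern_spectrum"))
  if (length(a$scales_px) != length(b$scales_px) ||
      any(a$scales_px != b$scales_px)) {
    stop("pattern spectra are on different scales", call. = FALSE)
  }
  if (!identical(a$normalized, b$normalized)) {
    stop("pattern spectra differ in normalization state", call. = FALSE)
  }
  d <- abs(a$energies - b$energies)
  val <- if (aggregate == "sum") sum(d) else mean(d)
  structure(list(ped = unname(val), per_scale = d, scales_px = a$scales_px,
                 aggregate = aggregate, normalized = a$normalized),
            class = "ped_result")
}

#' @export
print.ped_result <- function(x, ...) {
  cat(sprintf("<ped: %.4f (%s over %d scales%s)>\n", x$ped, x$aggregate,
              length(x$scales_px), if (x$normalized) ", normalized" else ""))
  invisible(x)
}
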