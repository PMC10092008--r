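# Evaluate expr under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Texture generator configuration
#'
#' Describes a synthetic substrate or wing texture. `lichen` and `moth`
#' textures are two-tone, high-contrast blotch patterns (thresholded
#' band-filtered Gaussian random fields); `bark` is a low-contrast texture
#' striated vertically by an anisotropic stretch.
#'
#' @param class `"lichen"`, `"bark"` or `"moth"`.
#' @param characteristic_scale_px Dominant blotch/striation scale (>= 2 px).
#' @param contrast Two-tone level separation in `[0, 1]`; defaults: 0.8 for
#'   lichen, 0.9 for moth (high-contrast black-and-white wings), 0.25 for
#'   bark.
#' @param anisotropy Vertical stretch factor (bark only; default 4).
#' @param seed RNG seed; the output is reproducible bit-for-bit.
#' @return A `"texture_config"` list.
#' @export
texture_config <- function(class = c("lichen", "bark", "moth"),
                           characteristic_scale_px = 32,
                           contrast = NULL, anisotropy = 4, seed = 1L) {
  class <- match.arg(class)
  if (characteristic_scale_px < 2) stop("scale must be >= 2 px", call. = FALSE)
  if (is.null(contrast)) {
    contrast <- switch(class, lichen = 0.8, moth = 0.9, bark = 0.25)
  }
  if (contrast < 0 || contrast > 1) stop("contrast must be in [0,1]",
                                         call. = FALSE)
  if (anisotropy < 1) stop("anisotropy must be >= 1", call. = FALSE)
  structure(list(class = class,
                 characteristic_scale_px = characteristic_scale_px,
                 contrast = contrast,
                 anisotropy = if (class == "bark") anisotropy else 1,
                 seed = as.integer(seed)),
            class = "texture_config")
}

#' Generate a synthetic texture
#'
#' A Gaussian white-noise field is bandpass-filtered at the configured
#' characteristic scale (anisotropically for bark), thresholded at its
#' median into two tones `0.5 +/- contrast/2`, and dusted with a little
#' fine-grained speckle (amplitude proportional to contrast) so the texture
#' is not perfectly binary. The empirical pattern-energy spectrum of the
#' output peaks within an octave of the configured scale.
#'
#' @param cfg A [texture_config()].
#' @param size Output size in px, length-1 or length-2 (rows, cols); must be
#'   at least 4x the characteristic scale.
#' @return Numeric matrix in `[0, 1]`.
#' @export
gen_texture <- function(cfg, size = c(256, 256)) {
  stopifnot(inherits(cfg, "texture_config"))
  if (length(size) == 1) size <- c(size, size)
  s <- cfg$characteristic_scale_px
  if (min(size) < 4 * s) {
    stop("size must be at least 4x the characteristic scale", call. = FALSE)
  }
  with_seed(cfg$seed, {
    noise <- matrix(stats::rnorm(prod(size)), size[1], size[2])
    speckle <- matrix(stats::rnorm(prod(size)), size[1], size[2])
    # anisotropic squared-frequency grid: stretching row frequencies by the
    # anisotropy factor elongates structure vertically
    f2 <- outer((fft_freq(size[1]) * cfg$anisotropy)^2, fft_freq(size[2])^2,
                "+")
    h <- sqrt(band_transfer_power(f2, s, multiplier = 2, finest = FALSE,
                                  complete_highpass = FALSE))
    field <- Re(stats::fft(stats::fft(noise) * h, inverse = TRUE)) /
      prod(size)
    tones <- ifelse(field > stats::median(field), 0.5 + cfg$contrast / 2,
                    0.5 - cfg$contrast / 2)
    out <- tones + 0.03 * cfg$contrast * speckle
    pmin(pmax(out, 0), 1)
  })
}

#' Compose a synthetic moth-on-background scene
#'
#' Fills the scene with a background texture, composites an elliptical
#' moth-shaped patch of wing texture at the centre, and derives per-receptor
#' catch-like channels from the grey texture through per-channel affine
#' maps, so chromatic and achromatic offsets between moth and background
#' are controllable. The default moth spans 22 mm (a typical resting
#' wingspan for the modelled species) at 10 px/mm.
#'
#' @param moth_cfg,bg_cfg [texture_config()]s for wing and substrate.
#' @param size Scene size in px (length 1 or 2).
#' @param scale_px_per_mm Scene pixel scale (default 10).
#' @param moth_span_mm Moth major-axis span in mm (default 22).
#' @param aspect Minor/major axis ratio of the moth ellipse (default 0.6).
#' @param channels Receptor channel names for the output stack.
#' @param gains,offsets Per-channel affine map `gain * grey + offset`
#'   (recycled; defaults 1 and 0.05).
#' @param moth_shift Per-channel additive shift applied inside the moth
#'   ROI only (recycled; default 0). Nonzero values introduce a chromatic
#'   and/or achromatic moth-background offset.
#' @return List with `image` (a [catch_image()]), `mask` (a [roi_mask()]:
#'   1 = moth, 2 = background), and `grey` (the composited texture).
#' @export
gen_scene <- function(moth_cfg, bg_cfg, size = c(512, 512),
                      scale_px_per_mm = 10, moth_span_mm = 22, aspect = 0.6,
                      channels = c("uv", "sw", "mw", "lw", "dbl"),
                      gains = 1, offsets = 0.05, moth_shift = 0) {
  if (length(size) == 1) size <- c(size, size)
  major_px <- moth_span_mm * scale_px_per_mm
  minor_px <- aspect * major_px
  if (major_px > min(size)) stop("moth larger than scene", call. = FALSE)
  bg <- gen_texture(bg_cfg, size)
  moth <- gen_texture(moth_cfg, size)
  cy <- (size[1] + 1) / 2; cx <- (size[2] + 1) / 2
  yy <- matrix(seq_len(size[1]), size[1], size[2])
  xx <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE)
  # moth span is horizontal: major axis along columns
  inside <- ((xx - cx) / (major_px / 2))^2 +
            ((yy - cy) / (minor_px / 2))^2 <= 1
  grey <- bg
  grey[inside] <- moth[inside]
  mask <- roi_mask(matrix(ifelse(inside, 1L, 2L), size[1], size[2]))
  gains <- rep_len(gains, length(channels))
  offsets <- rep_len(offsets, length(channels))
  moth_shift <- rep_len(moth_shift, length(channels))
  chans <- stats::setNames(lapply(seq_along(channels), function(i) {
    ch <- gains[i] * grey + offsets[i]
    ch[inside] <- ch[inside] + moth_shift[i]
    pmax(ch, 1e-6)
  }), channels)
  list(image = catch_image(chans, scale_px_per_mm, channels), mask = mask,
       grey = grey)
}

#' Predation simulation configuration
#'
#' Emulates an interval-checked field predation experiment: per-treatment
#' constant hazards, a fixed number of model replicates per treatment, and
#' checks at 24/48/72 h with right-censoring at the final check.
#'
#' @param hazards Named nonnegative numeric vector of attack rates
#'   (events/hour) per treatment.
#' @param n_per_treatment Replicates per treatment (default 100).
#' @param check_times_h Increasing check times (default `c(24, 48, 72)`).
#' @param record `"check"` (default): attack times are rounded up to the
#'   next check time, producing the heavily tied data of an
#'   interval-checked field design; `"exact"`: continuous event times are
#'   kept (censoring still at the last check), giving tie-free data.
#' @param seed RNG seed.
#' @return A `"predation_sim_config"` list.
#' @export
predation_sim_config <- function(hazards, n_per_treatment = 100,
                                 check_times_h = c(24, 48, 72),
                                 record = c("check", "exact"), seed = 1L) {
  record <- match.arg(record)
  if (is.null(names(hazards)) || any(names(hazards) == "")) {
    stop("hazards must be named by treatment", call. = FALSE)
  }
  if (any(hazards < 0)) stop("hazards must be nonnegative", call. = FALSE)
  if (any(diff(check_times_h) <= 0) || any(check_times_h <= 0)) {
    stop("check times must be positive and increasing", call. = FALSE)
  }
  structure(list(hazards = hazards, n_per_treatment = n_per_treatment,
                 check_times_h = check_times_h, record = record,
                 seed = as.integer(seed)),
            class = "predation_sim_config")
}

#' Simulate an interval-checked predation event table
#'
#' True attack times are exponential with the treatment's hazard; an attack
#' is recorded at the first check time at or after the true time (status 1),
#' and replicates surviving past the last check are censored there
#' (status 0).
#'
#' @param cfg A [predation_sim_config()].
#' @return An [event_table()] with columns `replicate_id`, `treatment`,
#'   `time_h`, `status`.
#' @export
gen_predation_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "predation_sim_config"))
  checks <- cfg$check_times_h
  end <- checks[length(checks)]
  with_seed(cfg$seed, {
    rows <- lapply(names(cfg$hazards), function(tr) {
      h <- cfg$hazards[[tr]]
      n <- cfg$n_per_treatment
      true_t <- if (h > 0) stats::rexp(n, rate = h) else rep(Inf, n)
      rec_t <- if (cfg$record == "exact") {
        pmin(true_t, end)
      } else {
        vapply(true_t, function(tt) {
          i <- which(checks >= tt)
          if (length(i) == 0) end else checks[min(i)]
        }, 0)
      }
      status <- as.integer(true_t <= end)
      rec_t[status == 0L] <- end
      data.frame(replicate_id = paste0(tr, "_", seq_len(n)), treatment = tr,
                 time_h = rec_t, status = status)
    })
    event_table(do.call(rbind, rows))
  })
}

#' Generate a Gaussian-sensitivity receptor set
#'
#' Builds Gaussian spectral sensitivity curves at the given peak
#' wavelengths plus a broad luminance (double-cone-like) channel, and
#' derives Weber fractions from the relative abundances. The default is a
#' blue-tit-like tetrachromat fixture (peaks 372/449/502/563 nm, relative
#' cone densities 1:1.92:2.68:2.7, reference Weber fraction 0.05): a
#' clearly labelled approximation, since measured sensitivities for any
#' particular receiver should be supplied by the user when available.
#'
#' @param lambda_max Named numeric vector of chromatic peak wavelengths
#'   (nm).
#' @param widths Gaussian SDs in nm (recycled; default 40).
#' @param abundances Relative cone densities (recycled).
#' @param reference_weber Weber fraction of the most abundant class.
#' @param luminance_lambda_max,luminance_width Peak and SD of the broad
#'   luminance channel (default 560 / 90 nm).
#' @param luminance_name Name of the luminance channel (default `"dbl"`).
#' @param wl_range Wavelength support (default 300-700 nm, 1-nm steps).
#' @return A [receptor_set()].
#' @export
gen_receptor_set <- function(lambda_max = c(uv = 372, sw = 449, mw = 502,
                                            lw = 563),
                             widths = 40,
                             abundances = c(1, 1.92, 2.68, 2.7),
                             reference_weber = 0.05,
                             luminance_lambda_max = 560,
                             luminance_width = 90,
                             luminance_name = "dbl",
                             wl_range = c(300, 700)) {
  nm <- names(lambda_max)
  if (is.null(nm) || anyDuplicated(c(nm, luminance_name))) {
    stop("channel names must be unique and non-empty", call. = FALSE)
  }
  wl <- seq(wl_range[1], wl_range[2], by = 1)
  if (any(lambda_max < wl_range[1]) || any(lambda_max > wl_range[2])) {
    stop("lambda_max outside the wavelength support", call. = FALSE)
  }
  widths <- rep_len(widths, length(lambda_max))
  abundances <- rep_len(abundances, length(lambda_max))
  sens <- stats::setNames(lapply(seq_along(lambda_max), function(i) {
    spectrum(wl, exp(-((wl - lambda_max[i])^2) / (2 * widths[i]^2)),
             "sensitivity")
  }), nm)
  sens[[luminance_name]] <- spectrum(
    wl, exp(-((wl - luminance_lambda_max)^2) / (2 * luminance_width^2)),
    "sensitivity")
  # the luminance channel carries the reference Weber fraction
  ab <- c(abundances, max(abundances))
  receptor_set(sens, ab, luminance_channel = luminance_name,
               reference_weber = reference_weber)
}

#' Flat spectrum of constant value
#'
#' @param value Constant level.
#' @param kind Spectrum kind (default `"reflectance"`).
#' @param wl_range Wavelength support (nm).
#' @param step Grid step (nm).
#' @return A [spectrum()].
#' @export
flat_spectrum <- function(value, kind = "reflectance",
                          wl_range = c(300, 700), step = 1) {
  wl <- seq(wl_range[1], wl_range[2], by = step)
  spectrum(wl, rep(value, length(wl)), kind, allow_above_one = TRUE)
}

#' Generate a smooth random reflectance spectrum
#'
#' Sum of a few random Gaussian bumps, squashed into (0, 1); useful as a
#' stand-in for measured wing or substrate reflectances.
#'
#' @param seed RNG seed.
#' @param n_bumps Number of Gaussian bumps (default 3).
#' @param wl_range Wavelength support (nm).
#' @return A reflectance [spectrum()].
#' @export
gen_reflectance <- function(seed = 1L, n_bumps = 3, wl_range = c(300, 700)) {
  wl <- seq(wl_range[1], wl_range[2], by = 1)
  with_seed(seed, {
    centres <- stats::runif(n_bumps, wl_range[1], wl_range[2])
    sds <- stats::runif(n_bumps, 30, 120)
    amps <- stats::runif(n_bumps, -1.5, 1.5)
    v <- rowSums(vapply(seq_len(n_bumps), function(i) {
      amps[i] * exp(-((wl - centres[i])^2) / (2 * sds[i]^2))
    }, numeric(length(wl))))
    spectrum(wl, stats::plogis(v), "reflectance")
  })
}
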