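#' Scale Weber fractions from relative receptor abundances
#'
#' In the receptor-noise-limited model the noise of channel i scales with
#' the inverse square root of its relative cone density eta_i:
#' omega_i = nu * sqrt(eta_max / eta_i), so the most abundant receptor class
#' carries the reference Weber fraction nu.
#'
#' @param abundances Positive numeric vector of relative cone densities.
#' @param reference_weber Positive scalar: Weber fraction of the most
#'   abundant receptor class (default 0.05, the conventional avian value).
#' @return Numeric vector of per-receptor Weber fractions, names preserved.
#' @examples
#' weber_fractions(c(1, 4), 0.1)  # c(0.2, 0.1)
#' @export
weber_fractions <- function(abundances, reference_weber = 0.05) {
  abundances <- as.numeric(abundances)
  if (any(!is.finite(abundances)) || any(abundances <= 0)) {
    stop("abundances must be positive", call. = FALSE)
  }
  if (!is.finite(reference_weber) || reference_weber <= 0) {
    stop("reference_weber must be positive", call. = FALSE)
  }
  reference_weber * sqrt(max(abundances) / abundances)
}

#' Construct a receptor set
#'
#' Bundles the receiver's spectral sensitivities with relative abundances,
#' Weber fractions and the designated luminance (double-cone) channel. The
#' chromatic channels are all channels except the luminance channel; at
#' least two are required for colour discrimination.
#'
#' @param sensitivities Named list of [spectrum()] objects (kind
#'   `"sensitivity"`), one per receptor, in channel order.
#' @param abundances Named or positional positive numerics, one per channel.
#' @param weber Per-receptor Weber fractions; if `NULL`, derived from
#'   `abundances` via [weber_fractions()] with `reference_weber`.
#' @param luminance_channel Name of the achromatic channel (default: last).
#' @param reference_weber See [weber_fractions()].
#' @return An object of class `"receptor_set"`.
#' @export
receptor_set <- function(sensitivities, abundances, weber = NULL,
                         luminance_channel = NULL, reference_weber = 0.05) {
  nm <- names(sensitivities)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("sensitivities must be a uniquely named list", call. = FALSE)
  }
  if (!all(vapply(sensitivities, inherits, TRUE, "spectrum"))) {
    stop("each sensitivity must be a spectrum", call. = FALSE)
  }
  if (length(abundances) != length(nm)) {
    stop("one abundance per receptor required", call. = FALSE)
  }
  abundances <- stats::setNames(as.numeric(abundances), nm)
  if (any(abundances <= 0)) stop("abundances must be positive", call. = FALSE)
  if (is.null(weber)) {
    weber <- weber_fractions(abundances, reference_weber)
  }
  weber <- stats::setNames(as.numeric(weber), nm)
  if (any(weber <= 0)) stop("Weber fractions must be positive", call. = FALSE)
  if (is.null(luminance_channel)) luminance_channel <- nm[length(nm)]
  if (!luminance_channel %in% nm) {
    stop("luminance_channel must name one of the receptors", call. = FALSE)
  }
  if (length(setdiff(nm, luminance_channel)) < 2) {
    stop("need at least two chromatic channels besides the luminance channel",
         call. = FALSE)
  }
  structure(list(names = nm, sensitivities = sensitivities,
                 abundances = abundances, weber = weber,
                 luminance_channel = luminance_channel),
            class = "receptor_set")
}

#' @export
print.receptor_set <- function(x, ...) {
  cat(sprintf("<receptor_set: %s; luminance = %s>\n",
              paste(x$names, collapse = ", "), x$luminance_channel))
  cat("  weber:", paste(sprintf("%s=%.4g", x$names, x$weber), collapse = " "),
      "\n")
  invisible(x)
}

#' Chromatic channel names of a receptor set
#' @param recs A [receptor_set()].
#' @return Character vector of channel names excluding the luminance channel.
#' @export
chromatic_channels <- function(recs) {
  stopifnot(inherits(recs, "receptor_set"))
  setdiff(recs$names, recs$luminance_channel)
}

#' Read a receptor set from a directory of CSV spectra plus a JSON config
#'
#' The config (`receptors.json`) names the channels in order and gives, per
#' channel, the sensitivity CSV file, abundance and optionally Weber
#' fraction, plus the `luminance_channel`.
#'
#' @param dir Directory containing `receptors.json` and the CSVs it names.
#' @return A [receptor_set()].
#' @export
read_receptor_set <- function(dir) {
  cfg_path <- file.path(dir, "receptors.json")
  if (!file.exists(cfg_path)) stop("no receptors.json in ", dir, call. = FALSE)
  cfg <- jsonlite::fromJSON(cfg_path, simplifyVector = TRUE)
  ch <- cfg$channels
  sens <- stats::setNames(lapply(ch$file, function(f) {
    read_spectrum_csv(file.path(dir, f), kind = "sensitivity")
  }), ch$name)
  weber <- if ("weber" %in% names(ch)) ch$weber else NULL
  receptor_set(sens, ch$abundance, weber = weber,
               luminance_channel = cfg$luminance_channel,
               reference_weber = if (is.null(cfg$reference_weber)) 0.05
                                 else cfg$reference_weber)
}

#' Write a receptor set as a directory of CSV spectra plus JSON config
#'
#' @param recs A [receptor_set()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_receptor_set <- function(recs, dir) {
  stopifnot(inherits(recs, "receptor_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- paste0(recs$names, ".csv")
  for (i in seq_along(recs$names)) {
    write_spectrum_csv(recs$sensitivities[[i]], file.path(dir, files[i]))
  }
  cfg <- list(
    channels = data.frame(name = recs$names, file = files,
                          abundance = unname(recs$abundances),
                          weber = unname(recs$weber)),
    luminance_channel = recs$luminance_channel)
  jsonlite::write_json(cfg, file.path(dir, "receptors.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
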