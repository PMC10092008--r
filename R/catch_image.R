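#' Construct a catch image
#'
#' A per-pixel stack of quantum-catch channels: a named list of equal-shaped
#' nonnegative matrices plus the physical pixel scale.
#'
#' @param channels Named list of numeric matrices, one per receptor channel.
#' @param scale_px_per_mm Positive pixel scale (px per mm in the scene).
#' @param receptor_names Optional character vector documenting the receptor
#'   set the channels correspond to (defaults to `names(channels)`).
#' @return An object of class `"catch_image"`.
#' @export
catch_image <- function(channels, scale_px_per_mm,
                        receptor_names = names(channels)) {
  nm <- names(channels)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("channels must be a uniquely named list of matrices", call. = FALSE)
  }
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m) || !is.numeric(m), TRUE))) {
    stop("each channel must be a numeric matrix", call. = FALSE)
  }
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1) {
    stop("all channels must share one shape", call. = FALSE)
  }
  if (!is.finite(scale_px_per_mm) || scale_px_per_mm <= 0) {
    stop("scale_px_per_mm must be positive", call. = FALSE)
  }
  structure(list(channels = channels, scale_px_per_mm = scale_px_per_mm,
                 receptor_names = receptor_names),
            class = "catch_image")
}

#' @export
print.catch_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<catch_image: %dx%d px, %d channel(s) [%s], %.3g px/mm>\n",
              d[1], d[2], length(x$channels),
              paste(names(x$channels), collapse = ", "), x$scale_px_per_mm))
  invisible(x)
}

#' @export
dim.catch_image <- function(x) dim(x$channels[[1]])

#' Construct an ROI label mask
#'
#' Integer label image with the convention 0 = ignore, 1 = animal,
#' 2 = background sample.
#'
#' @param labels Integer matrix with values in `{0, 1, 2}`.
#' @param require_both Require labels 1 and 2 each non-empty.
#' @return An object of class `"roi_mask"` (an integer matrix).
#' @export
roi_mask <- function(labels, require_both = TRUE) {
  if (!is.matrix(labels)) stop("labels must be a matrix", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (!all(labels %in% 0:2)) {
    stop("mask labels must be 0 (ignore), 1 (animal) or 2 (background)",
         call. = FALSE)
  }
  if (require_both && (!any(labels == 1L) || !any(labels == 2L))) {
    stop("mask must contain both label 1 (animal) and label 2 (background)",
         call. = FALSE)
  }
  structure(labels, class = c("roi_mask", "matrix", "array"))
}

#' Map a calibrated multi-channel image to quantum-catch channels
#'
#' Applies a user-supplied linear mapping (camera channels to receptor
#' channels) per pixel. The mapping matrix is estimated elsewhere (e.g. by a
#' camera-characterisation regression); here it is taken as given. Negative
#' results are clamped to a small positive epsilon (1e-6 of the channel
#' maximum) with a warning, because the log-form contrasts downstream
#' require positivity.
#'
#' @param img Named list of camera-channel matrices (linear,
#'   white-standard-normalised) or a `catch_image`.
#' @param mapping Numeric matrix, `n_receptors x n_camera_channels`; row
#'   names become the receptor channel names.
#' @param scale_px_per_mm Pixel scale of the scene.
#' @return A [catch_image()] with one channel per mapping row.
#' @export
image_to_catch <- function(img, mapping, scale_px_per_mm) {
  chans <- if (inherits(img, "catch_image")) img$channels else img
  if (!is.matrix(mapping)) stop("mapping must be a matrix", call. = FALSE)
  if (ncol(mapping) != length(chans)) {
    stop(sprintf("mapping has %d columns but image has %d channels",
                 ncol(mapping), length(chans)), call. = FALSE)
  }
  d <- dim(chans[[1]])
  flat <- vapply(chans, as.numeric, numeric(prod(d)))  # pixels x cam-channels
  out <- flat %*% t(mapping)                           # pixels x receptors
  rn <- rownames(mapping)
  if (is.null(rn)) rn <- paste0("r", seq_len(nrow(mapping)))
  res <- list()
  n_clamped <- 0L
  for (j in seq_len(ncol(out))) {
    v <- out[, j]
    mx <- max(v)
    if (mx <= 0) {
      stop("degenerate catch: channel ", rn[j],
           " is nonpositive everywhere after mapping", call. = FALSE)
    }
    neg <- v < 0
    if (any(neg)) {
      v[neg] <- 1e-6 * mx
      n_clamped <- n_clamped + sum(neg)
    }
    res[[rn[j]]] <- matrix(v, d[1], d[2])
  }
  if (n_clamped > 0) {
    warning(sprintf("clamped %d negative pixel catch(es) to 1e-6 of channel max",
                    n_clamped), call. = FALSE)
  }
  catch_image(res, scale_px_per_mm)
}

#' Mean quantum catch of each channel within one ROI
#'
#' @param img A [catch_image()].
#' @param mask A [roi_mask()] of the same shape.
#' @param roi_label Which label to average over (1 = animal, 2 = background).
#' @return A `"catch_vector"` of per-channel ROI means.
#' @export
roi_mean_catch <- function(img, mask, roi_label) {
  stopifnot(inherits(img, "catch_image"))
  if (!all(dim(mask) == dim(img))) {
    stop("mask shape does not match image", call. = FALSE)
  }
  sel <- mask == roi_label
  if (!any(sel)) stop("ROI label ", roi_label, " is empty", call. = FALSE)
  q <- vapply(img$channels, function(m) mean(m[sel]), 0)
  catch_vector(q, adapted = FALSE)
}

# --- plain-text image I/O -------------------------------------------------
# No PNG/TIFF reader ships with the installed R stack, so masks and single
# channels travel as ASCII PGM (P2) and catch images as per-channel CSVs.

#' Read an ASCII PGM (P2) image
#'
#' @param path PGM file path.
#' @return Integer matrix of pixel values (rows = image rows).
#' @export
read_pgm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^\\s*#", txt)]
  tok <- scan(text = paste(txt, collapse = " "), what = "", quiet = TRUE)
  if (tok[1] != "P2") stop("only ASCII PGM (P2) is supported", call. = FALSE)
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  vals <- as.integer(tok[-(1:4)])
  if (length(vals) != w * h) stop("PGM pixel count mismatch", call. = FALSE)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a matrix as ASCII PGM (P2)
#'
#' @param m Numeric matrix; values are rounded to integers.
#' @param path Output path.
#' @param maxval Maximum grey value declared in the header.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(m, path, maxval = max(1, max(round(m)))) {
  m <- round(m)
  if (any(m < 0) || any(m > maxval)) {
    stop("pixel values outside [0, maxval]", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(maxval)), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ROI mask from an ASCII PGM file
#' @param path PGM path with pixel values in `{0,1,2}`.
#' @param require_both See [roi_mask()].
#' @return A [roi_mask()].
#' @export
read_mask_pgm <- function(path, require_both = TRUE) {
  roi_mask(read_pgm(path), require_both = require_both)
}

#' Write a catch image as one CSV matrix per channel
#'
#' Files are named `<stem>_<channel>.csv`; a `<stem>_meta.json` records the
#' pixel scale and channel order.
#'
#' @param img A [catch_image()].
#' @param stem Path stem (directory must exist).
#' @return Character vector of files written, invisibly.
#' @export
write_catch_image_csv <- function(img, stem) {
  stopifnot(inherits(img, "catch_image"))
  files <- character(0)
  for (nm in names(img$channels)) {
    f <- paste0(stem, "_", nm, ".csv")
    utils::write.table(img$channels[[nm]], f, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    files <- c(files, f)
  }
  meta <- paste0(stem, "_meta.json")
  jsonlite::write_json(list(channels = names(img$channels),
                            scale_px_per_mm = img$scale_px_per_mm),
                       meta, auto_unbox = TRUE, digits = NA)
  invisible(c(files, meta))
}

#' Read a catch image written by [write_catch_image_csv()]
#' @param stem Path stem used when writing.
#' @return A [catch_image()].
#' @export
read_catch_image_csv <- function(stem) {
  meta <- jsonlite::fromJSON(paste0(stem, "_meta.json"))
  chans <- stats::setNames(lapply(meta$channels, function(nm) {
    as.matrix(utils::read.table(paste0(stem, "_", nm, ".csv"), sep = ","))
  }), meta$channels)
  chans <- lapply(chans, function(m) {
    dimnames(m) <- NULL
    m
  })
  catch_image(chans, meta$scale_px_per_mm)
}
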