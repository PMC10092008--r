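#' Quantum catch of a stimulus for each receptor
#'
#' Computes Q_i = integral of R(lambda) I(lambda) S_i(lambda) d lambda by the
#' trapezoid rule on a common 1-nm grid. With `vonkries = TRUE` each catch is
#' divided by the catch of a perfect (R = 1) white reflector under the same
#' illuminant, which makes catches invariant to rescaling of the illuminant
#' (von Kries chromatic adaptation).
#'
#' @param r Reflectance [spectrum()].
#' @param illum Illuminant [spectrum()].
#' @param recs A [receptor_set()].
#' @param vonkries Apply von Kries normalisation (default `TRUE`).
#' @param step Integration grid step in nm (default 1).
#' @return A `"catch_vector"`: named numeric vector of positive catches with
#'   attributes `adapted` (logical) and `receptor_names`.
#' @examples
#' # a flat grey reflector gives equal catches in every channel under von Kries
#' @export
quantum_catch <- function(r, illum, recs, vonkries = TRUE, step = 1) {
  stopifnot(inherits(r, "spectrum"), inherits(illum, "spectrum"),
            inherits(recs, "receptor_set"))
  grid <- do.call(common_grid,
                  c(list(r, illum), recs$sensitivities, list(step = step)))
  rv <- resample_spectrum(r, grid)$values
  iv <- resample_spectrum(illum, grid)$values
  q <- vapply(recs$sensitivities, function(s) {
    sv <- resample_spectrum(s, grid)$values
    trapz(grid, rv * iv * sv)
  }, 0)
  if (any(q <= 0)) {
    stop("degenerate quantum catch: zero integral for receptor(s) ",
         paste(recs$names[q <= 0], collapse = ", "), call. = FALSE)
  }
  if (vonkries) {
    qw <- vapply(recs$sensitivities, function(s) {
      sv <- resample_spectrum(s, grid)$values
      trapz(grid, iv * sv)
    }, 0)
    if (any(qw <= 0)) {
      stop("degenerate white-point catch under this illuminant", call. = FALSE)
    }
    q <- q / qw
  }
  catch_vector(q, adapted = vonkries)
}

#' Construct a catch vector
#'
#' @param q Named positive numeric vector of per-receptor quantum catches.
#' @param adapted Whether von Kries adaptation has been applied.
#' @return A `"catch_vector"`.
#' @export
catch_vector <- function(q, adapted = FALSE) {
  q <- unlist(q)
  if (any(!is.finite(q)) || any(q <= 0)) {
    stop("quantum catches must be positive and finite", call. = FALSE)
  }
  structure(as.numeric(q), names = names(q), adapted = isTRUE(adapted),
            class = "catch_vector")
}

#' @export
print.catch_vector <- function(x, ...) {
  cat(sprintf("<catch_vector%s>\n",
              if (isTRUE(attr(x, "adapted"))) " (von Kries adapted)" else ""))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}
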