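#' Log receptor contrasts between two stimuli
#'
#' Delta f_i = ln(Qa_i / Qb_i) per receptor; the basic quantity of the
#' log-form receptor-noise-limited model.
#'
#' @param a,b `catch_vector`s over the same receptors.
#' @return Named numeric vector of log contrasts.
#' @export
log_contrasts <- function(a, b) {
  if (length(a) != length(b)) stop("catch vectors differ in length", call. = FALSE)
  if (!is.null(names(a)) && !is.null(names(b)) &&
      !identical(names(a), names(b))) {
    stop("catch vectors are over different receptors", call. = FALSE)
  }
  if (any(a <= 0) || any(b <= 0)) {
    stop("log contrasts require positive catches", call. = FALSE)
  }
  stats::setNames(log(as.numeric(a) / as.numeric(b)), names(a))
}

# Variational RNL distance: dS^2 = min over scalar c of
# sum_i (df_i - c)^2 / w_i^2. The minimiser is the precision-weighted mean,
# so this is a closed weighted least-squares solution valid for any number
# of channels; the published 2/3/4-channel quotient formulas are algebraic
# specialisations of it.
rnl_variational <- function(df, w) {
  prec <- 1 / w^2
  cstar <- sum(df * prec) / sum(prec)
  sqrt(sum((df - cstar)^2 * prec))
}

# Published closed forms (Vorobyev-Osorio) for 2-4 chromatic channels.
rnl_closed_form <- function(df, w) {
  n <- length(df)
  if (n == 2) {
    abs(df[1] - df[2]) / sqrt(w[1]^2 + w[2]^2)
  } else if (n == 3) {
    num <- w[1]^2 * (df[3] - df[2])^2 + w[2]^2 * (df[3] - df[1])^2 +
           w[3]^2 * (df[2] - df[1])^2
    den <- (w[1] * w[2])^2 + (w[1] * w[3])^2 + (w[2] * w[3])^2
    sqrt(num / den)
  } else if (n == 4) {
    num <- (w[1] * w[2])^2 * (df[4] - df[3])^2 +
           (w[1] * w[3])^2 * (df[4] - df[2])^2 +
           (w[1] * w[4])^2 * (df[3] - df[2])^2 +
           (w[2] * w[3])^2 * (df[4] - df[1])^2 +
           (w[2] * w[4])^2 * (df[3] - df[1])^2 +
           (w[3] * w[4])^2 * (df[2] - df[1])^2
    den <- (w[1] * w[2] * w[3])^2 + (w[1] * w[2] * w[4])^2 +
           (w[1] * w[3] * w[4])^2 + (w[2] * w[3] * w[4])^2
    sqrt(num / den)
  } else {
    rnl_variational(df, w)
  }
}

#' Chromatic discriminability (Delta S) under the log-form RNL model
#'
#' Perceptual colour distance in just-noticeable-difference (JND) units
#' between two stimuli, limited by per-channel receptor noise (Weber
#' fractions). Values below 1 are conventionally indiscriminable. Uses the
#' chromatic channels of `recs` only; the luminance channel is handled by
#' [achromatic_jnd()].
#'
#' @param a,b `catch_vector`s named by receptor, covering at least the
#'   chromatic channels of `recs`.
#' @param recs A [receptor_set()].
#' @return Nonnegative Delta S (JND units).
#' @export
chromatic_jnd <- function(a, b, recs) {
  stopifnot(inherits(recs, "receptor_set"))
  ch <- chromatic_channels(recs)
  if (length(ch) < 2) stop("need at least two chromatic channels", call. = FALSE)
  av <- catch_subset(a, ch); bv <- catch_subset(b, ch)
  df <- log(av / bv)
  unname(rnl_closed_form(unname(df), unname(recs$weber[ch])))
}

#' Achromatic (luminance) discriminability (Delta L)
#'
#' Log-form single-channel contrast on the designated luminance
#' (double-cone) channel: Delta L = |ln(Qa_D / Qb_D)| / omega_D. The
#' achromatic use of the RNL model lacks strong behavioural validation, so
#' these values warrant more caution than chromatic JNDs.
#'
#' @inheritParams chromatic_jnd
#' @return Nonnegative Delta L (JND units).
#' @export
achromatic_jnd <- function(a, b, recs) {
  stopifnot(inherits(recs, "receptor_set"))
  d <- recs$luminance_channel
  av <- catch_subset(a, d); bv <- catch_subset(b, d)
  unname(abs(log(av / bv)) / recs$weber[d])
}

# Extract named channels from a catch vector (positional fall-back when the
# vector is unnamed and covers exactly the receptor set).
catch_subset <- function(q, ch) {
  v <- as.numeric(q)
  nm <- names(q)
  if (!is.null(nm)) {
    if (!all(ch %in% nm)) {
      stop("catch vector lacks channel(s): ",
           paste(setdiff(ch, nm), collapse = ", "), call. = FALSE)
    }
    v <- v[match(ch, nm)]
  } else if (length(v) < length(ch)) {
    stop("unnamed catch vector shorter than requested channels", call. = FALSE)
  }
  if (any(v <= 0)) stop("positive catches required", call. = FALSE)
  stats::setNames(v[seq_along(ch)], ch)
}

#' Rank candidate spectra by perceptual distance to a target
#'
#' Computes quantum catches for the target and every candidate under one
#' illuminant and receptor set, then sorts candidates by perceptual
#' distance: `sqrt(dS^2 + dL^2)` by default, or chromatic distance alone.
#' Ties are broken by input order, so the ranking is deterministic.
#'
#' @param target Reflectance [spectrum()].
#' @param candidates List of reflectance [spectrum()]s; names (or indices)
#'   label the output rows.
#' @param illum Illuminant [spectrum()].
#' @param recs A [receptor_set()].
#' @param metric `"combined"` (default) or `"chromatic"`.
#' @return `data.frame` with columns `candidate`, `rank`, `dS`, `dL`,
#'   `distance`, sorted ascending by distance.
#' @export
rank_spectral_match <- function(target, candidates, illum, recs,
                                metric = c("combined", "chromatic")) {
  metric <- match.arg(metric)
  if (length(candidates) < 1) stop("need at least one candidate", call. = FALSE)
  if (inherits(candidates, "spectrum")) candidates <- list(candidates)
  labs <- names(candidates)
  if (is.null(labs)) labs <- as.character(seq_along(candidates))
  qt <- quantum_catch(target, illum, recs, vonkries = TRUE)
  res <- do.call(rbind, lapply(seq_along(candidates), function(i) {
    qc <- quantum_catch(candidates[[i]], illum, recs, vonkries = TRUE)
    dS <- chromatic_jnd(qt, qc, recs)
    dL <- achromatic_jnd(qt, qc, recs)
    data.frame(candidate = labs[i], dS = dS, dL = dL)
  }))
  res$distance <- if (metric == "combined") sqrt(res$dS^2 + res$dL^2) else res$dS
  ord <- order(res$distance)  # order() is stable: ties keep input order
  res <- res[ord, ]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res[, c("candidate", "rank", "dS", "dL", "distance")]
}
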