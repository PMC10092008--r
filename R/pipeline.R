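#' Run the image-analysis pipeline over moth/background scenes
#'
#' For each scene and each viewing distance: apply Gaussian acuity control,
#' compute the ROI-mean chromatic and achromatic JNDs between the animal
#' (label 1) and background (label 2) regions, compute pattern-energy
#' spectra of both regions on the luminance channel, and score their
#' pattern energy difference (PED). All distances share the un-blurred
#' catch image and diverge only at acuity control.
#'
#' @param scenes List of scenes; each a list with elements `image`
#'   (a [catch_image()]), `mask` (a [roi_mask()]) and optional `specimen`
#'   and `background` labels. A single scene may be passed directly.
#' @param recs A [receptor_set()] supplying Weber fractions and the
#'   luminance channel; its channel names must match the image channels.
#' @param distances_mm Viewing distances in mm (default `c(500, 1000)`).
#' @param acuity_cpd Receiver acuity (default 6 cycles/degree).
#' @param px_per_mra Output resolution target (default 5 px per minimum
#'   resolvable angle).
#' @param normalize Normalize pattern spectra to unit sum before PED.
#'   Default `FALSE`: raw band energies retain the overall contrast
#'   difference between regions, which both carries the moth-lichen
#'   similarity signal and lets acuity blur at longer viewing distances
#'   reduce PED, as expected perceptually. Unit-sum normalization compares
#'   spectrum shape only.
#' @param aggregate PED aggregation over scales, `"sum"` or `"mean"`.
#' @return `data.frame` with one row per (scene, distance): `specimen`,
#'   `background`, `distance_mm`, `dS`, `dL`, `ped`, `n_scales`. Scenes
#'   whose mask loses a label during rescaling are skipped with a warning.
#' @export
run_image_pipeline <- function(scenes, recs, distances_mm = c(500, 1000),
                               acuity_cpd = 6, px_per_mra = 5,
                               normalize = FALSE,
                               aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(recs, "receptor_set"))
  if (!is.null(scenes$image)) scenes <- list(scenes)
  if (length(distances_mm) < 1) stop("need at least one viewing distance",
                                     call. = FALSE)
  rows <- list()
  for (si in seq_along(scenes)) {
    sc <- scenes[[si]]
    spec_lab <- if (is.null(sc$specimen)) paste0("scene", si) else sc$specimen
    bg_lab <- if (is.null(sc$background)) "background" else sc$background
    for (d in distances_mm) {
      g <- viewing_geometry(acuity_cpd, d, px_per_mra)
      out <- apply_acuity(sc$image, g, mask = sc$mask)
      mk <- attr(out, "mask")
      if (!any(mk == 1L) || !any(mk == 2L)) {
        warning(sprintf("scene %s at %g mm: ROI label lost in rescaling; skipped",
                        spec_lab, d), call. = FALSE)
        next
      }
      qa <- roi_mean_catch(out, mk, 1L)
      qb <- roi_mean_catch(out, mk, 2L)
      dS <- chromatic_jnd(qa, qb, recs)
      dL <- achromatic_jnd(qa, qb, recs)
      scales <- band_scales(dim(out))
      pa <- pattern_energy_spectrum(out, mk, 1L, scales = scales,
                                    channel = recs$luminance_channel,
                                    normalize = normalize)
      pb <- pattern_energy_spectrum(out, mk, 2L, scales = scales,
                                    channel = recs$luminance_channel,
                                    normalize = normalize)
      pd <- ped(pa, pb, aggregate = aggregate)
      rows[[length(rows) + 1L]] <-
        data.frame(specimen = spec_lab, background = bg_lab,
                   distance_mm = d, dS = dS, dL = dL, ped = pd$ped,
                   n_scales = length(scales))
    }
  }
  if (length(rows) == 0) {
    return(data.frame(specimen = character(), background = character(),
                      distance_mm = numeric(), dS = numeric(),
                      dL = numeric(), ped = numeric(),
                      n_scales = integer()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the survival-analysis pipeline on a predation event table
#'
#' Kaplan-Meier estimates per treatment (with survival at study end), a Cox
#' proportional hazards fit with treatment as the main effect, and pairwise
#' log-rank tests with Benjamini-Hochberg adjustment. Optional backward
#' selection drops non-significant extra covariates (Wald p above `alpha`)
#' before the final treatment-only style model; it is off by default.
#'
#' @param events An [event_table()].
#' @param covariates Optional extra main-effect columns (e.g. site, block).
#' @param select Drop covariates with Wald p > `alpha` one at a time
#'   (default `FALSE`).
#' @param alpha Selection threshold (default 0.05).
#' @param reference Reference treatment level for the Cox fit.
#' @param ties Tie handling for the Cox fit.
#' @param adjust Adjustment method for pairwise log-rank p-values.
#' @return List with `km` ([km_fit()]), `km_end` (survival at the last
#'   observed check time per treatment), `cox` ([cox_fit()]), `logrank`
#'   (pairwise table) and `covariates_used`.
#' @export
run_survival_pipeline <- function(events, covariates = NULL, select = FALSE,
                                  alpha = 0.05, reference = NULL,
                                  ties = "efron", adjust = "BH") {
  events <- event_table(as.data.frame(events))
  used <- covariates
  if (select && length(used) > 0) {
    repeat {
      fit <- cox_fit(events, covariates = used, ties = ties,
                     reference = reference)
      co <- fit$coefficients
      # worst covariate term (treatment always stays)
      cov_terms <- co[!grepl("^treatment", co$term), , drop = FALSE]
      if (nrow(cov_terms) == 0) break
      worst_p <- max(cov_terms$p)
      if (worst_p <= alpha) break
      worst <- cov_terms$term[which.max(cov_terms$p)]
      drop_cov <- used[vapply(used, function(cv) startsWith(worst, cv), TRUE)]
      used <- setdiff(used, drop_cov[1])
      if (length(used) == 0) break
    }
  }
  km <- km_fit(events)
  end <- max(events$time_h)
  list(km = km,
       km_end = km_survival_at(km, end),
       cox = cox_fit(events, covariates = used, ties = ties,
                     reference = reference),
       logrank = logrank_pairwise(events, adjust = adjust),
       covariates_used = used)
}

#' Per-group mean and standard error summary
#'
#' Descriptive summaries of camouflage metrics (JND, PED, ...) per group.
#' The standard error of a single observation is undefined and reported as
#' `NA`.
#'
#' @param df `data.frame` of results.
#' @param group_cols Character vector of grouping columns.
#' @param value_cols Character vector of numeric columns to summarise
#'   (default: all numeric columns not used for grouping).
#' @return Long-format `data.frame`: grouping columns, `variable`, `n`,
#'   `mean`, `se`.
#' @export
summarize_groups <- function(df, group_cols,
                             value_cols = NULL) {
  if (!all(group_cols %in% names(df))) stop("unknown grouping column",
                                            call. = FALSE)
  if (is.null(value_cols)) {
    value_cols <- setdiff(names(df)[vapply(df, is.numeric, TRUE)], group_cols)
  }
  if (nrow(df) == 0) stop("no rows to summarise", call. = FALSE)
  key <- interaction(df[group_cols], drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(split(df, key), function(g) {
    do.call(rbind, lapply(value_cols, function(v) {
      x <- g[[v]]
      n <- sum(!is.na(x))
      cbind(g[1, group_cols, drop = FALSE],
            data.frame(variable = v, n = n, mean = mean(x, na.rm = TRUE),
                       se = if (n > 1) stats::sd(x, na.rm = TRUE) / sqrt(n)
                            else NA_real_))
    }))
  }))
  rownames(out) <- NULL
  out
}

# FNV-1a hash of a string, as 8 hex digits (config fingerprinting for
# output manifests; not cryptographic). Arithmetic is done on doubles in
# 16-bit halves because the 32-bit state exceeds R's integer range.
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

#' Write a results table as CSV with a manifest header
#'
#' Prepends comment lines recording the package version and a fingerprint
#' of the configuration that produced the table, so every output file is
#' traceable to its run.
#'
#' @param df `data.frame` to write.
#' @param path Output path.
#' @param config Optional list describing the run; fingerprinted into the
#'   header.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(df, path, config = list()) {
  ver <- as.character(utils::packageVersion("camoquant"))
  hash <- fnv1a(paste(deparse(config), collapse = ""))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# camoquant %s", ver),
               sprintf("# config_hash %s", hash)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
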