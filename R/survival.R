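#' Validate a predation event table
#'
#' One row per model replicate: `treatment` (background type), `time_h`
#' (check time at which attack damage was observed, or study end), `status`
#' (1 = attacked, 0 = censored/survived). Optional columns (e.g.
#' `replicate_id`, `site`, `block`) are carried through untouched.
#'
#' @param df `data.frame` with at least `treatment`, `time_h`, `status`.
#' @return The validated `data.frame` with class `"event_table"` prepended.
#' @export
event_table <- function(df) {
  need <- c("treatment", "time_h", "status")
  if (!all(need %in% names(df))) {
    stop("event table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$treatment <- as.character(df$treatment)
  df$time_h <- as.numeric(df$time_h)
  df$status <- as.integer(df$status)
  if (any(!is.finite(df$time_h)) || any(df$time_h <= 0)) {
    stop("time_h must be positive", call. = FALSE)
  }
  if (!all(df$status %in% c(0L, 1L))) {
    stop("status must be 0 (censored) or 1 (attacked)", call. = FALSE)
  }
  if (nrow(df) == 0) stop("event table is empty", call. = FALSE)
  class(df) <- unique(c("event_table", "data.frame"))
  df
}

#' Read an event table CSV
#'
#' Expected columns: `replicate_id,treatment,site,block,time_h,status`
#' (only `treatment,time_h,status` are required).
#'
#' @param path CSV path.
#' @return An [event_table()].
#' @export
read_event_csv <- function(path) {
  event_table(utils::read.csv(path))
}

#' Kaplan-Meier survival estimates per treatment
#'
#' Product-limit estimator S(t) = prod(1 - d_j / n_j) with Greenwood
#' standard errors, per treatment group. Fitting is delegated to
#' `survival::survfit`; the result is reshaped into one tidy table.
#'
#' @param events An [event_table()] (or coercible `data.frame`).
#' @return A `"km_fit"`: list with `table` (columns `treatment`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`, `se`) and the underlying
#'   `survfit` object.
#' @export
km_fit <- function(events) {
  events <- event_table(as.data.frame(events))
  if (any(table(events$treatment) == 0)) {
    stop("empty treatment group", call. = FALSE)
  }
  fit <- survival::survfit(
    survival::Surv(time_h, status) ~ treatment,
    data = events, conf.type = "plain")
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(unique(events$treatment), length(s$time))
         else sub("^treatment=", "", as.character(s$strata))
  tab <- data.frame(treatment = grp, time = s$time, n_risk = s$n.risk,
                    n_event = s$n.event, n_censor = s$n.censor,
                    surv = s$surv, se = s$std.err)
  rownames(tab) <- NULL
  structure(list(table = tab, survfit = fit), class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat("<km_fit>\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Survival estimate at a given time, per treatment
#'
#' Reads the step function S(t) (and its Greenwood SE) at `time` for each
#' treatment: the value at the largest event/censor time not exceeding
#' `time`, or 1 (SE 0) before the first.
#'
#' @param fit A [km_fit()].
#' @param time Time point (same units as the event table).
#' @return `data.frame` with `treatment`, `surv`, `se`.
#' @export
km_survival_at <- function(fit, time) {
  stopifnot(inherits(fit, "km_fit"))
  tab <- fit$table
  do.call(rbind, lapply(split(tab, tab$treatment), function(g) {
    g <- g[order(g$time), ]
    at <- which(g$time <= time)
    if (length(at) == 0) {
      data.frame(treatment = g$treatment[1], surv = 1, se = 0)
    } else {
      i <- max(at)
      data.frame(treatment = g$treatment[1], surv = g$surv[i], se = g$se[i])
    }
  }))
}

#' Pairwise log-rank tests between treatments
#'
#' Standard log-rank chi-square per treatment pair with multiplicity
#' adjustment (Benjamini-Hochberg by default).
#'
#' @param events An [event_table()].
#' @param adjust p-adjustment method (see [stats::p.adjust()]).
#' @return `data.frame` with `group1`, `group2`, `chisq`, `df`, `p`,
#'   `p_adj`.
#' @export
logrank_pairwise <- function(events, adjust = "BH") {
  events <- event_table(as.data.frame(events))
  groups <- sort(unique(events$treatment))
  if (length(groups) < 2) stop("need at least two treatments", call. = FALSE)
  pairs <- utils::combn(groups, 2)
  res <- do.call(rbind, apply(pairs, 2, function(pr) {
    sub <- events[events$treatment %in% pr, ]
    sd <- survival::survdiff(survival::Surv(time_h, status) ~ treatment,
                             data = sub)
    data.frame(group1 = pr[1], group2 = pr[2], chisq = sd$chisq, df = 1,
               p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
  }))
  res$p_adj <- stats::p.adjust(res$p, method = adjust)
  rownames(res) <- NULL
  res
}

#' Cox proportional hazards fit on an event table
#'
#' Semi-parametric hazards regression via `survival::coxph` (Efron tie
#' handling by default, appropriate for the heavily tied check-time data).
#' Coefficients are reported against a reference treatment level
#' (alphabetical first unless specified); hazard ratios are
#' `exp(coefficient)` and the overall Wald statistic tests all coefficients
#' jointly.
#'
#' @param events An [event_table()].
#' @param covariates Optional character vector of extra main-effect columns
#'   (e.g. `c("site", "block")`).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param reference Reference treatment level.
#' @return A `"cox_fit"`: list with `coefficients` (a `data.frame` with
#'   `term`, `coef`, `hazard_ratio`, `se`, `z`, `p`), `wald`
#'   (statistic/df/p), `reference`, `ties` and the underlying `coxph`
#'   object.
#' @export
cox_fit <- function(events, covariates = NULL, ties = c("efron", "breslow"),
                    reference = NULL) {
  ties <- match.arg(ties)
  events <- event_table(as.data.frame(events))
  lev <- sort(unique(events$treatment))
  if (length(lev) < 2) {
    stop("Cox model needs at least two treatment levels", call. = FALSE)
  }
  if (sum(events$status) == 0) {
    stop("no events present; Cox model cannot be fitted", call. = FALSE)
  }
  if (is.null(reference)) reference <- lev[1]
  if (!reference %in% lev) stop("unknown reference level", call. = FALSE)
  events$treatment <- stats::relevel(factor(events$treatment, levels = lev),
                                     ref = reference)
  rhs <- paste(c("treatment", covariates), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(time_h, status) ~", rhs))
  fit <- survival::coxph(fml, data = events, ties = ties)
  sm <- summary(fit)
  co <- sm$coefficients
  coefs <- data.frame(term = rownames(co), coef = co[, "coef"],
                      hazard_ratio = exp(co[, "coef"]),
                      se = co[, "se(coef)"], z = co[, "z"],
                      p = co[, "Pr(>|z|)"])
  rownames(coefs) <- NULL
  structure(list(coefficients = coefs,
                 wald = list(statistic = unname(sm$waldtest["test"]),
                             df = unname(sm$waldtest["df"]),
                             p = unname(sm$waldtest["pvalue"])),
                 reference = reference, ties = ties, coxph = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit: reference = %s, ties = %s>\n", x$reference, x$ties))
  print(x$coefficients, digits = 4)
  cat(sprintf("Wald = %.3f on %d df, p = %.3g\n", x$wald$statistic,
              x$wald$df, x$wald$p))
  invisible(x)
}
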