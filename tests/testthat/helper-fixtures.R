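# Shared fixtures, built in code.

# Receptor set with explicit Weber fractions: n_chrom Gaussian chromatic
# channels plus one broad luminance channel.
make_recs <- function(n_chrom = 2, weber = rep(0.05, n_chrom),
                      weber_lum = 0.05) {
  peaks <- seq(380, 620, length.out = n_chrom)
  wl <- seq(300, 700, by = 2)
  sens <- stats::setNames(lapply(peaks, function(p) {
    spectrum(wl, exp(-((wl - p)^2) / (2 * 40^2)), "sensitivity")
  }), paste0("c", seq_len(n_chrom)))
  sens$lum <- spectrum(wl, exp(-((wl - 550)^2) / (2 * 90^2)), "sensitivity")
  receptor_set(sens, abundances = rep(1, n_chrom + 1),
               weber = c(weber, weber_lum), luminance_channel = "lum")
}

flat_illum <- function(value = 1) flat_spectrum(value, "irradiance")

# Catch vectors realising prescribed log contrasts df over the chromatic
# channels of recs (luminance ratio 1).
catches_from_df <- function(df, recs) {
  ch <- chromatic_channels(recs)
  stopifnot(length(df) == length(ch))
  a <- stats::setNames(rep(1, length(recs$names)), recs$names)
  b <- a
  a[ch] <- exp(df)
  list(a = catch_vector(a), b = catch_vector(b))
}

# Hand-built pattern spectrum (for PED arithmetic/property tests).
make_ps <- function(energies, scales = 2^(seq_along(energies)),
                    normalized = FALSE) {
  structure(list(scales_px = scales,
                 energies = stats::setNames(energies, as.character(scales)),
                 normalized = normalized, roi_label = 1L, channel = "lum"),
            class = "pattern_spectrum")
}

# Event table with ev events spread over the check times and the remainder
# censored at the end; the KM estimate at the end only depends on ev and n.
counts_events <- function(treatment, n, ev, split_seed = 1,
                          checks = c(24, 48, 72)) {
  t_ev <- camoquant:::with_seed(split_seed,
                                sample(checks, ev, replace = TRUE))
  data.frame(treatment = treatment,
             time_h = c(t_ev, rep(checks[length(checks)], n - ev)),
             status = c(rep(1L, ev), rep(0L, n - ev)))
}

# Independent two-group log-rank oracle (observed-minus-expected with the
# hypergeometric variance), used to cross-check survdiff-based results.
logrank_oracle <- function(time, status, group) {
  g <- sort(unique(group))
  stopifnot(length(g) == 2)
  tms <- sort(unique(time[status == 1]))
  O1 <- E1 <- V <- 0
  for (tt in tms) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g[1])
    d <- sum(time == tt & status == 1)
    d1 <- sum(time == tt & status == 1 & group == g[1])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}
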