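# Quantification maths for the dual-colour Rec/RcRE reporter: event gating,
# GFP/eBFP2 MFI ratios, Western-normalised activity, trans-dominant
# dose-response normalisation, and the 4PL p24 standard curve. Inputs are
# plain event/band/OD tables; compensation is assumed done upstream.

FLOW_CHANNELS <- c("FSC_A", "FSC_H", "SSC_A", "mCherry", "GFP", "eBFP2")

#' Gate specification for reporter flow data
#'
#' The gating hierarchy is fixed: scatter window on (FSC_A, SSC_A), doublet
#' exclusion on FSC_H vs FSC_A, then mCherry positivity (reporter cells) and
#' eBFP2 positivity (Rec-vector expression). The singlet gate keeps events
#' with `|FSC_H - k * FSC_A| / (k * FSC_A) <= singlet_tol`; the slope `k` is
#' part of the spec (fit it once from data with [fit_singlet_slope()]), so
#' gating with a fixed spec is deterministic and idempotent.
#'
#' @param fsc_range,ssc_range scatter windows (length-2 numeric).
#' @param singlet_k singlet slope k.
#' @param singlet_tol max relative deviation from proportionality, in (0, 1].
#' @param mcherry_min,ebfp2_min positivity thresholds.
#' @return A `gate_spec` list.
#' @export
gate_spec <- function(fsc_range = c(0, Inf), ssc_range = c(0, Inf),
                      singlet_k = 1, singlet_tol = 0.1,
                      mcherry_min = 0, ebfp2_min = 0) {
  stopifnot(singlet_tol > 0, singlet_tol <= 1, mcherry_min >= 0, ebfp2_min >= 0)
  structure(list(fsc_range = fsc_range, ssc_range = ssc_range,
                 singlet_k = singlet_k, singlet_tol = singlet_tol,
                 mcherry_min = mcherry_min, ebfp2_min = ebfp2_min),
            class = "gate_spec")
}

#' Least-squares singlet slope
#'
#' Fits k in `FSC_H ~ k * FSC_A` (through the origin) on the scatter-gated
#' events; use the result as `singlet_k` when building a [gate_spec()].
#'
#' @param events event table with FSC_A/FSC_H columns.
#' @return The fitted slope.
#' @export
fit_singlet_slope <- function(events) {
  stopifnot(nrow(events) > 0)
  sum(events$FSC_H * events$FSC_A) / sum(events$FSC_A^2)
}

#' Derive positivity thresholds from a negative-control table
#'
#' Mirrors threshold setting from untransduced control cells: the positivity
#' threshold for each fluorescence channel is the control's 99.9th
#' percentile.
#'
#' @param neg_events negative-control event table.
#' @param q quantile used for the threshold.
#' @return Named vector of thresholds for mCherry, eBFP2, GFP.
#' @export
control_thresholds <- function(neg_events, q = 0.999) {
  vapply(c("mCherry", "eBFP2", "GFP"),
         function(ch) stats::quantile(neg_events[[ch]], q, names = FALSE),
         numeric(1))
}

#' Apply the fixed gating hierarchy to an event table
#'
#' Sequential filter: scatter window -> singlets -> mCherry-positive ->
#' eBFP2-positive. Per-stage surviving counts are attached as the
#' `stage_counts` attribute. If any stage empties the table, the (empty)
#' result carries an `empty_stage` attribute naming it; downstream MFIs are
#' then undefined rather than zero.
#'
#' @param events event table with columns `r paste(FLOW_CHANNELS, collapse=", ")`.
#' @param spec a [gate_spec()].
#' @return The surviving events.
#' @export
gate <- function(events, spec) {
  missing_ch <- setdiff(FLOW_CHANNELS, names(events))
  if (length(missing_ch))
    stop("event table lacks channel(s): ", paste(missing_ch, collapse = ", "))
  stages <- c("scatter", "singlet", "mcherry", "ebfp2")
  counts <- stats::setNames(integer(4), stages)

  keep <- events$FSC_A >= spec$fsc_range[1] & events$FSC_A <= spec$fsc_range[2] &
          events$SSC_A >= spec$ssc_range[1] & events$SSC_A <= spec$ssc_range[2]
  ev <- events[keep, , drop = FALSE]; counts["scatter"] <- nrow(ev)
  dev <- abs(ev$FSC_H - spec$singlet_k * ev$FSC_A) / (spec$singlet_k * ev$FSC_A)
  ev <- ev[!is.na(dev) & dev <= spec$singlet_tol, , drop = FALSE]
  counts["singlet"] <- nrow(ev)
  ev <- ev[ev$mCherry >= spec$mcherry_min, , drop = FALSE]
  counts["mcherry"] <- nrow(ev)
  ev <- ev[ev$eBFP2 >= spec$ebfp2_min, , drop = FALSE]
  counts["ebfp2"] <- nrow(ev)

  attr(ev, "stage_counts") <- counts
  if (nrow(ev) == 0L)
    attr(ev, "empty_stage") <- stages[which(counts == 0L)[1]]
  ev
}

#' Rec/RcRE activity from a gated event table
#'
#' Arithmetic-mean fluorescence intensities of GFP and eBFP2 and their
#' ratio, the Rec activity readout of the dual-colour reporter (the
#' geometric mean is available as an option).
#'
#' @param events gated event table.
#' @param estimator `"arithmetic"` (default) or `"geometric"` MFI.
#' @return A list: `n_gated`, `gfp_mfi`, `ebfp2_mfi`, `ratio`.
#' @export
activity <- function(events, estimator = c("arithmetic", "geometric")) {
  estimator <- match.arg(estimator)
  if (nrow(events) == 0L) stop("no gated events; activity undefined")
  mfi <- switch(estimator,
                arithmetic = function(x) mean(x),
                geometric = function(x) exp(mean(log(pmax(x, .Machine$double.eps)))))
  g <- mfi(events$GFP); b <- mfi(events$eBFP2)
  if (b <= 0) stop("eBFP2 MFI is zero; activity ratio undefined")
  list(n_gated = nrow(events), gfp_mfi = g, ebfp2_mfi = b, ratio = g / b)
}

#' Normalise activity to Western-blot protein expression
#'
#' `normalized_mfi = mfi / (ha_signal / tubulin_signal)`: GFP MFI divided by
#' the tagged-Rec band intensity relative to its beta-tubulin loading
#' control.
#'
#' @param mfi mean fluorescence intensity (functional activity).
#' @param ha_signal tagged-Rec band intensity.
#' @param tubulin_signal beta-tubulin band intensity from the same lane.
#' @return Normalised MFI.
#' @export
normalize_to_expression <- function(mfi, ha_signal, tubulin_signal) {
  if (any(tubulin_signal <= 0) || any(ha_signal <= 0))
    stop("band intensities must be positive")
  mfi / (ha_signal / tubulin_signal)
}

#' Normalise a trans-dominant dose-response series
#'
#' Subtracts the empty-vector GFP background and scales so the control
#' condition (functional Rec alone) is exactly 1.0; values are floored at 0.
#'
#' @param raw raw GFP MFI per competitor dose.
#' @param background_mfi empty-vector background MFI.
#' @param control_mfi control (functional Rec alone) MFI.
#' @return Normalised values, parallel to `raw`.
#' @export
tdn_normalize <- function(raw, background_mfi, control_mfi) {
  if (control_mfi <= background_mfi)
    stop("control MFI does not exceed background; assay failure")
  pmax(0, (raw - background_mfi) / (control_mfi - background_mfi))
}

#' Fit a four-parameter logistic standard curve
#'
#' Least-squares fit of `od = d + (a - d) / (1 + (conc / c)^b)` to p24
#' standards: `a` is the zero-concentration asymptote, `d` the saturating
#' asymptote (so `a < d` for a sandwich ELISA whose OD rises with
#' concentration), `c` the midpoint (pg/mL) and `b` the slope. Standards
#' whose rank order is badly non-monotone (Spearman correlation below
#' `monotone_tol`) are rejected as a fit-quality error.
#'
#' @param concentration standard concentrations (pg/mL), >= 4 distinct.
#' @param od measured optical densities.
#' @param monotone_tol minimum Spearman correlation between OD and
#'   concentration.
#' @return A `fourpl_fit` list: parameters `a`, `b`, `c`, `d`, the fitted
#'   model, and the standards' concentration and OD ranges.
#' @export
fit_4pl <- function(concentration, od, monotone_tol = 0.8) {
  stopifnot(length(concentration) == length(od))
  if (length(unique(concentration)) < 4L)
    stop("need at least 4 distinct standard concentrations")
  rho <- stats::cor(concentration, od, method = "spearman")
  if (is.na(rho) || rho < monotone_tol)
    stop("standards are not monotone in concentration (spearman = ",
         signif(rho, 3), "); fit-quality error")
  df <- data.frame(conc = concentration, od = od)
  start <- list(a = od[which.min(concentration)], b = 1,
                c = exp(mean(log(range(concentration)))),
                d = od[which.max(concentration)])
  fit <- minpack.lm::nlsLM(od ~ d + (a - d) / (1 + (conc / c)^b),
                           data = df, start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- as.list(stats::coef(fit))
  structure(list(a = p$a, b = p$b, c = p$c, d = p$d, model = fit,
                 conc_range = range(concentration), od_range = range(od)),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf("4PL fit: a=%.4g b=%.4g c=%.4g d=%.4g (standards %g-%g pg/mL)\n",
              x$a, x$b, x$c, x$d, x$conc_range[1], x$conc_range[2]))
  invisible(x)
}

#' Interpolate concentrations from a 4PL standard curve
#'
#' Inverts the fitted curve. ODs outside the fitted OD range of the
#' standards are flagged out-of-range and returned as `NA` rather than
#' extrapolated.
#'
#' @param fit a [fit_4pl()] result.
#' @param od optical densities to interpolate.
#' @return A `data.frame`: `od`, `concentration` (pg/mL, `NA` when out of
#'   range), `out_of_range`.
#' @export
interpolate_4pl <- function(fit, od) {
  oor <- od < min(fit$od_range) | od > max(fit$od_range)
  conc <- fit$c * (((fit$a - fit$d) / (od - fit$d)) - 1)^(1 / fit$b)
  conc[oor] <- NA_real_
  data.frame(od = od, concentration = conc, out_of_range = oor)
}

#' p24 concentrations from duplicate sample ODs
#'
#' Interpolates each OD from the standard curve and reports the mean of the
#' duplicates per sample.
#'
#' @param fit a [fit_4pl()] result.
#' @param samples data.frame with `sample` and `od` columns (typically two
#'   rows per sample).
#' @return data.frame with one row per sample: mean concentration and the
#'   number of in-range replicates.
#' @export
p24_report <- function(fit, samples) {
  interp <- interpolate_4pl(fit, samples$od)
  agg <- stats::aggregate(interp$concentration,
                          by = list(sample = samples$sample),
                          FUN = function(x) mean(x, na.rm = TRUE))
  n_ok <- stats::aggregate(!interp$out_of_range,
                           by = list(sample = samples$sample), FUN = sum)
  data.frame(sample = agg$sample, concentration = agg$x,
             n_in_range = n_ok$x, stringsAsFactors = FALSE)
}

# --- simulators -------------------------------------------------------------

#' Simulate a reporter flow-cytometry event table
#'
#' Events are drawn from labelled populations: a doublet fraction (FSC_H
#' well below proportionality with FSC_A), mCherry-positive vs negative
#' cells, and eBFP2-positive vs negative cells within the mCherry-positive
#' population. Fluorescence channels are log-normal per population, so
#' expected MFIs have the closed form `exp(meanlog + sdlog^2/2)`. The truth
#' (population labels and expected MFIs) is attached as attributes.
#'
#' @param n_events number of events (the acquisition floor is 30,000).
#' @param frac_mcherry fraction of mCherry-positive cells.
#' @param frac_ebfp2 fraction eBFP2-positive within mCherry-positive.
#' @param gfp_meanlog,gfp_sdlog GFP log-normal parameters of the positive
#'   population.
#' @param ebfp2_meanlog,ebfp2_sdlog eBFP2 log-normal parameters of the
#'   positive population.
#' @param doublet_frac doublet fraction.
#' @param seed integer seed.
#' @return Event table (data.frame) with attributes `truth` (population
#'   labels) and `expected` (closed-form positive-population MFIs).
#' @export
simulate_events <- function(n_events = 30000L, frac_mcherry = 0.7,
                            frac_ebfp2 = 0.8, gfp_meanlog = log(2000),
                            gfp_sdlog = 0.4, ebfp2_meanlog = log(1000),
                            ebfp2_sdlog = 0.4, doublet_frac = 0.05,
                            seed = 1L) {
  stopifnot(n_events >= 1L, frac_mcherry >= 0, frac_mcherry <= 1,
            frac_ebfp2 >= 0, frac_ebfp2 <= 1)
  rng <- local_rng(seed)
  n <- n_events
  doublet <- rng$runif(n) < doublet_frac
  mch_pos <- rng$runif(n) < frac_mcherry
  bfp_pos <- mch_pos & (rng$runif(n) < frac_ebfp2)

  fsc <- rng$rlnorm(n, meanlog = 11, sdlog = 0.12)
  fsc[doublet] <- fsc[doublet] * 2
  fsc_h <- fsc * (1 + rng$rnorm(n, 0, 0.02))
  fsc_h[doublet] <- 0.55 * fsc[doublet] * (1 + rng$rnorm(sum(doublet), 0, 0.02))
  ssc <- rng$rlnorm(n, meanlog = 10, sdlog = 0.25)

  neg <- function(n) rng$rlnorm(n, meanlog = log(30), sdlog = 0.5)
  mch <- neg(n); mch[mch_pos] <- rng$rlnorm(sum(mch_pos), log(5000), 0.4)
  bfp <- neg(n); bfp[bfp_pos] <- rng$rlnorm(sum(bfp_pos), ebfp2_meanlog, ebfp2_sdlog)
  gfp <- neg(n); gfp[bfp_pos] <- rng$rlnorm(sum(bfp_pos), gfp_meanlog, gfp_sdlog)

  ev <- data.frame(FSC_A = fsc, FSC_H = fsc_h, SSC_A = ssc,
                   mCherry = mch, GFP = gfp, eBFP2 = bfp)
  attr(ev, "truth") <- data.frame(doublet = doublet, mcherry_pos = mch_pos,
                                  ebfp2_pos = bfp_pos)
  attr(ev, "expected") <- c(
    gfp_mfi = exp(gfp_meanlog + gfp_sdlog^2 / 2),
    ebfp2_mfi = exp(ebfp2_meanlog + ebfp2_sdlog^2 / 2),
    ratio = exp(gfp_meanlog + gfp_sdlog^2 / 2 - ebfp2_meanlog - ebfp2_sdlog^2 / 2))
  ev
}

#' Simulate a trans-dominant competition series
#'
#' A deliberately simple competitive stand-in used to exercise the
#' normalisation code, not a mechanistic claim: expected GFP activity at
#' competitor dose d is `a0 * c0 / (c0 + k * d)` with `c0` the constant
#' functional-Rec dose (100 ng), plus a background term and log-normal
#' noise. Doses follow the assay design (0, 200, 400, 800 ng).
#'
#' @param seed integer seed.
#' @param doses competitor plasmid doses (ng).
#' @param a0 control activity (GFP MFI above background at dose 0).
#' @param k competition strength (0 = no trans-dominance).
#' @param c0 functional-Rec dose (ng).
#' @param background empty-vector GFP MFI.
#' @param n_rep replicates per dose.
#' @param noise_sd log-scale noise (0 for a noiseless series).
#' @return data.frame: dose, rep, raw_gfp_mfi, plus attributes
#'   `background_mfi`, `control_mfi` (noiseless control), and `truth`
#'   (expected normalised curve).
#' @export
simulate_tdn <- function(seed = 1L, doses = c(0, 200, 400, 800), a0 = 50,
                         k = 0.05, c0 = 100, background = 3, n_rep = 3L,
                         noise_sd = 0.05) {
  stopifnot(a0 > 0, k >= 0)
  rng <- local_rng(seed)
  expected <- a0 * c0 / (c0 + k * doses)
  df <- expand.grid(rep = seq_len(n_rep), dose = doses)[, c("dose", "rep")]
  mu <- a0 * c0 / (c0 + k * df$dose)
  noise <- if (noise_sd > 0) rng$rlnorm(nrow(df), -noise_sd^2 / 2, noise_sd) else 1
  df$raw_gfp_mfi <- background + mu * noise
  attr(df, "background_mfi") <- background
  attr(df, "control_mfi") <- background + a0
  attr(df, "truth") <- data.frame(dose = doses, normalized = expected / a0)
  df
}

#' Simulate p24 ELISA standards from a 4PL model
#'
#' @param a,b,c,d 4PL parameters (zero-concentration asymptote, slope,
#'   midpoint, saturating asymptote).
#' @param concentration standard concentrations; default a 2-fold series
#'   from 12.5 to 1,600 pg/mL.
#' @param noise_sd additive OD noise (0 = noiseless).
#' @param seed integer seed.
#' @return data.frame: concentration, od.
#' @export
simulate_standards <- function(a = 0.05, b = 1.1, c = 180, d = 3.2,
                               concentration = 12.5 * 2^(0:7),
                               noise_sd = 0, seed = 1L) {
  od <- d + (a - d) / (1 + (concentration / c)^b)
  if (noise_sd > 0) {
    rng <- local_rng(seed)
    od <- od + rng$rnorm(length(od), 0, noise_sd)
  }
  data.frame(concentration = concentration, od = od)
}
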