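# gate built from the negative-control acquisition: thresholds at its 99.9th
# percentiles, singlet slope least-squares-fit on its (doublet-free) events
make_gate <- function(ev, neg) {
  thr <- control_thresholds(neg)
  gate_spec(fsc_range = c(2e4, 2e5), ssc_range = c(0, Inf),
            singlet_k = fit_singlet_slope(neg), singlet_tol = 0.1,
            mcherry_min = thr[["mCherry"]], ebfp2_min = thr[["eBFP2"]])
}

neg <- simulate_events(n_events = 5000, frac_mcherry = 0, frac_ebfp2 = 0,
                       doublet_frac = 0, seed = 71)

test_that("gating is sequential, logged, and idempotent", {
  ev <- simulate_events(n_events = 20000, seed = 72)
  spec <- make_gate(ev, neg)
  g1 <- gate(ev, spec)
  counts <- attr(g1, "stage_counts")
  expect_true(all(diff(c(nrow(ev), counts)) <= 0))  # stages only remove events
  g2 <- gate(g1, spec)
  expect_equal(nrow(g2), nrow(g1))
  expect_equal(g2$GFP, g1$GFP)

  # an all-pass spec is the identity
  open_spec <- gate_spec(singlet_k = 1, singlet_tol = 1)
  expect_equal(nrow(gate(ev, open_spec)), nrow(ev))

  # a threshold above the channel maximum empties the table at that stage
  hi <- gate_spec(singlet_k = 1, singlet_tol = 1,
                  mcherry_min = max(ev$mCherry) * 2)
  g0 <- gate(ev, hi)
  expect_equal(nrow(g0), 0L)
  expect_equal(attr(g0, "empty_stage"), "mcherry")
  expect_error(activity(g0), "no gated events")
  expect_error(gate(ev[, -4], open_spec), "lacks channel")
})

test_that("gated positive fraction recovers the generating fraction within 1%", {
  ev <- simulate_events(n_events = 30000, frac_mcherry = 0.7, seed = 73)
  spec <- make_gate(ev, neg)
  truth <- attr(ev, "truth")
  singlets <- gate(ev, gate_spec(singlet_k = spec$singlet_k, singlet_tol = 0.1,
                                 mcherry_min = spec$mcherry_min))
  frac <- nrow(singlets) / sum(!truth$doublet)
  expect_lt(abs(frac - 0.7), 0.01)
})

test_that("activity is the GFP/eBFP2 MFI ratio with its invariances", {
  ev <- data.frame(FSC_A = rep(1e5, 100), FSC_H = rep(1e5, 100),
                   SSC_A = 1e4, mCherry = 5000,
                   GFP = rep(1000, 100), eBFP2 = rep(500, 100))
  a <- activity(ev)
  expect_equal(a$ratio, 2)
  expect_equal(a$n_gated, 100L)
  # common rescaling leaves the ratio unchanged; one-channel scaling is
  # equivariant
  ev2 <- ev; ev2$GFP <- ev2$GFP * 3.7; ev2$eBFP2 <- ev2$eBFP2 * 3.7
  expect_equal(activity(ev2)$ratio, 2)
  ev3 <- ev; ev3$GFP <- ev3$GFP * 3
  expect_equal(activity(ev3)$ratio, 6)
  ev4 <- ev; ev4$eBFP2 <- 0
  expect_error(activity(ev4), "eBFP2")
  expect_equal(activity(ev, estimator = "geometric")$ratio, 2)
})

test_that("simulated activity matches the closed-form log-normal ratio", {
  ev <- simulate_events(n_events = 30000, gfp_meanlog = log(2000),
                        gfp_sdlog = 0.4, ebfp2_meanlog = log(1000),
                        ebfp2_sdlog = 0.4, seed = 74)
  spec <- make_gate(ev, neg)
  a <- activity(gate(ev, spec))
  expected <- attr(ev, "expected")
  se <- a$gfp_mfi / sqrt(a$n_gated) # scale of the sampling error
  expect_lt(abs(a$gfp_mfi - expected[["gfp_mfi"]]), 4 * se)
  expect_lt(abs(a$ratio - expected[["ratio"]]), 0.1 * expected[["ratio"]])
})

test_that("expression normalisation follows MFI / (HA / tubulin)", {
  expect_equal(normalize_to_expression(10, 2, 1), 5)
  expect_equal(normalize_to_expression(7.3, 4, 4), 7.3)
  expect_equal(normalize_to_expression(10, 4, 1),
               normalize_to_expression(10, 2, 1) / 2)
  expect_error(normalize_to_expression(10, 0, 1), "positive")
  expect_error(normalize_to_expression(10, 2, -1), "positive")
})

test_that("trans-dominant normalisation anchors the control at exactly 1", {
  s <- simulate_tdn(seed = 5, noise_sd = 0)
  bg <- attr(s, "background_mfi"); ctl <- attr(s, "control_mfi")
  norm <- tdn_normalize(s$raw_gfp_mfi, bg, ctl)
  expect_identical(tdn_normalize(ctl, bg, ctl), 1)
  expect_equal(norm[s$dose == 0], rep(1, 3))
  expect_identical(tdn_normalize(bg, bg, ctl), 0)
  expect_true(all(diff(tapply(norm, s$dose, mean)) <= 0))  # non-increasing
  # affine invariance: shifting raw values and background together
  expect_equal(tdn_normalize(s$raw_gfp_mfi + 11, bg + 11, ctl + 11), norm)
  expect_error(tdn_normalize(1, background_mfi = 5, control_mfi = 4), "control")
})

test_that("the competition constant is recovered from a noisy series", {
  k_true <- 0.05
  s <- simulate_tdn(seed = 9, k = k_true, noise_sd = 0.03, n_rep = 3)
  norm <- tdn_normalize(s$raw_gfp_mfi, attr(s, "background_mfi"),
                        attr(s, "control_mfi"))
  df <- data.frame(d = s$dose, y = norm)
  fit <- stats::nls(y ~ 100 / (100 + k * d), df, start = list(k = 0.02))
  expect_lt(abs(coef(fit)[["k"]] - k_true) / k_true, 0.10)
})

test_that("noiseless 4PL standards are recovered to 4 significant figures", {
  std <- simulate_standards(a = 0.05, b = 1.1, c = 180, d = 3.2)
  fit <- fit_4pl(std$concentration, std$od)
  expect_equal(signif(fit$a, 4), 0.05)
  expect_equal(signif(fit$b, 4), 1.1)
  expect_equal(signif(fit$c, 4), 180)
  expect_equal(signif(fit$d, 4), 3.2)
  # fit + interpolate is the identity on model-generated data
  interp <- interpolate_4pl(fit, std$od)
  expect_equal(interp$concentration, std$concentration, tolerance = 1e-6)
  expect_false(any(interp$out_of_range))
  # out-of-range ODs are flagged, not extrapolated
  oor <- interpolate_4pl(fit, c(0.01, 3.19))
  expect_true(oor$out_of_range[1])
  expect_true(is.na(oor$concentration[1]))
})

test_that("duplicate ODs are averaged per sample and bad standards rejected", {
  std <- simulate_standards()
  fit <- fit_4pl(std$concentration, std$od)
  samples <- data.frame(sample = rep(c("s1", "s2"), each = 2),
                        od = c(1.0, 1.1, 2.0, 2.1))
  rep_tab <- p24_report(fit, samples)
  by_hand <- mean(interpolate_4pl(fit, c(1.0, 1.1))$concentration)
  expect_equal(rep_tab$concentration[rep_tab$sample == "s1"], by_hand)
  expect_equal(rep_tab$n_in_range, c(2L, 2L))

  expect_error(fit_4pl(c(10, 20, 40), c(0.1, 0.5, 0.9)), "4 distinct")
  set.seed(2)
  expect_error(fit_4pl(std$concentration, sample(std$od)), "monotone")
})
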