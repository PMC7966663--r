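# Equilibrium denaturation: spectral reduction, three-state model, fitting,
# stability bookkeeping.

test_that("average emission wavelength reduces spectra correctly", {
  expect_equal(average_emission_wavelength(300:400, rep(2, 101)), 350)
  wl <- seq(300, 400, by = 10)
  f <- rep(0, length(wl)); f[wl == 330] <- 7
  expect_equal(average_emission_wavelength(wl, f), 330)
  expect_equal(average_emission_wavelength(c(330, 340, 350), c(1, 2, 1)), 340)
  expect_error(average_emission_wavelength(c(330, 340), c(0, 0)), "degenerate")
  expect_error(average_emission_wavelength(c(340, 330), c(1, 1)), "increasing")
  # value always inside the grid
  set.seed(7)
  for (i in 1:10) {
    f <- runif(21)
    v <- average_emission_wavelength(seq(300, 400, 5), f)
    expect_gte(v, 300); expect_lte(v, 400)
  }
})

test_that("CD averaging uses the inclusive 220-224 nm window", {
  expect_equal(average_cd_signal(215:230, rep(-10, 16)), -10)
  expect_equal(average_cd_signal(200:250, 200:250), 222)
  expect_error(average_cd_signal(200:219, rep(1, 20)), "window")
})

test_that("fraction folded normalises and orients curves", {
  cv <- denaturation_curve(c(0, 3, 6), c(350, 355, 360))  # red-shift up
  expect_equal(fraction_folded(cv)$signal, c(1, 0.5, 0))
  # idempotent on an already-normalised decreasing curve
  cv2 <- denaturation_curve(c(0, 3, 6), c(1, 0.5, 0))
  expect_equal(fraction_folded(cv2)$signal, c(1, 0.5, 0))
  # sign inversion gives the same output
  cv3 <- denaturation_curve(c(0, 3, 6), -c(350, 355, 360))
  expect_equal(fraction_folded(cv3)$signal, fraction_folded(cv)$signal)
  expect_error(fraction_folded(denaturation_curve(c(0, 1, 2), rep(5, 3))),
               "constant")
})

test_that("three-state signal obeys its limits and population closure", {
  pars <- c(a0 = 10, a1 = 0, a2 = 30, a3 = 0, a4 = 50, a5 = 0,
            m1 = 15, Cm1 = 2, m2 = 15, Cm2 = 40)
  # at c = Cm1 with Cm2 far away and flat baselines: midpoint of N and I
  expect_equal(three_state_signal(pars, 2), 20, tolerance = 1e-9)
  # native-baseline limit at low conc
  pars2 <- c(a0 = 10, a1 = 1.5, a2 = 30, a3 = 0, a4 = 50, a5 = 0,
             m1 = 15, Cm1 = 20, m2 = 15, Cm2 = 40)
  expect_equal(three_state_signal(pars2, c(0, 0.5)), c(10, 10.75),
               tolerance = 1e-9)
  # populations sum to one at every concentration, including extremes
  set.seed(11)
  for (i in 1:20) {
    p <- random_ts_pars()
    pop <- three_state_populations(p, seq(-2, 12, by = 0.5))
    expect_equal(rowSums(pop), rep(1, nrow(pop)), tolerance = 1e-12)
  }
})

test_that("unfolded fraction is monotone in denaturant for positive m", {
  set.seed(12)
  cc <- seq(0, 10, by = 0.1)
  for (i in 1:10) {
    pop <- three_state_populations(random_ts_pars(), cc)
    expect_true(all(diff(pop[, "pU"]) >= -1e-12))
  }
})

test_that("noiseless three-state fits recover their generating parameters", {
  pars <- c(a0 = 335, a1 = 0.8, a2 = 347, a3 = 0, a4 = 353, a5 = 0.2,
            m1 = 15, Cm1 = 2.8, m2 = 14, Cm2 = 3.0)
  cv <- gen_denaturation(pars, seq(0, 6, by = 0.25), noise_sd = 0)
  fit <- fit_three_state(cv)
  expect_true(fit$converged)
  expect_lt(max(rel_err(fit$pars[c("m1", "Cm1", "m2", "Cm2")],
                        pars[c("m1", "Cm1", "m2", "Cm2")])), 2e-6)
  expect_lt(max(abs(fit$pars - pars)), 1e-3)
  # two identical replicate curves fitted globally give the same thermodynamics
  fit2 <- fit_three_state(list(cv, cv))
  expect_equal(fit2$pars[c("m1", "Cm1", "m2", "Cm2")],
               fit$pars[c("m1", "Cm1", "m2", "Cm2")], tolerance = 1e-6)
  # per-curve baselines also supported
  fit3 <- fit_three_state(list(cv, cv), share_baselines = FALSE)
  expect_equal(unname(fit3$pars[c("m1", "Cm1", "m2", "Cm2")]),
               unname(pars[c("m1", "Cm1", "m2", "Cm2")]), tolerance = 1e-4)
})

test_that("random noiseless parameter sets are recovered to 1e-4 relative", {
  set.seed(101)
  for (i in 1:20) {
    p <- random_ts_pars()
    cc <- seq(0, p[["Cm2"]] + 3, length.out = 30)
    cv <- denaturation_curve(cc, three_state_signal(p, cc))
    fit <- fit_three_state(cv)
    expect_lt(max(rel_err(fit$pars[c("m1", "Cm1", "m2", "Cm2")],
                          p[c("m1", "Cm1", "m2", "Cm2")])), 1e-4)
  }
})

test_that("recovered dG_N is unbiased under 1% amplitude noise", {
  # resolved transitions: with near-coincident midpoints the three-state
  # model is weakly identified and no estimator is unbiased at this noise
  pars <- c(a0 = 335, a1 = 0.8, a2 = 347, a3 = 0, a4 = 353, a5 = 0.2,
            m1 = 15, Cm1 = 2.2, m2 = 14, Cm2 = 4.2)
  truth <- pars[["m1"]] * pars[["Cm1"]]
  amp <- diff(range(three_state_signal(pars, seq(0, 6, 0.25))))
  runs <- vapply(1:50, function(s) {
    cv <- gen_denaturation(pars, seq(0, 6, by = 0.25),
                           noise_sd = 0.01 * amp, seed = s)
    st <- domain_stability(fit_three_state(cv))
    c(st$dG_N, st$dG_N_sd)
  }, numeric(2))
  # bias must be inside one pooled (rms) per-fit standard error of dG_N
  pooled_se <- sqrt(mean(runs[2, ]^2))
  expect_lt(abs(mean(runs[1, ]) - truth), pooled_se)
})

test_that("domain stability propagates m-Cm uncertainty to first order", {
  pars <- c(a0 = 335, a1 = 0.8, a2 = 347, a3 = 0, a4 = 353, a5 = 0.2,
            m1 = 15, Cm1 = 2.8, m2 = 14, Cm2 = 3.0)
  fit <- fit_three_state(gen_denaturation(pars, seq(0, 6, by = 0.25)))
  st <- domain_stability(fit, "WT")
  expect_equal(st$dG_N, 42.0, tolerance = 1e-4)
  expect_equal(st$dG_C, 42.0, tolerance = 1e-4)
  # Eq. 3 consistency: dG reproducible from the stored fit
  expect_equal(st$dG_N, fit$pars[["m1"]] * fit$pars[["Cm1"]],
               tolerance = 1e-9)
  # propagation limits on a hand-built fit: sd(m)=0, sd(Cm)=s -> sd = m*s
  fk <- fit
  fk$pars[c("m1", "Cm1")] <- c(10, 2)
  fk$cov[] <- 0; fk$cov["Cm1", "Cm1"] <- 0.09
  expect_equal(domain_stability(fk)$dG_N_sd, 10 * 0.3, tolerance = 1e-12)
  # m = 0 gives dG = 0
  fk$pars[["m1"]] <- 0
  expect_equal(domain_stability(fk)$dG_N, 0)
})

test_that("ddG bookkeeping is antisymmetric with quadrature errors", {
  a <- list(dG_N = 42, dG_N_sd = 1.9, dG_C = 42, dG_C_sd = 2.8, variant = "A")
  b <- list(dG_N = 27.2, dG_N_sd = 2.8, dG_C = 39.7, dG_C_sd = 3.0,
            variant = "B")
  d_ab <- ddg(a, b, "N"); d_ba <- ddg(b, a, "N")
  expect_equal(d_ab$ddG, -d_ba$ddG)
  expect_equal(d_ab$ddG_sd, d_ba$ddG_sd)
  expect_equal(ddg(a, a, "N")$ddG, 0)
  expect_equal(d_ab$ddG_sd, sqrt(1.9^2 + 2.8^2))
})

test_that("amplitude ratio matches a dense-evaluation oracle", {
  # flat baselines, well-separated transitions: plateaus are the baselines
  pars <- c(a0 = 10, a1 = 0, a2 = 30, a3 = 0, a4 = 40, a5 = 0,
            m1 = 30, Cm1 = 2, m2 = 30, Cm2 = 7)
  cv <- denaturation_curve(seq(0, 10, by = 0.25),
                           three_state_signal(pars, seq(0, 10, by = 0.25)))
  fit <- fit_three_state(cv)
  # native->intermediate step is 20, intermediate->unfolded step is 10
  expect_equal(amplitude_ratio(fit), 2.0, tolerance = 1e-6)
  # numeric oracle: plateau levels from dense curve evaluation
  dense <- three_state_signal(fit$pars, c(0, 4.5, 12))
  oracle <- abs(dense[1] - dense[2]) / abs(dense[2] - dense[3])
  expect_equal(amplitude_ratio(fit), oracle, tolerance = 1e-6)
  # equal amplitudes give 1
  pars2 <- pars; pars2[["a4"]] <- 50
  cv2 <- denaturation_curve(seq(0, 10, by = 0.25),
                            three_state_signal(pars2, seq(0, 10, by = 0.25)))
  expect_equal(amplitude_ratio(fit_three_state(cv2)), 1.0, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected", {
  cv <- denaturation_curve(seq(0, 2, length.out = 8), rnorm(8))
  expect_error(fit_three_state(cv), "12 points")
  expect_error(denaturation_curve(c(-1, 0, 1), 1:3), "non-negative")
})
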