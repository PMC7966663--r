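# SPR 1:1 kinetics: simulation, referencing, global and local fitting,
# steady-state affinity.

test_that("closed-form simulation matches an independent RK4 integration", {
  set.seed(41)
  kon <- 10^runif(1, 4, 6); koff <- 10^runif(1, -3.5, -2)
  Rmax <- runif(1, 10, 100); cc <- 10^runif(1, -7.5, -6)
  g <- simulate_sensorgram(kon, koff, Rmax,
                           data.frame(conc = cc, t_assoc = 200, t_dissoc = 300),
                           dt = 5)
  a <- g[g$phase == "association", ]
  ode <- rk4_langmuir(kon, koff, Rmax, cc, a$time, R0 = 0, h = 0.01)
  expect_lt(max(abs(a$response - ode)), 1e-8 * Rmax)
  d <- g[g$phase == "dissociation", ]
  ode_d <- rk4_langmuir(kon, koff, Rmax, 0,
                        c(max(a$time), d$time),
                        R0 = a$response[nrow(a)], h = 0.01)[-1]
  expect_lt(max(abs(d$response - ode_d)), 1e-8 * Rmax)
})

test_that("association plateau equals the steady-state isotherm", {
  set.seed(42)
  for (i in 1:10) {
    kon <- 10^runif(1, 4, 6); koff <- 10^runif(1, -4, -2)
    Rmax <- runif(1, 5, 150); cc <- 10^runif(1, -8, -5)
    kobs <- kon * cc + koff
    plateau <- kon * cc * Rmax / kobs
    req <- Rmax * cc / (koff / kon + cc)
    expect_equal(plateau, req, tolerance = 1e-12)
    # and the simulator reaches it at long times
    g <- simulate_sensorgram(kon, koff, Rmax,
                             data.frame(conc = cc, t_assoc = 30 / kobs,
                                        t_dissoc = 10),
                             dt = max(1, 30 / kobs / 200))
    a <- g[g$phase == "association", ]
    expect_equal(a$response[nrow(a)], req, tolerance = 1e-8)
  }
})

test_that("zero analyte gives a flat zero trace", {
  g <- simulate_sensorgram(2e5, 4.3e-3, 18.2,
                           data.frame(conc = 1e-9, t_assoc = 10,
                                      t_dissoc = 10), dt = 1)
  # conc = 0 throughout is modelled by the blank construction
  quad <- gen_sensorgram(injections = data.frame(conc = 1e-7, t_assoc = 50,
                                                 t_dissoc = 50),
                         bulk_offset = 0)
  expect_true(all(quad$blank_active$response == 0))
})

test_that("double-blank referencing cancels shared artefacts exactly", {
  quad <- gen_sensorgram(kon = 2e5, koff = 4.3e-3, Rmax = 18.2,
                         injections = data.frame(
                           conc = c(1e-7, 4e-7), t_assoc = 100, t_dissoc = 150),
                         dt = 2, bulk_offset = 5, drift = 0.01)
  refd <- double_blank_reference(quad$active, quad$reference,
                                 quad$blank_active, quad$blank_reference)
  clean <- simulate_sensorgram(2e5, 4.3e-3, 18.2,
                               data.frame(conc = c(1e-7, 4e-7), t_assoc = 100,
                                          t_dissoc = 150), dt = 2)
  expect_equal(refd$response, clean$response, tolerance = 1e-10)
  # all four identical -> zero
  z <- double_blank_reference(quad$active, quad$active, quad$active,
                              quad$active)
  expect_true(all(abs(z$response) < 1e-12))
  # blanks zero -> active minus reference
  ar <- double_blank_reference(quad$active, quad$reference,
                               quad$blank_reference, quad$blank_reference)
  expect_equal(ar$response, quad$active$response - quad$reference$response,
               tolerance = 1e-12)
})

test_that("global kinetic fitting recovers noiseless generating rates", {
  g <- simulate_sensorgram(2.0e5, 4.3e-3, 18.2,
                           data.frame(conc = c(0.1e-6, 0.4e-6, 1.6e-6),
                                      t_assoc = 300, t_dissoc = 600), dt = 2)
  fit <- fit_kinetics(g)
  expect_lt(rel_err(fit$kon, 2.0e5), 1e-6)
  expect_lt(rel_err(fit$koff, 4.3e-3), 1e-6)
  expect_lt(rel_err(fit$Rmax, 18.2), 1e-6)
  # KD identity holds by construction
  expect_equal(fit$KD, fit$koff / fit$kon, tolerance = 1e-12)
  # identifiability: halving kon*c via Rmax doubling does not fit equally
  g2 <- simulate_sensorgram(1.0e5, 4.3e-3, 36.4,
                            data.frame(conc = c(0.1e-6, 0.4e-6, 1.6e-6),
                                       t_assoc = 300, t_dissoc = 600), dt = 2)
  expect_gt(max(abs(g2$response - g$response)), 1)
  expect_error(fit_kinetics(g[g$cycle == 1, ]), ">= 3")
})

test_that("noisy kinetic recovery stays within the stated error budget", {
  ests <- vapply(1:25, function(s) {
    quad <- gen_sensorgram(kon = 2.0e5, koff = 4.3e-3, Rmax = 18.2,
                           injections = data.frame(
                             conc = c(0.1e-6, 0.4e-6, 1.6e-6),
                             t_assoc = 300, t_dissoc = 600),
                           dt = 4, noise_sd = 1, seed = s)
    refd <- double_blank_reference(quad$active, quad$reference,
                                   quad$blank_active, quad$blank_reference)
    fit <- fit_kinetics(refd)
    c(fit$kon, fit$koff)
  }, numeric(2))
  expect_lt(median(rel_err(ests[2, ], 4.3e-3)), 0.05)
  expect_lt(median(rel_err(ests[1, ], 2.0e5)), 0.10)
})

test_that("local initial-dissociation fitting recovers koff", {
  g <- simulate_sensorgram(2.0e5, 4.3e-3, 18.2,
                           data.frame(conc = 1e-6, t_assoc = 300,
                                      t_dissoc = 600), dt = 1)
  out <- fit_initial_dissociation(g, window = 60)
  expect_lt(rel_err(out$koff, 4.3e-3), 1e-6)
  # flat trace flags
  flat <- g
  flat$response[flat$phase == "dissociation"] <- 5
  expect_true(all(fit_initial_dissociation(flat)$per_cycle$flag !=
                    "ok"))
})

test_that("biphasic decays bias the windowed estimate toward the fast phase", {
  k_fast <- 2e-2; k_slow <- 2e-3
  tt <- seq(0, 600, by = 1)
  resp <- 10 * exp(-k_fast * tt) + 10 * exp(-k_slow * tt)
  g <- sensorgram(time = c(0.5, tt + 1), response = c(20.5, resp),
                  conc = c(1e-7, rep(0, length(tt))),
                  phase = c("association", rep("dissociation", length(tt))),
                  cycle = 1L)
  est <- fit_initial_dissociation(g, window = 60)$koff
  expect_gt(est, k_slow); expect_lt(est, k_fast)
  # windowed oracle: single-exponential lsq on the same first 60 s
  w <- tt <= 60
  oracle <- coef(stats::nls(y ~ A * exp(-k * t),
                            data = data.frame(y = resp[w], t = tt[w]),
                            start = list(A = 20, k = 0.01)))[["k"]]
  expect_equal(est, oracle, tolerance = 1e-3)
  expect_gt(est, (k_fast + k_slow) / 2 * 0.8)  # closer to the fast rate
})

test_that("steady-state isotherm fitting recovers KD and Rmax", {
  cc <- twofold_dilutions(10e-9, 9)
  expect_equal(cc[9], 2.56e-6)
  req <- 18.2 * cc / (130e-9 + cc)
  fit <- fit_steady_state(cc, req)
  expect_lt(rel_err(fit$KD, 130e-9), 1e-8)
  expect_lt(rel_err(fit$Rmax, 18.2), 1e-8)
  # R at c = KD is half-maximal
  expect_equal(18.2 * 130e-9 / (130e-9 + 130e-9), 18.2 / 2)
  # saturation limit
  expect_equal(18.2 * 1 / (130e-9 + 1), 18.2, tolerance = 1e-6)
  # concentrations far below KD trigger the wide-CI warning flag
  low <- cc[1:4] / 100
  fit_low <- fit_steady_state(low, 18.2 * low / (130e-9 + low))
  expect_true(length(fit_low$flags) > 0)
})

test_that("steady-state readout extraction matches the configured time", {
  g <- simulate_sensorgram(2.0e5, 4.3e-3, 18.2,
                           data.frame(conc = c(1e-7, 1e-6), t_assoc = 300,
                                      t_dissoc = 100), dt = 1)
  ss <- steady_state_response(g, readout = 150)
  direct <- vapply(c(1e-7, 1e-6), function(cc) {
    kobs <- 2.0e5 * cc + 4.3e-3
    2.0e5 * cc * 18.2 / kobs * (1 - exp(-kobs * 150))
  }, numeric(1))
  expect_equal(ss$Req[order(ss$conc)], direct, tolerance = 1e-9)
})

test_that("single- and multi-cycle protocols agree after full decay", {
  inj <- data.frame(conc = c(1e-7, 2e-7), t_assoc = 100,
                    t_dissoc = ceiling(10 / 4.3e-3))
  gm <- simulate_sensorgram(2.0e5, 4.3e-3, 18.2, inj, protocol = "multi",
                            dt = 5)
  gs <- simulate_sensorgram(2.0e5, 4.3e-3, 18.2, inj, protocol = "single",
                            dt = 5)
  # second-injection association traces coincide (carry-over has decayed)
  am <- gm[gm$cycle == 2 & gm$phase == "association", ]
  as <- gs[gs$injection == 2 & gs$phase == "association", ]
  expect_equal(as$response, am$response[-1], tolerance = 1e-3)
})

test_that("sensorgram CSV round-trips through the readers", {
  g <- simulate_sensorgram(2e5, 4.3e-3, 18.2,
                           data.frame(conc = 1e-7, t_assoc = 20,
                                      t_dissoc = 20), dt = 2)
  f <- tempfile(fileext = ".csv")
  write_sensorgram_csv(g, f)
  rt <- read_sensorgram_csv(f)
  expect_equal(rt$response, g$response)
  expect_equal(rt$conc, g$conc)
})
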