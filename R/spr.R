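## Surface plasmon resonance: closed-form 1:1 Langmuir sensorgram
## simulation, double-blank referencing, global kinetic fitting, local
## initial-dissociation rates and steady-state affinity.

#' Construct a sensorgram
#'
#' @param time Time in seconds, strictly increasing within each cycle.
#' @param response Response in RU.
#' @param conc Injected analyte concentration in mol/L per point (0 during
#'   dissociation).
#' @param phase `"association"` or `"dissociation"` per point.
#' @param cycle Cycle id per point (default 1).
#' @param channel `"active"`, `"reference"` or `"blank"` role label.
#' @return A `sensorgram` data frame.
#' @export
sensorgram <- function(time, response, conc, phase, cycle = 1L,
                       channel = "active") {
  out <- data.frame(time = time, response = response, conc = conc,
                    phase = phase, cycle = as.integer(cycle),
                    channel = channel)
  for (cy in split(out, out$cycle)) {
    if (any(diff(cy$time) <= 0))
      stop("time must be strictly increasing within a cycle", call. = FALSE)
    if (any(cy$conc[cy$phase == "association"] <= 0))
      stop("association segments must have positive conc", call. = FALSE)
    if (any(cy$conc[cy$phase == "dissociation"] != 0))
      stop("dissociation segments must have conc 0", call. = FALSE)
  }
  class(out) <- c("sensorgram", "data.frame")
  out
}

#' The standard twofold dilution concentration series
#'
#' Nine twofold dilutions spanning 10 nM to 2.56 uM (ascending), the analyte
#' series of the multi-cycle binding protocol.
#' @param bottom Lowest concentration in mol/L, default 10 nM.
#' @param n Number of concentrations, default 9.
#' @return Numeric vector in mol/L.
#' @export
twofold_dilutions <- function(bottom = 10e-9, n = 9L) {
  bottom * 2^(seq_len(n) - 1L)
}

## closed-form 1:1 pseudo-first-order segment solutions:
## association from R0: R(t) = Req + (R0 - Req) exp(-kobs t),
##   kobs = kon c + koff, Req = kon c Rmax / kobs
## dissociation from R0: R(t) = R0 exp(-koff t)
.assoc_segment <- function(t, R0, kon, koff, Rmax, conc) {
  kobs <- kon * conc + koff
  Req <- kon * conc * Rmax / kobs
  Req + (R0 - Req) * exp(-kobs * t)
}

#' Simulate a 1:1 binding sensorgram
#'
#' Closed-form solution of the pseudo-first-order Langmuir model
#' \eqn{dR/dt = k_{on} c_a (R_{max} - R) - k_{off} R} over a sequence of
#' injections.  In the multi-cycle protocol every injection starts a fresh
#' regenerated cycle (R = 0); in the single-cycle protocol the response
#' carries forward between injections.
#'
#' @param kon Association rate constant, M^-1 s^-1.
#' @param koff Dissociation rate constant, s^-1.
#' @param Rmax Binding capacity in RU.
#' @param injections Data frame with columns `conc` (M), `t_assoc`,
#'   `t_dissoc` (s).
#' @param protocol `"multi"` (default) or `"single"`.
#' @param dt Sampling interval in s, default 1.
#' @param noise_sd Gaussian noise sd in RU, default 0.
#' @param drift Linear baseline drift in RU/s (exercises fit diagnostics).
#' @param seed Optional RNG seed for the noise.
#' @param channel Channel role label.
#' @return A [sensorgram()].
#' @export
simulate_sensorgram <- function(kon, koff, Rmax, injections,
                                protocol = c("multi", "single"), dt = 1,
                                noise_sd = 0, drift = 0, seed = NULL,
                                channel = "active") {
  protocol <- match.arg(protocol)
  stopifnot(kon > 0, koff > 0, Rmax > 0,
            all(c("conc", "t_assoc", "t_dissoc") %in% names(injections)))
  rows <- list()
  R <- 0
  for (i in seq_len(nrow(injections))) {
    cy <- if (protocol == "multi") i else 1L
    if (protocol == "multi") R <- 0
    # the t = 0 sample carries the cycle's starting response; later
    # injections of a single-cycle run start at dt to keep time strictly
    # increasing after stitching
    t_from <- if (protocol == "single" && i > 1L) dt else 0
    ta <- seq(t_from, injections$t_assoc[i], by = dt)
    ya <- .assoc_segment(ta, R, kon, koff, Rmax, injections$conc[i])
    R_end <- ya[length(ya)]
    td <- if (injections$t_dissoc[i] >= dt)
      seq(dt, injections$t_dissoc[i], by = dt) else numeric(0)
    yd <- R_end * exp(-koff * td)
    rows[[i]] <- data.frame(
      time = c(ta, injections$t_assoc[i] + td),
      response = c(ya, yd),
      conc = c(rep(injections$conc[i], length(ta)), rep(0, length(td))),
      phase = c(rep("association", length(ta)),
                rep("dissociation", length(td))),
      cycle = cy, injection = i)
    R <- yd[length(yd)]
  }
  df <- do.call(rbind, rows)
  if (protocol == "single") {
    # stitch injections onto one continuous time base
    off <- c(0, cumsum(injections$t_assoc + injections$t_dissoc))
    df$time <- df$time + off[df$injection]
  }
  if (drift != 0) df$response <- df$response + drift * df$time
  if (noise_sd > 0)
    df$response <- .with_seed(seed,
      df$response + stats::rnorm(nrow(df), 0, noise_sd))
  g <- sensorgram(df$time, df$response, df$conc, df$phase, df$cycle, channel)
  g$injection <- df$injection
  attr(g, "protocol") <- protocol
  g
}

#' Double-blank referencing of sensorgrams
#'
#' Subtracts the reference channel and the buffer-blank pair:
#' `(active - reference) - (blank_active - blank_reference)`, removing bulk
#' refractive-index jumps and surface drift common to the channels.  Traces
#' are linearly interpolated onto the active channel's time base per cycle.
#'
#' @param active,reference,blank_active,blank_reference [sensorgram()]s with
#'   matching cycle structure.
#' @return A referenced [sensorgram()].
#' @export
double_blank_reference <- function(active, reference, blank_active,
                                   blank_reference) {
  grams <- list(active, reference, blank_active, blank_reference)
  stopifnot(all(vapply(grams, inherits, TRUE, "sensorgram")))
  cyc <- sort(unique(active$cycle))
  for (g in grams[-1L])
    if (!identical(sort(unique(g$cycle)), cyc))
      stop("mismatched cycle structure across channels", call. = FALSE)
  interp <- function(g, cy, t) {
    gi <- g[g$cycle == cy, ]
    stats::approx(gi$time, gi$response, xout = t, rule = 2)$y
  }
  out <- active
  for (cy in cyc) {
    i <- active$cycle == cy
    t <- active$time[i]
    out$response[i] <- active$response[i] - interp(reference, cy, t) -
      (interp(blank_active, cy, t) - interp(blank_reference, cy, t))
  }
  out$channel <- "referenced"
  out
}

## Piecewise closed-form prediction for a whole sensorgram layout.  Segment
## boundaries fall at phase/concentration changes; each segment's time origin
## (where R = R0) is the previous segment's last sample, except the first
## segment of a cycle whose first sample is its own origin.
.predict_gram <- function(layout, kon, koff, Rmax) {
  out <- numeric(nrow(layout))
  for (cy in unique(layout$cycle)) {
    idx <- which(layout$cycle == cy)
    n <- length(idx)
    ph <- layout$phase[idx]; cc <- layout$conc[idx]
    seg_id <- cumsum(c(TRUE, ph[-1L] != ph[-n] | cc[-1L] != cc[-n]))
    R0 <- 0
    origin <- layout$time[idx][1L]
    for (s in unique(seg_id)) {
      si <- idx[seg_id == s]
      t <- layout$time[si] - origin
      y <- if (layout$phase[si][1L] == "association")
        .assoc_segment(t, R0, kon, koff, Rmax, layout$conc[si][1L])
      else R0 * exp(-koff * t)
      out[si] <- y
      origin <- layout$time[si][length(si)]
      R0 <- y[length(y)]
    }
  }
  out
}

#' Global 1:1 kinetic fit of a sensorgram set
#'
#' Least-squares fit of the pseudo-first-order Langmuir model to all
#' association and dissociation phases simultaneously, sharing `kon`, `koff`
#' and `Rmax`.  Residual diagnostics are reported because real two-domain
#' sensor data often deviates from 1:1 behaviour and the misfit must be
#' visible.
#'
#' @param gram A (referenced) [sensorgram()] covering >= 3 analyte
#'   concentrations.
#' @return A `kinetic_fit`: `kon`, `koff`, `Rmax`, `KD` (= koff/kon), sds
#'   (KD by the delta method), `diagnostics` (rmse, max abs residual, per-
#'   cycle rmse), `converged`, `flags`, `mode = "global"`.
#' @export
fit_kinetics <- function(gram) {
  stopifnot(inherits(gram, "sensorgram"))
  concs <- sort(unique(gram$conc[gram$conc > 0]))
  if (length(concs) < 3L)
    stop("global kinetic fitting requires >= 3 analyte concentrations",
         call. = FALSE)
  # starts: koff from late dissociation, kon from a grid
  koff0 <- tryCatch({
    d <- gram[gram$phase == "dissociation" & gram$response > 0, ]
    d <- d[d$cycle == d$cycle[1L], ]
    -stats::coef(stats::lm(log(response) ~ time, data = d))[[2L]]
  }, error = function(e) 1e-3)
  if (!is.finite(koff0) || koff0 <= 0) koff0 <- 1e-3
  Rmax0 <- max(gram$response) * 1.2
  best <- NULL
  for (kon0 in c(1e5, 1e4, 1e6)) {
    fit <- tryCatch(
      stats::nls(response ~ .predict_gram(gram, kon, koff, Rmax),
                 data = gram,
                 start = list(kon = kon0, koff = koff0, Rmax = Rmax0),
                 algorithm = "port", lower = c(1e-3, 1e-8, 1e-6),
                 control = stats::nls.control(maxiter = 500, tol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
      if (rss < 1e-14 * (1 + sum(gram$response^2))) break
    }
  }
  if (is.null(best))
    stop("kinetic fit did not converge from any start", call. = FALSE)
  fit <- best$fit
  cf <- stats::coef(fit)
  V <- tryCatch(stats::vcov(fit), error = function(e)
    matrix(NA_real_, 3, 3, dimnames = list(names(cf), names(cf))))
  kd <- cf[["koff"]] / cf[["kon"]]
  # delta method for KD = koff/kon
  gvec <- c(kon = -kd / cf[["kon"]], koff = 1 / cf[["kon"]], Rmax = 0)
  kd_sd <- tryCatch(sqrt(drop(t(gvec) %*% V %*% gvec)),
                    error = function(e) NA_real_)
  r <- stats::resid(fit)
  per_cycle <- tapply(r, gram$cycle, function(x) sqrt(mean(x^2)))
  flags <- character()
  if (any(cf <= 0)) flags <- c(flags, "non_positive_rate")
  structure(list(kon = cf[["kon"]], koff = cf[["koff"]], Rmax = cf[["Rmax"]],
                 KD = kd,
                 sd = c(kon = sqrt(V["kon", "kon"]),
                        koff = sqrt(V["koff", "koff"]),
                        Rmax = sqrt(V["Rmax", "Rmax"]), KD = kd_sd),
                 diagnostics = list(rmse = sqrt(mean(r^2)),
                                    max_abs_resid = max(abs(r)),
                                    per_cycle_rmse = per_cycle),
                 converged = fit$convInfo$isConv, flags = flags,
                 mode = "global", fit = fit),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("1:1 kinetic fit (%s): kon = %.3g M-1 s-1, koff = %.3g s-1, KD = %.3g M, Rmax = %.3g RU\n",
              x$mode, x$kon, x$koff, x$KD, x$Rmax))
  cat(sprintf("  rmse = %.3g RU, max |resid| = %.3g RU\n",
              x$diagnostics$rmse, x$diagnostics$max_abs_resid))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Local initial-dissociation rate estimate
#'
#' Single-exponential fit restricted to the first `window` seconds of each
#' dissociation phase, giving a model-light estimate of koff when the full
#' 1:1 model fits poorly.
#'
#' @param gram A [sensorgram()].
#' @param window Fit window in seconds from the start of dissociation,
#'   default 60.
#' @return List with `per_cycle` (data frame `cycle`, `koff`, `sd`, `flag`)
#'   and `koff` (mean over cycles with a decaying signal).
#' @export
fit_initial_dissociation <- function(gram, window = 60) {
  stopifnot(inherits(gram, "sensorgram"))
  res <- lapply(sort(unique(gram$cycle)), function(cy) {
    d <- gram[gram$cycle == cy & gram$phase == "dissociation", ]
    if (nrow(d) < 3L) return(NULL)
    t0 <- min(d$time)
    d <- d[d$time - t0 <= window, ]
    if (nrow(d) < 3L)
      return(data.frame(cycle = cy, koff = NA_real_, sd = NA_real_,
                        flag = "window_too_short"))
    t <- d$time - t0
    start <- tryCatch({
      cf <- stats::coef(stats::lm(log(pmax(d$response, 1e-12)) ~ t))
      list(A = exp(cf[[1L]]), koff = -cf[[2L]])
    }, error = function(e) list(A = max(d$response), koff = 1e-3))
    if (!is.finite(start$koff) || start$koff <= 0)
      return(data.frame(cycle = cy, koff = NA_real_, sd = NA_real_,
                        flag = "non_decaying"))
    fit <- tryCatch(
      stats::nls(response ~ A * exp(-koff * t),
                 data = data.frame(response = d$response, t = t),
                 start = start, algorithm = "port", lower = c(0, 0),
                 control = stats::nls.control(maxiter = 200, tol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(cycle = cy, koff = NA_real_, sd = NA_real_,
                        flag = "fit_failed"))
    cf <- stats::coef(fit)
    sdk <- tryCatch(sqrt(stats::vcov(fit)["koff", "koff"]),
                    error = function(e) NA_real_)
    data.frame(cycle = cy, koff = cf[["koff"]], sd = sdk,
               flag = if (cf[["koff"]] <= 0) "non_decaying" else "ok")
  })
  per_cycle <- do.call(rbind, res)
  ok <- per_cycle$flag == "ok"
  list(per_cycle = per_cycle,
       koff = if (any(ok)) mean(per_cycle$koff[ok]) else NA_real_,
       window = window)
}

#' Extract steady-state responses at a readout time
#'
#' Response at a fixed time after the start of each association phase (150 s
#' is the conventional best approximation to steady state for slow-dissociating
#' complexes on 600-s injections).
#'
#' @param gram A [sensorgram()].
#' @param readout Seconds after injection start, default 150.
#' @return Data frame `conc`, `Req`.
#' @export
steady_state_response <- function(gram, readout = 150) {
  stopifnot(inherits(gram, "sensorgram"))
  res <- lapply(sort(unique(gram$cycle)), function(cy) {
    a <- gram[gram$cycle == cy & gram$phase == "association", ]
    if (nrow(a) == 0L) return(NULL)
    do.call(rbind, lapply(unique(a$conc), function(cc) {
      ai <- a[a$conc == cc, ]
      t0 <- min(ai$time)
      data.frame(conc = cc,
                 Req = stats::approx(ai$time - t0, ai$response,
                                     xout = readout, rule = 2)$y)
    }))
  })
  do.call(rbind, res)
}

#' Steady-state affinity fit
#'
#' Least-squares fit of the rectangular hyperbola
#' \eqn{R_{eq} = R_{max} c_a / (K_D + c_a)} to equilibrium responses.
#'
#' @param conc Analyte concentrations in mol/L (>= 4, ideally spanning KD).
#' @param Req Equilibrium responses in RU.
#' @param readout Optional readout-time annotation in seconds.
#' @return A `steady_state_fit`: `KD`, `Rmax`, `sd`, `flags` (wide-CI
#'   warning when all concentrations are far below the fitted KD).
#' @export
fit_steady_state <- function(conc, Req, readout = NA_real_) {
  .check_numeric(conc, "conc"); .check_numeric(Req, "Req")
  if (length(conc) < 4L)
    stop("steady-state fitting requires >= 4 concentrations", call. = FALSE)
  Rmax0 <- max(Req) * 1.05
  kd0 <- conc[which.min(abs(Req - Rmax0 / 2))]
  fit <- stats::nls(Req ~ Rmax * conc / (KD + conc),
                    data = data.frame(conc = conc, Req = Req),
                    start = list(Rmax = Rmax0, KD = kd0),
                    algorithm = "port", lower = c(1e-12, 1e-15),
                    control = stats::nls.control(maxiter = 500, tol = 1e-12))
  cf <- stats::coef(fit)
  sdp <- tryCatch(sqrt(pmax(diag(stats::vcov(fit)), 0)),
                  error = function(e) c(Rmax = NA_real_, KD = NA_real_))
  flags <- if (max(conc) < cf[["KD"]] / 2)
    "wide_ci: all concentrations well below fitted KD" else character()
  structure(list(KD = cf[["KD"]], Rmax = cf[["Rmax"]],
                 sd = c(KD = sdp[["KD"]], Rmax = sdp[["Rmax"]]),
                 readout = readout, flags = flags, fit = fit),
            class = "steady_state_fit")
}

#' @export
print.steady_state_fit <- function(x, ...) {
  cat(sprintf("Steady-state fit: KD = %.3g M, Rmax = %.3g RU\n", x$KD, x$Rmax))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
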