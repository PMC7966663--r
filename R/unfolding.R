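## Equilibrium chemical denaturation: signal reduction, the three-state
## linear-extrapolation model N <-> I <-> U, global fitting, per-domain
## stabilities and between-variant stability differences.

#' Average emission wavelength of a fluorescence spectrum
#'
#' Reduces an emission spectrum to its intensity-weighted mean wavelength
#' \eqn{\langle\lambda\rangle = \sum_i F_i \lambda_i / \sum_i F_i}, the
#' standard scalar observable for tryptophan fluorescence unfolding curves
#' (unfolding red-shifts the emission).
#'
#' @param wavelengths Strictly increasing wavelength grid in nm
#'   (typically 300--400 nm with 295 nm excitation).
#' @param intensities Non-negative fluorescence intensities, same length.
#' @return The average emission wavelength in nm; always within
#'   `range(wavelengths)`.
#' @examples
#' average_emission_wavelength(300:400, rep(1, 101))  # 350
#' @export
average_emission_wavelength <- function(wavelengths, intensities) {
  .check_numeric(wavelengths, "wavelengths")
  .check_numeric(intensities, "intensities")
  if (length(wavelengths) != length(intensities))
    stop("'wavelengths' and 'intensities' must have equal length", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("'wavelengths' must be strictly increasing", call. = FALSE)
  if (any(intensities < 0))
    stop("'intensities' must be non-negative", call. = FALSE)
  if (all(intensities == 0))
    stop("degenerate spectrum: all intensities are zero", call. = FALSE)
  sum(intensities * wavelengths) / sum(intensities)
}

#' Average circular dichroism signal over a wavelength window
#'
#' Arithmetic mean of the raw CD signal over the helical-absorption window
#' (inclusive at both ends), the scalar observable for CD-monitored
#' unfolding curves.
#'
#' @param wavelengths Wavelength grid in nm.
#' @param cd Raw CD signal, same length.
#' @param window Two-element window in nm, default `c(220, 224)`.
#' @return Mean CD signal over the window.
#' @export
average_cd_signal <- function(wavelengths, cd, window = c(220, 224)) {
  .check_numeric(wavelengths, "wavelengths")
  .check_numeric(cd, "cd")
  stopifnot(length(window) == 2L, window[1] <= window[2])
  if (length(wavelengths) != length(cd))
    stop("'wavelengths' and 'cd' must have equal length", call. = FALSE)
  keep <- wavelengths >= window[1] & wavelengths <= window[2]
  if (!any(keep))
    stop(sprintf("no samples in the %g-%g nm window", window[1], window[2]),
         call. = FALSE)
  mean(cd[keep])
}

#' Construct a denaturation curve
#'
#' @param conc Denaturant (GdmCl) concentrations in mol/L, non-negative.
#' @param signal Reduced spectroscopic observable per point (average emission
#'   wavelength in nm, or mean CD signal).
#' @param direction `"unfolding"` or `"refolding"`.
#' @param label Variant name.
#' @return A `denaturation_curve` data frame with columns `conc` and `signal`.
#' @export
denaturation_curve <- function(conc, signal, direction = c("unfolding", "refolding"),
                               label = "variant") {
  direction <- match.arg(direction)
  .check_numeric(conc, "conc")
  .check_numeric(signal, "signal")
  if (length(conc) != length(signal))
    stop("'conc' and 'signal' must have equal length", call. = FALSE)
  if (any(conc < 0)) stop("'conc' must be non-negative", call. = FALSE)
  ord <- order(conc)
  out <- data.frame(conc = conc[ord], signal = signal[ord])
  attr(out, "direction") <- direction
  attr(out, "label") <- label
  class(out) <- c("denaturation_curve", "data.frame")
  out
}

#' Normalise a denaturation curve to fraction folded
#'
#' Affine rescale of the observable so the native-baseline extreme maps to 1
#' and the unfolded extreme to 0.  Orientation is resolved from the sign of
#' the end-to-end signal change: the signal at the lowest denaturant
#' concentration is taken as native.
#'
#' @param curve A [denaturation_curve()].
#' @return The curve with `signal` replaced by fraction folded in \[0, 1\].
#' @export
fraction_folded <- function(curve) {
  stopifnot(inherits(curve, "denaturation_curve"))
  s <- curve$signal
  if (max(s) == min(s))
    stop("constant signal: fraction folded is undefined", call. = FALSE)
  f <- (s - min(s)) / (max(s) - min(s))
  # native = lowest-conc end; if the signal rises on unfolding, flip
  if (s[length(s)] > s[1L]) f <- 1 - f
  out <- curve
  out$signal <- f
  out
}

## parameter bookkeeping -----------------------------------------------------

.TS_PARS <- c("a0", "a1", "a2", "a3", "a4", "a5", "m1", "Cm1", "m2", "Cm2")

.as_ts_pars <- function(pars) {
  p <- unlist(pars)
  if (!all(.TS_PARS %in% names(p)))
    stop("three-state parameters must be named ",
         paste(.TS_PARS, collapse = ", "), call. = FALSE)
  p[.TS_PARS]
}

#' Three-state unfolding signal
#'
#' Boltzmann-weighted three-state linear-extrapolation model for the
#' equilibrium N \eqn{\rightleftharpoons} I \eqn{\rightleftharpoons} U.
#' With \eqn{K_1 = \exp(m_1(c - C_{m1})/RT)} and
#' \eqn{K_2 = \exp(m_2(c - C_{m2})/RT)} the observable is
#' \deqn{f(c) = \frac{(a_0 + a_1 c) + (a_2 + a_3 c)K_1 + (a_4 + a_5 c)K_1K_2}
#'  {1 + K_1 + K_1 K_2}}
#' where each state contributes a linear baseline.  Transition 1 (lower
#' midpoint) is the N-domain; the intermediate has an unfolded N-domain and
#' folded C-domain.
#'
#' @param pars Named vector/list with `a0..a5` (baseline intercepts/slopes for
#'   native, intermediate, unfolded states), `m1`, `m2` (kJ mol^-1 M^-1) and
#'   `Cm1`, `Cm2` (mol/L).
#' @param conc Denaturant concentrations in mol/L.
#' @param temperature Kelvin; default 298.15.
#' @return Predicted signal at each concentration.
#' @seealso [three_state_populations()]
#' @export
three_state_signal <- function(pars, conc, temperature = 298.15) {
  p <- .as_ts_pars(pars)
  pop <- three_state_populations(p, conc, temperature)
  unname((p[["a0"]] + p[["a1"]] * conc) * pop[, "pN"] +
           (p[["a2"]] + p[["a3"]] * conc) * pop[, "pI"] +
           (p[["a4"]] + p[["a5"]] * conc) * pop[, "pU"])
}

#' State populations of the three-state model
#'
#' @inheritParams three_state_signal
#' @return Matrix with columns `pN`, `pI`, `pU`; rows sum to 1.
#' @export
three_state_populations <- function(pars, conc, temperature = 298.15) {
  p <- .as_ts_pars(pars)
  RT <- rt_kj(temperature)
  # log-weights relative to N, kept in log space for numerical stability
  l1 <- p["m1"] * (conc - p["Cm1"]) / RT
  l12 <- l1 + p["m2"] * (conc - p["Cm2"]) / RT
  lmax <- pmax(0, l1, l12)
  wN <- exp(0 - lmax); wI <- exp(l1 - lmax); wU <- exp(l12 - lmax)
  z <- wN + wI + wU
  cbind(pN = wN / z, pI = wI / z, pU = wU / z)
}

## Initial guesses: baselines from the terminal 15% of points; candidate
## midpoint pairs from (a) the two dominant peaks of a smoothed numerical
## derivative and (b) threshold crossings of the normalised curve (robust
## when the two transitions overlap).
.ts_start <- function(conc, signal) {
  n <- length(conc)
  k <- max(3L, ceiling(0.15 * n))
  lo <- seq_len(k); hi <- seq.int(n - k + 1L, n)
  fit_lin <- function(i) {
    if (length(unique(conc[i])) < 2L) return(c(mean(signal[i]), 0))
    stats::coef(stats::lm(signal[i] ~ conc[i]))
  }
  nb <- fit_lin(lo); ub <- fit_lin(hi)

  s <- (signal - min(signal)) / (max(signal) - min(signal))
  if (s[n] < s[1L]) s <- 1 - s  # orient so s rises with conc

  # candidate 1: derivative peaks
  d <- abs(diff(s) / pmax(diff(conc), 1e-9))
  if (length(d) >= 3L) d <- as.numeric(stats::filter(d, rep(1 / 3, 3), sides = 2))
  d[is.na(d)] <- 0
  mid <- (conc[-1] + conc[-n]) / 2
  o <- order(d, decreasing = TRUE)
  cm_a <- mid[o[1L]]
  sep <- which(abs(mid[o] - cm_a) > diff(range(conc)) / 6)
  cand <- list()
  if (length(sep)) cand <- c(cand, list(sort(c(cm_a, mid[o[sep[1L]]]))))

  # candidate 2: crossings of the oriented normalised curve at 0.3 / 0.7
  crossing <- function(level) {
    i <- which(s >= level)[1L]
    if (is.na(i) || i == 1L) return(conc[1L])
    stats::approx(s[(i - 1L):i], conc[(i - 1L):i], xout = level,
                  ties = "ordered")$y
  }
  cand <- c(cand, list(sort(c(crossing(0.3), crossing(0.7)))))
  # candidate 3: spread quartiles of the whole range
  q <- stats::quantile(range(conc), c(0.35, 0.65))
  cand <- c(cand, list(c(q[[1L]], q[[2L]])))
  cand <- unique(lapply(cand, function(x) {
    if (diff(x) < 1e-6) x[2L] <- x[2L] + max(0.2, diff(range(conc)) / 20)
    round(x, 4)
  }))

  a2 <- mean(c(nb[[1L]], ub[[1L]]))
  list(a0 = nb[[1L]], a1 = nb[[2L]], a2 = a2, a3 = 0,
       a4 = ub[[1L]], a5 = ub[[2L]], cm_candidates = cand)
}

#' Fit the three-state unfolding model
#'
#' Least-squares fit of [three_state_signal()] to one or more denaturation
#' curves.  With several curves the thermodynamic parameters (`m1`, `Cm1`,
#' `m2`, `Cm2`) are always shared globally; baselines may be shared or
#' per-curve.  Starting values are derived automatically (baselines from the
#' terminal 15% of points, midpoints from the smoothed numerical derivative)
#' with a multi-start over m-values of 10--20 kJ mol^-1 M^-1.
#'
#' @param curves A [denaturation_curve()] or list of them (e.g. unfolding and
#'   refolding limbs fitted globally).
#' @param share_baselines Share the six baseline coefficients across curves
#'   (default) or fit them per curve.
#' @param temperature Kelvin; default 298.15.
#' @param n_boot Optional number of Monte-Carlo residual-resampling rounds for
#'   uncertainty estimation (0 = covariance-based only).
#' @param seed Seed for the Monte-Carlo rounds.
#' @return A `three_state_fit` with elements `pars` (named vector), `sd`,
#'   `cov` (thermodynamic + baseline covariance), `temperature`, `converged`,
#'   `flags` (e.g. midpoint ordering violations), `rss`, `n`, and the fitted
#'   `nls` object.
#' @export
fit_three_state <- function(curves, share_baselines = TRUE,
                            temperature = 298.15, n_boot = 0, seed = NULL) {
  if (inherits(curves, "denaturation_curve")) curves <- list(curves)
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, TRUE, "denaturation_curve")))
  df <- do.call(rbind, lapply(seq_along(curves), function(i)
    data.frame(conc = curves[[i]]$conc, signal = curves[[i]]$signal, grp = i)))
  n_grp <- length(curves)
  n_base_grp <- if (share_baselines) 1L else n_grp
  base_of <- if (share_baselines) rep(1L, n_grp) else seq_len(n_grp)

  if (nrow(df) < 12L)
    stop("at least 12 points spanning both transitions are required", call. = FALSE)
  n_par <- 6L * n_base_grp + 4L
  if (nrow(df) <= n_par)
    stop("fewer data points than free parameters", call. = FALSE)

  # fit on a unit-scaled signal for conditioning; baselines are mapped back
  s_min <- min(df$signal); s_rng <- max(df$signal) - s_min
  if (s_rng == 0) stop("constant signal cannot be fitted", call. = FALSE)
  df$scaled <- (df$signal - s_min) / s_rng

  st <- .ts_start(df$conc, df$scaled)
  pred <- function(conc, grp, ab, m1, Cm1, m2, Cm2) {
    # ab: 6 baseline coefficients per baseline group, column-stacked
    out <- numeric(length(conc))
    for (g in seq_len(n_grp)) {
      i <- grp == g
      if (!any(i)) next
      a <- ab[(base_of[g] - 1L) * 6L + 1:6]
      out[i] <- three_state_signal(
        c(a0 = a[1], a1 = a[2], a2 = a[3], a3 = a[4], a4 = a[5], a5 = a[6],
          m1 = m1, Cm1 = Cm1, m2 = m2, Cm2 = Cm2), conc[i], temperature)
    }
    out
  }

  ab0 <- rep(c(st$a0, st$a1, st$a2, st$a3, st$a4, st$a5), n_base_grp)
  span <- diff(range(df$conc))
  best <- NULL
  stale <- 0L
  target_rss <- 1e-18 * (1 + sum(df$scaled^2)) * nrow(df)
  for (cm in st$cm_candidates) {
    for (m0 in c(15, 10, 20)) {
      start <- list(ab = ab0, m1 = m0, Cm1 = cm[1L], m2 = m0, Cm2 = cm[2L])
      # warnOnly tolerates port's conservative "false convergence" stops on
      # noisy data; candidate quality is judged by RSS below
      fit <- tryCatch(
        suppressWarnings(
          stats::nls(scaled ~ pred(conc, grp, ab, m1, Cm1, m2, Cm2), data = df,
                     start = start, algorithm = "port",
                     lower = c(rep(-Inf, 6L * n_base_grp), 0.1, 0, 0.1, 0),
                     upper = c(rep(Inf, 6L * n_base_grp), 200,
                               max(df$conc) + span, 200, max(df$conc) + span),
                     control = stats::nls.control(maxiter = 2000, tol = 1e-12,
                                                  warnOnly = TRUE))),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::resid(fit)^2)
        if (is.null(best) || rss < best$rss * (1 - 0.01)) {
          best <- list(fit = fit, rss = rss)
          stale <- 0L
        } else stale <- stale + 1L
      }
      if (!is.null(best) && (best$rss < target_rss || stale >= 3L)) break
    }
    if (!is.null(best) && (best$rss < target_rss || stale >= 3L)) break
  }
  if (is.null(best))
    stop("three-state fit did not converge from any start", call. = FALSE)
  fit <- best$fit

  cf <- stats::coef(fit)
  nm <- c(paste0("a", 0:5)[rep(seq_len(6), n_base_grp)], "m1", "Cm1", "m2", "Cm2")
  if (!share_baselines)
    nm[seq_len(6L * n_grp)] <- paste0(rep(paste0("a", 0:5), n_grp), ".",
                                      rep(seq_len(n_grp), each = 6L))
  names(cf) <- nm
  V <- tryCatch(stats::vcov(fit), error = function(e)
    matrix(NA_real_, length(cf), length(cf)))
  dimnames(V) <- list(nm, nm)

  # map baselines back from the unit-scaled signal
  n_base <- 6L * n_base_grp
  is_icept <- grepl("^a[024]", nm)
  scale_vec <- c(rep(s_rng, n_base), rep(1, 4L))
  cf <- cf * scale_vec
  cf[is_icept] <- cf[is_icept] + s_min
  V <- V * tcrossprod(scale_vec)
  sdp <- sqrt(pmax(diag(V), 0))

  flags <- character()
  if (cf[["Cm1"]] >= cf[["Cm2"]])
    flags <- c(flags, "midpoint_order: Cm1 >= Cm2 at the optimum")
  if (any(!is.finite(stats::resid(fit))))
    flags <- c(flags, "non_finite_residuals")

  boot <- NULL
  if (n_boot > 0) {
    boot <- .with_seed(seed, .ts_boot(fit, df, pred, n_base_grp, n_boot, nm))
    boot <- sweep(boot, 2, scale_vec, "*")
    boot[, is_icept] <- boot[, is_icept] + s_min
    sd_mc <- apply(boot, 2, stats::sd)
    sdp <- pmax(sdp, sd_mc, na.rm = TRUE)
  }

  structure(list(pars = cf, sd = sdp, cov = V, temperature = temperature,
                 converged = fit$convInfo$isConv, flags = flags,
                 rss = best$rss * s_rng^2, n = nrow(df), n_curves = n_grp,
                 share_baselines = share_baselines, fit = fit, boot = boot,
                 data = df),
            class = "three_state_fit")
}

.ts_boot <- function(fit, df, pred, n_base_grp, n_boot, nm) {
  r <- stats::resid(fit); yhat <- stats::fitted(fit)
  cf <- stats::coef(fit)
  out <- matrix(NA_real_, n_boot, length(cf), dimnames = list(NULL, nm))
  for (b in seq_len(n_boot)) {
    db <- df; db$scaled <- yhat + sample(r, replace = TRUE)
    fb <- tryCatch(
      stats::nls(scaled ~ pred(conc, grp, ab, m1, Cm1, m2, Cm2), data = db,
                 start = as.list(cf), algorithm = "port",
                 control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
      error = function(e) NULL)
    if (!is.null(fb)) out[b, ] <- stats::coef(fb)
  }
  out[stats::complete.cases(out), , drop = FALSE]
}

#' @export
print.three_state_fit <- function(x, ...) {
  cat("Three-state unfolding fit (", x$n, " points, ", x$n_curves,
      " curve(s))\n", sep = "")
  tab <- data.frame(estimate = x$pars, sd = x$sd)
  print(round(tab, 4))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

.thermo_name <- function(fit, nm) nm  # thermodynamic names are unsuffixed

#' Per-domain conformational stability from a three-state fit
#'
#' Under the linear extrapolation method the free energy of unfolding of each
#' domain is \eqn{\Delta G = m \cdot C_m}.  Transition 1 (lower midpoint) is
#' the N-domain, whose unfolding yields the intermediate with a still-folded
#' C-domain; transition 2 is the C-domain.  Uncertainties are first-order
#' propagated using the m--Cm covariance:
#' \eqn{\sigma^2_{\Delta G} = C_m^2\sigma^2_m + m^2\sigma^2_{C_m} +
#'   2 m C_m \mathrm{cov}(m, C_m)}.
#'
#' @param fit A `three_state_fit`.
#' @param variant Variant label for the result.
#' @return A `stability_result` with `dG_N`, `dG_C` (kJ/mol), their sds and
#'   the variant label.
#' @export
domain_stability <- function(fit, variant = "variant") {
  stopifnot(inherits(fit, "three_state_fit"))
  p <- fit$pars; V <- fit$cov
  dg <- function(m, cm) {
    val <- p[[m]] * p[[cm]]
    v <- p[[cm]]^2 * V[m, m] + p[[m]]^2 * V[cm, cm] +
      2 * p[[m]] * p[[cm]] * V[m, cm]
    c(val, sqrt(max(v, 0)))
  }
  n <- dg("m1", "Cm1"); c_ <- dg("m2", "Cm2")
  structure(list(dG_N = n[1], dG_N_sd = n[2], dG_C = c_[1], dG_C_sd = c_[2],
                 variant = variant, fit = fit),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("%s: dG_N = %.1f +/- %.1f, dG_C = %.1f +/- %.1f kJ/mol\n",
              x$variant, x$dG_N, x$dG_N_sd, x$dG_C, x$dG_C_sd))
  invisible(x)
}

#' Stability difference between two variants
#'
#' \eqn{\Delta\Delta G = \Delta G_{\mathrm{ref}} - \Delta G_{\mathrm{test}}}
#' for the chosen domain (positive = test variant destabilised), with the
#' uncertainty combined in quadrature,
#' \eqn{\sigma_{\Delta\Delta G} = \sqrt{\sigma_{\mathrm{ref}}^2 +
#'   \sigma_{\mathrm{test}}^2}}.
#'
#' @param reference,test `stability_result` objects (or lists carrying
#'   `dG_N`/`dG_C` and sds), e.g. the wild type and a truncation.
#' @param domain `"N"` or `"C"`.
#' @return A `delta_delta_g` list with `ddG`, `ddG_sd`, labels and domain.
#' @export
ddg <- function(reference, test, domain = c("N", "C")) {
  domain <- match.arg(domain)
  g <- function(x) x[[paste0("dG_", domain)]]
  s <- function(x) x[[paste0("dG_", domain, "_sd")]]
  structure(list(ddG = g(reference) - g(test),
                 ddG_sd = sqrt(s(reference)^2 + s(test)^2),
                 reference_variant = reference$variant %||% "reference",
                 test_variant = test$variant %||% "test",
                 domain = domain),
            class = "delta_delta_g")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.delta_delta_g <- function(x, ...) {
  cat(sprintf("ddG_%s(%s - %s) = %.1f +/- %.1f kJ/mol\n", x$domain,
              x$reference_variant, x$test_variant, x$ddG, x$ddG_sd))
  invisible(x)
}

#' Amplitude ratio of the two unfolding transitions
#'
#' Ratio of the signal change across the N-domain transition to that across
#' the C-domain transition, each amplitude evaluated as the difference of the
#' adjacent state baselines at the transition midpoint.  Used as a diagnostic
#' of whether the environment of the fluorophores (hence relative domain
#' compactness) changes across a variant series.
#'
#' @param fit A `three_state_fit` (shared baselines).
#' @return `|a_N(Cm1) - a_I(Cm1)| / |a_I(Cm2) - a_U(Cm2)|`.
#' @export
amplitude_ratio <- function(fit) {
  stopifnot(inherits(fit, "three_state_fit"))
  if (!fit$share_baselines)
    stop("amplitude_ratio requires a shared-baseline fit", call. = FALSE)
  p <- fit$pars
  amp1 <- (p[["a0"]] + p[["a1"]] * p[["Cm1"]]) -
    (p[["a2"]] + p[["a3"]] * p[["Cm1"]])
  amp2 <- (p[["a2"]] + p[["a3"]] * p[["Cm2"]]) -
    (p[["a4"]] + p[["a5"]] * p[["Cm2"]])
  if (amp2 == 0)
    stop("second transition has zero amplitude", call. = FALSE)
  abs(amp1) / abs(amp2)
}
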