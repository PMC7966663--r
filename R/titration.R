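## Weak-ligand (denaturant) binding followed by chemical shift titration.
## Each responsive residue's shift trajectory over 0-1 M GdmCl is fitted to a
## single-site binding isotherm with a linear baseline term.

#' Assemble a titration table from peak lists
#'
#' @param peaklists List of [peak_list()] objects, one per titration point.
#' @param conc Ligand (GdmCl) concentrations in mol/L, one per list.
#' @return Long data frame `residue`, `conc`, `h_ppm`, `n_ppm`.
#' @export
titration_table <- function(peaklists, conc) {
  stopifnot(length(peaklists) == length(conc),
            all(vapply(peaklists, inherits, TRUE, "peak_list")))
  do.call(rbind, lapply(seq_along(conc), function(i)
    data.frame(residue = peaklists[[i]]$residue, conc = conc[i],
               h_ppm = peaklists[[i]]$h_ppm, n_ppm = peaklists[[i]]$n_ppm)))
}

.titr_model <- function(conc, d0, dF, Kd, m) {
  d0 + (conc / (conc + Kd)) * (dF - d0) + m * conc
}

.fit_one_titration <- function(conc, delta, kd_range) {
  span <- delta[length(delta)] - delta[1L]
  if (abs(span) < 1e-12)
    return(list(flag = "degenerate_no_shift"))
  best <- NULL
  for (kd0 in c(0.1, 0.3, 1)) {
    # ignore m for the start; inflate the end shift toward saturation
    start <- list(d0 = delta[1L],
                  dF = delta[1L] + span * (1 + kd0 / max(conc)),
                  Kd = kd0, m = 0)
    fit <- tryCatch(
      stats::nls(delta ~ .titr_model(conc, d0, dF, Kd, m),
                 data = data.frame(conc = conc, delta = delta),
                 start = start, algorithm = "port",
                 lower = c(-Inf, -Inf, 1e-4, -Inf),
                 control = stats::nls.control(maxiter = 500, tol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) return(list(flag = "fit_failed"))
  cf <- stats::coef(best$fit)
  sdp <- tryCatch(sqrt(pmax(diag(stats::vcov(best$fit)), 0)),
                  error = function(e) rep(NA_real_, 4))
  flag <- if (cf[["Kd"]] < kd_range[1] || cf[["Kd"]] > kd_range[2])
    "kd_out_of_range"
  else if (abs(cf[["dF"]] - cf[["d0"]]) < 1e-9) "degenerate_no_shift"
  else "ok"
  list(pars = cf, sd = sdp, flag = flag)
}

#' Fit weak-binding titration trajectories
#'
#' For residues whose total (end-to-end) shift change exceeds the nucleus
#' threshold, fits \deqn{\delta([C]) = \delta_0 +
#'   \frac{[C]}{[C]+K_d}(\delta_F - \delta_0) + m[C]} separately per nucleus,
#' where \eqn{m} is a linear baseline correction.  The summary Kd is the
#' unweighted mean over accepted fits (converged, Kd inside the
#' titration-resolvable range).
#'
#' @param data Long titration table from [titration_table()] (columns
#'   `residue`, `conc`, `h_ppm`, `n_ppm`), covering at least 5 titration
#'   points.
#' @param h_threshold,n_threshold Selection thresholds on the absolute total
#'   1H and 15N shift change (ppm); defaults 0.08 and 0.4.
#' @param kd_range Acceptance window for fitted Kd in mol/L, default
#'   `c(0.01, 10)`.
#' @return A `titration_fit` list: `fits` (per residue/nucleus data frame
#'   with `d0`, `dF`, `Kd`, `m`, sds and `flag`), `mean_kd` (mol/L over
#'   accepted fits), `n_accepted`, `n_selected`.
#' @export
fit_titration <- function(data, h_threshold = 0.08, n_threshold = 0.4,
                          kd_range = c(0.01, 10)) {
  stopifnot(all(c("residue", "conc", "h_ppm", "n_ppm") %in% names(data)))
  if (length(unique(data$conc)) < 5L)
    stop("at least 5 titration points are required", call. = FALSE)
  rows <- list()
  for (res in sort(unique(data$residue))) {
    d <- data[data$residue == res, ]
    d <- d[order(d$conc), ]
    for (nuc in c("1H", "15N")) {
      delta <- if (nuc == "1H") d$h_ppm else d$n_ppm
      thr <- if (nuc == "1H") h_threshold else n_threshold
      if (abs(delta[length(delta)] - delta[1L]) <= thr) next
      f <- .fit_one_titration(d$conc, delta, kd_range)
      p <- if (is.null(f$pars)) c(d0 = NA_real_, dF = NA_real_, Kd = NA_real_,
                                  m = NA_real_) else f$pars
      rows[[length(rows) + 1L]] <- data.frame(
        residue = res, nucleus = nuc,
        d0 = p[["d0"]], dF = p[["dF"]], Kd = p[["Kd"]], m = p[["m"]],
        Kd_sd = if (is.null(f$sd)) NA_real_ else f$sd[[3L]],
        flag = f$flag)
    }
  }
  if (length(rows) == 0L)
    stop("no residues pass the shift-change thresholds", call. = FALSE)
  fits <- do.call(rbind, rows)
  acc <- fits$flag == "ok"
  structure(list(fits = fits,
                 mean_kd = if (any(acc)) mean(fits$Kd[acc]) else NA_real_,
                 n_accepted = sum(acc), n_selected = nrow(fits)),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("Titration fit: %d trajectories selected, %d accepted, mean Kd = %.3g M\n",
              x$n_selected, x$n_accepted, x$mean_kd))
  invisible(x)
}
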