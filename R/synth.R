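## Synthetic-data generators.  Each generator is a deterministic function of
## its parameters and seed, draws from its own substream of the master seed,
## and produces objects that satisfy the input invariants of the consuming
## analysis stage, so every fit is testable by parameter recovery.

## substream ids per data class
.SUBSTREAM <- c(denaturation = 1L, titration = 2L, relaxation = 3L,
                hetnoe = 4L, pre = 5L, sensorgram = 6L, msa = 7L)

#' Generating parameters mirroring the published study conditions
#'
#' The default generating profile: three-state thermodynamics of the wild-type
#' sensor (m1 = 15 kJ/mol/M, Cm1 = 2.8 M so dG_N = 42 kJ/mol; m2 = 14,
#' Cm2 = 3.0 M for the C-domain at ~42 kJ/mol), fluorescence baselines on the
#' average-emission-wavelength scale, the weak GdmCl-binding Kd of 0.38 M,
#' hetNOE region means of 0.72 (residues 176-185) and 0.37 (186-190),
#' a typical folded-protein R2 of 20 s^-1, and the full-length kinetic and
#' steady-state constants (kon = 2.0e5 M^-1 s^-1, koff = 4.3e-3 s^-1,
#' Rmax = 18.2 RU; equilibrium KD = 130 nM).
#'
#' @return Nested list of generating parameters per data class.
#' @export
published_profile <- function() {
  list(
    denaturation = list(
      pars = c(a0 = 335, a1 = 0.8, a2 = 347, a3 = 0, a4 = 353, a5 = 0.2,
               m1 = 15, Cm1 = 2.8, m2 = 14, Cm2 = 3.0),
      conc = seq(0, 6, by = 0.25), noise_sd = 0),
    titration = list(kd = 0.38, conc = seq(0, 1, by = 0.1), n_residues = 10,
                     noise_sd = 0),
    relaxation = list(r2 = 20, delays = r2_delay_set(), noise_sd = 0),
    hetnoe = list(region_means = c("176-185" = 0.72, "186-190" = 0.37),
                  noise_sd = 0),
    kinetics = list(kon = 2.0e5, koff = 4.3e-3, Rmax = 18.2),
    steady_state = list(KD = 130e-9, Rmax = 18.2,
                        conc = twofold_dilutions(10e-9, 9)),
    msa = list(n = 1000, tail_fraction = 0.10)
  )
}

#' Simulate a denaturation curve (optionally as raw emission spectra)
#'
#' Forward-simulates [three_state_signal()] plus Gaussian noise.  In spectra
#' mode each point is emitted as a Gaussian fluorescence band over the
#' 300-400 nm grid whose centroid equals the target average emission
#' wavelength, so the spectral reduction step is exercised end to end.
#'
#' @param pars Three-state parameters (see [three_state_signal()]); defaults
#'   to the wild-type published profile.
#' @param conc Denaturant grid in mol/L.
#' @param noise_sd Gaussian noise sd in signal units (nm), default 0.
#' @param seed Master seed (substreamed per data class).
#' @param label Variant label.
#' @param spectra If `TRUE`, also return the raw emission spectra.
#' @param band_sd Gaussian band width in nm for spectra mode, default 8.
#' @return A [denaturation_curve()]; in spectra mode a list
#'   `(curve, spectra)` where `spectra` is a list of
#'   `(wavelengths, intensities, denaturant_conc)`.
#' @export
gen_denaturation <- function(pars = published_profile()$denaturation$pars,
                             conc = seq(0, 6, by = 0.25), noise_sd = 0,
                             seed = NULL, label = "synthetic",
                             spectra = FALSE, band_sd = 8) {
  sub <- if (is.null(seed)) NULL else .substream(seed, .SUBSTREAM[["denaturation"]])
  signal <- three_state_signal(pars, conc)
  if (noise_sd > 0)
    signal <- .with_seed(sub, signal + stats::rnorm(length(conc), 0, noise_sd))
  curve <- denaturation_curve(conc, signal, label = label)
  if (!spectra) return(curve)
  wl <- seq(300, 400, by = 0.5)
  sp <- lapply(seq_along(conc), function(i) {
    list(wavelengths = wl,
         intensities = stats::dnorm(wl, mean = signal[i], sd = band_sd),
         denaturant_conc = conc[i])
  })
  list(curve = curve, spectra = sp)
}

#' Simulate weak-binding titration peak lists
#'
#' Per-residue 1H/15N shift trajectories over the denaturant titration,
#' following the single-site binding isotherm with a linear baseline.
#' Below-threshold residues (tiny end-to-end shifts) are included to
#' exercise the selection step of [fit_titration()].
#'
#' @param kd Generating dissociation constant in mol/L, default 0.38.
#' @param conc Titration concentrations, default 0-1 M in 0.1 M steps.
#' @param n_residues Number of responsive residues, default 10.
#' @param n_below Number of below-threshold residues, default 3.
#' @param noise_sd Gaussian shift noise in ppm, default 0.
#' @param seed Master seed.
#' @return List: `peaklists` (one [peak_list()] per concentration), `conc`,
#'   `truth` (generating per-residue parameters).
#' @export
gen_titration <- function(kd = 0.38, conc = seq(0, 1, by = 0.1),
                          n_residues = 10, n_below = 3, noise_sd = 0,
                          seed = NULL) {
  sub <- if (is.null(seed)) NULL else .substream(seed, .SUBSTREAM[["titration"]])
  .with_seed(sub, {
    n_tot <- n_residues + n_below
    res <- seq_len(n_tot)
    d0_h <- stats::runif(n_tot, 7.5, 9.5)
    d0_n <- stats::runif(n_tot, 110, 125)
    # responsive residues: end-to-end 1H span clearly above 0.08 ppm
    span_h <- c(stats::runif(n_residues, 0.15, 0.45) *
                  sample(c(-1, 1), n_residues, TRUE),
                stats::runif(n_below, 0.005, 0.02))
    span_n <- c(stats::runif(n_residues, 0.8, 2.5) *
                  sample(c(-1, 1), n_residues, TRUE),
                stats::runif(n_below, 0.01, 0.05))
    m_h <- stats::runif(n_tot, -0.01, 0.01)
    m_n <- stats::runif(n_tot, -0.05, 0.05)
    cmax <- max(conc)
    sat <- cmax / (cmax + kd)  # end-to-end span -> dF - d0 scaling
    truth <- data.frame(residue = res, d0_h = d0_h, d0_n = d0_n,
                        dF_h = d0_h + span_h / sat, dF_n = d0_n + span_n / sat,
                        m_h = m_h, m_n = m_n, kd = kd,
                        responsive = res <= n_residues)
    peaklists <- lapply(conc, function(cc) {
      h <- .titr_model(cc, truth$d0_h, truth$dF_h, kd, truth$m_h)
      n <- .titr_model(cc, truth$d0_n, truth$dF_n, kd, truth$m_n)
      if (noise_sd > 0) {
        h <- h + stats::rnorm(n_tot, 0, noise_sd)
        n <- n + stats::rnorm(n_tot, 0, noise_sd)
      }
      peak_list(res, h, n, intensity = 1,
                state = sprintf("%.2f M GdmCl", cc))
    })
    list(peaklists = peaklists, conc = conc, truth = truth)
  })
}

#' Simulate relaxation decay series
#'
#' Single-exponential decays at the standard delay set (with replicate
#' delays) plus Gaussian intensity noise.
#'
#' @param r2 Generating R2 rates in s^-1 (recycled over residues).
#' @param n_residues Number of residues, default `length(r2)`.
#' @param delays Delay set in seconds, default [r2_delay_set()].
#' @param i0 Initial intensities, default 100.
#' @param noise_sd Gaussian intensity noise (same units as `i0`), default 0.
#' @param seed Master seed.
#' @return A [relaxation_series()] with attribute `truth` (generating R2 per
#'   residue).
#' @export
gen_relaxation <- function(r2 = 20, n_residues = length(r2),
                           delays = r2_delay_set(), i0 = 100, noise_sd = 0,
                           seed = NULL) {
  sub <- if (is.null(seed)) NULL else .substream(seed, .SUBSTREAM[["relaxation"]])
  r2 <- rep_len(r2, n_residues)
  i0 <- rep_len(i0, n_residues)
  mat <- outer(seq_len(n_residues), seq_along(delays),
               function(r, d) i0[r] * exp(-r2[r] * delays[d]))
  if (noise_sd > 0)
    mat <- .with_seed(sub, mat + matrix(stats::rnorm(length(mat), 0, noise_sd),
                                        nrow(mat)))
  out <- relaxation_series(delays, mat)
  attr(out, "truth") <- r2
  out
}

#' Simulate heteronuclear NOE peak-list pairs
#'
#' Saturated/reference peak-list pair whose per-residue NOE values are the
#' configured region means plus noise: rigid core near 0.85, a tail-proximal
#' segment near 0.72 and a disordered distal tail near 0.37 by default.
#'
#' @param regions Named list of residue ranges.
#' @param region_means Generating mean NOE per region.
#' @param core Residue range and NOE level for the remaining (folded) core.
#' @param noise_sd Gaussian sd on the per-residue NOE, default 0.
#' @param seed Master seed.
#' @return List `sat`, `ref` ([peak_list()]s), `truth` (per-residue NOE).
#' @export
gen_hetnoe <- function(regions = list("176-185" = 176:185,
                                      "186-190" = 186:190),
                       region_means = c(0.72, 0.37),
                       core = list(residues = 2:175, noe = 0.85),
                       noise_sd = 0, seed = NULL) {
  sub <- if (is.null(seed)) NULL else .substream(seed, .SUBSTREAM[["hetnoe"]])
  res <- c(core$residues, unlist(regions))
  noe <- c(rep(core$noe, length(core$residues)),
           rep(region_means, lengths(regions)))
  if (noise_sd > 0)
    noe <- .with_seed(sub, noe + stats::rnorm(length(noe), 0, noise_sd))
  iref <- rep(100, length(res))
  list(sat = peak_list(res, 8.2, 118, iref * noe, state = "saturated"),
       ref = peak_list(res, 8.2, 118, iref, state = "reference"),
       truth = stats::setNames(noe, res))
}

#' Simulate a PRE peak-list pair
#'
#' Paramagnetic/diamagnetic pair with a smooth distance-like attenuation
#' profile centred on the spin-label site (ratio -> 0 near the label,
#' -> 1 far away), optional fully-bleached residues (absent from the
#' paramagnetic list) and Gaussian intensity noise.
#'
#' @param residues Residue numbers.
#' @param label_site Residue carrying the spin label, default 188.
#' @param width Attenuation length scale in residues, default 15.
#' @param bleached Residues removed from the paramagnetic list.
#' @param noise_sd Gaussian intensity noise (dia intensity = 100).
#' @param seed Master seed.
#' @return List `para`, `dia` ([peak_list()]s), `truth` (generating ratios).
#' @export
gen_pre <- function(residues = 2:190, label_site = 188, width = 15,
                    bleached = integer(), noise_sd = 0, seed = NULL) {
  sub <- if (is.null(seed)) NULL else .substream(seed, .SUBSTREAM[["pre"]])
  ratio <- 1 - exp(-abs(residues - label_site) / width)
  idia <- rep(100, length(residues))
  ipara <- idia * ratio
  if (noise_sd > 0) {
    noisy <- .with_seed(sub, list(
      ipara + stats::rnorm(length(ipara), 0, noise_sd),
      idia + stats::rnorm(length(idia), 0, noise_sd)))
    ipara <- pmax(noisy[[1L]], 0); idia <- pmax(noisy[[2L]], 1e-6)
  }
  keep <- !(residues %in% bleached)
  list(para = peak_list(residues[keep], 8.2, 118, ipara[keep],
                        state = "paramagnetic"),
       dia = peak_list(residues, 8.2, 118, idia, state = "diamagnetic"),
       truth = stats::setNames(ratio, residues))
}

#' Simulate an active/reference/blank sensorgram quadruple
#'
#' Wraps [simulate_sensorgram()] and adds a reference channel and the two
#' buffer blanks sharing the same bulk refractive-index offset and drift, so
#' [double_blank_reference()] cancels them exactly at zero noise.
#'
#' @inheritParams simulate_sensorgram
#' @param bulk_offset Bulk jump in RU added to active and reference channels
#'   during injections, default 5.
#' @return List of [sensorgram()]s: `active`, `reference`, `blank_active`,
#'   `blank_reference`, plus `truth`.
#' @export
gen_sensorgram <- function(kon = 2.0e5, koff = 4.3e-3, Rmax = 18.2,
                           injections = data.frame(
                             conc = twofold_dilutions(),
                             t_assoc = 600, t_dissoc = 1000),
                           protocol = "multi", dt = 1, noise_sd = 0,
                           drift = 0, bulk_offset = 5, seed = NULL) {
  sub <- if (is.null(seed)) NULL else .substream(seed, .SUBSTREAM[["sensorgram"]])
  seeds <- if (is.null(sub)) rep(list(NULL), 4L) else as.list(sub + 0:3)
  active <- simulate_sensorgram(kon, koff, Rmax, injections, protocol, dt,
                                noise_sd, drift, seed = seeds[[1L]])
  flat <- function(seed, channel) {
    g <- simulate_sensorgram(kon, koff, Rmax, injections, protocol, dt,
                             noise_sd = 0, drift = drift, seed = NULL,
                             channel = channel)
    g$response <- 0 * g$response + drift * g$time
    if (noise_sd > 0)
      g$response <- .with_seed(seed,
        g$response + stats::rnorm(nrow(g), 0, noise_sd))
    g
  }
  reference <- flat(seeds[[2L]], "reference")
  blank_active <- flat(seeds[[3L]], "blank")
  blank_reference <- flat(seeds[[4L]], "blank")
  # shared bulk jump during injections on the sample-facing channels
  bulk <- ifelse(active$phase == "association", bulk_offset, 0)
  active$response <- active$response + bulk
  reference$response <- reference$response + bulk
  list(active = active, reference = reference, blank_active = blank_active,
       blank_reference = blank_reference,
       truth = c(kon = kon, koff = koff, Rmax = Rmax))
}

## fixed 190-residue dummy reference; tail region 176-190 carries the
## anchor motif L183-S184-L185
.REF_SEQ <- local({
  core <- substr(strrep("ACDEFGHIKLMNPQRSTVWY", 9L), 1L, 175L)
  paste0(core, "APEIVQALSLYDGLV")  # 176-190, anchors L183-S184-L185
})

#' Simulate a reference-anchored MSA with a controllable tailed fraction
#'
#' Builds an alignment of width 190 (identity column map) around a fixed
#' reference.  Tailed rows carry residues across 176-190 with anchor columns
#' 183-185 sampled from configurable residue-class probabilities (defaults
#' echoing the family census: aliphatic at 183 in ~56% of tailed homologs,
#' aromatic in ~42%; \[AVILM\] at 185 in ~30%, aromatic in ~8%); untailed
#' rows are gapped across 183-190.  Optionally a tail-linked conserved
#' column (Lys at position 100 in tailed rows, random elsewhere) supports
#' tail-specific-conservation tests.
#'
#' @param n Number of homolog rows (reference row added on top).
#' @param tail_fraction Expected fraction of tailed rows, default 0.10.
#' @param p183 Class probabilities at position 183:
#'   `c(aliphatic, aromatic, other)`.
#' @param p184 Residue probabilities at 184: `c(S, T, other)`.
#' @param p185 Class probabilities at 185: `c(avilm, aromatic, other)`.
#' @param conserved_position Reference position fixed to Lys in tailed rows
#'   (NULL to disable), default 100.
#' @param core_conservation Probability that a core column copies the
#'   reference residue (the rest is uniform), default 0.7.
#' @param seed Master seed.
#' @return An [anchored_msa()] with attribute `truth` (logical tailed flag
#'   per generated row).
#' @export
gen_msa <- function(n = 1000, tail_fraction = 0.10,
                    p183 = c(aliphatic = 0.56, aromatic = 0.42, other = 0.02),
                    p184 = c(S = 0.35, T = 0.20, other = 0.45),
                    p185 = c(avilm = 0.30, aromatic = 0.08, other = 0.62),
                    conserved_position = 100, core_conservation = 0.7,
                    seed = NULL) {
  stopifnot(tail_fraction >= 0, tail_fraction <= 1)
  sub <- if (is.null(seed)) NULL else .substream(seed, .SUBSTREAM[["msa"]])
  aliph <- c("I", "L", "V", "M"); arom <- c("F", "W", "Y")
  avilm <- c("A", "V", "I", "L", "M")
  other20 <- .AA20
  ref <- strsplit(.REF_SEQ, "")[[1L]]
  .with_seed(sub, {
    tailed <- stats::runif(n) < tail_fraction
    draw_class <- function(k, p, classes) {
      cls <- sample(names(p), k, replace = TRUE, prob = p)
      vapply(cls, function(cl) sample(classes[[cl]], 1L), character(1))
    }
    rows <- matrix("-", nrow = n, ncol = 190L)
    for (j in 1:175)
      rows[, j] <- ifelse(stats::runif(n) < core_conservation, ref[j],
                          sample(other20, n, replace = TRUE))
    nt <- sum(tailed)
    if (nt > 0) {
      for (j in c(176:182, 186:190))
        rows[tailed, j] <- ifelse(stats::runif(nt) < core_conservation,
                                  ref[j], sample(other20, nt, replace = TRUE))
      rows[tailed, 183] <- draw_class(nt, p183, list(
        aliphatic = aliph, aromatic = arom,
        other = setdiff(other20, c(aliph, arom))))
      rows[tailed, 184] <- draw_class(nt, p184, list(
        S = "S", T = "T", other = setdiff(other20, c("S", "T"))))
      rows[tailed, 185] <- draw_class(nt, p185, list(
        avilm = avilm, aromatic = arom,
        other = setdiff(other20, c(avilm, arom))))
    }
    if (!is.null(conserved_position)) {
      rows[tailed, conserved_position] <- "K"
      rows[!tailed, conserved_position] <- sample(other20, n - nt,
                                                  replace = TRUE)
    }
    seqs <- c(stats::setNames(.REF_SEQ, "REF"),
              stats::setNames(apply(rows, 1, paste, collapse = ""),
                              sprintf("hom%04d", seq_len(n))))
    msa <- anchored_msa(seqs, reference_id = "REF")
    attr(msa, "truth") <- stats::setNames(tailed, names(seqs)[-1L])
    msa
  })
}
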