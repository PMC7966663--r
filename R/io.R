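## Plain-text readers and writers for the pipeline's tabular formats.

.read_table_auto <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a denaturation curve from a delimited file
#'
#' Narrow format: columns `conc_M` and `signal`.  Wide spectra format:
#' `conc_M` followed by one numeric column per emission wavelength in nm;
#' each spectrum is reduced with [average_emission_wavelength()].
#'
#' @param path CSV/TSV path.
#' @param label Variant label; defaults to the file stem.
#' @return A [denaturation_curve()].
#' @export
read_denaturation_curve <- function(path, label = NULL) {
  df <- .read_table_auto(path)
  if (is.null(label)) label <- tools::file_path_sans_ext(basename(path))
  if (!"conc_M" %in% names(df))
    stop("expected a 'conc_M' column in ", path, call. = FALSE)
  if ("signal" %in% names(df))
    return(denaturation_curve(df$conc_M, df$signal, label = label))
  wl <- suppressWarnings(as.numeric(setdiff(names(df), "conc_M")))
  if (any(is.na(wl)))
    stop("wide format requires numeric wavelength column names", call. = FALSE)
  sig <- apply(as.matrix(df[setdiff(names(df), "conc_M")]), 1, function(f)
    average_emission_wavelength(wl, as.numeric(f)))
  denaturation_curve(df$conc_M, sig, label = label)
}

#' Read an amide peak list from CSV
#'
#' Columns: `residue`, `h_ppm`, `n_ppm`, optional `intensity`, `assignment`.
#'
#' @param path CSV/TSV path.
#' @param state Optional state label.
#' @return A [peak_list()].
#' @export
read_peak_list <- function(path, state = NULL) {
  df <- .read_table_auto(path)
  peak_list(df$residue, df$h_ppm, df$n_ppm,
            intensity = if ("intensity" %in% names(df)) df$intensity else NA_real_,
            assignment = if ("assignment" %in% names(df)) df$assignment else NULL,
            state = state)
}

#' Read a relaxation series from wide CSV
#'
#' Columns: `residue` plus one intensity column per delay named
#' `tau_ms_<value>` with an optional `_rep<k>` suffix for replicates.
#'
#' @param path CSV/TSV path.
#' @return A [relaxation_series()].
#' @export
read_relaxation_csv <- function(path) {
  df <- .read_table_auto(path)
  tau_cols <- grep("^tau_ms_", names(df), value = TRUE)
  if (length(tau_cols) == 0L)
    stop("no 'tau_ms_*' columns found in ", path, call. = FALSE)
  delays <- as.numeric(sub("^tau_ms_([0-9.]+).*$", "\\1", tau_cols)) / 1000
  relaxation_series(delays, as.matrix(df[tau_cols]), residues = df$residue)
}

#' Read a sensorgram from long-format CSV
#'
#' Columns: `cycle`, `channel`, `phase`, `time_s`, `conc_M`, `response_RU`.
#'
#' @param path CSV/TSV path.
#' @param channel Restrict to one channel role (default: all).
#' @return A [sensorgram()] (or named list of them when several channels are
#'   present and `channel` is NULL).
#' @export
read_sensorgram_csv <- function(path, channel = NULL) {
  df <- .read_table_auto(path)
  need <- c("cycle", "channel", "phase", "time_s", "conc_M", "response_RU")
  if (!all(need %in% names(df)))
    stop("expected columns ", paste(need, collapse = ", "), call. = FALSE)
  build <- function(d) sensorgram(d$time_s, d$response_RU, d$conc_M, d$phase,
                                  d$cycle, d$channel[1L])
  if (!is.null(channel)) return(build(df[df$channel == channel, ]))
  chans <- unique(df$channel)
  if (length(chans) == 1L) return(build(df))
  stats::setNames(lapply(chans, function(ch) build(df[df$channel == ch, ])),
                  chans)
}

#' Write a sensorgram to long-format CSV
#'
#' @param gram A [sensorgram()] (or list of them).
#' @param path Output CSV path.
#' @export
write_sensorgram_csv <- function(gram, path) {
  if (inherits(gram, "sensorgram")) gram <- list(gram)
  df <- do.call(rbind, lapply(gram, function(g)
    data.frame(cycle = g$cycle, channel = g$channel, phase = g$phase,
               time_s = g$time, conc_M = g$conc, response_RU = g$response)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Published stability table of the truncation series
#'
#' Per-variant free energies of unfolding (with one-sigma uncertainties) of
#' the N- and C-domains of the calcium-sensor truncation series, as printed
#' in the study this package operationalises.  Used as the input for the
#' stability-difference bookkeeping.
#'
#' @return Data frame with columns `variant`, `terminal_residue`, `charge`,
#'   `dG_N`, `dG_N_sd`, `dG_C`, `dG_C_sd` (kJ/mol).
#' @export
published_stability_table <- function() {
  path <- system.file("extdata", "ncs1_truncation_stability.tsv",
                      package = "tailfold", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
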