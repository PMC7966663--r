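# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: brute-force enumeration, numerical integration
# and per-row scans.

# fixed-step RK4 integration of dR/dt = kon*c*(Rmax - R) - koff*R
rk4_langmuir <- function(kon, koff, Rmax, conc, times, R0 = 0, h = 0.01) {
  f <- function(R, cc) kon * cc * (Rmax - R) - koff * R
  out <- numeric(length(times))
  R <- R0
  t <- times[1L]
  out[1L] <- R0
  for (i in seq_along(times)[-1L]) {
    while (t < times[i] - 1e-12) {
      step <- min(h, times[i] - t)
      k1 <- f(R, conc)
      k2 <- f(R + step / 2 * k1, conc)
      k3 <- f(R + step / 2 * k2, conc)
      k4 <- f(R + step * k3, conc)
      R <- R + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + step
    }
    out[i] <- R
  }
  out
}

# brute-force greedy one-to-one matcher under the combined shift metric
greedy_match_oracle <- function(assigned, unassigned, n_weight = 0.154) {
  pairs <- expand.grid(i = seq_len(nrow(assigned)),
                       j = seq_len(nrow(unassigned)))
  pairs$d <- sqrt((assigned$h_ppm[pairs$i] - unassigned$h_ppm[pairs$j])^2 +
                    n_weight^2 *
                      (assigned$n_ppm[pairs$i] - unassigned$n_ppm[pairs$j])^2)
  pairs <- pairs[order(pairs$d), ]
  used_i <- used_j <- integer()
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    if (pairs$i[k] %in% used_i || pairs$j[k] %in% used_j) next
    keep[k] <- TRUE
    used_i <- c(used_i, pairs$i[k]); used_j <- c(used_j, pairs$j[k])
  }
  pairs[keep, ]
}

# per-row regexp scan of the anchor motif classes over tailed homolog rows
# (the anchoring reference row is not part of the census)
census_oracle <- function(msa) {
  cols <- msa$column_map[as.character(183:185)]
  seqs <- msa$sequences[setdiff(msa$ids, msa$reference_id)]
  rows <- vapply(seqs, function(s)
    paste(substring(s, cols, cols), collapse = ""), character(1))
  tailed <- !grepl("-", rows)
  tr <- rows[tailed]
  c(aliphatic_183 = sum(grepl("^[ILVM]", tr)),
    aromatic_183 = sum(grepl("^[FWY]", tr)),
    ser_184 = sum(grepl("^.S", tr)),
    thr_184 = sum(grepl("^.T", tr)),
    aliphatic_185 = sum(grepl("^..[AVILM]", tr)),
    aromatic_185 = sum(grepl("^..[FWY]", tr)),
    lsl_complete = sum(tr == "LSL"),
    total_tailed = length(tr))
}

# random valid three-state parameter set on the fluorescence scale
random_ts_pars <- function() {
  cm1 <- runif(1, 1.5, 3)
  c(a0 = runif(1, 330, 340), a1 = runif(1, -0.5, 1),
    a2 = runif(1, 342, 350), a3 = runif(1, -0.3, 0.3),
    a4 = runif(1, 352, 356), a5 = runif(1, -0.3, 0.3),
    m1 = runif(1, 10, 20), Cm1 = cm1,
    m2 = runif(1, 10, 20), Cm2 = cm1 + runif(1, 0.8, 2.5))
}

# relative error helper tolerant of near-zero truth
rel_err <- function(est, truth) {
  abs(est - truth) / pmax(abs(truth), 1e-8)
}
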