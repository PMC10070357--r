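## brute-force oracle for the species-filtered correlator: identical
## estimator definition (multi-tau grid, per-cascade rebinned signals,
## burst-window masking), but every lag is evaluated independently by
## explicit rebinning from the photon times and direct product sums.
oracle_filtered_correlation <- function(ps, filters, bt, pair = c("lf", "hf"),
                                        window_s = 10e-3, bin_s = 2e-6,
                                        n_casc = 6, m = 8, n_bins = 32) {
  j <- stacked_channel(ps, n_bins)
  fw1 <- filters[[paste0("f_", pair[1])]]
  fw2 <- filters[[paste0("f_", pair[2])]]
  w1 <- ifelse(is.na(j), 0, fw1[ifelse(is.na(j), 1, j)])
  w2 <- ifelse(is.na(j), 0, fw2[ifelse(is.na(j), 1, j)])
  ts <- macrotime_s(ps)
  iv <- cbind(pmax(bt$t_start_s - window_s, 0),
              pmin(bt$t_end_s + window_s, ps$duration_s))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  merged <- list(); cur <- iv[1, ]
  if (nrow(iv) > 1) for (r in 2:nrow(iv)) {
    if (iv[r, 1] <= cur[2]) cur[2] <- max(cur[2], iv[r, 2])
    else { merged[[length(merged) + 1]] <- cur; cur <- iv[r, ] }
  }
  merged[[length(merged) + 1]] <- cur
  ## lag grid identical by construction
  lag_bins <- as.list(1:m); casc <- rep(0, m)
  for (c in seq_len(n_casc - 1)) {
    lag_bins <- c(lag_bins, as.list((m / 2 + 1):m * 2^c))
    casc <- c(casc, rep(c, m / 2))
  }
  lag_bins <- unlist(lag_bins)
  nlag <- length(lag_bins)
  Sab <- Sa <- Sb <- Np <- numeric(nlag)
  for (seg in merged) {
    L0 <- max(2, ceiling((seg[2] - seg[1]) / bin_s))
    sel <- which(ts >= seg[1] & ts < seg[2] & (w1 != 0 | w2 != 0))
    bin0 <- pmin(floor((ts[sel] - seg[1]) / bin_s), L0 - 1) + 1
    for (k in seq_len(nlag)) {
      cc <- casc[k]
      ## trimmed length after cc halvings, then direct rebin from scratch
      L <- L0
      for (h in seq_len(cc)) L <- L %/% 2
      if (L < 2) next
      fac <- 2^cc
      a <- numeric(L); b <- numeric(L)
      for (i in seq_along(sel)) {
        bb <- (bin0[i] - 1) %/% fac + 1
        if (bb <= L) {
          a[bb] <- a[bb] + w1[sel[i]]
          b[bb] <- b[bb] + w2[sel[i]]
        }
      }
      lag <- lag_bins[k] / fac
      if (L - lag < 2) next
      for (t1 in 1:(L - lag)) {
        Sab[k] <- Sab[k] + a[t1] * b[t1 + lag]
        Sa[k] <- Sa[k] + a[t1]
        Sb[k] <- Sb[k] + b[t1 + lag]
        Np[k] <- Np[k] + 1
      }
    }
  }
  G <- rep(NA_real_, nlag)
  ok <- Np > 0 & Sa != 0 & Sb != 0
  G[ok] <- Sab[ok] * Np[ok] / (Sa[ok] * Sb[ok]) - 1
  data.frame(lag_s = lag_bins * bin_s, G = G)
}
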