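#' Proximity ratio to corrected FRET efficiency
#'
#' Converts a mean proximity ratio to the corrected FRET efficiency using
#' the crosstalk, direct-excitation and detection factors:
#' \deqn{E = \frac{1 - (1 + ct + \gamma\beta\, de)(1 - PR)}
#'                {1 - (1 + ct - \gamma)(1 - PR)}}
#'
#' @param PR proximity ratio(s).
#' @param corrections a [correction_set()].
#' @return corrected FRET efficiency values.
#' @export
pr_to_efficiency <- function(PR, corrections) {
  cr <- corrections
  (1 - (1 + cr$ct + cr$gamma * cr$beta * cr$de) * (1 - PR)) /
    (1 - (1 + cr$ct - cr$gamma) * (1 - PR))
}

#' Burst variance analysis
#'
#' Splits each burst's donor-excitation photon sequence into consecutive
#' non-overlapping windows of `n` photons, computes the window proximity
#' ratios `eps_ij = N_acc/n`, the burst proximity ratio `PR_i` and the
#' per-burst standard deviation
#' \deqn{s_i = \sqrt{ \frac{1}{M_i} \sum_j (\epsilon_{ij} - PR_i)^2 }}
#' Bursts are then grouped into `n_groups` equal PR intervals (groups with
#' more than `min_bursts` bursts are analysed); per group the pooled standard
#' deviation of the window values is compared with the binomial shot-noise
#' expectation \eqn{s = \sqrt{PR(1-PR)/n}} and a confidence interval built
#' from simulated static bursts with matched window counts. Group mean PRs
#' are converted to corrected E via [pr_to_efficiency()].
#'
#' @param photon_data per-burst photon data from [burst_photon_data()].
#' @param n photons per window.
#' @param n_groups number of PR intervals on `[0, 1]`.
#' @param min_bursts a group is analysed when it holds more than this many
#'   bursts.
#' @param corrections a [correction_set()] for the PR-to-E conversion.
#' @param repetitions static-burst simulation replicates for the CI.
#' @param alpha significance level (Bonferroni over groups).
#' @param seed integer seed.
#' @return list with `bursts` (data.frame `PR`, `s`, `M`) and `groups`
#'   (data.frame `PR_lo`, `PR_hi`, `n_bursts`, `PR_mean`, `E`, `s_obs`,
#'   `s_static`, `ci_lo`, `ci_hi`, `flagged`).
#' @export
bva <- function(photon_data, n = 5, n_groups = 20, min_bursts = 100,
                corrections = correction_set(), repetitions = 1000,
                alpha = 0.001, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nb <- length(photon_data)
  PR <- rep(NA_real_, nb); s_i <- rep(NA_real_, nb); M <- integer(nb)
  eps_list <- vector("list", nb)
  for (b in seq_len(nb)) {
    acc <- photon_data[[b]]$acc
    N <- length(acc)
    if (N < n) next
    Mi <- N %/% n
    eps <- colMeans(matrix(acc[seq_len(Mi * n)], nrow = n))
    PR[b] <- mean(acc)
    s_i[b] <- sqrt(mean((eps - PR[b])^2))
    M[b] <- Mi
    eps_list[[b]] <- eps
  }
  brk <- seq(0, 1, length.out = n_groups + 1)
  grp <- findInterval(PR, brk, rightmost.closed = TRUE)
  grp[is.na(PR)] <- NA
  keep <- which(tabulate(grp[!is.na(grp)], n_groups) > min_bursts)
  rows <- list()
  z_crit <- if (length(keep)) stats::qnorm(1 - alpha / (2 * length(keep))) else NA
  for (g in keep) {
    sel <- which(!is.na(grp) & grp == g)
    eps_all <- unlist(eps_list[sel])
    PR_mean <- mean(eps_all)
    s_obs <- stats::sd(eps_all)
    s_static <- sqrt(PR_mean * (1 - PR_mean) / n)
    n_win <- length(eps_all)
    sims <- vapply(seq_len(repetitions), function(r)
      stats::sd(stats::rbinom(n_win, n, PR_mean) / n), 0)
    mu <- mean(sims); sdev <- stats::sd(sims)
    rows[[length(rows) + 1L]] <- data.frame(
      PR_lo = brk[g], PR_hi = brk[g + 1], n_bursts = length(sel),
      PR_mean = PR_mean, E = pr_to_efficiency(PR_mean, corrections),
      s_obs = s_obs, s_static = s_static,
      ci_lo = mu - z_crit * sdev, ci_hi = mu + z_crit * sdev,
      flagged = s_obs > mu + z_crit * sdev)
  }
  list(bursts = data.frame(PR = PR, s = s_i, M = M),
       groups = if (length(rows)) do.call(rbind, rows) else data.frame())
}

#' Shot-noise expectation of the BVA standard deviation
#' @param PR proximity ratio.
#' @param n photons per window.
#' @return `sqrt(PR (1 - PR) / n)`.
#' @export
bva_static_sd <- function(PR, n = 5) sqrt(PR * (1 - PR) / n)
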