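#' Conformational kinetic scheme
#'
#' Describes the conformational states of the labeled molecule and the
#' first-order exchange rates between them. Each state carries either a FRET
#' efficiency directly or an apparent donor-acceptor distance (mean and
#' Gaussian linker width) that is converted to E through the Foerster relation
#' E = 1 / (1 + (R/R0)^6).
#'
#' @param states a data.frame with one row per state and columns `label`,
#'   and either `E` or `R_mean` (Angstrom); optional `R_sigma` (Angstrom,
#'   default 0) and `r_donor` (residual donor anisotropy, default 0.2).
#' @param rates square rate matrix (1/s), `rates[i, j]` = rate from state i to
#'   state j; diagonal ignored. All off-diagonal entries must be >= 0.
#' @param R0 Foerster distance in Angstrom used when states are given as
#'   distances.
#' @return An object of class `kinetic_scheme` with derived stationary
#'   populations and, for two-state subsystems, the exchange relaxation time
#'   `tau_ex = 1 / (k12 + k21)`.
#' @examples
#' kinetic_scheme(data.frame(label = c("MF", "HF"), E = c(0.5, 0.8)),
#'                rates = matrix(c(0, 1282, 1282, 0), 2, byrow = TRUE))
#' @export
kinetic_scheme <- function(states, rates = NULL, R0 = 49) {
  stopifnot(is.data.frame(states), nrow(states) >= 1)
  n <- nrow(states)
  if (is.null(states$label)) states$label <- paste0("S", seq_len(n))
  if (is.null(states$E)) {
    stopifnot(!is.null(states$R_mean))
    states$E <- fret_efficiency_from_distance(states$R_mean, R0)
  }
  if (is.null(states$R_sigma)) states$R_sigma <- 0
  if (is.null(states$R_mean)) states$R_mean <- distance_from_fret_efficiency(states$E, R0)
  if (is.null(states$r_donor)) states$r_donor <- 0.2
  if (is.null(rates)) rates <- matrix(0, n, n)
  stopifnot(is.matrix(rates), nrow(rates) == n, ncol(rates) == n)
  diag(rates) <- 0
  if (any(rates < 0)) stop("exchange rates must be nonnegative")
  pop <- ctmc_stationary(rates)
  tau_ex <- if (n == 2) 1 / (rates[1, 2] + rates[2, 1]) else NA_real_
  structure(list(states = states, rates = rates, R0 = R0,
                 populations = pop, tau_ex = tau_ex),
            class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf("<kinetic_scheme> %d state(s), R0 = %.3g A\n", nrow(x$states), x$R0))
  df <- data.frame(label = x$states$label, E = round(x$states$E, 3),
                   population = round(x$populations, 3))
  print(df, row.names = FALSE)
  if (!is.na(x$tau_ex)) cat(sprintf("  tau_ex = %.4g s\n", x$tau_ex))
  invisible(x)
}

#' FRET efficiency from donor-acceptor distance
#' @param R distance (Angstrom).
#' @param R0 Foerster distance (Angstrom).
#' @return E = 1 / (1 + (R/R0)^6)
#' @export
fret_efficiency_from_distance <- function(R, R0 = 49) 1 / (1 + (R / R0)^6)

#' Donor-acceptor distance from FRET efficiency
#' @param E FRET efficiency in (0, 1).
#' @param R0 Foerster distance (Angstrom).
#' @export
distance_from_fret_efficiency <- function(E, R0 = 49) R0 * ((1 - E) / E)^(1 / 6)

# stationary distribution of a CTMC with generator built from `rates`
ctmc_stationary <- function(rates) {
  n <- nrow(rates)
  if (n == 1) return(1)
  if (all(rates == 0)) return(rep(1 / n, n))
  Q <- rates
  diag(Q) <- -rowSums(rates)
  # solve pi Q = 0, sum(pi) = 1
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  sol <- qr.solve(A, b)
  if (any(sol < -1e-9)) stop("no valid stationary distribution (absorbing scheme?)")
  sol <- pmax(sol, 0)
  sol / sum(sol)
}

#' Simulate a continuous-time Markov state path
#'
#' Samples a piecewise-constant state trajectory of the scheme by Gillespie
#' dwell-time sampling: the initial state is drawn from the stationary
#' distribution and dwell times are exponential with the prescribed exit
#' rates.
#'
#' @param scheme a [kinetic_scheme()].
#' @param duration path duration in seconds.
#' @param seed optional integer seed.
#' @param init optional fixed initial state index; default draws from the
#'   stationary distribution.
#' @return A list with `t` (switch times, starting at 0) and `state` (state
#'   index valid from `t[i]` until `t[i+1]` or `duration`).
#' @export
simulate_state_trajectory <- function(scheme, duration, seed = NULL, init = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"), duration > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(scheme$states)
  exit <- rowSums(scheme$rates)
  if (n > 1 && any(exit == 0) && any(exit > 0)) {
    reachable_exit <- exit[scheme$populations > 0]
    if (any(reachable_exit == 0) && any(scheme$rates[, exit == 0] > 0))
      stop("scheme has an absorbing state; not allowed")
  }
  s <- if (is.null(init)) sample.int(n, 1, prob = scheme$populations) else as.integer(init)
  if (n == 2 && all(exit > 0)) {
    # alternating dwell times, drawn in batches
    ts <- 0; ss <- s
    t_end <- 0; cur <- s
    while (t_end < duration) {
      m <- max(64L, ceiling((duration - t_end) * max(exit)))
      states_seq <- if (cur == 1L) rep_len(c(1L, 2L), m) else rep_len(c(2L, 1L), m)
      dw <- stats::rexp(m, exit[states_seq])
      tt <- t_end + cumsum(dw)
      keep <- which(tt < duration)
      ts <- c(ts, tt[keep])
      nxt <- 3L - states_seq[keep]          # state entered at each switch
      ss <- c(ss, nxt)
      t_end <- if (length(keep) < m) duration else tt[m]
      cur <- if (length(keep)) nxt[length(keep)] else cur
    }
    return(list(t = ts, state = ss, duration = duration))
  }
  cap <- max(16L, ceiling(duration * max(exit) * 1.5) + 16L)
  ts <- numeric(cap)
  ss <- integer(cap)
  ts[1] <- 0
  ss[1] <- s
  k <- 1L
  t <- 0
  while (exit[s] > 0) {
    t <- t + stats::rexp(1, exit[s])
    if (t >= duration) break
    s <- sample.int(n, 1, prob = scheme$rates[s, ])
    k <- k + 1L
    if (k > length(ts)) {
      ts <- c(ts, numeric(length(ts)))
      ss <- c(ss, integer(length(ss)))
    }
    ts[k] <- t
    ss[k] <- s
  }
  list(t = ts[seq_len(k)], state = ss[seq_len(k)], duration = duration)
}

# state index at arbitrary times, given a trajectory from simulate_state_trajectory
state_at <- function(traj, times) {
  traj$state[findInterval(times, traj$t)]
}
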