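#' Monte Carlo ensembles of run-and-pause walkers
#'
#' Seeded ensemble simulation of the two-state walk, used to validate the
#' analytic engines and to generate trajectories in regimes of interest.
#' Each walker draws its initial state from `(q_m0, q_w0)`; at every step the
#' transition kernel is applied first and the walker then advances only if it
#' is in the motion state (so no displacement occurs at step 0, matching the
#' analytic convention). `simulate_single` moves all walkers in a fixed
#' positive direction; `simulate_network` starts each walker with a uniform
#' random direction, keeps the direction through waits, and at every motion
#' step keeps it with probability `p` or rotates it by a draw from the turn
#' distribution before stepping.
#'
#' All walkers advance together in vectorised sweeps from a single seeded
#' generator, so identical `(seed, parameters, n_walkers)` reproduce
#' identical output.
#'
#' @inheritParams msd_single
#' @param n_steps Number of steps to simulate (>= 1).
#' @param n_walkers Ensemble size (default `1e6`, matching the scale used for
#'   the reference curves; reduce for quick checks).
#' @param seed Integer seed.
#' @param record `"log"` (default) records ~60 log-spaced steps including
#'   `n_steps`; `"all"` records every step.
#' @return A data frame of class `ensemble_result` with columns `n`, `msd`
#'   (ensemble mean squared displacement), `se` (its standard error) and
#'   `frac_motion` (fraction of walkers in the motion state); attributes
#'   `seed` and `n_walkers`.
#' @examples
#' simulate_single(transition_rates(0.1, 0.001), initial_state(1),
#'                 n_steps = 100, n_walkers = 1000, seed = 1)
#' @export
simulate_single <- function(rates, init, steps = step_constant(),
                            n_steps, n_walkers = 1e6, seed = 1,
                            record = c("log", "all")) {
  stopifnot(inherits(rates, "transition_rates"),
            inherits(init, "initial_state"),
            inherits(steps, "step_model"))
  n_steps <- check_count(n_steps, "n_steps")
  n_walkers <- check_count(n_walkers, "n_walkers")
  record <- match.arg(record)
  if (is.null(steps$sampler)) {
    stop("step model has no sampler; supply one to simulate", call. = FALSE)
  }
  grid <- record_grid(n_steps, record)
  set.seed(as.integer(seed))
  state <- stats::runif(n_walkers) < init$q_m0
  x <- numeric(n_walkers)
  constant_step <- identical(steps$label, "constant")
  out <- matrix(NA_real_, length(grid), 3L)
  k <- 1L
  for (n in seq_len(n_steps)) {
    u <- stats::runif(n_walkers)
    state <- (state & u >= rates$kappa_w) | (!state & u < rates$kappa_m)
    if (constant_step) {
      x <- x + steps$mean_step * state
    } else {
      mov <- which(state)
      if (length(mov)) x[mov] <- x[mov] + steps$sampler(length(mov))
    }
    if (n == grid[k]) {
      sq <- x^2
      out[k, ] <- c(mean(sq), stats::sd(sq) / sqrt(n_walkers), mean(state))
      k <- k + 1L
    }
  }
  new_ensemble_result(grid, out, seed, n_walkers)
}

#' @rdname simulate_single
#' @inheritParams msd_network
#' @export
simulate_network <- function(model, n_steps, n_walkers = 1e6, seed = 1,
                             record = c("log", "all")) {
  stopifnot(inherits(model, "network_model"))
  n_steps <- check_count(n_steps, "n_steps")
  n_walkers <- check_count(n_walkers, "n_walkers")
  record <- match.arg(record)
  steps <- model$steps
  if (is.null(steps$sampler)) {
    stop("step model has no sampler; supply one to simulate", call. = FALSE)
  }
  rates <- model$rates
  grid <- record_grid(n_steps, record)
  set.seed(as.integer(seed))
  state <- stats::runif(n_walkers) < model$init$q_m0
  theta <- stats::runif(n_walkers, -pi, pi)
  x <- numeric(n_walkers)
  y <- numeric(n_walkers)
  constant_step <- identical(steps$label, "constant")
  out <- matrix(NA_real_, length(grid), 3L)
  k <- 1L
  for (n in seq_len(n_steps)) {
    u <- stats::runif(n_walkers)
    state <- (state & u >= rates$kappa_w) | (!state & u < rates$kappa_m)
    mov <- which(state)
    n_mov <- length(mov)
    if (n_mov) {
      turn <- if (model$p >= 1) {
        logical(0)
      } else if (model$p <= 0) {
        mov
      } else {
        mov[stats::runif(n_mov) >= model$p]
      }
      if (length(turn)) {
        theta[turn] <- theta[turn] + model$turns$sampler(length(turn))
      }
      l <- if (constant_step) steps$mean_step else steps$sampler(n_mov)
      x[mov] <- x[mov] + l * cos(theta[mov])
      y[mov] <- y[mov] + l * sin(theta[mov])
    }
    if (n == grid[k]) {
      sq <- x^2 + y^2
      out[k, ] <- c(mean(sq), stats::sd(sq) / sqrt(n_walkers), mean(state))
      k <- k + 1L
    }
  }
  new_ensemble_result(grid, out, seed, n_walkers)
}

new_ensemble_result <- function(grid, out, seed, n_walkers) {
  structure(
    data.frame(n = grid, msd = out[, 1L], se = out[, 2L],
               frac_motion = out[, 3L]),
    class = c("ensemble_result", "data.frame"),
    seed = seed, n_walkers = n_walkers
  )
}

record_grid <- function(n_steps, record) {
  if (record == "all") return(seq_len(n_steps))
  g <- unique(round(exp(seq(0, log(n_steps), length.out = 60))))
  sort(unique(c(g, n_steps)))
}

#' Sample residence times from the simulated switching dynamics
#'
#' Simulate an ensemble of sojourns in one motility state by applying the
#' per-step escape trial of the chain (escape probability `kappa_w` from
#' motion, `kappa_m` from waiting) until every sojourn ends, and return the
#' sojourn lengths — for goodness-of-fit checks against the geometric law of
#' [residence_time_pmf()].
#'
#' @inheritParams simulate_single
#' @param state `"motion"` or `"wait"`.
#' @param n_samples Number of sojourns to simulate.
#' @return Integer vector of `n_samples` sojourn lengths (in steps).
#' @export
simulate_residence_times <- function(rates, state = c("motion", "wait"),
                                     n_samples = 1e4, seed = 1) {
  stopifnot(inherits(rates, "transition_rates"))
  state <- match.arg(state)
  n_samples <- check_count(n_samples, "n_samples")
  kappa <- if (state == "motion") rates$kappa_w else rates$kappa_m
  if (kappa <= 0) {
    stop("escape probability is zero: sojourns in this state never end",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  times <- integer(n_samples)
  alive <- seq_len(n_samples)
  t <- 0L
  while (length(alive)) {
    t <- t + 1L
    escaped <- stats::runif(length(alive)) < kappa
    times[alive[escaped]] <- t
    alive <- alive[!escaped]
  }
  times
}
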