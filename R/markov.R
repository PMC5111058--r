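#' State occupancy of the two-state chain over time
#'
#' Closed-form evolution of the probability `q_m(n)` of being in the motion
#' state after `n` steps,
#' `q_m(n) = s + (q_m0 - s) r^n` with relaxation factor
#' `r = 1 - kappa_w - kappa_m` and stationary motion probability
#' `s = kappa_m / (kappa_m + kappa_w)`. Identical (to rounding) to iterating
#' the transition kernel `q_m(n) = q_m(n-1)(1 - kappa_w) + q_w(n-1) kappa_m`.
#'
#' @param rates A [transition_rates()] object.
#' @param init An [initial_state()] object.
#' @param n_max Largest step number (>= 1).
#' @return A data frame of class `occupancy_series` with columns `n`
#'   (`0:n_max`), `q_m` and `q_w`.
#' @examples
#' occupancy_evolution(transition_rates(0.1, 0.001), initial_state(1), 10)
#' @export
occupancy_evolution <- function(rates, init, n_max) {
  stopifnot(inherits(rates, "transition_rates"),
            inherits(init, "initial_state"))
  n_max <- check_count(n_max, "n_max")
  q_m <- occupancy_vector(rates, init, n_max)
  structure(
    data.frame(n = 0:n_max, q_m = q_m, q_w = 1 - q_m),
    class = c("occupancy_series", "data.frame"),
    rates = rates, init = init
  )
}

# q_m(0..n_max) as a bare vector; frozen chain handled via s = 1, r = 1
occupancy_vector <- function(rates, init, n_max) {
  s <- motion_stationary(rates, frozen_ok = TRUE)
  s + (init$q_m0 - s) * rates$r^(0:n_max)
}

#' Stationary state occupancies
#'
#' Long-time probabilities of the motion and waiting states,
#' `P_m = kappa_m / (kappa_m + kappa_w)` and
#' `P_w = kappa_w / (kappa_m + kappa_w)`.
#'
#' @inheritParams occupancy_evolution
#' @return Named numeric vector `c(P_m, P_w)`.
#' @examples
#' stationary_occupancy(transition_rates(0.1, 0.001))
#' @export
stationary_occupancy <- function(rates) {
  stopifnot(inherits(rates, "transition_rates"))
  s <- motion_stationary(rates)
  c(P_m = s, P_w = 1 - s)
}

#' Residence-time distribution in one motility state
#'
#' With constant switching probabilities the number of consecutive steps spent
#' in a state before escaping is geometric: the escape probability is
#' `kappa_w` from the motion state and `kappa_m` from the waiting state, so
#' `P(T = t) = (1 - kappa)^(t-1) kappa`, the discrete counterpart of the
#' exponential residence-time distribution, with mean `1 / kappa` steps.
#'
#' @param state `"motion"` or `"wait"`.
#' @inheritParams occupancy_evolution
#' @param t Vector of positive integer residence times.
#' @return `residence_time_pmf`: vector of probabilities `P(T = t)`.
#'   `mean_residence_time`: the mean `1 / kappa` (infinite when the escape
#'   probability is zero, with a warning).
#' @examples
#' residence_time_pmf("motion", transition_rates(0.5, 0.5), 1:4)
#' mean_residence_time("motion", transition_rates(0.1, 0.001))  # 10 steps
#' @export
residence_time_pmf <- function(state = c("motion", "wait"), rates, t) {
  state <- match.arg(state)
  stopifnot(inherits(rates, "transition_rates"))
  if (any(t < 1) || any(t != floor(t))) {
    stop("residence times t must be positive integers", call. = FALSE)
  }
  kappa <- if (state == "motion") rates$kappa_w else rates$kappa_m
  (1 - kappa)^(t - 1) * kappa
}

#' @rdname residence_time_pmf
#' @export
mean_residence_time <- function(state = c("motion", "wait"), rates) {
  state <- match.arg(state)
  stopifnot(inherits(rates, "transition_rates"))
  kappa <- if (state == "motion") rates$kappa_w else rates$kappa_m
  if (kappa == 0) {
    warning("escape probability is zero: residence time is infinite")
    return(Inf)
  }
  1 / kappa
}

#' Number of steps to reach the stationary occupancy
#'
#' Smallest `n` with `|q_m(n) - P_m| < tol`; because the deviation decays
#' geometrically with the relaxation factor `r`, this is
#' `ceiling(log(|q_m0 - s| / tol) / -log(|r|))` (0 when already stationary,
#' 1 when `r = 0`, i.e. `kappa_m + kappa_w = 1`).
#'
#' @inheritParams occupancy_evolution
#' @param tol Positive convergence tolerance on the occupancy.
#' @return Integer step count.
#' @examples
#' convergence_step(transition_rates(0.1, 0.001), initial_state(1), 1e-3)
#' @export
convergence_step <- function(rates, init, tol) {
  stopifnot(inherits(rates, "transition_rates"),
            inherits(init, "initial_state"))
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0) {
    stop("tol must be a single positive number", call. = FALSE)
  }
  s <- motion_stationary(rates)
  dev0 <- abs(init$q_m0 - s)
  if (dev0 < tol) return(0L)
  if (rates$r == 0) return(1L)
  n <- ceiling(log(dev0 / tol) / -log(abs(rates$r)))
  # guard against rounding at the boundary of the ceiling
  while (dev0 * abs(rates$r)^n >= tol) n <- n + 1
  as.integer(n)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stop(sprintf("%s must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}
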