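#' Exact MSD of run-and-pause motion along a single filament
#'
#' Ensemble mean squared displacement of the unidirectional two-state walk
#' `x(n) = sum_i sigma_i l_i`, where `sigma_i` is the motion indicator of the
#' switching chain at step `i` and the `l_i` are i.i.d. step lengths. The
#' state at step `i` is obtained by applying the transition kernel to the
#' state at step `i - 1`, and the displacement at step `i` uses that
#' post-transition state (the walker takes no step at `n = 0`).
#'
#' The engine evaluates the exact correlation sum
#' `<x^2(n)> = <l^2> sum_i P_i + 2 <l>^2 sum_{i<j} P_i G(j - i)`
#' with `P_i = q_m(i)` the motion occupancy and
#' `G(k) = s + (1 - s) r^k` the k-step motion -> motion return probability,
#' in linear time via a recursive accumulation of the inner geometric sum.
#'
#' @inheritParams occupancy_evolution
#' @param steps A step-length model (see [step_constant()]).
#' @param n_max Largest step number (>= 1).
#' @return A data frame of class `msd_series` with columns `n` (`1:n_max`)
#'   and `msd`.
#' @examples
#' msd_single(transition_rates(0.1, 0.001), initial_state(1), n_max = 10)
#' @export
msd_single <- function(rates, init, steps = step_constant(), n_max) {
  stopifnot(inherits(rates, "transition_rates"),
            inherits(init, "initial_state"),
            inherits(steps, "step_model"))
  n_max <- check_count(n_max, "n_max")
  P <- occupancy_vector(rates, init, n_max)[-1]   # q_m(1..n_max)
  s <- motion_stationary(rates, frozen_ok = TRUE)
  r <- if (rates$kappa_w + rates$kappa_m == 0) 1 else rates$r
  S1 <- cumsum(P)
  if (n_max == 1L) {
    cross <- 0
  } else {
    # U(j) = sum_{i<j} P_i r^(j-i) satisfies U(j) = r (U(j-1) + P_{j-1})
    U <- c(0, as.numeric(stats::filter(r * P[-n_max], r, "recursive")))
    tj <- s * c(0, S1[-n_max]) + (1 - s) * U      # sum_{i<j} P_i G(j-i)
    cross <- cumsum(tj)
  }
  msd <- steps$second_moment * S1 + 2 * steps$mean_step^2 * cross
  new_msd_series(msd, model = "single", rates = rates, init = init,
                 steps = steps)
}

new_msd_series <- function(msd, ...) {
  structure(
    data.frame(n = seq_along(msd), msd = msd),
    class = c("msd_series", "data.frame"),
    ...
  )
}

#' Initial anomalous exponent on a single filament
#'
#' Power-law fit through the first two MSD points,
#' `alpha_star = log2(MSD(2) / MSD(1))`. For `kappa_w = 0`, `kappa_m = 1`
#' and a constant step this gives 2, the ballistic value.
#'
#' @inheritParams msd_single
#' @return The initial exponent (a single number).
#' @examples
#' initial_exponent_single(transition_rates(0, 1), initial_state(1))  # 2
#' @export
initial_exponent_single <- function(rates, init, steps = step_constant()) {
  msd <- msd_single(rates, init, steps, n_max = 2L)$msd
  if (msd[1] <= 0) {
    stop("initial exponent undefined: MSD(1) = 0 (no walker moves at step 1)",
         call. = FALSE)
  }
  log2(msd[2] / msd[1])
}

#' Asymptotic ballistic prefactor on a single filament
#'
#' In the long-time limit the single-filament MSD is purely ballistic,
#' `MSD(n) -> c n^2` with prefactor
#' `c = (kappa_m / (kappa_m + kappa_w))^2 <l>^2 = s^2 <l>^2`:
#' the squared mean drift of a walker that moves a fraction `s` of the time.
#' `kappa_w = 0` gives `c = <l>^2`, the fastest possible propagation.
#'
#' @inheritParams msd_single
#' @return The prefactor `c` (length^2 per step^2).
#' @examples
#' asymptotic_msd_prefactor_single(transition_rates(0.1, 0.001))
#' @export
asymptotic_msd_prefactor_single <- function(rates, steps = step_constant()) {
  stopifnot(inherits(rates, "transition_rates"),
            inherits(steps, "step_model"))
  s <- motion_stationary(rates)
  (s * steps$mean_step)^2
}

#' Ensemble MSD for a waiting start without pauses (continuous time)
#'
#' Continuous-time companion of the all-waiting start with `kappa_w = 0`:
#' each particle stays immobile for an exponentially distributed time
#' `t0 ~ kappa exp(-kappa t0)` and then moves ballistically with speed `v`,
#' so the ensemble MSD is
#' `integral_0^t kappa exp(-kappa t0) v^2 (t - t0)^2 dt0
#'  = v^2 (t^2 - 2 t / kappa + 2 / kappa^2 - 2 exp(-kappa t) / kappa^2)`.
#' The small-`t` expansion starts at `(v^2 kappa / 3) t^3`, i.e. the initial
#' anomalous exponent is 3; at large `t` the motion is (delayed) ballistic.
#'
#' @param kappa_m_rate Escape rate from the waiting state (> 0, per unit
#'   time).
#' @param v Ballistic speed (> 0).
#' @param t Vector of non-negative times.
#' @return Vector of MSD values, same length as `t`.
#' @examples
#' waiting_start_msd_continuous(1, 1, 1)  # 0.264241...
#' @export
waiting_start_msd_continuous <- function(kappa_m_rate, v, t) {
  if (!is.numeric(kappa_m_rate) || length(kappa_m_rate) != 1L ||
      kappa_m_rate <= 0) {
    stop("kappa_m_rate must be a single positive rate", call. = FALSE)
  }
  if (!is.numeric(v) || length(v) != 1L || v <= 0) {
    stop("v must be a single positive speed", call. = FALSE)
  }
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  k <- kappa_m_rate
  v^2 * (t^2 - 2 * t / k + 2 / k^2 - 2 * exp(-k * t) / k^2)
}
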