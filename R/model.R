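#' Switching probabilities of the two-state motility chain
#'
#' Construct the pair of per-step transition probabilities of the run-and-pause
#' Markov chain: `kappa_w` is the probability of switching from the motion to
#' the waiting state at a given step, `kappa_m` the probability of switching
#' from waiting back to motion.
#'
#' The relaxation factor of the chain is `r = 1 - kappa_w - kappa_m`
#' (`|r| <= 1`). When `kappa_w + kappa_m > 0` the chain has a unique
#' stationary distribution; `kappa_w = kappa_m = 0` freezes each walker in its
#' initial state.
#'
#' @param kappa_w Probability per step of a motion -> wait transition, in
#'   `[0, 1]`.
#' @param kappa_m Probability per step of a wait -> motion transition, in
#'   `[0, 1]`.
#' @return An object of class `transition_rates` with fields `kappa_w`,
#'   `kappa_m` and the relaxation factor `r`.
#' @examples
#' transition_rates(0.1, 0.001)
#' @export
transition_rates <- function(kappa_w, kappa_m) {
  check_probability(kappa_w, "kappa_w")
  check_probability(kappa_m, "kappa_m")
  structure(
    list(kappa_w = kappa_w, kappa_m = kappa_m, r = 1 - kappa_w - kappa_m),
    class = "transition_rates"
  )
}

#' @export
print.transition_rates <- function(x, ...) {
  cat(sprintf(
    "Two-state switching probabilities: kappa_w = %g, kappa_m = %g (r = %g)\n",
    x$kappa_w, x$kappa_m, x$r
  ))
  invisible(x)
}

#' Initial state distribution of the walker
#'
#' @param q_m0 Probability in `[0, 1]` that a walker starts in the motion
#'   state; the complementary probability `1 - q_m0` is the probability of
#'   starting in the waiting state.
#' @return An object of class `initial_state` with fields `q_m0` and `q_w0`.
#' @examples
#' initial_state(1)    # all walkers start moving
#' initial_state(0)    # all walkers start waiting
#' @export
initial_state <- function(q_m0) {
  check_probability(q_m0, "q_m0")
  structure(list(q_m0 = q_m0, q_w0 = 1 - q_m0), class = "initial_state")
}

#' @export
print.initial_state <- function(x, ...) {
  cat(sprintf("Initial state: P(motion) = %g, P(wait) = %g\n", x$q_m0, x$q_w0))
  invisible(x)
}

#' Step-length models
#'
#' A step-length model carries the first two moments of the i.i.d. step (or
#' filament-segment) length distribution and, where available, a sampler used
#' by the Monte Carlo engines. The analytic engines depend on the distribution
#' only through the mean step `<l>` and the heterogeneity parameter
#' `lambda = <l^2> / <l>^2` (`lambda = 1` iff the step length is constant).
#'
#' * `step_constant(length)`: every step has the same length (`lambda = 1`).
#' * `step_exponential(mean)`: exponentially distributed lengths
#'   (`lambda = 2`), a common model for the spacing of network junctions.
#' * `step_custom(mean, lambda, sampler)`: user-specified moments; the sampler
#'   (a function of `n` returning `n` non-negative lengths) is optional and
#'   only required for simulation.
#'
#' @param length,mean Mean step length (> 0), in model length units.
#' @param lambda Heterogeneity `<l^2>/<l>^2`, must be >= 1.
#' @param sampler Optional function of `n` drawing step lengths.
#' @return An object of class `step_model` with fields `mean_step`,
#'   `second_moment`, `lambda_het` and `sampler` (possibly `NULL`).
#' @examples
#' step_constant(1)
#' step_exponential(0.1)
#' @name step_models
NULL

new_step_model <- function(mean_step, lambda_het, sampler, label) {
  if (!is.numeric(mean_step) || length(mean_step) != 1L || mean_step <= 0) {
    stop("mean step length must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(lambda_het) || length(lambda_het) != 1L || lambda_het < 1) {
    stop("heterogeneity lambda = <l^2>/<l>^2 must be >= 1", call. = FALSE)
  }
  structure(
    list(
      mean_step = mean_step,
      second_moment = lambda_het * mean_step^2,
      lambda_het = lambda_het,
      sampler = sampler,
      label = label
    ),
    class = "step_model"
  )
}

#' @rdname step_models
#' @export
step_constant <- function(length = 1) {
  new_step_model(length, 1, function(n) rep(length, n), "constant")
}

#' @rdname step_models
#' @export
step_exponential <- function(mean = 1) {
  new_step_model(mean, 2, function(n) stats::rexp(n, rate = 1 / mean),
                 "exponential")
}

#' @rdname step_models
#' @export
step_custom <- function(mean, lambda, sampler = NULL) {
  new_step_model(mean, lambda, sampler, "custom")
}

#' @export
print.step_model <- function(x, ...) {
  cat(sprintf("Step-length model (%s): <l> = %g, lambda = %g\n",
              x$label, x$mean_step, x$lambda_het))
  invisible(x)
}

#' Turn-angle models
#'
#' A turn-angle model describes the distribution `R(phi)` of the angle between
#' the incoming and outgoing filament at a network junction, on `(-pi, pi]`.
#' The analytic engines depend on it only through the anisotropy
#' `r_hat = E[cos phi]` (`0` for an isotropic network, `-> 1` for aligned
#' filaments, negative for predominantly backward turns). The distribution
#' must be symmetric about zero (`E[sin phi] = 0`); asymmetric distributions
#' are rejected because the planar moment algebra relies on that symmetry.
#'
#' * `turn_uniform()`: isotropic turning, `r_hat = 0`.
#' * `turn_delta(angle)`: turns of fixed magnitude, split evenly between
#'   `+angle` and `-angle`; `r_hat = cos(angle)`. `turn_delta(0)` always goes
#'   straight on.
#' * `turn_discrete(angles, weights)`: finite set of angles with probability
#'   weights; must be symmetric (each angle's weight equals that of its
#'   negative, up to wrapping).
#' * `turn_wrapped_normal(sd)`: wrapped normal centred at zero with standard
#'   deviation `sd`; `r_hat = exp(-sd^2 / 2)`.
#'
#' @param angle Turn magnitude in radians.
#' @param angles,weights Angles in radians and non-negative weights (summing
#'   to 1 after normalisation).
#' @param sd Standard deviation in radians of the unwrapped normal.
#' @return An object of class `turn_model` with fields `r_hat` and
#'   `sampler` (a function of `n` drawing turn angles).
#' @examples
#' turn_uniform()
#' turn_discrete(c(0, pi / 2, -pi / 2), c(1, 1, 1) / 3)  # square lattice
#' @name turn_models
NULL

new_turn_model <- function(r_hat, sampler, label) {
  if (abs(r_hat) > 1 + 1e-12) {
    stop("anisotropy r_hat = E[cos phi] must lie in [-1, 1]", call. = FALSE)
  }
  structure(
    list(r_hat = min(1, max(-1, r_hat)), sampler = sampler, label = label),
    class = "turn_model"
  )
}

#' @rdname turn_models
#' @export
turn_uniform <- function() {
  new_turn_model(0, function(n) stats::runif(n, -pi, pi), "uniform")
}

#' @rdname turn_models
#' @export
turn_delta <- function(angle = 0) {
  if (!is.numeric(angle) || length(angle) != 1L || !is.finite(angle)) {
    stop("angle must be a single finite number", call. = FALSE)
  }
  new_turn_model(
    cos(angle),
    function(n) sample(c(-1, 1), n, replace = TRUE) * angle,
    sprintf("delta(+/-%g)", angle)
  )
}

#' @rdname turn_models
#' @export
turn_discrete <- function(angles, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(angles))
  if (length(angles) != length(weights) || any(weights < 0) ||
      sum(weights) <= 0) {
    stop("weights must be non-negative, one per angle, with positive sum",
         call. = FALSE)
  }
  weights <- weights / sum(weights)
  mean_sin <- sum(weights * sin(angles))
  if (abs(mean_sin) > 1e-10) {
    stop(sprintf(
      "turn distribution must be symmetric about 0: E[sin phi] = %g != 0",
      mean_sin
    ), call. = FALSE)
  }
  new_turn_model(
    sum(weights * cos(angles)),
    function(n) sample(angles, n, replace = TRUE, prob = weights),
    "discrete"
  )
}

#' @rdname turn_models
#' @export
turn_wrapped_normal <- function(sd) {
  if (!is.numeric(sd) || length(sd) != 1L || sd < 0) {
    stop("sd must be a single non-negative number", call. = FALSE)
  }
  new_turn_model(
    exp(-sd^2 / 2),
    function(n) {
      phi <- stats::rnorm(n, 0, sd)
      ((phi + pi) %% (2 * pi)) - pi
    },
    "wrapped-normal"
  )
}

#' @export
print.turn_model <- function(x, ...) {
  cat(sprintf("Turn-angle model (%s): r_hat = E[cos phi] = %g\n",
              x$label, x$r_hat))
  invisible(x)
}

#' Assemble a network motility model
#'
#' Bundle the switching probabilities, initial state, step-length and
#' turn-angle statistics, and motor processivity into the full model of
#' persistent run-and-pause motion on a coarse-grained filament network. At
#' each motion step the walker keeps its direction with the processivity
#' probability `p` and otherwise turns by an angle drawn from the turn model;
#' the directional correlation therefore decays by the effective persistence
#'
#' `A = p + (1 - p) * r_hat`
#'
#' per motion step, which is the only combination of `p` and `r_hat` entering
#' the displacement moments. `A = 1` (fully processive motion, or perfectly
#' aligned filaments) recovers unidirectional motion on a single filament.
#'
#' Alternatively `A` may be supplied directly (leaving `turns` and `p` at
#' their defaults), in which case an equivalent fixed-angle turn model with
#' `cos(angle) = A` is attached so the model remains simulable.
#'
#' @param rates A [transition_rates()] object.
#' @param init An [initial_state()] object (default: start in motion).
#' @param steps A step-length model (default [step_constant()]).
#' @param turns A turn-angle model (default [turn_uniform()]).
#' @param p Processivity in `[0, 1]`: probability of continuing along the
#'   current filament at a junction.
#' @param A Optional effective persistence in `[-1, 1]`, overriding `turns`
#'   and `p`. Supplying `A` together with a non-default `turns`/`p`
#'   combination that implies a different value is an error.
#' @return An object of class `network_model`.
#' @examples
#' # non-processive motion on an isotropic actin-like network
#' network_model(transition_rates(0.05, 0.05))
#' # highly processive motion, A = 0.99
#' network_model(transition_rates(0.9, 0.01), A = 0.99)
#' @export
network_model <- function(rates, init = initial_state(1),
                          steps = step_constant(), turns = turn_uniform(),
                          p = 0, A = NULL) {
  stopifnot(inherits(rates, "transition_rates"),
            inherits(init, "initial_state"),
            inherits(steps, "step_model"),
            inherits(turns, "turn_model"))
  check_probability(p, "p")
  implied <- p + (1 - p) * turns$r_hat
  if (!is.null(A)) {
    if (!is.numeric(A) || length(A) != 1L || abs(A) > 1) {
      stop("A must be a single number in [-1, 1]", call. = FALSE)
    }
    if ((p != 0 || turns$label != "uniform") && abs(implied - A) > 1e-12) {
      stop(sprintf(
        "inconsistent parameters: p and the turn model imply A = %g but A = %g was supplied",
        implied, A
      ), call. = FALSE)
    }
    turns <- turn_delta(acos(A))
    p <- 0
  } else {
    A <- implied
  }
  structure(
    list(rates = rates, init = init, steps = steps, turns = turns,
         p = p, A = A),
    class = "network_model"
  )
}

#' @export
print.network_model <- function(x, ...) {
  cat("Run-and-pause network motility model\n")
  print(x$rates)
  print(x$init)
  print(x$steps)
  print(x$turns)
  cat(sprintf("Processivity p = %g; effective persistence A = %g\n",
              x$p, x$A))
  invisible(x)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("%s must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

# stationary motion probability; the frozen chain (both rates zero) keeps the
# initial state forever, for which s = 1, r = 1 reproduces q_m(n) = q_m0 and a
# unit motion->motion return probability in the moment recursions.
motion_stationary <- function(rates, frozen_ok = FALSE) {
  if (rates$kappa_w + rates$kappa_m == 0) {
    if (!frozen_ok) {
      stop("stationary state undefined: kappa_w = kappa_m = 0 freezes the chain",
           call. = FALSE)
    }
    return(1)
  }
  rates$kappa_m / (rates$kappa_m + rates$kappa_w)
}
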