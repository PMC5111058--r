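#' Parameter-space scans over the switching probabilities
#'
#' Evaluate a transport quantity on a grid over `(kappa_w, kappa_m)`:
#' `"n_c_single"` — crossover step to the asymptotic ballistic regime of the
#' single-filament walk; `"n_c_network"` — crossover step to the asymptotic
#' diffusive regime of the network walk; `"D_inf"` — asymptotic network
#' diffusion constant. Crossover cells that have not converged within the
#' horizon `n_max` are flagged (`converged = FALSE`) and their `n_c` is a
#' lower bound, never an extrapolation.
#'
#' @param quantity One of `"n_c_single"`, `"n_c_network"`, `"D_inf"`.
#' @param kappa_w,kappa_m Axis values in `(0, 1]`.
#' @param A Effective persistence (network quantities; `A < 1` for
#'   `"D_inf"`).
#' @param lambda Step-length heterogeneity (>= 1).
#' @param q_m0 Initial motion-state probability.
#' @param epsilon Crossover threshold on `|alpha - target|`.
#' @param n_max Horizon for the crossover search.
#' @param v Motor speed (for `"D_inf"`).
#' @param mean_step Mean step length (for `"D_inf"`).
#' @return An object of class `phase_grid`: a list with the axes, a
#'   `values` matrix (rows: `kappa_w`, columns: `kappa_m`), a logical
#'   `converged` matrix and the fixed parameters in `meta`.
#' @examples
#' phase_scan("D_inf", kappa_w = c(0.2, 0.5), kappa_m = c(0.2, 0.5))
#' @export
phase_scan <- function(quantity = c("n_c_single", "n_c_network", "D_inf"),
                       kappa_w, kappa_m, A = 0, lambda = 1, q_m0 = 1,
                       epsilon = 1e-2, n_max = 1e4, v = 1, mean_step = 1) {
  quantity <- match.arg(quantity)
  if (any(kappa_w <= 0) || any(kappa_w > 1) ||
      any(kappa_m <= 0) || any(kappa_m > 1)) {
    stop("grid values must lie in (0, 1]", call. = FALSE)
  }
  init <- initial_state(q_m0)
  steps <- step_custom(mean_step, lambda)
  vals <- matrix(NA_real_, length(kappa_w), length(kappa_m),
                 dimnames = list(kappa_w = kappa_w, kappa_m = kappa_m))
  conv <- matrix(TRUE, length(kappa_w), length(kappa_m))
  for (i in seq_along(kappa_w)) {
    for (j in seq_along(kappa_m)) {
      rates <- transition_rates(kappa_w[i], kappa_m[j])
      if (quantity == "D_inf") {
        m <- network_model(rates, init, steps, A = A)
        vals[i, j] <- asymptotic_diffusion(m, v)
      } else {
        msd <- if (quantity == "n_c_single") {
          msd_single(rates, init, steps, n_max)
        } else {
          msd_network(network_model(rates, init, steps, A = A), n_max)
        }
        target <- if (quantity == "n_c_single") 2 else 1
        # kappa_w = 1 with a sure motion start gives MSD(1) = 0; the
        # exponent is fitted from the first positive MSD point onwards
        msd <- msd[msd$msd > 0, ]
        cr <- crossover_time(alpha_series(msd), target, epsilon)
        vals[i, j] <- cr$n_c
        conv[i, j] <- cr$converged
      }
    }
  }
  structure(
    list(kappa_w = kappa_w, kappa_m = kappa_m, values = vals,
         converged = conv, quantity = quantity,
         meta = list(A = A, lambda = lambda, q_m0 = q_m0,
                     epsilon = epsilon, n_max = n_max, v = v,
                     mean_step = mean_step)),
    class = "phase_grid"
  )
}

#' @export
print.phase_grid <- function(x, ...) {
  cat(sprintf(
    "Phase grid of %s: %d x %d cells over (kappa_w, kappa_m)%s\n",
    x$quantity, length(x$kappa_w), length(x$kappa_m),
    if (all(x$converged)) "" else
      sprintf("; %d cells not converged (lower bounds)", sum(!x$converged))
  ))
  invisible(x)
}

#' @export
#' @rdname phase_scan
#' @param x A `phase_grid`.
#' @param ... Passed to [graphics::image()].
plot.phase_grid <- function(x, ...) {
  graphics::image(x$kappa_w, x$kappa_m, log10(x$values),
                  xlab = expression(kappa[w]), ylab = expression(kappa[m]),
                  main = sprintf("log10 %s", x$quantity), ...)
  invisible(x)
}

#' @export
#' @rdname phase_scan
as.data.frame.phase_grid <- function(x, ...) {
  data.frame(
    kappa_w = rep(x$kappa_w, times = length(x$kappa_m)),
    kappa_m = rep(x$kappa_m, each = length(x$kappa_w)),
    value = as.vector(x$values),
    converged = as.vector(x$converged)
  )
}

#' Transport quantities along the constrained slice kappa_m + kappa_w = 1
#'
#' When the two switching probabilities are inversely related through
#' `kappa_m = 1 - kappa_w`, the relaxation factor vanishes and the chain
#' equilibrates in a single step: the stationary motion occupancy is simply
#' `1 - kappa_w`, the initial exponent is independent of the initial state
#' probabilities, and the asymptotic diffusion constant becomes a function
#' of `kappa_w` alone.
#'
#' @param quantity `"D_inf"`, `"n_c_network"` or `"alpha_star"` (network
#'   initial exponent).
#' @param kappa_w Values in `(0, 1)`; `kappa_m = 1 - kappa_w`.
#' @inheritParams phase_scan
#' @return A data frame with columns `kappa_w`, `kappa_m`, `value` and (for
#'   crossover quantities) `converged`.
#' @examples
#' constrained_slice("D_inf", kappa_w = c(0.25, 0.5, 0.75))
#' @export
constrained_slice <- function(quantity = c("D_inf", "n_c_network",
                                           "alpha_star"),
                              kappa_w, A = 0, lambda = 1, q_m0 = 1,
                              epsilon = 1e-2, n_max = 1e4, v = 1,
                              mean_step = 1) {
  quantity <- match.arg(quantity)
  if (any(kappa_w <= 0) || any(kappa_w >= 1)) {
    stop("on the constrained slice kappa_w must lie in (0, 1)",
         call. = FALSE)
  }
  init <- initial_state(q_m0)
  steps <- step_custom(mean_step, lambda)
  value <- numeric(length(kappa_w))
  converged <- rep(NA, length(kappa_w))
  for (i in seq_along(kappa_w)) {
    rates <- transition_rates(kappa_w[i], 1 - kappa_w[i])
    m <- network_model(rates, init, steps, A = A)
    if (quantity == "D_inf") {
      value[i] <- asymptotic_diffusion(m, v)
    } else if (quantity == "alpha_star") {
      value[i] <- initial_exponent_network(m)
    } else {
      cr <- crossover_time(alpha_series(msd_network(m, n_max)), 1, epsilon)
      value[i] <- cr$n_c
      converged[i] <- cr$converged
    }
  }
  out <- data.frame(kappa_w = kappa_w, kappa_m = 1 - kappa_w, value = value)
  if (quantity == "n_c_network") out$converged <- converged
  out
}

#' Convert between step counts and physical time
#'
#' One discrete step of the model corresponds to traversing one step length
#' (a motor step or a network segment) at the motor speed `v`, so the tick
#' duration is `mean_step / v`; waiting steps consume the same tick. A motor
#' with 8 nm steps at 1 um/s has an 8 ms tick; a 100 nm actin mesh at
#' 1 um/s gives 0.1 s per step.
#'
#' @param n Step count (>= 0).
#' @param t Time (>= 0), in the units of `mean_step / v`.
#' @param mean_step Mean step length (> 0).
#' @param v Motor speed (> 0).
#' @return `steps_to_time`: time; `time_to_steps`: (fractional) step count.
#' @examples
#' steps_to_time(1, mean_step = 8e-3, v = 1)   # um & um/s -> 8 ms
#' time_to_steps(1, mean_step = 0.1, v = 1)    # 10 mesh crossings per second
#' @export
steps_to_time <- function(n, mean_step, v) {
  check_positive_scalar(mean_step, "mean_step")
  check_positive_scalar(v, "v")
  if (any(n < 0)) stop("n must be non-negative", call. = FALSE)
  n * mean_step / v
}

#' @rdname steps_to_time
#' @export
time_to_steps <- function(t, mean_step, v) {
  check_positive_scalar(mean_step, "mean_step")
  check_positive_scalar(v, "v")
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  t * v / mean_step
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("%s must be a single positive number", name), call. = FALSE)
  }
  invisible(x)
}
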