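#' Exact MSD of persistent run-and-pause motion on a filament network
#'
#' Ensemble mean squared displacement of the planar two-state persistent walk
#' `r(n) = sum_i sigma_i l_i e(theta_i)`: the initial direction is uniform on
#' `(-pi, pi]`, the direction is preserved through waiting steps (the motor
#' stays at a junction on the same filament), and at every motion step the
#' direction is first updated (kept with the processivity `p`, otherwise
#' rotated by a draw from the turn distribution) and the step then taken.
#' Each motion step therefore multiplies the directional correlation by the
#' effective persistence `A = p + (1 - p) E[cos phi]`.
#'
#' The engine evaluates the exact correlation sum
#' `<r^2(n)> = <l^2> sum_i P_i + 2 <l>^2 sum_{i<j} P_i g(j - i)`,
#' where `g(k)` is the motion entry of the `A`-weighted transfer matrix
#' `M = [[A(1-kappa_w), A kappa_m], [kappa_w, 1-kappa_m]]` applied `k` times
#' to the unit motion vector — one factor `A` per intervening motion step —
#' accumulated in linear time. With `A = 1` this reduces exactly to
#' [msd_single()].
#'
#' @param model A [network_model()].
#' @param n_max Largest step number (>= 1).
#' @return A data frame of class `msd_series` with columns `n` and `msd`.
#' @examples
#' m <- network_model(transition_rates(0.05, 0.05), A = 0.5)
#' msd_network(m, n_max = 10)
#' @export
msd_network <- function(model, n_max) {
  stopifnot(inherits(model, "network_model"))
  n_max <- check_count(n_max, "n_max")
  rates <- model$rates
  A <- model$A
  P <- occupancy_vector(rates, model$init, n_max)[-1]
  S1 <- cumsum(P)
  if (n_max == 1L) {
    cross <- 0
  } else {
    kw <- rates$kappa_w
    km <- rates$kappa_m
    m11 <- A * (1 - kw); m12 <- A * km
    m21 <- kw;           m22 <- 1 - km
    # V(j) = M (V(j-1) + P_{j-1} e1); T(j) = motion entry of V(j)
    tj <- numeric(n_max)
    v1 <- 0; v2 <- 0
    for (j in 2:n_max) {
      a <- v1 + P[j - 1L]
      v1 <- m11 * a + m12 * v2
      v2 <- m21 * a + m22 * v2
      tj[j] <- v1
    }
    cross <- cumsum(tj)
  }
  msd <- model$steps$second_moment * S1 +
    2 * model$steps$mean_step^2 * cross
  new_msd_series(msd, model = "network", network_model = model)
}

#' Initial anomalous exponent on a network
#'
#' Power-law fit through the first two MSD points of the network engine,
#' `alpha_star = log2(MSD(2) / MSD(1))`. In the single-state case
#' (`kappa_w = 0`, `kappa_m = 1`) this reduces to
#' `log2(2 + 2 A / lambda)`: 1 for non-processive motion on an isotropic
#' network (`A = 0`, `lambda = 1`), 2 in the ballistic limit `A = 1`.
#'
#' @inheritParams msd_network
#' @return The initial exponent (a single number).
#' @examples
#' m <- network_model(transition_rates(0, 1))  # A = 0: diffusive
#' initial_exponent_network(m)                 # 1
#' @export
initial_exponent_network <- function(model) {
  msd <- msd_network(model, n_max = 2L)$msd
  if (msd[1] <= 0) {
    stop("initial exponent undefined: MSD(1) = 0 (no walker moves at step 1)",
         call. = FALSE)
  }
  log2(msd[2] / msd[1])
}

#' Scale factor of the asymptotic network diffusion constant
#'
#' Renewal structure of the motion steps: a pair of motion steps `k` apart
#' contributes a directional correlation `A^k`, and summing the geometric
#' series gives the dimensionless scale factor
#' `Gamma(lambda, A) = lambda + 2 A / (1 - A)`
#' multiplying the asymptotic diffusion constant. `Gamma = lambda` for
#' uncorrelated steps (`A = 0`); `Gamma` diverges in the ballistic limit
#' `A -> 1`.
#'
#' @param lambda_het Heterogeneity `<l^2>/<l>^2` (>= 1).
#' @param A Effective persistence, `A < 1`.
#' @return The scale factor `Gamma`.
#' @examples
#' gamma_scale(1, 0.5)  # 3
#' @export
gamma_scale <- function(lambda_het, A) {
  if (any(lambda_het < 1)) stop("lambda_het must be >= 1", call. = FALSE)
  if (any(A >= 1)) {
    stop("Gamma diverges for A >= 1 (asymptotically ballistic motion)",
         call. = FALSE)
  }
  if (any(A < -1)) stop("A must be >= -1", call. = FALSE)
  lambda_het + 2 * A / (1 - A)
}

#' Asymptotic diffusion constant on a filament network
#'
#' For `A < 1` the long-time network dynamics is diffusive,
#' `MSD(n) -> P_m s <l>^2 Gamma(lambda, A) n` per step, and with the physical
#' tick `<l> / v` (one step traverses one segment at the motor speed `v`)
#' the asymptotic diffusion constant is
#' `D_inf = P_m v <l> Gamma(lambda, A) / 4`,
#' with `P_m = kappa_m / (kappa_m + kappa_w)` the stationary motion
#' occupancy. `D_inf` does not depend on the initial state probabilities.
#'
#' @inheritParams msd_network
#' @param v Average motor speed (> 0, physical units; with `v = 1` and
#'   `<l> = 1` the result is in model units per step).
#' @return The diffusion constant `D_inf` (length^2 per time).
#' @examples
#' m <- network_model(transition_rates(0.05, 0.05))  # A = 0
#' asymptotic_diffusion(m, v = 1)                    # <l> v / 8
#' @export
asymptotic_diffusion <- function(model, v = 1) {
  stopifnot(inherits(model, "network_model"))
  if (!is.numeric(v) || length(v) != 1L || v <= 0) {
    stop("v must be a single positive speed", call. = FALSE)
  }
  if (model$A >= 1) {
    stop("D_inf diverges for A = 1: the motion is asymptotically ballistic",
         call. = FALSE)
  }
  s <- motion_stationary(model$rates)
  s * v * model$steps$mean_step *
    gamma_scale(model$steps$lambda_het, model$A) / 4
}
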