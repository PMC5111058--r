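#' Brute-force MSD by enumeration over all state sequences
#'
#' Trust anchor for the analytic engines: the exact MSD at a single step
#' number `n` is computed by summing over all `2^n` motion/wait state
#' sequences, weighting each by its chain probability (marginalised over the
#' initial state) and accumulating the displacement moments directly.
#'
#' For the single filament a sequence with `k` motion steps contributes
#' `<l^2> k + <l>^2 k (k - 1)` (all displacements share one direction). On a
#' network, every motion pair `i < j` carries one persistence factor `A` per
#' motion step in `(i, j]`, so the pair sum is
#' `sum_{i<j, both motion} A^(number of motion steps in (i, j])`.
#'
#' Enumeration is exponential in `n` by construction; `n` is capped (16 for
#' the single filament, 12 for the network) with an explicit error. Sequence
#' probabilities are checked to sum to 1 on every call.
#'
#' @inheritParams msd_single
#' @param n Step number at which to evaluate the MSD.
#' @return The exact MSD at step `n` (a single number).
#' @examples
#' enumerate_msd_single(transition_rates(0.1, 0.001), initial_state(1), n = 2)
#' @export
enumerate_msd_single <- function(rates, init, steps = step_constant(), n) {
  stopifnot(inherits(rates, "transition_rates"),
            inherits(init, "initial_state"),
            inherits(steps, "step_model"))
  n <- check_count(n, "n")
  if (n > 16L) {
    stop("enumeration over 2^n sequences is capped at n = 16", call. = FALSE)
  }
  S <- sequence_matrix(n)
  p <- sequence_probabilities(S, rates, init)
  k <- rowSums(S)
  sum(p * (steps$second_moment * k +
             steps$mean_step^2 * k * (k - 1)))
}

#' @rdname enumerate_msd_single
#' @inheritParams msd_network
#' @export
enumerate_msd_network <- function(model, n) {
  stopifnot(inherits(model, "network_model"))
  n <- check_count(n, "n")
  if (n > 12L) {
    stop("enumeration over 2^n sequences is capped at n = 12", call. = FALSE)
  }
  S <- sequence_matrix(n)
  p <- sequence_probabilities(S, model$rates, model$init)
  k <- rowSums(S)
  A <- model$A
  pair_sum <- numeric(nrow(S))
  if (n >= 2L) {
    cum <- t(apply(S, 1L, cumsum))   # motion count up to each step
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        pair_sum <- pair_sum +
          S[, i] * S[, j] * A^(cum[, j] - cum[, i])
      }
    }
  }
  sum(p * (model$steps$second_moment * k +
             2 * model$steps$mean_step^2 * pair_sum))
}

# all 2^n motion (1) / wait (0) sequences, one row each
sequence_matrix <- function(n) {
  S <- as.matrix(expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE))
  dimnames(S) <- NULL
  S
}

# chain probability of each row of S, marginalised over the initial state;
# states at steps 1..n follow one kernel application each
sequence_probabilities <- function(S, rates, init) {
  kw <- rates$kappa_w
  km <- rates$kappa_m
  q1 <- init$q_m0 * (1 - kw) + init$q_w0 * km   # P(motion at step 1)
  p <- ifelse(S[, 1L] == 1, q1, 1 - q1)
  n <- ncol(S)
  if (n >= 2L) {
    for (t in 2:n) {
      from <- S[, t - 1L]
      to <- S[, t]
      p <- p * ifelse(from == 1,
                      ifelse(to == 1, 1 - kw, kw),
                      ifelse(to == 1, km, 1 - km))
    }
  }
  if (abs(sum(p) - 1) > 1e-12) {
    stop("internal error: sequence probabilities do not sum to 1",
         call. = FALSE)
  }
  p
}

#' Randomised cross-validation of the analytic engines
#'
#' Draw random parameter sets (including the boundary values 0 and 1 of the
#' switching probabilities) and compare both analytic MSD engines against the
#' enumeration oracle at every step up to `n`. Used by the `validate` CLI
#' subcommand and the test suite.
#'
#' @param n Horizon for the comparison (enumeration caps apply).
#' @param sweeps Number of random parameter draws.
#' @param seed Integer seed.
#' @return Invisibly, a list with the maximum absolute deviations
#'   `max_dev_single` and `max_dev_network` over the sweep.
#' @export
validate_engines <- function(n = 8, sweeps = 100, seed = 1) {
  n <- check_count(n, "n")
  sweeps <- check_count(sweeps, "sweeps")
  set.seed(seed)
  draw_prob <- function() {
    # mix interior draws with exact boundary values
    u <- stats::runif(1)
    if (u < 0.1) 0 else if (u < 0.2) 1 else stats::runif(1)
  }
  dev_s <- dev_n <- 0
  for (i in seq_len(sweeps)) {
    rates <- transition_rates(draw_prob(), draw_prob())
    init <- initial_state(draw_prob())
    lam <- 1 + stats::rexp(1)
    steps <- step_custom(stats::runif(1, 0.5, 2), lam)
    A <- stats::runif(1, -1, 1)
    m <- network_model(rates, init, steps, A = A)
    ana_s <- msd_single(rates, init, steps, n)$msd
    ana_n <- msd_network(m, n)$msd
    for (nn in seq_len(n)) {
      dev_s <- max(dev_s, abs(
        ana_s[nn] - enumerate_msd_single(rates, init, steps, nn)))
      dev_n <- max(dev_n, abs(
        ana_n[nn] - enumerate_msd_network(m, nn)))
    }
  }
  invisible(list(max_dev_single = dev_s, max_dev_network = dev_n))
}
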