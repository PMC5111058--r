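#' Running anomalous exponent of an MSD series
#'
#' Local power-law exponent from successive points of a mean squared
#' displacement series,
#' `alpha(n) = (ln MSD(n+1) - ln MSD(n)) / (ln(n+1) - ln n)`.
#' `alpha < 1` is subdiffusive, `alpha = 1` diffusive, `1 < alpha < 2`
#' superdiffusive, `alpha = 2` ballistic; transient ensemble effects can push
#' `alpha` above 2.
#'
#' @param msd A data frame with columns `n` (consecutive positive integers)
#'   and `msd` (positive), e.g. from [msd_single()] or [msd_network()].
#' @return A data frame of class `alpha_series` with columns `n` and `alpha`;
#'   row `n` holds the exponent fitted between steps `n` and `n + 1`.
#' @examples
#' alpha_series(msd_single(transition_rates(0.5, 0.5), initial_state(1),
#'                         n_max = 10))
#' @export
alpha_series <- function(msd) {
  if (!is.data.frame(msd) || !all(c("n", "msd") %in% names(msd))) {
    stop("msd must be a data frame with columns n and msd", call. = FALSE)
  }
  if (nrow(msd) < 2L) {
    stop("need at least two MSD points to fit an exponent", call. = FALSE)
  }
  if (any(diff(msd$n) != 1L)) {
    stop("msd must be given on consecutive integer steps", call. = FALSE)
  }
  if (any(msd$msd <= 0)) {
    stop("msd values must be positive to fit a log-log slope", call. = FALSE)
  }
  alpha <- diff(log(msd$msd)) / diff(log(msd$n))
  structure(
    data.frame(n = msd$n[-nrow(msd)], alpha = alpha),
    class = c("alpha_series", "data.frame")
  )
}

#' Crossover step to the asymptotic dynamics
#'
#' Step `n_c` at which the running exponent settles onto its asymptotic value
#' (2 for unidirectional motion on a single filament, 1 for a network): the
#' deviation `delta_alpha(n) = |alpha(n) - target|` must drop below the
#' threshold `epsilon` and stay there, so `n_c` is one past the last computed
#' step with `delta_alpha >= epsilon` (1 if the deviation is below threshold
#' everywhere). The sustained rule is robust to transient re-crossings such
#' as the super-ballistic overshoot of waiting-start ensembles. If the
#' deviation still exceeds `epsilon` at the end of the computed horizon the
#' result is flagged as not converged and `n_c` is a lower bound.
#'
#' @param alpha An [alpha_series()] data frame.
#' @param target Asymptotic exponent, 1 (network) or 2 (single filament).
#' @param epsilon Positive threshold on `|alpha - target|` (default `1e-2`).
#' @return An object of class `crossover_result`: a list with `n_c`,
#'   `epsilon`, `target_exponent` and `converged`.
#' @examples
#' msd <- msd_single(transition_rates(0.5, 0.5), initial_state(1),
#'                   n_max = 200)
#' crossover_time(alpha_series(msd), target = 2)  # n_c = 99
#' @export
crossover_time <- function(alpha, target = c(2, 1), epsilon = 1e-2) {
  if (!is.data.frame(alpha) || !all(c("n", "alpha") %in% names(alpha)) ||
      nrow(alpha) == 0L) {
    stop("alpha must be a non-empty data frame with columns n and alpha",
         call. = FALSE)
  }
  target <- target[1]
  if (!target %in% c(1, 2)) {
    stop("target must be 1 (diffusive) or 2 (ballistic)", call. = FALSE)
  }
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    stop("epsilon must be a single positive number", call. = FALSE)
  }
  da <- abs(alpha$alpha - target)
  bad <- which(da >= epsilon)
  n_c <- if (length(bad) == 0L) 1L else alpha$n[max(bad)] + 1L
  structure(
    list(n_c = as.integer(n_c), epsilon = epsilon,
         target_exponent = target,
         converged = da[length(da)] < epsilon),
    class = "crossover_result"
  )
}

#' @export
print.crossover_result <- function(x, ...) {
  cat(sprintf(
    "Crossover to alpha = %g (epsilon = %g): n_c = %d%s\n",
    x$target_exponent, x$epsilon, x$n_c,
    if (x$converged) "" else " (not converged within horizon; lower bound)"
  ))
  invisible(x)
}

#' Classify diffusive regimes along an exponent series
#'
#' Partition the step axis into maximal runs of constant transport regime:
#' `subdiffusive` (`alpha < 1 - tol`), `diffusive` (`|alpha - 1| <= tol`),
#' `superdiffusive` (`1 + tol < alpha < 2 - tol`), `ballistic`
#' (`|alpha - 2| <= tol`) and `super-ballistic` (`alpha > 2 + tol`).
#'
#' @inheritParams crossover_time
#' @param tol Positive half-width of the bands around 1 and 2.
#' @return A data frame with columns `n_start`, `n_end` and `label`, one row
#'   per maximal run.
#' @examples
#' msd <- msd_single(transition_rates(0.1, 0.001), initial_state(1),
#'                   n_max = 5000)
#' classify_regimes(alpha_series(msd))
#' @export
classify_regimes <- function(alpha, tol = 0.05) {
  if (!is.data.frame(alpha) || !all(c("n", "alpha") %in% names(alpha))) {
    stop("alpha must be a data frame with columns n and alpha", call. = FALSE)
  }
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0) {
    stop("tol must be a single positive number", call. = FALSE)
  }
  a <- alpha$alpha
  lab <- ifelse(a < 1 - tol, "subdiffusive",
         ifelse(a <= 1 + tol, "diffusive",
         ifelse(a < 2 - tol, "superdiffusive",
         ifelse(a <= 2 + tol, "ballistic", "super-ballistic"))))
  runs <- rle(lab)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  data.frame(
    n_start = alpha$n[starts],
    n_end = alpha$n[ends],
    label = runs$values,
    stringsAsFactors = FALSE
  )
}
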