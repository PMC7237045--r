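#' Saturating transfer function and its derivative
#'
#' `transfer()` maps membrane potential to firing rate,
#' `g(x) = 0.5 (1 + tanh(x - bias))`, strictly increasing with range (0, 1).
#' `transfer_deriv()` is its derivative `0.5 (1 - tanh(x - bias)^2)`.
#'
#' @param x membrane potential(s).
#' @param bias transfer bias `b` (default 2, giving spontaneous rates of
#'   about 0.018 at `x = 0`).
#' @return numeric vector of rates (or slopes).
#' @export
transfer <- function(x, bias = 2) 0.5 * (1 + tanh(x - bias))

#' @rdname transfer
#' @export
transfer_deriv <- function(x, bias = 2) 0.5 * (1 - tanh(x - bias)^2)

#' Zero-input fixed point of the network dynamics
#'
#' Solves `x = W g(x)` (the steady state of the rate equation with no
#' stimulus) by fixed-point iteration, which contracts because the linearized
#' network has spectral radius well below 1 for the parameter regimes used
#' here; falls back to damped (Euler) evolution of the dynamics if plain
#' iteration fails to contract.
#'
#' @param network an `ei_network`.
#' @param tol convergence tolerance on the max-norm residual.
#' @param max_iter iteration budget.
#' @return numeric membrane vector `x0` with attribute `"residual"`.
#' @export
find_fixed_point <- function(network, tol = 1e-12, max_iter = 500L) {
  stopifnot(inherits(network, "ei_network"))
  W <- network$weights
  b <- network$spec$bias
  x <- numeric(nrow(W))
  step <- 1
  for (i in seq_len(max_iter)) {
    x_new <- as.vector(W %*% transfer(x, b))
    d <- max(abs(x_new - x))
    x <- x + step * (x_new - x)
    if (d < tol) break
    if (i == 50L && d > 1) step <- 0.2  # damp if not contracting
  }
  res <- max(abs(as.vector(W %*% transfer(x, b)) - x))
  if (res > tol * 10) {
    stop("fixed-point iteration did not converge (residual ",
         format(res), ")", call. = FALSE)
  }
  attr(x, "residual") <- res
  x
}

#' Simulate network responses to a trial set
#'
#' Forward-Euler integration of
#' `tau dx/dt = W g(x) + c i(t) - x`
#' for every trial, starting from the zero-input fixed point. The recurrent
#' drive of all trials is computed as one matrix product per time step, and
#' firing rates are averaged on the fly into `bins` equal time windows
#' (1-tau windows by default, the resolution used by all analyses). Use
#' `bins = duration / dt` to record every integration step.
#'
#' @param network an `ei_network`.
#' @param trials a [trial_set()].
#' @param dt integration step in tau (must subdivide the trial into `bins`
#'   equal windows).
#' @param bins number of recording windows per trial.
#' @param x_init initial membrane vector; defaults to the zero-input fixed
#'   point.
#' @return an object of class `rate_activity`: list with `rates` (array
#'   neurons x bins x trials, values in (0, 1)), `labels`, `bin_width`, `dt`,
#'   `x_final`, and the generating `trials` tibble (pulse lists included).
#' @export
simulate_network <- function(network, trials, dt = 0.01, bins = 50L,
                             x_init = NULL) {
  stopifnot(inherits(network, "ei_network"), inherits(trials, "trial_set"))
  duration <- attr(trials, "duration")
  filter_a <- attr(trials, "filter_a")
  n_steps <- round(duration / dt)
  if (abs(n_steps * dt - duration) > 1e-9 || n_steps %% bins != 0) {
    stop("`dt` must divide the trial into `bins` equal windows", call. = FALSE)
  }
  if (is.null(x_init)) x_init <- find_fixed_point(network)
  times <- seq(0, duration - dt, by = dt)
  curr <- currents_matrix(trials$pulses, times, dt, filter_a, trials$alpha)
  sim <- .sim_rate_network_cpp(network$weights,
                               as.numeric(network$input_mask), curr, x_init,
                               network$spec$bias, dt, as.integer(bins))
  structure(
    list(rates = sim$rates, x_final = sim$x_final, labels = trials$label,
         bin_width = duration / bins, dt = dt, duration = duration,
         is_exc = network$is_exc, input_mask = network$input_mask,
         downsampled = bins < n_steps, trials = trials),
    class = "rate_activity"
  )
}

#' @export
print.rate_activity <- function(x, ...) {
  d <- dim(x$rates)
  cat("<rate_activity> ", d[3], " trials x ", d[1], " neurons x ", d[2],
      " bins of ", x$bin_width, " tau\n", sep = "")
  invisible(x)
}

#' Average an activity tensor over coarser time windows
#'
#' Non-overlapping window means along the time axis; with
#' `window = duration` each trial collapses to its time-averaged response.
#'
#' @param activity a `rate_activity`.
#' @param window new window width in tau (multiple of the current
#'   `bin_width`).
#' @return a `rate_activity` with fewer, wider bins.
#' @export
downsample_activity <- function(activity, window = 1) {
  stopifnot(inherits(activity, "rate_activity"))
  fac <- window / activity$bin_width
  if (abs(fac - round(fac)) > 1e-9) {
    stop("`window` must be a multiple of the current bin width", call. = FALSE)
  }
  fac <- round(fac)
  d <- dim(activity$rates)
  if (d[2] %% fac != 0) {
    stop("`window` must divide the trial length", call. = FALSE)
  }
  new_bins <- d[2] / fac
  r <- array(activity$rates, c(d[1], fac, new_bins, d[3]))
  activity$rates <- colMeans(aperm(r, c(2, 1, 3, 4)))
  activity$bin_width <- window
  activity$downsampled <- TRUE
  activity
}

# reference integrator: plain R, double precision, exact tanh; used as the
# independent oracle for the C++ core and for convergence checks
euler_reference <- function(network, trials, dt = 0.01, x_init = NULL) {
  duration <- attr(trials, "duration")
  filter_a <- attr(trials, "filter_a")
  n_steps <- round(duration / dt)
  if (is.null(x_init)) x_init <- find_fixed_point(network)
  times <- seq(0, duration - dt, by = dt)
  curr <- currents_matrix(trials$pulses, times, dt, filter_a, trials$alpha)
  W <- network$weights
  b <- network$spec$bias
  cm <- as.numeric(network$input_mask)
  n <- nrow(W)
  B <- nrow(trials)
  rates <- array(NA_real_, c(n, n_steps, B))
  X <- matrix(x_init, n, B)
  for (t in seq_len(n_steps)) {
    G <- transfer(X, b)
    rates[, t, ] <- G
    X <- X + dt * (W %*% G + outer(cm, curr[t, ]) - X)
  }
  list(rates = rates, x_final = X)
}
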