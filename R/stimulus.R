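#' Draw irregular pulse trains
#'
#' Each trial receives exactly `n_pulses` pulse times, drawn uniformly
#' without replacement from the discrete time grid with spacing `precision`
#' over `(0, duration]`. A trial of 8 pulses over the standard 50-tau window
#' corresponds to an average pulse frequency of 0.16 per tau (8 Hz with an
#' effective tau of 20 ms); the pulse count per trial is fixed, not Poisson.
#'
#' @param n_trials number of trials to draw.
#' @param n_pulses pulses per trial (may be 0).
#' @param duration stimulus duration in units of tau.
#' @param precision pulse-time grid spacing in tau.
#' @param seed integer seed.
#' @return a list of `n_trials` sorted numeric vectors of pulse times.
#' @export
draw_pulse_times <- function(n_trials, n_pulses, duration = 50,
                             precision = 0.01, seed) {
  grid_n <- round(duration / precision)
  if (n_pulses < 0) stop("`n_pulses` must be non-negative", call. = FALSE)
  if (n_pulses > grid_n) {
    stop("`n_pulses` exceeds the ", grid_n, " grid points of the stimulus ",
         "window", call. = FALSE)
  }
  local_seed(derive_seed(seed, 211), {
    lapply(seq_len(n_trials), function(i) {
      sort(sample.int(grid_n, n_pulses)) * precision
    })
  })
}

#' Filtered input current of a pulse train
#'
#' Pulses are filtered by upstream processing into alpha-function-like bumps:
#' `i(t) = alpha * sum_{t_k < t} ((t - t_k)^2 / a^2) exp(-(t - t_k) / a)`.
#' With the standard `filter_a = 0.5` a single pulse peaks at `4 exp(-2)`
#' at lag `2 a` and has a full width at half maximum of about 1.7 tau. The
#' current is linear in `alpha` and additive over pulses.
#'
#' @param pulse_times numeric vector of pulse times (tau units).
#' @param times strictly increasing evaluation grid.
#' @param filter_a filter time constant `a` (positive).
#' @param alpha amplitude scale.
#' @return numeric vector of current values, one per element of `times`.
#' @export
input_current <- function(pulse_times, times, filter_a = 0.5, alpha = 1) {
  if (filter_a <= 0) stop("`filter_a` must be positive", call. = FALSE)
  out <- numeric(length(times))
  for (tk in pulse_times) {
    s <- times - tk
    pos <- s > 0
    out[pos] <- out[pos] + (s[pos]^2 / filter_a^2) * exp(-s[pos] / filter_a)
  }
  alpha * out
}

# currents for many trials on the regular integration grid; pulse times are
# assumed to lie on multiples of dt. O(n_pulses * kernel_support) per trial.
currents_matrix <- function(pulses, times, dt, filter_a, alphas) {
  n_steps <- length(times)
  # kernel on lags dt, 2 dt, ...; support truncated where it falls below 1e-12
  lag <- seq_len(n_steps) * dt
  kern <- (lag^2 / filter_a^2) * exp(-lag / filter_a)
  keep <- max(which(kern > 1e-12 * max(kern)))
  kern <- kern[seq_len(keep)]
  out <- matrix(0, n_steps, length(pulses))
  t0 <- times[1]
  for (j in seq_along(pulses)) {
    col <- numeric(n_steps)
    for (tk in pulses[[j]]) {
      # first grid index strictly after tk
      i0 <- floor((tk - t0) / dt + 1 + 1e-9) + 1
      if (i0 > n_steps) next
      i1 <- min(n_steps, i0 + keep - 1)
      ks <- round((times[i0] - tk) / dt)
      col[i0:i1] <- col[i0:i1] + kern[ks:(ks + (i1 - i0))]
    }
    out[, j] <- col * alphas[j]
  }
  out
}

#' Build a two-category trial set
#'
#' Draws `n_trials_per` pulse trains for each of the two pulse counts and
#' attaches the per-category input amplitudes.
#'
#' @param n_trials_per trials per category.
#' @param n_pulses length-2 vector of pulses per trial for the (low, high)
#'   frequency categories.
#' @param alphas length-2 vector of input amplitudes for (low, high); use
#'   [calibrate_amplitudes()] to equalize mean network rates.
#' @param duration,precision,filter_a stimulus parameters, see
#'   [draw_pulse_times()] and [input_current()].
#' @param seed integer seed.
#' @return a tibble of class `trial_set` with columns `trial`, `label`
#'   (factor low/high), `n_pulses`, `alpha` and the list-column `pulses`.
#' @export
trial_set <- function(n_trials_per, n_pulses = c(8, 16), alphas = c(1, 1),
                      duration = 50, precision = 0.01, filter_a = 0.5, seed) {
  stopifnot(length(n_pulses) == 2, length(alphas) == 2)
  if (any(alphas <= 0)) stop("`alphas` must be positive", call. = FALSE)
  p_low <- draw_pulse_times(n_trials_per, n_pulses[1], duration, precision,
                            seed = derive_seed(seed, 1))
  p_high <- draw_pulse_times(n_trials_per, n_pulses[2], duration, precision,
                             seed = derive_seed(seed, 2))
  out <- tibble::tibble(
    trial = seq_len(2 * n_trials_per),
    label = factor(rep(c("low", "high"), each = n_trials_per),
                   levels = c("low", "high")),
    n_pulses = rep(n_pulses, each = n_trials_per),
    alpha = rep(alphas, each = n_trials_per),
    pulses = c(p_low, p_high)
  )
  attr(out, "duration") <- duration
  attr(out, "precision") <- precision
  attr(out, "filter_a") <- filter_a
  class(out) <- c("trial_set", class(out))
  out
}

#' Calibrate input amplitudes to an iso-firing-rate contour
#'
#' Simulates a grid of (pulse frequency, amplitude) combinations, computes
#' the time- and neuron-averaged network firing rate for each, interpolates
#' the rate surface with splines, and reads the amplitudes for the requested
#' frequencies off an iso-rate contour. The contour used is the highest-rate
#' level (on a ladder with spacing `level_step`) whose contour is defined,
#' within the calibrated amplitude range, over the whole frequency span the
#' task needs. This equalizes mean network activity across the two stimulus
#' categories, so that overall rate carries no category information.
#'
#' @param network an `ei_network`.
#' @param n_pulses length-2 vector of per-trial pulse counts for the (low,
#'   high) categories, e.g. `c(8, 16)`.
#' @param grid_freqs pulse frequencies (per tau) of the calibration grid.
#' @param grid_alphas amplitudes of the calibration grid (geometrically
#'   spaced over the standard 0.3-15 range by default).
#' @param trials_per_point simulated trials per grid point. The mean-rate
#'   statistic averages all neurons and time bins, so its per-trial standard
#'   error is well under 1% of the dynamic range; 10 trials stabilize the
#'   surface far below the network-to-network variability of the contour.
#' @param duration,precision,filter_a stimulus parameters.
#' @param dt integration step.
#' @param level_step spacing of the candidate contour ladder (rate units).
#' @param refine_iter validation-refinement steps: each step simulates a
#'   small batch of trials at the current amplitudes and Newton-corrects
#'   them toward the contour level, guarding against interpolation error
#'   near the saturating part of the rate surface. 0 disables refinement.
#' @param span_freqs frequency span (per tau) over which the contour must
#'   be defined, regardless of the requested pair: the standard rule spans
#'   low frequencies 0.14-0.2 together with their doubled partners, so
#'   every task run on a network uses the same contour level and hence the
#'   same mean firing rate.
#' @param seed integer seed.
#' @return an object of class `amplitude_calibration`: list with the grid
#'   tibble (`freq`, `alpha`, `mean_rate`), the chosen contour `level`, a
#'   tibble `alphas` (`freq`, `n_pulses`, `alpha`) and the low/high `ratio`.
#' @export
calibrate_amplitudes <- function(network, n_pulses = c(8, 16),
                                 grid_freqs = seq(0.1, 0.5, length.out = 5),
                                 grid_alphas = exp(seq(log(0.3), log(15),
                                                       length.out = 5)),
                                 trials_per_point = 10, duration = 50,
                                 precision = 0.01, filter_a = 0.5, dt = 0.01,
                                 level_step = 0.01, refine_iter = 3,
                                 span_freqs = c(0.14, 0.4), seed = 1) {
  stopifnot(inherits(network, "ei_network"), length(n_pulses) == 2)
  freqs_req <- sort(n_pulses) / duration
  if (min(freqs_req) < min(grid_freqs) || max(freqs_req) > max(grid_freqs)) {
    stop("requested frequencies fall outside the calibration grid",
         call. = FALSE)
  }
  x0 <- find_fixed_point(network)
  times <- seq(0, duration - dt, by = dt)
  grid <- tidyr::expand_grid(freq = grid_freqs, alpha = grid_alphas)

  # one pulse-train draw per grid frequency, shared across amplitudes (the
  # current is linear in alpha), all simulated as a single batch
  pulse_sets <- lapply(seq_along(grid_freqs), function(i) {
    draw_pulse_times(trials_per_point, round(grid_freqs[i] * duration),
                     duration, precision, seed = derive_seed(seed, 301, i))
  })
  pulses_all <- list()
  alphas_all <- numeric(0)
  for (r in seq_len(nrow(grid))) {
    fi <- match(grid$freq[r], grid_freqs)
    pulses_all <- c(pulses_all, pulse_sets[[fi]])
    alphas_all <- c(alphas_all, rep(grid$alpha[r], trials_per_point))
  }
  curr <- currents_matrix(pulses_all, times, dt, filter_a, alphas_all)
  sim <- .sim_rate_network_cpp(network$weights, as.numeric(network$input_mask),
                               curr, x0, network$spec$bias, dt, bins = 50L)
  point <- rep(seq_len(nrow(grid)), each = trials_per_point)
  rate_by_trial <- apply(sim$rates, 3, mean)
  grid$mean_rate <- as.numeric(tapply(rate_by_trial, point, mean))

  # per grid frequency, a monotone spline mapping amplitude -> mean rate,
  # inverted by root finding
  inverters <- lapply(grid_freqs, function(f) {
    g <- grid[grid$freq == f, ]
    y <- g$mean_rate
    fun <- if (!is.unsorted(y)) {
      splinefun(g$alpha, y, method = "hyman")
    } else {
      splinefun(g$alpha, y, method = "natural")
    }
    list(fun = fun, ymin = min(y), ymax = max(y), arange = range(g$alpha))
  })
  invert <- function(fi, level) {
    iv <- inverters[[fi]]
    if (level < iv$ymin || level > iv$ymax) return(NA_real_)
    root <- tryCatch(
      uniroot(function(a) iv$fun(a) - level, interval = iv$arange,
              tol = 1e-8)$root,
      error = function(e) NA_real_)
    root
  }

  # grid frequencies needed to support the contour across the rule's fixed
  # span (not just the requested pair): every task of a network uses the
  # same contour, so its level must not depend on which pair is requested
  span <- c(min(span_freqs[1], freqs_req[1]),
            max(span_freqs[2], freqs_req[2]))
  lo_i <- max(which(grid_freqs <= span[1] + 1e-12))
  hi_i <- min(which(grid_freqs >= span[2] - 1e-12))
  need <- lo_i:hi_i
  levels_cand <- seq(min(grid$mean_rate), max(grid$mean_rate), by = level_step)
  feasible <- function(level) {
    a <- vapply(need, invert, numeric(1), level = level)
    if (anyNA(a)) NULL else a
  }
  chosen <- NULL
  for (lv in rev(levels_cand)) {
    a <- feasible(lv)
    if (!is.null(a)) { chosen <- list(level = lv, alpha = a); break }
  }
  if (is.null(chosen)) {
    stop("no iso-rate contour spans the requested frequency range; ",
         "widen the calibration grid", call. = FALSE)
  }
  af <- if (length(need) == 1) {
    function(f) rep(chosen$alpha, length(f))
  } else if (length(need) >= 3) {
    splinefun(grid_freqs[need], chosen$alpha, method = "natural")
  } else {
    function(f) stats::approx(grid_freqs[need], chosen$alpha, xout = f)$y
  }
  alpha_req <- af(freqs_req)
  alpha_req <- pmin(pmax(alpha_req, min(grid_alphas)), max(grid_alphas))

  # refine each amplitude against short validation simulations: the 5x5
  # spline can misplace the contour near the saturating top of the surface,
  # so take up to `refine_iter` Newton-type steps on the actual simulated
  # rate, using the local log-log slope of the interpolated surface
  if (refine_iter > 0) {
    np_req <- sort(n_pulses)
    equal_freqs <- freqs_req[1] == freqs_req[2]
    hist_la <- list(numeric(0), numeric(0))  # log alpha iterates per side
    hist_lr <- list(numeric(0), numeric(0))  # log rate iterates per side
    for (k in seq_len(refine_iter)) {
      # escalating validation batches: a trial's mean network rate varies
      # 10-16% trial to trial, so the final correction needs ~100 trials
      # per category to pin the category means to ~1.5%
      n_val <- trials_per_point * if (k == refine_iter) 20L else 2L
      val_pulses <- list(); val_alphas <- numeric(0)
      for (j in 1:2) {
        ps <- draw_pulse_times(n_val, np_req[j], duration,
                               precision, seed = derive_seed(seed, 302, k, j))
        val_pulses <- c(val_pulses, ps)
        val_alphas <- c(val_alphas, rep(alpha_req[j], n_val))
      }
      vcurr <- currents_matrix(val_pulses, times, dt, filter_a, val_alphas)
      vsim <- .sim_rate_network_cpp(network$weights,
                                    as.numeric(network$input_mask), vcurr,
                                    x0, network$spec$bias, dt, bins = 50L)
      vr <- apply(vsim$rates, 3, mean)
      grp <- rep(1:2, each = n_val)
      r_hat <- as.numeric(tapply(vr, grp, mean))
      for (j in 1:2) {
        la0 <- log(alpha_req[j])
        lr0 <- log(max(r_hat[j], 1e-8))
        # local elasticity d log(rate) / d log(alpha): secant through the
        # measured iterates once available, else the (damped) spline slope
        eta <- NA_real_
        damp <- 1
        if (length(hist_la[[j]])) {
          dla <- la0 - hist_la[[j]][length(hist_la[[j]])]
          dlr <- lr0 - hist_lr[[j]][length(hist_lr[[j]])]
          if (abs(dla) > 1e-6 && dlr / dla > 0.05) eta <- dlr / dla
        }
        if (is.na(eta)) {
          fi <- which.min(abs(grid_freqs - freqs_req[j]))
          iv <- inverters[[fi]]
          a0 <- alpha_req[j]
          eta <- (log(max(iv$fun(a0 * 1.1), 1e-8)) -
                    log(max(iv$fun(a0 / 1.1), 1e-8))) / (2 * log(1.1))
          damp <- 0.7  # spline slopes over-steer near saturation
        }
        eta <- min(max(eta, 0.2), 3)
        hist_la[[j]] <- c(hist_la[[j]], la0)
        hist_lr[[j]] <- c(hist_lr[[j]], lr0)
        alpha_req[j] <- exp(la0 + damp * (log(chosen$level) - lr0) / eta)
      }
      if (equal_freqs) alpha_req[2] <- alpha_req[1]
    }
  }
  out <- list(
    grid = grid,
    level = chosen$level,
    contour = tibble::tibble(freq = grid_freqs[need], alpha = chosen$alpha),
    alphas = tibble::tibble(freq = freqs_req,
                            n_pulses = sort(n_pulses),
                            alpha = alpha_req),
    ratio = alpha_req[1] / alpha_req[2],
    seed = seed
  )
  class(out) <- "amplitude_calibration"
  out
}

#' @export
print.amplitude_calibration <- function(x, ...) {
  cat("<amplitude_calibration> contour level ", round(x$level, 4),
      "; alpha(", paste(round(x$alphas$freq, 3), collapse = ", "), ") = (",
      paste(round(x$alphas$alpha, 3), collapse = ", "), "), ratio ",
      round(x$ratio, 3), "\n", sep = "")
  invisible(x)
}

#' @describeIn calibrate_amplitudes the simulated calibration grid as a tibble.
#' @param x an `amplitude_calibration`.
#' @param ... unused.
#' @export
tidy.amplitude_calibration <- function(x, ...) x$grid

#' @describeIn calibrate_amplitudes one-row summary (level, alphas, ratio).
#' @export
glance.amplitude_calibration <- function(x, ...) {
  tibble::tibble(
    level = x$level,
    alpha_low = x$alphas$alpha[1],
    alpha_high = x$alphas$alpha[2],
    ratio = x$ratio
  )
}
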