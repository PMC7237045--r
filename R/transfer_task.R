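#' Selectivity transfer between two discrimination tasks
#'
#' Runs the full calibrate-simulate-selectivity pipeline on the same network
#' for two frequency pairs (by default 8 vs 16 Hz and 10 vs 20 Hz, i.e.
#' pulse counts (8, 16) and (10, 20) over the 50-tau trial), cross-tabulates
#' the shuffle-significance status of every neuron across tasks, and reports
#' the fraction of neurons whose status changed in either direction. Input
#' amplitudes are recalibrated independently for each pair. Both tasks are
#' simulated with fresh trial draws.
#'
#' @param network an `ei_network`.
#' @param n_pulses_1,n_pulses_2 pulse-count pairs of the two tasks.
#' @param n_trials_per trials per category per task.
#' @param n_shuffles label permutations for significance bounds.
#' @param seed integer seed.
#' @param task1 optionally, a precomputed task-1 result: a list with
#'   elements `selectivity` (a `selectivity_table`) and `calibration`, e.g.
#'   from a previous [analyze_network()] run with the same network and seed
#'   stream; task 1 is then not re-simulated.
#' @param ... further arguments passed to [calibrate_amplitudes()].
#' @return an object of class `transfer_report`: list with `neurons` tibble
#'   (`neuron`, `type`, `auc_1`, `auc_2`, `sig_1`, `sig_2`, `changed`),
#'   `crosstab` (2x2 matrix, task-1 status x task-2 status),
#'   `fraction_changed`, and the two calibrations.
#' @export
run_task_transfer <- function(network, n_pulses_1 = c(8, 16),
                              n_pulses_2 = c(10, 20), n_trials_per = 400,
                              n_shuffles = 1000, seed = 1, task1 = NULL,
                              ...) {
  stopifnot(inherits(network, "ei_network"))
  run_one <- function(n_pulses, k) {
    cal <- calibrate_amplitudes(network, n_pulses = n_pulses,
                                seed = derive_seed(seed, 601, k), ...)
    tr <- trial_set(n_trials_per, n_pulses = n_pulses,
                    alphas = cal$alphas$alpha,
                    seed = derive_seed(seed, 602, k))
    act <- simulate_network(network, tr)
    sel <- compute_selectivity(act, n_shuffles = n_shuffles,
                               seed = derive_seed(seed, 603, k))
    list(selectivity = sel, calibration = cal)
  }
  t1 <- if (!is.null(task1)) task1 else run_one(n_pulses_1, 1)
  t2 <- run_one(n_pulses_2, 2)
  s1 <- t1$selectivity
  s2 <- t2$selectivity
  neurons <- tibble::tibble(
    neuron = s1$neuron, type = s1$type,
    auc_1 = s1$auc, auc_2 = s2$auc,
    sig_1 = s1$significant, sig_2 = s2$significant,
    changed = s1$significant != s2$significant
  )
  crosstab <- table(
    task1 = factor(ifelse(s1$significant, "selective", "non-selective"),
                   levels = c("selective", "non-selective")),
    task2 = factor(ifelse(s2$significant, "selective", "non-selective"),
                   levels = c("selective", "non-selective"))
  )
  structure(
    list(neurons = neurons, crosstab = unclass(crosstab),
         fraction_changed = mean(neurons$changed),
         calibration_1 = t1$calibration, calibration_2 = t2$calibration,
         n_pulses_1 = n_pulses_1, n_pulses_2 = n_pulses_2),
    class = "transfer_report"
  )
}

#' @export
print.transfer_report <- function(x, ...) {
  cat("<transfer_report> tasks (", paste(x$n_pulses_1, collapse = ","),
      ") vs (", paste(x$n_pulses_2, collapse = ","), ") pulses: ",
      round(100 * x$fraction_changed, 1),
      "% of neurons changed selectivity status\n", sep = "")
  print(x$crosstab)
  invisible(x)
}

#' @describeIn run_task_transfer per-neuron AUC/significance for both tasks.
#' @param x a `transfer_report`.
#' @param ... unused.
#' @export
tidy.transfer_report <- function(x, ...) x$neurons

#' @describeIn run_task_transfer one-row summary with the crosstab counts.
#' @export
glance.transfer_report <- function(x, ...) {
  ct <- x$crosstab
  tibble::tibble(
    fraction_changed = x$fraction_changed,
    n_both = ct["selective", "selective"],
    n_gained = ct["non-selective", "selective"],
    n_lost = ct["selective", "non-selective"],
    n_neither = ct["non-selective", "non-selective"]
  )
}
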