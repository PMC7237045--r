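#' Z-score activity with stored statistics
#'
#' `zscore_fit()` standardizes each column (neuron) of a trials x neurons
#' matrix to mean 0 and sample SD 1 and stores the training statistics;
#' `zscore_apply()` reuses those statistics on new data, as required when
#' transforming test trials. Constant columns are flagged (SD set to `NA`)
#' and their z-scores are 0.
#'
#' @param x trials x neurons activity matrix.
#' @return for `zscore_fit()`, a list with `z`, `mean`, `sd`, `constant`.
#' @export
zscore_fit <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sdv <- sqrt(pmax(colSums(x^2) - n * mu^2, 0) / (n - 1))
  constant <- is.na(sdv) | sdv <= 1e-9 * pmax(abs(mu), 1)
  sdv[constant] <- NA_real_
  z <- sweep(x, 2, mu)
  z <- sweep(z, 2, ifelse(constant, 1, sdv), `/`)
  z[, constant] <- 0
  list(z = z, mean = mu, sd = sdv, constant = constant)
}

#' @rdname zscore_fit
#' @param stats a `zscore_fit()` result.
#' @export
zscore_apply <- function(x, stats) {
  z <- sweep(x, 2, stats$mean)
  z <- sweep(z, 2, ifelse(stats$constant, 1, stats$sd), `/`)
  z[, stats$constant] <- 0
  z
}

# fit a linear maximum-margin rule xi . z > eta <=> "high" on standardized
# activity; returns the primal weights with the sign convention fixed so
# that positive decision values mean the high-frequency category
fit_margin_rule <- function(z, labels, cost = 1) {
  y <- factor(labels, levels = c("low", "high"))
  if (length(unique(y)) < 2) {
    stop("training set contains a single class", call. = FALSE)
  }
  m <- e1071::svm(x = z, y = y, kernel = "linear", cost = cost,
                  scale = FALSE, type = "C-classification")
  xi <- drop(t(m$coefs) %*% m$SV)
  eta <- m$rho
  # e1071's decision value is positive for the first factor level present in
  # the training data; orient the rule toward "high"
  dv <- drop(z %*% xi) - eta
  pred_high <- predict(m, z) == "high"
  agree <- mean((dv > 0) == pred_high)
  if (agree < 0.5) {
    xi <- -xi
    eta <- -eta
  }
  list(xi = xi, eta = eta, model = m)
}

#' Convert a z-scored decision rule to raw firing rates
#'
#' Given a rule `xi . z > eta` on standardized activity with stored per-
#' neuron statistics (mean, sd), returns the equivalent rule `w . r > b` on
#' raw rates: `w_i = xi_i / sd_i` and `b = eta + sum_i xi_i mean_i / sd_i`.
#' The two rules classify every trial identically.
#'
#' @param xi,eta z-space weights and threshold.
#' @param mean,sd per-neuron training statistics.
#' @return list with `w` and `b`.
#' @export
raw_weight_conversion <- function(xi, eta, mean, sd) {
  sd_ <- ifelse(is.na(sd), Inf, sd)
  w <- xi / sd_
  b <- eta + sum((xi * mean / sd_)[is.finite(sd_)])
  list(w = w, b = b)
}

#' Linear readout of stimulus category from population activity
#'
#' Trains linear support-vector classifiers to predict the stimulus category
#' from z-scored single-time-bin population activity. Neurons that receive
#' direct stimulus input are always excluded. The classifier is fit at a
#' single time bin (the last bin of the stimulus window by default) on a
#' stratified half of the trials and evaluated at every time bin on the
#' reserved half; the whole procedure is repeated over `n_splits` random
#' splits, and the headline accuracy is the mean over the bins of
#' `eval_window`.
#'
#' @param activity a `rate_activity` (1-tau bins).
#' @param group which neurons feed the classifier: `"all"` non-input
#'   neurons, `"exc_sub"` a fixed random subset of `n_members` non-input
#'   excitatory neurons, or `"inh"` all inhibitory neurons.
#' @param exclude_input drop neurons that receive direct stimulus input.
#'   Defaults to `TRUE` unless every excitatory neuron is input-receiving
#'   (the all-E-input variant), where exclusion would leave no excitatory
#'   readout population and is therefore disabled.
#' @param n_splits number of random train/test splits.
#' @param n_members size of the excitatory subset for `group = "exc_sub"`.
#' @param fit_bin index of the time bin used for fitting (default: last).
#' @param eval_window time span (tau) over which test accuracy is averaged
#'   for the headline number (default: last half of the stimulus).
#' @param cost SVM regularization constant.
#' @param seed integer seed (splits and subset draw).
#' @param accuracy_curve `"full"` evaluates test accuracy at every time bin
#'   (for accuracy-over-time plots); `"eval"` only at the bins of
#'   `eval_window`, which is all the headline accuracy needs.
#' @return an object of class `population_decoder`; see [glance()] and
#'   [tidy()] methods. Key elements: `accuracy` (mean over splits, %),
#'   `accuracy_sd`, `accuracy_by_time` tibble, `weights` tibble of mean
#'   z-space and raw-space weights per neuron, `members`.
#' @export
fit_population_decoder <- function(activity,
                                   group = c("all", "exc_sub", "inh"),
                                   n_splits = 50, n_members = 100,
                                   fit_bin = NULL, eval_window = c(25, 50),
                                   cost = 1, seed = 1, exclude_input = NULL,
                                   accuracy_curve = c("full", "eval")) {
  stopifnot(inherits(activity, "rate_activity"))
  group <- match.arg(group)
  accuracy_curve <- match.arg(accuracy_curve)
  d <- dim(activity$rates)
  n_bins <- d[2]
  if (is.null(fit_bin)) fit_bin <- n_bins
  labels <- activity$labels
  if (is.null(exclude_input)) {
    exclude_input <- !all(activity$input_mask[activity$is_exc])
  }
  eligible <- if (exclude_input) which(!activity$input_mask) else
    seq_along(activity$input_mask)
  members <- switch(group,
    all = eligible,
    inh = which(!activity$is_exc),
    exc_sub = local_seed(derive_seed(seed, 501), {
      pool <- intersect(eligible, which(activity$is_exc))
      sort(sample(pool, min(n_members, length(pool))))
    })
  )
  bw <- activity$bin_width
  eval_bins <- which((seq_len(n_bins) * bw) > eval_window[1] &
                       (seq_len(n_bins) * bw) <= eval_window[2] + 1e-9)
  # per-bin trials x members matrices
  A <- lapply(seq_len(n_bins), function(b) t(activity$rates[members, b, ]))
  i_low <- which(labels == "low")
  i_high <- which(labels == "high")
  n_half <- c(floor(length(i_low) / 2), floor(length(i_high) / 2))

  acc_time <- matrix(NA_real_, n_splits, n_bins)
  acc_split <- numeric(n_splits)
  xi_all <- matrix(0, length(members), n_splits)
  w_all <- matrix(0, length(members), n_splits)
  b_all <- numeric(n_splits)
  for (s in seq_len(n_splits)) {
    tr <- local_seed(derive_seed(seed, 502, s), {
      c(sample(i_low, n_half[1]), sample(i_high, n_half[2]))
    })
    te <- setdiff(seq_along(labels), tr)
    zs <- zscore_fit(A[[fit_bin]][tr, , drop = FALSE])
    fit <- fit_margin_rule(zs$z, labels[tr], cost = cost)
    raw <- raw_weight_conversion(fit$xi, fit$eta, zs$mean, zs$sd)
    xi_all[, s] <- fit$xi
    w_all[, s] <- raw$w
    b_all[s] <- raw$b
    y_te <- labels[te] == "high"
    bins_to_eval <- if (accuracy_curve == "full") seq_len(n_bins) else
      union(eval_bins, fit_bin)
    for (b in bins_to_eval) {
      zs_b <- zscore_fit(A[[b]][tr, , drop = FALSE])
      z_te <- zscore_apply(A[[b]][te, , drop = FALSE], zs_b)
      pred <- drop(z_te %*% fit$xi) > fit$eta
      acc_time[s, b] <- mean(pred == y_te)
    }
    acc_split[s] <- mean(acc_time[s, eval_bins])
  }
  weights <- tibble::tibble(
    neuron = members,
    type = ifelse(activity$is_exc[members], "exc", "inh"),
    zweight = rowMeans(xi_all),
    raw_weight = rowMeans(w_all)
  )
  structure(
    list(group = group, members = members,
         accuracy = 100 * mean(acc_split),
         accuracy_sd = 100 * sd(acc_split),
         accuracy_by_split = 100 * acc_split,
         accuracy_by_time = tibble::tibble(
           bin = seq_len(n_bins), time = seq_len(n_bins) * bw,
           accuracy = 100 * colMeans(acc_time),
           sd = 100 * apply(acc_time, 2, sd)),
         weights = weights, raw_bias = mean(b_all),
         fit_bin = fit_bin, eval_window = eval_window,
         n_splits = n_splits, seed = seed),
    class = "population_decoder"
  )
}

#' @export
print.population_decoder <- function(x, ...) {
  cat("<population_decoder> group ", x$group, " (", length(x$members),
      " neurons): ", round(x$accuracy, 1), "% +/- ", round(x$accuracy_sd, 1),
      "% over ", x$eval_window[1], "-", x$eval_window[2], " tau (",
      x$n_splits, " splits)\n", sep = "")
  invisible(x)
}

#' @describeIn fit_population_decoder per-neuron mean readout weights.
#' @param x a `population_decoder`.
#' @param ... unused.
#' @export
tidy.population_decoder <- function(x, ...) x$weights

#' @describeIn fit_population_decoder one-row accuracy summary.
#' @export
glance.population_decoder <- function(x, ...) {
  tibble::tibble(
    group = x$group, n_neurons = length(x$members),
    accuracy = x$accuracy, accuracy_sd = x$accuracy_sd,
    n_splits = x$n_splits
  )
}

#' Compare excitatory and inhibitory readout-weight distributions
#'
#' For a full-population decoder: a rank-sum test of excitatory vs
#' inhibitory raw weights, a Lilliefors (Kolmogorov-Smirnov) normality test
#' of the pooled weights, and the matched-SD normal reference used for CDF
#' overlays.
#'
#' @param decoder a `population_decoder` fit with `group = "all"`.
#' @return one-row tibble: `p_exc_vs_inh`, `p_lilliefors`, `sd_weights`,
#'   `n_exc`, `n_inh`.
#' @export
weight_distribution_report <- function(decoder) {
  stopifnot(inherits(decoder, "population_decoder"))
  w <- decoder$weights
  we <- w$raw_weight[w$type == "exc"]
  wi <- w$raw_weight[w$type == "inh"]
  tibble::tibble(
    p_exc_vs_inh = wilcox.test(we, wi)$p.value,
    p_lilliefors = nortest::lillie.test(w$raw_weight)$p.value,
    sd_weights = sd(w$raw_weight),
    n_exc = length(we), n_inh = length(wi)
  )
}
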