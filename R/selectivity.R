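#' Per-trial scalar responses of every neuron
#'
#' Averages each neuron's firing rate over a time window of the trial,
#' yielding one number per trial per neuron — the response used by the
#' ideal-observer (AUC) analysis. The default window is the end of the
#' stimulus period (the final 5 tau).
#'
#' @param activity a `rate_activity` (1-tau bins).
#' @param window numeric length-2, start and end of the averaging window in
#'   tau (window is `(start, end]`).
#' @return matrix trials x neurons with the trial labels as attribute
#'   `"labels"`.
#' @export
trial_responses <- function(activity, window = c(45, 50)) {
  stopifnot(inherits(activity, "rate_activity"))
  bw <- activity$bin_width
  sel <- which((seq_len(dim(activity$rates)[2]) * bw) > window[1] &
                 (seq_len(dim(activity$rates)[2]) * bw) <= window[2] + 1e-9)
  if (!length(sel)) stop("empty response window", call. = FALSE)
  sub <- activity$rates[, sel, , drop = FALSE]
  resp <- t(colMeans(aperm(sub, c(2, 1, 3))))  # trials x neurons
  attr(resp, "labels") <- activity$labels
  resp
}

#' Nonparametric AUC between two response sets
#'
#' Area under the receiver-operating curve computed exactly over all
#' cross-pairs: `P(high > low) + 0.5 P(high == low)`. Computed from midranks,
#' which is algebraically identical to exhaustive pair counting, ties
#' included. Values below (above) 0.5 indicate a neuron responding more to
#' the low (high) category.
#'
#' @param low,high numeric response vectors for the two categories.
#' @return AUC in \[0, 1\].
#' @examples
#' auc_stat(c(1, 2, 3), c(2, 3, 4))  # 6.5 wins of 9 pairs = 0.722...
#' @export
auc_stat <- function(low, high) {
  if (!length(low) || !length(high)) {
    stop("both response sets must be non-empty", call. = FALSE)
  }
  r <- rank(c(low, high))
  nh <- length(high)
  nl <- length(low)
  (sum(r[nl + seq_len(nh)]) - nh * (nh + 1) / 2) / (nl * nh)
}

# AUC for every column of a trials x neurons response matrix
auc_columns <- function(resp, is_high) {
  nh <- sum(is_high)
  nl <- sum(!is_high)
  rk <- apply(resp, 2, rank)
  (colSums(rk[is_high, , drop = FALSE]) - nh * (nh + 1) / 2) / (nl * nh)
}

#' Permutation significance bounds for per-neuron AUC
#'
#' Shuffles the trial labels `n_shuffles` times, recomputes every neuron's
#' AUC under each shuffle, and returns the empirical 2.5 and 97.5 percentiles
#' of the null distribution. Ranks are computed once per neuron: a label
#' shuffle only changes which trials count as "high", so all shuffled AUCs
#' are obtained with a single matrix product.
#'
#' @param resp matrix trials x neurons.
#' @param is_high logical vector of trial labels.
#' @param n_shuffles number of label permutations (>= 200).
#' @param seed integer seed.
#' @return list with vectors `lo`, `hi` (length = neurons) and the matrix of
#'   shuffled AUCs (`n_shuffles` x neurons) as `null_auc`.
#' @export
shuffle_bounds <- function(resp, is_high, n_shuffles = 1000, seed = 1) {
  if (n_shuffles < 200) stop("use at least 200 shuffles", call. = FALSE)
  nh <- sum(is_high)
  nl <- sum(!is_high)
  n <- nh + nl
  rk <- apply(resp, 2, rank)
  perm <- local_seed(derive_seed(seed, 401), {
    m <- matrix(0, n, n_shuffles)
    for (s in seq_len(n_shuffles)) m[sample.int(n, nh), s] <- 1
    m
  })
  null_auc <- (crossprod(rk, perm) - nh * (nh + 1) / 2) / (nl * nh)
  qs <- apply(null_auc, 1, quantile, probs = c(0.025, 0.975), names = FALSE)
  list(lo = qs[1, ], hi = qs[2, ], null_auc = t(null_auc))
}

#' Ideal-observer selectivity of every neuron
#'
#' Computes, for each neuron, the AUC between its low- and high-category
#' trial responses, permutation significance bounds, a significance flag
#' (AUC outside the shuffled 2.5-97.5 percentile interval), the preferred
#' category, and the selectivity index `2 |AUC - 0.5|`.
#'
#' @param activity a `rate_activity`.
#' @param window response window passed to [trial_responses()].
#' @param n_shuffles label permutations for the significance bounds.
#' @param seed integer seed for the shuffles.
#' @return a tibble of class `selectivity_table` with columns `neuron`,
#'   `type` ("exc"/"inh"), `receives_input`, `auc`, `lo`, `hi`,
#'   `significant`, `preferred` ("low"/"high"/"none") and `index`.
#' @export
compute_selectivity <- function(activity, window = c(45, 50),
                                n_shuffles = 1000, seed = 1) {
  resp <- trial_responses(activity, window)
  is_high <- attr(resp, "labels") == "high"
  auc <- auc_columns(resp, is_high)
  sb <- shuffle_bounds(resp, is_high, n_shuffles, seed)
  significant <- auc < sb$lo | auc > sb$hi
  out <- tibble::tibble(
    neuron = seq_along(auc),
    type = ifelse(activity$is_exc, "exc", "inh"),
    receives_input = activity$input_mask,
    auc = auc, lo = sb$lo, hi = sb$hi,
    significant = significant,
    preferred = ifelse(!significant, "none",
                       ifelse(auc < 0.5, "low", "high")),
    index = 2 * abs(auc - 0.5)
  )
  attr(out, "window") <- window
  attr(out, "n_shuffles") <- n_shuffles
  class(out) <- c("selectivity_table", class(out))
  out
}

#' Summarize selectivity by cell type
#'
#' Fraction of significantly selective neurons and mean selectivity index
#' (over all cells, selective or not) for excitatory and inhibitory cells.
#'
#' @param table a `selectivity_table`.
#' @return a tibble with one row per cell type.
#' @export
selectivity_summary <- function(table) {
  stopifnot(inherits(table, "selectivity_table"))
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(table), .data$type),
    n = dplyr::n(),
    fraction_selective = mean(.data$significant),
    mean_index = mean(.data$index),
    .groups = "drop"
  )
}

#' @describeIn compute_selectivity one-row summary: overall and per-type
#'   selective fractions and mean index.
#' @param x a `selectivity_table`.
#' @param ... unused.
#' @export
glance.selectivity_table <- function(x, ...) {
  s <- selectivity_summary(x)
  tibble::tibble(
    fraction_selective = mean(x$significant),
    mean_index = mean(x$index),
    fraction_selective_exc = s$fraction_selective[s$type == "exc"],
    fraction_selective_inh = s$fraction_selective[s$type == "inh"],
    mean_index_exc = s$mean_index[s$type == "exc"],
    mean_index_inh = s$mean_index[s$type == "inh"]
  )
}

#' Trial-to-trial noise correlations
#'
#' Computes neuron-neuron Pearson correlations of the stimulus-subtracted
#' activity at the end of the stimulus period. Within each stimulus
#' category, the category's mean time course is subtracted from every
#' trial's activity, and the residual samples (time bins of the window, all
#' trials of the category) are correlated between neurons; the two
#' per-category correlation matrices are then averaged. Because the shared
#' pulse train is the only noise source, these correlations are much larger
#' than in real recordings. Neurons with zero residual variance in either
#' category are excluded with a warning (their correlations are `NA`).
#'
#' @param activity a `rate_activity`.
#' @param window time window in tau whose bins enter the correlation.
#' @return symmetric correlation matrix (unit diagonal for retained neurons).
#' @export
noise_correlations <- function(activity, window = c(45, 50)) {
  stopifnot(inherits(activity, "rate_activity"))
  bw <- activity$bin_width
  nb <- dim(activity$rates)[2]
  sel <- which((seq_len(nb) * bw) > window[1] &
                 (seq_len(nb) * bw) <= window[2] + 1e-9)
  if (!length(sel)) stop("empty correlation window", call. = FALSE)
  labels <- activity$labels
  if (min(table(labels)) < 2) {
    stop("need at least 2 trials per category", call. = FALSE)
  }
  n <- dim(activity$rates)[1]
  ok <- rep(TRUE, n)
  mats <- list()
  for (lv in levels(labels)) {
    x <- activity$rates[, sel, labels == lv, drop = FALSE]
    mu <- apply(x, c(1, 2), mean)
    res <- sweep(x, c(1, 2), mu)
    dim(res) <- c(n, length(sel) * dim(x)[3])
    v <- rowSums(res^2)
    ok <- ok & v > 0
    mats[[lv]] <- res
  }
  if (!all(ok)) {
    warning(sum(!ok), " zero-variance neuron(s) excluded from correlations")
  }
  out <- matrix(NA_real_, n, n)
  sub <- lapply(mats, function(res) {
    r <- res[ok, , drop = FALSE]
    cc <- tcrossprod(r)  # residuals have zero mean by construction
    d <- sqrt(diag(cc))
    cc / outer(d, d)
  })
  out[ok, ok] <- Reduce(`+`, sub) / length(sub)
  out
}

#' Mean noise correlation among same- and opposite-selectivity pairs
#'
#' Restricts to significantly selective neurons and averages the pairwise
#' noise correlations over pairs that prefer the same category and pairs
#' that prefer opposite categories.
#'
#' @param corr correlation matrix from [noise_correlations()].
#' @param table the matching `selectivity_table`.
#' @return tibble with rows `same` and `opposite`.
#' @export
correlation_by_selectivity <- function(corr, table) {
  stopifnot(inherits(table, "selectivity_table"))
  sig <- which(table$significant)
  pref <- table$preferred
  same_mask <- outer(pref[sig], pref[sig], `==`)
  cc <- corr[sig, sig, drop = FALSE]
  ut <- upper.tri(cc)
  tibble::tibble(
    relation = c("same", "opposite"),
    mean_correlation = c(mean(cc[ut & same_mask], na.rm = TRUE),
                         mean(cc[ut & !same_mask], na.rm = TRUE)),
    n_pairs = c(sum(ut & same_mask), sum(ut & !same_mask))
  )
}

#' Connection probabilities between selectivity-defined pools
#'
#' Splits significantly selective neurons into four pools by cell type and
#' preferred category (E1, E2, I1, I2) and computes the empirical
#' probability of a synapse for each directed (source type, target type,
#' same/opposite selectivity) combination, symmetrized across selectivity
#' pools (the 1-to-1 and 2-to-2 counts are pooled, as are 1-to-2 and
#' 2-to-1). Probabilities are also reported as ratios to the baseline
#' connection probability of the network spec.
#'
#' @param network the `ei_network` the activity came from.
#' @param table the `selectivity_table` of that network's simulation.
#' @return a tibble with columns `source_type`, `target_type`, `relation`,
#'   `n_conn`, `n_pairs`, `prob`, `ratio`; `prob` is `NA` when a pool is
#'   empty.
#' @export
pool_connection_stats <- function(network, table) {
  stopifnot(inherits(network, "ei_network"),
            inherits(table, "selectivity_table"))
  W <- network$weights
  pools <- list(
    E1 = which(table$type == "exc" & table$preferred == "low"),
    E2 = which(table$type == "exc" & table$preferred == "high"),
    I1 = which(table$type == "inh" & table$preferred == "low"),
    I2 = which(table$type == "inh" & table$preferred == "high")
  )
  count <- function(src, tgt) {
    if (!length(src) || !length(tgt)) return(c(0, 0))
    block <- W[tgt, src, drop = FALSE] != 0
    n_pairs <- length(src) * length(tgt) - length(intersect(src, tgt))
    c(sum(block), n_pairs)  # diagonal cells are zero by construction
  }
  combos <- tidyr::expand_grid(
    source_type = c("E", "I"), target_type = c("E", "I"),
    relation = c("same", "opposite")
  )
  rows <- purrr::pmap(combos, function(source_type, target_type, relation) {
    s1 <- pools[[paste0(source_type, 1)]]
    s2 <- pools[[paste0(source_type, 2)]]
    t1 <- pools[[paste0(target_type, 1)]]
    t2 <- pools[[paste0(target_type, 2)]]
    cnt <- if (relation == "same") {
      count(s1, t1) + count(s2, t2)
    } else {
      count(s1, t2) + count(s2, t1)
    }
    tibble::tibble(n_conn = cnt[1], n_pairs = cnt[2],
                   prob = if (cnt[2] > 0) cnt[1] / cnt[2] else NA_real_)
  })
  out <- dplyr::bind_cols(combos, dplyr::bind_rows(rows))
  out$ratio <- out$prob / network$spec$p_conn
  out
}
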