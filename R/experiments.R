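#' Configuration of a simulation experiment
#'
#' Bundles the network specification, task and analysis options used by
#' [run_ensemble()] so that a whole study is reproducible from one object
#' and one master seed. Round-trips losslessly through JSON
#' ([write_config()] / [read_config()]).
#'
#' @param spec a [network_spec()].
#' @param n_networks networks in the ensemble.
#' @param n_trials_per trials per stimulus category.
#' @param n_pulses pulse-count pair of the task.
#' @param n_shuffles label permutations for AUC significance.
#' @param n_splits train/test resamples for decoding.
#' @param decode_groups decoder populations to fit.
#' @param seed master seed.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(spec = network_spec(), n_networks = 6,
                              n_trials_per = 400, n_pulses = c(8, 16),
                              n_shuffles = 1000, n_splits = 50,
                              decode_groups = c("all", "inh"), seed = 1) {
  stopifnot(inherits(spec, "network_spec"),
            n_networks >= 1, n_trials_per >= 2, length(n_pulses) == 2)
  structure(
    list(spec = spec, n_networks = as.integer(n_networks),
         n_trials_per = as.integer(n_trials_per),
         n_pulses = as.integer(n_pulses),
         n_shuffles = as.integer(n_shuffles),
         n_splits = as.integer(n_splits),
         decode_groups = decode_groups, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' @rdname experiment_config
#' @param config an `experiment_config`.
#' @param path file path for the JSON serialization.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  obj <- unclass(config)
  obj$spec <- unclass(obj$spec)
  obj$spec$pool_weights <- if (is.null(obj$spec$pool_weights)) NULL else
    as.vector(obj$spec$pool_weights)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- obj$spec
  spec <- network_spec(
    n_exc = sp$n_exc, n_inh = sp$n_inh, p_conn = sp$p_conn,
    g_exc = sp$g_exc, g_inh = sp$g_inh, weight_sd = sp$weight_sd,
    bias = sp$bias, variant = sp$variant,
    input_fraction = sp$input_fraction,
    pool_weights = if (is.null(sp$pool_weights)) NULL else
      matrix(unlist(sp$pool_weights), 2, 2),
    weight_scale = sp$weight_scale, homogeneous = sp$homogeneous
  )
  experiment_config(
    spec = spec, n_networks = obj$n_networks,
    n_trials_per = obj$n_trials_per, n_pulses = obj$n_pulses,
    n_shuffles = obj$n_shuffles, n_splits = obj$n_splits,
    decode_groups = unlist(obj$decode_groups), seed = obj$seed
  )
}

#' Full analysis pipeline for one network
#'
#' Builds (or accepts) a network, calibrates the input amplitudes to the
#' iso-rate contour, simulates the discrimination task, and computes the
#' requested analyses: single-neuron selectivity, noise correlations by
#' shared selectivity, selectivity-conditioned pool connectivity, population
#' decoding, and the eigen-spectrum of the linearized network.
#'
#' @param spec a [network_spec()], or an already-built `ei_network`.
#' @param seed seed for this network's streams.
#' @param n_pulses pulse-count pair of the task.
#' @param n_trials_per trials per category.
#' @param n_shuffles,n_splits analysis options.
#' @param decode_groups decoder populations (`"all"`, `"exc_sub"`, `"inh"`).
#' @param compute character vector choosing analyses; any of
#'   `"selectivity"`, `"correlations"`, `"pools"`, `"decoding"`, `"spectra"`.
#' @param accuracy_curve passed to [fit_population_decoder()].
#' @param keep_activity keep the rate tensor in the result (off by default:
#'   an 800-trial tensor is ~160 MB).
#' @return an object of class `network_analysis`: list with elements
#'   `network`, `calibration`, `rate_by_category`, `selectivity`,
#'   `correlations` (summary tibble), `pools`, `decoders` (named list),
#'   `eigen`, `seed` (plus `activity` if kept).
#' @export
analyze_network <- function(spec, seed = 1, n_pulses = c(8, 16),
                            n_trials_per = 400, n_shuffles = 1000,
                            n_splits = 50, decode_groups = c("all", "inh"),
                            compute = c("selectivity", "correlations",
                                        "pools", "decoding", "spectra"),
                            accuracy_curve = "full",
                            keep_activity = FALSE) {
  network <- if (inherits(spec, "ei_network")) spec else
    build_network(spec, seed = derive_seed(seed, 701))
  cal <- calibrate_amplitudes(network, n_pulses = n_pulses,
                              seed = derive_seed(seed, 702))
  trials <- trial_set(n_trials_per, n_pulses = n_pulses,
                      alphas = cal$alphas$alpha,
                      seed = derive_seed(seed, 703))
  act <- simulate_network(network, trials)
  rate_by_category <- tibble::tibble(
    label = levels(act$labels),
    mean_rate = vapply(levels(act$labels), function(lv) {
      mean(act$rates[, , act$labels == lv])
    }, numeric(1))
  )
  out <- list(network = network, calibration = cal,
              rate_by_category = rate_by_category, seed = seed)
  sel <- NULL
  if (any(c("selectivity", "correlations", "pools", "spectra") %in% compute)) {
    sel <- compute_selectivity(act, n_shuffles = n_shuffles,
                               seed = derive_seed(seed, 704))
    out$selectivity <- sel
  }
  if ("correlations" %in% compute) {
    cc <- noise_correlations(act)
    out$correlations <- correlation_by_selectivity(cc, sel)
  }
  if ("pools" %in% compute) {
    out$pools <- pool_connection_stats(network, sel)
  }
  if ("decoding" %in% compute) {
    out$decoders <- lapply(stats::setNames(decode_groups, decode_groups),
                           function(g) {
      fit_population_decoder(act, group = g, n_splits = n_splits,
                             seed = derive_seed(seed, 705),
                             accuracy_curve = accuracy_curve)
    })
  }
  if ("spectra" %in% compute) {
    out$eigen <- eigen_selectivity(network, sel$auc)
  }
  if (keep_activity) out$activity <- act
  class(out) <- "network_analysis"
  out
}

#' @export
print.network_analysis <- function(x, ...) {
  cat("<network_analysis> seed ", x$seed, "\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @describeIn analyze_network one-row summary of every computed analysis.
#' @param x a `network_analysis`.
#' @param ... unused.
#' @export
glance.network_analysis <- function(x, ...) {
  out <- tibble::tibble(
    seed = x$seed,
    alpha_ratio = x$calibration$ratio,
    rate_low = x$rate_by_category$mean_rate[
      x$rate_by_category$label == "low"],
    rate_high = x$rate_by_category$mean_rate[
      x$rate_by_category$label == "high"]
  )
  if (!is.null(x$selectivity)) {
    out <- dplyr::bind_cols(out, glance(x$selectivity))
  }
  if (!is.null(x$correlations)) {
    cc <- x$correlations
    out$corr_same <- cc$mean_correlation[cc$relation == "same"]
    out$corr_opposite <- cc$mean_correlation[cc$relation == "opposite"]
  }
  if (!is.null(x$pools)) {
    p <- x$pools
    pick <- function(s, t, rel) {
      p$prob[p$source_type == s & p$target_type == t & p$relation == rel]
    }
    out$p_ie_same <- pick("I", "E", "same")
    out$p_ie_opposite <- pick("I", "E", "opposite")
    out$p_ei_same <- pick("E", "I", "same")
    out$p_ei_opposite <- pick("E", "I", "opposite")
  }
  if (!is.null(x$decoders)) {
    for (g in names(x$decoders)) {
      out[[paste0("accuracy_", g)]] <- x$decoders[[g]]$accuracy
      out[[paste0("accuracy_", g, "_sd")]] <- x$decoders[[g]]$accuracy_sd
    }
  }
  if (!is.null(x$eigen)) {
    eg <- glance(x$eigen)
    names(eg) <- paste0("eigen_", names(eg))
    out <- dplyr::bind_cols(out, eg)
  }
  out
}

#' Run an ensemble of independently drawn networks
#'
#' Repeats [analyze_network()] over `n_networks` seeds derived from the
#' master seed and binds the per-network summaries into one tibble. Failed
#' networks (e.g. an empty selectivity pool) are reported and skipped.
#'
#' @param config an [experiment_config()].
#' @param compute analyses to run, as in [analyze_network()].
#' @param keep_analyses keep the full per-network objects (in
#'   `attr(result, "analyses")`).
#' @return a tibble with one row per network (column `network` plus the
#'   [glance.network_analysis()] columns).
#' @export
run_ensemble <- function(config = experiment_config(),
                         compute = c("selectivity", "correlations", "pools",
                                     "decoding", "spectra"),
                         keep_analyses = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  analyses <- vector("list", config$n_networks)
  rows <- vector("list", config$n_networks)
  for (i in seq_len(config$n_networks)) {
    res <- tryCatch(
      analyze_network(config$spec, seed = derive_seed(config$seed, 801, i),
                      n_pulses = config$n_pulses,
                      n_trials_per = config$n_trials_per,
                      n_shuffles = config$n_shuffles,
                      n_splits = config$n_splits,
                      decode_groups = config$decode_groups,
                      compute = compute),
      error = function(e) {
        warning("network ", i, " failed: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(res)) next
    analyses[[i]] <- res
    rows[[i]] <- dplyr::bind_cols(tibble::tibble(network = i), glance(res))
  }
  out <- dplyr::bind_rows(rows)
  if (keep_analyses) attr(out, "analyses") <- analyses
  out
}

#' Parameter-robustness variants on a fixed topology
#'
#' From a base network, builds (i) the unchanged network, (ii) all weights
#' scaled by `scale_factor`, and (iii) homogeneous within-class weights,
#' keeping the sparsity pattern identical, then recalibrates input
#' amplitudes and fits population decoders for each variant.
#'
#' @param network the base `ei_network`.
#' @param scale_factor weight multiplier of variant (ii).
#' @param n_trials_per,n_splits,decode_groups analysis options.
#' @param seed integer seed.
#' @return a tibble with one row per (variant, decoder group): columns
#'   `variant`, `group`, `accuracy`, `accuracy_sd`, `alpha_ratio`.
#' @export
run_s3_variants <- function(network, scale_factor = 1.5, n_trials_per = 400,
                            n_splits = 50,
                            decode_groups = c("all", "exc_sub", "inh"),
                            seed = 1) {
  stopifnot(inherits(network, "ei_network"))
  variants <- list(
    original = network,
    scaled = network_variant(network, weight_scale = scale_factor),
    homogeneous = network_variant(network, homogeneous = TRUE)
  )
  rows <- purrr::imap(variants, function(net, nm) {
    cal <- calibrate_amplitudes(net, seed = derive_seed(seed, 901))
    trials <- trial_set(n_trials_per, alphas = cal$alphas$alpha,
                        seed = derive_seed(seed, 902))
    act <- simulate_network(net, trials)
    purrr::map_dfr(decode_groups, function(g) {
      dec <- fit_population_decoder(act, group = g, n_splits = n_splits,
                                    seed = derive_seed(seed, 903))
      tibble::tibble(variant = nm, group = g, accuracy = dec$accuracy,
                     accuracy_sd = dec$accuracy_sd,
                     alpha_ratio = cal$ratio)
    })
  })
  dplyr::bind_rows(rows)
}

#' Run the complete discrimination study
#'
#' Orchestrates the whole set of simulation experiments at the study's
#' standard conditions: an ensemble of default networks analyzed on the
#' 8 vs 16 Hz task (selectivity, correlations, pool connectivity, decoding
#' from the full non-input population and from inhibitory cells, and the
#' eigen-spectrum), a task-transfer run of every default network to the
#' 10 vs 20 Hz pair, and an ensemble of all-E-input variant networks with
#' decoding from all cells, an excitatory subset and inhibitory cells.
#'
#' @param seed master seed; every network, trial draw, shuffle and split
#'   stream is derived from it.
#' @param n_default,n_variant ensemble sizes.
#' @param n_trials_per trials per stimulus category.
#' @param n_shuffles,n_splits analysis options.
#' @param transfer run the task-transfer arm.
#' @param accuracy_curve `"eval"` evaluates test accuracy only over the
#'   bins of the headline window; `"full"` evaluates the whole stimulus
#'   period (needed for accuracy-over-time plots).
#' @return list of tibbles: `default` (one row per default network),
#'   `transfer` (one row per network), `variant` (one row per variant
#'   network).
#' @export
run_study <- function(seed = 1, n_default = 6, n_variant = 4,
                      n_trials_per = 400, n_shuffles = 1000, n_splits = 50,
                      transfer = TRUE, accuracy_curve = "eval") {
  def_rows <- list(); tr_rows <- list()
  for (i in seq_len(n_default)) {
    si <- derive_seed(seed, 801, i)
    a <- analyze_network(network_spec(), seed = si,
                         n_trials_per = n_trials_per,
                         n_shuffles = n_shuffles, n_splits = n_splits,
                         decode_groups = c("all", "inh"),
                         accuracy_curve = accuracy_curve)
    def_rows[[i]] <- dplyr::bind_cols(tibble::tibble(network = i), glance(a))
    if (transfer) {
      tr <- run_task_transfer(a$network, n_trials_per = n_trials_per,
                              n_shuffles = n_shuffles, seed = si,
                              task1 = list(selectivity = a$selectivity,
                                           calibration = a$calibration))
      tr_rows[[i]] <- dplyr::bind_cols(tibble::tibble(network = i),
                                       glance(tr))
    }
  }
  var_rows <- list()
  for (i in seq_len(n_variant)) {
    a <- analyze_network(network_spec(variant = "all_e_input"),
                         seed = derive_seed(seed, 802, i),
                         n_trials_per = n_trials_per,
                         n_shuffles = n_shuffles, n_splits = n_splits,
                         decode_groups = c("all", "exc_sub", "inh"),
                         accuracy_curve = accuracy_curve)
    var_rows[[i]] <- dplyr::bind_cols(tibble::tibble(network = i), glance(a))
  }
  list(default = dplyr::bind_rows(def_rows),
       transfer = dplyr::bind_rows(tr_rows),
       variant = dplyr::bind_rows(var_rows))
}
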