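#' Specify a random excitatory-inhibitory network
#'
#' Collects every scalar parameter that defines a network draw. Defaults are
#' the reference parameter set: 400 excitatory and 100 inhibitory neurons,
#' 20% connection probability, synaptic weight means `g_exc = 0.18` and
#' `g_inh = -0.72` with common SD 0.045, so that excitation and inhibition
#' balance on average (`n_exc * g_exc + n_inh * g_inh = 0`), and a transfer
#' function bias of 2 which keeps spontaneous rates at or below 0.05.
#'
#' Two input-targeting variants are supported. In `"subset_e_input"` (the
#' default) the stimulus current is delivered to a random fraction
#' (`input_fraction`, default 20%) of excitatory neurons. In `"all_e_input"`
#' every excitatory neuron receives the stimulus and none of the inhibitory
#' neurons do; the weight means are then set per (target, source) pool with
#' slightly stronger I-to-E than I-to-I weights (`-0.8` vs `-0.82`) to offset
#' the current that only excitatory cells receive.
#'
#' @param n_exc,n_inh numbers of excitatory and inhibitory neurons.
#' @param p_conn connection probability for each ordered pair of neurons.
#' @param g_exc,g_inh mean synaptic weight of excitatory (positive) and
#'   inhibitory (negative) connections.
#' @param weight_sd standard deviation of nonzero weights (both classes).
#' @param bias transfer-function bias `b` in `g(x) = 0.5 (1 + tanh(x - b))`.
#' @param variant `"subset_e_input"` or `"all_e_input"` (see Details).
#' @param input_fraction fraction of excitatory neurons receiving direct input
#'   under `"subset_e_input"`.
#' @param pool_weights optional 2x2 matrix of weight means indexed
#'   `[target_type, source_type]` with types ordered (exc, inh). Defaults to
#'   the class means; for `"all_e_input"` it defaults to
#'   `g_EE = g_IE = 0.2`, `g_EI = -0.8`, `g_II = -0.82`.
#' @param weight_scale multiplier applied to all realized weights (1.5 in the
#'   scaled robustness variant).
#' @param homogeneous if `TRUE`, every nonzero weight equals its pool mean.
#' @return an object of class `network_spec`.
#' @seealso [build_network()]
#' @export
network_spec <- function(n_exc = 400L, n_inh = 100L, p_conn = 0.2,
                         g_exc = 0.18, g_inh = -0.72, weight_sd = 0.045,
                         bias = 2,
                         variant = c("subset_e_input", "all_e_input"),
                         input_fraction = 0.2, pool_weights = NULL,
                         weight_scale = 1, homogeneous = FALSE) {
  variant <- match.arg(variant)
  n_exc <- as.integer(n_exc); n_inh <- as.integer(n_inh)
  if (n_exc <= 0 || n_inh < 0) {
    stop("network sizes must be positive", call. = FALSE)
  }
  if (p_conn < 0 || p_conn > 1) {
    stop("`p_conn` must be a probability in [0, 1]", call. = FALSE)
  }
  if (g_exc * g_inh >= 0) {
    stop("`g_exc` must be positive and `g_inh` negative", call. = FALSE)
  }
  if (weight_sd < 0) stop("`weight_sd` must be non-negative", call. = FALSE)
  if (input_fraction <= 0 || input_fraction > 1) {
    stop("`input_fraction` must be in (0, 1]", call. = FALSE)
  }
  if (is.null(pool_weights) && variant == "all_e_input") {
    pool_weights <- matrix(c(0.2, 0.2, -0.8, -0.82), 2, 2,
                           dimnames = list(c("exc", "inh"), c("exc", "inh")))
  }
  if (!is.null(pool_weights)) {
    pool_weights <- as.matrix(pool_weights)
    if (!all(dim(pool_weights) == c(2, 2))) {
      stop("`pool_weights` must be a 2x2 [target, source] matrix", call. = FALSE)
    }
    dimnames(pool_weights) <- list(c("exc", "inh"), c("exc", "inh"))
    if (any(pool_weights[, "exc"] <= 0) || any(pool_weights[, "inh"] >= 0)) {
      stop("`pool_weights` must have positive exc and negative inh columns",
           call. = FALSE)
    }
  }
  structure(
    list(n_exc = n_exc, n_inh = n_inh, p_conn = p_conn,
         g_exc = g_exc, g_inh = g_inh, weight_sd = weight_sd, bias = bias,
         tau = 1, variant = variant, input_fraction = input_fraction,
         pool_weights = pool_weights, weight_scale = weight_scale,
         homogeneous = isTRUE(homogeneous)),
    class = "network_spec"
  )
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec> ", x$n_exc, "E + ", x$n_inh, "I, p = ", x$p_conn,
      ", g = (", x$g_exc, ", ", x$g_inh, "), sd = ", x$weight_sd,
      ", variant = ", x$variant, "\n", sep = "")
  invisible(x)
}

# truncated-normal draws by rejection, truncated at zero on the side that
# would violate the sign of `mean`
rtrunc_signed <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, length.out = n))
  x <- rnorm(n, mean, sd)
  bad <- which(sign(x) != sign(mean) | x == 0)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), if (length(mean) > 1) mean[bad] else mean, sd)
    bad <- bad[sign(x[bad]) != sign(if (length(mean) > 1) mean[bad] else mean) |
                 x[bad] == 0]
  }
  x
}

#' Draw a random network from a specification
#'
#' Samples the signed weight matrix `W` (entry `W[i, j]` is the synaptic
#' weight onto neuron `i` from neuron `j`), the cell-type labels and the
#' input-target mask. Each ordered pair of distinct neurons is connected
#' independently with probability `p_conn`; nonzero weights are drawn from a
#' normal distribution with the pool mean and `weight_sd`, truncated at zero
#' so that every weight respects the sign of its source neuron (Dale's
#' principle). Self-connections are excluded.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for the draw (the network's own RNG stream).
#' @return an object of class `ei_network`: a list with elements `weights`
#'   (dense matrix), `is_exc` (logical), `input_mask` (logical), `spec`,
#'   `seed`.
#' @examples
#' net <- build_network(network_spec(n_exc = 40, n_inh = 10), seed = 1)
#' mean(net$weights != 0)  # close to p_conn
#' @export
build_network <- function(spec, seed) {
  stopifnot(inherits(spec, "network_spec"))
  n <- spec$n_exc + spec$n_inh
  is_exc <- c(rep(TRUE, spec$n_exc), rep(FALSE, spec$n_inh))
  local_seed(derive_seed(seed, 101), {
    conn <- matrix(runif(n * n) < spec$p_conn, n, n)
    diag(conn) <- FALSE
    idx <- which(conn)
    if (is.null(spec$pool_weights)) {
      src <- ((idx - 1) %/% n) + 1
      mu <- ifelse(is_exc[src], spec$g_exc, spec$g_inh)
    } else {
      src <- ((idx - 1) %/% n) + 1
      tgt <- ((idx - 1) %% n) + 1
      mu <- spec$pool_weights[cbind(2 - is_exc[tgt], 2 - is_exc[src])]
    }
    w <- if (spec$homogeneous) mu else rtrunc_signed(length(idx), mu, spec$weight_sd)
    weights <- matrix(0, n, n)
    weights[idx] <- w * spec$weight_scale
    input_mask <- rep(FALSE, n)
    if (spec$variant == "all_e_input") {
      input_mask[is_exc] <- TRUE
    } else {
      n_in <- round(spec$input_fraction * spec$n_exc)
      input_mask[sample(which(is_exc), n_in)] <- TRUE
    }
    structure(
      list(weights = weights, is_exc = is_exc, input_mask = input_mask,
           spec = spec, seed = as.integer(seed)),
      class = "ei_network"
    )
  })
}

#' @export
print.ei_network <- function(x, ...) {
  cat("<ei_network> ", sum(x$is_exc), "E + ", sum(!x$is_exc),
      "I, nonzero fraction ", round(mean(x$weights != 0), 3),
      ", ", sum(x$input_mask), " input-receiving neurons (seed ", x$seed,
      ")\n", sep = "")
  invisible(x)
}

#' Re-parameterize a network on a fixed topology
#'
#' Builds a parameter variant of an existing network while keeping the
#' sparsity pattern (which synapses exist) identical: either scale all
#' realized weights by `weight_scale`, or replace every nonzero weight by its
#' pool mean (`homogeneous = TRUE`). Used for the robustness variants.
#'
#' @param network an [build_network()] result.
#' @param weight_scale multiplier for all weights.
#' @param homogeneous replace weights by their pool means before scaling.
#' @return an `ei_network` sharing the topology and input mask of `network`.
#' @export
network_variant <- function(network, weight_scale = 1, homogeneous = FALSE) {
  stopifnot(inherits(network, "ei_network"))
  spec <- network$spec
  W <- network$weights
  if (homogeneous) {
    nz <- which(W != 0)
    n <- nrow(W)
    src <- ((nz - 1) %/% n) + 1
    if (is.null(spec$pool_weights)) {
      mu <- ifelse(network$is_exc[src], spec$g_exc, spec$g_inh)
    } else {
      tgt <- ((nz - 1) %% n) + 1
      mu <- spec$pool_weights[cbind(2 - network$is_exc[tgt],
                                    2 - network$is_exc[src])]
    }
    W[nz] <- mu * spec$weight_scale
    spec$homogeneous <- TRUE
  }
  W <- W * weight_scale
  spec$weight_scale <- spec$weight_scale * weight_scale
  out <- network
  out$weights <- W
  out$spec <- spec
  out
}

#' Empirical per-pool mean weights of a network
#'
#' Validation helper: the empirical mean (and SD, count) of nonzero weights
#' for each (target type, source type) pool, together with the empirical
#' connection probability of the pool.
#'
#' @param network an `ei_network`.
#' @return a tibble with one row per (target_type, source_type) pool.
#' @export
pool_mean_table <- function(network) {
  stopifnot(inherits(network, "ei_network"))
  W <- network$weights
  types <- ifelse(network$is_exc, "exc", "inh")
  out <- vector("list", 4)
  k <- 1
  for (tt in c("exc", "inh")) {
    for (st in c("exc", "inh")) {
      ti <- which(types == tt); si <- which(types == st)
      block <- W[ti, si, drop = FALSE]
      n_pairs <- length(ti) * length(si) - (if (tt == st) length(ti) else 0)
      w <- block[block != 0]
      out[[k]] <- tibble::tibble(
        target_type = tt, source_type = st,
        n_nonzero = length(w), n_pairs = n_pairs,
        p_conn = length(w) / n_pairs,
        mean_weight = if (length(w)) mean(w) else NA_real_,
        sd_weight = if (length(w) > 1) sd(w) else NA_real_
      )
      k <- k + 1
    }
  }
  dplyr::bind_rows(out)
}

#' @describeIn build_network tidy the nonzero synapses into an edge list
#'   tibble (`from`, `to`, `weight`, `from_type`).
#' @param x an `ei_network`.
#' @param ... unused.
#' @export
tidy.ei_network <- function(x, ...) {
  nz <- which(x$weights != 0, arr.ind = TRUE)
  tibble::tibble(
    to = nz[, 1], from = nz[, 2],
    weight = x$weights[nz],
    from_type = ifelse(x$is_exc[nz[, 2]], "exc", "inh")
  )
}

#' @describeIn build_network one-row summary of a network draw.
#' @export
glance.ei_network <- function(x, ...) {
  tibble::tibble(
    n_exc = sum(x$is_exc), n_inh = sum(!x$is_exc),
    p_conn_emp = {
      W <- x$weights
      mean(W[row(W) != col(W)] != 0)
    },
    mean_row_sum = mean(rowSums(x$weights)),
    n_input = sum(x$input_mask),
    variant = x$spec$variant
  )
}

#' Serialize a network to a plain-text JSON file
#'
#' Stores the full spec, cell types, input mask and the dense weight matrix
#' so that a network round-trips losslessly.
#'
#' @param network an `ei_network`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "ei_network"))
  spec <- network$spec
  spec$pool_weights <- if (is.null(spec$pool_weights)) NULL else
    as.vector(spec$pool_weights)
  obj <- list(
    spec = unclass(spec),
    seed = network$seed,
    is_exc = network$is_exc,
    input_mask = network$input_mask,
    weights = as.vector(network$weights)  # column-major
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- obj$spec
  spec <- network_spec(
    n_exc = sp$n_exc, n_inh = sp$n_inh, p_conn = sp$p_conn,
    g_exc = sp$g_exc, g_inh = sp$g_inh, weight_sd = sp$weight_sd,
    bias = sp$bias, variant = sp$variant,
    input_fraction = sp$input_fraction,
    pool_weights = if (is.null(sp$pool_weights)) NULL else
      matrix(sp$pool_weights, 2, 2),
    weight_scale = sp$weight_scale, homogeneous = sp$homogeneous
  )
  structure(
    list(weights = matrix(obj$weights, length(obj$is_exc)),
         is_exc = obj$is_exc, input_mask = obj$input_mask,
         spec = spec, seed = obj$seed),
    class = "ei_network"
  )
}
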