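#' Linearize the network about a fixed point
#'
#' Returns the effective connectivity of the linearized dynamics,
#' `Jt[i, j] = W[i, j] * g'(x0[j])`: each column is scaled by the
#' transfer-function slope of its source neuron at the fixed point. The
#' Jacobian of the rate dynamics at `x0` is `(Jt - I) / tau`.
#'
#' @param network an `ei_network`.
#' @param x0 fixed-point membrane vector; defaults to the zero-input fixed
#'   point.
#' @return dense matrix `Jt`.
#' @export
linearize_network <- function(network, x0 = NULL) {
  stopifnot(inherits(network, "ei_network"))
  if (is.null(x0)) x0 <- find_fixed_point(network)
  gp <- transfer_deriv(x0, network$spec$bias)
  sweep(network$weights, 2, gp, `*`)
}

# two-sided p-value of a Pearson correlation via the t distribution
cor_pval <- function(r, n) {
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(t), n - 2)
}

#' Eigen-decomposition of the linearized network and its relation to
#' selectivity
#'
#' Diagonalizes the linearized connectivity, correlates the real and
#' imaginary parts of every eigenvector with the per-neuron selectivity
#' (AUC) vector, and flags eigenvectors whose correlation passes a
#' Bonferroni-corrected threshold `p < alpha / N`. Complex eigenvalues come
#' in conjugate pairs whose eigenvectors carry identical correlation
#' magnitudes; a pair is counted once.
#'
#' @param network an `ei_network` (or a pre-computed linearized matrix via
#'   `Jt`).
#' @param auc per-neuron selectivity vector (length N), typically the `auc`
#'   column of a [compute_selectivity()] table.
#' @param x0 optional fixed point (computed if omitted).
#' @param Jt optional pre-computed linearized connectivity.
#' @param alpha familywise significance level before Bonferroni division.
#' @return an object of class `eigen_report`: list with `eigen` tibble (one
#'   row per eigenvalue: `re`, `im`, `mod`, `pair_id`, `is_complex`,
#'   `r_real`, `p_real`, `r_imag`, `p_imag`, `significant`), `norm_radius`
#'   (max |lambda|), `n_sig_pairs`, `n_sig_real`, `mean_sig_corr`,
#'   `max_corr`, `vectors`, `values`.
#' @export
eigen_selectivity <- function(network, auc, x0 = NULL, Jt = NULL,
                              alpha = 0.05) {
  if (is.null(Jt)) Jt <- linearize_network(network, x0)
  n <- nrow(Jt)
  if (length(auc) != n) {
    stop("`auc` must have one value per neuron", call. = FALSE)
  }
  if (sd(auc) == 0) {
    stop("selectivity vector is constant; correlations are undefined",
         call. = FALSE)
  }
  eig <- eigen(Jt)
  vals <- eig$values
  vecs <- eig$vectors
  re_v <- Re(vecs)
  im_v <- Im(vecs)
  r_real <- suppressWarnings(as.vector(cor(re_v, auc)))
  r_imag <- suppressWarnings(as.vector(cor(im_v, auc)))
  p_real <- ifelse(is.na(r_real), NA_real_, cor_pval(r_real, n))
  p_imag <- ifelse(is.na(r_imag), NA_real_, cor_pval(r_imag, n))
  thr <- alpha / n
  sig <- (!is.na(p_real) & p_real < thr) | (!is.na(p_imag) & p_imag < thr)

  # pair conjugate eigenvalues: members share (re, |im|)
  is_complex <- abs(Im(vals)) > 1e-10 * max(abs(vals))
  key <- paste0(signif(Re(vals), 12), "_", signif(abs(Im(vals)), 12))
  pair_id <- match(key, unique(key))
  tab <- tibble::tibble(
    re = Re(vals), im = Im(vals), mod = Mod(vals),
    pair_id = pair_id, is_complex = is_complex,
    r_real = r_real, p_real = p_real,
    r_imag = r_imag, p_imag = p_imag,
    significant = sig
  )
  by_pair <- dplyr::summarise(
    dplyr::group_by(tab, .data$pair_id),
    is_complex = .data$is_complex[1],
    significant = any(.data$significant),
    best = max(abs(c(.data$r_real, .data$r_imag)), na.rm = TRUE),
    .groups = "drop"
  )
  sig_corrs <- c(
    abs(tab$r_real[!is.na(tab$p_real) & tab$p_real < thr]),
    abs(tab$r_imag[!is.na(tab$p_imag) & tab$p_imag < thr])
  )
  structure(
    list(eigen = tab,
         norm_radius = max(Mod(vals)),
         n_sig_pairs = sum(by_pair$significant & by_pair$is_complex),
         n_sig_real = sum(by_pair$significant & !by_pair$is_complex),
         mean_sig_corr = if (length(sig_corrs)) mean(sig_corrs) else NA_real_,
         max_corr = max(by_pair$best),
         threshold = thr,
         values = vals, vectors = vecs),
    class = "eigen_report"
  )
}

#' @export
print.eigen_report <- function(x, ...) {
  cat("<eigen_report> max |lambda| = ", round(x$norm_radius, 4), "; ",
      x$n_sig_pairs, " significant complex pairs + ", x$n_sig_real,
      " real eigenvectors (p < ", format(x$threshold), ")\n", sep = "")
  invisible(x)
}

#' @describeIn eigen_selectivity per-eigenvalue tibble.
#' @param x an `eigen_report`.
#' @param ... unused.
#' @export
tidy.eigen_report <- function(x, ...) x$eigen

#' @describeIn eigen_selectivity one-row summary.
#' @export
glance.eigen_report <- function(x, ...) {
  tibble::tibble(
    norm_radius = x$norm_radius,
    n_sig_pairs = x$n_sig_pairs,
    n_sig_real = x$n_sig_real,
    mean_sig_corr = x$mean_sig_corr,
    max_corr = x$max_corr
  )
}

#' Smoothed eigenvalue density maps on the unit disk
#'
#' Normalizes eigenvalues by the per-network maximum modulus, smooths their
#' positions in the complex plane with a Gaussian kernel of width
#' `sigma = 0.1` (i.e. one tenth of the normalization radius), zeroes the
#' density outside the unit circle, and forms the density of all
#' eigenvalues, of the selectivity-correlated subset, and their ratio.
#' Multiple reports may be pooled (each normalized by its own radius).
#'
#' @param reports an `eigen_report` or list of them.
#' @param n_grid grid points per axis over \[-1, 1\].
#' @param sigma kernel width after normalization.
#' @return a tibble of class `eigen_density` with columns `re`, `im`,
#'   `density_all`, `density_sig`, `ratio` (NA where `density_all` is 0).
#' @export
eigen_density <- function(reports, n_grid = 101, sigma = 0.1) {
  if (inherits(reports, "eigen_report")) reports <- list(reports)
  pts <- dplyr::bind_rows(lapply(reports, function(r) {
    tibble::tibble(re = r$eigen$re / r$norm_radius,
                   im = r$eigen$im / r$norm_radius,
                   significant = r$eigen$significant)
  }))
  ax <- seq(-1, 1, length.out = n_grid)
  gx <- rep(ax, times = n_grid)
  gy <- rep(ax, each = n_grid)
  dens <- function(px, py) {
    if (!length(px)) return(numeric(length(gx)))
    out <- numeric(length(gx))
    for (k in seq_along(px)) {
      out <- out + exp(-((gx - px[k])^2 + (gy - py[k])^2) / (2 * sigma^2))
    }
    out / (2 * pi * sigma^2)
  }
  d_all <- dens(pts$re, pts$im)
  d_sig <- dens(pts$re[pts$significant], pts$im[pts$significant])
  outside <- gx^2 + gy^2 > 1
  d_all[outside] <- 0
  d_sig[outside] <- 0
  out <- tibble::tibble(
    re = gx, im = gy,
    density_all = d_all, density_sig = d_sig,
    ratio = ifelse(d_all > 0, d_sig / d_all, NA_real_)
  )
  attr(out, "sigma") <- sigma
  class(out) <- c("eigen_density", class(out))
  out
}
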