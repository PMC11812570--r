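# Deconvolution of spot-intensity distributions into multimer fractions.
#
# The intensity distribution of N puncta of unknown polydispersity is a
# mixture rho(x) = (1/N) sum_c A_c rho_c(x), where rho_c is the intensity
# distribution of puncta carrying c fluorophores and A_c the number of such
# puncta. rho_1 comes from a monomer calibration; higher orders are derived
# from it, and the mixture weights are estimated by reduced chi-squared
# minimization against the experimental histogram.

#' Bin intensity samples into a histogram
#'
#' @param samples Positive intensity samples (ADU).
#' @param n_bins Number of equal-width bins. Default 50.
#' @param range Intensity range `c(lo, hi)`. Default `c(0, q999)` where
#'   `q999` is the 99.9th percentile of the samples; samples above `hi` are
#'   counted in the last bin so that counts always sum to the sample count.
#' @return An object of class `intensity_histogram`: list with `bin_edges`
#'   (length B+1, strictly increasing), `counts` (length B) and `n_total`.
#' @export
build_histogram <- function(samples, n_bins = 50, range = NULL) {
  if (length(samples) == 0L) stop_arg("'samples' must be non-empty")
  if (any(!is.finite(samples)) || any(samples <= 0))
    stop_arg("'samples' must be positive and finite")
  check_scalar(n_bins, "n_bins", positive = TRUE, integerish = TRUE)
  if (is.null(range))
    range <- c(0, as.numeric(stats::quantile(samples, 0.999)))
  if (range[2] <= range[1]) stop_arg("invalid histogram range")
  edges <- seq(range[1], range[2], length.out = n_bins + 1)
  idx <- findInterval(samples, edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > n_bins] <- n_bins          # overflow pooled into last bin
  counts <- tabulate(idx, nbins = n_bins)
  new_histogram(edges, counts)
}

new_histogram <- function(bin_edges, counts) {
  stopifnot(length(bin_edges) == length(counts) + 1L,
            all(diff(bin_edges) > 0), all(counts >= 0))
  structure(list(bin_edges = bin_edges, counts = as.numeric(counts),
                 n_total = sum(counts)),
            class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat(sprintf("Intensity histogram: %d bins on [%.4g, %.4g], n = %.7g\n",
              length(x$counts), min(x$bin_edges), max(x$bin_edges),
              x$n_total))
  invisible(x)
}

hist_probs <- function(h) if (h$n_total > 0) h$counts / h$n_total else h$counts

hist_centers <- function(h) {
  e <- h$bin_edges
  (e[-1] + e[-length(e)]) / 2
}

hist_mean <- function(h) sum(hist_centers(h) * hist_probs(h))

hist_var <- function(h) {
  p <- hist_probs(h)
  m <- hist_mean(h)
  sum((hist_centers(h) - m)^2 * p)
}

# Piecewise-linear CDF (uniform within bins), evaluated at x.
hist_cdf <- function(h, x) {
  e <- h$bin_edges
  p <- hist_probs(h)
  cp <- c(0, cumsum(p))
  i <- findInterval(x, e)
  out <- numeric(length(x))
  out[i >= length(e)] <- 1
  inside <- i >= 1 & i < length(e)
  ii <- i[inside]
  w <- (x[inside] - e[ii]) / (e[ii + 1L] - e[ii])
  out[inside] <- cp[ii] + w * p[ii]
  out
}

# Redistribute histogram mass onto a new equal-width edge grid, assuming
# uniform density within source bins.
rebin_histogram <- function(h, edges) {
  if (length(h$bin_edges) == length(edges) &&
      all(abs(h$bin_edges - edges) < 1e-9))
    return(new_histogram(edges, h$counts))
  cdf_counts <- hist_cdf(h, edges) * h$n_total
  new_histogram(edges, pmax(diff(cdf_counts), 0))
}

#' Derive higher-order basis histograms from a monomer calibration
#'
#' Two transformations of the monomer histogram are supported. `scale`
#' stretches the intensity axis by c and renormalizes
#' (`rho_c(x) = rho_1(x/c)/c`), treating a c-mer as c-fold brighter with
#' the monomer's relative spread; this follows the axis-scaling transform
#' of the calibration histogram. `convolve` takes the c-fold
#' self-convolution of the monomer distribution, the model for c
#' independent emitters summing their photons. Both agree at c = 1; for
#' c >= 2 they share the mean (c times the monomer mean) but differ in
#' variance (c² vs c times the monomer variance).
#'
#' @param rho1 Monomer calibration as an `intensity_histogram` with
#'   equal-width bins starting at 0 (the [build_histogram()] default).
#' @param M Highest multimer order; >= 1. Default 3.
#' @param mode `"scale"` (default) or `"convolve"`.
#' @return An object of class `basis_set`: `bin_edges` (common extended
#'   grid reaching M times the calibration range), `rho` (B x M matrix of
#'   per-order probabilities, each column summing to 1), `M`, `mode`.
#' @export
derive_basis <- function(rho1, M = 3, mode = c("scale", "convolve")) {
  stopifnot(inherits(rho1, "intensity_histogram"))
  check_scalar(M, "M", integerish = TRUE)
  if (M < 1) stop_arg("'M' must be >= 1")
  mode <- match.arg(mode)
  e1 <- rho1$bin_edges
  w <- diff(e1)
  if (max(abs(w - w[1])) > 1e-9 * w[1])
    stop_arg("basis derivation requires equal-width bins")
  if (abs(e1[1]) > 1e-9)
    stop_arg("basis derivation requires bins starting at 0")
  w <- w[1]
  B1 <- length(rho1$counts)
  B <- B1 * M
  edges <- seq(0, B * w, length.out = B + 1)
  p1 <- hist_probs(rho1)
  rho <- matrix(0, nrow = B, ncol = M)
  norm1 <- new_histogram(e1, p1)
  for (c in seq_len(M)) {
    if (mode == "scale") {
      # mass of rho_c in [a,b] = F1(b/c) - F1(a/c)
      pc <- diff(hist_cdf(norm1, edges / c))
    } else {
      pc <- p1
      if (c > 1) for (k in seq_len(c - 1L)) {
        full <- stats::convolve(pc, rev(p1), type = "open")
        # bin centers add to bin *edges*: (i-1/2)w + (j-1/2)w = (i+j-1)w.
        # Split each coefficient between the two adjacent bins so the mean
        # is preserved exactly (adds w^2/4 of variance per fold, negligible
        # next to the distribution's own variance).
        ext <- c(0, full) / 2 + c(full, 0) / 2
        pc <- ext[seq_len(min(length(ext), B))]
      }
      pc <- c(pc, numeric(B - length(pc)))
    }
    pc[pc < 0] <- 0
    rho[, c] <- pc / sum(pc)
  }
  structure(list(bin_edges = edges, rho = rho, M = M, mode = mode),
            class = "basis_set")
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("Basis set: M = %d (%s mode), %d bins on [0, %.4g]\n",
              x$M, x$mode, nrow(x$rho), max(x$bin_edges)))
  invisible(x)
}

basis_component_histogram <- function(basis, c) {
  new_histogram(basis$bin_edges, basis$rho[, c])
}

# Inverse-CDF draw of n intensities from one basis column (uniform within
# the selected bin).
sample_basis <- function(basis, c, n) {
  p <- basis$rho[, c]
  cdf <- cumsum(p)
  u <- stats::runif(n)
  i <- findInterval(u, c(0, cdf), rightmost.closed = TRUE)
  i[i < 1L] <- 1L
  i[i > length(p)] <- length(p)
  e <- basis$bin_edges
  e[i] + stats::runif(n) * (e[i + 1L] - e[i])
}

#' Simulate a model histogram from a basis set
#'
#' Draws `n` spots by choosing an order c from `fractions` and then an
#' intensity from the corresponding basis histogram by inverse-CDF
#' sampling, and bins the result on the basis grid.
#'
#' @param basis A [derive_basis()] result.
#' @param fractions Simplex weights over c = 1..M.
#' @param n Number of draws; 0 gives an all-zero histogram.
#' @param seed Optional integer seed.
#' @return An `intensity_histogram` on the basis grid.
#' @export
simulate_model_histogram <- function(basis, fractions, n, seed = NULL) {
  stopifnot(inherits(basis, "basis_set"))
  check_fractions(fractions)
  if (length(fractions) != basis$M)
    stop_arg("'fractions' must have length M = %d", basis$M)
  check_scalar(n, "n", nonneg = TRUE, integerish = TRUE)
  if (n == 0)
    return(new_histogram(basis$bin_edges, numeric(nrow(basis$rho))))
  with_seed(seed, {
    ord <- sample.int(basis$M, n, replace = TRUE, prob = fractions)
    x <- numeric(n)
    for (c in seq_len(basis$M)) {
      idx <- which(ord == c)
      if (length(idx)) x[idx] <- sample_basis(basis, c, length(idx))
    }
    e <- basis$bin_edges
    i <- findInterval(x, e, rightmost.closed = TRUE)
    i[i < 1L] <- 1L; i[i > nrow(basis$rho)] <- nrow(basis$rho)
    new_histogram(e, tabulate(i, nbins = nrow(basis$rho)))
  })
}

# Pool adjacent bins left to right until each group's reference count
# reaches min_expected; a trailing underfull group merges into its
# predecessor. Returns an integer group index per bin (NA = excluded
# because the reference is all-zero beyond support).
pool_bins <- function(reference, min_expected = 5) {
  B <- length(reference)
  grp <- integer(B)
  g <- 1L; acc <- 0
  for (b in seq_len(B)) {
    grp[b] <- g
    acc <- acc + reference[b]
    if (acc >= min_expected) { g <- g + 1L; acc <- 0 }
  }
  if (acc > 0 && g > 1L) grp[grp == g] <- g - 1L
  grp
}

#' Reduced chi-squared between observed and expected histograms
#'
#' Computes `sum((obs - exp)^2 / exp)` over included bins divided by
#' `dof = bins_included - n_free_params - 1`. Bins with expected count
#' below `min_expected` are pooled into their right neighbours first
#' (trailing remainder into the last group), the standard validity
#' condition for the chi-squared approximation.
#'
#' @param obs,expected `intensity_histogram`s on a common grid (or bare
#'   count vectors of equal length).
#' @param n_free_params Number of fitted parameters consumed by the model.
#' @param min_expected Pooling threshold. Default 5.
#' @return The reduced chi-squared statistic, with attributes `chi2` (the
#'   unreduced sum), `dof` and `n_bins` (groups used).
#' @export
reduced_chi2 <- function(obs, expected, n_free_params = 0, min_expected = 5) {
  o <- if (inherits(obs, "intensity_histogram")) obs$counts else obs
  e <- if (inherits(expected, "intensity_histogram")) expected$counts
       else expected
  if (length(o) != length(e))
    stop_arg("observed and expected histograms must share a grid")
  keep <- e > 0 | o > 0
  o <- o[keep]; e <- e[keep]
  grp <- pool_bins(e, min_expected)
  og <- rowsum(o, grp); eg <- rowsum(e, grp)
  dof <- length(eg) - n_free_params - 1L
  if (dof <= 0) stop_arg("chi-squared dof <= 0 (too few occupied bins)")
  chi2 <- sum((og - eg)^2 / pmax(eg, .Machine$double.eps))
  structure(chi2 / dof, chi2 = chi2, dof = dof, n_bins = length(eg))
}

#' Fit multimer fractions by reduced chi-squared minimization
#'
#' Estimates the mixture weights A_c/N by minimizing the reduced
#' chi-squared between the experimental histogram and the model expectation
#' `n_total * sum_c f_c rho_c`. The basis columns are Monte-Carlo smoothed:
#' each is replaced by the empirical histogram of `n_draws` inverse-CDF
#' draws, mirroring a fit of randomly generated model distributions to the
#' data. The simplex constraint is enforced by a softmax parameterization
#' and the objective minimized by Nelder-Mead from `n_restarts` random
#' starting points; the best restart is reported.
#'
#' @param expt Experimental `intensity_histogram`; at least 100 spots.
#'   Rebinned onto the basis grid internally if the grids differ.
#' @param basis A [derive_basis()] result.
#' @param n_draws Monte-Carlo draws per basis component. Default
#'   `20 * expt$n_total`.
#' @param n_restarts Optimizer restarts. Default 10.
#' @param seed Integer seed controlling draws and restarts. Default 1.
#' @param min_expected Chi-squared pooling threshold. Default 5.
#' @return An object of class `mixture_fit`: `fractions` (simplex over
#'   c = 1..M), `chi2_red`, `dof`, `n_draws`, `seed`, `convergence`.
#' @export
fit_mixture <- function(expt, basis, n_draws = NULL, n_restarts = 10,
                        seed = 1, min_expected = 5) {
  stopifnot(inherits(expt, "intensity_histogram"),
            inherits(basis, "basis_set"))
  if (expt$n_total < 100)
    stop_arg("at least 100 spots are required for a mixture fit (got %d)",
             expt$n_total)
  if (all(expt$counts == 0)) stop_arg("experimental histogram is all zero")
  if (is.null(n_draws)) n_draws <- 20 * expt$n_total
  check_scalar(n_draws, "n_draws", positive = TRUE, integerish = TRUE)
  M <- basis$M
  obs <- rebin_histogram(expt, basis$bin_edges)$counts
  n_tot <- expt$n_total

  res <- with_seed(seed, {
    rho_hat <- matrix(0, nrow = nrow(basis$rho), ncol = M)
    for (c in seq_len(M)) {
      h <- simulate_model_histogram(basis,
                                    fractions = as.numeric(seq_len(M) == c),
                                    n = n_draws)
      rho_hat[, c] <- hist_probs(h)
    }
    # Pooling is frozen from the observed counts so the objective surface
    # is continuous in the fractions.
    keep <- obs > 0 | rowSums(rho_hat) > 0
    obs_k <- obs[keep]; rho_k <- rho_hat[keep, , drop = FALSE]
    grp <- pool_bins(obs_k, min_expected)
    og <- rowsum(obs_k, grp)
    rg <- rowsum(rho_k, grp)
    dof <- nrow(rg) - (M - 1L) - 1L
    if (dof <= 0) stop_arg("chi-squared dof <= 0 (too few occupied bins)")
    objective <- function(logits) {
      f <- exp(c(logits, 0)); f <- f / sum(f)
      eg <- pmax(n_tot * (rg %*% f), .Machine$double.eps)
      sum((og - eg)^2 / eg) / dof
    }
    if (M == 1L) {
      list(fractions = 1, chi2_red = objective(numeric(0)), dof = dof,
           convergence = 0L)
    } else {
      best <- NULL
      for (r in seq_len(n_restarts)) {
        p0 <- if (r == 1L) numeric(M - 1L) else stats::rnorm(M - 1L, 0, 2)
        opt <- stats::optim(p0, objective, method = "Nelder-Mead",
                            control = list(maxit = 2000, reltol = 1e-10))
        if (is.null(best) || opt$value < best$value) best <- opt
      }
      f <- exp(c(best$par, 0)); f <- f / sum(f)
      list(fractions = f, chi2_red = best$value, dof = dof,
           convergence = best$convergence)
    }
  })
  structure(list(fractions = res$fractions, chi2_red = res$chi2_red,
                 dof = res$dof, n_draws = n_draws, seed = seed,
                 M = M, mode = basis$mode, convergence = res$convergence),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Multimer mixture fit (M = %d, %s basis)\n", x$M, x$mode))
  cat("  fractions:",
      paste(sprintf("c=%d: %.3f", seq_len(x$M), x$fractions),
            collapse = ", "), "\n")
  cat(sprintf("  reduced chi-squared: %.3f on %d dof (seed %d)\n",
              x$chi2_red, x$dof, x$seed))
  invisible(x)
}
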