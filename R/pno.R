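#' Predicted niche occupancy (PNO) profile
#'
#' Bins one PC axis into `n_bins` evenly spaced categories over its observed
#' range and assigns each bin the total envelope suitability of the cells
#' whose PC value falls in it, normalized to a probability distribution: the
#' suitability-weighted distribution of the clade over that axis.
#'
#' @param suitability an `env_grid` of suitabilities (or numeric vector),
#'   e.g. from [suitability_map()].
#' @param pc_grid an `env_grid` (or numeric vector) of the PC score of every
#'   cell, sharing the suitability's geometry.
#' @param n_bins number of bins (default 100).
#' @param axis optional axis label stored in the profile.
#' @return object of class `pno_profile`: data.frame-like list with
#'   `bin_center` and `mass` (length `n_bins`, masses sum to 1).
#' @export
pno_profile <- function(suitability, pc_grid, n_bins = 100, axis = NA) {
  s <- if (inherits(suitability, "env_grid")) as.vector(suitability$values)
       else as.numeric(suitability)
  v <- if (inherits(pc_grid, "env_grid")) as.vector(pc_grid$values)
       else as.numeric(pc_grid)
  if (inherits(suitability, "env_grid") && inherits(pc_grid, "env_grid") &&
      !same_geometry(suitability, pc_grid))
    stop("suitability and PC grids do not share geometry")
  if (length(s) != length(v))
    stop("suitability and PC values have different lengths")
  ok <- is.finite(s) & is.finite(v)
  s <- s[ok]; v <- v[ok]
  if (length(s) == 0 || sum(s) <= 0)
    stop("total suitability is zero: no occupancy to profile")
  if (n_bins < 1) stop("'n_bins' must be >= 1")
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  idx <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1), n_bins)
  mass <- vapply(seq_len(n_bins), function(b) sum(s[idx == b]), numeric(1))
  structure(list(bin_center = centers, mass = mass / sum(mass),
                 n_bins = n_bins, axis = axis),
            class = "pno_profile")
}

#' @export
print.pno_profile <- function(x, ...) {
  mu <- sum(x$bin_center * x$mass)
  cat(sprintf(
    "pno_profile%s: %d bins over [%.4g, %.4g], mean %.4g\n",
    if (is.na(x$axis)) "" else paste0(" (", x$axis, ")"),
    x$n_bins, min(x$bin_center), max(x$bin_center), mu))
  invisible(x)
}

#' @export
plot.pno_profile <- function(x, ...) {
  graphics::plot(x$bin_center, x$mass, type = "h",
                 xlab = if (is.na(x$axis)) "PC score" else x$axis,
                 ylab = "occupancy probability", ...)
  invisible(x)
}

#' Draw random climatic-tolerance samples from a PNO profile
#'
#' i.i.d. draws of bin centers with probability equal to bin mass.
#'
#' @param profile a `pno_profile`.
#' @param n number of draws (default 1000).
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @export
sample_pno <- function(profile, n = 1000, seed = NULL) {
  stopifnot(inherits(profile, "pno_profile"))
  if (!is.null(seed)) set.seed(seed)
  profile$bin_center[sample.int(profile$n_bins, n, replace = TRUE,
                                prob = profile$mass)]
}

#' Equal-tail central density interval
#'
#' The central `mass` of a sample: the `(1-mass)/2` and `1-(1-mass)/2`
#' percentiles (default the 10th to 90th, i.e. the 80\% central density).
#'
#' @param samples numeric vector (>= 10 values).
#' @param mass central probability mass in (0, 1); default 0.80.
#' @return numeric `c(lo, hi)`.
#' @export
central_density_interval <- function(samples, mass = 0.80) {
  if (!is.numeric(mass) || length(mass) != 1 || mass <= 0 || mass >= 1)
    stop("'mass' must lie strictly between 0 and 1")
  if (length(samples) < 10) stop("need at least 10 samples")
  a <- (1 - mass) / 2
  stats::quantile(samples, c(a, 1 - a), names = FALSE)
}
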