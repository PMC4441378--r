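#' Occupancy-corrected density grid in 2-D environmental space
#'
#' Smooths occurrence and background scores on the first two PCs with a
#' Gaussian kernel onto a shared `r` x `r` lattice spanning the background
#' envelope (expanded by a 5\% margin), and corrects occurrence density `o`
#' by background availability `e`: the occupancy `z` is proportional to
#' `o / e` on the observed available environment -- lattice cells containing
#' at least one background point and with `e` above a floor -- and 0
#' elsewhere, normalized to sum 1. Restricting the ratio to the empirical
#' background support matters: beyond it the occurrence kernel's tails decay
#' more slowly than the background kernel's (the occurrence sample is
#' smaller, hence its bandwidth larger), so `o / e` grows without bound and a
#' single margin cell can otherwise swallow the occupancy mass. Per-axis
#' bandwidths follow the two-dimensional normal-reference (Silverman) rule
#' `sigma * n^(-1/6)`, computed from each point cloud.
#'
#' @param occ_scores numeric matrix (n x 2) of occurrence PC scores; n >= 5.
#' @param bg_scores numeric matrix (m x 2) of background PC scores whose
#'   envelope covers the occurrences.
#' @param r lattice resolution per axis (default 100).
#' @param bandwidth optional numeric length-2 kernel SDs overriding the
#'   normal-reference rule (applied to both clouds).
#' @param correct logical; if `FALSE`, `z` is the plain normalized occurrence
#'   density `o` (no availability correction).
#' @param e_floor background-density floor below which `z` is set to 0.
#' @param margin fractional envelope expansion.
#' @param support_mask logical; restrict `z` to lattice cells containing at
#'   least one background point (default) rather than to the floor rule only.
#' @return object of class `density_grid` with elements `o`, `e`, `z`
#'   (r x r matrices), `x`, `y` (cell centers) and `r`.
#' @export
density_grid <- function(occ_scores, bg_scores, r = 100, bandwidth = NULL,
                         correct = TRUE, e_floor = 1e-12, margin = 0.05,
                         support_mask = TRUE) {
  occ <- score_matrix(occ_scores, "occ_scores")
  bg <- score_matrix(bg_scores, "bg_scores")
  if (nrow(occ) < 5) stop("need at least 5 occurrence points")
  if (r < 2) stop("'r' must be at least 2")
  lims <- envelope_limits(bg, margin)
  kd_o <- kde2d_grid(occ, r, lims, bandwidth)
  kd_e <- kde2d_grid(bg, r, lims, bandwidth)
  o <- kd_o$z / sum(kd_o$z)
  e <- kd_e$z / sum(kd_e$z)
  avail <- e > e_floor
  if (support_mask)
    avail <- avail & cell_support(bg, kd_e$x, kd_e$y)
  z <- if (correct) ifelse(avail, o / e, 0) else o * avail
  if (sum(z) <= 0) stop("occupancy surface is identically zero")
  z <- z / sum(z)
  structure(list(o = o, e = e, z = z, x = kd_o$x, y = kd_o$y, r = r),
            class = "density_grid")
}

# TRUE for lattice cells holding at least one background point
cell_support <- function(pts, gx, gy) {
  ix <- pmin(pmax(findInterval(pts[, 1], gx - (gx[2] - gx[1]) / 2), 1),
             length(gx))
  iy <- pmin(pmax(findInterval(pts[, 2], gy - (gy[2] - gy[1]) / 2), 1),
             length(gy))
  m <- matrix(FALSE, length(gx), length(gy))
  m[cbind(ix, iy)] <- TRUE
  m
}

score_matrix <- function(x, what) {
  m <- cbind(x)
  if (ncol(m) < 2)
    stop("'", what, "' needs two columns (scores on PCs 1-2)")
  m <- m[, 1:2, drop = FALSE]
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (any(apply(m, 2, stats::sd) == 0))
    stop("'", what, "' is degenerate: zero variance on a PC axis")
  m
}

envelope_limits <- function(bg, margin) {
  rx <- range(bg[, 1]); ry <- range(bg[, 2])
  pad <- c(diff(rx), diff(ry)) * margin
  c(rx[1] - pad[1], rx[2] + pad[1], ry[1] - pad[2], ry[2] + pad[2])
}

# normal-reference (Silverman) bandwidth per axis for a 2-D kernel density:
# h_i = sigma_i * n^(-1/(d+4)) with d = 2; the robust IQR-based spread guards
# against heavy tails
silverman_bw <- function(v) {
  n <- length(v)
  s <- stats::sd(v)
  iqr <- stats::IQR(v)
  spread <- if (iqr > 0) min(s, iqr / 1.34) else s
  spread * n^(-1 / 6)
}

# MASS::kde2d evaluates a normal kernel with SD = h / 4
kde2d_grid <- function(pts, r, lims, bandwidth = NULL) {
  h <- if (is.null(bandwidth)) apply(pts, 2, silverman_bw) else bandwidth
  if (any(h <= 0)) stop("non-positive kernel bandwidth")
  MASS::kde2d(pts[, 1], pts[, 2], h = 4 * h, n = r, lims = lims)
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("density_grid: %d x %d cells over [%.3g, %.3g] x [%.3g, %.3g]\n",
              x$r, x$r, min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

#' @export
plot.density_grid <- function(x, which = c("z", "o", "e"), ...) {
  which <- match.arg(which)
  graphics::image(x$x, x$y, x[[which]], xlab = "PC1", ylab = "PC2",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}

#' Schoener's D overlap between two occupancy grids
#'
#' `D = 1 - 0.5 * sum(|z1 - z2|)`, from 0 (no overlap) to 1 (identical
#' occupancy).
#'
#' @param z1,z2 `density_grid` objects on the same lattice, or plain
#'   non-negative matrices/vectors that each sum to 1.
#' @return numeric scalar in `[0, 1]`.
#' @export
schoener_d <- function(z1, z2) {
  a <- occupancy_of(z1); b <- occupancy_of(z2)
  if (!identical(dim(rbind(a)), dim(rbind(b))))
    stop("occupancy grids are not on the same lattice")
  if (inherits(z1, "density_grid") && inherits(z2, "density_grid") &&
      (max(abs(z1$x - z2$x)) > 1e-8 || max(abs(z1$y - z2$y)) > 1e-8))
    stop("occupancy grids are not on the same lattice")
  max(0, min(1, 1 - 0.5 * sum(abs(a - b))))
}

occupancy_of <- function(z) {
  if (inherits(z, "density_grid")) return(z$z)
  if (!is.numeric(z)) stop("not an occupancy grid")
  if (abs(sum(z) - 1) > 1e-6)
    stop("occupancy values must sum to 1")
  z
}

#' Rank an overlap value on the standard qualitative scale
#'
#' Bins: `[0, 0.2)` none or very limited, `[0.2, 0.4)` low, `[0.4, 0.6)`
#' moderate, `[0.6, 0.8)` high, `[0.8, 1]` very high.
#'
#' @param d Schoener's D value in `[0, 1]`.
#' @return factor label among `none`, `low`, `moderate`, `high`, `very high`.
#' @export
classify_overlap <- function(d) {
  if (any(!is.finite(d) | d < 0 | d > 1))
    stop("'d' must lie in [0, 1]")
  cut(d, breaks = c(0, 0.2, 0.4, 0.6, 0.8, 1),
      labels = c("none", "low", "moderate", "high", "very high"),
      include.lowest = TRUE, right = FALSE)
}

# shared core for the two randomization tests
overlap_test_result <- function(method, observed, simulated, direction = NA) {
  n <- length(simulated)
  n_le <- sum(simulated <= observed)
  n_ge <- sum(simulated >= observed)
  p <- min(1, 2 * (min(n_le, n_ge) + 1) / (n + 1))
  ci <- stats::quantile(simulated, c(0.025, 0.975), names = FALSE)
  structure(
    list(method = method, observed = observed, simulated = simulated,
         p_value = p, ci = ci,
         rejected = observed < ci[1] || observed > ci[2],
         direction = direction, n_reps = n),
    class = "niche_overlap_test"
  )
}

#' @export
print.niche_overlap_test <- function(x, ...) {
  cat(sprintf("%s\n  observed D = %.4f, %d randomizations\n", x$method,
              x$observed, x$n_reps))
  if (!is.na(x$direction)) cat(sprintf("  direction: %s\n", x$direction))
  cat(sprintf("  95%% CI of simulated D: [%.4f, %.4f]\n", x$ci[1], x$ci[2]))
  cat(sprintf("  p = %.4g -> null %s at the 95%% level\n", x$p_value,
              if (x$rejected) "REJECTED" else "not rejected"))
  invisible(x)
}

#' Niche equivalency randomization test
#'
#' Pools the two clades' occurrence scores, randomly re-splits them into two
#' sets of the original sizes `n_reps` times, and recomputes Schoener's D on
#' each split (both densities corrected by the pooled background). The null
#' of niche equivalency is rejected when the observed D falls outside the 95\%
#' confidence interval of the simulated values; the reported p-value is the
#' two-sided add-one permutation p, so its floor at 100 randomizations is
#' `2 * 1 / 101`, printing as 0.02.
#'
#' @param occ1,occ2 occurrence PC-score matrices (n x 2) of the two clades.
#' @param pooled_background background PC-score matrix of the pooled
#'   available environmental space.
#' @param n_reps number of random re-splits (default 100).
#' @param seed integer seed.
#' @param ... passed to [density_grid()] (e.g. `r`, `bandwidth`).
#' @return a `niche_overlap_test`.
#' @export
equivalency_test <- function(occ1, occ2, pooled_background, n_reps = 100,
                             seed = NULL, ...) {
  if (n_reps < 1) stop("'n_reps' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  occ1 <- score_matrix(occ1, "occ1")
  occ2 <- score_matrix(occ2, "occ2")
  obs <- schoener_d(density_grid(occ1, pooled_background, ...),
                    density_grid(occ2, pooled_background, ...))
  pool <- rbind(occ1, occ2)
  n1 <- nrow(occ1)
  sim <- vapply(seq_len(n_reps), function(i) {
    pick <- sample.int(nrow(pool), n1)
    schoener_d(
      density_grid(pool[pick, , drop = FALSE], pooled_background, ...),
      density_grid(pool[-pick, , drop = FALSE], pooled_background, ...)
    )
  }, numeric(1))
  overlap_test_result("niche equivalency test", obs, sim)
}

#' Niche background-similarity randomization test (one direction)
#'
#' Compares the observed overlap of the focal clade with the other clade to
#' the overlaps obtained when the other clade is replaced by random records
#' drawn uniformly from its own available background (`n_reps` draws of the
#' other clade's sample size). Rejection (observed above the 97.5\% or below
#' the 2.5\% quantile of the simulated values) indicates the overlap is
#' driven by habitat selection, not by the structure of the available
#' environment. Run it in both directions by swapping the arguments.
#'
#' @param occ_focal focal clade's occurrence PC scores (n x 2).
#' @param occ_other other clade's occurrence PC scores; sets the size of the
#'   random record sets and the observed D.
#' @param bg_other background PC scores of the other clade, from which random
#'   records are drawn.
#' @param pooled_background background scores used for the density lattice
#'   and occupancy correction; defaults to `bg_other`.
#' @param n_reps number of randomizations (default 100).
#' @param seed integer seed.
#' @param direction free-text label stored in the result.
#' @param ... passed to [density_grid()].
#' @return a `niche_overlap_test`.
#' @export
similarity_test <- function(occ_focal, occ_other, bg_other,
                            pooled_background = bg_other, n_reps = 100,
                            seed = NULL, direction = NA, ...) {
  if (n_reps < 1) stop("'n_reps' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  occ_focal <- score_matrix(occ_focal, "occ_focal")
  occ_other <- score_matrix(occ_other, "occ_other")
  bg_other <- score_matrix(bg_other, "bg_other")
  if (nrow(bg_other) < 1) stop("empty background for the other clade")
  z_focal <- density_grid(occ_focal, pooled_background, ...)
  obs <- schoener_d(z_focal, density_grid(occ_other, pooled_background, ...))
  n_other <- nrow(occ_other)
  sim <- vapply(seq_len(n_reps), function(i) {
    rand <- bg_other[sample.int(nrow(bg_other), n_other, replace = TRUE), ,
                     drop = FALSE]
    schoener_d(z_focal, density_grid(rand, pooled_background, ...))
  }, numeric(1))
  overlap_test_result("niche background-similarity test", obs, sim,
                      direction = direction)
}
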