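#' Correlation-matrix PCA of environmental predictors
#'
#' Standardizes every variable (the inputs mix units: temperatures,
#' reflectance indices) and eigendecomposes the correlation matrix. Components
#' with eigenvalue strictly greater than 1 are retained (Kaiser rule, ties at
#' exactly 1 excluded). Constant variables are dropped with a warning. The
#' Pearson correlation of every input variable with every retained component
#' is exposed for loading tables.
#'
#' @param x a `predictor_set`, or a numeric cells-by-variables matrix.
#' @param cells optional logical or integer vector selecting the cells
#'   (rows) used for training; default: all rows with complete data.
#' @return object of class `env_pca` with elements `center`, `scale`,
#'   `rotation` (all components), `eigenvalues`, `retained`, `scores`
#'   (training scores on retained components), `correlations`
#'   (variables x retained PCs) and `variables`.
#' @export
fit_pca <- function(x, cells = NULL) {
  m <- if (inherits(x, "predictor_set")) as.matrix(x) else as.matrix(x)
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  if (!is.null(cells)) m <- m[cells, , drop = FALSE]
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2) stop("need at least 2 valid cells to fit a PCA")
  const <- apply(m, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("dropping constant variable(s): ",
            paste(colnames(m)[const], collapse = ", "))
    m <- m[, !const, drop = FALSE]
  }
  if (ncol(m) < 1) stop("no non-constant variables left")
  p <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  ev <- p$sdev^2
  retained <- max(1L, sum(ev > 1))
  scores <- p$x[, seq_len(retained), drop = FALSE]
  cors <- stats::cor(m, scores)
  structure(
    list(center = p$center, scale = p$scale, rotation = p$rotation,
         eigenvalues = ev, retained = retained, scores = scores,
         correlations = cors, variables = colnames(m)),
    class = "env_pca"
  )
}

#' @export
print.env_pca <- function(x, ...) {
  pvar <- 100 * x$eigenvalues / sum(x$eigenvalues)
  cat(sprintf(
    "env_pca: %d variables, %d retained components (eigenvalue > 1)\n",
    length(x$variables), x$retained))
  cat(sprintf("  PC%d: eigenvalue %.3f (%.2f%% of variance)\n",
              seq_len(x$retained), x$eigenvalues[seq_len(x$retained)],
              pvar[seq_len(x$retained)]), sep = "")
  invisible(x)
}

#' Project predictor values into PCA space
#'
#' @param object an `env_pca`.
#' @param newdata numeric vector or cells-by-variables matrix on the same
#'   variables the PCA was trained on.
#' @param n_components number of leading components to return; defaults to
#'   the retained count.
#' @param ... unused.
#' @return matrix of scores (rows = input rows); rows with `NA` input give
#'   `NA` scores.
#' @export
predict.env_pca <- function(object, newdata, n_components = object$retained,
                            ...) {
  m <- rbind(newdata)
  if (ncol(m) != length(object$variables))
    stop("newdata has ", ncol(m), " variables, PCA was trained on ",
         length(object$variables))
  z <- sweep(sweep(m, 2, object$center), 2, object$scale, `/`)
  s <- z %*% object$rotation[, seq_len(n_components), drop = FALSE]
  rownames(s) <- rownames(newdata)
  s
}

#' Alias for [predict.env_pca()]
#' @inheritParams predict.env_pca
#' @param transform an `env_pca`.
#' @param values predictor values to project.
#' @return matrix of PC scores.
#' @export
project <- function(transform, values, n_components = transform$retained) {
  predict(transform, values, n_components)
}

#' Geographic background mask around a clade's records
#'
#' A cell belongs to the background iff the great-circle (haversine,
#' spherical Earth, R = 6371 km) distance from its center to the nearest
#' record is at most `radius_km`. Masked (invalid) cells are never included.
#'
#' @param occurrences an `occurrence_set` (typically one clade) or data.frame
#'   with `lon`, `lat`.
#' @param grid an `env_grid` supplying geometry and valid-cell mask.
#' @param radius_km buffer radius in kilometres (default 100, the potentially
#'   colonisable neighbourhood).
#' @return object of class `background_mask`: logical matrix shaped like the
#'   grid plus `radius_km` attribute.
#' @export
background_mask <- function(occurrences, grid, radius_km = 100) {
  if (nrow(occurrences) < 1) stop("need at least one record")
  e <- grid_extent(grid)
  outside <- occurrences$lon < e["xmin"] | occurrences$lon > e["xmax"] |
    occurrences$lat < e["ymin"] | occurrences$lat > e["ymax"]
  if (any(outside))
    stop("record(s) outside the grid extent at rows: ",
         paste(which(outside), collapse = ", "))
  cc <- grid_coords(grid)
  dmin <- rep(Inf, nrow(cc))
  for (i in seq_len(nrow(occurrences))) {
    d <- geosphere::distHaversine(
      cbind(cc$lon, cc$lat),
      c(occurrences$lon[i], occurrences$lat[i]),
      r = 6371000
    )
    dmin <- pmin(dmin, d)
  }
  inside <- matrix(dmin <= radius_km * 1000,
                   nrow(grid$values), ncol(grid$values))
  inside[is.na(grid$values)] <- FALSE
  structure(inside, class = "background_mask", radius_km = radius_km)
}

#' Write PCA loadings in a component-loadings table layout
#'
#' One row per variable; per retained component, the loading and the Pearson
#' correlation of the variable with the component scores.
#'
#' @param pca an `env_pca`.
#' @param path CSV output path.
#' @export
write_loadings_csv <- function(pca, path) {
  k <- pca$retained
  tab <- data.frame(variable = pca$variables)
  for (j in seq_len(k)) {
    tab[[paste0("PC", j, "_loading")]] <- pca$rotation[, j]
    tab[[paste0("PC", j, "_r")]] <- pca$correlations[, j]
  }
  ev <- data.frame(variable = c("eigenvalue", "pct_variance"))
  for (j in seq_len(k)) {
    ev[[paste0("PC", j, "_loading")]] <-
      c(pca$eigenvalues[j], 100 * pca$eigenvalues[j] / sum(pca$eigenvalues))
    ev[[paste0("PC", j, "_r")]] <- NA_real_
  }
  utils::write.csv(rbind(tab, ev), path, row.names = FALSE)
  invisible(path)
}
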