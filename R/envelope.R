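#' Fit a boxcar (Bioclim) environmental envelope
#'
#' Stores the empirical training distribution of each environmental axis
#' (typically retained PC scores at a clade's records). Axes are independent:
#' no weighting or interaction between them.
#'
#' @param training_scores numeric matrix, one row per record, one column per
#'   axis; or a numeric vector for a single axis.
#' @return object of class `bioclim_envelope`: list of sorted per-axis
#'   training values plus `n_axes`.
#' @export
fit_envelope <- function(training_scores) {
  m <- cbind(training_scores)
  if (!is.numeric(m)) stop("training scores must be numeric")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2) stop("need at least 2 records with finite scores")
  axes <- lapply(seq_len(ncol(m)), function(j) sort(m[, j]))
  names(axes) <- colnames(m) %||% paste0("axis", seq_len(ncol(m)))
  degenerate <- vapply(axes, function(v) v[1] == v[length(v)], TRUE)
  if (any(degenerate))
    warning("axis with constant training values: predictions on it are ",
            "degenerate (0/1 only): ",
            paste(names(axes)[degenerate], collapse = ", "))
  structure(list(axes = axes, n_axes = length(axes)),
            class = "bioclim_envelope")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bioclim_envelope <- function(x, ...) {
  cat(sprintf("bioclim_envelope: %d axes, %d training records\n",
              x$n_axes, length(x$axes[[1]])))
  for (j in seq_len(x$n_axes)) {
    v <- x$axes[[j]]
    cat(sprintf("  %s: [%.4g, %.4g], median %.4g\n",
                names(x$axes)[j], v[1], v[length(v)], stats::median(v)))
  }
  invisible(x)
}

# midpoint-convention empirical CDF: (#{v < x} + 0.5 * #{v = x}) / n
ecdf_midpoint <- function(sorted_values, x) {
  n <- length(sorted_values)
  n_le <- findInterval(x, sorted_values)
  n_lt <- findInterval(x, sorted_values, left.open = TRUE)
  (n_lt + 0.5 * (n_le - n_lt)) / n
}

#' Predict envelope suitability
#'
#' Percentile-score dialect: on each axis the score is
#' `1 - 2 * |F(x) - 0.5|` with `F` the empirical CDF under the midpoint tie
#' convention, so suitability peaks at the axis median and declines to 0 at
#' the training range limits; it is exactly 0 outside the per-axis min--max
#' box. The overall suitability is the minimum across axes. `type = "binary"`
#' gives the classic presence/absence box instead.
#'
#' @param object a `bioclim_envelope`.
#' @param newdata numeric vector (one point) or matrix (rows = points) with
#'   one column per axis.
#' @param type `"percentile"` (continuous, default) or `"binary"`.
#' @param ... unused.
#' @return numeric vector of suitabilities in `[0, 1]`; `NA` for rows with
#'   non-finite input.
#' @export
predict.bioclim_envelope <- function(object, newdata,
                                     type = c("percentile", "binary"), ...) {
  type <- match.arg(type)
  m <- cbind(newdata)
  if (ncol(m) != object$n_axes)
    stop("query has ", ncol(m), " axes, envelope has ", object$n_axes)
  per_axis <- vapply(seq_len(object$n_axes), function(j) {
    v <- object$axes[[j]]
    x <- m[, j]
    s <- if (type == "percentile") {
      f <- ecdf_midpoint(v, x)
      1 - 2 * abs(f - 0.5)
    } else {
      as.numeric(x >= v[1] & x <= v[length(v)])
    }
    s[x < v[1] | x > v[length(v)]] <- 0
    s[!is.finite(x)] <- NA_real_
    s
  }, numeric(nrow(m)))
  per_axis <- matrix(per_axis, nrow = nrow(m), ncol = object$n_axes)
  apply(per_axis, 1, function(r) if (any(is.na(r))) NA_real_ else min(r))
}

#' Suitability surface over a grid of PC scores
#'
#' @param model a `bioclim_envelope`.
#' @param pc_grids list of `env_grid`s, one per envelope axis, holding the PC
#'   score of every cell.
#' @param ... passed to [predict.bioclim_envelope()].
#' @return an `env_grid` of suitabilities in `[0, 1]` (`NA` on masked cells).
#' @export
suitability_map <- function(model, pc_grids, ...) {
  ref <- pc_grids[[1]]
  scores <- vapply(pc_grids, function(g) as.vector(g$values),
                   numeric(length(ref$values)))
  s <- predict(model, scores, ...)
  env_grid(matrix(s, nrow(ref$values), ncol(ref$values)),
           ref$xmin, ref$ymin, ref$cellsize)
}
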