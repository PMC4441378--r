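#' Seasonal (bioclim-style) summaries of one 12-month series
#'
#' Computes the seven temperature-style transformations used for a single
#' monthly variable: BIO1 annual mean; BIO4 seasonality (standard deviation
#' of the 12 monthly values, scaled by 100 by default); BIO5 value of the
#' highest month; BIO6 value of the lowest month; BIO7 annual range
#' (BIO5 - BIO6); BIO10 / BIO11 mean of the three-consecutive-month quarter
#' (December wraps to January) with the highest / lowest mean, ties broken by
#' the earliest starting month.
#'
#' @param monthly numeric vector of 12 monthly values.
#' @param seasonality_scale multiplier applied to the standard deviation for
#'   BIO4; 100 by convention of the classic bioclim tooling, set 1 for raw SD.
#' @param sd_type `"sample"` (n-1 denominator, the default of the classic
#'   tooling) or `"population"`.
#' @return named numeric vector `BIO1, BIO4, BIO5, BIO6, BIO7, BIO10, BIO11`;
#'   all `NA` if any input is non-finite (mask propagation).
#' @export
biovars_single <- function(monthly, seasonality_scale = 100,
                           sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(monthly) != 12) stop("'monthly' must have length 12")
  out_names <- c("BIO1", "BIO4", "BIO5", "BIO6", "BIO7", "BIO10", "BIO11")
  if (any(!is.finite(monthly)))
    return(stats::setNames(rep(NA_real_, 7), out_names))
  q <- quarter_means(monthly)
  s <- if (sd_type == "sample") stats::sd(monthly)
       else sqrt(mean((monthly - mean(monthly))^2))
  stats::setNames(c(
    mean(monthly),
    s * seasonality_scale,
    max(monthly),
    min(monthly),
    max(monthly) - min(monthly),
    max(q),
    min(q)
  ), out_names)
}

# means of the 12 quarters starting at each month, with Dec -> Jan wrap
quarter_means <- function(monthly) {
  idx <- outer(0:2, 0:11, `+`) %% 12 + 1
  colMeans(matrix(monthly[idx], nrow = 3))
}

#' Seasonal summaries of a day/night temperature pair
#'
#' Treats the daytime series as the monthly maximum and the nighttime series
#' as the monthly minimum, which makes the diurnal-range variables available:
#' BIO1 annual mean of the monthly midpoints; BIO2 mean diurnal range;
#' BIO3 isothermality 100*BIO2/BIO7 (0 when BIO7 = 0); BIO4 seasonality of
#' the midpoints; BIO5 max of the daytime series; BIO6 min of the nighttime
#' series; BIO7 = BIO5 - BIO6; BIO10 / BIO11 warmest / coldest quarter means
#' of the midpoints.
#'
#' @param dlst,ntlst numeric vectors of 12 monthly daytime / nighttime values.
#' @inheritParams biovars_single
#' @return named numeric vector
#'   `BIO1, BIO2, BIO3, BIO4, BIO5, BIO6, BIO7, BIO10, BIO11`; all `NA` if any
#'   input is non-finite.
#' @export
biovars_daynight <- function(dlst, ntlst, seasonality_scale = 100,
                             sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(dlst) != 12 || length(ntlst) != 12)
    stop("'dlst' and 'ntlst' must both have length 12")
  out_names <- c("BIO1", "BIO2", "BIO3", "BIO4", "BIO5", "BIO6", "BIO7",
                 "BIO10", "BIO11")
  if (any(!is.finite(dlst)) || any(!is.finite(ntlst)))
    return(stats::setNames(rep(NA_real_, 9), out_names))
  if (any(dlst < ntlst))
    warning("daytime value below nighttime value in at least one month")
  m <- (dlst + ntlst) / 2
  q <- quarter_means(m)
  s <- if (sd_type == "sample") stats::sd(m)
       else sqrt(mean((m - mean(m))^2))
  bio2 <- mean(dlst - ntlst)
  bio5 <- max(dlst); bio6 <- min(ntlst)
  bio7 <- bio5 - bio6
  stats::setNames(c(
    mean(m),
    bio2,
    if (bio7 == 0) 0 else 100 * bio2 / bio7,
    s * seasonality_scale,
    bio5,
    bio6,
    bio7,
    max(q),
    min(q)
  ), out_names)
}

# lexicographic BIO-name order within each variable group, the order an R
# raster stack of these layers sorts into; this is what puts seasonality at
# X4 (MIR) and X13 (LST)
.bio_order_single <- c("BIO1", "BIO10", "BIO11", "BIO4", "BIO5", "BIO6", "BIO7")
.bio_order_pair <- c("BIO1", "BIO10", "BIO11", "BIO2", "BIO3", "BIO4",
                     "BIO5", "BIO6", "BIO7")

#' Build the 30 bioclim-style predictors from five monthly stacks
#'
#' Applies [biovars_single()] to the MIR, NDVI and EVI stacks (7 variables
#' each) and [biovars_daynight()] to the DTLST/NTLST pair (9 variables),
#' giving 30 predictors named `X1`--`X30`. Groups are ordered MIR
#' (X1--X7), LST (X8--X16), NDVI (X17--X23), EVI (X24--X30), each group
#' sorted lexicographically by BIO name, so X4 is the MIR seasonality, X7 the
#' MIR annual range and X13 the LST seasonality. A cell masked in any input
#' layer is masked in all 30 outputs.
#'
#' @param stacks named list with elements `MIR`, `DTLST`, `NTLST`, `NDVI`,
#'   `EVI`, each a `monthly_stack` on one shared grid.
#' @inheritParams biovars_single
#' @return object of class `predictor_set`: list with `grids` (named list of
#'   30 `env_grid`s), `manifest` (data.frame: name, source, transformation)
#'   and the shared `geometry`.
#' @export
build_predictor_set <- function(stacks, seasonality_scale = 100,
                                sd_type = "sample") {
  need <- c("MIR", "DTLST", "NTLST", "NDVI", "EVI")
  if (!all(need %in% names(stacks)))
    stop("stacks must be named ", paste(need, collapse = ", "))
  ref <- stacks$MIR$grids[[1]]
  for (nm in need) {
    if (!inherits(stacks[[nm]], "monthly_stack"))
      stop("'", nm, "' is not a monthly_stack")
    if (!same_geometry(ref, stacks[[nm]]$grids[[1]]))
      stop("stack '", nm, "' is not on the shared grid")
  }

  mats <- lapply(stacks[need], stack_matrix)
  shared_valid <- Reduce(`&`, lapply(mats, stats::complete.cases))

  single <- function(M) {
    n <- nrow(M)
    mu <- rowMeans(M)
    s <- sqrt(rowSums((M - mu)^2) /
                (if (sd_type == "sample") 11 else 12)) * seasonality_scale
    hi <- do.call(pmax, as.data.frame(M))
    lo <- do.call(pmin, as.data.frame(M))
    q <- quarter_matrix(M)
    cbind(BIO1 = mu, BIO4 = s, BIO5 = hi, BIO6 = lo, BIO7 = hi - lo,
          BIO10 = do.call(pmax, as.data.frame(q)),
          BIO11 = do.call(pmin, as.data.frame(q)))
  }
  pair <- function(D, N) {
    M <- (D + N) / 2
    base <- single(M)
    bio2 <- rowMeans(D - N)
    bio5 <- do.call(pmax, as.data.frame(D))
    bio6 <- do.call(pmin, as.data.frame(N))
    bio7 <- bio5 - bio6
    bio3 <- ifelse(bio7 == 0, 0, 100 * bio2 / bio7)
    cbind(BIO1 = base[, "BIO1"], BIO2 = bio2, BIO3 = bio3,
          BIO4 = base[, "BIO4"], BIO5 = bio5, BIO6 = bio6, BIO7 = bio7,
          BIO10 = base[, "BIO10"], BIO11 = base[, "BIO11"])
  }

  groups <- list(
    MIR = single(mats$MIR)[, .bio_order_single, drop = FALSE],
    LST = pair(mats$DTLST, mats$NTLST)[, .bio_order_pair, drop = FALSE],
    NDVI = single(mats$NDVI)[, .bio_order_single, drop = FALSE],
    EVI = single(mats$EVI)[, .bio_order_single, drop = FALSE]
  )

  vals <- do.call(cbind, groups)
  vals[!shared_valid, ] <- NA_real_
  xnames <- paste0("X", seq_len(ncol(vals)))
  manifest <- data.frame(
    name = xnames,
    source = rep(names(groups), vapply(groups, ncol, 0L)),
    transformation = unlist(lapply(groups, colnames), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  grids <- lapply(seq_len(ncol(vals)), function(j)
    env_grid(matrix(vals[, j], nrow(ref$values), ncol(ref$values)),
             ref$xmin, ref$ymin, ref$cellsize))
  names(grids) <- xnames
  structure(
    list(grids = grids, manifest = manifest,
         geometry = list(xmin = ref$xmin, ymin = ref$ymin,
                         cellsize = ref$cellsize, dim = dim(ref$values))),
    class = "predictor_set"
  )
}

# rolling 3-month means with December -> January wrap, per row
quarter_matrix <- function(M) {
  M3 <- cbind(M, M[, 1:2, drop = FALSE])
  vapply(1:12, function(i)
    (M3[, i] + M3[, i + 1] + M3[, i + 2]) / 3, numeric(nrow(M)))
}

#' @export
print.predictor_set <- function(x, ...) {
  cat(sprintf("predictor_set: %d variables on a %d x %d grid\n",
              length(x$grids), x$geometry$dim[1], x$geometry$dim[2]))
  print(utils::head(x$manifest, 8))
  if (nrow(x$manifest) > 8) cat("  ...\n")
  invisible(x)
}

#' Predictor values as a cells-by-variables matrix
#'
#' @param x a `predictor_set`.
#' @param ... unused.
#' @return numeric matrix (cells in column-major grid order x 30 variables);
#'   masked cells are `NA` rows.
#' @export
as.matrix.predictor_set <- function(x, ...) {
  m <- vapply(x$grids, function(g) as.vector(g$values),
              numeric(prod(x$geometry$dim)))
  colnames(m) <- names(x$grids)
  m
}
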