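#' Generate synthetic seasonal raster stacks
#'
#' Produces the five remote-sensing-style variables (middle infra-red
#' reflectance MIR, daytime and nighttime land-surface temperature DTLST and
#' NTLST, and the vegetation indices NDVI and EVI) as 12 monthly layers each,
#' 60 layers in total. Every cell value is
#' `center + latitudinal gradient + seasonal sinusoid + Gaussian noise`,
#' with a per-variable seasonal phase so that different variables peak in
#' different months. The two land-surface temperatures are generated as a
#' shared monthly mean plus/minus half a strictly non-negative diurnal range,
#' so `DTLST >= NTLST` holds at every cell and month by construction.
#'
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in degrees.
#' @param resolution cell size in degrees (> 0).
#' @param seasonal_amplitude half-range of the sinusoidal seasonal cycle, in
#'   each variable's units (>= 0).
#' @param spatial_gradient change of the cell mean per degree of latitude.
#' @param noise_sd standard deviation of i.i.d. Gaussian cell noise (>= 0).
#' @param seed integer seed; the same seed reproduces bit-identical stacks.
#' @param mask_fraction fraction of cells masked as invalid (e.g. sea), drawn
#'   once and shared by all 60 layers.
#' @return named list of five `monthly_stack` objects
#'   (`MIR`, `DTLST`, `NTLST`, `NDVI`, `EVI`).
#' @export
generate_monthly_stacks <- function(extent = c(-10, 5, 28, 44),
                                    resolution = 0.5,
                                    seasonal_amplitude = 5,
                                    spatial_gradient = 1,
                                    noise_sd = 0.5,
                                    seed = NULL,
                                    mask_fraction = 0) {
  if (length(extent) != 4 || extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("'extent' must be c(xmin, xmax, ymin, ymax) with positive spans")
  if (!is.finite(resolution) || resolution <= 0)
    stop("'resolution' must be positive")
  if (seasonal_amplitude < 0) stop("'seasonal_amplitude' must be >= 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (mask_fraction < 0 || mask_fraction >= 1)
    stop("'mask_fraction' must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)

  nc <- max(1L, round((extent[2] - extent[1]) / resolution))
  nr <- max(1L, round((extent[4] - extent[3]) / resolution))
  ymax <- extent[3] + nr * resolution
  lat <- ymax - (seq_len(nr) - 0.5) * resolution          # per row, N to S
  lat_dev <- matrix(lat - mean(lat), nr, nc)              # centred gradient

  mask <- matrix(FALSE, nr, nc)
  if (mask_fraction > 0) {
    n_bad <- floor(mask_fraction * nr * nc)
    mask[sample.int(nr * nc, n_bad)] <- TRUE
  }

  # per-variable baseline level, seasonal phase (months) and gradient sign
  spec <- list(
    MIR   = list(center = 30, phase = 0,  sign = +1),
    LST   = list(center = 25, phase = 1,  sign = +1),   # shared day/night mean
    RANGE = list(center = 10, phase = 2,  sign = 0),    # diurnal range, >= 0
    NDVI  = list(center = 0.5, phase = 6, sign = -1),
    EVI   = list(center = 0.4, phase = 7, sign = -1)
  )

  month_field <- function(center, phase, sign, m, scale = 1) {
    seas <- seasonal_amplitude * scale * sin(2 * pi * (m - 1 - phase) / 12)
    v <- center + sign * spatial_gradient * scale * lat_dev + seas +
      matrix(stats::rnorm(nr * nc, 0, noise_sd * scale), nr, nc)
    v[mask] <- NA_real_
    v
  }

  make_stack <- function(kind, fields)
    monthly_stack(kind, lapply(fields, env_grid,
                               xmin = extent[1], ymin = extent[3],
                               cellsize = resolution))

  mir <- lapply(1:12, function(m)
    month_field(spec$MIR$center, spec$MIR$phase, spec$MIR$sign, m))
  lst_mean <- lapply(1:12, function(m)
    month_field(spec$LST$center, spec$LST$phase, spec$LST$sign, m))
  # half the diurnal range; clamped at 0 so DTLST >= NTLST everywhere
  half_rng <- lapply(1:12, function(m)
    pmax(month_field(spec$RANGE$center, spec$RANGE$phase, spec$RANGE$sign,
                     m, scale = 0.5), 0) / 2)
  ndvi <- lapply(1:12, function(m)
    month_field(spec$NDVI$center, spec$NDVI$phase, spec$NDVI$sign, m,
                scale = 0.02))
  evi <- lapply(1:12, function(m)
    month_field(spec$EVI$center, spec$EVI$phase, spec$EVI$sign, m,
                scale = 0.02))

  list(
    MIR   = make_stack("MIR", mir),
    DTLST = make_stack("DTLST", Map(`+`, lst_mean, half_rng)),
    NTLST = make_stack("NTLST", Map(`-`, lst_mean, half_rng)),
    NDVI  = make_stack("NDVI", ndvi),
    EVI   = make_stack("EVI", evi)
  )
}

#' Describe a synthetic niche scenario
#'
#' A scenario fixes, for each clade, the center and breadth of an
#' axis-aligned Gaussian suitability function over chosen environmental axes
#' (annual means of the named variables), plus the number of records to
#' sample. Identical centers/breadths across clades give an
#' "identical niches" scenario; centers separated by much more than the
#' breadths give a "disjoint niches" scenario.
#'
#' @param clades character vector of clade labels.
#' @param centers numeric matrix, one row per clade, one column per axis, in
#'   the units of the axis variables.
#' @param breadths numeric matrix like `centers`; all entries > 0.
#' @param n_records integer vector of per-clade record counts.
#' @param axes character vector of stack names defining the environmental
#'   axes (annual mean of each named variable).
#' @param jitter_within_cell logical; add uniform within-cell positional
#'   jitter to sampled coordinates.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(clades,
                          centers,
                          breadths,
                          n_records,
                          axes = c("MIR", "DTLST"),
                          jitter_within_cell = TRUE) {
  clades <- as.character(clades)
  if (length(clades) == 0) stop("scenario needs at least one clade")
  centers <- rbind(centers); breadths <- rbind(breadths)
  if (nrow(centers) != length(clades) || nrow(breadths) != length(clades))
    stop("'centers' and 'breadths' need one row per clade")
  if (ncol(centers) != length(axes) || ncol(breadths) != length(axes))
    stop("'centers' and 'breadths' need one column per axis")
  if (any(breadths <= 0)) stop("all breadths must be positive")
  if (length(n_records) != length(clades) || any(n_records < 1))
    stop("'n_records' needs one positive count per clade")
  structure(
    list(clades = clades, centers = centers, breadths = breadths,
         n_records = as.integer(n_records), axes = axes,
         jitter_within_cell = jitter_within_cell),
    class = "scenario_spec"
  )
}

#' Canonical niche scenarios
#'
#' Pre-defined study conditions on the default synthetic grids (MIR annual
#' mean spanning roughly 25--35, LST annual mean roughly 20--30):
#' \describe{
#'   \item{identical}{two clades with the same niche center `(30, 25)` and
#'     breadth 4: samples from one generative niche, the null of the
#'     equivalency test true by construction.}
#'   \item{disjoint}{two clades at `(27.5, 22.5)` and `(32.5, 27.5)` with
#'     breadth 0.8, i.e. separated by about six niche breadths: effectively
#'     non-overlapping environmental ranges.}
#'   \item{nested}{a broad clade (breadth 4) and a narrow one (breadth 1.2)
#'     sharing the center.}
#'   \item{reference}{six clades I--VI with the real per-clade record counts
#'     (40, 47, 121, 15, 21, 17; 261 in total) at staggered, partially
#'     overlapping centers.}
#' }
#' Two-clade scenarios use 150 records per clade, the same order of
#' magnitude as the best-sampled real clade.
#'
#' @param type scenario name.
#' @return a [scenario_spec()].
#' @export
canonical_scenario <- function(type = c("identical", "disjoint", "nested",
                                        "reference")) {
  type <- match.arg(type)
  switch(type,
    identical = scenario_spec(
      clades = c("A", "B"),
      centers = rbind(c(30, 25), c(30, 25)),
      breadths = rbind(c(4, 4), c(4, 4)),
      n_records = c(150, 150)
    ),
    disjoint = scenario_spec(
      clades = c("A", "B"),
      centers = rbind(c(27.5, 22.5), c(32.5, 27.5)),
      breadths = rbind(c(0.8, 0.8), c(0.8, 0.8)),
      n_records = c(150, 150)
    ),
    nested = scenario_spec(
      clades = c("A", "B"),
      centers = rbind(c(30, 25), c(30, 25)),
      breadths = rbind(c(4, 4), c(1.2, 1.2)),
      n_records = c(150, 150)
    ),
    reference = scenario_spec(
      clades = c("I", "II", "III", "IV", "V", "VI"),
      centers = rbind(c(28, 23), c(29, 24), c(30, 25),
                      c(31, 26), c(32, 27), c(30.5, 24.5)),
      breadths = matrix(2, 6, 2),
      n_records = c(40, 47, 121, 15, 21, 17)
    )
  )
}

#' Sample clade occurrence records under a niche scenario
#'
#' Cells are drawn (with replacement) with probability proportional to each
#' clade's Gaussian suitability evaluated on the annual means of the
#' scenario's axis variables; coordinates are the cell centers, optionally
#' jittered uniformly within the cell.
#'
#' @param stacks named list of `monthly_stack` objects (as produced by
#'   [generate_monthly_stacks()]); must contain every axis named in the
#'   scenario.
#' @param scenario a [scenario_spec()].
#' @param seed integer seed for reproducible sampling.
#' @return an `occurrence_set`: data.frame with columns `lon`, `lat`, `clade`
#'   and class `occurrence_set`.
#' @export
generate_clade_occurrences <- function(stacks, scenario, seed = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"))
  missing_axes <- setdiff(scenario$axes, names(stacks))
  if (length(missing_axes))
    stop("stacks are missing scenario axes: ",
         paste(missing_axes, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)

  ref <- stacks[[scenario$axes[1]]]$grids[[1]]
  env <- vapply(scenario$axes,
                function(a) rowMeans(stack_matrix(stacks[[a]])),
                numeric(length(ref$values)))
  valid <- stats::complete.cases(env)
  if (!any(valid)) stop("no valid cells in the axis stacks")
  coords <- grid_coords(ref)

  out <- vector("list", length(scenario$clades))
  for (k in seq_along(scenario$clades)) {
    z <- sweep(env[valid, , drop = FALSE], 2, scenario$centers[k, ]) /
      matrix(scenario$breadths[k, ], sum(valid), ncol(env), byrow = TRUE)
    w <- exp(-0.5 * rowSums(z^2))
    if (max(w) < 1e-300)
      stop("clade '", scenario$clades[k],
           "' has zero achievable suitability everywhere on the grid")
    idx <- which(valid)[sample.int(sum(valid), scenario$n_records[k],
                                   replace = TRUE, prob = w)]
    lon <- coords$lon[idx]; lat <- coords$lat[idx]
    if (scenario$jitter_within_cell) {
      half <- ref$cellsize / 2
      lon <- lon + stats::runif(length(idx), -half, half)
      lat <- lat + stats::runif(length(idx), -half, half)
    }
    out[[k]] <- data.frame(lon = lon, lat = lat,
                           clade = scenario$clades[k],
                           stringsAsFactors = FALSE)
  }
  occurrence_set(do.call(rbind, out))
}

#' Construct (and validate) an occurrence set
#'
#' @param df data.frame with numeric columns `lon`, `lat` and a character
#'   `clade` column.
#' @return the data.frame with class `occurrence_set` prepended; duplicated
#'   coordinate rows are flagged in the `duplicated_coord` attribute.
#' @export
occurrence_set <- function(df) {
  if (!all(c("lon", "lat", "clade") %in% names(df)))
    stop("occurrence data need columns lon, lat, clade")
  if (!is.numeric(df$lon) || !is.numeric(df$lat))
    stop("lon and lat must be numeric")
  if (any(!stats::complete.cases(df[c("lon", "lat", "clade")])))
    stop("occurrence rows contain missing values")
  if (any(table(df$clade) < 1)) stop("every clade needs at least one record")
  df$clade <- as.character(df$clade)
  rownames(df) <- NULL
  attr(df, "duplicated_coord") <- duplicated(df[c("lon", "lat")])
  class(df) <- c("occurrence_set", "data.frame")
  df
}

#' The calibrated six-clade reference tree
#'
#' A rooted ultrametric tree over clade labels I--VI with topology
#' `(VI,(V,(I,(IV,(II,III)))))` and internal node ages 5.88, 4.82, 4.32,
#' 4.14 and 2.47 Ma (root to youngest split), matching the dated multilocus
#' phylogeny of the *Tarentola mauritanica* species complex.
#'
#' @return an [ape::read.tree()] `phylo` object with branch lengths in Ma.
#' @export
build_reference_tree <- function() {
  ape::read.tree(text = paste0(
    "(VI:5.88,(V:4.82,(I:4.32,(IV:4.14,(II:2.47,III:2.47):1.67)",
    ":0.18):0.50):1.06);"
  ))
}

# ages of all nodes (tips and internal) above the tips, in time units
node_ages <- function(tree) {
  n_tip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth  # assumes ultrametric: tips at ~0
}

# rebuild branch lengths from a vector of node ages (tips first, ape order)
tree_from_ages <- function(tree, ages) {
  tree$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  tree
}

#' Jitter node ages to emulate a posterior sample of trees
#'
#' Keeps the topology fixed and perturbs each internal node age with
#' independent Gaussian noise, resampling any draw that violates the
#' parent-older-than-child ordering (or non-positive ages).
#'
#' @param tree an ultrametric `phylo` tree.
#' @param n_trees number of trees to generate.
#' @param age_jitter_sd standard deviation of the age perturbation (Ma).
#' @param seed integer seed.
#' @param max_attempts resampling attempts per tree before giving up.
#' @return a `multiPhylo` list of `n_trees` valid ultrametric trees.
#' @export
perturb_tree_posterior <- function(tree, n_trees, age_jitter_sd,
                                   seed = NULL, max_attempts = 100) {
  stopifnot(inherits(tree, "phylo"))
  if (n_trees < 1) stop("'n_trees' must be >= 1")
  if (age_jitter_sd < 0) stop("'age_jitter_sd' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n_tip <- length(tree$tip.label)
  ages <- node_ages(tree)
  internal <- (n_tip + 1):(n_tip + tree$Nnode)
  out <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    for (att in seq_len(max_attempts)) {
      a <- ages
      a[internal] <- a[internal] +
        stats::rnorm(length(internal), 0, age_jitter_sd)
      cand <- tree_from_ages(tree, a)
      if (all(cand$edge.length > 0) || age_jitter_sd == 0) break
      cand <- NULL
    }
    if (is.null(cand))
      stop("could not preserve age ordering after ", max_attempts,
           " attempts; reduce 'age_jitter_sd'")
    out[[i]] <- cand
  }
  class(out) <- "multiPhylo"
  out
}
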