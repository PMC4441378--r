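#' Read an occurrence CSV (lon, lat, clade)
#'
#' @param path CSV file with header `lon,lat,clade`.
#' @param grid optional `env_grid`; records outside its extent raise an error
#'   listing the offending line numbers.
#' @return an `occurrence_set`; malformed rows (non-numeric coordinates,
#'   missing fields) are dropped with a warning naming their line numbers.
#' @export
read_occurrences <- function(path, grid = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("lon", "lat", "clade") %in% names(raw)))
    stop("'", path, "' must have columns lon, lat, clade")
  lon <- suppressWarnings(as.numeric(raw$lon))
  lat <- suppressWarnings(as.numeric(raw$lat))
  bad <- !is.finite(lon) | !is.finite(lat) | is.na(raw$clade) |
    raw$clade == ""
  if (any(bad))
    warning(sum(bad), " malformed row(s) dropped at line(s): ",
            paste(which(bad) + 1, collapse = ", "))
  df <- data.frame(lon = lon[!bad], lat = lat[!bad],
                   clade = raw$clade[!bad], stringsAsFactors = FALSE)
  if (!is.null(grid)) {
    e <- grid_extent(grid)
    out <- df$lon < e["xmin"] | df$lon > e["xmax"] |
      df$lat < e["ymin"] | df$lat > e["ymax"]
    if (any(out))
      stop("record(s) outside the raster extent at line(s): ",
           paste((which(!bad))[out] + 1, collapse = ", "))
  }
  occurrence_set(df)
}

#' Write an occurrence set as CSV
#'
#' @param occ an `occurrence_set`.
#' @param path output path.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ)[c("lon", "lat", "clade")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a calibrated ultrametric tree from Newick
#'
#' @param path Newick file, branch lengths in Ma.
#' @param tol relative tolerance on tip-depth equality.
#' @return a `phylo` tree.
#' @export
read_tree <- function(path, tol = 1e-6) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse a Newick tree from ", path)
  if (is.null(tree$edge.length)) stop("tree in ", path, " has no branch lengths")
  if (!ape::is.ultrametric(tree, tol = max(tol, 1e-8)))
    stop("tree in ", path, " is not ultrametric within tolerance")
  tree
}

#' Read five monthly stacks from a directory of .asc grids
#'
#' Expects files named `{VAR}_{MM}.asc` with VAR in MIR, DTLST, NTLST, NDVI,
#' EVI and MM in 01..12.
#'
#' @param dir directory path.
#' @return named list of five `monthly_stack`s.
#' @export
read_stacks <- function(dir) {
  kinds <- c("MIR", "DTLST", "NTLST", "NDVI", "EVI")
  out <- lapply(kinds, function(k) {
    paths <- file.path(dir, sprintf("%s_%02d.asc", k, 1:12))
    missing <- !file.exists(paths)
    if (any(missing))
      stop("missing layer file(s): ",
           paste(basename(paths[missing]), collapse = ", "))
    monthly_stack(k, lapply(paths, read_asc))
  })
  stats::setNames(out, kinds)
}

#' Write five monthly stacks as .asc grids
#'
#' @param stacks named list of `monthly_stack`s.
#' @param dir output directory (created if absent).
#' @export
write_stacks <- function(stacks, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (k in names(stacks))
    for (m in 1:12)
      write_asc(stacks[[k]]$grids[[m]],
                file.path(dir, sprintf("%s_%02d.asc", k, m)))
  invisible(dir)
}

#' Pipeline configuration
#'
#' Bundles the inputs and tuning parameters of [run_pipeline()]. Defaults
#' follow the study design: 100-km background buffer, 100 x 100 density
#' lattice, 100 randomizations per test, 100 PNO bins, 1000 Monte-Carlo
#' samples for the ancestral reconstruction.
#'
#' @param stacks named list of five `monthly_stack`s (or a directory path for
#'   [read_stacks()]).
#' @param occurrences an `occurrence_set` (or a CSV path).
#' @param trees a `phylo` / `multiPhylo` (or a Newick path).
#' @param buffer_km,r,n_reps,pno_bins,n_samples tuning parameters; see above.
#' @param seed single integer master seed; per-stage seeds are derived from
#'   it by fixed offsets so each stage can be replayed in isolation.
#' @param out_dir optional output directory; when given, all result tables
#'   and grids are written there.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(stacks, occurrences, trees,
                            buffer_km = 100, r = 100, n_reps = 100,
                            pno_bins = 100, n_samples = 1000,
                            seed = 1, out_dir = NULL) {
  counts <- c(buffer_km = buffer_km, r = r, n_reps = n_reps,
              pno_bins = pno_bins, n_samples = n_samples)
  if (any(counts <= 0)) stop("all counts/sizes must be positive")
  structure(
    list(stacks = stacks, occurrences = occurrences, trees = trees,
         buffer_km = buffer_km, r = r, n_reps = n_reps,
         pno_bins = pno_bins, n_samples = n_samples,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

# fixed per-stage seed derivation from the master seed (kept below 2^31)
stage_seed <- function(seed, stage) {
  offsets <- c(stacks = 11L, occurrences = 23L, overlap = 37L,
               pno = 53L, ancestral = 71L)
  (as.integer(seed) * 101L + offsets[[stage]]) %% .Machine$integer.max
}

#' PCA-env comparison of one clade pair
#'
#' Trains a correlation PCA on the union of the two clades' background cells,
#' projects occurrences and backgrounds, builds occupancy-corrected density
#' grids on PCs 1--2, and runs Schoener's D plus the equivalency and (both
#' directions of) the background-similarity randomization tests.
#'
#' @param predictors a `predictor_set`.
#' @param occ an `occurrence_set` containing both clades.
#' @param clade_a,clade_b clade labels to compare.
#' @param buffer_km background buffer radius.
#' @param r density lattice resolution.
#' @param n_reps randomizations per test.
#' @param seed integer seed.
#' @return list with `d`, `class`, `equivalency`, `similarity_ab`,
#'   `similarity_ba`, `pca` and the per-clade score matrices.
#' @export
pca_env_compare <- function(predictors, occ, clade_a, clade_b,
                            buffer_km = 100, r = 100, n_reps = 100,
                            seed = NULL) {
  ref <- predictors$grids[[1]]
  pm <- as.matrix(predictors)
  occ_a <- occ[occ$clade == clade_a, , drop = FALSE]
  occ_b <- occ[occ$clade == clade_b, , drop = FALSE]
  if (nrow(occ_a) < 5 || nrow(occ_b) < 5)
    stop("both clades need at least 5 records")

  bg_a <- background_mask(occ_a, ref, buffer_km)
  bg_b <- background_mask(occ_b, ref, buffer_km)
  cells_a <- which(as.vector(bg_a))
  cells_b <- which(as.vector(bg_b))
  pooled_cells <- union(cells_a, cells_b)

  pca <- fit_pca(pm, cells = pooled_cells)
  sc <- function(cells) predict(pca, pm[cells, , drop = FALSE],
                                n_components = 2)
  occ_cells <- function(o) {
    rc <- cell_of(ref, o$lon, o$lat)
    (rc[, 2] - 1L) * nrow(ref$values) + rc[, 1]
  }
  s_occ_a <- sc(occ_cells(occ_a)); s_occ_b <- sc(occ_cells(occ_b))
  keep_a <- stats::complete.cases(s_occ_a)
  keep_b <- stats::complete.cases(s_occ_b)
  if (sum(!keep_a) + sum(!keep_b) > 0)
    warning(sum(!keep_a) + sum(!keep_b),
            " record(s) on masked cells dropped")
  s_occ_a <- s_occ_a[keep_a, , drop = FALSE]
  s_occ_b <- s_occ_b[keep_b, , drop = FALSE]
  s_bg_a <- sc(cells_a); s_bg_b <- sc(cells_b)
  s_bg <- sc(pooled_cells)

  z_a <- density_grid(s_occ_a, s_bg, r = r)
  z_b <- density_grid(s_occ_b, s_bg, r = r)
  d_obs <- schoener_d(z_a, z_b)

  eq <- equivalency_test(s_occ_a, s_occ_b, s_bg, n_reps = n_reps,
                         seed = seed, r = r)
  sim_ab <- similarity_test(s_occ_a, s_occ_b, s_bg_b, pooled_background = s_bg,
                            n_reps = n_reps, seed = seed, r = r,
                            direction = paste0(clade_a, "->", clade_b))
  sim_ba <- similarity_test(s_occ_b, s_occ_a, s_bg_a, pooled_background = s_bg,
                            n_reps = n_reps, seed = seed, r = r,
                            direction = paste0(clade_b, "->", clade_a))

  list(d = d_obs, class = as.character(classify_overlap(d_obs)),
       equivalency = eq, similarity_ab = sim_ab, similarity_ba = sim_ba,
       pca = pca, scores = list(occ_a = s_occ_a, occ_b = s_occ_b,
                                bg_a = s_bg_a, bg_b = s_bg_b, pooled = s_bg))
}

#' Run the full niche-evolution analysis
#'
#' biovars -> global PCA -> per-clade envelopes and suitability maps -> all
#' pairwise PCA-env overlap comparisons -> PNO profiles -> ancestral
#' tolerance reconstruction. When `config$out_dir` is set, writes the
#' pairwise overlap table, the PCA loadings table, per-clade suitability
#' grids, per-node tolerance tables and a log of every stage seed.
#'
#' @param config a [pipeline_config()].
#' @return list with `predictors`, `pca`, `envelopes`, `suitability`,
#'   `overlap_table`, `comparisons`, `pno`, `ancestral`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  stacks <- if (is.character(config$stacks)) read_stacks(config$stacks)
            else config$stacks
  ref <- stacks$MIR$grids[[1]]
  occ <- if (is.character(config$occurrences))
    read_occurrences(config$occurrences, grid = ref) else config$occurrences
  trees <- if (is.character(config$trees)) read_tree(config$trees)
           else config$trees
  tree1 <- if (inherits(trees, "phylo")) trees else trees[[1]]

  known <- tree1$tip.label
  unknown <- !(occ$clade %in% known)
  if (any(unknown)) {
    warning(sum(unknown), " record(s) with clade labels not in the tree ",
            "excluded: ", paste(unique(occ$clade[unknown]), collapse = ", "))
    say("excluded %d record(s) with unknown clade labels", sum(unknown))
    occ <- occurrence_set(as.data.frame(occ)[!unknown, ])
  }
  clades <- intersect(known, unique(occ$clade))
  if (length(clades) < 2) stop("need at least two clades with records")
  # drop tree tips without records (generic tip-dropping)
  prune <- function(t)
    if (length(setdiff(t$tip.label, clades)) > 0) ape::keep.tip(t, clades)
    else t
  trees <- if (inherits(trees, "phylo")) prune(trees)
           else structure(lapply(trees, prune), class = "multiPhylo")
  tree1 <- if (inherits(trees, "phylo")) trees else trees[[1]]

  say("stage biovars: 5 stacks x 12 months -> 30 predictors")
  predictors <- run_stage("biovars", build_predictor_set(stacks))

  say("stage pca: global correlation PCA on the full valid extent")
  pca <- run_stage("pca", fit_pca(predictors))
  say("  retained %d component(s)", pca$retained)

  pm <- as.matrix(predictors)
  all_scores <- predict(pca, pm)
  pc_grids <- lapply(seq_len(pca$retained), function(j)
    env_grid(matrix(all_scores[, j], nrow(ref$values), ncol(ref$values)),
             ref$xmin, ref$ymin, ref$cellsize))
  names(pc_grids) <- paste0("PC", seq_len(pca$retained))

  occ_cell <- function(o) {
    rc <- cell_of(ref, o$lon, o$lat)
    (rc[, 2] - 1L) * nrow(ref$values) + rc[, 1]
  }
  say("stage sdm: Bioclim envelopes per clade on %d PCs", pca$retained)
  envelopes <- list(); suitability <- list()
  for (cl in clades) {
    sc <- all_scores[occ_cell(occ[occ$clade == cl, ]), , drop = FALSE]
    drop_n <- sum(!stats::complete.cases(sc))
    if (drop_n > 0)
      say("  clade %s: dropped %d record(s) on masked cells", cl, drop_n)
    sc <- sc[stats::complete.cases(sc), , drop = FALSE]
    envelopes[[cl]] <- run_stage("sdm", fit_envelope(sc))
    suitability[[cl]] <- run_stage("sdm",
                                   suitability_map(envelopes[[cl]], pc_grids))
  }

  seed_overlap <- stage_seed(config$seed, "overlap")
  say("stage overlap: %d pairwise comparisons (seed %d)",
      choose(length(clades), 2), seed_overlap)
  comparisons <- list(); rows <- list()
  pair_id <- 0L
  for (i in seq_along(clades)) for (j in seq_along(clades)) {
    if (j <= i) next
    pair_id <- pair_id + 1L
    cmp <- run_stage("overlap", pca_env_compare(
      predictors, occ, clades[i], clades[j],
      buffer_km = config$buffer_km, r = config$r, n_reps = config$n_reps,
      seed = (seed_overlap + pair_id) %% .Machine$integer.max
    ))
    comparisons[[paste(clades[i], clades[j], sep = "-")]] <- cmp
    rows[[pair_id]] <- data.frame(
      pair = paste(clades[i], clades[j], sep = "-"),
      D = cmp$d, class = cmp$class,
      equivalency_p = cmp$equivalency$p_value,
      similarity_p_2to1 = cmp$similarity_ba$p_value,
      similarity_p_1to2 = cmp$similarity_ab$p_value,
      stringsAsFactors = FALSE
    )
  }
  overlap_table <- do.call(rbind, rows)

  seed_pno <- stage_seed(config$seed, "pno")
  say("stage pno: %d bins per PC per clade (seed %d)", config$pno_bins,
      seed_pno)
  pno <- lapply(names(pc_grids), function(pc)
    stats::setNames(lapply(clades, function(cl)
      pno_profile(suitability[[cl]], pc_grids[[pc]],
                  n_bins = config$pno_bins, axis = pc)), clades))
  names(pno) <- names(pc_grids)

  seed_anc <- stage_seed(config$seed, "ancestral")
  say("stage ancestral: %d Monte-Carlo samples (seed %d)", config$n_samples,
      seed_anc)
  ancestral <- run_stage("ancestral", ancestral_niche_history(
    trees, pno, n_samples = config$n_samples, seed = seed_anc))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(overlap_table,
                     file.path(config$out_dir, "overlap_table.csv"),
                     row.names = FALSE)
    write_loadings_csv(pca, file.path(config$out_dir, "pca_loadings.csv"))
    for (cl in clades)
      write_asc(suitability[[cl]],
                file.path(config$out_dir, paste0("suitability_", cl, ".asc")))
    write_tolerance_csv(ancestral,
                        file.path(config$out_dir, "node_tolerances.csv"))
    writeLines(log_lines, file.path(config$out_dir, "pipeline_log.txt"))
  }

  list(predictors = predictors, pca = pca, envelopes = envelopes,
       suitability = suitability, overlap_table = overlap_table,
       comparisons = comparisons, pno = pno, ancestral = ancestral,
       log = log_lines)
}
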