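# small shared fixtures, generated in code

tiny_stacks <- function(seed = 42, resolution = 0.5,
                        extent = c(0, 10, 0, 10), ...) {
  generate_monthly_stacks(extent = extent, resolution = resolution,
                          seed = seed, ...)
}

# scores for overlap tests directly in a 2-D environmental space
cloud2d <- function(n, center = c(0, 0), sd = 1) {
  cbind(stats::rnorm(n, center[1], sd), stats::rnorm(n, center[2], sd))
}

uniform_bg <- function(n, lo = -8, hi = 8) {
  cbind(stats::runif(n, lo, hi), stats::runif(n, lo, hi))
}

# exhaustive-window oracle for quarter means (wrap-around), independent of
# the implementation's rolling construction
oracle_quarters <- function(x) {
  sapply(1:12, function(i) mean(x[(c(i, i + 1, i + 2) - 1) %% 12 + 1]))
}

# column-major cell indices of occurrence records on a grid
cell_index_test <- function(g, o) {
  rc <- cell_of(g, o$lon, o$lat)
  (rc[, 2] - 1L) * nrow(g$values) + rc[, 1]
}

# cells x 12 matrix of a stack's monthly values
stack_rows <- function(stk)
  vapply(1:12, function(m) as.vector(stk$grids[[m]]$values),
         numeric(length(stk$grids[[1]]$values)))
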