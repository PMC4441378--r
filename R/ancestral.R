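#' Brownian-motion GLS ancestral state estimates
#'
#' Point estimates of a continuous trait at every internal node of an
#' ultrametric tree under Brownian motion, by generalized least squares. For
#' a node `u`, the estimate is the GLS mean `(1' V_u^-1 1)^-1 1' V_u^-1 y`
#' where `V_u[i, j]` is the shared path length of tips `i` and `j` measured
#' from `u` (the re-rooting construction: the estimate at `u` equals the root
#' estimate of the tree re-rooted at `u`, which is exact under BM).
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param tip_values named numeric vector covering every tip label.
#' @return named numeric vector of estimates for internal nodes, names
#'   `node<ape id>`, ordered root first (ape numbering `n_tip + 1, ...`).
#' @export
bm_ancestral_gls <- function(tree, tip_values) {
  stopifnot(inherits(tree, "phylo"))
  miss <- setdiff(tree$tip.label, names(tip_values))
  if (length(miss))
    stop("missing tip value(s) for: ", paste(miss, collapse = ", "))
  W <- gls_weight_matrix(tree)
  y <- tip_values[tree$tip.label]
  est <- as.vector(W %*% y)
  names(est) <- rownames(W)
  est
}

# internal-nodes x tips matrix of GLS weights; estimates = W %*% y(tips in
# tree$tip.label order)
gls_weight_matrix <- function(tree) {
  n_tip <- length(tree$tip.label)
  nodes <- (n_tip + 1):(n_tip + tree$Nnode)
  D <- ape::dist.nodes(tree)
  tips <- seq_len(n_tip)
  W <- matrix(NA_real_, length(nodes), n_tip,
              dimnames = list(paste0("node", nodes), tree$tip.label))
  one <- rep(1, n_tip)
  for (k in seq_along(nodes)) {
    u <- nodes[k]
    # shared path length of each tip pair, measured from u as the root
    V <- (outer(D[u, tips], one) + outer(one, D[u, tips]) - D[tips, tips]) / 2
    diag(V) <- D[u, tips]
    Vi1 <- solve(V, one)
    W[k, ] <- Vi1 / sum(Vi1)
  }
  W
}

#' Reconstruct the history of climatic-tolerance occupancy
#'
#' Monte-Carlo propagation of PNO uncertainty onto ancestral nodes: in each
#' of `n_samples` iterations one tolerance value is drawn from every tip's
#' PNO profile, one tree is taken from the supplied set (cycling in order,
#' which also absorbs topology/age uncertainty when a posterior sample is
#' supplied), and the BM/GLS estimates are computed at every internal node.
#' Node clouds are summarized by their mean and the 80\% equal-tail central
#' density interval; tips are summarized from their own PNO samples.
#'
#' @param trees a `phylo`, a `multiPhylo`, or a list of trees sharing tip
#'   labels.
#' @param profiles named list: one `pno_profile` per tip label (one PC axis);
#'   or a list of such lists, one per axis, with names used as axis labels.
#' @param n_samples Monte-Carlo iterations (default 1000).
#' @param seed integer seed.
#' @param interval_mass central density mass of the reported intervals.
#' @return object of class `ancestral_profile`: data.frame `summary` with
#'   columns `node`, `axis`, `age`, `mean`, `lo`, `hi`, `is_tip`, plus the
#'   per-node sample clouds in `samples`.
#' @export
ancestral_niche_history <- function(trees, profiles, n_samples = 1000,
                                    seed = NULL, interval_mass = 0.80) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (!length(trees)) stop("need at least one tree")
  if (inherits(profiles[[1]], "pno_profile")) profiles <- list(PC1 = profiles)
  axes <- names(profiles) %||% paste0("PC", seq_along(profiles))
  tree1 <- trees[[1]]
  n_tip <- length(tree1$tip.label)
  for (ax in seq_along(profiles)) {
    miss <- setdiff(tree1$tip.label, names(profiles[[ax]]))
    if (length(miss))
      stop("axis ", axes[ax], ": no PNO profile for tip(s): ",
           paste(miss, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)

  Ws <- lapply(trees, gls_weight_matrix)
  ages <- node_ages(tree1)
  node_ids <- (n_tip + 1):(n_tip + tree1$Nnode)
  tree_of_iter <- rep_len(seq_along(trees), n_samples)

  out_summary <- list(); out_samples <- list()
  for (ax in seq_along(profiles)) {
    draws <- vapply(tree1$tip.label, function(tp)
      sample_pno(profiles[[ax]][[tp]], n_samples), numeric(n_samples))
    node_cloud <- matrix(NA_real_, n_samples, tree1$Nnode)
    for (ti in seq_along(trees)) {
      it <- which(tree_of_iter == ti)
      if (!length(it)) next
      # weights are per tip in tip.label order for every tree (shared labels)
      node_cloud[it, ] <- draws[it, colnames(Ws[[ti]]), drop = FALSE] %*%
        t(Ws[[ti]])
    }
    ci_n <- apply(node_cloud, 2, central_density_interval,
                  mass = interval_mass)
    ci_t <- apply(draws, 2, central_density_interval, mass = interval_mass)
    out_summary[[ax]] <- data.frame(
      node = c(paste0("node", node_ids), tree1$tip.label),
      axis = axes[ax],
      age = c(ages[node_ids], rep(0, n_tip)),
      mean = c(colMeans(node_cloud), colMeans(draws)),
      lo = c(ci_n[1, ], ci_t[1, ]),
      hi = c(ci_n[2, ], ci_t[2, ]),
      is_tip = rep(c(FALSE, TRUE), c(tree1$Nnode, n_tip)),
      stringsAsFactors = FALSE
    )
    colnames(node_cloud) <- paste0("node", node_ids)
    out_samples[[axes[ax]]] <- node_cloud
  }
  structure(
    list(summary = do.call(rbind, out_summary), samples = out_samples,
         tree = tree1, n_samples = n_samples),
    class = "ancestral_profile"
  )
}

#' @export
print.ancestral_profile <- function(x, ...) {
  cat(sprintf("ancestral_profile: %d Monte-Carlo samples, %d axes\n",
              x$n_samples, length(x$samples)))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot a niche-occupancy history (age vs tolerance)
#'
#' One panel per axis: node and tip means plotted at their ages, solid lines
#' connecting each ancestor to its descendants, dashed vertical-style ranges
#' marking every terminal's central density interval.
#'
#' @param x an `ancestral_profile`.
#' @param axis which axis label to draw (default the first).
#' @param ... passed to [graphics::plot()].
#' @export
plot.ancestral_profile <- function(x, axis = NULL, ...) {
  ax <- axis %||% x$summary$axis[1]
  s <- x$summary[x$summary$axis == ax, ]
  tree <- x$tree
  n_tip <- length(tree$tip.label)
  id_of <- function(node) match(node, s$node)
  lab <- function(v) ifelse(v <= n_tip, tree$tip.label[v], paste0("node", v))
  graphics::plot(s$age, s$mean, xlim = rev(range(s$age)),
                 xlab = "age (Ma)", ylab = paste(ax, "tolerance"),
                 pch = 19, ...)
  for (k in seq_len(nrow(tree$edge))) {
    a <- s[id_of(lab(tree$edge[k, 1])), ]
    b <- s[id_of(lab(tree$edge[k, 2])), ]
    graphics::segments(a$age, a$mean, b$age, b$mean)
  }
  tips <- s[s$is_tip, ]
  graphics::segments(tips$age, tips$lo, tips$age, tips$hi, lty = 2)
  graphics::text(tips$age, tips$mean, tips$node, pos = 4, cex = 0.8)
  invisible(x)
}

#' Write per-node tolerance tables
#'
#' @param x an `ancestral_profile`.
#' @param path CSV output path.
#' @export
write_tolerance_csv <- function(x, path) {
  utils::write.csv(x$summary, path, row.names = FALSE)
  invisible(path)
}
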