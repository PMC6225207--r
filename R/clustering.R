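#' Distance matrix between protein composition vectors
#'
#' Correlation distance `1 - r` between the 20-dimensional composition rows
#' (default), or Euclidean distance.
#'
#' @param matrix A `CompositionMatrix` with >= 2 proteins.
#' @param method `"correlation"` or `"euclidean"`.
#' @return A `dist` object over proteins.
#' @export
distance_matrix <- function(matrix, method = c("correlation", "euclidean")) {
  stopifnot(inherits(matrix, "CompositionMatrix"), nrow(matrix) >= 2L)
  method <- match.arg(method)
  x <- unclass(matrix)
  if (method == "euclidean") return(stats::dist(x))
  v <- apply(x, 1L, stats::var)
  if (any(v == 0))
    stop("zero-variance composition vector(s) under correlation distance: ",
         paste(rownames(x)[v == 0], collapse = ", "))
  stats::as.dist(1 - stats::cor(t(x)))
}

#' Average-linkage (UPGMA-style) agglomeration
#'
#' Merges the pair of clusters with minimal mean inter-cluster distance; the
#' merge height equals that mean. Thin wrapper over [stats::hclust()] with
#' `method = "average"` returning the package's `ClusterTree` container
#' (heights and memberships, support values unset until
#' [multiscale_bootstrap_support()] is run).
#'
#' @param dist A `dist` object (e.g. from [distance_matrix()]).
#' @return A `ClusterTree`: list with `hclust` (the fitted tree), `labels`,
#'   `clusters` (leaf-index set per internal node, root last is node
#'   `n - 1`), `heights`, and `au`/`bp` (NA until support is attached).
#' @export
average_linkage <- function(dist) {
  stopifnot(inherits(dist, "dist"))
  hc <- stats::hclust(dist, method = "average")
  .as_cluster_tree(hc)
}

.as_cluster_tree <- function(hc) {
  cl <- .node_leaves(hc$merge)
  structure(list(hclust = hc, labels = hc$labels,
                 clusters = cl, heights = hc$height,
                 au = rep(NA_real_, length(cl)),
                 bp = rep(NA_real_, length(cl)),
                 degenerate = rep(FALSE, length(cl))),
            class = "ClusterTree")
}

# leaf index sets (sorted) under each internal node of an hclust merge matrix
.node_leaves <- function(merge) {
  n_nodes <- nrow(merge)
  out <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) {
    kids <- merge[i, ]
    leaves <- integer()
    for (k in kids)
      leaves <- c(leaves, if (k < 0) -k else out[[k]])
    out[[i]] <- sort(leaves)
  }
  out
}

.signatures <- function(clusters) {
  vapply(clusters, paste, "", collapse = ",")
}

#' @export
print.ClusterTree <- function(x, ...) {
  cat("ClusterTree: ", length(x$labels), " leaves, ",
      length(x$clusters), " internal nodes",
      if (!all(is.na(x$au))) ", AU/BP support attached", "\n", sep = "")
  invisible(x)
}

#' Bootstrap configuration for cluster support
#'
#' @param n_boot Total bootstrap replicates, split evenly across scales
#'   (default 10000).
#' @param scales Relative resample sizes r of the feature (residue) columns
#'   (default 0.5 to 1.4 by 0.1).
#' @param seed Integer seed.
#' @param distance `"correlation"` or `"euclidean"`.
#' @return A list of class `BootstrapConfig`.
#' @export
bootstrap_config <- function(n_boot = 10000L,
                             scales = seq(0.5, 1.4, by = 0.1),
                             seed = 1L,
                             distance = c("correlation", "euclidean")) {
  stopifnot(all(scales > 0), n_boot >= length(scales))
  per_scale <- as.integer(floor(n_boot / length(scales)))
  if (per_scale < 100L)
    warning("fewer than 100 replicates per scale; AU fits will be unstable")
  structure(list(n_boot = as.integer(n_boot), scales = scales,
                 per_scale = per_scale, seed = as.integer(seed),
                 distance = match.arg(distance)),
            class = "BootstrapConfig")
}

# distance between rows of x for bootstrap replicates; NA-safe
.boot_dist <- function(x, method) {
  if (method == "euclidean") return(stats::dist(x))
  r <- suppressWarnings(stats::cor(t(x)))
  r[is.na(r)] <- 0   # zero-variance resampled rows: treat as uncorrelated
  stats::as.dist(1 - r)
}

# raw bootstrap proportions of each original cluster at one scale.
# Replicate b draws its column indices as
#   sample.int(f, size, replace = TRUE)
# from the stream seeded with set.seed(seed), sequentially for b = 1..n_boot.
.bp_one_scale <- function(x, signatures, size, n_boot, seed, method) {
  set.seed(seed)
  f <- ncol(x)
  counts <- integer(length(signatures))
  for (b in seq_len(n_boot)) {
    cols <- sample.int(f, size, replace = TRUE)
    hc <- stats::hclust(.boot_dist(x[, cols, drop = FALSE], method),
                        method = "average")
    sig_b <- .signatures(.node_leaves(hc$merge))
    counts <- counts + (signatures %in% sig_b)
  }
  counts / n_boot
}

#' Attach multiscale-bootstrap AU and BP support to a composition dendrogram
#'
#' Clusters the proteins of a composition matrix by average linkage and
#' estimates, for every internal node, the approximately unbiased (AU)
#' p-value by multiscale bootstrap: the 20 residue-fraction columns are
#' resampled with replacement at several relative sizes r, the tree is
#' re-fitted, and the per-scale proportion `BP_r` of replicates containing
#' the cluster is recorded. The probit-transformed proportions
#' `psi(r) = qnorm(1 - BP_r)` are fitted by weighted least squares to
#' `d * sqrt(r) + c / sqrt(r)`; then `AU = 100 * (1 - pnorm(d - c))` and
#' `BP = 100 * (1 - pnorm(d + c))`. Proportions of 0 or 1 are clipped to
#' `1/(2 n)` and `1 - 1/(2 n)` before the probit transform. Clusters never
#' (always) observed at every scale get AU = 0 (100) with a degenerate-fit
#' flag. Replicates at scale i are drawn from a stream seeded with
#' `cfg$seed + i`, making per-scale proportions independently reproducible.
#'
#' @param matrix A `CompositionMatrix`.
#' @param cfg A [bootstrap_config()].
#' @return A `ClusterTree` with `au`, `bp`, `degenerate` vectors (one entry
#'   per internal node, root last), `bp_table` (nodes x scales raw
#'   proportions) and `fit` (d, c per node) attached.
#' @export
multiscale_bootstrap_support <- function(matrix, cfg = bootstrap_config()) {
  stopifnot(inherits(matrix, "CompositionMatrix"),
            inherits(cfg, "BootstrapConfig"))
  x <- unclass(matrix)
  tree <- average_linkage(distance_matrix(matrix, cfg$distance))
  sigs <- .signatures(tree$clusters)
  n_nodes <- length(sigs)
  scales <- cfg$scales
  f <- ncol(x)
  bp_table <- matrix(NA_real_, n_nodes, length(scales),
                     dimnames = list(NULL, sprintf("r=%g", scales)))
  for (i in seq_along(scales)) {
    size <- max(1L, as.integer(round(f * scales[i])))
    bp_table[, i] <- .bp_one_scale(x, sigs, size, cfg$per_scale,
                                   cfg$seed + i, cfg$distance)
  }
  nb <- cfg$per_scale
  eps <- 1 / (2 * nb)
  au <- bp <- numeric(n_nodes)
  degenerate <- logical(n_nodes)
  dpar <- cpar <- rep(NA_real_, n_nodes)
  for (j in seq_len(n_nodes)) {
    raw <- bp_table[j, ]
    if (all(raw == 1)) {
      au[j] <- 100; bp[j] <- 100; degenerate[j] <- TRUE; next
    }
    if (all(raw == 0)) {
      au[j] <- 0; bp[j] <- 0; degenerate[j] <- TRUE; next
    }
    pr <- pmin(pmax(raw, eps), 1 - eps)
    psi <- stats::qnorm(1 - pr)
    X <- cbind(sqrt(scales), 1 / sqrt(scales))
    w <- nb * stats::dnorm(psi)^2 / (pr * (1 - pr))
    fit <- stats::lm.wfit(X, psi, w)
    dpar[j] <- fit$coefficients[1L]
    cpar[j] <- fit$coefficients[2L]
    au[j] <- 100 * (1 - stats::pnorm(dpar[j] - cpar[j]))
    bp[j] <- 100 * (1 - stats::pnorm(dpar[j] + cpar[j]))
  }
  tree$au <- au
  tree$bp <- bp
  tree$degenerate <- degenerate
  tree$bp_table <- bp_table
  tree$fit <- data.frame(d = dpar, c = cpar)
  tree$config <- cfg
  tree
}

#' Maximal clusters passing an AU support threshold
#'
#' Returns the maximal (non-nested) internal nodes whose AU support meets
#' `min_au`, plus the proteins belonging to none of them. The root
#' bipartition is present in every bootstrap replicate by construction, so it
#' is excluded unless `include_root = TRUE`.
#'
#' @param tree A `ClusterTree` with AU values attached.
#' @param min_au Support threshold on the 0-100 scale (default 95).
#' @param include_root Whether the root node is eligible (default FALSE).
#' @return List with `clusters` (list of character vectors of protein ids),
#'   `au`, `bp` (support of each returned cluster) and `unassigned`
#'   (ids in no supported cluster).
#' @export
cut_by_support <- function(tree, min_au = 95, include_root = FALSE) {
  stopifnot(inherits(tree, "ClusterTree"))
  if (all(is.na(tree$au))) stop("tree has no AU support; run ",
                                "multiscale_bootstrap_support() first")
  n_nodes <- length(tree$clusters)
  eligible <- which(tree$au >= min_au)
  if (!include_root) eligible <- setdiff(eligible, n_nodes)
  # maximal: drop nodes nested inside another eligible node
  keep <- eligible[vapply(eligible, function(j) {
    !any(vapply(setdiff(eligible, j), function(k)
      all(tree$clusters[[j]] %in% tree$clusters[[k]]), TRUE))
  }, TRUE)]
  keep <- keep[order(-lengths(tree$clusters[keep]))]
  clusters <- lapply(keep, function(j) tree$labels[tree$clusters[[j]]])
  covered <- unique(unlist(clusters))
  list(clusters = clusters,
       au = tree$au[keep], bp = tree$bp[keep],
       unassigned = setdiff(tree$labels, covered))
}

#' Serialise a ClusterTree to newick
#'
#' Branch lengths are differences of merge heights; internal nodes carry
#' `"AU|BP"` labels (rounded to integers) when support has been attached.
#'
#' @param tree A `ClusterTree`.
#' @param digits Branch-length precision (default 10 significant digits).
#' @return A single newick string ending in `";"`.
#' @export
to_newick <- function(tree, digits = 10L) {
  stopifnot(inherits(tree, "ClusterTree"))
  hc <- tree$hclust
  has_support <- !all(is.na(tree$au))
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  node_str <- function(k, parent_h) {
    if (k < 0) {
      paste0(hc$labels[-k], ":", fmt(parent_h))
    } else {
      h <- hc$height[k]
      lab <- if (has_support)
        sprintf("%d|%d", round(tree$au[k]), round(tree$bp[k])) else ""
      paste0("(", node_str(hc$merge[k, 1], h), ",",
             node_str(hc$merge[k, 2], h), ")", lab,
             ":", fmt(parent_h - h))
    }
  }
  n_nodes <- nrow(hc$merge)
  h_root <- hc$height[n_nodes]
  lab_root <- if (has_support)
    sprintf("%d|%d", round(tree$au[n_nodes]), round(tree$bp[n_nodes])) else ""
  paste0("(", node_str(hc$merge[n_nodes, 1], h_root), ",",
         node_str(hc$merge[n_nodes, 2], h_root), ")", lab_root, ";")
}
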