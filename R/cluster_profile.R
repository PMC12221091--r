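# Sample-level PCA, log2-centered protein profiles, k-means under Pearson
# distance with a pattern-based relabeling convention, and cluster-level
# pattern accounting.

#' Center protein profiles
#'
#' Subtracts each protein's mean over all samples ("log2-centered
#' intensities"), so every row averages zero.
#'
#' @param m An [intensity_matrix()] or a numeric matrix.
#' @return A numeric matrix of centered profiles.
#' @export
center_profiles <- function(m) {
  x <- if (inherits(m, "intensity_matrix")) m$values else m
  x - rowMeans(x, na.rm = TRUE)
}

#' PCA of samples
#'
#' Singular value decomposition of the column-centered data with samples as
#' observations; proteins with missing values are dropped first (and
#' logged in the `n_dropped` field).
#'
#' @param m An [intensity_matrix()] (normalized scale expected).
#' @return A `pca_result`: `variance_fraction` per component (nonincreasing,
#'   summing to 1), `scores` (samples x components), `n_proteins_used`,
#'   `n_dropped`.
#' @export
pca_samples <- function(m) {
  x <- if (inherits(m, "intensity_matrix")) m$values else m
  complete <- rowSums(!is.finite(x)) == 0
  xc <- x[complete, , drop = FALSE]
  if (nrow(xc) < 2)
    abort_sp("fewer than 2 complete rows for PCA", "settleprot_cluster_error")
  pc <- stats::prcomp(t(xc), center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(variance_fraction = vf, scores = pc$x,
                 n_proteins_used = nrow(xc), n_dropped = sum(!complete)),
            class = "pca_result")
}

# z-score rows: mean 0, sd 1; Pearson distance 1 - r between two z-scored
# rows equals their squared Euclidean distance / (2 (p - 1))
zscore_rows <- function(x) {
  mu <- rowMeans(x)
  sd <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  (x - mu) / sd
}

#' Pearson distance between profile rows
#' @param x Numeric matrix.
#' @return Dense matrix of 1 - Pearson correlation between rows.
#' @export
pearson_distance <- function(x) {
  1 - stats::cor(t(x))
}

#' K-means clustering of temporal profiles under Pearson distance
#'
#' Rows are z-scored so that Pearson distance is proportional to squared
#' Euclidean distance, then Lloyd's algorithm is run from `n_restarts`
#' random initializations and the restart with the lowest total
#' within-cluster Pearson distance is kept. Constant (zero-variance)
#' profiles are excluded before clustering with a reason code. An emptied
#' cluster is re-seeded at the point farthest from its assigned centroid.
#' Clusters are then relabeled by a pattern convention: descending centroid
#' value at the reference timepoint, ties broken by ascending timepoint of
#' the centroid maximum — so C1/C2 are the zoospore-high clusters and the
#' late-rise cluster is named after the early-rise one.
#'
#' @param profiles Numeric matrix of (centered) profiles, or an
#'   [intensity_matrix()].
#' @param k Number of clusters.
#' @param seed Integer seed (restarts are deterministic given it).
#' @param n_restarts Random initializations.
#' @param design Optional [sample_design()]; required to average centroids
#'   per timepoint when `profiles` is a bare matrix.
#' @param max_iter Lloyd iteration cap per restart.
#' @return A `cluster_model`: `assignments` (named C1..Ck per protein),
#'   `centroids` (k x samples, z-score space), `centroid_by_timepoint`,
#'   `inertia` (total Pearson distance), `excluded`, `seed`, `n_restarts`.
#' @export
kmeans_pearson <- function(profiles, k = 4, seed = 1, n_restarts = 25,
                           design = NULL, max_iter = 100) {
  if (inherits(profiles, "intensity_matrix")) {
    design <- profiles$design
    profiles <- profiles$values
  }
  complete <- rowSums(!is.finite(profiles)) == 0
  x <- profiles[complete, , drop = FALSE]
  sds <- sqrt(row_vars(x))
  constant <- !is.finite(sds) | sds < 1e-12
  excluded <- data.frame(
    protein_id = c(rownames(profiles)[!complete], rownames(x)[constant]),
    reason = c(rep("missing_values", sum(!complete)),
               rep("constant_profile", sum(constant))),
    stringsAsFactors = FALSE
  )
  z <- zscore_rows(x[!constant, , drop = FALSE])
  n <- nrow(z)
  if (n < k)
    abort_sp("fewer usable profiles than clusters", "settleprot_cluster_error")

  best <- with_stream_seed(seed, "kmeans", {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- lloyd_once(z, k, max_iter)
      if (is.null(best) || fit$ss < best$ss) best <- fit
    }
    best
  })

  p <- ncol(z)
  inertia <- best$ss / (2 * (p - 1)) # squared-Euclidean -> Pearson units

  # pattern-based relabeling
  if (!is.null(design)) {
    tps <- sort(unique(design$timepoint))
    cbt <- vapply(tps, function(t)
      rowMeans(best$centers[, design$timepoint == t, drop = FALSE]),
      numeric(k))
    if (k == 1) cbt <- matrix(cbt, nrow = 1)
    colnames(cbt) <- paste0("T", tps)
  } else {
    cbt <- best$centers
    colnames(cbt) <- colnames(z) %||% paste0("S", seq_len(p))
  }
  ord <- order(-cbt[, 1], apply(cbt, 1, which.max))
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels <- paste0("C", relabel[best$cluster])
  centroids <- best$centers[ord, , drop = FALSE]
  cbt <- cbt[ord, , drop = FALSE]
  rownames(centroids) <- rownames(cbt) <- paste0("C", seq_len(k))
  colnames(centroids) <- colnames(z)

  structure(list(
    assignments = stats::setNames(labels, rownames(z)),
    centroids = centroids, centroid_by_timepoint = cbt,
    inertia = inertia, excluded = excluded,
    k = k, seed = seed, n_restarts = n_restarts
  ), class = "cluster_model")
}

# one Lloyd run from a random initialization; objective never increases
lloyd_once <- function(z, k, max_iter) {
  n <- nrow(z)
  centers <- z[sample.int(n, k), , drop = FALSE]
  cluster <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(z^2), rowSums(centers^2), "+") - 2 * z %*% t(centers)
    new_cluster <- max.col(-d2, ties.method = "first")
    # re-seed each emptied cluster at the point farthest from its centroid
    movable <- rep(TRUE, n)
    repeat {
      empty <- setdiff(seq_len(k), unique(new_cluster))
      if (length(empty) == 0) break
      own <- d2[cbind(seq_len(n), new_cluster)]
      own[!movable] <- -Inf
      far <- which.max(own)
      new_cluster[far] <- empty[1]
      movable[far] <- FALSE
    }
    if (identical(new_cluster, cluster)) break
    cluster <- new_cluster
    for (j in seq_len(k)) {
      members <- which(cluster == j)
      if (length(members) > 0)
        centers[j, ] <- colMeans(z[members, , drop = FALSE])
    }
  }
  d2 <- outer(rowSums(z^2), rowSums(centers^2), "+") - 2 * z %*% t(centers)
  ss <- sum(d2[cbind(seq_len(n), cluster)])
  list(cluster = cluster, centers = centers, ss = ss)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: k = %d, %d profiles, inertia %.3f (Pearson)\n",
              x$k, length(x$assignments), x$inertia))
  print(table(x$assignments))
  invisible(x)
}

#' Per-cluster significance pattern accounting
#'
#' For each cluster and timepoint: cluster size and the count/fraction of
#' member proteins significantly down (resp. up) at that timepoint.
#'
#' @param model A `cluster_model`.
#' @param table A called contrast table from [adjust_and_call()].
#' @return Data frame with one row per cluster x timepoint.
#' @export
cluster_pattern_stats <- function(model, table) {
  stopifnot(inherits(model, "cluster_model"))
  ids <- names(model$assignments)
  tab <- table[table$protein_id %in% ids, , drop = FALSE]
  tab$cluster <- model$assignments[tab$protein_id]
  out <- do.call(rbind, lapply(split(tab, list(tab$cluster, tab$timepoint)),
    function(d) {
      if (nrow(d) == 0) return(NULL)
      size <- sum(model$assignments == d$cluster[1])
      data.frame(cluster = d$cluster[1], timepoint = d$timepoint[1],
                 size = size,
                 n_down = sum(d$direction == "down", na.rm = TRUE),
                 n_up = sum(d$direction == "up", na.rm = TRUE),
                 frac_down = sum(d$direction == "down", na.rm = TRUE) / size,
                 frac_up = sum(d$direction == "up", na.rm = TRUE) / size,
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out[order(out$cluster, out$timepoint), , drop = FALSE]
}
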