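# Ward minimum-variance hierarchical clustering of the training scores,
# cutting into lettered clusters, and nearest-centroid assignment.

#' Ward/Euclidean hierarchical linkage
#'
#' Agglomerative minimum-variance clustering via the Lance-Williams
#' recurrence on squared Euclidean distances. The height recorded for a
#' merge is its Ward cost, i.e. the increase in total within-cluster sum of
#' squares; heights are non-decreasing. Ties are broken deterministically:
#' among equal-cost pairs the one whose smallest member index (then second
#' smallest) is lowest merges first.
#'
#' @param scores numeric matrix (ILs x components); row names identify ILs
#'   and must be unique
#' @return list of class \code{"wardLinkage"} with hclust-compatible
#'   \code{merge}, \code{height}, \code{order}, \code{labels} fields.
#' @export
wardLinkage <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 2L) stop("need at least 2 rows to cluster", call. = FALSE)
  labs <- rownames(scores) %||% as.character(seq_len(n))
  if (anyDuplicated(labs)) {
    stop("duplicate il_ids: ", paste(unique(labs[duplicated(labs)]),
                                     collapse = ", "), call. = FALSE)
  }
  # D[i, j] = Ward merge cost of current clusters i and j;
  # for singletons that is ||x_i - x_j||^2 / 2
  d2 <- as.matrix(stats::dist(scores))^2
  D <- d2 / 2
  diag(D) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  node <- -seq_len(n)                 # hclust convention: negatives = leaves
  minmem <- seq_len(n)                # smallest original member index
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    best <- NULL; best_cost <- Inf
    for (ai in seq_along(idx)) {
      i <- idx[ai]
      for (aj in seq_along(idx)[-seq_len(ai)]) {
        j <- idx[aj]
        cost <- D[i, j]
        cand <- sort(c(minmem[i], minmem[j]))
        if (cost < best_cost - 1e-12 ||
            (abs(cost - best_cost) <= 1e-12 && !is.null(best) &&
             (cand[1] < best$mem[1] ||
              (cand[1] == best$mem[1] && cand[2] < best$mem[2])))) {
          best <- list(i = min(i, j), j = max(i, j), mem = cand)
          best_cost <- cost
        }
      }
    }
    i <- best$i; j <- best$j
    height[step] <- best_cost
    merge[step, ] <- c(node[i], node[j])[order(c(node[i], node[j]))]
    # Lance-Williams update for Ward: new cluster at slot i
    for (k in idx) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <-
        ((size[i] + size[k]) * D[i, k] + (size[j] + size[k]) * D[j, k] -
           size[k] * D[i, j]) / (size[i] + size[j] + size[k])
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    node[i] <- step
    minmem[i] <- min(minmem[i], minmem[j])
  }
  # tied merges can pick up O(eps) rounding noise in the recurrence; Ward is
  # monotone, so flatten inversions that are numerically zero
  for (s in seq_len(n - 1L)[-1]) {
    if (height[s] < height[s - 1L] &&
        height[s - 1L] - height[s] <= 1e-9 * max(1, height[s - 1L])) {
      height[s] <- height[s - 1L]
    }
  }
  ord <- .dendro_order(merge, n)
  structure(list(merge = merge, height = height, order = ord, labels = labs,
                 method = "ward", dist.method = "euclidean"),
            class = c("wardLinkage", "hclust"))
}

.dendro_order <- function(merge, n) {
  expand <- function(k) {
    if (k < 0) return(-k)
    c(expand(merge[k, 1]), expand(merge[k, 2]))
  }
  expand(n - 1L)
}

.letters_for_centroids <- function(centroids, k) {
  # low-PC1 group reads A (low PC2) upward; high-PC1 group reads F (low PC2),
  # then D, E upward -- the lettering the cluster descriptions use
  pc1 <- centroids[, 1]
  pc2 <- if (ncol(centroids) >= 2) centroids[, 2] else rep(0, nrow(centroids))
  lab <- character(k)
  if (k == 6L && sum(pc1 < 0) == 3L) {
    low <- which(pc1 < 0); high <- which(pc1 >= 0)
    lab[low[order(pc2[low])]] <- c("A", "B", "C")
    lab[high[order(pc2[high])]] <- c("F", "D", "E")
  } else {
    lab[order(pc1, pc2)] <- LETTERS[seq_len(k)]
  }
  lab
}

#' Cut a Ward tree into lettered clusters
#'
#' Cuts the linkage at \code{k} clusters and assigns letters by the map
#' geometry: with the default \code{k = 6} and a balanced split over the
#' PC1 sign, the negative-PC1 centroids get A (lowest PC2), B, C (highest
#' PC2) and the positive-PC1 centroids get F (lowest PC2), D, E -- matching
#' the verbal cluster descriptions (A small cations + halides, C the
#' TFSI-type anions, E the large phosphonium/amino-acid salts). For any
#' other configuration letters run alphabetically by (PC1, PC2) centroid
#' order.
#'
#' @param linkage result of [wardLinkage()]
#' @param scores the score matrix the linkage was built on
#' @param k number of clusters (default 6)
#' @return a [ClusterModel-class]
#' @export
cutAndLabel <- function(linkage, scores, k = 6L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  if (k > n) stop("k cannot exceed the number of ILs", call. = FALSE)
  groups <- stats::cutree(linkage, k = k)
  centroids <- do.call(rbind, lapply(seq_len(k), function(g) {
    colMeans(scores[groups == g, , drop = FALSE])
  }))
  letters_ <- .letters_for_centroids(centroids, k)
  rownames(centroids) <- letters_
  centroids <- centroids[order(letters_), , drop = FALSE]
  colnames(centroids) <- colnames(scores)
  labels <- letters_[groups]
  names(labels) <- linkage$labels
  new("ClusterModel", merge = linkage$merge, height = linkage$height,
      k = as.integer(k), labels = labels, centroids = centroids)
}

#' Assign a score to its nearest cluster
#'
#' Euclidean nearest-centroid rule. Exact ties go to the alphabetically
#' first label and are flagged.
#'
#' @param model a [ClusterModel-class]
#' @param score numeric vector or matrix of scores (rows = queries)
#' @return data.frame: label, distance to the winning centroid, tie flag,
#'   plus one distance column per cluster.
#' @export
assignCluster <- function(model, score) {
  stopifnot(is(model, "ClusterModel"))
  if (is.null(dim(score))) score <- matrix(score, nrow = 1)
  cen <- model@centroids
  d <- sqrt(outer(rowSums(score^2), rep(1, nrow(cen))) -
              2 * score %*% t(cen) +
              outer(rep(1, nrow(score)), rowSums(cen^2)))
  d[d < 0] <- 0  # numeric noise
  lab <- character(nrow(score)); tie <- logical(nrow(score))
  for (r in seq_len(nrow(score))) {
    dr <- d[r, ]
    win <- which(dr <= min(dr) + 1e-12)
    lab[r] <- rownames(cen)[win[1]]   # centroids are letter-sorted
    tie[r] <- length(win) > 1L
  }
  out <- data.frame(label = lab, distance = apply(d, 1, min), tie = tie)
  dd <- as.data.frame(d)
  names(dd) <- paste0("d_", rownames(cen))
  cbind(out, dd)
}

#' Export merge order as Newick text
#'
#' Text serialization of the dendrogram (branch lengths are merge heights).
#'
#' @param linkage result of [wardLinkage()]
#' @return character(1), a Newick tree string.
#' @export
linkageNewick <- function(linkage) {
  bld <- function(k) {
    if (k < 0) return(linkage$labels[-k])
    h <- linkage$height[k]
    sprintf("(%s,%s):%g", bld(linkage$merge[k, 1]), bld(linkage$merge[k, 2]), h)
  }
  paste0(bld(length(linkage$height)), ";")
}
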