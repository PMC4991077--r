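# Autoscaling, the principal-component chemical-space map, projection of new
# ions, and loading interpretation by the |r| > 0.7 significance rule.

#' Autoscale a descriptor matrix
#'
#' Centers every descriptor to mean 0 and scales to standard deviation 1
#' (sample sd, n-1). Constant descriptors -- those whose sd is below
#' \code{tol * max(1, |mean|)} -- cannot be scaled and are dropped and
#' reported, mirroring the treatment of descriptors for which a correlation
#' with a component is undefined.
#'
#' @param X numeric matrix or data.frame, ILs x descriptors, no missing values
#' @param tol relative sd tolerance for constant-column detection
#' @return list with \code{scaled} (matrix over retained descriptors),
#'   \code{center}, \code{scale} (named stats of retained descriptors) and
#'   \code{dropped} (character).
#' @export
autoscale <- function(X, tol = 1e-12) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("autoscale needs at least 2 rows", call. = FALSE)
  if (anyNA(X)) {
    idx <- which(is.na(X), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at row %d, column %s", idx[1],
                 colnames(X)[idx[2]] %||% idx[2]), call. = FALSE)
  }
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  constant <- sd_ < tol * pmax(1, abs(mu))
  dropped <- colnames(X)[constant]
  keep <- !constant
  scaled <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sd_[keep], "/")
  list(scaled = scaled, center = mu[keep], scale = sd_[keep],
       dropped = as.character(dropped))
}

.orient_components <- function(L, anchors) {
  # base convention: the largest-|loading| entry of each component is positive
  flip <- rep(1, ncol(L))
  for (k in seq_len(ncol(L))) {
    top <- which.max(abs(L[, k]))
    if (L[top, k] < 0) flip[k] <- -1
  }
  # anchor convention: a named size descriptor must load positively, so the
  # map keeps the orientation in which components grow with ion size
  for (k in seq_along(anchors)) {
    if (k > ncol(L)) break
    a <- anchors[k]
    if (!is.na(a) && a %in% rownames(L) && L[a, k] != 0) {
      flip[k] <- sign(L[a, k])
    }
  }
  sweep(L, 2, flip, "*")
}

#' Fit the principal-component chemical-space map
#'
#' Correlation-matrix PCA: eigendecomposition of the covariance of the
#' autoscaled descriptor matrix. Components are ordered by decreasing
#' eigenvalue. Sign convention: the largest-|loading| entry of each component
#' is positive, and a component whose orientation anchor (by default the
#' cation molecular weight for PC1 and the anion molecular weight for PC2)
#' loads negatively is flipped, so that both components increase with ion
#' size as the trend rules expect.
#'
#' @param X raw descriptor matrix or data.frame (ILs x descriptors); row
#'   names (or an \code{il_id} column) identify the training ILs
#' @param nComponents number of components kept (default 2)
#' @param tol constant-column tolerance passed to [autoscale()]
#' @param anchors character, orientation anchor descriptor per component
#' @return a [ChemSpaceModel-class]
#' @export
fitChemSpace <- function(X, nComponents = 2L, tol = 1e-12,
                         anchors = c("MW^C", "MW^A")) {
  if (is.data.frame(X) && "il_id" %in% names(X)) {
    ids <- X$il_id
    X <- as.matrix(X[, setdiff(names(X), "il_id"), drop = FALSE])
    rownames(X) <- ids
  }
  X <- as.matrix(X)
  sc <- autoscale(X, tol = tol)
  Z <- sc$scaled
  p <- ncol(Z)
  if (nComponents > p) {
    stop(sprintf("nComponents (%d) exceeds the %d retained descriptors",
                 nComponents, p), call. = FALSE)
  }
  R <- stats::cov(Z)
  ei <- eigen(R, symmetric = TRUE)
  lambda <- pmax(ei$values, 0)
  L <- .orient_components(ei$vectors[, seq_len(nComponents), drop = FALSE] |>
                            `rownames<-`(colnames(Z)), anchors)
  colnames(L) <- paste0("PC", seq_len(nComponents))
  scores <- Z %*% L
  new("ChemSpaceModel",
      center = sc$center, scale = sc$scale, dropped = sc$dropped,
      loadings = L, eigenvalues = lambda,
      explainedFraction = lambda[seq_len(nComponents)] / sum(lambda),
      trainingScores = scores, nComponents = as.integer(nComponents))
}

#' Project raw descriptor vectors onto a fitted map
#'
#' Applies the stored centering/scaling and the loading matrix to new raw
#' descriptor data. Projecting a training row reproduces its stored training
#' score.
#'
#' @param model a [ChemSpaceModel-class]
#' @param x named numeric vector, matrix or data.frame of raw descriptors;
#'   must cover every retained descriptor by name
#' @return score matrix (rows x components)
#' @export
projectScores <- function(model, x) {
  stopifnot(is(model, "ChemSpaceModel"))
  if (is.data.frame(x)) {
    ids <- if ("il_id" %in% names(x)) x$il_id else rownames(x)
    x <- as.matrix(x[, setdiff(names(x), "il_id"), drop = FALSE])
    rownames(x) <- ids
  } else if (is.null(dim(x))) {
    x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  }
  need <- rownames(model@loadings)
  miss <- setdiff(need, colnames(x))
  if (length(miss)) {
    stop("missing descriptor(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  Z <- sweep(sweep(x[, need, drop = FALSE], 2, model@center), 2,
             model@scale, "/")
  Z %*% model@loadings
}

#' Loading significance by the 0.7 correlation rule
#'
#' For every retained descriptor and component, the Pearson correlation
#' between the descriptor column and the component score column. A
#' descriptor significantly shapes a component when |r| strictly exceeds the
#' threshold (default 0.7); |r| equal to the threshold is not flagged. On
#' autoscaled data the identity r = loading * sqrt(eigenvalue) holds and is
#' verified internally.
#'
#' @param model a [ChemSpaceModel-class]
#' @param X the raw training descriptor matrix/data.frame the model was
#'   fitted on
#' @param threshold significance threshold on |r|
#' @return data.frame: descriptor, component, r, significant.
#' @export
interpretLoadings <- function(model, X, threshold = 0.7) {
  stopifnot(is(model, "ChemSpaceModel"))
  Z <- projectScores(model, X)  # scores
  if (is.data.frame(X)) X <- X[, setdiff(names(X), "il_id"), drop = FALSE]
  X <- as.matrix(X)[, rownames(model@loadings), drop = FALSE]
  if (any(apply(Z, 2, stats::sd) == 0)) {
    stop("constant score column: correlation undefined", call. = FALSE)
  }
  r <- stats::cor(X, Z)
  # internal consistency: r = loading * sqrt(lambda) on autoscaled fits
  rid <- sweep(model@loadings, 2,
               sqrt(model@eigenvalues[seq_len(model@nComponents)]), "*")
  if (max(abs(r - rid)) > 1e-8) {
    warning("r deviates from loading*sqrt(eigenvalue): ",
            "was the model fitted on this matrix?")
  }
  out <- data.frame(
    descriptor = rep(rownames(r), times = ncol(r)),
    component = rep(colnames(Z), each = nrow(r)),
    r = as.vector(r))
  out$significant <- abs(out$r) > threshold
  attr(out, "threshold") <- threshold
  out
}

#' Reconstruct autoscaled data from scores
#'
#' Inverse transform; with all components retained this reproduces the
#' autoscaled matrix.
#'
#' @param model a [ChemSpaceModel-class]
#' @param scores score matrix
#' @return matrix in autoscaled descriptor space
#' @export
reconstructScaled <- function(model, scores = model@trainingScores) {
  scores %*% t(model@loadings)
}
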