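#' @import methods
NULL

#' MolecularGraph: one ion as an attributed graph
#'
#' Holds a single ion (cation or anion) as a table of heavy atoms and a table
#' of bonds. Implicit hydrogens are stored per atom, never as graph vertices.
#'
#' @slot atoms data.frame with one row per heavy atom and columns
#'   \code{element} (symbol), \code{charge} (formal charge, e),
#'   \code{hcount} (implicit hydrogens) and \code{aromatic} (logical).
#' @slot bonds data.frame with columns \code{i}, \code{j} (1-based atom
#'   indices, \code{i < j}), \code{order} (1, 2 or 3; 1 for aromatic bonds),
#'   \code{aromatic} (logical) and \code{ring} (logical, bond lies on a cycle).
#' @slot netCharge integer, sum of formal charges.
#'
#' @seealso [parseSmiles()], [constitutionalVector()]
#' @export
setClass("MolecularGraph",
  representation(atoms = "data.frame", bonds = "data.frame",
                 netCharge = "integer"))

setValidity("MolecularGraph", function(object) {
  a <- object@atoms; b <- object@bonds
  msg <- character()
  need_a <- c("element", "charge", "hcount", "aromatic")
  need_b <- c("i", "j", "order", "aromatic", "ring")
  if (!all(need_a %in% names(a))) {
    msg <- c(msg, "atoms must have columns element, charge, hcount, aromatic")
  }
  if (!all(need_b %in% names(b))) {
    msg <- c(msg, "bonds must have columns i, j, order, aromatic, ring")
  }
  if (length(msg)) return(msg)
  n <- nrow(a)
  if (n < 1L) msg <- c(msg, "graph must contain at least one atom")
  if (nrow(b)) {
    if (any(b$i < 1L | b$i > n | b$j < 1L | b$j > n)) {
      msg <- c(msg, "bond atom indices out of range")
    } else {
      if (any(b$i == b$j)) msg <- c(msg, "self-bonds (i == j) are not allowed")
      key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
      if (anyDuplicated(key)) msg <- c(msg, "duplicate bonds")
    }
  }
  if (n >= 1L && !length(msg) && !.is_connected(n, b)) {
    msg <- c(msg, "graph is disconnected: not a single ion")
  }
  if (!length(msg) && object@netCharge != sum(a$charge)) {
    msg <- c(msg, "netCharge does not equal the sum of formal charges")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn MolecularGraph compact structural summary
#' @param object a \code{MolecularGraph}
#' @export
setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf("MolecularGraph: %d heavy atoms, %d bonds, %d implicit H, net charge %+d\n",
              nrow(object@atoms), nrow(object@bonds),
              sum(object@atoms$hcount), object@netCharge))
  cat("  formula atoms:",
      paste(sprintf("%s:%d", names(tab <- table(object@atoms$element)), tab),
            collapse = " "), "\n")
  invisible(object)
})

#' ChemSpaceModel: autoscaling + principal-component map
#'
#' The fitted two-(or more-)component chemical-space map: per-descriptor
#' autoscaling statistics, correlation-matrix PCA loadings and eigenvalues,
#' and the training scores the reference ionic liquids occupy.
#'
#' @slot center named numeric, training means of retained descriptors.
#' @slot scale named numeric, training standard deviations (sample sd).
#' @slot dropped character, descriptors removed as constant before the fit.
#' @slot loadings matrix (retained descriptor x component), orthonormal columns.
#' @slot eigenvalues numeric, the full non-increasing spectrum (all retained
#'   descriptors); on autoscaled data it sums to the number of retained
#'   descriptors.
#' @slot explainedFraction numeric, eigenvalue / number of retained descriptors.
#' @slot trainingScores matrix (IL x component), zero column means.
#' @slot nComponents integer.
#' @seealso [fitChemSpace()], [projectScores()], [interpretLoadings()]
#' @export
setClass("ChemSpaceModel",
  representation(center = "numeric", scale = "numeric", dropped = "character",
                 loadings = "matrix", eigenvalues = "numeric",
                 explainedFraction = "numeric", trainingScores = "matrix",
                 nComponents = "integer"))

setValidity("ChemSpaceModel", function(object) {
  msg <- character()
  L <- object@loadings
  k <- object@nComponents
  if (ncol(L) != k) msg <- c(msg, "loadings must have nComponents columns")
  if (length(object@eigenvalues) < k) {
    msg <- c(msg, "eigenvalues must cover at least the kept components")
  }
  if (is.unsorted(rev(object@eigenvalues), strictly = FALSE)) {
    msg <- c(msg, "eigenvalues must be non-increasing")
  }
  if (length(object@explainedFraction) != k) {
    msg <- c(msg, "one explained fraction per kept component")
  }
  p <- nrow(L)
  if (abs(sum(object@eigenvalues) - p) > 1e-6 * max(1, p)) {
    msg <- c(msg, "eigenvalues must sum to the number of retained descriptors")
  }
  if (!length(msg)) {
    G <- crossprod(L)
    if (max(abs(G - diag(k))) > 1e-8) {
      msg <- c(msg, "loading columns must be orthonormal (tolerance 1e-8)")
    }
    if (max(abs(colMeans(object@trainingScores))) > 1e-6) {
      msg <- c(msg, "training scores must have zero mean per component")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ChemSpaceModel summary of variance bookkeeping
#' @param object a \code{ChemSpaceModel}
#' @export
setMethod("show", "ChemSpaceModel", function(object) {
  cat(sprintf("ChemSpaceModel: %d retained descriptors (%d dropped as constant), %d components\n",
              nrow(object@loadings), length(object@dropped), object@nComponents))
  ef <- 100 * object@explainedFraction
  cat(sprintf("  explained variance: %s (total %.2f%%)\n",
              paste(sprintf("PC%d %.2f%%", seq_along(ef), ef), collapse = ", "),
              sum(ef)))
  cat(sprintf("  training set: %d ionic liquids\n", nrow(object@trainingScores)))
  invisible(object)
})

#' ClusterModel: Ward/Euclidean hierarchy cut into labelled clusters
#'
#' @slot merge integer matrix (n-1 x 2), hclust-style merge records (negative
#'   entries are singletons).
#' @slot height numeric, Ward merge cost (increase in within-cluster sum of
#'   squares) per merge; non-decreasing.
#' @slot k integer, number of clusters the model was cut at.
#' @slot labels named character, cluster letter per training IL.
#' @slot centroids matrix (cluster x component), mean score of members.
#' @seealso [wardLinkage()], [cutAndLabel()], [assignCluster()]
#' @export
setClass("ClusterModel",
  representation(merge = "matrix", height = "numeric", k = "integer",
                 labels = "character", centroids = "matrix"))

setValidity("ClusterModel", function(object) {
  msg <- character()
  n <- length(object@labels)
  if (nrow(object@merge) != n - 1L) msg <- c(msg, "merge must have n-1 rows")
  if (length(object@height) != n - 1L) msg <- c(msg, "one height per merge")
  if (is.unsorted(object@height)) {
    msg <- c(msg, "Ward merge heights must be non-decreasing")
  }
  if (nrow(object@centroids) != object@k) {
    msg <- c(msg, "one centroid per cluster")
  }
  if (!all(object@labels %in% rownames(object@centroids))) {
    msg <- c(msg, "every label must have a centroid")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ClusterModel cluster census
#' @param object a \code{ClusterModel}
#' @export
setMethod("show", "ClusterModel", function(object) {
  tab <- table(object@labels)
  cat(sprintf("ClusterModel: %d training ILs in %d clusters (Ward/Euclidean)\n",
              length(object@labels), object@k))
  cat(" ", paste(sprintf("%s:%d", names(tab), tab), collapse = "  "), "\n")
  invisible(object)
})

#' QSPRModel: multiple linear regression model with validation statistics
#'
#' @slot descriptors character, selected descriptor names.
#' @slot coefficients named numeric, intercept first.
#' @slot trainX matrix, training design (descriptor columns only).
#' @slot trainY numeric, training response (kJ/mol for enthalpy of fusion).
#' @slot stats list with r2, rmse_train, q2_loo and (after external
#'   validation) q2_ext, rmse_ext.
#' @slot leverageThreshold numeric, h* = 3(p+1)/n.
#' @seealso [fitMLR()], [q2Loo()], [externalValidation()], [applicabilityDomain()]
#' @export
setClass("QSPRModel",
  representation(descriptors = "character", coefficients = "numeric",
                 trainX = "matrix", trainY = "numeric", stats = "list",
                 leverageThreshold = "numeric"))

setValidity("QSPRModel", function(object) {
  msg <- character()
  if (length(object@coefficients) != length(object@descriptors) + 1L) {
    msg <- c(msg, "coefficients must be intercept + one per descriptor")
  }
  s <- object@stats
  if (!is.null(s$r2) && (s$r2 < -1e-9 || s$r2 > 1 + 1e-9)) {
    msg <- c(msg, "R^2 must lie in [0, 1]")
  }
  if (!is.null(s$q2_loo) && !is.na(s$q2_loo) && !is.null(s$r2) &&
      s$q2_loo > s$r2 + 1e-9) {
    msg <- c(msg, "Q^2_LOO cannot exceed R^2 on the training data")
  }
  if (object@leverageThreshold <= 0) msg <- c(msg, "h* must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn QSPRModel equation and statistics
#' @param object a \code{QSPRModel}
#' @export
setMethod("show", "QSPRModel", function(object) {
  co <- object@coefficients
  eq <- paste(sprintf("%+.4g*%s", co[-1], object@descriptors), collapse = " ")
  cat("QSPRModel (MLR):\n  y =", sprintf("%.4g", co[1]), eq, "\n")
  s <- object@stats
  cat(sprintf("  n_train = %d, R2 = %.4f, RMSE = %.4g, Q2_LOO = %.4f\n",
              nrow(object@trainX), s$r2, s$rmse_train, s$q2_loo))
  if (!is.null(s$q2_ext)) {
    cat(sprintf("  Q2_ext = %.4f, RMSE_ext = %.4g\n", s$q2_ext, s$rmse_ext))
  }
  cat(sprintf("  applicability domain: h* = %.4f\n", object@leverageThreshold))
  invisible(object)
})

#' ModelBundle: the complete fitted reference map
#'
#' Everything needed to place a new ionic liquid: descriptor registry version,
#' the chemical-space model, the cluster model built on its training scores,
#' and the property overlays (training trend-score distributions plus the
#' standardized property bins of the reference measurements).
#'
#' @slot chemspace a \code{ChemSpaceModel}.
#' @slot clusters a \code{ClusterModel}.
#' @slot overlays list: \code{trend} (data.frame of training trend scores per
#'   property), \code{bins} (data.frame of standardized measured properties
#'   with bin assignments), \code{edges} (bin edges), \code{weights}
#'   (trend-rule weight matrix).
#' @slot provenance list: registry version, config, seed, content hash.
#' @seealso [buildReferenceModel()], [predictNew()], [saveBundle()]
#' @export
setClass("ModelBundle",
  representation(chemspace = "ChemSpaceModel", clusters = "ClusterModel",
                 overlays = "list", provenance = "list"))

setValidity("ModelBundle", function(object) {
  msg <- character()
  sc <- object@chemspace@trainingScores
  if (length(object@clusters@labels) != nrow(sc)) {
    msg <- c(msg, "cluster model must label exactly the bundled training scores")
  }
  tr <- object@overlays$trend
  if (!is.null(tr) && nrow(tr) != nrow(sc)) {
    msg <- c(msg, "trend overlays must reference the bundled training ILs only")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ModelBundle bundle overview
#' @param object a \code{ModelBundle}
#' @export
setMethod("show", "ModelBundle", function(object) {
  cat("ModelBundle (reference chemical-space map)\n")
  show(object@chemspace)
  show(object@clusters)
  cat(sprintf("  overlays: %s\n",
              paste(names(object@overlays$trend)[-1], collapse = ", ")))
  cat(sprintf("  registry %s, content hash %s\n",
              object@provenance$registry_version,
              substr(object@provenance$hash %||% "<none>", 1, 12)))
  invisible(object)
})

`%||%` <- function(x, y) if (is.null(x)) y else x
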