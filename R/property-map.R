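# Range-scale standardization of measured properties, binning to the color
# scale, and qualitative predictions from the documented trend rules on the
# component scores.

.LOG_PROPERTIES <- c("viscosity", "Kow", "solubility")

.DEFAULT_EDGES <- c(-1.5, -0.5, 0.5, 1.5)
.BIN_LABELS <- c("very-low", "low", "medium", "high", "very-high")
.BIN_COLORS <- c("#2166AC", "#92C5DE", "#F7F7F7", "#F4A582", "#B2182B")

# unit trend-rule weights on (PC1, PC2): rows are properties
.DEFAULT_TREND_WEIGHTS <- matrix(
  c( 1, -1,   # viscosity rises with PC1, falls with PC2
     1,  0,   # Kow proportional to PC1
    -1,  1,   # solubility opposite to Kow, rising with PC2
     0,  1),  # enthalpy of fusion mostly follows PC2
  ncol = 2, byrow = TRUE,
  dimnames = list(.PROPERTIES, c("PC1", "PC2")))

#' Standardize property values to z-scores
#'
#' Within each property, values are transformed to mean 0 and standard
#' deviation 1 (sample sd). Heavy-tailed properties in raw units --
#' viscosity, Kow and solubility -- are log10-transformed first (a value
#' already on a log scale can be marked with \code{logged = TRUE} in the
#' input or by passing units \code{"log"}); enthalpy of fusion stays linear.
#' Standardization is invariant to affine transforms of the input.
#'
#' @param values numeric vector of measured values for one property
#' @param property property name from the closed set
#' @param log_transform override the per-property default log rule
#' @return numeric z-scores, with attributes \code{center}, \code{scale},
#'   \code{logged}.
#' @export
standardizeProperty <- function(values, property = "enthalpy_of_fusion",
                                log_transform = NULL) {
  property <- match.arg(property, .PROPERTIES)
  if (length(values) < 2L || !all(is.finite(values))) {
    stop("need at least 2 finite values to standardize", call. = FALSE)
  }
  logged <- log_transform %||% (property %in% .LOG_PROPERTIES)
  x <- if (logged) {
    if (any(values <= 0)) {
      stop("log transform requires positive values (property ", property, ")",
           call. = FALSE)
    }
    log10(values)
  } else values
  s <- stats::sd(x)
  if (s < 1e-12 * max(1, abs(mean(x)))) {
    stop("constant property: standardization undefined", call. = FALSE)
  }
  structure((x - mean(x)) / s, center = mean(x), scale = s, logged = logged)
}

#' Bin standardized values onto the color range scale
#'
#' Five bins over the default edges (-1.5, -0.5, 0.5, 1.5), half-open on the
#' right: a value equal to an edge belongs to the upper of the two adjacent
#' bins, and values beyond the outer edges are clamped into the outer bins.
#'
#' @param z numeric standardized values
#' @param edges strictly increasing bin edges
#' @return data.frame: z, bin (0-based index), level label, color key.
#' @export
binToLevels <- function(z, edges = .DEFAULT_EDGES) {
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("bin edges must be strictly increasing", call. = FALSE)
  }
  bin <- findInterval(z, edges)          # number of edges <= z
  nb <- length(edges) + 1L
  labels <- if (nb == 5L) .BIN_LABELS else paste0("bin", seq_len(nb) - 1L)
  colors <- if (nb == 5L) .BIN_COLORS else rep(NA_character_, nb)
  data.frame(z = z, bin = bin, level = labels[bin + 1L],
             color = colors[bin + 1L])
}

#' Trend scores from component scores
#'
#' Linear trend rules with unit weights on the component scores:
#' T_viscosity = +PC1 - PC2, T_Kow = +PC1, T_solubility = -PC1 + PC2,
#' T_enthalpy_of_fusion = +PC2. Only the signs (and the dominance of PC2 for
#' the enthalpy of fusion) are asserted by the underlying map reading; the
#' unit magnitudes are configurable defaults.
#'
#' @param scores matrix or vector of (PC1, PC2) scores
#' @param weights property x component weight matrix
#' @return matrix (rows x properties) of trend scores.
#' @export
trendScores <- function(scores, weights = .DEFAULT_TREND_WEIGHTS) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  scores <- as.matrix(scores)[, seq_len(ncol(weights)), drop = FALSE]
  out <- scores %*% t(weights)
  colnames(out) <- rownames(weights)
  out
}

.DHF_CLUSTER_NOTE <- c(
  A = "low-prone", B = "uncertain", C = "high-prone",
  D = "uncertain", E = "uncertain", F = "low-prone")

.level_from_percentile <- function(p, cuts = c(1 / 3, 2 / 3)) {
  ifelse(p <= cuts[1], "low", ifelse(p <= cuts[2], "medium", "high"))
}

#' Qualitative property prediction for projected ILs
#'
#' Converts trend scores into ordinal levels by their percentile against the
#' training trend distribution (cut points at 33 1/3 % and 66 2/3 %), and
#' attaches the cluster-based rationale: for the enthalpy of fusion the
#' cluster heuristic (C high-prone, A/F low-prone, B/D/E uncertain, always
#' with a reduced-confidence note), for viscosity a note when the IL sits in
#' the TFSI-type cluster C whose salts tend to the lowest viscosities, and a
#' caveat flag on the solubility PC2 term for high-PC1 ILs where the cation
#' dominates.
#'
#' @param trend matrix of query trend scores from [trendScores()]
#' @param training_trend data.frame/matrix of training trend scores (the
#'   bundle overlay)
#' @param cluster character vector of assigned cluster labels
#' @param scores matrix of query (PC1, PC2) scores (for the caveat flag)
#' @param cuts percentile cut points for low/medium/high
#' @return data.frame with per-property levels, percentiles, flags and
#'   rationale notes.
#' @export
qualitativePredict <- function(trend, training_trend, cluster, scores,
                               cuts = c(1 / 3, 2 / 3)) {
  if (is.null(dim(trend))) trend <- matrix(trend, nrow = 1,
                                           dimnames = list(NULL, names(trend)))
  training_trend <- as.data.frame(training_trend)
  if (!nrow(training_trend)) {
    stop("empty training trend distribution", call. = FALSE)
  }
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  out <- data.frame(row.names = seq_len(nrow(trend)))
  for (prop in .PROPERTIES) {
    ref <- training_trend[[prop]]
    p <- stats::ecdf(ref)(trend[, prop])
    out[[paste0(prop, "_percentile")]] <- p
    out[[paste0(prop, "_level")]] <- .level_from_percentile(p, cuts)
  }
  out$cluster <- cluster
  out$dhf_cluster_note <- unname(.DHF_CLUSTER_NOTE[cluster])
  out$dhf_confidence <- "reduced confidence: cluster trend only partly consistent across data sources"
  out$visc_note <- ifelse(cluster == "C",
                          "TFSI-type cluster C: tends to the lowest viscosities",
                          "")
  out$sol_caveat_high_pc1 <- scores[, 1] > 0
  out
}
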