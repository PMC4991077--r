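# End-to-end orchestration: build the reference map (descriptors ->
# autoscale -> PCA -> Ward clusters -> property overlays) and place new ILs
# on it.

#' Default pipeline configuration
#'
#' Every tunable default of the pipeline in one list: number of components,
#' number of clusters, orientation anchors, constant-column tolerance, bin
#' edges, trend-rule weights and percentile cut points.
#'
#' @return named list of defaults.
#' @export
ilpcConfig <- function() {
  list(nComponents = 2L, k = 6L, anchors = c("MW^C", "MW^A"), tol = 1e-12,
       edges = .DEFAULT_EDGES, weights = .DEFAULT_TREND_WEIGHTS,
       cuts = c(1 / 3, 2 / 3))
}

.stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[ilpc] ", fmt), ...))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage \"%s\": %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Build the reference model bundle
#'
#' Runs the full fit: 82-descriptor computation, autoscaling with
#' constant-descriptor drop, two-component PCA, Ward/Euclidean clustering of
#' the training scores cut into lettered clusters, and the property overlays
#' (training trend-score distributions and the standardized/binned reference
#' measurements). Deterministic: identical inputs and config give an
#' identical bundle.
#'
#' @param ils IL table with parsed ions ([readILTable()] /
#'   [generateReferenceSet()] format); at least 10 rows
#' @param properties property records (il_id, property, value, units); at
#'   least one property
#' @param config list from [ilpcConfig()] (entries may be overridden)
#' @param verbose log one line per stage
#' @return a [ModelBundle-class]
#' @export
buildReferenceModel <- function(ils, properties, config = ilpcConfig(),
                                verbose = FALSE) {
  cfg <- utils::modifyList(ilpcConfig(), config)
  if (nrow(ils) < 10L) {
    stop("need at least 10 ILs to build a reference model", call. = FALSE)
  }
  if (!nrow(properties)) stop("need at least one property record", call. = FALSE)

  desc <- .stage("descriptors", descriptorTable(ils))
  .stage_log(verbose, "descriptors: %d ILs x %d descriptors",
             nrow(desc), ncol(desc) - 1L)

  cs <- .stage("chemspace", fitChemSpace(desc, nComponents = cfg$nComponents,
                                         tol = cfg$tol, anchors = cfg$anchors))
  .stage_log(verbose, "chemspace: %d retained (%d constant dropped), PC1+PC2 explain %.1f%%",
             nrow(cs@loadings), length(cs@dropped),
             100 * sum(cs@explainedFraction))

  scores <- trainingScores(cs)
  cl <- .stage("clustering", {
    lk <- wardLinkage(scores)
    cutAndLabel(lk, scores, k = cfg$k)
  })
  .stage_log(verbose, "clustering: k = %d clusters (%s)", cfg$k,
             paste(sort(unique(cl@labels)), collapse = ""))

  overlays <- .stage("overlays", {
    tr <- as.data.frame(trendScores(scores, cfg$weights))
    tr <- cbind(il_id = rownames(scores) %||% ils$il_id, tr)
    rownames(tr) <- NULL
    bins <- do.call(rbind, lapply(intersect(.PROPERTIES,
                                            unique(properties$property)),
      function(prop) {
        sub <- properties[properties$property == prop, ]
        z <- standardizeProperty(sub$value, prop)
        cbind(data.frame(il_id = sub$il_id, property = prop,
                         value = sub$value), binToLevels(as.numeric(z),
                                                         cfg$edges))
      }))
    rownames(bins) <- NULL
    list(trend = tr, bins = bins, edges = cfg$edges, weights = cfg$weights)
  })
  .stage_log(verbose, "overlays: %d property records binned", nrow(overlays$bins))

  bundle <- new("ModelBundle", chemspace = cs, clusters = cl,
                overlays = overlays,
                provenance = list(
                  registry_version = .REGISTRY_VERSION,
                  schema_version = .BUNDLE_SCHEMA_VERSION,
                  n_training = nrow(ils),
                  config = list(nComponents = cfg$nComponents, k = cfg$k,
                                edges = cfg$edges, cuts = cfg$cuts)))
  bundle@provenance$hash <- bundleHash(bundle)
  bundle
}

#' Content hash of a bundle
#'
#' MD5 of the canonical JSON serialization (with any stored hash removed);
#' rebuilding from identical inputs and config reproduces it bit-exactly.
#'
#' @param bundle a [ModelBundle-class]
#' @return character(1) MD5 hex digest.
#' @export
bundleHash <- function(bundle) {
  bundle@provenance$hash <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  saveBundle(bundle, tmp)
  unname(tools::md5sum(tmp))
}

#' Place new ionic liquids on a fitted reference map
#'
#' For every row: compute the 82 descriptors, project onto the map, assign
#' the nearest cluster, and derive the four qualitative property levels from
#' the trend rules against the bundled training distributions. A row that
#' fails (unparsable SMILES, wrong charge sign) yields an error entry; the
#' remaining rows are still processed.
#'
#' @param bundle a [ModelBundle-class]
#' @param ils data.frame with il_id, cation_smiles, anion_smiles (parsed
#'   graph columns are used if already present)
#' @param cuts percentile cut points for low/medium/high
#' @return data.frame: il_id, PC1, PC2, cluster, tie flag, the four
#'   \code{*_level} columns, percentiles, notes/flags, and \code{error}
#'   (NA for successful rows).
#' @export
predictNew <- function(bundle, ils, cuts = bundle@provenance$config$cuts) {
  stopifnot(is(bundle, "ModelBundle"))
  if (is.null(cuts)) cuts <- c(1 / 3, 2 / 3)
  rows <- lapply(seq_len(nrow(ils)), function(r) {
    tryCatch({
      cg <- if ("cation" %in% names(ils)) ils[["cation"]][[r]] else
        parseSmiles(ils[["cation_smiles"]][r])
      ag <- if ("anion" %in% names(ils)) ils[["anion"]][[r]] else
        parseSmiles(ils[["anion_smiles"]][r])
      if (cg@netCharge < 1L) stop("cation net charge must be >= +1")
      if (ag@netCharge > -1L) stop("anion net charge must be <= -1")
      v <- ilVector(constitutionalVector(cg), constitutionalVector(ag),
                    ils$il_id[r])
      sc <- projectScores(bundle@chemspace, v)
      asg <- assignCluster(bundle@clusters, sc)
      tr <- trendScores(sc, bundle@overlays$weights)
      q <- qualitativePredict(tr, bundle@overlays$trend[, -1, drop = FALSE],
                              asg$label, sc, cuts)
      cbind(data.frame(il_id = ils$il_id[r], PC1 = sc[1, 1], PC2 = sc[1, 2],
                       tie = asg$tie), q,
            data.frame(error = NA_character_))
    }, error = function(e) {
      data.frame(il_id = ils$il_id[r], PC1 = NA_real_, PC2 = NA_real_,
                 tie = NA, cluster = NA_character_,
                 error = conditionMessage(e))
    })
  })
  ok <- which(vapply(rows, function(r) is.na(r$error[1]), logical(1)))
  cols <- names(rows[[if (length(ok)) ok[1] else 1L]])
  out <- do.call(rbind, lapply(rows, function(x) {
    for (m in setdiff(cols, names(x))) x[[m]] <- NA
    x[, cols, drop = FALSE]
  }))
  rownames(out) <- NULL
  out
}

#' Score-plot of the reference map with highlighted queries
#'
#' Draws the training ILs in the PC1 x PC2 plane, colored by cluster, and
#' overlays up to \code{max_highlight} query ILs (the default 10 mirrors the
#' comparison slots of the original worksheet tool; pass a larger value for
#' more).
#'
#' @param bundle a [ModelBundle-class]
#' @param queries optional result of [predictNew()]
#' @param file optional SVG path; when given the plot is written there
#' @param max_highlight cap on highlighted queries
#' @return invisibly, NULL.
#' @export
plotChemSpace <- function(bundle, queries = NULL, file = NULL,
                          max_highlight = 10L) {
  draw <- function() {
    sc <- trainingScores(bundle)
    lab <- clusterLabels(bundle)
    pal <- stats::setNames(grDevices::hcl.colors(max(6, bundle@clusters@k),
                                                 "Dark 3"),
                           sort(unique(lab)))
    plot(sc[, 1], sc[, 2], col = pal[lab], pch = 16,
         xlab = "PC1 (ion size)", ylab = "PC2 (anion heavy-atom size)",
         main = "Chemical-space map")
    cen <- clusterCentroids(bundle@clusters)
    text(cen[, 1], cen[, 2], rownames(cen), font = 2, cex = 1.3)
    if (!is.null(queries)) {
      q <- queries[is.na(queries$error), , drop = FALSE]
      q <- utils::head(q, max_highlight)
      points(q$PC1, q$PC2, pch = 8, cex = 1.5, lwd = 2)
      text(q$PC1, q$PC2, q$il_id, pos = 3, cex = 0.8)
    }
  }
  if (!is.null(file)) {
    grDevices::svg(file, width = 7, height = 6)
    on.exit(grDevices::dev.off())
    draw()
  } else draw()
  invisible(NULL)
}
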