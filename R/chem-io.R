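# Tabular input (IL tables, property tables), the V2000 SDF alternative
# reader, and JSON persistence of the fitted reference bundle.

.BUNDLE_SCHEMA_VERSION <- "1.0"

#' Read a table of ionic liquids
#'
#' Reads a UTF-8 comma-separated file with header columns \code{il_id},
#' \code{cation_smiles}, \code{anion_smiles} (and optional \code{family}),
#' parses both ions of every row and validates the charge signs: a cation
#' must have net charge of at least +1 and an anion at most -1. All row
#' failures are collected and reported together with their row numbers.
#'
#' @param path path to the CSV file
#' @return data.frame with columns il_id, family, cation_smiles,
#'   anion_smiles and list-columns \code{cation}, \code{anion} holding the
#'   parsed [MolecularGraph-class] objects. Zero rows for an empty file.
#' @export
readILTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("il_id", "cation_smiles", "anion_smiles")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("schema error: missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"family" %in% names(d)) d$family <- rep(NA_character_, nrow(d))
  if (!nrow(d)) {
    d$cation <- list(); d$anion <- list()
    return(d[, c("il_id", "family", "cation_smiles", "anion_smiles",
                 "cation", "anion")])
  }
  if (anyDuplicated(d$il_id)) {
    stop("validation error: duplicate il_id: ",
         paste(unique(d$il_id[duplicated(d$il_id)]), collapse = ", "),
         call. = FALSE)
  }
  cat_g <- vector("list", nrow(d)); an_g <- vector("list", nrow(d))
  fails <- character()
  for (r in seq_len(nrow(d))) {
    res <- tryCatch({
      cg <- parseSmiles(d$cation_smiles[r])
      ag <- parseSmiles(d$anion_smiles[r])
      if (cg@netCharge < 1L) {
        stop(sprintf("cation of %s has non-positive net charge %+d",
                     d$il_id[r], cg@netCharge), call. = FALSE)
      }
      if (ag@netCharge > -1L) {
        stop(sprintf("anion of %s has non-negative net charge %+d",
                     d$il_id[r], ag@netCharge), call. = FALSE)
      }
      list(cg, ag)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      fails <- c(fails, sprintf("row %d (%s): %s", r, d$il_id[r], res))
    } else {
      cat_g[[r]] <- res[[1]]; an_g[[r]] <- res[[2]]
    }
  }
  if (length(fails)) {
    stop("validation error in IL table:\n  ", paste(fails, collapse = "\n  "),
         call. = FALSE)
  }
  d$cation <- cat_g; d$anion <- an_g
  d[, c("il_id", "family", "cation_smiles", "anion_smiles", "cation", "anion")]
}

.PROPERTIES <- c("viscosity", "Kow", "solubility", "enthalpy_of_fusion")

#' Read a property table
#'
#' CSV with columns \code{il_id}, \code{property}, \code{value},
#' \code{units}; property names must come from the closed set
#' viscosity (cP), Kow (dimensionless or log), solubility (g/L or mole
#' fraction), enthalpy_of_fusion (kJ/mol), and values must be finite.
#'
#' @param path path to the CSV file
#' @return data.frame with the validated records.
#' @export
readPropertyTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("il_id", "property", "value", "units")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("schema error: missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(d$property), .PROPERTIES)
  if (length(bad)) {
    stop("unknown property name(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(.PROPERTIES, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(d) && any(!is.finite(d$value))) {
    stop("non-finite property value(s) in row(s): ",
         paste(which(!is.finite(d$value)), collapse = ", "), call. = FALSE)
  }
  d
}

#' Read single-ion structures from a V2000 SDF file
#'
#' Alternative structure reader producing the same [MolecularGraph-class]
#' contract as [parseSmiles()]: formal charges are taken from \code{M  CHG}
#' lines (falling back to the legacy atom-block charge column), bond type 4
#' is read as aromatic, and hydrogens not drawn explicitly are inferred with
#' the same strict valence model. Explicit hydrogen atoms are folded into
#' the implicit-H count of their heavy neighbour.
#'
#' @param path path to an SDF (MDL V2000) file
#' @return named list of [MolecularGraph-class], one per record; names are
#'   the record title lines (or record index when blank).
#' @export
readSDF <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  txt <- readLines(path, warn = FALSE)
  recs <- split(txt, cumsum(c(TRUE, head(txt, -1) == "$$$$")))
  out <- list()
  for (rec in recs) {
    rec <- rec[rec != "$$$$"]
    if (length(rec) < 4L || !any(nzchar(rec))) next
    counts <- rec[4]
    na <- as.integer(substr(counts, 1, 3))
    nb <- as.integer(substr(counts, 4, 6))
    if (is.na(na) || is.na(nb)) stop("malformed SDF counts line", call. = FALSE)
    at <- rec[4 + seq_len(na)]
    element <- trimws(substr(at, 32, 34))
    legacy <- as.integer(substr(at, 37, 39))
    charge <- ifelse(!is.na(legacy) & legacy > 0L & legacy != 4L,
                     4L - legacy, 0L)
    bi <- integer(nb); bj <- integer(nb); bt <- integer(nb)
    if (nb) {
      bl <- rec[4 + na + seq_len(nb)]
      bi <- as.integer(substr(bl, 1, 3))
      bj <- as.integer(substr(bl, 4, 6))
      bt <- as.integer(substr(bl, 7, 9))
    }
    for (ln in grep("^M  CHG", rec, value = TRUE)) {
      f <- as.integer(strsplit(trimws(substring(ln, 7)), "[[:space:]]+")[[1]])
      nn <- f[1]
      for (q in seq_len(nn)) charge[f[2 * q]] <- f[2 * q + 1]
    }
    arom <- bt == 4L
    order <- ifelse(arom, 1L, bt)
    # fold explicit H atoms into their heavy neighbour's implicit count
    is_h <- element == "H"
    hplus <- integer(na)
    keep_bond <- rep(TRUE, nb)
    for (r in seq_len(nb)) {
      hi <- is_h[bi[r]]; hj <- is_h[bj[r]]
      if (hi && hj) stop("H-H bond in SDF record", call. = FALSE)
      if (hi || hj) {
        heavy <- if (hi) bj[r] else bi[r]
        hplus[heavy] <- hplus[heavy] + 1L
        keep_bond[r] <- FALSE
      }
    }
    remap <- cumsum(!is_h)
    bonds <- data.frame(i = remap[pmin(bi, bj)[keep_bond]],
                        j = remap[pmax(bi, bj)[keep_bond]],
                        order = order[keep_bond],
                        aromatic = arom[keep_bond], ring = FALSE)
    element2 <- element[!is_h]; charge2 <- charge[!is_h]
    hp <- hplus[!is_h]
    arom_atom <- rep(FALSE, length(element2))
    if (nrow(bonds)) {
      arom_atom[unique(c(bonds$i[bonds$aromatic], bonds$j[bonds$aromatic]))] <- TRUE
    }
    hcount <- integer(length(element2))
    for (a in seq_along(element2)) {
      if (charge2[a] != 0L) { hcount[a] <- hp[a]; next }  # charged: as drawn
      rows <- which(bonds$i == a | bonds$j == a)
      bondsum <- sum(ifelse(bonds$aromatic[rows], 1.5, bonds$order[rows])) + hp[a]
      hcount[a] <- hp[a] +
        .implicit_h(element2[a], arom_atom[a],
                    bondsum, length(rows) + hp[a], paste0("SDF:", rec[1]))
    }
    bonds$ring <- .ring_bonds(length(element2), bonds)
    g <- new("MolecularGraph",
             atoms = data.frame(element = element2, charge = charge2,
                                hcount = hcount, aromatic = arom_atom),
             bonds = bonds, netCharge = as.integer(sum(charge2)))
    nm <- trimws(rec[1])
    out[[if (nzchar(nm)) nm else as.character(length(out) + 1L)]] <- g
  }
  out
}

.df_to_json <- function(d) lapply(d, function(col) col)

#' Save / load a fitted reference bundle
#'
#' The bundle is stored as a single JSON document with a
#' \code{schema_version} field; numeric fields are written with 17
#' significant digits so that \code{loadBundle(saveBundle(x))} reproduces
#' every number bit-exactly (reprojected training scores are identical).
#'
#' @param bundle a [ModelBundle-class]
#' @param path file path for the JSON document
#' @return \code{saveBundle} returns \code{path} invisibly;
#'   \code{loadBundle} returns the restored [ModelBundle-class].
#' @export
saveBundle <- function(bundle, path) {
  stopifnot(is(bundle, "ModelBundle"))
  cs <- bundle@chemspace; cl <- bundle@clusters
  doc <- list(
    schema_version = .BUNDLE_SCHEMA_VERSION,
    chemspace = list(
      center = as.list(cs@center), scale = as.list(cs@scale),
      dropped = cs@dropped,
      descriptor_names = rownames(cs@loadings),
      loadings = cs@loadings,
      eigenvalues = cs@eigenvalues,
      explained_fraction = cs@explainedFraction,
      training_ids = rownames(cs@trainingScores),
      training_scores = cs@trainingScores,
      n_components = cs@nComponents),
    clusters = list(
      merge = cl@merge, height = cl@height, k = cl@k,
      labels = as.list(cl@labels),
      centroid_names = rownames(cl@centroids),
      centroids = cl@centroids),
    overlays = list(
      trend = .df_to_json(bundle@overlays$trend),
      bins = .df_to_json(bundle@overlays$bins),
      edges = bundle@overlays$edges,
      weights = bundle@overlays$weights),
    provenance = bundle@provenance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

.need_field <- function(doc, field, where) {
  if (is.null(doc[[field]])) {
    stop(sprintf("bundle load error: missing field \"%s\" in %s", field, where),
         call. = FALSE)
  }
  doc[[field]]
}

#' @rdname saveBundle
#' @export
loadBundle <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("bundle load error: not a valid JSON document (",
                         conditionMessage(e), ")", call. = FALSE)
                  })
  ver <- .need_field(doc, "schema_version", "bundle")
  if (!identical(ver, .BUNDLE_SCHEMA_VERSION)) {
    stop(sprintf("bundle schema version mismatch: file has \"%s\", this build reads \"%s\"",
                 ver, .BUNDLE_SCHEMA_VERSION), call. = FALSE)
  }
  csd <- .need_field(doc, "chemspace", "bundle")
  for (f in c("center", "scale", "descriptor_names", "loadings", "eigenvalues",
              "explained_fraction", "training_ids", "training_scores",
              "n_components")) .need_field(csd, f, "chemspace")
  L <- as.matrix(csd$loadings)
  dimnames(L) <- list(csd$descriptor_names, paste0("PC", seq_len(ncol(L))))
  S <- as.matrix(csd$training_scores)
  dimnames(S) <- list(csd$training_ids, paste0("PC", seq_len(ncol(S))))
  cs <- new("ChemSpaceModel",
            center = unlist(csd$center), scale = unlist(csd$scale),
            dropped = as.character(csd$dropped %||% character()),
            loadings = L, eigenvalues = csd$eigenvalues,
            explainedFraction = csd$explained_fraction,
            trainingScores = S, nComponents = as.integer(csd$n_components))
  cld <- .need_field(doc, "clusters", "bundle")
  for (f in c("merge", "height", "k", "labels", "centroid_names", "centroids")) {
    .need_field(cld, f, "clusters")
  }
  cen <- as.matrix(cld$centroids)
  dimnames(cen) <- list(cld$centroid_names, colnames(S))
  cl <- new("ClusterModel",
            merge = matrix(as.integer(as.matrix(cld$merge)), ncol = 2L),
            height = cld$height, k = as.integer(cld$k),
            labels = unlist(cld$labels), centroids = cen)
  ov <- .need_field(doc, "overlays", "bundle")
  overlays <- list(
    trend = as.data.frame(ov$trend, check.names = FALSE),
    bins = as.data.frame(ov$bins, check.names = FALSE),
    edges = ov$edges,
    weights = {
      w <- as.matrix(ov$weights)
      dimnames(w) <- list(.PROPERTIES, c("PC1", "PC2"))
      w
    })
  new("ModelBundle", chemspace = cs, clusters = cl, overlays = overlays,
      provenance = as.list(.need_field(doc, "provenance", "bundle")))
}
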