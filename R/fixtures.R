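# Deterministic synthetic reference sets: template-built ions across the six
# cation families and four anion classes, with property values that follow
# the documented map trends plus Gaussian noise. A stand-in for the original
# curated reference measurements, which are not redistributable; everything
# here is synthetic by construction.

.CATION_FAMILIES <- c("imidazolium", "ammonium", "phosphonium", "pyridinium",
                      "pyrrolidinium", "sulfonium")
.ANION_CLASSES <- c("halide", "BF4-like", "TFSI-like", "amino-acid-like")

# all alkyl substituents grow together, the way homologous IL series
# (tetraalkylammonium, tetraalkylphosphonium, dialkylimidazolium) are built
.cation_smiles <- function(family, chain) {
  a <- strrep("C", chain)
  switch(family,
    imidazolium   = paste0(a, "[n+]1ccn(", a, ")c1"),
    ammonium      = paste0(a, "[N+](", a, ")(", a, ")", a),
    phosphonium   = paste0(a, "[P+](", a, ")(", a, ")", a),
    pyridinium    = paste0(a, "[n+]1ccccc1"),
    pyrrolidinium = paste0(a, "[N+]1(", a, ")CCCC1"),
    sulfonium     = paste0(a, "[S+](", a, ")", a),
    stop("unknown cation family: ", family, call. = FALSE))
}

.aa_anion <- function(k) paste0(strrep("C", k), "C(N)C(=O)[O-]")

.ANION_SMILES <- list(
  "halide" = c("[Cl-]", "[Br-]", "[I-]"),
  "BF4-like" = c("[B-](F)(F)(F)F", "F[P-](F)(F)(F)(F)F",
                 "CS(=O)(=O)[O-]", "OS(=O)(=O)[O-]"),
  "TFSI-like" = c("C(F)(F)(F)S(=O)(=O)[N-]S(=O)(=O)C(F)(F)F",
                  "C(F)(F)(F)S(=O)(=O)[O-]",
                  "FS(=O)(=O)[N-]S(=O)(=O)F"),
  "amino-acid-like" = vapply(c(2, 4, 6, 8), .aa_anion, character(1)))

# anion classes paired with each cation-size tier: small cations carry the
# halide/fluoroborate/TFSI-type anions, large cations the amino-acid-type
# plus halide/fluoroborate ones -- the joint structure the six reference
# clusters describe
.SMALL_TIER_CLASSES <- c("halide", "BF4-like", "TFSI-like")
.LARGE_TIER_CLASSES <- c("amino-acid-like", "halide", "BF4-like")

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic reference set of ionic liquids
#'
#' Builds ILs by template SMILES. Every cation family contributes a
#' homologous series in which all alkyl substituents grow together, split
#' into a small-cation tier and a large-cation tier. Anions are paired the
#' way the six reference clusters describe: small cations carry halide,
#' fluoroborate/sulfonate ("BF4-like") and TFSI-type anions, large cations
#' amino-acid-type plus halide and BF4-like anions, with several concrete
#' anions per class so the anion block is structurally diverse.
#'
#' Synthetic property values follow the documented trend structure on two
#' structural latents -- the organic size u (carbon count of both ions) and
#' the anion heavy-atom size: viscosity grows with u and falls with anion
#' size (TFSI-type salts are the least viscous at matched cation), Kow grows
#' with u, solubility falls with u and grows with anion size, and the
#' enthalpy of fusion grows with ion-size similarity (anion size relative to
#' the cation) -- plus Gaussian noise. The seed fully determines the output.
#'
#' @param n_per_family ILs per cation family (default 10; the first half of
#'   each family is the small-cation tier)
#' @param families subset of the six cation families
#' @param anion_classes subset of the four anion classes
#' @param chain_range integer range of alkyl chain lengths spanned by the
#'   two tiers
#' @param noise_sd sd of the Gaussian noise on the latent (log) property
#'   scales; the enthalpy noise is 5 * noise_sd kJ/mol
#' @param seed integer seed
#' @return list with \code{ils} (data.frame like [readILTable()] output,
#'   including parsed graphs), \code{properties} (long property records) and
#'   \code{truth} (generator labels and latent sizes per IL).
#' @export
generateReferenceSet <- function(n_per_family = 10L,
                                 families = .CATION_FAMILIES,
                                 anion_classes = .ANION_CLASSES,
                                 chain_range = c(1L, 16L),
                                 noise_sd = 0.3, seed = 1L) {
  if (!length(families)) stop("empty cation family list", call. = FALSE)
  families <- match.arg(families, .CATION_FAMILIES, several.ok = TRUE)
  if (!length(anion_classes)) stop("empty anion class list", call. = FALSE)
  anion_classes <- match.arg(anion_classes, .ANION_CLASSES, several.ok = TRUE)

  span <- chain_range[2] - chain_range[1]
  small_chains <- unique(floor(seq(chain_range[1], chain_range[1] + 0.3 * span,
                                   length.out = 5)))
  large_chains <- unique(round(seq(chain_range[1] + 0.55 * span,
                                   chain_range[2], length.out = 5)))
  small_cls <- intersect(.SMALL_TIER_CLASSES, anion_classes)
  if (!length(small_cls)) small_cls <- anion_classes
  large_cls <- intersect(.LARGE_TIER_CLASSES, anion_classes)
  if (!length(large_cls)) large_cls <- anion_classes

  rows <- list()
  for (fi in seq_along(families)) {
    fam <- families[fi]
    half <- ceiling(n_per_family / 2)
    for (t in seq_len(n_per_family)) {
      small <- t <= half
      chain <- if (small) {
        small_chains[(t - 1L) %% length(small_chains) + 1L]
      } else {
        large_chains[(t - half - 1L) %% length(large_chains) + 1L]
      }
      acl <- if (small) {
        small_cls[(t + fi - 2L) %% length(small_cls) + 1L]
      } else {
        large_cls[(t - half + fi - 2L) %% length(large_cls) + 1L]
      }
      variants <- .ANION_SMILES[[acl]]
      an <- variants[(t + fi) %% length(variants) + 1L]
      rows[[length(rows) + 1L]] <- data.frame(
        il_id = sprintf("%s_%02d", substr(fam, 1, 4), t),
        family = fam, anion_class = acl, chain_length = chain,
        size_tier = if (small) "small" else "large",
        cation_smiles = .cation_smiles(fam, chain), anion_smiles = an)
    }
  }
  d <- do.call(rbind, rows)
  d$cation <- lapply(d$cation_smiles, parseSmiles)
  d$anion <- lapply(d$anion_smiles, parseSmiles)
  cat_nC <- vapply(d$cation, function(g) sum(g@atoms$element == "C"), numeric(1))
  an_nC <- vapply(d$anion, function(g) sum(g@atoms$element == "C"), numeric(1))
  an_heavy <- vapply(d$anion, function(g) nrow(g@atoms), numeric(1))
  u <- cat_nC + an_nC

  props <- .with_seed(seed, {
    n <- nrow(d)
    log_visc <- 1 + 0.06 * u - 0.08 * an_heavy + stats::rnorm(n, 0, noise_sd)
    log_kow <- -2 + 0.09 * u + stats::rnorm(n, 0, noise_sd)
    log_sol <- 2 - 0.075 * u + 0.10 * an_heavy + stats::rnorm(n, 0, noise_sd)
    dhf <- 5 + 0.8 * an_heavy - 0.3 * cat_nC + stats::rnorm(n, 0, 5 * noise_sd)
    rbind(
      data.frame(il_id = d$il_id, property = "viscosity",
                 value = 10^log_visc, units = "cP"),
      data.frame(il_id = d$il_id, property = "Kow",
                 value = 10^log_kow, units = "-"),
      data.frame(il_id = d$il_id, property = "solubility",
                 value = 10^log_sol, units = "g/L"),
      data.frame(il_id = d$il_id, property = "enthalpy_of_fusion",
                 value = dhf, units = "kJ/mol"))
  })
  truth <- data.frame(il_id = d$il_id, family = d$family,
                      anion_class = d$anion_class,
                      size_tier = d$size_tier,
                      chain_length = d$chain_length,
                      cation_carbons = cat_nC, anion_carbons = an_nC,
                      anion_heavy_atoms = an_heavy)
  ils <- d[, c("il_id", "family", "cation_smiles", "anion_smiles",
               "cation", "anion")]
  list(ils = ils, properties = props, truth = truth)
}

.hadamard <- function(m) {
  H <- matrix(1, 1, 1)
  while (nrow(H) < m) H <- rbind(cbind(H, H), cbind(H, -H))
  H
}

#' Generate a descriptor matrix with planted latent structure
#'
#' Builds X = scores %*% t(loadings) + noise with exactly controlled latent
#' structure: score columns are exactly centered, orthogonal, with sample
#' variances \code{variance_split * p}, and the loading columns are
#' orthonormal with equal-magnitude entries (a Sylvester sign-pattern
#' construction), so each data column has unit variance and autoscaling
#' leaves the planted variance split intact. With zero noise a
#' correlation-matrix PCA recovers the split to machine precision.
#'
#' @param n rows (samples)
#' @param p columns (descriptors); for latent_rank > 1, p must be a multiple
#'   of the smallest power of two not below latent_rank
#' @param latent_rank number of planted components
#' @param variance_split fractions of total variance per component
#'   (decreasing, summing to at most 1); default splits proportionally to
#'   latent_rank..1
#' @param noise_sd sd of added Gaussian noise
#' @param seed integer seed
#' @return numeric matrix with a \code{"truth"} attribute (loadings, scores,
#'   split).
#' @export
generateDescriptorTable <- function(n, p, latent_rank = 2L,
                                    variance_split = NULL, noise_sd = 0,
                                    seed = 1L) {
  r <- as.integer(latent_rank)
  if (r < 1L || r > min(n - 1L, p)) {
    stop("latent_rank must lie in 1..min(n-1, p)", call. = FALSE)
  }
  if (is.null(variance_split)) variance_split <- (r:1) / sum(r:1)
  if (length(variance_split) != r) {
    stop("variance_split must have one entry per latent component", call. = FALSE)
  }
  if (r == 1L) {
    L <- matrix(1 / sqrt(p), p, 1)
  } else {
    m <- 2^ceiling(log2(r))
    if (p %% m != 0) {
      stop(sprintf("p must be a multiple of %d for latent_rank %d", m, r),
           call. = FALSE)
    }
    H <- .hadamard(m)[, seq_len(r), drop = FALSE]
    L <- H[rep(seq_len(m), p / m), , drop = FALSE] / sqrt(p)
  }
  .with_seed(seed, {
    S0 <- matrix(stats::rnorm(n * r), n, r)
    Q <- qr.Q(qr(cbind(1, S0)))[, -1, drop = FALSE]  # zero-mean orthonormal
    lambda <- variance_split * p
    S <- sweep(Q, 2, sqrt((n - 1) * lambda), "*")
    X <- S %*% t(L)
    if (noise_sd > 0) X <- X + matrix(stats::rnorm(n * p, 0, noise_sd), n, p)
    colnames(X) <- paste0("d", seq_len(p))
    rownames(X) <- paste0("s", seq_len(n))
    attr(X, "truth") <- list(loadings = L, scores = S, split = variance_split)
    X
  })
}

#' Write fixture files to a directory
#'
#' Materializes a synthetic reference set as \code{ils.csv},
#' \code{properties.csv} and \code{truth.json}.
#'
#' @param dir output directory (created if missing)
#' @param seed integer seed
#' @param ... passed to [generateReferenceSet()]
#' @return invisibly, the list of written paths.
#' @export
writeFixtures <- function(dir, seed = 1L, ...) {
  ref <- generateReferenceSet(seed = seed, ...)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "ils.csv")
  p2 <- file.path(dir, "properties.csv")
  p3 <- file.path(dir, "truth.json")
  utils::write.csv(ref$ils[, c("il_id", "family", "cation_smiles",
                               "anion_smiles")], p1, row.names = FALSE)
  utils::write.csv(ref$properties, p2, row.names = FALSE)
  jsonlite::write_json(list(seed = seed, truth = ref$truth), p3,
                       auto_unbox = TRUE, digits = I(17))
  invisible(c(ils = p1, properties = p2, truth = p3))
}
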