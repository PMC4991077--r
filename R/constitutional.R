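# The 41-member constitutional (0D) descriptor block per ion, and the 82-slot
# concatenated cation+anion vector per ionic liquid.

.REGISTRY_VERSION <- "1.0"

.REGISTRY <- c(
  # weighted sums / means (carbon-scaled, except MW/AMW in u)
  "MW", "AMW", "Sv", "Se", "Sp", "Si", "Me", "Mp", "Mi",
  # graph counts
  "nAT", "nSK", "nBT", "nBO", "nBM", "SCBO", "ARR", "RBN", "RBF",
  "nDB", "nTB", "nAB",
  # element counts
  "nH", "nC", "nN", "nO", "nP", "nS", "nF", "nCl", "nBr", "nI", "nX", "nHet",
  # percentage composition
  "H%", "C%", "N%", "O%", "X%",
  # carbon hybridization
  "nCsp3", "nCsp2", "nCsp")

#' Constitutional descriptor registry
#'
#' The ordered, versioned list of the 41 constitutional descriptors computed
#' per ion. Whether a historical 41-member block contained the carbon-scaled
#' van der Waals volume mean is ambiguous in the descriptor literature;
#' registry version 1.0 keeps the cumulative volume sum Sv and omits its mean,
#' so that the block holds exactly 41 entries while covering every descriptor
#' the map interpretation relies on (Se/Sp/Si, nAT, nBT, RBN/RBF, nH, nC,
#' nCsp3, MW, H\%, nSK, nBO, SCBO, nDB, nO, nS, nF, nHet, ...).
#'
#' @return character vector of 41 descriptor names, with a \code{"version"}
#'   attribute.
#' @export
constitutionalRegistry <- function() {
  structure(.REGISTRY, version = .REGISTRY_VERSION)
}

#' Element and composition counts for one ion
#'
#' Atom-census part of the constitutional block. \code{nH} includes implicit
#' hydrogens; \code{nHet} counts heavy atoms that are neither carbon nor
#' hydrogen; \code{nX = nF + nCl + nBr + nI}. Percentages are over all atoms
#' including hydrogens, e.g. \code{H\% = 100 * nH / nAT}.
#'
#' @param g a [MolecularGraph-class]
#' @return named numeric with nAT, nSK, nH, nC, nN, nO, nP, nS, nF, nCl,
#'   nBr, nI, nX, nHet, `H%`, `C%`, `N%`, `O%`, `X%`.
#' @export
elementCounts <- function(g) {
  stopifnot(is(g, "MolecularGraph"))
  el <- g@atoms$element
  .element_lookup(el)  # errors on unsupported elements
  cnt <- function(sym) sum(el == sym)
  nH <- sum(g@atoms$hcount)
  nSK <- length(el)
  nAT <- nSK + nH
  out <- c(nAT = nAT, nSK = nSK, nH = nH, nC = cnt("C"), nN = cnt("N"),
           nO = cnt("O"), nP = cnt("P"), nS = cnt("S"), nF = cnt("F"),
           nCl = cnt("Cl"), nBr = cnt("Br"), nI = cnt("I"))
  out["nX"] <- out["nF"] + out["nCl"] + out["nBr"] + out["nI"]
  out["nHet"] <- nSK - out[["nC"]]
  out["H%"] <- 100 * nH / nAT
  out["C%"] <- 100 * out[["nC"]] / nAT
  out["N%"] <- 100 * out[["nN"]] / nAT
  out["O%"] <- 100 * out[["nO"]] / nAT
  out["X%"] <- 100 * out[["nX"]] / nAT
  out
}

.heavy_degree <- function(g) {
  n <- nrow(g@atoms)
  deg <- integer(n)
  if (nrow(g@bonds)) {
    t1 <- table(factor(g@bonds$i, levels = seq_len(n)))
    t2 <- table(factor(g@bonds$j, levels = seq_len(n)))
    deg <- as.integer(t1 + t2)
  }
  deg
}

#' Bond counts for one ion
#'
#' \code{nBT} counts every bond including bonds to (implicit) hydrogens;
#' \code{nBO} only heavy-heavy bonds. \code{SCBO} sums conventional bond
#' orders over the hydrogen-depleted graph with aromatic bonds counted as
#' 1.5. \code{RBN} is the number of non-ring single bonds whose two endpoints
#' are heavy atoms with heavy-atom degree of at least 2 (no amide or other
#' chemical exclusions: the rule is purely topological);
#' \code{RBF = RBN / nBT}. \code{ARR = nAB / nBO} is the aromatic bond ratio.
#'
#' @param g a [MolecularGraph-class]
#' @return named numeric with nBT, nBO, nBM, SCBO, ARR, RBN, RBF, nDB, nTB,
#'   nAB.
#' @export
bondBlock <- function(g) {
  stopifnot(is(g, "MolecularGraph"))
  b <- g@bonds
  nH <- sum(g@atoms$hcount)
  nBO <- nrow(b)
  nBT <- nBO + nH
  nAB <- sum(b$aromatic)
  nDB <- sum(!b$aromatic & b$order == 2L)
  nTB <- sum(!b$aromatic & b$order == 3L)
  SCBO <- sum(ifelse(b$aromatic, 1.5, b$order))
  deg <- .heavy_degree(g)
  rot <- !b$ring & !b$aromatic & b$order == 1L &
    deg[b$i] >= 2L & deg[b$j] >= 2L
  RBN <- sum(rot)
  c(nBT = nBT, nBO = nBO, nBM = nDB + nTB + nAB, SCBO = SCBO,
    ARR = if (nBO) nAB / nBO else 0, RBN = RBN,
    RBF = if (nBT) RBN / nBT else 0, nDB = nDB, nTB = nTB, nAB = nAB)
}

#' Weighted atomic sums for one ion
#'
#' Molecular weight and the cumulative carbon-scaled atomic properties:
#' \code{Se} (Sanderson electronegativity), \code{Sp} (polarizability),
#' \code{Si} (first ionization potential), \code{Sv} (van der Waals volume),
#' summed over all atoms including implicit hydrogens; \code{Me/Mp/Mi} are
#' the corresponding means (sum divided by \code{nAT}), as is
#' \code{AMW = MW / nAT}. Formal charge does not change an element lookup.
#'
#' @param g a [MolecularGraph-class]
#' @param table element table, see [elementTable()]
#' @return named numeric with MW, AMW, Sv, Se, Sp, Si, Me, Mp, Mi.
#' @export
weightedSums <- function(g, table = elementTable()) {
  stopifnot(is(g, "MolecularGraph"))
  el <- g@atoms$element
  rows <- .element_lookup(el)
  nH <- sum(g@atoms$hcount)
  nAT <- length(el) + nH
  h <- .element_lookup("H")
  tot <- function(col) sum(rows[[col]]) + nH * h[[col]]
  MW <- tot("mass")
  Se <- tot("en_c"); Sp <- tot("pol_c"); Si <- tot("ip_c"); Sv <- tot("vdw_c")
  c(MW = MW, AMW = MW / nAT, Sv = Sv, Se = Se, Sp = Sp, Si = Si,
    Me = Se / nAT, Mp = Sp / nAT, Mi = Si / nAT)
}

#' Carbon hybridization counts for one ion
#'
#' A carbon is sp3 when it carries only single bonds, sp2 with exactly one
#' double bond or any aromatic bond, and sp with a triple bond or two double
#' bonds.
#'
#' @param g a [MolecularGraph-class]
#' @return named numeric with nCsp3, nCsp2, nCsp.
#' @export
hybridizationCounts <- function(g) {
  stopifnot(is(g, "MolecularGraph"))
  a <- g@atoms; b <- g@bonds
  sp3 <- sp2 <- sp <- 0L
  for (idx in which(a$element == "C")) {
    rows <- which(b$i == idx | b$j == idx)
    if (a$aromatic[idx] || any(b$aromatic[rows])) { sp2 <- sp2 + 1L; next }
    nd <- sum(b$order[rows] == 2L)
    nt <- sum(b$order[rows] == 3L)
    if (nt >= 1L || nd >= 2L) sp <- sp + 1L
    else if (nd == 1L) sp2 <- sp2 + 1L
    else sp3 <- sp3 + 1L
  }
  c(nCsp3 = sp3, nCsp2 = sp2, nCsp = sp)
}

#' The full 41-slot constitutional vector of one ion
#'
#' Assembles the weighted sums, bond counts, element counts, percentage
#' composition and hybridization counts in the fixed registry order. A pure
#' function of the molecular graph: atom-ordering permutations of the input
#' SMILES yield identical vectors.
#'
#' @param g a [MolecularGraph-class]
#' @param table element table, see [elementTable()]
#' @return named numeric of length 41 in [constitutionalRegistry()] order,
#'   with a \code{"registry_version"} attribute.
#' @examples
#' v <- constitutionalVector(parseSmiles("C[N+](C)(C)C"))
#' v[c("MW", "nAT", "nH", "RBN")]
#' @export
constitutionalVector <- function(g, table = elementTable()) {
  vals <- c(weightedSums(g, table), bondBlock(g), elementCounts(g),
            hybridizationCounts(g))
  out <- vals[.REGISTRY]
  stopifnot(!anyNA(out))
  names(out) <- .REGISTRY
  attr(out, "registry_version") <- .REGISTRY_VERSION
  out
}

#' Concatenate cation and anion blocks into the 82-slot IL vector
#'
#' @param cation,anion constitutional vectors from [constitutionalVector()]
#' @param il_id character(1) identifier
#' @return named numeric of length 82: the cation block first with names
#'   suffixed \code{^C}, then the anion block suffixed \code{^A}; the
#'   identifier is kept in the \code{"il_id"} attribute.
#' @export
ilVector <- function(cation, anion, il_id = NA_character_) {
  reg <- constitutionalRegistry()
  if (!identical(names(cation), as.character(reg)) ||
      !identical(names(anion), as.character(reg))) {
    stop("cation and anion blocks must each be complete 41-slot registry vectors",
         call. = FALSE)
  }
  out <- c(cation, anion)
  names(out) <- c(paste0(reg, "^C"), paste0(reg, "^A"))
  attr(out, "il_id") <- il_id
  attr(out, "registry_version") <- .REGISTRY_VERSION
  out
}

#' Descriptor table for a set of ionic liquids
#'
#' Computes the 82-column descriptor matrix (one row per IL) from a table of
#' parsed ions, the input of the chemical-space fit.
#'
#' @param ils data.frame as returned by [readILTable()] (columns il_id,
#'   cation, anion with parsed graphs)
#' @return data.frame: il_id plus the 82 descriptor columns in registry order.
#' @export
descriptorTable <- function(ils) {
  stopifnot(all(c("il_id", "cation", "anion") %in% names(ils)))
  rows <- lapply(seq_len(nrow(ils)), function(r) {
    ilVector(constitutionalVector(ils$cation[[r]]),
             constitutionalVector(ils$anion[[r]]), ils$il_id[r])
  })
  mat <- do.call(rbind, rows)
  out <- data.frame(il_id = ils$il_id, mat, check.names = FALSE)
  rownames(out) <- NULL
  out
}
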