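# Minimal, strict SMILES reader for single ions.
#
# Supported subset: organic-subset atoms (B C N O P S F Cl Br I), bracket
# atoms with isotope/charge/explicit H/atom class, aromatic lowercase atoms,
# bond symbols - = # : / \, branches, ring-bond closures (digits and %nn).
# Dots (multi-fragment input) are rejected: an ion is one connected graph.
# There is no valence "repair": an organic-subset atom whose bonds exceed its
# allowed valence is an error.

.ORGANIC <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_OK <- c("b", "c", "n", "o", "p", "s")
.VALENCES <- list(B = 3, C = 4, N = 3, O = 2, P = c(3, 5), S = c(2, 4, 6),
                  F = 1, Cl = 1, Br = 1, I = 1)

.parse_error <- function(smiles, pos, what) {
  stop(sprintf("SMILES parse error in \"%s\" at position %d: %s",
               smiles, pos, what), call. = FALSE)
}

.parse_bracket <- function(body, smiles, pos) {
  m <- regmatches(body, regexec(
    "^([0-9]+)?([A-Z][a-z]?|[a-z])(@@?)?(H[0-9]*)?([+][0-9]+|[-][0-9]+|[+]+|[-]+)?(:[0-9]+)?$",
    body))[[1]]
  if (!length(m)) .parse_error(smiles, pos, sprintf("bad bracket atom \"[%s]\"", body))
  sym <- m[3]
  aromatic <- sym %in% .AROMATIC_OK
  element <- if (aromatic) toupper(sym) else sym
  hcount <- 0L
  if (nzchar(m[5])) {
    hcount <- if (m[5] == "H") 1L else as.integer(substring(m[5], 2))
  }
  charge <- 0L
  if (nzchar(m[6])) {
    ch <- m[6]
    charge <- if (grepl("^[+-][0-9]+$", ch)) {
      as.integer(ch)
    } else {
      s <- if (substring(ch, 1, 1) == "+") 1L else -1L
      s * nchar(ch)
    }
  }
  list(element = element, aromatic = aromatic, hcount = hcount,
       charge = charge, explicit_h = TRUE)
}

.tokenize_smiles <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1L
  push <- function(type, value, pos) toks[[length(toks) + 1L]] <<- list(
    type = type, value = value, pos = pos)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) .parse_error(smiles, i, "unclosed bracket \"[\"")
      push("atom", .parse_bracket(paste(chars[(i + 1L):(j - 1L)], collapse = ""),
                                  smiles, i), i)
      i <- j + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      push("bond", ch, i); i <- i + 1L
    } else if (ch == "(") {
      push("open", ch, i); i <- i + 1L
    } else if (ch == ")") {
      push("close", ch, i); i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      push("ring", ch, i); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste(chars[i + 1:2], collapse = ""))) {
        .parse_error(smiles, i, "\"%\" must be followed by two digits")
      }
      push("ring", paste(chars[i + 1:2], collapse = ""), i)
      i <- i + 3L
    } else if (ch == ".") {
      stop(sprintf("\"%s\" is not a single ion: multi-fragment SMILES (\".\") are not accepted",
                   smiles), call. = FALSE)
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      push("atom", list(element = paste0(ch, chars[i + 1L]), aromatic = FALSE,
                        hcount = NA_integer_, charge = 0L, explicit_h = FALSE), i)
      i <- i + 2L
    } else if (ch %in% .ORGANIC) {
      push("atom", list(element = ch, aromatic = FALSE, hcount = NA_integer_,
                        charge = 0L, explicit_h = FALSE), i)
      i <- i + 1L
    } else if (ch %in% .AROMATIC_OK) {
      push("atom", list(element = toupper(ch), aromatic = TRUE,
                        hcount = NA_integer_, charge = 0L, explicit_h = FALSE), i)
      i <- i + 1L
    } else {
      .parse_error(smiles, i, sprintf("unexpected token \"%s\"", ch))
    }
  }
  toks
}

.is_connected <- function(n, bonds) {
  if (n == 1L) return(TRUE)
  if (!nrow(bonds)) return(FALSE)
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    adj[[bonds$i[r]]] <- c(adj[[bonds$i[r]]], bonds$j[r])
    adj[[bonds$j[r]]] <- c(adj[[bonds$j[r]]], bonds$i[r])
  }
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

# a bond lies on a ring iff removing it leaves the graph connected
.ring_bonds <- function(n, bonds) {
  if (!nrow(bonds)) return(logical(0))
  vapply(seq_len(nrow(bonds)), function(r) {
    .is_connected(n, bonds[-r, , drop = FALSE])
  }, logical(1))
}

.implicit_h <- function(element, aromatic, bondsum, nbonds, smiles) {
  v <- .VALENCES[[element]]
  if (is.null(v)) return(0L)  # beyond the valence model: leave 0, no repair
  if (aromatic) {
    # aromatic atom commits one bonding slot to the ring pi system:
    # effective occupancy is the bond count plus one
    fit <- v[v >= nbonds + 1L]
    if (!length(fit)) return(0L)
    return(as.integer(fit[1] - (nbonds + 1L)))
  }
  need <- ceiling(bondsum)
  fit <- v[v >= need]
  if (!length(fit)) {
    stop(sprintf("impossible valence in \"%s\": %s with bond order sum %g exceeds allowed valence(s) %s",
                 smiles, element, bondsum, paste(v, collapse = "/")),
         call. = FALSE)
  }
  as.integer(fit[1] - need)
}

#' Parse a SMILES string into a MolecularGraph
#'
#' Reads one ion written in a deliberately small SMILES subset (organic-subset
#' and bracket atoms, aromatic lowercase notation, branches, ring closures)
#' and returns the attributed graph used by the descriptor calculator.
#' Aromaticity is taken from the aromatic (lowercase / \code{:}) notation;
#' kekulized input is kept as written. Implicit hydrogen counts follow the
#' usual SMILES valence model (B 3, C 4, N 3, O 2, P 3/5, S 2/4/6,
#' halogens 1); bracket atoms carry exactly the hydrogens they declare.
#' Impossible valences and multi-fragment (dot-separated) input are errors,
#' never silently repaired.
#'
#' @param smiles character(1), the SMILES of a single ion.
#' @return a [MolecularGraph-class] with perceived ring membership.
#' @examples
#' parseSmiles("[Cl-]")
#' parseSmiles("C[N+](C)(C)C")    # tetramethylammonium
#' parseSmiles("C[n+]1ccn(CC)c1") # 1-ethyl-3-methylimidazolium
#' @export
parseSmiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("smiles must be a single non-empty character string", call. = FALSE)
  }
  toks <- .tokenize_smiles(smiles)

  atoms <- list()
  bond_i <- integer(); bond_j <- integer(); bond_sym <- character()
  prev <- NA_integer_
  stack <- integer()
  pending <- NA_character_
  rings <- list()  # ring digit -> list(atom, sym, pos)

  add_bond <- function(a, b, sym, pos) {
    if (a == b) .parse_error(smiles, pos, "ring bond closing onto the same atom")
    bond_i <<- c(bond_i, min(a, b)); bond_j <<- c(bond_j, max(a, b))
    bond_sym <<- c(bond_sym, sym)
  }

  for (tk in toks) {
    if (tk$type == "atom") {
      atoms[[length(atoms) + 1L]] <- tk$value
      idx <- length(atoms)
      if (!is.na(prev)) {
        add_bond(prev, idx, if (is.na(pending)) "" else pending, tk$pos)
      } else if (!is.na(pending)) {
        .parse_error(smiles, tk$pos, "bond symbol before the first atom")
      }
      pending <- NA_character_
      prev <- idx
    } else if (tk$type == "bond") {
      if (!is.na(pending)) .parse_error(smiles, tk$pos, "two bond symbols in a row")
      pending <- tk$value
    } else if (tk$type == "open") {
      if (is.na(prev)) .parse_error(smiles, tk$pos, "branch before the first atom")
      stack <- c(stack, prev)
    } else if (tk$type == "close") {
      if (!length(stack)) .parse_error(smiles, tk$pos, "unmatched \")\"")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tk$type == "ring") {
      if (is.na(prev)) .parse_error(smiles, tk$pos, "ring closure before the first atom")
      key <- tk$value
      if (is.null(rings[[key]])) {
        rings[[key]] <- list(atom = prev, sym = pending, pos = tk$pos)
      } else {
        op <- rings[[key]]
        sym <- if (!is.na(pending)) pending else if (!is.na(op$sym)) op$sym else ""
        if (!is.na(pending) && !is.na(op$sym) && pending != op$sym) {
          .parse_error(smiles, tk$pos, "conflicting bond symbols on ring closure")
        }
        add_bond(op$atom, prev, sym, tk$pos)
        rings[[key]] <- NULL
      }
      pending <- NA_character_
    }
  }
  if (length(rings)) {
    .parse_error(smiles, nchar(smiles),
                 sprintf("unclosed ring bond(s): %s", paste(names(rings), collapse = ", ")))
  }
  if (length(stack)) .parse_error(smiles, nchar(smiles), "unmatched \"(\"")
  if (!is.na(pending)) .parse_error(smiles, nchar(smiles), "dangling bond symbol")
  if (!length(atoms)) .parse_error(smiles, 1L, "no atoms")

  el <- vapply(atoms, `[[`, character(1), "element")
  arom_atom <- vapply(atoms, `[[`, logical(1), "aromatic")

  nb <- length(bond_i)
  order <- integer(nb); arom_bond <- logical(nb)
  for (r in seq_len(nb)) {
    s <- bond_sym[r]
    if (s == ":" || (s == "" && arom_atom[bond_i[r]] && arom_atom[bond_j[r]])) {
      order[r] <- 1L; arom_bond[r] <- TRUE
    } else {
      order[r] <- switch(s, "=" = 2L, "#" = 3L, 1L)  # "", "-", "/", "\\" -> 1
    }
  }
  key <- paste(bond_i, bond_j)
  if (anyDuplicated(key)) {
    .parse_error(smiles, nchar(smiles), "duplicate bond between the same atom pair")
  }

  hcount <- integer(length(atoms))
  for (a in seq_along(atoms)) {
    at <- atoms[[a]]
    if (at$explicit_h) {
      hcount[a] <- at$hcount
    } else {
      rows <- which(bond_i == a | bond_j == a)
      bondsum <- sum(ifelse(arom_bond[rows], 1.5, order[rows]))
      hcount[a] <- .implicit_h(at$element, arom_atom[a], bondsum, length(rows),
                               smiles)
    }
  }

  bonds <- data.frame(i = bond_i, j = bond_j, order = order,
                      aromatic = arom_bond, ring = logical(nb))
  if (!.is_connected(length(atoms), bonds)) {
    stop(sprintf("\"%s\" is not a single ion: disconnected graph", smiles),
         call. = FALSE)
  }
  bonds$ring <- .ring_bonds(length(atoms), bonds)

  new("MolecularGraph",
      atoms = data.frame(element = el,
                         charge = vapply(atoms, `[[`, integer(1), "charge"),
                         hcount = hcount, aromatic = arom_atom),
      bonds = bonds,
      netCharge = as.integer(sum(vapply(atoms, `[[`, integer(1), "charge"))))
}
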