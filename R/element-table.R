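# Versioned element-property table used by the weighted constitutional sums.
#
# Sources:
#   mass  - IUPAC standard atomic weights (2021, conventional values), u
#   en    - Sanderson electronegativity (Sanderson, J. Chem. Educ. 1988, 65, 112)
#   pol   - static dipole polarizability, CRC Handbook 95th ed., A^3
#   ip    - first ionization potential, NIST ASD, eV
#   vdw   - van der Waals volume 4/3*pi*r^3 from Bondi radii
#           (Bondi, J. Phys. Chem. 1964, 68, 441; B from Batsanov 2001), A^3
.ELEMENT_TABLE_VERSION <- "1.0"

.element_raw <- local({
  d <- data.frame(
    element = c("H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I"),
    mass = c(1.008, 10.81, 12.011, 14.007, 15.999, 18.998, 30.974, 32.06,
             35.45, 79.904, 126.904),
    en   = c(2.592, 2.275, 2.746, 3.194, 3.654, 4.000, 2.515, 2.957,
             3.475, 3.219, 2.778),
    pol  = c(0.667, 3.030, 1.760, 1.100, 0.802, 0.557, 3.630, 2.900,
             2.180, 3.050, 5.350),
    ip   = c(13.598, 8.298, 11.260, 14.534, 13.618, 17.423, 10.487, 10.360,
             12.968, 11.814, 10.451),
    vdw_r = c(1.20, 1.92, 1.70, 1.55, 1.52, 1.47, 1.80, 1.80, 1.75, 1.85, 1.98)
  )
  d$vdw <- 4 / 3 * pi * d$vdw_r^3
  d$vdw_r <- NULL
  rownames(d) <- d$element
  d
})

#' Element property table
#'
#' Atomic mass, Sanderson electronegativity, polarizability, first ionization
#' potential and van der Waals volume for the elements the descriptor
#' calculator supports (H, B, C, N, O, F, P, S, Cl, Br, I), each also as the
#' ratio to the carbon value (columns \code{en_c}, \code{pol_c}, \code{ip_c},
#' \code{vdw_c}). The carbon-scaled ratios feed the cumulative
#' electronegativity/polarizability/ionization-potential/volume descriptors
#' Se, Sp, Si, Sv and their means. Formal charge does not alter a lookup:
#' constitutional descriptors are composition counts, so N+ uses the values
#' of N.
#'
#' @return data.frame, one row per element, with a
#'   \code{"version"} attribute identifying the table revision.
#' @examples
#' elementTable()["Cl", "mass"]
#' @export
elementTable <- function() {
  d <- .element_raw
  for (col in c("en", "pol", "ip", "vdw")) {
    d[[paste0(col, "_c")]] <- d[[col]] / d["C", col]
  }
  attr(d, "version") <- .ELEMENT_TABLE_VERSION
  d
}

.element_lookup <- function(symbols) {
  tab <- elementTable()
  bad <- setdiff(unique(symbols), rownames(tab))
  if (length(bad)) {
    stop("unsupported element(s): ", paste(bad, collapse = ", "),
         " (element table v", .ELEMENT_TABLE_VERSION, " covers ",
         paste(rownames(tab), collapse = ", "), ")", call. = FALSE)
  }
  tab[symbols, , drop = FALSE]
}
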