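#' Monoisotopic residue masses
#'
#' Residue (not free amino acid) monoisotopic masses for the 20 standard
#' amino acids, in daltons. Isoleucine and leucine are isobaric
#' (113.08406 Da) and are never distinguished by mass; both letters are
#' accepted everywhere a residue letter is expected.
#'
#' @return A tibble with columns `residue` (one-letter code) and `mass` (Da).
#' @examples
#' residue_masses()
#' @export
residue_masses <- function() {
  tibble::tibble(
    residue = names(.residue_mass_table),
    mass = unname(.residue_mass_table)
  )
}

# Monoisotopic residue masses, >= 5 decimals; sub-mDa accuracy is required
# because peak-difference matching runs at a 4 mDa tolerance.
.residue_mass_table <- c(
  G = 57.02146,  A = 71.03711,  S = 87.03203,  P = 97.05276,
  V = 99.06841,  T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' Monoisotopic mass of water
#'
#' Mass of H2O in daltons, used for water-loss detection and for precursor
#' masses of simulated spectra.
#' @export
water_mass <- 18.010565

#' Residue mass lookup
#'
#' @param aa Character vector of one-letter residue codes.
#' @return Numeric vector of monoisotopic residue masses (Da).
#' @examples
#' residue_mass("G")
#' residue_mass(c("I", "L")) # isobaric
#' @export
residue_mass <- function(aa) {
  m <- .residue_mass_table[aa]
  if (anyNA(m)) {
    bad <- unique(aa[is.na(m)])
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(m)
}

#' Mass of an amino-acid string
#'
#' Sum of monoisotopic residue masses. No terminal water is added: fragment
#' offsets and gap masses are residue-mass sums, so gap arithmetic such as
#' subtracting the mass of a spurious terminal dimer from a theoretical gap
#' balances only without a water term.
#'
#' @param s Character vector of amino-acid strings (may contain `""`).
#' @return Numeric vector of masses (Da); 0 for the empty string.
#' @examples
#' sequence_mass("RP") # 253.15 Da
#' sequence_mass("PSQT") - sequence_mass("GY")
#' @export
sequence_mass <- function(s) {
  vapply(s, function(x) {
    if (nchar(x) == 0L) return(0)
    sum(residue_mass(strsplit(x, "", fixed = TRUE)[[1L]]))
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Match a mass difference to a residue
#'
#' Returns the residue whose monoisotopic mass lies within `tol` of `delta`,
#' or `NA` if none does. Isoleucine/leucine matches are reported as the
#' canonical letter `"L"`; a mass match can never distinguish the two.
#' K and Q differ by ~0.036 Da, so they do not collide at the default
#' tolerances (2 * 4 mDa).
#'
#' @param delta Numeric vector of mass differences (Da).
#' @param tol Tolerance (Da), > 0.
#' @return Character vector of residue letters, `NA` where no residue matches.
#' @examples
#' match_residue(57.0215, tol = 0.008)
#' match_residue(60, tol = 0.008) # NA
#' @export
match_residue <- function(delta, tol = 0.008) {
  stopifnot(is.numeric(delta), tol > 0)
  # canonical alphabet: drop I so that I/L always reports "L"
  tab <- .residue_mass_table[names(.residue_mass_table) != "I"]
  idx <- vapply(delta, function(d) {
    err <- abs(tab - d)
    i <- which.min(err)
    if (err[i] <= tol) i else NA_integer_
  }, integer(1L))
  names(tab)[idx]
}

#' Reverse an amino-acid string
#'
#' @param s Character vector of strings.
#' @return The reversed strings.
#' @examples
#' reverse_sequence("SGATF")
#' @export
reverse_sequence <- function(s) {
  vapply(strsplit(s, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""),
         character(1L), USE.NAMES = FALSE)
}
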