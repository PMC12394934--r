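# Residue-level constants shared across the package.

#' The twenty canonical amino acids
#'
#' One-letter codes for the canonical amino acids, in alphabetical order.
#' This is the alphabet every peptide sequence in the package is validated
#' against; residues outside it (B, J, O, U, X, Z, `*`) are treated as
#' non-canonical and flagged at ingest.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values used by [gravy()]. Positive values are
#' hydrophobic on this scale's sign convention.
#'
#' @return Named numeric vector over the 20 canonical residues, with a
#'   `name` attribute identifying the scale.
#' @export
kd_hydropathy <- function() {
  s <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
         Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
         L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
         S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)
  attr(s, "name") <- "Kyte-Doolittle 1982"
  s[amino_acids()]
}

#' Ionization constants for net-charge and pI computation
#'
#' Returns a pKa set: values for the free N- and C-termini and the seven
#' ionizable side chains (D, E, C, Y, H, K, R). The default set is the
#' EMBOSS set; the choice of set is recorded in output metadata because
#' small differences between published sets shift computed pI values by
#' a few tenths of a pH unit.
#'
#' @param name Which set to return; currently only `"emboss"`.
#' @return A list with elements `nterm`, `cterm`, `D`, `E`, `C`, `Y`,
#'   `H`, `K`, `R` and `name`.
#' @export
pka_set <- function(name = "emboss") {
  name <- match.arg(name, "emboss")
  list(nterm = 8.6, cterm = 3.6,
       D = 3.9, E = 4.1, C = 8.5, Y = 10.1, H = 6.5, K = 10.8, R = 12.5,
       name = "EMBOSS")
}

# Monoisotopic residue masses (Da); a peptide's mass adds one water.
.residue_mono_mass <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

.water_mono_mass <- 18.010565

# Split sequences into residue characters; errors name the offender.
.check_sequence <- function(sequence, what = "sequence") {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop(what, " must be a single nonempty string", call. = FALSE)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), amino_acids())
  if (length(bad))
    stop("non-canonical residue(s) in ", what, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  chars
}

#' Round half away from zero
#'
#' Display rounding used in property tables (so -0.4875 prints as
#' -0.49), as opposed to R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
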