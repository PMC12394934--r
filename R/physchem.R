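# Per-peptide physicochemical properties: GRAVY hydropathy, net charge,
# isoelectric point, monoisotopic mass.

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of per-residue hydropathy values over the peptide.
#' Full precision is returned; tables conventionally display two
#' decimals (see [round_half_away()] semantics in property tables).
#'
#' @param sequence Peptide sequence(s) over the canonical alphabet.
#' @param scale Hydropathy scale; default [kd_hydropathy()].
#' @return Numeric vector of GRAVY scores.
#' @export
gravy <- function(sequence, scale = kd_hydropathy()) {
  vapply(sequence, function(s) {
    chars <- .check_sequence(s)
    mean(scale[chars])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Net charge at a given pH
#'
#' Henderson-Hasselbalch summation: positive contributions from the free
#' N-terminus and H, K, R side chains, `+1 / (1 + 10^(pH - pKa))`;
#' negative contributions from the free C-terminus and D, E, C, Y side
#' chains, `-1 / (1 + 10^(pKa - pH))`. The result is strictly decreasing
#' in pH.
#'
#' @param sequence Peptide sequence(s).
#' @param pH pH at which to evaluate (in (0, 14)); default 7.
#' @param pka A [pka_set()].
#' @return Numeric vector of net charges.
#' @export
net_charge <- function(sequence, pH = 7, pka = pka_set()) {
  stopifnot(pH > 0, pH < 14)
  pos_pka <- c(pka$nterm, pka$H, pka$K, pka$R)
  names(pos_pka) <- c("nterm", "H", "K", "R")
  neg_pka <- c(pka$cterm, pka$D, pka$E, pka$C, pka$Y)
  names(neg_pka) <- c("cterm", "D", "E", "C", "Y")
  vapply(sequence, function(s) {
    chars <- .check_sequence(s)
    counts <- table(factor(chars, levels = amino_acids()))
    npos <- c(nterm = 1, counts[c("H", "K", "R")])
    nneg <- c(cterm = 1, counts[c("D", "E", "C", "Y")])
    sum(npos / (1 + 10^(pH - pos_pka))) -
      sum(nneg / (1 + 10^(neg_pka - pH)))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Isoelectric point by bisection
#'
#' The pI is the unique pH at which [net_charge()] vanishes; since net
#' charge is strictly decreasing in pH the root exists and is unique on
#' (0, 14). Bisection proceeds until `|charge| < tol`.
#'
#' @param sequence Peptide sequence(s).
#' @param pka A [pka_set()].
#' @param tol Charge tolerance at the returned pH; default 1e-4.
#' @return Numeric vector of pI values.
#' @export
isoelectric_point <- function(sequence, pka = pka_set(), tol = 1e-4) {
  vapply(sequence, function(s) {
    lo <- 1e-3; hi <- 14 - 1e-3
    mid <- (lo + hi) / 2
    # bisect to a tight pH interval; this makes |charge| at the returned
    # pH far below tol even where the titration curve is nearly flat
    while (hi - lo > 1e-7) {
      mid <- (lo + hi) / 2
      q <- net_charge(s, mid, pka)
      if (abs(q) < tol && hi - lo < 1e-4) break
      if (q > 0) lo <- mid else hi <- mid
    }
    mid
  }, numeric(1), USE.NAMES = FALSE)
}

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water (free termini).
#'
#' @param sequence Peptide sequence(s).
#' @return Numeric vector of masses in Da.
#' @export
mono_mass <- function(sequence) {
  vapply(sequence, function(s) {
    chars <- .check_sequence(s)
    sum(.residue_mono_mass[chars]) + .water_mono_mass
  }, numeric(1), USE.NAMES = FALSE)
}

#' Property table for a peptide population
#'
#' Computes length, GRAVY, pI, net charge at the stated pH (both the
#' continuous Henderson-Hasselbalch value and its nearest-integer bin,
#' used for charge histograms) and monoisotopic mass for every peptide.
#'
#' @param pop A [peptide_population()] or character vector of sequences.
#' @param pH pH for the net-charge column; default 7.
#' @param pka A [pka_set()].
#' @param scale Hydropathy scale.
#' @return Data frame with columns `peptide`, `length`, `gravy`, `pI`,
#'   `net_charge`, `net_charge_int`, `mono_mass`; the pKa set name and
#'   pH are attached as attributes.
#' @export
peptide_properties <- function(pop, pH = 7, pka = pka_set(),
                               scale = kd_hydropathy()) {
  seqs <- if (is.character(pop)) pop else pop$sequence
  if (!length(seqs)) stop("empty population", call. = FALSE)
  q <- net_charge(seqs, pH, pka)
  out <- data.frame(peptide = seqs,
                    length = nchar(seqs),
                    gravy = gravy(seqs, scale),
                    pI = isoelectric_point(seqs, pka),
                    net_charge = q,
                    net_charge_int = round_half_away(q, 0),
                    mono_mass = mono_mass(seqs),
                    stringsAsFactors = FALSE)
  attr(out, "pka_set") <- pka$name
  attr(out, "pH") <- pH
  out
}
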