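# In-silico enzymatic digestion with missed cleavages.

#' Define an enzyme cleavage rule
#'
#' A rule cleaves on the C-terminal side of any residue in `p1_residues`
#' (never after the final residue). Fragments carrying up to
#' `max_missed_cleavages` internal uncleaved sites are emitted, then
#' length bounds are applied.
#'
#' @param enzyme_name Name of the enzyme (free text).
#' @param p1_residues Residues after which cleavage occurs.
#' @param max_missed_cleavages Maximum internal uncleaved sites per
#'   emitted peptide; default 2, matching common search settings.
#' @param min_length,max_length Peptide length bounds applied after
#'   enumeration.
#' @param no_cleave_before_P If `TRUE`, suppress cleavage when the
#'   following residue is proline (off by default).
#' @return An object of class `cleavage_rule`.
#' @export
cleavage_rule <- function(enzyme_name, p1_residues,
                          max_missed_cleavages = 2L,
                          min_length = 1L, max_length = Inf,
                          no_cleave_before_P = FALSE) {
  p1_residues <- unique(toupper(p1_residues))
  bad <- setdiff(p1_residues, amino_acids())
  if (length(bad))
    stop("p1_residues outside the canonical alphabet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  stopifnot(max_missed_cleavages >= 0, min_length >= 1,
            min_length <= max_length)
  structure(list(enzyme_name = enzyme_name,
                 p1_residues = p1_residues,
                 max_missed_cleavages = as.integer(max_missed_cleavages),
                 min_length = min_length,
                 max_length = max_length,
                 no_cleave_before_P = no_cleave_before_P),
            class = "cleavage_rule")
}

#' @export
print.cleavage_rule <- function(x, ...) {
  cat(sprintf("cleavage_rule '%s': cleave after {%s}, <=%d missed, length %s-%s\n",
              x$enzyme_name, paste(x$p1_residues, collapse = ""),
              x$max_missed_cleavages, x$min_length,
              if (is.finite(x$max_length)) x$max_length else "Inf"))
  invisible(x)
}

#' Built-in enzyme rules
#'
#' Presets for the proteases used in hydrolysate preparation. Trypsin
#' cleaves C-terminal to arginine and lysine. Pepsin is promiscuous at
#' aromatic and hydrophobic residues; the default P1 set \{F, W, Y, L\} is
#' a conventional reduction of that promiscuity and is configurable via
#' [cleavage_rule()]. Papain prefers basic or hydrophobic residues;
#' default P1 set \{K, R, H, L, V, I, F, W, A\}.
#'
#' @param enzyme One of `"trypsin"`, `"pepsin"`, `"papain"`.
#' @param ... Overrides passed to [cleavage_rule()]
#'   (`max_missed_cleavages`, `min_length`, `max_length`,
#'   `no_cleave_before_P`).
#' @return A [cleavage_rule()].
#' @export
enzyme_rule <- function(enzyme = c("trypsin", "pepsin", "papain"), ...) {
  enzyme <- match.arg(enzyme)
  p1 <- switch(enzyme,
               trypsin = c("K", "R"),
               pepsin = c("F", "W", "Y", "L"),
               papain = c("K", "R", "H", "L", "V", "I", "F", "W", "A"))
  cleavage_rule(enzyme, p1, ...)
}

# Cleavage-site positions: i in 1..(L-1) means a cut between residue i
# and i+1. The terminal residue never defines a site.
.cleavage_sites <- function(chars, rule) {
  L <- length(chars)
  if (L < 2L || !length(rule$p1_residues)) return(integer(0))
  i <- which(chars[-L] %in% rule$p1_residues)
  if (rule$no_cleave_before_P && length(i))
    i <- i[chars[i + 1L] != "P"]
  i
}

#' Digest a protein with one enzyme rule
#'
#' Fragments are the maximal runs between adjacent cleavage sites; in
#' addition, every concatenation of up to `max_missed_cleavages + 1`
#' adjacent fragments is emitted (a peptide with k internal uncleaved
#' sites corresponds to k missed cleavages). Length bounds are applied
#' last.
#'
#' @param protein A protein sequence over the canonical alphabet.
#' @param rule A [cleavage_rule()].
#' @return Character vector of peptides in N-to-C order (ordered by
#'   start position, then by missed-cleavage count).
#' @export
digest <- function(protein, rule) {
  chars <- .check_sequence(protein, "protein")
  stopifnot(inherits(rule, "cleavage_rule"))
  sites <- .cleavage_sites(chars, rule)
  bounds <- c(0L, sites, length(chars))   # fragment k spans bounds[k]+1 .. bounds[k+1]
  nfrag <- length(bounds) - 1L
  out <- character(0)
  for (i in seq_len(nfrag)) {
    jmax <- min(nfrag, i + rule$max_missed_cleavages)
    for (j in i:jmax) {
      len <- bounds[j + 1L] - bounds[i]
      if (len >= rule$min_length && len <= rule$max_length)
        out <- c(out, substr(protein, bounds[i] + 1L, bounds[j + 1L]))
    }
  }
  out
}

#' Sequential two-enzyme digestion
#'
#' Applies `second` to every fragment produced by `first`, emulating a
#' sequential digestion protocol (e.g. pepsin followed by trypsin). With
#' zero missed cleavages on both rules this is equivalent to a single
#' digestion at the union of both site sets.
#'
#' @param protein Protein sequence.
#' @param first,second [cleavage_rule()]s applied in order.
#' @return Character vector of peptides.
#' @export
sequential_digest <- function(protein, first, second) {
  frags <- digest(protein, first)
  unlist(lapply(frags, digest, rule = second), use.names = FALSE)
}

#' Digest a set of proteins into a peptide population
#'
#' @param proteins Data frame with `protein_id` and `sequence` columns
#'   (as returned by [read_fasta()]); invalid records are skipped with a
#'   message.
#' @param rule A [cleavage_rule()], or a list of two rules for
#'   sequential digestion.
#' @param condition Condition label stamped on the peptides.
#' @param label Population label.
#' @return A [peptide_population()].
#' @export
digest_proteins <- function(proteins, rule, condition = "other",
                            label = condition) {
  if (!is.null(proteins$valid) && any(!proteins$valid)) {
    message(sum(!proteins$valid),
            " protein record(s) with non-canonical residues skipped")
    proteins <- proteins[proteins$valid, , drop = FALSE]
  }
  if (!nrow(proteins)) stop("no valid proteins to digest", call. = FALSE)
  res <- lapply(seq_len(nrow(proteins)), function(i) {
    peps <- if (inherits(rule, "cleavage_rule"))
      digest(proteins$sequence[i], rule)
    else
      sequential_digest(proteins$sequence[i], rule[[1L]], rule[[2L]])
    if (length(peps))
      data.frame(sequence = peps, protein_id = proteins$protein_id[i],
                 stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res) || !nrow(res))
    stop("digestion produced no peptides within the length bounds",
         call. = FALSE)
  peptide_population(res$sequence, protein_id = res$protein_id,
                     condition = condition, label = label)
}
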