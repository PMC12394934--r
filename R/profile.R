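# Global composition, enrichment ratios against a background profile,
# and position-specific frequency matrices.

#' Global amino-acid composition of a population
#'
#' Residue counts pooled over all peptides, as a percent of all residues
#' in the population. Every residue is present in the result (zeros
#' allowed) and the percents sum to 100.
#'
#' @param pop A [peptide_population()] or character vector.
#' @return Named numeric vector of class `composition_profile`, with a
#'   `total_residues` attribute.
#' @export
global_composition <- function(pop) {
  seqs <- if (is.character(pop)) pop else pop$sequence
  if (!length(seqs)) stop("empty population", call. = FALSE)
  chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  counts <- table(factor(chars, levels = amino_acids()))
  out <- 100 * as.numeric(counts) / length(chars)
  names(out) <- amino_acids()
  structure(out, total_residues = length(chars),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat("composition_profile over", attr(x, "total_residues"),
      "residues (%):\n")
  v <- unclass(x)
  attr(v, "total_residues") <- NULL
  print(round(v[order(-v)], 1))
  invisible(x)
}

#' Per-residue enrichment ratios against a background
#'
#' Ratio of observed percent to background percent, residue by residue.
#' Residues with zero background are returned as `NA` (undefined), not
#' infinity.
#'
#' @param observed A [global_composition()] profile (or named percent
#'   vector).
#' @param background Named percent vector, e.g.
#'   [rice_bran_background()] or a profile read with
#'   [read_background_profile()].
#' @return Named numeric vector of ratios.
#' @export
enrichment_ratio <- function(observed, background) {
  res <- amino_acids()
  obs <- unclass(observed)[res]
  bg <- background[res]
  ratio <- ifelse(!is.na(bg) & bg > 0, obs / bg, NA_real_)
  names(ratio) <- res
  ratio
}

#' Read a background composition profile
#'
#' Two-column delimited table (`residue`, `percent`), `#` comments
#' allowed. The shipped example `extdata/rice_bran_background.tsv`
#' carries literature-style midpoint abundances for rice bran protein.
#'
#' @param path Path to the table.
#' @return Named percent vector over the residues present.
#' @export
read_background_profile <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  stats::setNames(tab$percent, tab$residue)
}

#' Position-specific amino-acid frequency matrix
#'
#' For the three N-terminal positions (N1-N3) and the three C-terminal
#' positions (C3 = third-to-last, C2, C1 = last), the percent of
#' peptides whose residue at that position is each amino acid. The
#' denominator is the number of peptides contributing to the column, so
#' a statement like "32% of peptides have histidine at N1" reads
#' directly off the matrix. Peptides shorter than `min_length` are
#' excluded and counted (never silently dropped); for a length-5
#' peptide the middle residue contributes to both N3 and C3, since the
#' two windows are computed independently.
#'
#' @param pop A [peptide_population()] or character vector.
#' @param min_length Minimum peptide length for inclusion; default 5 so
#'   both terminal windows are well defined.
#' @return A 20 x 6 matrix of class `positional_matrix` (rows =
#'   residues, alphabetical; columns N1, N2, N3, C3, C2, C1), with
#'   attributes `n_peptides` and `n_excluded`.
#' @export
positional_matrix <- function(pop, min_length = 5L) {
  seqs <- if (is.character(pop)) pop else pop$sequence
  if (!length(seqs)) stop("empty population", call. = FALSE)
  L <- nchar(seqs)
  excluded <- sum(L < min_length)
  seqs <- seqs[L >= min_length]
  if (!length(seqs))
    stop("no peptides of length >= ", min_length, call. = FALSE)
  L <- nchar(seqs)
  cols <- list(N1 = substr(seqs, 1L, 1L),
               N2 = substr(seqs, 2L, 2L),
               N3 = substr(seqs, 3L, 3L),
               C3 = substr(seqs, L - 2L, L - 2L),
               C2 = substr(seqs, L - 1L, L - 1L),
               C1 = substr(seqs, L, L))
  m <- vapply(cols, function(ch)
    100 * as.numeric(table(factor(ch, levels = amino_acids()))) /
      length(ch), numeric(20L))
  rownames(m) <- amino_acids()
  structure(m, n_peptides = length(seqs), n_excluded = excluded,
            class = c("positional_matrix", "matrix"))
}

#' @export
print.positional_matrix <- function(x, digits = 1, ...) {
  cat(sprintf("positional_matrix: %d peptides (%d excluded as too short)\n",
              attr(x, "n_peptides"), attr(x, "n_excluded")))
  m <- x
  attributes(m) <- attributes(x)[c("dim", "dimnames")]
  print(round(m, digits))
  invisible(x)
}

#' Positional matrices stratified by digestion condition
#'
#' One matrix per condition present in the population, plus the pooled
#' matrix over all peptides, all with identical layout. The pooled
#' matrix equals the peptide-count-weighted average of the per-condition
#' matrices.
#'
#' @param pop A [peptide_population()] with condition labels.
#' @param min_length Passed to [positional_matrix()].
#' @return Named list of `positional_matrix` objects; the pooled matrix
#'   is under `"pooled"`.
#' @export
positional_matrix_by_condition <- function(pop, min_length = 5L) {
  conds <- unique(pop$condition)
  out <- lapply(conds, function(cc)
    positional_matrix(pop[pop$condition == cc, , drop = FALSE],
                      min_length = min_length))
  names(out) <- conds
  out$pooled <- positional_matrix(pop, min_length = min_length)
  out
}

#' Write a positional matrix as TSV
#'
#' Rows are the 20 residues (alphabetical), columns N1, N2, N3, C3, C2,
#' C1, values percent with one decimal; `#` metadata lines record the
#' peptide counts.
#'
#' @param m A `positional_matrix`.
#' @param path Output path.
#' @param metadata Optional named list of extra `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_positional_matrix <- function(m, path, metadata = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(list(n_peptides = attr(m, "n_peptides"),
                 n_excluded = attr(m, "n_excluded")), metadata)
  writeLines(sprintf("# %s: %s", names(meta),
                     vapply(meta, paste, "", collapse = ",")), con)
  tab <- data.frame(residue = rownames(m),
                    round(unclass(m), 1), check.names = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
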