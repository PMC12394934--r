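# Reading and writing the formats the pipeline touches: FASTA proteins,
# delimited peptide-identification reports, and result tables.

#' Construct a peptide population
#'
#' The central container of the package: an ordered collection of peptide
#' records with their provenance labels. Implemented as a data frame with
#' columns `sequence`, `protein_id`, `probability`, `condition`,
#' `fraction` and logical `valid`; a `label` attribute names the
#' population.
#'
#' @param sequence Character vector of peptide sequences (upper-case
#'   one-letter codes).
#' @param protein_id Optional source-protein identifiers.
#' @param probability Optional identification probabilities in `[0, 1]`.
#' @param condition Digestion condition label: `"pep_tryp"`, `"papain"`
#'   or `"other"`.
#' @param fraction Enrichment fraction label: `"RBPH"` (whole
#'   hydrolysate), `"FT"` (flow-through), `"E"` (eluent) or
#'   `"synthetic"`.
#' @param label Population label (free text).
#' @return An object of class `peptide_population`.
#' @export
peptide_population <- function(sequence, protein_id = NA_character_,
                               probability = NA_real_,
                               condition = "other",
                               fraction = "synthetic",
                               label = "") {
  sequence <- toupper(as.character(sequence))
  n <- length(sequence)
  condition <- .check_enum(condition, c("pep_tryp", "papain", "other"), n)
  fraction <- .check_enum(fraction, c("RBPH", "FT", "E", "synthetic"), n)
  probability <- rep_len(as.numeric(probability), n)
  if (any(!is.na(probability) & (probability < 0 | probability > 1)))
    stop("probability must lie in [0, 1]", call. = FALSE)
  valid <- vapply(sequence, function(s) {
    nzchar(s) && !is.na(s) &&
      all(strsplit(s, "", fixed = TRUE)[[1L]] %in% amino_acids())
  }, logical(1), USE.NAMES = FALSE)
  pop <- data.frame(sequence = sequence,
                    protein_id = rep_len(as.character(protein_id), n),
                    probability = probability,
                    condition = condition,
                    fraction = fraction,
                    valid = valid,
                    stringsAsFactors = FALSE)
  structure(pop, label = label,
            class = c("peptide_population", "data.frame"))
}

.check_enum <- function(x, levels, n) {
  x <- rep_len(as.character(x), n)
  bad <- setdiff(unique(x[!is.na(x)]), levels)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(levels, collapse = ", "),
         call. = FALSE)
  x
}

#' @export
print.peptide_population <- function(x, ...) {
  cat(sprintf("peptide_population '%s': %d peptides (%d valid)\n",
              attr(x, "label"), nrow(x), sum(x$valid)))
  if (nrow(x)) {
    tab <- table(x$condition)
    cat("  conditions:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    cat("  length range:", paste(range(nchar(x$sequence)), collapse = "-"),
        "\n")
  }
  invisible(x)
}

#' @export
summary.peptide_population <- function(object, ...) {
  data.frame(label = attr(object, "label"),
             n = nrow(object),
             n_valid = sum(object$valid),
             n_with_probability = sum(!is.na(object$probability)),
             median_length = if (nrow(object))
               stats::median(nchar(object$sequence)) else NA_real_)
}

#' Read a protein FASTA file
#'
#' Parses a multi-record FASTA file, concatenating wrapped sequence lines
#' and upper-casing sequences. Records containing characters outside the
#' 20-letter canonical alphabet (e.g. B, J, O, U, X, Z, `*`) are kept but
#' flagged `valid = FALSE` so downstream steps can report rather than
#' silently drop them.
#'
#' @param path Path to a FASTA file.
#' @return Data frame with columns `protein_id` (first token of the
#'   header), `sequence` and logical `valid`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (!length(headers))
    stop("no FASTA records in ", path, call. = FALSE)
  ends <- c(headers[-1L] - 1L, length(lines))
  out <- lapply(seq_along(headers), function(i) {
    h <- headers[i]
    if (ends[i] < h + 1L)
      stop("FASTA record without sequence at line ", h, call. = FALSE)
    id <- strsplit(sub("^>", "", lines[h]), "\\s+")[[1L]][1L]
    seq <- toupper(paste(lines[(h + 1L):ends[i]], collapse = ""))
    data.frame(protein_id = id, sequence = seq, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$valid <- vapply(out$sequence, function(s)
    all(strsplit(s, "", fixed = TRUE)[[1L]] %in% amino_acids()),
    logical(1), USE.NAMES = FALSE)
  out
}

#' Write proteins to a FASTA file
#'
#' @param proteins Data frame with `protein_id` and `sequence` columns.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(paste0(">", proteins$protein_id[i]), con)
    s <- proteins$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

#' Strip modification annotations from reported peptide strings
#'
#' Removes bracketed/parenthesised mass tags such as `[+42.0106]` or
#' `(UniMod:1)`, drops the lowercase `n`/`c` terminal markers used in
#' modified-peptide notation, and upper-cases lowercase residue letters
#' marking modified positions, leaving the bare residue sequence on
#' which all compositional and positional analysis operates.
#'
#' @param sequence Character vector of annotated peptide strings.
#' @return Character vector of bare sequences.
#' @export
strip_modifications <- function(sequence) {
  bare <- gsub("\\[[^]]*\\]|\\([^)]*\\)", "", sequence)
  bare <- gsub("[^A-Za-z]", "", bare)
  bare <- sub("^n", "", bare)
  bare <- sub("c$", "", bare)
  toupper(bare)
}

#' Read a peptide identification report
#'
#' Parses a delimited peptide report (the format emitted by FragPipe /
#' MSFragger peptide tables: one row per peptide with sequence, source
#' protein and identification probability). The delimiter is
#' auto-detected between tab and comma. Modification annotations in
#' sequence cells (bracketed mass tags, lowercase residues) are stripped
#' to bare residues; rows where stripping changed the sequence are noted
#' in the `modified` column. Row order is preserved.
#'
#' @param path Path to the report.
#' @param column_map Named character vector binding report headers to
#'   peptide fields; names are the fields `sequence`, `protein_id`,
#'   `probability`, `condition`, `fraction`, values the report's column
#'   headers. Missing entries fall back to the defaults
#'   `Peptide`/`Protein`/`Probability`/`Condition`/`Fraction`.
#' @param label Label for the returned population.
#' @param condition,fraction Values used when the report lacks the
#'   corresponding column.
#' @return A [peptide_population()] with an extra logical column
#'   `modified` and attributes `n_unparseable_probability`.
#' @export
read_peptide_report <- function(path, column_map = NULL, label = basename(path),
                                condition = "other", fraction = "synthetic") {
  if (!file.exists(path))
    stop("report not found: ", path, call. = FALSE)
  defaults <- c(sequence = "Peptide", protein_id = "Protein",
                probability = "Probability", condition = "Condition",
                fraction = "Fraction")
  map <- defaults
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  header <- readLines(path, n = 50L)
  header <- header[!startsWith(header, "#")][1L]
  sep <- if (lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE))) >=
             lengths(regmatches(header, gregexpr(",", header, fixed = TRUE))))
    "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           check.names = FALSE, quote = "\"")
  if (!map[["sequence"]] %in% names(tab))
    stop("report lacks a peptide-sequence column '", map[["sequence"]],
         "'; columns seen: ", paste(names(tab), collapse = ", "),
         call. = FALSE)
  raw_seq <- as.character(tab[[map[["sequence"]]]])
  bare <- strip_modifications(raw_seq)
  get <- function(field, fallback) {
    col <- map[[field]]
    if (col %in% names(tab)) tab[[col]] else fallback
  }
  prob_raw <- get("probability", NA)
  prob <- suppressWarnings(as.numeric(prob_raw))
  n_unparseable <- sum(!is.na(prob_raw) & nzchar(as.character(prob_raw)) &
                         is.na(prob))
  pop <- peptide_population(
    sequence = bare,
    protein_id = as.character(get("protein_id", NA_character_)),
    probability = prob,
    condition = as.character(get("condition", condition)),
    fraction = as.character(get("fraction", fraction)),
    label = label)
  pop$modified <- bare != raw_seq
  pop$valid[is.na(prob) & !is.na(prob_raw) &
              nzchar(as.character(prob_raw))] <- FALSE
  attr(pop, "n_unparseable_probability") <- n_unparseable
  if (n_unparseable)
    warning(n_unparseable, " probability value(s) could not be parsed; ",
            "rows flagged invalid, not dropped", call. = FALSE)
  pop
}

#' Write a peptide population as a TSV report
#'
#' Output is tab-separated with a header row; an optional metadata header
#' of `#`-prefixed lines records how the table was produced.
#'
#' @param pop A [peptide_population()].
#' @param path Output path.
#' @param metadata Optional named list written as `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_peptide_report <- function(pop, path, metadata = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(metadata))
    writeLines(sprintf("# %s: %s", names(metadata),
                       vapply(metadata, paste, "", collapse = ",")), con)
  cols <- data.frame(Peptide = pop$sequence, Protein = pop$protein_id,
                     Probability = pop$probability,
                     Condition = pop$condition, Fraction = pop$fraction,
                     stringsAsFactors = FALSE)
  utils::write.table(cols, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Filter peptides on identification probability
#'
#' Retains exactly the peptides whose probability is greater than or
#' equal to `threshold` (inclusive: removing "probability less than the
#' threshold" keeps the boundary). Peptides lacking a probability are
#' dropped and their count recorded in the `n_dropped_missing` attribute.
#'
#' @param pop A [peptide_population()].
#' @param threshold Probability cutoff in `[0, 1]`; default 0.99.
#' @return The filtered population, with attributes `n_dropped_missing`
#'   and `n_dropped_below`.
#' @export
filter_by_probability <- function(pop, threshold = 0.99) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  missing <- is.na(pop$probability)
  keep <- !missing & pop$probability >= threshold
  out <- pop[keep, , drop = FALSE]
  attr(out, "label") <- attr(pop, "label")
  class(out) <- class(pop)
  attr(out, "n_dropped_missing") <- sum(missing)
  attr(out, "n_dropped_below") <- sum(!missing & !keep)
  if (any(missing))
    warning(sum(missing), " peptide(s) without probability dropped",
            call. = FALSE)
  out
}
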