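# Sliding-window motif generation, frequency-filtered catalogues, and
# cross-condition comparison by normalized Hamming distance.

#' Contiguous sequence windows of a peptide
#'
#' All `L - N + 1` contiguous substrings of length `N`, in N-to-C
#' order. `N` must not exceed the peptide length.
#'
#' @param peptide A peptide sequence.
#' @param N Window length (>= 1).
#' @return Character vector of windows.
#' @export
generate_windows <- function(peptide, N) {
  L <- nchar(peptide)
  if (N < 1L) stop("window length must be >= 1", call. = FALSE)
  if (N > L)
    stop("window length ", N, " exceeds peptide length ", L, call. = FALSE)
  starts <- seq_len(L - N + 1L)
  substring(peptide, starts, starts + N - 1L)
}

#' Build a frequency-filtered motif catalogue
#'
#' Pools window counts per condition over a population, then removes
#' motifs whose pooled count falls below `min_count`. Every window of
#' every peptide is counted with multiplicity by default; with
#' `per_peptide_unique = TRUE` a motif counts at most once per peptide.
#' Provenance (which peptides contributed each motif) is retained.
#'
#' @param pop A nonempty [peptide_population()].
#' @param N Window length; peptides shorter than `N` are skipped and
#'   counted in the `n_skipped` attribute.
#' @param min_count Minimum pooled count for a motif to be kept;
#'   default 2 (the lightest possible frequency filter).
#' @param per_peptide_unique Count each motif at most once per peptide.
#' @return An object of class `motif_catalog`: a list with `N`,
#'   `counts` (matrix, motifs x conditions), `total` (pooled counts),
#'   and `provenance` (list of contributing peptide row indices).
#' @export
build_catalog <- function(pop, N, min_count = 2L,
                          per_peptide_unique = FALSE) {
  if (!nrow(pop)) stop("empty population", call. = FALSE)
  stopifnot(min_count >= 1L)
  ok <- nchar(pop$sequence) >= N
  rows <- which(ok)
  if (!length(rows))
    stop("no peptides of length >= ", N, call. = FALSE)
  win <- lapply(rows, function(i) {
    w <- generate_windows(pop$sequence[i], N)
    if (per_peptide_unique) unique(w) else w
  })
  motif <- unlist(win, use.names = FALSE)
  peprow <- rep(rows, lengths(win))
  cond <- pop$condition[peprow]
  counts <- table(motif, factor(cond, levels = sort(unique(pop$condition))))
  counts <- as.matrix(unclass(counts))
  total <- rowSums(counts)
  keep <- total >= min_count
  prov <- split(peprow, motif)
  structure(list(N = as.integer(N),
                 counts = counts[keep, , drop = FALSE],
                 total = total[keep],
                 provenance = prov[names(total)[keep]],
                 min_count = as.integer(min_count),
                 per_peptide_unique = per_peptide_unique),
            n_skipped = sum(!ok),
            class = "motif_catalog")
}

#' @export
print.motif_catalog <- function(x, ...) {
  cat(sprintf("motif_catalog: N=%d, %d motifs (min_count=%d) over conditions %s\n",
              x$N, nrow(x$counts), x$min_count,
              paste(colnames(x$counts), collapse = ", ")))
  top <- utils::head(x$total[order(-x$total, names(x$total))], 10L)
  if (length(top)) {
    cat("  top motifs:",
        paste(sprintf("%s(%d)", names(top), top), collapse = " "), "\n")
  }
  invisible(x)
}

#' Normalized Hamming distance
#'
#' Fraction of positions at which two equal-length sequences differ;
#' a metric on fixed-length strings, in `[0, 1]`.
#'
#' @param a,b Sequences of equal length.
#' @return Distance in `[0, 1]`.
#' @export
normalized_hamming <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("Hamming distance undefined for unequal lengths (",
         nchar(a), " vs ", nchar(b), ")", call. = FALSE)
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  mean(ca != cb)
}

# Top-k motifs of one condition, by count descending then lexicographic.
.top_motifs <- function(cat, condition, top_k) {
  cnt <- cat$counts[, condition]
  cnt <- cnt[cnt > 0]
  ord <- order(-cnt, names(cnt))
  names(cnt)[ord][seq_len(min(top_k, length(cnt)))]
}

#' Compare frequent motifs across digestion conditions
#'
#' Takes each condition's `top_k` most frequent motifs (ties broken
#' lexicographically) and reports every cross-condition pair whose
#' normalized Hamming distance is at most `max_distance`, sorted by
#' distance then lexicographically.
#'
#' @param cat A [build_catalog()] result with at least two conditions.
#' @param top_k Number of most frequent motifs per condition.
#' @param max_distance Maximum normalized Hamming distance reported.
#' @return Data frame with columns `condition_a`, `motif_a`,
#'   `condition_b`, `motif_b`, `distance`.
#' @export
cross_condition_compare <- function(cat, top_k = 50L, max_distance = 0.4) {
  conds <- colnames(cat$counts)
  if (length(conds) < 2L)
    stop("cross-condition comparison needs >= 2 conditions, found: ",
         paste(conds, collapse = ", "), call. = FALSE)
  out <- list()
  for (i in seq_len(length(conds) - 1L)) for (j in (i + 1L):length(conds)) {
    ma <- .top_motifs(cat, conds[i], top_k)
    mb <- .top_motifs(cat, conds[j], top_k)
    if (!length(ma) || !length(mb)) next
    grid <- expand.grid(motif_a = ma, motif_b = mb,
                        stringsAsFactors = FALSE)
    grid$distance <- mapply(normalized_hamming, grid$motif_a, grid$motif_b)
    grid <- grid[grid$distance <= max_distance, , drop = FALSE]
    if (nrow(grid)) {
      grid$condition_a <- conds[i]
      grid$condition_b <- conds[j]
      out[[length(out) + 1L]] <- grid
    }
  }
  if (!length(out))
    return(data.frame(condition_a = character(0), motif_a = character(0),
                      condition_b = character(0), motif_b = character(0),
                      distance = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$distance, res$motif_a, res$motif_b), ,
             drop = FALSE]
  rownames(res) <- NULL
  res[, c("condition_a", "motif_a", "condition_b", "motif_b", "distance")]
}

#' Core motifs shared by two populations
#'
#' Length-`N` windows present (count >= 1) in both populations — the
#' conserved cores that appear under both digestion schemes.
#'
#' @param popA,popB Nonempty [peptide_population()]s (or character
#'   vectors of sequences).
#' @param N Window length.
#' @return Sorted character vector of shared motifs.
#' @export
shared_cores <- function(popA, popB, N) {
  winset <- function(pop) {
    seqs <- if (is.character(pop)) pop else pop$sequence
    seqs <- seqs[nchar(seqs) >= N]
    unique(unlist(lapply(seqs, generate_windows, N = N),
                  use.names = FALSE))
  }
  sort(intersect(winset(popA), winset(popB)))
}

#' Write a motif catalogue as TSV
#'
#' @param cat A [build_catalog()] result.
#' @param path Output path.
#' @param metadata Optional named list of `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(cat, path, metadata = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(list(N = cat$N, min_count = cat$min_count,
                 per_peptide_unique = cat$per_peptide_unique), metadata)
  writeLines(sprintf("# %s: %s", names(meta),
                     vapply(meta, paste, "", collapse = ",")), con)
  ord <- order(-cat$total, names(cat$total))
  tab <- data.frame(motif = names(cat$total)[ord],
                    total = as.integer(cat$total[ord]),
                    cat$counts[ord, , drop = FALSE],
                    check.names = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
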