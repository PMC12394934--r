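# Independent oracles and fixture builders used across the suite.

# Random peptide sequences drawn uniformly over the canonical alphabet.
random_peptides <- function(n, len_range = c(5L, 30L), seed = 1L) {
  set.seed(seed)
  lens <- sample(len_range[1L]:len_range[2L], n, replace = TRUE)
  vapply(lens, function(L)
    paste(sample(amino_acids(), L, replace = TRUE), collapse = ""), "")
}

# Brute-force digestion oracle: tests EVERY substring (i, j) of the
# protein against the cleavage-site definition, independently of how
# digest() builds fragments. A substring is a valid peptide iff its
# start follows a cleavage site (or the N-terminus), its end is a
# cleavage site (or the C-terminus), it contains at most `missed`
# internal cleavage sites, and it satisfies the length bounds.
brute_digest <- function(protein, p1, missed, min_len = 1L,
                         max_len = Inf) {
  chars <- strsplit(protein, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  sites <- which(chars[-L] %in% p1)   # cut after position s
  out <- character(0)
  for (i in seq_len(L)) for (j in i:L) {
    start_ok <- (i == 1L) || ((i - 1L) %in% sites)
    end_ok <- (j == L) || (j %in% sites)
    internal <- sum(sites >= i & sites < j)
    len <- j - i + 1L
    if (start_ok && end_ok && internal <= missed &&
        len >= min_len && len <= max_len)
      out <- c(out, substr(protein, i, j))
  }
  out
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# choose(n, nx) rank assignments (no ties assumed).
mwu_enum_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  u_all <- apply(combos, 2L, function(ix) sum(ix) - nx * (nx + 1) / 2)
  center <- nx * ny / 2
  p <- mean(abs(u_all - center) >= abs(u_obs - center) - 1e-9)
  list(U = u_obs, p = p)
}

# Two-sample KS statistic straight from the ECDF definition.
ks_d_oracle <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(grid) - stats::ecdf(y)(grid)))
}

# A small two-condition peptide report: 40 peptides, both conditions
# embedding the shared cores ASEGG and HWPLPPF, three peptides below
# probability 0.99. Returns the file path.
write_fixture_report <- function(path, seed = 42L) {
  set.seed(seed)
  embed <- function(core, n) {
    vapply(seq_len(n), function(i) {
      pre <- paste(sample(amino_acids(), sample(1:4, 1), TRUE),
                   collapse = "")
      post <- paste(sample(amino_acids(), sample(1:4, 1), TRUE),
                    collapse = "")
      paste0(pre, core, post)
    }, "")
  }
  seqs <- c(embed("ASEGG", 10), embed("HWPLPPF", 10),
            random_peptides(20, c(6L, 15L), seed = seed + 1L))
  cond <- rep(c("pep_tryp", "papain"), 20)
  prob <- rep(0.999, 40)
  prob[c(3, 17, 33)] <- c(0.95, 0.80, 0.42)
  tab <- data.frame(Peptide = seqs, Protein = "synthetic",
                    Probability = prob, Condition = cond,
                    Fraction = "E", stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# A reproducible tryptic peptide population of exactly n peptides from
# rice-bran-like random proteins (fully cleaved, lengths 5-30).
tryptic_population <- function(n = 2000L, seed = 1L) {
  prots <- random_proteins(ceiling(n / 20), seed = seed)
  pop <- digest_proteins(prots,
                         enzyme_rule("trypsin", max_missed_cleavages = 0,
                                     min_length = 5, max_length = 30),
                         condition = "pep_tryp")
  while (nrow(pop) < n) {
    prots <- random_proteins(20, seed = seed + nrow(pop))
    extra <- digest_proteins(prots,
                             enzyme_rule("trypsin",
                                         max_missed_cleavages = 0,
                                         min_length = 5, max_length = 30),
                             condition = "pep_tryp")
    pop <- peptide_population(c(pop$sequence, extra$sequence),
                              condition = "pep_tryp", label = "tryptic")
  }
  out <- pop[seq_len(n), , drop = FALSE]
  class(out) <- class(pop)
  attr(out, "label") <- "tryptic"
  out
}

# Vectorized, unnamed wrapper over the scalar Hamming distance.
hamming_vec <- function(a, b)
  mapply(normalized_hamming, a, b, USE.NAMES = FALSE)
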