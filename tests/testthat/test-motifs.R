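test_that("window generation enumerates contiguous substrings N to C", {
  expect_equal(generate_windows("ASEGG", 3), c("ASE", "SEG", "EGG"))
  expect_equal(generate_windows("ASEGG", 5), "ASEGG")
  expect_error(generate_windows("ASEGG", 6), "exceeds")
  expect_error(generate_windows("ASEGG", 0), ">= 1")
  for (s in random_peptides(20, seed = 97))
    for (N in c(2L, 5L))
      expect_length(generate_windows(s, N), nchar(s) - N + 1L)
})

test_that("catalogues count windows with multiplicity and filter on pooled frequency", {
  pop <- peptide_population(c("ABCD", "XBCD"),
                            condition = c("pep_tryp", "papain"))
  # only BCD occurs twice across the population
  filtered <- suppressWarnings(build_catalog(pop, 3, min_count = 2))
  expect_equal(names(filtered$total), "BCD")
  expect_equal(unname(filtered$total), 2)

  full <- suppressWarnings(build_catalog(pop, 3, min_count = 1))
  expect_equal(sort(names(full$total)), c("ABC", "BCD", "XBC"))
  expect_equal(sort(unique(unlist(full$provenance$BCD))), c(1L, 2L))
})

test_that("total window multiplicity equals the combinatorial count", {
  pop <- peptide_population(random_peptides(300, seed = 101))
  for (N in c(5L, 6L, 7L)) {
    cat_n <- build_catalog(pop, N, min_count = 1)
    expect_equal(sum(cat_n$total),
                 sum(pmax(nchar(pop$sequence) - N + 1L, 0L)))
  }
})

test_that("catalogue counts are order-invariant and double under duplication", {
  seqs <- random_peptides(100, seed = 103)
  pop <- peptide_population(seqs)
  rev_pop <- peptide_population(rev(seqs))
  a <- build_catalog(pop, 5, min_count = 1)
  b <- build_catalog(rev_pop, 5, min_count = 1)
  expect_equal(a$total[sort(names(a$total))],
               b$total[sort(names(b$total))])
  doubled <- build_catalog(peptide_population(c(seqs, seqs)), 5,
                           min_count = 1)
  expect_equal(doubled$total[names(a$total)], 2 * a$total)
  ord <- function(x) names(sort(-x))
  expect_equal(ord(doubled$total), ord(a$total))
})

test_that("normalized Hamming distance handles the boundary cases", {
  expect_equal(normalized_hamming("AAA", "AAA"), 0)
  expect_equal(normalized_hamming("AAA", "TTT"), 1)
  expect_equal(normalized_hamming("HWP", "HWA"), 1 / 3)
  expect_error(normalized_hamming("AA", "AAA"), "unequal")
})

test_that("normalized Hamming distance satisfies the metric axioms", {
  set.seed(107)
  n_triples <- 2000L
  L <- 6L
  mk <- function() paste(sample(amino_acids(), L, TRUE), collapse = "")
  for (i in seq_len(n_triples)) {
    a <- mk(); b <- mk(); cc <- mk()
    dab <- normalized_hamming(a, b)
    dba <- normalized_hamming(b, a)
    expect_identical(dab, dba)
    expect_identical(normalized_hamming(a, a), 0)
    expect_true(dab <= normalized_hamming(a, cc) +
                  normalized_hamming(cc, b) + 1e-12)
    if (dab == 0) expect_identical(a, b)
  }
})

test_that("cross-condition comparison reports close motif pairs sorted by distance", {
  pop <- peptide_population(
    c("AAASEGGR", "KASEGGW", "GASEGGH", "PASEGGY"),
    condition = c("pep_tryp", "pep_tryp", "papain", "papain"))
  cat5 <- build_catalog(pop, 5, min_count = 1)
  pairs <- cross_condition_compare(cat5, top_k = 10, max_distance = 0.4)
  expect_equal(pairs$motif_a[1], "ASEGG")
  expect_equal(pairs$motif_b[1], "ASEGG")
  expect_equal(pairs$distance[1], 0)
  expect_true(!is.unsorted(pairs$distance))

  verbatim <- cross_condition_compare(cat5, top_k = 10, max_distance = 0)
  expect_true(all(verbatim$motif_a == verbatim$motif_b))

  single <- peptide_population(c("ASEGGK"), condition = "pep_tryp")
  expect_error(cross_condition_compare(build_catalog(single, 5,
                                                     min_count = 1)),
               ">= 2 conditions")
})

test_that("shared cores are the symmetric substring intersection", {
  popA <- c("KKHWPLPPFGG", "AAAAA")
  popB <- c("RHWPLPPFY", "CCCCC")
  cores <- shared_cores(popA, popB, 7)
  expect_true("HWPLPPF" %in% cores)
  expect_equal(shared_cores(popA, popB, 7), shared_cores(popB, popA, 7))
  expect_length(shared_cores("AAAAA", "CCCCC", 3), 0)
})

test_that("per-peptide-unique mode counts a motif once per peptide", {
  pop <- peptide_population("GGGGGG")   # five GG windows in one peptide
  multi <- build_catalog(pop, 2, min_count = 1)
  uniq <- build_catalog(pop, 2, min_count = 1, per_peptide_unique = TRUE)
  expect_equal(unname(multi$total["GG"]), 5)
  expect_equal(unname(uniq$total["GG"]), 1)
})

test_that("catalogues write to TSV ordered by pooled count", {
  pop <- peptide_population(random_peptides(50, seed = 109))
  cat5 <- build_catalog(pop, 5, min_count = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(cat5, f)
  tab <- utils::read.delim(f, comment.char = "#")
  expect_equal(nrow(tab), length(cat5$total))
  expect_true(!is.unsorted(-tab$total))
})
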