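test_that("FASTA records are parsed, wrapped lines concatenated, and odd residues flagged", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "MKR",
               ">p2 some description", "MKGG", "HHAA",
               ">p3", "MKXR"), f)
  rec <- read_fasta(f)
  expect_equal(rec$protein_id, c("p1", "p2", "p3"))
  expect_equal(rec$sequence[1], "MKR")
  expect_equal(rec$sequence[2], "MKGGHHAA")   # two lines joined
  expect_equal(rec$valid, c(TRUE, TRUE, FALSE))

  expect_error(read_fasta(file.path(tempdir(), "absent.fasta")),
               "not found")
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), "no FASTA records")
})

test_that("FASTA round-trips through write_fasta", {
  prot <- data.frame(protein_id = c("a", "b"),
                     sequence = c(paste(rep("MKRGH", 30), collapse = ""),
                                  "GG"))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(prot, f, width = 60)
  back <- read_fasta(f)
  expect_equal(back$protein_id, prot$protein_id)
  expect_equal(back$sequence, prot$sequence)
})

test_that("peptide reports parse with modification stripping and flexible columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Peptide\tProtein\tProbability",
               "HWPLPPF\tp1\t0.995",
               "AS[+42.0106]EGG\tp1\t1.0",
               "gGHH\tp2\t0.98"), f)
  pop <- read_peptide_report(f)
  expect_s3_class(pop, "peptide_population")
  expect_equal(nrow(pop), 3L)
  expect_equal(pop$sequence, c("HWPLPPF", "ASEGG", "GGHH"))
  expect_equal(pop$probability, c(0.995, 1.0, 0.98))
  expect_equal(pop$modified, c(FALSE, TRUE, TRUE))

  # strip-annotation oracle on hand-built strings
  cases <- c("AS[+42.0106]EGG" = "ASEGG",
             "n[-17.0265]QGHH" = "QGHH",
             "M(UniMod:35)KR" = "MKR",
             "PLAIN" = "PLAIN")
  expect_equal(strip_modifications(names(cases)), unname(cases))
})

test_that("delimiter auto-detection accepts CSV and a column map overrides headers", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("seq,prob", "MKR,0.999", "GGH,0.5"), f)
  pop <- read_peptide_report(f, column_map = c(sequence = "seq",
                                               probability = "prob"))
  expect_equal(pop$sequence, c("MKR", "GGH"))
  expect_equal(pop$probability, c(0.999, 0.5))

  expect_error(read_peptide_report(f), "peptide-sequence column")
})

test_that("unparseable probabilities flag rows instead of dropping them", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Peptide\tProbability", "MKR\t0.999", "GGH\tn/a"), f)
  expect_warning(pop <- read_peptide_report(f), "could not be parsed")
  expect_equal(nrow(pop), 2L)
  expect_true(is.na(pop$probability[2]))
  expect_false(pop$valid[2])
  expect_equal(attr(pop, "n_unparseable_probability"), 1L)
})

test_that("probability filtering is inclusive at the threshold and accounts for missing values", {
  pop <- peptide_population(c("MKR", "GGH", "HHA"),
                            probability = c(0.98, 0.99, 1.0))
  kept <- filter_by_probability(pop, 0.99)
  expect_equal(nrow(kept), 2L)           # 0.99 itself retained
  expect_equal(kept$sequence, c("GGH", "HHA"))
  expect_equal(attr(kept, "n_dropped_below"), 1L)

  all_kept <- filter_by_probability(pop, 0)
  expect_equal(nrow(all_kept), 3L)

  missing <- peptide_population(c("MKR", "GGH"))
  expect_warning(none <- filter_by_probability(missing, 0.99),
                 "without probability")
  expect_equal(nrow(none), 0L)
  expect_equal(attr(none, "n_dropped_missing"), 2L)
})

test_that("probability filtering is idempotent and monotone in the threshold", {
  set.seed(11)
  pop <- peptide_population(random_peptides(50, seed = 11),
                            probability = round(runif(50), 3))
  counts <- vapply(seq(0, 1, by = 0.1), function(th)
    nrow(suppressWarnings(filter_by_probability(pop, th))), 0L)
  expect_true(all(diff(counts) <= 0))
  once <- filter_by_probability(pop, 0.5)
  twice <- filter_by_probability(once, 0.5)
  expect_equal(once$sequence, twice$sequence)
})

test_that("a population round-trips through write_peptide_report", {
  pop <- peptide_population(c("HWPLPPF", "ASEGG"),
                            protein_id = c("p1", "p2"),
                            probability = c(0.995, 1),
                            condition = c("pep_tryp", "papain"),
                            fraction = c("E", "FT"), label = "rt")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_peptide_report(pop, f, metadata = list(seed = 1))
  back <- read_peptide_report(f, label = "rt")
  expect_equal(back$sequence, pop$sequence)
  expect_equal(back$probability, pop$probability)
  expect_equal(back$condition, pop$condition)
  expect_equal(back$fraction, pop$fraction)
})

test_that("population constructor validates labels and probabilities", {
  expect_error(peptide_population("MKR", condition = "tryp"),
               "unknown label")
  expect_error(peptide_population("MKR", probability = 1.2), "\\[0, 1\\]")
  pop <- peptide_population(c("MKR", "MXR"))
  expect_equal(pop$valid, c(TRUE, FALSE))
})
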