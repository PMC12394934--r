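test_that("global composition pools residues over the population", {
  comp <- global_composition(c("GG", "PP"))
  expect_equal(unname(unclass(comp)[c("G", "P", "A")]), c(50, 50, 0))
  expect_equal(sum(unclass(comp)), 100, tolerance = 1e-6)
  expect_equal(attr(comp, "total_residues"), 4L)

  single <- global_composition("H")
  expect_equal(unname(unclass(single)["H"]), 100)

  pop <- random_peptides(40, seed = 61)
  expect_equal(as.numeric(unclass(global_composition(pop))),
               as.numeric(unclass(global_composition(c(pop, pop)))))
  expect_error(global_composition(character(0)), "empty")
})

test_that("enrichment ratios divide observed by background percent", {
  obs <- global_composition(c("GGHH"))
  bg <- c(G = 25, H = 25)
  bg_full <- stats::setNames(rep(2.5, 20), amino_acids())
  bg_full[c("G", "H")] <- 25
  r <- enrichment_ratio(obs, bg_full)
  expect_equal(unname(r["G"]), 2.0)   # 50% observed over 25% background
  expect_equal(unname(r["A"]), 0)
  r_self <- enrichment_ratio(obs, unclass(obs))
  expect_true(all(r_self[unclass(obs) > 0] == 1))
  expect_true(all(is.na(r_self[unclass(obs) == 0])))

  # mid-range worked example: 14% observed over 2% background
  expect_equal(14 / 2, 7)
})

test_that("positional matrices count peptides per terminal position", {
  m <- positional_matrix(c("HAGLY", "GAGLY"))
  expect_equal(unname(m["H", "N1"]), 50)
  expect_equal(unname(m["G", "N1"]), 50)
  expect_equal(unname(m["A", "N2"]), 100)
  # length-5 peptide: middle residue feeds both N3 and C3
  expect_equal(unname(m["G", "N3"]), 100)
  expect_equal(unname(m["G", "C3"]), 100)
  expect_equal(colnames(m), c("N1", "N2", "N3", "C3", "C2", "C1"))
})

test_that("every positional column sums to 100 and short peptides are counted out", {
  pops <- list(random_peptides(100, seed = 67),
               random_peptides(50, c(5L, 8L), seed = 71),
               c("HAGLY", "GAGLY", "AAA"))
  for (p in pops) {
    m <- positional_matrix(p)
    expect_equal(unname(colSums(m)), rep(100, 6), tolerance = 1e-6)
  }
  m <- positional_matrix(c("HAGLY", "GAGLY", "AAA"))
  expect_equal(attr(m, "n_excluded"), 1L)
  expect_equal(attr(m, "n_peptides"), 2L)
  expect_error(positional_matrix(c("AAA", "GG")), "length >= 5")
})

test_that("pooled matrix is the peptide-count-weighted mean of per-condition matrices", {
  pop <- peptide_population(random_peptides(120, seed = 73),
                            condition = rep(c("pep_tryp", "papain"),
                                            c(80, 40)))
  mats <- positional_matrix_by_condition(pop)
  expect_setequal(names(mats), c("pep_tryp", "papain", "pooled"))
  na <- attr(mats$pep_tryp, "n_peptides")
  nb <- attr(mats$papain, "n_peptides")
  pooled <- (na * unclass(mats$pep_tryp) + nb * unclass(mats$papain)) /
    (na + nb)
  expect_equal(unclass(mats$pooled), pooled,
               ignore_attr = TRUE, tolerance = 1e-9)

  one <- pop[pop$condition == "papain", , drop = FALSE]
  m1 <- positional_matrix_by_condition(one)
  expect_equal(unclass(m1$papain), unclass(m1$pooled), ignore_attr = TRUE)
})

test_that("per-condition N1-His rates recover the generating frequencies", {
  set.seed(79)
  mk <- function(n, p_his) {
    first <- ifelse(runif(n) < p_his, "H",
                    sample(setdiff(amino_acids(), "H"), n, TRUE))
    paste0(first, random_peptides(n, c(7L, 12L), seed = 83))
  }
  pop <- peptide_population(c(mk(500, 0.5), mk(500, 0.1)),
                            condition = rep(c("pep_tryp", "papain"),
                                            each = 500))
  mats <- positional_matrix_by_condition(pop)
  ci <- function(p, n) 1.96 * sqrt(p * (1 - p) / n) * 100
  expect_lt(abs(mats$pep_tryp["H", "N1"] - 50), ci(0.5, 500))
  expect_lt(abs(mats$papain["H", "N1"] - 10), ci(0.1, 500))
})

test_that("positional matrices write to TSV with their metadata header", {
  m <- positional_matrix(random_peptides(20, seed = 89))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_positional_matrix(m, f, metadata = list(condition = "pooled"))
  lines <- readLines(f)
  expect_true(any(grepl("^# n_peptides: 20", lines)))
  tab <- utils::read.delim(f, comment.char = "#")
  expect_equal(nrow(tab), 20L)
  expect_equal(tab$residue, amino_acids())
})

test_that("the shipped background profile loads and matches the generator default", {
  f <- system.file("extdata", "rice_bran_background.tsv", package = "cupep")
  bg <- read_background_profile(f)
  expect_equal(bg[amino_acids()], rice_bran_background()[amino_acids()])
  expect_equal(sum(bg), 100)
})
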