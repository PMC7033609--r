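test_that("genotype classification follows the diagnostic priority rules", {
  expect_equal(unname(classifyGenotype(0, 2)), "M1M1")
  expect_equal(unname(classifyGenotype(4, 0)), "M2M2")
  expect_equal(unname(classifyGenotype(1, 2)), "HET_DEL")
  expect_equal(unname(classifyGenotype(2, 3)), "NORMAL_2")
  expect_equal(unname(classifyGenotype(5, 1)), "MULTI")
  expect_equal(unname(classifyGenotype(0, 0)), "NULL_BOTH")
  expect_error(classifyGenotype(2), "SMN2_e7")
  expect_error(classifyGenotype(-1, 2), "non-negative")
})

test_that("classification is total and single-valued over all copy pairs", {
  grid <- expand.grid(s1 = 0:8, s2 = 0:8)
  lab <- classifyGenotype(grid$s1, grid$s2)
  expect_true(all(lab %in% c("M1M1", "M2M2", "HET_DEL", "NORMAL_2",
                             "MULTI", "NULL_BOTH")))
  expect_length(lab, nrow(grid))
  # priority spot checks
  expect_equal(unname(lab[grid$s1 == 0 & grid$s2 == 0]), "NULL_BOTH")
  expect_true(all(lab[grid$s1 == 0 & grid$s2 > 0] == "M1M1"))
  expect_true(all(lab[grid$s1 > 0 & grid$s2 == 0] == "M2M2"))
})

test_that("cohort fixtures reproduce every published bin count exactly", {
  binfile <- system.file("extdata", "cohort_bins.tsv", package = "SMNcnv")
  bins <- read.delim(binfile)
  smn <- c("SMN1_e7", "SMN1_e8", "SMN2_e7", "SMN2_e8")
  for (grp in unique(bins$group)) {
    cn <- readCopyNumbers(file.path(fixtureDir(),
                                    sprintf("cohort_%s.tsv", grp)))
    s <- summarizeCohort(cn, grp)
    for (r in smn) {
      want <- bins[bins$group == grp & bins$region == r,
                   c("b0", "b1", "b2", "bgt2")]
      got <- s$count[s$region == r]
      expect_equal(got, as.integer(want), info = paste(grp, r))
      expect_equal(sum(got), unique(s$n), info = paste(grp, r))
    }
  }
})

test_that("percentages use one-decimal half-up rounding like the published table", {
  expect_equal(cohortPercentages(62, 122), 50.8)
  expect_equal(cohortPercentages(0, 122), 0.0)
  expect_equal(cohortPercentages(33, 122), 27.0)
  expect_equal(cohortPercentages(1, 8), 12.5)
  expect_equal(cohortPercentages(5, 1000), 0.5)   # 0.5 rounds up, not to even
  s <- summarizeCohort(readCopyNumbers(file.path(fixtureDir(),
                                                 "cohort_NNw.tsv")), "NNw")
  p <- cohortPercentages(s)
  expect_equal(p$pct[p$region == "SMN1_e7" & p$bin == "2"], 96.7)
})

test_that("single-sample summaries and empty-input errors behave", {
  m <- matrix(c(2L, 2L, 2L, 2L), ncol = 1,
              dimnames = list(c("SMN1_e7", "SMN1_e8", "SMN2_e7", "SMN2_e8"),
                              "S1"))
  s <- summarizeCohort(m)
  expect_equal(s$count[s$bin == "2"], rep(1L, 4))
  expect_error(summarizeCohort(m[, 0, drop = FALSE]), "empty")
})
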