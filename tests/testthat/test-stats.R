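test_that("Kruskal-Wallis reproduces the hand-computed no-tie case", {
  kw <- kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$H, 3.857, tolerance = 5e-4)
  expect_equal(kw$df, 1L)
  kw0 <- kruskalWallis(list(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(kw0$H, 0)
  expect_equal(kw0$p, 1)
  expect_error(kruskalWallis(list(1:3)), "2 groups")
  expect_error(kruskalWallis(c(1, 2), c("a", "b")), "3 observations")
})

test_that("tie-corrected H matches the reference implementation on copy numbers", {
  set.seed(51)
  for (i in 1:60) {
    g1 <- sample(0:4, 25, replace = TRUE)
    g2 <- sample(0:5, 35, replace = TRUE)
    g3 <- sample(1:3, 15, replace = TRUE)
    vals <- c(g1, g2, g3)
    grp <- rep(1:3, c(25, 35, 15))
    kw <- kruskalWallis(vals, grp)
    ref <- kruskal.test(vals, factor(grp))
    expect_equal(kw$H, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(kw$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("H is invariant under strictly monotone transformations", {
  set.seed(52)
  vals <- sample(0:6, 40, replace = TRUE)
  grp <- rep(1:2, each = 20)
  h1 <- kruskalWallis(vals, grp)$H
  h2 <- kruskalWallis(exp(vals), grp)$H
  h3 <- kruskalWallis(vals^3 + 7, grp)$H
  expect_equal(h1, h2, tolerance = 1e-12)
  expect_equal(h1, h3, tolerance = 1e-12)
})

test_that("Pearson chi-square matches hand computation and the reference", {
  flat <- matrix(10, 2, 2)
  r <- pearsonChi2(flat)
  expect_equal(r$chisq, 0)
  expect_equal(r$p, 1)

  audit <- matrix(c(123, 9, 868, 183), 2)
  r2 <- pearsonChi2(audit)
  expect_equal(round(r2$chisq, 2), 9.68)
  expect_equal(r2$df, 1L)
  ref <- chisq.test(audit, correct = FALSE)
  expect_equal(r2$chisq, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(r2$p, ref$p.value, tolerance = 1e-9)

  ry <- pearsonChi2(audit, yates = TRUE)
  refy <- chisq.test(audit, correct = TRUE)
  expect_equal(ry$chisq, unname(refy$statistic), tolerance = 1e-9)

  expect_error(pearsonChi2(matrix(c(0, 0, 5, 5), 2)), "margin")
  expect_error(pearsonChi2(matrix(1:3, 1)), "2x2")
})

test_that("random tables agree with reference implementations to 1e-9", {
  set.seed(53)
  for (i in 1:100) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    r <- pearsonChi2(tab)
    ref <- chisq.test(tab, correct = FALSE)
    expect_equal(r$chisq, unname(ref$statistic), tolerance = 1e-9)
  }
})

test_that("cohort comparison flags gross differences and none under self-comparison", {
  a <- readCopyNumbers(file.path(fixtureDir(), "cohort_NNb.tsv"))
  b <- readCopyNumbers(file.path(fixtureDir(), "cohort_NNw.tsv"))
  res <- compareGroups(a, b)
  expect_true(res$significant[res$region == "SMN1_e7"])
  self <- compareGroups(a, a)
  expect_false(any(self$significant))
  expect_true(all(self$H == 0))
})

test_that("pre-binned copy-number input is rejected, not approximated", {
  df <- data.frame(sample_id = c("s1", "s2"),
                   SMN1_e7 = c("2", ">2"), stringsAsFactors = FALSE)
  b <- readCopyNumbers(file.path(fixtureDir(), "cohort_NNw.tsv"))
  expect_error(suppressWarnings(compareGroups(df, b, regions = "SMN1_e7")),
               "raw integer totals")
  a2 <- b + 0.5
  expect_error(compareGroups(a2, b), "raw integer totals")
})
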