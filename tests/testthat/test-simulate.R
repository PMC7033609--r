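test_that("population presets reproduce the published SMN1 exon-7 marginals", {
  set.seed(21)
  tb <- simulateCohort(blackModel(), 10000)$totals["SMN1_e7", ]
  expect_lt(abs(mean(tb > 2) - 0.508), 0.03)
  expect_lt(abs(mean(tb == 2) - 0.492), 0.03)
  tw <- simulateCohort(whiteModel(), 10000)$totals["SMN1_e7", ]
  expect_lt(abs(mean(tw == 2) - 0.967), 0.03)
})

test_that("point-mass models are deterministic and invalid frequencies refused", {
  m <- makePopulationModel(list(SMN1_e7 = c(0, 1, 0)), de_novo_rate = 0)
  d <- sampleDiplotype(m)
  expect_true(all(d$mat + d$pat ==
                  ifelse(smnRegions() %in% combinedRegions(), 4L, 2L)))
  expect_error(makePopulationModel(list(SMN1_e7 = c(0.5, 0.2))), "sum to 1")
  expect_error(makePopulationModel("martian"), "unknown preset")
})

test_that("explicit haplotype tables drive linked draws", {
  hap <- matrix(1L, nrow = 2, ncol = length(smnRegions()),
                dimnames = list(NULL, smnRegions()))
  hap[2, "SMN1_e7"] <- 3L
  m <- makePopulationModel(list(haplotypes = hap, freqs = c(0.5, 0.5)),
                           de_novo_rate = 0)
  set.seed(22)
  tot <- simulateCohort(m, 500)$totals["SMN1_e7", ]
  expect_true(all(tot %in% c(2L, 4L, 6L)))
  expect_lt(abs(mean(tot == 4) - 0.5), 3 * sqrt(0.25 / 500))
})

test_that("same seed reproduces the identical diplotype stream", {
  m <- blackModel()
  set.seed(23); d1 <- replicate(5, sampleDiplotype(m), simplify = FALSE)
  set.seed(23); d2 <- replicate(5, sampleDiplotype(m), simplify = FALSE)
  expect_identical(d1, d2)
})

test_that("empirical haplotype frequencies track the model within 3 binomial SD", {
  f <- c(0.2, 0.5, 0.3)
  m <- makePopulationModel(list(SMN1_e7 = f), de_novo_rate = 0)
  set.seed(24)
  n <- 4000
  draws <- vapply(seq_len(n), function(i) sampleDiplotype(m)$mat[["SMN1_e7"]],
                  integer(1))
  for (k in 0:2)
    expect_lt(abs(mean(draws == k) - f[k + 1]),
              3 * sqrt(f[k + 1] * (1 - f[k + 1]) / n))
})

test_that("transmission copies parental haplotypes exactly at rate zero", {
  m <- makePopulationModel("black_SA", de_novo_rate = 0)
  set.seed(25)
  ped <- simulatePedigree(m, n_children = 3)
  expect_equal(nrow(deNovoEvents(ped)), 0)
  fa <- ped@diplotypes$FA; mo <- ped@diplotypes$MO
  for (k in c("C1", "C2", "C3")) {
    expect_true(identical(ped@diplotypes[[k]]$pat, fa$mat) ||
                identical(ped@diplotypes[[k]]$pat, fa$pat))
    expect_true(identical(ped@diplotypes[[k]]$mat, mo$mat) ||
                identical(ped@diplotypes[[k]]$mat, mo$pat))
  }
})

test_that("rate one forces one recorded event per transmitted haplotype", {
  m <- makePopulationModel("black_SA", de_novo_rate = 1)
  set.seed(26)
  ped <- simulatePedigree(m, n_children = 1)
  expect_equal(nrow(deNovoEvents(ped)), 2)
  expect_setequal(deNovoEvents(ped)$parent, c("father", "mother"))
})

test_that("the family-level event rate matches its per-haplotype rate", {
  # P(family has >= 1 event) = 1 - (1 - r)^2 = 0.0327 at r = 0.0165
  m <- makePopulationModel("black_SA", de_novo_rate = 0.0165)
  set.seed(27)
  reps <- 250
  hits <- vapply(seq_len(reps), function(i)
    sum(vapply(seq_len(61), function(j)
      nrow(deNovoEvents(simulatePedigree(m, 1))) > 0, logical(1))),
    numeric(1))
  pfam <- 1 - (1 - 0.0165)^2
  expect_lt(abs(mean(hits) - 61 * pfam),
            4 * sqrt(61 * pfam * (1 - pfam) / reps))
})

test_that("fixture generation is fully deterministic", {
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  makeFixtures(d1); makeFixtures(d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("simulator guards its preconditions", {
  panel <- p021()
  prof <- setNames(ifelse(smnRegions() %in% combinedRegions(), 4L, 2L),
                   smnRegions())
  expect_error(simulateMlpaRun(cbind(S1 = prof), panel, noise_sigma = -1),
               "noise_sigma")
  expect_error(simulateMlpaRun(cbind(S1 = prof), panel, n_controls = 2),
               "control")
  expect_error(simulatePedigree(blackModel(), 0), "n_children")
})
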