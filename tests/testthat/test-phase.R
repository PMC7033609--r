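test_that("allelic decompositions enumerate cis/trans configurations", {
  s <- alleleSplits(2)
  expect_equal(s, data.frame(a = c(0L, 1L), b = c(2L, 1L)))
  expect_equal(alleleSplits(0), data.frame(a = 0L, b = 0L))
  expect_equal(nrow(alleleSplits(5)), 3)
  expect_equal(nrow(alleleSplits(8, k_max = 6)), 3)  # (2,6),(3,5),(4,4)
  expect_error(alleleSplits(5, k_max = 2), "infeasible")
})

test_that("trio phasing labels informative, uninformative and discrepant cases", {
  ped <- trioPed()
  r1 <- phaseFamily(ped, trioTotals(0, 2, 1), regions = "SMN1_e7")
  expect_equal(r1@status, "informative")
  expect_equal(r1@assignments$SMN1_e7[[1]]$mother, c(1, 1))

  r2 <- phaseFamily(ped, trioTotals(2, 2, 2), regions = "SMN1_e7")
  expect_equal(r2@status, "uninformative")
  expect_gte(r2@nFeasible[["SMN1_e7"]], 2)

  r3 <- phaseFamily(ped, trioTotals(0, 0, 1), regions = "SMN1_e7")
  expect_equal(r3@status, "discrepant")
  expect_equal(r3@nFeasible[["SMN1_e7"]], 0L)
  expect_true(length(r3@events) > 0)
  expect_true(all(vapply(r3@events, function(e) all(e$type == "gain"),
                         logical(1))))
})

test_that("phasing agrees with the brute-force oracle for all trio totals 0-6", {
  ped <- trioPed()
  for (F in 0:6) for (M in 0:6) for (C in 0:6) {
    rep <- phaseFamily(ped, trioTotals(F, M, C), regions = "SMN1_e7",
                       max_events = 0)
    expect_equal(rep@nFeasible[["SMN1_e7"]], oracleTrioFeasible(F, M, C),
                 info = sprintf("F=%d M=%d C=%d", F, M, C))
  }
})

test_that("simulated pedigrees without de novo events are never discrepant", {
  m <- blackModel()
  set.seed(31)
  for (i in 1:40) {
    ped <- simulatePedigree(makePopulationModel("black_SA", de_novo_rate = 0),
                            n_children = sample(1:3, 1),
                            family_id = sprintf("S%02d", i))
    tot <- trueTotals(ped)
    rep <- phaseFamily(ped, tot, max_events = 0)
    expect_true(rep@status %in% c("informative", "uninformative"), info = i)
    # conservation: each child haplotype is one of the parental haplotypes
    fa <- ped@diplotypes$FA; mo <- ped@diplotypes$MO
    kids <- grep("^C", names(ped@diplotypes), value = TRUE)
    for (k in kids) {
      expect_true(identical(ped@diplotypes[[k]]$pat, fa$mat) ||
                  identical(ped@diplotypes[[k]]$pat, fa$pat))
      expect_true(identical(ped@diplotypes[[k]]$mat, mo$mat) ||
                  identical(ped@diplotypes[[k]]$mat, mo$pat))
    }
  }
})

test_that("a planted copy gain is recovered as a minimal single event", {
  ped <- trioPed()
  tot <- trioTotals(0, 0, 1, region = "SMN2_e7")
  ex <- detectDeNovo(ped, tot, regions = "SMN2_e7", max_events = 2)
  expect_true(length(ex) >= 1)
  expect_true(all(vapply(ex, nrow, integer(1)) == 1))  # minimal, not 2-event
  expect_true(all(vapply(ex, function(e)
    e$type == "gain" && e$region == "SMN2_e7" && e$member_id == "C1",
    logical(1))))
})

test_that("conversion ranks among minimal explanations of paired exon-7 shifts", {
  ped <- trioPed()
  tot <- matrix(as.integer(c(2, 2, 1,   0, 0, 1)), ncol = 2,
                dimnames = list(c("FA", "MO", "C1"),
                                c("SMN1_e7", "SMN2_e7")))
  ex <- detectDeNovo(ped, tot, regions = c("SMN1_e7", "SMN2_e7"),
                     max_events = 1)
  expect_true(length(ex) > 0)
  types <- vapply(ex, function(e) e$type, character(1))
  expect_true("conversion" %in% types)  # one event, not loss + gain
  expect_true(all(vapply(ex, nrow, integer(1)) == 1))
  # consistent family yields no explanations at all
  expect_length(detectDeNovo(ped, trioTotals(2, 2, 2), regions = "SMN1_e7"),
                0)
})

test_that("joint phasing ties transmissions across regions", {
  ped <- trioPed()
  # father carries (2,0) x (0,2) arrangement possibilities at two regions;
  # child totals force a shared transmitted haplotype
  tot <- matrix(as.integer(c(2, 0, 2,   2, 0, 0)), ncol = 2,
                dimnames = list(c("FA", "MO", "C1"),
                                c("SMN1_e7", "SMN1_e8")))
  indep <- phaseFamily(ped, tot, regions = c("SMN1_e7", "SMN1_e8"))
  joint <- phaseFamily(ped, tot, regions = c("SMN1_e7", "SMN1_e8"),
                       joint = TRUE)
  expect_true(all(joint@nFeasible <= indep@nFeasible))
  expect_true(all(joint@nFeasible >= 1))
})

test_that("the 61-family fixture flags exactly the two planted event families", {
  d <- fixtureDir()
  peds <- readPedigree(file.path(d, "families.ped"))
  expect_length(peds, 61)
  tot <- t(readCopyNumbers(file.path(d, "families_cn.tsv")))
  reps <- phaseFamilies(peds, tot, max_events = 1)
  rate <- deNovoRateReport(reps)
  expect_equal(rate$n_discrepant, 2)
  expect_equal(rate$n_event_families, 2)
  expect_equal(rate$event_rate_pct, 3.3)
})

test_that("malformed pedigrees are rejected", {
  expect_error(new("Pedigree", familyId = "B1",
                   members = data.frame(member_id = c("A", "B"),
                                        father_id = c(NA, "Z"),
                                        mother_id = c(NA, NA),
                                        sex = c("M", "F")),
                   diplotypes = list(), events = data.frame()),
               "does not resolve")
  expect_error(new("Pedigree", familyId = "B2",
                   members = data.frame(member_id = "A",
                                        father_id = "A",
                                        mother_id = NA,
                                        sex = "M"),
                   diplotypes = list(), events = data.frame()),
               "cycle")
  ped <- trioPed()
  expect_error(phaseFamily(ped, trioTotals(0, 0, 1)), "missing for region")
})
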