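# shared lazily-built test fixtures

.cache <- new.env(parent = emptyenv())

p021 <- function() {
  if (is.null(.cache$panel)) .cache$panel <- loadPanel("P021")
  .cache$panel
}

fixtureDir <- function() {
  if (is.null(.cache$fixdir)) {
    d <- file.path(tempdir(), "smncnv-fixtures")
    makeFixtures(d)
    .cache$fixdir <- d
  }
  .cache$fixdir
}

blackModel <- function() {
  if (is.null(.cache$black)) .cache$black <- makePopulationModel("black_SA")
  .cache$black
}

whiteModel <- function() {
  if (is.null(.cache$white)) .cache$white <- makePopulationModel("white_SA")
  .cache$white
}

# a trio Pedigree with given member ids (FA, MO, C1)
trioPed <- function(fid = "T1") {
  new("Pedigree", familyId = fid,
      members = data.frame(
        member_id = c("FA", "MO", "C1"),
        father_id = c(NA, NA, "FA"),
        mother_id = c(NA, NA, "MO"),
        sex = c("M", "F", "F"), stringsAsFactors = FALSE),
      diplotypes = list(), events = data.frame())
}

# one-region totals matrix for a trio
trioTotals <- function(fa, mo, ch, region = "SMN1_e7") {
  m <- matrix(as.integer(c(fa, mo, ch)), ncol = 1,
              dimnames = list(c("FA", "MO", "C1"), region))
  m
}

# independent brute-force trio phasing oracle for a single region:
# counts parental (father split, mother split) pairs, splits written as
# unordered {a,b}, for which the child total is reachable
oracleTrioFeasible <- function(F, M, C, k_max = 6) {
  count <- 0
  for (fa in 0:(F %/% 2)) {
    fb <- F - fa
    if (fb > k_max) next
    for (ma in 0:(M %/% 2)) {
      mb <- M - ma
      if (mb > k_max) next
      ok <- FALSE
      for (x in c(fa, fb)) for (y in c(ma, mb))
        if (x + y == C) ok <- TRUE
      if (ok) count <- count + 1
    }
  }
  count
}
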