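# shared numeric helpers

# round half away from zero (Table 2 prints percentages rounded half-up;
# base round() rounds half to even)
.roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# deterministic expansion of a ">2" copy-number bin into concrete totals:
# threes, except one four per ten samples (the fours placed last)
.expandGt2 <- function(n) {
  if (n <= 0) return(integer())
  n4 <- n %/% 10L
  c(rep(3L, n - n4), rep(4L, n4))
}

# totals vector from a 0/1/2/>2 bin count row
.binTotals <- function(b0, b1, b2, bgt2) {
  c(rep(0L, b0), rep(1L, b1), rep(2L, b2), .expandGt2(bgt2))
}

.stopIf <- function(cond, ...) if (cond) stop(..., call. = FALSE)
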