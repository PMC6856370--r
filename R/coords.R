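# TSS-relative coordinate model shared by every stage.
#
# Promoter windows are stored 5'->3' in the gene's sense orientation. A record
# with U upstream and D downstream bases has string indices 1..U+D; index i
# maps to TSS-relative position i-U-1 for i <= U (so -U..-1) and i-U for
# i > U (+1..+D). There is no position 0: -1 abuts +1. All bounds inclusive.

#' Convert TSS-relative positions to 1-based string indices
#'
#' @param pos integer vector of signed TSS-relative positions (no zeroes).
#' @param upstream,downstream the record's window extents in bases.
#' @return integer vector of 1-based indices into the sense-oriented sequence.
#' @keywords internal
tssToIndex <- function(pos, upstream, downstream) {
  if (any(pos == 0))
    stop("position 0 does not exist under the TSS coordinate convention")
  if (any(pos < -upstream | pos > downstream))
    stop("position outside the record window [-", upstream, ", +", downstream, "]")
  ifelse(pos < 0, pos + upstream + 1L, pos + upstream)
}

#' Convert 1-based string indices to TSS-relative positions
#' @keywords internal
indexToTss <- function(i, upstream) {
  ifelse(i <= upstream, i - upstream - 1L, i - upstream)
}

#' Length of an inclusive TSS-relative window
#'
#' Same-sign bounds span to - from + 1 positions; bounds straddling the TSS
#' span to - from positions because position 0 is skipped.
#' @keywords internal
tssWindowLength <- function(from, to) {
  if (from == 0 || to == 0) stop("position 0 requested")
  if (from > to) stop("window bounds reversed")
  if (sign(from) == sign(to)) to - from + 1L else to - from
}

#' TSS-relative end position of a k-long feature starting at `from`
#' @keywords internal
tssShift <- function(from, k) {
  # position reached after advancing k-1 bases from `from`, skipping 0
  to <- from + k - 1L
  if (from < 0 && to >= 0) to <- to + 1L
  to
}
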