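#' Effort-To-Compress (ETC) complexity of a symbol sequence
#'
#' ETC measures complexity as the number of iterations the Non-sequential
#' Recursive Pair Substitution (NSRPS) algorithm needs to reduce a symbol
#' sequence to a constant sequence. Each iteration finds the adjacent symbol
#' pair with the highest frequency of occurrence (non-overlapping,
#' left-to-right counting, ties broken by leftmost first occurrence) and
#' replaces all its non-overlapping occurrences with a new symbol. A
#' constant sequence has ETC 0; a length-`m` sequence of all-distinct
#' symbols has ETC `m - 1`, so the normalized value `steps / (m - 1)` lies
#' in `[0, 1]`.
#'
#' @param seq integer (or coercible) symbol sequence of length at least 2.
#'   Character strings such as `"12121112"` of single-character symbols are
#'   accepted for convenience.
#' @param normalized if `TRUE` (default) return `steps / (m - 1)` where `m`
#'   is the original length; otherwise return the raw iteration count.
#' @return a single number: normalized ETC in `[0, 1]`, or the raw step
#'   count.
#' @examples
#' etc_complexity("12121112", normalized = FALSE)  # 5
#' etc_complexity("12121112")                      # 5/7
#' etc_complexity(c(1, 1, 1, 1), normalized = FALSE)  # 0
#' @seealso [etc_joint()] for the joint measure on aligned pairs.
#' @export
etc_complexity <- function(seq, normalized = TRUE) {
  s <- as_symbols(seq)
  m <- length(s)
  if (m < 2) stop("sequence must have length >= 2")
  steps <- .etc_steps(s)
  if (normalized) steps / (m - 1) else steps
}

#' Joint Effort-To-Compress of an aligned pair of sequences
#'
#' Extends NSRPS to a pair of equal-length symbol sequences: each iteration
#' scans both sequences simultaneously and replaces the most frequent
#' jointly occurring adjacent pair with a new symbol in each sequence. The
#' algorithm halts when no two aligned symbol tuples differ (or length 1),
#' so the step count equals `etc_complexity()` of any bijective tuple
#' fusion of the pair (see [dictionary_sequence()]). Joint ETC is
#' subadditive: `ETC(X, Y) <= ETC(X) + ETC(Y)`.
#'
#' @param x,y symbol sequences of equal length (length at least 2); single
#'   character strings are accepted as in [etc_complexity()].
#' @inheritParams etc_complexity
#' @return normalized joint ETC in `[0, 1]`, or the raw step count.
#' @examples
#' etc_joint("121212", "abacac", normalized = FALSE)  # 4
#' etc_joint("121212", "abacac")                      # 4/5
#' @export
etc_joint <- function(x, y, normalized = TRUE) {
  sx <- as_symbols(x)
  sy <- as_symbols(y)
  if (length(sx) != length(sy)) stop("sequences must have equal length")
  m <- length(sx)
  if (m < 2) stop("sequence must have length >= 2")
  steps <- .etc_joint_steps(sx, sy)
  if (normalized) steps / (m - 1) else steps
}

#' Complexity rate of a block given its past (contrast to dynamical complexity)
#'
#' The complexity rate `CR(dx | x_past) = C(x_past, dx) - C(x_past)` is the
#' *joint*-complexity analogue of the dynamical complexity used by CCC. It
#' conditions on joint occurrences of the past and current blocks rather
#' than on the temporal evolution of the appended sequence, and is provided
#' purely as a contrast utility: it generally differs from
#' [dynamical_cc()] on the same inputs, which is the point of using
#' dynamical complexity for causality. Joint complexity of two blocks is
#' only defined here for equal-length blocks (aligned joint ETC).
#'
#' @param dx,x_past numeric blocks of equal length (at least 2).
#' @param B number of uniform bins used to symbolize each block.
#' @return `ETC(x_past, dx) - ETC(x_past)` on normalized ETC values.
#' @export
complexity_rate <- function(dx, x_past, B) {
  if (length(dx) != length(x_past))
    stop("complexity rate is defined here only for equal-length blocks")
  sp <- bin_block(x_past, B)
  sd <- bin_block(dx, B)
  etc_joint(sp, sd) - etc_complexity(sp)
}

# coerce symbol input: integer-ish vectors pass through, single strings are
# split into per-character symbols and factor-coded
as_symbols <- function(x) {
  if (is.character(x) && length(x) == 1) {
    ch <- strsplit(x, "")[[1]]
    return(as.integer(factor(ch, levels = unique(ch))))
  }
  if (is.factor(x)) return(as.integer(x))
  if (!is.numeric(x)) stop("cannot interpret input as a symbol sequence")
  if (anyNA(x)) stop("symbol sequence contains missing values")
  if (any(x != round(x)) || any(x < 1))
    stop("symbols must be positive integers")
  as.integer(x)
}
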