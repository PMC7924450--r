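#' Bin a real-valued block into a symbol sequence
#'
#' Converts a block of real-valued measurements into a finite-alphabet symbol
#' sequence using `B` uniformly sized bins spanning the block's own range
#' (`[min(block), max(block)]`). The encoding is exactly invariant under
#' positive affine transforms of the block (scaling and addition of a
#' constant), which is what makes the downstream causality estimate
#' invariant to a common rescaling of the data.
#'
#' Values falling exactly on an internal right bin edge are assigned to the
#' lower bin; the block maximum goes to bin `B`. A constant block (zero
#' range) maps to symbol 1 everywhere: constant windows legitimately occur
#' and carry zero complexity.
#'
#' @param block numeric vector, length at least 2.
#' @param B integer number of bins, at least 2.
#' @return integer vector of symbols in `1..B` with attribute
#'   `alphabet_size = B`.
#' @examples
#' bin_block(c(0, 1, 0, 1), B = 2)
#' bin_block(c(5, 5, 5, 5), B = 4)  # constant block -> all 1s
#' @export
bin_block <- function(block, B) {
  if (!is.numeric(block) || length(block) < 2)
    stop("'block' must be a numeric vector of length >= 2")
  if (anyNA(block)) stop("'block' contains missing values")
  if (!is.numeric(B) || length(B) != 1 || B < 2 || B != round(B))
    stop("'B' must be a single integer >= 2")
  B <- as.integer(B)
  lo <- min(block)
  hi <- max(block)
  if (hi == lo) {
    sym <- rep.int(1L, length(block))
  } else {
    # ceil((x - lo) / width) puts internal right edges in the lower bin;
    # clamp so lo -> 1 and fp round-off at hi cannot exceed B
    width <- (hi - lo) / B
    sym <- as.integer(ceiling((block - lo) / width))
    sym[sym < 1L] <- 1L
    sym[sym > B] <- B
  }
  structure(sym, alphabet_size = B)
}

#' Fuse aligned symbol sequences into a single dictionary sequence
#'
#' Encodes the tuple of symbols at each position across several aligned
#' symbol sequences as a single symbol, using a fixed mixed-radix code with
#' the first sequence as the most significant digit. Two positions receive
#' the same dictionary symbol iff their full tuples match, so any complexity
#' measure that is invariant under alphabet relabeling (such as ETC) gives
#' identical values for any bijective tuple code.
#'
#' @param blocks a list of integer symbol vectors of equal length, or a
#'   single symbol vector.
#' @param alphabet_sizes integer vector of member alphabet sizes; defaults
#'   to each block's `alphabet_size` attribute, falling back to its maximum
#'   symbol.
#' @return integer vector of dictionary symbols in
#'   `1..prod(alphabet_sizes)`, with attribute `alphabet_size`.
#' @examples
#' dictionary_sequence(list(c(1, 1, 2, 2), c(1, 2, 1, 2)))  # 1 2 3 4
#' @export
dictionary_sequence <- function(blocks, alphabet_sizes = NULL) {
  if (!is.list(blocks)) blocks <- list(blocks)
  if (length(blocks) < 1) stop("need at least one block")
  lens <- lengths(blocks)
  if (length(unique(lens)) != 1)
    stop("all blocks must have equal length")
  if (is.null(alphabet_sizes)) {
    alphabet_sizes <- vapply(blocks, function(b) {
      a <- attr(b, "alphabet_size")
      if (is.null(a)) max(b) else a
    }, numeric(1))
  }
  if (length(alphabet_sizes) != length(blocks))
    stop("'alphabet_sizes' must match the number of blocks")
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    if (any(b < 1L) || any(b > alphabet_sizes[k]))
      stop("symbols must lie in 1..alphabet_size for every block")
  }
  if (prod(alphabet_sizes) > .Machine$integer.max)
    stop("combined alphabet too large to encode")
  code <- rep.int(0, lens[1])
  for (k in seq_along(blocks)) {
    code <- code * alphabet_sizes[k] + (as.numeric(blocks[[k]]) - 1)
  }
  structure(as.integer(code + 1), alphabet_size = prod(alphabet_sizes))
}
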