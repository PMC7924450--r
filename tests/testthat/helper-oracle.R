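# Independent brute-force NSRPS reference, written against the algorithm
# description only (no shared code with the package internals): each pass
# recounts every distinct adjacent pair exhaustively with a greedy
# non-overlapping scan, picks the most frequent (leftmost first occurrence on
# ties), and rebuilds the sequence.

oracle_count_pair <- function(s, a, b) {
  n <- 0L
  i <- 1L
  while (i < length(s)) {
    if (s[i] == a && s[i + 1] == b) {
      n <- n + 1L
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  n
}

oracle_replace_pair <- function(s, a, b, fresh) {
  out <- s[0]
  i <- 1L
  while (i <= length(s)) {
    if (i < length(s) && s[i] == a && s[i + 1] == b) {
      out <- c(out, fresh)
      i <- i + 2L
    } else {
      out <- c(out, s[i])
      i <- i + 1L
    }
  }
  out
}

# full NSRPS trace: list of sequences, starting with the input, ending when
# the sequence is constant or has length 1
oracle_etc_trace <- function(s) {
  s <- as.integer(s)
  trace <- list(s)
  while (length(s) > 1 && any(s != s[1])) {
    left <- s[-length(s)]
    right <- s[-1]
    pairs <- unique(cbind(left, right))
    counts <- apply(pairs, 1, function(p) oracle_count_pair(s, p[1], p[2]))
    firsts <- apply(pairs, 1, function(p) which(left == p[1] & right == p[2])[1])
    best <- order(-counts, firsts)[1]
    s <- oracle_replace_pair(s, pairs[best, 1], pairs[best, 2], max(s) + 1L)
    trace[[length(trace) + 1]] <- s
  }
  trace
}

oracle_etc_steps <- function(s) length(oracle_etc_trace(s)) - 1L

# literal simultaneous pair substitution on an aligned pair: the most
# frequent adjacent pair of symbol tuples is replaced in both sequences by
# fresh per-sequence symbols; halts when no two aligned tuples differ
oracle_joint_steps <- function(x, y) {
  x <- as.integer(x)
  y <- as.integer(y)
  stopifnot(length(x) == length(y))
  steps <- 0L
  repeat {
    n <- length(x)
    if (n <= 1) break
    tup <- paste(x, y, sep = ",")
    if (all(tup == tup[1])) break
    left <- tup[-n]
    right <- tup[-1]
    pairs <- unique(cbind(left, right))
    counts <- apply(pairs, 1, function(p) oracle_count_pair(tup, p[1], p[2]))
    firsts <- apply(pairs, 1, function(p) which(left == p[1] & right == p[2])[1])
    best <- order(-counts, firsts)[1]
    ab <- strsplit(pairs[best, 1], ",", fixed = TRUE)[[1]]
    cd <- strsplit(pairs[best, 2], ",", fixed = TRUE)[[1]]
    a <- as.integer(ab[1]); b <- as.integer(ab[2])
    cc_ <- as.integer(cd[1]); dd <- as.integer(cd[2])
    fx <- max(x) + 1L
    fy <- max(y) + 1L
    nx <- integer(0); ny <- integer(0)
    i <- 1L
    while (i <= n) {
      if (i < n && x[i] == a && y[i] == b && x[i + 1] == cc_ && y[i + 1] == dd) {
        nx <- c(nx, fx); ny <- c(ny, fy)
        i <- i + 2L
      } else {
        nx <- c(nx, x[i]); ny <- c(ny, y[i])
        i <- i + 1L
      }
    }
    x <- nx
    y <- ny
    steps <- steps + 1L
  }
  steps
}

# random short symbol sequence for property checks
random_symbols <- function(len, alphabet) sample.int(alphabet, len, replace = TRUE)
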