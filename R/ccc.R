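#' Window decomposition for causality estimation
#'
#' Splits a pair of aligned series into the moving-window blocks used by the
#' CCC estimator: for each window position, the current block `dx` of length
#' `w` from the target series, and the synchronous immediate-past blocks
#' `x_past`, `y_past` of length `L`. Windows start at the earliest index
#' where a full `L`-sample past exists and advance by `delta`; a trailing
#' window that would need samples beyond the end of the series is dropped.
#'
#' @param x numeric target series.
#' @param y numeric source series of the same length (optional; when `NULL`
#'   only `x_past`/`dx` blocks are returned).
#' @param L past-window length in samples (`>= 2`).
#' @param w current-window length in samples (`>= 1`).
#' @param delta window step in samples (`>= 1`).
#' @return a list of windows; each element has `start_index` (0-based
#'   position of `dx` in the series), `x_past`, `dx`, and `y_past` when `y`
#'   is supplied.
#' @examples
#' length(decompose_windows(rnorm(1000), L = 150, w = 15, delta = 80))  # 11
#' @export
decompose_windows <- function(x, y = NULL, L, w, delta) {
  check_ccc_params(L, w, delta, B = 2)
  if (!is.null(y) && length(y) != length(x))
    stop("'x' and 'y' must have equal length")
  N <- length(x)
  if (N < L + w)
    stop("series too short: need length >= L + w = ", L + w)
  starts <- seq.int(L + 1L, N - w + 1L, by = delta)
  lapply(starts, function(s) {
    win <- list(
      start_index = s - 1L,
      x_past = x[(s - L):(s - 1)],
      dx = x[s:(s + w - 1)]
    )
    if (!is.null(y)) win$y_past <- y[(s - L):(s - 1)]
    win
  })
}

#' Dynamical compression-complexity of a block given its past
#'
#' `CC(dx | x_past) = ETC(x_past + dx) - ETC(x_past)`, where `+` is
#' appending and each of the two blocks (the past, and the appended block
#' as one unit) is symbolized separately with `B` uniform bins over its
#' own range. Positive values mean appending `dx` made the past less
#' structured (more complex); negative values mean more structured.
#'
#' @param dx numeric current block.
#' @param x_past numeric immediate-past block.
#' @param B number of uniform bins per block.
#' @param normalized use normalized ETC (default) or raw step counts.
#' @return a single number in `[-1, 1]` for normalized ETC.
#' @export
dynamical_cc <- function(dx, x_past, B, normalized = TRUE) {
  etc_complexity(bin_block(c(x_past, dx), B), normalized = normalized) -
    etc_complexity(bin_block(x_past, B), normalized = normalized)
}

#' Dynamical compression-complexity given two pasts (interventional block)
#'
#' `CC(dx | x_past, y_past) = ETC(x_past + dx, y_past + dx) -
#' ETC(x_past, y_past)` on joint ETC values. The block `y_past + dx` does
#' not exist in the recorded data: it is created by surgery and implements
#' the intervention of treating `dx` as a dynamical evolution of the
#' source's past as well. All four blocks (`x_past`, `y_past`, and the two
#' appended blocks, each as one unit) are binned separately over their own
#' range; the surgical block therefore mixes the raw amplitudes of the
#' source's past and the target's current window, which is where much of
#' its sensitivity comes from.
#'
#' @param dx numeric current block of the target.
#' @param x_past,y_past synchronous immediate-past blocks of equal length.
#' @inheritParams dynamical_cc
#' @return a single number in `[-1, 1]` for normalized ETC.
#' @export
dynamical_cc_joint <- function(dx, x_past, y_past, B, normalized = TRUE) {
  if (length(x_past) != length(y_past))
    stop("'x_past' and 'y_past' must have equal length")
  etc_joint(bin_block(c(x_past, dx), B), bin_block(c(y_past, dx), B),
            normalized = normalized) -
    etc_joint(bin_block(x_past, B), bin_block(y_past, B),
              normalized = normalized)
}

#' Compression-Complexity Causality
#'
#' Estimates the causal influence of a source series `y` on a target series
#' `x` by comparing, over moving windows, the dynamical
#' compression-complexity of the target's current block given its own past
#' with the same quantity given both pasts via a surgically constructed
#' interventional block:
#' `CCC(y -> x) = mean over windows of CC(dx | x_past) - CC(dx | x_past, y_past)`.
#' A value statistically indistinguishable from zero means no detected
#' causal influence (or identical processes). Positive CCC means the
#' source's past influences the target's dynamics similarly to the target's
#' own past; negative CCC means a dissimilar dynamical influence (both are
#' genuine causation).
#'
#' With `conditioning` series supplied, the conditional variant is
#' computed on dictionary sequences that encode the aligned symbol tuples
#' across variables: `D'` encodes the target plus conditioning variables,
#' `D` additionally encodes the source, and
#' `CCC(y -> x | z, ...) = mean CC(dx | D') - mean CC(dx | D)`. Every
#' member variable's past is extended by the target's current block `dx`
#' (the surgical interventional block `v_past + dx`), treating `dx` as a
#' dynamical evolution of each variable's past.
#'
#' @param x numeric target series (the *effect* candidate).
#' @param y numeric source series (the *cause* candidate), same length.
#' @param L past-window length in samples.
#' @param w current-window length in samples (default 15).
#' @param delta window step in samples (default `w`).
#' @param B number of uniform bins per variable (default 2; 8 suits
#'   deterministic/chaotic-looking data).
#' @param conditioning optional list of numeric series (same length as `x`)
#'   to condition on.
#' @param significance `"ttest"` (default): two-sided one-sample t-test of
#'   the window CCCs against 0; `"surrogate"`: null distribution of the
#'   mean CCC from circular shifts of `y` by uniform random offsets of at
#'   least `L`; `"none"`: skip (p-value `NA`). Circular-shift surrogates
#'   preserve the source's marginal distribution and amplitude, which for
#'   this estimator carry part of the causal signal, so the surrogate test
#'   asks a narrower question (alignment-specific influence) and can be
#'   very conservative; see the package vignette.
#' @param n_surrogates number of circular-shift surrogates (default 100).
#' @param alpha significance level used to label the sign (default 0.05).
#' @param seed optional seed for the surrogate RNG (restores the caller's
#'   RNG state afterwards).
#' @param normalized use normalized ETC values (default); raw step counts
#'   are available for diagnostics.
#' @return an object of class `"ccc"`: a list with `per_window`
#'   (data.frame of window start, `cc_x`, `cc_xy`, `ccc`), `mean_ccc`,
#'   `n_windows`, `p_value`, `sign_label`, `params`, `conditional`, `call`.
#' @examples
#' sim <- simulate_ar1(n = 400, epsilon = 0.8, nu = 0.03, seed = 7)
#' fit <- ccc(sim$X, sim$Y, L = 100, w = 15, delta = 30, B = 2,
#'            significance = "none")
#' coef(fit)
#' @seealso [etc_complexity()], [simulate_ar1()], [summary.ccc()]
#' @export
ccc <- function(x, y, L, w = 15, delta = w, B = 2, conditioning = NULL,
                significance = c("ttest", "surrogate", "none"),
                n_surrogates = 100, alpha = 0.05, seed = NULL,
                normalized = TRUE) {
  significance <- match.arg(significance)
  check_ccc_params(L, w, delta, B)
  x <- check_series(x)
  y <- check_series(y)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (!is.null(conditioning)) {
    if (!is.list(conditioning)) conditioning <- list(conditioning)
    conditioning <- lapply(conditioning, check_series)
    if (any(lengths(conditioning) != length(x)))
      stop("conditioning series must have the same length as 'x'")
  }
  per <- ccc_window_values(x, y, conditioning, L, w, delta, B, normalized)
  mean_ccc <- mean(per$ccc)

  p_value <- NA_real_
  if (significance == "ttest") {
    if (nrow(per) < 2) stop("significance requires at least 2 windows")
    p_value <- safe_t_pvalue(per$ccc)
  } else if (significance == "surrogate") {
    if (nrow(per) < 2) stop("significance requires at least 2 windows")
    null_means <- with_seed(seed, {
      N <- length(y)
      hi <- max(L, N - L)
      offsets <- sample(seq.int(L, hi), n_surrogates, replace = TRUE)
      vapply(offsets, function(o) {
        o <- ((o - 1L) %% N) + 1L
        ys <- c(y[(o + 1):N], y[seq_len(o)])
        mean(ccc_window_values(x, ys, conditioning, L, w, delta, B,
                               normalized)$ccc)
      }, numeric(1))
    })
    p_value <- mean(abs(null_means) >= abs(mean_ccc))
  }
  sign_label <- if (is.na(p_value) || p_value >= alpha) "null"
                else if (mean_ccc > 0) "positive" else "negative"

  structure(list(
    per_window = per,
    mean_ccc = mean_ccc,
    n_windows = nrow(per),
    p_value = p_value,
    sign_label = sign_label,
    alpha = alpha,
    significance = significance,
    params = list(L = L, w = w, delta = delta, B = B,
                  normalized = normalized, n_surrogates = n_surrogates,
                  seed = seed),
    conditional = !is.null(conditioning) && length(conditioning) > 0,
    n_conditioning = if (is.null(conditioning)) 0L else length(conditioning),
    call = match.call()
  ), class = "ccc")
}

# per-window CCC values; cond = NULL/empty gives the pairwise estimator,
# otherwise the conditional dictionary-based estimator
ccc_window_values <- function(x, y, cond, L, w, delta, B, normalized = TRUE) {
  N <- length(x)
  if (N < L + w)
    stop("series too short: need length >= L + w = ", L + w)
  starts <- seq.int(L + 1L, N - w + 1L, by = delta)
  conditional <- !is.null(cond) && length(cond) > 0
  cc_x <- cc_xy <- numeric(length(starts))
  for (k in seq_along(starts)) {
    s <- starts[k]
    ip <- (s - L):(s - 1)
    ic <- s:(s + w - 1)
    xp <- x[ip]; dx <- x[ic]; yp <- y[ip]
    if (!conditional) {
      bx_p <- bin_block(xp, B)
      bx_a <- bin_block(c(xp, dx), B)
      by_p <- bin_block(yp, B)
      by_a <- bin_block(c(yp, dx), B)  # interventional block y_past + dx
      cc_x[k] <- etc_complexity(bx_a, normalized = normalized) -
        etc_complexity(bx_p, normalized = normalized)
      cc_xy[k] <- etc_joint(bx_a, by_a, normalized = normalized) -
        etc_joint(bx_p, by_p, normalized = normalized)
    } else {
      # every member past is extended by the target's current block dx
      # (surgical interventional blocks for source and conditioning alike)
      zp <- lapply(cond, function(z) bin_block(z[ip], B))
      za <- lapply(cond, function(z) bin_block(c(z[ip], dx), B))
      bx_p <- bin_block(xp, B)
      bx_a <- bin_block(c(xp, dx), B)
      by_p <- bin_block(yp, B)
      by_a <- bin_block(c(yp, dx), B)
      dprime_p <- dictionary_sequence(c(list(bx_p), zp))
      dprime_a <- dictionary_sequence(c(list(bx_a), za))
      d_p <- dictionary_sequence(c(list(bx_p), list(by_p), zp))
      d_a <- dictionary_sequence(c(list(bx_a), list(by_a), za))
      cc_x[k] <- etc_complexity(dprime_a, normalized = normalized) -
        etc_complexity(dprime_p, normalized = normalized)
      cc_xy[k] <- etc_complexity(d_a, normalized = normalized) -
        etc_complexity(d_p, normalized = normalized)
    }
  }
  data.frame(start_index = starts - 1L, cc_x = cc_x, cc_xy = cc_xy,
             ccc = cc_x - cc_xy)
}

check_ccc_params <- function(L, w, delta, B) {
  if (!is.numeric(L) || length(L) != 1 || L < 2 || L != round(L))
    stop("'L' must be a single integer >= 2")
  if (!is.numeric(w) || length(w) != 1 || w < 1 || w != round(w))
    stop("'w' must be a single integer >= 1")
  if (!is.numeric(delta) || length(delta) != 1 || delta < 1 ||
      delta != round(delta))
    stop("'delta' must be a single integer >= 1")
  if (!is.numeric(B) || length(B) != 1 || B < 2 || B != round(B))
    stop("'B' must be a single integer >= 2")
  invisible(TRUE)
}

check_series <- function(x) {
  if (!is.numeric(x)) stop("series must be numeric")
  if (anyNA(x))
    stop("series contains missing values; remove samples rather than ",
         "passing NA placeholders")
  as.numeric(x)
}

safe_t_pvalue <- function(v) {
  if (stats::sd(v) == 0) return(if (mean(v) == 0) 1 else 0)
  stats::t.test(v, mu = 0)$p.value
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
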