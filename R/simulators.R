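#' Coupled first-order autoregressive processes
#'
#' Simulates the unidirectionally coupled AR(1) pair
#' `X(t) = a X(t-1) + epsilon Y(t-1) + nu eta_X(t)`,
#' `Y(t) = b Y(t-1) + nu eta_Y(t)` with standard-normal innovations `eta`.
#' `Y` is the independent (cause) process and `X` the dependent (effect)
#' process; `epsilon` is the coupling strength and `nu` the noise
#' intensity. Series start at 0 and lagged terms before the start are
#' treated as 0; with stable coefficients the initialization washes out.
#'
#' @param n series length (default 1000).
#' @param a,b AR self-coefficients of `X` and `Y` (defaults 0.9 and 0.8).
#' @param epsilon coupling strength from `Y` to `X`.
#' @param nu noise intensity (default 0.03).
#' @param seed optional RNG seed (caller's RNG state is restored).
#' @return a list with numeric vectors `X` and `Y` of length `n`.
#' @examples
#' sim <- simulate_ar1(n = 200, epsilon = 0.8, seed = 1)
#' @export
simulate_ar1 <- function(n = 1000, a = 0.9, b = 0.8, epsilon = 0, nu = 0.03,
                         seed = NULL) {
  simulate_ar_lagged(n = n, a = a, b = b, epsilon = epsilon, nu = nu,
                     self_lag = 1L, cross_lag = 1L, seed = seed)
}

#' Coupled autoregressive processes with lag-100 coupling
#'
#' As [simulate_ar1()] but the cross term uses the source's lag 100:
#' `X(t) = a X(t-1) + epsilon Y(t-100) + nu eta_X(t)`. This long-range
#' memory defeats associational causality estimators while remaining
#' detectable by CCC.
#'
#' @inheritParams simulate_ar1
#' @return a list with numeric vectors `X` and `Y` of length `n`.
#' @export
simulate_ar100 <- function(n = 1000, a = 0.9, b = 0.8, epsilon = 0,
                           nu = 0.03, seed = NULL) {
  if (n <= 100) stop("'n' must exceed the coupling lag of 100")
  simulate_ar_lagged(n = n, a = a, b = b, epsilon = epsilon, nu = nu,
                     self_lag = 1L, cross_lag = 100L, seed = seed)
}

#' Coupled autoregressive processes with lag-5 self terms
#'
#' Simulates `Y(t) = 0.7 Y(t-5) + nu eta_Y(t)` and
#' `X(t) = 0.9 X(t-5) + 0.8 Y(t-1) + nu eta_X(t)`: the system used to study
#' robustness of causality estimates to filtering and decimation.
#'
#' @param n series length (default 2000).
#' @inheritParams simulate_ar1
#' @return a list with numeric vectors `X` and `Y` of length `n`.
#' @export
simulate_ar_lag5 <- function(n = 2000, a = 0.9, b = 0.7, epsilon = 0.8,
                             nu = 0.03, seed = NULL) {
  simulate_ar_lagged(n = n, a = a, b = b, epsilon = epsilon, nu = nu,
                     self_lag = 5L, cross_lag = 1L, seed = seed)
}

# shared AR recursion: X(t) = a X(t-self_lag) + epsilon Y(t-cross_lag) + nu eta
#                      Y(t) = b Y(t-self_lag) + nu eta
simulate_ar_lagged <- function(n, a, b, epsilon, nu, self_lag, cross_lag,
                               seed = NULL) {
  if (n < 2) stop("'n' must be at least 2")
  if (nu < 0) stop("'nu' must be non-negative")
  with_seed(seed, {
    ex <- nu * stats::rnorm(n)
    ey <- nu * stats::rnorm(n)
    X <- numeric(n)
    Y <- numeric(n)
    lag <- function(v, t, k) if (t - k >= 1) v[t - k] else 0
    for (t in seq_len(n)) {
      Y[t] <- b * lag(Y, t, self_lag) + ey[t]
      X[t] <- a * lag(X, t, self_lag) + epsilon * lag(Y, t, cross_lag) + ex[t]
    }
    list(X = X, Y = Y)
  })
}

#' Coupled tent maps
#'
#' Simulates the chaotic tent map `Y(t) = 2 Y(t-1)` for `Y(t-1) < 1/2`,
#' `2 - 2 Y(t-1)` otherwise, and a dependent process mixing the source with
#' its own tent-map update `h(t)`:
#' linear coupling `X(t) = epsilon Y(t) + (1 - epsilon) h(t)`, or nonlinear
#' coupling `X(t) = epsilon Y(t)^2 + (1 - epsilon) h(t)` (a reconstruction
#' of the quadratic variant; results with it are only interpreted
#' qualitatively). At `epsilon = 1` the two series synchronize completely.
#'
#' Iterating the exact slope-2 tent map in binary floating point collapses
#' every dyadic-rational orbit to 0 within about 50 steps, so each tent
#' update is perturbed by a jitter uniform on `[0, 1e-12]` (reflected back
#' into `[0, 1]`). The jitter is far below any bin width used downstream
#' and keeps the orbit on the chaotic attractor; it is not applied to the
#' coupling mix, so `epsilon = 1` still gives `X = Y` exactly.
#'
#' @param n number of samples returned after discarding the transient
#'   (default 1000).
#' @param epsilon coupling strength in `[0, 1]`.
#' @param coupling `"linear"` (default) or `"nonlinear"`.
#' @param transient number of initial samples discarded (default 2000).
#' @param x0,y0 initial conditions in `[0, 1]`; by default drawn uniformly
#'   on (0, 1) away from the fixed points 0 and 2/3.
#' @param seed optional RNG seed.
#' @return a list with numeric vectors `X` and `Y` of length `n`, all
#'   values in `[0, 1]`.
#' @export
simulate_tent <- function(n = 1000, epsilon = 0,
                          coupling = c("linear", "nonlinear"),
                          transient = 2000, x0 = NULL, y0 = NULL,
                          seed = NULL) {
  coupling <- match.arg(coupling)
  if (epsilon < 0 || epsilon > 1) stop("'epsilon' must be in [0, 1]")
  with_seed(seed, {
    draw_ic <- function() {
      repeat {
        v <- stats::runif(1)
        if (v > 1e-3 && v < 1 - 1e-3 && abs(v - 2 / 3) > 1e-3) return(v)
      }
    }
    if (is.null(x0)) x0 <- draw_ic()
    if (is.null(y0)) y0 <- draw_ic()
    if (x0 < 0 || x0 > 1 || y0 < 0 || y0 > 1)
      stop("initial conditions must lie in [0, 1]")
    total <- n + transient
    jx <- stats::runif(total) * 1e-12
    jy <- stats::runif(total) * 1e-12
    tent <- function(v) if (v < 0.5) 2 * v else 2 - 2 * v
    X <- numeric(total)
    Y <- numeric(total)
    xprev <- x0
    yprev <- y0
    for (t in seq_len(total)) {
      yt <- tent(yprev) + jy[t]
      if (yt > 1) yt <- 2 - yt
      h <- tent(xprev) + jx[t]
      if (h > 1) h <- 2 - h
      xt <- if (coupling == "linear") epsilon * yt + (1 - epsilon) * h
            else epsilon * yt^2 + (1 - epsilon) * h
      X[t] <- xt
      Y[t] <- yt
      xprev <- xt
      yprev <- yt
    }
    keep <- seq.int(transient + 1L, total)
    list(X = X[keep], Y = Y[keep])
  })
}

#' Three-variable autoregressive system with a common driver
#'
#' Simulates `Z(t) = 0.8 Z(t-1) + nu eta_Z(t)` driving
#' `X(t) = 0.9 X(t-1) + 0.4 Z(t-100) + nu eta_X(t)` and
#' `Y(t) = 0.9 Y(t-1) + 0.8 Z(t-100) + nu eta_Y(t)`. The true graph is
#' `Z -> X` and `Z -> Y` with no direct coupling between `X` and `Y`; the
#' short retained length makes this a stress test for conditional
#' causality estimation.
#'
#' @param n number of samples returned after the transient (default 250).
#' @param transient initial samples discarded (default 50).
#' @param cx,cy coupling weights of `Z(t-100)` into `X` and `Y` (defaults
#'   0.4 and 0.8).
#' @inheritParams simulate_ar1
#' @return a list with numeric vectors `X`, `Y`, `Z` of length `n`.
#' @export
simulate_mvar3 <- function(n = 250, transient = 50, cx = 0.4, cy = 0.8,
                           nu = 0.03, seed = NULL) {
  with_seed(seed, {
    total <- n + transient
    ez <- nu * stats::rnorm(total)
    ex <- nu * stats::rnorm(total)
    ey <- nu * stats::rnorm(total)
    Z <- X <- Y <- numeric(total)
    lag <- function(v, t, k) if (t - k >= 1) v[t - k] else 0
    for (t in seq_len(total)) {
      Z[t] <- 0.8 * lag(Z, t, 1) + ez[t]
      X[t] <- 0.9 * lag(X, t, 1) + cx * lag(Z, t, 100) + ex[t]
      Y[t] <- 0.9 * lag(Y, t, 1) + cy * lag(Z, t, 100) + ey[t]
    }
    keep <- seq.int(transient + 1L, total)
    list(X = X[keep], Y = Y[keep], Z = Z[keep])
  })
}

#' Non-uniform sampling of a coupled pair
#'
#' Models missing/non-synchronous measurements: removes `round(alpha/100 *
#' N)` samples at uniformly random positions from the dependent series `x`
#' (keeping no time stamps), and truncates the independent series `y` from
#' the end to match the shortened length, yielding a non-synchronous pair.
#'
#' @param x dependent series (samples are deleted from it).
#' @param y independent series of the same length (truncated to match).
#' @param alpha percentage of samples removed, in `[0, 100)`.
#' @param seed optional RNG seed.
#' @return a list with the shortened `x` and `y`.
#' @export
nonuniform_sample <- function(x, y, alpha, seed = NULL) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (alpha < 0 || alpha >= 100) stop("'alpha' must be in [0, 100)")
  n <- length(x)
  k <- round(alpha / 100 * n)
  with_seed(seed, {
    if (k > 0) {
      drop <- sample.int(n, k)
      x <- x[-drop]
    }
    list(x = x, y = y[seq_along(x)])
  })
}

#' Moving-average filter
#'
#' Low-pass filters a series with a moving average of the given window
#' length, advancing by `step` samples: `output[k]` is the mean of
#' `window` consecutive samples starting at position `1 + (k-1) * step`.
#' The output length is `floor((N - window) / step) + 1` (e.g. 2000
#' samples filter to 1998 with window 3, step 1).
#'
#' @param x numeric series.
#' @param window window length (`>= 1`, at most `length(x)`).
#' @param step stride between successive windows (default 1).
#' @return the filtered series.
#' @examples
#' moving_average(c(1, 2, 3, 4), window = 3)  # 2 3
#' @export
moving_average <- function(x, window, step = 1) {
  n <- length(x)
  if (window < 1 || window != round(window)) stop("'window' must be a positive integer")
  if (step < 1 || step != round(step)) stop("'step' must be a positive integer")
  if (window > n) stop("'window' must not exceed the series length")
  starts <- seq.int(1L, n - window + 1L, by = step)
  cs <- cumsum(c(0, x))
  (cs[starts + window] - cs[starts]) / window
}

#' Decimate a series
#'
#' Keeps every `factor`-th sample starting at the first, halving (etc.) the
#' sampling rate by sample dropping.
#'
#' @param x numeric series.
#' @param factor positive integer decimation factor.
#' @return the decimated series.
#' @examples
#' decimate(c(1, 2, 3, 4), 2)  # 1 3
#' @export
decimate <- function(x, factor) {
  if (factor < 1 || factor != round(factor))
    stop("'factor' must be a positive integer")
  x[seq.int(1L, length(x), by = factor)]
}
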