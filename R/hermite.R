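#' Orthonormal Hermite-function basis on a discrete time grid
#'
#' Builds the first `N` Hermite functions
#' \eqn{\phi_n(t;\sigma) = H_n(t/\sigma) e^{-t^2/(2\sigma^2)} / \sqrt{\sigma\, 2^n n! \sqrt{\pi}}}
#' (physicists' Hermite polynomials \eqn{H_n}) sampled on `grid_ms`, then
#' re-orthonormalised with respect to the discrete inner product
#' \eqn{\langle f,g\rangle = \Delta t \sum f g} (Gram--Schmidt) so that the
#' Gram matrix is the identity to machine precision at any sampling rate.
#' A single width `sigma_ms` is shared by all `N` functions.
#'
#' @param N number of basis functions (>= 1).
#' @param sigma_ms width parameter in milliseconds (> 0).
#' @param grid_ms numeric vector of time samples in ms, symmetric about 0.
#' @return An object of class `hermite_basis`: list with `N`, `sigma_ms`,
#'   `grid_ms`, `dt_ms`, and `functions` (length(grid) x N matrix whose columns
#'   are orthonormal under the discrete inner product).
#' @export
hermite_basis <- function(N, sigma_ms, grid_ms) {
  if (N < 1) stop("N must be >= 1")
  if (sigma_ms <= 0) stop("sigma_ms must be > 0")
  if (abs(grid_ms[1] + grid_ms[length(grid_ms)]) > 1e-9)
    stop("grid_ms must be symmetric about 0")
  dt <- diff(grid_ms)
  if (max(dt) - min(dt) > 1e-9) stop("grid_ms must be uniformly spaced")
  dt <- dt[1]

  raw <- hermite_raw(N, sigma_ms, grid_ms)
  # grid must be wide enough for the Gaussian envelope (and polynomial growth)
  edge <- max(abs(raw[c(1L, nrow(raw)), ])) / max(abs(raw))
  if (edge > 1e-3)
    stop("grid too narrow for sigma: basis edge value exceeds 1e-3 of maximum")

  # discrete Gram-Schmidt, inner product <f,g> = dt * sum(f*g)
  B <- raw
  for (n in seq_len(N)) {
    if (n > 1) {
      prev <- B[, seq_len(n - 1L), drop = FALSE]
      B[, n] <- B[, n] - prev %*% (dt * crossprod(prev, B[, n]))
    }
    B[, n] <- B[, n] / sqrt(dt * sum(B[, n]^2))
  }
  structure(
    list(N = N, sigma_ms = sigma_ms, grid_ms = grid_ms, dt_ms = dt,
         functions = B),
    class = "hermite_basis"
  )
}

# Continuous-normalisation Hermite functions before discrete
# re-orthonormalisation; recurrence H_{n+1} = 2u H_n - 2n H_{n-1}.
hermite_raw <- function(N, sigma_ms, grid_ms) {
  u <- grid_ms / sigma_ms
  env <- exp(-u^2 / 2)
  out <- matrix(0, length(grid_ms), N)
  Hnm1 <- rep(1, length(u))          # H_0
  out[, 1] <- Hnm1 * env / sqrt(sigma_ms * sqrt(pi))
  if (N >= 2) {
    Hn <- 2 * u                      # H_1
    out[, 2] <- Hn * env / sqrt(sigma_ms * 2 * sqrt(pi))
    if (N >= 3) {
      for (n in 2:(N - 1)) {
        Hnp1 <- 2 * u * Hn - 2 * (n - 1) * Hnm1
        Hnm1 <- Hn
        Hn <- Hnp1
        out[, n + 1] <- Hn * env / sqrt(sigma_ms * 2^n * factorial(n) * sqrt(pi))
      }
    }
  }
  out
}

#' Pre-build Hermite bases over a sigma grid
#'
#' The width search in [fit_hermite_window()] evaluates every candidate sigma;
#' bases depend only on `(N, sigma, grid)`, so they are built once and reused
#' across leads and subjects.
#'
#' @param N number of basis functions.
#' @param sigma_grid_ms candidate widths in ms.
#' @param grid_ms common time grid in ms.
#' @return list of `hermite_basis`, one per sigma.
#' @export
hermite_basis_bank <- function(N, sigma_grid_ms, grid_ms) {
  lapply(sigma_grid_ms, function(s) hermite_basis(N, s, grid_ms))
}

#' Fit a QRS window by Hermite projection with width optimisation
#'
#' Projects a single-lead QRS window (centred on the R peak, zero-padded to the
#' basis grid) onto the Hermite basis for every candidate width and keeps the
#' width maximising the recovered energy fraction
#' \eqn{\|\hat x\|^2 / \|x\|^2}. Because the basis is orthonormal, the
#' projection coefficients are the discrete inner products and the fit is the
#' least-squares optimum for that basis.
#'
#' @param x numeric vector, QRS window amplitudes in microvolts.
#' @param t_ms time stamps of `x` in ms relative to the R peak.
#' @param N number of Hermite functions (3-4 typical).
#' @param sigma_grid_ms candidate widths in ms (default 5-50 ms in 0.5 ms steps).
#' @param grid_halfwidth_ms half-width of the zero-padded basis grid in ms.
#' @param bank optional precomputed [hermite_basis_bank()] matching the other
#'   arguments.
#' @return list with `sigma_ms` (optimal width), `coefficients` (length N,
#'   units uV*sqrt(ms)), `energy_fraction`, `qrs_window_ms`, `N`, `grid_ms`,
#'   and `energy_by_sigma` (the full search curve).
#' @export
fit_hermite_window <- function(x, t_ms, N = 4,
                               sigma_grid_ms = seq(5, 50, by = 0.5),
                               grid_halfwidth_ms = 400, bank = NULL) {
  stopifnot(length(x) == length(t_ms))
  dt <- t_ms[2] - t_ms[1]
  grid_ms <- seq(-grid_halfwidth_ms, grid_halfwidth_ms, by = dt)
  xg <- numeric(length(grid_ms))
  idx <- round((t_ms - grid_ms[1]) / dt) + 1L
  if (any(idx < 1L | idx > length(grid_ms)))
    stop("QRS window does not fit inside the basis grid")
  xg[idx] <- x
  energy <- dt * sum(xg^2)
  if (energy <= 0) stop("zero-energy QRS window: Hermite fit undefined")

  if (is.null(bank)) bank <- hermite_basis_bank(N, sigma_grid_ms, grid_ms)
  ef <- numeric(length(bank))
  co <- matrix(0, N, length(bank))
  for (i in seq_along(bank)) {
    cc <- dt * crossprod(bank[[i]]$functions, xg)[, 1]
    co[, i] <- cc
    ef[i] <- sum(cc^2) / energy
  }
  best <- which.max(ef)
  list(sigma_ms = sigma_grid_ms[best],
       coefficients = co[, best],
       energy_fraction = ef[best],
       qrs_window_ms = diff(range(t_ms)) + dt,
       N = N,
       grid_ms = grid_ms,
       energy_by_sigma = stats::setNames(ef, sigma_grid_ms))
}

#' Reconstruct a waveform from Hermite coefficients
#'
#' @param coefficients numeric vector of projection coefficients.
#' @param basis a [hermite_basis()] with matching `N`.
#' @return numeric vector on the basis grid (microvolts).
#' @export
hermite_reconstruct <- function(coefficients, basis) {
  if (!inherits(basis, "hermite_basis")) stop("basis must be a hermite_basis")
  if (length(coefficients) != basis$N)
    stop("coefficient length does not match basis order N")
  drop(basis$functions %*% coefficients)
}

#' Hermite QRS representation of an averaged beat, all leads
#'
#' Applies [fit_hermite_window()] to the QRS window of every lead of an
#' averaged beat. The window (default 130 ms) is centred on the R peak (or on
#' an explicitly supplied anchor, e.g. from the cohort-level envelope
#' alignment in [cohort_features()]) and zero-padded to the basis grid; the
#' width sigma is optimised per lead.
#'
#' @param beat an `averaged_beat` (see [average_beat()]).
#' @param N number of Hermite functions (default 4).
#' @param sigma_grid_ms candidate widths in ms.
#' @param window_ms QRS window length in ms.
#' @param bank optional precomputed basis bank.
#' @param center optional window-centre sample index overriding the R peak.
#' @return list of per-lead fits (class `hermite_representation`), each as
#'   returned by [fit_hermite_window()].
#' @export
fit_hermite_beat <- function(beat, N = 4, sigma_grid_ms = seq(5, 50, by = 0.5),
                             window_ms = 130, bank = NULL, center = NULL) {
  fs <- beat$fs
  half <- round(window_ms / 2 * fs / 1000)
  r <- if (is.null(center)) beat$fiducials$r_peak else center
  idx <- (r - half):(r + half)
  idx <- idx[idx >= 1 & idx <= nrow(beat$samples)]
  t_ms <- (idx - r) * 1000 / fs
  dt <- 1000 / fs
  grid_ms <- seq(-400, 400, by = dt)
  if (is.null(bank)) bank <- hermite_basis_bank(N, sigma_grid_ms, grid_ms)
  fits <- lapply(seq_along(beat$leads), function(l) {
    fit_hermite_window(beat$samples[idx, l], t_ms, N = N,
                       sigma_grid_ms = sigma_grid_ms,
                       grid_halfwidth_ms = 400, bank = bank)
  })
  names(fits) <- beat$leads
  class(fits) <- "hermite_representation"
  fits
}
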