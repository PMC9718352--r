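#' Highest density interval
#'
#' The shortest interval containing a given fraction of the draws: all sorted
#' windows spanning `ceiling(mass * N)` draws are scanned and the narrowest
#' returned. For a unimodal posterior this estimates the HDI -- the region of
#' highest posterior density; a value inside it belongs to the `mass` most
#' probable values. On multimodal draw sets the single shortest window is
#' still returned, which may bridge modes.
#'
#' @param draws Numeric vector of posterior draws (at least 100).
#' @param mass Probability mass to cover, in (0, 1); default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' set.seed(1)
#' hdi(rbeta(10000, 61, 41))
#' @export
hdi <- function(draws, mass = 0.95) {
  draws <- as.numeric(draws)
  if (anyNA(draws)) stop("draws contain NA")
  if (length(draws) < 100) stop("need at least 100 draws for an HDI")
  if (mass <= 0 || mass >= 1) stop("mass must lie in (0, 1)")
  xs <- sort(draws)
  n <- length(xs)
  m <- ceiling(mass * n)
  if (m >= n) return(c(xs[1], xs[n]))
  starts <- seq_len(n - m + 1L)
  widths <- xs[starts + m - 1L] - xs[starts]
  i <- which.min(widths)
  c(lower = xs[i], upper = xs[i + m - 1L])
}

as_chain_matrix <- function(draws) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  draws <- as.matrix(draws)
  if (nrow(draws) < 4) stop("chains too short for diagnostics")
  draws
}

split_chains <- function(x) {
  n <- nrow(x)
  half <- n %/% 2L
  x <- x[seq_len(2L * half), , drop = FALSE]
  cbind(x[seq_len(half), , drop = FALSE],
        x[half + seq_len(half), , drop = FALSE])
}

#' Split-R-hat convergence diagnostic
#'
#' The classic Gelman-Rubin potential scale reduction factor computed on
#' split chains (each chain halved, so a single trending chain is also
#' detected): `sqrt(((n-1)/n * W + B/n) / W)` with `W` the mean within-chain
#' variance and `B/n` the between-chain variance of the means. Values near 1
#' indicate convergence; the usual threshold here is 1.05.
#'
#' @param draws Numeric matrix, iterations x chains (a vector is treated as
#'   one chain and split in two).
#' @return The split-R-hat; `NA` with a warning when all chains are constant.
#' @export
rhat <- function(draws) {
  x <- split_chains(as_chain_matrix(draws))
  n <- nrow(x)
  w <- mean(apply(x, 2, stats::var))
  if (w == 0 || !is.finite(w)) {
    warning("R-hat undefined: constant chains")
    return(NA_real_)
  }
  b_over_n <- stats::var(colMeans(x))
  sqrt(((n - 1) / n * w + b_over_n) / w)
}

# biased autocovariance (divisor n) via FFT, lags 0..n-1
autocov_fft <- function(x) {
  n <- length(x)
  xd <- x - mean(x)
  npad <- 2^ceiling(log2(2 * n))
  ft <- stats::fft(c(xd, rep(0, npad - n)))
  Re(stats::fft(Mod(ft)^2, inverse = TRUE))[seq_len(n)] / (npad * n)
}

#' Effective sample size
#'
#' Autocorrelation-adjusted number of independent-equivalent draws, computed
#' on split chains with the combined-chain autocorrelation estimate and
#' Geyer's initial monotone positive-sequence truncation. For an AR(1) chain
#' with coefficient `phi` this approaches `N * (1 - phi) / (1 + phi)`. The
#' estimate is capped at the total number of draws.
#'
#' @param draws Numeric matrix, iterations x chains (a vector is treated as
#'   one chain).
#' @return Effective sample size; 0 with a warning for constant chains.
#' @export
ess <- function(draws) {
  x <- split_chains(as_chain_matrix(draws))
  n <- nrow(x)
  m <- ncol(x)
  chain_vars <- apply(x, 2, stats::var)
  w <- mean(chain_vars)
  if (w == 0 || !is.finite(w)) {
    warning("ESS is 0: constant chains")
    return(0)
  }
  b_over_n <- if (m > 1) stats::var(colMeans(x)) else 0
  var_plus <- (n - 1) / n * w + b_over_n
  acov <- rowMeans(vapply(seq_len(m), function(j) autocov_fft(x[, j]),
                          numeric(n)))
  rho <- 1 - (w - acov) / var_plus
  # Geyer: sum pairs, truncate at first negative pair, enforce monotone
  max_pairs <- (n - 1) %/% 2
  tau <- -rho[1]  # corrects for pairing starting at lag 0
  running_min <- Inf
  s <- 0
  for (kpair in seq_len(max_pairs)) {
    g <- rho[2 * kpair - 1] + rho[2 * kpair]
    if (g < 0) break
    running_min <- min(running_min, g)
    s <- s + running_min
  }
  tau <- tau + 2 * s
  tau <- max(tau, 1 / (m * n))
  min(m * n / tau, m * n)
}
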