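# Shared internal helpers: seed derivation, MCMC diagnostics, small checks.

#' Derive a child seed from a master seed and a stage label
#'
#' One master seed drives a whole pipeline run; each stage (simulation,
#' baseline fit per animal, regression fit, ...) receives its own
#' deterministic child seed so that stages can be re-run in isolation
#' without seed collisions.
#'
#' @param master integer master seed.
#' @param label character stage label.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  h <- 0
  for (cc in utf8ToInt(paste(label, collapse = "/"))) {
    h <- (h * 31 + cc) %% 2147483647
  }
  as.integer((abs(master) %% 2147483647 * 48271 + h) %% 2147483645 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_tm <- function(...) stop(..., call. = FALSE)

# Split-chain potential scale reduction factor (rank-free classic version).
# x: iterations x chains matrix of draws for one parameter.
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(xs)
  nn <- nrow(xs)
  means <- colMeans(xs)
  vars <- apply(xs, 2, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# Crude effective sample size from pooled chains via initial positive
# sequence of autocorrelations.
ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- ncol(x)
  if (n < 8L) return(NA_real_)
  rho_sum <- 0
  for (j in seq_len(m)) {
    v <- x[, j] - mean(x[, j])
    if (sd(v) == 0) next
    ac <- stats::acf(v, lag.max = min(n - 2L, 200L), plot = FALSE)$acf[-1]
    pos <- which(ac < 0.05)
    cut <- if (length(pos)) pos[1] - 1L else length(ac)
    rho_sum <- rho_sum + sum(ac[seq_len(cut)])
  }
  rho_sum <- rho_sum / m
  max(1, n * m / (1 + 2 * rho_sum))
}

# Quantile of a Gaussian mixture sum_i w N(mu_i, sd_i^2), vectorized over a
# set of mixtures sharing the draw index: mu is draws x K, sdv is draws (or
# scalar). Solved by bisection; monotone, so convergence is guaranteed.
mixture_quantile <- function(mu, sdv, p, tol = 1e-8, maxit = 200L) {
  mu <- as.matrix(mu)
  K <- ncol(mu)
  n <- nrow(mu)
  if (length(sdv) == 1L) sdv <- rep(sdv, n)
  stopifnot(length(sdv) == n, p > 0, p < 1)
  smax <- max(sdv)
  lo <- apply(mu, 2, min) - (smax + 1e-12) * 10
  hi <- apply(mu, 2, max) + (smax + 1e-12) * 10
  for (it in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    # P(Y <= mid_k) for each k, averaged over draws
    pr <- colMeans(pnorm((rep(mid, each = n) - mu) / sdv))
    below <- pr < p
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
    if (max(hi - lo) < tol) break
  }
  (lo + hi) / 2
}
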