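#' MCMC settings
#'
#' The default chain (50,000 iterations, 20,000 burn-in, thinning 5) matches
#' the full analysis profile used for final inference; [mcmc_quick()] is the
#' short profile used by the cross-validation drivers, tests and smoke runs.
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in iterations discarded; must be `< n_iter`.
#' @param thin thinning interval (>= 1); `(n_iter - burn_in) %/% thin` draws
#'   are kept.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = 50000, burn_in = 20000, thin = 5) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (n_iter < 1 || burn_in < 0 || thin < 1)
    stop("invalid MCMC settings")
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if ((n_iter - burn_in) %/% thin < 1)
    stop("zero-length chain: (n_iter - burn_in) %/% thin must be >= 1")
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin),
            class = "mcmc_settings")
}

#' @rdname mcmc_settings
#' @export
mcmc_quick <- function() mcmc_settings(n_iter = 2000, burn_in = 500, thin = 2)

#' @export
print.mcmc_settings <- function(x, ...) {
  cat(sprintf("<mcmc_settings> %d iterations, %d burn-in, thin %d (%d draws)\n",
              x$n_iter, x$burn_in, x$thin, (x$n_iter - x$burn_in) %/% x$thin))
  invisible(x)
}

#' Prior specification for whole-genome regression
#'
#' Variance components get scaled inverse chi-square priors with `df` degrees
#' of freedom; scale parameters are derived from the sample phenotypic
#' variance under the assumption that the model explains a proportion `r2` of
#' it (see [complete_prior()]). `pi` is the prior exclusion probability of
#' the BayesB/BayesC spike-and-slab marker prior.
#'
#' @param df prior degrees of freedom (> 0), default 5.
#' @param r2 prior proportion of phenotypic variance explained, in (0, 1),
#'   default 0.5.
#' @param pi BayesB/BayesC mixture proportion (probability a marker effect is
#'   zero), in (0, 1), default 0.99.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(df = 5, r2 = 0.5, pi = 0.99) {
  if (df <= 0) stop("df must be positive")
  if (r2 <= 0 || r2 >= 1) stop("r2 must lie in (0, 1)")
  if (pi <= 0 || pi >= 1) stop("pi must lie in (0, 1)")
  structure(list(df = df, r2 = r2, pi = pi), class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("<prior_spec> df = %g, r2 = %g, pi = %g\n", x$df, x$r2, x$pi))
  if (!is.null(x$S_u)) cat("  kernel scales S_u:", format(x$S_u, digits = 4), "\n")
  if (!is.null(x$S_alpha)) cat("  marker scale S_alpha:", format(x$S_alpha, digits = 4), "\n")
  if (!is.null(x$S_e)) cat("  residual scale S_e:", format(x$S_e, digits = 4), "\n")
  invisible(x)
}

#' Derive prior scale parameters from the phenotypic variance
#'
#' Completes a [prior_spec()] with the scale parameters of the scaled inverse
#' chi-square priors, following the standard default rules: for kernel models
#' the genetic scale per kernel k is
#' `S_u = Vy * r2_k * (df + 2) / mean(diag(K_k))` (with `r2` split equally
#' across kernels), and for marker models
#' `S_alpha = Vy * r2 * (df + 2) / MSx` with `MSx` the summed sample variance
#' of the marker covariates; spike-and-slab models divide further by
#' `(1 - pi)` because only that fraction of markers carries the slab.
#' The residual scale is `S_e = Vy * (1 - r2) * (df + 2)`.
#'
#' @param y phenotype vector (missing values allowed).
#' @param model `"kernel"` or `"marker"`.
#' @param kernels list of [kernel_matrix()] (kernel model).
#' @param W marker covariate matrix as used in the sampler (marker model).
#' @param prior a [prior_spec()].
#' @param spike logical: is the marker prior spike-and-slab (BayesB/BayesC)?
#' @return The `prior_spec` with `S_u` (per kernel) or `S_alpha` and `MSx`,
#'   plus `S_e` and `df_e`, filled in.
#' @export
complete_prior <- function(y, model = c("kernel", "marker"), kernels = NULL,
                           W = NULL, prior = prior_spec(), spike = FALSE) {
  model <- match.arg(model)
  vy <- var(y, na.rm = TRUE)
  if (!is.finite(vy) || vy <= 0)
    stop("phenotypic variance is zero: cannot derive prior scales")
  p <- prior
  p$Vy <- vy
  if (model == "kernel") {
    if (is.null(kernels)) stop("kernels required for the kernel model")
    nk <- length(kernels)
    mdk <- vapply(kernels, function(k) mean(diag(k$values)), numeric(1))
    p$S_u <- vy * (p$r2 / nk) * (p$df + 2) / mdk
    p$mean_diag <- mdk
  } else {
    if (is.null(W)) stop("W required for the marker model")
    msx <- sum(apply(W, 2, var))
    if (msx <= 0) stop("marker covariates have zero variance")
    p$MSx <- msx
    p$S_alpha <- vy * p$r2 * (p$df + 2) / msx
    if (spike) p$S_alpha <- p$S_alpha / (1 - p$pi)
  }
  p$S_e <- vy * (1 - p$r2) * (p$df + 2)
  p$df_e <- p$df
  p
}

# ---- internal chain helpers -------------------------------------------------

# effective sample size from the initial positive autocorrelation sequence
.ess <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  r <- acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(r < 0.05)
  upto <- if (length(pos)) pos[1] - 1 else length(r)
  denom <- 1 + 2 * sum(r[seq_len(upto)])
  max(1, n / max(denom, 1e-8))
}

# Geweke convergence z-score (first 10% vs last 50% of the chain)
.geweke_z <- function(x) {
  n <- length(x)
  if (n < 20) return(NA_real_)
  a <- x[seq_len(floor(0.1 * n))]
  b <- x[seq.int(ceiling(0.5 * n), n)]
  se2a <- var(a) / .ess(a)   # ESS-deflated variance of the section mean
  se2b <- var(b) / .ess(b)
  (mean(a) - mean(b)) / sqrt(se2a + se2b)
}

.chain_diagnostics <- function(chains) {
  out <- lapply(chains, function(x) {
    if (is.matrix(x))
      t(apply(x, 2, function(cc) c(ess = .ess(cc), geweke_z = .geweke_z(cc))))
    else c(ess = .ess(x), geweke_z = .geweke_z(x))
  })
  out
}
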