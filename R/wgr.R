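#' Bayesian whole-genome regression
#'
#' Fits the single-environment whole-genome regression models used in
#' genomic prediction by Gibbs sampling:
#'
#' * `"gblup"` — kernel regression `y = 1 mu + u + e`, `u ~ N(0, K sigma2_u)`
#'   with K the genomic relationship matrix G = WW'/m;
#' * `"rkhs"` — the same kernel regression with one or more Gaussian kernels;
#'   several kernels (kernel averaging) are fitted as separate random effects
#'   whose variances are learned;
#' * `"bayesb"` / `"bayesc"` — marker regression `y_i = mu + sum_j w_ij a_j + e_i`
#'   with a spike-and-slab prior on the marker effects: a_j = 0 with
#'   probability `pi`, else Gaussian with a per-marker (BayesB) or shared
#'   (BayesC) slab variance; markers are coded 0/1/2 and centred;
#' * `"rrblup"` — ridge regression on centred and standardized markers, the
#'   marker-effect parameterization of GBLUP.
#'
#' All variance components carry scaled inverse chi-square priors whose scales
#' derive from the phenotypic variance (see [complete_prior()]); the
#' intercept has a flat prior. Missing phenotypes are allowed for kernel
#' models (those lines are predicted, not fitted, via data augmentation) and
#' are dropped from the likelihood for marker models (their genetic values
#' are still returned via their marker rows).
#'
#' @param y named numeric phenotype vector (typically per-environment BLUEs).
#' @param markers a [genotype_matrix()], [standardize_markers()] object or
#'   plain numeric matrix of marker covariates. Required for marker models;
#'   for kernel models it is used to build the kernel(s) when `kernels` is
#'   not given.
#' @param kernels a [kernel_matrix()] or list of them (kernel models only).
#' @param model one of `"gblup"`, `"rkhs"`, `"bayesb"`, `"bayesc"`, `"rrblup"`.
#' @param mcmc an [mcmc_settings()] object.
#' @param prior a [prior_spec()] object.
#' @param thetas Gaussian-kernel bandwidths used when `model = "rkhs"` and
#'   kernels are built from `markers` (default `c(0.2, 1.2)`).
#' @param fix_var_u optional fixed genetic variance(s) (per kernel, or the
#'   ridge variance for `"rrblup"`): disables sampling of that component.
#' @param fix_var_e optional fixed residual variance.
#' @param store_u if `TRUE` (kernel models) the full chain of genetic values
#'   is kept (memory permitting) so Monte-Carlo standard errors per line can
#'   be computed.
#' @return An object of class `wgr` with posterior means (`mu`, `g`, and for
#'   marker models `alpha` and `pip`), variance-component chains, the
#'   per-draw heritability chain, and bookkeeping needed by [predict.wgr()].
#' @examples
#' cfg <- sim_config(n_lines = 60, m_markers = 120, seed = 5)
#' panel <- simulate_panel(cfg)
#' y <- panel$phenotypes[, 1]
#' fit <- wgr(y, markers = panel$geno, model = "gblup", mcmc = mcmc_quick())
#' summary(fit)
#' @export
wgr <- function(y, markers = NULL, kernels = NULL,
                model = c("gblup", "rkhs", "bayesb", "bayesc", "rrblup"),
                mcmc = mcmc_settings(), prior = prior_spec(),
                thetas = c(0.2, 1.2),
                fix_var_u = NULL, fix_var_e = NULL, store_u = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(mcmc, "mcmc_settings"), inherits(prior, "prior_spec"))
  if (!is.numeric(y)) stop("y must be numeric")
  if (all(is.na(y))) stop("y has no observed values")

  if (model %in% c("gblup", "rkhs")) {
    if (is.null(kernels)) {
      if (is.null(markers)) stop("provide either kernels or markers")
      W <- if (inherits(markers, "std_markers")) markers
           else standardize_markers(impute_genotypes(markers))
      kernels <- if (model == "gblup") list(G = genomic_relationship(W))
                 else kernel_list(W, thetas)
    }
    if (inherits(kernels, "kernel_matrix")) kernels <- list(kernels)
    if (is.null(names(kernels)))
      names(kernels) <- paste0("K", seq_along(kernels))
    fit <- .wgr_kernel(y, kernels, mcmc, prior, fix_var_u, fix_var_e, store_u)
  } else {
    if (is.null(markers)) stop("markers required for marker models")
    fit <- .wgr_marker(y, markers, model, mcmc, prior, fix_var_u, fix_var_e)
  }
  fit$model <- model
  fit$mcmc <- mcmc
  class(fit) <- "wgr"
  fit
}

# align a named phenotype vector with container line ids
.align_y <- function(y, ids) {
  if (is.null(names(y))) {
    if (length(y) != length(ids))
      stop("unnamed y must have one entry per line")
    names(y) <- ids
    return(y)
  }
  unmatched <- setdiff(names(y)[!is.na(y)], ids)
  if (length(unmatched))
    stop(sprintf("phenotyped lines missing from the genomic data: %s",
                 paste(head(unmatched, 5), collapse = ", ")))
  out <- setNames(rep(NA_real_, length(ids)), ids)
  common <- intersect(names(y), ids)
  out[common] <- y[common]
  out
}

# kernel-model Gibbs sampler; works in the eigenbasis of each kernel and
# treats missing phenotypes by data augmentation so every iteration is a
# sequence of independent scalar draws.
.wgr_kernel <- function(y, kernels, mcmc, prior, fix_var_u, fix_var_e,
                        store_u) {
  ids <- kernels[[1]]$line_ids
  for (k in kernels)
    if (!identical(k$line_ids, ids))
      stop("all kernels must share the same line ids")
  y <- .align_y(y, ids)
  n <- length(y)
  obs <- !is.na(y)
  if (sum(obs) < 3) stop("need at least 3 phenotyped lines")

  pr <- complete_prior(y[obs], "kernel", kernels = kernels, prior = prior)
  nk <- length(kernels)
  eig <- lapply(kernels, function(k) {
    e <- attr(k, "eigen")
    if (is.null(e)) e <- eigen(k$values, symmetric = TRUE)
    lmax <- max(e$values, 0)
    if (min(e$values) < -1e-8 * max(lmax, 1))
      stop("kernel is not positive semi-definite")
    keep <- e$values > 1e-10 * max(lmax, 1)
    list(Q = e$vectors[, keep, drop = FALSE], d = e$values[keep])
  })

  n_iter <- mcmc$n_iter; burn_in <- mcmc$burn_in; thin <- mcmc$thin
  n_keep <- (n_iter - burn_in) %/% thin

  vy <- pr$Vy
  var_u <- rep(vy * pr$r2 / nk, nk)
  var_e <- vy * (1 - pr$r2)
  if (!is.null(fix_var_u)) {
    fix_var_u <- rep_len(fix_var_u, nk)
    var_u <- fix_var_u
  }
  if (!is.null(fix_var_e)) var_e <- fix_var_e

  mu <- mean(y[obs])
  yfull <- y
  yfull[!obs] <- mu
  delta <- lapply(eig, function(e) numeric(length(e$d)))
  g <- lapply(eig, function(e) numeric(n))
  gtot <- numeric(n)

  mu_chain <- numeric(n_keep)
  var_u_chain <- matrix(NA_real_, n_keep, nk,
                        dimnames = list(NULL, names(kernels)))
  var_e_chain <- numeric(n_keep)
  h2_chain <- numeric(n_keep)
  g_sum <- numeric(n)
  g_sq <- numeric(n)
  u_chain <- if (store_u) matrix(NA_real_, n_keep, n) else NULL
  mdk <- pr$mean_diag

  kept <- 0
  for (it in seq_len(n_iter)) {
    mu <- rnorm(1, mean(yfull - gtot), sqrt(var_e / n))
    for (k in seq_len(nk)) {
      Q <- eig[[k]]$Q; d <- eig[[k]]$d
      r <- yfull - mu - gtot + g[[k]]
      rstar <- crossprod(Q, r)[, 1]
      prec <- 1 / var_e + 1 / (d * var_u[k])
      mn <- (rstar / var_e) / prec
      delta[[k]] <- mn + rnorm(length(d)) / sqrt(prec)
      gk_new <- as.numeric(Q %*% delta[[k]])
      gtot <- gtot - g[[k]] + gk_new
      g[[k]] <- gk_new
      if (is.null(fix_var_u))
        var_u[k] <- (pr$S_u[k] + sum(delta[[k]]^2 / d)) /
          rchisq(1, pr$df + length(d))
    }
    e <- yfull - mu - gtot
    if (is.null(fix_var_e))
      var_e <- (pr$S_e + sum(e^2)) / rchisq(1, pr$df_e + n)
    if (any(!obs))
      yfull[!obs] <- mu + gtot[!obs] + rnorm(sum(!obs), 0, sqrt(var_e))

    if (it > burn_in && (it - burn_in) %% thin == 0 && kept < n_keep) {
      kept <- kept + 1
      mu_chain[kept] <- mu
      var_u_chain[kept, ] <- var_u
      var_e_chain[kept] <- var_e
      vg <- sum(var_u * mdk)
      h2_chain[kept] <- vg / (vg + var_e)
      g_sum <- g_sum + gtot
      g_sq <- g_sq + gtot^2
      if (store_u) u_chain[kept, ] <- gtot
    }
  }

  g_mean <- g_sum / kept
  g_sd <- sqrt(pmax(g_sq / kept - g_mean^2, 0) * kept / max(kept - 1, 1))
  chains <- list(mu = mu_chain, var_u = var_u_chain, var_e = var_e_chain,
                 h2 = h2_chain)
  list(y = y, line_ids = ids, n = n, n_obs = sum(obs),
       kernels = kernels, mu = mean(mu_chain),
       g = setNames(g_mean, ids), g_sd = setNames(g_sd, ids),
       var_u = setNames(colMeans(var_u_chain), names(kernels)),
       var_e = mean(var_e_chain), h2 = mean(h2_chain),
       chains = chains, u_chain = u_chain, n_draws = kept,
       prior = pr, diagnostics = .chain_diagnostics(chains))
}

# marker-model front end: resolves the covariate coding, drops missing
# phenotypes from the likelihood and calls the compiled sampler.
.wgr_marker <- function(y, markers, model, mcmc, prior, fix_var_u,
                        fix_var_e) {
  if (inherits(markers, "std_markers")) {
    W <- markers$values
    ids <- markers$line_ids
    centers <- markers$centers; scales <- markers$scales
  } else if (inherits(markers, "genotype_matrix")) {
    X <- impute_genotypes(markers)$values
    centers <- colMeans(X)
    if (model == "rrblup") {
      scales <- apply(X, 2, sd)
      if (any(scales < 1e-12))
        stop("monomorphic marker: cannot standardize for rrblup")
      W <- sweep(sweep(X, 2, centers, "-"), 2, scales, "/")
    } else {
      # spike-and-slab models use the raw 0/1/2 coding, centred only
      scales <- rep(1, ncol(X))
      W <- sweep(X, 2, centers, "-")
    }
    ids <- markers$line_ids
  } else {
    W <- as.matrix(markers)
    ids <- rownames(W)
    if (is.null(ids)) ids <- paste0("L", seq_len(nrow(W)))
    centers <- rep(0, ncol(W)); scales <- rep(1, ncol(W))
  }
  y <- .align_y(y, ids)
  obs <- !is.na(y)
  if (sum(obs) < 3) stop("need at least 3 phenotyped lines")
  if (ncol(W) < 1) stop("no markers available")

  spike <- model %in% c("bayesb", "bayesc")
  pr <- complete_prior(y[obs], "marker", W = W[obs, , drop = FALSE],
                       prior = prior, spike = spike)
  vy <- pr$Vy
  var_a_init <- vy * pr$r2 / pr$MSx / (if (spike) (1 - pr$pi) else 1)
  model_code <- switch(model, rrblup = 0L, bayesb = 1L, bayesc = 2L)

  res <- .cpp_wgr_marker(as.numeric(y[obs]), W[obs, , drop = FALSE],
                         model_code, pr$pi, pr$df, pr$S_alpha,
                         pr$df_e, pr$S_e,
                         mcmc$n_iter, mcmc$burn_in, mcmc$thin,
                         var_a_init, vy * (1 - pr$r2),
                         if (is.null(fix_var_u)) -1 else fix_var_u,
                         if (is.null(fix_var_e)) -1 else fix_var_e)

  alpha <- setNames(as.numeric(res$alpha), colnames(W))
  g_all <- as.numeric(W %*% alpha)
  chains <- list(mu = res$mu_chain, var_alpha = res$var_a_chain,
                 var_e = res$var_e_chain, var_g = res$var_g_chain,
                 n_incl = res$n_incl_chain)
  h2_chain <- res$var_g_chain / (res$var_g_chain + res$var_e_chain)
  list(y = y, line_ids = ids, n = length(ids), n_obs = sum(obs),
       mu = mean(res$mu_chain), alpha = alpha,
       pip = setNames(as.numeric(res$pip), colnames(W)),
       g = setNames(g_all, ids),
       var_alpha = mean(res$var_a_chain), var_e = mean(res$var_e_chain),
       var_g = mean(res$var_g_chain), h2 = mean(h2_chain),
       chains = c(chains, list(h2 = h2_chain)), n_draws = res$n_draws,
       centers = centers, scales = scales, prior = pr,
       diagnostics = .chain_diagnostics(chains[c("mu", "var_alpha", "var_e")]))
}

#' @export
print.wgr <- function(x, ...) {
  cat(sprintf("<wgr> %s fit: %d lines (%d phenotyped), %d posterior draws\n",
              toupper(x$model), x$n, x$n_obs, x$n_draws))
  cat(sprintf("  mu = %.4g, var_e = %.4g, h2 = %.3f\n", x$mu, x$var_e, x$h2))
  if (!is.null(x$var_u))
    cat("  genetic variances:", paste(sprintf("%s = %.4g", names(x$var_u),
                                              x$var_u), collapse = ", "), "\n")
  if (!is.null(x$var_alpha))
    cat(sprintf("  marker variance = %.4g, genetic variance = %.4g\n",
                x$var_alpha, x$var_g))
  invisible(x)
}

#' @export
summary.wgr <- function(object, ...) {
  ci <- function(v) quantile(v, c(0.025, 0.975))
  comps <- list(mu = object$chains$mu, var_e = object$chains$var_e,
                h2 = object$chains$h2)
  if (!is.null(object$chains$var_u))
    for (k in colnames(object$chains$var_u))
      comps[[paste0("var_u.", k)]] <- object$chains$var_u[, k]
  if (!is.null(object$chains$var_alpha)) {
    comps$var_alpha <- object$chains$var_alpha
    comps$var_g <- object$chains$var_g
  }
  tab <- t(vapply(comps, function(v) c(mean = mean(v), sd = sd(v), ci(v),
                                       ess = .ess(v)),
                  numeric(5)))
  out <- list(model = object$model, n = object$n, n_obs = object$n_obs,
              n_draws = object$n_draws, table = tab)
  class(out) <- "summary.wgr"
  out
}

#' @export
print.summary.wgr <- function(x, ...) {
  cat(sprintf("Whole-genome regression (%s), %d lines (%d phenotyped), %d draws\n\n",
              toupper(x$model), x$n, x$n_obs, x$n_draws))
  print(round(x$table, 4))
  invisible(x)
}

#' @export
coef.wgr <- function(object, ...) {
  if (!is.null(object$alpha)) object$alpha else object$g
}

#' @export
fitted.wgr <- function(object, ...) object$mu + object$g

#' @export
residuals.wgr <- function(object, ...) object$y - fitted(object)

#' Predict genetic values or phenotypes from a fitted model
#'
#' Kernel fits predict lines contained in the kernel (phenotyped or not, the
#' latter via their kernel rows); marker fits can also predict new genotypes
#' through their marker covariates.
#'
#' @param object a [wgr()] fit.
#' @param lines character vector of line ids to predict (default: all lines
#'   of the fit).
#' @param newdata optional [genotype_matrix()] (or matrix) of new genotypes,
#'   marker models only; coded like the training data.
#' @param type `"genetic"` for genetic values, `"response"` to add the
#'   intercept.
#' @param ... unused.
#' @return Named numeric vector of predictions.
#' @export
predict.wgr <- function(object, lines = NULL, newdata = NULL,
                        type = c("genetic", "response"), ...) {
  type <- match.arg(type)
  if (!is.null(newdata)) {
    if (is.null(object$alpha))
      stop("kernel fits predict only lines present in the kernel; refit or use marker models for new genotypes")
    X <- if (inherits(newdata, "genotype_matrix"))
      impute_genotypes(newdata)$values else as.matrix(newdata)
    if (ncol(X) != length(object$alpha))
      stop("newdata must have the training markers as columns")
    W <- sweep(sweep(X, 2, object$centers, "-"), 2, object$scales, "/")
    g <- as.numeric(W %*% object$alpha)
    names(g) <- rownames(X)
  } else {
    g <- object$g
    if (!is.null(lines)) {
      unknown <- setdiff(lines, object$line_ids)
      if (length(unknown))
        stop(sprintf("unknown line(s): %s", paste(head(unknown, 5), collapse = ", ")))
      g <- g[lines]
    }
  }
  if (type == "response") g <- g + object$mu
  g
}

#' @export
simulate.wgr <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  out <- matrix(NA_real_, n, nsim, dimnames = list(object$line_ids, NULL))
  draws <- sample.int(object$n_draws, nsim, replace = TRUE)
  for (s in seq_len(nsim)) {
    ve <- object$chains$var_e[draws[s]]
    out[, s] <- object$chains$mu[draws[s]] + object$g + rnorm(n, 0, sqrt(ve))
  }
  as.data.frame(out)
}

#' @export
plot.wgr <- function(x, which = c("trace", "fit"), ...) {
  which <- match.arg(which)
  if (which == "trace") {
    ch <- if (!is.null(x$chains$var_u)) cbind(x$chains$var_u,
                                              var_e = x$chains$var_e)
          else cbind(var_g = x$chains$var_g, var_e = x$chains$var_e)
    op <- par(mfrow = c(ncol(ch), 1), mar = c(2.5, 4, 1, 1))
    on.exit(par(op))
    for (j in seq_len(ncol(ch)))
      plot(ch[, j], type = "l", ylab = colnames(ch)[j], xlab = "")
  } else {
    plot(fitted(x), x$y, xlab = "fitted", ylab = "observed", ...)
    abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' Closed-form kernel BLUP
#'
#' Deterministic best linear unbiased prediction for a single kernel with a
#' known variance ratio: `u_hat = K (K + lambda I)^{-1} (y - mu_hat)` on the
#' phenotyped lines, extended to unphenotyped lines through their kernel
#' rows. Used as a fast non-MCMC baseline and as an independent oracle in
#' validation.
#'
#' @param y named phenotype vector (NA = unphenotyped).
#' @param K a [kernel_matrix()].
#' @param h2 assumed heritability; the shrinkage ratio is
#'   `lambda = (1 - h2) / h2`.
#' @return Named vector of predicted genetic values for every line of `K`.
#' @export
kernel_blup <- function(y, K, h2 = 0.5) {
  stopifnot(inherits(K, "kernel_matrix"), h2 > 0, h2 < 1)
  y <- .align_y(y, K$line_ids)
  obs <- !is.na(y)
  lambda <- (1 - h2) / h2
  Koo <- K$values[obs, obs, drop = FALSE]
  M <- Koo + diag(lambda, sum(obs))
  ridge_inv_y <- solve(M, y[obs] - mean(y[obs]))
  u <- setNames(numeric(length(y)), K$line_ids)
  u[obs] <- Koo %*% ridge_inv_y
  if (any(!obs))
    u[!obs] <- K$values[!obs, obs, drop = FALSE] %*% ridge_inv_y
  u
}
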