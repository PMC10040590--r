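#' Marker-by-environment interaction model
#'
#' Fits the M-by-E ridge-regression BLUP model
#' \deqn{y_{il} = \mu_l + \sum_k w_{ilk} (\alpha_{0k} + \alpha_{lk}) + \epsilon_{il}}
#' by Gibbs sampling: every marker effect decomposes into a main component
#' `alpha_0` shared across environments (which borrows information between
#' them) and an environment-specific deviation `alpha_l`, with heterogeneous
#' residual variances per environment. Marker covariates are centred and
#' standardized per environment over the lines observed there. Variance
#' components carry scaled inverse chi-square priors with the prior means of
#' the genetic components summing to half of the phenotypic variance, split
#' equally between the main and specific parts.
#'
#' @param Y lines x environments numeric matrix of phenotypes (per-trait
#'   BLUEs); rownames are line ids, `NA` marks cells not observed (those are
#'   predicted). At least two environments are required.
#' @param geno a [genotype_matrix()] covering the lines of `Y`.
#' @param mcmc an [mcmc_settings()].
#' @param prior a [prior_spec()] (the `pi` slot is unused here).
#' @param fix_var_specific optional fixed value for the environment-specific
#'   marker variances (e.g. ~0 to reduce the model to across-environment
#'   ridge regression).
#' @return An object of class `mxe` with posterior means of the intercepts,
#'   marker effects and genetic values for every line x environment cell
#'   (including unobserved cells), the variance-component chains, and the
#'   per-environment marker-variance multiplier `MSx` used to express
#'   genetic variances on the genetic-value scale.
#' @examples
#' panel <- simulate_panel(sim_config(n_lines = 50, m_markers = 80, seed = 7))
#' fit <- mxe(panel$phenotypes, panel$geno, mcmc = mcmc_quick())
#' genomic_heritability(fit)
#' variance_proportions(fit)
#' @export
mxe <- function(Y, geno, mcmc = mcmc_settings(), prior = prior_spec(),
                fix_var_specific = NULL) {
  stopifnot(is.matrix(Y), inherits(mcmc, "mcmc_settings"),
            inherits(prior, "prior_spec"))
  if (ncol(Y) < 2)
    stop("single environment: use wgr() for single-environment analysis")
  if (is.null(rownames(Y))) stop("Y needs line ids as rownames")
  env_ids <- colnames(Y)
  if (is.null(env_ids)) env_ids <- paste0("env", seq_len(ncol(Y)))
  colnames(Y) <- env_ids
  ids <- rownames(Y)
  unmatched <- setdiff(ids, geno$line_ids)
  if (length(unmatched))
    stop(sprintf("lines missing from the genotypes: %s",
                 paste(head(unmatched, 5), collapse = ", ")))
  obs_mat <- !is.na(Y)
  if (sum(rowSums(obs_mat) >= 2) < 2)
    stop("environments share fewer than 2 phenotyped lines")
  L <- ncol(Y)
  X <- impute_genotypes(geno)$values[ids, , drop = FALSE]
  m <- ncol(X)

  # per-environment centring/scaling on the observed lines; the same
  # transform extends to unobserved lines for prediction
  W_env <- vector("list", L)
  y_list <- vector("list", L)
  vy_env <- numeric(L)
  for (l in seq_len(L)) {
    obs <- obs_mat[, l]
    if (sum(obs) < 3) stop(sprintf("environment '%s' has fewer than 3 phenotyped lines", env_ids[l]))
    ctr <- colMeans(X[obs, , drop = FALSE])
    scl <- apply(X[obs, , drop = FALSE], 2, sd)
    scl[scl < 1e-12] <- 1   # markers monomorphic within this environment carry no signal
    W_env[[l]] <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
    y_list[[l]] <- Y[obs, l]
    vy_env[l] <- var(Y[obs, l])
    if (vy_env[l] <= 0) stop(sprintf("environment '%s' has zero phenotypic variance", env_ids[l]))
  }
  vy <- mean(vy_env)
  # prior means of the genetic variance components (on the value scale,
  # i.e. sigma2_alpha * MSx with MSx = m for standardized covariates) sum to
  # half the phenotypic variance, split equally between main and specific:
  # scaled inv-chi2 prior mean is S/(df-2)
  if (prior$df <= 2) stop("prior df must exceed 2 for the M-by-E scale rule")
  S_a0 <- (prior$r2 / 2) * vy * (prior$df - 2) / m
  S_al <- (prior$r2 / 2) * vy_env * (prior$df - 2) / m
  S_el <- vy_env * (1 - prior$r2) * (prior$df + 2)

  stacked_y <- unlist(y_list, use.names = FALSE)
  env_off <- c(0L, cumsum(vapply(y_list, length, integer(1))))
  Wstack <- do.call(rbind, lapply(seq_len(L), function(l)
    W_env[[l]][obs_mat[, l], , drop = FALSE]))

  res <- .cpp_wgr_mxe(stacked_y, as.integer(env_off), Wstack,
                      S_a0, S_al, prior$df, S_el, prior$df,
                      mcmc$n_iter, mcmc$burn_in, mcmc$thin,
                      vy * prior$r2 / 2 / m, vy_env * (1 - prior$r2),
                      if (is.null(fix_var_specific)) -1 else fix_var_specific)

  alpha0 <- setNames(as.numeric(res$alpha0), colnames(X))
  alpha_env <- res$alpha_env
  dimnames(alpha_env) <- list(colnames(X), env_ids)
  g <- matrix(NA_real_, length(ids), L, dimnames = list(ids, env_ids))
  g_main <- matrix(NA_real_, length(ids), L, dimnames = list(ids, env_ids))
  for (l in seq_len(L)) {
    g_main[, l] <- W_env[[l]] %*% alpha0
    g[, l] <- g_main[, l] + W_env[[l]] %*% alpha_env[, l]
  }
  mu <- setNames(as.numeric(res$mu), env_ids)
  chains <- list(var_main = res$var_a0_chain,
                 var_specific = res$var_al_chain,
                 var_e = res$var_el_chain)
  colnames(chains$var_specific) <- colnames(chains$var_e) <- env_ids
  structure(list(mu = mu, alpha0 = alpha0, alpha_env = alpha_env,
                 g = g, g_main = g_main,
                 yhat = sweep(g, 2, mu, "+"),
                 var_main = mean(res$var_a0_chain),
                 var_specific = setNames(colMeans(res$var_al_chain), env_ids),
                 var_e = setNames(colMeans(res$var_el_chain), env_ids),
                 MSx = setNames(rep(m, L), env_ids), m = m,
                 chains = chains, n_draws = res$n_draws,
                 line_ids = ids, env_ids = env_ids, Y = Y,
                 diagnostics = .chain_diagnostics(chains)),
            class = "mxe")
}

#' @export
print.mxe <- function(x, ...) {
  cat(sprintf("<mxe> marker-by-environment fit: %d lines, %d markers, environments: %s\n",
              length(x$line_ids), x$m, paste(x$env_ids, collapse = ", ")))
  vp <- variance_proportions(x)
  cat("  variance proportions (rows: main, specific, residual):\n")
  print(round(vp, 3))
  invisible(x)
}

#' @export
summary.mxe <- function(object, ...) {
  h2 <- genomic_heritability(object)
  vp <- variance_proportions(object)
  ryp <- tryCatch(variance_derived_phenotypic_correlation(object),
                  error = function(e) NULL)
  out <- list(h2 = h2, proportions = vp, r_y_prime = ryp,
              var_main = object$var_main,
              var_specific = object$var_specific, var_e = object$var_e,
              n_draws = object$n_draws, env_ids = object$env_ids)
  class(out) <- "summary.mxe"
  out
}

#' @export
print.summary.mxe <- function(x, ...) {
  cat("Marker-by-environment interaction model\n")
  cat(sprintf("  posterior draws: %d\n", x$n_draws))
  cat("  genomic heritability per environment:\n")
  h2 <- x$h2; mean_h2 <- attr(h2, "mean"); attributes(h2) <- list(names = names(h2))
  print(round(h2, 3))
  cat(sprintf("  mean h2 across environments: %.3f\n", mean_h2))
  cat("  variance proportions:\n")
  print(round(x$proportions, 3))
  if (!is.null(x$r_y_prime) && is.numeric(x$r_y_prime) &&
      length(x$r_y_prime) == 1)
    cat(sprintf("  variance-derived phenotypic correlation: %.3f\n",
                x$r_y_prime))
  invisible(x)
}

#' @export
coef.mxe <- function(object, ...)
  cbind(main = object$alpha0, object$alpha_env)

#' @export
fitted.mxe <- function(object, ...) object$yhat

#' @export
residuals.mxe <- function(object, ...) object$Y - object$yhat

#' @export
predict.mxe <- function(object, lines = NULL, env = NULL,
                        type = c("genetic", "response"), ...) {
  type <- match.arg(type)
  out <- if (type == "genetic") object$g else object$yhat
  if (!is.null(lines)) {
    unknown <- setdiff(lines, object$line_ids)
    if (length(unknown))
      stop(sprintf("unknown line(s): %s", paste(head(unknown, 5), collapse = ", ")))
    out <- out[lines, , drop = FALSE]
  }
  if (!is.null(env)) out <- out[, env]
  out
}

#' @export
plot.mxe <- function(x, ...) {
  vp <- variance_proportions(x)
  barplot(vp, beside = FALSE, legend.text = rownames(vp),
          ylab = "proportion of variance", ...)
  invisible(x)
}

#' Genomic heritability
#'
#' Proportion of phenotypic variance captured by markers. For the M-by-E
#' model, per environment l:
#' \deqn{h^2_l = (\sigma^2_{u0} + \sigma^2_{ul}) /
#'   (\sigma^2_{u0} + \sigma^2_{ul} + \sigma^2_{\epsilon l})}
#' with the genetic components on the genetic-value scale (marker variance
#' times `MSx`). The `"mean"` attribute carries the average across
#' environments, the single-number summary conventionally reported for a
#' multi-environment trial.
#'
#' @param fit a fitted [mxe()] or [wgr()] object.
#' @param ... unused.
#' @return For `mxe`: named per-environment vector with attribute `"mean"`;
#'   for `wgr`: a single posterior-mean heritability.
#' @export
genomic_heritability <- function(fit, ...) UseMethod("genomic_heritability")

#' @export
genomic_heritability.mxe <- function(fit, ...) {
  vg_main <- fit$var_main * fit$MSx
  vg_spec <- fit$var_specific * fit$MSx
  h2 <- (vg_main + vg_spec) / (vg_main + vg_spec + fit$var_e)
  attr(h2, "mean") <- mean(h2)
  h2
}

#' @export
genomic_heritability.wgr <- function(fit, ...) fit$h2

#' Variance proportions of the M-by-E model
#'
#' Per environment, the proportions of phenotypic variance attributed to the
#' main (across-environment) genetic component, the environment-specific
#' genetic component and the residual; genetic components are expressed on
#' the genetic-value scale. Columns sum to one.
#'
#' @param fit a fitted [mxe()] object.
#' @return 3 x L matrix with rows `main`, `specific`, `residual`.
#' @export
variance_proportions <- function(fit) {
  stopifnot(inherits(fit, "mxe"))
  vg_main <- fit$var_main * fit$MSx
  vg_spec <- fit$var_specific * fit$MSx
  tot <- vg_main + vg_spec + fit$var_e
  rbind(main = vg_main / tot, specific = vg_spec / tot,
        residual = fit$var_e / tot)
}

#' Variance-component-derived phenotypic correlation
#'
#' From the M-by-E variance components, the phenotypic correlation between
#' two environments implied by the shared main genetic variance:
#' \deqn{r_y' = \sigma^2_{u0} / \sqrt{(\sigma^2_{u0} + \sigma^2_{u1} +
#'   \sigma^2_{\epsilon 1})(\sigma^2_{u0} + \sigma^2_{u2} +
#'   \sigma^2_{\epsilon 2})}}
#' computed by plugging in posterior-mean variance components on the
#' genetic-value scale.
#'
#' @param fit a fitted [mxe()] object.
#' @return A single correlation for two environments, otherwise the L x L
#'   matrix of pairwise values.
#' @export
variance_derived_phenotypic_correlation <- function(fit) {
  stopifnot(inherits(fit, "mxe"))
  vg_main <- fit$var_main * fit$MSx
  vg_spec <- fit$var_specific * fit$MSx
  tot <- vg_main + vg_spec + fit$var_e
  L <- length(tot)
  out <- matrix(1, L, L, dimnames = list(fit$env_ids, fit$env_ids))
  for (a in seq_len(L - 1)) for (b in seq((a + 1), L)) {
    num <- sqrt(vg_main[a] * vg_main[b])   # equal across envs when MSx equal
    out[a, b] <- out[b, a] <- num / sqrt(tot[a] * tot[b])
  }
  if (L == 2) unname(out[1, 2]) else out
}

# ---- bivariate GBLUP --------------------------------------------------------

#' Bivariate GBLUP for the genomic correlation between two environments
#'
#' Treats the same trait in two environments as two correlated traits:
#' `(u, e) ~ N(0, Sigma_u x G, Sigma_e x I)` with 2x2 genetic and residual
#' covariance matrices carrying inverse Wishart priors (identity scale
#' matrices by default). Sampling is done in the eigenbasis of G so every
#' iteration reduces to independent 2x2 Gaussian draws; lines missing a
#' phenotype in one environment are handled by data augmentation.
#'
#' @param Y lines x 2 phenotype matrix (rownames = line ids, `NA` allowed).
#' @param K a [kernel_matrix()] (typically G) over all lines of `Y`.
#' @param mcmc an [mcmc_settings()].
#' @param nu_u,nu_e inverse Wishart degrees of freedom (default 4, weakly
#'   informative for a 2x2 matrix).
#' @param S_u,S_e inverse Wishart scale matrices (default identity).
#' @return An object of class `bivariate_gblup` with posterior means of
#'   `Sigma_u`, `Sigma_e`, genetic values `u` (n x 2), the chains of the
#'   covariance elements, the posterior-mean genomic correlation `r_g`, and
#'   the count of non-positive-definite draws that had to be re-jittered.
#' @examples
#' panel <- simulate_panel(sim_config(n_lines = 60, m_markers = 100, seed = 9))
#' G <- genomic_relationship(standardize_markers(panel$geno))
#' fit <- bivariate_gblup(panel$phenotypes, G, mcmc = mcmc_quick())
#' genomic_correlation(fit)
#' @export
bivariate_gblup <- function(Y, K, mcmc = mcmc_settings(), nu_u = 4, nu_e = 4,
                            S_u = diag(2), S_e = diag(2)) {
  stopifnot(is.matrix(Y), ncol(Y) == 2, inherits(K, "kernel_matrix"),
            inherits(mcmc, "mcmc_settings"))
  if (is.null(rownames(Y))) stop("Y needs line ids as rownames")
  ids <- K$line_ids
  missing_ids <- setdiff(rownames(Y), ids)
  if (length(missing_ids))
    stop(sprintf("lines missing from the kernel: %s",
                 paste(head(missing_ids, 5), collapse = ", ")))
  Yfull <- matrix(NA_real_, length(ids), 2, dimnames = list(ids, colnames(Y)))
  Yfull[rownames(Y), ] <- Y
  n <- length(ids)
  obs <- !is.na(Yfull)
  if (any(colSums(obs) < 3)) stop("need >= 3 phenotyped lines per environment")

  e <- eigen(K$values, symmetric = TRUE)
  lmax <- max(e$values, 0)
  keep <- e$values > 1e-10 * max(lmax, 1)
  if (min(e$values) < -1e-8 * max(lmax, 1))
    stop("kernel is not positive semi-definite")
  Q <- e$vectors[, keep, drop = FALSE]
  d <- e$values[keep]
  r <- length(d)

  n_iter <- mcmc$n_iter; burn_in <- mcmc$burn_in; thin <- mcmc$thin
  n_keep <- (n_iter - burn_in) %/% thin

  vys <- apply(Yfull, 2, var, na.rm = TRUE)
  Sigma_u <- diag(vys / 2); Sigma_e <- diag(vys / 2)
  mu <- colMeans(Yfull, na.rm = TRUE)
  Ycur <- Yfull
  for (l in 1:2) Ycur[!obs[, l], l] <- mu[l]
  U <- matrix(0, n, 2)
  V <- matrix(0, r, 2)

  su_chain <- matrix(NA_real_, n_keep, 3,
                     dimnames = list(NULL, c("var1", "var2", "cov")))
  se_chain <- matrix(NA_real_, n_keep, 3,
                     dimnames = list(NULL, c("var1", "var2", "cov")))
  mu_chain <- matrix(NA_real_, n_keep, 2)
  rg_chain <- numeric(n_keep)
  U_sum <- matrix(0, n, 2)
  n_bad <- 0L

  riwish <- function(S, nu) {
    # inverse Wishart draw via the Wishart of the inverse scale
    for (try in 1:50) {
      P <- tryCatch(rWishart(1, nu, solve(S))[, , 1], error = function(x) NULL)
      if (!is.null(P)) {
        ch <- tryCatch(chol(P), error = function(x) NULL)
        if (!is.null(ch)) return(chol2inv(ch))
      }
      n_bad <<- n_bad + 1L
      S <- S + diag(1e-8 * mean(diag(S)), nrow(S))
    }
    stop("inverse Wishart draw failed repeatedly")
  }

  kept <- 0
  for (it in seq_len(n_iter)) {
    # intercepts: rows iid N(mu + u_i, Sigma_e)
    Emat <- Ycur - U
    mu <- as.numeric(colMeans(Emat)) +
      as.numeric(crossprod(chol(Sigma_e / n), rnorm(2)))
    # genetic values in the eigenbasis: per component j a 2x2 GLS draw
    A <- solve(Sigma_e)
    B <- solve(Sigma_u)
    Ystar <- crossprod(Q, sweep(Ycur, 2, mu, "-"))  # r x 2
    Tm <- Ystar %*% A                               # A y*, r x 2
    p11 <- A[1, 1] + B[1, 1] / d
    p22 <- A[2, 2] + B[2, 2] / d
    p12 <- A[1, 2] + B[1, 2] / d
    det <- p11 * p22 - p12^2
    c11 <- p22 / det; c22 <- p11 / det; c12 <- -p12 / det
    m1 <- c11 * Tm[, 1] + c12 * Tm[, 2]
    m2 <- c12 * Tm[, 1] + c22 * Tm[, 2]
    L11 <- sqrt(c11)
    L21 <- c12 / L11
    L22 <- sqrt(pmax(c22 - L21^2, 1e-300))
    z1 <- rnorm(r); z2 <- rnorm(r)
    V[, 1] <- m1 + L11 * z1
    V[, 2] <- m2 + L21 * z1 + L22 * z2
    U <- Q %*% V
    # covariance matrices
    SSu <- crossprod(V, V / d)
    Sigma_u <- riwish(S_u + SSu, nu_u + r)
    Emat <- sweep(Ycur - U, 2, mu, "-")
    Sigma_e <- riwish(S_e + crossprod(Emat), nu_e + n)
    # augmentation of missing cells given the other environment's residual
    for (l in 1:2) {
      mis <- !obs[, l]
      if (!any(mis)) next
      o <- 3 - l
      cond_ok <- obs[mis, o]
      mcond <- sdcond <- numeric(sum(mis))
      rho_num <- Sigma_e[1, 2] / Sigma_e[o, o]
      e_other <- Ycur[mis, o] - mu[o] - U[mis, o]
      mcond <- ifelse(cond_ok, rho_num * e_other, 0)
      vcond <- ifelse(cond_ok,
                      Sigma_e[l, l] - Sigma_e[1, 2]^2 / Sigma_e[o, o],
                      Sigma_e[l, l])
      Ycur[mis, l] <- mu[l] + U[mis, l] + mcond +
        rnorm(sum(mis), 0, sqrt(pmax(vcond, 1e-12)))
    }

    if (it > burn_in && (it - burn_in) %% thin == 0 && kept < n_keep) {
      kept <- kept + 1
      su_chain[kept, ] <- c(Sigma_u[1, 1], Sigma_u[2, 2], Sigma_u[1, 2])
      se_chain[kept, ] <- c(Sigma_e[1, 1], Sigma_e[2, 2], Sigma_e[1, 2])
      mu_chain[kept, ] <- mu
      rg_chain[kept] <- Sigma_u[1, 2] / sqrt(Sigma_u[1, 1] * Sigma_u[2, 2])
      U_sum <- U_sum + U
    }
  }

  Sigma_u_hat <- matrix(c(mean(su_chain[, 1]), mean(su_chain[, 3]),
                          mean(su_chain[, 3]), mean(su_chain[, 2])), 2, 2)
  Sigma_e_hat <- matrix(c(mean(se_chain[, 1]), mean(se_chain[, 3]),
                          mean(se_chain[, 3]), mean(se_chain[, 2])), 2, 2)
  U_mean <- U_sum / kept
  dimnames(U_mean) <- list(ids, colnames(Y))
  chains <- list(Sigma_u = su_chain, Sigma_e = se_chain, r_g = rg_chain)
  structure(list(Sigma_u = Sigma_u_hat, Sigma_e = Sigma_e_hat,
                 u = U_mean, mu = setNames(as.numeric(colMeans(mu_chain)),
                                           colnames(Y)),
                 r_g = mean(rg_chain), chains = chains, n_draws = kept,
                 n_bad_draws = n_bad, line_ids = ids,
                 env_ids = colnames(Y)),
            class = "bivariate_gblup")
}

#' @export
print.bivariate_gblup <- function(x, ...) {
  cat(sprintf("<bivariate_gblup> %d lines, %d posterior draws\n",
              length(x$line_ids), x$n_draws))
  cat(sprintf("  genomic correlation r_g = %.3f\n", x$r_g))
  cat("  Sigma_u:\n"); print(round(x$Sigma_u, 4))
  cat("  Sigma_e:\n"); print(round(x$Sigma_e, 4))
  if (x$n_bad_draws > 0)
    cat(sprintf("  (%d covariance draws required jitter)\n", x$n_bad_draws))
  invisible(x)
}

#' Genomic correlation between environments
#'
#' `r_g = sigma_u12 / sqrt(sigma2_u1 sigma2_u2)`, computed per posterior draw
#' of the genetic covariance matrix and summarized by the posterior mean.
#' Draws with (numerically) zero genetic variance are skipped and counted.
#'
#' @param fit a [bivariate_gblup()] object, or a matrix/data frame of draws
#'   with columns (covariance, variance 1, variance 2).
#' @return Posterior-mean genomic correlation with attribute `"n_skipped"`.
#' @export
genomic_correlation <- function(fit) {
  if (inherits(fit, "bivariate_gblup")) {
    draws <- cbind(fit$chains$Sigma_u[, "cov"],
                   fit$chains$Sigma_u[, "var1"],
                   fit$chains$Sigma_u[, "var2"])
  } else {
    draws <- as.matrix(fit)
    if (ncol(draws) != 3)
      stop("draws must have columns (covariance, variance 1, variance 2)")
  }
  ok <- draws[, 2] > 1e-12 & draws[, 3] > 1e-12
  rg <- draws[ok, 1] / sqrt(draws[ok, 2] * draws[ok, 3])
  out <- mean(rg)
  attr(out, "n_skipped") <- sum(!ok)
  out
}
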