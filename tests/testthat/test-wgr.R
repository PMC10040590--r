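test_that("prior scale rules follow the stated defaults", {
  # kernel rule: S_u = Vy * r2 * (df + 2) / mean(diag(K))
  y <- c(-1, 1)           # sample variance exactly 2
  K <- kernel_matrix(diag(2))
  pr <- complete_prior(y, "kernel", kernels = list(K))
  expect_equal(unname(pr$S_u), 2 * 0.5 * 7 / 1)
  expect_equal(pr$S_e, 2 * 0.5 * 7)
  # r2 -> 0 collapses the prior genetic scale
  pr0 <- complete_prior(y, "kernel", kernels = list(K),
                        prior = prior_spec(r2 = 1e-9))
  expect_lt(pr0$S_u, 1e-7)
  # marker rule divides by MSx, and by (1 - pi) for spike-and-slab priors
  W <- matrix(c(-1, 0, 1, 2, 0, -2), 3, 2)
  msx <- sum(apply(W, 2, var))
  prm <- complete_prior(c(0, 1, 3), "marker", W = W)
  expect_equal(prm$S_alpha, var(c(0, 1, 3)) * 0.5 * 7 / msx)
  prs <- complete_prior(c(0, 1, 3), "marker", W = W, spike = TRUE)
  expect_equal(prs$S_alpha, prm$S_alpha / (1 - 0.99))
  expect_equal(prs$pi, 0.99)          # default mixture proportion retained
  expect_error(complete_prior(c(1, 1, 1), "marker", W = W),
               "variance is zero")
})

test_that("scaled inverse chi-square posterior draws have the stated moments", {
  # the full conditional used everywhere is (S + SS) / chisq(df + k):
  # its mean must be (S + SS) / (df + k - 2)
  set.seed(1)
  S <- 3; SS <- 12; df <- 5; k <- 9
  draws <- (S + SS) / rchisq(2e5, df + k)
  expect_equal(mean(draws), (S + SS) / (df + k - 2), tolerance = 0.01)
})

test_that("fixed-variance Gibbs matches the conjugate closed form on a toy", {
  set.seed(2)
  n <- 8
  W <- scale(matrix(rnorm(n * 30), n))
  G <- genomic_relationship(W)
  y <- setNames(rnorm(n), G$line_ids)
  vu <- 0.7; ve <- 0.4
  set.seed(3)
  fit <- wgr(y, kernels = G, model = "gblup",
             mcmc = mcmc_settings(6000, 1000, 2),
             fix_var_u = vu, fix_var_e = ve, store_u = TRUE)
  oracle <- conjugate_oracle(y, G$values, vu, ve)
  expect_gt(cor(fit$g, oracle), 0.999)
  expect_lt(max(abs(fit$g - oracle)), 0.05)
  expect_equal(unique(fit$chains$var_e), ve)
})

test_that("near-zero genetic variance collapses predictions to the mean", {
  set.seed(4)
  g <- tiny_geno(n = 20, m = 40, seed = 5)
  y <- setNames(rnorm(20, 10), g$line_ids)
  fit <- wgr(y, markers = g, model = "gblup", mcmc = mc_test(),
             fix_var_u = 1e-12)
  expect_lt(max(abs(fit$g)), 1e-4)
  expect_equal(unname(predict(fit, type = "response")),
               rep(fit$mu, 20), tolerance = 1e-3)
})

test_that("chains are bit-identical under the same seed and settings", {
  g <- tiny_geno(n = 15, m = 30, seed = 6)
  y <- planted_qtl_phenotype(g, 3, seed = 7)
  for (mod in c("gblup", "bayesc")) {
    set.seed(11); f1 <- wgr(y, markers = g, model = mod, mcmc = mc_test())
    set.seed(11); f2 <- wgr(y, markers = g, model = mod, mcmc = mc_test())
    expect_identical(f1$chains, f2$chains)
    expect_identical(f1$g, f2$g)
  }
})

test_that("fits are location-scale equivariant (matched seeds)", {
  g <- tiny_geno(n = 20, m = 40, seed = 8)
  y <- planted_qtl_phenotype(g, 1, seed = 9)
  a <- 2.5; b <- -4
  set.seed(21); f1 <- wgr(y, markers = g, model = "gblup", mcmc = mc_test())
  set.seed(21); f2 <- wgr(a * y + b, markers = g, model = "gblup",
                          mcmc = mc_test())
  expect_equal(f2$mu, a * f1$mu + b, tolerance = 1e-8)
  expect_equal(f2$chains$var_e, a^2 * f1$chains$var_e, tolerance = 1e-8)
  expect_equal(f2$chains$var_u[, 1], a^2 * f1$chains$var_u[, 1],
               tolerance = 1e-8)
  expect_equal(cor(f1$g, f2$g), 1, tolerance = 1e-10)
  set.seed(22); m1 <- wgr(y, markers = g, model = "bayesb", mcmc = mc_test())
  set.seed(22); m2 <- wgr(a * y + b, markers = g, model = "bayesb",
                          mcmc = mc_test())
  expect_equal(m2$chains$var_e, a^2 * m1$chains$var_e, tolerance = 1e-8)
  expect_identical(m1$chains$n_incl, m2$chains$n_incl)
})

test_that("averaging two identical kernels splits variance but keeps predictions", {
  set.seed(31)
  panel <- simulate_panel(sim_config(n_lines = 60, m_markers = 150, seed = 32))
  y <- panel$phenotypes[, 1]
  G <- genomic_relationship(standardize_markers(panel$geno))
  mc <- mcmc_settings(3000, 500, 2)
  set.seed(33); single <- wgr(y, kernels = G, model = "gblup", mcmc = mc)
  set.seed(34); dual <- wgr(y, kernels = list(a = G, b = G), model = "rkhs",
                            mcmc = mc)
  expect_gt(cor(single$g, dual$g), 0.99)
  expect_equal(sum(dual$var_u), single$var_u[[1]], tolerance = 0.25)
})

test_that("unphenotyped lines are predicted through their kernel rows", {
  set.seed(41)
  panel <- simulate_panel(sim_config(n_lines = 70, m_markers = 200,
                                     h2 = 0.8, seed = 42))
  y <- panel$phenotypes[, 1]
  miss <- sample(names(y), 20)
  ymask <- y; ymask[miss] <- NA
  G <- genomic_relationship(standardize_markers(panel$geno))
  set.seed(43)
  fit <- wgr(ymask, kernels = G, model = "gblup",
             mcmc = mcmc_settings(2000, 500, 2))
  expect_equal(fit$n_obs, 50)
  expect_gt(cor(fit$g[miss], panel$truth$g[miss, 1]), 0.3)
  # kernel fits refuse genuinely new genotypes but serve known lines
  expect_error(predict(fit, lines = "nope"), "unknown line")
  expect_equal(predict(fit, lines = miss), fit$g[miss])
})

test_that("chain bookkeeping and summaries are consistent", {
  g <- tiny_geno(n = 12, m = 20, seed = 51)
  y <- planted_qtl_phenotype(g, 2, seed = 52)
  fit <- wgr(y, markers = g, model = "gblup",
             mcmc = mcmc_settings(1000, 400, 3))
  expect_equal(fit$n_draws, (1000 - 400) %/% 3)
  expect_length(fit$chains$var_e, fit$n_draws)
  s <- summary(fit)
  expect_true(all(c("mean", "sd", "ess") %in% colnames(s$table)))
  expect_true(all(fit$chains$var_e > 0))
  expect_true(all(fit$chains$h2 >= 0 & fit$chains$h2 <= 1))
  expect_error(wgr(y, markers = g, mcmc = mcmc_settings(100, 99, 5)),
               "zero-length chain")
})

test_that("residuals, fitted and simulate methods are coherent", {
  g <- tiny_geno(n = 30, m = 25, seed = 61)
  y <- planted_qtl_phenotype(g, 4, seed = 62)
  fit <- wgr(y, markers = g, model = "rrblup", mcmc = mc_test())
  expect_equal(fitted(fit) + residuals(fit), y, ignore_attr = TRUE)
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(30L, 3L))
})
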