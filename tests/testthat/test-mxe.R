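# minimal fitted-object stub for the plug-in parameter formulas
mxe_stub <- function(var_main, var_specific, var_e, env_ids = c("e1", "e2")) {
  structure(list(var_main = var_main,
                 var_specific = setNames(var_specific, env_ids),
                 var_e = setNames(var_e, env_ids),
                 MSx = setNames(rep(1, length(env_ids)), env_ids),
                 env_ids = env_ids),
            class = "mxe")
}

test_that("variance proportions, heritability and r_y' match hand calculations", {
  f <- mxe_stub(1, c(1, 1), c(2, 2))
  vp <- variance_proportions(f)
  expect_equal(unname(vp[, 1]), c(0.25, 0.25, 0.5))
  expect_equal(colSums(vp), c(e1 = 1, e2 = 1), tolerance = 1e-12)
  h2 <- genomic_heritability(f)
  expect_equal(as.numeric(h2), c(0.5, 0.5))
  expect_equal(attr(h2, "mean"), 0.5)
  # zero residual: proportions still sum to one, residual share zero
  vp0 <- variance_proportions(mxe_stub(1, c(1, 1), c(0, 0)))
  expect_equal(unname(vp0["residual", ]), c(0, 0))
  expect_equal(colSums(vp0), c(e1 = 1, e2 = 1), tolerance = 1e-12)
  # r_y' plug-ins
  expect_equal(variance_derived_phenotypic_correlation(
    mxe_stub(1, c(0, 0), c(1, 1))), 0.5)
  expect_equal(variance_derived_phenotypic_correlation(
    mxe_stub(0, c(1, 2), c(1, 1))), 0)
  expect_equal(variance_derived_phenotypic_correlation(
    mxe_stub(2, c(1, 0), c(1, 2))), 2 / sqrt(4 * 4))
  # zero genetic variance gives zero heritability
  expect_equal(as.numeric(genomic_heritability(mxe_stub(0, c(0, 0), c(1, 1)))),
               c(0, 0))
})

test_that("genomic correlation summarises posterior draws with skips counted", {
  expect_equal(as.numeric(genomic_correlation(
    matrix(c(0.5, 1, 1), 1))), 0.5)
  expect_equal(as.numeric(genomic_correlation(
    matrix(c(1, 1, 1), 1))), 1)
  draws <- rbind(c(0.4, 1, 1), c(0.6, 1, 1))
  expect_equal(as.numeric(genomic_correlation(draws)), 0.5)
  withskip <- rbind(c(0.4, 1, 1), c(0.6, 1, 1), c(1, 0, 1))
  out <- genomic_correlation(withskip)
  expect_equal(as.numeric(out), 0.5)
  expect_equal(attr(out, "n_skipped"), 1L)
})

test_that("duplicated environments load the variance on the main effects", {
  panel <- simulate_panel(sim_config(n_lines = 100, m_markers = 250,
                                     seed = 21))
  y <- panel$phenotypes[, 1]
  Y <- cbind(env1 = y, env2 = y)
  set.seed(22)
  fit <- mxe(Y, panel$geno, mcmc = mcmc_settings(1500, 500, 2))
  vp <- variance_proportions(fit)
  main_share <- vp["main", ] / (vp["main", ] + vp["specific", ])
  expect_true(all(main_share > 0.8))
  expect_gt(vp["main", 1], vp["specific", 1])
})

test_that("independent environments put more variance on specific effects", {
  panel <- simulate_panel(sim_config(n_lines = 100, m_markers = 250,
                                     r_g = 0, h2 = 0.5, seed = 23))
  set.seed(24)
  fit <- mxe(panel$phenotypes, panel$geno, mcmc = mcmc_settings(1500, 500, 2))
  vp <- variance_proportions(fit)
  expect_true(all(vp["main", ] < vp["specific", ]))
})

test_that("swapping environment labels swaps the specific summaries", {
  panel <- simulate_panel(sim_config(n_lines = 80, m_markers = 200,
                                     h2 = c(0.7, 0.3), seed = 25))
  Y <- panel$phenotypes
  set.seed(26); f12 <- mxe(Y, panel$geno, mcmc = mcmc_settings(1500, 500, 2))
  set.seed(26); f21 <- mxe(Y[, 2:1], panel$geno,
                           mcmc = mcmc_settings(1500, 500, 2))
  expect_lt(abs(f12$var_e[["env1"]] - f21$var_e[["env1"]]),
            0.2 * f12$var_e[["env1"]])
  expect_lt(abs(f12$var_main - f21$var_main), 0.3 * f12$var_main)
  h12 <- genomic_heritability(f12); h21 <- genomic_heritability(f21)
  expect_lt(abs(h12[["env1"]] - h21[["env1"]]), 0.1)
  expect_lt(abs(h12[["env2"]] - h21[["env2"]]), 0.1)
})

test_that("single-environment input is redirected to the single-env models", {
  panel <- simulate_panel(sim_config(n_lines = 20, m_markers = 30, seed = 27))
  expect_error(mxe(panel$phenotypes[, 1, drop = FALSE], panel$geno),
               "single environment")
  Ybad <- panel$phenotypes
  rownames(Ybad) <- paste0("X", seq_len(nrow(Ybad)))
  expect_error(mxe(Ybad, panel$geno), "missing from the genotypes")
})

test_that("bivariate GBLUP recovers a duplicated environment and the zero case", {
  panel <- simulate_panel(sim_config(n_lines = 90, m_markers = 200,
                                     seed = 31))
  y <- panel$phenotypes[, 1]
  G <- genomic_relationship(standardize_markers(panel$geno))
  Y <- cbind(env1 = y, env2 = y)
  set.seed(32)
  fit <- bivariate_gblup(Y, G, mcmc = mcmc_settings(1500, 500, 2))
  expect_gt(fit$r_g, 0.95)
  expect_true(all(eigen(fit$Sigma_u, TRUE, TRUE)$values > 0))
  expect_true(all(eigen(fit$Sigma_e, TRUE, TRUE)$values > 0))
  expect_true(abs(fit$r_g) <= 1)
})

test_that("bivariate r_g and the M-by-E main share increase with true r_g", {
  rg_grid <- c(0, 0.4, 0.8)
  rg_hat <- main_share <- numeric(3)
  for (i in seq_along(rg_grid)) {
    panel <- simulate_panel(sim_config(n_lines = 150, m_markers = 300,
                                       r_g = rg_grid[i], h2 = 0.5,
                                       seed = 40 + i))
    G <- genomic_relationship(standardize_markers(panel$geno))
    set.seed(50 + i)
    fb <- bivariate_gblup(panel$phenotypes, G,
                          mcmc = mcmc_settings(1500, 500, 2))
    rg_hat[i] <- fb$r_g
    set.seed(60 + i)
    fm <- mxe(panel$phenotypes, panel$geno,
              mcmc = mcmc_settings(1500, 500, 2))
    vp <- variance_proportions(fm)
    main_share[i] <- mean(vp["main", ] / (vp["main", ] + vp["specific", ]))
  }
  expect_true(all(diff(rg_hat) > 0))
  expect_true(all(diff(main_share) > 0))
  expect_true(all(abs(rg_hat) <= 1))
})
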