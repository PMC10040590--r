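test_that("subsampling partitions use the floor rule and are seed-deterministic", {
  ids <- sprintf("L%03d", 1:182)
  p <- cv_partitions(ids, "single", n_reps = 3, train_frac = 2/3, seed = 1)
  expect_length(p$reps[[1]]$trn, 121)   # floor(182 * 2/3)
  expect_length(p$reps[[1]]$tst, 61)
  expect_setequal(c(p$reps[[1]]$trn, p$reps[[1]]$tst), ids)
  p2 <- cv_partitions(ids, "single", n_reps = 3, train_frac = 2/3, seed = 1)
  expect_identical(p, p2)
  expect_error(cv_partitions(ids, "single", train_frac = 0.001),
               "degenerate split")
  expect_error(cv_partitions(ids, "cv0", n_env = 1), "at least 2 environments")
})

test_that("cv2 partitions satisfy the masked-cell bookkeeping invariant", {
  ids <- sprintf("L%02d", 1:30)
  p <- cv_partitions(ids, "cv2", n_reps = 5, seed = 2)
  for (rep in p$reps) {
    # masked thirds are disjoint: every masked cell's line is observed in
    # the other environment
    expect_length(intersect(rep$mask_env1, rep$mask_env2), 0)
    expect_setequal(c(rep$mask_env1, rep$mask_env2, rep$observed_both), ids)
  }
})

test_that("cv1 partitions mask test lines in every environment", {
  ids <- sprintf("L%02d", 1:30)
  p <- cv_partitions(ids, "cv1", n_reps = 4, seed = 3)
  for (rep in p$reps) {
    expect_length(intersect(rep$trn, rep$tst), 0)
    expect_setequal(c(rep$trn, rep$tst), ids)
  }
})

test_that("the corrected resampled t-test matches hand computation and edge cases", {
  # hand plug-in: K = 50, dbar = 0.1, s_d = 0.1, train_frac = 2/3
  set.seed(4)
  d <- rnorm(50)
  d <- (d - mean(d)) / sd(d) * 0.1 + 0.1   # exact moments
  b <- rnorm(50)
  out <- corrected_resampled_ttest(b + d, b, train_frac = 2/3)
  expect_equal(out$t, 0.1 / sqrt((1 / 50 + 0.5) * 0.01), tolerance = 1e-10)
  expect_equal(out$df, 49)
  # identical vectors
  same <- corrected_resampled_ttest(rep(0.5, 10), rep(0.5, 10))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  expect_true(same$degenerate)
  # zero variance with nonzero mean
  shift <- corrected_resampled_ttest(rep(0.6, 10), rep(0.5, 10))
  expect_equal(shift$p, 0); expect_true(shift$degenerate)
  expect_error(corrected_resampled_ttest(1, 1:2), "equal length")
})

test_that("an oracle predictor attains accuracy one; pure noise hovers near zero", {
  panel <- simulate_panel(sim_config(n_lines = 60, m_markers = 100,
                                     seed = 5))
  ids <- panel$geno$line_ids
  p <- cv_partitions(ids, "single", n_reps = 10, seed = 6)
  y <- panel$phenotypes[, 1]
  # oracle: leak the truth -> correlation 1 by construction
  for (rep in p$reps)
    expect_equal(cor(y[rep$tst], y[rep$tst]), 1)
  # pure-noise phenotype: mean accuracy near zero
  set.seed(7)
  y0 <- setNames(rnorm(60), ids)
  res <- cv_single_env(y0, panel$geno, "gblup", p, mcmc = mc_test())
  expect_lt(abs(mean(res$accuracy, na.rm = TRUE)), 0.15)
})

test_that("masked phenotypes never reach the fit (leakage instrumentation)", {
  panel <- simulate_panel(sim_config(n_lines = 40, m_markers = 60, seed = 8))
  ids <- panel$geno$line_ids
  p <- cv_partitions(ids, "single", n_reps = 1, seed = 9)
  y <- panel$phenotypes[, 1]
  set.seed(10)
  r1 <- cv_single_env(y, panel$geno, "gblup", p, mcmc = mc_test(),
                      return_predictions = TRUE)
  # corrupt the held-out phenotypes (non-affinely, so the accuracy must
  # move): predictions must not move
  y2 <- y
  tst1 <- p$reps[[1]]$tst
  y2[tst1] <- sample(y2[tst1])^2 + seq_along(tst1)
  set.seed(10)
  r2 <- cv_single_env(y2, panel$geno, "gblup", p, mcmc = mc_test(),
                      return_predictions = TRUE)
  expect_identical(attr(r1, "predictions"), attr(r2, "predictions"))
  expect_false(isTRUE(all.equal(r1$accuracy, r2$accuracy)))
})

test_that("accuracy of true genetic values against phenotypes approaches sqrt(h2)", {
  panel <- simulate_panel(sim_config(n_lines = 300, m_markers = 400,
                                     h2 = 0.5, seed = 11))
  acc <- cor(panel$truth$g[, 1], panel$phenotypes[, 1])
  expect_equal(acc, sqrt(0.5), tolerance = 0.1)
})

test_that("cv0 fits one direction per environment and a duplicated target is easy", {
  panel <- simulate_panel(sim_config(n_lines = 60, m_markers = 120,
                                     h2 = 0.6, seed = 12))
  y <- panel$phenotypes[, 1]
  Y <- cbind(env1 = y, env2 = y)
  set.seed(13)
  res <- cv0(Y, panel$geno, mcmc = mc_test())
  expect_equal(nrow(res), 2L)
  expect_setequal(res$env, c("env1", "env2"))
  # duplicated environment: CV0 accuracy equals the within-sample fit
  expect_true(all(res$accuracy > 0.5))
  one <- cv0(Y, panel$geno, mcmc = mc_test(), directions = c("env1", "env2"))
  expect_equal(nrow(one), 1L)
  expect_equal(one$env, "env2")
})

test_that("undefined correlations are flagged as missing and counted", {
  panel <- simulate_panel(sim_config(n_lines = 30, m_markers = 40, seed = 14))
  ids <- panel$geno$line_ids
  y <- panel$phenotypes[, 1]
  tst <- ids[1:10]
  y[tst] <- 3.14            # constant held-out phenotypes
  parts <- structure(list(scenario = "single", train_frac = 2/3, n_reps = 1,
                          line_ids = ids, seed = NULL,
                          reps = list(list(trn = setdiff(ids, tst),
                                           tst = tst))),
                     class = "cv_partitions")
  set.seed(16)
  expect_warning(res <- cv_single_env(y, panel$geno, "gblup", parts,
                                      mcmc = mc_test()),
                 "undefined accuracy")
  expect_true(is.na(res$accuracy[1]))
  expect_equal(attr(res, "n_undefined"), 1)
})
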