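test_that("genotype container validates codes and identifiers", {
  expect_error(genotype_matrix(matrix(c(0, 3), 1, 2)), "invalid gene content")
  expect_error(genotype_matrix(matrix(0, 2, 2),
                               line_ids = c("a", "a")), "duplicate line_ids")
  g <- genotype_matrix(matrix(c(0, 1, 2, NA), 2, 2))
  expect_equal(dim(g), c(2L, 2L))
  expect_equal(unname(allele_freq(g)), c(0.25, 1))
})

test_that("marker QC removes low-MAF, heterozygous and all-missing markers", {
  # column 1: freq 0.03 -> removed at maf_min = 0.05; column 2: clean;
  # column 3: het rate 0.5 -> removed; column 4: all missing
  n <- 100
  X <- cbind(c(rep(1, 6), rep(0, 94)),            # af = 0.03
             rep(c(0, 2), 50),
             rep(c(1, 1, 0, 2), 25),              # het = 0.5
             rep(NA_real_, n))
  colnames(X) <- paste0("M", 1:4)
  g <- genotype_matrix(X)
  qc <- marker_qc(g, maf_min = 0.05, het_max = 0.2, r2_max = 0.99)
  expect_equal(qc$report$removed_maf, "M1")
  expect_equal(qc$report$removed_het, "M3")
  expect_equal(qc$report$removed_missing, "M4")
  expect_equal(qc$genotypes$marker_ids, "M2")
  expect_equal(qc$report$n_retained, 1L)
})

test_that("clean panels pass QC unchanged and QC is deterministic", {
  g <- tiny_geno(n = 60, m = 30, seed = 7)
  qc <- marker_qc(g, maf_min = 0.01, het_max = 1, r2_max = 0.999999)
  keep_clean <- marker_qc(qc$genotypes, maf_min = 0.01, het_max = 1,
                          r2_max = 0.999999)
  expect_identical(keep_clean$genotypes$values, qc$genotypes$values)
  expect_length(keep_clean$report$removed_maf, 0)
  expect_length(keep_clean$report$removed_ld, 0)
  again <- marker_qc(g, maf_min = 0.01, het_max = 1, r2_max = 0.999999)
  expect_identical(again$genotypes$marker_ids, qc$genotypes$marker_ids)
})

test_that("LD pruning keeps the first of a tightly linked pair (brute-force oracle)", {
  set.seed(5)
  base <- rbinom(5, 2, 0.5)
  X <- cbind(M1 = base, M2 = rbinom(5, 2, 0.5), M3 = base,
             M4 = rbinom(5, 2, 0.5))
  while (sd(X[, "M2"]) == 0 || sd(X[, "M4"]) == 0 ||
         cor(X[, "M2"], X[, "M1"])^2 >= 0.99 ||
         cor(X[, "M4"], X[, "M1"])^2 >= 0.99 ||
         cor(X[, "M4"], X[, "M2"])^2 >= 0.99) {
    X[, "M2"] <- rbinom(5, 2, 0.5); X[, "M4"] <- rbinom(5, 2, 0.5)
  }
  g <- genotype_matrix(X)
  r2 <- brute_force_r2(X)
  expect_true(r2[1, 3] >= 0.99)          # the duplicated pair
  qc <- marker_qc(g, maf_min = 0.01, het_max = 1, r2_max = 0.99)
  expect_equal(qc$report$removed_ld, "M3")
  expect_equal(qc$genotypes$marker_ids, c("M1", "M2", "M4"))
})

test_that("all markers removed raises an empty-panel error", {
  X <- matrix(c(rep(0, 19), 1), 10, 2)   # both columns af <= 0.05
  g <- genotype_matrix(X)
  expect_error(marker_qc(g, maf_min = 0.4), "empty panel")
})

test_that("standardization gives exact zero mean and unit sample sd", {
  g <- genotype_matrix(matrix(c(0, 1, 2, 1), 4, 1, dimnames = list(NULL, "M1")))
  W <- standardize_markers(g)
  expect_lt(abs(mean(W$values)), 1e-10)
  expect_lt(abs(sd(W$values) - 1), 1e-10)
  # hand value: centred first entry -1, sample sd sqrt(2/3)
  expect_equal(W$values[1, 1], -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_error(standardize_markers(
    genotype_matrix(matrix(1, 4, 1, dimnames = list(NULL, "Mc")))),
    "monomorphic marker 'Mc'")
  # idempotence: re-standardizing W is a no-op
  W2 <- standardize_markers(W$values)
  expect_lt(max(abs(W2$values - W$values)), 1e-10)
})

test_that("G = WW'/m matches direct computation and algebraic identities", {
  Wt <- matrix(c(1, -1, 0, -1, 1, 0), 3, 2)
  G <- genomic_relationship(Wt)
  expect_equal(unname(G$values),
               matrix(c(1, -1, 0, -1, 1, 0, 0, 0, 0), 3, 3))
  # duplicated lines give exactly equal G rows/blocks
  g <- tiny_geno(n = 6, m = 40, seed = 2)
  X2 <- rbind(g$values, g$values[1, , drop = FALSE])
  rownames(X2) <- c(g$line_ids, "dup")
  X2 <- X2[, apply(X2, 2, sd) > 0, drop = FALSE]
  W <- standardize_markers(genotype_matrix(X2))
  G2 <- genomic_relationship(W)
  expect_equal(G2$values["dup", ], G2$values[g$line_ids[1], ],
               ignore_attr = TRUE)
  expect_equal(G2$values["dup", "dup"],
               G2$values[g$line_ids[1], g$line_ids[1]])
  # mean diagonal identity for sample-standardized columns: (n-1)/n
  gg <- tiny_geno(n = 50, m = 500, seed = 3)
  Gs <- genomic_relationship(standardize_markers(gg))
  expect_equal(mean(diag(Gs$values)), 49 / 50, tolerance = 1e-10)
})

test_that("sample and HWE standardization agree under Hardy-Weinberg sampling", {
  g <- tiny_geno(n = 150, m = 2000, seed = 13)
  G1 <- genomic_relationship(standardize_markers(g, "sample"))$values
  G2 <- genomic_relationship(standardize_markers(g, "hwe"))$values
  expect_gt(cor(G1[upper.tri(G1)], G2[upper.tri(G2)]), 0.99)
})

test_that("Gaussian kernel has the closed form, unit diagonal and PSD spectrum", {
  W <- matrix(c(0, 1, 0, 0), 2, 2)       # rows at squared distance 1
  GK <- gaussian_kernel(W, 0.2)
  expect_equal(GK$values[1, 2], exp(-0.2), tolerance = 1e-12)
  expect_equal(diag(GK$values), rep(1, 2), ignore_attr = TRUE)
  expect_error(gaussian_kernel(W, -1), "nonnegative")
  expect_equal(unname(gaussian_kernel(W, 0)$values), matrix(1, 2, 2))
  # identical lines -> entry 1
  W2 <- rbind(a = c(1, 2), b = c(1, 2))
  expect_equal(gaussian_kernel(W2, 1.2)$values["a", "b"], 1)
  # eigenvalues nonnegative (within tolerance) for a random panel
  g <- tiny_geno(n = 120, m = 300, seed = 17)
  K <- gaussian_kernel(standardize_markers(g), 0.2)
  ev <- eigen(K$values, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
})

test_that("kernel averaging list is ordered and entrywise monotone in theta", {
  g <- tiny_geno(n = 20, m = 50, seed = 19)
  W <- standardize_markers(g)
  kl <- kernel_list(W)
  expect_length(kl, 2)
  expect_equal(vapply(kl, `[[`, numeric(1), "bandwidth"), c(0.2, 1.2),
               ignore_attr = TRUE)
  off <- upper.tri(kl[[1]]$values)
  expect_true(all(kl[[1]]$values[off] >= kl[[2]]$values[off]))
  expect_error(kernel_list(W, numeric(0)), "non-empty")
  expect_equal(unname(kernel_list(W, 0)[[1]]$values),
               matrix(1, 20, 20))
})

test_that("kernel constructor rejects asymmetric and indefinite matrices", {
  A <- matrix(c(1, 0.5, 0.4, 1), 2, 2)
  expect_error(kernel_matrix(A), "symmetric")
  B <- matrix(c(1, 2, 2, 1), 2, 2)       # eigenvalues 3, -1
  expect_error(kernel_matrix(B), "positive semi-definite")
})
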