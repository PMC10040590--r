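#' Cross-validation partitions
#'
#' Builds the replicate training/testing partitions for the four evaluation
#' designs used in multi-environment genomic prediction:
#'
#' * `"single"` — repeated random subsampling within one environment:
#'   `train_frac` of the lines (floor) are the training set (TRN), the rest
#'   the testing set (TST);
#' * `"cv0"` — leave one environment out: all lines of one environment
#'   predict the same lines in the other (no line-level partitions);
#' * `"cv1"` — new lines: TST lines are unphenotyped in every environment;
#' * `"cv2"` — sparse trials: per replicate the lines are split into thirds;
#'   one third is masked in environment 1, a disjoint third is masked in
#'   environment 2 and the remaining third is observed in both, so every
#'   masked cell's line is observed in the other environment.
#'
#' @param line_ids character vector of line identifiers (>= 3).
#' @param scenario one of `"single"`, `"cv0"`, `"cv1"`, `"cv2"`.
#' @param n_env number of environments (must be >= 2 for cv0/cv1/cv2).
#' @param n_reps number of replicates (default 50).
#' @param train_frac training fraction in (0, 1) (default 2/3).
#' @param seed optional integer seed; partitions are deterministic given it.
#' @return An object of class `cv_partitions`: a list with the scenario,
#'   the fractions, and one element per replicate describing the TRN/TST
#'   roles.
#' @examples
#' p <- cv_partitions(paste0("L", 1:182), "single", n_reps = 2, seed = 1)
#' lengths(p$reps[[1]])
#' @export
cv_partitions <- function(line_ids, scenario = c("single", "cv0", "cv1", "cv2"),
                          n_env = 2, n_reps = 50, train_frac = 2/3,
                          seed = NULL) {
  scenario <- match.arg(scenario)
  n <- length(line_ids)
  if (n < 3) stop("need at least 3 lines")
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must lie in (0, 1)")
  if (scenario %in% c("cv0", "cv1", "cv2") && n_env < 2)
    stop(sprintf("scenario %s needs at least 2 environments", scenario))
  if (!is.null(seed)) set.seed(seed)

  reps <- vector("list", n_reps)
  if (scenario == "single" || scenario == "cv1") {
    n_trn <- floor(n * train_frac)
    n_tst <- n - n_trn
    if (n_tst < 1 || n_trn < 2)
      stop("degenerate split: empty training or testing set")
    for (r in seq_len(n_reps)) {
      tst <- sort(sample(line_ids, n_tst))
      reps[[r]] <- list(trn = setdiff(line_ids, tst), tst = tst)
    }
  } else if (scenario == "cv2") {
    k <- floor(n / 3)
    if (k < 1) stop("too few lines for the thirds design")
    for (r in seq_len(n_reps)) {
      perm <- sample(line_ids)
      reps[[r]] <- list(mask_env1 = sort(perm[seq_len(k)]),
                        mask_env2 = sort(perm[k + seq_len(k)]),
                        observed_both = sort(perm[-(seq_len(2 * k))]))
    }
  } else { # cv0: whole environments as TRN/TST
    reps <- list(list(directions = "all"))
    n_reps <- 1
  }
  structure(list(scenario = scenario, train_frac = train_frac,
                 n_reps = n_reps, line_ids = line_ids, seed = seed,
                 reps = reps),
            class = "cv_partitions")
}

#' @export
print.cv_partitions <- function(x, ...) {
  cat(sprintf("<cv_partitions> scenario %s, %d replicates, train fraction %.3f\n",
              x$scenario, x$n_reps, x$train_frac))
  invisible(x)
}

.new_cv_result <- function(df, n_undefined = 0, predictions = NULL) {
  structure(df, class = c("cv_result", "data.frame"),
            n_undefined = n_undefined, predictions = predictions)
}

.safe_cor <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3 || sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
  cor(a[ok], b[ok])
}

#' Single-environment cross-validation
#'
#' Repeated random subsampling evaluation of the single-environment
#' whole-genome regressions: per replicate each model is fitted on the TRN
#' lines and the predictive Pearson correlation between observed and
#' predicted values is computed on the TST lines. Undefined correlations
#' (constant predictions) are recorded as `NA`, counted, and excluded from
#' the replicate mean.
#'
#' @param y named phenotype vector for one environment (BLUEs).
#' @param geno a [genotype_matrix()] (QC'd) covering the lines.
#' @param models subset of `c("gblup", "rkhs", "bayesb", "bayesc")`.
#' @param partitions a `"single"`-scenario [cv_partitions()].
#' @param mcmc an [mcmc_settings()]; defaults to the short profile.
#' @param prior a [prior_spec()].
#' @param return_predictions keep the per-replicate TST predictions (for
#'   auditing that masked phenotypes never reach the fit).
#' @return A `cv_result` data frame with columns `scenario`, `model`, `env`,
#'   `replicate`, `accuracy`.
#' @export
cv_single_env <- function(y, geno, models = "gblup", partitions,
                          mcmc = mcmc_quick(), prior = prior_spec(),
                          return_predictions = FALSE) {
  stopifnot(inherits(partitions, "cv_partitions"))
  if (partitions$scenario != "single")
    stop("partitions must use the 'single' scenario")
  models <- match.arg(models, c("gblup", "rkhs", "bayesb", "bayesc"),
                      several.ok = TRUE)
  W <- standardize_markers(impute_genotypes(geno))
  kernel_sets <- list()
  if ("gblup" %in% models) {
    G <- genomic_relationship(W)
    attr(G, "eigen") <- eigen(G$values, symmetric = TRUE)
    kernel_sets$gblup <- list(G = G)
  }
  if ("rkhs" %in% models) {
    kl <- kernel_list(W)
    kl <- lapply(kl, function(k) {
      attr(k, "eigen") <- eigen(k$values, symmetric = TRUE); k
    })
    kernel_sets$rkhs <- kl
  }
  y <- .align_y(y, geno$line_ids)

  rows <- list(); preds <- list(); n_undef <- 0
  for (r in seq_len(partitions$n_reps)) {
    part <- partitions$reps[[r]]
    y_trn <- y
    y_trn[part$tst] <- NA
    for (mod in models) {
      if (mod %in% c("gblup", "rkhs")) {
        fit <- wgr(y_trn, kernels = kernel_sets[[mod]], model = mod,
                   mcmc = mcmc, prior = prior)
      } else {
        fit <- wgr(y_trn, markers = geno, model = mod, mcmc = mcmc,
                   prior = prior)
      }
      pred <- fit$g[part$tst]
      acc <- .safe_cor(y[part$tst], pred)
      if (is.na(acc)) {
        n_undef <- n_undef + 1
        warning(sprintf("replicate %d, model %s: undefined accuracy (constant vector)",
                        r, mod))
      }
      rows[[length(rows) + 1]] <- data.frame(
        scenario = "single", model = mod, env = "env", replicate = r,
        accuracy = acc, stringsAsFactors = FALSE)
      if (return_predictions)
        preds[[paste(mod, r, sep = ".")]] <- pred
    }
  }
  .new_cv_result(do.call(rbind, rows), n_undef,
                 if (return_predictions) preds else NULL)
}

#' CV0: predict known lines in a new environment
#'
#' Fits single-environment GBLUP on all lines of the source environment and
#' correlates the fitted genetic values with the phenotypes of the same
#' lines in the target environment. No target-environment information enters
#' the fit; the Pearson correlation is scale-free, so genetic values are
#' compared to target phenotypes directly.
#'
#' @param Y lines x environments phenotype matrix.
#' @param geno a [genotype_matrix()].
#' @param mcmc,prior passed to [wgr()].
#' @param directions `"both"` (each environment predicts the other, default)
#'   or a single `c(from, to)` pair of environment names.
#' @return A `cv_result` data frame, one row per direction, `env` naming the
#'   predicted (target) environment.
#' @export
cv0 <- function(Y, geno, mcmc = mcmc_quick(), prior = prior_spec(),
                directions = "both") {
  stopifnot(is.matrix(Y), ncol(Y) >= 2)
  envs <- colnames(Y)
  if (is.null(envs)) envs <- colnames(Y) <- paste0("env", seq_len(ncol(Y)))
  dirs <- if (identical(directions, "both"))
    lapply(seq_along(envs), function(i) c(envs[i], envs[setdiff(seq_along(envs), i)][1]))
  else list(directions)
  W <- standardize_markers(impute_genotypes(geno))
  G <- genomic_relationship(W)
  attr(G, "eigen") <- eigen(G$values, symmetric = TRUE)

  rows <- list(); n_undef <- 0
  for (d in dirs) {
    from <- d[1]; to <- d[2]
    shared <- rownames(Y)[!is.na(Y[, from]) & !is.na(Y[, to])]
    if (!length(shared)) stop("no overlapping phenotyped lines between environments")
    fit <- wgr(Y[, from], kernels = G, model = "gblup", mcmc = mcmc,
               prior = prior)
    acc <- .safe_cor(Y[shared, to], fit$g[shared])
    if (is.na(acc)) n_undef <- n_undef + 1
    rows[[length(rows) + 1]] <- data.frame(
      scenario = "cv0", model = "gblup", env = to, replicate = 1,
      accuracy = acc, stringsAsFactors = FALSE)
  }
  .new_cv_result(do.call(rbind, rows), n_undef)
}

#' CV1: predict entirely new lines
#'
#' Per replicate the TST lines are masked in every environment; the M-by-E
#' model is fitted on the TRN cells and benchmarked against per-environment
#' single-environment GBLUP fitted on the same TRN lines. Accuracies are the
#' per-environment Pearson correlations on the TST lines. Both arms share
#' partitions so model comparisons are paired.
#'
#' @param Y lines x environments phenotype matrix.
#' @param geno a [genotype_matrix()].
#' @param partitions a `"single"` or `"cv1"` scenario [cv_partitions()].
#' @param mcmc,prior passed to the fitters.
#' @return A `cv_result` data frame with arms `mxe` and `gblup`.
#' @export
cv1 <- function(Y, geno, partitions, mcmc = mcmc_quick(),
                prior = prior_spec()) {
  stopifnot(is.matrix(Y), ncol(Y) >= 2, inherits(partitions, "cv_partitions"))
  if (!partitions$scenario %in% c("single", "cv1"))
    stop("partitions must use the 'single'/'cv1' subsampling scenario")
  envs <- colnames(Y)
  W <- standardize_markers(impute_genotypes(geno))
  G <- genomic_relationship(W)
  attr(G, "eigen") <- eigen(G$values, symmetric = TRUE)

  rows <- list(); n_undef <- 0
  for (r in seq_len(partitions$n_reps)) {
    part <- partitions$reps[[r]]
    Ym <- Y
    Ym[part$tst, ] <- NA
    fit_me <- mxe(Ym, geno, mcmc = mcmc, prior = prior)
    for (l in envs) {
      acc <- .safe_cor(Y[part$tst, l], fit_me$g[part$tst, l])
      if (is.na(acc)) n_undef <- n_undef + 1
      rows[[length(rows) + 1]] <- data.frame(
        scenario = "cv1", model = "mxe", env = l, replicate = r,
        accuracy = acc, stringsAsFactors = FALSE)
    }
    for (l in envs) {
      fit_g <- wgr(Ym[, l], kernels = G, model = "gblup", mcmc = mcmc,
                   prior = prior)
      acc <- .safe_cor(Y[part$tst, l], fit_g$g[part$tst])
      if (is.na(acc)) n_undef <- n_undef + 1
      rows[[length(rows) + 1]] <- data.frame(
        scenario = "cv1", model = "gblup", env = l, replicate = r,
        accuracy = acc, stringsAsFactors = FALSE)
    }
  }
  .new_cv_result(do.call(rbind, rows), n_undef)
}

#' CV2: predict lines observed in only one environment
#'
#' Emulates sparse multi-environment trials: per replicate the lines are
#' split into thirds — one third masked in environment 1, a disjoint third
#' masked in environment 2, one third observed in both — so that every
#' masked cell's line is phenotyped in the other environment. The M-by-E
#' model predicts the masked cells by borrowing information within line
#' across environments; the GBLUP benchmark trains within the target
#' environment only, on its observed lines.
#'
#' @param Y lines x 2 phenotype matrix.
#' @param geno a [genotype_matrix()].
#' @param partitions a `"cv2"` scenario [cv_partitions()].
#' @param mcmc,prior passed to the fitters.
#' @return A `cv_result` data frame with arms `mxe` and `gblup`, `env`
#'   naming the environment of the masked (predicted) cells.
#' @export
cv2 <- function(Y, geno, partitions, mcmc = mcmc_quick(),
                prior = prior_spec()) {
  stopifnot(is.matrix(Y), ncol(Y) == 2, inherits(partitions, "cv_partitions"))
  if (partitions$scenario != "cv2")
    stop("partitions must use the 'cv2' scenario")
  envs <- colnames(Y)
  W <- standardize_markers(impute_genotypes(geno))
  G <- genomic_relationship(W)
  attr(G, "eigen") <- eigen(G$values, symmetric = TRUE)

  rows <- list(); n_undef <- 0
  for (r in seq_len(partitions$n_reps)) {
    part <- partitions$reps[[r]]
    masks <- list(part$mask_env1, part$mask_env2)
    Ym <- Y
    Ym[masks[[1]], 1] <- NA
    Ym[masks[[2]], 2] <- NA
    fit_me <- mxe(Ym, geno, mcmc = mcmc, prior = prior)
    for (l in 1:2) {
      acc <- .safe_cor(Y[masks[[l]], l], fit_me$g[masks[[l]], l])
      if (is.na(acc)) n_undef <- n_undef + 1
      rows[[length(rows) + 1]] <- data.frame(
        scenario = "cv2", model = "mxe", env = envs[l], replicate = r,
        accuracy = acc, stringsAsFactors = FALSE)
      fit_g <- wgr(Ym[, l], kernels = G, model = "gblup", mcmc = mcmc,
                   prior = prior)
      acc_g <- .safe_cor(Y[masks[[l]], l], fit_g$g[masks[[l]]])
      if (is.na(acc_g)) n_undef <- n_undef + 1
      rows[[length(rows) + 1]] <- data.frame(
        scenario = "cv2", model = "gblup", env = envs[l], replicate = r,
        accuracy = acc_g, stringsAsFactors = FALSE)
    }
  }
  .new_cv_result(do.call(rbind, rows), n_undef)
}

#' @export
summary.cv_result <- function(object, ...) {
  agg <- aggregate(accuracy ~ scenario + model + env, data = object,
                   FUN = function(v) c(mean = mean(v, na.rm = TRUE),
                                       sd = sd(v, na.rm = TRUE),
                                       n = sum(!is.na(v))))
  out <- cbind(agg[, c("scenario", "model", "env")],
               as.data.frame(agg$accuracy))
  attr(out, "n_undefined") <- attr(object, "n_undefined")
  out
}

#' @export
plot.cv_result <- function(x, ...) {
  boxplot(accuracy ~ model + env, data = x, ylab = "predictive correlation",
          las = 2, ...)
  invisible(x)
}

#' Corrected resampled t-test for paired cross-validation accuracies
#'
#' Repeated random subsampling produces correlated replicates because the
#' training sets overlap; the naive paired t-test is anticonservative. The
#' corrected statistic inflates the variance term by the resampling ratio:
#' \deqn{t = \bar d / \sqrt{(1/K + n_{test}/n_{train})\, s_d^2}}
#' on K - 1 degrees of freedom, where d are the per-replicate accuracy
#' differences and `n_test / n_train = (1 - train_frac) / train_frac`.
#'
#' @param acc_a,acc_b equal-length vectors of per-replicate accuracies from
#'   the two arms (paired by replicate); `NA` pairs are dropped.
#' @param train_frac training fraction used by the subsampling.
#' @return List with `t`, `p` (two-sided), `df`, `mean_diff`, and a
#'   `degenerate` flag for zero-variance differences.
#' @examples
#' corrected_resampled_ttest(rnorm(50, 0.6, 0.05), rnorm(50, 0.55, 0.05))
#' @export
corrected_resampled_ttest <- function(acc_a, acc_b, train_frac = 2/3) {
  if (length(acc_a) != length(acc_b))
    stop("accuracy vectors must have equal length")
  ok <- is.finite(acc_a) & is.finite(acc_b)
  d <- acc_a[ok] - acc_b[ok]
  K <- length(d)
  if (K < 2) stop("need at least 2 paired replicates")
  ratio <- (1 - train_frac) / train_frac
  md <- mean(d)
  s2 <- var(d)
  if (s2 == 0) {
    if (md == 0) return(list(t = 0, p = 1, df = K - 1, mean_diff = 0,
                             degenerate = TRUE))
    return(list(t = sign(md) * Inf, p = 0, df = K - 1, mean_diff = md,
                degenerate = TRUE))
  }
  t <- md / sqrt((1 / K + ratio) * s2)
  list(t = t, p = 2 * pt(-abs(t), df = K - 1), df = K - 1, mean_diff = md,
       degenerate = FALSE)
}
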