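#' Simulation configuration
#'
#' Describes a synthetic diversity-panel study: biallelic genotypes with a
#' bounded minor-allele-frequency range, marker effects decomposed into an
#' across-environment main component and environment-specific deviations
#' (which fixes the between-environment genetic correlation), per-environment
#' target heritabilities, and an RCBD field layout. Defaults mirror the
#' structure of a two-season sesame diversity panel: 182 lines, two
#' environments with 7 and 5 blocks, MAF in \[0.05, 0.5\].
#'
#' @param n_lines number of lines (default 182).
#' @param m_markers number of independent biallelic markers (default 1000; a
#'   desk-scale stand-in for a dense GBS panel, which adds markers but no new
#'   statistical structure under linkage equilibrium).
#' @param n_env number of environments (default 2).
#' @param maf_range allele-frequency range, a subset of (0, 0.5\].
#' @param h2 target per-environment heritability in (0, 1); recycled.
#' @param r_g target between-environment genetic correlation in \[0, 1\],
#'   realized as the main-effect share of genetic variance.
#' @param pi_null fraction of markers with exactly zero effect (sparse
#'   architecture option; default 0 = fully polygenic).
#' @param blocks RCBD blocks per environment (default `c(7, 5)`).
#' @param var_block block variance at the plot level.
#' @param var_plot plot-level residual variance.
#' @param mu_env environment intercepts (default 0).
#' @param ld_block_size if > 1, markers are generated in blocks of this size
#'   that are near-copies of the block head (for LD-pruning tests only).
#' @param seed optional seed used by [simulate_panel()] and by the
#'   generators when called with their default `seed = cfg$seed`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_lines = 182, m_markers = 1000, n_env = 2,
                       maf_range = c(0.05, 0.5), h2 = 0.5, r_g = 0.8,
                       pi_null = 0, blocks = c(7, 5), var_block = 1,
                       var_plot = 1, mu_env = NULL, ld_block_size = 1,
                       seed = NULL) {
  h2 <- rep_len(h2, n_env)
  blocks <- rep_len(blocks, n_env)
  if (any(h2 <= 0 | h2 >= 1)) stop("h2 must lie in (0, 1)")
  if (r_g < 0 || r_g > 1) stop("r_g must lie in [0, 1]")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must be a subset of (0, 0.5]")
  if (pi_null < 0 || pi_null >= 1) stop("pi_null must lie in [0, 1)")
  if (is.null(mu_env)) mu_env <- rep(0, n_env)
  structure(list(n_lines = n_lines, m_markers = m_markers, n_env = n_env,
                 maf_range = maf_range, h2 = h2, r_g = r_g,
                 pi_null = pi_null, blocks = blocks, var_block = var_block,
                 var_plot = var_plot, mu_env = rep_len(mu_env, n_env),
                 ld_block_size = ld_block_size, seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d lines x %d markers, %d environments, h2 = %s, r_g = %g\n",
              x$n_lines, x$m_markers, x$n_env,
              paste(format(x$h2), collapse = "/"), x$r_g))
  invisible(x)
}

#' Simulate a biallelic genotype panel
#'
#' Allele frequencies are drawn uniformly in the configured MAF range and
#' genotypes independently as Binomial(2, p) per line (Hardy-Weinberg,
#' linkage equilibrium). With `ld_block_size > 1`, markers within a block
#' are near-copies of the block head (each entry resampled with probability
#' 0.05), giving tightly linked markers for LD-pruning tests.
#'
#' @param cfg a [sim_config()].
#' @param seed seed (default `cfg$seed`); the draw is deterministic given it.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_lines; m <- cfg$m_markers
  p <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  X <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  if (cfg$ld_block_size > 1) {
    heads <- seq(1, m, by = cfg$ld_block_size)
    for (h in heads) {
      tail_idx <- seq(h + 1, min(h + cfg$ld_block_size - 1, m))
      for (j in tail_idx) {
        flip <- runif(n) < 0.05
        X[, j] <- ifelse(flip, rbinom(n, 2, p[h]), X[, h])
      }
    }
  }
  width <- nchar(as.character(max(n, m)))
  genotype_matrix(X,
                  line_ids = sprintf("L%0*d", width, seq_len(n)),
                  marker_ids = sprintf("M%0*d", width, seq_len(m)))
}

#' Simulate multi-environment phenotypes with known truth
#'
#' Generates line-level phenotypic means per environment from the
#' marker-by-environment generative model
#' `y_il = mu_l + sum_k w_ik (alpha_0k + alpha_lk) + e_il` on centred and
#' standardized markers. The main and specific effect variances are solved
#' from the target genetic correlation (`r_g` equals the main-effect share
#' of genetic variance), a `pi_null` fraction of markers is set to exactly
#' zero effect, and residuals are orthogonalized against the genetic values
#' and rescaled so the realized heritability matches the target exactly
#' (given the realized genetic variance), which keeps recovery tolerances
#' tight.
#'
#' @param geno a [genotype_matrix()].
#' @param cfg a [sim_config()].
#' @param seed optional seed (default `NULL`: continue the current RNG
#'   stream, as done by [simulate_panel()]).
#' @return List with `means` (lines x environments matrix of phenotypic
#'   means, the BLUE-scale truth) and `truth`, a `sim_truth` object holding
#'   the marker effects, genetic values, realized heritabilities and the
#'   realized genetic correlation matrix.
#' @export
simulate_multi_env_phenotypes <- function(geno, cfg, seed = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  W <- standardize_markers(geno)$values
  n <- nrow(W); m <- ncol(W); L <- cfg$n_env
  m_active <- round(m * (1 - cfg$pi_null))
  if (m_active < 1) stop("pi_null leaves no active markers")
  active <- sort(sample.int(m, m_active))

  # unit total genetic variance split r_g : (1 - r_g) between main and
  # specific components (per-marker variances over the active set)
  alpha0 <- numeric(m)
  alpha0[active] <- rnorm(m_active, 0, sqrt(cfg$r_g / m_active))
  alpha_env <- matrix(0, m, L)
  for (l in seq_len(L))
    alpha_env[active, l] <- rnorm(m_active, 0, sqrt((1 - cfg$r_g) / m_active))

  g <- W %*% (alpha0 + alpha_env)          # n x L genetic values
  colnames(g) <- paste0("env", seq_len(L))
  e <- matrix(rnorm(n * L), n, L)
  means <- matrix(NA_real_, n, L,
                  dimnames = list(rownames(W), colnames(g)))
  realized_h2 <- numeric(L)
  for (l in seq_len(L)) {
    vg <- var(g[, l])
    if (vg <= 0) stop("degenerate genetic variance; increase m_markers")
    # orthogonalize the residual against the genetic value, then scale its
    # sample variance exactly to vg * (1 - h2) / h2
    el <- e[, l] - mean(e[, l])
    el <- el - g[, l] * (sum(el * (g[, l] - mean(g[, l]))) /
                           sum((g[, l] - mean(g[, l]))^2))
    el <- el / sd(el) * sqrt(vg * (1 - cfg$h2[l]) / cfg$h2[l])
    means[, l] <- cfg$mu_env[l] + g[, l] + el
    realized_h2[l] <- vg / var(means[, l])
  }
  truth <- structure(list(alpha0 = alpha0, alpha_env = alpha_env,
                          active = active, g = g,
                          realized_h2 = realized_h2,
                          realized_r_g = stats::cor(g),
                          cfg = cfg),
                     class = "sim_truth")
  list(means = means, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> realized h2: %s; realized r_g (env 1-2): %.3f\n",
              paste(sprintf("%.3f", x$realized_h2), collapse = ", "),
              if (ncol(x$g) > 1) x$realized_r_g[1, 2] else 1))
  invisible(x)
}

#' Simulate an RCBD field trial from line-level means
#'
#' Lays out a complete randomized block design per environment: every line
#' appears once per block, plot values are the line-environment mean plus a
#' shared block effect `N(0, var_block)` and plot noise `N(0, var_plot)`.
#'
#' @param means lines x environments matrix of phenotypic means (as from
#'   [simulate_multi_env_phenotypes()]).
#' @param cfg a [sim_config()] (provides blocks per environment and the
#'   variance settings).
#' @param seed optional seed.
#' @param trait trait label used in the field book.
#' @return A [fieldbook()] with `n_lines * blocks[l]` records per
#'   environment.
#' @export
simulate_field_trial <- function(means, cfg, seed = NULL, trait = "y") {
  stopifnot(is.matrix(means), inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  L <- ncol(means)
  out <- list()
  for (l in seq_len(L)) {
    nb <- cfg$blocks[l]
    b_eff <- rnorm(nb, 0, sqrt(cfg$var_block))
    for (b in seq_len(nb)) {
      out[[length(out) + 1]] <- data.frame(
        line = rownames(means),
        env = colnames(means)[l],
        block = paste0("B", b),
        trait = trait,
        value = means[, l] + b_eff[b] +
          rnorm(nrow(means), 0, sqrt(cfg$var_plot)),
        stringsAsFactors = FALSE)
    }
  }
  fieldbook(do.call(rbind, out))
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: genotypes, multi-environment phenotypic means with
#' known truth, and the plot-level RCBD field book, all from one seed.
#'
#' @param cfg a [sim_config()].
#' @return List with `geno`, `phenotypes` (the line-level means matrix),
#'   `truth`, and `fieldbook`.
#' @examples
#' panel <- simulate_panel(sim_config(n_lines = 40, m_markers = 60, seed = 3))
#' panel$truth
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  geno <- simulate_genotypes(cfg, seed = NULL)
  ph <- simulate_multi_env_phenotypes(geno, cfg, seed = NULL)
  fb <- simulate_field_trial(ph$means, cfg, seed = NULL)
  list(geno = geno, phenotypes = ph$means, truth = ph$truth, fieldbook = fb)
}
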