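#' Construct a genotype matrix
#'
#' Lines-by-markers table of biallelic SNP gene contents coded 0/1/2
#' (alternate-allele dosage), with `NA` for missing calls.
#'
#' @param values numeric matrix, lines in rows, markers in columns; entries
#'   must be 0, 1, 2 or `NA`.
#' @param line_ids,marker_ids character identifiers; default to the dimnames
#'   of `values`. Must be unique.
#' @return An object of class `genotype_matrix` with elements `values`,
#'   `line_ids`, `marker_ids`.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 1, 0, 2), 3, 2,
#'   dimnames = list(paste0("L", 1:3), c("M1", "M2"))))
#' allele_freq(g)
#' @export
genotype_matrix <- function(values, line_ids = rownames(values),
                            marker_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(line_ids)) line_ids <- paste0("L", seq_len(nrow(values)))
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(ncol(values)))
  if (anyDuplicated(line_ids)) stop("duplicate line_ids")
  if (anyDuplicated(marker_ids)) stop("duplicate marker_ids")
  if (length(line_ids) != nrow(values) || length(marker_ids) != ncol(values))
    stop("id lengths must match the matrix dimensions")
  bad <- which(!(values %in% c(0, 1, 2) | is.na(values)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(values)) + 1
    j <- ((bad[1] - 1) %/% nrow(values)) + 1
    stop(sprintf("invalid gene content %s at line '%s', marker '%s' (codes must be 0/1/2/NA)",
                 format(values[bad[1]]), line_ids[i], marker_ids[j]))
  }
  dimnames(values) <- list(line_ids, marker_ids)
  structure(list(values = values, line_ids = line_ids, marker_ids = marker_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d lines x %d markers, %.1f%% missing\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' @export
as.matrix.genotype_matrix <- function(x, ...) x$values

#' Per-marker alternate-allele frequency
#'
#' @param geno a [genotype_matrix()].
#' @return Named numeric vector of alternate-allele frequencies in \[0, 1\]
#'   (missing calls excluded).
#' @export
allele_freq <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  colMeans(geno$values, na.rm = TRUE) / 2
}

#' Marker quality control
#'
#' Filters a genotype panel the way diversity-panel GBS data are routinely
#' cleaned: fully missing markers are dropped first, then markers with minor
#' allele frequency below `maf_min`, then markers with heterozygosity rate
#' (fraction of calls equal to 1) above `het_max`, and finally tightly linked
#' markers with squared correlation at or above `r2_max` are pruned by a
#' greedy left-to-right scan (the earlier marker in panel order is kept)
#' within a sliding window of `ld_window` markers.
#'
#' @param geno a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency retained (default 0.05).
#' @param het_max maximum heterozygosity rate retained (default 0.2).
#' @param r2_max squared-correlation threshold for LD pruning (default 0.99).
#' @param ld_window window width (in markers) for the LD scan.
#' @return A list with elements `genotypes` (the filtered
#'   [genotype_matrix()]) and `report`, a `qc_report` listing the markers
#'   removed by each rule in application order.
#' @examples
#' g <- simulate_genotypes(sim_config(n_lines = 40, m_markers = 60, seed = 1))
#' # the Hardy-Weinberg simulator produces outbred heterozygosity levels,
#' # so the selfing-panel default het_max = 0.2 is relaxed here
#' qc <- marker_qc(g, het_max = 1)
#' qc$report
#' @export
marker_qc <- function(geno, maf_min = 0.05, het_max = 0.2, r2_max = 0.99,
                      ld_window = 1000) {
  stopifnot(inherits(geno, "genotype_matrix"))
  for (thr in c(maf_min, het_max, r2_max))
    if (!is.numeric(thr) || thr <= 0 || thr > 1)
      stop("QC thresholds must lie in (0, 1]")
  X <- geno$values
  ids <- geno$marker_ids

  all_missing <- colSums(!is.na(X)) == 0
  removed_missing <- ids[all_missing]
  keep <- !all_missing

  af <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  fail_maf <- keep & (maf < maf_min)
  removed_maf <- ids[fail_maf]
  keep <- keep & !fail_maf

  het <- colMeans(X == 1, na.rm = TRUE)
  fail_het <- keep & (het > het_max)
  removed_het <- ids[fail_het]
  keep <- keep & !fail_het

  # greedy LD prune on mean-imputed columns, original marker order
  cand <- which(keep)
  removed_ld <- character(0)
  if (length(cand) > 1) {
    Xi <- X[, cand, drop = FALSE]
    cm <- colMeans(Xi, na.rm = TRUE)
    for (j in seq_along(cand)) {
      col <- Xi[, j]
      col[is.na(col)] <- cm[j]
      Xi[, j] <- col
    }
    kept_idx <- integer(0)
    for (j in seq_along(cand)) {
      in_window <- kept_idx[cand[kept_idx] > cand[j] - ld_window]
      drop_j <- FALSE
      if (length(in_window)) {
        if (sd(Xi[, j]) < 1e-12) {
          # monomorphic after imputation: correlation undefined, keep
          drop_j <- FALSE
        } else {
          r <- suppressWarnings(cor(Xi[, j], Xi[, in_window, drop = FALSE]))
          r[is.na(r)] <- 0
          drop_j <- any(r^2 >= r2_max)
        }
      }
      if (drop_j) removed_ld <- c(removed_ld, ids[cand[j]])
      else kept_idx <- c(kept_idx, j)
    }
    keep[cand[-kept_idx]] <- FALSE
    keep[cand[kept_idx]] <- TRUE
  }

  if (!any(keep))
    stop("empty panel: all markers removed by quality control")

  out <- genotype_matrix(X[, keep, drop = FALSE], geno$line_ids, ids[keep])
  report <- structure(list(removed_missing = removed_missing,
                           removed_maf = removed_maf,
                           removed_het = removed_het,
                           removed_ld = removed_ld,
                           n_retained = sum(keep),
                           thresholds = list(maf_min = maf_min,
                                             het_max = het_max,
                                             r2_max = r2_max)),
                      class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  removed: %d all-missing, %d MAF, %d heterozygosity, %d LD\n",
              length(x$removed_missing), length(x$removed_maf),
              length(x$removed_het), length(x$removed_ld)))
  cat(sprintf("  retained: %d markers\n", x$n_retained))
  invisible(x)
}

#' Mean-impute missing genotype calls
#'
#' Replaces missing calls by the marker mean gene content, the standard
#' pre-processing before building the genomic relationship matrix.
#'
#' @param geno a [genotype_matrix()].
#' @return A `genotype_matrix`-like object whose `values` may be fractional;
#'   markers with no observed calls cannot be imputed and raise an error.
#' @export
impute_genotypes <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  X <- geno$values
  if (!anyNA(X)) return(geno)
  nobs <- colSums(!is.na(X))
  if (any(nobs == 0))
    stop(sprintf("marker '%s' has no observed calls; run marker_qc() first",
                 geno$marker_ids[which(nobs == 0)[1]]))
  cm <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  X[idx] <- cm[idx[, 2]]
  out <- geno
  out$values <- X
  out
}

#' Centre and standardize marker gene contents
#'
#' Builds the matrix W used in the genomic relationship matrix G = WW'/m and
#' in Gaussian kernels: each marker column is centred and scaled to unit
#' standard deviation. The default uses the sample mean and sample standard
#' deviation (denominator n-1) of the observed codes; `method = "hwe"` uses
#' the Hardy-Weinberg parameterization (centre 2p, scale sqrt(2p(1-p))).
#'
#' @param geno a [genotype_matrix()] with no missing values (see
#'   [impute_genotypes()]).
#' @param method `"sample"` (default) or `"hwe"`.
#' @return An object of class `std_markers` with elements `values` (the n x m
#'   matrix W), `centers`, `scales`, `line_ids`, `marker_ids`, `method`.
#' @export
standardize_markers <- function(geno, method = c("sample", "hwe")) {
  stopifnot(inherits(geno, "genotype_matrix") || is.matrix(geno))
  method <- match.arg(method)
  X <- if (inherits(geno, "genotype_matrix")) geno$values else geno
  if (anyNA(X))
    stop("missing genotypes present: impute first (impute_genotypes())")
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("M", seq_len(ncol(X)))
  if (method == "sample") {
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
  } else {
    p <- colMeans(X) / 2
    ctr <- 2 * p
    scl <- sqrt(2 * p * (1 - p))
  }
  mono <- which(scl < 1e-12)
  if (length(mono))
    stop(sprintf("monomorphic marker '%s': cannot standardize", ids[mono[1]]))
  W <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  structure(list(values = W, centers = ctr, scales = scl,
                 line_ids = rownames(X), marker_ids = ids, method = method),
            class = "std_markers")
}

#' @export
print.std_markers <- function(x, ...) {
  cat(sprintf("<std_markers> %d lines x %d markers (%s standardization)\n",
              nrow(x$values), ncol(x$values), x$method))
  invisible(x)
}

#' Construct (and validate) a line-by-line kernel matrix
#'
#' @param values symmetric n x n numeric matrix.
#' @param line_ids line identifiers (default rownames).
#' @param kind one of `"G"`, `"GK"`, `"custom"`.
#' @param bandwidth Gaussian-kernel bandwidth (GK only).
#' @return An object of class `kernel_matrix`. Symmetry is enforced to 1e-10;
#'   eigenvalues below `-1e-8 * lambda_max` raise an error, small negative
#'   eigenvalues within that tolerance are treated as zero downstream.
#' @export
kernel_matrix <- function(values, line_ids = rownames(values),
                          kind = c("custom", "G", "GK"), bandwidth = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("kernel must be square")
  if (max(abs(values - t(values))) > 1e-10) stop("kernel must be symmetric")
  values <- (values + t(values)) / 2
  if (is.null(line_ids)) line_ids <- paste0("L", seq_len(nrow(values)))
  ev <- eigen(values, symmetric = TRUE, only.values = TRUE)$values
  lmax <- max(ev, 0)
  if (min(ev) < -1e-8 * max(lmax, 1))
    stop(sprintf("kernel is not positive semi-definite (min eigenvalue %.3e)",
                 min(ev)))
  dimnames(values) <- list(line_ids, line_ids)
  structure(list(values = values, line_ids = line_ids, kind = kind,
                 bandwidth = bandwidth),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  bw <- if (is.null(x$bandwidth)) "" else sprintf(", bandwidth %.3g", x$bandwidth)
  cat(sprintf("<kernel_matrix> %s, %d lines%s\n", x$kind, nrow(x$values), bw))
  invisible(x)
}

#' Genomic relationship matrix
#'
#' G = WW'/m from centred/standardized marker gene contents; captures
#' additive gene action and is the kernel of GBLUP.
#'
#' @param W a [standardize_markers()] object (or a plain numeric matrix
#'   already centred and standardized).
#' @return A [kernel_matrix()] of kind `"G"`.
#' @export
genomic_relationship <- function(W) {
  V <- if (inherits(W, "std_markers")) W$values else as.matrix(W)
  m <- ncol(V)
  if (m < 1) stop("at least one marker required")
  G <- tcrossprod(V) / m
  kernel_matrix(G, rownames(V), kind = "G")
}

#' Gaussian kernel
#'
#' GK(i, i') = exp(-theta * d^2(i, i')) with d the Euclidean distance between
#' the standardized marker rows of lines i and i'. Small bandwidths give a
#' global kernel (entries near 1), large bandwidths a local one. Used by RKHS
#' regression to capture interactions beyond additive gene action.
#'
#' @param W a [standardize_markers()] object or numeric matrix.
#' @param theta bandwidth parameter, must be >= 0.
#' @param scale_dist if `TRUE`, squared distances are divided by their
#'   off-diagonal mean before applying the bandwidth (off by default: the
#'   kernel is applied to raw squared distances).
#' @return A [kernel_matrix()] of kind `"GK"` with unit diagonal and entries
#'   in (0, 1\].
#' @export
gaussian_kernel <- function(W, theta, scale_dist = FALSE) {
  if (!is.numeric(theta) || length(theta) != 1 || theta < 0)
    stop("theta must be a single nonnegative number")
  V <- if (inherits(W, "std_markers")) W$values else as.matrix(W)
  sq <- rowSums(V^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(V)
  D2[D2 < 0] <- 0
  if (scale_dist) {
    md <- mean(D2[upper.tri(D2)])
    if (md > 0) D2 <- D2 / md
  }
  K <- exp(-theta * D2)
  diag(K) <- 1
  kernel_matrix(K, rownames(V), kind = "GK", bandwidth = theta)
}

#' Kernel list for kernel averaging
#'
#' Multiple-kernel learning approximates bandwidth selection by fitting
#' several Gaussian kernels as separate random effects whose variances are
#' learned from the data. The default bandwidths 0.2 and 1.2 give one global
#' and one local kernel.
#'
#' @param W a [standardize_markers()] object or numeric matrix.
#' @param thetas non-empty numeric vector of bandwidths (default `c(0.2, 1.2)`).
#' @param scale_dist passed to [gaussian_kernel()].
#' @return A named list of [kernel_matrix()] objects, one per bandwidth, in
#'   the order given.
#' @export
kernel_list <- function(W, thetas = c(0.2, 1.2), scale_dist = FALSE) {
  if (length(thetas) < 1) stop("thetas must be non-empty")
  out <- lapply(thetas, function(th) gaussian_kernel(W, th, scale_dist))
  names(out) <- paste0("GK_", format(thetas, trim = TRUE))
  out
}
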