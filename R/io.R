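#' Read a genotype table
#'
#' CSV layout: first column the line id, header row the marker ids, cells
#' 0/1/2 or NA. VCF files (read via \pkg{vcfR}) are converted to
#' alternate-allele dosage; non-biallelic records are skipped with a count
#' (reported as attribute `n_skipped` and a message).
#'
#' @param path file path.
#' @param format `"csv"` (default) or `"vcf"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("csv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "csv") {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("genotype CSV needs a line-id column plus markers")
    ids <- as.character(df[[1]])
    X <- as.matrix(df[, -1, drop = FALSE])
    suppressWarnings(storage.mode(X) <- "double")
    bad <- which(!(X %in% c(0, 1, 2) | is.na(X)))
    if (length(bad)) {
      i <- ((bad[1] - 1) %% nrow(X)) + 1
      j <- ((bad[1] - 1) %/% nrow(X)) + 1
      stop(sprintf("malformed genotype cell at row %d (line '%s'), column '%s'",
                   i, ids[i], colnames(X)[j]))
    }
    return(genotype_matrix(X, line_ids = ids, marker_ids = colnames(X)))
  }
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  n_skipped <- sum(!bi)
  if (n_skipped > 0) {
    message(sprintf("skipped %d non-biallelic VCF record(s)", n_skipped))
    v <- v[bi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- apply(gt, c(1, 2), function(x) {
    if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_real_)
    sum(as.numeric(strsplit(x, "[/|]")[[1]]) > 0)
  })
  out <- genotype_matrix(t(dose), line_ids = colnames(dose),
                         marker_ids = rownames(dose))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a genotype table as CSV
#'
#' @param geno a [genotype_matrix()].
#' @param path output path.
#' @export
write_genotypes <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  df <- data.frame(line_id = geno$line_ids, geno$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a field book CSV
#'
#' Accepts long format (`line`, `env`, `block`, `trait`, `value`) or wide
#' format (`line`, `env`, `block` plus one column per trait, melted
#' internally). Duplicate (line, env, block, trait) records raise an error.
#'
#' @param path file path.
#' @return A [fieldbook()].
#' @export
read_fieldbook <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!nrow(df)) stop("empty field book")
  fieldbook(df)
}

#' Write a field book CSV
#'
#' @param fb a [fieldbook()].
#' @param path output path.
#' @param shape `"long"` (default) or `"wide"` (one column per trait).
#' @export
write_fieldbook <- function(fb, path, shape = c("long", "wide")) {
  stopifnot(inherits(fb, "fieldbook"))
  shape <- match.arg(shape)
  df <- as.data.frame(fb)
  if (shape == "wide") {
    traits <- unique(df$trait)
    wide <- unique(df[, c("line", "env", "block")])
    for (tr in traits) {
      sub <- df[df$trait == tr, ]
      key <- paste(wide$line, wide$env, wide$block, sep = "\r")
      skey <- paste(sub$line, sub$env, sub$block, sep = "\r")
      wide[[tr]] <- sub$value[match(key, skey)]
    }
    df <- wide
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a marker-QC report as JSON
#'
#' @param report the `report` element of [marker_qc()].
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(
    list(removed_missing = report$removed_missing,
         removed_maf = report$removed_maf,
         removed_het = report$removed_het,
         removed_ld = report$removed_ld,
         n_retained = report$n_retained),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write cross-validation results as CSV
#'
#' @param cv a `cv_result` (see [cv_single_env()] and friends).
#' @param path output path.
#' @export
write_cv_results <- function(cv, path) {
  stopifnot(inherits(cv, "cv_result"))
  write.csv(as.data.frame(cv), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Genetic-parameter table for one trait
#'
#' Gathers, for a two-environment trait, the genomic heritability (mean
#' across environments) and the variance-derived phenotypic correlation from
#' the M-by-E fit, the genomic correlation from the bivariate GBLUP fit, and
#' the sample phenotypic correlation between the environments.
#'
#' @param mxe_fit a fitted [mxe()] model.
#' @param biv_fit a fitted [bivariate_gblup()] model (optional).
#' @param trait trait label for the output row.
#' @return One-row data frame with columns `trait`, `h2`, `r_g`, `r_y`,
#'   `r_y_prime`.
#' @export
genetic_parameters <- function(mxe_fit, biv_fit = NULL, trait = "trait") {
  stopifnot(inherits(mxe_fit, "mxe"))
  h2 <- attr(genomic_heritability(mxe_fit), "mean")
  Y <- mxe_fit$Y
  r_y <- if (ncol(Y) == 2)
    cor(Y[, 1], Y[, 2], use = "pairwise.complete.obs") else NA_real_
  r_g <- if (!is.null(biv_fit)) as.numeric(genomic_correlation(biv_fit))
         else NA_real_
  ryp <- variance_derived_phenotypic_correlation(mxe_fit)
  if (!is.numeric(ryp) || length(ryp) != 1) ryp <- NA_real_
  data.frame(trait = trait, h2 = h2, r_g = r_g, r_y = r_y,
             r_y_prime = ryp, stringsAsFactors = FALSE)
}
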