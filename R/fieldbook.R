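#' Construct a field book
#'
#' Plot-level observations from a randomized complete block design (RCBD):
#' one record per line x environment x block x trait.
#'
#' @param df data frame with columns `line`, `env`, `block`, `trait`, `value`
#'   (long format), or `line`, `env`, `block` plus one column per trait (wide
#'   format, melted internally).
#' @return A data frame of class `fieldbook` in long format. Duplicate
#'   (line, env, block, trait) records raise an error.
#' @export
fieldbook <- function(df) {
  df <- as.data.frame(df)
  base_cols <- c("line", "env", "block")
  if (!all(base_cols %in% names(df)))
    stop("field book needs columns 'line', 'env', 'block'")
  if (!all(c("trait", "value") %in% names(df))) {
    trait_cols <- setdiff(names(df), base_cols)
    if (!length(trait_cols)) stop("no trait columns found")
    long <- do.call(rbind, lapply(trait_cols, function(tr) {
      data.frame(line = df$line, env = df$env, block = df$block,
                 trait = tr, value = as.numeric(df[[tr]]),
                 stringsAsFactors = FALSE)
    }))
    df <- long
  }
  df <- df[, c("line", "env", "block", "trait", "value")]
  df$line <- as.character(df$line)
  df$env <- as.character(df$env)
  df$block <- as.character(df$block)
  df$trait <- as.character(df$trait)
  df$value <- as.numeric(df$value)
  key <- paste(df$line, df$env, df$block, df$trait, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), ][1, ]
    stop(sprintf("duplicate record: line '%s', env '%s', block '%s', trait '%s'",
                 d$line, d$env, d$block, d$trait))
  }
  class(df) <- c("fieldbook", "data.frame")
  df
}

#' @export
print.fieldbook <- function(x, ...) {
  cat(sprintf("<fieldbook> %d records: %d lines, %d environments, %d traits\n",
              nrow(x), length(unique(x$line)), length(unique(x$env)),
              length(unique(x$trait))))
  NextMethod()
}

#' Best linear unbiased estimates of line means from RCBD data
#'
#' Fits, per environment and trait, the mixed model
#' \deqn{y_{io} = \mu + g_i + b_o + \epsilon_{io}}
#' with genotype fixed and block random, by REML (via \pkg{lme4}). The
#' returned BLUEs are the estimated genotype means; they are invariant to the
#' fixed-effect coding. Environments with fewer than two blocks for a trait
#' fall back to raw line means with a warning flag.
#'
#' @param fb a [fieldbook()].
#' @param traits,envs optional subsets; default all.
#' @return An object of class `blue_table`: per environment a lines x traits
#'   matrix of BLUEs plus the REML block and residual variances per trait and
#'   a logical fallback flag.
#' @examples
#' cfg <- sim_config(n_lines = 30, m_markers = 50, seed = 2)
#' panel <- simulate_panel(cfg)
#' bt <- rcbd_blues(panel$fieldbook)
#' head(phenotype_matrix(bt))
#' @export
rcbd_blues <- function(fb, traits = NULL, envs = NULL) {
  stopifnot(inherits(fb, "fieldbook"))
  if (is.null(traits)) traits <- sort(unique(fb$trait))
  if (is.null(envs)) envs <- sort(unique(fb$env))
  lines_all <- sort(unique(fb$line))
  res <- list()
  for (ev in envs) {
    blues <- matrix(NA_real_, length(lines_all), length(traits),
                    dimnames = list(lines_all, traits))
    var_block <- var_resid <- setNames(rep(NA_real_, length(traits)), traits)
    fallback <- setNames(rep(FALSE, length(traits)), traits)
    for (tr in traits) {
      d <- fb[fb$env == ev & fb$trait == tr & !is.na(fb$value), , drop = FALSE]
      if (!nrow(d)) next
      nb <- length(unique(d$block))
      nl <- length(unique(d$line))
      if (nb < 2 || nl < 2) {
        mns <- tapply(d$value, d$line, mean)
        blues[names(mns), tr] <- mns
        fallback[tr] <- TRUE
        if (nb < 2)
          warning(sprintf("env '%s', trait '%s': fewer than 2 blocks, using raw line means",
                          ev, tr))
        next
      }
      d$line <- factor(d$line)
      d$block <- factor(d$block)
      fit <- suppressMessages(lme4::lmer(
        value ~ 0 + line + (1 | block), data = d, REML = TRUE,
        control = lme4::lmerControl(check.conv.singular = "ignore",
                                    calc.derivs = FALSE)))
      fe <- lme4::fixef(fit)
      names(fe) <- sub("^line", "", names(fe))
      blues[names(fe), tr] <- fe
      vc <- as.data.frame(lme4::VarCorr(fit))
      var_block[tr] <- vc$vcov[vc$grp == "block"]
      var_resid[tr] <- vc$vcov[vc$grp == "Residual"]
    }
    res[[ev]] <- list(blues = blues, var_block = var_block,
                      var_resid = var_resid, fallback = fallback)
  }
  structure(list(envs = res, traits = traits, env_ids = envs,
                 line_ids = lines_all),
            class = "blue_table")
}

#' @export
print.blue_table <- function(x, ...) {
  cat(sprintf("<blue_table> %d lines, %d traits, environments: %s\n",
              length(x$line_ids), length(x$traits),
              paste(x$env_ids, collapse = ", ")))
  invisible(x)
}

#' Extract a lines-by-environments phenotype matrix for one trait
#'
#' @param bt a [rcbd_blues()] result.
#' @param trait trait name; default the first trait.
#' @return Numeric matrix, lines in rows, environments in columns, `NA` where
#'   a line has no BLUE in an environment.
#' @export
phenotype_matrix <- function(bt, trait = NULL) {
  stopifnot(inherits(bt, "blue_table"))
  if (is.null(trait)) trait <- bt$traits[1]
  if (!trait %in% bt$traits) stop(sprintf("unknown trait '%s'", trait))
  out <- sapply(bt$env_ids, function(ev) bt$envs[[ev]]$blues[, trait])
  out <- matrix(out, nrow = length(bt$line_ids),
                dimnames = list(bt$line_ids, bt$env_ids))
  out
}
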