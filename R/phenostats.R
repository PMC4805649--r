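#' Per-environment descriptive statistics
#'
#' Mean, sample SD, coefficient of variation (CV% = 100 * SD / mean),
#' minimum and maximum of the plot-level records in each environment.
#' An environment with a single record gets `NA` SD and CV.
#'
#' @param pheno a `phenotype_table`.
#' @return data frame: `environment`, `n`, `mean`, `sd`, `cv_pct`,
#'   `min`, `max`.
#' @export
descriptive_stats <- function(pheno) {
  sp <- split(pheno$value, pheno$environment)
  out <- do.call(rbind, lapply(names(sp), function(e) {
    v <- sp[[e]]
    s <- if (length(v) >= 2) sd(v) else NA_real_
    data.frame(environment = e, n = length(v), mean = mean(v), sd = s,
               cv_pct = 100 * s / mean(v), min = min(v), max = max(v))
  }))
  rownames(out) <- NULL
  out
}

#' Per-line means by environment
#'
#' Averages replications within each (line, environment) cell.
#'
#' @param pheno a `phenotype_table`.
#' @return numeric matrix, lines x environments, `NA` where a line was
#'   not grown in an environment.
#' @export
line_means <- function(pheno) {
  tapply(pheno$value, list(pheno$line, pheno$environment),
         mean, default = NA_real_)
}

#' Pairwise Pearson correlations of line means between environments
#'
#' Line means over replications; each pair of environments uses
#' pairwise-complete lines and needs at least 3 shared lines (otherwise
#' `NA`).
#'
#' @param pheno a `phenotype_table`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
env_correlations <- function(pheno) {
  lm_ <- line_means(pheno)
  k <- ncol(lm_)
  r <- diag(1, k)
  dimnames(r) <- list(colnames(lm_), colnames(lm_))
  if (k < 2) return(r)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- stats::complete.cases(lm_[, c(i, j)])
      r[i, j] <- r[j, i] <-
        if (sum(ok) >= 3) cor(lm_[ok, i], lm_[ok, j]) else NA_real_
    }
  }
  r
}

#' Two-way fixed-effects ANOVA of flowering time
#'
#' Fits `value ~ environment + genotype + environment:genotype` with
#' `aov()`, all effects fixed, and reports the sequential decomposition
#' as sums of squares, mean squares, F ratios against the residual mean
#' square, and p-values.  On a balanced design (equal replications in
#' every cell) the decomposition is exact and order-free; on an
#' unbalanced design the sequential (type-I) sums of squares are
#' returned with a warning.  With a single replication everywhere the
#' interaction and plot error are not separable, so the model drops the
#' interaction: the residual row then pools interaction and error and
#' the result is flagged with `attr(, "pooled_interaction")`.
#'
#' @param pheno a `phenotype_table`.
#' @return data frame of class `anova_table`: `source` (`E`, `G`, `GxE`,
#'   `Residual`), `DF`, `SS`, `MS`, `F`, `p`; attributes `balanced`,
#'   `pooled_interaction`, `n_env`, `b_rep` (effective replications,
#'   harmonic mean over environments).
#' @export
anova_two_way <- function(pheno) {
  d <- data.frame(value = pheno$value,
                  environment = factor(pheno$environment),
                  line = factor(pheno$line))
  cells <- table(d$line, d$environment)
  balanced <- length(unique(as.vector(cells))) == 1 && all(cells > 0)
  single_rep <- all(cells <= 1)
  if (!balanced && !single_rep) {
    warning("unbalanced design: sequential (type-I) sums of squares reported")
  }
  if (single_rep) {
    fit <- aov(value ~ environment + line, data = d)
    src <- c("E", "G", "Residual")
  } else {
    fit <- aov(value ~ environment + line + environment:line, data = d)
    src <- c("E", "G", "GxE", "Residual")
  }
  tab <- summary(fit)[[1]]
  out <- data.frame(source = src,
                    DF = tab[["Df"]],
                    SS = tab[["Sum Sq"]],
                    MS = tab[["Mean Sq"]],
                    F = tab[["F value"]],
                    p = tab[["Pr(>F)"]])
  ## per-environment mean replication, combined by harmonic mean
  b_env <- colMeans(cells[rowSums(cells > 0) > 0, , drop = FALSE])
  b_rep <- length(b_env) / sum(1 / b_env)
  structure(out, class = c("anova_table", "data.frame"),
            balanced = balanced, pooled_interaction = single_rep,
            n_env = nlevels(d$environment), b_rep = b_rep)
}

#' Mean squares and F ratios from (source, DF, SS) rows
#'
#' Completes a published ANOVA skeleton: `MS = SS / DF` and
#' `F = MS_source / MS_residual`.  Values are returned at full precision;
#' rounding belongs to presentation.
#'
#' @param ss_rows data frame with columns `source`, `DF`, `SS`; one row's
#'   source must be `"Residual"` (case-insensitive, `"Residuals"`
#'   accepted).
#' @return data frame `source`, `DF`, `SS`, `MS`, `F` (residual F is
#'   `NA`).
#' @export
f_from_ss <- function(ss_rows) {
  ss_rows <- as.data.frame(ss_rows)
  stopifnot(all(c("source", "DF", "SS") %in% names(ss_rows)))
  if (any(ss_rows$DF == 0)) stop("DF = 0 row in ANOVA input")
  is_res <- tolower(ss_rows$source) %in% c("residual", "residuals")
  if (!any(is_res)) stop("residual row required")
  ms <- ss_rows$SS / ss_rows$DF
  ms_res <- ms[is_res][1]
  f <- ms / ms_res
  f[is_res] <- NA_real_
  data.frame(source = ss_rows$source, DF = ss_rows$DF, SS = ss_rows$SS,
             MS = ms, F = f)
}

#' Variance components from ANOVA expected mean squares
#'
#' Random-model expected mean squares for the two-way layout with `b`
#' replications and `n` environments: `sigma2_e = MS_res`,
#' `sigma2_ge = (MS_GxE - MS_res) / b`,
#' `sigma2_g = (MS_G - MS_GxE) / (n b)`.  Negative estimates are
#' truncated to zero with a warning.  For unbalanced designs `b` is the
#' harmonic mean of the per-environment mean replication counts.
#'
#' @param anova an `anova_table` from [anova_two_way()].
#' @param b_rep override for the effective replication number.
#' @return list of class `variance_components`: `sigma2_g`, `sigma2_ge`,
#'   `sigma2_e`, `n_env`, `b_rep`.
#' @export
variance_components <- function(anova, b_rep = NULL) {
  stopifnot(inherits(anova, "anova_table"))
  if (isTRUE(attr(anova, "pooled_interaction"))) {
    stop("interaction pooled with residual (single replication); ",
         "variance components not separable")
  }
  ms <- setNames(anova$MS, anova$source)
  n <- attr(anova, "n_env")
  b <- b_rep %||% attr(anova, "b_rep")
  s2_e <- ms[["Residual"]]
  s2_ge <- (ms[["GxE"]] - s2_e) / b
  s2_g <- (ms[["G"]] - ms[["GxE"]]) / (n * b)
  comp <- c(sigma2_g = s2_g, sigma2_ge = s2_ge, sigma2_e = s2_e)
  if (any(comp < 0)) {
    warning("negative variance component estimate truncated to 0: ",
            paste(names(comp)[comp < 0], collapse = ", "))
    comp[comp < 0] <- 0
  }
  structure(list(sigma2_g = comp[["sigma2_g"]],
                 sigma2_ge = comp[["sigma2_ge"]],
                 sigma2_e = comp[["sigma2_e"]],
                 n_env = n, b_rep = b),
            class = "variance_components")
}

#' Broad-sense heritability on an entry-mean basis
#'
#' `H^2 = sigma2_g / (sigma2_g + sigma2_ge / n + sigma2_e / (n b))`
#' with `n` environments and `b` replications per environment.
#'
#' @param vc a `variance_components` object (from [variance_components()]
#'   or built by hand as a list with the same fields), or an
#'   `anova_table`, which is converted first.
#' @param b_rep optional override of the replication number when `vc` is
#'   an `anova_table`.
#' @return heritability in `[0, 1]`.
#' @export
heritability <- function(vc, b_rep = NULL) {
  if (inherits(vc, "anova_table")) vc <- variance_components(vc, b_rep = b_rep)
  stopifnot(all(c("sigma2_g", "sigma2_ge", "sigma2_e", "n_env", "b_rep") %in%
                  names(vc)))
  with(vc, {
    stopifnot(sigma2_g >= 0, sigma2_ge >= 0, sigma2_e >= 0,
              n_env > 0, b_rep > 0)
    denom <- sigma2_g + sigma2_ge / n_env + sigma2_e / (n_env * b_rep)
    if (denom == 0) stop("all variance components are zero")
    sigma2_g / denom
  })
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("variance components (days^2): sigma2_g = %.3f, sigma2_ge = %.3f, sigma2_e = %.3f\n",
              x$sigma2_g, x$sigma2_ge, x$sigma2_e))
  cat(sprintf("  n_env = %d, effective replications b = %.3f, H^2 = %.3f\n",
              x$n_env, x$b_rep, heritability(x)))
  invisible(x)
}
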