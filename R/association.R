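## core least-squares scan: tests each column of Gmat as the last
## predictor added to the design X (which must include the intercept).
## Returns effect, p, partial r2 per marker.  Assumes no NAs; callers
## route markers with missing calls through the complete-case path.
ols_scan_core <- function(y, X, Gmat) {
  n <- length(y)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("covariates rank-deficient; redundant columns dropped")
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  df <- n - ncol(X) - 1
  if (df < 1) stop("not enough lines for the design")
  y_r <- qr.resid(qrX, y)
  G_r <- qr.resid(qrX, Gmat)
  sxx <- colSums(G_r^2)
  sxy <- colSums(G_r * y_r)
  syy <- sum(y_r^2)
  ok <- sxx > 1e-10 * n
  beta <- ifelse(ok, sxy / sxx, NA_real_)
  rss <- syy - ifelse(ok, sxy^2 / sxx, 0)
  se <- sqrt(pmax(rss, 0) / df / sxx)
  tval <- beta / se
  p <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  p[!ok] <- NA_real_
  r2 <- ifelse(ok, sxy^2 / (sxx * syy), NA_real_)
  list(effect = beta, p = p, r2 = pmin(pmax(r2, 0), 1))
}

## per-marker complete-case fallback when dosages have missing calls
ols_scan_missing <- function(y, X, Gmat) {
  m <- ncol(Gmat)
  eff <- p <- r2 <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    g <- Gmat[, j]
    ok <- !is.na(g)
    if (sum(ok) < ncol(X) + 2) next
    res <- ols_scan_core(y[ok], X[ok, , drop = FALSE],
                         matrix(g[ok], ncol = 1))
    eff[j] <- res$effect; p[j] <- res$p; r2[j] <- res$r2
  }
  list(effect = eff, p = p, r2 = r2)
}

assoc_records <- function(G, res, environment_id, model) {
  data.frame(marker_id = G$map$marker_id,
             chromosome = G$map$chromosome,
             position = G$map$position,
             environment = environment_id,
             model = model,
             effect = res$effect,
             p = res$p,
             neglog10p = -log10(res$p),
             r2_marker = res$r2)
}

align_y <- function(G, y) {
  if (!is.null(names(y))) {
    y <- y[G$lines]
    if (anyNA(y)) stop("phenotype missing for some lines")
  } else if (length(y) != length(G$lines)) {
    stop("y length does not match lines")
  }
  as.numeric(y)
}

#' General linear model association scan (naive / Q / PCA models)
#'
#' Ordinary least squares of the per-line phenotype on (intercept,
#' covariates, marker dosage), one marker at a time; the marker p-value
#' comes from its coefficient t-test and `r2_marker` is the partial
#' R-squared of the marker given the covariates.  Markers collinear with
#' the covariates (or constant) get `NA` p-values.  Lines with a missing
#' dosage call are dropped for that marker.
#'
#' @param G a [genotypes()] object.
#' @param y numeric phenotype per line (typically line means for one
#'   environment), optionally named by line id.
#' @param covariates `NULL` (naive model) or a lines x c numeric matrix
#'   (Q with one column dropped, or PCA scores).
#' @param environment_id label stored in the records.
#' @param model model tag stored in the records.
#' @return data frame of association records: `marker_id`, `chromosome`,
#'   `position`, `environment`, `model`, `effect`, `p`, `neglog10p`,
#'   `r2_marker`.
#' @export
glm_scan <- function(G, y, covariates = NULL, environment_id = "E1",
                     model = if (is.null(covariates)) "naive" else "GLM") {
  y <- align_y(G, y)
  X <- cbind(`(Intercept)` = rep(1, length(y)), covariates)
  res <- if (anyNA(G$dosage)) ols_scan_missing(y, X, G$dosage)
         else ols_scan_core(y, X, G$dosage)
  assoc_records(G, res, environment_id, model)
}

## concentrated REML criterion for the single-ratio mixed model in the
## kinship eigenbasis; lam = sigma2_g / sigma2_e, d = kinship eigenvalues
reml_neg_loglik <- function(loglam, yr, Xr, d) {
  lam <- exp(loglam)
  v <- lam * d + 1
  sw <- 1 / sqrt(v)
  Xw <- Xr * sw
  yw <- yr * sw
  fit <- lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)
  p <- ncol(Xr)
  n <- length(yr)
  XtX <- crossprod(Xw)
  0.5 * ((n - p) * log(rss) + sum(log(v)) +
           determinant(XtX, logarithm = TRUE)$modulus)
}

#' Mixed linear model association scan (K / Q+K / PCA+K models)
#'
#' EMMAX/P3D scheme: the polygenic variance ratio
#' `lambda = sigma2_g / sigma2_e` of the no-marker model
#' `y = X beta + u + e`, `u ~ N(0, sigma2_g K)`, is estimated once per
#' environment by REML as a single 1-D optimization in the kinship
#' eigenbasis; every marker is then tested by generalized least squares
#' with that covariance held fixed.  The marker p-value is the Wald
#' t-test of its GLS coefficient and `r2_marker` is the partial
#' R-squared on the whitened data.  Missing dosage calls are imputed
#' with the marker mean (dropping lines per marker would invalidate the
#' shared eigenbasis).
#'
#' @param G a [genotypes()] object.
#' @param y numeric phenotype per line, optionally named.
#' @param covariates `NULL`, or Q / PCA covariate matrix.
#' @param K kinship matrix aligned to the lines (positive semi-definite).
#' @param lambda optional fixed variance ratio; when `NULL` (default) it
#'   is estimated by REML.
#' @param environment_id,model labels stored in the records.
#' @return association records as in [glm_scan()], with attributes
#'   `"lambda"` and `"sigma2_e"`.
#' @export
mlm_scan <- function(G, y, covariates = NULL, K, lambda = NULL,
                     environment_id = "E1", model = "MLM") {
  y <- align_y(G, y)
  n <- length(y)
  stopifnot(is.matrix(K), nrow(K) == n, ncol(K) == n)
  if (max(abs(K - t(K))) > 1e-8) stop("K must be symmetric")
  eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(eig$values) < -1e-8 * max(abs(eig$values), 1)) {
    stop("K is not positive semi-definite")
  }
  d <- pmax(eig$values, 0)
  U <- eig$vectors

  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  yr <- drop(crossprod(U, y))
  Xr <- crossprod(U, X)

  if (is.null(lambda)) {
    if (max(d) - min(d) < 1e-12) {
      lambda <- 0  # K proportional to I: GLS is OLS for any ratio
    } else {
      opt <- optimize(reml_neg_loglik, interval = c(-14, 14),
                      yr = yr, Xr = Xr, d = d)
      lambda <- exp(opt$minimum)
    }
  }

  v <- lambda * d + 1
  sw <- 1 / sqrt(v)
  dos <- G$dosage
  if (anyNA(dos)) {
    message("missing dosage calls mean-imputed for the mixed-model scan")
    dos <- impute_mean(dos)
  }
  Gr <- crossprod(U, dos)
  res <- ols_scan_core(yr * sw, Xr * sw, Gr * sw)
  out <- assoc_records(G, res, environment_id, model)
  p <- ncol(Xr)
  rss0 <- sum(lm.fit(Xr * sw, yr * sw)$residuals^2)
  attr(out, "lambda") <- lambda
  attr(out, "sigma2_e") <- rss0 / (n - p)
  out
}

#' Association scans over all environments for one model
#'
#' Convenience wrapper: takes the plot-level phenotype table, computes
#' line means within each environment, and runs the requested model on
#' every environment.  Model tags follow the field convention:
#' `naive`, `Q`, `PCA` (GLM algorithm) and `K`, `Q+K`, `PCA+K` (MLM
#' algorithm).
#'
#' @param G a [genotypes()] object.
#' @param pheno a `phenotype_table`.
#' @param model one of `"naive"`, `"Q"`, `"PCA"`, `"K"`, `"Q+K"`,
#'   `"PCA+K"`.
#' @param Q full membership matrix from [q_matrix()] (its last column is
#'   dropped internally); required for the Q models.
#' @param PCA score matrix from [genotype_pca()]; required for the PCA
#'   models.
#' @param K kinship matrix; required for the MLM models.
#' @return pooled association records across environments.
#' @export
association_scan <- function(G, pheno, model = c("naive", "Q", "PCA", "K",
                                                 "Q+K", "PCA+K"),
                             Q = NULL, PCA = NULL, K = NULL) {
  model <- match.arg(model)
  lm_ <- line_means(pheno)
  lm_ <- lm_[G$lines, , drop = FALSE]
  needs_q <- model %in% c("Q", "Q+K")
  needs_p <- model %in% c("PCA", "PCA+K")
  needs_k <- model %in% c("K", "Q+K", "PCA+K")
  if (needs_q && is.null(Q)) stop("model ", model, " needs Q")
  if (needs_p && is.null(PCA)) stop("model ", model, " needs PCA")
  if (needs_k && is.null(K)) stop("model ", model, " needs K")
  covar <- NULL
  if (needs_q) covar <- Q[G$lines, -ncol(Q), drop = FALSE]
  if (needs_p) covar <- PCA[G$lines, , drop = FALSE]
  out <- lapply(colnames(lm_), function(env) {
    y <- lm_[, env]
    ok <- !is.na(y)
    Gi <- if (all(ok)) G else subset_lines(G, which(ok))
    ci <- if (is.null(covar)) NULL else covar[ok, , drop = FALSE]
    if (needs_k) {
      mlm_scan(Gi, y[ok], covariates = ci, K = K[ok, ok],
               environment_id = env, model = model)
    } else {
      glm_scan(Gi, y[ok], covariates = ci, environment_id = env, model = model)
    }
  })
  do.call(rbind, out)
}

#' Quantile-quantile data and genomic inflation factor
#'
#' Pools the p-values of one model (typically across environments),
#' pairs the ordered observed `-log10(p)` with the uniform expected
#' quantiles `-log10((i - 0.5) / m)`, and reports the median-based
#' genomic inflation factor
#' `lambda_gc = median(chisq_obs) / qchisq(0.5, 1)`.
#'
#' @param records association records, or a numeric vector of p-values.
#' @return list with `points` (data frame `expected`, `observed`, both
#'   `-log10` scale, ascending) and `lambda_gc`.
#' @export
qq_data <- function(records) {
  p <- if (is.data.frame(records)) records$p else records
  p <- p[!is.na(p)]
  stopifnot(length(p) >= 1)
  m <- length(p)
  p_sorted <- sort(p, decreasing = TRUE)  # ascending -log10
  expected <- -log10((m:1 - 0.5) / m)
  observed <- -log10(p_sorted)
  lambda_gc <- median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
  list(points = data.frame(expected = expected, observed = observed),
       lambda_gc = lambda_gc)
}

#' Pooled Benjamini-Hochberg FDR significance threshold
#'
#' Applies the BH step-up procedure to the pooled p-values of all
#' environments and reports the largest raw p-value whose adjusted value
#' stays at or below `fdr_level`; SNPs are then declared significant at
#' raw `p < p_star`.  When nothing passes, `p_star` is `NA`.
#'
#' @param records association records across all environments, or a
#'   numeric vector of p-values.
#' @param fdr_level target false discovery rate (default 0.10).
#' @return list of class `significance_threshold`: `p_star`,
#'   `neglog10_p_star`, `fdr_level`, `n_tests_pooled`.
#' @export
pooled_fdr_threshold <- function(records, fdr_level = 0.10) {
  p <- if (is.data.frame(records)) records$p else records
  p <- p[!is.na(p)]
  stopifnot(length(p) >= 1)
  adj <- p.adjust(p, method = "BH")
  pass <- adj <= fdr_level
  p_star <- if (any(pass)) max(p[pass]) else NA_real_
  structure(list(p_star = p_star,
                 neglog10_p_star = -log10(p_star),
                 fdr_level = fdr_level,
                 n_tests_pooled = length(p)),
            class = "significance_threshold")
}

#' @export
print.significance_threshold <- function(x, ...) {
  if (is.na(x$p_star)) {
    cat(sprintf("no SNP passes BH FDR %.2f over %d pooled tests\n",
                x$fdr_level, x$n_tests_pooled))
  } else {
    cat(sprintf("BH FDR %.2f threshold over %d pooled tests: p* = %.3g (-log10 = %.2f)\n",
                x$fdr_level, x$n_tests_pooled, x$p_star, x$neglog10_p_star))
  }
  invisible(x)
}
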