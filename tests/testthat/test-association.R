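test_that("the GLM scan reproduces textbook simple-regression arithmetic", {
  y <- c(3.1, 4.0, 5.2, 6.1, 6.8, 8.2)
  g <- c(0, 0, 1, 1, 2, 2)
  G <- suppressWarnings(make_genotypes(matrix(as.integer(g), 6, 1), "A01", 100L))
  rec <- glm_scan(G, y)
  # closed-form simple regression
  b <- sum((g - mean(g)) * (y - mean(y))) / sum((g - mean(g))^2)
  res <- y - mean(y) - b * (g - mean(g))
  se <- sqrt(sum(res^2) / 4 / sum((g - mean(g))^2))
  tval <- b / se
  expect_equal(rec$effect, b)
  expect_equal(rec$p, 2 * pt(abs(tval), 4, lower.tail = FALSE))
  expect_equal(rec$neglog10p, -log10(rec$p))
  # and agrees with lm() as an independent route
  fit <- summary(lm(y ~ g))
  expect_equal(rec$p, fit$coefficients["g", "Pr(>|t|)"])
  expect_equal(rec$r2_marker, fit$r.squared)
})

test_that("constant markers and covariate-collinear markers yield NA p", {
  set.seed(21)
  G <- random_genotypes(30, 5)
  d <- G$dosage
  d[, 3] <- 2L
  G2 <- genotypes(d, G$map)
  y <- rnorm(30)
  rec <- glm_scan(G2, y)
  expect_true(is.na(rec$p[3]))
  expect_false(anyNA(rec$p[-3]))
  # the marker itself as a fixed covariate: collinear, NA, no crash
  rec2 <- glm_scan(G, y, covariates = cbind(g1 = G$dosage[, 1]))
  expect_true(is.na(rec2$p[1]))
})

test_that("null GLM p-values are uniform", {
  ks <- vapply(1:5, function(seed) {
    set.seed(400 + seed)
    G <- random_genotypes(200, 1000)
    y <- rnorm(200)
    rec <- glm_scan(G, y)
    p <- rec$p[!is.na(rec$p)]
    suppressWarnings(ks.test(p, "punif")$statistic)
  }, numeric(1))
  expect_gte(sum(ks < 0.05), 4L)
})

test_that("the mixed scan with identity kinship equals the GLM scan", {
  set.seed(22)
  G <- random_genotypes(200, 500)
  y <- rnorm(200, 160, 5) + G$dosage[, 7] * 0.8
  K <- diag(200)
  dimnames(K) <- list(G$lines, G$lines)
  g_rec <- glm_scan(G, y)
  m_rec <- mlm_scan(G, y, K = K)
  expect_equal(m_rec$p, g_rec$p, tolerance = 1e-8)
  expect_equal(m_rec$effect, g_rec$effect, tolerance = 1e-8)
  # scale invariance: K = cI gives the same result for any c > 0
  m_rec2 <- mlm_scan(G, y, K = 5.5 * K)
  expect_equal(m_rec2$p, g_rec$p, tolerance = 1e-8)
})

test_that("the mixed-model marker test equals the explicit GLS formula", {
  # 8-line fixture with a fixed variance ratio
  set.seed(23)
  n <- 8
  A <- matrix(rnorm(n * 20), n, 20)
  K <- tcrossprod(scale(t(scale(t(A))))) / 20
  K <- (K + t(K)) / 2 + diag(n) * 0.01
  dimnames(K) <- list(sprintf("L%03d", 1:n), sprintf("L%03d", 1:n))
  g <- c(0L, 2L, 0L, 2L, 2L, 0L, 0L, 2L)
  G <- make_genotypes(matrix(g, n, 1), "A01", 500L)
  y <- rnorm(n, 160, 4)
  lam <- 1.7
  rec <- mlm_scan(G, y, K = K, lambda = lam)

  V <- lam * K + diag(n)
  Vi <- solve(V)
  X <- cbind(1, g)
  XtVX <- solve(t(X) %*% Vi %*% X)
  beta <- XtVX %*% t(X) %*% Vi %*% y
  resid <- y - X %*% beta
  sigma2 <- drop(t(resid) %*% Vi %*% resid) / (n - 2)
  se <- sqrt(sigma2 * XtVX[2, 2])
  tval <- beta[2] / se
  p_oracle <- 2 * pt(abs(tval), n - 2, lower.tail = FALSE)
  expect_equal(rec$effect, beta[2], tolerance = 1e-10)
  expect_equal(rec$p, p_oracle, tolerance = 1e-10)
})

test_that("the mixed model deflates stratification-driven inflation", {
  wins <- 0L
  for (seed in 1:5) {
    cfg <- sim_config(n_lines = c(spring = 75, winter = 75),
                      chromosomes = c(A01 = 1e7, A02 = 1e7), n_markers = 400,
                      background_fst = 0.25,
                      env_means = c(E1 = 160), replications = 2,
                      var_g = 0, var_ge = 0, var_e = 8, seed = 500 + seed)
    co <- simulate_cohort(cfg)
    # phenotype confounded with sub-population, no marker effects
    shift <- ifelse(co$labels$growth_type == "spring", -3, 3)
    y <- setNames(tapply(co$phenotypes$value, co$phenotypes$line, mean)[co$genotypes$lines] +
                    shift, co$genotypes$lines)
    G <- filter_maf(co$genotypes)
    K <- kinship(G)
    Q <- q_matrix(G, "labels", labels = co$labels)
    naive <- qq_data(glm_scan(G, y))$lambda_gc
    qk <- qq_data(mlm_scan(G, y, covariates = Q[, -2, drop = FALSE], K = K))$lambda_gc
    if (abs(qk - 1) < abs(naive - 1)) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("power is monotone in effect size for a planted QTL", {
  med <- vapply(c(1, 2, 4), function(eff) {
    nlp <- vapply(1:3, function(seed) {
      cfg <- sim_config(n_lines = c(spring = 75, winter = 75),
                        chromosomes = c(A01 = 1e7), n_markers = 150,
                        qtls = data.frame(chromosome = "A01", position = 5e6,
                                          effect = eff),
                        env_means = c(E1 = 160), replications = 2,
                        var_g = 30, var_ge = 0, var_e = 12,
                        seed = 600 + seed)
      co <- simulate_cohort(cfg)
      y <- tapply(co$phenotypes$value, co$phenotypes$line,
                  mean)[co$genotypes$lines]
      rec <- glm_scan(co$genotypes, y)
      rec$neglog10p[rec$marker_id == co$truth$qtls$marker_id[1]]
    }, numeric(1))
    median(nlp)
  }, numeric(1))
  expect_true(all(diff(med) >= 0))
})

test_that("QQ data pairs ordered observations with uniform quantiles", {
  qd <- qq_data(0.01)
  expect_equal(qd$points$expected, -log10(0.5))
  expect_equal(qd$points$observed, 2)

  # ties: observed constant, expected strictly increasing
  qt <- qq_data(rep(0.2, 5))
  expect_equal(unique(qt$points$observed), -log10(0.2))
  expect_true(all(diff(qt$points$expected) > 0))

  set.seed(24)
  p <- runif(1e4)
  qd2 <- qq_data(p)
  slope <- coef(lm(observed ~ expected, data = qd2$points))[2]
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
  expect_equal(qd2$lambda_gc, 1, tolerance = 0.1)
})

test_that("the pooled BH threshold implements the step-up rule", {
  thr <- pooled_fdr_threshold(rep(0.001, 100))
  expect_equal(thr$p_star, 0.001)

  # hand step-up: 0.0001 adjusts to 0.01 <= 0.10, the rest adjust to >= 0.5
  p <- c(1e-4, seq(0.5, 0.995, length.out = 99))
  thr2 <- pooled_fdr_threshold(p)
  expect_equal(thr2$p_star, 1e-4)

  # the reported -log10 of a threshold of 4.06e-4 is 3.39
  expect_equal(round(-log10(4.06e-4), 2), 3.39)

  none <- pooled_fdr_threshold(runif(50, 0.5, 1))
  expect_true(is.na(none$p_star))
})

test_that("the realized FDR with sparse true effects stays near the target", {
  fdp <- vapply(1:5, function(seed) {
    set.seed(700 + seed)
    G <- random_genotypes(150, 600)
    causal <- sample.int(600, 10)
    y <- drop(scale(G$dosage[, causal]) %*% rep(1, 10)) + rnorm(150)
    rec <- glm_scan(G, y)
    thr <- pooled_fdr_threshold(rec, fdr_level = 0.10)
    if (is.na(thr$p_star)) return(0)
    hits <- rec$marker_id[!is.na(rec$p) & rec$p < thr$p_star]
    if (length(hits) == 0) return(0)
    mean(!hits %in% G$map$marker_id[causal])
  }, numeric(1))
  expect_lte(mean(fdp), 0.10 + 2 * sd(fdp) / sqrt(5) + 0.05)
})
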