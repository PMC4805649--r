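#' Thin markers by spacing and MAF for structure estimation
#'
#' Selects the marker subset used to estimate kinship and population
#' structure: markers with MAF strictly above `maf_min` whose spacing
#' exceeds the genome-wide mean adjacent-marker distance.  The default
#' `"greedy"` rule walks each chromosome left to right and keeps a marker
#' only if its distance to the preceding marker of the map strictly
#' exceeds the mean gap (the first marker of a chromosome, having no
#' left neighbor, is kept when its MAF qualifies); equally spaced markers
#' at exactly the mean spacing therefore thin to the first marker per
#' chromosome.  The alternative `"neighbors"` rule requires the distance
#' to both adjacent neighbors to exceed the mean gap.
#'
#' @param map marker map data frame (`marker_id`, `chromosome`,
#'   `position`), sorted.
#' @param maf named per-marker MAF vector (from [marker_maf()]).
#' @param maf_min markers must have MAF strictly above this; default 0.05.
#' @param method `"greedy"` (default) or `"neighbors"`.
#' @return character vector of retained marker ids (possibly empty).
#' @export
thin_markers <- function(map, maf, maf_min = 0.05, method = c("greedy", "neighbors")) {
  method <- match.arg(method)
  maf <- maf[map$marker_id]
  mean_gap <- mean_adjacent_gap(map)
  keep <- logical(nrow(map))
  for (chr in unique(map$chromosome)) {
    idx <- which(map$chromosome == chr)
    pos <- map$position[idx]
    ok_maf <- !is.na(maf[idx]) & maf[idx] > maf_min
    if (method == "greedy") {
      gaps_l <- c(Inf, diff(pos))
      keep[idx] <- ok_maf & gaps_l > mean_gap
    } else {
      gaps_l <- c(Inf, diff(pos))
      gaps_r <- c(diff(pos), Inf)
      keep[idx] <- ok_maf & gaps_l > mean_gap & gaps_r > mean_gap
    }
  }
  map$marker_id[keep]
}

## genome-wide mean distance between adjacent markers (within chromosomes)
mean_adjacent_gap <- function(map) {
  gaps <- unlist(lapply(split(map$position, map$chromosome), diff),
                 use.names = FALSE)
  if (length(gaps) == 0) return(Inf)
  mean(gaps)
}

#' Kinship (relatedness) matrix
#'
#' Default is the centered-and-scaled cross-product (VanRaden-type) form
#' `K = Z Z' / m`, where `Z` is the dosage matrix with each marker column
#' centered and divided by its sample SD and `m` is the number of
#' markers.  The `"ibs"` option returns mean identity-by-state similarity
#' `1 - mean(|g_i - g_j|) / 2`.  Missing dosages are imputed with the
#' per-marker mean; monomorphic markers are excluded with a warning.
#'
#' @param G a [genotypes()] object (a thinned subset is recommended).
#' @param method `"vanraden"` (default) or `"ibs"`.
#' @return symmetric positive semi-definite lines x lines matrix.
#' @export
kinship <- function(G, method = c("vanraden", "ibs")) {
  method <- match.arg(method)
  stopifnot(length(G$lines) >= 2)
  X <- impute_mean(G$dosage)
  v <- apply(X, 2, var)
  mono <- v == 0 | is.na(v)
  if (any(mono)) {
    warning(sum(mono), " monomorphic marker(s) excluded from kinship")
    X <- X[, !mono, drop = FALSE]
  }
  if (ncol(X) == 0) stop("no polymorphic markers for kinship")
  if (method == "vanraden") {
    Z <- scale(X)
    K <- tcrossprod(Z) / ncol(Z)
  } else {
    n <- nrow(X)
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      d <- abs(sweep(X, 2, X[i, ]))
      K[i, ] <- 1 - rowMeans(d) / 2
    }
  }
  dimnames(K) <- list(G$lines, G$lines)
  (K + t(K)) / 2
}

#' Principal components of the genotype matrix
#'
#' Scores are the left singular vectors of the column-centered dosage
#' matrix scaled by their singular values (missing dosages imputed with
#' the marker mean).  Component variances are non-increasing.  Sign
#' convention: the largest-magnitude marker loading of each component is
#' made positive.
#'
#' @param G a [genotypes()] object.
#' @param n_components number of components (default 5).
#' @return matrix of scores, lines x `n_components`, columns `PC1..`,
#'   with attribute `"sdev"`.
#' @export
genotype_pca <- function(G, n_components = 5) {
  n <- length(G$lines)
  stopifnot(n >= n_components + 1)
  if (nrow(G$map) < n_components) {
    stop("fewer markers than requested components")
  }
  X <- scale(impute_mean(G$dosage), center = TRUE, scale = FALSE)
  sv <- svd(X, nu = n_components, nv = n_components)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  for (k in seq_len(n_components)) {
    i <- which.max(abs(sv$v[, k]))
    if (sv$v[i, k] < 0) scores[, k] <- -scores[, k]
  }
  dimnames(scores) <- list(G$lines, paste0("PC", seq_len(n_components)))
  attr(scores, "sdev") <- sv$d[seq_len(n_components)] / sqrt(max(1, n - 1))
  scores
}

#' Sub-population membership (Q) matrix
#'
#' Builds the fixed-effect membership covariate used by the Q models.
#' `source = "labels"` turns growth-type labels into one-hot memberships;
#' `source = "pca_kmeans"` runs k-means on the leading genotype principal
#' components and sets memberships to normalized inverse distances to the
#' cluster centroids (a point on a centroid gets membership 1).  Full-Q
#' rows sum to one; for use in a regression drop one column (the
#' convention here: the last), e.g. `Q[, -ncol(Q), drop = FALSE]`.
#'
#' @param G a [genotypes()] object (needed for `"pca_kmeans"`).
#' @param source `"labels"` or `"pca_kmeans"`.
#' @param labels growth-type labels (data frame `line`/`growth_type` or
#'   named vector) when `source = "labels"`.
#' @param k number of sub-populations (default 2; for `"labels"` the
#'   number of distinct labels is used).
#' @param n_pcs principal components fed to k-means (default 3).
#' @return lines x k membership matrix with row sums 1.
#' @export
q_matrix <- function(G, source = c("labels", "pca_kmeans"), labels = NULL,
                     k = 2, n_pcs = 3) {
  source <- match.arg(source)
  n <- length(G$lines)
  if (k > n) stop("k exceeds number of lines")
  if (source == "labels") {
    lab <- growth_labels(labels)[G$lines]
    if (anyNA(lab)) stop("labels missing for some lines")
    f <- factor(lab)
    Q <- diag(nlevels(f))[as.integer(f), , drop = FALSE]
    colnames(Q) <- levels(f)
  } else {
    stopifnot(k >= 2)
    pcs <- genotype_pca(G, n_components = min(n_pcs, n - 1))
    km <- kmeans(pcs, centers = k, nstart = 10)
    d <- vapply(seq_len(k), function(j) {
      sqrt(rowSums(sweep(pcs, 2, km$centers[j, ])^2))
    }, numeric(n))
    Q <- t(apply(d, 1, function(di) {
      hit <- di < 1e-12
      if (any(hit)) as.numeric(hit) / sum(hit) else (1 / di) / sum(1 / di)
    }))
    colnames(Q) <- paste0("Q", seq_len(k))
  }
  rownames(Q) <- G$lines
  Q
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of two dosage vectors over their complete
#' pairs; `NA` with fewer than 3 complete pairs or zero variance.
#'
#' @param g_a,g_b dosage vectors.
#' @return r-squared in `[0, 1]`, or `NA`.
#' @export
ld_r2 <- function(g_a, g_b) {
  ok <- !is.na(g_a) & !is.na(g_b)
  if (sum(ok) < 3) return(NA_real_)
  a <- g_a[ok]; b <- g_b[ok]
  if (var(a) == 0 || var(b) == 0) return(NA_real_)
  cor(a, b)^2
}
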