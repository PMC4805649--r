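#' Construct a genotype matrix with its marker map
#'
#' The central genotype container: an integer dosage matrix (lines x
#' markers, values 0/1/2 or `NA`) together with a marker map giving the
#' chromosome and 1-based bp position of every marker.  Markers are stored
#' sorted by chromosome (natural order `A01..A10`, `C01..C09`, then other
#' names lexicographically) and position.
#'
#' Inbred panels are expected to be near-homozygous; a heterozygous call
#' fraction above 5% triggers a warning.
#'
#' @param dosage numeric matrix, lines in rows, markers in columns; entries
#'   in `{0, 1, 2}` or `NA`.  Column names must match `map$marker_id`.
#' @param map data frame with columns `marker_id`, `chromosome`, `position`.
#' @param lines character vector of line ids (defaults to
#'   `rownames(dosage)`).
#' @return an object of class `genotype_matrix`: a list with elements
#'   `dosage`, `map`, `lines`.
#' @export
genotypes <- function(dosage, map, lines = rownames(dosage)) {
  stopifnot(is.matrix(dosage))
  map <- as.data.frame(map)
  need <- c("marker_id", "chromosome", "position")
  if (!all(need %in% names(map))) {
    stop("map must have columns marker_id, chromosome, position")
  }
  map$marker_id <- as.character(map$marker_id)
  map$chromosome <- as.character(map$chromosome)
  map$position <- as.integer(map$position)
  if (anyDuplicated(map$marker_id)) {
    stop("duplicate marker_id: ",
         paste(unique(map$marker_id[duplicated(map$marker_id)]), collapse = ", "))
  }
  if (nrow(map) != ncol(dosage)) {
    stop("map rows (", nrow(map), ") do not match dosage columns (",
         ncol(dosage), ")")
  }
  if (is.null(lines)) lines <- sprintf("L%03d", seq_len(nrow(dosage)))
  lines <- as.character(lines)
  if (length(lines) != nrow(dosage)) stop("lines do not match dosage rows")
  if (is.null(colnames(dosage))) colnames(dosage) <- map$marker_id
  if (!identical(colnames(dosage), map$marker_id)) {
    dosage <- dosage[, map$marker_id, drop = FALSE]
  }
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stop("dosage entries must be 0, 1, 2 or NA")

  ord <- order(chromosome_rank(map$chromosome), map$position)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  dosage <- dosage[, ord, drop = FALSE]
  for (chr in unique(map$chromosome)) {
    pos <- map$position[map$chromosome == chr]
    if (anyDuplicated(pos)) {
      stop("duplicate positions on chromosome ", chr)
    }
  }
  rownames(dosage) <- lines
  storage.mode(dosage) <- "integer"

  het <- mean(dosage == 1L, na.rm = TRUE)
  if (!is.nan(het) && het > 0.05) {
    warning(sprintf(
      "heterozygous call fraction %.1f%% exceeds 5%%; inbred lines expected near-homozygous",
      100 * het))
  }
  structure(list(dosage = dosage, map = map, lines = lines),
            class = "genotype_matrix")
}

#' Natural chromosome ordering rank
#'
#' Ranks chromosome names so that letter-prefix + number names sort by
#' prefix then number (`A01 < A02 < ... < A10 < C01 < ... < C09`), with any
#' non-conforming names after them in lexicographic order.
#'
#' @param chrom character vector of chromosome names.
#' @return integer rank vector usable in `order()`.
#' @export
chromosome_rank <- function(chrom) {
  chrom <- as.character(chrom)
  u <- unique(chrom)
  m <- regmatches(u, regexec("^([A-Za-z]+)0*([0-9]+)$", u))
  ok <- lengths(m) == 3L
  pref <- ifelse(ok, vapply(m, function(x) if (length(x) == 3) x[2] else "", ""), NA)
  num <- ifelse(ok, vapply(m, function(x) if (length(x) == 3) as.numeric(x[3]) else NA_real_, 0), NA)
  key <- order(!ok, pref, num, u)
  rank <- match(chrom, u[key])
  rank
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$lines), "lines x", nrow(x$map), "markers\n")
  cat("  chromosomes:", paste(unique(x$map$chromosome), collapse = " "), "\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing calls: %.2f%%   het calls: %.2f%%\n",
              100 * miss, 100 * mean(x$dosage == 1L, na.rm = TRUE)))
  invisible(x)
}

#' Per-marker minor allele frequency
#'
#' MAF computed from non-missing dosage calls; markers with no non-missing
#' calls get `NA`.
#'
#' @param G a [genotypes()] object.
#' @return named numeric vector, one MAF per marker.
#' @export
marker_maf <- function(G) {
  p <- colMeans(G$dosage, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  names(maf) <- G$map$marker_id
  maf
}

#' Drop markers below a minor-allele-frequency threshold
#'
#' Markers with MAF strictly below `threshold` (computed on non-missing
#' calls) are excluded; a marker with MAF exactly at the threshold is
#' retained.  Marker order is preserved.
#'
#' @param G a [genotypes()] object.
#' @param threshold MAF cutoff in `[0, 0.5]`; default 0.05.
#' @return a filtered `genotype_matrix`.
#' @export
filter_maf <- function(G, threshold = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"),
            threshold >= 0, threshold <= 0.5)
  maf <- marker_maf(G)
  keep <- !is.na(maf) & maf >= threshold
  if (!any(keep)) {
    stop("all markers removed at MAF threshold ", threshold,
         "; lower the threshold")
  }
  subset_markers(G, which(keep))
}

#' Subset a genotype matrix by marker index
#' @param G a [genotypes()] object.
#' @param idx integer or logical index into the markers.
#' @return a `genotype_matrix` with the selected markers.
#' @export
subset_markers <- function(G, idx) {
  structure(list(dosage = G$dosage[, idx, drop = FALSE],
                 map = {
                   m <- G$map[idx, , drop = FALSE]
                   rownames(m) <- NULL
                   m
                 },
                 lines = G$lines),
            class = "genotype_matrix")
}

#' Subset a genotype matrix by line index
#' @param G a [genotypes()] object.
#' @param idx integer or logical index into the lines.
#' @return a `genotype_matrix` with the selected lines.
#' @export
subset_lines <- function(G, idx) {
  structure(list(dosage = G$dosage[idx, , drop = FALSE],
                 map = G$map,
                 lines = G$lines[idx]),
            class = "genotype_matrix")
}

## per-marker mean imputation, used by kinship/PCA (not by the scans)
impute_mean <- function(dosage) {
  if (!anyNA(dosage)) return(dosage)
  mu <- colMeans(dosage, na.rm = TRUE)
  idx <- which(is.na(dosage), arr.ind = TRUE)
  dosage[idx] <- mu[idx[, 2]]
  dosage
}
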