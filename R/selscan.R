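#' Per-SNP F_ST between two growth-habit sub-populations
#'
#' Default is the Weir-Cockerham (1984) single-locus estimator
#' `theta = a / (a + b + c)` computed from the spring and winter allele
#' counts (the variance components `a`, `b`, `c` are the among-population,
#' among-individual and within-individual terms; heterozygote frequencies
#' enter `c`, which vanishes in fully homozygous inbred panels).  The
#' Hudson estimator is available behind `estimator = "hudson"`.  Negative
#' estimates are clamped to zero by default.  Lines with labels other
#' than the two contrast groups are ignored; a marker needs at least two
#' lines with non-missing calls in each sub-population, otherwise `NA`.
#' Markers monomorphic across both sub-populations have an undefined
#' estimate and also return `NA`.
#'
#' @param G a [genotypes()] object.
#' @param labels growth-type labels (data frame `line`/`growth_type` or
#'   named vector).
#' @param groups the two labels contrasted (default spring vs winter).
#' @param estimator `"wc"` (Weir-Cockerham, default) or `"hudson"`.
#' @param clamp clamp negative estimates to 0 (default `TRUE`).
#' @return named numeric vector of per-marker F_ST.
#' @export
snp_fst <- function(G, labels, groups = c("spring", "winter"),
                    estimator = c("wc", "hudson"), clamp = TRUE) {
  estimator <- match.arg(estimator)
  stopifnot(length(groups) == 2)
  lab <- growth_labels(labels)[G$lines]
  i1 <- which(!is.na(lab) & lab == groups[1])
  i2 <- which(!is.na(lab) & lab == groups[2])
  if (length(i1) < 2 || length(i2) < 2) {
    stop("need at least 2 lines in each sub-population")
  }
  d1 <- G$dosage[i1, , drop = FALSE]
  d2 <- G$dosage[i2, , drop = FALSE]
  n1 <- colSums(!is.na(d1))
  n2 <- colSums(!is.na(d2))
  p1 <- colMeans(d1, na.rm = TRUE) / 2
  p2 <- colMeans(d2, na.rm = TRUE) / 2
  h1 <- colMeans(d1 == 1L, na.rm = TRUE)
  h2 <- colMeans(d2 == 1L, na.rm = TRUE)
  valid <- n1 >= 2 & n2 >= 2

  if (estimator == "wc") {
    r <- 2
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    denom <- a + b + cc
    fst <- ifelse(denom == 0, NA_real_, a / denom)
  } else {
    m1 <- 2 * n1  # allele counts
    m2 <- 2 * n2
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (m1 - 1) - p2 * (1 - p2) / (m2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    fst <- ifelse(den == 0, NA_real_, num / den)
  }
  fst[!valid] <- NA_real_
  if (clamp) fst <- pmax(fst, 0)
  names(fst) <- G$map$marker_id
  fst
}

#' Sliding-window mean F_ST
#'
#' Per chromosome, windows of `window` bp advance by `step` bp starting
#' at position 1 and continuing while the window start does not pass the
#' chromosome's last marker.  A window averages the per-SNP values of
#' the markers falling in `[start, start + window)`; windows holding
#' fewer than 2 markers with an estimate get mean 0.
#'
#' @param fst named per-marker F_ST vector (from [snp_fst()]).
#' @param map marker map data frame.
#' @param window window size in bp (default 5e5).
#' @param step slide in bp (default 5e4); must not exceed `window`.
#' @return data frame: `chromosome`, `start`, `end` (1-based inclusive,
#'   `end = start + window - 1`), `n_snps`, `mean_fst`.
#' @export
fst_windows <- function(fst, map, window = 5e5, step = 5e4) {
  stopifnot(window >= step, step >= 1)
  fst <- fst[map$marker_id]
  out <- lapply(unique(map$chromosome), function(chr) {
    on_chr <- map$chromosome == chr
    pos <- map$position[on_chr]
    val <- fst[on_chr]
    o <- order(pos)
    pos <- pos[o]; val <- val[o]
    has <- !is.na(val)
    cs_n <- cumsum(has)
    cs_v <- cumsum(ifelse(has, val, 0))
    starts <- seq(1, max(pos), by = step)
    lo <- findInterval(starts - 0.5, pos)          # markers before window
    hi <- findInterval(starts + window - 0.5, pos) # markers up to window end
    n <- c(0, cs_n)[hi + 1] - c(0, cs_n)[lo + 1]
    v <- c(0, cs_v)[hi + 1] - c(0, cs_v)[lo + 1]
    mean_fst <- ifelse(n >= 2, v / n, 0)
    data.frame(chromosome = chr, start = as.integer(starts),
               end = as.integer(starts + window - 1),
               n_snps = as.integer(n), mean_fst = mean_fst)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call selection regions from the top window decile
#'
#' Windows whose mean F_ST lies strictly above the
#' `(1 - top_fraction)` quantile of all window means qualify (the top
#' decile by default), and overlapping or book-ended qualifying windows
#' are merged into maximal regions per chromosome.
#'
#' @param windows window table from [fst_windows()].
#' @param top_fraction fraction of windows taken as selection targets
#'   (default 0.10).
#' @return data frame of disjoint regions: `chromosome`, `start`, `end`,
#'   `n_windows`, `max_window_fst`; attribute `"threshold"` holds the
#'   quantile cutoff.
#' @export
call_selection_regions <- function(windows, top_fraction = 0.10) {
  stopifnot(nrow(windows) >= 10, top_fraction > 0, top_fraction < 1)
  thr <- quantile(windows$mean_fst, 1 - top_fraction, names = FALSE)
  qual <- windows[windows$mean_fst > thr, , drop = FALSE]
  empty <- data.frame(chromosome = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      max_window_fst = numeric())
  if (nrow(qual) == 0) {
    warning("no window strictly above the F_ST quantile threshold")
    attr(empty, "threshold") <- thr
    return(empty)
  }
  out <- lapply(unique(qual$chromosome), function(chr) {
    q <- qual[qual$chromosome == chr, , drop = FALSE]
    ir <- IRanges::IRanges(start = q$start, end = q$end)
    red <- IRanges::reduce(ir)
    hits <- IRanges::findOverlaps(ir, red)
    reg <- as.data.frame(red)
    mx <- tapply(q$mean_fst[S4Vectors::queryHits(hits)],
                 S4Vectors::subjectHits(hits), max)
    nw <- tabulate(S4Vectors::subjectHits(hits), nbins = nrow(reg))
    data.frame(chromosome = chr, start = reg$start, end = reg$end,
               n_windows = nw, max_window_fst = as.numeric(mx))
  })
  res <- do.call(rbind, out)
  res <- res[order(chromosome_rank(res$chromosome), res$start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "threshold") <- thr
  res
}

## shared interval-vs-region overlap counting (>= 1 bp, same chromosome)
interval_overlap_report <- function(items, regions, id_col) {
  assignments <- data.frame(item = character(), chromosome = character(),
                            region_start = integer(), region_end = integer())
  hit_items <- character(0)
  hit_regions <- character(0)
  region_key <- paste0(regions$chromosome, ":", regions$start, "-", regions$end)
  for (chr in intersect(unique(items$chromosome), unique(regions$chromosome))) {
    it <- items[items$chromosome == chr, , drop = FALSE]
    rg <- regions[regions$chromosome == chr, , drop = FALSE]
    fo <- IRanges::findOverlaps(
      IRanges::IRanges(it$start, it$end),
      IRanges::IRanges(rg$start, rg$end))
    if (length(fo) == 0) next
    qh <- S4Vectors::queryHits(fo); sh <- S4Vectors::subjectHits(fo)
    hit_items <- c(hit_items, unique(it[[id_col]][qh]))
    hit_regions <- c(hit_regions,
                     unique(paste0(chr, ":", rg$start[sh], "-", rg$end[sh])))
    assignments <- rbind(assignments, data.frame(
      item = it[[id_col]][qh], chromosome = chr,
      region_start = rg$start[sh], region_end = rg$end[sh]))
  }
  list(n_items = length(unique(hit_items)),
       n_regions = length(unique(hit_regions)),
       assignments = assignments)
}

#' Overlap of QTL loci with selection regions
#'
#' A locus counts as overlapping iff it shares at least one bp with any
#' selection region; both directions are reported (loci hit, regions
#' hit).
#'
#' @param loci locus table from [merge_loci()].
#' @param regions region table from [call_selection_regions()].
#' @return list: `n_qtls_overlapping`, `n_regions_hit_by_qtls`,
#'   `assignments` (locus-to-region pairs).
#' @export
overlap_qtls <- function(loci, regions) {
  if (nrow(loci) == 0 || nrow(regions) == 0) {
    return(list(n_qtls_overlapping = 0L, n_regions_hit_by_qtls = 0L,
                assignments = data.frame()))
  }
  rep_ <- interval_overlap_report(loci, regions, id_col = "name")
  list(n_qtls_overlapping = rep_$n_items,
       n_regions_hit_by_qtls = rep_$n_regions,
       assignments = rep_$assignments)
}

#' Candidate genes falling in selection regions
#'
#' As [overlap_qtls()], with gene intervals: a gene counts iff it shares
#' at least one bp with any selection region.
#'
#' @param genes gene table (see [read_gene_table()]).
#' @param regions region table from [call_selection_regions()].
#' @return list: `n_genes_in_regions`, `n_regions_hit_by_genes`,
#'   `assignments`.
#' @export
genes_in_regions <- function(genes, regions) {
  if (nrow(genes) == 0 || nrow(regions) == 0) {
    return(list(n_genes_in_regions = 0L, n_regions_hit_by_genes = 0L,
                assignments = data.frame()))
  }
  rep_ <- interval_overlap_report(genes, regions, id_col = "gene_id")
  list(n_genes_in_regions = rep_$n_items,
       n_regions_hit_by_genes = rep_$n_regions,
       assignments = rep_$assignments)
}
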