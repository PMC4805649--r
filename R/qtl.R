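#' Per-environment significant SNP sets
#'
#' A marker is significant in an environment iff its raw p-value is
#' strictly below the pooled threshold `p_star`; a p-value exactly at
#' the threshold is excluded.
#'
#' @param records association records across environments.
#' @param threshold a `significance_threshold` from
#'   [pooled_fdr_threshold()], or a raw p cutoff.
#' @return named list: environment id -> character vector of marker ids.
#' @export
significant_snps <- function(records, threshold) {
  p_star <- if (inherits(threshold, "significance_threshold"))
    threshold$p_star else threshold
  envs <- unique(records$environment)
  out <- lapply(envs, function(e) {
    r <- records[records$environment == e, , drop = FALSE]
    if (is.na(p_star)) return(character(0))
    r$marker_id[!is.na(r$p) & r$p < p_star]
  })
  names(out) <- envs
  out
}

#' Merge significant SNPs into QTL loci
#'
#' The union of significant SNPs over environments is chained per
#' chromosome by single linkage: consecutive significant SNPs at most
#' `gap` bp apart join one cluster, so locus widths are variable (a run
#' of SNPs each within 1.5 Mb of the next can span many Mb).  A cluster
#' becomes a locus iff it has at least two member SNPs, or its single
#' SNP is significant in at least two environments; remaining singletons
#' are reported as unassigned.  The locus interval is the span of its
#' member SNP positions (single-SNP loci are zero-width), its name is
#' `qFTi:<chromosome>:<start>-<end>`, its environments are all
#' environments in which at least one member is significant, and the
#' lead SNP is the member with the largest `-log10(p)` over
#' environments (ties broken by smaller position).
#'
#' @param sig named list environment -> significant marker ids (from
#'   [significant_snps()]).
#' @param map marker map data frame.
#' @param gap single-linkage chaining distance in bp (default 1.5e6).
#' @param records optional association records used to annotate lead
#'   SNP, max `-log10(p)` and max marker R-squared.
#' @return data frame of loci (`name`, `chromosome`, `start`, `end`,
#'   `n_snps`, `members`, `lead_snp`, `max_neglog10p`, `max_r2_pct`,
#'   `n_env`, `environments`) with attribute `"unassigned"`: a data
#'   frame of rejected singleton SNPs.
#' @export
merge_loci <- function(sig, map, gap = 1.5e6, records = NULL) {
  all_ids <- sort(unique(unlist(sig, use.names = FALSE)))
  empty <- data.frame(name = character(), chromosome = character(),
                      start = integer(), end = integer(), n_snps = integer(),
                      members = character(), lead_snp = character(),
                      max_neglog10p = numeric(), max_r2_pct = numeric(),
                      n_env = integer(), environments = character())
  unassigned0 <- data.frame(marker_id = character(), chromosome = character(),
                            position = integer(), n_env = integer())
  if (length(all_ids) == 0) {
    attr(empty, "unassigned") <- unassigned0
    return(empty)
  }
  idx <- match(all_ids, map$marker_id)
  if (anyNA(idx)) stop("significant marker absent from map: ",
                       all_ids[is.na(idx)][1])
  snp <- data.frame(marker_id = all_ids,
                    chromosome = map$chromosome[idx],
                    position = map$position[idx])
  snp$n_env <- vapply(snp$marker_id, function(id) {
    sum(vapply(sig, function(s) id %in% s, logical(1)))
  }, integer(1))

  ## marker-level annotation from the records
  best_nlp <- best_r2 <- setNames(rep(NA_real_, nrow(snp)), snp$marker_id)
  if (!is.null(records)) {
    r <- records[records$marker_id %in% snp$marker_id & !is.na(records$p), ]
    if (nrow(r) > 0) {
      best_nlp[] <- tapply(r$neglog10p, r$marker_id, max)[snp$marker_id]
      best_r2[] <- tapply(r$r2_marker, r$marker_id, max)[snp$marker_id]
    }
  }

  loci <- list()
  unassigned <- list()
  for (chr in unique(snp$chromosome)) {
    s <- snp[snp$chromosome == chr, , drop = FALSE]
    s <- s[order(s$position), , drop = FALSE]
    cl <- cumsum(c(1, diff(s$position) > gap))
    for (g in split(seq_len(nrow(s)), cl)) {
      mem <- s[g, , drop = FALSE]
      if (nrow(mem) >= 2 || mem$n_env[1] >= 2) {
        envs_hit <- names(sig)[vapply(sig, function(set) {
          any(mem$marker_id %in% set)
        }, logical(1))]
        nlp <- best_nlp[mem$marker_id]
        lead <- if (all(is.na(nlp))) {
          mem$marker_id[1]
        } else {
          top <- which(nlp == max(nlp, na.rm = TRUE))
          mem$marker_id[top[which.min(mem$position[top])]]
        }
        loci[[length(loci) + 1]] <- data.frame(
          name = sprintf("qFTi:%s:%d-%d", chr, min(mem$position), max(mem$position)),
          chromosome = chr, start = min(mem$position), end = max(mem$position),
          n_snps = nrow(mem),
          members = paste(mem$marker_id, collapse = ";"),
          lead_snp = lead,
          max_neglog10p = suppressWarnings(max(nlp, na.rm = TRUE)),
          max_r2_pct = 100 * suppressWarnings(max(best_r2[mem$marker_id], na.rm = TRUE)),
          n_env = length(envs_hit),
          environments = paste(sort(envs_hit), collapse = ";"))
      } else {
        unassigned[[length(unassigned) + 1]] <- mem
      }
    }
  }
  out <- if (length(loci)) do.call(rbind, loci) else empty
  out$max_neglog10p[!is.finite(out$max_neglog10p)] <- NA_real_
  out$max_r2_pct[!is.finite(out$max_r2_pct)] <- NA_real_
  ord <- order(chromosome_rank(out$chromosome), out$start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  ua <- if (length(unassigned)) do.call(rbind, unassigned) else unassigned0
  rownames(ua) <- NULL
  attr(out, "unassigned") <- ua
  out
}

#' Attach candidate genes to QTL loci
#'
#' A gene is assigned to a locus iff its interval overlaps the locus
#' interval by at least one bp on the same chromosome; loci may end up
#' with no candidate genes.
#'
#' @param loci locus table from [merge_loci()].
#' @param genes gene table (see [read_gene_table()]).
#' @return `loci` with added columns `candidate_genes`
#'   (semicolon-separated gene ids) and `n_genes`.
#' @export
assign_candidate_genes <- function(loci, genes) {
  loci$candidate_genes <- ""
  loci$n_genes <- 0L
  if (nrow(loci) == 0 || nrow(genes) == 0) return(loci)
  for (i in seq_len(nrow(loci))) {
    hit <- genes$chromosome == loci$chromosome[i] &
      genes$start <= loci$end[i] & genes$end >= loci$start[i]
    loci$candidate_genes[i] <- paste(genes$gene_id[hit], collapse = ";")
    loci$n_genes[i] <- sum(hit)
  }
  loci
}

#' Call QTLs from association records
#'
#' Wrapper chaining [significant_snps()] and [merge_loci()], optionally
#' attaching candidate genes.
#'
#' @param records association records across environments.
#' @param threshold a `significance_threshold` (or raw p cutoff).
#' @param map marker map.
#' @param gap chaining distance in bp (default 1.5e6).
#' @param genes optional gene table.
#' @return locus table as in [merge_loci()].
#' @export
call_qtls <- function(records, threshold, map, gap = 1.5e6, genes = NULL) {
  sig <- significant_snps(records, threshold)
  loci <- merge_loci(sig, map, gap = gap, records = records)
  if (!is.null(genes)) {
    ua <- attr(loci, "unassigned")
    loci <- assign_candidate_genes(loci, genes)
    attr(loci, "unassigned") <- ua
  }
  loci
}
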