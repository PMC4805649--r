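#' Run the full association-and-adaptation pipeline on one cohort
#'
#' Chains the analysis stages on in-memory inputs: phenotype
#' descriptives, correlations, ANOVA and heritability; marker thinning,
#' kinship, PCA and Q; the requested association model in every
#' environment; the pooled BH-FDR threshold; QTL merging and candidate
#' gene assignment; and, when spring/winter labels are available, the
#' F_ST selection scan with QTL/gene overlap.
#'
#' @param genotypes a [genotypes()] object (already MAF-filtered, or set
#'   `maf_threshold`).
#' @param phenotypes a `phenotype_table`.
#' @param labels optional growth-type labels (needed for the selection
#'   scan and the label-based Q matrix).
#' @param genes optional candidate-gene table.
#' @param model association model (default `"Q+K"`).
#' @param maf_threshold MAF filter applied first (default 0.05).
#' @param fdr_level pooled BH FDR level (default 0.10).
#' @param gap QTL chaining distance, bp (default 1.5e6).
#' @param window,step F_ST window and slide, bp (defaults 5e5 / 5e4).
#' @param top_fraction fraction of windows called as selection targets
#'   (default 0.10).
#' @param n_pcs principal components for the PCA covariate (default 5).
#' @param q_source `"labels"` (default when labels given) or
#'   `"pca_kmeans"`.
#' @return list with elements `descriptives`, `correlations`, `anova`,
#'   `heritability`, `records`, `threshold`, `loci`, `unassigned_snps`,
#'   and (when the scan runs) `fst`, `windows`, `regions`,
#'   `qtl_overlap`, `gene_overlap`.
#' @export
run_pipeline <- function(genotypes, phenotypes, labels = NULL, genes = NULL,
                         model = "Q+K", maf_threshold = 0.05,
                         fdr_level = 0.10, gap = 1.5e6,
                         window = 5e5, step = 5e4, top_fraction = 0.10,
                         n_pcs = 5,
                         q_source = if (is.null(labels)) "pca_kmeans" else "labels") {
  G <- filter_maf(genotypes, maf_threshold)

  out <- list()
  out$descriptives <- descriptive_stats(phenotypes)
  out$correlations <- env_correlations(phenotypes)
  out$anova <- anova_two_way(phenotypes)
  out$heritability <- if (!isTRUE(attr(out$anova, "pooled_interaction")))
    heritability(out$anova) else NA_real_

  thin_ids <- thin_markers(G$map, marker_maf(G))
  G_thin <- if (length(thin_ids) >= 2)
    subset_markers(G, match(thin_ids, G$map$marker_id)) else G
  K <- if (model %in% c("K", "Q+K", "PCA+K")) kinship(G_thin) else NULL
  PCA <- if (model %in% c("PCA", "PCA+K")) genotype_pca(G, n_components = n_pcs) else NULL
  Q <- if (model %in% c("Q", "Q+K")) {
    if (q_source == "labels") q_matrix(G, "labels", labels = labels)
    else q_matrix(G, "pca_kmeans", k = 2)
  } else NULL

  out$records <- association_scan(G, phenotypes, model = model,
                                  Q = Q, PCA = PCA, K = K)
  out$threshold <- pooled_fdr_threshold(out$records, fdr_level = fdr_level)
  out$loci <- call_qtls(out$records, out$threshold, G$map, gap = gap,
                        genes = genes)
  out$unassigned_snps <- attr(out$loci, "unassigned")

  if (!is.null(labels)) {
    lab <- growth_labels(labels)[G$lines]
    if (sum(lab == "spring", na.rm = TRUE) >= 2 &&
        sum(lab == "winter", na.rm = TRUE) >= 2) {
      out$fst <- snp_fst(G, labels)
      out$windows <- fst_windows(out$fst, G$map, window = window, step = step)
      out$regions <- call_selection_regions(out$windows,
                                            top_fraction = top_fraction)
      out$qtl_overlap <- overlap_qtls(out$loci, out$regions)
      if (!is.null(genes)) {
        out$gene_overlap <- genes_in_regions(genes, out$regions)
      }
    }
  }
  out
}
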