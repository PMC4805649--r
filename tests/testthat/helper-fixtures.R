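# shared fixture builders; all randomness is seeded by the caller

make_genotypes <- function(dosage, chrom, pos, ids = NULL) {
  ids <- ids %||% paste0(chrom, "_", pos)
  ftqtl::genotypes(dosage, data.frame(marker_id = ids, chromosome = chrom,
                                      position = pos))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random unstructured genotype matrix, no missing calls
random_genotypes <- function(n_lines, n_markers, chrom = "A01",
                             chrom_len = 1e7, maf_range = c(0.1, 0.5)) {
  p <- runif(n_markers, maf_range[1], maf_range[2])
  dos <- matrix(2L * rbinom(n_lines * n_markers, 1, rep(p, each = n_lines)),
                n_lines, n_markers)
  pos <- sort(sample.int(chrom_len, n_markers))
  rownames(dos) <- sprintf("L%03d", seq_len(n_lines))
  make_genotypes(dos, chrom, pos)
}

# independent transcription of the Weir-Cockerham (1984) two-population
# variance components for a single biallelic locus
wc_fst_oracle <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# two sub-populations stacked into one labelled genotype panel
two_pop_genotypes <- function(d1, d2) {
  dos <- rbind(d1, d2)
  n <- nrow(dos)
  rownames(dos) <- sprintf("L%03d", seq_len(n))
  G <- suppressWarnings(make_genotypes(dos, "A01", sort(sample.int(1e7, ncol(dos)))))
  labels <- data.frame(line = G$lines,
                       growth_type = rep(c("spring", "winter"),
                                         c(nrow(d1), nrow(d2))))
  list(G = G, labels = labels)
}

# balanced phenotype table from a lines x envs matrix of genetic values
pheno_from_matrix <- function(vals, reps = 2, sd_plot = 0) {
  envs <- colnames(vals) %||% paste0("E", seq_len(ncol(vals)))
  lines <- rownames(vals) %||% sprintf("L%03d", seq_len(nrow(vals)))
  recs <- expand.grid(line = lines, environment = envs,
                      replication = seq_len(reps), stringsAsFactors = FALSE)
  recs$value <- vals[cbind(match(recs$line, lines),
                           match(recs$environment, envs))] +
    if (sd_plot > 0) rnorm(nrow(recs), 0, sd_plot) else 0
  ftqtl::phenotype_table(recs)
}
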