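#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the structure of a rapeseed core-collection trial:
#' 448 inbred lines in spring (106), winter (153) and semi-winter (189)
#' growth types, ~2 x 10^4 SNPs on 19 chromosomes (A01-A10, C01-C09,
#' ~63 Mb each, ~1.2 Gb genome), four environments grown with up to three
#' replications, and a genotype / environment / interaction variance
#' structure whose expected-mean-square decomposition matches a
#' multi-environment flowering-time trial (genetic variance ~36,
#' interaction ~32, plot error ~12.3 days^2).
#'
#' @param n_lines named integer vector of lines per sub-population; names
#'   are growth types (`spring`/`winter` enter the selection scan).
#' @param chromosomes named numeric vector of chromosome lengths in bp.
#' @param n_markers total number of SNP markers to place.
#' @param background_fst genome-background divergence between any two
#'   sub-populations, in `[0, 1)`.
#' @param selected_windows `NULL` or data frame `chromosome`, `start`,
#'   `end`, `fst`: windows whose markers are drawn at the elevated
#'   divergence `fst` (planted selection targets).
#' @param qtls `NULL` or data frame `chromosome`, `position`, `effect`
#'   (days per dosage unit), optional `environments` (semicolon-separated
#'   environment ids, `NA` = all), optional `maf` (ancestral allele
#'   frequency pinned at the causal marker, `NA` = drawn like any other
#'   marker), optional `n_tags` (markers planted with correlated dosages
#'   at the locus, default 1), optional `tag_span` (bp around the causal
#'   marker holding the tags, default 5e5) and `tag_flip` (per-line
#'   probability that a tag dosage is flipped, default 0.05).
#' @param env_means named numeric vector: mean days-to-flower per
#'   environment.
#' @param replications replications per environment (scalar, or vector
#'   recycled over environments; unbalanced designs such as 3/3/1/2 are
#'   supported).
#' @param var_g,var_ge,var_e genotype, genotype-by-environment and plot
#'   error variances, days^2.  `var_g` is the *total* genetic variance:
#'   planted QTL variance is subtracted from it and the remainder realized
#'   as a line-level polygenic draw.
#' @param het_rate probability that a call is recorded heterozygous
#'   (dosage 1); inbred default 0.
#' @param p_ancestral_range range of the uniform draw of ancestral allele
#'   frequencies.
#' @param seed integer seed; all generator randomness derives from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_lines = c(spring = 106, winter = 153, semi_winter = 189),
                       chromosomes = setNames(rep(63e6, 19),
                                              c(sprintf("A%02d", 1:10),
                                                sprintf("C%02d", 1:9))),
                       n_markers = 20342,
                       background_fst = 0.05,
                       selected_windows = NULL,
                       qtls = NULL,
                       env_means = c(JX2007 = 163.4, JX2012 = 159.8,
                                     WH2013 = 154.6, YL2013 = 164.8),
                       replications = 3,
                       var_g = 36, var_ge = 32, var_e = 12.3,
                       het_rate = 0,
                       p_ancestral_range = c(0.05, 0.95),
                       seed = 1) {
  stopifnot(length(n_lines) >= 1, all(n_lines >= 1),
            !is.null(names(n_lines)), !is.null(names(chromosomes)),
            all(chromosomes > 0),
            var_g >= 0, var_ge >= 0, var_e >= 0,
            background_fst >= 0, background_fst < 1,
            het_rate >= 0, het_rate <= 1,
            length(env_means) >= 1, !is.null(names(env_means)),
            all(replications >= 1))
  if (!is.null(selected_windows)) {
    selected_windows <- as.data.frame(selected_windows)
    stopifnot(all(c("chromosome", "start", "end", "fst") %in% names(selected_windows)),
              all(selected_windows$fst >= 0), all(selected_windows$fst < 1),
              all(selected_windows$chromosome %in% names(chromosomes)))
    len <- chromosomes[selected_windows$chromosome]
    if (any(selected_windows$start < 1 | selected_windows$end > len |
            selected_windows$start > selected_windows$end)) {
      stop("selected window outside chromosome bounds")
    }
  }
  if (!is.null(qtls)) {
    qtls <- as.data.frame(qtls)
    stopifnot(all(c("chromosome", "position", "effect") %in% names(qtls)))
    if (is.null(qtls$environments)) qtls$environments <- NA_character_
    if (is.null(qtls$maf)) qtls$maf <- NA_real_
    if (is.null(qtls$n_tags)) qtls$n_tags <- 1L
    if (is.null(qtls$tag_span)) qtls$tag_span <- 5e5
    if (is.null(qtls$tag_flip)) qtls$tag_flip <- 0.05
    if (!all(qtls$chromosome %in% names(chromosomes))) {
      stop("QTL chromosome not in config")
    }
  }
  replications <- as.integer(rep_len(replications, length(env_means)))
  names(replications) <- names(env_means)
  structure(list(n_lines = n_lines, chromosomes = chromosomes,
                 n_markers = as.integer(n_markers),
                 background_fst = background_fst,
                 selected_windows = selected_windows, qtls = qtls,
                 env_means = env_means, replications = replications,
                 var_g = var_g, var_ge = var_ge, var_e = var_e,
                 het_rate = het_rate,
                 p_ancestral_range = p_ancestral_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Balding-Nichols sub-population allele frequencies
#'
#' Draws one allele frequency per sub-population from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, the pure-drift divergence model whose
#' between-population frequency variance is `F p (1 - p)`.  `fst = 0` is
#' the degenerate point mass at the ancestral frequency.
#'
#' @param p_ancestral ancestral frequency (vectorized), in (0, 1).
#' @param fst divergence parameter (vectorized), in `[0, 1)`.
#' @param n_pops number of sub-populations to draw (columns).
#' @return matrix with `length(p_ancestral)` rows and `n_pops` columns of
#'   frequencies in `[0, 1]`.  Uses the current RNG state; seed outside.
#' @export
balding_nichols_frequencies <- function(p_ancestral, fst, n_pops = 2) {
  stopifnot(all(p_ancestral > 0), all(p_ancestral < 1),
            all(fst >= 0), all(fst < 1), n_pops >= 1)
  m <- length(p_ancestral)
  fst <- rep_len(fst, m)
  out <- matrix(rep(p_ancestral, n_pops), nrow = m)
  pos <- fst > 0
  if (any(pos)) {
    a <- p_ancestral[pos] * (1 - fst[pos]) / fst[pos]
    b <- (1 - p_ancestral[pos]) * (1 - fst[pos]) / fst[pos]
    for (k in seq_len(n_pops)) {
      out[pos, k] <- stats::rbeta(sum(pos), a, b)
    }
  }
  out
}

#' Simulate structured genotypes with planted divergence windows
#'
#' Markers are placed uniformly at random along each chromosome (then
#' sorted); each marker's sub-population frequencies are Balding-Nichols
#' draws at the window divergence inside planted selected windows and at
#' the background divergence elsewhere; inbred-line dosages are drawn
#' homozygous as `2 * Bernoulli(p_subpop)` (a nonzero `het_rate`
#' introduces dosage-1 calls).  Planted QTLs may carry extra tag markers
#' whose dosages are noisy copies of the causal marker, giving local
#' co-significant SNPs without simulating recombination.
#'
#' @param config a [sim_config()].
#' @return list with elements `genotypes` ([genotypes()] object), `labels`
#'   (data frame `line`, `growth_type`) and `truth` (planted QTL markers,
#'   planted windows, sub-population sizes).  Deterministic given
#'   `config$seed`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- config$chromosomes
  n_chr <- length(chroms)
  ## proportional allocation, >= 2 markers per chromosome required
  alloc <- floor(config$n_markers * chroms / sum(chroms))
  rem <- config$n_markers - sum(alloc)
  if (rem > 0) {
    extra <- order(config$n_markers * chroms / sum(chroms) - alloc,
                   decreasing = TRUE)[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1
  }
  if (any(alloc < 2)) {
    stop("fewer than 2 markers allocated to a chromosome; increase n_markers")
  }

  map <- do.call(rbind, lapply(seq_len(n_chr), function(i) {
    pos <- sort(sample.int(chroms[i], alloc[i]))
    data.frame(marker_id = paste0(names(chroms)[i], "_", pos),
               chromosome = names(chroms)[i], position = pos)
  }))
  m <- nrow(map)

  fst <- rep(config$background_fst, m)
  if (!is.null(config$selected_windows)) {
    for (i in seq_len(nrow(config$selected_windows))) {
      w <- config$selected_windows[i, ]
      hit <- map$chromosome == w$chromosome &
        map$position >= w$start & map$position <= w$end
      fst[hit] <- w$fst
    }
  }

  p_anc <- runif(m, config$p_ancestral_range[1], config$p_ancestral_range[2])
  if (!is.null(config$qtls)) {
    ## pin the ancestral frequency of causal markers where requested
    for (i in seq_len(nrow(config$qtls))) {
      q <- config$qtls[i, ]
      if (is.na(q$maf)) next
      on_chr <- which(map$chromosome == q$chromosome)
      causal <- on_chr[which.min(abs(map$position[on_chr] - q$position))]
      p_anc[causal] <- q$maf
    }
  }
  pops <- names(config$n_lines)
  freqs <- balding_nichols_frequencies(p_anc, fst, n_pops = length(pops))

  n_total <- sum(config$n_lines)
  line_ids <- sprintf("L%04d", seq_len(n_total))
  growth <- rep(pops, config$n_lines)
  dosage <- matrix(NA_integer_, n_total, m)
  row0 <- 0L
  for (k in seq_along(pops)) {
    nk <- config$n_lines[k]
    pk <- freqs[, k]
    block <- matrix(2L * rbinom(nk * m, 1L, rep(pk, each = nk)), nk, m)
    if (config$het_rate > 0) {
      het <- matrix(runif(nk * m) < config$het_rate, nk, m)
      block[het] <- 1L
    }
    dosage[row0 + seq_len(nk), ] <- block
    row0 <- row0 + nk
  }
  rownames(dosage) <- line_ids
  colnames(dosage) <- map$marker_id

  ## plant QTL tag markers: noisy copies of the causal column
  qtl_truth <- NULL
  if (!is.null(config$qtls)) {
    qtl_truth <- do.call(rbind, lapply(seq_len(nrow(config$qtls)), function(i) {
      q <- config$qtls[i, ]
      on_chr <- which(map$chromosome == q$chromosome)
      if (length(on_chr) == 0) stop("no markers on QTL chromosome ", q$chromosome)
      causal <- on_chr[which.min(abs(map$position[on_chr] - q$position))]
      tags <- integer(0)
      if (q$n_tags > 1) {
        near <- on_chr[abs(map$position[on_chr] - map$position[causal]) <= q$tag_span &
                         on_chr != causal]
        near <- near[order(abs(map$position[near] - map$position[causal]))]
        tags <- head(near, q$n_tags - 1)
        for (t in tags) {
          col <- dosage[, causal]
          flip <- runif(n_total) < q$tag_flip
          col[flip] <- 2L - col[flip]
          dosage[, t] <<- col
        }
      }
      data.frame(marker_id = map$marker_id[causal],
                 chromosome = map$chromosome[causal],
                 position = map$position[causal],
                 effect = q$effect,
                 environments = q$environments,
                 tag_markers = paste(map$marker_id[tags], collapse = ";"))
    }))
  }

  G <- genotypes(dosage, map, lines = line_ids)
  labels <- data.frame(line = line_ids, growth_type = growth)
  truth <- list(qtls = qtl_truth,
                selected_windows = config$selected_windows,
                subpopulations = as.list(config$n_lines),
                background_fst = config$background_fst,
                seed = config$seed)
  list(genotypes = G, labels = labels, truth = truth)
}

#' Simulate plot-level flowering-time phenotypes
#'
#' Each record is
#' `env_mean + sum(effect * centered QTL dosage) + polygenic line term +
#' line-by-environment interaction + plot noise`.  The polygenic variance
#' is `var_g` minus the realized variance of the planted QTL term
#' (truncated at zero), so `var_g` stays the total genetic variance.
#' QTL effects restricted to a subset of environments contribute to the
#' interaction.
#'
#' @param G a [genotypes()] object.
#' @param config a [sim_config()].
#' @param truth optional truth list from [simulate_genotypes()]; when
#'   given, its resolved QTL marker ids are used, otherwise QTLs are
#'   resolved to the nearest marker afresh.
#' @return list with `phenotypes` (a `phenotype_table`) and `truth`
#'   (planted effects plus realized variance components and the
#'   plug-in broad-sense heritability target).
#' @export
simulate_phenotypes <- function(G, config, truth = NULL) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(config, "sim_config"))
  set.seed(config$seed + 7919L)
  envs <- names(config$env_means)
  n_env <- length(envs)
  n <- length(G$lines)

  qtls <- if (!is.null(truth)) truth$qtls else NULL
  if (is.null(qtls) && !is.null(config$qtls)) {
    qtls <- do.call(rbind, lapply(seq_len(nrow(config$qtls)), function(i) {
      q <- config$qtls[i, ]
      on_chr <- which(G$map$chromosome == q$chromosome)
      if (length(on_chr) == 0) stop("no markers on QTL chromosome ", q$chromosome)
      causal <- on_chr[which.min(abs(G$map$position[on_chr] - q$position))]
      data.frame(marker_id = G$map$marker_id[causal],
                 chromosome = q$chromosome,
                 position = G$map$position[causal],
                 effect = q$effect, environments = q$environments,
                 tag_markers = "")
    }))
  }

  ## per-line QTL genetic value, per environment
  qval <- matrix(0, n, n_env, dimnames = list(G$lines, envs))
  if (!is.null(qtls)) {
    miss <- setdiff(qtls$marker_id, G$map$marker_id)
    if (length(miss) > 0) stop("QTL marker absent from genotypes: ", miss[1])
    for (i in seq_len(nrow(qtls))) {
      g <- G$dosage[, qtls$marker_id[i]]
      g[is.na(g)] <- mean(g, na.rm = TRUE)
      contrib <- qtls$effect[i] * (g - mean(g))
      aff <- if (is.na(qtls$environments[i])) envs else
        strsplit(qtls$environments[i], ";", fixed = TRUE)[[1]]
      qval[, intersect(aff, envs)] <- qval[, intersect(aff, envs)] + contrib
    }
  }
  var_qtl <- mean(apply(qval, 2, var))
  var_poly <- config$var_g - var_qtl
  if (var_poly < 0) {
    warning("planted QTL variance exceeds var_g; polygenic variance set to 0")
    var_poly <- 0
  }

  g_line <- rnorm(n, 0, sqrt(var_poly))
  ge <- matrix(rnorm(n * n_env, 0, sqrt(config$var_ge)), n, n_env)

  recs <- vector("list", n_env)
  for (e in seq_len(n_env)) {
    b <- config$replications[e]
    genetic <- config$env_means[e] + qval[, e] + g_line + ge[, e]
    recs[[e]] <- data.frame(
      line = rep(G$lines, times = b),
      environment = envs[e],
      replication = rep(seq_len(b), each = n),
      value = rep(genetic, times = b) + rnorm(n * b, 0, sqrt(config$var_e)))
  }
  pheno <- phenotype_table(do.call(rbind, recs))

  b_mean <- mean(config$replications)
  out_truth <- truth %||% list()
  out_truth$qtls <- qtls
  out_truth$variance_components <- list(
    var_g = config$var_g, var_ge = config$var_ge, var_e = config$var_e,
    var_qtl = var_qtl, var_polygenic = var_poly)
  out_truth$h2_target <- config$var_g /
    (config$var_g + config$var_ge / n_env + config$var_e / (n_env * b_mean))
  list(phenotypes = pheno, truth = out_truth)
}

#' Simulate a full cohort (genotypes, phenotypes, labels, truth)
#'
#' @param config a [sim_config()].
#' @return list with `genotypes`, `phenotypes`, `labels`, `truth`.
#' @export
simulate_cohort <- function(config) {
  gen <- simulate_genotypes(config)
  ph <- simulate_phenotypes(gen$genotypes, config, truth = gen$truth)
  list(genotypes = gen$genotypes, phenotypes = ph$phenotypes,
       labels = gen$labels, truth = ph$truth)
}

#' Write a truth file as JSON
#'
#' Serializes planted QTLs, planted windows and variance components so a
#' downstream run can be scored against the generator's ground truth.
#'
#' @param truth truth list from [simulate_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
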