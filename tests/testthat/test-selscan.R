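test_that("per-SNP F_ST matches the component-formula oracle and its limits", {
  # identical allele counts in both sub-populations -> 0 after clamping
  d <- matrix(rep(c(0L, 0L, 2L, 2L), 2), 4, 2)
  tp <- two_pop_genotypes(d[1:2, , drop = FALSE] * 0L + c(0L, 2L),
                          matrix(c(0L, 2L, 0L, 2L), 2, 2))
  # build explicitly: both pops have dosages {0,2} at both markers
  f <- snp_fst(tp$G, tp$labels)
  expect_equal(unname(f), c(0, 0))

  # fixed difference at 50 + 50 lines
  tp2 <- two_pop_genotypes(matrix(2L, 50, 1), matrix(0L, 50, 1))
  expect_gte(unname(snp_fst(tp2$G, tp2$labels)), 0.97)

  # p1 = 0.2, p2 = 0.8, n1 = n2 = 50: hand-transcribed components
  d1 <- matrix(2L * rep(c(1, 0), c(10, 40)), 50, 1)
  d2 <- matrix(2L * rep(c(1, 0), c(40, 10)), 50, 1)
  tp3 <- two_pop_genotypes(d1, d2)
  expect_equal(unname(snp_fst(tp3$G, tp3$labels)),
               wc_fst_oracle(50, 0.2, 0, 50, 0.8, 0))
})

test_that("F_ST equals the oracle on randomized instances and is label-symmetric", {
  set.seed(41)
  for (rep in 1:100) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    d1 <- matrix(sample(c(0L, 1L, 2L), n1, replace = TRUE), n1, 1)
    d2 <- matrix(sample(c(0L, 1L, 2L), n2, replace = TRUE), n2, 1)
    tp <- two_pop_genotypes(d1, d2)
    got <- snp_fst(tp$G, tp$labels, clamp = FALSE)
    want <- wc_fst_oracle(n1, mean(d1) / 2, mean(d1 == 1L),
                          n2, mean(d2) / 2, mean(d2 == 1L))
    if (is.nan(want)) {
      expect_true(is.na(got))
    } else {
      expect_equal(unname(got), want)
    }
    # swapping the sub-population labels changes nothing
    swapped <- tp$labels
    swapped$growth_type <- c(spring = "winter", winter = "spring")[swapped$growth_type]
    expect_equal(snp_fst(tp$G, swapped, clamp = FALSE), got)
  }
})

test_that("markers callable in one sub-population only are NA", {
  d1 <- matrix(c(NA, NA, NA, 2L), 4, 1)
  d2 <- matrix(c(0L, 2L, 0L, 2L), 4, 1)
  tp <- two_pop_genotypes(d1, d2)
  expect_true(is.na(snp_fst(tp$G, tp$labels)))
})

test_that("window means follow the sparse-zeroing rule", {
  map <- data.frame(marker_id = c("a", "b", "c"), chromosome = "A01",
                    position = c(100L, 200L, 700000L))
  fst <- setNames(c(0.2, 0.4, 0.9), map$marker_id)
  w <- fst_windows(fst, map, window = 5e5, step = 5e4)
  # first window holds a and b -> mean 0.3; the window holding only c -> 0
  expect_equal(w$mean_fst[1], 0.3)
  only_c <- w$start > 200 & w$start <= 700000
  expect_true(all(w$mean_fst[only_c] == 0))
  expect_equal(w$end - w$start + 1, rep(5e5, nrow(w)))
})

test_that("dense constant F_ST gives constant qualifying windows", {
  set.seed(42)
  map <- data.frame(marker_id = paste0("m", 1:200), chromosome = "A01",
                    position = sort(sample.int(2e6, 200)))
  fst <- setNames(rep(0.25, 200), map$marker_id)
  w <- fst_windows(fst, map)
  expect_true(all(w$mean_fst[w$n_snps >= 2] == 0.25))
})

test_that("window means match a brute-force double loop", {
  set.seed(43)
  map <- data.frame(marker_id = paste0("m", 1:30),
                    chromosome = rep(c("A01", "A02"), each = 15),
                    position = c(sort(sample.int(2e6, 15)),
                                 sort(sample.int(2e6, 15))))
  fst <- setNames(runif(30), map$marker_id)
  fst[c(4, 20)] <- NA
  w <- fst_windows(fst, map, window = 5e5, step = 5e4)
  for (i in seq_len(nrow(w))) {
    hit <- map$chromosome == w$chromosome[i] &
      map$position >= w$start[i] & map$position < w$start[i] + 5e5 &
      !is.na(fst[map$marker_id])
    expect_equal(w$n_snps[i], sum(hit))
    expect_equal(w$mean_fst[i],
                 if (sum(hit) >= 2) mean(fst[map$marker_id[hit]]) else 0)
  }
})

test_that("selection regions take the strict top decile and merge adjacency", {
  w <- data.frame(chromosome = "A01",
                  start = as.integer(seq(1, by = 5e4, length.out = 100)),
                  end = as.integer(seq(5e5, by = 5e4, length.out = 100)),
                  n_snps = 5L, mean_fst = seq(0.01, 1, length.out = 100))
  r <- call_selection_regions(w, top_fraction = 0.10)
  # 100 distinct means: exactly 10 windows qualify (overlapping -> 1 region)
  expect_equal(sum(r$n_windows), 10L)

  w2 <- data.frame(chromosome = "A01",
                   start = c(1L, 50001L, 5000001L),
                   end = c(500000L, 550000L, 5500000L),
                   n_snps = 5L, mean_fst = c(0.9, 0.8, 0.85))
  w2 <- rbind(w2, data.frame(chromosome = "A01",
                             start = as.integer(1e7 + seq(1, by = 5e4, length.out = 30)),
                             end = as.integer(1e7 + seq(5e5, by = 5e4, length.out = 30)),
                             n_snps = 5L, mean_fst = 0.01))
  r2 <- call_selection_regions(w2, top_fraction = 0.10)
  expect_equal(r2$start[1], 1L)
  expect_equal(r2$end[1], 550000L)  # overlapping qualifiers merge

  w3 <- w
  w3$mean_fst <- 0.5
  expect_warning(r3 <- call_selection_regions(w3), "no window")
  expect_equal(nrow(r3), 0L)
})

test_that("overlap counting equals an all-pairs enumeration", {
  set.seed(44)
  for (rep in 1:50) {
    n_items <- sample(5:20, 1)
    n_reg <- sample(2:8, 1)
    chroms <- c("A01", "A02")
    items <- data.frame(name = paste0("q", seq_len(n_items)),
                        gene_id = paste0("g", seq_len(n_items)),
                        chromosome = sample(chroms, n_items, replace = TRUE),
                        start = sample.int(1e6, n_items))
    items$end <- items$start + sample.int(2e5, n_items)
    regions <- data.frame(chromosome = sample(chroms, n_reg, replace = TRUE),
                          start = sample.int(1e6, n_reg))
    regions$end <- regions$start + sample.int(3e5, n_reg)

    rep_q <- overlap_qtls(items, regions)
    hit_mat <- outer(seq_len(n_items), seq_len(n_reg), Vectorize(function(i, j) {
      items$chromosome[i] == regions$chromosome[j] &&
        items$start[i] <= regions$end[j] && items$end[i] >= regions$start[j]
    }))
    expect_equal(rep_q$n_qtls_overlapping, sum(rowSums(hit_mat) > 0))
    expect_equal(rep_q$n_regions_hit_by_qtls, sum(colSums(hit_mat) > 0))

    rep_g <- genes_in_regions(items, regions)
    expect_equal(rep_g$n_genes_in_regions, sum(rowSums(hit_mat) > 0))
    expect_equal(rep_g$n_regions_hit_by_genes, sum(colSums(hit_mat) > 0))
  }
  # disjoint chromosome sets and exact-match edge cases
  expect_equal(overlap_qtls(data.frame(name = "q1", chromosome = "A09",
                                       start = 1L, end = 10L),
                            data.frame(chromosome = "C05", start = 1L,
                                       end = 10L))$n_qtls_overlapping, 0L)
  eq <- overlap_qtls(data.frame(name = "q1", chromosome = "A01",
                                start = 5L, end = 10L),
                     data.frame(chromosome = "A01", start = 5L, end = 10L))
  expect_equal(eq$n_qtls_overlapping, 1L)
  expect_equal(eq$n_regions_hit_by_qtls, 1L)
})

test_that("region totals agree with an interval-union oracle and stay disjoint", {
  set.seed(45)
  cfg <- sim_config(n_lines = c(spring = 50, winter = 50),
                    chromosomes = c(A01 = 1e7, A02 = 1e7), n_markers = 600,
                    background_fst = 0.05, seed = 45)
  sim <- simulate_genotypes(cfg)
  fst <- snp_fst(sim$genotypes, sim$labels)
  w <- fst_windows(fst, sim$genotypes$map)
  r <- call_selection_regions(w)
  thr <- attr(r, "threshold")
  qual <- w[w$mean_fst > thr, ]
  for (chr in unique(r$chromosome)) {
    rc <- r[r$chromosome == chr, ]
    expect_true(all(rc$start[-1] > rc$end[-nrow(rc)] + 1))  # disjoint, sorted
    # union length oracle over qualifying windows
    cover <- logical(0)
    qc <- qual[qual$chromosome == chr, ]
    pos_len <- max(qc$end)
    cover <- rep(FALSE, pos_len)
    for (i in seq_len(nrow(qc))) cover[qc$start[i]:qc$end[i]] <- TRUE
    expect_equal(sum(rc$end - rc$start + 1), sum(cover))
  }
})

test_that("planted high-divergence windows are recovered by the scan", {
  found <- 0L
  for (seed in 1:5) {
    cfg <- sim_config(n_lines = c(spring = 100, winter = 100),
                      chromosomes = c(A01 = 2e7, A02 = 2e7), n_markers = 1000,
                      background_fst = 0.02,
                      selected_windows = data.frame(
                        chromosome = c("A01", "A01", "A02"),
                        start = c(2e6, 12e6, 6e6),
                        end = c(4e6, 14e6, 8e6),
                        fst = 0.4),
                      seed = 800 + seed)
    sim <- simulate_genotypes(cfg)
    fst <- snp_fst(sim$genotypes, sim$labels)
    w <- fst_windows(fst, sim$genotypes$map)
    r <- call_selection_regions(w)
    ok <- all(vapply(seq_len(3), function(i) {
      pw <- cfg$selected_windows[i, ]
      any(r$chromosome == pw$chromosome & r$start <= pw$end & r$end >= pw$start)
    }, logical(1)))
    if (ok) found <- found + 1L
  }
  expect_gte(found, 4L)
})
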