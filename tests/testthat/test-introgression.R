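test_that("within-site segments are filtered and unmapped samples rejected", {
  segs <- data.frame(sample1 = c("a", "a", "c"), hap1 = 1L,
                     sample2 = c("b", "c", "d"), hap2 = 2L,
                     chrom = "chr1", start = 1, end = 50000, score = NA)
  map <- c(a = "FD", b = "FD", c = "ZS", d = "ZS")
  out <- filter_segments(segs, map)
  expect_equal(nrow(out), 1)                       # a-c only (FD x ZS)
  expect_equal(out$sample2, "c")
  expect_equal(nrow(filter_segments(segs[0, ], map)), 0)
  expect_error(filter_segments(segs, map[1:2]), "unmapped")
})

test_that("the naive detector finds exactly shared tracts", {
  # two identical haplotypes across sites -> one segment spanning outermost SNPs
  h <- rbind(rep(0L, 6), c(0L, 1L, 0L, 1L, 0L, 1L),
             rep(0L, 6), c(1L, 0L, 1L, 0L, 1L, 0L))
  pos <- c(100, 2000, 4000, 6000, 8000, 9900)
  panel <- panel_from_matrix(h, pos, chrom_len = 10000,
                             sites = c("P1", "P2"))
  segs <- detect_shared_segments(panel, min_len = 5000)
  expect_equal(nrow(segs), 1)
  expect_equal(c(segs$start, segs$end), c(100, 9900))
  expect_equal(sort(c(segs$hap1, segs$hap2)), c(1L, 1L))
  # min_len larger than the chromosome span -> empty
  expect_equal(nrow(detect_shared_segments(panel, min_len = 1e6)), 0)
})

test_that("planted introgression tracts are recovered with high breakpoint overlap", {
  jacc_all <- c()
  for (s in 1:3) {
    cfg <- sim_config(seed = s, stock_of_site = c(S1 = "A", S2 = "B"),
                      n_diploids_per_site = 8,
                      chrom_lengths = c(chr1 = 2e6), n_snps_per_chrom = 2000,
                      divergence = 0.05, mosaic_switch_rate = 2e-6,
                      introgression_specs = list(
                        introgression_spec("A", "S2", 0.8, 5e5,
                          list(chrom = "chr1", start = 1, end = 2e6),
                          donor_carrier_freq = 0)))
    res <- simulate_panel(cfg)
    truth <- res$truth$segments
    truth <- truth[truth$end - truth$start >= 1e5, ]
    segs <- detect_shared_segments(res$panel, 5e4)
    for (k in seq_len(nrow(truth))) {
      tr <- truth[k, ]
      hit <- segs[(segs$sample1 == tr$sample1 & segs$hap1 == tr$hap1 &
                     segs$sample2 == tr$sample2 & segs$hap2 == tr$hap2) |
                    (segs$sample1 == tr$sample2 & segs$hap1 == tr$hap2 &
                       segs$sample2 == tr$sample1 & segs$hap2 == tr$hap1), ]
      if (!nrow(hit)) { jacc_all <- c(jacc_all, 0); next }
      inter <- pmax(0, pmin(hit$end, tr$end) - pmax(hit$start, tr$start))
      uni <- pmax(hit$end, tr$end) - pmin(hit$start, tr$start)
      jacc_all <- c(jacc_all, max(inter / uni))
    }
  }
  expect_gt(length(jacc_all), 5)
  expect_gte(mean(jacc_all >= 0.9), 0.9)
})

test_that("SHF window counting matches the pair-enumeration contract", {
  # stock A: 3 sites x 2 individuals; stock B: 2 sites x 2 individuals
  sos <- c(A1 = "A", A2 = "A", A3 = "A", B1 = "B", B2 = "B")
  site_map <- c(a1 = "A1", a2 = "A1", a3 = "A2", a4 = "A2", a5 = "A3",
                a6 = "A3", b1 = "B1", b2 = "B1", b3 = "B2", b4 = "B2")
  win <- make_windows(c(chr1 = 1e5))
  seg <- function(s1, s2, start, end)
    data.frame(sample1 = s1, hap1 = 1L, sample2 = s2, hap2 = 1L,
               chrom = "chr1", start = start, end = end, score = NA)
  # every cross-site pair of stock A shares the whole chromosome -> nSHF_A = 1
  pairs_A <- list(c("a1","a3"), c("a1","a4"), c("a2","a3"), c("a2","a4"),
                  c("a1","a5"), c("a1","a6"), c("a2","a5"), c("a2","a6"),
                  c("a3","a5"), c("a3","a6"), c("a4","a5"), c("a4","a6"))
  segs <- do.call(rbind, lapply(pairs_A, function(p) seg(p[1], p[2], 1, 1e5)))
  tab <- window_shf(segs, win, site_map, sos, stocks = c("A", "B"),
                    focal_pair = c("A1", "B1"), include_focal_sites = TRUE)
  expect_equal(tab$tshf_A[1], 2 * 2 * 3)          # 12 cross-site pairs
  # windows whose span can exceed the 10 kb overlap rule are all shared
  can_count <- (tab$end - tab$start) > 10000
  expect_true(all(tab$nshf_A[can_count] == 1))
  expect_true(all(tab$nshf_A[!can_count] == 0))
  expect_true(all(tab$nshf_B == 0))
  expect_true(all(is.na(tab$rshf)))               # censored: one side zero
  expect_true(all(tab$censored[can_count]))
  # duplicating a segment never changes cSHF (pair idempotence)
  tab2 <- window_shf(rbind(segs, segs[1, ]), win, site_map, sos,
                     stocks = c("A", "B"), focal_pair = c("A1", "B1"),
                     include_focal_sites = TRUE)
  expect_equal(tab2$cshf_A, tab$cshf_A)
  # no segments at all -> nSHF 0 everywhere
  tab0 <- window_shf(segs[0, ], win, site_map, sos, stocks = c("A", "B"),
                     focal_pair = c("A1", "B1"), include_focal_sites = TRUE)
  expect_true(all(tab0$nshf_A == 0) && all(tab0$nshf_B == 0))
})

test_that("window overlap must strictly exceed the 10 kb rule", {
  sos <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
  site_map <- c(a1 = "A1", a2 = "A2", b1 = "B1", b2 = "B2")
  win <- make_windows(c(chr1 = 50000))
  # segment overlapping window 1 ([0,25000)) by exactly 10 kb: not counted
  segs <- data.frame(sample1 = "a1", hap1 = 1L, sample2 = "a2", hap2 = 1L,
                     chrom = "chr1", start = 15001, end = 40000, score = NA)
  tab <- window_shf(segs, win, site_map, sos, stocks = c("A", "B"),
                    focal_pair = c("A1", "B1"), include_focal_sites = TRUE)
  expect_equal(tab$cshf_A[1], 0)
  segs$start <- 15000   # overlap 10001 > 10 kb
  tab2 <- window_shf(segs, win, site_map, sos, stocks = c("A", "B"),
                     focal_pair = c("A1", "B1"), include_focal_sites = TRUE)
  expect_equal(tab2$cshf_A[1], 1)
})

test_that("rSHF arithmetic, censoring and classification", {
  expect_equal(rshf(0.3, 0.3), 0)
  expect_equal(rshf(0.40, 0.05), 3)
  expect_equal(rshf(c(0.4, 0.2), c(0.1, 0.4)),
               -rshf(c(0.1, 0.4), c(0.4, 0.2)))
  expect_true(is.na(rshf(0, 0.5)))
  expect_equal(as.character(classify_rshf(c(3, 0, -3))),
               c("A-origin", "symmetric", "B-origin"))
  expect_equal(as.character(classify_rshf(2.5)), "symmetric")  # not strict
})

test_that("nSHF group comparisons: identical groups, oracle H, separated groups", {
  a <- c(0.1, 0.2, 0.3, 0.4)
  res <- compare_nshf(a, a)
  expect_gt(res$anova_p, 0.999)
  expect_gt(res$kruskal_p, 0.999)
  # Kruskal-Wallis H matches the exhaustive rank oracle
  g1 <- c(0.05, 0.11, 0.31); g2 <- c(0.22, 0.4, 0.18, 0.09)
  kt <- stats::kruskal.test(list(g1, g2))
  expect_equal(unname(kt$statistic), oracle_kruskal_h(list(g1, g2)),
               tolerance = 1e-10)
  # large separation: all three tests significant
  set.seed(4)
  x <- rnorm(40, 0, 0.01); y <- rnorm(40, 1, 0.01)
  res2 <- compare_nshf(x, y)
  expect_lt(res2$anova_p, 1e-6)
  expect_lt(res2$kruskal_p, 1e-6)
  expect_lt(res2$alexander_govern_p, 1e-6)
  expect_error(compare_nshf(0.1, 0.2), "need >= 2")
})

test_that("Alexander-Govern agrees with ANOVA under homoscedasticity", {
  set.seed(6)
  x <- rnorm(200); y <- rnorm(200, 0.2)
  ag <- alexander_govern(list(x, y))
  an <- summary(stats::aov(c(x, y) ~ factor(rep(1:2, each = 200))))[[1]]
  expect_lt(abs(ag$p.value - an$`Pr(>F)`[1]), 0.02)
  expect_error(alexander_govern(list(c(1, 1), c(2, 3))), "zero within-group")
})

test_that("rSHF correlations match brute-force covariance and rank oracles", {
  set.seed(5)
  n <- 10
  scan <- data.frame(window = 1:n, fst = runif(n), pi_lr = rnorm(n),
                     rsb = rnorm(n), css = rnorm(n))
  attr(scan, "stocks") <- c("A", "B")
  shf <- data.frame(window = 1:n, rshf = -scan$rsb)  # exact anti-dependence
  res <- correlate_with_selection(shf, scan)
  rsb_row <- res[res$index == "rsb", ]
  expect_equal(rsb_row$pearson_r, -1, tolerance = 1e-12)
  expect_equal(rsb_row$r_squared, 1, tolerance = 1e-12)
  fst_row <- res[res$index == "fst", ]
  expect_equal(fst_row$pearson_r, oracle_pearson(scan$fst, shf$rshf),
               tolerance = 1e-10)
  expect_equal(fst_row$spearman_rho, oracle_spearman(scan$fst, shf$rshf),
               tolerance = 1e-10)
  # Spearman invariant under monotone transform
  shf2 <- shf; shf2$rshf <- exp(shf$rshf)
  res2 <- correlate_with_selection(shf2, scan)
  expect_equal(res2$spearman_rho, res$spearman_rho, tolerance = 1e-12)
})

test_that("focal-window count grows with the introgressed fraction", {
  counts <- vapply(c(0, 0.3, 0.8), function(fr) {
    cfg <- sim_config(seed = 20, stock_of_site = c(P1 = "A", P2 = "A",
                                                   Q1 = "B", Q2 = "B"),
                      n_diploids_per_site = 8,
                      chrom_lengths = c(chr1 = 2e6), n_snps_per_chrom = 2000,
                      introgression_specs = if (fr == 0) list() else list(
                        introgression_spec("A", "Q1", fr, 2e5,
                          list(chrom = "chr1", start = 2e5, end = 1.8e6))))
    res <- simulate_panel(cfg)
    segs <- detect_shared_segments(res$panel, 1e5)
    win <- make_windows(res$panel$chrom_lengths)
    tab <- window_shf(segs, win, res$panel$site_of_sample,
                      res$panel$stock_of_site, stocks = c("A", "B"),
                      focal_pair = c("P1", "Q1"), include_focal_sites = TRUE)
    sum(tab$focal)
  }, numeric(1))
  expect_true(counts[1] <= counts[2] && counts[2] <= counts[3])
  expect_gt(counts[3], counts[1])
})
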