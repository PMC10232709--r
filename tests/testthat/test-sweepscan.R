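# a synthetic scan table with known structure, for classification tests
fake_scan <- function(n = 100, seed = 1) {
  set.seed(seed)
  scan <- data.frame(chrom = "chr1", start = (seq_len(n) - 1) * 5000,
                     end = (seq_len(n) - 1) * 5000 + 25000,
                     window = seq_len(n), truncated = FALSE,
                     n_snps = 10L,
                     fst = runif(n, 0, 0.1),
                     pi_A = runif(n, 1e-4, 2e-4), pi_B = runif(n, 1e-4, 2e-4),
                     rsb = rnorm(n, 0, 0.5),
                     tajd_A = rnorm(n), tajd_B = rnorm(n))
  scan$pi_lr <- pi_log_ratio(scan$pi_A, scan$pi_B)
  scan$css <- css(scan$fst, scan$pi_lr, scan$rsb)
  attr(scan, "stocks") <- c("A", "B")
  scan
}

test_that("Pi log-ratio is antisymmetric and handles zero diversity", {
  expect_equal(pi_log_ratio(2e-4, 2e-4), 0)
  expect_equal(pi_log_ratio(1e-4, 2e-4), 1)
  a <- c(1e-4, 3e-4); b <- c(2e-4, 1.5e-4)
  expect_equal(pi_log_ratio(a, b), -pi_log_ratio(b, a))
  # zero in one stock: floored at half the smallest nonzero value
  v <- pi_log_ratio(c(0, 2e-4), c(2e-4, 2e-4))
  expect_equal(v[1], log2(2e-4 / 1e-4))
  expect_true(is.na(pi_log_ratio(0, 0)))
})

test_that("CSS follows the rank-probit construction", {
  n <- 99
  set.seed(2)
  fst <- runif(n); pi <- runif(n); rsb <- rnorm(n)
  top <- which.max(fst)
  fst[top] <- 2; pi[top] <- 2; rsb[top] <- 99   # top in all three
  v <- css(fst, pi, rsb)
  expect_equal(v[top], qnorm(99 / 100), tolerance = 1e-12)
  # invariance under strictly monotone transforms
  v2 <- css(exp(3 * fst), pi^3, atan(rsb))
  expect_equal(v, v2, tolerance = 1e-12)
  # symmetry of the probit of uniform ranks: mean ~ 0
  set.seed(3)
  m <- 10000
  v3 <- css(runif(m), runif(m), rnorm(m))
  expect_lt(abs(mean(v3)), 0.01)
  expect_error(css(1, 1, 1), "at least 2")
})

test_that("outlier sets have percentile-exact sizes and degenerate to empty", {
  scan <- fake_scan(100)
  sets <- call_outlier_sets(scan)
  expect_equal(lengths(sets)[c("fst_top", "pi_A", "pi_B", "rsb_A", "rsb_B")],
               c(fst_top = 5L, pi_A = 5L, pi_B = 5L, rsb_A = 5L, rsb_B = 5L))
  scan$fst <- rep(0.05, 100)
  expect_equal(length(call_outlier_sets(scan)$fst_top), 0)
  expect_error(call_outlier_sets(fake_scan(10)), "too few")
})

test_that("raising the percentile never adds outlier windows", {
  scan <- fake_scan(200, seed = 5)
  s95 <- call_outlier_sets(scan, 95)
  s97 <- call_outlier_sets(scan, 97.5)
  s99 <- call_outlier_sets(scan, 99)
  for (nm in names(s95)) {
    expect_true(all(s97[[nm]] %in% s95[[nm]]))
    expect_true(all(s99[[nm]] %in% s97[[nm]]))
  }
})

test_that("classification follows the two-index evidence rules", {
  scan <- fake_scan(100, seed = 7)
  # engineer memberships: window 1 Fst+PiA; 2 PiA+RsbA; 3 Fst+RsbA;
  # window 4 PiA+RsbB (conflict); window 5 Fst only
  sets <- list(fst_top = c(1L, 3L, 5L), pi_A = c(1L, 2L, 4L),
               pi_B = integer(0), rsb_A = c(2L, 3L), rsb_B = 4L)
  res <- classify_psrs(sets, scan)
  w <- res$windows
  expect_equal(w$class[w$window == 1], "NF")
  expect_equal(w$class[w$window == 2], "RS")
  expect_equal(w$class[w$window == 3], "UD")
  expect_true(all(w$stock[w$window %in% 1:3] == "A"))
  expect_false(4 %in% w$window)      # conflicting directions dropped
  expect_equal(res$n_conflicting, 1L)
  expect_false(5 %in% w$window)      # one index is not enough
  # every classified window has exactly one (stock, class)
  expect_equal(anyDuplicated(w$window), 0L)
})

test_that("all-three windows split by diversity depletion (and can be forced)", {
  scan <- fake_scan(100, seed = 8)
  scan$pi_lr[10] <- 5    # deeply depleted in A
  scan$pi_lr[11] <- 1    # mildly depleted
  sets <- list(fst_top = c(10L, 11L), pi_A = c(10L, 11L), pi_B = integer(0),
               rsb_A = c(10L, 11L), rsb_B = integer(0))
  w <- classify_psrs(sets, scan)$windows
  expect_equal(w$class[w$window == 10], "NF")
  expect_equal(w$class[w$window == 11], "RS")
  w2 <- classify_psrs(sets, scan, all_three = "NF")$windows
  expect_true(all(w2$class == "NF"))
})

test_that("same-class neighbouring windows merge; different classes never do", {
  scan <- fake_scan(100, seed = 9)
  sets <- list(fst_top = c(20L, 21L, 22L, 40L), pi_A = c(20L, 21L, 22L),
               pi_B = integer(0), rsb_A = 40L, rsb_B = integer(0))
  res <- classify_psrs(sets, scan)
  nf <- res$psrs[res$psrs$class == "NF", ]
  expect_equal(nrow(nf), 1)
  expect_equal(nf$n_windows, 3L)
  expect_equal(nf$start, scan$start[20])
  expect_equal(nf$end, scan$end[22])
  expect_equal(nrow(res$psrs), 2)    # the UD window stays separate
})

test_that("PSR summaries: KS uniformity bound and LSD equals the pooled t-test", {
  scan <- fake_scan(200, seed = 10)
  # two categories with >= 2 PSRs each, far apart so they never merge
  wNF <- c(10L, 50L, 90L, 130L)
  wUD <- c(30L, 70L, 110L, 150L)
  sets <- list(fst_top = c(wNF, wUD), pi_A = wNF, pi_B = integer(0),
               rsb_A = wUD, rsb_B = integer(0))
  res <- classify_psrs(sets, scan)
  s <- psr_summaries(res, scan, c(chr1 = 200 * 5000 + 20000))
  expect_true(all(c("counts", "ks", "anova") %in% names(s)))
  # with only two classes the LSD decision equals a pooled two-sample t-test
  vals_by_cat <- split(seq_len(nrow(res$psrs)), paste(res$psrs$stock,
                                                      res$psrs$class, sep = "-"))
  per_psr_css <- vapply(seq_len(nrow(res$psrs)), function(i) {
    w <- scan$chrom == res$psrs$chrom[i] & scan$start < res$psrs$end[i] &
      scan$end > res$psrs$start[i]
    mean(scan$css[w], na.rm = TRUE)
  }, numeric(1))
  tt <- t.test(per_psr_css[vals_by_cat[[1]]], per_psr_css[vals_by_cat[[2]]],
               var.equal = TRUE)
  expect_equal(s$anova$css$lsd$p[1], tt$p.value, tolerance = 1e-10)
  # equally spaced midpoints: KS statistic attains its lower bound 1/(2m)
  m <- 10
  u <- (seq_len(m) - 0.5) / m
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  expect_equal(unname(ks$statistic), 1 / (2 * m), tolerance = 1e-12)
  expect_gt(ks$p.value, 0.99)
})

test_that("gene overlap produces PSGs with interval-exact overlap lengths", {
  scan <- fake_scan(100, seed = 11)
  sets <- list(fst_top = c(10L, 11L, 30L), pi_A = c(10L, 11L),
               pi_B = integer(0), rsb_A = 30L, rsb_B = integer(0))
  res <- classify_psrs(sets, scan)
  nf <- res$psrs[res$psrs$class == "NF", ]   # one NF PSR windows 10-11
  ud <- res$psrs[res$psrs$class == "UD", ]
  genes <- data.frame(
    chrom = "chr1",
    start = c(nf$start + 1000, ud$end + 60000, nf$end - 2000),
    end = c(nf$start + 3000, ud$end + 70000, nf$end + 5000),
    gene_id = c("inside", "outside", "spanning"))
  ov <- overlap_genes(res, genes)
  expect_true("inside" %in% ov$psgs$gene_id)
  expect_false("outside" %in% ov$psgs$gene_id)
  ins <- ov$psgs[ov$psgs$gene_id == "inside", ]
  expect_equal(ins$overlap_bp, 3000 - 1000 + 1)   # fully inside
  sp <- ov$psgs[ov$psgs$gene_id == "spanning", ]
  expect_equal(sp$overlap_bp,
               oracle_overlap_len(nf$end - 2000, nf$end + 5000,
                                  nf$start + 1, nf$end))
  expect_warning(overlap_genes(res, data.frame(chrom = "chrX", start = 1,
                                               end = 10, gene_id = "g"),
                               chroms = "chr1"),
                 "skipped")
  # a gene on a scan chromosome without PSRs is simply absent, not "unknown"
  ov2 <- suppressWarnings(
    overlap_genes(res, data.frame(chrom = "chr2", start = 1, end = 10,
                                  gene_id = "g2"),
                  chroms = c("chr1", "chr2")))
  expect_equal(nrow(ov2$psgs), 0)
})

test_that("planted sweeps are recovered in the expected outlier sets", {
  hits <- vapply(1:6, function(s) {
    cfg <- sim_config(seed = s, stock_of_site = c(S1 = "A", S2 = "B"),
                      n_diploids_per_site = 15,
                      chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
                      n_snps_per_chrom = 2000, divergence = 0.05,
                      sweep_specs = list(sweep_spec("A", "chr1", 1e6, 1.0,
                                                    75000, "NF")))
    panel <- simulate_panel(cfg)$panel
    scan <- scan_windows(panel, c("A", "B"))
    sets <- call_outlier_sets(scan)
    tract <- scan$window[scan$chrom == "chr1" & scan$start < 1e6 + 75000 &
                           scan$end > 1e6 - 75000]
    mean(tract %in% sets$fst_top & tract %in% sets$pi_A) > 0.5
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
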