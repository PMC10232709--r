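# Brute-force / closed-form oracles, deliberately written in a different
# style (scalar loops, direct enumeration) from the package implementations
# they check.

# tiny panel straight from a haplotype matrix (rows = haplotypes, 2 per
# sample; columns = SNPs)
panel_from_matrix <- function(h, pos, chrom_len = max(pos) + 10,
                              sites = NULL, stocks = NULL, chrom = "chr1") {
  n_hap <- nrow(h)
  stopifnot(n_hap %% 2 == 0)
  n <- n_hap / 2
  samples <- sprintf("S%02d", seq_len(n))
  rownames(h) <- paste(rep(samples, each = 2), 1:2, sep = "_")
  if (is.null(sites)) sites <- rep(c("P1", "P2"), length.out = n)
  site_of_sample <- stats::setNames(sites, samples)
  if (is.null(stocks)) {
    us <- unique(sites)
    stocks <- stats::setNames(rep(c("A", "B"), length.out = length(us)), us)
  }
  cl <- stats::setNames(chrom_len, chrom)
  haplotype_panel(cl, stats::setNames(list(as.integer(pos)), chrom),
                  stats::setNames(list(h), chrom), site_of_sample, stocks)
}

random_tiny_panel <- function(seed, n_hap = 8, n_snp = 10, chrom_len = 1000) {
  set.seed(seed)
  h <- matrix(rbinom(n_hap * n_snp, 1, runif(1, 0.2, 0.8)),
              nrow = n_hap)
  # ensure every SNP is polymorphic
  for (j in seq_len(n_snp)) {
    if (length(unique(h[, j])) == 1) h[1, j] <- 1L - h[1, j]
  }
  pos <- sort(sample.int(chrom_len - 10, n_snp))
  panel_from_matrix(h, pos, chrom_len)
}

# Weir & Cockerham (1984) variance components for one SNP, two populations,
# computed term by term from the published formulas
oracle_wc_single <- function(gt1, gt2) {
  # gt1, gt2: integer genotype vectors (0/1/2) per diploid
  r <- 2
  n <- c(length(gt1), length(gt2))
  p <- c(sum(gt1) / (2 * n[1]), sum(gt2) / (2 * n[2]))
  h <- c(mean(gt1 == 1), mean(gt2 == 1))
  nbar <- (n[1] + n[2]) / r
  CV2 <- 0
  for (i in 1:r) CV2 <- CV2 + n[i]^2
  nc <- (r * nbar - CV2 / (r * nbar)) / (r - 1)
  pbar <- (n[1] * p[1] + n[2] * p[2]) / (r * nbar)
  s2 <- (n[1] * (p[1] - pbar)^2 + n[2] * (p[2] - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n[1] * h[1] + n[2] * h[2]) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# genotypes of a panel population at SNP j of chrom
panel_genotypes <- function(panel, pop, chrom, j) {
  rows <- hap_rows(panel, pop)
  h <- panel$haps[[chrom]]
  i1 <- seq(1, length(rows), 2)
  h[rows[i1], j] + h[rows[i1 + 1], j]
}

# mean pairwise differences over all haplotype pairs (Tajima's pi-hat)
oracle_mean_pairwise_diff <- function(h) {
  n <- nrow(h)
  tot <- 0; np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(h[i, ] != h[j, ])
    np <- np + 1
  }
  tot / np
}

oracle_tajima_d <- function(h) {
  n <- nrow(h)
  p <- colMeans(h)
  S <- sum(p > 0 & p < 1)
  if (S == 0) return(NA_real_)
  k <- tajima_constants(n)
  pihat <- oracle_mean_pairwise_diff(h[, p > 0 & p < 1, drop = FALSE])
  (pihat - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

# EHHS by direct pair counting: fraction of haplotype pairs identical over
# every SNP of [min(core,x), max(core,x)], normalised at the core
oracle_ehhs <- function(h, core, x) {
  n <- nrow(h)
  homozygous_pairs <- function(cols) {
    cnt <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (all(h[i, cols] == h[j, cols])) cnt <- cnt + 1
    cnt / (n * (n - 1) / 2)
  }
  homozygous_pairs(min(core, x):max(core, x)) / homozygous_pairs(core)
}

# Kruskal-Wallis H with tie correction, from first principles
oracle_kruskal_h <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  N <- length(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * mean(ri)^2)) - 3 * (N + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

oracle_spearman <- function(x, y) oracle_pearson(rank(x), rank(y))

# overlap length of two 1-based inclusive intervals
oracle_overlap_len <- function(a1, a2, b1, b2) {
  max(0, min(a2, b2) - max(a1, b1) + 1)
}

# exact two-group split by full enumeration of contiguous sorted splits
oracle_two_cluster <- function(values) {
  o <- order(values); x <- values[o]; n <- length(x)
  best <- Inf; bestk <- NA
  for (k in 1:(n - 1)) {
    w <- sum((x[1:k] - mean(x[1:k]))^2) +
      sum((x[(k + 1):n] - mean(x[(k + 1):n]))^2)
    if (w < best) { best <- w; bestk <- k }
  }
  grp <- rep(2L, n); grp[1:bestk] <- 1L
  stats::setNames(grp[order(o)], names(values))
}

# all permutations of 1..p (p small)
all_perms <- function(p) {
  if (p == 1) return(list(1L))
  out <- list()
  for (perm in all_perms(p - 1))
    for (pos in 0:(p - 1))
      out[[length(out) + 1]] <- append(perm, p, after = pos)
  out
}

# general dominance as the literal average over all p! orderings of the
# incremental R^2 when each predictor enters
oracle_general_dominance <- function(y, X) {
  X <- as.matrix(X); p <- ncol(X)
  r2 <- function(S) {
    if (!length(S)) return(0)
    summary(stats::lm(y ~ X[, S, drop = FALSE]))$r.squared
  }
  acc <- numeric(p)
  perms <- all_perms(p)
  for (perm in perms) {
    sofar <- integer(0)
    for (j in perm) {
      acc[j] <- acc[j] + r2(c(sofar, j)) - r2(sofar)
      sofar <- c(sofar, j)
    }
  }
  acc / length(perms)
}
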