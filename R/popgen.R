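#' Sliding genomic windows
#'
#' Builds the 25 kb / 5 kb sliding-window grid used throughout the package.
#' Windows are 0-based half-open internally; the last window on a chromosome
#' is the last start strictly below the chromosome length, and trailing
#' windows are truncated at the chromosome end and flagged.
#'
#' @param chrom_lengths named numeric vector (bp).
#' @param size window size in bp.
#' @param step distance between consecutive starts in bp.
#' @return data.frame with chrom, start, end (0-based half-open), window id
#'   and `truncated` flag.
#' @export
make_windows <- function(chrom_lengths, size = 25000, step = 5000) {
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (step <= 0 || size < step) stop("need size >= step > 0")
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0, L - 1, by = step)
    data.frame(chrom = ch, start = starts, end = pmin(starts + size, L))
  })
  res <- do.call(rbind, out)
  res$window <- seq_len(nrow(res))
  res$truncated <- (res$end - res$start) < size
  res
}

# per-SNP column indices falling in a 0-based half-open window
.win_cols <- function(pos, start, end) {
  # pos is 1-based: snp at bp p occupies [p-1, p) in 0-based space
  which(pos > start & pos <= end)
}

# Weir & Cockerham (1984) per-SNP variance components a, b, c for r
# populations, from allele frequencies, heterozygote proportions and diploid
# counts. Returns a 3-column matrix (one row per SNP).
.wc_components <- function(p_mat, h_mat, n_vec) {
  r <- length(n_vec)
  nbar <- mean(n_vec)
  nc <- (r * nbar - sum(n_vec^2) / (r * nbar)) / (r - 1)
  w <- n_vec / (r * nbar)
  pbar <- as.vector(p_mat %*% w)
  s2 <- as.vector(((p_mat - pbar)^2) %*% n_vec) / ((r - 1) * nbar)
  hbar <- as.vector(h_mat %*% w)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  c <- hbar / 2
  cbind(a = a, b = b, c = c)
}

# frequencies / heterozygote proportions per SNP for a set of haplotype rows
.freq_het <- function(hmat, rows, cols) {
  sub <- hmat[rows, cols, drop = FALSE]
  n_dip <- length(rows) / 2
  i1 <- seq(1, length(rows), 2)
  p <- colMeans(sub)
  het <- colMeans(sub[i1, , drop = FALSE] != sub[i1 + 1, , drop = FALSE])
  list(p = p, het = het, n = n_dip)
}

#' Windowed Weir-Cockerham Fst
#'
#' The weighted (ratio-of-sums) windowed estimator: the per-SNP
#' Weir-Cockerham (1984) variance components a, b, c are summed over the
#' SNPs of a window and Fst = sum(a) / sum(a + b + c). Slightly negative
#' values are possible and retained. Windows without a polymorphic SNP get
#' `NA`.
#'
#' @param panel a [haplotype_panel()].
#' @param pops list of two character vectors of sample ids (or use
#'   `stocks =` to select by stock label).
#' @param windows window table from [make_windows()]; defaults to the full
#'   grid on the panel's chromosomes.
#' @param stocks optional length-2 character vector of stock labels.
#' @param per_snp if TRUE, return per-SNP components instead of window values.
#' @return `windows` with columns `n_snps` and `fst` appended (or a per-SNP
#'   list when `per_snp`).
#' @export
weir_cockerham_fst <- function(panel, pops = NULL, windows = NULL,
                               stocks = NULL, per_snp = FALSE) {
  if (is.null(pops)) {
    stopifnot(length(stocks) == 2)
    pops <- lapply(stocks, function(s) {
      sos <- stock_of_sample(panel)
      names(sos)[sos == s]
    })
  }
  stopifnot(length(pops) == 2, all(lengths(pops) >= 2))
  rows <- lapply(pops, function(s) hap_rows(panel, s))
  if (is.null(windows)) windows <- make_windows(panel$chrom_lengths)
  comp <- list()
  for (ch in names(panel$chrom_lengths)) {
    h <- panel$haps[[ch]]
    S <- ncol(h)
    if (!S) { comp[[ch]] <- cbind(a = numeric(0), b = numeric(0), c = numeric(0)); next }
    f1 <- .freq_het(h, rows[[1]], seq_len(S))
    f2 <- .freq_het(h, rows[[2]], seq_len(S))
    cc <- .wc_components(cbind(f1$p, f2$p), cbind(f1$het, f2$het),
                         c(f1$n, f2$n))
    poly <- (f1$p + f2$p) > 0 & (f1$p + f2$p) < 2
    cc[!poly, ] <- NA_real_
    comp[[ch]] <- cc
  }
  if (per_snp) return(comp)
  windows$n_snps <- NA_integer_
  windows$fst <- NA_real_
  for (i in seq_len(nrow(windows))) {
    ch <- windows$chrom[i]
    cols <- .win_cols(panel$pos[[ch]], windows$start[i], windows$end[i])
    cc <- comp[[ch]][cols, , drop = FALSE]
    cc <- cc[!is.na(cc[, 1]), , drop = FALSE]
    windows$n_snps[i] <- nrow(cc)
    if (nrow(cc)) {
      den <- sum(cc)
      windows$fst[i] <- if (den != 0) sum(cc[, 1]) / den else NA_real_
    }
  }
  windows
}

#' Windowed nucleotide diversity
#'
#' Per-bp nucleotide diversity of one population over each window: the sum
#' over SNPs of the unbiased per-site heterozygosity `2p(1-p) n/(n-1)` (n =
#' haplotype count), divided by the window span in bp. Empty windows give 0.
#'
#' @inheritParams weir_cockerham_fst
#' @param pop character vector of sample ids, or a stock label via `stock =`.
#' @param stock optional stock label.
#' @return numeric vector of per-bp pi, one value per window row.
#' @export
windowed_pi <- function(panel, pop = NULL, windows = NULL, stock = NULL) {
  if (is.null(pop)) {
    sos <- stock_of_sample(panel)
    pop <- names(sos)[sos %in% stock]
  }
  rows <- hap_rows(panel, pop)
  n <- length(rows)
  if (is.null(windows)) windows <- make_windows(panel$chrom_lengths)
  persite <- lapply(panel$haps, function(h) {
    p <- colMeans(h[rows, , drop = FALSE])
    2 * p * (1 - p) * n / (n - 1)
  })
  vapply(seq_len(nrow(windows)), function(i) {
    ch <- windows$chrom[i]
    cols <- .win_cols(panel$pos[[ch]], windows$start[i], windows$end[i])
    sum(persite[[ch]][cols]) / (windows$end[i] - windows$start[i])
  }, numeric(1))
}

#' Windowed Tajima's D
#'
#' Computed from the classical constants (a1, a2, b1, b2, c1, c2, e1, e2):
#' D = (pi_hat - S/a1) / sqrt(e1 S + e2 S (S-1)), where pi_hat is the mean
#' number of pairwise differences among haplotypes over the window's
#' segregating sites. Windows with no segregating site give `NA`.
#'
#' @inheritParams windowed_pi
#' @return numeric vector of D, one per window row.
#' @export
tajimas_d <- function(panel, pop = NULL, windows = NULL, stock = NULL) {
  if (is.null(pop)) {
    sos <- stock_of_sample(panel)
    pop <- names(sos)[sos %in% stock]
  }
  rows <- hap_rows(panel, pop)
  n <- length(rows)
  if (n < 3) stop("Tajima's D needs at least 3 haplotypes")
  k <- tajima_constants(n)
  if (is.null(windows)) windows <- make_windows(panel$chrom_lengths)
  persite <- lapply(panel$haps, function(h) {
    p <- colMeans(h[rows, , drop = FALSE])
    list(pi = 2 * p * (1 - p) * n / (n - 1), seg = p > 0 & p < 1)
  })
  vapply(seq_len(nrow(windows)), function(i) {
    ch <- windows$chrom[i]
    cols <- .win_cols(panel$pos[[ch]], windows$start[i], windows$end[i])
    S <- sum(persite[[ch]]$seg[cols])
    if (S == 0) return(NA_real_)
    pihat <- sum(persite[[ch]]$pi[cols])
    (pihat - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  }, numeric(1))
}

#' Tajima (1989) constants for n haplotypes
#' @param n number of haplotypes (>= 3).
#' @return list with a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Site-EHH profile around a core SNP
#'
#' EHHS at a flanking SNP x is H(core..x) / H(core), where H over an
#' interval is the probability that two random haplotypes are identical at
#' every SNP of the interval, estimated without replacement as
#' sum_k n_k (n_k - 1) / (n (n - 1)) over haplotype classes k. The profile
#' is extended left and right until EHHS drops below `cutoff` (the first
#' sub-cutoff SNP is not retained) or the chromosome ends.
#'
#' @param panel a [haplotype_panel()].
#' @param pop sample ids (or `stock =`).
#' @param chrom chromosome id.
#' @param core_snp index of the core SNP on that chromosome.
#' @param cutoff truncation threshold (default 0.05).
#' @param stock optional stock label.
#' @return data.frame with snp index, pos and ehhs, ordered by position and
#'   containing the core (ehhs = 1).
#' @export
ehhs_profile <- function(panel, pop = NULL, chrom, core_snp, cutoff = 0.05,
                         stock = NULL) {
  if (is.null(pop)) {
    sos <- stock_of_sample(panel)
    pop <- names(sos)[sos %in% stock]
  }
  rows <- hap_rows(panel, pop)
  h <- panel$haps[[chrom]][rows, , drop = FALSE]
  S <- ncol(h)
  if (core_snp < 1 || core_snp > S) stop("core_snp out of range")
  n <- nrow(h)
  hom <- function(cls) {
    nk <- tabulate(cls)
    sum(nk * (nk - 1)) / (n * (n - 1))
  }
  h0 <- hom(h[, core_snp] + 1L)
  if (h0 == 0) h0 <- NA_real_   # all classes singletons at the core itself
  walk <- function(dir) {
    cls <- match(h[, core_snp], unique(h[, core_snp]))
    out_i <- integer(0); out_e <- numeric(0)
    j <- core_snp + dir
    while (j >= 1 && j <= S) {
      key <- cls * 2L + h[, j]
      cls <- match(key, unique(key))
      e <- hom(cls) / h0
      if (is.na(e) || e < cutoff) break
      out_i <- c(out_i, j); out_e <- c(out_e, e)
      j <- j + dir
    }
    list(i = out_i, e = out_e)
  }
  lft <- walk(-1L); rgt <- walk(1L)
  idx <- c(rev(lft$i), core_snp, rgt$i)
  eh <- c(rev(lft$e), 1, rgt$e)
  data.frame(snp = idx, pos = panel$pos[[chrom]][idx], ehhs = eh)
}

#' Integrated EHHS (iES)
#'
#' Trapezoidal integral of an EHHS profile over physical position (bp).
#'
#' @param profile output of [ehhs_profile()].
#' @return iES in bp-equivalents.
#' @export
ies <- function(profile) {
  if (nrow(profile) < 2) return(0)
  x <- profile$pos; y <- profile$ehhs
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' iES at every SNP for one population
#'
#' Convenience scan computing [ehhs_profile()] + [ies()] at every SNP of
#' every chromosome.
#'
#' @inheritParams ehhs_profile
#' @return named list per chromosome of per-SNP iES vectors.
#' @export
ies_scan <- function(panel, pop = NULL, cutoff = 0.05, stock = NULL) {
  if (is.null(pop)) {
    sos <- stock_of_sample(panel)
    pop <- names(sos)[sos %in% stock]
  }
  out <- list()
  for (ch in names(panel$chrom_lengths)) {
    S <- ncol(panel$haps[[ch]])
    out[[ch]] <- vapply(seq_len(S), function(j)
      ies(ehhs_profile(panel, pop, ch, j, cutoff)), numeric(1))
  }
  out
}

#' Windowed standardized Rsb between two populations
#'
#' Per SNP, Rsb = ln(iES_A / iES_B); SNPs with zero iES in either population
#' are skipped. The per-SNP values are standardized genome-wide robustly as
#' (x - median) / (IQR / 1.349) and averaged within each window. Positive
#' values indicate longer haplotype homozygosity (recent selection) in
#' population A.
#'
#' @param panel a [haplotype_panel()].
#' @param popA,popB sample-id vectors (or `stocks =` with two stock labels).
#' @param windows window table from [make_windows()].
#' @param stocks optional length-2 stock labels.
#' @param ies_A,ies_B optional precomputed [ies_scan()] results.
#' @return list with `window_rsb` (per window row), `snp_rsb` (per-chrom
#'   standardized per-SNP values).
#' @export
rsb <- function(panel, popA = NULL, popB = NULL, windows = NULL,
                stocks = NULL, ies_A = NULL, ies_B = NULL) {
  if (is.null(popA)) {
    stopifnot(length(stocks) == 2)
    sos <- stock_of_sample(panel)
    popA <- names(sos)[sos == stocks[1]]
    popB <- names(sos)[sos == stocks[2]]
  }
  if (is.null(ies_A)) ies_A <- ies_scan(panel, popA)
  if (is.null(ies_B)) ies_B <- ies_scan(panel, popB)
  raw <- lapply(names(ies_A), function(ch) {
    a <- ies_A[[ch]]; b <- ies_B[[ch]]
    r <- rep(NA_real_, length(a))
    ok <- a > 0 & b > 0
    r[ok] <- log(a[ok] / b[ok])
    r
  })
  names(raw) <- names(ies_A)
  all_r <- unlist(raw, use.names = FALSE)
  med <- stats::median(all_r, na.rm = TRUE)
  iqr <- stats::IQR(all_r, na.rm = TRUE)
  scl <- if (iqr > 0) iqr / 1.349 else 1
  std <- lapply(raw, function(r) (r - med) / scl)
  if (is.null(windows)) windows <- make_windows(panel$chrom_lengths)
  wr <- vapply(seq_len(nrow(windows)), function(i) {
    ch <- windows$chrom[i]
    cols <- .win_cols(panel$pos[[ch]], windows$start[i], windows$end[i])
    v <- std[[ch]][cols]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  list(window_rsb = wr, snp_rsb = std)
}

#' Per-site diversity summary
#'
#' Observed heterozygosity H_O, expected heterozygosity H_E (unbiased,
#' Nei 1978), method-of-moments inbreeding coefficient F = 1 - H_O / H_E and
#' mean per-bp nucleotide diversity pi, per sampling site. H_O / H_E are
#' averaged over polymorphic-in-the-panel SNPs.
#'
#' @param panel a [haplotype_panel()].
#' @return data.frame with site, n, ho, he, f, pi.
#' @export
diversity_summary <- function(panel) {
  sites <- sort(unique(panel$site_of_sample))
  genome <- sum(panel$chrom_lengths)
  res <- lapply(sites, function(s) {
    rows <- hap_rows(panel, site = s)
    n <- length(rows)
    ho_num <- 0; he_num <- 0; nsnp <- 0; pisum <- 0
    for (ch in names(panel$chrom_lengths)) {
      h <- panel$haps[[ch]]
      pall <- colMeans(h)
      poly <- pall > 0 & pall < 1
      f <- .freq_het(h, rows, which(poly))
      ho_num <- ho_num + sum(f$het)
      he_num <- he_num + sum(2 * f$p * (1 - f$p) * n / (n - 1))
      nsnp <- nsnp + sum(poly)
      pisum <- pisum + sum(2 * f$p * (1 - f$p) * n / (n - 1))
    }
    ho <- ho_num / nsnp
    he <- he_num / nsnp
    data.frame(site = s, n = n / 2, ho = ho, he = he,
               f = if (he > 0) 1 - ho / he else NA_real_,
               pi = pisum / genome)
  })
  do.call(rbind, res)
}

#' Exact two-group 1-D partition plus one-way ANOVA
#'
#' Partitions a vector of per-site values into two groups by minimising the
#' within-group sum of squares over every split point of the sorted values
#' (the exact 1-D two-cluster solution), then tests the difference between
#' the groups with a one-way ANOVA.
#'
#' @param values named numeric vector (one value per site).
#' @return list with `groups` (named membership, 1 = lower group), `split`
#'   (index of last member of the lower group in sort order), `f`, `p`.
#' @export
partition_and_test <- function(values) {
  stopifnot(length(values) >= 3)
  if (length(unique(values)) == 1)
    return(list(groups = NULL, split = NA, f = NA_real_, p = NA_real_,
                degenerate = TRUE))
  o <- order(values)
  x <- values[o]
  n <- length(x)
  wss <- vapply(seq_len(n - 1), function(k) {
    sum((x[1:k] - mean(x[1:k]))^2) + sum((x[(k + 1):n] - mean(x[(k + 1):n]))^2)
  }, numeric(1))
  k <- which.min(wss)
  groups <- stats::setNames(rep(2L, n), names(values))
  groups[names(x)[1:k]] <- 1L
  fit <- stats::aov(values ~ factor(groups[names(values)]))
  s <- summary(fit)[[1]]
  list(groups = groups, split = k, f = s$`F value`[1], p = s$`Pr(>F)`[1],
       degenerate = FALSE)
}

#' Genome-wide pairwise Fst between sites (or stocks)
#'
#' Weighted Weir-Cockerham estimate over all SNPs for every pair of groups.
#'
#' @param panel a [haplotype_panel()].
#' @param by group samples by `"site"` (default) or `"stock"`.
#' @return symmetric matrix of pairwise Fst.
#' @export
pairwise_fst <- function(panel, by = c("site", "stock")) {
  by <- match.arg(by)
  grp <- if (by == "site") panel$site_of_sample else stock_of_sample(panel)
  levs <- sort(unique(grp))
  rows <- lapply(levs, function(g) hap_rows(panel, names(grp)[grp == g]))
  names(rows) <- levs
  out <- matrix(NA_real_, length(levs), length(levs),
                dimnames = list(levs, levs))
  diag(out) <- 0
  for (i in seq_along(levs)[-length(levs)]) {
    for (j in (i + 1):length(levs)) {
      num <- 0; den <- 0
      for (ch in names(panel$chrom_lengths)) {
        h <- panel$haps[[ch]]
        if (!ncol(h)) next
        f1 <- .freq_het(h, rows[[i]], seq_len(ncol(h)))
        f2 <- .freq_het(h, rows[[j]], seq_len(ncol(h)))
        poly <- (f1$p + f2$p) > 0 & (f1$p + f2$p) < 2
        cc <- .wc_components(cbind(f1$p, f2$p)[poly, , drop = FALSE],
                             cbind(f1$het, f2$het)[poly, , drop = FALSE],
                             c(f1$n, f2$n))
        num <- num + sum(cc[, 1])
        den <- den + sum(cc)
      }
      out[i, j] <- out[j, i] <- if (den != 0) num / den else NA_real_
    }
  }
  out
}
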