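#' Empty shared-segment table
#'
#' Canonical layout for shared-haplotype (identity-by-descent) segments:
#' sample1, hap1 (1 or 2), sample2, hap2, chrom, start, end (bp, 1-based
#' inclusive), score (LOD-like, optional). A `donor` column may be present
#' in truth tables from [plant_introgression()].
#'
#' @return zero-row data.frame in segment layout.
#' @export
empty_segment_table <- function() {
  data.frame(sample1 = character(0), hap1 = integer(0),
             sample2 = character(0), hap2 = integer(0),
             chrom = character(0), start = numeric(0), end = numeric(0),
             score = numeric(0), donor = character(0))
}

#' Read a shared-segment TSV
#'
#' Accepts the common IBD-detector output layout (columns sample1, hap1,
#' sample2, hap2, chrom, start, end, score), with or without a header.
#'
#' @param path TSV path.
#' @return segment data.frame.
#' @export
read_segments <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("sample", first)
  df <- utils::read.table(path, header = has_header, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!has_header)
    names(df)[1:8] <- c("sample1", "hap1", "sample2", "hap2", "chrom",
                        "start", "end", "score")
  df
}

#' Filter out within-site segments
#'
#' Shared haplotypes between individuals sampled from the same site carry no
#' cross-site information and are removed before any SHF computation.
#'
#' @param segments segment data.frame.
#' @param site_of_sample named character vector sample -> site.
#' @return the cross-site subset of `segments`.
#' @export
filter_segments <- function(segments, site_of_sample) {
  if (!nrow(segments)) return(segments)
  un <- setdiff(unique(c(segments$sample1, segments$sample2)),
                names(site_of_sample))
  if (length(un))
    stop("segments mention unmapped samples: ", paste(un, collapse = ", "))
  keep <- site_of_sample[segments$sample1] != site_of_sample[segments$sample2]
  segments[keep, , drop = FALSE]
}

#' Detect exactly shared haplotype segments in a panel
#'
#' Naive shared-haplotype detector used on synthetic panels (external IBD
#' detector output is accepted through [read_segments()] for real data):
#' reports every maximal interval over which two haplotypes are identical at
#' every SNP, when its physical span (first to last matching SNP) reaches
#' `min_len`. Segment coordinates are the outermost matching SNP positions.
#'
#' @param panel a [haplotype_panel()].
#' @param min_len minimum physical span in bp.
#' @param cross_site_only skip same-site haplotype pairs (default TRUE;
#'   they would be filtered later anyway).
#' @return segment data.frame.
#' @export
detect_shared_segments <- function(panel, min_len, cross_site_only = TRUE) {
  hapnames <- rownames(panel$haps[[1]])
  nh <- length(hapnames)
  samp <- sub("_[12]$", "", hapnames)
  hapno <- as.integer(sub("^.*_", "", hapnames))
  site <- panel$site_of_sample[samp]
  out <- vector("list", 1000); oi <- 0
  add <- function(df) {
    oi <<- oi + 1
    if (oi > length(out)) length(out) <<- 2 * oi
    out[[oi]] <<- df
  }
  for (ch in names(panel$chrom_lengths)) {
    h <- panel$haps[[ch]]
    p <- panel$pos[[ch]]
    if (!ncol(h)) next
    for (i in seq_len(nh - 1)) {
      hi <- h[i, ]
      for (j in (i + 1):nh) {
        if (samp[i] == samp[j]) next
        if (cross_site_only && site[i] == site[j]) next
        eq <- hi == h[j, ]
        r <- rle(eq)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        k <- which(r$values)
        if (!length(k)) next
        span <- p[ends[k]] - p[starts[k]]
        k <- k[span >= min_len]
        if (!length(k)) next
        add(data.frame(sample1 = samp[i], hap1 = hapno[i],
                       sample2 = samp[j], hap2 = hapno[j],
                       chrom = ch, start = p[starts[k]], end = p[ends[k]],
                       score = NA_real_))
      }
    }
  }
  if (!oi) return(empty_segment_table()[, 1:8])
  res <- do.call(rbind, out[seq_len(oi)])
  rownames(res) <- NULL
  res
}

#' Per-window shared-haplotype frequencies (SHF table)
#'
#' For each window of the 25 kb / 5 kb grid and each of the two stocks:
#' cSHF counts the individual pairs from *different sites of that stock*
#' sharing a haplotype segment whose overlap with the window exceeds
#' `min_overlap` bp (at most one event per individual pair per window);
#' tSHF is the total number of cross-site individual pairs of the stock; and
#' nSHF = cSHF / tSHF, ranging from 0 (no sharing) to 1 (every pair shares).
#' The focal-pair flag marks windows overlapped (by more than `min_overlap`)
#' by a segment shared between the two boundary sites `focal_pair`.
#'
#' rSHF = log2(nSHF_A / nSHF_B) is attached where both nSHF are positive;
#' windows with sharing on only one side are censored (rSHF `NA`,
#' `censored` flag set).
#'
#' @param segments cross-site segment table (see [filter_segments()]).
#' @param windows window grid from [make_windows()].
#' @param site_of_sample,stock_of_site sample and site maps.
#' @param stocks length-2 character vector (A, B) of stock labels.
#' @param focal_pair length-2 character vector (site in A, site in B).
#' @param min_overlap minimum window overlap in bp (default 10000,
#'   exclusive: overlap must be strictly greater).
#' @param include_focal_sites should segments involving the focal boundary
#'   sites count towards their own stock's cSHF/tSHF? Default FALSE: the
#'   boundary sites are the tested signal, not the background. Set TRUE for
#'   designs with too few sites per stock to leave them out.
#' @return `windows` with cshf/tshf/nshf per stock, `focal` flag, `rshf`
#'   and `censored` columns appended.
#' @export
window_shf <- function(segments, windows, site_of_sample, stock_of_site,
                       stocks, focal_pair, min_overlap = 10000,
                       include_focal_sites = FALSE) {
  stopifnot(length(stocks) == 2, length(focal_pair) == 2)
  site1 <- segments$sample1; site1 <- site_of_sample[site1]
  site2 <- segments$sample2; site2 <- site_of_sample[site2]
  if (anyNA(site1) || anyNA(site2)) stop("unmapped samples in segments")
  st1 <- stock_of_site[site1]; st2 <- stock_of_site[site2]

  n_per_site <- table(site_of_sample)
  tshf <- numeric(2)
  for (d in 1:2) {
    ss <- names(stock_of_site)[stock_of_site == stocks[d]]
    ss <- ss[ss %in% names(n_per_site)]
    if (!include_focal_sites) ss <- setdiff(ss, focal_pair)
    tshf[d] <- if (length(ss) >= 2) {
      pr <- utils::combn(ss, 2)
      sum(apply(pr, 2, function(x) n_per_site[[x[1]]] * n_per_site[[x[2]]]))
    } else 0
  }
  if (any(tshf == 0))
    warning("stock with fewer than two usable sites: tSHF = 0, all nSHF NA")

  # which windows does a segment overlap by > min_overlap?
  seg_windows <- function(idx) {
    if (!length(idx)) return(data.frame(pair = character(0), window = integer(0)))
    res <- lapply(idx, function(i) {
      w <- windows$chrom == segments$chrom[i]
      ov <- pmin(segments$end[i], windows$end[w]) -
        pmax(segments$start[i] - 1, windows$start[w])
      win <- windows$window[w][ov > min_overlap]
      if (!length(win)) return(NULL)
      data.frame(pair = paste(segments$sample1[i], segments$sample2[i]),
                 window = win)
    })
    out <- do.call(rbind, res)
    if (is.null(out)) data.frame(pair = character(0), window = integer(0))
    else out
  }
  nwin <- nrow(windows)
  for (d in 1:2) {
    within <- st1 == stocks[d] & st2 == stocks[d] & site1 != site2
    if (!include_focal_sites)
      within <- within & !(site1 %in% focal_pair) & !(site2 %in% focal_pair)
    pw <- seg_windows(which(within))
    pw <- unique(pw)                      # <= one event per pair per window
    cshf <- tabulate(pw$window, nbins = nwin)
    windows[[paste0("cshf_", stocks[d])]] <- cshf
    windows[[paste0("tshf_", stocks[d])]] <- tshf[d]
    windows[[paste0("nshf_", stocks[d])]] <-
      if (tshf[d] > 0) cshf / tshf[d] else NA_real_
  }
  focal <- (site1 == focal_pair[1] & site2 == focal_pair[2]) |
    (site1 == focal_pair[2] & site2 == focal_pair[1])
  fw <- seg_windows(which(focal))
  windows$focal <- windows$window %in% fw$window
  na <- windows[[paste0("nshf_", stocks[1])]]
  nb <- windows[[paste0("nshf_", stocks[2])]]
  windows$rshf <- rshf(na, nb)
  windows$censored <- !is.na(na) & !is.na(nb) & xor(na == 0, nb == 0)
  attr(windows, "stocks") <- stocks
  windows
}

#' Relative shared-haplotype frequency
#'
#' rSHF = log2(nSHF_A / nSHF_B); defined only where both inputs are
#' positive (windows with sharing on one side only are censored, not
#' assigned an infinite value).
#'
#' @param nshf_A,nshf_B normalized shared-haplotype frequencies.
#' @return numeric vector (NA where undefined).
#' @export
rshf <- function(nshf_A, nshf_B) {
  out <- rep(NA_real_, length(nshf_A))
  ok <- !is.na(nshf_A) & !is.na(nshf_B) & nshf_A > 0 & nshf_B > 0
  out[ok] <- log2(nshf_A[ok] / nshf_B[ok])
  out
}

#' Classify rSHF values into introgression direction
#'
#' @param value rSHF values.
#' @param threshold asymmetry threshold on |rSHF| (default 2.5).
#' @return factor with levels `A-origin`, `symmetric`, `B-origin` (NA where
#'   rSHF is undefined).
#' @export
classify_rshf <- function(value, threshold = 2.5) {
  out <- rep(NA_character_, length(value))
  out[!is.na(value) & value > threshold] <- "A-origin"
  out[!is.na(value) & value < -threshold] <- "B-origin"
  out[!is.na(value) & abs(value) <= threshold] <- "symmetric"
  factor(out, levels = c("A-origin", "symmetric", "B-origin"))
}

#' Alexander-Govern approximation test
#'
#' Heteroscedastic one-way test on group means: each group's t-like
#' statistic t = (m - mu_hat) / se (mu_hat the inverse-variance weighted
#' grand mean) is carried through the normalising transformation
#' z = c + (c^3 + 3c)/b - (4c^7 + 33c^5 + 240c^3 + 855c) /
#' (10b^2 + 8bc^4 + 1000b), with a = df - 0.5, b = 48a^2,
#' c = sqrt(a log(1 + t^2/df)); the statistic sum(z^2) is chi-squared with
#' J - 1 degrees of freedom under the null.
#'
#' @param groups list of numeric vectors (>= 2 values each).
#' @return list with statistic, df, p.value.
#' @export
alexander_govern <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  m <- vapply(groups, mean, 1)
  se <- vapply(groups, function(x) stats::sd(x) / sqrt(length(x)), 1)
  if (any(se == 0)) stop("zero within-group variance")
  w <- (1 / se^2) / sum(1 / se^2)
  mu <- sum(w * m)
  tt <- (m - mu) / se
  df <- lengths(groups) - 1
  a <- df - 0.5
  b <- 48 * a^2
  cc <- sqrt(a * log(1 + tt^2 / df))
  z <- cc + (cc^3 + 3 * cc) / b -
    (4 * cc^7 + 33 * cc^5 + 240 * cc^3 + 855 * cc) /
    (10 * b^2 + 8 * b * cc^4 + 1000 * b)
  stat <- sum(z^2)
  list(statistic = stat, df = length(groups) - 1,
       p.value = stats::pchisq(stat, length(groups) - 1, lower.tail = FALSE))
}

#' Compare per-window nSHF between the two stocks
#'
#' One parametric (one-way ANOVA) and two non-parametric (Kruskal-Wallis,
#' Alexander-Govern) tests of the difference between the two stocks'
#' per-window normalized shared-haplotype frequencies.
#'
#' @param nshf_A,nshf_B per-window nSHF vectors (NAs dropped pairwise-free).
#' @return list with `anova_p`, `kruskal_p`, `alexander_govern_p` and the
#'   two group means.
#' @export
compare_nshf <- function(nshf_A, nshf_B) {
  a <- nshf_A[!is.na(nshf_A)]; b <- nshf_B[!is.na(nshf_B)]
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 values per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(list(anova_p = NA_real_, kruskal_p = NA_real_,
                alexander_govern_p = NA_real_, mean_A = mean(a),
                mean_B = mean(b), degenerate = TRUE))
  y <- c(a, b)
  g <- factor(rep(c("A", "B"), c(length(a), length(b))))
  s <- summary(stats::aov(y ~ g))[[1]]
  kw <- stats::kruskal.test(y, g)
  ag <- tryCatch(alexander_govern(list(a, b))$p.value,
                 error = function(e) NA_real_)
  list(anova_p = s$`Pr(>F)`[1], kruskal_p = kw$p.value,
       alexander_govern_p = ag, mean_A = mean(a), mean_B = mean(b),
       degenerate = FALSE)
}

#' Correlate rSHF with selection-scan indices
#'
#' Pearson and Spearman correlations (with two-sided p-values) and a simple
#' OLS fit of rSHF against each selection index over the non-censored
#' windows shared by the two tables.
#'
#' @param shf_table output of [window_shf()].
#' @param scan output of [scan_windows()] on the same window grid.
#' @param indices scan columns to correlate against (default fst, pi_lr,
#'   rsb, css).
#' @return data.frame: index, n, pearson_r, pearson_p, spearman_rho,
#'   spearman_p, ols_slope, ols_intercept, r_squared.
#' @export
correlate_with_selection <- function(shf_table, scan,
                                     indices = c("fst", "pi_lr", "rsb", "css")) {
  m <- merge(shf_table[, c("window", "rshf")],
             scan[, c("window", indices)], by = "window")
  res <- lapply(indices, function(v) {
    ok <- !is.na(m$rshf) & !is.na(m[[v]])
    n <- sum(ok)
    if (n < 3 || stats::sd(m$rshf[ok]) == 0 || stats::sd(m[[v]][ok]) == 0)
      return(data.frame(index = v, n = n, pearson_r = NA_real_,
                        pearson_p = NA_real_, spearman_rho = NA_real_,
                        spearman_p = NA_real_, ols_slope = NA_real_,
                        ols_intercept = NA_real_, r_squared = NA_real_))
    x <- m[[v]][ok]; y <- m$rshf[ok]
    pe <- stats::cor.test(x, y, method = "pearson")
    sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    fit <- stats::lm(y ~ x)
    data.frame(index = v, n = n,
               pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
               spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
               ols_slope = unname(stats::coef(fit)[2]),
               ols_intercept = unname(stats::coef(fit)[1]),
               r_squared = summary(fit)$r.squared)
  })
  do.call(rbind, res)
}

#' Write a segment table as TSV
#' @param segments segment data.frame.
#' @param path output path.
#' @export
write_segments <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
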