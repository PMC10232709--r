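#' Log-ratio nucleotide-diversity index (Pi)
#'
#' Pi = log2(pi_B / pi_A). The orientation is fixed throughout the package:
#' large positive values mean diversity is depleted in stock A (the first,
#' high-latitude stock), i.e. evidence of selection in A. Windows where one
#' stock has zero diversity are kept in range with a half-count floor (the
#' smallest nonzero window pi across both stocks, halved) so that
#' near-fixation sweeps - the NF signal itself - are not dropped; windows
#' with zero diversity in both stocks give `NA`.
#'
#' @param pi_A,pi_B per-window per-bp diversity of stocks A and B.
#' @return numeric vector of Pi values.
#' @export
pi_log_ratio <- function(pi_A, pi_B) {
  stopifnot(length(pi_A) == length(pi_B), all(pi_A >= 0, na.rm = TRUE),
            all(pi_B >= 0, na.rm = TRUE))
  nz <- c(pi_A[pi_A > 0], pi_B[pi_B > 0])
  floor_pi <- if (length(nz)) min(nz) / 2 else NA_real_
  a <- ifelse(pi_A == 0, floor_pi, pi_A)
  b <- ifelse(pi_B == 0, floor_pi, pi_B)
  out <- log2(b / a)
  out[pi_A == 0 & pi_B == 0] <- NA_real_
  out
}

#' Composite selection score
#'
#' Rank-probit combination of the three selection indices: each index is
#' converted to fractional ranks r = rank / (n + 1) (average ranks on ties,
#' computed over non-missing windows), probit-transformed, and the three
#' z-scores are averaged per window. Being rank-based, CSS is invariant to
#' any strictly monotone transform of an input index.
#'
#' @param fst,pi,rsb equal-length per-window index vectors.
#' @return per-window CSS (NA where any input is missing).
#' @export
css <- function(fst, pi, rsb) {
  n <- length(fst)
  if (n < 2 || length(pi) != n || length(rsb) != n)
    stop("need equal-length vectors over at least 2 windows")
  zscore <- function(x) {
    ok <- !is.na(x)
    r <- rep(NA_real_, n)
    r[ok] <- rank(x[ok]) / (sum(ok) + 1)
    stats::qnorm(r)
  }
  (zscore(fst) + zscore(pi) + zscore(rsb)) / 3
}

#' Full per-window selection scan between two stocks
#'
#' Builds the scan table: per window SNP count, Weir-Cockerham Fst, per-bp
#' diversity of both stocks, the Pi log-ratio, windowed standardized Rsb,
#' Tajima's D per stock and the composite selection score. Index
#' orientation: positive Pi and positive Rsb both point at selection in
#' stock A (`stocks[1]`).
#'
#' @param panel a [haplotype_panel()].
#' @param stocks length-2 character vector (A, B) of stock labels.
#' @param size,step window grid parameters (bp).
#' @return data.frame (one row per window) with attribute `stocks`.
#' @export
scan_windows <- function(panel, stocks, size = 25000, step = 5000) {
  stopifnot(length(stocks) == 2)
  win <- make_windows(panel$chrom_lengths, size, step)
  scan <- weir_cockerham_fst(panel, stocks = stocks, windows = win)
  scan$pi_A <- windowed_pi(panel, stock = stocks[1], windows = win)
  scan$pi_B <- windowed_pi(panel, stock = stocks[2], windows = win)
  scan$pi_lr <- pi_log_ratio(scan$pi_A, scan$pi_B)
  rs <- rsb(panel, stocks = stocks, windows = win)
  scan$rsb <- rs$window_rsb
  scan$tajd_A <- tajimas_d(panel, stock = stocks[1], windows = win)
  scan$tajd_B <- tajimas_d(panel, stock = stocks[2], windows = win)
  scan$css <- css(scan$fst, scan$pi_lr, scan$rsb)
  attr(scan, "stocks") <- stocks
  scan
}

#' Outlier window sets at a percentile threshold
#'
#' The five outlier sets feeding PSR classification: the top tail of Fst,
#' and - for the signed, oriented indices Pi and Rsb - one set per
#' direction (top tail = stock A, bottom tail = stock B). A window is an
#' outlier when its value strictly exceeds the `pct`-th percentile (or falls
#' strictly below the `100 - pct`-th); with all-equal values a set is empty.
#' Truncated trailing windows are excluded from both the threshold and the
#' sets by default.
#'
#' @param scan table from [scan_windows()].
#' @param pct percentile threshold (default 95).
#' @param exclude_truncated drop truncated windows first (default TRUE).
#' @return named list of window-id vectors: `fst_top`, `pi_A`, `pi_B`,
#'   `rsb_A`, `rsb_B`, plus the thresholds used as attribute `thresholds`.
#' @export
call_outlier_sets <- function(scan, pct = 95, exclude_truncated = TRUE) {
  use <- if (exclude_truncated) !scan$truncated else rep(TRUE, nrow(scan))
  if (sum(use) < 20) stop("too few windows for percentile thresholds")
  hi <- pct / 100; lo <- 1 - hi
  q <- function(x, p) stats::quantile(x[use], p, na.rm = TRUE, names = FALSE)
  thr <- c(fst = q(scan$fst, hi),
           pi_hi = q(scan$pi_lr, hi), pi_lo = q(scan$pi_lr, lo),
           rsb_hi = q(scan$rsb, hi), rsb_lo = q(scan$rsb, lo))
  pick <- function(cond) scan$window[which(use & cond)]
  sets <- list(
    fst_top = pick(scan$fst > thr["fst"]),
    pi_A = pick(scan$pi_lr > thr["pi_hi"]),
    pi_B = pick(scan$pi_lr < thr["pi_lo"]),
    rsb_A = pick(scan$rsb > thr["rsb_hi"]),
    rsb_B = pick(scan$rsb < thr["rsb_lo"]))
  attr(sets, "thresholds") <- thr
  sets
}

#' Classify positively selected regions
#'
#' A window becomes part of a PSR when it lies in at least two outlier sets
#' with a consistent stock direction. Classes follow the evidence
#' combination: Pi + Fst = NF (nearly fixed), Pi + Rsb = RS (recently
#' selected), Fst + Rsb without Pi = UD (undetermined). Windows whose
#' directional sets disagree between the stocks are dropped and counted.
#' Adjacent or overlapping windows of the same stock and class are merged
#' into PSR intervals.
#'
#' Windows lying in all three sets carry both the NF and the RS evidence
#' combination. By default (`all_three = "split"`) they are resolved by the
#' near-fixation evidence itself: NF when the focal stock retains less than
#' `2^-nf_pi_bits` of the comparator stock's window diversity (|Pi| beyond
#' `nf_pi_bits`), RS otherwise - an incomplete sweep leaves substantially
#' more diversity standing than a completed one, so strong outlier status
#' in all three indices alone cannot separate the two. `all_three = "NF"`
#' or `"RS"` force the respective class instead.
#'
#' @param sets output of [call_outlier_sets()].
#' @param scan the scan table the sets came from.
#' @param all_three how to class windows in all three outlier sets.
#' @param nf_pi_bits diversity-depletion threshold (log2 units) for
#'   `all_three = "split"`; default 2, i.e. a four-fold depletion.
#' @return list with `windows` (window-level stock/class), `psrs` (merged
#'   intervals: chrom, start, end, stock, class, n_windows) and
#'   `n_conflicting` (dropped windows).
#' @export
classify_psrs <- function(sets, scan, all_three = c("split", "NF", "RS"),
                          nf_pi_bits = 2) {
  all_three <- match.arg(all_three)
  stocks <- attr(scan, "stocks")
  if (is.null(stocks)) stocks <- c("A", "B")
  all_w <- sort(unique(unlist(sets)))
  inset <- function(nm) all_w %in% sets[[nm]]
  fst <- inset("fst_top")
  dirA <- inset("pi_A") | inset("rsb_A")
  dirB <- inset("pi_B") | inset("rsb_B")
  conflict <- dirA & dirB
  pi_lr_w <- scan$pi_lr[match(all_w, scan$window)]
  cls <- rep(NA_character_, length(all_w))
  stk <- rep(NA_character_, length(all_w))
  for (d in 1:2) {
    pi_d <- inset(c("pi_A", "pi_B")[d])
    rsb_d <- inset(c("rsb_A", "rsb_B")[d])
    this <- !conflict & (if (d == 1) dirA else dirB)
    triple <- this & pi_d & rsb_d & fst
    nf <- this & pi_d & fst & !triple
    rs <- this & pi_d & rsb_d & !fst
    ud <- this & !pi_d & rsb_d & fst
    cls[nf] <- "NF"; cls[rs] <- "RS"; cls[ud] <- "UD"
    if (any(triple)) {
      if (all_three == "split") {
        depleted <- !is.na(pi_lr_w) & abs(pi_lr_w) > nf_pi_bits
        cls[triple & depleted] <- "NF"
        cls[triple & !depleted] <- "RS"
      } else cls[triple] <- all_three
    }
    stk[nf | rs | ud | triple] <- stocks[d]
  }
  keep <- !is.na(cls)
  wtab <- data.frame(window = all_w[keep], stock = stk[keep],
                     class = cls[keep])
  wtab <- merge(wtab, scan[, c("window", "chrom", "start", "end")],
                by = "window", sort = TRUE)
  psrs <- if (nrow(wtab)) {
    parts <- split(wtab, paste(wtab$stock, wtab$class, sep = "."))
    do.call(rbind, lapply(parts, function(df) {
      gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
        df$chrom, IRanges::IRanges(df$start + 1, df$end)))
      data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1,
                 end = GenomicRanges::end(gr),
                 stock = df$stock[1], class = df$class[1],
                 n_windows = GenomicRanges::countOverlaps(
                   gr, GenomicRanges::GRanges(df$chrom,
                     IRanges::IRanges(df$start + 1, df$end))))
    }))
  } else {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               stock = character(0), class = character(0),
               n_windows = integer(0))
  }
  rownames(psrs) <- NULL
  list(windows = wtab, psrs = psrs, n_conflicting = sum(conflict))
}

#' Comparative summaries of PSR classes
#'
#' Per stock-by-class category: PSR counts and merged lengths; a
#' Kolmogorov-Smirnov test of the uniformity of PSR midpoints along the
#' cumulative genome coordinate; and a one-way ANOVA across categories of
#' the per-PSR mean composite selection score and mean Tajima's D (of the
#' PSR's own stock), followed by pairwise least-significant-difference
#' t-tests using the pooled ANOVA mean square. Categories with fewer than
#' two PSRs are excluded from the comparisons and reported.
#'
#' @param psr result of [classify_psrs()].
#' @param scan the scan table.
#' @param chrom_lengths named chromosome lengths (bp).
#' @param alpha LSD significance level (default 0.05).
#' @return list with `counts`, `ks` (per category: statistic, p), `anova`
#'   (per index: F, p, and the LSD pairwise table), `excluded`.
#' @export
psr_summaries <- function(psr, scan, chrom_lengths, alpha = 0.05) {
  psrs <- psr$psrs
  if (!nrow(psrs)) stop("no PSRs to summarise")
  psrs$category <- paste(psrs$stock, psrs$class, sep = "-")
  counts <- do.call(rbind, lapply(split(psrs, psrs$category), function(df)
    data.frame(category = df$category[1], n = nrow(df),
               total_bp = sum(df$end - df$start))))
  rownames(counts) <- NULL
  offs <- cumsum(c(0, unname(chrom_lengths)))
  names(offs) <- c(names(chrom_lengths), ".total")
  total <- sum(chrom_lengths)
  mids <- (offs[psrs$chrom] + (psrs$start + psrs$end) / 2) / total
  ks <- do.call(rbind, lapply(split(seq_len(nrow(psrs)), psrs$category),
    function(i) {
      if (length(i) < 2) return(NULL)
      kt <- suppressWarnings(stats::ks.test(mids[i], "punif"))
      data.frame(category = psrs$category[i[1]], n = length(i),
                 statistic = unname(kt$statistic), p = kt$p.value)
    }))
  rownames(ks) <- NULL
  # per-PSR mean CSS and own-stock Tajima's D over member windows
  stocks <- attr(scan, "stocks")
  per_psr <- lapply(seq_len(nrow(psrs)), function(i) {
    w <- scan$chrom == psrs$chrom[i] & scan$start < psrs$end[i] &
      scan$end > psrs$start[i]
    tcol <- if (!is.null(stocks) && psrs$stock[i] == stocks[2]) "tajd_B"
            else "tajd_A"
    c(css = mean(scan$css[w], na.rm = TRUE),
      tajd = mean(scan[[tcol]][w], na.rm = TRUE))
  })
  vals <- do.call(rbind, per_psr)
  use_cat <- names(which(table(psrs$category) >= 2))
  excluded <- setdiff(unique(psrs$category), use_cat)
  keep <- psrs$category %in% use_cat
  anova <- NULL
  if (length(use_cat) >= 2) {
    anova <- lapply(c(css = "css", tajd = "tajd"), function(v) {
      y <- vals[keep, v]; gmm <- factor(psrs$category[keep])
      ok <- !is.na(y)
      y <- y[ok]; gmm <- droplevels(gmm[ok])
      if (nlevels(gmm) < 2) return(NULL)
      fit <- stats::aov(y ~ gmm)
      s <- summary(fit)[[1]]
      mse <- s$`Mean Sq`[2]; dfe <- s$Df[2]
      lev <- levels(gmm)
      prs <- utils::combn(lev, 2)
      lsd <- do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
        a <- prs[1, j]; b <- prs[2, j]
        na <- sum(gmm == a); nb <- sum(gmm == b)
        tstat <- (mean(y[gmm == a]) - mean(y[gmm == b])) /
          sqrt(mse * (1 / na + 1 / nb))
        pv <- 2 * stats::pt(-abs(tstat), dfe)
        data.frame(a = a, b = b, t = tstat, p = pv,
                   significant = pv < alpha)
      }))
      list(F = s$`F value`[1], p = s$`Pr(>F)`[1], lsd = lsd)
    })
  }
  list(counts = counts, ks = ks, anova = anova, excluded = excluded)
}

#' Overlap PSRs with gene annotations into PSG calls
#'
#' A gene becomes a positively selected gene (PSG) for every stock-by-class
#' category whose PSR it overlaps by at least one bp; overlap lengths are
#' computed per interval intersection. Also reports, per category, the gene
#' count, gene density and the proportion of PSR length that is genic.
#'
#' @param psr result of [classify_psrs()].
#' @param genes data.frame with chrom, start, end (1-based inclusive),
#'   gene_id; e.g. from [read_genes_gff3()] or [simulate_genes()].
#' @param chroms chromosome ids of the scan; when supplied, genes on other
#'   chromosomes are skipped with a warning (genes on scan chromosomes
#'   without PSRs simply produce no overlap).
#' @return list with `psgs` (gene_id, stock, class, overlap_bp) and
#'   `summary` per category.
#' @export
overlap_genes <- function(psr, genes, chroms = NULL) {
  psrs <- psr$psrs
  if (!is.null(chroms)) {
    bad <- !(genes$chrom %in% chroms)
    if (any(bad)) {
      warning(sum(bad), " genes on chromosomes absent from the scan skipped")
      genes <- genes[!bad, , drop = FALSE]
    }
  }
  if (!nrow(psrs) || !nrow(genes))
    return(list(psgs = data.frame(), summary = data.frame()))
  g_gr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end))
  p_gr <- GenomicRanges::GRanges(psrs$chrom,
                                 IRanges::IRanges(psrs$start + 1, psrs$end))
  ov <- GenomicRanges::findOverlaps(g_gr, p_gr)
  if (!length(ov))
    return(list(psgs = data.frame(), summary = data.frame()))
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  inter <- IRanges::pintersect(IRanges::ranges(g_gr)[qi],
                               IRanges::ranges(p_gr)[si])
  psgs <- data.frame(gene_id = genes$gene_id[qi],
                     stock = psrs$stock[si], class = psrs$class[si],
                     overlap_bp = IRanges::width(inter))
  # one record per gene x category, overlap summed over that category's PSRs
  psgs <- stats::aggregate(overlap_bp ~ gene_id + stock + class, psgs, sum)
  psrs$category <- paste(psrs$stock, psrs$class, sep = "-")
  summary <- do.call(rbind, lapply(split(seq_len(nrow(psrs)), psrs$category),
    function(i) {
      cat_len <- sum(psrs$end[i] - psrs$start[i])
      sel <- psgs$stock == psrs$stock[i[1]] & psgs$class == psrs$class[i[1]]
      # genic bp within the category's PSRs (union over genes)
      sub <- suppressWarnings(GenomicRanges::intersect(
        GenomicRanges::reduce(g_gr),
        GenomicRanges::reduce(p_gr[i])))
      data.frame(category = psrs$category[i[1]], n_genes = sum(sel),
                 psr_bp = cat_len,
                 genic_bp = sum(IRanges::width(sub)),
                 genic_fraction = sum(IRanges::width(sub)) / cat_len,
                 genes_per_mb = sum(sel) / (cat_len / 1e6))
    }))
  rownames(summary) <- NULL
  list(psgs = psgs, summary = summary)
}

#' Read gene features from a GFF3 file
#'
#' Thin wrapper over `rtracklayer::import` keeping only `gene` features (or
#' all features when none are typed `gene`).
#'
#' @param path GFF3 file.
#' @return data.frame with chrom, start, end, gene_id.
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path)
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
  ids <- if (!is.null(gr$ID)) gr$ID else sprintf("gene%04d", seq_along(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             gene_id = ids)
}

#' Write PSRs as a BED file (name = stock_class)
#' @param psr result of [classify_psrs()].
#' @param path output BED path.
#' @export
write_psr_bed <- function(psr, path) {
  df <- psr$psrs
  utils::write.table(
    data.frame(df$chrom, as.integer(df$start), as.integer(df$end),
               paste(df$stock, df$class, sep = "_")),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
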