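#' Phased haplotype panel
#'
#' The substrate of every genetic statistic in the package: phased, biallelic
#' diploid haplotypes together with the sample-to-site and site-to-stock
#' assignment. Haplotypes are stored per chromosome as an integer matrix with
#' one row per haplotype (two per diploid, named `<sample>_1`, `<sample>_2`)
#' and one column per SNP; alleles are coded 0/1. Positions are 1-based and
#' strictly increasing within a chromosome.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param pos named list, one sorted integer vector of SNP positions per
#'   chromosome.
#' @param haps named list, one 0/1 integer matrix (haplotypes x SNPs) per
#'   chromosome; row names must be `<sample>_1` / `<sample>_2`.
#' @param site_of_sample named character vector mapping sample id to site.
#' @param stock_of_site named character vector mapping site to stock label.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(chrom_lengths, pos, haps, site_of_sample,
                            stock_of_site) {
  chrom_lengths <- stats::setNames(as.numeric(chrom_lengths),
                                   names(chrom_lengths))
  stopifnot(length(names(chrom_lengths)) == length(chrom_lengths),
            identical(sort(names(pos)), sort(names(chrom_lengths))),
            identical(sort(names(haps)), sort(names(chrom_lengths))))
  samples <- unique(sub("_[12]$", "", rownames(haps[[1]])))
  for (ch in names(chrom_lengths)) {
    p <- pos[[ch]]
    h <- haps[[ch]]
    if (length(p) != ncol(h))
      stop("chromosome ", ch, ": ", length(p), " positions but ",
           ncol(h), " SNP columns")
    if (length(p) && (any(diff(p) <= 0) || p[1] < 1 || p[length(p)] > chrom_lengths[ch]))
      stop("chromosome ", ch, ": positions must be strictly increasing and in [1, length]")
    if (!identical(sort(rownames(h)),
                   sort(paste(rep(samples, each = 2), 1:2, sep = "_"))))
      stop("chromosome ", ch, ": haplotype row names inconsistent with samples")
  }
  missing_site <- setdiff(samples, names(site_of_sample))
  if (length(missing_site))
    stop("samples without a site assignment: ",
         paste(missing_site, collapse = ", "))
  missing_stock <- setdiff(unique(site_of_sample[samples]), names(stock_of_site))
  if (length(missing_stock))
    stop("sites without a stock assignment: ",
         paste(missing_stock, collapse = ", "))
  structure(list(
    chrom_lengths = chrom_lengths,
    pos = pos[names(chrom_lengths)],
    haps = haps[names(chrom_lengths)],
    samples = samples,
    site_of_sample = site_of_sample[samples],
    stock_of_site = stock_of_site
  ), class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", length(x$samples), "diploid samples,",
      length(x$chrom_lengths), "chromosome(s),",
      sum(vapply(x$pos, length, 1L)), "SNPs\n")
  cat("  sites: ", paste(sort(unique(x$site_of_sample)), collapse = " "), "\n")
  cat("  stocks:", paste(sort(unique(x$stock_of_site)), collapse = " "), "\n")
  invisible(x)
}

#' @rdname haplotype_panel
#' @param panel a `haplotype_panel`.
#' @export
panel_samples <- function(panel) panel$samples

#' Stock label of each sample
#' @param panel a `haplotype_panel`.
#' @return named character vector, sample id -> stock.
#' @export
stock_of_sample <- function(panel) {
  stats::setNames(unname(panel$stock_of_site[panel$site_of_sample]),
                  names(panel$site_of_sample))
}

#' Haplotype row indices of a set of samples
#'
#' @param panel a `haplotype_panel`.
#' @param samples sample ids; alternatively use `site =` or `stock =`.
#' @param site,stock select every sample from these sites / stocks instead.
#' @return integer row indices into the per-chromosome haplotype matrices
#'   (row order is identical across chromosomes).
#' @export
hap_rows <- function(panel, samples = NULL, site = NULL, stock = NULL) {
  if (is.null(samples)) {
    if (!is.null(site)) {
      samples <- names(panel$site_of_sample)[panel$site_of_sample %in% site]
    } else if (!is.null(stock)) {
      sos <- stock_of_sample(panel)
      samples <- names(sos)[sos %in% stock]
    } else stop("one of samples / site / stock must be given")
  }
  bad <- setdiff(samples, panel$samples)
  if (length(bad)) stop("unknown samples: ", paste(bad, collapse = ", "))
  want <- paste(rep(samples, each = 2), 1:2, sep = "_")
  match(want, rownames(panel$haps[[1]]))
}

#' Write a panel as a phased VCF plus a sample map
#'
#' The VCF carries phased GT fields (`0|1`); alleles are written as A/T
#' placeholders since the panel is biallelic-by-construction. The sample map
#' is a three-column TSV (sample, site, stock).
#'
#' @param panel a `haplotype_panel`.
#' @param vcf_path,map_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_panel_vcf <- function(panel, vcf_path, map_path) {
  con <- file(vcf_path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##source=stockscan"),
    sprintf("##contig=<ID=%s,length=%d>", names(panel$chrom_lengths),
            as.integer(panel$chrom_lengths)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples), collapse = "\t")
  ), con)
  for (ch in names(panel$chrom_lengths)) {
    h <- panel$haps[[ch]]
    if (!ncol(h)) next
    i1 <- hap_rows(panel, panel$samples)
    a1 <- h[i1[seq(1, length(i1), 2)], , drop = FALSE]
    a2 <- h[i1[seq(2, length(i1), 2)], , drop = FALSE]
    gt <- matrix(paste(a1, a2, sep = "|"), nrow = nrow(a1))
    lines <- apply(rbind(matrix(c(rep(ch, ncol(h)),
                                  as.character(panel$pos[[ch]]),
                                  paste0(ch, "_", panel$pos[[ch]]),
                                  rep("A", ncol(h)), rep("T", ncol(h)),
                                  rep(".", ncol(h)), rep("PASS", ncol(h)),
                                  rep(".", ncol(h)), rep("GT", ncol(h))),
                                nrow = 9, byrow = TRUE), gt),
                  2, paste, collapse = "\t")
    writeLines(lines, con)
  }
  map <- data.frame(sample = panel$samples,
                    site = unname(panel$site_of_sample[panel$samples]),
                    stock = unname(stock_of_sample(panel)[panel$samples]))
  utils::write.table(map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(vcf = vcf_path, map = map_path))
}

#' Read a phased VCF plus sample map into a panel
#'
#' Multi-allelic and unphased records are dropped (mirroring the biallelic
#' filter applied upstream of this kind of analysis). Missing genotypes are
#' not supported in the panel container; records containing any are dropped
#' with a warning.
#'
#' @param vcf_path phased VCF (plain text or bgzipped).
#' @param map_path TSV with columns sample, site, stock.
#' @param chrom_lengths optional named lengths; defaults to contig headers,
#'   or to the last SNP position when no contig headers are present.
#' @return a [haplotype_panel()].
#' @export
read_panel_vcf <- function(vcf_path, map_path, chrom_lengths = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  biallelic <- !grepl(",", fix[, "ALT"]) & nchar(fix[, "REF"]) == 1 &
    nchar(fix[, "ALT"]) == 1
  phased <- apply(gt, 1, function(r) all(grepl("^[01]\\|[01]$", r)))
  keep <- biallelic & phased
  if (any(!keep))
    warning(sum(!keep), " records dropped (multi-allelic, unphased or missing)")
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  samples <- colnames(gt)
  map <- utils::read.table(map_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  site_of_sample <- stats::setNames(map$site, map$sample)
  stock_of_site <- stats::setNames(map$stock, map$site)
  stock_of_site <- stock_of_site[!duplicated(names(stock_of_site))]
  chroms <- unique(fix[, "CHROM"])
  if (is.null(chrom_lengths)) {
    meta <- v@meta
    ctg <- regmatches(meta, regexec("##contig=<ID=([^,>]+),length=([0-9]+)", meta))
    ctg <- ctg[lengths(ctg) == 3]
    if (length(ctg)) {
      chrom_lengths <- stats::setNames(
        as.numeric(vapply(ctg, `[`, "", 3)), vapply(ctg, `[`, "", 2))
      chrom_lengths <- chrom_lengths[chroms]
    } else {
      chrom_lengths <- stats::setNames(
        vapply(chroms, function(ch) max(as.numeric(fix[fix[, "CHROM"] == ch, "POS"])),
               0), chroms)
    }
  }
  pos <- list(); haps <- list()
  hapnames <- paste(rep(samples, each = 2), 1:2, sep = "_")
  for (ch in chroms) {
    sel <- fix[, "CHROM"] == ch
    p <- as.integer(fix[sel, "POS"])
    o <- order(p)
    g <- gt[sel, , drop = FALSE][o, , drop = FALSE]
    h <- matrix(0L, nrow = 2 * length(samples), ncol = nrow(g),
                dimnames = list(hapnames, NULL))
    for (j in seq_along(samples)) {
      sp <- strsplit(g[, j], "|", fixed = TRUE)
      h[2 * j - 1, ] <- as.integer(vapply(sp, `[`, "", 1))
      h[2 * j, ] <- as.integer(vapply(sp, `[`, "", 2))
    }
    pos[[ch]] <- p[o]
    haps[[ch]] <- h
  }
  haplotype_panel(chrom_lengths, pos, haps, site_of_sample, stock_of_site)
}
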