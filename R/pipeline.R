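#' Read a pipeline configuration from YAML
#'
#' The configuration drives [run_all()]: a `simulate` block (passed to
#' [sim_config()]), a `scan` block (stocks, window size/step, percentile),
#' an `shf` block (stocks, focal pair, rSHF threshold, minimum overlap,
#' minimum segment length), an `isolation` block (bootstrap replicates) and
#' an `output` directory. Seeds must be explicit.
#'
#' @param path YAML file.
#' @return config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set an explicit seed")
  cfg
}

.default_pipeline_config <- function(seed = 1L) {
  list(
    seed = seed,
    simulate = list(),
    scan = list(stocks = c("DQ", "NH"), size = 25000, step = 5000, pct = 95),
    shf = list(stocks = c("NH", "MD"), focal_pair = c("PT", "FF"),
               threshold = 2.5, min_overlap = 10000, min_len = 100000,
               include_focal_sites = TRUE),
    isolation = list(bootstrap = 200),
    output = "stockscan_out"
  )
}

#' Run the whole pipeline on a simulated cohort
#'
#' Executes simulate -> selection scan -> PSR/PSG classification ->
#' shared-haplotype introgression analysis -> isolation analysis, writing
#' every intermediate as a plain re-ingestible file (VCF, TSV, BED) plus a
#' run manifest with seeds and input checksums. Any stage failure aborts
#' with the stage name.
#'
#' @param config list as from [read_pipeline_config()]; missing entries
#'   take defaults emulating the 8-site / 3-stock study design.
#' @param quiet suppress stage messages.
#' @return list with the stage results and the summary report.
#' @export
run_all <- function(config = list(), quiet = FALSE) {
  cfg <- utils::modifyList(.default_pipeline_config(), config)
  say <- function(...) if (!quiet) message(sprintf(...))
  out_dir <- cfg$output
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    say("stage %-10s %6.1fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    res
  }

  sim <- stage("simulate", {
    sc <- do.call(sim_config, c(list(seed = cfg$seed), cfg$simulate))
    res <- simulate_panel(sc)
    res$config <- sc
    res$geo <- simulate_geography(sc)
    write_panel_vcf(res$panel, file.path(out_dir, "panel.vcf"),
                    file.path(out_dir, "samples.tsv"))
    res
  })
  panel <- sim$panel

  scan <- stage("scan", {
    s <- scan_windows(panel, cfg$scan$stocks, cfg$scan$size, cfg$scan$step)
    utils::write.table(s, file.path(out_dir, "scan.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    s
  })
  psr <- stage("psr", {
    sets <- call_outlier_sets(scan, cfg$scan$pct)
    p <- classify_psrs(sets, scan)
    write_psr_bed(p, file.path(out_dir, "psr.bed"))
    p
  })
  genes <- stage("genes", {
    set.seed(cfg$seed + 101L)
    g <- simulate_genes(panel$chrom_lengths)
    psg <- if (nrow(psr$psrs))
      overlap_genes(psr, g, chroms = names(panel$chrom_lengths)) else
      list(psgs = data.frame(), summary = data.frame())
    if (nrow(psg$psgs))
      utils::write.table(psg$psgs, file.path(out_dir, "psg.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    list(genes = g, psg = psg)
  })
  shf <- stage("shf", {
    segs <- detect_shared_segments(panel, cfg$shf$min_len)
    segs <- filter_segments(segs, panel$site_of_sample)
    write_segments(segs, file.path(out_dir, "segments.tsv"))
    win <- make_windows(panel$chrom_lengths, cfg$scan$size, cfg$scan$step)
    tab <- window_shf(segs, win, panel$site_of_sample, panel$stock_of_site,
                      cfg$shf$stocks, cfg$shf$focal_pair,
                      cfg$shf$min_overlap,
                      include_focal_sites = isTRUE(cfg$shf$include_focal_sites))
    utils::write.table(tab, file.path(out_dir, "shf.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tab
  })
  iso <- stage("isolation", {
    fst <- pairwise_fst(panel, by = "site")
    tab <- build_isolation_table(sim$geo$sites, sim$geo$coast, sim$geo$sst,
                                 fst)
    Xp <- as.matrix(tab[, c("d_csl", "d_lat", "d_crf",
                            "dsst_max", "dsst_min", "dsst_mean")])
    dec <- mlr_decomposition(tab$gdist, Xp)
    utils::write.table(tab, file.path(out_dir, "isolation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(dec, file.path(out_dir, "decomposition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ci <- bootstrap_ci(tab$gdist, Xp, B = cfg$isolation$bootstrap,
                       seed = cfg$seed + 211L)
    utils::write.table(ci$ci, file.path(out_dir, "decomposition_ci.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(fst = fst, table = tab, decomposition = dec, ci = ci)
  })

  dirn <- classify_rshf(shf$rshf[shf$focal], cfg$shf$threshold)
  report <- list(
    n_windows = nrow(scan),
    psr_per_class = if (nrow(psr$psrs))
      table(paste(psr$psrs$stock, psr$psrs$class, sep = "-")) else table(character(0)),
    n_focal_windows = sum(shf$focal),
    asymmetric_windows = table(dirn),
    mean_pairwise_fst = mean(iso$fst[upper.tri(iso$fst)]),
    decomposition_r2 = attr(iso$decomposition, "r_squared"))
  strip_classes <- function(x)
    if (is.list(x)) lapply(unclass(x), strip_classes) else x
  manifest <- list(
    package_version = as.character(utils::packageVersion("stockscan")),
    seed = cfg$seed,
    config = strip_classes(cfg[setdiff(names(cfg), "output")]),
    checksums = vapply(list.files(out_dir, full.names = TRUE),
                       function(f) unname(tools::md5sum(f)), ""))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(sim = sim, scan = scan, psr = psr, genes = genes, shf = shf,
       isolation = iso, report = report, manifest = manifest)
}
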