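#' Simulation configuration
#'
#' Builds the configuration object for [simulate_panel()] and
#' [simulate_geography()]. The defaults emulate the study design the package
#' targets: 104 diploids from 8 coastal sites grouped into 3 stocks (one
#' high-latitude stock `DQ`, a central stock `MD` and a southern stock `NH`),
#' moderate between-stock differentiation, and haplotypes with realistic
#' linkage disequilibrium.
#'
#' The population model is deliberately simple and auditable rather than
#' coalescent: per-stock SNP frequencies follow a Balding-Nichols law around
#' an ancestral frequency drawn from a minor-allele-filtered neutral spectrum
#' (density proportional to 1/p on `maf_range`), each stock carries a founder
#' pool whose allele counts match the stock frequency, and every sampled
#' haplotype is a mosaic of founders with a per-bp switch probability
#' `mosaic_switch_rate`. Sites within a stock share the founder pool, so
#' within-stock differentiation is sampling noise only.
#'
#' @param seed integer seed; all randomness in the generators flows from it.
#' @param stock_of_site named character vector site -> stock.
#' @param n_diploids_per_site diploid sample size per site.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param n_snps_per_chrom SNP count per chromosome (recycled); must not
#'   exceed the chromosome length.
#' @param founder_pool_size haplotypes in each stock's founder pool.
#' @param mosaic_switch_rate per-bp probability of switching founder when
#'   walking along a haplotype (controls LD and baseline IBD sharing).
#' @param divergence Balding-Nichols drift parameter F in (0, 1); the
#'   expected between-stock per-SNP Fst.
#' @param maf_range ancestral allele-frequency truncation bounds.
#' @param sweep_specs list of [sweep_spec()] objects applied after the
#'   neutral panel is drawn.
#' @param introgression_specs list of [introgression_spec()] objects.
#' @param geography list of geography / sea-surface-temperature parameters
#'   (see [simulate_geography()]); missing entries take defaults.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       stock_of_site = c(ZS = "DQ",
                                         FD = "MD", DY = "MD", FF = "MD",
                                         PT = "NH", DS = "NH", ZJ = "NH",
                                         XW = "NH"),
                       n_diploids_per_site = 13L,
                       chrom_lengths = c(chr1 = 3e6, chr2 = 3e6, chr3 = 3e6),
                       n_snps_per_chrom = round(chrom_lengths / 1000),
                       founder_pool_size = 100L,
                       mosaic_switch_rate = 1e-5,
                       divergence = 0.05,
                       maf_range = c(0.05, 0.95),
                       sweep_specs = list(),
                       introgression_specs = list(),
                       geography = list()) {
  # tolerate YAML-style named lists
  if (is.list(stock_of_site)) stock_of_site <- unlist(stock_of_site)
  if (is.list(chrom_lengths)) chrom_lengths <- unlist(chrom_lengths)
  if (anyDuplicated(names(stock_of_site)))
    stop("site labels must be unique")
  if (divergence < 0 || divergence >= 1)
    stop("divergence must be in [0, 1)")
  if (mosaic_switch_rate < 0 || mosaic_switch_rate > 1)
    stop("mosaic_switch_rate must be a per-bp probability in [0, 1]")
  n_snps_per_chrom <- rep_len(as.integer(n_snps_per_chrom),
                              length(chrom_lengths))
  if (any(n_snps_per_chrom > chrom_lengths))
    stop("n_snps_per_chrom exceeds chromosome length")
  geo_defaults <- list(
    coast_km = 1600, n_vertices = 400, bend_km = 120, bend_waves = 2,
    lat_range = c(20.5, 30.5), lon_range = c(110, 122.5),
    n_months = 36, sst_at_lat_ref = 24, lat_ref = 25, sst_lat_gradient = 0.9,
    seasonal_amplitude = 5, seasonal_peak_month = 8, sst_noise_sd = 0.4,
    winter_site_sd = 0.8,
    ibe_intercept = 0.01, ibe_slope = 0.012, ibe_noise_sd = 0.003
  )
  geography <- utils::modifyList(geo_defaults, geography)
  structure(list(
    seed = as.integer(seed),
    stock_of_site = stock_of_site,
    n_diploids_per_site = as.integer(n_diploids_per_site),
    chrom_lengths = chrom_lengths,
    n_snps_per_chrom = n_snps_per_chrom,
    founder_pool_size = as.integer(founder_pool_size),
    mosaic_switch_rate = mosaic_switch_rate,
    divergence = divergence,
    maf_range = maf_range,
    sweep_specs = sweep_specs,
    introgression_specs = introgression_specs,
    geography = geography
  ), class = "sim_config")
}

#' Planted selective sweep specification
#'
#' Describes a hard (`NF`, nearly fixed: carrier frequency >= 0.95) or
#' partial (`RS`, recently selected: carrier frequency in \[0.5, 0.9\]) sweep
#' to be planted into a stock: one carrier haplotype is copied over the tract
#' `[core_pos - tract_half_length, core_pos + tract_half_length]` into the
#' stated fraction of the stock's haplotypes.
#'
#' @param stock target stock label.
#' @param chrom chromosome id.
#' @param core_pos sweep core (bp).
#' @param carrier_freq fraction of stock haplotypes made identical over the
#'   tract, in (0, 1].
#' @param tract_half_length half-length of the swept tract (bp).
#' @param mode `"NF"` or `"RS"`; constrains `carrier_freq`.
#' @return a list of class `sweep_spec`.
#' @export
sweep_spec <- function(stock, chrom, core_pos, carrier_freq,
                       tract_half_length, mode = c("NF", "RS")) {
  mode <- match.arg(mode)
  if (carrier_freq <= 0 || carrier_freq > 1)
    stop("carrier_freq must be in (0, 1]")
  if (mode == "NF" && carrier_freq < 0.95)
    stop("NF mode requires carrier_freq >= 0.95")
  if (mode == "RS" && (carrier_freq < 0.5 || carrier_freq > 0.9))
    stop("RS mode requires carrier_freq in [0.5, 0.9]")
  structure(list(stock = stock, chrom = chrom, core_pos = core_pos,
                 carrier_freq = carrier_freq,
                 tract_half_length = tract_half_length, mode = mode),
            class = "sweep_spec")
}

#' Planted introgression specification
#'
#' Donor-to-recipient introgression into one recipient site: a fraction of
#' recipient individuals have one haplotype replaced, over an exponential-
#' length tract truncated to `region`, by a copy of a donor-stock haplotype.
#' `donor_carrier_freq` models the standard situation in which an introgressed
#' haplotype detectable by frequency-based direction inference is locally
#' common in the donor stock: before transfer, one donor haplotype is raised
#' to that carrier frequency across the donor stock's sites within `region`
#' (set it to 0 to transfer an arbitrary donor haplotype instead).
#'
#' @param donor_stock stock label of the donor.
#' @param recipient_site recipient site label (its stock must differ from
#'   the donor stock).
#' @param fraction_recipients fraction of recipient-site individuals that
#'   receive a tract, in \[0, 1\].
#' @param tract_length_mean mean of the exponential tract length (bp).
#' @param region list with `chrom`, `start`, `end` (bp) bounding the tracts.
#' @param donor_carrier_freq frequency of the donor haplotype within the
#'   donor stock over `region` (see above).
#' @return a list of class `introgression_spec`.
#' @export
introgression_spec <- function(donor_stock, recipient_site,
                               fraction_recipients, tract_length_mean,
                               region, donor_carrier_freq = 0.5) {
  if (fraction_recipients < 0 || fraction_recipients > 1)
    stop("fraction_recipients must be in [0, 1]")
  stopifnot(is.list(region), all(c("chrom", "start", "end") %in% names(region)),
            region$start < region$end)
  structure(list(donor_stock = donor_stock, recipient_site = recipient_site,
                 fraction_recipients = fraction_recipients,
                 tract_length_mean = tract_length_mean, region = region,
                 donor_carrier_freq = donor_carrier_freq),
            class = "introgression_spec")
}

# density proportional to 1/p on [lo, hi] by inverse-CDF
.rsfs <- function(n, lo, hi) lo * (hi / lo)^stats::runif(n)

#' Simulate a haplotype panel with planted truth
#'
#' Draws a neutral panel under the model described in [sim_config()], then
#' applies the configured sweeps and introgression events in order. All
#' randomness derives from `config$seed`; the draw order is fixed
#' (per chromosome: positions, ancestral frequencies, stock frequencies,
#' founder pools; then haplotypes by site and sample; then sweeps; then
#' introgression events), so identical configurations give bit-identical
#' output.
#'
#' @param config a [sim_config()].
#' @return a list with elements `panel` (a [haplotype_panel()]) and `truth`
#'   (planted sweep tracts, planted introgression segments in shared-segment
#'   layout, and the per-stock founder pools).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  stocks <- unique(config$stock_of_site)
  sites <- names(config$stock_of_site)
  samples <- unlist(lapply(sites, function(s)
    sprintf("%s_%02d", s, seq_len(config$n_diploids_per_site))))
  site_of_sample <- stats::setNames(rep(sites, each = config$n_diploids_per_site),
                                    samples)
  hapnames <- paste(rep(samples, each = 2), 1:2, sep = "_")
  K <- config$founder_pool_size
  theta <- if (config$divergence > 0)
    (1 - config$divergence) / config$divergence else Inf

  pos <- list(); haps <- list(); founders <- list()
  for (ci in seq_along(config$chrom_lengths)) {
    ch <- names(config$chrom_lengths)[ci]
    L <- config$chrom_lengths[ci]
    S <- config$n_snps_per_chrom[ci]
    p <- sort(sample.int(L, S))
    anc <- .rsfs(S, config$maf_range[1], config$maf_range[2])
    pool <- list()
    for (st in stocks) {
      q <- if (is.finite(theta)) stats::rbeta(S, anc * theta, (1 - anc) * theta)
           else anc
      n1 <- round(K * q)
      fm <- matrix(0L, nrow = K, ncol = S)
      for (j in seq_len(S))
        if (n1[j] > 0) fm[sample.int(K, n1[j]), j] <- 1L
      pool[[st]] <- fm
    }
    h <- matrix(0L, nrow = length(hapnames), ncol = S,
                dimnames = list(hapnames, NULL))
    gaps <- diff(p)
    psw <- 1 - exp(-config$mosaic_switch_rate * gaps)
    for (i in seq_along(hapnames)) {
      st <- config$stock_of_site[[site_of_sample[[sub("_[12]$", "", hapnames[i])]]]]
      sw <- stats::runif(S - 1) < psw
      seg <- cumsum(c(1L, sw))
      fid <- sample.int(K, max(seg), replace = TRUE)[seg]
      h[i, ] <- pool[[st]][cbind(fid, seq_len(S))]
    }
    pos[[ch]] <- p
    haps[[ch]] <- h
    founders[[ch]] <- pool
  }
  panel <- haplotype_panel(config$chrom_lengths, pos, haps, site_of_sample,
                           config$stock_of_site)
  truth <- list(sweeps = list(), segments = empty_segment_table(),
                founders = founders)
  for (sp in config$sweep_specs) {
    panel <- plant_sweep(panel, sp)
    truth$sweeps[[length(truth$sweeps) + 1]] <-
      data.frame(stock = sp$stock, chrom = sp$chrom, mode = sp$mode,
                 start = max(1, sp$core_pos - sp$tract_half_length),
                 end = min(panel$chrom_lengths[[sp$chrom]],
                           sp$core_pos + sp$tract_half_length))
  }
  if (length(truth$sweeps)) truth$sweeps <- do.call(rbind, truth$sweeps)
  for (isp in config$introgression_specs) {
    res <- plant_introgression(panel, isp)
    panel <- res$panel
    truth$segments <- rbind(truth$segments, res$segments)
  }
  list(panel = panel, truth = truth)
}

#' Plant a selective sweep into a panel
#'
#' Copies one randomly chosen carrier haplotype of the target stock over the
#' sweep tract into a `carrier_freq` fraction of that stock's haplotypes;
#' haplotypes outside the tract are untouched. Uses the current RNG state.
#'
#' @param panel a [haplotype_panel()].
#' @param spec a [sweep_spec()].
#' @return the modified panel.
#' @export
plant_sweep <- function(panel, spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  L <- panel$chrom_lengths[[spec$chrom]]
  if (is.null(L) || spec$core_pos < 1 || spec$core_pos > L)
    stop("core_pos outside chromosome ", spec$chrom)
  rows <- hap_rows(panel, stock = spec$stock)
  cols <- which(panel$pos[[spec$chrom]] >= spec$core_pos - spec$tract_half_length &
                panel$pos[[spec$chrom]] <= spec$core_pos + spec$tract_half_length)
  if (!length(cols)) return(panel)
  template <- rows[sample.int(length(rows), 1)]
  m <- round(spec$carrier_freq * length(rows))
  carriers <- rows[sample.int(length(rows), m)]
  tmpl <- panel$haps[[spec$chrom]][template, cols]
  panel$haps[[spec$chrom]][carriers, cols] <-
    matrix(tmpl, nrow = length(carriers), ncol = length(cols), byrow = TRUE)
  panel
}

#' Plant directional introgression into a panel
#'
#' See [introgression_spec()] for the model. Returns the modified panel and
#' the planted tracts as a shared-segment truth table (one row per recipient
#' tract, donor sample recorded), whose coordinates are exactly the mutated
#' interval. Uses the current RNG state.
#'
#' @param panel a [haplotype_panel()].
#' @param spec an [introgression_spec()].
#' @return list with `panel` and `segments` (see [empty_segment_table()]).
#' @export
plant_introgression <- function(panel, spec) {
  stopifnot(inherits(spec, "introgression_spec"))
  reg <- spec$region
  L <- panel$chrom_lengths[[reg$chrom]]
  if (is.null(L) || reg$start < 1 || reg$end > L)
    stop("region outside chromosome ", reg$chrom)
  rec_stock <- panel$stock_of_site[[spec$recipient_site]]
  if (identical(rec_stock, spec$donor_stock))
    stop("donor and recipient stocks must differ")
  segs <- empty_segment_table()
  if (spec$fraction_recipients == 0)
    return(list(panel = panel, segments = segs))

  donor_rows <- hap_rows(panel, stock = spec$donor_stock)
  pos <- panel$pos[[reg$chrom]]
  reg_cols <- which(pos >= reg$start & pos <= reg$end)
  # make the introgressing haplotype common in the donor stock over the region
  if (spec$donor_carrier_freq > 0) {
    template <- donor_rows[sample.int(length(donor_rows), 1)]
    m <- round(spec$donor_carrier_freq * length(donor_rows))
    carrier_rows <- donor_rows[sample.int(length(donor_rows), m)]
    carrier_rows <- union(carrier_rows, template)
    if (length(reg_cols)) {
      tmpl <- panel$haps[[reg$chrom]][template, reg_cols]
      panel$haps[[reg$chrom]][carrier_rows, reg_cols] <-
        matrix(tmpl, nrow = length(carrier_rows), ncol = length(reg_cols),
               byrow = TRUE)
    }
    source_rows <- carrier_rows
  } else {
    source_rows <- donor_rows
  }
  rec_samples <- names(panel$site_of_sample)[
    panel$site_of_sample == spec$recipient_site]
  m <- round(spec$fraction_recipients * length(rec_samples))
  recipients <- sample(rec_samples, m)
  hap_of_row <- rownames(panel$haps[[reg$chrom]])
  for (rs in recipients) {
    t_start <- floor(stats::runif(1, reg$start, reg$end))
    t_len <- stats::rexp(1, 1 / spec$tract_length_mean)
    t_end <- min(floor(t_start + t_len), reg$end)
    which_hap <- sample.int(2, 1)
    src <- source_rows[sample.int(length(source_rows), 1)]
    cols <- which(pos >= t_start & pos <= t_end)
    dst <- hap_rows(panel, rs)[which_hap]
    if (length(cols))
      panel$haps[[reg$chrom]][dst, cols] <- panel$haps[[reg$chrom]][src, cols]
    src_name <- hap_of_row[src]
    segs <- rbind(segs, data.frame(
      sample1 = rs, hap1 = which_hap,
      sample2 = sub("_[12]$", "", src_name),
      hap2 = as.integer(sub("^.*_", "", src_name)),
      chrom = reg$chrom, start = t_start, end = t_end,
      score = NA_real_, donor = spec$donor_stock))
  }
  list(panel = panel, segments = segs)
}

#' Simulate sites, coastline, SST series and an isolation-by-environment truth
#'
#' Places the configured sites along a synthetic coastline (a gently bending
#' polyline in projected km coordinates), assigns each a monthly
#' sea-surface-temperature series from a latitudinal gradient plus a seasonal
#' sinusoid, a site-idiosyncratic winter offset (local winter regimes - cold
#' current intrusion, river discharge - vary between coastal sites, so winter
#' minima carry information the annual mean does not) and noise, and draws
#' pairwise linearised genetic distances as
#' `intercept + slope * |dSST_min| + noise` — the isolation-by-environment
#' ground truth. The per-site SST summaries entering the truth are computed
#' with [sst_summaries()].
#'
#' @param config a [sim_config()]; uses `config$geography` and a seed offset
#'   from `config$seed` so genetic and geographic draws are independent.
#' @return list with `sites` (site, lon, lat, anchor vertex), `coast`
#'   (ordered projected vertices, km), `sst` (site x month matrix, deg C) and
#'   `gdist` (site1, site2, gdist: linearised genetic distance truth).
#' @export
simulate_geography <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$geography
  sites <- names(config$stock_of_site)
  if (length(sites) < 3) stop("need at least 3 sites")
  set.seed(config$seed + 7919L)
  tt <- seq(0, g$coast_km, length.out = g$n_vertices)
  coast <- data.frame(
    x = tt,
    y = g$bend_km * sin(2 * pi * g$bend_waves * tt / g$coast_km))
  # arc position of each site, evenly spread with a small jitter
  s_arc <- seq(0.05, 0.95, length.out = length(sites)) * g$coast_km +
    stats::runif(length(sites), -0.02, 0.02) * g$coast_km
  anchor <- vapply(s_arc, function(a) which.min(abs(tt - a)), 1L)
  frac <- tt[anchor] / g$coast_km
  lat <- g$lat_range[2] - frac * diff(g$lat_range)   # site 1 = northernmost
  lon <- g$lon_range[2] - frac * diff(g$lon_range)
  months <- seq_len(g$n_months)
  seasonal <- g$seasonal_amplitude *
    cos(2 * pi * (months - g$seasonal_peak_month) / 12)
  # winter months: within two months of the coldest month of the cycle
  coldest <- (g$seasonal_peak_month + 6 - 1) %% 12 + 1
  dm <- abs(((months - coldest) + 6) %% 12 - 6)
  winter <- dm <= 2
  winter_off <- stats::rnorm(length(sites), 0, g$winter_site_sd)
  sst <- t(vapply(seq_along(sites), function(i) {
    g$sst_at_lat_ref - g$sst_lat_gradient * (lat[i] - g$lat_ref) +
      seasonal + winter * winter_off[i] +
      stats::rnorm(g$n_months, 0, g$sst_noise_sd)
  }, numeric(g$n_months)))
  rownames(sst) <- sites
  sstmin <- apply(sst, 1, function(s) sst_summaries(s)[["sst_min"]])
  pr <- t(utils::combn(length(sites), 2))
  dsst <- abs(sstmin[pr[, 1]] - sstmin[pr[, 2]])
  gdist <- data.frame(
    site1 = sites[pr[, 1]], site2 = sites[pr[, 2]],
    gdist = g$ibe_intercept + g$ibe_slope * dsst +
      stats::rnorm(nrow(pr), 0, g$ibe_noise_sd))
  list(sites = data.frame(site = sites, lon = lon, lat = lat, anchor = anchor),
       coast = coast, sst = sst, gdist = gdist)
}

#' Simulate non-overlapping gene annotations
#'
#' Uniform-random non-overlapping gene intervals per chromosome, as a
#' GFF3-compatible data frame; plumbing for exercising gene-overlap logic on
#' synthetic panels.
#'
#' @param chrom_lengths named lengths (bp).
#' @param n_genes_per_mb gene density (default 10 per Mb).
#' @param mean_length mean gene length (bp).
#' @return data.frame with chrom, start, end, gene_id (1-based inclusive).
#' @export
simulate_genes <- function(chrom_lengths, n_genes_per_mb = 10,
                           mean_length = 20000) {
  out <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    n <- max(1, round(n_genes_per_mb * L / 1e6))
    len <- pmax(200, round(stats::rexp(n, 1 / mean_length)))
    start <- sort(sample.int(max(1, L - max(len)), n))
    end <- pmin(start + len - 1, L)
    keep <- c(TRUE, start[-1] > cummax(end)[-n])  # drop overlaps
    out[[ch]] <- data.frame(chrom = ch, start = start[keep], end = end[keep])
  }
  res <- do.call(rbind, out)
  res$gene_id <- sprintf("gene%04d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}
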